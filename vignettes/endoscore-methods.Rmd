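---
title: "Scoring endothelial signatures and stratifying survival with endoscore"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring endothelial signatures and stratifying survival with endoscore}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Tumor endothelial cells (TECs) shift between a matrix-building,
vessel-supporting state and a perturbed, proliferative state when Wnt
signaling through BCL9 is disrupted. Two 50-gene signatures summarize this
axis: a **True list** (collagens, SPARC, DCN, ... — the intact program) and
a **False list** (ribosomal, chaperone and proliferation genes — the
perturbed program). `endoscore` scores each cell or patient for both
programs and combines them into the **BCL9-endo-Score**

$$\mathrm{score}_j \;=\; \frac{ES_j(\mathrm{True})}{ES_j(\mathrm{False}) + 10^{-10}},$$

then asks whether a cohort split on this score separates survival. Both
signature lists ship built-in (`bcl9_gene_lists()`), transcribed in their
published order; the non-standard symbol `PDSSTN` is kept verbatim and
simply never matches data.

## The enrichment statistic

`gsva_scores()` implements a single-sample enrichment score from scratch,
in three stages:

1. **Kernel CDF transform** (`kernel_cdf_transform()`): each gene's values
   are passed through a Gaussian-kernel smoothed CDF,
   $\hat z_{gj} = \tfrac1n \sum_k \Phi\!\big((x_{gj}-x_{gk})/h_g\big)$ with
   bandwidth $h_g = \mathrm{sd}(x_g)/4$. This expresses every value as a
   within-gene quantile, robust to scale differences between genes. A
   zero-variance gene is mapped to 0.5 — the well-defined limit of the
   kernel average — so constant genes are inert rather than undefined.
2. **Within-sample ranking** (`rank_genes()`): rank 1 is the most highly
   expressed (relative to the gene's own distribution). Ties are broken by
   ascending gene identifier in C-locale byte order: platform-independent
   determinism, and invariance to the storage order of the matrix.
3. **Weighted rank random walk** (`random_walk_es()`): walking down the
   ranked list, member genes push the statistic up in proportion to
   $|r_g - (G+1)/2|^\tau$ (tail ranks count more; $\tau = 1$ by default)
   and non-members push it down by $1/(G-m)$. The default `gsva_diff`
   variant reports $\nu^+ + \nu^-$, the sum of the maximal positive and
   negative deviations; `gsva_max` reports the single largest deviation
   with its sign. Both are bounded in $[-1, 1]$.

The transform assumes continuous input; pass log-normalized counts
(`normalize_log()`, counts-per-`scale` then $\log(1+x)$). Whether raw or
normalized values feed the kernel is left to the caller — both are
meaningful, and the simulator exposes both — but normalized input is the
package default in the pipeline.

`mean_z_scores()` is a deliberately naive alternative (per-gene z-score,
averaged over the set) kept as a cross-check: on planted signals the two
methods should, and in the test suite do, rank samples concordantly
(Spearman $\ge 0.8$).

### Numerical choices

* Symbol matching is case-insensitive exact matching after upper-casing,
  so mouse-cased lists score human cohorts. Unmatched symbols are dropped
  and counted; a set matching under `min_match_fraction` (default 0.8) of
  its symbols is scored but flagged.
* A set matching zero genes, or every gene, is an error (the walk's
  normalizers are undefined).
* The kernel sum is evaluated in compiled code with repeated values
  collapsed and contributions beyond ten bandwidths rounded to 0/1, which
  is exact at double precision.

## The ratio and its pathology

`bcl9_endo_score()` computes the ratio exactly as defined, and attaches
two diagnostic flags instead of altering it:

* `unstable` — $|ES(\mathrm{False})| < 10^{-6}$: the $10^{-10}$ guard
  dominates the denominator and the score's magnitude is meaningless;
* `sign_caution` — $ES(\mathrm{False}) < 0$: a negative denominator
  inverts the numerator's sign.

These flags matter. Enrichment scores are signed, and in a cell enriched
for the True program the False program is typically *depleted*:
$ES(\mathrm{True}) \approx +a$, $ES(\mathrm{False}) \approx -a$, so the
ratio lands near $-1$. In a False-program cell the same argument gives
$ES(\mathrm{True})/ES(\mathrm{False}) \approx (-a)/(+a) \approx -1$ as
well: writing $ES(\mathrm{True}) = a + u$, $ES(\mathrm{False}) = -a + v$
for a True cell, the score is $\approx -1 - (u+v)/a$, while a False cell
gives $\approx -1 + (u'+v')/a$ with $(u', v')$ distributed like $(u, v)$.
The two distributions are near mirror images about $-1$ — one is close to
the reciprocal of the other — so the *ratio* discriminates symmetric
opposing programs only through higher-order skew, even when its numerator
alone separates them perfectly. On the package's own simulation (two
populations of 2000 cells, one-log2 shifts) the ratio reaches an AUC of
only about 0.64 between the two programs while $ES(\mathrm{True})$ and
the difference $ES(\mathrm{True}) - ES(\mathrm{False})$ both reach 1.0.
The acceptance suite records this honestly rather than papering over it.
The pathology propagates downstream: a survival stratification driven by
the ratio inherits the collapsed contrast, so the pipeline-level recovery
guarantee (planted hazard ratio rediscovered from expression alone) is
stated and tested for the difference statistic,
`score_cohort(..., statistic = "difference")` — clearly labeled as not
the published definition and off by default. The ratio behaves more
usefully in the regime where the False enrichment stays positive across
the cohort, because only its numerator then varies the sign structure.

## Deriving list pairs from labeled clusters

`derive_gene_lists()` rebuilds a True/False pair from any two labeled cell
groups by the classic signal-to-noise metric
$(\bar x_1 - \bar x_0)/(s_1 + s_0)$ (denominator floored at $10^{-8}$),
taking the top-k genes in each direction (default $k = 50$). Signal-to-noise
is the long-standing default marker metric for two-group enrichment
ranking; since the built-in lists — not the derivation — drive the headline
score, this choice is isolated. Ties break by gene identifier, and the two
directions use mirrored orderings, so swapping label polarity swaps the
lists exactly.

## Survival stratification

`stratify_and_analyze()` reproduces the standard prognostic workflow on a
scored cohort:

1. **Cut-point selection** (`maxstat_cutpoint()`): every distinct score
   value whose induced "high" fraction lies in `[minprop, maxprop]`
   (defaults 0.1/0.9, the reference tool's documented defaults) is a
   candidate threshold; each is scored by the standardized log-rank
   statistic of the split, and the largest absolute statistic wins (ties
   to the smallest threshold; "high" means strictly above). The
   standardization uses log-rank (Savage) scores
   $a_i = \delta_i - \hat\Lambda(t_i)$ with their conditional permutation
   moments — the Lausen–Schumacher formulation — which makes each
   permutation of the selection-adjusted p-value an $O(n)$ cumulative sum.
   The p-value is a seeded permutation tail probability with add-one
   smoothing $(b+1)/(B+1)$, $B = 1000$ by default: assumption-light, never
   below $1/(B+1)$, and uniform under the null (verified by simulation in
   the acceptance suite). Fewer than 100 permutations triggers a warning.
2. **Kaplan–Meier** (`km_estimate()`): the product-limit estimator per
   group; an all-censored group yields the constant estimate 1.
3. **Log-rank test** (`logrank_test()`): the classic
   $(O_1-E_1)^2/V$ statistic with hypergeometric variance — deliberately a
   *different* formulation from the maxstat scores, so the two stay
   independent cross-checks (on tie-free data the Cox score test at
   $\beta = 0$ equals it, a property the tests verify to $10^{-6}$).
4. **Cox hazard ratio** (`cox_hr()`): Newton–Raphson on the partial
   likelihood for the single binary high/low covariate, Breslow tie
   handling, convergence at $|U(\beta)| < 10^{-8}$ within 50 iterations.
   Complete separation is detected ($|\beta| > 20$) and reported as a
   flagged, signed infinite trend rather than an error.

Records join scores by `sample_id` (inner join, at least 10 shared IDs);
all outputs are deterministic given the seed.

## The simulator: what it emulates, and what it does not

The paper-scale data behind this kind of analysis (droplet scRNA-seq of
treated tumors; a public pan-cancer cohort) are deliberately not required.
`simulate_expression()` emulates the *statistical structure the analysis
assumes*: negative-binomial counts (gene-wise mean `baseline_mean = 5`,
shared dispersion `nb_dispersion = 0.3` — overdispersion typical of
droplet data), log-normal library-size factors (`library_size_cv = 0.3`),
and populations that over-express one program by `log2_fold_change`, with
the planted blocks carrying the real built-in symbols so the
symbol-matching path is exercised. The default configuration — two
populations of 2000 cells at a one-log2 shift — mirrors the scale at which
the package's separation guarantees are stated. `simulate_cohort()` plants
a high/low group (default 300 patients, half high) with opposing one-log2
program shifts and exponential event/censoring times (rates 0.1 and 0.05),
so the planted hazard ratio (default 3) is exact by construction.

Not emulated: doublets, ambient RNA, batch effects, cell-cycle structure,
differentiation topologies, non-proportional hazards. Passing tests on
these simulations therefore demonstrates correctness of the *statistics*,
not robustness to every artifact of real data.

Problem sizes in the test and acceptance suites are the ones the
guarantees are stated at: 2000 cells per population for program
separation, 500 replicates of 200 permutations for maxstat calibration,
50 replicates of 300 patients for hazard-ratio recovery, and a 60-patient
pipeline run for byte-level determinism.

## Known limitations

* The ratio statistic is unstable whenever the False-list enrichment is
  near zero or negative; the flags and the analysis above are the
  package's answer, and downstream interpretation should filter or at
  least stratify on them.
* The kernel CDF transform is quadratic in sample count per gene (in
  compiled code); cohorts beyond ~10^4 samples will feel it.
* Only one kernel (Gaussian, sd/4) is implemented; count-mode (Poisson)
  kernels are not, so raw counts should be normalized first.
* The permutation p-value resolution is bounded by $1/(B+1)$.
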