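# endoscore

Gene-signature scoring and prognostic stratification for tumor
endothelial programs.

Tumor endothelial cells sit on an axis between an intact, matrix-building
program and a perturbed, proliferative program that appears when Wnt
signaling through BCL9 is disrupted. `endoscore` quantifies where each
cell or patient sits on that axis and asks whether the answer predicts
survival. It is aimed at transcriptomics analysts who have a gene-by-sample
expression matrix (single-cell or bulk) and, optionally, right-censored
survival data.

The package implements, from scratch and with tests against independent
oracles:

* **Single-sample enrichment scoring** (`gsva_scores()`): a Gaussian
  kernel CDF transform per gene (bandwidth sd/4), within-sample ranking,
  and a weighted rank random walk whose signed deviation
  ES ∈ [−1, 1] measures how far a gene set concentrates at the top of a
  sample's ranking (`mean_z_scores()` is a simple cross-check method).
* **The BCL9-endo-Score** (`score_cohort()`): the per-sample ratio

      score = ES(True list) / (ES(False list) + 1e-10)

  over the two built-in 50-gene signatures (`bcl9_gene_lists()`), with
  `unstable` and `sign_caution` flags for epsilon-dominated and
  negative denominators, plus signature derivation from labeled clusters
  by signal-to-noise ranking (`derive_gene_lists()`).
* **Survival stratification** (`stratify_and_analyze()`): maximally
  selected rank statistics cut-point with a seeded permutation p-value
  (`maxstat_cutpoint()`), Kaplan–Meier curves (`km_estimate()`), the
  log-rank test (`logrank_test()`), and a Newton–Raphson Cox
  proportional-hazards hazard ratio with Breslow ties (`cox_hr()`).
* **A synthetic-data module** (`simulate_expression()`,
  `simulate_cohort()`): negative-binomial counts with planted programs
  and exponential survival with a planted hazard ratio, so the whole
  pipeline is testable without any download.
* **I/O and a CLI**: MatrixMarket / dense TSV expression, GMT gene sets,
  survival TSV, and an `endoscore simulate|score|stratify|run-all`
  command (`inst/cli/endoscore`).

## Worked example

Simulate a 300-patient cohort whose high-risk half over-expresses the
False program (planted hazard ratio 3), score every patient, and let the
cut-point search rediscover the prognosis from expression alone:

```r
library(endoscore)
sim    <- simulate_cohort(sim_cohort_config(n_patients = 300,
                                            planted_hr = 3, seed = 7))
scores <- score_cohort(normalize_log(sim$matrix), statistic = "difference")
head(scores, 3)
#>   sample_id   es_true   es_false    score unstable sign_caution
#> 1     P0001 0.6529009 -0.6117148 1.264616    FALSE         TRUE
#> 2     P0002 0.5371854 -0.6857738 1.222959    FALSE         TRUE
#> 3     P0003 0.6351639 -0.6166912 1.251855    FALSE         TRUE

stratify_and_analyze(scores, sim$survival, n_permutations = 1000, seed = 7)
#> <maxstat_result> cutpoint = -1.055812, |standardized statistic| = 7.001168
#>   permutation p = 0.000999001 (B = 1000), n high/low = 151/149
#> log-rank chi-square = 59.52899, p = 1.205057e-14
#> <cox_result> HR = 2.887249 (logHR 1.060304 +/- 0.1426934), Wald p = 1.080673e-13
```

Patient P0001 is enriched for the True program (ES 0.65) and depleted for
the False one (ES −0.61); the `sign_caution` flag marks the negative
denominator that would make the *ratio* form of the score hard to
interpret here, which is why this example uses the labeled difference
variant (`statistic = "difference"`; the default is the ratio exactly as
published). The selected cut-point splits the cohort 151/149 almost on
the planted boundary, and the Cox hazard ratio of 2.89 recovers the
planted value 3 within sampling error. The vignette
(`vignettes/endoscore-methods.Rmd`) analyzes when the ratio does and does
not discriminate, and every other methodological choice.

The same pipeline runs from a shell:

```sh
Rscript inst/cli/endoscore run-all --seed 7 --out results_dir
```

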