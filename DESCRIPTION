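Package: endoscore
Title: Endothelial Gene-Signature Scoring and Prognostic Stratification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Single-sample gene-set enrichment scoring of paired
    tumor-endothelial gene signatures and survival stratification of scored
    cohorts. Implements a kernel-CDF rank random-walk enrichment statistic,
    the BCL9-endo-Score ratio of paired True/False signature enrichment,
    derivation of signature pairs from labeled cell clusters by
    signal-to-noise ranking, maximally selected rank statistics cut-point
    selection with a permutation p-value, and Kaplan-Meier, log-rank and
    Cox proportional-hazards summaries of the resulting high/low groups.
    Ships a negative-binomial single-cell and survival-cohort simulator so
    the whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    methods,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    survival,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
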