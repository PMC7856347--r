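#' The BCL9-endo-Score ratio
#'
#' Combines the enrichment scores of the paired signatures into the single
#' per-sample statistic
#' \deqn{\mathrm{score} = \frac{ES_{true}}{ES_{false} + \epsilon}}
#' with \eqn{\epsilon = 10^{-10}} guarding against an exactly-zero
#' denominator. The statistic is computed exactly as defined; because
#' enrichment scores are signed, two diagnostic flags accompany it rather
#' than any modification of the formula:
#' \itemize{
#'   \item `unstable`: |ES_false| < 1e-6, i.e. the ratio's magnitude is
#'     dominated by the epsilon guard and should not be interpreted;
#'   \item `sign_caution`: ES_false < 0, i.e. the denominator is negative
#'     and the ratio's sign inverts the numerator's.
#' }
#'
#' @param es_true,es_false Numeric vectors of enrichment scores for the
#'   True and False lists (recycled to common length).
#' @param epsilon Additive guard on the denominator (default 1e-10).
#' @return A data.frame with columns `score`, `unstable`, `sign_caution`.
#' @examples
#' bcl9_endo_score(0.5, 0.25)   # score 2, no flags
#' bcl9_endo_score(0.5, -0.25)  # negative denominator: sign_caution
#' @export
bcl9_endo_score <- function(es_true, es_false, epsilon = 1e-10) {
  stopifnot(is.numeric(es_true), is.numeric(es_false),
            all(is.finite(es_true)), all(is.finite(es_false)),
            is.numeric(epsilon), length(epsilon) == 1L, is.finite(epsilon))
  denom <- es_false + epsilon
  if (any(denom == 0)) {
    stop("es_false + epsilon is exactly zero: ratio undefined")
  }
  data.frame(
    score = es_true / denom,
    unstable = abs(es_false) < 1e-6,
    sign_caution = es_false < 0
  )
}

#' Score every sample of a cohort with the BCL9-endo-Score
#'
#' Computes enrichment scores for the True and False lists with the chosen
#' single-sample method and forms the per-sample ratio statistic
#' ([bcl9_endo_score()]). The default is the bounded random-walk statistic;
#' `mean_z` is the simple standardized-mean alternative. An optional
#' difference statistic (ES_true - ES_false) is available for robustness
#' studies; it is not the published ratio and is off by default.
#'
#' @param matrix Gene-by-sample numeric matrix (continuous values).
#' @param lists A [gene_list_pair()]; defaults to the built-in
#'   [bcl9_gene_lists()].
#' @param method Enrichment method: `"gsva_diff"` (default), `"gsva_max"`
#'   or `"mean_z"`.
#' @param epsilon Denominator guard for the ratio.
#' @param statistic `"ratio"` (the published definition, default) or
#'   `"difference"` (ES_true - ES_false).
#' @param tau,min_match_fraction Passed to the enrichment method.
#' @return A `score_table` data.frame with columns `sample_id`, `es_true`,
#'   `es_false`, `score`, `unstable`, `sign_caution`.
#' @export
score_cohort <- function(matrix, lists = bcl9_gene_lists(),
                         method = c("gsva_diff", "gsva_max", "mean_z"),
                         epsilon = 1e-10,
                         statistic = c("ratio", "difference"),
                         tau = 1, min_match_fraction = 0.8) {
  method <- match.arg(method)
  statistic <- match.arg(statistic)
  stopifnot(inherits(lists, "gene_list_pair"))
  es <- if (method == "mean_z") {
    mean_z_scores(matrix, lists, min_match_fraction = min_match_fraction)
  } else {
    gsva_scores(matrix, lists, tau = tau, variant = method,
                min_match_fraction = min_match_fraction)
  }
  es_true <- es$scores[1L, ]
  es_false <- es$scores[2L, ]
  tab <- bcl9_endo_score(es_true, es_false, epsilon)
  if (statistic == "difference") {
    tab$score <- es_true - es_false
  }
  out <- data.frame(
    sample_id = colnames(matrix),
    es_true = unname(es_true),
    es_false = unname(es_false),
    score = tab$score,
    unstable = tab$unstable,
    sign_caution = tab$sign_caution,
    stringsAsFactors = FALSE
  )
  class(out) <- c("score_table", "data.frame")
  attr(out, "method") <- method
  attr(out, "statistic") <- statistic
  attr(out, "epsilon") <- epsilon
  out
}

#' Derive a True/False gene-list pair from labeled cell clusters
#'
#' Given an expression matrix and a boolean label marking membership of the
#' "True" cluster, ranks genes by the signal-to-noise ratio
#' \deqn{s_g = \frac{\bar x_{g,\mathrm{True}} - \bar x_{g,\mathrm{False}}}
#'             {sd_{g,\mathrm{True}} + sd_{g,\mathrm{False}}}}
#' (denominator floored at 1e-8) and returns the top-k genes by descending
#' metric as the True list and the top-k by ascending metric as the False
#' list. Ties are broken by ascending gene identifier, so the derivation is
#' invariant to gene and sample order, and swapping the label polarity
#' swaps the two lists exactly.
#'
#' @param matrix Gene-by-sample numeric matrix.
#' @param labels Logical vector per sample: TRUE for the True cluster.
#'   Both groups need at least 3 samples.
#' @param k Genes per list (default 50); at most half the gene count.
#' @return A [gene_list_pair()] of derived signatures.
#' @export
derive_gene_lists <- function(matrix, labels, k = 50L) {
  validate_expression(matrix)
  stopifnot(is.logical(labels), length(labels) == ncol(matrix),
            !anyNA(labels))
  n1 <- sum(labels)
  n0 <- sum(!labels)
  if (n1 < 3L || n0 < 3L) {
    stop("both label groups need at least 3 samples (got ", n1, " / ", n0, ")")
  }
  if (k > nrow(matrix) / 2) {
    stop("k = ", k, " exceeds half the gene count (", nrow(matrix), " genes)")
  }
  x1 <- matrix[, labels, drop = FALSE]
  x0 <- matrix[, !labels, drop = FALSE]
  s2n <- (rowMeans(x1) - rowMeans(x0)) /
    pmax(apply(x1, 1L, sd) + apply(x0, 1L, sd), 1e-8)
  ids <- rownames(matrix)
  top <- ids[order(-s2n, ids, method = "radix")][seq_len(k)]
  bottom <- ids[order(s2n, ids, method = "radix")][seq_len(k)]
  if (length(intersect(toupper(top), toupper(bottom))) > 0L) {
    stop("degenerate metric ties: derived lists would overlap")
  }
  gene_list_pair(gene_set("derived_true", top),
                 gene_set("derived_false", bottom))
}
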