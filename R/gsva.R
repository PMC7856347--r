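#' Gaussian-kernel CDF transform
#'
#' First stage of the single-sample enrichment statistic. For each gene g
#' with expression x_g1..x_gn across n samples, returns
#' \deqn{\hat z_{gj} = \frac{1}{n} \sum_k \Phi\!\left(\frac{x_{gj} - x_{gk}}{h_g}\right)}
#' a smoothed within-gene cumulative distribution value, with bandwidth
#' h_g = sd(x_g)/4 and \eqn{\Phi} the standard normal CDF. The transform
#' places every sample on a common (0, 1) scale per gene, so genes with
#' very different dynamic ranges become comparable before ranking. A gene
#' with zero variance carries no ordering information and maps to 0.5 for
#' every sample.
#'
#' @param matrix Gene-by-sample numeric matrix with unique dimnames and at
#'   least two samples; values must be finite. Intended for continuous
#'   (e.g. log-normalized) expression.
#' @return Matrix of the same shape and dimnames with values in (0, 1)
#'   (exactly 0.5 for zero-variance genes).
#' @seealso [gsva_scores()] for the full pipeline.
#' @export
kernel_cdf_transform <- function(matrix) {
  validate_expression(matrix)
  h <- apply(matrix, 1L, sd) / 4
  z <- .kcdf_gaussian(matrix, h)
  dimnames(z) <- dimnames(matrix)
  z
}

#' Per-sample gene ranks
#'
#' Ranks genes within each sample by decreasing transformed expression:
#' rank 1 is the largest value, rank G the smallest. Ties are broken by
#' ascending gene identifier (C-locale byte order), which makes the
#' gene-to-rank mapping independent of the row order of the input.
#'
#' @param z Gene-by-sample numeric matrix (typically the output of
#'   [kernel_cdf_transform()]).
#' @return Integer matrix of ranks with the same shape and dimnames.
#' @export
rank_genes <- function(z) {
  validate_expression(z)
  ids <- rownames(z)
  g <- nrow(z)
  ranks <- base::matrix(0L, g, ncol(z), dimnames = dimnames(z))
  seq_g <- seq_len(g)
  for (j in seq_len(ncol(z))) {
    ord <- order(-z[, j], ids, method = "radix")
    ranks[ord, j] <- seq_g
  }
  ranks
}

#' Weighted rank random-walk enrichment score
#'
#' Core of the single-sample enrichment statistic. Genes are visited in
#' rank order (rank 1 first). At a member gene the walk rises by its rank
#' weight \eqn{w_g = |r_g - (G+1)/2|^\tau} normalized by the summed member
#' weights; at a non-member it falls by 1/(G - m). With \eqn{\nu^+} the
#' maximum positive and \eqn{\nu^-} the minimum negative walk deviation,
#' the `gsva_diff` variant returns \eqn{\nu^+ + \nu^-} and `gsva_max` the
#' deviation of largest magnitude (sign preserved). Either way the result
#' lies in [-1, 1], positive when member genes concentrate among the
#' top-ranked genes of the sample. If every member gene sits exactly at
#' the central rank (total weight zero), member increments fall back to
#' the uniform 1/m so the walk stays defined.
#'
#' @param ranks Integer vector: the rank of each gene within one sample
#'   (a permutation of 1..G).
#' @param member_flags Logical vector flagging set membership per gene;
#'   at least one member and at least one non-member are required.
#' @param tau Rank-weight exponent (default 1).
#' @param variant `"gsva_diff"` or `"gsva_max"`.
#' @return A single enrichment score in [-1, 1].
#' @export
random_walk_es <- function(ranks, member_flags, tau = 1,
                           variant = c("gsva_diff", "gsva_max")) {
  variant <- match.arg(variant)
  g <- length(ranks)
  stopifnot(length(member_flags) == g, is.logical(member_flags))
  m <- sum(member_flags)
  if (m == 0L || m == g) {
    stop("gene set must contain between 1 and G-1 of the G genes ",
         "(walk normalizers are undefined otherwise)")
  }
  ord <- order(ranks)
  member_path <- member_flags[ord]
  r_path <- ranks[ord]
  w <- abs(r_path - (g + 1) / 2)^tau
  w_total <- sum(w[member_path])
  # all members exactly at the central rank: zero total weight; fall back
  # to uniform member increments so the walk stays defined
  up <- if (w_total > 0) w / w_total else rep(1 / m, g)
  steps <- ifelse(member_path, up, -1 / (g - m))
  walk <- cumsum(steps)
  nu_pos <- max(0, max(walk))
  nu_neg <- min(0, min(walk))
  if (variant == "gsva_diff") {
    nu_pos + nu_neg
  } else {
    if (nu_pos >= -nu_neg) nu_pos else nu_neg
  }
}

# Match a gene set's symbols against matrix gene ids, case-insensitively.
match_set_genes <- function(set, gene_ids) {
  which(toupper(gene_ids) %in% toupper(set$symbols))
}

as_gene_set_list <- function(sets) {
  if (inherits(sets, "gene_set")) return(list(sets))
  if (inherits(sets, "gene_list_pair")) {
    return(list(sets$true_list, sets$false_list))
  }
  stopifnot(is.list(sets), all(vapply(sets, inherits, TRUE, "gene_set")))
  sets
}

#' Single-sample enrichment scores for gene sets
#'
#' Computes per-sample, per-set enrichment scores by composing the
#' kernel CDF transform, within-sample gene ranking, and the weighted rank
#' random walk ([kernel_cdf_transform()], [rank_genes()],
#' [random_walk_es()]). Symbol matching is case-insensitive; a set matching
#' none of the matrix genes is an error, and a set matching fewer than
#' `min_match_fraction` of its symbols is scored but flagged.
#'
#' @param matrix Gene-by-sample numeric matrix (continuous values, e.g.
#'   log-normalized counts) with unique dimnames, at least 2 samples.
#' @param sets A `gene_set`, a list of them, or a `gene_list_pair`.
#' @param tau Rank-weight exponent passed to [random_walk_es()].
#' @param variant Enrichment-score variant, `"gsva_diff"` (default) or
#'   `"gsva_max"`.
#' @param min_match_fraction Sets matching fewer than this fraction of
#'   their symbols are flagged (default 0.8).
#' @return An `enrichment_scores` object: list with `scores` (set x sample
#'   matrix in [-1, 1]), `method`, `n_matched`, `set_size` and `flagged`.
#' @examples
#' x <- expression_matrix(matrix(rnorm(40), 8, 5),
#'                        gene_ids = paste0("G", 1:8),
#'                        sample_ids = paste0("S", 1:5))
#' gsva_scores(x, gene_set("top", c("G1", "G2")))$scores
#' @export
gsva_scores <- function(matrix, sets, tau = 1,
                        variant = c("gsva_diff", "gsva_max"),
                        min_match_fraction = 0.8) {
  variant <- match.arg(variant)
  sets <- as_gene_set_list(sets)
  validate_expression(matrix)
  idx <- prepare_set_index(sets, rownames(matrix), min_match_fraction)
  full <- idx$n_matched == nrow(matrix)
  if (any(full)) {
    stop("gene set(s) covering every matrix gene cannot be walk-scored: ",
         paste(idx$names[full], collapse = ", "))
  }
  ranks <- rank_genes(kernel_cdf_transform(matrix))
  g <- nrow(matrix)
  scores <- base::matrix(
    NA_real_, length(sets), ncol(matrix),
    dimnames = list(idx$names, colnames(matrix))
  )
  for (s in seq_along(sets)) {
    flags <- logical(g)
    flags[idx$rows[[s]]] <- TRUE
    for (j in seq_len(ncol(matrix))) {
      scores[s, j] <- random_walk_es(ranks[, j], flags, tau, variant)
    }
  }
  structure(
    list(scores = scores, method = variant, n_matched = idx$n_matched,
         set_size = idx$set_size, flagged = idx$flagged),
    class = "enrichment_scores"
  )
}

#' Mean z-score enrichment (cross-check method)
#'
#' A deliberately simple alternative to the random-walk statistic, used as
#' an internal cross-check: each gene is z-standardized across samples
#' (zero-variance genes map to 0) and a set's score in a sample is the mean
#' z over its matched genes. Unlike the walk statistic it is unbounded, but
#' it should rank samples similarly when a signature is genuinely
#' differential.
#'
#' @inheritParams gsva_scores
#' @return An `enrichment_scores` object with `method = "mean_z"`.
#' @export
mean_z_scores <- function(matrix, sets, min_match_fraction = 0.8) {
  sets <- as_gene_set_list(sets)
  validate_expression(matrix)
  idx <- prepare_set_index(sets, rownames(matrix), min_match_fraction)
  mu <- rowMeans(matrix)
  sigma <- apply(matrix, 1L, sd)
  z <- (matrix - mu) / ifelse(sigma > 0, sigma, 1)
  z[sigma == 0, ] <- 0
  scores <- base::matrix(
    NA_real_, length(sets), ncol(matrix),
    dimnames = list(idx$names, colnames(matrix))
  )
  for (s in seq_along(sets)) {
    rows <- idx$rows[[s]]
    scores[s, ] <- colMeans(z[rows, , drop = FALSE])
  }
  structure(
    list(scores = scores, method = "mean_z", n_matched = idx$n_matched,
         set_size = idx$set_size, flagged = idx$flagged),
    class = "enrichment_scores"
  )
}

prepare_set_index <- function(sets, gene_ids, min_match_fraction) {
  names_ <- vapply(sets, function(s) s$name, "")
  rows <- lapply(sets, match_set_genes, gene_ids = gene_ids)
  n_matched <- vapply(rows, length, 0L)
  set_size <- vapply(sets, function(s) length(s$symbols), 0L)
  zero <- n_matched == 0L
  if (any(zero)) {
    stop("gene set(s) with no gene matched in the matrix: ",
         paste(names_[zero], collapse = ", "))
  }
  flagged <- n_matched < min_match_fraction * set_size
  list(names = names_, rows = rows, n_matched = setNames(n_matched, names_),
       set_size = setNames(set_size, names_),
       flagged = setNames(flagged, names_))
}

#' @exportS3Method base::print
print.enrichment_scores <- function(x, ...) {
  cat("<enrichment_scores> ", nrow(x$scores), " set(s) x ", ncol(x$scores),
      " sample(s), method = ", x$method, "\n", sep = "")
  if (any(x$flagged)) {
    cat("  low-match sets: ",
        paste(names(x$flagged)[x$flagged], collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}
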