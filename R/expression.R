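#' Construct / validate a gene-by-sample expression matrix
#'
#' The package represents expression data as a plain numeric matrix with
#' genes as rows and samples as columns, carrying unique gene identifiers
#' as rownames and unique sample identifiers as colnames. This helper
#' attaches identifiers and enforces the invariants every scoring function
#' assumes.
#'
#' @param values Numeric matrix, genes x samples, all values finite.
#' @param gene_ids Character vector of unique gene identifiers
#'   (default: existing rownames).
#' @param sample_ids Character vector of unique sample identifiers
#'   (default: existing colnames).
#' @return The validated matrix with dimnames set.
#' @export
expression_matrix <- function(values, gene_ids = rownames(values),
                              sample_ids = colnames(values)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(gene_ids) || is.null(sample_ids)) {
    stop("expression matrix needs gene and sample identifiers")
  }
  rownames(values) <- as.character(gene_ids)
  colnames(values) <- as.character(sample_ids)
  validate_expression(values)
  values
}

# Invariant checks shared by every consumer of an expression matrix.
validate_expression <- function(x, min_samples = 2L) {
  if (!is.matrix(x) || !is.numeric(x)) {
    stop("expression data must be a numeric matrix")
  }
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    stop("expression matrix must carry gene rownames and sample colnames")
  }
  if (anyDuplicated(rownames(x))) {
    stop("duplicate gene identifiers: ",
         paste(unique(rownames(x)[duplicated(rownames(x))]), collapse = ", "))
  }
  if (anyDuplicated(colnames(x))) {
    stop("duplicate sample identifiers: ",
         paste(unique(colnames(x)[duplicated(colnames(x))]), collapse = ", "))
  }
  if (nrow(x) < 2L) stop("expression matrix needs at least 2 genes")
  if (ncol(x) < min_samples) {
    stop("expression matrix needs at least ", min_samples, " samples")
  }
  if (!all(is.finite(x))) stop("expression matrix contains non-finite values")
  invisible(x)
}
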