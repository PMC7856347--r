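#' @importFrom stats pchisq pnorm rbinom rexp rnbinom rlnorm runif sd setNames
#' @importFrom utils read.delim write.table
NULL

# The two 50-gene endothelial signatures, in their published order. The
# "True" list marks the BCL9-intact (matrix-building) endothelial program,
# the "False" list the BCL9-perturbed program. They are a transcription,
# not a curation: PDSSTN matches no standard symbol and is kept as printed.
.bcl9_true_genes <- c(
  "IGFBP7", "SPARC", "RARRES2", "BGN", "LOXL1", "COL5A2", "FSTL1", "COL6A2",
  "DCN", "MFAP5", "SERPING1", "AEBP1", "GPX3", "THY1", "MMP2", "BMP1",
  "FBN1", "ADAMTS2", "COL1A1", "COL6A3", "RCN3", "FBLN2", "PLPP3", "LOXL2",
  "CD248", "COL6A1", "PDSSTN", "RNASE4", "COL3A1", "COL1A2", "COL5A3",
  "C1QTNF6", "MGST1", "SERPINF1", "SOD3", "EBF1", "EFEMP2", "CYGB", "SULF1",
  "FXYD1", "VCAN", "NBL1", "FN1", "TGFBR2", "SERPINA3", "SELENOM", "MMP14",
  "RCN1", "GPX7", "BICC1"
)

.bcl9_false_genes <- c(
  "TCP1", "RPL12", "RPL3", "RPL4", "TMPO", "RPL7", "PRKG2", "RRM2", "LARS2",
  "FCER1G", "RAD21", "EZR", "MTAP", "CD9", "RPS6", "TOP2A", "HSP90AB1",
  "HSPA9", "MT-CYB", "HBEGF", "AMIGO2", "ACTN4", "ACTB", "CAVIN2", "PLA2G7",
  "CENPF", "ATP5F1B", "HSPA8", "EEF2", "TUBA1C", "RPS18", "ANLN", "RAN",
  "WDR31", "NOLC1", "CPE", "TM4SF1", "HSPD1", "SPP1", "PHGDH", "TUBA1B",
  "S100A4", "CD74", "UBE2C", "LGALS7", "HMGB2", "CAV2", "ESM1", "CCND1",
  "HMGA1"
)

#' Construct a gene set
#'
#' A gene set is a named collection of gene symbols. Symbols must be unique
#' after case-folding to upper case (matching elsewhere in the package is
#' case-insensitive).
#'
#' @param name Single character label for the set.
#' @param symbols Character vector of gene symbols; non-empty, unique after
#'   upper-casing.
#' @return An object of class `gene_set`: a list with elements `name` and
#'   `symbols`.
#' @export
gene_set <- function(name, symbols) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!is.character(symbols) || length(symbols) == 0L) {
    stop("gene set '", name, "' must contain at least one symbol")
  }
  if (anyDuplicated(toupper(symbols))) {
    stop("gene set '", name, "' has duplicate symbols after upper-casing")
  }
  structure(list(name = name, symbols = symbols), class = "gene_set")
}

#' @exportS3Method base::print
print.gene_set <- function(x, ...) {
  cat("<gene_set> ", x$name, ": ", length(x$symbols), " symbols\n", sep = "")
  invisible(x)
}

#' Construct a True/False gene-list pair
#'
#' Houses a pair of complementary signatures: a "True" list of genes marking
#' the intact endothelial program and a "False" list marking the perturbed
#' program. The two lists must be disjoint after upper-casing.
#'
#' @param true_list,false_list `gene_set` objects (or character vectors,
#'   which are wrapped with default names).
#' @return An object of class `gene_list_pair` with elements `true_list`
#'   and `false_list`.
#' @seealso [bcl9_gene_lists()] for the built-in pair.
#' @export
gene_list_pair <- function(true_list, false_list) {
  if (is.character(true_list)) true_list <- gene_set("true", true_list)
  if (is.character(false_list)) false_list <- gene_set("false", false_list)
  stopifnot(inherits(true_list, "gene_set"), inherits(false_list, "gene_set"))
  overlap <- intersect(toupper(true_list$symbols), toupper(false_list$symbols))
  if (length(overlap) > 0L) {
    stop("true and false lists overlap: ", paste(overlap, collapse = ", "))
  }
  structure(list(true_list = true_list, false_list = false_list),
            class = "gene_list_pair")
}

#' @exportS3Method base::print
print.gene_list_pair <- function(x, ...) {
  cat("<gene_list_pair>\n  true:  ", x$true_list$name, " (",
      length(x$true_list$symbols), " symbols)\n  false: ",
      x$false_list$name, " (", length(x$false_list$symbols),
      " symbols)\n", sep = "")
  invisible(x)
}

#' Built-in BCL9 endothelial gene lists
#'
#' Returns the two published 50-gene endothelial signatures used by the
#' BCL9-endo-Score: the "True" list (genes enriched in BCL9-intact tumor
#' endothelial/fibroblast clusters, dominated by matrix and collagen genes)
#' and the "False" list (genes enriched after BCL9 perturbation, dominated
#' by ribosomal, proliferation and chaperone genes). The lists are
#' transcribed verbatim in their published order; the non-standard symbol
#' PDSSTN is retained and simply never matches an expression matrix.
#'
#' @return A [gene_list_pair()] whose `true_list` and `false_list` each hold
#'   50 symbols.
#' @examples
#' pair <- bcl9_gene_lists()
#' length(pair$true_list$symbols)
#' @export
bcl9_gene_lists <- function() {
  gene_list_pair(gene_set("BCL9_true", .bcl9_true_genes),
                 gene_set("BCL9_false", .bcl9_false_genes))
}
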