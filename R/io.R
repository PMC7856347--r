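#' Read a gene-by-sample expression matrix
#'
#' Supports two plain-text formats: MatrixMarket coordinate (`.mtx`) with
#' `genes.tsv` / `samples.tsv` sidecar files in the same directory (one
#' identifier per line), and dense TSV with genes as rows, a `gene_id`
#' first column and a header row of sample identifiers. Duplicate
#' identifiers and non-numeric cells are rejected.
#'
#' @param path Path to the `.mtx` or `.tsv` file.
#' @param format `"auto"` (by extension), `"mtx"` or `"tsv"`.
#' @return A dense numeric matrix with gene rownames and sample colnames.
#' @export
read_expression <- function(path, format = c("auto", "mtx", "tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("expression file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.mtx$", path)) "mtx" else "tsv"
  }
  if (format == "mtx") {
    m <- Matrix::readMM(path)
    gene_file <- file.path(dirname(path), "genes.tsv")
    sample_file <- file.path(dirname(path), "samples.tsv")
    for (f in c(gene_file, sample_file)) {
      if (!file.exists(f)) stop("missing sidecar file: ", f)
    }
    genes <- readLines(gene_file)
    samples <- readLines(sample_file)
    if (length(genes) != nrow(m)) {
      stop("genes.tsv has ", length(genes), " entries but the matrix has ",
           nrow(m), " rows")
    }
    if (length(samples) != ncol(m)) {
      stop("samples.tsv has ", length(samples),
           " entries but the matrix has ", ncol(m), " columns")
    }
    expression_matrix(as.matrix(m), gene_ids = genes, sample_ids = samples)
  } else {
    lines <- readLines(path)
    if (length(lines) < 2L) stop("dense TSV needs a header and data rows")
    header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
    samples <- header[-1L]
    if (anyDuplicated(samples)) {
      stop("duplicate sample identifiers in TSV header: ",
           paste(unique(samples[duplicated(samples)]), collapse = ", "))
    }
    rows <- strsplit(lines[-1L], "\t", fixed = TRUE)
    genes <- vapply(rows, `[[`, "", 1L)
    values <- base::matrix(NA_real_, length(rows), length(samples))
    for (i in seq_along(rows)) {
      if (length(rows[[i]]) != length(samples) + 1L) {
        stop("row ", i + 1L, " has ", length(rows[[i]]),
             " fields, expected ", length(samples) + 1L)
      }
      v <- suppressWarnings(as.numeric(rows[[i]][-1L]))
      if (anyNA(v)) {
        bad <- which(is.na(v))[1L]
        stop("non-numeric value at row ", i + 1L, ", column ", bad + 1L,
             " ('", rows[[i]][bad + 1L], "')")
      }
      values[i, ] <- v
    }
    expression_matrix(values, gene_ids = genes, sample_ids = samples)
  }
}

#' Write an expression matrix
#'
#' Inverse of [read_expression()]: `mtx` writes MatrixMarket coordinate
#' format plus `genes.tsv` / `samples.tsv` sidecars; `tsv` writes a dense
#' table with a `gene_id` first column.
#'
#' @param matrix Gene-by-sample numeric matrix with dimnames.
#' @param path Output `.mtx` or `.tsv` path.
#' @param format `"mtx"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_expression <- function(matrix, path, format = c("mtx", "tsv")) {
  format <- match.arg(format)
  validate_expression(matrix, min_samples = 1L)
  if (format == "mtx") {
    Matrix::writeMM(methods::as(Matrix::Matrix(matrix, sparse = TRUE),
                                "generalMatrix"), path)
    writeLines(rownames(matrix), file.path(dirname(path), "genes.tsv"))
    writeLines(colnames(matrix), file.path(dirname(path), "samples.tsv"))
  } else {
    tab <- cbind(gene_id = rownames(matrix), as.data.frame(matrix))
    write_tsv_plain(tab, path)
  }
  invisible(path)
}

# Deterministic TSV writer used for every tabular output.
write_tsv_plain <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' Each GMT line is tab-separated: set name, description, then one or
#' more gene symbols. Lines with fewer than three fields are an error
#' naming the line; an empty file yields an empty list with a warning.
#'
#' @param path Path to the GMT file.
#' @return A list of [gene_set()] objects; descriptions are kept in the
#'   `description` attribute of each set.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    warning("empty GMT file: ", path)
    return(list())
  }
  sets <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 3L) {
      stop("GMT line ", i, " has ", length(fields),
           " field(s); need name, description and at least one symbol")
    }
    s <- gene_set(fields[1L], fields[-(1:2)])
    attr(s, "description") <- fields[2L]
    sets[[i]] <- s
  }
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets A `gene_set`, list of them, or a [gene_list_pair()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  sets <- as_gene_set_list(sets)
  lines <- vapply(sets, function(s) {
    desc <- attr(s, "description")
    if (is.null(desc)) desc <- "na"
    paste(c(s$name, desc, s$symbols), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read right-censored survival records from TSV
#'
#' Expects a header `sample_id  time  event` (tab-separated). Times must
#' be positive and events 0 or 1; offending rows are reported by number.
#'
#' @param path Path to the TSV file.
#' @return Data.frame with columns `sample_id` (character), `time`
#'   (numeric) and `event` (integer).
#' @export
read_survival_tsv <- function(path) {
  if (!file.exists(path)) stop("survival file not found: ", path)
  tab <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  required <- c("sample_id", "time", "event")
  if (!identical(names(tab)[seq_along(required)], required)) {
    stop("survival TSV must start with header: ",
         paste(required, collapse = ", "))
  }
  time <- suppressWarnings(as.numeric(tab$time))
  bad_time <- which(!is.finite(time) | time <= 0)
  if (length(bad_time) > 0L) {
    stop("non-positive or non-numeric time on row(s): ",
         paste(bad_time + 1L, collapse = ", "))
  }
  event <- suppressWarnings(as.numeric(tab$event))
  bad_event <- which(!(event %in% c(0, 1)))
  if (length(bad_event) > 0L) {
    stop("event values outside {0, 1} on row(s): ",
         paste(bad_event + 1L, collapse = ", "))
  }
  data.frame(sample_id = as.character(tab$sample_id), time = time,
             event = as.integer(event), stringsAsFactors = FALSE)
}

#' Write survival records to TSV
#'
#' @param records Data.frame with `sample_id`, `time`, `event`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_survival_tsv <- function(records, path) {
  validate_records(records)
  write_tsv_plain(records[, c("sample_id", "time", "event")], path)
}
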