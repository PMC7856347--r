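#' Describe one simulated cell population
#'
#' @param name Population label.
#' @param n_cells Number of cells (>= 1).
#' @param program Which planted signature the population over-expresses:
#'   `"none"`, `"true_program"` (the built-in True list block) or
#'   `"false_program"` (the False list block).
#' @param log2_fold_change Log2 shift applied to the program genes'
#'   negative-binomial mean (>= 0, finite).
#' @return A `sim_population` list.
#' @export
sim_population <- function(name, n_cells,
                           program = c("none", "true_program",
                                       "false_program"),
                           log2_fold_change = 0) {
  program <- match.arg(program)
  stopifnot(is.character(name), length(name) == 1L,
            length(n_cells) == 1L, n_cells >= 1, n_cells == round(n_cells),
            length(log2_fold_change) == 1L, is.finite(log2_fold_change),
            log2_fold_change >= 0)
  structure(list(name = name, n_cells = as.integer(n_cells),
                 program = program, log2_fold_change = log2_fold_change),
            class = "sim_population")
}

#' Configuration for the single-cell-like expression simulator
#'
#' Defaults describe the emulated study conditions: a few hundred genes of
#' which the first 100 carry the two built-in 50-gene programs, a
#' moderately expressed negative-binomial baseline (mean 5, dispersion 0.3
#' — overdispersion typical of droplet scRNA-seq counts) and log-normal
#' library-size factors with 30% coefficient of variation.
#'
#' @param n_genes Total genes (>= 200 so the two 50-gene program blocks
#'   leave background genes).
#' @param populations List of [sim_population()] specs (non-empty).
#' @param baseline_mean Negative-binomial mean per gene before shifts.
#' @param nb_dispersion Shared NB dispersion (variance = mu + phi mu^2).
#' @param library_size_cv Coefficient of variation of per-cell log-normal
#'   library-size factors (0 disables).
#' @param seed Integer seed; fixed seed gives bit-identical output.
#' @return A `sim_expression_config` list.
#' @export
sim_expression_config <- function(n_genes = 200L,
                                  populations = list(
                                    sim_population("true_cells", 2000L,
                                                   "true_program", 1),
                                    sim_population("false_cells", 2000L,
                                                   "false_program", 1)
                                  ),
                                  baseline_mean = 5,
                                  nb_dispersion = 0.3,
                                  library_size_cv = 0.3,
                                  seed = 1L) {
  if (n_genes < 200L) {
    stop("n_genes must be >= 200 so the two 50-gene program blocks ",
         "leave background genes")
  }
  if (!is.list(populations) || length(populations) == 0L ||
      !all(vapply(populations, inherits, TRUE, "sim_population"))) {
    stop("populations must be a non-empty list of sim_population specs")
  }
  stopifnot(baseline_mean > 0, nb_dispersion > 0, library_size_cv >= 0,
            length(seed) == 1L, is.finite(seed))
  structure(list(n_genes = as.integer(n_genes), populations = populations,
                 baseline_mean = baseline_mean, nb_dispersion = nb_dispersion,
                 library_size_cv = library_size_cv, seed = as.integer(seed)),
            class = "sim_expression_config")
}

# Gene identifiers: the two built-in program blocks first, then background.
sim_gene_ids <- function(n_genes) {
  c(.bcl9_true_genes, .bcl9_false_genes,
    sprintf("BG%04d", seq_len(n_genes - 100L)))
}

# Log-normal size factors with mean 1 and the requested CV.
sim_size_factors <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Simulate a single-cell-like count matrix with planted programs
#'
#' Draws negative-binomial counts for each configured population. Genes of
#' a population's program have mean `baseline_mean * 2^log2_fold_change`,
#' all other genes `baseline_mean`; every cell additionally receives a
#' log-normal library-size factor. The first 50 gene rows carry the
#' built-in True-list symbols and the next 50 the False-list symbols, so
#' downstream symbol matching is exercised on real identifiers.
#'
#' @param config A [sim_expression_config()].
#' @return A list with `matrix` (genes x cells count matrix) and `truth`
#'   (a `sim_truth` list: per-cell `labels`, `program` per population, and
#'   `program_gene_ids` for the two planted blocks).
#' @export
simulate_expression <- function(config = sim_expression_config()) {
  stopifnot(inherits(config, "sim_expression_config"))
  set.seed(config$seed)
  g <- config$n_genes
  ids <- sim_gene_ids(g)
  n_total <- sum(vapply(config$populations, function(p) p$n_cells, 0L))
  counts <- base::matrix(0L, g, n_total)
  labels <- character(n_total)
  cells <- character(n_total)
  block <- list(true_program = 1:50, false_program = 51:100)
  offset <- 0L
  size <- 1 / config$nb_dispersion
  for (p in config$populations) {
    mu <- rep(config$baseline_mean, g)
    if (p$program != "none") {
      mu[block[[p$program]]] <- config$baseline_mean * 2^p$log2_fold_change
    }
    sf <- sim_size_factors(p$n_cells, config$library_size_cv)
    cols <- offset + seq_len(p$n_cells)
    counts[, cols] <- rnbinom(g * p$n_cells, size = size,
                              mu = outer(mu, sf))
    labels[cols] <- p$name
    cells[cols] <- sprintf("%s_c%04d", p$name, seq_len(p$n_cells))
    offset <- offset + p$n_cells
  }
  mat <- expression_matrix(counts, gene_ids = ids, sample_ids = cells)
  truth <- structure(
    list(labels = setNames(labels, cells),
         programs = setNames(
           vapply(config$populations, function(p) p$program, ""),
           vapply(config$populations, function(p) p$name, "")),
         program_gene_ids = list(true_program = ids[1:50],
                                 false_program = ids[51:100])),
    class = "sim_truth"
  )
  list(matrix = mat, truth = truth)
}

#' Configuration for the survival-cohort simulator
#'
#' Emulates a cohort whose prognosis depends on a planted high/low group:
#' high-group patients over-express the True program and under-express the
#' False program (and vice versa), and their event hazard is multiplied by
#' `planted_hr`. Event and censoring times are exponential, so the planted
#' hazard ratio is exact. Defaults: 300 patients, half high, hazard ratio
#' 3, baseline event rate 0.1 and censoring rate 0.05 per time unit, and a
#' one-log2 expression shift.
#'
#' @param n_patients Cohort size.
#' @param frac_high Fraction assigned to the high group, in (0, 1); both
#'   groups must end up with >= 2 patients.
#' @param planted_hr Hazard ratio of high vs low (> 0).
#' @param baseline_rate Exponential event rate of the low group (> 0).
#' @param censor_rate Exponential censoring rate (> 0).
#' @param expression_lfc Log2 shift applied to the program blocks (>= 0).
#' @param n_genes Genes in the bulk matrix (>= 200).
#' @param seed Integer seed.
#' @return A `sim_cohort_config` list.
#' @export
sim_cohort_config <- function(n_patients = 300L, frac_high = 0.5,
                              planted_hr = 3, baseline_rate = 0.1,
                              censor_rate = 0.05, expression_lfc = 1,
                              n_genes = 200L, seed = 1L) {
  stopifnot(n_patients >= 4L, frac_high > 0, frac_high < 1,
            planted_hr > 0, baseline_rate > 0, censor_rate > 0,
            expression_lfc >= 0, is.finite(expression_lfc),
            length(seed) == 1L, is.finite(seed))
  n_high <- round(frac_high * n_patients)
  if (n_high < 2L || n_patients - n_high < 2L) {
    stop("frac_high leaves fewer than 2 patients in one group")
  }
  if (n_genes < 200L) stop("n_genes must be >= 200")
  structure(list(n_patients = as.integer(n_patients), frac_high = frac_high,
                 planted_hr = planted_hr, baseline_rate = baseline_rate,
                 censor_rate = censor_rate, expression_lfc = expression_lfc,
                 n_genes = as.integer(n_genes), seed = as.integer(seed)),
            class = "sim_cohort_config")
}

#' Simulate a bulk cohort with survival tied to a planted group
#'
#' High-group patients have True-program genes shifted up and
#' False-program genes shifted down by `expression_lfc` (low-group
#' patients the reverse); their event times are exponential with rate
#' `baseline_rate * planted_hr` versus `baseline_rate`. Censoring times
#' are exponential with rate `censor_rate`; the observed time is the
#' minimum and the event indicator marks whether the event came first.
#'
#' @param config A [sim_cohort_config()].
#' @return A list with `matrix` (genes x patients counts), `survival`
#'   (data.frame `sample_id`, `time`, `event`) and `truth` (per-patient
#'   `labels` "high"/"low" and the planted hazard ratio).
#' @export
simulate_cohort <- function(config = sim_cohort_config()) {
  stopifnot(inherits(config, "sim_cohort_config"))
  set.seed(config$seed)
  n <- config$n_patients
  g <- config$n_genes
  ids <- sim_gene_ids(g)
  patients <- sprintf("P%04d", seq_len(n))
  n_high <- round(config$frac_high * n)
  high <- c(rep(TRUE, n_high), rep(FALSE, n - n_high))
  lfc <- config$expression_lfc
  mu <- base::matrix(5, g, n)
  mu[1:50, high] <- 5 * 2^lfc
  mu[51:100, high] <- 5 * 2^-lfc
  mu[1:50, !high] <- 5 * 2^-lfc
  mu[51:100, !high] <- 5 * 2^lfc
  counts <- base::matrix(rnbinom(g * n, size = 1 / 0.3, mu = mu), g, n)
  mat <- expression_matrix(counts, gene_ids = ids, sample_ids = patients)
  rate <- config$baseline_rate * ifelse(high, config$planted_hr, 1)
  t_event <- rexp(n, rate)
  t_censor <- rexp(n, config$censor_rate)
  survival <- data.frame(
    sample_id = patients,
    time = pmin(t_event, t_censor),
    event = as.integer(t_event <= t_censor),
    stringsAsFactors = FALSE
  )
  truth <- structure(
    list(labels = setNames(ifelse(high, "high", "low"), patients),
         planted_hr = config$planted_hr),
    class = "sim_truth"
  )
  list(matrix = mat, survival = survival, truth = truth)
}

#' Library-size normalization with log transform
#'
#' Scales every column (sample) to a common total `scale`, then applies
#' log(1 + x). Doubling all of a sample's counts leaves its normalized
#' values unchanged.
#'
#' @param matrix Gene-by-sample matrix of non-negative counts.
#' @param scale Target column total (default 1e4).
#' @return Normalized matrix of the same shape and dimnames, all finite.
#' @export
normalize_log <- function(matrix, scale = 1e4) {
  validate_expression(matrix, min_samples = 1L)
  stopifnot(length(scale) == 1L, scale > 0)
  if (any(matrix < 0)) stop("counts must be non-negative")
  totals <- colSums(matrix)
  if (any(totals == 0)) {
    stop("sample(s) with zero total counts cannot be normalized: ",
         paste(colnames(matrix)[totals == 0], collapse = ", "))
  }
  log1p(sweep(matrix, 2L, totals / scale, "/"))
}
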