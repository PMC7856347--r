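#' @useDynLib endoscore, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

default_pipeline_config <- function() {
  list(
    # simulation
    n_genes = 200L, n_cells_per_population = 500L, expression_lfc = 1,
    baseline_mean = 5, nb_dispersion = 0.3, library_size_cv = 0.3,
    n_patients = 150L, frac_high = 0.5, planted_hr = 3,
    baseline_rate = 0.1, censor_rate = 0.05,
    # scoring
    method = "gsva_diff", tau = 1, epsilon = 1e-10,
    min_match_fraction = 0.8, statistic = "ratio", normalize_scale = 1e4,
    # stratification
    minprop = 0.1, maxprop = 0.9, n_permutations = 1000L,
    # inputs (NULL means simulate)
    expression = NULL, gene_sets = NULL, survival = NULL,
    seed = 1L
  )
}

#' Read a flat key-value pipeline configuration
#'
#' The configuration file is flat YAML (`key: value` per line) whose keys
#' mirror the simulation, scoring and stratification parameters; unknown
#' keys are an error. Omitted keys take the package defaults.
#'
#' @param path Path to the YAML file, or `NULL` for pure defaults.
#' @return A named list of configuration values.
#' @export
read_pipeline_config <- function(path = NULL) {
  config <- default_pipeline_config()
  if (is.null(path)) return(config)
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- yaml::read_yaml(path)
  if (length(user) == 0L) return(config)
  unknown <- setdiff(names(user), names(config))
  if (length(unknown) > 0L) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  config[names(user)] <- user
  config
}

pipeline_log <- function(verbose, ...) {
  if (verbose) message("[endoscore] ", ...)
}

#' Run the simulate / score / stratify pipeline
#'
#' Chains the three stages end to end and writes every result as a
#' diffable TSV under `out_dir`:
#' \itemize{
#'   \item `simulate`: cohort expression (`expression.mtx` + sidecars),
#'     `survival.tsv` and `truth.tsv`;
#'   \item `score`: `score_table.tsv` (`sample_id`, `es_true`, `es_false`,
#'     `score`, `unstable`, `sign_caution`);
#'   \item `stratify`: `stratify_report.tsv` (one row: cut-point,
#'     standardized statistic, permutation p, log-rank chi-square and p,
#'     HR with 95% CI) and `km_curves.tsv` (per-group step tables).
#' }
#' Expression input is normalized with [normalize_log()] before scoring.
#' All randomness derives from `seed`, so a fixed seed reproduces every
#' output byte for byte.
#'
#' @param config Configuration list from [read_pipeline_config()] (or a
#'   path to a YAML file).
#' @param out_dir Output directory, created if needed.
#' @param stage `"run-all"` or one of `"simulate"`, `"score"`,
#'   `"stratify"` (later stages read this run's earlier outputs from
#'   `out_dir`, or the configured input paths).
#' @param seed Overrides `config$seed` when non-NULL.
#' @param verbose Emit progress messages.
#' @return Invisibly, a list with whatever the final stage produced.
#' @export
run_pipeline <- function(config = read_pipeline_config(), out_dir,
                         stage = c("run-all", "simulate", "score",
                                   "stratify"),
                         seed = NULL, verbose = FALSE) {
  stage <- match.arg(stage)
  if (is.character(config)) config <- read_pipeline_config(config)
  if (!is.null(seed)) config$seed <- as.integer(seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  pipeline_log(verbose, "seed = ", config$seed)
  result <- list(config = config)

  do_sim <- stage %in% c("run-all", "simulate")
  do_score <- stage %in% c("run-all", "score")
  do_strat <- stage %in% c("run-all", "stratify")

  if (do_sim) {
    pipeline_log(verbose, "simulating cohort (n = ", config$n_patients, ")")
    sim <- simulate_cohort(sim_cohort_config(
      n_patients = config$n_patients, frac_high = config$frac_high,
      planted_hr = config$planted_hr, baseline_rate = config$baseline_rate,
      censor_rate = config$censor_rate,
      expression_lfc = config$expression_lfc, n_genes = config$n_genes,
      seed = config$seed
    ))
    write_expression(sim$matrix, file.path(out_dir, "expression.mtx"))
    write_survival_tsv(sim$survival, file.path(out_dir, "survival.tsv"))
    write_tsv_plain(
      data.frame(sample_id = names(sim$truth$labels),
                 group = unname(sim$truth$labels)),
      file.path(out_dir, "truth.tsv")
    )
    result$simulation <- sim
  }

  if (do_score) {
    expr_path <- config$expression
    if (is.null(expr_path)) expr_path <- file.path(out_dir, "expression.mtx")
    if (!file.exists(expr_path)) {
      stop("score stage needs an expression input (config key 'expression'",
           " or a prior simulate stage); not found: ", expr_path)
    }
    mat <- read_expression(expr_path)
    lists <- if (is.null(config$gene_sets)) {
      bcl9_gene_lists()
    } else {
      sets <- read_gmt(config$gene_sets)
      if (length(sets) != 2L) {
        stop("gene_sets GMT must contain exactly two sets (true, false)")
      }
      gene_list_pair(sets[[1L]], sets[[2L]])
    }
    pipeline_log(verbose, "scoring ", ncol(mat), " samples (method = ",
                 config$method, ")")
    normalized <- normalize_log(mat, scale = config$normalize_scale)
    st <- score_cohort(normalized, lists, method = config$method,
                       epsilon = config$epsilon,
                       statistic = config$statistic, tau = config$tau,
                       min_match_fraction = config$min_match_fraction)
    write_tsv_plain(st, file.path(out_dir, "score_table.tsv"))
    result$score_table <- st
  }

  if (do_strat) {
    st <- result$score_table
    if (is.null(st)) {
      score_path <- file.path(out_dir, "score_table.tsv")
      if (!file.exists(score_path)) {
        stop("stratify stage needs score_table.tsv in ", out_dir)
      }
      st <- read.delim(score_path, stringsAsFactors = FALSE)
    }
    surv_path <- config$survival
    if (is.null(surv_path)) surv_path <- file.path(out_dir, "survival.tsv")
    if (!file.exists(surv_path)) {
      stop("stratify stage needs a survival input (config key 'survival'",
           " or a prior simulate stage); not found: ", surv_path)
    }
    records <- read_survival_tsv(surv_path)
    pipeline_log(verbose, "stratifying ", nrow(records), " records (B = ",
                 config$n_permutations, ")")
    report <- stratify_and_analyze(st, records, minprop = config$minprop,
                                   maxprop = config$maxprop,
                                   n_permutations = config$n_permutations,
                                   seed = config$seed)
    ci <- exp(report$cox$log_hr + c(-1, 1) * 1.96 * report$cox$se)
    write_tsv_plain(
      data.frame(cutpoint = report$maxstat$cutpoint,
                 statistic = report$maxstat$statistic,
                 permutation_p = report$maxstat$p_value,
                 n_high = report$maxstat$n_high,
                 n_low = report$maxstat$n_low,
                 logrank_chisq = report$logrank$statistic,
                 logrank_p = report$logrank$p_value,
                 hr = report$cox$hr,
                 hr_ci_low = ci[1L], hr_ci_high = ci[2L],
                 cox_p = report$cox$p_value,
                 cox_converged = report$cox$converged),
      file.path(out_dir, "stratify_report.tsv")
    )
    km <- rbind(cbind(group = "high", report$km_high),
                cbind(group = "low", report$km_low))
    write_tsv_plain(km, file.path(out_dir, "km_curves.tsv"))
    result$report <- report
  }

  invisible(result)
}

#' Command-line entry point
#'
#' Backs the `endoscore` Rscript shipped under `inst/cli/`. Subcommands
#' `simulate`, `score`, `stratify` and `run-all` map onto
#' [run_pipeline()] stages; flags are `--config <file>`, `--seed <int>`,
#' `--method <gsva_diff|gsva_max|mean_z>`, `--epsilon <num>`,
#' `--n-perm <int>`, `--out <dir>` and `-v`.
#'
#' @param args Character vector of command-line arguments (defaults to
#'   the process's trailing arguments).
#' @return Integer exit status: 0 on success, 1 on any error (message
#'   printed to stderr).
#' @export
endoscore_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: endoscore <simulate|score|stratify|run-all>",
    "[--config FILE] [--seed N] [--method gsva_diff|gsva_max|mean_z]",
    "[--epsilon NUM] [--n-perm N] [--out DIR] [-v]"
  )
  status <- tryCatch({
    if (length(args) == 0L) stop(usage, call. = FALSE)
    stage <- args[[1L]]
    if (!stage %in% c("simulate", "score", "stratify", "run-all")) {
      stop("unknown subcommand '", stage, "'\n", usage, call. = FALSE)
    }
    args <- args[-1L]
    opts <- list(config = NULL, seed = NULL, out = "endoscore_out",
                 verbose = FALSE, method = NULL, epsilon = NULL,
                 n_perm = NULL)
    i <- 1L
    take <- function(flag) {
      if (i + 1L > length(args)) stop("flag ", flag, " needs a value",
                                      call. = FALSE)
      args[[i + 1L]]
    }
    while (i <= length(args)) {
      a <- args[[i]]
      if (a == "-v" || a == "--verbose") {
        opts$verbose <- TRUE
      } else if (a == "--config") {
        opts$config <- take(a); i <- i + 1L
      } else if (a == "--seed") {
        opts$seed <- as.integer(take(a)); i <- i + 1L
      } else if (a == "--method") {
        opts$method <- take(a); i <- i + 1L
      } else if (a == "--epsilon") {
        opts$epsilon <- as.numeric(take(a)); i <- i + 1L
      } else if (a == "--n-perm") {
        opts$n_perm <- as.integer(take(a)); i <- i + 1L
      } else if (a == "--out") {
        opts$out <- take(a); i <- i + 1L
      } else {
        stop("unknown flag '", a, "'\n", usage, call. = FALSE)
      }
      i <- i + 1L
    }
    config <- read_pipeline_config(opts$config)
    if (!is.null(opts$method)) config$method <- opts$method
    if (!is.null(opts$epsilon)) config$epsilon <- opts$epsilon
    if (!is.null(opts$n_perm)) config$n_permutations <- opts$n_perm
    run_pipeline(config, out_dir = opts$out, stage = stage,
                 seed = opts$seed, verbose = opts$verbose)
    0L
  }, error = function(e) {
    message("endoscore: ", conditionMessage(e))
    1L
  })
  status
}
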