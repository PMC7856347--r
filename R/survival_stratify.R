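# Shared validation for (time, event) survival records.
validate_records <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("sample_id", "time", "event") %in% names(records)))
  if (nrow(records) < 1L) stop("need at least one survival record")
  if (any(!is.finite(records$time)) || any(records$time <= 0)) {
    stop("survival times must be positive and finite")
  }
  if (!all(records$event %in% c(0, 1))) {
    stop("event indicators must be 0 (censored) or 1 (event)")
  }
  invisible(records)
}

#' Kaplan-Meier product-limit estimate
#'
#' Estimates the survival function S(t) under right censoring as the
#' product over distinct event times t_i <= t of (1 - d_i / n_i), with d_i
#' events and n_i subjects at risk at t_i. Inputs containing only censored
#' observations yield the constant estimate S = 1 (an empty step table).
#'
#' @param records Data.frame with columns `sample_id`, `time` (> 0) and
#'   `event` (0/1).
#' @return A `km_estimate` data.frame with one row per distinct event
#'   time: `time`, `n_risk`, `n_event`, `survival` (non-increasing).
#' @export
km_estimate <- function(records) {
  validate_records(records)
  event_times <- sort(unique(records$time[records$event == 1]))
  if (length(event_times) == 0L) {
    out <- data.frame(time = numeric(0), n_risk = integer(0),
                      n_event = integer(0), survival = numeric(0))
  } else {
    n_risk <- vapply(event_times,
                     function(t) sum(records$time >= t), 0L)
    n_event <- vapply(event_times,
                      function(t) sum(records$time == t & records$event == 1),
                      0L)
    out <- data.frame(time = event_times, n_risk = n_risk,
                      n_event = n_event,
                      survival = cumprod(1 - n_event / n_risk))
  }
  class(out) <- c("km_estimate", "data.frame")
  out
}

#' Two-group log-rank test
#'
#' At each distinct event time, compares the observed events in group 1
#' with the hypergeometric expectation given the at-risk counts; the
#' statistic is (O1 - E1)^2 / V with V the summed hypergeometric variance,
#' referred to a chi-square distribution with 1 degree of freedom.
#'
#' @param records Survival records (see [km_estimate()]).
#' @param group Logical (or 0/1) vector per record; both groups must be
#'   non-empty and at least one event must occur overall.
#' @return A `logrank_result` list: `statistic`, `p_value`, `observed`,
#'   `expected` (group-1 event counts).
#' @export
logrank_test <- function(records, group) {
  validate_records(records)
  group <- as.logical(group)
  stopifnot(length(group) == nrow(records), !anyNA(group))
  if (all(group) || all(!group)) stop("both groups must be non-empty")
  if (sum(records$event) == 0) {
    stop("log-rank statistic undefined without any event")
  }
  event_times <- sort(unique(records$time[records$event == 1]))
  o1 <- e1 <- v <- 0
  for (t in event_times) {
    at_risk <- records$time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & group)
    dead <- records$time == t & records$event == 1
    d <- sum(dead)
    o1 <- o1 + sum(dead & group)
    e1 <- e1 + d * n1 / n
    if (n > 1) {
      v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
    }
  }
  stat <- if (v > 0) (o1 - e1)^2 / v else 0
  structure(list(statistic = stat,
                 p_value = if (v > 0) pchisq(stat, 1, lower.tail = FALSE)
                           else 1,
                 observed = o1, expected = e1, variance = v),
            class = "logrank_result")
}

# Log-rank (Savage) scores: the martingale residual at each subject's own
# follow-up time, a_i = event_i - NelsonAalen(time_i). Permuting these
# scores is equivalent to relinking biomarker values to survival records,
# which is what makes the maxstat permutation p-value cheap.
logrank_scores <- function(records) {
  n <- nrow(records)
  event_times <- sort(unique(records$time[records$event == 1]))
  d <- vapply(event_times,
              function(t) sum(records$time == t & records$event == 1), 0L)
  r <- vapply(event_times, function(t) sum(records$time >= t), 0L)
  haz <- cumsum(d / r)
  cumhaz <- vapply(records$time, function(t) {
    k <- sum(event_times <= t)
    if (k == 0L) 0 else haz[k]
  }, 0)
  records$event - cumhaz
}

#' Maximally selected rank statistics cut-point
#'
#' Scans every admissible threshold on a per-sample score and selects the
#' one that maximizes the absolute standardized log-rank statistic of the
#' induced high/low split, where "high" means score strictly greater than
#' the threshold. Standardization uses the permutation moments of the
#' log-rank scores (conditional mean m * a-bar and variance
#' m (N - m) / (N - 1) * Var(a) for a low group of size m), and the
#' selection-adjusted p-value is obtained by permutation: scores are
#' randomly relinked to survival records `n_permutations` times and the
#' maximal statistic recomputed, with add-one smoothing
#' (b + 1) / (B + 1).
#'
#' @param scores Numeric per-sample scores (length >= 10).
#' @param records Survival records aligned with `scores`.
#' @param minprop,maxprop Admissible range for the fraction of samples
#'   above a candidate threshold (defaults 0.1 and 0.9).
#' @param n_permutations Permutations for the p-value (default 1000; a
#'   value below 100 triggers a warning).
#' @param seed Integer seed for the permutation draw.
#' @return A `maxstat_result` list: `cutpoint`, `statistic` (signed
#'   standardized statistic at the cut), `p_value`, `n_high`, `n_low`,
#'   `n_permutations`, `seed` and the `candidates` table.
#' @export
maxstat_cutpoint <- function(scores, records, minprop = 0.1, maxprop = 0.9,
                             n_permutations = 1000L, seed = 1L) {
  validate_records(records)
  n <- length(scores)
  stopifnot(is.numeric(scores), all(is.finite(scores)),
            n == nrow(records))
  if (n < 10L) stop("maxstat needs at least 10 samples")
  if (sum(records$event) == 0) stop("maxstat needs at least one event")
  if (n_permutations < 100L) {
    warning("n_permutations < 100 gives a coarse permutation p-value")
  }
  a <- logrank_scores(records)
  ord <- order(scores)
  s_sorted <- scores[ord]
  a_sorted <- a[ord]
  # thresholds at distinct score values; m = size of the low group {s <= c}
  is_last <- c(s_sorted[-n] != s_sorted[-1], TRUE)
  cand_m <- which(is_last)
  frac_high <- 1 - cand_m / n
  keep <- frac_high >= minprop & frac_high <= maxprop
  cand_m <- cand_m[keep]
  if (length(cand_m) < 2L) {
    stop("fewer than 2 distinct score values inside the ",
         "[minprop, maxprop] candidate window")
  }
  a_bar <- mean(a)
  ss_a <- sum((a - a_bar)^2)
  e_m <- cand_m * a_bar
  sd_m <- sqrt(cand_m * (n - cand_m) / (n * (n - 1)) * ss_a)
  stat_for <- function(a_vec) {
    (cumsum(a_vec)[cand_m] - e_m) / sd_m
  }
  z <- stat_for(a_sorted)
  best <- which.max(abs(z))  # ties resolve to the smallest threshold
  m_obs <- max(abs(z))
  set.seed(seed)
  exceed <- 0L
  for (b in seq_len(n_permutations)) {
    m_b <- max(abs(stat_for(sample(a))))
    if (m_b >= m_obs) exceed <- exceed + 1L
  }
  cutpoint <- s_sorted[cand_m[best]]
  structure(
    list(cutpoint = cutpoint,
         statistic = z[best],
         p_value = (exceed + 1) / (n_permutations + 1),
         n_high = n - cand_m[best],
         n_low = cand_m[best],
         n_permutations = as.integer(n_permutations),
         seed = as.integer(seed),
         candidates = data.frame(cutpoint = s_sorted[cand_m],
                                 statistic = z)),
    class = "maxstat_result"
  )
}

#' @exportS3Method base::print
print.maxstat_result <- function(x, ...) {
  cat("<maxstat_result> cutpoint = ", format(x$cutpoint),
      ", |standardized statistic| = ", format(abs(x$statistic)),
      "\n  permutation p = ", format(x$p_value), " (B = ",
      x$n_permutations, "), n high/low = ", x$n_high, "/", x$n_low,
      "\n", sep = "")
  invisible(x)
}

#' Cox proportional-hazards fit for a binary group
#'
#' Maximizes the Cox partial likelihood for a single binary covariate by
#' Newton iteration, handling tied event times with the Breslow
#' approximation. Convergence is declared when the absolute score
#' function falls below 1e-8 (at most 50 iterations). Complete separation
#' of the event orderings makes the likelihood monotone in the
#' coefficient; this is detected, flagged as non-converged, and reported
#' as a signed infinite trend rather than an error.
#'
#' @param records Survival records (see [km_estimate()]).
#' @param group Logical (or 0/1) vector; both groups must contain at
#'   least one event.
#' @return A `cox_result` list: `log_hr`, `hr`, `se`, `p_value` (Wald),
#'   `converged`.
#' @export
cox_hr <- function(records, group) {
  validate_records(records)
  group <- as.logical(group)
  stopifnot(length(group) == nrow(records), !anyNA(group))
  if (sum(records$event[group]) < 1 || sum(records$event[!group]) < 1) {
    stop("both groups need at least one event for a hazard ratio")
  }
  event_times <- sort(unique(records$time[records$event == 1]))
  d <- vapply(event_times,
              function(t) sum(records$time == t & records$event == 1), 0)
  d1 <- vapply(event_times,
               function(t) sum(records$time == t & records$event == 1 &
                                 group), 0)
  r1 <- vapply(event_times, function(t) sum(records$time >= t & group), 0)
  r0 <- vapply(event_times, function(t) sum(records$time >= t & !group), 0)
  beta <- 0
  converged <- FALSE
  for (iter in seq_len(50L)) {
    eb <- exp(beta)
    s0 <- r0 + r1 * eb
    p1 <- r1 * eb / s0
    score <- sum(d1 - d * p1)        # Breslow: denominator repeated d times
    info <- sum(d * p1 * (1 - p1))
    if (abs(score) < 1e-8) {
      converged <- TRUE
      break
    }
    if (info <= 0 || abs(beta) > 20) break
    beta <- beta + score / info
  }
  if (abs(beta) > 20) {
    # separation: likelihood increases without bound in this direction
    return(structure(list(log_hr = sign(beta) * Inf,
                          hr = exp(sign(beta) * Inf), se = Inf,
                          p_value = NA_real_, converged = FALSE),
                     class = "cox_result"))
  }
  eb <- exp(beta)
  p1 <- r1 * eb / (r0 + r1 * eb)
  info <- sum(d * p1 * (1 - p1))
  se <- 1 / sqrt(info)
  structure(list(log_hr = beta, hr = exp(beta), se = se,
                 p_value = 2 * pnorm(-abs(beta) / se),
                 converged = converged),
            class = "cox_result")
}

#' @exportS3Method base::print
print.cox_result <- function(x, ...) {
  cat("<cox_result> HR = ", format(x$hr), " (logHR ", format(x$log_hr),
      " +/- ", format(x$se), "), Wald p = ", format(x$p_value),
      if (!x$converged) " [not converged]", "\n", sep = "")
  invisible(x)
}

#' Stratify a scored cohort and quantify prognosis
#'
#' Joins a per-sample score table with survival records on `sample_id`
#' (inner join; mismatches are reported via a message), selects the
#' score cut-point by [maxstat_cutpoint()], and summarizes the resulting
#' high/low groups ("high" = score strictly above the cut-point) with
#' per-group Kaplan-Meier estimates, the log-rank test and a Cox hazard
#' ratio of high versus low.
#'
#' @param score_table A `score_table` from [score_cohort()], or any
#'   data.frame with `sample_id` and `score` columns.
#' @param records Survival records (see [km_estimate()]).
#' @param minprop,maxprop,n_permutations,seed Passed to
#'   [maxstat_cutpoint()].
#' @return An `endo_strat_report` list: `maxstat`, `km_high`, `km_low`,
#'   `logrank`, `cox`, `groups` (data.frame `sample_id`, `score`, `time`,
#'   `event`, `group`).
#' @export
stratify_and_analyze <- function(score_table, records, minprop = 0.1,
                                 maxprop = 0.9, n_permutations = 1000L,
                                 seed = 1L) {
  stopifnot(is.data.frame(score_table),
            all(c("sample_id", "score") %in% names(score_table)))
  validate_records(records)
  joined <- merge(score_table[, c("sample_id", "score")],
                  records[, c("sample_id", "time", "event")],
                  by = "sample_id", sort = TRUE)
  n_dropped <- (nrow(score_table) - nrow(joined)) +
    (nrow(records) - nrow(joined))
  if (nrow(joined) < 10L) {
    stop("score table and survival records share only ", nrow(joined),
         " sample IDs (>= 10 required)")
  }
  if (n_dropped > 0L) {
    message(n_dropped, " unmatched record(s) dropped in the join")
  }
  ms <- maxstat_cutpoint(joined$score, joined, minprop = minprop,
                         maxprop = maxprop,
                         n_permutations = n_permutations, seed = seed)
  joined$group <- ifelse(joined$score > ms$cutpoint, "high", "low")
  high <- joined$group == "high"
  structure(
    list(maxstat = ms,
         km_high = km_estimate(joined[high, ]),
         km_low = km_estimate(joined[!high, ]),
         logrank = logrank_test(joined, high),
         cox = cox_hr(joined, high),
         groups = joined),
    class = "endo_strat_report"
  )
}

#' @exportS3Method base::print
print.endo_strat_report <- function(x, ...) {
  print(x$maxstat)
  cat("log-rank chi-square = ", format(x$logrank$statistic), ", p = ",
      format(x$logrank$p_value), "\n", sep = "")
  print(x$cox)
  invisible(x)
}
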