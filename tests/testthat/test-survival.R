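test_that("Kaplan-Meier estimate matches the product-limit closed forms", {
  recs <- data.frame(sample_id = c("a", "b", "c"), time = c(1, 2, 3),
                     event = c(1, 1, 1))
  km <- km_estimate(recs)
  expect_equal(km$survival, c(2/3, 1/3, 0))
  expect_equal(km$n_risk, c(3L, 2L, 1L))

  # all censored: S identically 1 (empty step table)
  km0 <- km_estimate(transform(recs, event = 0))
  expect_identical(nrow(km0), 0L)

  # censoring at 2 removes one subject from the risk set at t = 3
  recs2 <- data.frame(sample_id = c("a", "b", "c"), time = c(1, 2, 3),
                      event = c(1, 0, 1))
  km2 <- km_estimate(recs2)
  expect_equal(km2$survival, c(2/3, 0))
  expect_equal(km2$time, c(1, 3))

  expect_error(km_estimate(data.frame(sample_id = "a", time = 0,
                                      event = 1)),
               "positive")
})

test_that("KM equals one minus the empirical CDF without censoring", {
  set.seed(11)
  recs <- data.frame(sample_id = sprintf("s%02d", 1:40),
                     time = rexp(40, 0.5), event = 1)
  km <- km_estimate(recs)
  expect_equal(km$survival, 1 - ecdf(recs$time)(km$time))
})

test_that("KM agrees with the survival package on censored data", {
  set.seed(12)
  recs <- random_cohort(60)
  km <- km_estimate(recs)
  fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = recs)
  at_events <- summary(fit, times = km$time)
  expect_equal(km$survival, at_events$surv, tolerance = 1e-12)
})

test_that("log-rank test matches hand and reference computations", {
  recs <- data.frame(sample_id = letters[1:6],
                     time = c(1, 1, 2, 3, 3, 4), event = 1)
  # duplicated groups: observed equals expected by symmetry
  dup <- rbind(recs, transform(recs, sample_id = LETTERS[1:6]))
  res <- logrank_test(dup, rep(c(TRUE, FALSE), each = 6))
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)

  # group A fails strictly before group B (4 + 4, no censoring):
  # hand-summed O/E/V table frozen below
  ab <- data.frame(sample_id = letters[1:8],
                   time = c(1, 2, 3, 4, 11, 12, 13, 14), event = 1)
  grp <- rep(c(TRUE, FALSE), each = 4)
  o1 <- 4
  e1 <- 4/8 + 3/7 + 2/6 + 1/5  # d = 1 at each time, n1/n while A at risk
  v <- (4/8)*(4/8) + (3/7)*(4/7) + (2/6)*(4/6) + (1/5)*(4/5)
  res_ab <- logrank_test(ab, grp)
  expect_equal(res_ab$statistic, (o1 - e1)^2 / v)

  # invariant to which group is labeled TRUE
  res_flip <- logrank_test(ab, !grp)
  expect_equal(res_flip$statistic, res_ab$statistic)

  # reference cross-check on a censored random cohort
  set.seed(13)
  rc <- random_cohort(50)
  g <- rbinom(50, 1, 0.5) == 1
  ref <- survival::survdiff(survival::Surv(time, event) ~ g, data = rc)
  expect_equal(logrank_test(rc, g)$statistic, ref$chisq, tolerance = 1e-10)

  expect_error(logrank_test(recs, rep(TRUE, 6)), "non-empty")
  expect_error(logrank_test(transform(recs, event = 0), rep(c(TRUE, FALSE), 3)),
               "without any event")
})

test_that("Cox fit matches brute-force and reference maximizers", {
  # duplicated groups: exchangeable, HR = 1
  recs <- data.frame(sample_id = letters[1:6],
                     time = c(1, 2, 3, 4, 5, 6), event = 1)
  dup <- rbind(recs, transform(recs, sample_id = LETTERS[1:6]))
  fit <- cox_hr(dup, rep(c(TRUE, FALSE), each = 6))
  expect_equal(fit$hr, 1, tolerance = 1e-6)

  # n = 6 tie-free toy: grid search over the Breslow partial likelihood
  toy <- data.frame(sample_id = letters[1:6],
                    time = c(0.5, 1.2, 1.9, 2.6, 3.1, 4.4),
                    event = c(1, 1, 0, 1, 1, 1))
  x <- c(1, 0, 1, 0, 1, 0)
  fit_toy <- cox_hr(toy, x == 1)
  beta_grid <- grid_cox_beta(toy$time, toy$event, x)
  expect_lt(abs(fit_toy$log_hr - beta_grid), 1e-4)

  # reference cross-check, including ties
  set.seed(14)
  rc <- random_cohort(80)
  rc$time <- round(rc$time, 1) + 0.05
  g <- rbinom(80, 1, 0.5) == 1
  ref <- survival::coxph(survival::Surv(time, event) ~ g, data = rc,
                         ties = "breslow")
  fit_rc <- cox_hr(rc, g)
  expect_equal(fit_rc$log_hr, unname(coef(ref)), tolerance = 1e-7)
  expect_equal(fit_rc$se, unname(sqrt(vcov(ref)[1, 1])), tolerance = 1e-6)

  # complete separation is flagged, not fatal
  sep <- data.frame(sample_id = letters[1:8],
                    time = c(1, 2, 3, 4, 11, 12, 13, 14), event = 1)
  fit_sep <- cox_hr(sep, rep(c(TRUE, FALSE), each = 4))
  expect_false(fit_sep$converged)
  expect_true(is.infinite(fit_sep$log_hr) && fit_sep$log_hr > 0)

  expect_error(cox_hr(transform(recs, event = c(1, 1, 1, 0, 0, 0)),
                      rep(c(FALSE, TRUE), each = 3)),
               "at least one event")
})

test_that("Cox score test at beta = 0 equals the log-rank statistic", {
  # tie-free cohorts: the score test and the hypergeometric log-rank
  # statistic coincide analytically
  set.seed(15)
  for (rep_i in 1:5) {
    recs <- data.frame(sample_id = sprintf("s%02d", 1:30),
                       time = runif(30, 1, 100), event = rbinom(30, 1, 0.8))
    if (sum(recs$event) == 0) next
    g <- rbinom(30, 1, 0.5) == 1
    if (all(g) || all(!g)) next
    event_times <- sort(unique(recs$time[recs$event == 1]))
    u <- 0; info <- 0
    for (t in event_times) {
      risk <- recs$time >= t
      p1 <- sum(risk & g) / sum(risk)
      d <- sum(recs$time == t & recs$event == 1)
      u <- u + sum(recs$time == t & recs$event == 1 & g) - d * p1
      info <- info + d * p1 * (1 - p1)
    }
    score_stat <- u^2 / info
    lr <- logrank_test(recs, g)$statistic
    # hypergeometric variance has the (n-d)/(n-1) factor; tie-free d = 1
    # makes it equal the score-test information exactly
    expect_equal(score_stat, lr, tolerance = 1e-6)
  }
})

test_that("maxstat selects a planted cut and rejects degenerate windows", {
  set.seed(16)
  n <- 60L
  high <- rep(c(TRUE, FALSE), each = n / 2)
  scores <- ifelse(high, 1, 0) + runif(n, -0.05, 0.05)
  recs <- data.frame(
    sample_id = sprintf("s%02d", 1:n),
    time = rexp(n, ifelse(high, 0.4, 0.1)),
    event = 1
  )
  res <- maxstat_cutpoint(scores, recs, n_permutations = 500, seed = 99)
  # the cut separates the two score clusters (jitter keeps them inside
  # [-0.05, 0.05] and [0.95, 1.05]): the threshold is an observed value
  # at the top of the low cluster, within a few samples of the boundary
  expect_lt(res$cutpoint, min(scores[high]))
  expect_gte(res$cutpoint, sort(scores[!high], decreasing = TRUE)[5])
  expect_lte(abs(res$n_high - n / 2), 4)
  expect_lte(res$p_value, 0.05)
  expect_gte(res$p_value, 1 / 501)
  expect_identical(res$n_high + res$n_low, n)
  expect_true(res$cutpoint %in% scores)

  # the cut reproduces with the same seed
  res2 <- maxstat_cutpoint(scores, recs, n_permutations = 500, seed = 99)
  expect_identical(res2$p_value, res$p_value)

  # no admissible candidate window
  small <- data.frame(sample_id = letters[1:10], time = 1:10, event = 1)
  expect_error(
    maxstat_cutpoint(seq(0, 1, length.out = 10), small,
                     minprop = 0.45, maxprop = 0.55,
                     n_permutations = 100),
    "candidate window")
  expect_error(maxstat_cutpoint(1:8, small[1:8, ], n_permutations = 100),
               "at least 10")
  expect_warning(
    maxstat_cutpoint(scores, recs, n_permutations = 50, seed = 1),
    "coarse")
})

test_that("end-to-end stratification recovers a planted prognosis", {
  # cohort -> enrichment -> cut-point -> Cox, scored with the difference
  # statistic (the ratio's signed denominator hides the planted contrast;
  # see the vignette)
  hits <- vapply(1:20, function(i) {
    sim <- simulate_cohort(sim_cohort_config(n_patients = 300,
                                             seed = 5000 + i))
    st <- score_cohort(normalize_log(sim$matrix),
                       statistic = "difference")
    rep <- stratify_and_analyze(st, sim$survival,
                                n_permutations = 200, seed = i)
    rep$cox$hr > 1 && rep$cox$p_value < 0.05
  }, NA)
  expect_gte(mean(hits), 0.9)
})

test_that("stratification report is complete and order-invariant", {
  sim <- simulate_cohort(sim_cohort_config(n_patients = 120, seed = 41))
  scores <- data.frame(sample_id = sim$survival$sample_id,
                       score = ifelse(sim$truth$labels == "high", 1, 0) +
                         runif(120, -0.1, 0.1))
  rep1 <- stratify_and_analyze(scores, sim$survival,
                               n_permutations = 200, seed = 7)
  expect_s3_class(rep1$maxstat, "maxstat_result")
  expect_gt(rep1$cox$hr, 1)

  # permuting the input rows changes nothing
  set.seed(3)
  perm <- sample(120)
  rep2 <- stratify_and_analyze(scores[perm, ], sim$survival[sample(120), ],
                               n_permutations = 200, seed = 7)
  expect_equal(rep2$maxstat$cutpoint, rep1$maxstat$cutpoint)
  expect_equal(rep2$maxstat$p_value, rep1$maxstat$p_value)
  expect_equal(rep2$cox$hr, rep1$cox$hr)
  expect_equal(rep2$logrank$statistic, rep1$logrank$statistic)

  # disjoint sample IDs cannot be joined
  bad <- transform(scores, sample_id = paste0("X", sample_id))
  expect_error(stratify_and_analyze(bad, sim$survival), "share only")
})
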