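# Independent reference implementations used to cross-check the package.

# Brute-force rank random walk: build the walk position by position from
# first principles, without reusing any package code.
brute_force_walk <- function(ranks, member_flags, tau = 1,
                             variant = "gsva_diff") {
  g <- length(ranks)
  m <- sum(member_flags)
  walk <- numeric(g)
  level <- 0
  w_total <- 0
  for (i in seq_len(g)) {
    gene <- which(ranks == i)
    if (member_flags[gene]) {
      w_total <- w_total + abs(ranks[gene] - (g + 1) / 2)^tau
    }
  }
  for (i in seq_len(g)) {
    gene <- which(ranks == i)
    if (member_flags[gene]) {
      level <- level + if (w_total > 0) {
        abs(ranks[gene] - (g + 1) / 2)^tau / w_total
      } else {
        1 / m  # zero-weight degenerate case: uniform member steps
      }
    } else {
      level <- level - 1 / (g - m)
    }
    walk[i] <- level
  }
  up <- max(c(0, walk))
  down <- min(c(0, walk))
  if (variant == "gsva_diff") up + down
  else if (up >= -down) up else down
}

# Grid-search maximizer of the Breslow log partial likelihood for one
# binary covariate.
grid_cox_loglik <- function(time, event, x, beta) {
  ll <- 0
  for (i in which(event == 1)) {
    risk <- time >= time[i]
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
  }
  ll
}

grid_cox_beta <- function(time, event, x,
                          grid = seq(-4, 4, by = 1e-4)) {
  ll <- vapply(grid, function(b) grid_cox_loglik(time, event, x, b), 0)
  grid[which.max(ll)]
}

# Mann-Whitney AUC of score for the positive class.
rank_auc <- function(score, positive) {
  r <- rank(score)
  n1 <- sum(positive)
  n0 <- sum(!positive)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Small random survival cohort with continuous (a.s. tie-free) times.
random_cohort <- function(n, p_event = 0.7) {
  data.frame(sample_id = sprintf("S%03d", seq_len(n)),
             time = rexp(n, 0.2),
             event = rbinom(n, 1, p_event),
             stringsAsFactors = FALSE)
}

# Tiny deterministic expression matrix for I/O and scoring tests.
toy_matrix <- function(genes = 12L, samples = 6L, seed = 42L) {
  set.seed(seed)
  expression_matrix(matrix(rpois(genes * samples, 20), genes, samples),
                    gene_ids = sprintf("G%02d", seq_len(genes)),
                    sample_ids = sprintf("S%02d", seq_len(samples)))
}
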