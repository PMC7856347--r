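test_that("kernel CDF transform obeys its closed-form limits", {
  # constant gene: no ordering information, everything maps to 0.5
  x <- expression_matrix(rbind(c(3, 3, 3, 3), c(1, 2, 3, 4)),
                         gene_ids = c("C", "V"),
                         sample_ids = paste0("S", 1:4))
  z <- kernel_cdf_transform(x)
  expect_equal(unname(z["C", ]), rep(0.5, 4))

  # with two samples the separation is always 4*sqrt(2) ~ 5.7 bandwidths
  # (h = sd/4), so each value averages Phi(0) = 0.5 with a far tail,
  # giving {0.25, 0.75} to ~1e-8
  x2 <- expression_matrix(rbind(c(0, 1000), c(1, 2)),
                          gene_ids = c("A", "B"),
                          sample_ids = c("S1", "S2"))
  z2 <- kernel_cdf_transform(x2)
  expect_equal(unname(z2["A", ]), c(0.25, 0.75), tolerance = 1e-6)

  # monotone: larger expression cannot get a smaller transformed value
  set.seed(7)
  x3 <- toy_matrix(genes = 5, samples = 30, seed = 7)
  z3 <- kernel_cdf_transform(x3)
  for (g in 1:5) {
    ord <- order(x3[g, ])
    expect_true(all(diff(z3[g, ord]) >= 0))
  }
  expect_true(all(z3 > 0 & z3 < 1))
})

test_that("shrinking the bandwidth recovers the empirical CDF", {
  set.seed(101)
  n <- 500
  vals <- rnorm(n)
  x <- expression_matrix(rbind(vals, rnorm(n)),
                         gene_ids = c("G1", "G2"),
                         sample_ids = sprintf("S%03d", 1:n))
  # the transform with bandwidth sd/4, then the same sum evaluated at
  # bandwidth (sd/4)/100 via the exported kernel with a pre-scaled matrix
  h <- sd(vals) / 4
  z_small <- endoscore:::.kcdf_gaussian(x, c(h / 100, sd(x[2, ]) / 400))
  ecdf_vals <- ecdf(vals)(vals)
  expect_lte(max(abs(z_small[1, ] - ecdf_vals)), 0.02)
})

test_that("per-sample ranking is deterministic and order-invariant", {
  z <- expression_matrix(rbind(c(0.9, 0.1), c(0.5, 0.5), c(0.5, 0.9)),
                         gene_ids = c("B", "A", "C"),
                         sample_ids = c("S1", "S2"))
  r <- rank_genes(z)
  # S1: B (0.9) first, then tie 0.5 broken by id: A before C
  expect_equal(unname(r[, "S1"]), c(1L, 2L, 3L))
  # S2: C (0.9), then tie 0.5/0.1: A (0.5) then B
  expect_equal(unname(r[, "S2"]), c(3L, 2L, 1L))

  # permuting rows leaves the gene -> rank mapping untouched
  perm <- c(3, 1, 2)
  r2 <- rank_genes(z[perm, ])
  expect_identical(r2[rownames(r), ], r)
})

test_that("random walk matches hand-computed cases and brute force", {
  # members at top ranks {1, 2} of G = 5: walk peaks at 1
  expect_equal(random_walk_es(1:5, c(TRUE, TRUE, FALSE, FALSE, FALSE)),
               1.0)
  expect_equal(random_walk_es(1:5, c(TRUE, TRUE, FALSE, FALSE, FALSE),
                              variant = "gsva_max"), 1.0)
  # mirrored: members at bottom ranks {4, 5}
  expect_equal(random_walk_es(1:5, c(FALSE, FALSE, FALSE, TRUE, TRUE)),
               -1.0)
  # degenerate memberships are rejected
  expect_error(random_walk_es(1:4, rep(TRUE, 4)), "between 1 and G-1")
  expect_error(random_walk_es(1:4, rep(FALSE, 4)), "between 1 and G-1")

  # exhaustive agreement with the independent walk on all G <= 6, m <= 3
  for (g in 2:6) {
    members <- unlist(lapply(1:min(3, g - 1),
                             function(m) combn(g, m, simplify = FALSE)),
                      recursive = FALSE)
    ranks <- seq_len(g)
    for (mem in members) {
      flags <- seq_len(g) %in% mem
      for (variant in c("gsva_diff", "gsva_max")) {
        # agreement to floating-point roundoff (summation order differs)
        expect_equal(random_walk_es(ranks, flags, variant = variant),
                     brute_force_walk(ranks, flags, variant = variant),
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("enrichment scores are bounded, gene-order invariant and signed", {
  x <- toy_matrix(genes = 30, samples = 12, seed = 9)
  sets <- list(gene_set("s1", c("G01", "G05", "G09")),
               gene_set("s2", c("G02", "G17", "G30", "MISSING")))
  es <- gsva_scores(x, sets)
  expect_true(all(es$scores >= -1 & es$scores <= 1))
  expect_equal(unname(es$n_matched), c(3L, 3L))
  expect_true(es$flagged[["s2"]])  # 3/4 < 0.8 matched
  expect_false(es$flagged[["s1"]])

  # exact invariance to gene row order
  set.seed(1)
  perm <- sample(nrow(x))
  es_perm <- gsva_scores(x[perm, ], sets)
  expect_identical(es$scores, es_perm$scores)

  # a single-gene set holding a sample's top-ranked gene scores positive
  z <- kernel_cdf_transform(x)
  top_gene <- rownames(x)[which.max(z[, "S01"])]
  es_top <- gsva_scores(x, gene_set("top", top_gene))
  expect_gt(es_top$scores[1, "S01"], 0)

  expect_error(gsva_scores(x, gene_set("nohit", c("FOO", "BAR"))),
               "nohit")
  expect_error(gsva_scores(x, gene_set("all", rownames(x))), "every")
})

test_that("mean-z scoring behaves as the simple standardized mean", {
  # identical columns: zero variance everywhere, all scores 0
  x <- expression_matrix(matrix(rep(c(1, 5, 9), 4), 3, 4),
                         gene_ids = c("A", "B", "C"),
                         sample_ids = paste0("S", 1:4))
  es <- mean_z_scores(x, gene_set("ab", c("A", "B")))
  expect_equal(unname(es$scores[1, ]), rep(0, 4))

  # one sample uniformly shifted up scores highest on the all-gene set
  y <- toy_matrix(genes = 10, samples = 5, seed = 3)
  y[, 4] <- y[, 4] + 50
  es2 <- mean_z_scores(y, gene_set("all", rownames(y)))
  expect_identical(unname(which.max(es2$scores[1, ])), 4L)
})

test_that("planted program separates populations consistently across methods", {
  sim <- simulate_expression(sim_expression_config(
    populations = list(
      sim_population("prog", 300L, "true_program", 1),
      sim_population("bg", 300L, "none", 0)
    ),
    library_size_cv = 0, seed = 21
  ))
  x <- normalize_log(sim$matrix)
  truth <- sim$truth$labels
  true_set <- gene_set("true_prog", sim$truth$program_gene_ids$true_program)
  es <- gsva_scores(x, true_set)
  in_prog <- truth[colnames(x)] == "prog"
  expect_gt(mean(es$scores[1, in_prog]), mean(es$scores[1, !in_prog]))

  # the walk statistic and the mean-z cross-check rank samples alike
  mz <- mean_z_scores(x, true_set)
  expect_gte(cor(es$scores[1, ], mz$scores[1, ], method = "spearman"), 0.8)
})

test_that("negating the planted shift flips the score contrast", {
  base_pops <- function(lfc) list(
    sim_population("a", 150L, "true_program", lfc),
    sim_population("b", 150L, "none", 0)
  )
  true_set <- gene_set("true_prog", bcl9_gene_lists()$true_list$symbols)
  diff_for <- function(sim) {
    x <- normalize_log(sim$matrix)
    es <- gsva_scores(x, true_set)
    lab <- sim$truth$labels[colnames(x)] == "a"
    mean(es$scores[1, lab]) - mean(es$scores[1, !lab])
  }
  up <- diff_for(simulate_expression(sim_expression_config(
    populations = base_pops(1), library_size_cv = 0, seed = 5)))
  # "negated" program: the complementary population carries the shift, so
  # population a sits below baseline for the program genes
  sim_dn <- simulate_expression(sim_expression_config(
    populations = list(sim_population("a", 150L, "none", 0),
                       sim_population("b", 150L, "true_program", 1)),
    library_size_cv = 0, seed = 5))
  dn <- diff_for(sim_dn)
  expect_gt(up, 0)
  expect_lt(dn, 0)
})
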