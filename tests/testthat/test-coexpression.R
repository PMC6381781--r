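test_that("bf_score counts matched non-zero levels and is symmetric", {
  a <- c(c1 = 1L, c2 = 0L, c3 = -1L, c4 = 1L)
  self <- bf_score(a, a)
  expect_equal(self$bf, 3L)
  expect_setequal(self$support, c("c1", "c3", "c4"))
  expect_equal(self$sign, 1L)

  expect_equal(bf_score(c(1L, 1L, 1L), c(-1L, -1L, -1L))$bf, 0L)
  opp <- bf_score(c(1L, 1L, 1L), c(-1L, -1L, -1L), "allow-opposite")
  expect_equal(opp$bf, 3L)
  expect_equal(opp$sign, -1L)

  set.seed(42)
  for (rep in 1:100) {
    n <- sample(10:200, 1)
    a <- random_levels(n, c("-1" = 0.2, "0" = 0.6, "1" = 0.2))
    b <- random_levels(n, c("-1" = 0.2, "0" = 0.6, "1" = 0.2))
    for (mode in c("same-sign", "allow-opposite")) {
      expect_equal(bf_score(a, b, mode)$bf, brute_bf(a, b, mode))
      expect_equal(bf_score(a, b, mode)$bf, bf_score(b, a, mode)$bf)
    }
  }
  expect_error(bf_score(c(1L, 0L), c(1L, 0L, 1L)), "length")
})

test_that("the exact null pmf matches exhaustive permutation at small n", {
  set.seed(5)
  for (rep in 1:6) {
    n <- 6L
    a <- random_levels(n, c("-1" = 0.3, "0" = 0.4, "1" = 0.3))
    b <- random_levels(n, c("-1" = 0.3, "0" = 0.4, "1" = 0.3))
    for (mode in c("same-sign", "allow-opposite")) {
      pmf <- bf_null_distribution(level_counts_public(a),
                                  level_counts_public(b), n, mode)
      bfs <- vapply(all_perms(n), function(p) brute_bf(a, b[p], mode), 0L)
      truth <- table(factor(bfs, levels = 0:(length(pmf) - 1L))) / length(bfs)
      expect_equal(unname(as.numeric(pmf)), unname(as.numeric(truth)),
                   tolerance = 1e-12)
    }
  }
})

test_that("exact expectation, tail and permutation p-value agree", {
  ca <- c("-1" = 6L, "0" = 81L, "1" = 6L)
  pmf <- bf_null_distribution(ca, ca, 93L)
  expect_equal(sum(pmf), 1)
  expect_equal(sum(as.numeric(names(pmf)) * pmf),
               bf_null_expectation(ca, ca, 93L))
  expect_equal(bf_null_expectation(ca, ca, 93L), (36 + 36) / 93)

  # a large permutation run reproduces the exact tail within Monte Carlo error
  set.seed(9)
  a <- c(rep(1L, 6), rep(-1L, 6), rep(0L, 81))
  b <- sample(a)
  obs <- bf_score(a, b)$bf
  exact <- bf_null_tail(obs, a, b)
  p_hat <- bf_null_pvalue(obs, a, b, n_permutations = 4000, seed = 2)
  expect_lt(abs(p_hat - exact), 3 * sqrt(exact * (1 - exact) / 4000) + 1e-3)

  # degenerate and error cases
  z <- integer(10)
  expect_equal(bf_null_pvalue(0L, z, z, 200, seed = 1), 1)
  expect_identical(bf_null_pvalue(3L, a, b, 500, seed = 3),
                   bf_null_pvalue(3L, a, b, 500, seed = 3))
  expect_warning(bf_null_pvalue(1L, a, b, 50, seed = 1), "coarse")
  expect_error(bf_null_pvalue(1L, a, b, 0, seed = 1), "positive")

  # identical strongly non-zero vectors are extreme under their own null
  p_self <- bf_null_pvalue(bf_score(a, a)$bf, a, a, 1000, seed = 4)
  expect_lte(p_self, 0.01)
})

test_that("screen_baits recovers a noiseless planted module exactly", {
  spec <- synthetic_spec(n_genes = 50, n_conditions = 100, n_modules = 2,
                         partners_per_module = 3, subset_fraction = 0.1,
                         noise_sd = 1e-9, effect_size = 1, seed = 3)
  sim <- generate_matrix(spec)
  d <- discretize_matrix(sim$matrix, discretization_params(q = 0.1))
  edges <- screen_baits(d, c("bait01", "bait02"),
                        screen_params(alpha = 0.01))
  called <- paste(edges$bait, edges$partner)
  planted <- paste(sim$truth$bait, sim$truth$partner)
  expect_true(all(planted %in% called))
  # every planted condition supports the pair: bf >= planted subset size
  expect_true(all(edges$bf[called %in% planted] >= 10L))
})

test_that("screen_baits respects min_bf, missing baits and determinism", {
  set.seed(12)
  m <- make_matrix(rnorm(30 * 20), paste0("g", 1:30), paste0("c", 1:20))
  d <- discretize_matrix(m, discretization_params(q = 0.15))
  expect_identical(nrow(screen_baits(d, "g1",
                                     screen_params(min_bf = 21L, alpha = 1,
                                                   adjust = "none"))), 0L)
  expect_warning(e <- screen_baits(d, c("g1", "nope"),
                                   screen_params(alpha = 0.5, adjust = "none")),
                 "nope")
  expect_error(suppressWarnings(screen_baits(d, "nope")), "no bait")
  e2 <- suppressWarnings(screen_baits(d, c("g1", "nope"),
                                      screen_params(alpha = 0.5, adjust = "none")))
  expect_identical(e, e2)
})

test_that("support grouping follows the greedy consistency rule", {
  e <- make_edges(bait = rep("b", 2), partner = c("x", "y"), bf = c(4L, 4L),
                  support = c("c1,c2,c3,c4", "c1,c2,c3,c4"))
  g <- condition_support_module(e, consistency = 0.95)
  expect_length(g, 1L)
  expect_setequal(g[[1]]$genes, c("x", "y"))
  expect_setequal(g[[1]]$conditions, c("c1", "c2", "c3", "c4"))

  e2 <- make_edges(bait = rep("b", 2), partner = c("x", "y"), bf = c(3L, 3L),
                   support = c("c1,c2,c3", "c4,c5,c6"))
  g2 <- condition_support_module(e2, consistency = 1)
  expect_length(g2, 2L)
  expect_equal(sort(vapply(g2, function(x) x$genes, "")), c("x", "y"))

  # planted two-module fixture: groups recover the planted condition subsets
  spec <- synthetic_spec(n_genes = 30, n_conditions = 80, n_modules = 2,
                         partners_per_module = 4, subset_fraction = 0.125,
                         noise_sd = 1e-9, effect_size = 1, seed = 8)
  sim <- generate_matrix(spec)
  d <- discretize_matrix(sim$matrix, discretization_params(q = 0.125))
  for (bait in c("bait01", "bait02")) {
    edges <- screen_baits(d, bait, screen_params())
    edges <- edges[edges$partner %in% sim$truth$partner[sim$truth$bait == bait], ]
    g <- condition_support_module(edges, consistency = 0.7)
    planted <- strsplit(sim$truth$conditions[sim$truth$bait == bait][1], ",")[[1]]
    expect_length(g, 1L)
    expect_setequal(g[[1]]$genes, edges$partner)
    expect_true(all(planted %in% g[[1]]$conditions))
  }
  expect_error(condition_support_module(e[0, ]), "at least one edge")
})

test_that("pearson_score is the product-moment correlation", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(pearson_score(x, 2 * x + 1), 1)
  expect_equal(pearson_score(c(1, -1, 1, -1), c(1, 1, -1, -1)), 0)
  set.seed(2)
  a <- rnorm(20); b <- rnorm(20)
  closed <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(pearson_score(a, b), closed)
  expect_error(pearson_score(rep(1, 5), rnorm(5)), "zero variance")
  expect_error(pearson_score(1:2, 1:2), "at least 3")
})

test_that("compare_methods scores every other gene by both methods", {
  spec <- synthetic_spec(n_genes = 60, n_conditions = 93, n_modules = 1,
                         partners_per_module = 3, subset_fraction = 1,
                         noise_sd = 0.5, seed = 21)
  sim <- generate_matrix(spec)
  tab <- compare_methods(sim$matrix, "bait01")
  expect_equal(nrow(tab), 59L)
  expect_false("bait01" %in% tab$gene)
  # a globally correlated partner ranks high under both scores
  partners <- sim$truth$partner
  expect_gte(min(rank(tab$bf)[tab$gene %in% partners]), 59 - 10)
  expect_gte(min(rank(tab$pcc)[tab$gene %in% partners]), 59 - 10)
})
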