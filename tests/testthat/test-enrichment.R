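test_that("score-sum permutation p matches exhaustive enumeration", {
  scores <- stats::setNames(1:6, paste0("g", 1:6))
  universe <- names(scores)
  hits <- c("g5", "g6")                      # sum 11, the unique maximum
  res <- score_sum_enrichment(hits, scores, universe, n_perm = 30000,
                              seed = 101)
  exact <- oracle_exact_subset_p(1:6, 2, 11, "greater")   # 1/15
  expect_equal(exact, 1 / 15)
  mc_sd <- sqrt(exact * (1 - exact) / res$n_permutations)
  expect_lt(abs(res$p - exact), 3 * mc_sd + 1 / res$n_permutations)
  # degenerate draws: hits = universe and total ties both give p = 1
  expect_equal(score_sum_enrichment(universe, scores, universe,
                                    n_perm = 50, seed = 1)$p, 1)
  tied <- stats::setNames(rep(2, 6), universe)
  expect_equal(score_sum_enrichment(hits, tied, universe, n_perm = 50,
                                    seed = 1)$p, 1)
  expect_error(score_sum_enrichment(c("g1", "zz"), scores, universe),
               "subset")
})

test_that("rank-sum permutation p matches exhaustive enumeration", {
  qv <- stats::setNames(c(0.01, 0.02, 0.03, 0.04, 0.05, 0.9),
                        paste0("g", 1:6))
  universe <- names(qv)
  res <- rank_sum_enrichment(paste0("g", 1:5), qv, universe,
                             n_perm = 30000, seed = 102)
  # C(6,5) = 6 subsets; only ranks {1..5} reach sum 15 -> exact p = 1/6
  expect_equal(oracle_exact_subset_p(rank(qv), 5, 15, "less"), 1 / 6)
  mc_sd <- sqrt((1 / 6) * (5 / 6) / res$n_permutations)
  expect_lt(abs(res$p - 1 / 6), 3 * mc_sd + 1 / res$n_permutations)
  # worst-ranked targets: every subset is at least as small -> p = 1
  worst <- rank_sum_enrichment(c("g5", "g6"), qv, universe,
                               n_perm = 200, seed = 3)
  expect_equal(worst$p, 1)
  # relabelling non-target genes leaves the observed rank sum unchanged
  qv2 <- qv; qv2[c("g3", "g4")] <- qv[c("g4", "g3")]
  a <- rank_sum_enrichment(c("g1", "g2"), qv, universe, 100, seed = 4)
  b <- rank_sum_enrichment(c("g1", "g2"), qv2, universe, 100, seed = 4)
  expect_equal(a$observed, b$observed)
  expect_error(rank_sum_enrichment(c("g1", "g1"), qv, universe), "duplicate")
})

test_that("overlap enrichment reports exact hypergeometric alongside MC", {
  universe <- paste0("g", 1:10)
  flagged <- paste0("g", 1:4)
  hits <- c("g1", "g2", "g3", "g9", "g10")   # overlap 3
  res <- overlap_enrichment(hits, flagged, universe, n_perm = 20000,
                            seed = 103)
  expect_equal(res$observed, 3)
  expect_equal(res$exact_p, 66 / 252)
  mc_sd <- sqrt(res$exact_p * (1 - res$exact_p) / res$n_permutations)
  expect_lt(abs(res$p - res$exact_p), 3 * mc_sd + 1 / res$n_permutations)
  # zero overlap when zero is the minimum possible -> exact p = 1
  res0 <- overlap_enrichment(c("g9", "g10"), flagged, universe,
                             n_perm = 100, seed = 5)
  expect_equal(res0$exact_p, 1)
})

test_that("Monte-Carlo overlap p tracks the exact tail over random configs", {
  set.seed(104)
  for (r in 1:25) {
    n <- sample(8:30, 1)
    universe <- paste0("g", seq_len(n))
    flagged <- sample(universe, sample.int(n - 1, 1))
    hits <- sample(universe, sample.int(n - 1, 1))
    res <- overlap_enrichment(hits, flagged, universe, n_perm = 4000)
    tol <- 3 * sqrt(res$exact_p * (1 - res$exact_p) / 4000) + 1 / 4000
    expect_lt(abs(res$p - res$exact_p), tol + 1e-12)
  }
})

test_that("stage z-scoring follows the within-gene definition", {
  expr <- rbind(gA = c(1, 2, 3), gB = c(4, 4, 4), gC = c(0, 1, 5))
  colnames(expr) <- paste0("stage", 1:3)
  universe <- rownames(expr)
  res <- stage_expression_enrichment("gA", expr, universe, n_perm = 500,
                                     seed = 106)
  # gene (1,2,3): z = (-1, 0, 1) with sample SD 1
  expect_equal(unname(vapply(res, `[[`, 0, "observed")), c(-1, 0, 1))
  # a constant gene contributes zero at every stage
  resB <- stage_expression_enrichment("gB", expr, universe, n_perm = 500,
                                      seed = 106)
  expect_equal(unname(vapply(resB, `[[`, 0, "observed")), c(0, 0, 0))
  # within-gene centering: stage-summed observed statistic is zero
  resAll <- stage_expression_enrichment(c("gA", "gC"), expr, universe,
                                        n_perm = 100, seed = 1)
  expect_equal(sum(vapply(resAll, `[[`, 0, "observed")), 0)
  expect_error(stage_expression_enrichment("gA", expr[, 1, drop = FALSE],
                                           universe), "2 stages")
})

test_that("permutation results are add-one corrected and reproducible", {
  scores <- stats::setNames(rnorm(20), paste0("g", 1:20))
  universe <- names(scores)
  hits <- paste0("g", 1:6)
  a <- score_sum_enrichment(hits, scores, universe, n_perm = 1000,
                            seed = 107)
  b <- score_sum_enrichment(hits, scores, universe, n_perm = 1000,
                            seed = 107)
  expect_identical(a$n_extreme, b$n_extreme)
  expect_identical(a$p, b$p)
  expect_gt(a$p, 0)
  expect_equal(a$p, (a$n_extreme + 1) / (a$n_permutations + 1))
})

test_that("genes without annotation are dropped from universe and hits", {
  scores <- stats::setNames(1:4, paste0("g", 1:4))
  universe <- paste0("g", 1:6)
  expect_message(
    res <- score_sum_enrichment(c("g1", "g5"), scores, universe,
                                n_perm = 100, seed = 9),
    "lack")
  expect_equal(res$observed, 1)   # only g1 survives
})
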