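test_that("exact-fit data is returned in closed form and flagged", {
  fc0 <- make_gene_fc(gamma = 0, sigma_hairpin = 0, sigma_resid = 0)
  f0 <- fit_gene(fc0)
  expect_equal(unname(f0$beta), rep(0, 5))
  expect_equal(f0$sigma_h, 0)
  expect_equal(f0$status, "degenerate")
  # noiseless linear dropout: beta_k = gamma * (t_k - t0) exactly
  fc <- make_gene_fc(gamma = -0.2, sigma_hairpin = 0, sigma_resid = 0)
  f <- fit_gene(fc)
  expect_equal(unname(f$beta), c(-0.4, -1.0, -1.6, -2.0, -2.4))
  expect_equal(f$status, "degenerate")
  expect_equal(f$sigma_resid, 0)
})

test_that("with no hairpin heterogeneity the fit equals per-day OLS means", {
  fc <- make_gene_fc(gamma = -0.15, sigma_hairpin = 0, sigma_resid = 0.1,
                     seed = 71)
  f <- fit_gene(fc)
  ols <- tapply(fc$y, fc$day, mean)
  expect_equal(unname(f$beta), unname(as.numeric(ols)), tolerance = 1e-6)
})

test_that("doubling the response doubles every coefficient", {
  fc <- make_gene_fc(gamma = -0.2, sigma_hairpin = 0.05,
                     sigma_resid = 0.1, seed = 72)
  f1 <- fit_gene(fc)
  fc2 <- fc; fc2$y <- 2 * fc$y
  f2 <- fit_gene(fc2)
  expect_equal(unname(f2$beta), 2 * unname(f1$beta), tolerance = 1e-7)
})

test_that("Wald intervals cover the true cumulative effect", {
  covered <- 0L; total <- 0L; n_sim <- 150
  for (r in seq_len(n_sim)) {
    fc <- make_gene_fc(gamma = -0.2, sigma_hairpin = 0.05,
                       sigma_resid = 0.1, seed = 1000 + r)
    f <- fit_gene(fc)
    truth <- -0.2 * (f$days - 4)
    covered <- covered + sum(abs(f$beta - truth) <= 3 * f$se)
    total <- total + length(f$beta)
  }
  expect_gte(covered / total, 0.95)
})

test_that("per-day slopes convert coefficients in both modes", {
  beta <- c(-0.4, -1.0, -1.6, -2.0, -2.4)
  days <- c(6, 9, 12, 14, 16)
  expect_equal(unname(slope_per_day(beta, days = days, baseline_day = 4)),
               rep(-0.2, 5))
  expect_equal(unname(slope_per_day(beta, mode = "incremental",
                                    days = days, baseline_day = 4)),
               rep(-0.2, 5))
  # a saturating trajectory: cumulative dilutes, incremental goes to zero
  flat <- rep(1, 5)
  cum <- slope_per_day(flat, days = days, baseline_day = 4)
  inc <- slope_per_day(flat, mode = "incremental", days = days,
                       baseline_day = 4)
  expect_equal(unname(cum[5]), 1 / 12)
  expect_equal(unname(inc), c(1 / 2, 0, 0, 0, 0))
})

test_that("BH adjustment matches the step-up oracle and handles NaN", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.37), 0.37)
  expect_equal(bh_fdr(rep(0.2, 5)), rep(0.2, 5))
  # NaN propagates and is excluded from m
  q <- bh_fdr(c(0.05, NaN, 0.1))
  expect_true(is.nan(q[2]))
  expect_equal(q[c(1, 3)], c(0.1, 0.1))
  expect_error(bh_fdr(c(0.5, 1.2)), "0, 1")
  set.seed(41)
  for (r in 1:50) {
    p <- runif(sample(2:40, 1))
    expect_equal(bh_fdr(p), oracle_bh(p))
    # permutation invariance
    perm <- sample(length(p))
    expect_equal(bh_fdr(p[perm]), oracle_bh(p)[perm])
  }
})

test_that("the dual-threshold gate requires both magnitude and confidence", {
  days <- c(6, 9, 12, 14, 16)
  beta <- rbind(
    tiny_confident = 0.05 * (days - 4),   # slope 0.05/day everywhere
    strong_day12 = c(0, 0, -0.15 * 8, 0, 0),
    nothing = rep(0.01, 5))
  p <- rbind(tiny_confident = rep(1e-6, 5),
             strong_day12 = c(0.9, 0.9, 1e-4, 0.9, 0.9),
             nothing = rep(0.8, 5))
  fit <- fake_fit(beta, p)
  hits <- call_hits(fit)
  expect_false(hits$hit[hits$gene == "tiny_confident"])
  expect_true(hits$hit[hits$gene == "strong_day12"])
  expect_equal(hits$direction[hits$gene == "strong_day12"], "depleted")
  expect_equal(hits$best_day[hits$gene == "strong_day12"], 12)
  expect_false(hits$hit[hits$gene == "nothing"])
})

test_that("failed fits are reported but excluded from hit calling", {
  days <- c(6, 9, 12, 14, 16)
  beta <- rbind(g1 = -0.2 * (days - 4), g2 = -0.2 * (days - 4))
  p <- rbind(g1 = rep(1e-6, 5), g2 = rep(1e-6, 5))
  fit <- fake_fit(beta, p)
  fit$status["g2"] <- "failed"
  hits <- call_hits(fit)
  expect_true(hits$hit[hits$gene == "g1"])
  expect_false(hits$hit[hits$gene == "g2"])
  expect_equal(hits$status[hits$gene == "g2"], "failed")
})

test_that("screen-wide fitting recovers simulated effects per locus", {
  cfg <- sim_config(n_loci = 10, n_genes = 40, depth_per_sample = 5e5,
                    effect_fraction = 0.25, effect_range = c(0.2, 0.3),
                    seed = 55)
  sim <- simulate_screen(cfg)
  fc <- fold_change_vs_baseline(log2_cpm(sim$counts), sim$samples,
                                sim$library)
  fit <- screen_lmm(fc)
  expect_s3_class(fit, "screen_lmm")
  expect_equal(sort(rownames(fit$beta)), sort(sim$truth$genes$gene))
  hits <- call_hits(fit, library = sim$library)
  ls <- attr(hits, "locus_summary")
  expect_equal(ls$n_loci, 10)
  # the locus summary reconciles with the hit table
  expect_equal(ls$n_hit_loci,
               length(unique(hits$locus[hits$hit])))
  expect_equal(sum(ls$hits_per_locus), sum(hits$hit))
  # methods are coherent
  expect_equal(coef(fit), fit$beta)
  expect_equal(length(residuals(fit)), nrow(fc))
  expect_lt(mean(abs(residuals(fit))), 1)
})

test_that("the per-day random-effect alternative also fits", {
  fc <- make_gene_fc(gamma = -0.2, sigma_hairpin = 0.05,
                     sigma_resid = 0.1, seed = 90)
  f <- fit_gene(fc, random = "day")
  expect_true(f$status %in% c("ok", "singular"))
  expect_equal(unname(f$beta), -0.2 * (c(6, 9, 12, 14, 16) - 4),
               tolerance = 0.3)
})
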