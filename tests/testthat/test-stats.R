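test_that("summary-statistic t matches published two-group rows", {
  # SHAPS: anhedonia 38.14 (3.97, n=29) vs no-anhedonia 26.94 (5.03, n=33)
  shaps <- t_from_summary(38.14, 3.97, 29, 26.94, 5.03, 33)
  expect_equal(shaps$t, 9.642, tolerance = 0.05)
  expect_lt(shaps$p, 0.001)
  # HAMD: 25.34 (3.24, 29) vs 24.27 (3.84, 33)
  hamd <- t_from_summary(25.34, 3.24, 29, 24.27, 3.84, 33)
  expect_equal(hamd$t, 1.178, tolerance = 0.05)
  # equal means give t = 0
  expect_equal(t_from_summary(5, 1, 10, 5, 2, 12)$t, 0)
  expect_error(t_from_summary(1, 0, 10, 2, 1, 10), "positive")
})

test_that("summary-statistic F matches published three-group rows", {
  age <- anova_from_summary(list(c(28.48, 6.99, 29), c(30.73, 7.06, 33),
                                 c(27.20, 6.40, 30)))
  expect_equal(age$F, 2.165, tolerance = 0.05)
  expect_equal(age$df1, 2)
  expect_equal(age$df2, 89)
  edu <- anova_from_summary(list(c(13.97, 3.05, 29), c(14.85, 2.18, 33),
                                 c(15.07, 2.32, 30)))
  expect_equal(edu$F, 1.571, tolerance = 0.05)
  # equal means -> F = 0
  eq <- anova_from_summary(list(c(3, 1, 10), c(3, 2, 10), c(3, 1.5, 10)))
  expect_equal(eq$F, 0)
})

test_that("chi-square matches the expected-counts oracle", {
  expect_equal(chi2_from_counts(rbind(c(10, 10), c(10, 10)))$chi2, 0)
  # hand oracle: all expected counts are 15
  res <- chi2_from_counts(rbind(c(20, 10), c(10, 20)))
  expect_equal(res$chi2, 4 * 25 / 15, tolerance = 1e-12)
  expect_equal(res$df, 1)
  # published gender table: the printed p (0.081) is reproduced by the
  # expected-counts statistic (~5.04), not the printed statistic
  gen <- chi2_from_counts(rbind(c(6, 9, 14), c(23, 24, 16)))
  expect_equal(gen$chi2, 5.04, tolerance = 0.01)
  expect_equal(gen$df, 2)
  expect_equal(gen$p, 0.081, tolerance = 0.01)
  expect_error(chi2_from_counts(rbind(c(0, 0), c(1, 2))), "zero row")
})

test_that("BH-FDR equals the hand-applied step-up rule", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4),
               tolerance = 1e-12)
  expect_equal(bh_fdr(0.37), 0.37)
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  set.seed(61)
  for (rep in 1:10) {
    p <- runif(sample(3:40, 1))
    adj <- bh_fdr(p)
    expect_equal(adj, hand_bh(p), tolerance = 1e-12)
    expect_true(all(adj >= p))
  }
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("ANCOVA without covariates equals the one-way ANOVA oracle", {
  set.seed(62)
  rec <- simulate_covariates(c(HC = 12, MDD_noanh = 12, MDD_anh = 12),
                             seed = 62)
  y <- rnorm(36) + rep(c(0, 0.5, 1), each = 12)  # records come group-blocked
  res <- ancova_region(y, rec, covariates = NULL)
  # textbook between/within sums of squares
  groups <- split(y, rec$group)
  grand <- mean(y)
  ssb <- sum(vapply(groups, function(g) length(g) * (mean(g) - grand)^2,
                    numeric(1)))
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  F_oracle <- (ssb / 2) / (ssw / (36 - 3))
  expect_equal(res$F, F_oracle, tolerance = 1e-10)
  expect_equal(res$eta_sq_partial, ssb / (ssb + ssw), tolerance = 1e-10)
})

test_that("identical group means with zero covariate effect give F ~ 0", {
  rec <- simulate_covariates(c(HC = 5, MDD_noanh = 5, MDD_anh = 5),
                             seed = 63)
  y <- rep(c(1, 2, 3, 4, 5), 3)  # same values in each group
  res <- ancova_region(y, rec, covariates = NULL)
  expect_equal(res$F, 0, tolerance = 1e-10)
})

test_that("a covariate duplicating the group dummy triggers the rank error", {
  rec <- simulate_covariates(c(HC = 8, MDD_noanh = 8, MDD_anh = 8),
                             seed = 64)
  rec$dummy <- as.numeric(rec$group == "MDD_anh")
  set.seed(64)
  expect_error(ancova_region(rnorm(24), rec, covariates = c("age", "dummy")),
               "collinear")
})

test_that("pure-noise covariates barely move the group F", {
  set.seed(65)
  rec <- simulate_covariates(c(HC = 20, MDD_noanh = 20, MDD_anh = 20),
                             seed = 65)
  y <- rnorm(60) + as.numeric(rec$group == "MDD_anh")
  f0 <- ancova_region(y, rec, covariates = NULL)$F
  rec$noise1 <- rnorm(60); rec$noise2 <- rnorm(60)
  f1 <- ancova_region(y, rec, covariates = c("noise1", "noise2"))$F
  expect_lt(abs(f1 - f0) / f0, 0.25)
})

test_that("missing coupling values are excluded with a message", {
  rec <- simulate_covariates(c(HC = 6, MDD_noanh = 6, MDD_anh = 6),
                             seed = 66)
  set.seed(66)
  y <- rnorm(18); y[c(2, 9)] <- NA
  expect_message(res <- ancova_region(y, rec, covariates = NULL),
                 "2 subject")
  expect_equal(res$n_used, 16)
})

test_that("post-hoc contrasts find the HC effect and respect antisymmetry", {
  set.seed(67)
  n <- c(HC = 30, MDD_noanh = 30, MDD_anh = 30)
  rec <- simulate_covariates(n, seed = 67)
  # HC elevated, both MDD groups identical in expectation
  y <- rnorm(90, sd = 0.5) + ifelse(rec$group == "HC", 1.5, 0)
  kls <- matrix(y, ncol = 1, dimnames = list(rec$subject_id, "r1"))
  ct <- structure(list(kls = kls, whole_brain = rnorm(90, 0.5, 0.05),
                       subject_ids = rec$subject_id, region_names = "r1"),
                  class = "coupling_table")
  ph <- posthoc_pairwise(ct, rec, regions = 1)
  expect_equal(nrow(ph), 3)
  hc_rows <- grepl("HC", ph$contrast)
  expect_true(all(ph$p_adj[hc_rows] < 0.05))
  expect_gt(ph$p_adj[!hc_rows], 0.05)
  # direction is the sign of the adjusted difference
  expect_equal(ph$direction,
               ifelse(ph$adjusted_mean_diff >= 0, "increase", "decrease"))
  # HC - MDD contrasts are positive (HC was elevated)
  expect_true(all(ph$adjusted_mean_diff[hc_rows] > 0))
})

test_that("partial correlation matches the residual-then-correlate oracle", {
  set.seed(68)
  # reduction to plain Pearson with no covariates
  x <- rnorm(40); y <- 0.6 * x + rnorm(40)
  pc <- partial_corr(x, y)
  expect_equal(pc$r, cor(x, y), tolerance = 1e-12)
  expect_equal(pc$p, cor.test(x, y)$p.value, tolerance = 1e-10)
  # y identical to x -> r = 1 regardless of covariates
  covs <- matrix(rnorm(40 * 2), 40, 2)
  expect_equal(partial_corr(x, x + 0 * covs[, 1], covs)$r, 1,
               tolerance = 1e-12)
  # n = 60, 6 covariates vs brute-force oracle
  n <- 60
  covs6 <- matrix(rnorm(n * 6), n, 6)
  x2 <- rnorm(n) + covs6 %*% runif(6)
  y2 <- rnorm(n) + covs6 %*% runif(6) + 0.4 * x2
  pc2 <- partial_corr(x2, y2, covs6)
  expect_equal(pc2$r, hand_partial_corr(x2, y2, covs6), tolerance = 1e-10)
  expect_equal(pc2$df, n - 6 - 2)
  expect_error(partial_corr(rep(1, 20), rnorm(20)), "zero residual")
})

test_that("clinical partial correlations run over the patient subset with FDR", {
  set.seed(69)
  rec <- simulate_covariates(seed = 69)
  n <- nrow(rec)
  kls <- matrix(rnorm(n * 2, 0.5, 0.1), n, 2,
                dimnames = list(rec$subject_id, c("rA", "rB")))
  # build in a SHAPS association for region A within patients
  pat <- rec$group != "HC"
  kls[pat, 1] <- kls[pat, 1] + 0.012 * rec$SHAPS[pat]
  ct <- structure(list(kls = kls, whole_brain = rnorm(n, 0.5, 0.05),
                       subject_ids = rec$subject_id,
                       region_names = c("rA", "rB")),
                  class = "coupling_table")
  res <- clinical_partial_corr(ct, rec, regions = c("rA", "rB"))
  expect_equal(nrow(res), 8)  # 2 regions x 4 clinical variables
  expect_true(all(abs(res$r) <= 1))
  expect_true(all(res$p_fdr >= res$p - 1e-12))
  ra_shaps <- res[res$region_name == "rA" & res$clinical_variable == "SHAPS", ]
  expect_gt(ra_shaps$r, 0)
})

test_that("FDR keeps the observed false-discovery proportion controlled", {
  # 20% of tests carry true effects; average FDP at alpha = 0.05 stays
  # below 0.10 across seeded replicates
  set.seed(70)
  fdp <- replicate(200, {
    m <- 50; m1 <- 10
    z <- c(rnorm(m1, mean = 3.5), rnorm(m - m1))
    p <- 2 * pnorm(-abs(z))
    adj <- bh_fdr(p)
    disc <- which(adj < 0.05)
    if (length(disc) == 0) 0 else mean(disc > m1)
  })
  expect_lt(mean(fdp), 0.10)
})
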