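test_that("estimate_pdf yields a normalized, permutation-invariant distribution", {
  set.seed(31)
  x <- rexp(200)
  P <- estimate_pdf(x)
  expect_equal(sum(P$prob), 1, tolerance = 1e-9)
  expect_true(all(P$prob > 0))
  # permuting the sample changes nothing
  Q <- estimate_pdf(sample(x))
  expect_equal(P$prob, Q$prob, tolerance = 1e-12)
  expect_equal(P$support, Q$support, tolerance = 1e-12)
})

test_that("estimate_pdf approaches the analytic normal on a large sample", {
  set.seed(32)
  x <- rnorm(10000)
  P <- estimate_pdf(x)
  # oracle: normal CDF differences on the same grid cells
  g <- P$support
  half <- (g[2] - g[1]) / 2
  q <- pnorm(g + half) - pnorm(g - half)
  q <- q / sum(q)
  expect_lt(0.5 * sum(abs(P$prob - q)), 0.02)  # total variation
})

test_that("constant samples become a point mass, not a KDE failure", {
  P <- estimate_pdf(rep(2.5, 50))
  expect_equal(sum(P$prob), 1, tolerance = 1e-9)
  expect_equal(max(P$prob), 1, tolerance = 1e-6)
  expect_equal(P$support[which.max(P$prob)], 2.5, tolerance = 0.01)
})

test_that("sym_kl matches hand summation and is symmetric and non-negative", {
  # 2-point hand-computed case: D = 0.4 * ln 9
  P <- pdf_on_grid(c(0.5, 0.5))
  Q <- pdf_on_grid(c(0.9, 0.1))
  expect_equal(sym_kl(P, Q), 0.4 * log(9), tolerance = 1e-12)
  expect_equal(sym_kl(P, P), 0, tolerance = 1e-15)

  # random 2-5-bin distributions vs term-by-term oracle
  set.seed(33)
  for (nb in 2:5) {
    for (rep in 1:5) {
      p <- runif(nb) + 0.05; p <- p / sum(p)
      q <- runif(nb) + 0.05; q <- q / sum(q)
      P <- pdf_on_grid(p); Q <- pdf_on_grid(q)
      expect_equal(sym_kl(P, Q), hand_sym_kl(p, q), tolerance = 1e-12)
      expect_equal(sym_kl(P, Q), sym_kl(Q, P), tolerance = 1e-12)
      expect_gte(sym_kl(P, Q), 0)
      # asymmetric option equals the one-directional sum
      expect_equal(sym_kl(P, Q, divergence = "asymmetric"),
                   sum(p * log(p / q)), tolerance = 1e-12)
    }
  }
  expect_error(sym_kl(pdf_on_grid(c(0.5, 0.5), 1:2),
                      pdf_on_grid(c(0.5, 0.5), 3:4)),
               "same support")
})

test_that("KLS of identical samples is 1 and range is (0, 1]", {
  set.seed(34)
  x <- rnorm(500)
  cv <- kls_from_samples(x, x)
  expect_equal(cv$kls, 1, tolerance = 1e-9)
  expect_equal(cv$d_kl, 0, tolerance = 1e-9)
  # arbitrary pairs stay in (0, 1]
  for (rep in 1:10) {
    a <- rnorm(100, sd = runif(1, 0.5, 2))
    b <- rexp(100)
    k <- kls_from_samples(a, b)$kls
    expect_true(k > 0 && k <= 1)
  }
})

test_that("KLS decreases monotonically with a location shift", {
  set.seed(35)
  n <- 5000
  base <- rnorm(n)
  shifted <- rnorm(n)
  kls <- vapply(c(0, 0.5, 1, 2), function(d)
    kls_from_samples(base, shifted + d)$kls, numeric(1))
  expect_true(all(diff(kls) < 0))
})

test_that("KLS is symmetric in its two samples", {
  set.seed(36)
  a <- rnorm(300); b <- rexp(300)
  expect_equal(kls_from_samples(a, b)$kls, kls_from_samples(b, a)$kls,
               tolerance = 1e-12)
})

test_that("small samples are flagged missing rather than estimated", {
  cv <- kls_from_samples(rnorm(5), rnorm(100))
  expect_true(cv$flagged)
  expect_true(is.na(cv$kls))
})

test_that("region_coupling: identity region, rank order, and contracts", {
  atl <- make_phantom_atlas(c(14, 14, 14), R = 6, seed = 41)
  set.seed(42)
  gvol <- array(runif(14^3, 0.2, 0.9), dim = c(14, 14, 14))
  avol <- array(rnorm(14^3, 0.8, 0.2), dim = c(14, 14, 14))
  # region 1's ALFF values a copy of its GMV values -> KLS = 1 after
  # shared normalization; increasing distortion in later regions
  deltas <- c(0, 0.3, 0.6, 0.9, 1.3, 1.8)
  for (r in 1:6) {
    idx <- which(atl$labels == r)
    z <- as.numeric(scale(gvol[idx]))
    avol[idx] <- 0.8 + 0.15 * (z + deltas[r] / 4 * (z^2 - 1))
  }
  gmv <- volumetric_map(gvol, "GMV", "s1")
  alff <- volumetric_map(avol, "ALFF", "s1")
  rc <- region_coupling(gmv, alff, atl)
  expect_equal(nrow(rc), 6)
  expect_equal(rc$kls[1], 1, tolerance = 1e-9)
  # kls rank-order inversely matches the designed divergence
  expect_equal(order(rc$kls, decreasing = TRUE), 1:6)
  expect_true(all(rc$kls > 0 & rc$kls <= 1))
  expect_equal(rc$kls, exp(-rc$d_kl), tolerance = 1e-12)

  # shape mismatch is a contract error
  small <- volumetric_map(array(1, dim = c(4, 4, 4)), "ALFF", "s1")
  expect_error(region_coupling(gmv, small, atl), "grids differ")
})

test_that("KLS is invariant to positive affine rescaling of one modality", {
  atl <- make_phantom_atlas(c(12, 12, 12), R = 4, seed = 43)
  set.seed(44)
  gvol <- array(runif(12^3, 0.2, 0.9), dim = c(12, 12, 12))
  avol <- array(rnorm(12^3, 1, 0.3), dim = c(12, 12, 12))
  gmv <- volumetric_map(gvol, "GMV", "s1")
  a1 <- volumetric_map(avol, "ALFF", "s1")
  a2 <- volumetric_map(3.7 * avol + 11, "ALFF", "s1")
  expect_equal(region_coupling(gmv, a1, atl)$kls,
               region_coupling(gmv, a2, atl)$kls, tolerance = 1e-9)
})

test_that("voxel ordering within regions never affects KLS", {
  set.seed(45)
  g <- rnorm(400); a <- rexp(400)
  k1 <- kls_from_samples(g, a, normalize = TRUE)$kls
  k2 <- kls_from_samples(sample(g), sample(a), normalize = TRUE)$kls
  expect_equal(k1, k2, tolerance = 1e-12)
})

test_that("whole-brain coupling is 1 for identical volumes and lies in (0,1]", {
  atl <- make_phantom_atlas(c(12, 12, 12), R = 4, seed = 46)
  set.seed(47)
  vol <- array(runif(12^3, 0.2, 0.9), dim = c(12, 12, 12))
  gmv <- volumetric_map(vol, "GMV", "s1")
  alff <- volumetric_map(vol, "ALFF", "s1")
  expect_equal(whole_brain_coupling(gmv, alff, atl), 1, tolerance = 1e-9)

  avol <- array(rnorm(12^3), dim = c(12, 12, 12))
  wb <- whole_brain_coupling(gmv, volumetric_map(avol, "ALFF", "s1"), atl)
  expect_true(wb > 0 && wb <= 1)
})

test_that("pooled whole-brain coupling tracks the per-region values", {
  # same distortion delta in every region: the pooled KLS should land
  # within the span of the regional values (KDE tolerance 0.05)
  atl <- make_phantom_atlas(c(14, 14, 14), R = 5, seed = 48)
  set.seed(49)
  gvol <- array(rnorm(14^3, 0.5, 0.1), dim = c(14, 14, 14))
  avol <- array(0, dim = c(14, 14, 14))
  for (r in 1:5) {
    idx <- which(atl$labels == r)
    avol[idx] <- klscoupling:::.alff_from_gmv(gvol[idx], delta = 0.5,
                                              noise_sd = 0)
  }
  gmv <- volumetric_map(gvol, "GMV", "s1")
  alff <- volumetric_map(avol, "ALFF", "s1")
  rc <- region_coupling(gmv, alff, atl)
  wb <- whole_brain_coupling(gmv, alff, atl)
  expect_gte(wb, min(rc$kls) - 0.05)
  expect_lte(wb, max(rc$kls) + 0.05)
  # averaging option equals the mean of the regional values
  cfg <- kls_config(whole_brain = "mean")
  expect_equal(whole_brain_coupling(gmv, alff, atl, cfg), mean(rc$kls),
               tolerance = 1e-12)
})

test_that("coupling_table assembles the cohort matrix in subject order", {
  ph <- tiny_phantom(R = 4, shape = c(12, 12, 12), seed = 51,
                     n_per_group = c(HC = 2, MDD_noanh = 2, MDD_anh = 2))
  ct <- coupling_table(ph$gmv, ph$alff, ph$atlas)
  expect_equal(dim(ct$kls), c(6, 4))
  expect_equal(ct$subject_ids, ph$records$subject_id)
  expect_true(all(ct$kls > 0 & ct$kls <= 1, na.rm = TRUE))
  df <- as.data.frame(ct)
  expect_equal(names(df), c("subject_id", ph$atlas$region_names,
                            "whole_brain"))
})

test_that("246-region atlas yields 246 coupling values", {
  atl <- make_phantom_atlas(c(32, 32, 32), R = 246, seed = 52,
                            min_voxels = 10)
  set.seed(53)
  vol <- array(rnorm(32^3, 0.5, 0.1), dim = c(32, 32, 32))
  gmv <- volumetric_map(vol, "GMV", "s1")
  alff <- volumetric_map(vol + rnorm(32^3, 0, 0.01), "ALFF", "s1")
  rc <- region_coupling(gmv, alff, atl)
  expect_equal(nrow(rc), 246)
  expect_true(all(is.finite(rc$kls)))
})
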