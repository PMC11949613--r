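#' Generate a phantom parcellation atlas
#'
#' Partitions the interior of a 3D grid (everything except a one-voxel
#' background shell) into `R` contiguous nonempty regions by a Voronoi
#' tessellation around `R` randomly placed seed voxels. Deterministic given
#' `seed`.
#'
#' @param shape Grid dimensions, length-3 integer (default `c(30, 30, 30)`).
#' @param R Number of regions (default 20).
#' @param seed Integer RNG seed.
#' @param min_voxels Minimum voxels any region must receive.
#' @return A `"parcellation_atlas"`.
#' @export
make_phantom_atlas <- function(shape = c(30, 30, 30), R = 20, seed = 1,
                               min_voxels = 10) {
  stopifnot(length(shape) == 3L, all(shape >= 5L), R >= 1L)
  interior <- prod(shape - 2L)
  if (R * min_voxels > interior)
    stop("R = ", R, " regions cannot each get ", min_voxels,
         " voxels on a ", paste(shape, collapse = "x"), " grid")
  set.seed(seed)
  coords <- as.matrix(expand.grid(x = 2:(shape[1] - 1L),
                                  y = 2:(shape[2] - 1L),
                                  z = 2:(shape[3] - 1L)))
  centers <- coords[sample(nrow(coords), R), , drop = FALSE]
  d2 <- sapply(seq_len(R), function(r)
    (coords[, 1] - centers[r, 1])^2 + (coords[, 2] - centers[r, 2])^2 +
      (coords[, 3] - centers[r, 3])^2)
  assign <- max.col(-d2, ties.method = "first")
  labels <- array(0L, dim = shape)
  labels[coords] <- assign
  counts <- tabulate(assign, nbins = R)
  if (any(counts < min_voxels))
    stop("region(s) smaller than min_voxels = ", min_voxels, ": ",
         paste(which(counts < min_voxels), collapse = ", "),
         "; use a larger grid or fewer regions")
  parcellation_atlas(labels)
}

#' Ground-truth divergence structure for a phantom cohort
#'
#' Holds the per-region, per-group divergence parameter delta that the
#' simulator uses: delta = 0 means the GMV and ALFF voxel distributions of
#' that region share the same shape (perfect coupling, expected KLS near 1);
#' growing delta injects skew and a bimodal component into the ALFF
#' distribution so the expected KLS decreases. The default affected pattern
#' `c(HC = 0, MDD_noanh = 0.8, MDD_anh = 1.6)` emulates a deficit present
#' in patients and further accentuated in the anhedonia subgroup.
#'
#' @param R Number of regions.
#' @param affected_regions Integer region ids carrying a group effect.
#' @param delta_pattern Named length-3 numeric: delta for HC, MDD_noanh,
#'   MDD_anh in the affected regions.
#' @param baseline_delta Delta shared by all groups in unaffected regions
#'   (default 0).
#' @return Object of class `"phantom_truth"`: `delta` (`R x 3` matrix,
#'   columns HC/MDD_noanh/MDD_anh), `affected_regions`, `R`.
#' @export
phantom_truth <- function(R = 20, affected_regions = integer(0),
                          delta_pattern = c(HC = 0, MDD_noanh = 0.8,
                                            MDD_anh = 1.6),
                          baseline_delta = 0) {
  stopifnot(all(affected_regions >= 1), all(affected_regions <= R),
            baseline_delta >= 0, all(delta_pattern >= 0))
  delta <- matrix(baseline_delta, nrow = R, ncol = 3,
                  dimnames = list(NULL, .group_levels))
  for (g in .group_levels)
    delta[affected_regions, g] <- delta_pattern[[g]]
  structure(list(delta = delta,
                 affected_regions = sort(unique(as.integer(affected_regions))),
                 R = R),
            class = "phantom_truth")
}

# Table-1-style generating parameters per group (HC, MDD_noanh, MDD_anh)
.covariate_params <- list(
  age       = list(mean = c(27.20, 30.73, 28.48), sd = c(6.40, 7.06, 6.99),
                   lo = 18, hi = 45),
  education = list(mean = c(15.07, 14.85, 13.97), sd = c(2.32, 2.18, 3.05),
                   lo = 6, hi = Inf),
  mFD       = list(mean = c(0.11, 0.10, 0.15), sd = c(0.05, 0.05, 0.12),
                   lo = 0.01, hi = Inf),
  TIV       = list(mean = c(1470, 1445, 1430), sd = c(110, 110, 110),
                   lo = 900, hi = Inf),
  SHAPS     = list(mean = c(20.0, 26.94, 38.14), sd = c(4.0, 5.03, 3.97),
                   lo = 14, hi = 56),
  HAMD      = list(mean = c(2.0, 24.27, 25.34), sd = c(1.5, 3.84, 3.24),
                   lo = 0, hi = 34)
)
.male_prob <- c(HC = 14 / 30, MDD_noanh = 9 / 33, MDD_anh = 6 / 29)

#' Simulate a cohort table with realistic covariates
#'
#' Draws demographics, motion, head-size and clinical scores from
#' group-specific normal distributions parameterized on published
#' three-group summaries (ages around 27-31 years, SHAPS elevated in the
#' anhedonia group, mFD slightly higher in that group, TIV mildly
#' correlated with group so covariate adjustment is genuinely exercised).
#' Clinical history columns (onset age, episode times, illness duration)
#' are `NA` for healthy controls.
#'
#' @param n_per_group Named integer vector `c(HC = , MDD_noanh = ,
#'   MDD_anh = )`; default the study-sized `c(30, 33, 29)`.
#' @param seed Integer RNG seed.
#' @return Cohort `data.frame` in [load_cohort()] layout.
#' @export
simulate_covariates <- function(n_per_group = c(HC = 30, MDD_noanh = 33,
                                                MDD_anh = 29),
                                seed = 1) {
  stopifnot(setequal(names(n_per_group), .group_levels))
  set.seed(seed)
  rows <- list()
  for (g in .group_levels) {
    n <- n_per_group[[g]]
    gi <- match(g, .group_levels)
    draw <- function(p) pmin(pmax(stats::rnorm(n, p$mean[gi], p$sd[gi]),
                                  p$lo), p$hi)
    r <- data.frame(group = g,
                    age = round(draw(.covariate_params$age), 1),
                    gender = stats::rbinom(n, 1, .male_prob[[g]]),
                    education = round(draw(.covariate_params$education), 1),
                    mFD = round(draw(.covariate_params$mFD), 3),
                    TIV = round(draw(.covariate_params$TIV), 1),
                    SHAPS = round(draw(.covariate_params$SHAPS), 0),
                    HAMD = round(draw(.covariate_params$HAMD), 0),
                    stringsAsFactors = FALSE)
    if (g == "HC") {
      r$onset_age <- NA_real_
      r$episode_times <- NA_real_
      r$illness_duration <- NA_real_
    } else {
      on_mean <- if (g == "MDD_noanh") 28.81 else 26.21
      on_sd <- if (g == "MDD_noanh") 7.82 else 6.75
      ep_mean <- if (g == "MDD_noanh") 1.47 else 1.67
      ep_sd <- if (g == "MDD_noanh") 0.63 else 1.07
      du_mean <- if (g == "MDD_noanh") 18.82 else 21.19
      du_sd <- if (g == "MDD_noanh") 23.30 else 20.61
      r$onset_age <- round(pmin(pmax(stats::rnorm(n, on_mean, on_sd), 18),
                                r$age), 1)
      r$episode_times <- pmax(round(stats::rnorm(n, ep_mean, ep_sd)), 1)
      r$illness_duration <- round(pmax(stats::rnorm(n, du_mean, du_sd), 1), 1)
    }
    rows[[g]] <- r
  }
  out <- do.call(rbind, rows)
  out <- data.frame(subject_id = sprintf("sub-%03d", seq_len(nrow(out))),
                    out, row.names = NULL, stringsAsFactors = FALSE)
  out$group <- .as_group(out$group)
  out
}

# derive one region's ALFF voxels from its GMV voxels: at delta = 0 the
# functional values are an affine map of the structural ones plus small
# measurement noise (tight coupling, KLS near 1); growing delta injects a
# skew term and a bimodal component that distort the distribution shape,
# so the expected KLS after min-max normalization decreases monotonically.
# The output is mapped back to the region's GMV location/scale so that the
# pooled (whole-brain) distributions also coincide at delta = 0.
.alff_from_gmv <- function(gmv_values, delta, noise_sd = 0.1) {
  n <- length(gmv_values)
  m <- mean(gmv_values)
  s <- stats::sd(gmv_values)
  z <- if (s > 0) (gmv_values - m) / s else numeric(n)
  y <- z + (delta / 4) * (z^2 - 1)
  flip <- stats::runif(n) < 0.15 * (1 - exp(-delta / 2))
  y[flip] <- y[flip] + 1.5
  y <- y + noise_sd * stats::rnorm(n)
  if (s > 0) m + s * y else m + y
}

#' Simulate a phantom cohort of GMV and ALFF maps
#'
#' For every subject and region, GMV voxels are drawn from a truncated
#' normal with region-specific mean and SD (plus a subject-level mean
#' shift), and ALFF voxels are derived voxel-wise from the region's GMV
#' values — an affine map plus small measurement noise when the subject's
#' group delta in `truth` is 0 (tight structure-function coupling), with a
#' skew-plus-bimodality shape distortion that grows with delta (and
#' subject-level jitter on delta). Expected regional KLS is near 1 at
#' delta = 0 and decreases monotonically as delta grows.
#'
#' @param atlas A `"parcellation_atlas"` (e.g. [make_phantom_atlas()]).
#' @param truth A `"phantom_truth"` with `truth$R == atlas$R`.
#' @param n_per_group Named group sizes, default `c(HC = 30, MDD_noanh = 33,
#'   MDD_anh = 29)`.
#' @param seed Integer RNG seed; all output is a pure function of
#'   (arguments, seed).
#' @param delta_jitter SD of the subject-level additive jitter on delta
#'   (default 0.05; truncated at 0).
#' @return List: `gmv` and `alff` (lists of `"volumetric_map"`), `records`
#'   (cohort `data.frame` from [simulate_covariates()]), `truth`.
#' @export
simulate_cohort <- function(atlas, truth,
                            n_per_group = c(HC = 30, MDD_noanh = 33,
                                            MDD_anh = 29),
                            seed = 1, delta_jitter = 0.05) {
  stopifnot(inherits(atlas, "parcellation_atlas"),
            inherits(truth, "phantom_truth"))
  if (truth$R != atlas$R)
    stop("truth has ", truth$R, " regions but atlas has ", atlas$R)
  records <- simulate_covariates(n_per_group, seed = seed)
  set.seed(seed + 104729L)  # separate stream for the maps
  region_mu <- stats::runif(atlas$R, 0.3, 0.7)
  region_sd <- stats::runif(atlas$R, 0.08, 0.15)
  region_idx <- lapply(seq_len(atlas$R),
                       function(r) which(atlas$labels == r))
  gmv_maps <- vector("list", nrow(records))
  alff_maps <- vector("list", nrow(records))
  for (i in seq_len(nrow(records))) {
    g <- as.character(records$group[i])
    gvol <- array(0, dim = dim(atlas$labels))
    avol <- array(0, dim = dim(atlas$labels))
    for (r in seq_len(atlas$R)) {
      idx <- region_idx[[r]]
      n_r <- length(idx)
      mu_s <- region_mu[r] + stats::rnorm(1, 0, 0.02)
      gvol[idx] <- pmax(stats::rnorm(n_r, mu_s, region_sd[r]), 0.01)
      delta_s <- max(0, truth$delta[r, g] + stats::rnorm(1, 0, delta_jitter))
      avol[idx] <- .alff_from_gmv(gvol[idx], delta_s)
    }
    gmv_maps[[i]] <- volumetric_map(gvol, "GMV", records$subject_id[i])
    alff_maps[[i]] <- volumetric_map(avol, "ALFF", records$subject_id[i])
  }
  list(gmv = gmv_maps, alff = alff_maps, records = records, truth = truth)
}

#' Simulate BOLD series with known in-band amplitude
#'
#' Each voxel's time course is a sinusoid of given amplitude at an on-bin
#' low-frequency band frequency, plus optional white noise and an optional
#' linear drift. For the noiseless part the ALFF is available in closed
#' form, enabling exact recovery checks.
#'
#' @param n_voxels Number of voxels (laid out on an `n x 1 x 1` grid).
#' @param T_len Number of time points (default 180).
#' @param tr Repetition time in seconds (default 2).
#' @param freqs Sinusoid frequency per voxel in Hz (recycled); should sit
#'   exactly on a DFT bin (`f * T_len * tr` integer) for the closed form to
#'   be exact.
#' @param amplitudes Sinusoid amplitude per voxel (recycled, >= 0).
#' @param noise_sd SD of additive white noise (default 0).
#' @param drift Linear drift total amplitude over the scan (default 0).
#' @param band Band used for the analytic ALFF (default 0.01-0.08 Hz).
#' @param seed Integer RNG seed (used for the noise).
#' @return List: `series` (a `"bold_series"`), `analytic_alff` (closed-form
#'   ALFF of the noiseless sinusoidal part per voxel), `freqs`,
#'   `amplitudes`.
#' @export
simulate_bold <- function(n_voxels, T_len = 180, tr = 2.0, freqs = 0.025,
                          amplitudes = 1, noise_sd = 0, drift = 0,
                          band = c(0.01, 0.08), seed = 1) {
  freqs <- rep_len(freqs, n_voxels)
  amplitudes <- rep_len(amplitudes, n_voxels)
  if (any(amplitudes < 0)) stop("amplitudes must be >= 0")
  if (any(freqs >= 1 / (2 * tr)))
    stop("frequency at or above the Nyquist limit ", 1 / (2 * tr), " Hz")
  set.seed(seed)
  t_idx <- seq_len(T_len)
  Y <- vapply(seq_len(n_voxels), function(v)
    amplitudes[v] * sin(2 * pi * freqs[v] * t_idx * tr), numeric(T_len))
  if (drift != 0) Y <- Y + drift * (t_idx / T_len)
  if (noise_sd > 0) Y <- Y + matrix(stats::rnorm(T_len * n_voxels,
                                                 sd = noise_sd),
                                    T_len, n_voxels)
  bins <- .band_bins(T_len, tr, band)
  n_b <- length(bins)
  bin_of <- round(freqs * T_len * tr)
  in_band <- bin_of %in% bins
  # an on-bin sinusoid of amplitude A has |DFT| = A*T/2 at its bin, so its
  # sqrt(power) contribution is sqrt(A^2 * T / 4) = A*sqrt(T)/2
  analytic <- ifelse(in_band, amplitudes * sqrt(T_len) / 2 / n_b, 0)
  list(series = bold_series(array(t(Y), dim = c(n_voxels, 1L, 1L, T_len)),
                            tr = tr, subject_id = "phantom"),
       analytic_alff = analytic, freqs = freqs, amplitudes = amplitudes)
}
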