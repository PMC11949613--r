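#' Estimate a discrete probability distribution from a sample
#'
#' Gaussian-kernel density estimate evaluated exactly (no binning) on a
#' uniform grid; discrete probabilities are density times grid spacing,
#' floored at `epsilon` and renormalized to sum to one. A zero-variance
#' sample is represented as a point mass on its nearest grid cell instead
#' of a KDE failure.
#'
#' @param values Numeric sample (regional voxel values), length >= 2.
#' @param grid Optional explicit uniform evaluation grid. If `NULL`, a grid
#'   of `grid_points` points spanning `range(values) +/- 3h` is built.
#' @param grid_points Number of grid points when `grid` is `NULL`.
#' @param bandwidth Kernel bandwidth; `NULL` uses Silverman's rule-of-thumb
#'   ([stats::bw.nrd0()]).
#' @param epsilon Probability floor.
#' @return An object of class `"discrete_pdf"`: list with `support` (grid),
#'   `prob` (probabilities summing to 1) and `bandwidth`.
#' @export
estimate_pdf <- function(values, grid = NULL, grid_points = 100,
                         bandwidth = NULL, epsilon = 1e-12) {
  values <- as.numeric(values)
  if (length(values) < 2L) stop("need at least 2 values for a PDF estimate")
  if (any(!is.finite(values))) stop("sample contains non-finite values")
  degenerate <- stats::sd(values) == 0
  h <- bandwidth
  if (is.null(h)) h <- if (degenerate) 0 else stats::bw.nrd0(values)
  if (is.null(grid)) {
    if (degenerate) {
      grid <- seq(values[1] - 0.5, values[1] + 0.5,
                  length.out = grid_points)
    } else {
      grid <- seq(min(values) - 3 * h, max(values) + 3 * h,
                  length.out = grid_points)
    }
  }
  n <- length(grid)
  if (n < 2L) stop("grid must have at least 2 points")
  dg <- grid[2] - grid[1]
  if (degenerate || h == 0) {
    prob <- numeric(n)
    prob[which.min(abs(grid - values[1]))] <- 1
  } else {
    dens <- rowMeans(stats::dnorm(outer(grid, values, "-") / h)) / h
    prob <- dens * dg
  }
  prob <- pmax(prob, epsilon)
  prob <- prob / sum(prob)
  structure(list(support = grid, prob = prob, bandwidth = h),
            class = "discrete_pdf")
}

#' Symmetric Kullback-Leibler divergence between two discrete PDFs
#'
#' `D(P, Q) = sum_i [P_i ln(P_i/Q_i) + Q_i ln(Q_i/P_i)]` in nats
#' (`divergence = "symmetric"`, the default), or the one-directional
#' `sum_i P_i ln(P_i/Q_i)` (`"asymmetric"`). Both PDFs must live on the
#' same support grid and be epsilon-floored (as [estimate_pdf()] output is).
#'
#' @param P,Q `"discrete_pdf"` objects on a common grid.
#' @param divergence `"symmetric"` or `"asymmetric"`.
#' @return Divergence in nats (non-negative scalar).
#' @export
sym_kl <- function(P, Q, divergence = c("symmetric", "asymmetric")) {
  divergence <- match.arg(divergence)
  stopifnot(inherits(P, "discrete_pdf"), inherits(Q, "discrete_pdf"))
  if (length(P$support) != length(Q$support) ||
      max(abs(P$support - Q$support)) > 1e-9 * max(1, abs(P$support)))
    stop("P and Q must share the same support grid")
  if (any(P$prob <= 0) || any(Q$prob <= 0))
    stop("probabilities must be strictly positive (epsilon-floored)")
  d <- sum(P$prob * log(P$prob / Q$prob))
  if (divergence == "symmetric")
    d <- d + sum(Q$prob * log(Q$prob / P$prob))
  max(d, 0)
}

# min-max normalization to [0, 1]; a constant sample maps to 0.5
.minmax <- function(x) {
  r <- range(x)
  if (r[2] > r[1]) (x - r[1]) / (r[2] - r[1]) else rep(0.5, length(x))
}

#' KLS coupling of two voxel-value samples
#'
#' Estimates the two distributions on a shared uniform grid spanning the
#' pooled sample range extended by three bandwidths (bandwidth per sample by
#' Silverman's rule; the grid uses the larger of the two), computes the
#' symmetric KL divergence `D`, and returns the similarity
#' `KLS = exp(-D)` in `(0, 1]` — 1 for identical distributions, toward 0
#' the more the distribution shapes diverge.
#'
#' @param gmv_values,alff_values Numeric samples from the same region's
#'   voxels (one per modality).
#' @param config A [kls_config()].
#' @param normalize If `TRUE`, each sample is min-max normalized to
#'   `[0, 1]` before estimation (the regional pipeline does this so KLS
#'   compares distribution *shape*, invariant to each modality's scale).
#'   Default `FALSE`: raw values on the pooled grid.
#' @return List of class `"coupling_value"`: `d_kl` (nats), `kls`,
#'   `n_gmv`, `n_alff`, `flagged` (TRUE when a sample is below
#'   `config$min_voxels`, in which case `d_kl`/`kls` are `NA`).
#' @export
kls_from_samples <- function(gmv_values, alff_values,
                             config = kls_config(), normalize = FALSE) {
  gmv_values <- as.numeric(gmv_values)
  alff_values <- as.numeric(alff_values)
  n_g <- length(gmv_values); n_a <- length(alff_values)
  if (n_g < config$min_voxels || n_a < config$min_voxels) {
    return(structure(list(d_kl = NA_real_, kls = NA_real_, n_gmv = n_g,
                          n_alff = n_a, flagged = TRUE),
                     class = "coupling_value"))
  }
  if (normalize) {
    gmv_values <- .minmax(gmv_values)
    alff_values <- .minmax(alff_values)
  }
  h_g <- config$bandwidth %||%
    (if (stats::sd(gmv_values) > 0) stats::bw.nrd0(gmv_values) else 0)
  h_a <- config$bandwidth %||%
    (if (stats::sd(alff_values) > 0) stats::bw.nrd0(alff_values) else 0)
  h <- max(h_g, h_a, 1e-8)
  lo <- min(gmv_values, alff_values) - 3 * h
  hi <- max(gmv_values, alff_values) + 3 * h
  grid <- seq(lo, hi, length.out = config$kde_grid_points)
  P <- estimate_pdf(gmv_values, grid = grid, bandwidth = h_g,
                    epsilon = config$epsilon)
  Q <- estimate_pdf(alff_values, grid = grid, bandwidth = h_a,
                    epsilon = config$epsilon)
  d <- sym_kl(P, Q, divergence = config$divergence)
  structure(list(d_kl = d, kls = exp(-d), n_gmv = n_g, n_alff = n_a,
                 flagged = FALSE),
            class = "coupling_value")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.check_grids <- function(gmv, alff, atlas) {
  if (!all(dim(gmv$data) == dim(atlas$labels)) ||
      !all(dim(alff$data) == dim(atlas$labels)))
    stop("GMV, ALFF and atlas grids differ: ",
         paste(dim(gmv$data), collapse = "x"), " vs ",
         paste(dim(alff$data), collapse = "x"), " vs ",
         paste(dim(atlas$labels), collapse = "x"))
  if (max(abs(gmv$affine - alff$affine)) > 1e-4)
    stop("GMV and ALFF affines differ by more than 1e-4")
}

#' Regional structure-function coupling for one subject
#'
#' For every atlas region: extract the GMV and ALFF values of its voxels,
#' min-max normalize each modality (so KLS measures distribution shape,
#' invariant to positive affine rescaling of either map), estimate both
#' PDFs on a common grid, and return the KLS similarity. Background voxels
#' (label 0) are ignored; regions below `config$min_voxels` yield `NA` with
#' a warning.
#'
#' @param gmv,alff `"volumetric_map"` objects on the atlas grid.
#' @param atlas A `"parcellation_atlas"`.
#' @param config A [kls_config()].
#' @return `data.frame` with one row per region: `region_id`, `region_name`,
#'   `n_voxels`, `d_kl`, `kls`.
#' @export
region_coupling <- function(gmv, alff, atlas, config = kls_config()) {
  .check_grids(gmv, alff, atlas)
  lab <- as.integer(atlas$labels)
  gv <- as.numeric(gmv$data)
  av <- as.numeric(alff$data)
  out <- data.frame(region_id = seq_len(atlas$R),
                    region_name = atlas$region_names,
                    n_voxels = NA_integer_, d_kl = NA_real_,
                    kls = NA_real_, stringsAsFactors = FALSE)
  for (r in seq_len(atlas$R)) {
    idx <- lab == r
    out$n_voxels[r] <- sum(idx)
    cv <- kls_from_samples(gv[idx], av[idx], config, normalize = TRUE)
    if (cv$flagged) {
      warning("region ", r, " (", atlas$region_names[r], ") has ",
              out$n_voxels[r], " voxels < min_voxels = ",
              config$min_voxels, "; coupling set missing", call. = FALSE)
    } else {
      out$d_kl[r] <- cv$d_kl
      out$kls[r] <- cv$kls
    }
  }
  out
}

#' Whole-brain structure-function coupling for one subject
#'
#' The overall GMV-ALFF distribution similarity across the entire brain,
#' used downstream as a per-subject covariate. By default computed on the
#' pooled voxel set of all labeled regions (same normalization and KDE
#' settings as [region_coupling()]); `config$whole_brain = "mean"` averages
#' the regional KLS values instead.
#'
#' @inheritParams region_coupling
#' @return Scalar KLS in `(0, 1]`.
#' @export
whole_brain_coupling <- function(gmv, alff, atlas, config = kls_config()) {
  .check_grids(gmv, alff, atlas)
  if (config$whole_brain == "mean") {
    rc <- region_coupling(gmv, alff, atlas, config)
    return(mean(rc$kls, na.rm = TRUE))
  }
  idx <- atlas$labels > 0L
  cv <- kls_from_samples(gmv$data[idx], alff$data[idx], config,
                         normalize = TRUE)
  if (cv$flagged) stop("fewer than min_voxels labeled voxels in the atlas")
  cv$kls
}

#' Regional coupling table for a cohort
#'
#' Runs [region_coupling()] and [whole_brain_coupling()] for every subject
#' and assembles the subjects x regions KLS matrix plus the per-subject
#' whole-brain coupling covariate.
#'
#' @param gmv_maps,alff_maps Lists of `"volumetric_map"` objects, one per
#'   subject, in matching order.
#' @param atlas A `"parcellation_atlas"`.
#' @param config A [kls_config()].
#' @return An object of class `"coupling_table"`: list with `kls`
#'   (`n x R` matrix, dimnames subject x region), `whole_brain` (length-n
#'   vector), `subject_ids`, `region_names`.
#' @export
coupling_table <- function(gmv_maps, alff_maps, atlas,
                           config = kls_config()) {
  stopifnot(length(gmv_maps) == length(alff_maps),
            length(gmv_maps) >= 1L)
  n <- length(gmv_maps)
  ids <- vapply(gmv_maps, function(m) m$subject_id, character(1))
  kls <- matrix(NA_real_, n, atlas$R,
                dimnames = list(ids, atlas$region_names))
  wb <- numeric(n)
  for (i in seq_len(n)) {
    if (gmv_maps[[i]]$subject_id != alff_maps[[i]]$subject_id)
      stop("subject order mismatch at position ", i, ": ",
           gmv_maps[[i]]$subject_id, " vs ", alff_maps[[i]]$subject_id)
    rc <- region_coupling(gmv_maps[[i]], alff_maps[[i]], atlas, config)
    kls[i, ] <- rc$kls
    wb[i] <- whole_brain_coupling(gmv_maps[[i]], alff_maps[[i]], atlas,
                                  config)
  }
  structure(list(kls = kls, whole_brain = wb, subject_ids = ids,
                 region_names = atlas$region_names),
            class = "coupling_table")
}

#' @export
print.coupling_table <- function(x, ...) {
  cat(sprintf("<coupling_table> %d subjects x %d regions; whole-brain KLS %.3f-%.3f\n",
              nrow(x$kls), ncol(x$kls), min(x$whole_brain),
              max(x$whole_brain)))
  invisible(x)
}

#' @export
as.data.frame.coupling_table <- function(x, ...) {
  data.frame(subject_id = x$subject_ids, x$kls,
             whole_brain = x$whole_brain,
             row.names = NULL, check.names = FALSE,
             stringsAsFactors = FALSE)
}
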