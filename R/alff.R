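#' Construct a BOLD series
#'
#' @param data 4D numeric array `(x, y, z, T)` of BOLD signal, or a `T x V`
#'   matrix (treated as V voxels on a `V x 1 x 1` grid).
#' @param tr Repetition time in seconds.
#' @param subject_id Subject identifier.
#' @return An object of class `"bold_series"`.
#' @export
bold_series <- function(data, tr, subject_id = "subject") {
  if (is.matrix(data)) {
    # T x V matrix convenience form
    data <- array(t(data), dim = c(ncol(data), 1L, 1L, nrow(data)))
  }
  if (length(dim(data)) != 4L)
    stop("BOLD data must be 4D (x, y, z, T)")
  T_len <- dim(data)[4]
  if (T_len < 16L) stop("time series too short: T = ", T_len, " < 16")
  if (tr <= 0) stop("tr must be positive")
  if (any(!is.finite(data))) stop("BOLD data contains non-finite values")
  structure(list(data = data, tr = tr, subject_id = subject_id),
            class = "bold_series")
}

# internal: T x V matrix view of the series
.bold_matrix <- function(series) {
  d <- dim(series$data)
  t(matrix(series$data, nrow = prod(d[1:3]), ncol = d[4]))
}

.bold_from_matrix <- function(series, Y) {
  d <- dim(series$data)
  out <- series
  out$data <- array(t(Y), dim = d)
  out
}

# DFT bin frequencies retained for a band: k/(T*tr), k = 1..floor(T/2),
# half-open [low, high) tie-breaking at the upper edge
.band_bins <- function(T_len, tr, band) {
  k <- seq_len(floor(T_len / 2))
  f <- k / (T_len * tr)
  k[f >= band[1] & f < band[2]]
}

.check_band <- function(band, tr) {
  nyquist <- 1 / (2 * tr)
  if (length(band) != 2L || band[1] <= 0 || band[1] >= band[2])
    stop("band must be c(low, high) with 0 < low < high")
  if (band[2] > nyquist + 1e-12)
    stop(sprintf("band upper edge %.4g Hz exceeds the Nyquist frequency %.4g Hz for tr = %g s",
                 band[2], nyquist, tr))
}

#' Regress nuisance signals out of a BOLD series
#'
#' Replaces every voxel's time course by its least-squares residual against
#' an intercept plus the supplied confound columns (e.g. 24 head-motion
#' parameters and the white-matter and CSF mean signals). Residuals are
#' orthogonal to every confound column.
#'
#' @param series A `"bold_series"`.
#' @param confounds `T x C` numeric matrix of nuisance regressors, or `NULL`
#'   for intercept-only regression (demeaning).
#' @return A `"bold_series"` of residuals.
#' @export
regress_nuisance <- function(series, confounds = NULL) {
  Y <- .bold_matrix(series)
  T_len <- nrow(Y)
  if (is.null(confounds)) {
    X <- matrix(1, T_len, 1L)
    colnames(X) <- "intercept"
  } else {
    confounds <- as.matrix(confounds)
    if (nrow(confounds) != T_len)
      stop("confounds have ", nrow(confounds), " rows but series has T = ",
           T_len)
    if (is.null(colnames(confounds)))
      colnames(confounds) <- paste0("confound_", seq_len(ncol(confounds)))
    X <- cbind(intercept = 1, confounds)
  }
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    dropped <- colnames(X)[qx$pivot[(qx$rank + 1L):ncol(X)]]
    stop("nuisance design is rank deficient; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }
  .bold_from_matrix(series, qr.resid(qx, Y))
}

#' Ideal band-pass filter a BOLD series
#'
#' Removes the linear trend of each voxel's time course (unless
#' `detrend = FALSE`) and zeroes every Fourier coefficient whose frequency
#' lies outside the band (rectangular filter in the DFT domain; bins
#' retained for `low <= f < high`). Note that a linear trend is not
#' band-limited, so detrending a signal and then masking its spectrum are
#' not exactly interchangeable; with `detrend = FALSE` an on-bin passband
#' sinusoid passes through unchanged to machine precision.
#'
#' @param series A `"bold_series"`.
#' @param band `c(low, high)` in Hz; `high` must not exceed the Nyquist
#'   frequency `1/(2*tr)`.
#' @param detrend Remove each voxel's linear trend before filtering
#'   (default `TRUE`).
#' @return A filtered `"bold_series"` (real-valued).
#' @export
bandpass <- function(series, band = c(0.01, 0.08), detrend = TRUE) {
  .check_band(band, series$tr)
  Y <- .bold_matrix(series)
  T_len <- nrow(Y)
  if (detrend)
    Y <- qr.resid(qr(cbind(1, seq_len(T_len))), Y)
  F <- stats::mvfft(Y)
  k <- 0:(T_len - 1)
  f <- pmin(k, T_len - k) / (T_len * series$tr)  # folded frequency per bin
  keep <- f >= band[1] & f < band[2]
  F[!keep, ] <- 0
  .bold_from_matrix(series, Re(stats::mvfft(F, inverse = TRUE)) / T_len)
}

#' Compute a voxel-wise ALFF map
#'
#' Converts each voxel's (preprocessed) time course to the frequency domain
#' with an FFT, takes the square root of the power spectrum
#' (`|X_k|^2 / T`), and averages it over the DFT bins falling in the
#' low-frequency band. The averaged square root is the ALFF value of the
#' voxel.
#'
#' @param series A `"bold_series"`, already nuisance-regressed/detrended.
#' @param band `c(low, high)` in Hz (default 0.01-0.08).
#' @param malff If `TRUE`, divide the map by its global (nonzero-voxel) mean
#'   (standardized mALFF); default `FALSE`, raw ALFF.
#' @return A `"volumetric_map"` with `modality = "ALFF"`.
#' @export
compute_alff <- function(series, band = c(0.01, 0.08), malff = FALSE) {
  .check_band(band, series$tr)
  Y <- .bold_matrix(series)
  T_len <- nrow(Y)
  bins <- .band_bins(T_len, series$tr, band)
  if (length(bins) == 0L) {
    min_T <- ceiling(1 / (band[1] * series$tr)) + 1
    stop(sprintf("no DFT bin falls in [%.3g, %.3g) Hz for T = %d, tr = %g s; need T >= %d",
                 band[1], band[2], T_len, series$tr, min_T))
  }
  F <- stats::mvfft(Y)
  sqrt_power <- sqrt(Mod(F[bins, , drop = FALSE])^2 / T_len)
  alff <- colMeans(sqrt_power)
  if (malff) {
    m <- mean(alff[alff > 0])
    if (is.finite(m) && m > 0) alff <- alff / m
  }
  d <- dim(series$data)[1:3]
  volumetric_map(array(alff, dim = d), modality = "ALFF",
                 subject_id = series$subject_id)
}

#' Head-motion screening report
#'
#' Applies the cohort exclusion thresholds (maximum translation, maximum
#' rotation, mean framewise displacement) and reports which subjects exceed
#' them. Nothing is dropped silently: the return value is a per-subject
#' flag table.
#'
#' @param records Cohort `data.frame` with an `mFD` column; optional columns
#'   `max_translation` (mm) and `max_rotation` (degrees) are checked when
#'   present.
#' @param trans_thresh Maximum allowed translation in mm (default 2.5).
#' @param rot_thresh Maximum allowed rotation in degrees (default 2.5).
#' @param mfd_thresh Maximum allowed mean framewise displacement (default 0.5).
#' @return `data.frame` with `subject_id`, the checked values, per-criterion
#'   logical flags and an overall `exclude` column.
#' @export
screen_motion <- function(records, trans_thresh = 2.5, rot_thresh = 2.5,
                          mfd_thresh = 0.5) {
  out <- data.frame(subject_id = records$subject_id,
                    mFD = records$mFD,
                    flag_mFD = records$mFD > mfd_thresh,
                    stringsAsFactors = FALSE)
  out$flag_translation <- if ("max_translation" %in% names(records))
    records$max_translation > trans_thresh else FALSE
  out$flag_rotation <- if ("max_rotation" %in% names(records))
    records$max_rotation > rot_thresh else FALSE
  out$exclude <- out$flag_mFD | out$flag_translation | out$flag_rotation
  out
}
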