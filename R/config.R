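#' Analysis configuration
#'
#' Collects the tunable parameters of the coupling pipeline in one validated
#' object. Defaults correspond to the standard analysis: 100-point KDE grid,
#' Silverman bandwidth, symmetric KL divergence, probability floor 1e-12,
#' regions with fewer than 10 voxels flagged as missing, 0.01-0.08 Hz band.
#'
#' @param band Low-frequency band in Hz, length-2 numeric `c(low, high)`.
#' @param tr Repetition time of the BOLD acquisition in seconds.
#' @param kde_grid_points Number of points of the common KDE evaluation grid.
#' @param epsilon Probability floor applied before taking log ratios.
#' @param min_voxels Minimum voxels a region must have; smaller regions yield
#'   a missing coupling value rather than an unstable KDE.
#' @param bandwidth Optional fixed KDE bandwidth; `NULL` (default) uses
#'   Silverman's rule-of-thumb per sample ([stats::bw.nrd0()]).
#' @param divergence `"symmetric"` (default) or `"asymmetric"` KL divergence.
#' @param whole_brain `"pooled"` (default): whole-brain coupling from the
#'   pooled voxel set of all labeled regions; `"mean"`: average of regional
#'   KLS values.
#' @param fdr_alpha Significance level applied to FDR-adjusted p-values.
#' @param covariates Character vector of covariate columns used by the
#'   ANCOVA stage (whole-brain coupling is always appended by the callers
#'   that have it).
#' @param seed Optional integer seed echoed into run manifests.
#'
#' @return A list of class `"kls_config"`.
#' @export
#' @examples
#' cfg <- kls_config(kde_grid_points = 50)
#' cfg$band
kls_config <- function(band = c(0.01, 0.08),
                       tr = 2.0,
                       kde_grid_points = 100,
                       epsilon = 1e-12,
                       min_voxels = 10,
                       bandwidth = NULL,
                       divergence = c("symmetric", "asymmetric"),
                       whole_brain = c("pooled", "mean"),
                       fdr_alpha = 0.05,
                       covariates = c("age", "gender", "education",
                                      "mFD", "TIV"),
                       seed = NULL) {
  divergence <- match.arg(divergence)
  whole_brain <- match.arg(whole_brain)
  stopifnot(length(band) == 2L, band[1] > 0, band[1] < band[2],
            tr > 0, kde_grid_points >= 10, epsilon > 0, epsilon < 1e-3,
            min_voxels >= 2, fdr_alpha > 0, fdr_alpha < 1)
  if (!is.null(bandwidth) && bandwidth <= 0)
    stop("'bandwidth' must be positive or NULL")
  structure(list(band = as.numeric(band), tr = tr,
                 kde_grid_points = as.integer(kde_grid_points),
                 epsilon = epsilon, min_voxels = as.integer(min_voxels),
                 bandwidth = bandwidth, divergence = divergence,
                 whole_brain = whole_brain, fdr_alpha = fdr_alpha,
                 covariates = covariates, seed = seed),
            class = "kls_config")
}

#' Read a JSON configuration file
#'
#' Reads a JSON object whose keys are arguments of [kls_config()]; keys not
#' present keep their defaults, unknown keys are an error.
#'
#' @param path Path to a JSON file.
#' @return A `"kls_config"` object.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(kls_config))
  bad <- setdiff(names(raw), known)
  if (length(bad))
    stop("unknown config keys: ", paste(bad, collapse = ", "))
  do.call(kls_config, raw)
}

# shared internal group coding: factor with HC as reference level
.group_levels <- c("HC", "MDD_noanh", "MDD_anh")

.as_group <- function(x) {
  x <- as.character(x)
  bad <- setdiff(unique(x), .group_levels)
  if (length(bad))
    stop("unknown group label(s): ", paste(bad, collapse = ", "),
         " (expected ", paste(.group_levels, collapse = ", "), ")")
  factor(x, levels = .group_levels)
}
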