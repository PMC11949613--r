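#' Construct a volumetric map
#'
#' A volumetric map is one subject's 3D scalar image — either a modulated
#' gray matter volume (GMV) map or an ALFF map — together with its
#' voxel-to-world affine.
#'
#' @param data 3D numeric array of voxel values; all finite.
#' @param modality `"GMV"` or `"ALFF"`.
#' @param subject_id Subject identifier string.
#' @param affine 4x4 voxel-to-world transform (default: identity spacing).
#' @return An object of class `"volumetric_map"`.
#' @export
volumetric_map <- function(data, modality = c("GMV", "ALFF"),
                           subject_id = "subject", affine = diag(4)) {
  modality <- match.arg(modality)
  if (length(dim(data)) != 3L)
    stop("volumetric map must be 3D, got ", length(dim(data)), "D")
  n_bad <- sum(!is.finite(data))
  if (n_bad > 0)
    stop("volume contains ", n_bad, " non-finite voxel value(s)")
  if (!all(dim(affine) == c(4L, 4L)) || abs(det(affine)) < 1e-12)
    stop("affine must be an invertible 4x4 matrix")
  structure(list(data = data, affine = affine, subject_id = subject_id,
                 modality = modality),
            class = "volumetric_map")
}

#' @export
print.volumetric_map <- function(x, ...) {
  cat(sprintf("<volumetric_map> %s [%s] %s voxels, range [%.4g, %.4g]\n",
              x$subject_id, x$modality, paste(dim(x$data), collapse = "x"),
              min(x$data), max(x$data)))
  invisible(x)
}

#' Construct a parcellation atlas
#'
#' @param labels 3D integer array; 0 is background, regions are labeled
#'   1..R with no gaps and every region occupying at least one voxel.
#' @param region_names Optional character vector of R names; defaults to
#'   `region_1` .. `region_R`.
#' @return An object of class `"parcellation_atlas"` with fields `labels`,
#'   `region_names` and `R`.
#' @export
parcellation_atlas <- function(labels, region_names = NULL) {
  if (length(dim(labels)) != 3L) stop("atlas labels must be 3D")
  if (any(!is.finite(labels)) || any(labels != round(labels)))
    stop("atlas contains non-integer voxel values")
  labels <- array(as.integer(round(labels)), dim = dim(labels))
  if (any(labels < 0L)) stop("atlas labels must be non-negative")
  R <- max(labels)
  if (R < 1L) stop("atlas has no labeled regions")
  present <- sort(unique(labels[labels > 0L]))
  missing <- setdiff(seq_len(R), present)
  if (length(missing))
    stop("atlas label(s) with zero voxels: ",
         paste(missing, collapse = ", "))
  if (is.null(region_names)) {
    region_names <- paste0("region_", seq_len(R))
  } else if (length(region_names) != R) {
    stop("region_names has length ", length(region_names),
         " but atlas has ", R, " regions")
  }
  structure(list(labels = labels, region_names = as.character(region_names),
                 R = R),
            class = "parcellation_atlas")
}

#' @export
print.parcellation_atlas <- function(x, ...) {
  cat(sprintf("<parcellation_atlas> %d regions on a %s grid (%d labeled voxels)\n",
              x$R, paste(dim(x$labels), collapse = "x"), sum(x$labels > 0)))
  invisible(x)
}

#' Load a NIfTI volume as a volumetric map
#'
#' @param path Path to a 3D NIfTI-1 file (`.nii` / `.nii.gz`).
#' @param modality `"GMV"` or `"ALFF"`.
#' @param subject_id Subject identifier; defaults to the file stem.
#' @param na_action `"error"` (default) rejects volumes containing NaN/NA,
#'   reporting how many voxels are affected; `"zero"` replaces them with 0.
#' @return A `"volumetric_map"`.
#' @export
load_volume <- function(path, modality = c("GMV", "ALFF"),
                        subject_id = NULL, na_action = c("error", "zero")) {
  modality <- match.arg(modality)
  na_action <- match.arg(na_action)
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) == 4L && d[4] == 1L) {
    img <- img[, , , 1L]
    d <- dim(img)
  }
  if (length(d) != 3L)
    stop("expected a 3D volume, got ", length(d), "D: ", path)
  data <- array(as.numeric(img), dim = d)
  n_bad <- sum(!is.finite(data))
  if (n_bad > 0) {
    if (na_action == "error")
      stop("volume has ", n_bad, " non-finite voxel(s): ", path)
    data[!is.finite(data)] <- 0
  }
  if (is.null(subject_id))
    subject_id <- sub("\\.nii(\\.gz)?$", "", basename(path))
  volumetric_map(data, modality, subject_id,
                 affine = unclass(RNifti::xform(img)))
}

#' Write a volumetric map or atlas to NIfTI
#'
#' @param x A `"volumetric_map"` or `"parcellation_atlas"`.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(x, path) {
  data <- if (inherits(x, "parcellation_atlas")) x$labels else x$data
  RNifti::writeNifti(RNifti::asNifti(data), path)
  invisible(path)
}

#' Load a parcellation atlas from NIfTI
#'
#' @param path Path to an integer-valued NIfTI volume.
#' @param names_path Optional TSV with columns `label` and `name`, one row
#'   per region label; absent labels default to `region_k`.
#' @return A `"parcellation_atlas"`.
#' @export
load_atlas <- function(path, names_path = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L) stop("atlas must be a 3D volume: ", path)
  vals <- array(as.numeric(img), dim = dim(img))
  if (any(abs(vals - round(vals)) > 1e-6))
    stop("atlas contains non-integer voxel values: ", path)
  region_names <- NULL
  if (!is.null(names_path)) {
    tab <- utils::read.delim(names_path, stringsAsFactors = FALSE)
    if (!all(c("label", "name") %in% names(tab)))
      stop("names table must have columns 'label' and 'name'")
    R <- max(round(vals))
    region_names <- paste0("region_", seq_len(R))
    keep <- tab$label >= 1 & tab$label <= R
    region_names[tab$label[keep]] <- tab$name[keep]
  }
  parcellation_atlas(round(vals), region_names)
}

# required cohort columns and their types; clinical history columns may be
# NA for healthy controls
.cohort_required <- c("subject_id", "group", "age", "gender", "education",
                      "mFD", "TIV", "SHAPS", "HAMD")
.cohort_optional <- c("onset_age", "episode_times", "illness_duration")

#' Load a cohort table
#'
#' Reads a TSV of subject records: identifiers, group membership
#' (`HC`, `MDD_noanh`, `MDD_anh`), the ANCOVA covariates (age, gender coded
#' 0 = female / 1 = male, education years, mean framewise displacement,
#' total intracranial volume) and clinical scores (SHAPS, HAMD, plus
#' optional onset age / episode times / illness duration, which may be
#' missing for healthy controls).
#'
#' @param path Path to a tab-separated table with a header row.
#' @return A `data.frame` with one row per subject; `group` is a factor with
#'   levels `HC`, `MDD_noanh`, `MDD_anh`.
#' @export
load_cohort <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(.cohort_required, names(tab))
  if (length(missing_cols))
    stop("cohort table missing column(s): ",
         paste(missing_cols, collapse = ", "))
  tab$group <- .as_group(tab$group)
  validate_cohort(tab)
  for (col in setdiff(.cohort_optional, names(tab))) tab[[col]] <- NA_real_
  tab
}

#' Validate a cohort table
#'
#' Checks the record invariants: no missing values among the ANCOVA
#' covariates, mFD >= 0, TIV > 0, gender coded 0/1. Errors name the
#' offending subject and column.
#'
#' @param records Cohort `data.frame` (see [load_cohort()]).
#' @return `records`, invisibly.
#' @export
validate_cohort <- function(records) {
  covs <- c("age", "gender", "education", "mFD", "TIV")
  for (col in covs) {
    bad <- which(!is.finite(as.numeric(records[[col]])))
    if (length(bad))
      stop("missing covariate '", col, "' for subject(s): ",
           paste(records$subject_id[bad], collapse = ", "))
  }
  if (any(records$mFD < 0)) stop("mFD must be >= 0")
  if (any(records$TIV <= 0)) stop("TIV must be > 0")
  if (!all(records$gender %in% c(0, 1)))
    stop("gender must be coded 0 (female) / 1 (male)")
  if (anyDuplicated(records$subject_id))
    stop("duplicated subject_id values")
  invisible(records)
}

#' Write result tables plus a run manifest
#'
#' Writes each named table as a TSV (deterministic column order, fixed
#' 15-significant-digit formatting so reruns are byte-identical) and a JSON
#' manifest recording the files, the configuration echo and package version.
#'
#' @param tables Named list of data frames (possibly empty).
#' @param out_dir Output directory, created if needed.
#' @param config Optional `"kls_config"` echoed into the manifest.
#' @return Manifest list, invisibly; written to `manifest.json`.
#' @export
write_results <- function(tables = list(), out_dir, config = NULL) {
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", out_dir)
  stopifnot(is.list(tables))
  if (length(tables) && is.null(names(tables)))
    stop("'tables' must be a named list")
  files <- character(0)
  for (nm in names(tables)) {
    tab <- as.data.frame(tables[[nm]])
    num <- vapply(tab, is.numeric, logical(1))
    tab[num] <- lapply(tab[num], function(x) sprintf("%.15g", x))
    f <- file.path(out_dir, paste0(nm, ".tsv"))
    utils::write.table(tab, f, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    files <- c(files, basename(f))
  }
  manifest <- list(
    tables = as.list(files),
    n_tables = length(files),
    config = if (is.null(config)) NULL else unclass(config),
    package_version = as.character(utils::packageVersion("klscoupling"))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, null = "null", pretty = TRUE)
  invisible(manifest)
}
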