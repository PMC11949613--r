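#' ANCOVA on one region's coupling values
#'
#' Fits `kls ~ group + covariates` by least squares and tests the 2-df group
#' factor with the full-versus-reduced model F test (equivalent to the
#' Type III group test in this main-effects-only design). Effect size is
#' partial eta squared, `SS_group / (SS_group + SS_residual)`. Subjects with
#' a missing coupling value are excluded with a message.
#'
#' @param kls_values Per-subject KLS values for one region.
#' @param records Cohort `data.frame` ([load_cohort()] layout) in matching
#'   subject order.
#' @param whole_brain Optional per-subject whole-brain coupling covariate.
#' @param covariates Character vector of covariate columns in `records`
#'   (default the standard five: age, gender, education, mFD, TIV);
#'   `NULL` for an unadjusted one-way ANOVA.
#' @return One-row `data.frame`: `F`, `df1`, `df2`, `p`, `eta_sq_partial`,
#'   `n_used`.
#' @export
ancova_region <- function(kls_values, records, whole_brain = NULL,
                          covariates = c("age", "gender", "education",
                                         "mFD", "TIV")) {
  stopifnot(length(kls_values) == nrow(records))
  df <- data.frame(kls = as.numeric(kls_values),
                   group = .as_group(records$group))
  for (cv in covariates) {
    if (!cv %in% names(records))
      stop("covariate column not found in records: ", cv)
    df[[cv]] <- as.numeric(records[[cv]])
  }
  if (!is.null(whole_brain)) {
    stopifnot(length(whole_brain) == nrow(records))
    df$whole_brain <- as.numeric(whole_brain)
    covariates <- c(covariates, "whole_brain")
  }
  keep <- is.finite(df$kls)
  if (any(!keep)) {
    message(sum(!keep), " subject(s) excluded for missing coupling value")
    df <- df[keep, , drop = FALSE]
  }
  if (any(table(df$group) < 3L))
    stop("fewer than 3 subjects in a group after exclusions")
  rhs <- if (length(covariates))
    paste(c("group", covariates), collapse = " + ") else "group"
  full <- stats::lm(stats::as.formula(paste("kls ~", rhs)), data = df)
  X <- stats::model.matrix(full)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    dropped <- colnames(X)[qx$pivot[(qx$rank + 1L):ncol(X)]]
    stop("ANCOVA design is rank deficient; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }
  rhs0 <- if (length(covariates))
    paste(covariates, collapse = " + ") else "1"
  reduced <- stats::lm(stats::as.formula(paste("kls ~", rhs0)), data = df)
  ss_group <- sum(stats::resid(reduced)^2) - sum(stats::resid(full)^2)
  ss_res <- sum(stats::resid(full)^2)
  df1 <- full$rank - reduced$rank
  df2 <- stats::df.residual(full)
  Fval <- (ss_group / df1) / (ss_res / df2)
  data.frame(F = Fval, df1 = df1, df2 = df2,
             p = stats::pf(Fval, df1, df2, lower.tail = FALSE),
             eta_sq_partial = ss_group / (ss_group + ss_res),
             n_used = nrow(df))
}

#' ANCOVA across all regions of a coupling table
#'
#' Runs [ancova_region()] for every region, with whole-brain coupling
#' appended to the covariate set, and adds Benjamini-Hochberg adjusted
#' p-values across the region family.
#'
#' @param coupling A `"coupling_table"`.
#' @param records Cohort `data.frame` in the table's subject order.
#' @param covariates Covariate columns (default the standard five).
#' @return `data.frame` with one row per region: `region_id`, `region_name`,
#'   `F`, `df1`, `df2`, `p`, `p_fdr`, `eta_sq_partial`, `n_used`.
#' @export
ancova_table <- function(coupling, records,
                         covariates = c("age", "gender", "education",
                                        "mFD", "TIV")) {
  stopifnot(inherits(coupling, "coupling_table"),
            nrow(coupling$kls) == nrow(records))
  rows <- lapply(seq_along(coupling$region_names), function(r) {
    res <- ancova_region(coupling$kls[, r], records,
                         whole_brain = coupling$whole_brain,
                         covariates = covariates)
    cbind(data.frame(region_id = r,
                     region_name = coupling$region_names[r],
                     stringsAsFactors = FALSE), res)
  })
  out <- do.call(rbind, rows)
  out$p_fdr <- bh_fdr(out$p)
  out[, c("region_id", "region_name", "F", "df1", "df2", "p", "p_fdr",
          "eta_sq_partial", "n_used")]
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values across a family of tests; each adjusted value
#' is at least the raw value and the adjusted values are monotone in the
#' raw ordering.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order.
#' @export
bh_fdr <- function(p_values) {
  p <- as.numeric(p_values)
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p-values must all lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Post-hoc pairwise group contrasts on significant regions
#'
#' For each listed region, fits the same ANCOVA linear model and compares
#' the three covariate-adjusted group means pairwise (estimated marginal
#' means), with Bonferroni adjustment over the 3 contrasts within each
#' region. Intended for the regions surviving FDR in [ancova_table()].
#'
#' @param coupling A `"coupling_table"`.
#' @param records Cohort `data.frame` in matching order.
#' @param regions Integer region ids (or region names) to test.
#' @param covariates Covariate columns (whole-brain coupling appended).
#' @return `data.frame`: `region_id`, `region_name`, `contrast`,
#'   `adjusted_mean_diff`, `se`, `p_adj`, `direction` (sign of the
#'   difference: `"increase"` if the first-named group is higher).
#' @export
posthoc_pairwise <- function(coupling, records, regions,
                             covariates = c("age", "gender", "education",
                                            "mFD", "TIV")) {
  stopifnot(inherits(coupling, "coupling_table"))
  if (is.character(regions))
    regions <- match(regions, coupling$region_names)
  if (any(is.na(regions)) || any(regions < 1) ||
      any(regions > ncol(coupling$kls)))
    stop("unknown region in 'regions'")
  out <- list()
  for (r in regions) {
    df <- data.frame(kls = coupling$kls[, r],
                     group = .as_group(records$group),
                     whole_brain = coupling$whole_brain)
    for (cv in covariates) df[[cv]] <- as.numeric(records[[cv]])
    df <- df[is.finite(df$kls), , drop = FALSE]
    rhs <- paste(c("group", covariates, "whole_brain"), collapse = " + ")
    fit <- stats::lm(stats::as.formula(paste("kls ~", rhs)), data = df)
    emm <- emmeans::emmeans(fit, "group", data = df)
    prs <- summary(emmeans::contrast(emm, method = "pairwise",
                                     adjust = "bonferroni"))
    out[[length(out) + 1L]] <- data.frame(
      region_id = r,
      region_name = coupling$region_names[r],
      contrast = as.character(prs$contrast),
      adjusted_mean_diff = prs$estimate,
      se = prs$SE,
      p_adj = prs$p.value,
      direction = ifelse(prs$estimate >= 0, "increase", "decrease"),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Partial correlation
#'
#' Pearson correlation of the residuals of `x` and `y` after each is
#' regressed on an intercept plus the covariates; the p-value comes from
#' the t transform with `n - k - 2` degrees of freedom (`k` covariates).
#'
#' @param x,y Numeric vectors of equal length.
#' @param covariates Optional numeric matrix/data.frame of covariates
#'   (`NULL` reduces to plain Pearson correlation).
#' @return List: `r`, `p`, `df`, `n`.
#' @export
partial_corr <- function(x, y, covariates = NULL) {
  x <- as.numeric(x); y <- as.numeric(y)
  stopifnot(length(x) == length(y))
  keep <- is.finite(x) & is.finite(y)
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    stopifnot(nrow(covariates) == length(x))
    keep <- keep & apply(is.finite(covariates), 1L, all)
    covariates <- covariates[keep, , drop = FALSE]
  }
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  k <- if (is.null(covariates)) 0L else ncol(covariates)
  if (n <= k + 2L) stop("need n > number of covariates + 2")
  if (k > 0L) {
    qx <- qr(cbind(1, covariates))
    x <- qr.resid(qx, x)
    y <- qr.resid(qx, y)
  } else {
    x <- x - mean(x); y <- y - mean(y)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero residual variance; partial correlation undefined")
  r <- sum(x * y) / sqrt(sum(x^2) * sum(y^2))
  df <- n - k - 2L
  tval <- r * sqrt(df / max(1 - r^2, .Machine$double.eps))
  list(r = r, p = 2 * stats::pt(-abs(tval), df), df = df, n = n)
}

#' Partial correlations of regional coupling with clinical variables
#'
#' For each (region, clinical variable) pair, the partial correlation of
#' the regional KLS values with the clinical score in the patient subset,
#' adjusting for the standard covariates plus whole-brain coupling, with
#' BH-FDR across the whole family.
#'
#' @param coupling A `"coupling_table"`.
#' @param records Cohort `data.frame` in matching order.
#' @param regions Region ids or names (typically the FDR-significant set).
#' @param clinical Character vector of clinical columns (default SHAPS,
#'   onset_age, episode_times, illness_duration).
#' @param subset Logical vector selecting subjects (default: the two MDD
#'   groups).
#' @param covariates Covariate columns.
#' @return `data.frame`: `region_id`, `region_name`, `clinical_variable`,
#'   `r`, `p`, `p_fdr`, `n`.
#' @export
clinical_partial_corr <- function(coupling, records, regions,
                                  clinical = c("SHAPS", "onset_age",
                                               "episode_times",
                                               "illness_duration"),
                                  subset = records$group != "HC",
                                  covariates = c("age", "gender",
                                                 "education", "mFD",
                                                 "TIV")) {
  if (is.character(regions))
    regions <- match(regions, coupling$region_names)
  covs <- cbind(as.matrix(records[, covariates, drop = FALSE]),
                whole_brain = coupling$whole_brain)
  out <- list()
  for (r in regions) {
    for (cl in clinical) {
      pc <- partial_corr(coupling$kls[subset, r],
                         as.numeric(records[[cl]])[subset],
                         covs[subset, , drop = FALSE])
      out[[length(out) + 1L]] <- data.frame(
        region_id = r, region_name = coupling$region_names[r],
        clinical_variable = cl, r = pc$r, p = pc$p, n = pc$n,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, out)
  out$p_fdr <- bh_fdr(out$p)
  out
}

#' Pooled two-sample t statistic from printed summaries
#'
#' `t = (m1 - m2) / sqrt(s_p^2 (1/n1 + 1/n2))` with the pooled variance
#' `s_p^2 = ((n1-1) s1^2 + (n2-1) s2^2) / (n1 + n2 - 2)`. Lets published
#' group mean/SD/n rows be recomputed into their test statistics.
#'
#' @param m1,s1,n1 Mean, SD and size of group 1.
#' @param m2,s2,n2 Mean, SD and size of group 2.
#' @return List: `t`, `df`, `p` (two-sided).
#' @export
t_from_summary <- function(m1, s1, n1, m2, s2, n2) {
  if (s1 <= 0 || s2 <= 0) stop("standard deviations must be positive")
  if (n1 < 2 || n2 < 2) stop("group sizes must be >= 2")
  sp2 <- ((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2)
  tval <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  df <- n1 + n2 - 2
  list(t = tval, df = df, p = 2 * stats::pt(-abs(tval), df))
}

#' One-way ANOVA F statistic from printed summaries
#'
#' `F = MSB / MSW` with `SSB = sum n_i (m_i - grand_mean)^2` and
#' `SSW = sum (n_i - 1) s_i^2`.
#'
#' @param groups List of `c(mean, sd, n)` triples (or a 3-column matrix,
#'   one row per group).
#' @return List: `F`, `df1`, `df2`, `p`.
#' @export
anova_from_summary <- function(groups) {
  if (is.matrix(groups) || is.data.frame(groups))
    groups <- split(as.matrix(groups), row(as.matrix(groups)))
  g <- do.call(rbind, lapply(groups, function(x) as.numeric(x[1:3])))
  if (nrow(g) < 2L) stop("need at least 2 groups")
  m <- g[, 1]; s <- g[, 2]; n <- g[, 3]
  if (any(s <= 0)) stop("standard deviations must be positive")
  if (any(n < 2)) stop("group sizes must be >= 2")
  N <- sum(n)
  grand <- sum(n * m) / N
  ssb <- sum(n * (m - grand)^2)
  ssw <- sum((n - 1) * s^2)
  df1 <- nrow(g) - 1L
  df2 <- N - nrow(g)
  Fval <- (ssb / df1) / (ssw / df2)
  list(F = Fval, df1 = df1, df2 = df2,
       p = stats::pf(Fval, df1, df2, lower.tail = FALSE))
}

#' Pearson chi-square test on a contingency table
#'
#' Standard expected-counts chi-square without continuity correction.
#'
#' @param counts Matrix of non-negative counts with no zero marginal.
#' @return List: `chi2`, `df`, `p`.
#' @export
chi2_from_counts <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop("zero row or column total")
  res <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  list(chi2 = unname(res$statistic), df = unname(res$parameter),
       p = unname(res$p.value))
}
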