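# binary label helper: returns logical vector (TRUE = positive class)
.as_binary <- function(labels, positive) {
  labels <- as.character(labels)
  classes <- unique(labels)
  if (length(classes) != 2L)
    stop("need exactly 2 classes, got: ", paste(classes, collapse = ", "))
  if (is.null(positive)) positive <- sort(classes)[2]
  if (!positive %in% classes)
    stop("positive class '", positive, "' not present in labels")
  labels == positive
}

#' ROC analysis of one feature
#'
#' Empirical AUC (rank / Mann-Whitney statistic, ties counted one half)
#' with a DeLong variance, DeLong 95% confidence interval, a normal
#' approximation p-value against AUC = 0.5, and the Youden-optimal
#' operating point (threshold maximizing sensitivity + specificity over the
#' observed scores; ties broken toward the smallest threshold).
#'
#' By default the feature is oriented so the positive class has the higher
#' mean score (`orientation` records which way); set `orient = FALSE` to
#' score the feature as given.
#'
#' @param scores Per-subject numeric feature values.
#' @param labels Two-class labels.
#' @param positive Value of `labels` treated as the positive class
#'   (default: the lexicographically larger class).
#' @param orient Orient the feature so the positive class scores higher
#'   (default `TRUE`).
#' @param feature_id Optional feature name carried into the result.
#' @return List of class `"roc_result"`: `feature_id`, `auc`, `auc_ci`
#'   (DeLong 95%), `var_auc`, `p_auc`, `youden_threshold` (on the oriented
#'   score scale), `youden_j`, `sensitivity` and `specificity` (percent),
#'   `orientation` (`"higher"`/`"lower"`), `n_pos`, `n_neg`.
#' @export
roc_analysis <- function(scores, labels, positive = NULL, orient = TRUE,
                         feature_id = "feature") {
  scores <- as.numeric(scores)
  pos <- .as_binary(labels, positive)
  if (length(scores) != length(pos))
    stop("scores and labels differ in length")
  orientation <- "higher"
  s <- scores
  if (orient && mean(s[pos]) < mean(s[!pos])) {
    s <- -s
    orientation <- "lower"
  }
  constant <- stats::sd(s) == 0
  if (constant) {
    warning("constant scores: AUC = 0.5 with degenerate confidence interval")
    auc <- 0.5; v <- 0; ci <- c(0.5, 0.5)
  } else {
    r <- pROC::roc(response = factor(pos, levels = c(FALSE, TRUE)),
                   predictor = s, direction = "<", quiet = TRUE)
    auc <- as.numeric(pROC::auc(r))
    # pROC warns that var/ci are degenerate at AUC == 1; that is expected
    v <- suppressWarnings(as.numeric(pROC::var(r, method = "delong")))
    ci_full <- suppressWarnings(as.numeric(pROC::ci.auc(r, method = "delong")))
    ci <- c(ci_full[1], ci_full[3])
  }
  p_auc <- if (v > 0) 2 * stats::pnorm(-abs(auc - 0.5) / sqrt(v)) else NA_real_
  # Youden scan over observed thresholds (predict positive when s >= t)
  thresholds <- sort(unique(s))
  sens <- vapply(thresholds, function(t) mean(s[pos] >= t), numeric(1))
  spec <- vapply(thresholds, function(t) mean(s[!pos] < t), numeric(1))
  j <- sens + spec - 1
  best <- which(j == max(j))[1]  # sorted ascending -> smallest threshold
  structure(list(feature_id = feature_id, auc = auc, auc_ci = ci,
                 var_auc = v, p_auc = p_auc,
                 youden_threshold = thresholds[best],
                 youden_j = j[best],
                 sensitivity = 100 * sens[best],
                 specificity = 100 * spec[best],
                 orientation = orientation,
                 n_pos = sum(pos), n_neg = sum(!pos)),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> %s: AUC = %.3f (95%% CI %.3f-%.3f, p = %.3g), sens %.1f%% / spec %.1f%% at J = %.3f\n",
              x$feature_id, x$auc, x$auc_ci[1], x$auc_ci[2], x$p_auc,
              x$sensitivity, x$specificity, x$youden_j))
  invisible(x)
}

# ridge-stabilized logistic regression by Newton iterations; the L2
# penalty (slopes only) keeps coefficients finite under quasi-separation
.ridge_logistic <- function(X, y, lambda = 1e-4, max_iter = 100,
                            tol = 1e-8) {
  p <- ncol(X)
  pen <- diag(c(0, rep(lambda, p - 1L)), p)
  beta <- numeric(p)
  for (i in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    g <- drop(crossprod(X, y - mu)) - drop(pen %*% beta)
    H <- crossprod(X * w, X) + pen
    step <- solve(H, g)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  beta
}

#' Combined logistic predictor (PRE) over several regional features
#'
#' Fits a maximum-likelihood logistic regression of the binary group on the
#' supplied KLS features (all subjects, in-sample, as in the published
#' procedure), takes the fitted probabilities as the combined prediction
#' score ("PRE"), and scores them with [roc_analysis()]. Under perfect or
#' quasi-separation the fit is flagged and refit with a small L2 penalty
#' (ridge, lambda = 1e-4) so the probabilities stay finite.
#'
#' @param features `n x k` numeric matrix (or data.frame) of features.
#' @param labels Two-class labels.
#' @param positive Positive class (see [roc_analysis()]).
#' @return List of class `"pre_result"`: `probabilities` (per subject),
#'   `coefficients`, `separation` flag, `roc` (a `"roc_result"` on the
#'   probabilities).
#' @export
combined_pre <- function(features, labels, positive = NULL) {
  X <- as.matrix(features)
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  pos <- .as_binary(labels, positive)
  if (nrow(X) != length(pos)) stop("features and labels differ in length")
  if (nrow(X) <= ncol(X) + 1L) stop("need n > k + 1 subjects")
  y <- as.numeric(pos)
  df <- data.frame(y = y, X)
  separation <- FALSE
  fit <- withCallingHandlers(
    stats::glm(y ~ ., data = df, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)) ||
          grepl("algorithm did not converge", conditionMessage(w)))
        separation <<- TRUE
      invokeRestart("muffleWarning")
    })
  if (separation) {
    warning("perfect or quasi-separation detected; refitting with ridge penalty (lambda = 1e-4)")
    Xd <- cbind(1, X)
    beta <- .ridge_logistic(Xd, y)
    probs <- stats::plogis(drop(Xd %*% beta))
    coefs <- stats::setNames(beta, c("(Intercept)", colnames(X)))
  } else {
    probs <- stats::fitted(fit)
    coefs <- stats::coef(fit)
  }
  structure(list(probabilities = unname(probs), coefficients = coefs,
                 separation = separation,
                 roc = roc_analysis(probs, labels, positive,
                                    orient = FALSE, feature_id = "PRE")),
            class = "pre_result")
}

#' Binary classification metrics from a confusion matrix
#'
#' Accuracy, precision, recall, F1 and the Matthews correlation coefficient
#' (MCC), all as fractions; MCC is defined as 0 when any confusion-matrix
#' marginal is zero.
#'
#' @param tp,fp,fn,tn Confusion counts.
#' @return List: `accuracy`, `precision`, `recall`, `f1`, `mcc`.
#' @export
confusion_metrics <- function(tp, fp, fn, tn) {
  n <- tp + fp + fn + tn
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f1 <- if (is.finite(precision) && is.finite(recall) &&
            precision + recall > 0)
    2 * precision * recall / (precision + recall) else NA_real_
  denom <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (denom > 0) (tp * tn - fp * fn) / sqrt(denom) else 0
  list(accuracy = (tp + tn) / n, precision = precision, recall = recall,
       f1 = f1, mcc = mcc)
}

# stratified fold assignment within each class
.stratified_folds <- function(pos, folds) {
  id <- integer(length(pos))
  for (cls in c(TRUE, FALSE)) {
    idx <- which(pos == cls)
    id[idx] <- sample(rep(seq_len(folds), length.out = length(idx)))
  }
  id
}

#' Cross-validated linear SVM classification
#'
#' Stratified 80/20 train/test split (by `seed`), linear-kernel SVM
#' (`C = 1`) assessed by stratified 5-fold cross-validation on the training
#' portion, then refit on the whole training portion and evaluated on the
#' held-out test portion with the six standard metrics: accuracy, precision
#' (percent), recall, F1, AUC (from the decision values) and MCC. Features
#' are standardized with training-set statistics only.
#'
#' @param features `n x k` numeric matrix of features.
#' @param labels Two-class labels.
#' @param positive Positive class (default: lexicographically larger).
#' @param seed Integer seed controlling the split and fold assignment.
#' @param folds Number of CV folds (default 5).
#' @param train_frac Training fraction (default 0.8).
#' @param cost SVM regularization parameter C (default 1).
#' @return List of class `"svm_report"`: `comparison`, `accuracy` (%),
#'   `precision` (%), `recall`, `f1`, `auc`, `mcc` (test-set values),
#'   `cv_accuracy` (%, cross-validated on the training portion),
#'   `confusion` (tp/fp/fn/tn), `n_train`, `n_test`, `seed`, `fold_count`.
#' @export
svm_crossval <- function(features, labels, positive = NULL, seed = 17,
                         folds = 5, train_frac = 0.8, cost = 1) {
  X <- as.matrix(features)
  pos <- .as_binary(labels, positive)
  if (nrow(X) != length(pos)) stop("features and labels differ in length")
  classes <- unique(as.character(labels))
  positive <- if (is.null(positive)) sort(classes)[2] else positive
  set.seed(seed)
  # stratified train/test split
  train_idx <- unlist(lapply(c(TRUE, FALSE), function(cls) {
    idx <- which(pos == cls)
    sample(idx, round(train_frac * length(idx)))
  }))
  test_idx <- setdiff(seq_len(nrow(X)), train_idx)
  y <- factor(ifelse(pos, "pos", "neg"), levels = c("neg", "pos"))
  if (length(unique(y[train_idx])) < 2L || length(unique(y[test_idx])) < 2L)
    stop("a split is missing a class; increase n or adjust train_frac")
  scale_fit <- function(train_X, other_X) {
    mu <- colMeans(train_X)
    sd <- apply(train_X, 2, stats::sd)
    sd[sd == 0] <- 1
    list(train = sweep(sweep(train_X, 2, mu), 2, sd, "/"),
         other = sweep(sweep(other_X, 2, mu), 2, sd, "/"))
  }
  # stratified k-fold CV on the training portion
  fold_id <- .stratified_folds(pos[train_idx], folds)
  if (min(table(fold_id, y[train_idx])) < 1L)
    stop("a CV fold is missing a class; reduce 'folds'")
  cv_correct <- 0L
  for (k in seq_len(folds)) {
    tr <- train_idx[fold_id != k]
    va <- train_idx[fold_id == k]
    sc <- scale_fit(X[tr, , drop = FALSE], X[va, , drop = FALSE])
    m <- e1071::svm(x = sc$train, y = y[tr], kernel = "linear",
                    cost = cost, scale = FALSE)
    cv_correct <- cv_correct + sum(predict(m, sc$other) == y[va])
  }
  cv_accuracy <- cv_correct / length(train_idx)
  # final model on the full training portion, evaluated on the test portion
  sc <- scale_fit(X[train_idx, , drop = FALSE], X[test_idx, , drop = FALSE])
  model <- e1071::svm(x = sc$train, y = y[train_idx], kernel = "linear",
                      cost = cost, scale = FALSE)
  pred <- predict(model, sc$other, decision.values = TRUE)
  dv <- drop(attr(pred, "decision.values"))
  # orient decision values toward the positive class
  if (colnames(attr(pred, "decision.values"))[1] == "neg/pos") dv <- -dv
  truth <- y[test_idx]
  tp <- sum(pred == "pos" & truth == "pos")
  fp <- sum(pred == "pos" & truth == "neg")
  fn <- sum(pred == "neg" & truth == "pos")
  tn <- sum(pred == "neg" & truth == "neg")
  met <- confusion_metrics(tp, fp, fn, tn)
  auc <- if (stats::sd(dv) > 0) {
    r <- pROC::roc(response = truth, predictor = dv, levels = c("neg", "pos"),
                   direction = "<", quiet = TRUE)
    as.numeric(pROC::auc(r))
  } else 0.5
  structure(list(comparison = paste(sort(classes), collapse = " vs "),
                 positive = positive,
                 accuracy = 100 * met$accuracy,
                 precision = 100 * met$precision,
                 recall = met$recall, f1 = met$f1, auc = auc,
                 mcc = met$mcc,
                 cv_accuracy = 100 * cv_accuracy,
                 confusion = c(tp = tp, fp = fp, fn = fn, tn = tn),
                 n_train = length(train_idx), n_test = length(test_idx),
                 seed = seed, fold_count = folds),
            class = "svm_report")
}

#' @export
print.svm_report <- function(x, ...) {
  cat(sprintf("<svm_report> %s (positive = %s)\n", x$comparison, x$positive))
  cat(sprintf("  test:  accuracy %.2f%%, precision %.2f%%, recall %.2f, F1 %.2f, AUC %.2f, MCC %.2f\n",
              x$accuracy, x$precision, x$recall, x$f1, x$auc, x$mcc))
  cat(sprintf("  cv:    accuracy %.2f%% (%d-fold, train n = %d; test n = %d; seed %d)\n",
              x$cv_accuracy, x$fold_count, x$n_train, x$n_test, x$seed))
  invisible(x)
}
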