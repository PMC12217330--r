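# Leave-one-out evaluation, subscore prediction, the randomized
# medication-state-transition experiment, and ROC metrics.

#' Leave-one-out cross-validated regression metrics
#'
#' For each held-out subject the coefficients are refit on the remaining
#' subjects with the feature set fixed (selection is not re-run). Reports
#' MAE, RMSE, and `R2_pred = 1 - SSE_loo / SST`, which can be negative for
#' uninformative models.
#'
#' @param X Matrix/data frame of the selected predictors.
#' @param y Numeric outcome.
#' @return An `evaluation_report` with `mode = "regression"`, `mae`, `rmse`,
#'   `r2_pred`, and `predictions`.
#' @export
loocv_regression <- function(X, y) {
  X <- as.matrix(as.data.frame(X))
  n <- nrow(X)
  if (n < ncol(X) + 3) stop("need n >= p + 3", call. = FALSE)
  preds <- numeric(n)
  for (i in seq_len(n)) {
    fit <- tryCatch(lm.fit(cbind(1, X[-i, , drop = FALSE]), y[-i]),
                    error = function(e)
                      stop("singular design in fold ", i, call. = FALSE))
    b <- fit$coefficients
    if (anyNA(b)) stop("singular design in fold ", i, call. = FALSE)
    preds[i] <- sum(c(1, X[i, ]) * b)
  }
  resid <- y - preds
  sst <- sum((y - mean(y))^2)
  structure(list(mode = "regression",
                 mae = mean(abs(resid)),
                 rmse = sqrt(mean(resid^2)),
                 r2_pred = 1 - sum(resid^2) / sst,
                 predictions = preds),
            class = "evaluation_report")
}

#' LOOCV prediction of MDS-UPDRS-III subscores
#'
#' Refits the fixed hypokinetic feature set against each subscore change
#' (bradykinesia, axial, rigidity, tremor) and reports LOOCV metrics per
#' subscore.
#'
#' @param X Matrix/data frame of selected biomarker changes.
#' @param subscore_changes Data frame of subscore change columns.
#' @return Named list of `evaluation_report`s.
#' @export
predict_subscores <- function(X, subscore_changes) {
  subscore_changes <- as.data.frame(subscore_changes)
  lapply(as.list(subscore_changes), function(y) {
    if (sd(y) == 0) stop("subscore has zero variance", call. = FALSE)
    loocv_regression(X, y)
  })
}

#' Build the randomized medication-state-transition dataset
#'
#' Each subject draws a fair-coin label from the seeded generator: label 0
#' keeps the ON - OFF change vector (an OFF-to-ON transition), label 1
#' negates it (an ON-to-OFF transition).
#'
#' @param changes Matrix/data frame of ON - OFF biomarker changes (rows =
#'   subjects).
#' @param seed Integer seed for the label draw.
#' @return A `transition_dataset`: list with `X` (oriented changes),
#'   `labels`, `seed`.
#' @export
make_transition_dataset <- function(changes, seed = NULL) {
  X <- as.matrix(as.data.frame(changes))
  if (anyNA(X)) stop("change vectors must be complete", call. = FALSE)
  labels <- with_truth_seed(seed, rbinom(nrow(X), 1L, 0.5))
  Xo <- X * ifelse(labels == 1L, -1, 1)
  structure(list(X = Xo, labels = labels, seed = seed),
            class = "transition_dataset")
}

#' Area under the ROC curve
#'
#' Rank-statistic AUC: the probability that a positive score exceeds a
#' negative one, counting ties as one half.
#'
#' @param scores Numeric classifier scores.
#' @param labels Binary labels (1 = positive).
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L)
    stop("both classes must be present", call. = FALSE)
  r <- rank(scores)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Evaluate the medication-state-transition classifier
#'
#' Backward stepwise logistic selection on the candidate pool, then LOOCV:
#' the selected feature set is fixed and only coefficients are refit per
#' fold (set `nested = TRUE` to re-run selection inside each fold). AUC is
#' computed from the pooled LOO probabilities; accuracy, sensitivity,
#' specificity, PPV and NPV at a 0.5 threshold, with a Clopper-Pearson 95%
#' interval for accuracy.
#'
#' @param ds A `transition_dataset`.
#' @param pool Candidate feature names (subset of the dataset columns).
#' @param nested Re-run selection within each fold?
#' @return An `evaluation_report` with `mode = "classification"`.
#' @export
transition_eval <- function(ds, pool = colnames(ds$X), nested = FALSE) {
  stopifnot(inherits(ds, "transition_dataset"))
  if (!all(pool %in% colnames(ds$X)))
    stop("pool must be a subset of the dataset features", call. = FALSE)
  X <- ds$X[, pool, drop = FALSE]
  y <- ds$labels
  sw <- stepwise_logistic(X, y)
  n <- nrow(X)
  probs <- numeric(n)
  for (i in seq_len(n)) {
    sel <- if (nested) {
      swi <- suppressWarnings(stepwise_logistic(X[-i, , drop = FALSE], y[-i]))
      swi$selected
    } else sw$selected
    dtr <- data.frame(X[-i, sel, drop = FALSE], .y = y[-i])
    fit <- suppressWarnings(glm(.y ~ ., data = dtr, family = binomial()))
    nd <- as.data.frame(X[i, sel, drop = FALSE])
    probs[i] <- if (length(sel))
      suppressWarnings(predict(fit, newdata = nd, type = "response"))
    else mean(y[-i])
  }
  pred <- as.integer(probs > 0.5)
  tp <- sum(pred == 1 & y == 1); tn <- sum(pred == 0 & y == 0)
  fp <- sum(pred == 1 & y == 0); fn <- sum(pred == 0 & y == 1)
  acc_ci <- binom.test(tp + tn, n)$conf.int
  structure(list(mode = "classification",
                 auc = roc_auc(probs, y),
                 accuracy = (tp + tn) / n,
                 accuracy_ci = as.numeric(acc_ci),
                 sensitivity = if (tp + fn) tp / (tp + fn) else NA_real_,
                 specificity = if (tn + fp) tn / (tn + fp) else NA_real_,
                 ppv = if (tp + fp) tp / (tp + fp) else NA_real_,
                 npv = if (tn + fn) tn / (tn + fn) else NA_real_,
                 selected = sw$selected, model = sw,
                 predictions = probs, labels = y),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  if (x$mode == "regression") {
    cat(sprintf("<evaluation_report> LOOCV regression: MAE %.3f  RMSE %.3f  R2_pred %.3f\n",
                x$mae, x$rmse, x$r2_pred))
  } else {
    cat(sprintf("<evaluation_report> classification: AUC %.3f  acc %.1f%% (CI %.2f-%.2f)\n",
                x$auc, 100 * x$accuracy, x$accuracy_ci[1], x$accuracy_ci[2]))
    cat(sprintf("  sens %.2f  spec %.2f  ppv %.2f  npv %.2f;  %d features\n",
                x$sensitivity, x$specificity, x$ppv, x$npv, length(x$selected)))
  }
  invisible(x)
}
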