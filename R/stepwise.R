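# Backward stepwise selection by AIC, linear and logistic, behind one
# result shape. The search itself is stats::step (backward, k = 2);
# candidate columns are ordered lexicographically so removal ties break
# deterministically.

as_model_df <- function(X, y, yname = ".y") {
  X <- as.data.frame(X)
  if (is.null(colnames(X)) || any(!nzchar(colnames(X))))
    stop("predictor columns must be named", call. = FALSE)
  X <- X[, order(colnames(X)), drop = FALSE]
  keep <- complete.cases(X) & is.finite(y)
  if (sum(!keep))
    message(sum(!keep), " row(s) with missing values dropped")
  df <- X[keep, , drop = FALSE]
  df[[yname]] <- y[keep]
  df
}

check_collinear <- function(X) {
  Xs <- scale(as.matrix(X))
  Xs <- Xs[, apply(Xs, 2, function(c) all(is.finite(c))), drop = FALSE]
  if (ncol(Xs) < 2) return(invisible())
  if (kappa(Xs, exact = TRUE) > 1e8) {
    cc <- cor(Xs)
    diag(cc) <- 0
    ij <- which(abs(cc) == max(abs(cc)), arr.ind = TRUE)[1, ]
    pair <- sort(colnames(Xs)[ij])
    stop("collinear predictors: ", pair[1], " and ", pair[2], call. = FALSE)
  }
}

step_trace <- function(st) {
  an <- st$anova
  if (is.null(an) || nrow(an) < 2)
    return(data.frame(removed = character(0), aic = numeric(0)))
  data.frame(removed = trimws(sub("^- ", "", an$Step[-1])), aic = an$AIC[-1])
}

#' Backward stepwise linear regression by AIC
#'
#' Starts from the full candidate set and iteratively removes the predictor
#' whose removal lowers AIC most, stopping when no removal lowers AIC, then
#' refits the final OLS model.
#'
#' @param X Matrix or data frame of candidate predictors (named columns).
#' @param y Numeric outcome.
#' @return A `stepwise_result`: `selected` (final feature names),
#'   `coefficients` (including intercept), `aic_trace` (removed feature +
#'   AIC after each accepted removal), `final_aic`, `r2`, `adj_r2`, `fit`.
#' @export
stepwise_linear <- function(X, y) {
  df <- as_model_df(X, y)
  p <- ncol(df) - 1L
  if (nrow(df) <= p + 2) stop("need n > p + 2", call. = FALSE)
  check_collinear(df[, setdiff(names(df), ".y"), drop = FALSE])
  full <- lm(.y ~ ., data = df)
  st <- step(full, direction = "backward", trace = 0, k = 2)
  sm <- summary(st)
  structure(list(selected = setdiff(names(coef(st)), "(Intercept)"),
                 coefficients = coef(st), aic_trace = step_trace(st),
                 final_aic = extractAIC(st, k = 2)[2],
                 r2 = sm$r.squared, adj_r2 = sm$adj.r.squared,
                 family = "linear", fit = st, data = df),
            class = "stepwise_result")
}

#' Backward stepwise logistic regression by AIC
#'
#' As [stepwise_linear()] with binomial deviance AIC; reports null and
#' residual deviance. If the final fit shows complete separation the
#' coefficients are refit with a small ridge penalty (warning logged); the
#' selection is kept.
#'
#' @param X Matrix or data frame of candidate predictors.
#' @param labels Binary outcome (0/1 or logical).
#' @return A `stepwise_result` with `null_deviance` and `residual_deviance`.
#' @export
stepwise_logistic <- function(X, labels) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2)
    stop("both classes must be present", call. = FALSE)
  df <- as_model_df(X, labels)
  p <- ncol(df) - 1L
  if (nrow(df) <= p + 2) stop("need n > p + 2", call. = FALSE)
  check_collinear(df[, setdiff(names(df), ".y"), drop = FALSE])
  full <- suppressWarnings(glm(.y ~ ., data = df, family = binomial()))
  st <- suppressWarnings(step(full, direction = "backward", trace = 0, k = 2))
  coefs <- coef(st)
  mu <- fitted(st)
  if (any(mu < 1e-8 | mu > 1 - 1e-8) && length(coefs) > 1L) {
    warning("possible complete separation; coefficients refit with a small ",
            "ridge penalty", call. = FALSE)
    sel <- setdiff(names(coefs), "(Intercept)")
    Xs <- as.matrix(df[, sel, drop = FALSE])
    coefs <- ridge_logistic(Xs, df$.y, lambda = 1e-2)
  }
  structure(list(selected = setdiff(names(coef(st)), "(Intercept)"),
                 coefficients = coefs, aic_trace = step_trace(st),
                 final_aic = extractAIC(st, k = 2)[2],
                 null_deviance = st$null.deviance,
                 residual_deviance = st$deviance,
                 family = "logistic", fit = st, data = df),
            class = "stepwise_result")
}

# Newton iterations for ridge-penalized logistic coefficients (intercept
# unpenalized); used only as a separation fallback.
ridge_logistic <- function(X, y, lambda = 1e-2, maxit = 50) {
  Z <- cbind(`(Intercept)` = 1, X)
  b <- numeric(ncol(Z))
  pen <- diag(c(0, rep(lambda, ncol(X))))
  for (i in seq_len(maxit)) {
    eta <- as.numeric(Z %*% b)
    mu <- 1 / (1 + exp(-eta))
    Wv <- pmax(mu * (1 - mu), 1e-10)
    H <- crossprod(Z, Z * Wv) + pen
    g <- crossprod(Z, y - mu) - pen %*% b
    db <- solve(H, g)
    b <- b + as.numeric(db)
    if (max(abs(db)) < 1e-8) break
  }
  setNames(as.numeric(b), colnames(Z))
}

#' @export
print.stepwise_result <- function(x, ...) {
  cat(sprintf("<stepwise_result> %s; %d selected of %d candidates; AIC %.2f\n",
              x$family, length(x$selected),
              length(x$selected) + nrow(x$aic_trace), x$final_aic))
  if (x$family == "linear")
    cat(sprintf("  R2 %.3f  adj R2 %.3f\n", x$r2, x$adj_r2))
  else
    cat(sprintf("  null dev %.3f  resid dev %.3f\n",
                x$null_deviance, x$residual_deviance))
  print(round(x$coefficients, 5))
  invisible(x)
}
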