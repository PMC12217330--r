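test_that("backward AIC selection keeps a real predictor among noise", {
  kept <- vapply(1:100, function(s) {
    set.seed(s)
    X <- matrix(rnorm(500 * 6), 500,
                dimnames = list(NULL, paste0("x", 1:6)))
    y <- 2 * X[, "x1"] + rnorm(500)
    "x1" %in% stepwise_linear(X, y)$selected
  }, logical(1))
  expect_gte(mean(kept), 0.95)
})

test_that("pure-noise candidates collapse to the intercept-only model", {
  # per noise candidate, AIC retention is ~P(chisq_1 > 2) = 0.157, so the
  # intercept-only probability is ~0.843^p: a majority needs p <= 3
  sizes <- vapply(1:100, function(s) {
    set.seed(s)
    X <- matrix(rnorm(500 * 3), 500,
                dimnames = list(NULL, paste0("x", 1:3)))
    length(stepwise_linear(X, rnorm(500))$selected)
  }, numeric(1))
  expect_gt(mean(sizes == 0), 0.5)
  expect_lte(median(sizes), 1)
})

test_that("a perfect single candidate is kept with an empty AIC path", {
  set.seed(2)
  x <- rnorm(60)
  sw <- suppressWarnings(stepwise_linear(data.frame(x1 = x), x))
  expect_equal(sw$r2, 1)
  expect_equal(nrow(sw$aic_trace), 0)
  expect_equal(sw$selected, "x1")
})

test_that("the AIC trace decreases and the final model is locally optimal", {
  set.seed(5)
  X <- matrix(rnorm(80 * 8), 80, dimnames = list(NULL, paste0("x", 1:8)))
  y <- X[, 1] - 0.8 * X[, 3] + rnorm(80, 0, 2)
  sw <- stepwise_linear(X, y)
  if (nrow(sw$aic_trace) > 1)
    expect_true(all(diff(sw$aic_trace$aic) < 0))
  # no single removal from the final model lowers AIC
  df <- data.frame(X[, sw$selected, drop = FALSE], .y = y)
  for (k in sw$selected) {
    red <- lm(.y ~ ., data = df[, setdiff(names(df), k), drop = FALSE])
    expect_gte(extractAIC(red)[2] + 1e-8, sw$final_aic)
  }
})

test_that("collinear candidates are reported by name", {
  set.seed(6)
  x <- rnorm(50)
  X <- cbind(a = x, b = x * 2 + 1e-10 * rnorm(50), c = rnorm(50))
  expect_error(stepwise_linear(X, rnorm(50)), "collinear.*a.*b")
})

test_that("balanced-label logistic null deviance matches 2n log 2", {
  set.seed(9)
  X <- matrix(rnorm(51 * 3), 51, dimnames = list(NULL, paste0("x", 1:3)))
  labels <- rep(c(0L, 1L), length.out = 51)   # 26/25 split at n = 51
  sw <- suppressWarnings(stepwise_logistic(X, labels))
  k <- sum(labels)
  exact <- -2 * (k * log(k / 51) + (51 - k) * log(1 - k / 51))
  expect_equal(sw$null_deviance, exact, tolerance = 1e-8)
  expect_equal(sw$null_deviance, 2 * 51 * log(2), tolerance = 0.1 / 70)
})

test_that("logistic selection finds an informative feature", {
  set.seed(10)
  n <- 120
  X <- matrix(rnorm(n * 4), n, dimnames = list(NULL, paste0("x", 1:4)))
  labels <- as.integer(X[, "x2"] + rnorm(n, 0, 0.4) > 0)
  sw <- suppressWarnings(stepwise_logistic(X, labels))
  expect_true("x2" %in% sw$selected)
  expect_lt(sw$residual_deviance, 0.6 * sw$null_deviance)
  # label-independent features: intercept-only in the majority of seeds
  empty <- vapply(1:100, function(s) {
    set.seed(s)
    Xn <- matrix(rnorm(200 * 4), 200, dimnames = list(NULL, paste0("x", 1:4)))
    ln <- rbinom(200, 1, 0.5)
    length(suppressWarnings(stepwise_logistic(Xn, ln))$selected) == 0
  }, logical(1))
  expect_gt(mean(empty), 0.5)
})
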