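test_that("a single predictor receives the full R-squared", {
  set.seed(1)
  x <- rnorm(100); y <- x + rnorm(100)
  for (m in c("pmvd", "lmg")) {
    im <- importance(data.frame(x1 = x), y, method = m)
    expect_equal(unname(im$shares["x1"]), subset_r2(data.frame(x1 = x), y),
                 tolerance = 1e-12)
    expect_equal(sum(im$shares), im$total, tolerance = 1e-12)
  }
})

test_that("orthogonal predictors get their marginal R-squared as share", {
  set.seed(2)
  n <- 400
  x1 <- rnorm(n); x2 <- residuals(lm(rnorm(n) ~ x1))
  x1 <- x1 - mean(x1)
  y <- 1.2 * x1 + 0.6 * x2 + rnorm(n)
  X <- data.frame(x1 = x1, x2 = x2)
  m1 <- subset_r2(X, y, "x1"); m2 <- subset_r2(X, y, "x2")
  for (m in c("pmvd", "lmg")) {
    sh <- importance(X, y, method = m)$shares
    expect_equal(unname(sh), c(m1, m2), tolerance = 1e-10)
  }
})

test_that("lattice computation equals explicit p! ordering enumeration", {
  set.seed(3)
  n <- 120; p <- 5
  X <- as.data.frame(matrix(rnorm(n * p), n))
  names(X) <- paste0("x", 1:p)
  # moderate correlation so the two methods genuinely differ
  X$x2 <- X$x2 + 0.6 * X$x1
  X$x4 <- X$x4 + 0.4 * X$x3
  y <- X$x1 - 0.5 * X$x3 + 0.3 * X$x5 + rnorm(n)
  for (m in c("lmg", "pmvd")) {
    exact <- importance(X, y, method = m)$shares
    oracle <- enumerate_importance(X, y, method = m)
    expect_equal(unname(exact), oracle, tolerance = 1e-10,
                 label = paste(m, "vs enumeration"))
  }
  expect_gt(max(abs(importance(X, y, method = "pmvd")$shares -
                      importance(X, y, method = "lmg")$shares)), 1e-4)
})

test_that("shares are non-negative, sum to R2, and ignore column order", {
  set.seed(4)
  n <- 200; p <- 6
  X <- as.data.frame(matrix(rnorm(n * p), n)); names(X) <- paste0("x", 1:p)
  X$x3 <- X$x3 + 0.5 * X$x1
  y <- X$x1 + 0.5 * X$x2 + rnorm(n)
  for (m in c("pmvd", "lmg")) {
    im <- importance(X, y, method = m)
    expect_true(all(im$shares >= 0))
    expect_equal(sum(im$shares), im$total, tolerance = 1e-8)
    perm <- sample(names(X))
    im2 <- importance(X[, perm], y, method = m)
    expect_equal(im2$shares[names(im$shares)], im$shares, tolerance = 1e-10)
  }
})

test_that("pmvd excludes a zero-coefficient correlated predictor", {
  set.seed(5)
  n <- 5000
  x1 <- rnorm(n)
  x2 <- 0.7 * x1 + rnorm(n, 0, sqrt(1 - 0.49))
  y <- x1 + rnorm(n)
  X <- data.frame(x1 = x1, x2 = x2)
  pm <- importance(X, y, method = "pmvd")
  lm_ <- importance(X, y, method = "lmg")
  expect_lt(pm$shares["x2"] / pm$total, 0.01)
  expect_gt(lm_$shares["x2"] / lm_$total, 0.05)
})

test_that("large candidate sets require the sampling mode", {
  set.seed(6)
  X <- as.data.frame(matrix(rnorm(60 * 13), 60))
  names(X) <- paste0("x", 1:13)
  y <- rnorm(60)
  expect_error(importance(X, y, method = "lmg"), "n_orderings")
  # sampling mode approximates the exact lattice on a small problem
  Xs <- X[, 1:4]; ys <- X$x1 + rnorm(60)
  exact <- importance(Xs, ys, method = "lmg")$shares
  samp <- importance(Xs, ys, method = "lmg", exact_max = 2,
                     n_orderings = 3000, seed = 1)$shares
  expect_equal(unname(samp), unname(exact), tolerance = 0.05)
})

test_that("subset R2 is consistent with its edge cases", {
  set.seed(7)
  X <- data.frame(a = rnorm(50), b = rnorm(50))
  y <- X$a + rnorm(50)
  expect_equal(subset_r2(X, y, character(0)), 0)
  expect_equal(subset_r2(X, y), summary(lm(y ~ a + b, data = X))$r.squared)
  expect_error(subset_r2(X, y, "zz"), "not in X")
})
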