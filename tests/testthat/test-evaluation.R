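test_that("LOOCV is exact for a noiseless linear outcome", {
  set.seed(1)
  X <- matrix(rnorm(40 * 3), 40, dimnames = list(NULL, c("a", "b", "c")))
  y <- X %*% c(1, -2, 0.5)
  ev <- loocv_regression(X, as.numeric(y))
  expect_lt(ev$mae, 1e-10)
  expect_equal(ev$r2_pred, 1, tolerance = 1e-10)
  expect_lte(ev$mae, ev$rmse)
})

test_that("explicit refits match the hat-matrix LOO identity", {
  set.seed(2)
  X <- matrix(rnorm(60 * 4), 60, dimnames = list(NULL, paste0("x", 1:4)))
  y <- X[, 1] + rnorm(60)
  ev <- loocv_regression(X, y)
  Z <- cbind(1, X)
  H <- Z %*% solve(crossprod(Z), t(Z))
  e <- residuals(lm(y ~ X))
  loo <- e / (1 - diag(H))
  expect_equal(y - ev$predictions, unname(loo), tolerance = 1e-8)
})

test_that("uninformative predictors give non-positive predictive R2", {
  r2p <- vapply(1:100, function(s) {
    set.seed(s)
    X <- matrix(rnorm(51 * 5), 51, dimnames = list(NULL, paste0("x", 1:5)))
    loocv_regression(X, rnorm(51))$r2_pred
  }, numeric(1))
  expect_lte(median(r2p), 0)
})

test_that("AUC matches exhaustive pair counting", {
  expect_equal(roc_auc(c(0.35, 0.8, 0.1, 0.4), c(1, 1, 0, 0)), 0.75)
  expect_equal(roc_auc(c(5, 6, 1, 2), c(1, 1, 0, 0)), 1)
  set.seed(3)
  for (i in 1:10) {
    n <- sample(20:200, 1)
    sc <- sample(seq(0, 1, 0.05), n, replace = TRUE)   # ties included
    lb <- rbinom(n, 1, 0.4)
    if (length(unique(lb)) < 2) next
    pos <- sc[lb == 1]; neg <- sc[lb == 0]
    cnt <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
    expect_equal(roc_auc(sc, lb), mean(cnt))
    expect_equal(roc_auc(-sc, lb), 1 - roc_auc(sc, lb))
  }
  expect_error(roc_auc(1:4, rep(1, 4)), "both classes")
})

test_that("transition datasets orient change vectors by their label", {
  set.seed(4)
  ch <- matrix(rnorm(30 * 4), 30, dimnames = list(NULL, paste0("f", 1:4)))
  ds <- make_transition_dataset(ch, seed = 9)
  for (i in seq_len(nrow(ch))) {
    if (ds$labels[i] == 1L) expect_equal(ds$X[i, ], -ch[i, ])
    else expect_equal(ds$X[i, ], ch[i, ])
  }
  # fair coin: class-1 fraction 0.5 across many draws
  fr <- vapply(1:1000, function(s)
    mean(make_transition_dataset(ch[1:30, ], seed = s)$labels), numeric(1))
  expect_equal(mean(fr), 0.5, tolerance = 0.015 / 0.5)
})

test_that("the transition pipeline is label-symmetric", {
  coh <- small_cohort(seed = 6)
  ch <- cohort_changes(coh)
  X <- as.data.frame(ch[, canonical_features()[1:6]])
  ds <- make_transition_dataset(X, seed = 2)
  ev1 <- suppressWarnings(transition_eval(ds))
  ds2 <- ds
  ds2$labels <- 1L - ds$labels
  ds2$X <- -ds$X
  ev2 <- suppressWarnings(transition_eval(ds2))
  expect_equal(ev2$auc, ev1$auc, tolerance = 1e-8)
})

test_that("a perfectly separating feature yields AUC 1", {
  set.seed(7)
  lab <- rep(c(0L, 1L), each = 15)
  X <- data.frame(f1 = ifelse(lab == 1, rnorm(30, 5), rnorm(30, -5)),
                  f2 = rnorm(30))
  ds <- structure(list(X = as.matrix(X), labels = lab, seed = 1),
                  class = "transition_dataset")
  ev <- suppressWarnings(transition_eval(ds))
  expect_equal(ev$auc, 1)
})

test_that("subscore prediction mirrors the main LOOCV and guards degeneracy", {
  set.seed(8)
  X <- matrix(rnorm(40 * 3), 40, dimnames = list(NULL, paste0("x", 1:3)))
  y <- X[, 1] + rnorm(40)
  same <- predict_subscores(X, data.frame(total = y))
  ref <- loocv_regression(X, y)
  expect_equal(same$total$mae, ref$mae)
  expect_equal(same$total$r2_pred, ref$r2_pred)
  expect_error(predict_subscores(X, data.frame(flat = rep(1, 40))),
               "zero variance")
})

test_that("planted loadings predict bradykinesia better than tremor", {
  wins <- vapply(1:25, function(s) {
    coh <- gen_cohort(synthetic_cohort_spec(n_hc = 4, seed = 300 + s))
    ch <- cohort_changes(coh)
    X <- as.data.frame(ch[, names(default_hypo_loadings())])
    sub <- predict_subscores(X, ch[, c("d_bradykinesia", "d_tremor")])
    sub$d_bradykinesia$r2_pred > sub$d_tremor$r2_pred
  }, logical(1))
  expect_gte(mean(wins), 0.9)
})
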