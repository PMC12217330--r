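test_that("paired comparison routes on normality and computes effect sizes", {
  coh <- gen_cohort(synthetic_cohort_spec(n_pd = 3, n_hc = 3, seed = 2))
  # plant exact differences [1, 2, 3]: Cohen's d = mean 2 / sd 1 = 2
  f <- coh$features
  n <- sum(f$state == "OFF")
  d <- c(1, 2, 3)
  f$sdF0_text[f$state == "ON"] <- f$sdF0_text[f$state == "OFF"] + d
  coh$features <- f
  res <- paired_compare(coh, "sdF0_text")
  expect_equal(res$effect_size, mean(d) / sd(d), tolerance = 1e-12)
  expect_equal(res$test, "paired_t")
  # degenerate: ON identical to OFF
  f$sdF0_text[f$state == "ON"] <- f$sdF0_text[f$state == "OFF"]
  coh$features <- f
  expect_warning(res0 <- paired_compare(coh, "sdF0_text"), "zero")
  expect_equal(res0$p_raw, 1)
  expect_equal(res0$effect_size, 0)
})

test_that("Shapiro routing picks the t-test at its nominal rate", {
  picks <- vapply(1:1000, function(s) {
    set.seed(s)
    shapiro.test(rnorm(51, 0.5, 1))$p.value >= 0.05
  }, logical(1))
  expect_equal(mean(picks), 0.95, tolerance = 0.03 / 0.95)
})

test_that("Holm adjustment matches hand-stepped values and its invariants", {
  expect_equal(holm_adjust(c(0.01, 0.04)), c(0.02, 0.04))
  expect_equal(holm_adjust(c(0.05, 0.05, 0.05)), c(0.15, 0.15, 0.15))
  expect_equal(holm_adjust(0.3), 0.3)
  expect_equal(holm_adjust(numeric(0)), numeric(0))
  set.seed(1)
  for (i in 1:20) {
    p <- runif(7)
    h <- holm_adjust(p)
    expect_true(all(h >= p & h <= 1))
    expect_true(all(diff(h[order(p)]) >= -1e-12))
  }
  expect_error(holm_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("effect size classification uses the conventional thresholds", {
  expect_equal(effect_size_classify(0.47), "medium")
  expect_equal(effect_size_classify(0.2), "small")
  expect_equal(effect_size_classify(-0.9), "large")
  expect_equal(effect_size_classify(0), "none")
  expect_equal(effect_size_classify(0.65), "medium-to-large")
  expect_error(effect_size_classify(NaN), "finite")
})

test_that("covariate-adjusted contrast recovers a planted group shift", {
  # planted +1 sd group shift: the 95% CI of the group coefficient covers
  # the truth at its nominal rate
  cover <- vapply(1:300, function(s) {
    set.seed(s)
    age_pd <- rnorm(50, 63, 8); age_hc <- rnorm(50, 67, 8)
    coh <- fake_hc_cohort(rnorm(50, 1, 1), rnorm(50, 0, 1), age_pd, age_hc,
                          moca_pd = rnorm(50, 26, 2), moca_hc = rnorm(50, 27, 2))
    r <- hc_adjusted_compare(coh, "sdF0_text", "OFF_vs_HC")
    half <- qt(0.975, 95) * r$se
    r$estimate - half <= 1 && 1 <= r$estimate + half
  }, logical(1))
  expect_equal(mean(cover), 0.95, tolerance = 0.03 / 0.95)
  # no planted effect: standardized beta near zero on average
  betas <- vapply(1:100, function(s) {
    set.seed(1000 + s)
    coh <- fake_hc_cohort(rnorm(50), rnorm(50), rnorm(50, 63, 8),
                          rnorm(50, 67, 8), rnorm(50, 26, 2), rnorm(50, 27, 2))
    hc_adjusted_compare(coh, "sdF0_text", "OFF_vs_HC")$effect_size
  }, numeric(1))
  expect_lt(mean(abs(betas)), 0.1)
  # purely age-driven feature: group coefficient vanishes after adjustment
  confs <- vapply(1:100, function(s) {
    set.seed(2000 + s)
    age_pd <- rnorm(60, 60, 8); age_hc <- rnorm(60, 70, 8)
    coh <- fake_hc_cohort(0.1 * age_pd + rnorm(60, 0, 0.2),
                          0.1 * age_hc + rnorm(60, 0, 0.2),
                          age_pd, age_hc, rnorm(60, 26, 2), rnorm(60, 27, 2))
    hc_adjusted_compare(coh, "sdF0_text", "OFF_vs_HC")$effect_size
  }, numeric(1))
  expect_lt(abs(mean(confs)), 0.1)
  # constant covariate -> error naming it
  coh <- fake_hc_cohort(rnorm(10), rnorm(10), rep(65, 10), rep(65, 10))
  expect_error(hc_adjusted_compare(coh, "sdF0_text"), "age")
})

test_that("group estimate is invariant to affine covariate rescaling", {
  set.seed(7)
  age_pd <- rnorm(40, 63, 8); age_hc <- rnorm(40, 67, 8)
  coh <- fake_hc_cohort(rnorm(40, 1), rnorm(40), age_pd, age_hc,
                        rnorm(40, 26, 2), rnorm(40, 27, 2))
  r1 <- hc_adjusted_compare(coh, "sdF0_text")
  coh2 <- coh
  coh2$clinical$age <- coh$clinical$age * 12 + 100
  coh2$hc$age <- coh$hc$age * 12 + 100
  r2 <- hc_adjusted_compare(coh2, "sdF0_text")
  expect_equal(r2$effect_size, r1$effect_size, tolerance = 1e-10)
  expect_equal(r2$p_raw, r1$p_raw, tolerance = 1e-10)
})

test_that("test-retest reliability behaves at its planted levels", {
  feats <- canonical_features()[1:8]
  mk <- function(M) { colnames(M) <- feats; as.data.frame(M) }
  set.seed(3)
  off1 <- mk(matrix(rnorm(10 * 8), 10))
  expect_true(all(abs(test_retest(off1, off1)$r - 1) < 1e-12))
  # independent noise: weak correlations at n = 10
  rs <- unlist(lapply(1:100, function(s) {
    set.seed(s)
    abs(test_retest(mk(matrix(rnorm(80), 10)), mk(matrix(rnorm(80), 10)))$r)
  }))
  expect_lt(mean(rs), 0.3)
  # planted reliability 0.9: x2 = x1 + noise with var chosen by attenuation
  rs9 <- unlist(lapply(1:100, function(s) {
    set.seed(s)
    M1 <- matrix(rnorm(80), 10)
    M2 <- M1 + matrix(rnorm(80, 0, sqrt(1 / 0.81 - 1)), 10)
    test_retest(mk(M1), mk(M2))$r
  }))
  expect_equal(mean(rs9), 0.9, tolerance = 0.05 / 0.9)
  # zero variance -> NA marker, not NaN propagation
  offc <- mk(matrix(1, 5, 8))
  r0 <- test_retest(offc, mk(matrix(rnorm(40), 5)))
  expect_true(all(is.na(r0$r)))
})

test_that("paired-t power matches the noncentral-t closed form", {
  expect_equal(round(power_paired_t(51, 0.5), 2), 0.94)
  expect_equal(round(power_paired_t(51, 0.7), 3), 0.998)
  expect_equal(power_paired_t(51, 0), 0.05, tolerance = 1e-10)
  expect_gt(power_paired_t(51, 0.5, two_sided = FALSE),
            power_paired_t(51, 0.5))
  expect_error(power_paired_t(1, 0.5), "n")
  expect_error(power_paired_t(51, 0.5, alpha = 1.5), "alpha")
})

test_that("rank-biserial equals one when all differences share a sign", {
  coh <- small_cohort(seed = 4)
  f <- coh$features
  n <- sum(f$state == "OFF")
  set.seed(1)
  d <- abs(rcauchy(n)) + 0.1   # heavy-tailed: forces the Wilcoxon route
  f$DPI_text[f$state == "ON"] <- f$DPI_text[f$state == "OFF"] + d
  coh$features <- f
  res <- paired_compare(coh, "DPI_text")
  expect_equal(res$test, "wilcoxon")
  expect_equal(res$effect_size, 1)
})
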