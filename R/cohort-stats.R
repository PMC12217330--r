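# Univariate OFF/ON statistics: Shapiro-routed paired tests, Holm-Bonferroni
# correction, effect sizes, covariate-adjusted contrasts against healthy
# controls, test-retest reliability, and the paired-t power calculation.

#' Paired OFF/ON comparison for one biomarker
#'
#' Routes on normality of the paired differences (Shapiro-Wilk at
#' `alpha_normality`): normal differences get a paired t-test with Cohen's d
#' (mean difference / sd of differences); otherwise a Wilcoxon signed-rank
#' test with the matched-pairs rank-biserial correlation
#' `(W+ - W-) / (W+ + W-)`.
#'
#' @param cohort A `paired_cohort`.
#' @param feature A canonical biomarker name.
#' @param alpha_normality Shapiro-Wilk routing level.
#' @return One-row tibble: `feature`, `test`, `statistic`, `p_raw`, `p_holm`
#'   (`NA` until adjusted across a family), `effect_size`, `effect_type`.
#' @export
paired_compare <- function(cohort, feature, alpha_normality = 0.05) {
  ch <- cohort_changes(cohort)
  if (!feature %in% names(ch)) stop("unknown feature: ", feature, call. = FALSE)
  d <- ch[[feature]]
  d <- d[is.finite(d)]
  if (length(d) < 3) stop("need >= 3 complete pairs", call. = FALSE)
  row <- function(test, statistic, p, es, et)
    tibble::tibble(feature = feature, test = test, statistic = statistic,
                   p_raw = p, p_holm = NA_real_, effect_size = es,
                   effect_type = et)
  if (all(d == 0)) {
    warning("all paired differences are zero for ", feature, call. = FALSE)
    return(row("wilcoxon", 0, 1, 0, "rank_biserial"))
  }
  sw_p <- if (sd(d) > 0) shapiro.test(d)$p.value else 0
  if (sw_p >= alpha_normality) {
    tt <- t.test(d)
    row("paired_t", unname(tt$statistic), tt$p.value,
        mean(d) / sd(d), "cohen_d")
  } else {
    wt <- suppressWarnings(wilcox.test(d, exact = FALSE, correct = TRUE))
    dn <- d[d != 0]
    r <- rank(abs(dn))
    wp <- sum(r[dn > 0]); wm <- sum(r[dn < 0])
    row("wilcoxon", unname(wt$statistic), wt$p.value,
        (wp - wm) / (wp + wm), "rank_biserial")
  }
}

#' Paired comparisons across a biomarker family with Holm adjustment
#'
#' @param cohort A `paired_cohort`.
#' @param features Biomarker names (default: all 16).
#' @param alpha_normality Shapiro-Wilk routing level.
#' @return Tibble with one row per feature, `p_holm` filled in.
#' @export
paired_compare_all <- function(cohort, features = canonical_features(),
                               alpha_normality = 0.05) {
  res <- dplyr::bind_rows(lapply(features, function(f)
    paired_compare(cohort, f, alpha_normality)))
  res$p_holm <- holm_adjust(res$p_raw)
  res
}

#' Holm-Bonferroni step-down adjustment
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, order preserved relative to the input.
#' @export
holm_adjust <- function(p_values) {
  if (!length(p_values)) return(numeric(0))
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  p.adjust(p_values, method = "holm")
}

#' Classify an effect size magnitude
#'
#' Thresholds on the absolute value: 0 is `none`, up to 0.2 `small`, up to
#' 0.5 `medium`, at least 0.8 `large`; the open gap (0.5, 0.8) is labeled
#' `medium-to-large`.
#'
#' @param value Effect size (any sign).
#' @return Character label.
#' @export
effect_size_classify <- function(value) {
  if (!is.finite(value)) stop("effect size must be finite", call. = FALSE)
  a <- abs(value)
  if (a == 0) "none"
  else if (a <= 0.2) "small"
  else if (a <= 0.5) "medium"
  else if (a < 0.8) "medium-to-large"
  else "large"
}

#' Covariate-adjusted PD-vs-HC contrast for one biomarker
#'
#' Linear model `feature ~ group + age + gender + MoCA` over one PD
#' medication state plus the healthy controls; the effect size is the
#' standardized group coefficient.
#'
#' @param cohort A `paired_cohort` with HC rows.
#' @param feature A canonical biomarker name.
#' @param group `"OFF_vs_HC"` or `"ON_vs_HC"`.
#' @return One-row tibble as in [paired_compare()] with `test = "regression"`
#'   and `effect_type = "std_beta"`.
#' @export
hc_adjusted_compare <- function(cohort, feature,
                                group = c("OFF_vs_HC", "ON_vs_HC")) {
  group <- match.arg(group)
  stopifnot(inherits(cohort, "paired_cohort"))
  if (is.null(cohort$hc) || !nrow(cohort$hc))
    stop("cohort has no healthy-control rows", call. = FALSE)
  state <- if (group == "OFF_vs_HC") "OFF" else "ON"
  f <- cohort$features; cl <- cohort$clinical
  pd <- f[f$state == state, c("subject", feature)]
  clm <- cl[cl$state == state, c("subject", "age", "gender", "moca")]
  pd <- dplyr::inner_join(pd, clm, by = "subject")
  hc <- cohort$hc[, c(feature, "age", "gender", "moca")]
  df <- rbind(
    data.frame(value = pd[[feature]], grp = 1, age = pd$age,
               gender = pd$gender, moca = pd$moca),
    data.frame(value = hc[[feature]], grp = 0, age = hc$age,
               gender = hc$gender, moca = hc$moca))
  if (sum(df$grp == 1) < 3 || sum(df$grp == 0) < 3)
    stop("need >= 3 subjects per group", call. = FALSE)
  df$gender <- as.integer(df$gender == "m")
  for (v in c("age", "gender", "moca"))
    if (sd(df[[v]]) == 0)
      stop("singular design: covariate `", v, "` is constant", call. = FALSE)
  fit <- lm(value ~ grp + age + gender + moca, data = df)
  if (anyNA(coef(fit)))
    stop("singular design in covariates", call. = FALSE)
  sm <- summary(fit)$coefficients
  tibble::tibble(feature = feature, test = "regression",
                 statistic = sm["grp", "t value"],
                 estimate = sm["grp", "Estimate"],
                 se = sm["grp", "Std. Error"],
                 p_raw = sm["grp", "Pr(>|t|)"], p_holm = NA_real_,
                 effect_size = coef(fit)[["grp"]] * sd(df$grp) / sd(df$value),
                 effect_type = "std_beta")
}

#' Test-retest reliability across repeated OFF assessments
#'
#' Per-feature correlation between two OFF-state biomarker matrices: Pearson
#' when both margins pass Shapiro-Wilk at 0.05, Spearman otherwise. Features
#' with zero variance return an `NA` marker.
#'
#' @param off1,off2 Matrices/data frames of paired rows with canonical
#'   feature columns.
#' @return Tibble: `feature`, `method`, `r`.
#' @export
test_retest <- function(off1, off2) {
  off1 <- as.data.frame(off1); off2 <- as.data.frame(off2)
  common <- intersect(names(off1), canonical_features())
  if (!length(common)) stop("no canonical feature columns", call. = FALSE)
  if (nrow(off1) != nrow(off2) || nrow(off1) < 3)
    stop("need paired rows, n >= 3", call. = FALSE)
  rows <- lapply(common, function(k) {
    x <- off1[[k]]; y <- off2[[k]]
    ok <- is.finite(x) & is.finite(y)
    x <- x[ok]; y <- y[ok]
    if (length(x) < 3 || sd(x) == 0 || sd(y) == 0)
      return(tibble::tibble(feature = k, method = NA_character_, r = NA_real_))
    normal <- sd(x) > 0 && sd(y) > 0 &&
      shapiro.test(x)$p.value >= 0.05 && shapiro.test(y)$p.value >= 0.05
    m <- if (normal) "pearson" else "spearman"
    tibble::tibble(feature = k, method = m, r = cor(x, y, method = m))
  })
  dplyr::bind_rows(rows)
}

#' Exact power of a paired t-test
#'
#' Noncentral-t power with `df = n - 1` and noncentrality `d * sqrt(n)`.
#'
#' @param n Number of pairs.
#' @param d Effect size (Cohen's d of the paired differences).
#' @param alpha Significance level.
#' @param two_sided Two-sided test?
#' @return Power in `[0, 1]`.
#' @export
power_paired_t <- function(n, d, alpha = 0.05, two_sided = TRUE) {
  if (n < 2) stop("`n` must be >= 2", call. = FALSE)
  if (!is.finite(d)) stop("`d` must be finite", call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("`alpha` must be in (0, 1)", call. = FALSE)
  df <- n - 1
  ncp <- d * sqrt(n)
  if (two_sided) {
    tc <- qt(1 - alpha / 2, df)
    pt(-tc, df, ncp) + 1 - pt(tc, df, ncp)
  } else {
    1 - pt(qt(1 - alpha, df), df, ncp)
  }
}
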