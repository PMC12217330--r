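# Shared fixtures: small synthetic signals and cohorts built in code.

make_tone <- function(freq = 150, dur = 1, rate = 48000, amp = 0.4,
                      task = "phon") {
  t <- (seq_len(round(dur * rate)) - 1) / rate
  waveform(amp * sin(2 * pi * freq * t), rate, task)
}

quick_phon <- function(seed = 1, ...) {
  synth_phonation(audio_ground_truth("phon", seed = seed, ...))
}

# a tiny cohort for structural tests (fast to generate)
small_cohort <- function(seed = 1, ...) {
  gen_cohort(synthetic_cohort_spec(n_pd = 12, n_hc = 10, seed = seed, ...))
}

# minimal paired_cohort built by hand: one feature, custom values
fake_hc_cohort <- function(pd_value, hc_value, age_pd, age_hc,
                           moca_pd = NULL, moca_hc = NULL,
                           feature = "sdF0_text") {
  n <- length(pd_value); m <- length(hc_value)
  if (is.null(moca_pd)) moca_pd <- rep(26, n)
  if (is.null(moca_hc)) moca_hc <- rep(27, m)
  subj <- sprintf("PD%02d", seq_len(n))
  feat <- tibble::tibble(subject = rep(subj, 2),
                         state = rep(c("OFF", "ON"), each = n))
  feat[[feature]] <- c(pd_value, pd_value)
  clin <- tibble::tibble(subject = rep(subj, 2),
                         state = rep(c("OFF", "ON"), each = n),
                         age = rep(age_pd, 2),
                         gender = rep(rep(c("m", "f"), length.out = n), 2),
                         moca = rep(moca_pd, 2))
  hc <- tibble::tibble(subject = sprintf("HC%02d", seq_len(m)),
                       age = age_hc,
                       gender = rep(c("m", "f"), length.out = m),
                       moca = moca_hc)
  hc[[feature]] <- hc_value
  structure(list(features = feat, clinical = clin, hc = hc, truth = NULL),
            class = "paired_cohort")
}

# brute-force ordering-enumeration oracle for importance decompositions
enumerate_importance <- function(X, y, method = "lmg") {
  X <- as.data.frame(X)
  p <- ncol(X)
  perms <- pracma::perms(seq_len(p))
  full <- subset_r2(X, y)
  shares <- numeric(p)
  wts <- numeric(nrow(perms))
  incs <- matrix(0, nrow(perms), p)
  for (i in seq_len(nrow(perms))) {
    ord <- perms[i, ]
    r2s <- vapply(seq_len(p), function(j) subset_r2(X, y, ord[seq_len(j)]),
                  numeric(1))
    incs[i, ord] <- diff(c(0, r2s))
    wts[i] <- if (method == "pmvd")
      prod(1 / pmax(full - r2s[seq_len(p - 1)], 1e-12)) else 1
  }
  colSums(incs * wts) / sum(wts)
}
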