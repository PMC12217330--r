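test_that("F0 tracking recovers a pure tone and rejects noise", {
  tr <- track_f0(make_tone(150, dur = 1))
  expect_equal(median(tr$f0, na.rm = TRUE), 150, tolerance = 1 / 150)
  # white noise: fewer than 5% of frames called voiced, across seeds
  frac <- vapply(1:20, function(s) {
    set.seed(s)
    mean(track_f0(waveform(rnorm(38400) * 0.1, 48000, "text"))$voiced)
  }, numeric(1))
  expect_lt(mean(frac), 0.05)
})

test_that("vibrato-implied sdF0 matches the sinusoid closed form", {
  # sd of a sinusoid is amplitude / sqrt(2): +-2 st at 5 Hz -> 1.414 st
  w <- synth_phonation(audio_ground_truth("phon", f0_mean = 120,
                                          f0_sd = 2 / sqrt(2), vibrato_rate = 5,
                                          snr = 35, phonation_dur = 3, seed = 2))
  tr <- track_f0(w)
  expect_equal(sd(12 * log2(tr$f0[tr$voiced])), 2 / sqrt(2), tolerance = 0.11)
})

test_that("intensity contour obeys the log laws", {
  w <- make_tone(150, dur = 1)
  ic <- intensity_contour(w)
  expect_lt(sd(ic$intensity), 0.2)
  w2 <- waveform(w$samples * 2, w$rate, w$task)
  ic2 <- intensity_contour(w2)
  expect_equal(ic2$intensity - ic$intensity,
               rep(20 * log10(2), length(ic$intensity)), tolerance = 1e-6)
  expect_equal(sd(ic2$intensity), sd(ic$intensity), tolerance = 1e-9)
  # silence floors at the configured dB floor, never -Inf
  z <- intensity_contour(waveform(numeric(4800), 48000, "phon"))
  expect_true(all(is.finite(z$intensity)))
})

test_that("segmentation recovers planted pauses and syllable nuclei", {
  tt <- audio_ground_truth("text", pause_durations = c(0.2, 0.4),
                           syllable_count = 10, intensity_sd = 1.5,
                           f0_sd = 1, snr = 35, seed = 9)
  w <- synth_reading(tt)
  seg <- segment_speech_pauses(track_f0(w), w = w)
  lens <- seg$pause_intervals[, 2] - seg$pause_intervals[, 1]
  expect_equal(sort(lens), c(0.2, 0.4), tolerance = 0.012 / 0.2)
  # syllable nuclei within +-1 of planted, across seeds
  counts <- vapply(1:20, function(s) {
    tt <- audio_ground_truth("text", pause_durations = c(0.25, 0.3),
                             syllable_count = 10, intensity_sd = 1.5,
                             f0_sd = 1, snr = 35, seed = s)
    w <- synth_reading(tt)
    length(segment_speech_pauses(track_f0(w), w = w)$syllable_times)
  }, numeric(1))
  expect_true(all(abs(counts - 10) <= 1))
  # continuous phonation: no pauses
  segp <- segment_speech_pauses(track_f0(quick_phon(seed = 1)))
  expect_equal(nrow(segp$pause_intervals), 0)
})

test_that("phonation features recover planted MPT, slope, and HNR", {
  w <- synth_phonation(audio_ground_truth("phon", phonation_dur = 3,
                                          intensity_slope = -2, snr = 20,
                                          seed = 4))
  v <- phonation_features(w)
  expect_equal(unname(v["MPT_phon"]), 3, tolerance = 0.05 / 3)
  expect_equal(unname(v["Int_slope_phon"]), -2, tolerance = 0.2 / 2)
  # HNR of a harmonic + white-noise mixture equals the SNR in expectation
  expect_equal(unname(v["HNR_phon"]), 20, tolerance = 3 / 20)
  # sub-threshold stretch yields missing markers
  short <- synth_phonation(audio_ground_truth("phon", phonation_dur = 0.5,
                                              seed = 5))
  short$samples <- short$samples * c(rep(1, 48000 * 0.3), rep(0, length(short$samples) - 14400))
  expect_warning(v2 <- phonation_features(short), "missing")
  expect_true(all(is.na(v2[c("MPT_phon", "HNR_phon")])))
})

test_that("ddk VOT handles zero gap and refuses pure noise", {
  v0 <- ddk_features(synth_ddk(audio_ground_truth("ddk", vot_gap = 0,
                                                  syllable_count = 12,
                                                  snr = 35, seed = 6)))
  expect_lte(v0["VOT_ddk"], 10)
  set.seed(8)
  noise <- waveform(rnorm(48000) * 0.2, 48000, "ddk")
  expect_warning(vn <- ddk_features(noise), "syllables")
  expect_true(is.na(vn["VOT_ddk"]))
})

test_that("all 16 features are amplitude-scale invariant", {
  truths <- list(
    phon = audio_ground_truth("phon", phonation_dur = 2, snr = 30, seed = 21),
    ddk = audio_ground_truth("ddk", syllable_count = 12, snr = 30, seed = 22),
    text = audio_ground_truth("text", pause_durations = c(0.2, 0.3),
                              syllable_count = 12, f0_sd = 1,
                              intensity_sd = 1.5, snr = 30, seed = 23))
  recs <- list(phon = synth_phonation(truths$phon),
               ddk = synth_ddk(truths$ddk),
               text = synth_reading(truths$text))
  v1 <- extract_all(recs)
  half <- lapply(recs, function(w) waveform(w$samples * 0.5, w$rate, w$task))
  v2 <- extract_all(half)
  expect_equal(v2, v1, tolerance = 1e-6)
})

test_that("time reversal preserves distributional features and negates slope", {
  w <- synth_phonation(audio_ground_truth("phon", phonation_dur = 2.5,
                                          intensity_slope = -1.5, f0_sd = 0.5,
                                          snr = 30, seed = 31))
  wr <- waveform(rev(w$samples), w$rate, "phon")
  v <- phonation_features(w); vr <- phonation_features(wr)
  expect_equal(unname(vr["Int_slope_phon"]), -unname(v["Int_slope_phon"]),
               tolerance = 0.05)
  expect_equal(unname(vr["Int_sd_phon"]), unname(v["Int_sd_phon"]),
               tolerance = 0.05)
  expect_equal(unname(vr["MPT_phon"]), unname(v["MPT_phon"]), tolerance = 0.02)
  tt <- audio_ground_truth("text", pause_durations = c(0.2, 0.3),
                           syllable_count = 12, f0_sd = 1, intensity_sd = 1.5,
                           snr = 30, seed = 32)
  wt <- synth_reading(tt)
  wtr <- waveform(rev(wt$samples), wt$rate, "text")
  ft <- text_features(wt); ftr <- text_features(wtr)
  for (k in c("sdF0_text", "Int_sd_text", "Int_kurt_text", "LTAS_mean",
              "LTAS_sd", "LTAS_skew", "LTAS_kurt"))
    expect_equal(unname(ftr[k]), unname(ft[k]), tolerance = 0.05,
                 label = paste("reversed", k))
})

test_that("extract_all averages repeats and marks absent tasks", {
  p1 <- synth_phonation(audio_ground_truth("phon", phonation_dur = 2.8,
                                           snr = 30, seed = 41))
  p2 <- synth_phonation(audio_ground_truth("phon", phonation_dur = 3.2,
                                           snr = 30, seed = 42))
  v <- extract_all(list(phon = list(p1, p2)))
  expect_equal(unname(v["MPT_phon"]), 3, tolerance = 0.02)
  expect_true(all(is.na(v[c("sdF0_text", "VOT_ddk")])))
  tt <- audio_ground_truth("text", pause_durations = 0.25, syllable_count = 8,
                           f0_sd = 1, snr = 30, seed = 43)
  vt <- extract_all(list(text = synth_reading(tt)))
  expect_true(all(is.na(vt[c("MPT_phon", "VOT_ddk")])))
  expect_true(all(is.finite(vt[c("sdF0_text", "NSR_text", "LTAS_mean")])))
  expect_error(extract_all(list()), "at least one")
})
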