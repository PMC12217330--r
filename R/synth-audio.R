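# Ground-truthed audio synthesis for the three speech tasks.
#
# The glottal source is a sum of 10 harmonics with a -12 dB/octave rolloff:
# simple enough that every planted parameter (F0 contour, intensity envelope,
# SNR, segment timing) stays analytically recoverable, which is the point of
# the generator. Formant filtering is deliberately absent so the long-term
# average spectrum moments follow directly from the source + noise model.

SYNTH_RATE <- 48000
SYNTH_MARGIN <- 0.15   # leading/trailing silence, s (spec floor is 0.1)

# Harmonic source for an instantaneous F0 contour (Hz per sample).
harmonic_source <- function(f0_inst, rate, n_harm = 10) {
  phase <- 2 * pi * cumsum(f0_inst) / rate
  amps <- (seq_len(n_harm))^-2          # -12 dB/octave
  x <- numeric(length(phase))
  nyq <- rate / 2
  fmax <- max(f0_inst)
  for (k in seq_len(n_harm)) {
    if (k * fmax >= nyq) break
    x <- x + amps[k] * sin(k * phase)
  }
  x / sqrt(mean(x^2))
}

raised_cosine_fade <- function(n_total, n_fade) {
  env <- rep(1, n_total)
  if (n_fade > 0 && n_total >= 2 * n_fade) {
    ramp <- 0.5 * (1 - cos(pi * seq_len(n_fade) / n_fade))
    env[seq_len(n_fade)] <- ramp
    env[n_total - n_fade + seq_len(n_fade)] <- rev(ramp)
  }
  env
}

# Additive white recording noise over the whole file, scaled so that
# signal power over `active` / noise power = 10^(snr/10).
add_recording_noise <- function(x, active, snr) {
  p_sig <- mean(x[active]^2)
  sigma <- sqrt(p_sig / 10^(snr / 10))
  x + rnorm(length(x), 0, sigma)
}

finish_wave <- function(x, task) {
  peak <- max(abs(x))
  if (peak > 0.99) x <- x * (0.99 / peak)
  waveform(x, SYNTH_RATE, task)
}

#' Synthesize a sustained /a/ phonation recording
#'
#' Harmonic source with mean F0 plus sinusoidal vibrato (amplitude
#' `f0_sd * sqrt(2)` semitones at `vibrato_rate` Hz, so the F0 standard
#' deviation equals `f0_sd`), a linear intensity trend of `intensity_slope`
#' dB/s, 10 ms onset/offset fades, additive white noise at `snr` dB, and
#' 150 ms of leading/trailing silence.
#'
#' @param truth An [audio_ground_truth()] with `task = "phon"`.
#' @return A [waveform()] at 48 kHz.
#' @export
synth_phonation <- function(truth) {
  stopifnot(inherits(truth, "audio_ground_truth"))
  if (truth$task != "phon") stop("truth$task must be 'phon'", call. = FALSE)
  if (truth$phonation_dur < 0.5)
    stop("`phonation_dur` must be >= 0.5 s", call. = FALSE)
  with_truth_seed(truth$seed, {
    fs <- SYNTH_RATE
    n <- round(truth$phonation_dur * fs)
    t <- (seq_len(n) - 1) / fs
    vib_st <- truth$f0_sd * sqrt(2) * sin(2 * pi * truth$vibrato_rate * t)
    f0 <- truth$f0_mean * 2^(vib_st / 12)
    x <- harmonic_source(f0, fs)
    x <- x * raised_cosine_fade(n, round(0.01 * fs))
    x <- x * 10^(truth$intensity_slope * t / 20)
    x <- x * (0.4 / max(abs(x)))
    pad <- numeric(round(SYNTH_MARGIN * fs))
    y <- c(pad, x, pad)
    active <- seq.int(length(pad) + 1L, length(pad) + n)
    finish_wave(add_recording_noise(y, active, truth$snr), "phon")
  })
}

#' Synthesize a /pa/-/ta/-/ka/ syllable repetition (DDK) recording
#'
#' Each syllable is a 4 ms broadband burst, aspiration noise (high-pass,
#' above 2.5 kHz) until voicing onset at `vot_gap` ms after the burst onset,
#' then a voiced vowel segment at `f0_mean`. Syllables repeat at `syll_rate`
#' per second.
#'
#' @param truth An [audio_ground_truth()] with `task = "ddk"`.
#' @return A [waveform()] at 48 kHz.
#' @export
synth_ddk <- function(truth) {
  stopifnot(inherits(truth, "audio_ground_truth"))
  if (truth$task != "ddk") stop("truth$task must be 'ddk'", call. = FALSE)
  if (truth$syllable_count < 3L)
    stop("`syllable_count` must be >= 3 for a ddk recording", call. = FALSE)
  period <- 1 / truth$syll_rate
  vot_s <- truth$vot_gap / 1000
  if (vot_s + 0.05 > period)
    stop("`vot_gap` too long for the syllable period", call. = FALSE)
  with_truth_seed(truth$seed, {
    fs <- SYNTH_RATE
    burst_dur <- 0.004
    vowel_dur <- min(0.12, period - vot_s - 0.01)
    n_total <- round((2 * SYNTH_MARGIN + truth$syllable_count * period) * fs)
    y <- numeric(n_total)
    hp <- signal::butter(4, 2500 / (fs / 2), type = "high")
    active <- logical(n_total)
    for (i in seq_len(truth$syllable_count)) {
      t0 <- SYNTH_MARGIN + (i - 1) * period
      i0 <- round(t0 * fs) + 1L
      # burst: short, loud, broadband
      nb <- round(burst_dur * fs)
      burst <- rnorm(nb) * raised_cosine_fade(nb, round(nb / 4))
      burst <- burst * (0.9 / max(abs(burst)))
      y[i0:(i0 + nb - 1L)] <- y[i0:(i0 + nb - 1L)] + burst
      # aspiration from burst offset to voicing onset
      na <- round((vot_s - burst_dur) * fs)
      if (na > 24) {
        asp <- signal::filtfilt(hp, rnorm(na + 200))[101:(100 + na)]
        asp <- asp / sd(asp) * 0.05
        ia <- i0 + nb
        y[ia:(ia + na - 1L)] <- y[ia:(ia + na - 1L)] + asp
      }
      # voiced vowel
      nv <- round(vowel_dur * fs)
      vow <- harmonic_source(rep(truth$f0_mean, nv), fs)
      vow <- vow * raised_cosine_fade(nv, round(0.008 * fs))
      vow <- vow * (0.45 / max(abs(vow)))
      iv <- i0 + round(vot_s * fs)
      y[iv:(iv + nv - 1L)] <- y[iv:(iv + nv - 1L)] + vow
      active[i0:(iv + nv - 1L)] <- TRUE
    }
    finish_wave(add_recording_noise(y, which(active), truth$snr), "ddk")
  })
}

#' Synthesize a reading-passage recording
#'
#' Alternating voiced pseudo-syllabic stretches and silent pauses of exactly
#' `pause_durations`. The `syllable_count` syllables (0.2 s each, amplitude
#' humps dipping 10.5 dB between nuclei) are split as evenly as possible
#' across the `length(pause_durations) + 1` stretches. F0 follows a slow
#' wander scaled to a standard deviation of `f0_sd` semitones; per-syllable
#' gains are scaled to a standard deviation of `intensity_sd` dB.
#'
#' Pauses shorter than the 60 ms segmentation floor trigger a warning but are
#' synthesized as requested.
#'
#' @param truth An [audio_ground_truth()] with `task = "text"`.
#' @return A [waveform()] at 48 kHz.
#' @export
synth_reading <- function(truth) {
  stopifnot(inherits(truth, "audio_ground_truth"))
  if (truth$task != "text") stop("truth$task must be 'text'", call. = FALSE)
  if (!length(truth$pause_durations))
    stop("`pause_durations` must be non-empty for a reading recording", call. = FALSE)
  n_stretch <- length(truth$pause_durations) + 1L
  if (truth$syllable_count < n_stretch)
    stop("need at least one syllable per voiced stretch", call. = FALSE)
  if (any(truth$pause_durations < 0.06))
    warning("pause(s) shorter than the 60 ms segmentation floor", call. = FALSE)
  with_truth_seed(truth$seed, {
    fs <- SYNTH_RATE
    syll_dur <- 0.2
    n_syll_tot <- truth$syllable_count
    counts <- diff(round(seq(0, n_syll_tot, length.out = n_stretch + 1L)))
    counts[counts < 1L] <- 1L
    # per-syllable gains in dB, scaled to an exact sd of intensity_sd
    gains_db <- rnorm(n_syll_tot)
    if (n_syll_tot >= 2 && truth$intensity_sd > 0) {
      gains_db <- (gains_db - mean(gains_db)) / sd(gains_db) * truth$intensity_sd
    } else gains_db <- rep(0, n_syll_tot)
    # slow F0 wander: spline through control points every 250 ms
    total_speech <- n_syll_tot * syll_dur
    n_ctrl <- max(4L, ceiling(total_speech / 0.25))
    ctrl <- rnorm(n_ctrl)
    n_sp <- round(total_speech * fs)
    wander <- spline(seq(0, 1, length.out = n_ctrl), ctrl, n = n_sp)$y
    wander <- if (truth$f0_sd > 0 && sd(wander) > 0)
      (wander - mean(wander)) / sd(wander) * truth$f0_sd else rep(0, n_sp)
    f0_speech <- truth$f0_mean * 2^(wander / 12)
    src <- harmonic_source(f0_speech, fs)
    # assemble stretches and pauses
    nsy <- round(syll_dur * fs)
    dip <- 10^(-10.5 / 20)
    bump <- dip + (1 - dip) * 0.5 * (1 - cos(2 * pi * seq_len(nsy) / nsy))
    pieces <- list()
    isy <- 0L
    used <- 0L
    for (s in seq_len(n_stretch)) {
      env <- numeric(0)
      for (j in seq_len(counts[s])) {
        isy <- isy + 1L
        env <- c(env, bump * 10^(gains_db[isy] / 20))
      }
      nseg <- length(env)
      seg <- src[(used + 1L):(used + nseg)] * env *
        raised_cosine_fade(nseg, round(0.01 * fs))
      used <- used + nseg
      pieces[[length(pieces) + 1L]] <- seg
      if (s < n_stretch)
        pieces[[length(pieces) + 1L]] <-
          numeric(round(truth$pause_durations[s] * fs))
    }
    body <- unlist(pieces)
    body <- body * (0.45 / max(abs(body)))
    pad <- numeric(round(SYNTH_MARGIN * fs))
    y <- c(pad, body, pad)
    active <- which(abs(y) > 0)
    finish_wave(add_recording_noise(y, active, truth$snr), "text")
  })
}
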