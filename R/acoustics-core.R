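# Frame-based acoustic analysis primitives.
#
# Defaults (frame 40 ms, hop 10 ms, F0 range 60-400 Hz, autocorrelation
# voicing threshold 0.45) are fixed here and shared by every feature
# extractor; see the methods vignette for the rationale behind each.

DB_FLOOR <- -120

amp_db <- function(rms) 20 * log10(pmax(rms, 10^(DB_FLOOR / 20)))

# Start times of analysis frames for a signal of `dur` seconds.
frame_starts <- function(dur, frame, hop) {
  n <- floor((dur - frame) / hop + 1e-9) + 1
  if (n < 1) return(numeric(0))
  (seq_len(n) - 1) * hop
}

# Windowed, window-corrected normalized autocorrelation per frame, plus the
# best peak in the pitch lag range. Returns one row per frame.
acf_track <- function(x, fs, frame = 0.04, hop = 0.01,
                      f_min = 60, f_max = 400) {
  dur <- length(x) / fs
  starts <- frame_starts(dur, frame, hop)
  nfr <- length(starts)
  frame_n <- round(frame * fs)
  if (nfr == 0L)
    return(list(times = numeric(0), f0 = numeric(0), peak_r = numeric(0),
                int_db = numeric(0), frame = frame, hop = hop, dur = dur))
  idx <- outer(seq_len(frame_n) - 1L, round(starts * fs) + 1L, "+")
  M <- matrix(x[idx], nrow = frame_n)
  rms <- sqrt(colMeans(M^2))
  M <- sweep(M, 2, colMeans(M))
  win <- 0.5 * (1 - cos(2 * pi * (seq_len(frame_n) - 1) / (frame_n - 1)))
  N <- 2^ceiling(log2(2 * frame_n))
  lmin <- max(2L, floor(fs / f_max))
  lmax <- min(frame_n - 1L, ceiling(fs / f_min))
  # FFT-based autocorrelation of all frames at once
  P <- Mod(mvfft(rbind(M * win, matrix(0, N - frame_n, nfr))))^2
  A <- Re(mvfft(P, inverse = TRUE)) / N
  aw <- Re(fft(Mod(fft(c(win, numeric(N - frame_n))))^2, inverse = TRUE)) / N
  rw <- aw / aw[1]
  a0 <- A[1, ]
  ok <- a0 > 1e-12
  lags <- lmin:lmax
  R <- sweep(A[lags + 1L, , drop = FALSE], 2, pmax(a0, 1e-12), "/") / rw[lags + 1L]
  # small octave cost keeps the tracker off subharmonics when the 2*T0 peak
  # rivals the T0 peak (window correction favors long lags otherwise)
  penalty <- 0.04 * log2(lags / lmin)
  best <- max.col(t(R - penalty), ties.method = "first")
  peak_r <- R[cbind(best, seq_len(nfr))]
  lag_best <- lags[best]
  # parabolic refinement of the peak lag
  lag_ref <- vapply(seq_len(nfr), function(j) {
    i <- best[j]
    if (i <= 1L || i >= length(lags)) return(as.numeric(lag_best[j]))
    y1 <- R[i - 1L, j]; y2 <- R[i, j]; y3 <- R[i + 1L, j]
    den <- y1 - 2 * y2 + y3
    d <- if (abs(den) > 1e-12) 0.5 * (y1 - y3) / den else 0
    lag_best[j] + max(-0.5, min(0.5, d))
  }, numeric(1))
  peak_r[!ok] <- 0
  list(times = starts, f0 = fs / lag_ref, peak_r = peak_r,
       int_db = amp_db(rms), frame = frame, hop = hop, dur = dur)
}

#' Track fundamental frequency and frame intensity
#'
#' Frame-wise F0 by window-corrected autocorrelation with a voicing decision
#' (peak autocorrelation above `voicing_threshold`); unvoiced frames carry
#' `NA` F0. The signal is decimated to ~12 kHz for pitch analysis. Frame
#' intensity is the RMS level in dB re full scale.
#'
#' @param w A [waveform()].
#' @param f_min,f_max F0 search range, Hz.
#' @param frame,hop Frame length and hop, s.
#' @param voicing_threshold Autocorrelation peak required to call a frame
#'   voiced.
#' @return A `frame_track`: list with `times` (frame start times, s), `f0`
#'   (Hz, `NA` where unvoiced), `intensity` (dB), `voiced` (logical).
#' @export
track_f0 <- function(w, f_min = 60, f_max = 400, frame = 0.04, hop = 0.01,
                     voicing_threshold = 0.45) {
  stopifnot(inherits(w, "waveform"))
  if (!(f_min > 0 && f_min < f_max && f_max <= w$rate / 2))
    stop("need 0 < f_min < f_max <= rate/2", call. = FALSE)
  q <- max(1L, floor(w$rate / 12000))
  x <- if (q > 1L) signal::decimate(w$samples, q) else w$samples
  tr <- acf_track(x, w$rate / q, frame, hop, f_min, f_max)
  voiced <- tr$peak_r >= voicing_threshold & is.finite(tr$int_db)
  f0 <- ifelse(voiced, tr$f0, NA_real_)
  # halving/doubling rejection: partial frames at segment edges occasionally
  # lock onto a sub- or super-harmonic; anything half an octave from the voiced
  # median is relabeled unvoiced
  if (sum(voiced) >= 5L) {
    med <- median(f0[voiced])
    jump <- abs(12 * log2(f0 / med)) > 6
    jump[is.na(jump)] <- FALSE
    voiced[jump] <- FALSE
    f0[jump] <- NA_real_
  }
  structure(list(times = tr$times, f0 = f0, intensity = tr$int_db,
                 voiced = voiced, frame = frame, hop = hop, dur = tr$dur),
            class = "frame_track")
}

#' Frame intensity contour
#'
#' Frame RMS converted to dB re full scale on the same time grid as
#' [track_f0()]. Zero-energy frames are floored at -120 dB, never `-Inf`.
#'
#' @inheritParams track_f0
#' @return A `frame_track` with `intensity` and `times` (no F0).
#' @export
intensity_contour <- function(w, frame = 0.04, hop = 0.01) {
  stopifnot(inherits(w, "waveform"))
  if (!length(w$samples)) stop("empty audio", call. = FALSE)
  dur <- wave_duration(w)
  starts <- frame_starts(dur, frame, hop)
  frame_n <- round(frame * w$rate)
  idx <- outer(seq_len(frame_n) - 1L, round(starts * w$rate) + 1L, "+")
  rms <- sqrt(colMeans(matrix(w$samples[idx], nrow = frame_n)^2))
  structure(list(times = starts, f0 = rep(NA_real_, length(starts)),
                 intensity = amp_db(rms), voiced = rep(NA, length(starts)),
                 frame = frame, hop = hop, dur = dur),
            class = "frame_track")
}

# Short-window RMS envelope at fine time resolution (for boundary work).
fine_envelope <- function(x, fs, win = 0.012, hop = 0.001) {
  n <- round(win * fs)
  h <- max(1L, round(hop * fs))
  starts <- seq(1L, length(x) - n + 1L, by = h)
  csum <- c(0, cumsum(x^2))
  rms <- sqrt((csum[starts + n] - csum[starts]) / n)
  list(times = (starts - 1L) / fs + win / 2, db = amp_db(rms), win = win)
}

#' Segment a frame track into speech, pauses, and syllable nuclei
#'
#' Energy-threshold labeling (frames within `silence_rel_db` of the track
#' maximum are speech) with half-hop boundary correction, merging of pauses
#' shorter than `pause_min` and speech islands shorter than `speech_min`.
#' Syllable nuclei are intensity peaks inside speech intervals.
#'
#' @param track A `frame_track` from [track_f0()] or [intensity_contour()].
#' @param w Optional source [waveform()]; when supplied, pause boundaries are
#'   refined on a 1 ms envelope (recommended for pause-duration accuracy).
#' @param silence_rel_db Threshold below the intensity maximum, dB.
#' @param pause_min,speech_min Minimum pause / speech segment durations, s.
#' @param syll_min_gap Minimum spacing between syllable nuclei, s.
#' @return A `segmentation`: list with `speech_intervals`, `pause_intervals`
#'   (two-column matrices of start/end, s) and `syllable_times` (s).
#' @export
segment_speech_pauses <- function(track, w = NULL, silence_rel_db = 25,
                                  pause_min = 0.06, speech_min = 0.06,
                                  syll_min_gap = 0.1) {
  stopifnot(inherits(track, "frame_track"))
  if (!length(track$times)) stop("empty frame track", call. = FALSE)
  int <- track$intensity
  thr <- max(int) - silence_rel_db
  speech <- int > thr
  hop <- track$hop; frame <- track$frame
  runs <- rle(speech)
  ends <- cumsum(runs$lengths); starts <- ends - runs$lengths + 1L
  iv <- cbind(track$times[starts[runs$values]] + frame - hop / 2,
              track$times[ends[runs$values]] + hop / 2)
  iv <- iv[iv[, 2] > iv[, 1], , drop = FALSE]
  # merge pauses below the floor, then drop speech islands below the floor
  merge_close <- function(iv, gap_min) {
    if (nrow(iv) < 2L) return(iv)
    out <- iv[1, , drop = FALSE]
    for (i in 2:nrow(iv)) {
      if (iv[i, 1] - out[nrow(out), 2] < gap_min) out[nrow(out), 2] <- iv[i, 2]
      else out <- rbind(out, iv[i, ])
    }
    out
  }
  if (nrow(iv)) {
    iv <- merge_close(iv, pause_min)
    iv <- iv[iv[, 2] - iv[, 1] >= speech_min, , drop = FALSE]
  }
  pauses <- if (nrow(iv) >= 2L)
    cbind(iv[-nrow(iv), 2], iv[-1, 1]) else matrix(numeric(0), 0, 2)
  # refine pause boundaries on a fine envelope when the waveform is at hand
  if (!is.null(w) && nrow(pauses)) {
    env <- fine_envelope(w$samples, w$rate, win = 0.008, hop = 0.001)
    floor_db <- quantile(env$db, 0.05, names = FALSE)
    for (i in seq_len(nrow(pauses))) {
      near <- env$times >= pauses[i, 1] - 0.2 & env$times <= pauses[i, 2] + 0.2
      if (!any(near)) next
      thr2 <- max(max(env$db[near]) - silence_rel_db, floor_db + 6)
      mid <- mean(pauses[i, ])
      below <- env$db <= thr2 | env$times < pauses[i, 1] - 0.2 |
        env$times > pauses[i, 2] + 0.2
      j <- which.min(abs(env$times - mid))
      if (!below[j]) next
      a <- j; while (a > 1L && below[a - 1L]) a <- a - 1L
      b <- j; while (b < length(below) && below[b + 1L]) b <- b + 1L
      lo <- max(env$times[a], pauses[i, 1] - 0.2)
      hi <- min(env$times[b], pauses[i, 2] + 0.2)
      if (hi > lo) pauses[i, ] <- c(lo, hi)
    }
    # keep speech interval edges consistent with the refined pauses
    for (i in seq_len(nrow(pauses))) {
      iv[i, 2] <- pauses[i, 1]
      iv[i + 1L, 1] <- pauses[i, 2]
    }
  }
  # syllable nuclei: smoothed intensity peaks inside speech
  syl <- numeric(0)
  if (nrow(iv)) {
    sm <- as.numeric(stats::filter(int, rep(1 / 3, 3), sides = 2))
    sm[is.na(sm)] <- int[is.na(sm)]
    pk <- pracma::findpeaks(sm, minpeakheight = max(int) - silence_rel_db + 5,
                            minpeakdistance = max(1L, round(syll_min_gap / hop)),
                            nups = 1, ndowns = 1)
    if (!is.null(pk)) {
      pt <- track$times[pk[, 2]] + frame / 2
      keep <- vapply(pt, function(t)
        any(t >= iv[, 1] - frame / 2 & t <= iv[, 2] + frame / 2), logical(1))
      syl <- sort(pt[keep])
    }
  }
  structure(list(speech_intervals = iv, pause_intervals = pauses,
                 syllable_times = syl, dur = track$dur),
            class = "segmentation")
}

#' Long-term average spectrum of the speech portion
#'
#' Welch-averaged power spectrum (Hann window, 50% overlap) over frames whose
#' level is within 40 dB of the loudest frame, restricted to `band`.
#'
#' @param w A [waveform()].
#' @param band Two-element frequency band `[f_lo, f_hi]`, Hz.
#' @param frame Analysis frame length, s.
#' @return An `ltas_spectrum`: list with `freqs` (Hz), `power` (linear power
#'   density, unnormalized), and `band`.
#' @export
ltas_spectrum <- function(w, band = c(0, 8000), frame = 0.04) {
  stopifnot(inherits(w, "waveform"))
  if (wave_duration(w) < 0.5) stop("need >= 0.5 s of audio", call. = FALSE)
  fs <- w$rate
  starts <- frame_starts(wave_duration(w), frame, frame / 2)
  frame_n <- round(frame * fs)
  idx <- outer(seq_len(frame_n) - 1L, round(starts * fs) + 1L, "+")
  M <- matrix(w$samples[idx], nrow = frame_n)
  rms <- sqrt(colMeans(M^2))
  keep <- amp_db(rms) > max(amp_db(rms)) - 40 & rms > 0
  if (!any(keep)) stop("silent input: no speech frames for LTAS", call. = FALSE)
  M <- M[, keep, drop = FALSE]
  win <- 0.5 * (1 - cos(2 * pi * (seq_len(frame_n) - 1) / (frame_n - 1)))
  S <- Mod(mvfft(M * win))^2
  pw <- rowMeans(S)[seq_len(frame_n %/% 2 + 1L)]
  freqs <- (seq_len(frame_n %/% 2 + 1L) - 1L) * fs / frame_n
  sel <- freqs >= band[1] & freqs <= band[2]
  structure(list(freqs = freqs[sel], power = pw[sel], band = band),
            class = "ltas_spectrum")
}

# First four standardized moments of a distribution over frequency.
spectral_moments <- function(freqs, power, db_weight = FALSE) {
  if (db_weight) power <- pmax(10 * log10(pmax(power, 1e-300)) -
                                 (10 * log10(max(power)) - 60), 0)
  p <- power / sum(power)
  m <- sum(p * freqs)
  v <- sum(p * (freqs - m)^2)
  s <- sqrt(v)
  c(LTAS_mean = m, LTAS_sd = s,
    LTAS_skew = if (s > 0) sum(p * (freqs - m)^3) / s^3 else 0,
    LTAS_kurt = if (s > 0) sum(p * (freqs - m)^4) / s^4 else 0)
}

#' Moments of the long-term average spectrum
#'
#' Normalizes the LTAS to a distribution over frequency and returns its mean,
#' standard deviation, skewness, and kurtosis (Pearson convention: a normal
#' shape gives kurtosis 3). Linear power weighting by default; `db_weight`
#' switches to a 60 dB-floored dB weighting dialect.
#'
#' @param w A [waveform()] or an `ltas_spectrum`.
#' @param band,frame Passed to [ltas_spectrum()] when `w` is a waveform.
#' @param db_weight Use dB-domain weights instead of linear power.
#' @return Named vector `LTAS_mean`, `LTAS_sd` (Hz), `LTAS_skew`, `LTAS_kurt`.
#' @export
ltas_moments <- function(w, band = c(0, 8000), frame = 0.04,
                         db_weight = FALSE) {
  sp <- if (inherits(w, "ltas_spectrum")) w else ltas_spectrum(w, band, frame)
  if (!length(sp$power) || sum(sp$power) <= 0)
    stop("no spectral energy in band", call. = FALSE)
  spectral_moments(sp$freqs, sp$power, db_weight)
}
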