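# The 16 canonical digital speech biomarkers and their per-task extractors.
# Missing features are explicit NA markers, never silent zeros.

#' Canonical biomarker names
#'
#' The 16 digital speech biomarkers in canonical order: 12 basic features
#' (prosody, timing, articulation, phonatory) and the 4 long-term average
#' spectrum moments (computed from the reading task).
#' @return Character vector of length 16.
#' @export
canonical_features <- function() {
  c("sdF0_text", "Int_sd_text", "Int_kurt_text", "Int_skew_text",
    "NSR_text", "DPI_text", "RST_text", "VOT_ddk",
    "HNR_phon", "MPT_phon", "Int_slope_phon", "Int_sd_phon",
    "LTAS_mean", "LTAS_sd", "LTAS_skew", "LTAS_kurt")
}

empty_biomarkers <- function() {
  setNames(rep(NA_real_, 16L), canonical_features())
}

# central sample moments (Pearson skewness / kurtosis, normal kurtosis = 3)
moment_skew <- function(x) { m <- mean(x); s <- sqrt(mean((x - m)^2))
  if (s == 0) 0 else mean((x - m)^3) / s^3 }
moment_kurt <- function(x) { m <- mean(x); s <- sqrt(mean((x - m)^2))
  if (s == 0) 0 else mean((x - m)^4) / s^4 }

st_of <- function(f0) 12 * log2(f0)

#' Reading-task biomarkers
#'
#' Extracts the text-task features: `sdF0_text` (semitone sd of F0 over
#' voiced frames), intensity distribution statistics over speech frames
#' (`Int_sd_text`, `Int_kurt_text`, `Int_skew_text`), net speech rate
#' `NSR_text` (syllables per second of net speech time), mean pause duration
#' `DPI_text` (ms), rate of speech timing `RST_text` (speech + pause segments
#' per minute of passage duration), and the four LTAS moments over the speech
#' portion.
#'
#' @param w A [waveform()] with `task = "text"`.
#' @param f_min,f_max,frame,hop,voicing_threshold Passed to [track_f0()].
#' @param silence_rel_db,pause_min,speech_min Passed to
#'   [segment_speech_pauses()].
#' @param ltas_band LTAS band, Hz.
#' @return Named numeric vector over the 16 canonical names; non-text entries
#'   are `NA`.
#' @export
text_features <- function(w, f_min = 60, f_max = 400, frame = 0.04,
                          hop = 0.01, voicing_threshold = 0.45,
                          silence_rel_db = 25, pause_min = 0.06,
                          speech_min = 0.06, ltas_band = c(0, 8000)) {
  stopifnot(inherits(w, "waveform"))
  if (w$task != "text") stop("waveform task must be 'text'", call. = FALSE)
  out <- empty_biomarkers()
  tr <- track_f0(w, f_min, f_max, frame, hop, voicing_threshold)
  if (!any(tr$voiced)) {
    warning("no voiced frames in reading task; text features missing",
            call. = FALSE)
    return(out)
  }
  seg <- segment_speech_pauses(tr, w = w, silence_rel_db = silence_rel_db,
                               pause_min = pause_min, speech_min = speech_min)
  out["sdF0_text"] <- sd(st_of(tr$f0[tr$voiced]))
  centers <- tr$times + frame / 2
  in_speech <- vapply(centers, function(t)
    any(t >= seg$speech_intervals[, 1] & t <= seg$speech_intervals[, 2]),
    logical(1))
  int_sp <- tr$intensity[in_speech]
  out["Int_sd_text"] <- sd(int_sp)
  out["Int_kurt_text"] <- moment_kurt(int_sp)
  out["Int_skew_text"] <- moment_skew(int_sp)
  net_speech <- sum(seg$speech_intervals[, 2] - seg$speech_intervals[, 1])
  n_syll <- length(seg$syllable_times)
  out["NSR_text"] <- if (net_speech > 0) n_syll / net_speech else NA_real_
  out["DPI_text"] <- if (nrow(seg$pause_intervals))
    mean(seg$pause_intervals[, 2] - seg$pause_intervals[, 1]) * 1000 else 0
  out["RST_text"] <-
    (nrow(seg$speech_intervals) + nrow(seg$pause_intervals)) / (seg$dur / 60)
  out[c("LTAS_mean", "LTAS_sd", "LTAS_skew", "LTAS_kurt")] <-
    ltas_moments(w, band = ltas_band, frame = frame)
  out
}

#' Phonation-task biomarkers
#'
#' Extracts `MPT_phon` (duration of the longest voiced stretch, s),
#' `HNR_phon` (mean frame harmonicity `10*log10(r/(1-r))` in dB, from the
#' full-rate autocorrelation peak `r`), `Int_slope_phon` (least-squares
#' intensity slope over the voiced stretch, dB/s), and `Int_sd_phon`
#' (intensity sd over the stretch). If the voiced stretch is shorter than
#' 0.5 s all phonation entries are `NA` markers.
#'
#' @inheritParams text_features
#' @param w A [waveform()] with `task = "phon"`.
#' @param edge_trim Margin excluded at each stretch end for the intensity and
#'   harmonicity statistics, s.
#' @return Named numeric vector over the 16 canonical names.
#' @export
phonation_features <- function(w, f_min = 60, f_max = 400, frame = 0.04,
                               hop = 0.01, voicing_threshold = 0.45,
                               edge_trim = 0.05) {
  stopifnot(inherits(w, "waveform"))
  if (w$task != "phon") stop("waveform task must be 'phon'", call. = FALSE)
  out <- empty_biomarkers()
  tr <- track_f0(w, f_min, f_max, frame, hop, voicing_threshold)
  runs <- voiced_runs(tr$voiced, max_gap = 2L)
  if (!nrow(runs)) {
    warning("no voiced stretch found; phonation features missing", call. = FALSE)
    return(out)
  }
  main <- runs[which.max(runs[, 2] - runs[, 1]), ]
  t1 <- tr$times[main[1]]; t2 <- tr$times[main[2]] + frame
  # refine the stretch boundaries on a fine envelope at the level midpoint
  env <- fine_envelope(w$samples, w$rate)
  inside <- env$times > t1 + 0.05 & env$times < t2 - 0.05
  outside <- env$times < t1 - 0.05 | env$times > t2 + 0.05
  ls <- median(env$db[inside])
  ln <- if (any(outside)) median(env$db[outside]) else min(env$db)
  thr <- (ls + ln) / 2
  above <- env$db > thr
  r <- rle(above); ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  cand <- which(r$values)
  if (length(cand)) {
    lens <- env$times[ends[cand]] - env$times[starts[cand]]
    b <- cand[which.max(lens)]
    t1 <- env$times[starts[b]]; t2 <- env$times[ends[b]]
  }
  mpt <- t2 - t1
  if (mpt < 0.5) {
    warning("voiced stretch < 0.5 s; phonation features missing", call. = FALSE)
    return(out)
  }
  out["MPT_phon"] <- mpt
  sel <- tr$times >= t1 + edge_trim & tr$times + frame <= t2 - edge_trim &
    tr$voiced
  if (sum(sel) >= 5) {
    out["Int_slope_phon"] <-
      unname(coef(lm(tr$intensity[sel] ~ tr$times[sel]))[2])
    out["Int_sd_phon"] <- sd(tr$intensity[sel])
    # harmonicity at the native rate (noise above the pitch band counts)
    ac <- acf_track(w$samples, w$rate, frame, hop, f_min, f_max)
    hsel <- ac$times >= t1 + edge_trim & ac$times + frame <= t2 - edge_trim
    rpk <- pmin(pmax(ac$peak_r[hsel], 1e-6), 1 - 1e-6)
    out["HNR_phon"] <- mean(10 * log10(rpk / (1 - rpk)))
  }
  out
}

# runs of TRUE allowing gaps of up to `max_gap` FALSE frames inside
voiced_runs <- function(v, max_gap = 2L) {
  idx <- which(v)
  if (!length(idx)) return(matrix(integer(0), 0, 2))
  brk <- which(diff(idx) > max_gap + 1L)
  starts <- idx[c(1L, brk + 1L)]
  ends <- idx[c(brk, length(idx))]
  cbind(starts, ends)
}

#' DDK-task biomarker: voice onset time
#'
#' Detects syllables as voiced segments on a low-band (80-900 Hz) fine
#' envelope; for each, the burst is located as the strongest high-band
#' (> 3 kHz) envelope peak shortly before voicing, and VOT is the interval
#' from burst onset to voicing onset. `VOT_ddk` is the mean over syllables,
#' in ms. Fewer than 3 detected syllables yields an `NA` marker.
#'
#' @param w A [waveform()] with `task = "ddk"`.
#' @param ... Ignored (accepted so task extractors share a calling
#'   convention).
#' @return Named numeric vector over the 16 canonical names.
#' @export
ddk_features <- function(w, ...) {
  stopifnot(inherits(w, "waveform"))
  if (w$task != "ddk") stop("waveform task must be 'ddk'", call. = FALSE)
  out <- empty_biomarkers()
  fs <- w$rate
  lo <- signal::butter(4, c(80, 900) / (fs / 2), type = "pass")
  hi <- signal::butter(4, 3000 / (fs / 2), type = "high")
  xlo <- signal::filtfilt(lo, w$samples)
  xhi <- signal::filtfilt(hi, w$samples)
  env_lo <- fine_envelope(xlo, fs, win = 0.008, hop = 0.001)
  env_hi <- fine_envelope(xhi, fs, win = 0.003, hop = 0.0005)
  thr <- max(env_lo$db) - 20
  above <- env_lo$db > thr
  r <- rle(above); ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  vi <- which(r$values)
  vi <- vi[(ends[vi] - starts[vi]) * 0.001 >= 0.03]
  if (length(vi) < 3L) {
    warning("fewer than 3 syllables detected; VOT missing", call. = FALSE)
    return(out)
  }
  vots <- rep(NA_real_, length(vi))
  for (j in seq_along(vi)) {
    # voicing onset: crossing of (local vowel level - 6 dB)
    s <- starts[vi[j]]; e <- ends[vi[j]]
    loc_ref <- max(env_lo$db[s:min(e, s + 80L)])
    k <- s
    while (k > 1L && env_lo$db[k - 1L] > loc_ref - 6) k <- k - 1L
    t_voice <- env_lo$times[k]
    # burst: strongest high-band peak from 90 ms before to just after voicing
    w0 <- t_voice - 0.09; w1 <- t_voice + 0.006
    hsel <- which(env_hi$times >= w0 & env_hi$times <= w1)
    if (!length(hsel)) next
    pk <- hsel[which.max(env_hi$db[hsel])]
    ref <- env_hi$db[pk]
    if (ref < max(env_hi$db) - 25) next   # no credible burst for this syllable
    k2 <- pk
    while (k2 > 1L && env_hi$db[k2 - 1L] > ref - 10 &&
           env_hi$times[k2 - 1L] > w0) k2 <- k2 - 1L
    t_burst <- env_hi$times[k2] - env_hi$win / 2
    if (t_voice > t_burst) vots[j] <- (t_voice - t_burst) * 1000
  }
  vots <- vots[is.finite(vots)]
  if (length(vots) < 3L) {
    warning("fewer than 3 usable syllables; VOT missing", call. = FALSE)
    return(out)
  }
  out["VOT_ddk"] <- mean(vots)
  attr(out, "n_syllables") <- length(vi)
  out
}

#' Extract the full biomarker vector for one subject/state
#'
#' Aggregates per-task features into the 16-entry vector; phonation and DDK
#' features are averaged over available repeats (the protocol performs those
#' two tasks twice). Absent tasks leave their entries as `NA` markers.
#'
#' @param recordings Named list with elements `phon`, `ddk`, `text`; each a
#'   [waveform()] or a list of repeat [waveform()]s (text takes one).
#' @param ... Passed on to the per-task extractors.
#' @return Named numeric vector over the 16 canonical names.
#' @export
extract_all <- function(recordings, ...) {
  if (!length(recordings) || !any(names(recordings) %in% c("phon", "ddk", "text")))
    stop("need at least one of phon/ddk/text recordings", call. = FALSE)
  out <- empty_biomarkers()
  avg_over <- function(ws, f) {
    if (inherits(ws, "waveform")) ws <- list(ws)
    vs <- lapply(ws, f, ...)
    m <- do.call(rbind, vs)
    colMeans(m, na.rm = TRUE)
  }
  if (!is.null(recordings$phon)) {
    v <- avg_over(recordings$phon, phonation_features)
    k <- c("HNR_phon", "MPT_phon", "Int_slope_phon", "Int_sd_phon")
    out[k] <- v[k]
  }
  if (!is.null(recordings$ddk)) {
    v <- avg_over(recordings$ddk, ddk_features)
    out["VOT_ddk"] <- v["VOT_ddk"]
  }
  if (!is.null(recordings$text)) {
    wtext <- recordings$text
    if (!inherits(wtext, "waveform")) wtext <- wtext[[1]]
    v <- text_features(wtext, ...)
    k <- c("sdF0_text", "Int_sd_text", "Int_kurt_text", "Int_skew_text",
           "NSR_text", "DPI_text", "RST_text",
           "LTAS_mean", "LTAS_sd", "LTAS_skew", "LTAS_kurt")
    out[k] <- v[k]
  }
  out[is.nan(out)] <- NA_real_
  out
}
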