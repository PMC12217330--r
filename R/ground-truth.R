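#' Ground truth for a synthetic speech recording
#'
#' Collects every parameter the audio synthesizers plant, so downstream
#' extraction can be validated against known values. Tasks use the
#' parameters differently:
#'
#' * `phon`: `phonation_dur`, `f0_mean`, `f0_sd` (realized as sinusoidal
#'   vibrato at `vibrato_rate` with amplitude `f0_sd * sqrt(2)`, so the F0
#'   track standard deviation equals `f0_sd` semitones), `intensity_slope`,
#'   `snr`.
#' * `ddk`: `syllable_count` syllables at `syll_rate` per second, each a
#'   broadband burst, `vot_gap` ms from burst onset to voicing onset, then a
#'   voiced vowel at `f0_mean`.
#' * `text`: alternating voiced pseudo-syllabic stretches and silent pauses of
#'   exactly `pause_durations`; `syllable_count` nuclei in total, slow F0
#'   wander with standard deviation `f0_sd` semitones, per-syllable intensity
#'   scatter `intensity_sd` dB.
#'
#' @param task One of `"phon"`, `"ddk"`, `"text"`.
#' @param f0_mean Mean fundamental frequency, Hz.
#' @param f0_sd Target F0 variability, semitones.
#' @param vibrato_rate Vibrato rate for phonation, Hz.
#' @param intensity_slope Intensity trend during phonation, dB/s.
#' @param intensity_sd Per-syllable intensity scatter for reading, dB.
#' @param snr Signal-to-noise ratio of the additive recording noise, dB.
#' @param phonation_dur Voiced duration for phonation, s.
#' @param pause_durations Silent pause durations for reading, s.
#' @param syllable_count Number of syllables (ddk, text).
#' @param vot_gap Voice onset time, ms (burst onset to voicing onset, ddk).
#' @param syll_rate Syllable rate for ddk, per second.
#' @param seed Integer seed; a fixed seed makes the waveform byte-identical.
#' @return An object of class `audio_ground_truth`.
#' @export
audio_ground_truth <- function(task = c("phon", "ddk", "text"),
                               f0_mean = 120, f0_sd = 0.3, vibrato_rate = 5,
                               intensity_slope = 0, intensity_sd = 0.8,
                               snr = 30, phonation_dur = 3,
                               pause_durations = numeric(),
                               syllable_count = 0L, vot_gap = 25,
                               syll_rate = 6, seed = NULL) {
  task <- match.arg(task)
  num1 <- function(x, nm, finite = TRUE) {
    if (!is.numeric(x) || length(x) != 1L || (finite && !is.finite(x)))
      stop("`", nm, "` must be a finite numeric scalar", call. = FALSE)
  }
  num1(f0_mean, "f0_mean"); num1(f0_sd, "f0_sd"); num1(vibrato_rate, "vibrato_rate")
  num1(intensity_slope, "intensity_slope"); num1(intensity_sd, "intensity_sd")
  num1(snr, "snr"); num1(phonation_dur, "phonation_dur")
  num1(vot_gap, "vot_gap"); num1(syll_rate, "syll_rate")
  if (f0_mean <= 0) stop("`f0_mean` must be positive", call. = FALSE)
  if (f0_sd < 0 || intensity_sd < 0) stop("variabilities must be >= 0", call. = FALSE)
  if (phonation_dur <= 0) stop("`phonation_dur` must be positive", call. = FALSE)
  if (length(pause_durations) && (anyNA(pause_durations) || any(pause_durations <= 0)))
    stop("`pause_durations` must all be positive", call. = FALSE)
  syllable_count <- as.integer(syllable_count)
  if (is.na(syllable_count) || syllable_count < 0L)
    stop("`syllable_count` must be a non-negative integer", call. = FALSE)
  if (vot_gap < 0) stop("`vot_gap` must be >= 0", call. = FALSE)
  if (syll_rate <= 0) stop("`syll_rate` must be positive", call. = FALSE)
  if (!is.null(seed)) seed <- as.integer(seed)
  structure(list(task = task, f0_mean = f0_mean, f0_sd = f0_sd,
                 vibrato_rate = vibrato_rate, intensity_slope = intensity_slope,
                 intensity_sd = intensity_sd, snr = snr,
                 phonation_dur = phonation_dur,
                 pause_durations = as.numeric(pause_durations),
                 syllable_count = syllable_count, vot_gap = vot_gap,
                 syll_rate = syll_rate, seed = seed),
            class = "audio_ground_truth")
}

# Run `expr` under the truth's seed when one is set, restoring RNG state.
with_truth_seed <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(seed, expr)
}
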