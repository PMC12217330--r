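#' Speech waveform container
#'
#' A light container for mono speech audio: a numeric sample vector in
#' `[-1, 1]`, a sampling rate in Hz, and the speech-task label the recording
#' protocol uses (`"phon"` sustained /a/ phonation, `"ddk"` /pa/-/ta/-/ka/
#' syllable repetition, `"text"` passage reading).
#'
#' @param samples Numeric vector of audio samples.
#' @param rate Sampling rate in Hz (positive scalar).
#' @param task Task label: one of `"phon"`, `"ddk"`, `"text"`.
#' @return An object of class `waveform`.
#' @export
waveform <- function(samples, rate, task = c("phon", "ddk", "text")) {
  task <- match.arg(task)
  if (!is.numeric(samples)) stop("`samples` must be numeric", call. = FALSE)
  if (!is.numeric(rate) || length(rate) != 1L || !is.finite(rate) || rate <= 0)
    stop("`rate` must be a positive finite scalar", call. = FALSE)
  if (anyNA(samples) || any(!is.finite(samples)))
    stop("`samples` must be finite and non-missing", call. = FALSE)
  structure(list(samples = as.numeric(samples), rate = rate, task = task),
            class = "waveform")
}

#' Duration of a waveform in seconds
#' @param w A [waveform()].
#' @return Duration in seconds.
#' @export
wave_duration <- function(w) {
  stopifnot(inherits(w, "waveform"))
  length(w$samples) / w$rate
}

#' @export
print.waveform <- function(x, ...) {
  cat(sprintf("<waveform> task=%s  %.3f s @ %g Hz  peak=%.3f\n",
              x$task, wave_duration(x), x$rate,
              if (length(x$samples)) max(abs(x$samples)) else 0))
  invisible(x)
}
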