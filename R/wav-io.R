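# RIFF/WAVE PCM I/O.  Only the plain 16-bit mono PCM layout used by the
# recording protocol is written; reading also accepts stereo (downmixed) and
# resamples to the analysis rate when the file rate differs.

#' Write a waveform to a 16-bit PCM WAV file
#'
#' @param w A [waveform()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(w, path) {
  stopifnot(inherits(w, "waveform"))
  x <- pmax(pmin(w$samples, 1), -1)
  pcm <- as.integer(round(x * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  n_bytes <- length(pcm) * 2L
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_bytes), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")          # fmt chunk size
  writeBin(1L, con, size = 2, endian = "little")           # PCM
  writeBin(1L, con, size = 2, endian = "little")           # mono
  writeBin(as.integer(w$rate), con, size = 4, endian = "little")
  writeBin(as.integer(w$rate * 2L), con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")           # block align
  writeBin(16L, con, size = 2, endian = "little")          # bits per sample
  writeChar("data", con, eos = NULL)
  writeBin(n_bytes, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Read a PCM WAV file as a waveform
#'
#' Parses the RIFF chunk list, decodes 16-bit PCM (stereo is averaged to
#' mono), and resamples to `target_rate` when the file rate differs.
#'
#' @param path WAV file path.
#' @param task Task label to attach to the waveform.
#' @param target_rate Analysis sampling rate, Hz; `NULL` keeps the file rate.
#' @return A [waveform()].
#' @export
read_wav <- function(path, task = c("phon", "ddk", "text"),
                     target_rate = 48000) {
  task <- match.arg(task)
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF/WAVE file: ", path, call. = FALSE)
  invisible(readBin(con, "integer", 1, size = 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a RIFF/WAVE file: ", path, call. = FALSE)
  rate <- NULL; n_chan <- NULL; bits <- NULL; fmt_code <- NULL; samples <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    sz <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt_code <- readBin(con, "integer", 1, size = 2, endian = "little")
      n_chan <- readBin(con, "integer", 1, size = 2, endian = "little")
      rate <- readBin(con, "integer", 1, size = 4, endian = "little")
      invisible(readBin(con, "integer", 1, size = 4, endian = "little"))
      invisible(readBin(con, "integer", 1, size = 2, endian = "little"))
      bits <- readBin(con, "integer", 1, size = 2, endian = "little")
      extra <- sz - 16L
      if (extra > 0) invisible(readBin(con, "raw", extra))
    } else if (identical(id, "data")) {
      if (is.null(bits)) stop("malformed WAV (data before fmt): ", path, call. = FALSE)
      if (fmt_code != 1L || bits != 16L)
        stop("unsupported WAV encoding (only 16-bit PCM): ", path, call. = FALSE)
      pcm <- readBin(con, "integer", n = sz %/% 2L, size = 2,
                     signed = TRUE, endian = "little")
      samples <- pcm / 32767
      break
    } else {
      invisible(readBin(con, "raw", sz + (sz %% 2L)))
    }
  }
  if (is.null(samples)) stop("no data chunk found in ", path, call. = FALSE)
  if (n_chan > 1L) {
    samples <- rowMeans(matrix(samples, ncol = n_chan, byrow = TRUE))
  }
  if (!is.null(target_rate) && rate != target_rate) {
    samples <- signal::resample(samples, p = target_rate, q = rate)
    rate <- target_rate
  }
  waveform(samples, rate, task)
}
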