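#' Sampled audio waveform
#'
#' The universal currency between processing stages: a finite, real-valued,
#' pressure-like sample sequence together with its sampling rate.
#'
#' @param samples Numeric vector of (dimensionless) amplitudes; must be finite.
#' @param rate Sampling rate in Hz; must be a single positive number.
#' @return An object of class `waveform` with fields `$samples` and `$rate`.
#' @examples
#' w <- waveform(sin(2 * pi * 440 * (0:999) / 22050), 22050)
#' duration(w)
#' @export
waveform <- function(samples, rate) {
  if (!is.numeric(samples)) stop("`samples` must be numeric")
  if (anyNA(samples) || any(!is.finite(samples))) {
    stop("all waveform samples must be finite")
  }
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 0) {
    stop("`rate` must be a single positive number (Hz)")
  }
  structure(list(samples = as.numeric(samples), rate = as.numeric(rate)),
            class = "waveform")
}

#' @rdname waveform
#' @param x Object to test or print.
#' @export
is_waveform <- function(x) inherits(x, "waveform")

#' @rdname waveform
#' @export
duration <- function(x) {
  stopifnot(is_waveform(x))
  length(x$samples) / x$rate
}

#' @param ... Ignored.
#' @rdname waveform
#' @export
print.waveform <- function(x, ...) {
  cat(sprintf("<waveform: %d samples @ %g Hz (%.3f s), peak %.4g, rms %.4g>\n",
              length(x$samples), x$rate, duration(x),
              if (length(x$samples)) max(abs(x$samples)) else 0, rms(x$samples)))
  invisible(x)
}

# root mean square of a numeric vector
rms <- function(x) if (length(x)) sqrt(mean(x^2)) else 0

#' Read a 16-bit PCM mono WAV file
#'
#' Minimal RIFF/WAVE reader restricted to the format used throughout: 16-bit
#' linear PCM, single channel. Samples are rescaled by 1/32767 so that a
#' full-scale waveform round-trips through [write_wav()] within half a
#' quantization step.
#'
#' @param path Path to a `.wav` file.
#' @return A [waveform].
#' @export
read_wav <- function(path) {
  if (!file.exists(path)) stop("WAV file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path)
  readBin(con, "integer", 1, 4, endian = "little")     # chunk size
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path)
  rate <- NULL; bits <- NULL; nchan <- NULL; samples <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    sz <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- readBin(con, "integer", sz %/% 2, 2, signed = FALSE,
                     endian = "little")
      audio_format <- fmt[1]; nchan <- fmt[2]
      rate <- fmt[3] + 65536 * fmt[4]
      bits <- fmt[8]
      if (audio_format != 1L) stop("only linear PCM WAV is supported")
    } else if (identical(id, "data")) {
      samples <- readBin(con, "integer", sz %/% 2, 2, signed = TRUE,
                         endian = "little")
      break
    } else {
      seek(con, sz + sz %% 2, origin = "current")
    }
  }
  if (is.null(rate) || is.null(samples)) stop("malformed WAV file: ", path)
  if (bits != 16L) stop("only 16-bit WAV is supported (got ", bits, "-bit)")
  if (nchan != 1L) stop("only mono WAV is supported (got ", nchan, " channels)")
  waveform(samples / 32767, rate)
}

#' Write a waveform as a 16-bit PCM mono WAV file
#'
#' Samples are quantized by rounding `samples * 32767` and clipped to the
#' 16-bit range; a warning reports how many samples clipped.
#'
#' @param x A [waveform] with samples nominally in \[-1, 1\].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(x, path) {
  stopifnot(is_waveform(x))
  q <- round(x$samples * 32767)
  n_clip <- sum(q > 32767 | q < -32768)
  if (n_clip > 0) {
    warning(n_clip, " sample(s) clipped during 16-bit quantization")
    q <- pmin(pmax(q, -32768), 32767)
  }
  con <- file(path, "wb")
  on.exit(close(con))
  data_bytes <- 2L * length(q)
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_bytes), con, 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, 4, endian = "little")
  writeBin(c(1L, 1L), con, 2, endian = "little")          # PCM, mono
  writeBin(as.integer(round(x$rate)), con, 4, endian = "little")
  writeBin(as.integer(round(x$rate) * 2L), con, 4, endian = "little")
  writeBin(c(2L, 16L), con, 2, endian = "little")         # block align, bits
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_bytes), con, 4, endian = "little")
  writeBin(as.integer(q), con, 2, endian = "little")
  invisible(path)
}
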