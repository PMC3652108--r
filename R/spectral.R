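#' Cochlear partition specification
#'
#' The dominant-frequency analysis divides 100 Hz to 10 kHz into 181
#' log-spaced cochlear partitions (log spacing matches cochlear tonotopy).
#'
#' @param f_lo,f_hi Frequency range bounds in Hz.
#' @param n Number of partitions (>= 2).
#' @return A list of class `partition_spec`.
#' @export
partition_spec <- function(f_lo = 100, f_hi = 10000, n = 181) {
  if (!(0 < f_lo && f_lo < f_hi)) stop("need 0 < f_lo < f_hi")
  if (n < 2) stop("need at least 2 partitions")
  structure(list(f_lo = f_lo, f_hi = f_hi, n = as.integer(n),
                 spacing = "log"),
            class = "partition_spec")
}

#' @rdname partition_spec
#' @param spec A `partition_spec`.
#' @return `partition_cfs()` returns the `n` log-spaced center frequencies
#'   from `f_lo` to `f_hi` inclusive.
#' @examples
#' partition_cfs(partition_spec())[91]  # 1000 (geometric mean of the range)
#' @export
partition_cfs <- function(spec = partition_spec()) {
  stopifnot(inherits(spec, "partition_spec"))
  exp(seq(log(spec$f_lo), log(spec$f_hi), length.out = spec$n))
}

#' Dominant frequency of a signal within a band
#'
#' Frequency of the maximum-magnitude bin of the Hann-windowed FFT of the full
#' signal, zero-padded to at least 2^16 points, restricted to `band`. At
#' 22.05 kHz the bin spacing is about 0.34 Hz.
#'
#' @param y A nonempty [waveform].
#' @param band Length-2 numeric `(f_lo, f_hi)` inside (0, Nyquist).
#' @param nfft_min Minimum FFT length (zero-padded; default `2^16`).
#' @return Dominant frequency in Hz.
#' @export
dominant_frequency <- function(y, band, nfft_min = 2^16) {
  stopifnot(is_waveform(y), length(band) == 2, band[1] < band[2])
  n <- length(y$samples)
  if (n == 0L || all(y$samples == 0)) {
    stop("no dominant component: signal is empty or all zero")
  }
  if (band[2] > y$rate / 2) stop("band must lie below Nyquist")
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))   # Hann
  nfft <- max(nfft_min, 2^ceiling(log2(n)))
  mag <- Mod(stats::fft(c(y$samples * w, numeric(nfft - n))))
  half <- seq_len(nfft %/% 2 + 1)
  freqs <- (half - 1) * y$rate / nfft
  sel <- which(freqs >= band[1] & freqs <= band[2])
  if (!length(sel)) stop("band contains no FFT bins")
  freqs[sel[which.max(mag[sel])]]
}

#' Dominant-frequency-component profile across cochlear partitions
#'
#' For every partition center frequency, builds a channel (bandwidth
#' interpolated log-log from the 12-channel allocation table, tail/tip split
#' via [split_bandwidths()]), processes the stimulus with the chosen
#' frequency-decomposition model, and records the dominant frequency of the
#' channel output within the analysis range. The stimulus is peak-normalized
#' and scaled to `level` dB SPL through `calib` first. Formant capture shows
#' up as horizontal bands in the profile; channel-dominated output as a
#' diagonal.
#'
#' @param x Input [waveform].
#' @param model `"linear"` or `"sdpn"`.
#' @param partitions A [partition_spec()].
#' @param level Presentation level in dB SPL.
#' @param calib A [calibration()].
#' @param params [sdpn_params()] for the sdpn model.
#' @param linear_order Conventional-filter prototype order.
#' @return A data.frame of class `dfc_profile` with columns
#'   `partition_cf_hz`, `dominant_freq_hz`.
#' @export
dfc_profile <- function(x, model = c("linear", "sdpn"),
                        partitions = partition_spec(), level = 60,
                        calib = calibration(), params = sdpn_params(),
                        linear_order = 4) {
  stopifnot(is_waveform(x))
  model <- match.arg(model)
  if (x$rate < 2 * partitions$f_hi) {
    stop("sampling rate ", x$rate, " Hz cannot represent f_hi = ",
         partitions$f_hi, " Hz")
  }
  cfs <- partition_cfs(partitions)
  amp <- spl_to_amplitude(level, calib)
  peak <- max(abs(x$samples))
  if (peak <= 0) stop("input signal is all zero")
  xs <- waveform(x$samples / peak * amp, x$rate)
  band <- c(partitions$f_lo, partitions$f_hi)
  dom <- vapply(cfs, function(cf) {
    bw <- interp_channel_bandwidth(cf)
    spec <- channel_spec(cf, bw)
    out <- if (model == "sdpn") {
      filt <- design_channel_filters(spec, params, x$rate)
      process_sdpn_channel(xs, filt, params)
    } else {
      process_linear_channel(xs, spec, x$rate, linear_order)
    }
    dominant_frequency(out, band)
  }, numeric(1))
  structure(data.frame(partition_cf_hz = cfs, dominant_freq_hz = dom),
            class = c("dfc_profile", "data.frame"),
            model = model, level = level)
}

#' Formant extraction ratios from a dominant-frequency profile
#'
#' FER1 and FER2 are the fractions of cochlear partitions whose dominant
#' output frequency coincides with the first and second formant, within a
#' relative tolerance (default 2 percent, which keeps the windows of the
#' standard test vowels disjoint). High FERs mean salient formant
#' representation in the processed output.
#'
#' @param profile A [dfc_profile()] (or data.frame with `dominant_freq_hz`).
#' @param f1,f2 First and second formant frequencies in Hz.
#' @param tol Relative tolerance defining the formant windows.
#' @return A list of class `fer_result` with `fer1`, `fer2`, `f1`, `f2`,
#'   `tol`, `n`.
#' @examples
#' p <- data.frame(dominant_freq_hz = c(270, 270, 270, 2290, 2290, 500,
#'                                      500, 500, 500, 500))
#' formant_extraction_ratios(p, 270, 2290)  # fer1 0.3, fer2 0.2
#' @export
formant_extraction_ratios <- function(profile, f1, f2, tol = 0.02) {
  stopifnot(f1 > 0, f2 > f1, tol > 0)
  if (f1 * (1 + tol) >= f2 * (1 - tol)) {
    stop("formant tolerance windows overlap: shrink `tol`")
  }
  d <- profile$dominant_freq_hz
  n <- length(d)
  structure(list(fer1 = sum(abs(d - f1) <= tol * f1) / n,
                 fer2 = sum(abs(d - f2) <= tol * f2) / n,
                 f1 = f1, f2 = f2, tol = tol, n = n),
            class = "fer_result")
}

#' @rdname formant_extraction_ratios
#' @param x An `fer_result`.
#' @param ... Ignored.
#' @export
print.fer_result <- function(x, ...) {
  cat(sprintf(
    "<fer_result: FER1 %.3f (F1 %g Hz), FER2 %.3f (F2 %g Hz), tol %.1f%%, %d partitions>\n",
    x$fer1, x$f1, x$fer2, x$f2, 100 * x$tol, x$n))
  invisible(x)
}
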