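#' Envelope detector parameters
#'
#' The standard detector is a full-wave rectifier followed by a 4th-order
#' Butterworth lowpass at 400 Hz. The transient-enhanced detector runs a
#' second, slow detector (20 Hz cutoff) in parallel and boosts the fast
#' envelope wherever the fast/slow ratio signals a rapid onset: with ratio
#' `r = fast / (slow + smoothing_eps)`, the applied gain is 1 for `r <=
#' boost_threshold` and `min(1 + boost_factor * (r - boost_threshold),
#' boost_max)` above it. The boost rule is one admissible realization of
#' onset emphasis; its magnitude and cap are fully parameterized.
#'
#' @param lpf_order Butterworth prototype order of both lowpass filters.
#' @param lpf_fc Fast-envelope cutoff in Hz (default 400).
#' @param slow_fc Slow-envelope cutoff in Hz (default 20).
#' @param boost_threshold Ratio threshold above which boosting starts
#'   (default 1.5).
#' @param boost_factor Boost slope per unit ratio excess (default 1).
#' @param boost_max Gain cap (default 3).
#' @param smoothing_eps Amplitude floor added to the slow envelope before the
#'   ratio, guarding silence.
#' @return A list of class `envelope_params`.
#' @export
envelope_params <- function(lpf_order = 4, lpf_fc = 400, slow_fc = 20,
                            boost_threshold = 1.5, boost_factor = 1,
                            boost_max = 3, smoothing_eps = 1e-6) {
  stopifnot(lpf_order > 0, 0 < slow_fc, slow_fc < lpf_fc,
            boost_threshold >= 1, boost_max >= 1, smoothing_eps > 0)
  structure(list(lpf_order = lpf_order, lpf_fc = lpf_fc, slow_fc = slow_fc,
                 boost_threshold = boost_threshold,
                 boost_factor = boost_factor, boost_max = boost_max,
                 smoothing_eps = smoothing_eps),
            class = "envelope_params")
}

.envelope_lowpass <- function(x, fc, params) {
  if (fc >= x$rate / 2) {
    stop("envelope cutoff ", fc, " Hz reaches Nyquist at rate ", x$rate, " Hz")
  }
  sos <- butter_lowpass_sos(params$lpf_order, fc, x$rate)
  pmax(sos_filter(abs(x$samples), sos), 0)
}

#' Standard envelope detection
#'
#' Full-wave rectification followed by a causal Butterworth lowpass (DC gain
#' 1); negative filter undershoot is clipped at zero. For a steady tone of
#' amplitude A the envelope settles to the rectified mean `2A/pi`.
#'
#' @param x A [waveform].
#' @param params [envelope_params()].
#' @return A nonnegative [waveform] of the same length and rate.
#' @export
envelope_standard <- function(x, params = envelope_params()) {
  stopifnot(is_waveform(x))
  waveform(.envelope_lowpass(x, params$lpf_fc, params), x$rate)
}

#' Transient-enhanced envelope detection
#'
#' Compares the 400 Hz (fast) and 20 Hz (slow) envelopes and multiplies the
#' fast envelope by a bounded gain wherever the fast/slow ratio exceeds the
#' onset threshold (see [envelope_params()]). On steady signals the ratio
#' settles near 1 and the output equals the standard envelope; at abrupt
#' onsets the fast envelope outruns the slow one and gets boosted by a factor
#' in (1, `boost_max`].
#'
#' @inheritParams envelope_standard
#' @return A nonnegative [waveform]; everywhere `>=` the standard envelope and
#'   `<= boost_max` times it.
#' @export
envelope_enhanced <- function(x, params = envelope_params()) {
  stopifnot(is_waveform(x))
  fast <- .envelope_lowpass(x, params$lpf_fc, params)
  slow <- .envelope_lowpass(x, params$slow_fc, params)
  r <- fast / (slow + params$smoothing_eps)
  g <- pmin(1 + params$boost_factor * pmax(r - params$boost_threshold, 0),
            params$boost_max)
  waveform(fast * g, x$rate)
}

#' Export an envelope as CSV (time_s, value)
#'
#' @param x A [waveform] (typically an envelope).
#' @param path CSV output path.
#' @return `path`, invisibly.
#' @export
write_envelope_csv <- function(x, path) {
  stopifnot(is_waveform(x))
  utils::write.csv(
    data.frame(time_s = (seq_along(x$samples) - 1) / x$rate,
               value = x$samples),
    path, row.names = FALSE)
  invisible(path)
}
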