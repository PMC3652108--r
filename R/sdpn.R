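#' Parameters of the dual-path nonlinear channel
#'
#' Each channel sums a broad linear pathway (gain `linear_gain` into the
#' 2nd-order "tail" bandpass) with a sharp nonlinear pathway (4th-order "tip"
#' bandpass into the compressive nonlinearity `y = nl_scale * atan(nl_slope *
#' x)`, defaults `2 * atan(15 x)`). The nonlinearity mimics outer-hair-cell
#' saturation: its contribution dominates at low level and saturates at high
#' level, producing level-dependent tuning.
#'
#' @param linear_gain Linear-pathway gain (dimensionless, default 6).
#' @param nl_scale,nl_slope Nonlinearity scale and slope (defaults 2 and 15).
#' @param tail_order,tip_order Butterworth prototype orders of the tail and
#'   tip bandpass filters (defaults 2 and 4).
#' @param rms_window Running-RMS window in seconds for `rms_gain` mode
#'   (default 0.008).
#' @param nl_mode How the nonlinearity is applied to the tip-filtered signal:
#'   `"rms_gain"` (default) drives a time-varying gain `nl_scale *
#'   atan(nl_slope * rms) / rms` from the causal running RMS, preserving
#'   waveform shape; `"instantaneous"` applies `nl_scale * atan(nl_slope * x)`
#'   per sample; `"fixed_gain"` applies the constant `fixed_gain` (making the
#'   whole channel linear, useful for superposition checks).
#' @param fixed_gain Gain used by `nl_mode = "fixed_gain"`; defaults to the
#'   small-signal limit `nl_scale * nl_slope`.
#' @return A list of class `sdpn_params`.
#' @export
sdpn_params <- function(linear_gain = 6, nl_scale = 2, nl_slope = 15,
                        tail_order = 2, tip_order = 4, rms_window = 0.008,
                        nl_mode = c("rms_gain", "instantaneous", "fixed_gain"),
                        fixed_gain = nl_scale * nl_slope) {
  nl_mode <- match.arg(nl_mode)
  stopifnot(linear_gain > 0, nl_scale > 0, nl_slope > 0,
            tail_order > 0, tip_order > 0, rms_window > 0)
  structure(list(linear_gain = linear_gain, nl_scale = nl_scale,
                 nl_slope = nl_slope, tail_order = tail_order,
                 tip_order = tip_order, rms_window = rms_window,
                 nl_mode = nl_mode, fixed_gain = fixed_gain),
            class = "sdpn_params")
}

#' Compressive gain of the saturating nonlinearity
#'
#' The equivalent amplitude gain `nl_scale * atan(nl_slope * level) / level`
#' applied to the tip pathway when the nonlinearity is driven at a given RMS
#' level, with the continuous small-signal limit `nl_scale * nl_slope` at
#' level 0 (30 with defaults). Monotonically non-increasing in level.
#'
#' @param level RMS amplitude(s), non-negative; vectorized.
#' @param params [sdpn_params()].
#' @return Dimensionless gain(s).
#' @examples
#' compressive_gain(0)  # 30
#' compressive_gain(1)  # 2 * atan(15)
#' @export
compressive_gain <- function(level, params = sdpn_params()) {
  if (any(level < 0)) stop("level must be non-negative")
  g <- rep(params$nl_scale * params$nl_slope, length(level))
  pos <- level > 0
  g[pos] <- params$nl_scale * atan(params$nl_slope * level[pos]) / level[pos]
  g
}

#' Design the tail and tip bandpass filters of a channel
#'
#' @param spec A [channel_spec()] giving cf and the tail/tip bandwidths.
#' @param params [sdpn_params()] (supplies the filter orders).
#' @param rate Sampling rate in Hz; the tail passband must sit below Nyquist.
#' @return A list of class `channel_filters` with `$tail` and `$tip` biquad
#'   matrices plus design metadata.
#' @export
design_channel_filters <- function(spec, params = sdpn_params(), rate = 22050) {
  stopifnot(inherits(spec, "channel_spec"))
  hi <- spec$cf + spec$bw_tail / 2
  if (rate <= 2 * hi) {
    stop("channel cf ", spec$cf, " Hz: tail passband edge ", round(hi, 1),
         " Hz reaches Nyquist at rate ", rate, " Hz")
  }
  tail <- butter_bandpass_sos(params$tail_order,
                              spec$cf - spec$bw_tail / 2,
                              spec$cf + spec$bw_tail / 2, rate)
  tip <- butter_bandpass_sos(params$tip_order,
                             spec$cf - spec$bw_tip / 2,
                             spec$cf + spec$bw_tip / 2, rate)
  stopifnot(sos_is_stable(tail), sos_is_stable(tip))
  structure(list(tail = tail, tip = tip, spec = spec, rate = rate,
                 params = params),
            class = "channel_filters")
}

#' Process a waveform through one dual-path nonlinear channel
#'
#' Output is `linear_gain * tail(x) + NL[tip(x)]`: the broad linear pathway
#' plus the compressed sharp pathway, summed sample-wise. See [sdpn_params()]
#' for the nonlinearity modes.
#'
#' @param x A [waveform] at the rate the filters were designed for.
#' @param filters A `channel_filters` object from [design_channel_filters()].
#' @param params [sdpn_params()]; defaults to the parameters stored at design
#'   time.
#' @return A [waveform] of the same length and rate.
#' @export
process_sdpn_channel <- function(x, filters, params = NULL) {
  stopifnot(is_waveform(x), inherits(filters, "channel_filters"))
  if (is.null(params)) params <- filters$params
  if (!isTRUE(all.equal(x$rate, filters$rate))) {
    stop("waveform rate ", x$rate, " Hz does not match filter design rate ",
         filters$rate, " Hz")
  }
  tail_out <- params$linear_gain * sos_filter(x$samples, filters$tail)
  tip_f <- sos_filter(x$samples, filters$tip)
  tip_out <- switch(params$nl_mode,
    rms_gain = {
      r <- running_rms(tip_f, round(params$rms_window * x$rate))
      compressive_gain(r, params) * tip_f
    },
    instantaneous = params$nl_scale * atan(params$nl_slope * tip_f),
    fixed_gain = params$fixed_gain * tip_f
  )
  waveform(tail_out + tip_out, x$rate)
}

#' Process a waveform through one conventional linear channel
#'
#' The fixed linear bandpass used by conventional processors: a Butterworth
#' bandpass with passband `cf +/- bw_channel/2`. Prototype order defaults to
#' 4, as typical for CIS-style analysis filters.
#'
#' @param x A [waveform].
#' @param spec A [channel_spec()].
#' @param rate Sampling rate in Hz (must match `x`).
#' @param order Butterworth prototype order.
#' @return A [waveform].
#' @export
process_linear_channel <- function(x, spec, rate = x$rate, order = 4) {
  stopifnot(is_waveform(x), inherits(spec, "channel_spec"))
  if (!isTRUE(all.equal(x$rate, rate))) {
    stop("waveform rate ", x$rate, " Hz does not match requested rate ",
         rate, " Hz")
  }
  hi <- spec$cf + spec$bw_channel / 2
  if (rate <= 2 * hi) {
    stop("channel cf ", spec$cf, " Hz: passband edge ", round(hi, 1),
         " Hz reaches Nyquist at rate ", rate, " Hz")
  }
  sos <- butter_bandpass_sos(order, spec$cf - spec$bw_channel / 2,
                             spec$cf + spec$bw_channel / 2, rate)
  waveform(sos_filter(x$samples, sos), x$rate)
}
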