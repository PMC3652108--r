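#' Strategy configuration for the full processing chain
#'
#' Bundles the choices defining one sound-processing strategy: frequency
#' decomposition model (`"linear"` fixed bandpass array or `"sdpn"` dual-path
#' nonlinear array), envelope detector (`"standard"` or `"enhanced"`), the
#' channel map, SPL calibration, and output normalization. The logarithmic
#' compression applied before electrical stimulation in a real processor is
#' bypassed in acoustic simulation; a `compression` hook is exposed and
#' defaults to identity.
#'
#' @param model `"linear"` or `"sdpn"`.
#' @param envelope `"standard"` or `"enhanced"`.
#' @param map A [channel_map()]; default the 8-channel table.
#' @param calib A [calibration()].
#' @param normalize_output If `TRUE` (default) the output RMS is rescaled to
#'   the input RMS, preventing clipping on 16-bit export.
#' @param params [sdpn_params()] for the sdpn model.
#' @param env_params [envelope_params()].
#' @param linear_order Butterworth prototype order of the conventional
#'   analysis filters.
#' @param compression Function applied to each channel envelope before
#'   vocoding; default identity.
#' @return A list of class `strategy_config`.
#' @export
strategy_config <- function(model = c("linear", "sdpn"),
                            envelope = c("standard", "enhanced"),
                            map = make_channel_map(8),
                            calib = calibration(),
                            normalize_output = TRUE,
                            params = sdpn_params(),
                            env_params = envelope_params(),
                            linear_order = 4,
                            compression = identity) {
  model <- match.arg(model)
  envelope <- match.arg(envelope)
  stopifnot(inherits(map, "channel_map"))
  structure(list(model = model, envelope = envelope, map = map,
                 calib = calib, normalize_output = normalize_output,
                 params = params, env_params = env_params,
                 linear_order = linear_order, compression = compression),
            class = "strategy_config")
}

#' Sum envelope-modulated sinusoidal carriers
#'
#' The acoustic-simulation synthesis stage: each channel contributes one
#' sinusoid at its center frequency (zero initial phase), amplitude-modulated
#' by the channel envelope, and the channels are summed.
#'
#' @param envelopes List of per-channel envelope [waveform]s, all of one rate
#'   and length, one per channel of `map`.
#' @param map A [channel_map()].
#' @return A [waveform]: `sum_i env_i(t) * sin(2 pi cf_i t)`.
#' @export
vocode_channels <- function(envelopes, map) {
  stopifnot(inherits(map, "channel_map"))
  if (length(envelopes) != length(map$channels)) {
    stop("need one envelope per channel (", length(map$channels),
         "), got ", length(envelopes))
  }
  stopifnot(all(vapply(envelopes, is_waveform, logical(1))))
  rates <- vapply(envelopes, `[[`, numeric(1), "rate")
  lens <- vapply(envelopes, function(e) length(e$samples), integer(1))
  if (length(unique(rates)) != 1L) stop("envelope rates differ")
  if (length(unique(lens)) != 1L) stop("envelope lengths differ")
  rate <- rates[1]
  t <- (seq_len(lens[1]) - 1) / rate
  out <- numeric(lens[1])
  for (i in seq_along(envelopes)) {
    cf <- map$channels[[i]]$cf
    out <- out + envelopes[[i]]$samples * sin(2 * pi * cf * t)
  }
  waveform(out, rate)
}

#' Run a complete sound-processing strategy
#'
#' Frequency decomposition (linear bandpass array or dual-path nonlinear
#' array) -> per-channel envelope detection -> sinusoidal vocoding, with
#' optional RMS normalization of the output to the input level.
#'
#' @param x Input [waveform].
#' @param config A [strategy_config()].
#' @return The vocoded [waveform].
#' @examples
#' v <- synth_vowel(vowel_preset("i", duration = 0.2))
#' y <- run_strategy(v, strategy_config("sdpn", map = make_channel_map(4)))
#' @export
run_strategy <- function(x, config = strategy_config()) {
  stopifnot(is_waveform(x), inherits(config, "strategy_config"))
  envs <- lapply(config$map$channels, function(spec) {
    band <- if (config$model == "sdpn") {
      filt <- design_channel_filters(spec, config$params, x$rate)
      process_sdpn_channel(x, filt, config$params)
    } else {
      process_linear_channel(x, spec, x$rate, config$linear_order)
    }
    env <- if (config$envelope == "enhanced") {
      envelope_enhanced(band, config$env_params)
    } else {
      envelope_standard(band, config$env_params)
    }
    waveform(config$compression(env$samples), env$rate)
  })
  out <- vocode_channels(envs, config$map)
  if (isTRUE(config$normalize_output)) {
    r_in <- rms(x$samples); r_out <- rms(out$samples)
    if (r_out > 0 && r_in > 0) {
      out <- waveform(out$samples * r_in / r_out, out$rate)
    }
  }
  out
}
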