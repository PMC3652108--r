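#' SPL-to-amplitude calibration
#'
#' Maps sound pressure level in dB to digital peak amplitude by fixing the
#' level that corresponds to peak amplitude 1.0. The default reference of
#' 40 dB SPL places the 35 and 85 dB operating points of the channel
#' characterization on either side of the compressive knee of the
#' `2 atan(15 x)` nonlinearity.
#'
#' @param dbspl_at_unit_amplitude dB SPL mapped to peak amplitude 1.0
#'   (default 40).
#' @return A list of class `calibration`.
#' @export
calibration <- function(dbspl_at_unit_amplitude = 40) {
  stopifnot(is.finite(dbspl_at_unit_amplitude))
  structure(list(dbspl_at_unit_amplitude = dbspl_at_unit_amplitude),
            class = "calibration")
}

#' @rdname calibration
#' @param spl Sound pressure level(s) in dB; vectorized.
#' @param calib A `calibration`.
#' @examples
#' spl_to_amplitude(40)  # 1
#' spl_to_amplitude(60)  # 10
#' @export
spl_to_amplitude <- function(spl, calib = calibration()) {
  stopifnot(all(is.finite(spl)))
  10^((spl - calib$dbspl_at_unit_amplitude) / 20)
}

#' Formant vowel specification and presets
#'
#' A source-filter vowel: an impulse train at the fundamental passed through a
#' cascade of two-pole formant resonators and a first-difference radiation
#' filter. The /i/ preset uses F1/F2/F3 = 270/2290/3010 Hz; /a/ =
#' 730/1090/2440 Hz and /u/ = 300/870/2240 Hz are classic reference values.
#' Default formant bandwidths are 60/90/120 Hz and the default fundamental is
#' 100 Hz.
#'
#' @param formants Numeric vector of formant frequencies in Hz, increasing.
#' @param bandwidths Formant bandwidths in Hz (recycled).
#' @param f0 Fundamental frequency in Hz.
#' @param duration Token duration in seconds.
#' @return A list of class `vowel_spec`.
#' @export
vowel_spec <- function(formants, bandwidths = c(60, 90, 120), f0 = 100,
                       duration = 0.5) {
  stopifnot(length(formants) >= 1, all(diff(formants) > 0), f0 > 0,
            duration > 0, all(bandwidths > 0))
  bandwidths <- rep_len(bandwidths, length(formants))
  structure(list(formants = formants, bandwidths = bandwidths, f0 = f0,
                 duration = duration),
            class = "vowel_spec")
}

#' @rdname vowel_spec
#' @param vowel One of `"i"`, `"a"`, `"u"`.
#' @param ... Overrides passed to [vowel_spec()] (`bandwidths`, `f0`,
#'   `duration`).
#' @export
vowel_preset <- function(vowel = c("i", "a", "u"), ...) {
  vowel <- match.arg(vowel)
  formants <- switch(vowel,
    i = c(270, 2290, 3010),
    a = c(730, 1090, 2440),
    u = c(300, 870, 2240)
  )
  vowel_spec(formants, ...)
}

#' Synthesize a formant vowel
#'
#' Impulse train at `f0` through a cascade of two-pole resonators (poles at
#' radius `exp(-pi * bw / rate)`, unit DC gain) and a first-difference
#' radiation filter; the result is peak-normalized to 1.0.
#'
#' @param spec A [vowel_spec()].
#' @param rate Sampling rate in Hz.
#' @return A [waveform].
#' @examples
#' v <- synth_vowel(vowel_preset("i"))
#' duration(v)
#' @export
synth_vowel <- function(spec, rate = 22050) {
  stopifnot(inherits(spec, "vowel_spec"))
  if (any(spec$formants >= rate / 2)) {
    stop("formant frequency reaches Nyquist at rate ", rate, " Hz")
  }
  n <- round(spec$duration * rate)
  x <- numeric(n)
  pulses <- round(seq(0, spec$duration, by = 1 / spec$f0) * rate) + 1
  pulses <- pulses[pulses <= n]
  x[pulses] <- 1
  for (i in seq_along(spec$formants)) {
    r <- exp(-pi * spec$bandwidths[i] / rate)
    th <- 2 * pi * spec$formants[i] / rate
    b <- 2 * r * cos(th); c2 <- -r^2
    a0 <- 1 - b - c2                       # unit gain at DC
    x <- as.numeric(stats::filter(a0 * x, c(b, c2), method = "recursive"))
  }
  x <- c(x[1], diff(x))                    # radiation (first difference)
  waveform(x / max(abs(x)), rate)
}

# run expr with a private RNG seeded at `seed`, restoring the caller's state
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Generate white Gaussian noise
#'
#' Zero-mean unit-variance Gaussian samples; the seed fully determines the
#' realization and the caller's RNG state is left untouched.
#'
#' @param duration Seconds.
#' @param rate Sampling rate in Hz.
#' @param seed Integer seed.
#' @return A [waveform].
#' @export
gen_wgn <- function(duration, rate = 22050, seed = 1) {
  stopifnot(duration > 0, rate > 0)
  n <- round(duration * rate)
  waveform(.with_seed(seed, stats::rnorm(n)), rate)
}

#' Generate speech-shaped noise
#'
#' White Gaussian noise through a 2nd-order Butterworth lowpass at `ssn_fc`
#' (default 1100 Hz), approximating the long-term spectrum of speech: flat
#' below the cutoff, rolling off at about 12 dB per octave above it.
#'
#' @inheritParams gen_wgn
#' @param ssn_fc Lowpass cutoff in Hz (default 1100).
#' @param ssn_order Butterworth prototype order (default 2).
#' @return A [waveform].
#' @export
gen_ssn <- function(duration, rate = 22050, seed = 1, ssn_fc = 1100,
                    ssn_order = 2) {
  if (ssn_fc >= rate / 2) stop("ssn_fc reaches Nyquist")
  w <- gen_wgn(duration, rate, seed)
  sos <- butter_lowpass_sos(ssn_order, ssn_fc, rate)
  waveform(sos_filter(w$samples, sos), rate)
}

#' Mix signal and noise at an exact SNR
#'
#' Rescales the noise so that `10*log10(P_signal / P_noise)` equals `snr_db`
#' exactly (powers measured over the full duration, no silence trimming), then
#' adds it to the signal. `snr_db = Inf` returns the signal unchanged.
#'
#' @param signal,noise [waveform]s of equal rate and length.
#' @param snr_db Target signal-to-noise ratio in dB (may be `Inf`).
#' @return A [waveform].
#' @export
mix_at_snr <- function(signal, noise, snr_db) {
  stopifnot(is_waveform(signal), is_waveform(noise))
  if (is.infinite(snr_db) && snr_db > 0) return(signal)
  if (!isTRUE(all.equal(signal$rate, noise$rate))) {
    stop("signal and noise rates differ")
  }
  if (length(signal$samples) != length(noise$samples)) {
    stop("signal and noise lengths differ")
  }
  p_s <- mean(signal$samples^2)
  p_n <- mean(noise$samples^2)
  if (p_s <= 0) stop("signal has zero power")
  if (p_n <= 0) stop("noise has zero power")
  scale <- sqrt(p_s / (p_n * 10^(snr_db / 10)))
  waveform(signal$samples + scale * noise$samples, signal$rate)
}
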