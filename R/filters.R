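# Butterworth IIR design in pole-zero form, realized as cascaded biquads
# (second-order sections). Designing in zpk and pairing conjugate poles keeps
# the narrow low-frequency bandpass filters needed by the 181-partition
# analysis numerically stable where a single high-order (b, a) polynomial is
# not. Causal filtering with zero initial conditions throughout, matching a
# real-time processor.

# analog Butterworth lowpass prototype poles, unit cutoff
butter_prototype_poles <- function(n) {
  k <- seq_len(n)
  exp(1i * pi * (2 * k + n - 1) / (2 * n))
}

sos_response <- function(sos, f, fs) {
  z <- exp(-2i * pi * f / fs)
  H <- rep(1 + 0i, length(z))
  for (i in seq_len(nrow(sos))) {
    H <- H * (sos[i, 1] + sos[i, 2] * z + sos[i, 3] * z^2) /
      (sos[i, 4] + sos[i, 5] * z + sos[i, 6] * z^2)
  }
  H
}

# pair digital poles (one per conjugate pair, Im > 0) with per-section zeros
.sos_from_poles <- function(zpos, zeros_b) {
  t(vapply(seq_along(zpos), function(i) {
    p <- zpos[i]
    c(zeros_b, 1, -2 * Re(p), Mod(p)^2)
  }, numeric(6)))
}

#' Design a Butterworth bandpass as second-order sections
#'
#' Prototype (lowpass) order `n` gives a `2n`-pole bandpass with -3 dB edges
#' at `f1` and `f2`, unit amplitude at the (bilinear-mapped) center frequency.
#'
#' @param n Prototype order (even).
#' @param f1,f2 Lower and upper -3 dB edge frequencies in Hz, `0 < f1 < f2 <
#'   fs/2`.
#' @param fs Sampling rate in Hz.
#' @return A matrix with one row per biquad, columns `b0 b1 b2 a0 a1 a2`.
#' @export
butter_bandpass_sos <- function(n, f1, f2, fs) {
  if (n %% 2 != 0 || n < 2) stop("prototype order must be even and >= 2")
  if (!(0 < f1 && f1 < f2)) stop("need 0 < f1 < f2")
  if (f2 >= fs / 2) stop("upper band edge ", round(f2, 1),
                         " Hz reaches Nyquist (fs = ", fs, " Hz)")
  w1 <- 2 * fs * tan(pi * f1 / fs)
  w2 <- 2 * fs * tan(pi * f2 / fs)
  w0 <- sqrt(w1 * w2)
  B <- w2 - w1
  p <- butter_prototype_poles(n)
  bp <- unlist(lapply(p, function(pk) {
    disc <- sqrt((pk * B)^2 - 4 * w0^2 + 0i)
    c((pk * B + disc) / 2, (pk * B - disc) / 2)
  }))
  zd <- (1 + bp / (2 * fs)) / (1 - bp / (2 * fs))
  zpos <- zd[Im(zd) > 0]
  if (length(zpos) != n) stop("pole pairing failed; band too extreme for fs")
  # n zeros at z = 1 and n at z = -1: one of each per section, b = (1, 0, -1)
  sos <- .sos_from_poles(zpos, c(1, 0, -1))
  f0d <- fs / pi * atan(w0 / (2 * fs))
  g <- Mod(sos_response(sos, f0d, fs))
  sos[1, 1:3] <- sos[1, 1:3] / g
  attr(sos, "design") <- list(type = "bandpass", order = n, f1 = f1, f2 = f2,
                              fs = fs, fcenter = f0d)
  sos
}

#' Design a Butterworth lowpass as second-order sections
#'
#' @inheritParams butter_bandpass_sos
#' @param fc Cutoff (-3 dB) frequency in Hz.
#' @return A biquad coefficient matrix as in [butter_bandpass_sos()].
#' @export
butter_lowpass_sos <- function(n, fc, fs) {
  if (n %% 2 != 0 || n < 2) stop("prototype order must be even and >= 2")
  if (fc <= 0 || fc >= fs / 2) stop("cutoff ", fc, " Hz must lie in (0, fs/2)")
  wc <- 2 * fs * tan(pi * fc / fs)
  p <- butter_prototype_poles(n) * wc
  zd <- (1 + p / (2 * fs)) / (1 - p / (2 * fs))
  zpos <- zd[Im(zd) > 0]
  sos <- .sos_from_poles(zpos, c(1, 2, 1))
  g <- Mod(sos_response(sos, 0, fs))
  sos[1, 1:3] <- sos[1, 1:3] / g
  attr(sos, "design") <- list(type = "lowpass", order = n, fc = fc, fs = fs)
  sos
}

#' Apply a second-order-section filter causally
#'
#' Zero initial conditions; each biquad's moving-average part is vectorized
#' and its autoregressive part runs through `stats::filter(method =
#' "recursive")`.
#'
#' @param x Numeric sample vector.
#' @param sos Biquad matrix from the designers above.
#' @return Filtered numeric vector, same length as `x`.
#' @export
sos_filter <- function(x, sos) {
  y <- as.numeric(x)
  n <- length(y)
  if (n == 0L) return(y)
  for (i in seq_len(nrow(sos))) {
    b <- sos[i, 1:3]; a <- sos[i, 4:6]
    v <- b[1] * y
    if (n > 1L) v <- v + b[2] * c(0, y[-n])
    if (n > 2L) v <- v + b[3] * c(0, 0, y[-c(n - 1L, n)])
    y <- as.numeric(stats::filter(v, -a[2:3] / a[1], method = "recursive"))
  }
  y
}

# all poles strictly inside the unit circle?
sos_is_stable <- function(sos) {
  all(vapply(seq_len(nrow(sos)), function(i) {
    r <- Mod(polyroot(rev(sos[i, 4:6])))
    all(r < 1)
  }, logical(1)))
}

# causal running RMS over a trailing rectangular window of `win` samples;
# the first win-1 samples use the partial (cumulative) window
running_rms <- function(x, win) {
  n <- length(x)
  if (n == 0L) return(numeric(0))
  win <- max(1L, as.integer(win))
  cs <- cumsum(x^2)
  i <- seq_len(n)
  m <- cs / pmin(i, win)
  if (n > win) {
    idx <- (win + 1L):n
    m[idx] <- (cs[idx] - cs[idx - win]) / win
  }
  sqrt(pmax(m, 0))
}
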