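# shared fixtures and small DSP oracles used across tests

FS <- 22050

tone <- function(freq, amp = 1, dur = 0.5, rate = FS, phase = 0) {
  t <- (seq_len(round(dur * rate)) - 1) / rate
  waveform(amp * sin(2 * pi * freq * t + phase), rate)
}

silence <- function(dur = 0.5, rate = FS) {
  waveform(numeric(round(dur * rate)), rate)
}

# Welch PSD estimate: Hann-windowed segments with 50% overlap, averaged
# periodograms. Returns freq (Hz) and psd (linear power).
welch_psd <- function(x, fs, nseg = 1024) {
  n <- length(x)
  step <- nseg %/% 2
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(nseg) - 1) / (nseg - 1))
  starts <- seq(1, n - nseg + 1, by = step)
  acc <- numeric(nseg %/% 2 + 1)
  for (s in starts) {
    seg <- x[s:(s + nseg - 1)] * w
    p <- Mod(stats::fft(seg))^2
    acc <- acc + p[seq_len(nseg %/% 2 + 1)]
  }
  list(freq = (seq_len(nseg %/% 2 + 1) - 1) * fs / nseg,
       psd = acc / length(starts) / sum(w^2) / fs)
}

# mean PSD (dB) over a frequency band
band_db <- function(p, lo, hi) {
  sel <- p$freq >= lo & p$freq <= hi
  10 * log10(mean(p$psd[sel]))
}
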