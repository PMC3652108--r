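test_that("vowel tokens have the requested duration and harmonic structure", {
  v <- synth_vowel(vowel_preset("i"), 22050)
  expect_length(v$samples, 11025)
  expect_equal(max(abs(v$samples)), 1)

  # spectral lines at multiples of f0 = 100 Hz
  mag <- Mod(stats::fft(v$samples))[1:5512]
  freqs <- (0:5511) * FS / 11025
  peaks <- freqs[order(mag, decreasing = TRUE)[1:10]]
  expect_true(all(abs(peaks - round(peaks / 100) * 100) < 4))
})

test_that("the /i/ preset's spectral envelope peaks near F1 and F2", {
  # a dense fundamental (50 Hz) resolves the envelope between harmonics;
  # the default 100 Hz token samples the same envelope more coarsely
  f0 <- 50
  v <- synth_vowel(vowel_preset("i", f0 = f0, duration = 1), 22050)
  n <- length(v$samples)
  mag <- Mod(stats::fft(v$samples))
  freqs <- (seq_len(n) - 1) * FS / n
  # envelope through the harmonic amplitudes (spline in log-amplitude)
  h <- seq(f0, 4000, by = f0)
  amp <- vapply(h, function(f) max(mag[abs(freqs - f) < f0 / 2.5]), numeric(1))
  env <- stats::splinefun(h, log(amp))
  grid <- seq(150, 3500, by = 1)
  e <- env(grid)
  loc_max <- grid[which(diff(sign(diff(e))) == -2) + 1]
  expect_true(any(abs(loc_max - 270) <= 0.05 * 270))
  expect_true(any(abs(loc_max - 2290) <= 0.05 * 2290))
})

test_that("vowel tokens are periodic at the fundamental", {
  v <- synth_vowel(vowel_preset("a"), 22050)
  x <- v$samples
  lag <- round(22050 / 100)
  r0 <- sum(x * x)
  rlag <- sum(x[1:(length(x) - lag)] * x[(lag + 1):length(x)])
  expect_gt(rlag / r0, 0.9)
})

test_that("formants beyond Nyquist are rejected", {
  expect_error(synth_vowel(vowel_preset("i"), 4000), "Nyquist")
  expect_error(vowel_spec(c(500, 400)), "diff")
})

test_that("noise generators are bit-reproducible and leave the RNG alone", {
  w1 <- gen_wgn(0.5, FS, 42)
  w2 <- gen_wgn(0.5, FS, 42)
  expect_identical(w1$samples, w2$samples)
  expect_false(identical(gen_wgn(0.5, FS, 43)$samples, w1$samples))
  s1 <- gen_ssn(0.5, FS, 42)
  s2 <- gen_ssn(0.5, FS, 42)
  expect_identical(s1$samples, s2$samples)

  set.seed(99)
  before <- rnorm(5)
  set.seed(99)
  invisible(gen_wgn(0.1, FS, 7))
  after <- rnorm(5)
  expect_identical(before, after)
})

test_that("white noise is zero-mean with a flat spectrum", {
  w <- gen_wgn(1, FS, 3)
  n <- length(w$samples)
  expect_lt(abs(mean(w$samples)), 4 / sqrt(n))
  p <- welch_psd(w$samples, FS)
  # octave-band averages flat within +/- 1.5 dB of the overall level
  edges <- c(100, 200, 400, 800, 1600, 3200, 6400, 10000)
  bands <- vapply(seq_len(length(edges) - 1), function(i) {
    band_db(p, edges[i], edges[i + 1])
  }, numeric(1))
  expect_lt(max(bands) - min(bands), 1.5)
})

test_that("speech-shaped noise rolls off 12 dB per octave above the cutoff", {
  s <- gen_ssn(10, FS, 8)
  p <- welch_psd(s$samples, FS, nseg = 4096)
  plateau <- band_db(p, 100, 500)
  at2200 <- band_db(p, 2150, 2250)
  at4400 <- band_db(p, 4350, 4450)
  expect_equal(plateau - at2200, 12, tolerance = 1.5 / 12)
  expect_lt(at4400, at2200)
  expect_error(gen_ssn(0.1, FS, 1, ssn_fc = 12000), "Nyquist")
})

test_that("SNR mixing is exact and handles the quiet condition", {
  v <- synth_vowel(vowel_preset("i"), FS)
  nz <- gen_wgn(duration(v), FS, 2)
  mixed <- mix_at_snr(v, nz, 0)
  scaled_noise <- mixed$samples - v$samples
  expect_equal(mean(scaled_noise^2), mean(v$samples^2), tolerance = 1e-9)

  m2 <- mix_at_snr(v, nz, 2)
  sn2 <- m2$samples - v$samples
  snr_meas <- 10 * log10(mean(v$samples^2) / mean(sn2^2))
  expect_equal(snr_meas, 2, tolerance = 1e-6)

  expect_identical(mix_at_snr(v, nz, Inf), v)
  expect_error(mix_at_snr(silence(0.5), nz, 5), "zero power")
  expect_error(mix_at_snr(v, silence(0.5), 5), "zero power")
  expect_error(mix_at_snr(v, gen_wgn(0.4, FS, 1), 5), "lengths")
})

test_that("SPL calibration is a pure exponential around the reference", {
  calib <- calibration(40)
  expect_equal(spl_to_amplitude(40, calib), 1)
  expect_equal(spl_to_amplitude(60, calib), 10)
  expect_equal(spl_to_amplitude(0, calib), 0.01)
  expect_equal(spl_to_amplitude(35, calib), 10^(-0.25))
})
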