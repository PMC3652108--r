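test_that("compressive gain has the right limit, values, and monotonicity", {
  expect_equal(compressive_gain(0), 30)
  expect_equal(compressive_gain(1e-9), 30, tolerance = 1e-6)
  expect_equal(compressive_gain(1), 2 * atan(15))
  lv <- 10^seq(-4, 3, length.out = 200)
  g <- compressive_gain(lv)
  expect_true(all(diff(g) <= 1e-12))
  expect_error(compressive_gain(-0.1), "non-negative")
})

test_that("zero input yields zero output through a dual-path channel", {
  filt <- design_channel_filters(channel_spec(1500, 357), rate = FS)
  out <- process_sdpn_channel(silence(0.2), filt)
  expect_true(all(out$samples == 0))
  lin <- process_linear_channel(silence(0.2), channel_spec(1500, 357))
  expect_true(all(lin$samples == 0))
})

test_that("small-signal behavior matches the equivalent linear system within 1%", {
  # oracle: brute-force simulation of 6*H_tail + 30*H_tip on the same input
  params <- sdpn_params()
  filt <- design_channel_filters(channel_spec(1500, 357), params, FS)
  inputs <- list(
    tone(1500, amp = 1e-4, dur = 0.3),
    tone(1450, amp = 2e-4, dur = 0.3),
    waveform(1e-4 * sin(2 * pi * 1500 * (0:6614) / FS) +
               5e-5 * sin(2 * pi * 1600 * (0:6614) / FS), FS)
  )
  for (x in inputs) {
    expect_lt(15 * sqrt(mean(x$samples^2)), 0.01)
    oracle <- 6 * sos_filter(x$samples, filt$tail) +
      30 * sos_filter(x$samples, filt$tip)
    got <- process_sdpn_channel(x, filt, params)$samples
    expect_lt(sqrt(mean((got - oracle)^2)) / sqrt(mean(oracle^2)), 0.01)
  }
})

test_that("small-signal amplitude gain equals the sum of measured pathway gains", {
  params <- sdpn_params()
  filt <- design_channel_filters(channel_spec(1500, 357), params, FS)
  A <- 1e-5
  x <- tone(1500, amp = A, dur = 0.4)
  keep <- seq(round(0.2 * FS), length(x$samples))
  h_tail <- sqrt(mean(sos_filter(x$samples, filt$tail)[keep]^2)) / (A / sqrt(2))
  h_tip <- sqrt(mean(sos_filter(x$samples, filt$tip)[keep]^2)) / (A / sqrt(2))
  out <- process_sdpn_channel(x, filt, params)
  gain <- sqrt(mean(out$samples[keep]^2)) / (A / sqrt(2))
  expect_equal(gain, 6 * h_tail + 30 * h_tip, tolerance = 0.02)
})

test_that("gain compresses with level: louder tones get strictly less gain", {
  filt <- design_channel_filters(channel_spec(1500, 357), rate = FS)
  gain_at <- function(A) {
    x <- tone(1500, amp = A, dur = 0.3)
    out <- process_sdpn_channel(x, filt)
    keep <- seq(round(0.15 * FS), length(x$samples))
    sqrt(mean(out$samples[keep]^2)) / A
  }
  a <- 1e-4
  expect_lt(gain_at(100 * a), gain_at(a))
  expect_lt(gain_at(1e4 * a), gain_at(100 * a))
})

test_that("with a fixed nonlinear gain the whole channel obeys superposition", {
  params <- sdpn_params(nl_mode = "fixed_gain", fixed_gain = 12)
  filt <- design_channel_filters(channel_spec(1500, 357), params, FS)
  x1 <- tone(1400, amp = 0.7, dur = 0.1)
  x2 <- tone(1650, amp = 1.3, dur = 0.1)
  y1 <- process_sdpn_channel(x1, filt, params)$samples
  y2 <- process_sdpn_channel(x2, filt, params)$samples
  y12 <- process_sdpn_channel(waveform(x1$samples + x2$samples, FS),
                              filt, params)$samples
  expect_equal(y12, y1 + y2, tolerance = 1e-10)
})

test_that("instantaneous nonlinearity bounds the tip contribution by pi", {
  params <- sdpn_params(nl_mode = "instantaneous")
  filt <- design_channel_filters(channel_spec(1500, 357), params, FS)
  x <- tone(1500, amp = 1e4, dur = 0.1)
  out <- process_sdpn_channel(x, filt, params)
  tail_only <- params$linear_gain * sos_filter(x$samples, filt$tail)
  expect_lte(max(abs(out$samples - tail_only)),
             params$nl_scale * pi / 2 + 1e-12)
})

test_that("rate mismatches are rejected", {
  filt <- design_channel_filters(channel_spec(1500, 357), rate = FS)
  x <- tone(1500, rate = 16000, dur = 0.1)
  expect_error(process_sdpn_channel(x, filt), "rate")
  expect_error(process_linear_channel(x, channel_spec(1500, 357), rate = FS),
               "rate")
})

test_that("linear channel passes its center and rejects far-off tones", {
  spec <- channel_spec(1000, 300)
  x_in <- tone(1000, amp = 0.5, dur = 0.4)
  x_out <- tone(4000, amp = 0.5, dur = 0.4)
  keep <- seq(round(0.2 * FS), length(x_in$samples))
  g_in <- sqrt(mean(process_linear_channel(x_in, spec)$samples[keep]^2)) /
    (0.5 / sqrt(2))
  g_out <- sqrt(mean(process_linear_channel(x_out, spec)$samples[keep]^2)) /
    (0.5 / sqrt(2))
  expect_equal(g_in, 1, tolerance = 0.01)
  expect_lt(20 * log10(g_out / g_in), -20)
})
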