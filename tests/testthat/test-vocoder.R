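test_that("vocoding zero envelopes yields silence", {
  map <- make_channel_map(4)
  envs <- replicate(4, silence(0.1), simplify = FALSE)
  out <- vocode_channels(envs, map)
  expect_true(all(out$samples == 0))
})

test_that("a single constant envelope synthesizes a pure carrier", {
  map <- channel_map(list(channel_spec(1000, 300)))
  env <- waveform(rep(1, FS), FS)
  out <- vocode_channels(list(env), map)
  t <- (seq_len(FS) - 1) / FS
  expect_equal(out$samples, sin(2 * pi * 1000 * t), tolerance = 1e-12)
})

test_that("two constant envelopes give exactly two spectral lines", {
  map <- channel_map(list(channel_spec(1000, 300), channel_spec(3000, 500)))
  env <- waveform(rep(0.5, FS), FS)
  out <- vocode_channels(list(env, env), map)
  mag <- Mod(stats::fft(out$samples))[1:(FS / 2)]
  freqs <- (seq_len(FS / 2) - 1) * FS / FS
  top2 <- sort(freqs[order(mag, decreasing = TRUE)[1:2]])
  expect_equal(top2, c(1000, 3000))
  others <- mag[!freqs %in% c(1000, 3000)]
  expect_lt(max(others) / max(mag), 1e-6)
})

test_that("envelope count and geometry mismatches are rejected", {
  map <- make_channel_map(4)
  envs <- replicate(3, silence(0.1), simplify = FALSE)
  expect_error(vocode_channels(envs, map), "one envelope per channel")
  envs <- c(replicate(3, silence(0.1), simplify = FALSE),
            list(silence(0.2)))
  expect_error(vocode_channels(envs, map), "lengths differ")
})

test_that("vocoding is additive across channel subsets", {
  map <- make_channel_map(4)
  x <- synth_vowel(vowel_preset("a", duration = 0.15))
  envs <- lapply(map$channels, function(sp) {
    envelope_standard(process_linear_channel(x, sp))
  })
  full <- vocode_channels(envs, map)
  zero <- waveform(numeric(length(x$samples)), FS)
  part1 <- vocode_channels(list(envs[[1]], zero, envs[[3]], zero), map)
  part2 <- vocode_channels(list(zero, envs[[2]], zero, envs[[4]]), map)
  expect_equal(part1$samples + part2$samples, full$samples, tolerance = 1e-12)
})

test_that("silence propagates through a full strategy", {
  out <- run_strategy(silence(0.1), strategy_config(map = make_channel_map(4)))
  expect_true(all(out$samples == 0))
})

test_that("a tone at a channel center dominates that channel's carrier", {
  map <- make_channel_map(8)
  cf3 <- map$channels[[3]]$cf
  x <- tone(cf3, amp = 0.5, dur = 0.4)
  out <- run_strategy(x, strategy_config("linear", map = map))
  dom <- dominant_frequency(waveform(out$samples[round(0.1 * FS):
                                                   length(out$samples)], FS),
                            c(100, 10000))
  expect_equal(dom, cf3, tolerance = 1)
})

test_that("strategy output stays within the carrier band", {
  map <- make_channel_map(8)
  x <- synth_vowel(vowel_preset("i", duration = 0.3))
  out <- run_strategy(x, strategy_config("sdpn", map = map))
  mag2 <- Mod(stats::fft(out$samples))^2
  n <- length(out$samples)
  freqs <- (seq_len(n) - 1) * FS / n
  half <- freqs <= FS / 2
  lo <- map$channels[[1]]$cf - map$channels[[1]]$bw_channel / 2
  hi <- map$channels[[8]]$cf + map$channels[[8]]$bw_channel / 2
  out_band <- sum(mag2[half & (freqs < lo | freqs > hi)])
  expect_lt(out_band / sum(mag2[half]), 0.01)
})

test_that("identical input and config give bit-identical output", {
  x <- synth_vowel(vowel_preset("u", duration = 0.15))
  cfg <- strategy_config("sdpn", "enhanced", make_channel_map(4))
  y1 <- run_strategy(x, cfg)
  y2 <- run_strategy(x, cfg)
  expect_identical(y1$samples, y2$samples)
})

test_that("the dual-path strategy reproduces frozen regression values", {
  x <- synth_vowel(vowel_preset("i"))
  y <- run_strategy(x, strategy_config("sdpn", "standard",
                                       make_channel_map(8)))
  expect_equal(sqrt(mean(y$samples^2)), 0.245844843931, tolerance = 1e-9)
  expect_equal(y$samples[c(1000, 5000, 9000)],
               c(0.140301989983, 0.369538816904, -0.234500239103),
               tolerance = 1e-8)
})
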