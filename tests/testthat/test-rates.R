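test_that("extrema detection counts sinusoid peaks and ignores flats", {
  fs <- 95
  t <- (0:(10 * fs - 1)) / fs
  x <- sin(2 * pi * 1 * t)
  ex <- detect_extrema(x)
  expect_true(abs(length(ex$maxima) - 10) <= 1)
  expect_true(abs(length(ex$minima) - 10) <= 1)
  expect_true(all(diff(ex$maxima) > 0))

  flat <- detect_extrema(rep(2, 100))
  expect_length(flat$maxima, 0)
  expect_length(flat$minima, 0)

  # 20 dB SNR noise does not change the count once separation + swing apply
  set.seed(9)
  noisy <- x + rnorm(length(x), sd = sqrt(0.5) / 10)
  exn <- detect_extrema(noisy, min_separation = 0.4 * fs, min_swing = 0.5)
  expect_equal(length(exn$maxima), length(ex$maxima))
  expect_equal(length(exn$minima), length(ex$minima))
})

test_that("hysteresis rejects low-swing wiggles but keeps genuine peaks", {
  fs <- 95
  t <- (0:(10 * fs - 1)) / fs
  x <- sin(2 * pi * t) + 0.05 * sin(2 * pi * 7 * t)
  loose <- detect_extrema(x)
  strict <- detect_extrema(x, min_swing = 0.5)
  expect_gt(length(loose$maxima), 10)      # wiggles show up without hysteresis
  expect_true(abs(length(strict$maxima) - 10) <= 1)
})

test_that("mean interval inversion yields the frequency", {
  expect_equal(mean_interval_frequency(c(1, 96, 191), integer(0), 95), 1)
  expect_true(is.na(mean_interval_frequency(c(5), c(50), 95)))
  # equal-weight average of maxima- and minima-derived estimates
  f <- mean_interval_frequency(c(1, 96), c(48, 144), 96)
  expect_equal(f, mean(c(96 / 95, 1)))
})

test_that("quantization error follows the sampling-resolution law", {
  qe <- quantization_error(80, 95)
  expect_equal(qe$relative_pct, 1.40, tolerance = 0.005)
  expect_equal(qe$absolute, 1.12, tolerance = 0.005)
  expect_equal(quantization_error(1, 95)$relative_pct, 0.0175,
               tolerance = 3e-3)
  expect_lt(quantization_error(1e-6, 95)$absolute, 1e-10)
})

test_that("a clean 80 bpm oscillation is recovered within the quantization bound", {
  cfg <- akf_config("DS")
  t <- (0:(50 * 95 - 1)) / 95
  x <- sin(2 * pi * 80 / 60 * t)
  tr <- estimate_rate_track(x, "heart", cfg)
  final <- mean(tail(tr$rate_hz, 5 * 95)) * 60
  expect_lt(abs(final - 80), 1.12)
})

test_that("rate estimator holds initialization until buffer and warm-up pass", {
  cfg <- akf_config("SE1")   # f_f0 = 1.3 Hz
  est <- rate_estimator("heart", cfg)
  x <- sin(2 * pi * 1.0 * (0:1999) / 95)
  hats <- numeric(length(x))
  for (k in seq_along(x)) {
    est <- rate_tick(est, x[k])
    hats[k] <- est$rate_hat
  }
  warm <- round(cfg$warmup_s * 95)
  expect_true(all(hats == cfg$f_f0))
  expect_false(est$valid)    # 2000 samples < 22.5 s (2138 sample) warm-up
})

test_that("out-of-band inputs are clamped to the plausibility band", {
  cfg <- akf_config("DS")
  t <- (0:(40 * 95 - 1)) / 95
  x <- sin(2 * pi * 5 * t)   # 5 Hz, above the 3 Hz heart band edge
  tr <- estimate_rate_track(x, "heart", cfg)
  expect_true(all(tr$rate_hz[tr$valid] <= cfg$heart_band_hz[2] + 1e-9))
  expect_true(all(tr$rate_hz[tr$valid] >= cfg$heart_band_hz[1] - 1e-9))
})

test_that("a rate step transitions monotonically without overshoot", {
  cfg <- akf_config("DS")
  fs <- 95
  t <- (0:(90 * fs - 1)) / fs
  f_tr <- ifelse(t < 50, 1, 1.5)          # 60 -> 90 bpm
  x <- sin(2 * pi * cumsum(f_tr) / fs)
  tr <- estimate_rate_track(x, "heart", cfg)
  after <- tr$rate_hz[tr$t > 50]
  expect_lt(max(after), 1.5 * 1.05)       # < 5 % overshoot
  before <- mean(tr$rate_hz[tr$t > 45 & tr$t < 50])
  expect_equal(before, 1, tolerance = 0.02)
  expect_equal(mean(tail(after, 5 * fs)), 1.5, tolerance = 0.02)
})
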