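test_that("differenced short-window std recovers white-noise sigma", {
  expect_equal(estimate_noise_std(rep(3.7, 50)), 0)
  set.seed(5)
  sigma <- 2.4
  x <- rnorm(1e5, sd = sigma)
  expect_equal(estimate_noise_std(x), sigma, tolerance = 0.01)
  # differencing suppresses a large slow oscillation: a 0.3 Hz sinusoid at
  # 95 Hz contributes far less than its own std (attenuation 2 sin(pi f/fs))
  t <- (0:(95 * 30)) / 95
  slow <- 1000 * sin(2 * pi * 0.3 * t)
  expect_lt(estimate_noise_std(slow), 0.05 * stats::sd(slow))
  expect_warning(est <- estimate_noise_std(numeric(1)), "holding")
  expect_true(is.na(est))
})

test_that("long-window std measures the respiratory amplitude", {
  t <- (0:(95 * 20 - 1)) / 95
  a <- 123
  x <- a * sin(2 * pi * 0.3 * t)   # whole periods in 20 s
  expect_equal(estimate_resp_std(x), a / sqrt(2), tolerance = 1e-3)
  expect_equal(estimate_resp_std(rep(9, 100)), 0)
  # mean-invariance
  expect_equal(estimate_resp_std(x + 5555), estimate_resp_std(x))
})

test_that("trend std is 10 percent of the respiratory std", {
  expect_equal(estimate_trend_std(10), 1)
  expect_equal(estimate_trend_std(0), 0)
  expect_equal(estimate_trend_std(10195.7), 1019.57)
  expect_error(estimate_trend_std(-1), class = "akf_invalid_parameter")
})

test_that("short-window std halves into the cardiac estimate", {
  expect_equal(estimate_heart_std(rep(1, 48)), 0)
  t <- (0:47) / 95              # 0.5 s window, most of a 1.3 Hz cycle
  a <- 10
  x <- a * sin(2 * pi * 1.3 * t)
  # 0.5 s covers only 0.65 of a 1.3 Hz cycle, so the windowed std sits
  # somewhat below the full-cycle RMS
  expect_equal(estimate_heart_std(x), (a / sqrt(2)) / 2, tolerance = 0.3)
  expect_equal(estimate_heart_std(x, divisor = 1), stats::sd(x))
})

test_that("fusion gains follow the published signal-to-noise law", {
  h <- compute_h_entries(c(1, 1, 1), c(1, 1, 1), c(1, 1, 1),
                         scal_f = c(1, 1, 1), scal_s = c(1, 1, 1))
  expect_equal(h$h_f, c(1, 1, 1))
  h <- compute_h_entries(c(10, 1, 1), c(1, 1, 1), c(1, 1, 1),
                         scal_f = c(1, 0.1, 0.1), scal_s = c(0.1, 1, 1))
  expect_equal(h$h_f, c(100, 0.1, 0.1))
  h <- compute_h_entries(c(1, 1, 1), c(1, 1, 1), c(2, 3, 4),
                         scal_f = c(1, 0.1, 0.1), scal_s = c(0.1, 1, 1))
  expect_equal(h$h_s, c(0.4, 9, 16))
  # zero noise estimates are floored, not divided by
  expect_warning(h <- compute_h_entries(c(1, 1, 1), c(0, 1, 1), c(1, 1, 1)),
                 "floored")
  expect_true(all(is.finite(h$h_f)))
})

test_that("the recursive lowpass has unit DC gain and first-order dynamics", {
  sm <- lowpass_smoother(0.1, rate = 9.5, init = 4)
  for (i in 1:50) sm <- smooth_step(sm, 4)
  expect_equal(sm$y, 4, tolerance = 1e-12)

  # unit-step response: monotone, time constant ~ 1/(2 pi fc)
  sm <- lowpass_smoother(0.1, rate = 9.5, init = 0)
  ys <- numeric(500)
  for (i in seq_along(ys)) { sm <- smooth_step(sm, 1); ys[i] <- sm$y }
  expect_true(all(diff(ys) > -1e-12))
  tau <- 1 / (2 * pi * 0.1)
  t63 <- which(ys >= 1 - exp(-1))[1] / 9.5
  expect_equal(t63, tau, tolerance = 0.25)

  # >= 19 dB attenuation of a 1 Hz sinusoid sampled at 9.5 Hz
  sm <- lowpass_smoother(0.1, rate = 9.5, init = 0)
  t <- (0:949) / 9.5
  x <- sin(2 * pi * 1 * t)
  y <- numeric(length(x))
  for (i in seq_along(x)) { sm <- smooth_step(sm, x[i]); y[i] <- sm$y }
  gain <- max(abs(y[500:950]))
  expect_lt(20 * log10(gain), -19)
})

test_that("estimates change only at decimation instants", {
  cfg <- akf_config("DS", fs = 95)
  ad <- adaptation_state(cfg)
  set.seed(2)
  n <- 230
  z <- matrix(rnorm(3 * n, sd = 10), ncol = 3) + 100
  changes <- 0L
  prev <- adaptation_params(ad)$sigma_noise
  for (k in seq_len(n)) {
    ad <- adaptation_tick(ad, z[k, ])
    cur <- adaptation_params(ad)$sigma_noise
    if (!identical(cur, prev)) {
      changes <- changes + 1L
      expect_equal(k %% cfg$cadence, 0L)
    }
    prev <- cur
  }
  expect_equal(changes, n %/% cfg$cadence)
  expect_true(all(adaptation_params(ad)$sigma_noise >= 0))
})

test_that("streaming adaptation converges to known noise on stationary input", {
  spec <- session_preset("subject1_like", duration = 70, seed = 21,
                         noise_sigma = c(500, 100, 500))
  sess <- generate_session(spec)
  cfg <- akf_config("DS")
  ad <- adaptation_state(cfg)
  for (k in seq_along(sess$t)) ad <- adaptation_tick(ad, sess$sensors[k, ])
  est <- adaptation_params(ad)
  expect_equal(est$sigma_noise, spec$noise_sigma, tolerance = 0.1)
  expect_equal(est$sigma_resp, adaptation_targets(sess, cfg)$sigma_resp,
               tolerance = 0.1)
  expect_equal(est$sigma_trend, 0.1 * est$sigma_resp)
})
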