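test_that("noise-free constant-rate sessions have the closed-form amplitude", {
  spec <- session_spec(duration = 40, heart_rate_track = 60,
                       resp_rate_track = 15,
                       resp_amplitude = c(100, 200, 300),
                       heart_amplitude = c(10, 20, 30),
                       noise_sigma = c(0, 0, 0),
                       drift_sigma = c(0, 0, 0),
                       offset_level = c(1000, 2000, 3000),
                       resp_harmonics = list(c(2, 0.3), c(3, 0.1)))
  sess <- generate_session(spec)
  wave_var <- (1 + 0.3^2 + 0.1^2) / 2
  for (i in 1:3) {
    x <- sess$sensors[, i]
    expect_equal(mean(x), spec$offset_level[i], tolerance = 1e-2)
    expect_equal(stats::sd(x),
                 sqrt(spec$resp_amplitude[i]^2 * wave_var +
                        spec$heart_amplitude[i]^2 / 2),
                 tolerance = 0.01)
  }
  expect_equal(sess$truth$sigma_noise, c(0, 0, 0))
})

test_that("identical seed and spec give bit-identical sessions", {
  spec <- session_preset("subject1_like", duration = 10, seed = 77)
  s1 <- generate_session(spec)
  s2 <- generate_session(spec)
  expect_identical(s1$sensors, s2$sensors)
  s3 <- generate_session(session_preset("subject1_like", duration = 10,
                                        seed = 78))
  expect_false(identical(s1$sensors, s3$sensors))
})

test_that("session presets encode the documented frequencies", {
  p1 <- session_preset("subject1_like")
  expect_equal(p1$heart_rate_track$rate[1], 78)    # 1.3 Hz
  expect_equal(p1$resp_rate_track$rate[1], 18)     # 0.3 Hz
  p2 <- session_preset("subject2_like")
  expect_equal(p2$resp_rate_track$rate[1], 12)     # 0.2 Hz
  expect_equal(p2$heart_rate_track$rate[1], 102)   # 1.7 Hz
  wc <- session_preset("worst_case")
  ff <- wc$heart_rate_track$rate[1] / 60
  fss <- wc$resp_rate_track$rate[1] / 60
  expect_equal(ff, 2 * fss)                       # exact harmonic collision
  # sensor 1 is the cardiac-dominant channel in every preset
  for (p in list(p1, p2, wc)) {
    ratio <- p$heart_amplitude / p$resp_amplitude
    expect_equal(which.max(ratio), 1L)
  }
  expect_error(session_preset("nope"), "valid presets")
})

test_that("respiratory harmonics overlap the cardiac band in the worst case", {
  sess <- generate_session(session_preset("worst_case", duration = 60,
                                          seed = 2))
  x <- sess$truth$resp_component[, 2]
  n <- length(x)
  mag <- Mod(stats::fft(x - mean(x)))[1:(n %/% 2)]
  freqs <- (0:(n %/% 2 - 1)) * 95 / n
  f_f <- sess$truth$heart_rate_bpm[1] / 60
  near_heart <- freqs > f_f - 0.03 & freqs < f_f + 0.03
  # the respiration component alone carries energy at the cardiac frequency
  expect_gt(max(mag[near_heart]), 0.1 * max(mag))
})

test_that("flow reference is phase-locked to the respiratory component", {
  sess <- generate_session(session_preset("subject1_like", duration = 30,
                                          seed = 4))
  z <- which(diff(sign(sess$flow_ref)) != 0)
  phase <- sess$truth$phi_s[z] %% pi
  dphi <- 2 * pi * max(sess$truth$resp_rate_permin) / 60 / 95
  expect_true(all(pmin(phase, pi - phase) <= dphi + 1e-9))
})

test_that("ground-truth noise is recoverable from a long session", {
  spec <- session_preset("subject1_like", duration = 120, seed = 10)
  sess <- generate_session(spec)
  clean <- sess$truth$offset_track + sess$truth$resp_component +
    sess$truth$heart_component
  est <- apply(sess$sensors - clean, 2, stats::sd)
  expect_equal(unname(est), spec$noise_sigma, tolerance = 0.02)
})

test_that("invalid session specs name the offending fields", {
  expect_error(session_spec(duration = -5), "duration")
  expect_error(session_spec(noise_sigma = c(-1, 1, 1)), "noise_sigma")
  expect_error(session_spec(resp_rate_track = rate_track(0, -3)),
               "resp_rate_track")
  expect_error(rate_track(c(1, 0), c(10, 10)), "non-decreasing")
})

test_that("sessions round-trip through CSV with a JSON sidecar", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "sess.csv")
  sess <- generate_session(session_preset("subject2_like", duration = 5,
                                          seed = 3))
  write_session(sess, path)
  expect_true(file.exists(paste0(path, ".json")))
  df <- read_session(path)
  expect_equal(df$s1, unname(sess$sensors[, 1]), tolerance = 1e-8)
  expect_equal(df$flow, sess$flow_ref, tolerance = 1e-8)
  sc <- attr(df, "sidecar")
  expect_equal(sc$spec$seed, 3)
  expect_equal(sc$truth_summary$sigma_noise, sess$truth$sigma_noise)

  # malformed rows are reported with their line number
  writeLines(c("time,s1,s2,s3", "0,1,2,3", "0.01,oops,2,3"),
             file.path(dir, "bad.csv"))
  expect_error(read_session(file.path(dir, "bad.csv")), "line 2")
})

test_that("simulate() on a spec honors nsim and seed offsets", {
  spec <- session_preset("subject1_like", duration = 5, seed = 1)
  out <- simulate(spec, nsim = 2, seed = 40)
  expect_length(out, 2)
  expect_identical(out[[1]]$sensors,
                   generate_session(session_preset("subject1_like",
                                                   duration = 5,
                                                   seed = 40))$sensors)
  expect_false(identical(out[[1]]$sensors, out[[2]]$sensors))
})
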