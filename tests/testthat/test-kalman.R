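test_that("prediction propagates mean and covariance", {
  st <- filter_state(rep(1, 7), diag(7), dt = 1 / 95)
  # identity dynamics, no process noise: state unchanged
  out <- kf_predict(st, diag(7), matrix(0, 7, 7))
  expect_equal(out$x_hat, st$x_hat)
  expect_equal(out$P, st$P)

  # unit cardiac position maps to -omega^2 dt cardiac velocity
  wf <- 2 * pi * 1.1
  A <- build_transition(wf, 0, 1 / 95)
  st <- filter_state(c(1, rep(0, 6)), diag(7), dt = 1 / 95)
  out <- kf_predict(st, A, matrix(0, 7, 7))
  expect_equal(out$x_hat, c(1, -wf^2 / 95, rep(0, 5)),
               ignore_attr = TRUE)

  # zero prior covariance: P becomes Q
  st <- filter_state(rep(0, 7), matrix(0, 7, 7), dt = 1 / 95)
  out <- kf_predict(st, diag(7), diag(0.3, 7))
  expect_equal(out$P, diag(0.3, 7), ignore_attr = TRUE)
  expect_error(kf_predict(st, diag(6), diag(7)), "dimension")
})

test_that("scalar measurement update reproduces the textbook gain", {
  st <- filter_state(0, matrix(1), dt = 1)
  out <- kf_update(st, z = 1, H = matrix(1), R = matrix(1))
  expect_equal(drop(out$K), 0.5)
  expect_equal(out$x_hat, 0.5)
  expect_equal(drop(out$P), 0.5)
})

test_that("zero innovation leaves the state estimate untouched", {
  set.seed(42)
  x <- rnorm(7)
  P <- random_spd(7)
  H <- build_measurement_matrix(runif(3), runif(3))
  R <- diag(runif(3, 0.5, 2))
  st <- filter_state(x, P, dt = 1 / 95)
  out <- kf_update(st, z = drop(H %*% x), H = H, R = R)
  expect_equal(out$x_hat, x, tolerance = 1e-12)
  # covariance still shrinks: P = (I - KH) P
  expect_true(sum(diag(out$P)) < sum(diag(P)))
})

test_that("full steps match an independent dense-algebra oracle", {
  set.seed(7)
  for (i in 1:100) {
    n <- sample(2:7, 1)
    m <- sample(1:3, 1)
    x <- rnorm(n)
    P <- random_spd(n)
    A <- matrix(rnorm(n * n, sd = 0.5), n) + diag(n)
    Q <- random_spd(n) * 0.1
    H <- matrix(rnorm(m * n), m)
    R <- random_spd(m)
    z <- rnorm(m)
    ref <- oracle_kf_step(x, P, A, Q, H, R, z)
    st <- kf_step(filter_state(x, P, dt = 1 / 95), z,
                  list(A = A, Q = Q, H = H, R = R))
    expect_equal(st$x_hat, ref$x, tolerance = 1e-10)
    expect_equal(st$P, (ref$P + t(ref$P)) / 2, tolerance = 1e-10)
    expect_equal(st$K, ref$K, tolerance = 1e-10, ignore_attr = TRUE)
  }
})

test_that("huge measurement noise with zero process noise freezes the estimate", {
  set.seed(1)
  st <- filter_state(rnorm(7), random_spd(7), dt = 1 / 95)
  mats <- list(A = diag(7), Q = matrix(0, 7, 7),
               H = build_measurement_matrix(c(1, 1, 1), c(1, 1, 1)),
               R = diag(1e12, 3))
  x0 <- st$x_hat
  for (k in 1:20) st <- kf_step(st, rnorm(3, sd = 10), mats)
  expect_equal(st$x_hat, x0, tolerance = 1e-6)
  expect_true(all(abs(st$K) < 1e-8))
})

test_that("offset-only filter converges to a constant measurement", {
  mats <- list(A = diag(7),
               Q = build_process_noise(0, 0, c(0.1, 0.1, 0.1)),
               H = build_measurement_matrix(c(0, 0, 0), c(0, 0, 0)),
               R = diag(0.01, 3))
  st <- filter_state(rep(0, 7), diag(7), dt = 1 / 95)
  z <- c(3, -5, 11)
  for (k in 1:300) st <- kf_step(st, z, mats)
  expect_equal(st$x_hat[5:7], z, tolerance = 1e-3, ignore_attr = TRUE)
})

test_that("one step equals predict followed by update and advances the index", {
  set.seed(3)
  x <- rnorm(7); P <- random_spd(7)
  mats <- list(A = build_transition(2, 1, 1 / 95),
               Q = build_process_noise(2, 1, c(1, 1, 1)),
               H = build_measurement_matrix(c(1, 0.1, 0.1), c(0.1, 1, 1)),
               R = diag(3))
  z <- rnorm(3)
  st1 <- kf_step(filter_state(x, P, dt = 1 / 95), z, mats)
  st2 <- kf_update(kf_predict(filter_state(x, P, dt = 1 / 95),
                              mats$A, mats$Q), z, mats$H, mats$R)
  expect_equal(st1$x_hat, st2$x_hat)
  expect_equal(st1$P, st2$P)
  expect_equal(st1$k, 1L)
})

test_that("a numerically singular innovation covariance is diagnosed", {
  st <- filter_state(rep(0, 2), matrix(0, 2, 2), dt = 1)
  H <- matrix(c(1, 0, 1, 0), 2, byrow = TRUE)   # identical rows, R = 0
  expect_error(kf_update(st, c(0, 0), H, matrix(0, 2, 2)),
               "singular")
})
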