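# Independent dense-algebra oracle for one Kalman predict/correct cycle:
# textbook equations with explicit matrix inversion, no shortcuts shared
# with the package implementation.
oracle_kf_step <- function(x, P, A, Q, H, R, z) {
  x_pred <- A %*% x
  P_pred <- A %*% P %*% t(A) + Q
  S <- H %*% P_pred %*% t(H) + R
  K <- P_pred %*% t(H) %*% solve(S)
  x_new <- x_pred + K %*% (z - H %*% x_pred)
  P_new <- (diag(nrow(P)) - K %*% H) %*% P_pred
  list(x = drop(x_new), P = P_new, K = K)
}

# Random symmetric positive-definite matrix.
random_spd <- function(n) {
  M <- matrix(rnorm(n * n), n)
  crossprod(M) + diag(n) * 0.5
}

# A short stationary session, cheap enough for unit tests.
quick_session <- function(duration = 40, seed = 1, preset = "subject1_like",
                          ...) {
  generate_session(session_preset(preset, duration = duration, seed = seed,
                                  ...))
}
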