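#' Model matrices of the seven-state cardiorespiratory filter
#'
#' The filter carries seven states: a cardiac position/velocity pair
#' (X_f, V_f), a respiratory position/velocity pair (X_s, V_s) and three
#' per-sensor baseline offsets (C1, C2, C3). The builders below assemble the
#' time-varying model matrices consumed by one predict/correct step. They are
#' pure functions: how their parameters (frequencies, noise standard
#' deviations, fusion gains) are obtained is the adaptation layer's business.
#'
#' @name model-matrices
#' @keywords internal
NULL

STATE_NAMES <- c("Xf", "Vf", "Xs", "Vs", "C1", "C2", "C3")

stop_invalid <- function(...) {
  stop(structure(class = c("akf_invalid_parameter", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

check_scalar <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_invalid(name, " must be a finite numeric scalar")
  if (positive && x <= 0) stop_invalid(name, " must be > 0, got ", x)
  if (nonneg && x < 0) stop_invalid(name, " must be >= 0, got ", x)
  invisible(x)
}

check_vec3 <- function(x, name, nonneg = TRUE) {
  if (!is.numeric(x) || length(x) != 3L || any(!is.finite(x)))
    stop_invalid(name, " must be a finite numeric 3-vector")
  if (nonneg && any(x < 0)) stop_invalid(name, " must be non-negative")
  invisible(as.numeric(x))
}

#' Build the state-transition matrix
#'
#' Assembles the 7x7 transition matrix: one discretized harmonic-oscillator
#' block per periodic component,
#' \deqn{\begin{pmatrix} 1 & \Delta t \\ -\omega^2 \Delta t & 1 \end{pmatrix},}
#' for the cardiac pair (angular frequency \code{omega_f}) and the
#' respiratory pair (\code{omega_s}), and an identity block for the three
#' offsets, which evolve as random walks. With \code{omega = 0} an oscillator
#' block degenerates to a pure integrator.
#'
#' @param omega_f Cardiac angular frequency in rad/s (non-negative).
#' @param omega_s Respiratory angular frequency in rad/s (non-negative).
#' @param dt Sampling interval in seconds (positive).
#' @return A 7x7 numeric matrix.
#' @examples
#' A <- build_transition(2 * pi * 1.3, 2 * pi * 0.3, 1 / 95)
#' A[1:2, 1:2]
#' @export
build_transition <- function(omega_f, omega_s, dt) {
  check_scalar(omega_f, "omega_f", nonneg = TRUE)
  check_scalar(omega_s, "omega_s", nonneg = TRUE)
  check_scalar(dt, "dt", positive = TRUE)
  A <- diag(7)
  A[1, 2] <- dt
  A[2, 1] <- -omega_f^2 * dt
  A[3, 4] <- dt
  A[4, 3] <- -omega_s^2 * dt
  dimnames(A) <- list(STATE_NAMES, STATE_NAMES)
  A
}

#' Build the process-noise covariance
#'
#' Diagonal 7x7 covariance: unit variance on the two position states,
#' \eqn{\omega^2} on the matching velocity states (a faster oscillation has a
#' proportionally larger velocity excursion), and the squared long-term trend
#' standard deviation of each sensor on its offset state.
#'
#' @param omega_f,omega_s Angular frequencies in rad/s (non-negative).
#' @param sigma_trend Per-sensor trend standard deviations, 3-vector, in
#'   sensor amplitude units.
#' @return A 7x7 diagonal numeric matrix.
#' @export
build_process_noise <- function(omega_f, omega_s, sigma_trend) {
  check_scalar(omega_f, "omega_f", nonneg = TRUE)
  check_scalar(omega_s, "omega_s", nonneg = TRUE)
  check_vec3(sigma_trend, "sigma_trend")
  Q <- diag(c(1, omega_f^2, 1, omega_s^2, sigma_trend^2))
  dimnames(Q) <- list(STATE_NAMES, STATE_NAMES)
  Q
}

#' Build the measurement-noise covariance
#'
#' @param sigma_noise Per-sensor noise standard deviations, 3-vector, in
#'   sensor amplitude units.
#' @return A 3x3 diagonal numeric matrix \code{diag(sigma_noise^2)}.
#' @export
build_measurement_noise <- function(sigma_noise) {
  check_vec3(sigma_noise, "sigma_noise")
  R <- diag(sigma_noise^2, nrow = 3)
  dimnames(R) <- list(paste0("s", 1:3), paste0("s", 1:3))
  R
}

#' Build the sensor-fusion measurement matrix
#'
#' Row i maps the state vector to sensor i:
#' \code{(h_f[i], 0, h_s[i], 0, e_i)} where \code{e_i} is the i-th row of the
#' 3x3 identity. The velocity states are never observed directly, and each
#' offset state is hard-linked to exactly one sensor; only the cardiac and
#' respiratory gains \code{h_f}, \code{h_s} vary.
#'
#' @param h_f Per-sensor cardiac gains, non-negative 3-vector.
#' @param h_s Per-sensor respiratory gains, non-negative 3-vector.
#' @return A 3x7 numeric matrix.
#' @export
build_measurement_matrix <- function(h_f, h_s) {
  check_vec3(h_f, "h_f")
  check_vec3(h_s, "h_s")
  H <- cbind(h_f, 0, h_s, 0, diag(3), deparse.level = 0)
  dimnames(H) <- list(paste0("s", 1:3), STATE_NAMES)
  H
}
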