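#' Create a filter state
#'
#' Bundles the state estimate, its error covariance and the discrete time
#' index. The covariance is re-symmetrized on construction so that repeated
#' predict/correct cycles cannot accumulate asymmetry.
#'
#' @param x_hat State estimate (7-vector by default, any length accepted so
#'   the recursion can be exercised on reduced models).
#' @param P Estimation-error covariance, square matrix conforming to
#'   \code{x_hat}.
#' @param k Non-negative integer sample index.
#' @param dt Sampling interval in seconds.
#' @return An object of class \code{"akf_state"}: a list with fields
#'   \code{x_hat}, \code{P}, \code{k}, \code{dt}.
#' @export
filter_state <- function(x_hat, P, k = 0L, dt = 1 / 95) {
  x_hat <- as.numeric(x_hat)
  P <- as.matrix(P)
  n <- length(x_hat)
  if (!all(dim(P) == c(n, n)))
    stop_invalid("P must be ", n, "x", n, " to conform to x_hat")
  if (k < 0) stop_invalid("k must be non-negative")
  check_scalar(dt, "dt", positive = TRUE)
  structure(list(x_hat = x_hat, P = (P + t(P)) / 2,
                 k = as.integer(k), dt = dt),
            class = "akf_state")
}

#' Kalman prediction (time update)
#'
#' Propagates the state estimate and covariance one sample forward:
#' \eqn{x^- = A x}, \eqn{P^- = A P A^T + Q}. The returned covariance is
#' re-symmetrized.
#'
#' @param state An \code{"akf_state"}.
#' @param A State-transition matrix.
#' @param Q Process-noise covariance.
#' @return The predicted \code{"akf_state"} (same index \code{k}; the index
#'   advances once per full \code{\link{kf_step}}).
#' @export
kf_predict <- function(state, A, Q) {
  n <- length(state$x_hat)
  if (!all(dim(A) == c(n, n)) || !all(dim(Q) == c(n, n)))
    stop("dimension mismatch between state and A/Q")
  x <- drop(A %*% state$x_hat)
  P <- tcrossprod(A %*% state$P, A) + Q
  state$x_hat <- x
  state$P <- (P + t(P)) / 2
  state
}

#' Kalman correction (measurement update)
#'
#' Blends the predicted state with a new measurement vector:
#' \eqn{K = P^- H^T (H P^- H^T + R)^{-1}}, \eqn{x = x^- + K (z - H x^-)},
#' \eqn{P = (I - K H) P^-}. The innovation covariance is factored by a linear
#' solve rather than an explicit inverse; a near-singular innovation
#' covariance (reciprocal condition below 1e-15, i.e. no longer resolvable
#' in double precision) raises an error reporting its smallest singular
#' value. The published initialization presets legitimately produce
#' innovation-covariance conditions around 1e12 during the first samples --
#' the fusion gains scale with the squared respiratory amplitude -- so the
#' guard is placed at the numerical breakdown point, not earlier. The standard covariance form is used (not
#' the Joseph form); the covariance is re-symmetrized afterwards.
#'
#' @param state Predicted \code{"akf_state"} (apply \code{\link{kf_predict}}
#'   first).
#' @param z Measurement vector (length = rows of \code{H}), finite.
#' @param H Measurement matrix.
#' @param R Measurement-noise covariance.
#' @return The corrected \code{"akf_state"} with the Kalman gain attached as
#'   field \code{K} (n x m matrix).
#' @export
kf_update <- function(state, z, H, R) {
  n <- length(state$x_hat)
  z <- as.numeric(z)
  m <- length(z)
  if (any(!is.finite(z))) stop("measurement contains non-finite values")
  if (!all(dim(H) == c(m, n)) || !all(dim(R) == c(m, m)))
    stop("dimension mismatch between state, z and H/R")
  P <- state$P
  PHt <- tcrossprod(P, H)              # n x m
  S <- H %*% PHt + R                   # innovation covariance, m x m
  S <- (S + t(S)) / 2
  if (rcond(S) < 1e-15) {
    sv <- svd(S, nu = 0, nv = 0)$d
    stop("innovation covariance numerically singular (smallest singular value ",
         format(min(sv), digits = 3), ")")
  }
  K <- t(solve(S, t(PHt)))             # P^- H^T S^{-1}, n x m
  innov <- z - drop(H %*% state$x_hat)
  state$x_hat <- state$x_hat + drop(K %*% innov)
  P <- (diag(n) - K %*% H) %*% P
  state$P <- (P + t(P)) / 2
  state$K <- K
  state
}

#' One full filter step
#'
#' Prediction followed by correction with the current model matrices;
#' increments the sample index.
#'
#' @param state An \code{"akf_state"}.
#' @param z Measurement vector.
#' @param matrices List with elements \code{A}, \code{Q}, \code{H}, \code{R}
#'   (as built by the \code{build_*} constructors).
#' @return The updated \code{"akf_state"} (with gain \code{K}).
#' @seealso \code{\link{kf_predict}}, \code{\link{kf_update}}
#' @export
kf_step <- function(state, z, matrices) {
  state <- kf_predict(state, matrices$A, matrices$Q)
  state <- kf_update(state, z, matrices$H, matrices$R)
  state$k <- state$k + 1L
  state
}
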