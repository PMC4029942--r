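#' Adaptive Kalman separation of cardiorespiratory sensor channels
#'
#' Runs the seven-state time-varying Kalman filter over a three-channel
#' recording, separating each channel into its baseline offset and two
#' shared oscillations (respiration and heart), and continuously estimating
#' both rates from the filtered oscillatory states. In adaptive mode
#' (default) the measurement-noise covariance, the process-noise covariance,
#' the sensor-fusion measurement matrix and -- after the warm-up -- the
#' oscillator frequencies of the state-transition matrix are re-estimated
#' from the data at every \code{cadence}-th sample. In non-adaptive mode all
#' matrices stay at their initialization values for the whole run (the
#' baseline filter); rates are still estimated and reported, but not fed
#' back.
#'
#' The state vector is \code{(Xf, Vf, Xs, Vs, C1, C2, C3)}: cardiac
#' position/velocity, respiratory position/velocity and the three sensor
#' offsets. Initialization: oscillator states zero, each offset at the first
#' sample of its sensor; the initial covariance is diagonal with oscillator
#' entries \code{p0_osc_factor} times the corresponding process-noise
#' entries and offset entries equal to the initial trend variances.
#'
#' @param x Input signals: an \code{"akf_session"}, a data frame with
#'   columns \code{s1,s2,s3} (and optionally \code{time,flow,ppg}), or an
#'   n x 3 numeric matrix. All values must be finite.
#' @param config An \code{\link{akf_config}}; \code{config$adaptive} selects
#'   the adaptive or the baseline filter.
#' @return An object of class \code{"akf"}: a list with
#'   \describe{
#'     \item{states}{n x 7 matrix of state estimates.}
#'     \item{rates}{data frame \code{t, hr_bpm, hr_raw_bpm, rr_permin,
#'       rr_raw_permin, hr_valid, rr_valid} (smoothed and raw
#'       peak-detector rates).}
#'     \item{fitted, residuals}{n x 3 matrices of model-implied sensor
#'       values after the measurement update and the corresponding
#'       post-fit residuals (see \code{\link{residuals.akf}}).}
#'     \item{adaptation_log}{data frame, one row per estimation instant,
#'       with all smoothed sigma estimates, fusion gains and rates.}
#'     \item{K}{final Kalman gain (7 x 3).}
#'     \item{P_health}{worst-case covariance diagnostics over the run,
#'       sampled at estimation instants: maximum relative asymmetry and
#'       minimum eigenvalue relative to \code{trace(P)}.}
#'     \item{config, truth, provenance}{run configuration, attached ground
#'       truth when \code{x} was a synthetic session, and run provenance
#'       (config hash, input digest, dimensions).}
#'   }
#' @examples
#' sess <- generate_session(session_preset("subject1_like", duration = 40))
#' fit <- akf(sess, akf_config("SE1"))
#' coef(fit)
#' @export
akf <- function(x, config = akf_config()) {
  truth <- NULL
  tcol <- NULL
  if (inherits(x, "akf_session")) {
    truth <- x$truth
    tcol <- x$t
    S <- x$sensors
  } else if (is.data.frame(x)) {
    miss <- setdiff(c("s1", "s2", "s3"), names(x))
    if (length(miss))
      stop_invalid("input data frame lacks column(s): ",
                   paste(miss, collapse = ", "))
    S <- as.matrix(x[c("s1", "s2", "s3")])
    if ("time" %in% names(x)) tcol <- x$time
  } else {
    S <- as.matrix(x)
    if (ncol(S) != 3L) stop_invalid("input matrix must have 3 columns")
  }
  storage.mode(S) <- "double"
  nf <- which(!is.finite(S))
  if (length(nf)) {
    idx <- ((nf[1] - 1L) %% nrow(S)) + 1L
    stop_invalid("non-finite value in input at sample ", idx)
  }
  n <- nrow(S)
  fs <- config$fs
  dt <- 1 / fs
  if (n < round(config$warmup_s * fs))
    stop_invalid("input shorter than the warm-up period (",
                 config$warmup_s, " s at ", fs, " Hz)")
  if (is.null(tcol)) tcol <- (seq_len(n) - 1) / fs

  cad <- config$cadence
  adaptive <- config$adaptive
  short_len <- round(config$short_window_s * fs)
  long_len <- round(config$long_window_s * fs)
  warm_n <- round(config$warmup_s * fs)

  ## --- initialization --------------------------------------------------
  omega_f <- 2 * pi * config$f_f0
  omega_s <- 2 * pi * config$f_s0
  sig_noise <- config$sigma_noise0
  sig_resp <- config$sigma_resp0
  sig_heart <- config$sigma_heart0
  sig_trend <- config$sigma_trend0
  h <- compute_h_entries(sig_heart, sig_noise, sig_resp,
                         config$scal_f, config$scal_s,
                         config$noise_floor_factor)

  A <- build_transition(omega_f, omega_s, dt)
  Q <- build_process_noise(omega_f, omega_s, sig_trend)
  R <- build_measurement_noise(sig_noise)
  H <- build_measurement_matrix(h$h_f, h$h_s)

  P0 <- diag(c(config$p0_osc_factor * diag(Q)[1:4], sig_trend^2))
  state <- filter_state(c(0, 0, 0, 0, S[1, ]), P0, k = 0L, dt = dt)

  ## one shared smoother design for all sigma estimates (3 sensors each)
  est_rate <- fs / cad
  ba <- signal::butter(1, config$estimate_cutoff_hz / (est_rate / 2), "low")
  b1 <- ba$b[1]; b2 <- ba$b[2]; a2 <- ba$a[2]
  sm <- list(noise = list(x1 = sig_noise, y1 = sig_noise),
             resp = list(x1 = sig_resp, y1 = sig_resp),
             heart = list(x1 = sig_heart, y1 = sig_heart))
  sm_step3 <- function(st, x) {
    y <- b1 * x + b2 * st$x1 - a2 * st$y1
    list(x1 = x, y1 = y)
  }

  ## rate estimators (smoothers designed at the estimation rate)
  hr_band <- config$heart_band_hz; rr_band <- config$resp_band_hz
  hr_len <- round(config$heart_buffer_s * fs)
  rr_len <- round(config$resp_buffer_s * fs)
  hr_sm <- lowpass_smoother(config$heart_rate_cutoff_hz, est_rate,
                            init = config$f_f0)
  rr_sm <- lowpass_smoother(config$resp_rate_cutoff_hz, est_rate,
                            init = config$f_s0)
  hr_raw <- hr_hat <- config$f_f0
  rr_raw <- rr_hat <- config$f_s0
  hr_valid <- rr_valid <- FALSE

  ## --- storage ---------------------------------------------------------
  X <- matrix(NA_real_, n, 7, dimnames = list(NULL, STATE_NAMES))
  fitted <- innov <- matrix(NA_real_, n, 3,
                            dimnames = list(NULL, paste0("s", 1:3)))
  hr_t <- rr_t <- numeric(n)
  hr_rt <- rr_rt <- numeric(n)
  hr_v <- rr_v <- logical(n)
  P_max_asym <- 0
  P_min_eig <- Inf
  n_log <- n %/% cad
  log_mat <- matrix(NA_real_, n_log, 23)
  colnames(log_mat) <- c("t",
    paste0("sigma_noise", 1:3), paste0("sigma_resp", 1:3),
    paste0("sigma_heart", 1:3), paste0("sigma_trend", 1:3),
    paste0("h_f", 1:3), paste0("h_s", 1:3),
    "hr_bpm", "rr_permin", "hr_raw_bpm", "rr_raw_permin")
  log_row <- 0L

  ## --- main loop -------------------------------------------------------
  for (k in seq_len(n)) {
    decim <- k %% cad == 0L

    if (adaptive && decim) {
      lo_s <- max(1L, k - short_len + 1L)
      noise_raw <- heart_raw <- numeric(3)
      for (i in 1:3) {
        seg <- S[lo_s:k, i]
        noise_raw[i] <- stats::sd(seg[-1] - seg[-length(seg)]) /
          config$noise_diff_divisor
        heart_raw[i] <- stats::sd(seg) / config$heart_std_divisor
      }
      sm$noise <- sm_step3(sm$noise, noise_raw)
      sm$heart <- sm_step3(sm$heart, heart_raw)
      sig_noise <- sm$noise$y1
      sig_heart <- sm$heart$y1
      if (k >= long_len) {
        resp_raw <- c(stats::sd(S[(k - long_len + 1L):k, 1]),
                      stats::sd(S[(k - long_len + 1L):k, 2]),
                      stats::sd(S[(k - long_len + 1L):k, 3]))
        sm$resp <- sm_step3(sm$resp, resp_raw)
        sig_resp <- sm$resp$y1
      }
      sig_trend <- estimate_trend_std(sig_resp)
      h <- compute_h_entries(sig_heart, sig_noise, sig_resp,
                             config$scal_f, config$scal_s,
                             config$noise_floor_factor)
      R <- build_measurement_noise(sig_noise)
      H <- build_measurement_matrix(h$h_f, h$h_s)
      omega_f <- 2 * pi * (if (hr_valid) hr_hat else config$f_f0)
      omega_s <- 2 * pi * (if (rr_valid) rr_hat else config$f_s0)
      A <- build_transition(omega_f, omega_s, dt)
      Q <- build_process_noise(omega_f, omega_s, sig_trend)
    }

    state <- kf_step(state, S[k, ], list(A = A, Q = Q, H = H, R = R))
    X[k, ] <- state$x_hat
    fitted[k, ] <- H %*% state$x_hat
    innov[k, ] <- S[k, ] - fitted[k, ]   # post-fit residual

    if (decim) {
      if (k >= hr_len && k >= warm_n) {
        f <- rate_measure(X[(k - hr_len + 1L):k, 1], fs,
                          config$heart_min_sep_frac, hr_band,
                          config$heart_swing_frac, config$heart_detrend_s)
        if (!is.na(f)) {
          hr_raw <- f
          hr_sm <- smooth_step(hr_sm, f)
          hr_hat <- hr_sm$y
          hr_valid <- TRUE
        }
      }
      if (k >= rr_len && k >= warm_n) {
        f <- rate_measure(X[(k - rr_len + 1L):k, 3], fs,
                          config$resp_min_sep_frac, rr_band,
                          config$resp_swing_frac, config$resp_detrend_s)
        if (!is.na(f)) {
          rr_raw <- f
          rr_sm <- smooth_step(rr_sm, f)
          rr_hat <- rr_sm$y
          rr_valid <- TRUE
        }
      }
      log_row <- log_row + 1L
      log_mat[log_row, ] <- c(tcol[k], sig_noise, sig_resp, sig_heart,
                              sig_trend, h$h_f, h$h_s,
                              hr_hat * 60, rr_hat * 60,
                              hr_raw * 60, rr_raw * 60)
      ## covariance health, tracked at estimation instants
      P_asym <- max(abs(state$P - t(state$P))) / max(abs(state$P))
      P_eig <- min(eigen(state$P, symmetric = TRUE,
                         only.values = TRUE)$values)
      if (P_asym > P_max_asym) P_max_asym <- P_asym
      rel_eig <- P_eig / sum(diag(state$P))
      if (rel_eig < P_min_eig) P_min_eig <- rel_eig
    }
    hr_t[k] <- hr_hat; rr_t[k] <- rr_hat
    hr_rt[k] <- hr_raw; rr_rt[k] <- rr_raw
    hr_v[k] <- hr_valid; rr_v[k] <- rr_valid
  }

  rates <- data.frame(t = tcol,
                      hr_bpm = hr_t * 60, hr_raw_bpm = hr_rt * 60,
                      rr_permin = rr_t * 60, rr_raw_permin = rr_rt * 60,
                      hr_valid = hr_v, rr_valid = rr_v)

  structure(list(
    states = X, rates = rates, fitted = fitted, residuals = innov,
    adaptation_log = as.data.frame(log_mat[seq_len(log_row), , drop = FALSE]),
    K = state$K, P = state$P,
    P_health = c(max_rel_asymmetry = P_max_asym,
                 min_rel_eigenvalue = P_min_eig),
    sensors = S, t = tcol, config = config, truth = truth,
    provenance = list(config_hash = object_md5(unclass(config)),
                      input_digest = object_md5(S),
                      n = n, fs = fs),
    call = match.call()
  ), class = "akf")
}

object_md5 <- function(obj) {
  f <- tempfile()
  on.exit(unlink(f))
  writeBin(serialize(obj, NULL, version = 2), f)
  unname(tools::md5sum(f))
}

#' @export
print.akf <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("%s Kalman filter run: %d samples (%.1f s at %g Hz), preset %s\n",
              if (cfg$adaptive) "Adaptive" else "Non-adaptive",
              x$provenance$n, x$provenance$n / cfg$fs, cfg$fs, cfg$preset))
  cc <- coef(x)
  cat(sprintf("  final rates: heart %.1f bpm, respiration %.1f /min\n",
              cc["hr_bpm"], cc["rr_permin"]))
  cat("  states: Xf Vf Xs Vs C1 C2 C3; see summary() for separation metrics\n")
  invisible(x)
}

#' @export
coef.akf <- function(object, ...) {
  last <- nrow(object$rates)
  al <- object$adaptation_log
  out <- c(hr_bpm = object$rates$hr_bpm[last],
           rr_permin = object$rates$rr_permin[last])
  if (nrow(al)) {
    lastl <- nrow(al)
    out <- c(out,
             structure(as.numeric(al[lastl, paste0("sigma_noise", 1:3)]),
                       names = paste0("sigma_noise", 1:3)),
             structure(as.numeric(al[lastl, paste0("sigma_resp", 1:3)]),
                       names = paste0("sigma_resp", 1:3)),
             structure(as.numeric(al[lastl, paste0("sigma_heart", 1:3)]),
                       names = paste0("sigma_heart", 1:3)))
  }
  out
}

#' @export
fitted.akf <- function(object, ...) object$fitted

#' Residuals of a filter run
#'
#' @param object An \code{"akf"} fit.
#' @param type \code{"response"}: raw sensor minus model-implied sensor
#'   value after the measurement update; \code{"offset"}: raw sensor minus
#'   estimated offset, i.e. the oscillatory content the filter attributes to
#'   respiration + heart + noise.
#' @param ... Unused.
#' @return n x 3 numeric matrix.
#' @export
residuals.akf <- function(object, type = c("response", "offset"), ...) {
  type <- match.arg(type)
  if (type == "response") object$residuals
  else object$sensors - object$states[, 5:7]
}

#' @export
summary.akf <- function(object, ...) {
  cfg <- object$config
  keep <- object$t >= cfg$warmup_s
  off <- evaluate_offsets(object$states[, 5:7], object$sensors,
                          t = object$t, warmup_s = cfg$warmup_s)
  rate_err <- NULL
  if (!is.null(object$truth)) {
    rate_err <- list(
      heart = evaluate_rates(object$rates$hr_bpm[keep],
                             object$truth$heart_rate_bpm[keep]),
      resp = evaluate_rates(object$rates$rr_permin[keep],
                            object$truth$resp_rate_permin[keep]))
  }
  structure(list(config = cfg, n = object$provenance$n,
                 offset_residuals = off, rate_errors = rate_err,
                 final = coef(object)),
            class = "summary.akf")
}

#' @export
print.summary.akf <- function(x, ...) {
  cat(sprintf("%s Kalman filter, preset %s, %d samples (warm-up %.1f s excluded from metrics)\n",
              if (x$config$adaptive) "Adaptive" else "Non-adaptive",
              x$config$preset, x$n, x$config$warmup_s))
  if (!is.null(x$rate_errors)) {
    cat(sprintf("  heart-rate error vs truth:       mean %6.2f bpm   (sd %.2f)\n",
                x$rate_errors$heart["mean_error"], x$rate_errors$heart["sd_error"]))
    cat(sprintf("  respiration-rate error vs truth: mean %6.2f /min  (sd %.2f)\n",
                x$rate_errors$resp["mean_error"], x$rate_errors$resp["sd_error"]))
  }
  cat("  offset residuals (raw - offset), per sensor:\n")
  for (i in 1:3)
    cat(sprintf("    s%d: mean %10.1f   sd %10.1f\n", i,
                x$offset_residuals$mean_error[i], x$offset_residuals$sd_error[i]))
  invisible(x)
}

#' Plot a filter run
#'
#' Four stacked panels: raw sensors with estimated offsets, the cardiac
#' state Xf, the respiratory state Xs, and the estimated rates (with ground
#' truth overlaid when the input was a synthetic session).
#'
#' @param x An \code{"akf"} fit.
#' @param ... Passed to \code{matplot} for the first panel.
#' @export
plot.akf <- function(x, ...) {
  op <- graphics::par(mfrow = c(4, 1), mar = c(2.5, 4, 1.5, 1))
  on.exit(graphics::par(op))
  t <- x$t
  graphics::matplot(t, x$sensors, type = "l", lty = 1,
                    col = grDevices::adjustcolor(1:3, 0.5),
                    ylab = "raw / offset", main = "sensors & estimated offsets",
                    xlab = "", ...)
  graphics::matlines(t, x$states[, 5:7], lty = 2, col = 1:3)
  graphics::plot(t, x$states[, 1], type = "l", ylab = "Xf (cardiac)", xlab = "")
  graphics::plot(t, x$states[, 3], type = "l", ylab = "Xs (respiration)", xlab = "")
  graphics::plot(t, x$rates$hr_bpm, type = "l", col = 2,
                 ylim = range(x$rates$hr_bpm, x$rates$rr_permin),
                 ylab = "rate", xlab = "time [s]")
  graphics::lines(t, x$rates$rr_permin, col = 4)
  if (!is.null(x$truth)) {
    graphics::lines(t, x$truth$heart_rate_bpm, col = 2, lty = 3)
    graphics::lines(t, x$truth$resp_rate_permin, col = 4, lty = 3)
  }
  graphics::legend("topright", c("heart [bpm]", "respiration [/min]"),
                   col = c(2, 4), lty = 1, bty = "n", cex = 0.8)
  invisible(x)
}
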