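#' Online estimators feeding the adaptive filter
#'
#' Every time-varying quantity the filter consumes is estimated from short
#' (0.5 s) and long (20 s) rolling windows of the raw sensor channels:
#' the measurement-noise standard deviation from the first difference of the
#' short window, the respiratory standard deviation from the long window,
#' the trend standard deviation as a fixed fraction (10 percent) of the
#' respiratory one, and the cardiac standard deviation from the short window.
#' Estimation runs only at every \code{cadence}-th sample (every 10th by
#' default, 9.5 Hz effective rate at 95 Hz) and each estimate is smoothed by
#' a first-order lowpass before it reaches the model matrices; between
#' estimation instants the last value is held.
#'
#' @name adaptation
#' @keywords internal
NULL

#' Estimate the measurement-noise standard deviation of a short segment
#'
#' First-differencing suppresses the slow respiratory and offset content and
#' doubles the variance of white noise; the standard deviation of the
#' differenced segment divided by \code{divisor} (default \code{sqrt(2)},
#' the unbiased correction for white noise) estimates the sensor noise.
#'
#' @param segment Numeric vector, the most recent ~0.5 s of one raw channel.
#' @param divisor Positive scalar applied to the differenced standard
#'   deviation.
#' @return Non-negative scalar estimate, or \code{NA_real_} (with a warning)
#'   when the segment is too short to difference; callers hold the previous
#'   estimate in that case.
#' @export
estimate_noise_std <- function(segment, divisor = sqrt(2)) {
  if (length(segment) < 2L) {
    warning("segment shorter than 2 samples; holding previous noise estimate")
    return(NA_real_)
  }
  stats::sd(diff(segment)) / divisor
}

#' Estimate the respiratory standard deviation from a long segment
#'
#' Plain standard deviation over the 20 s window; the window is long enough
#' that respiration, the dominant oscillation, sets its value.
#'
#' @param segment Numeric vector, the most recent ~20 s of one raw channel.
#' @return Non-negative scalar, or \code{NA_real_} when fewer than 2 samples.
#' @export
estimate_resp_std <- function(segment) {
  if (length(segment) < 2L) return(NA_real_)
  stats::sd(segment)
}

#' Trend standard deviation from the respiratory one
#'
#' The slow baseline trend is modelled as having 1 percent of the respiratory
#' variance, i.e. \code{sigma_trend = 0.1 * sigma_resp}.
#'
#' @param sigma_resp Non-negative respiratory standard deviation(s).
#' @return \code{0.1 * sigma_resp}.
#' @export
estimate_trend_std <- function(sigma_resp) {
  if (any(sigma_resp < 0)) stop_invalid("sigma_resp must be non-negative")
  0.1 * sigma_resp
}

#' Estimate the cardiac standard deviation of a short segment
#'
#' Standard deviation of the raw 0.5 s window divided by \code{divisor}
#' (default 2): over half a second respiration moves little, so the window
#' variation is mostly cardiac plus noise, and halving approximates the
#' cardiac share.
#'
#' @inheritParams estimate_noise_std
#' @return Non-negative scalar estimate, or \code{NA_real_} when fewer than
#'   2 samples (with a warning).
#' @export
estimate_heart_std <- function(segment, divisor = 2) {
  if (length(segment) < 2L) {
    warning("segment shorter than 2 samples; holding previous heart estimate")
    return(NA_real_)
  }
  stats::sd(segment) / divisor
}

#' Cardiac and respiratory fusion gains
#'
#' Computes the per-sensor entries of the measurement matrix:
#' \code{h_f[i] = (sigma_heart[i] / sigma_noise[i])^2 * scal_f[i]} weights a
#' sensor by its cardiac signal-to-noise ratio, and
#' \code{h_s[i] = sigma_resp[i]^2 * scal_s[i]} by its respiratory variance.
#' \code{scal_f}, \code{scal_s} are the only a-priori knowledge: a sensor
#' known to sit over the heart keeps \code{scal_f = 1} while the others are
#' down-weighted (defaults \code{c(1, 0.1, 0.1)} and \code{c(0.1, 1, 1)});
#' with no prior knowledge use all ones.
#'
#' @param sigma_heart,sigma_noise,sigma_resp Non-negative 3-vectors of
#'   standard-deviation estimates.
#' @param scal_f,scal_s Scaling 3-vectors with entries in (0, 1].
#' @param noise_floor_factor Zero noise estimates are floored at
#'   \code{noise_floor_factor * sigma_resp} (with an absolute floor of
#'   \code{.Machine$double.eps}) to keep the ratio finite on noiseless input;
#'   a warning is issued when the floor engages.
#' @return List with non-negative finite 3-vectors \code{h_f} and \code{h_s}.
#' @export
compute_h_entries <- function(sigma_heart, sigma_noise, sigma_resp,
                              scal_f = c(1, 0.1, 0.1),
                              scal_s = c(0.1, 1, 1),
                              noise_floor_factor = 1e-12) {
  check_vec3(sigma_heart, "sigma_heart")
  check_vec3(sigma_noise, "sigma_noise")
  check_vec3(sigma_resp, "sigma_resp")
  floor_i <- pmax(noise_floor_factor * sigma_resp, .Machine$double.eps)
  if (any(sigma_noise < floor_i)) {
    warning("zero/near-zero noise estimate floored for fusion-gain computation")
    sigma_noise <- pmax(sigma_noise, floor_i)
  }
  list(h_f = (sigma_heart / sigma_noise)^2 * scal_f,
       h_s = sigma_resp^2 * scal_s)
}

#' Create the adaptation state for streaming use
#'
#' Rolling ring buffers over the three raw channels plus one lowpass smoother
#' per estimated standard deviation. \code{\link{adaptation_tick}} advances
#' it one sample at a time; batch processing in \code{\link{akf}} uses the
#' same estimator functions on slices of the stored signal.
#'
#' @param config An \code{\link{akf_config}}.
#' @return A list of class \code{"akf_adaptation"}.
#' @export
adaptation_state <- function(config = akf_config()) {
  fs <- config$fs
  short_len <- round(config$short_window_s * fs)
  long_len <- round(config$long_window_s * fs)
  rate <- fs / config$cadence
  mk3 <- function(init) lapply(init, function(v)
    lowpass_smoother(config$estimate_cutoff_hz, rate, init = v))
  structure(list(
    config = config,
    short_len = short_len, long_len = long_len,
    buffer = matrix(NA_real_, long_len, 3L),
    pos = 0L, count = 0L,
    sigma_noise_hat = config$sigma_noise0,
    sigma_resp_hat = config$sigma_resp0,
    sigma_heart_hat = config$sigma_heart0,
    sigma_trend_hat = config$sigma_trend0,
    sm_noise = mk3(config$sigma_noise0),
    sm_resp = mk3(config$sigma_resp0),
    sm_heart = mk3(config$sigma_heart0)
  ), class = "akf_adaptation")
}

#' Advance the adaptation state by one sample
#'
#' Pushes the new 3-sensor sample into the rolling buffers; at every
#' \code{cadence}-th sample recomputes all standard-deviation estimates,
#' smooths them, derives the trend estimate and the fusion gains; at all
#' other samples the previous values are held. Until the long buffer has
#' filled, the respiratory estimate stays at its initialization value.
#'
#' @param ad An \code{"akf_adaptation"}.
#' @param z New raw sample, 3-vector.
#' @return The updated \code{"akf_adaptation"}; current filter parameters
#'   are available via \code{\link{adaptation_params}}.
#' @export
adaptation_tick <- function(ad, z) {
  ad$pos <- ad$pos %% ad$long_len + 1L
  ad$buffer[ad$pos, ] <- z
  ad$count <- ad$count + 1L
  if (ad$count %% ad$config$cadence != 0L) return(ad)

  n <- min(ad$count, ad$long_len)
  idx <- ((ad$pos - n) %% ad$long_len) + seq_len(n)   # oldest..newest
  idx <- (idx - 1L) %% ad$long_len + 1L
  win <- ad$buffer[idx, , drop = FALSE]
  ns <- min(n, ad$short_len)
  short <- win[(n - ns + 1L):n, , drop = FALSE]

  cfg <- ad$config
  for (i in 1:3) {
    noise_raw <- estimate_noise_std(short[, i], cfg$noise_diff_divisor)
    heart_raw <- estimate_heart_std(short[, i], cfg$heart_std_divisor)
    if (!is.na(noise_raw)) {
      ad$sm_noise[[i]] <- smooth_step(ad$sm_noise[[i]], noise_raw)
      ad$sigma_noise_hat[i] <- ad$sm_noise[[i]]$y
    }
    if (!is.na(heart_raw)) {
      ad$sm_heart[[i]] <- smooth_step(ad$sm_heart[[i]], heart_raw)
      ad$sigma_heart_hat[i] <- ad$sm_heart[[i]]$y
    }
    if (n >= ad$long_len) {
      resp_raw <- estimate_resp_std(win[, i])
      ad$sm_resp[[i]] <- smooth_step(ad$sm_resp[[i]], resp_raw)
      ad$sigma_resp_hat[i] <- ad$sm_resp[[i]]$y
    }
  }
  ad$sigma_trend_hat <- estimate_trend_std(ad$sigma_resp_hat)
  ad
}

#' Current filter parameters from an adaptation state
#'
#' @param ad An \code{"akf_adaptation"}.
#' @return List with the smoothed \code{sigma_noise}, \code{sigma_resp},
#'   \code{sigma_heart}, \code{sigma_trend} 3-vectors and the fusion gains
#'   \code{h_f}, \code{h_s}, ready for the \code{build_*} constructors.
#' @export
adaptation_params <- function(ad) {
  h <- compute_h_entries(ad$sigma_heart_hat, ad$sigma_noise_hat,
                         ad$sigma_resp_hat,
                         ad$config$scal_f, ad$config$scal_s,
                         ad$config$noise_floor_factor)
  list(sigma_noise = ad$sigma_noise_hat,
       sigma_resp = ad$sigma_resp_hat,
       sigma_heart = ad$sigma_heart_hat,
       sigma_trend = ad$sigma_trend_hat,
       h_f = h$h_f, h_s = h$h_s)
}
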