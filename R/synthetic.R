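#' Synthetic cardiorespiratory sessions
#'
#' No public recordings exist for the kind of non-contact sensor array this
#' package targets, so every module is exercised against generated sessions
#' with known ground truth. A session emulates the documented properties of
#' the real signals: a very large, slowly drifting per-sensor offset; a
#' dominant respiratory oscillation with higher harmonics that can reach
#' into the cardiac band; a much smaller cardiac oscillation; additive white
#' sensor noise; and per-sensor mixing in which sensor 1 is the
#' cardiac-dominant channel. Noise-free flow and PPG reference channels are
#' phase-locked to the respiratory and cardiac components.
#'
#' @name synthetic-sessions
#' @keywords internal
NULL

#' Piecewise-linear rate track
#'
#' @param t Breakpoint times in seconds (non-decreasing).
#' @param rate Rates at the breakpoints (bpm for heart, min^-1 for
#'   respiration); values are interpolated linearly and held constant
#'   outside the breakpoint range.
#' @return A data frame with columns \code{t} and \code{rate}.
#' @examples
#' rate_track(c(0, 60, 61), c(60, 60, 90))   # step from 60 to 90 bpm at 60 s
#' @export
rate_track <- function(t, rate) {
  if (length(t) != length(rate) || is.unsorted(t))
    stop_invalid("t and rate must have equal length with non-decreasing t")
  data.frame(t = as.numeric(t), rate = as.numeric(rate))
}

track_eval <- function(track, t) {
  if (nrow(track) == 1L) return(rep(track$rate, length(t)))
  stats::approx(track$t, track$rate, xout = t, rule = 2)$y
}

#' Specify a synthetic session
#'
#' Amplitudes can be given either directly (\code{resp_amplitude},
#' \code{heart_amplitude}) or as target component standard deviations
#' (\code{resp_std}, \code{heart_std}), from which amplitudes are derived
#' using the RMS of the configured waveform (a sinusoid with the listed
#' respiratory harmonics).
#'
#' @param duration Session length in seconds.
#' @param fs Sampling rate in Hz.
#' @param heart_rate_track Heart-rate track in bpm: a scalar (constant) or a
#'   \code{\link{rate_track}}.
#' @param resp_rate_track Respiration-rate track in min^-1, same forms.
#' @param offset_level Per-sensor constant offset, 3-vector (amplitude
#'   units).
#' @param drift_sigma Per-sensor random-walk increment standard deviation
#'   per sample (the offsets drift as Gaussian random walks).
#' @param resp_std,heart_std Target per-sensor component standard
#'   deviations, 3-vectors.
#' @param resp_amplitude,heart_amplitude Fundamental amplitudes, 3-vectors;
#'   override the \code{*_std} form when given.
#' @param noise_sigma Per-sensor white-noise standard deviation, 3-vector.
#' @param resp_harmonics Respiratory harmonic content: list of
#'   \code{c(order, relative_amplitude)} pairs added to the fundamental.
#' @param seed Integer seed; identical spec + seed gives a bit-identical
#'   session.
#' @return A validated list of class \code{"akf_session_spec"}.
#' @export
session_spec <- function(duration = 150, fs = 95,
                         heart_rate_track = 78, resp_rate_track = 18,
                         offset_level = c(60000, 20000, 90000),
                         drift_sigma = c(102, 11, 85),
                         resp_std = c(10200, 1100, 8500),
                         heart_std = c(1100, 100, 800),
                         resp_amplitude = NULL, heart_amplitude = NULL,
                         noise_sigma = c(53.6, 11.2, 64.2),
                         resp_harmonics = list(c(2, 0.3), c(3, 0.1)),
                         seed = 1L) {
  as_track <- function(x) if (is.data.frame(x)) x else rate_track(0, x)
  wave_rms <- resp_wave_rms(resp_harmonics)
  if (is.null(resp_amplitude)) resp_amplitude <- resp_std / wave_rms
  if (is.null(heart_amplitude)) heart_amplitude <- heart_std * sqrt(2)
  spec <- structure(list(
    duration = duration, fs = fs,
    heart_rate_track = as_track(heart_rate_track),
    resp_rate_track = as_track(resp_rate_track),
    offset_level = as.numeric(offset_level),
    drift_sigma = as.numeric(drift_sigma),
    resp_amplitude = as.numeric(resp_amplitude),
    heart_amplitude = as.numeric(heart_amplitude),
    noise_sigma = as.numeric(noise_sigma),
    resp_harmonics = resp_harmonics,
    seed = as.integer(seed)
  ), class = "akf_session_spec")
  validate_session_spec(spec)
  spec
}

resp_wave_rms <- function(harmonics) {
  rel <- vapply(harmonics, `[`, numeric(1), 2)
  sqrt((1 + sum(rel^2)) / 2)
}

validate_session_spec <- function(spec) {
  bad <- character(0)
  if (!is.numeric(spec$duration) || spec$duration <= 0) bad <- c(bad, "duration")
  if (!is.numeric(spec$fs) || spec$fs <= 0) bad <- c(bad, "fs")
  for (f in c("offset_level", "drift_sigma", "resp_amplitude",
              "heart_amplitude", "noise_sigma")) {
    v <- spec[[f]]
    if (!is.numeric(v) || length(v) != 3L || any(!is.finite(v)))
      bad <- c(bad, f)
  }
  for (f in c("drift_sigma", "resp_amplitude", "heart_amplitude",
              "noise_sigma")) {
    v <- spec[[f]]
    if (is.numeric(v) && length(v) == 3L && any(v < 0)) bad <- c(bad, f)
  }
  for (f in c("heart_rate_track", "resp_rate_track")) {
    tr <- spec[[f]]
    if (!is.data.frame(tr) || any(tr$rate <= 0)) bad <- c(bad, f)
  }
  for (h in spec$resp_harmonics) {
    if (length(h) != 2L || h[1] < 2 || h[2] < 0) bad <- c(bad, "resp_harmonics")
  }
  if (length(bad))
    stop_invalid("invalid session spec field(s): ",
                 paste(unique(bad), collapse = ", "))
  invisible(TRUE)
}

#' Session presets
#'
#' Three ready-made specifications. \code{"subject1_like"} (heart 1.3 Hz,
#' respiration 0.3 Hz) and \code{"subject2_like"} (1.7 Hz / 0.2 Hz) mirror
#' the frequency and amplitude relations of the two recorded subjects under
#' the best-case initialization columns; \code{"worst_case"} places the
#' heart rate exactly on the second respiratory harmonic (0.7 Hz heart,
#' 0.35 Hz respiration), the configuration in which frequency-selective
#' filtering cannot separate the two signals.
#'
#' @param name One of \code{"subject1_like"}, \code{"subject2_like"},
#'   \code{"worst_case"}.
#' @param ... Overrides passed to \code{\link{session_spec}} (e.g.
#'   \code{duration}, \code{seed}).
#' @return An \code{"akf_session_spec"}.
#' @export
session_preset <- function(name = c("subject1_like", "subject2_like",
                                    "worst_case"), ...) {
  if (!is.character(name) || !(name[1] %in%
      c("subject1_like", "subject2_like", "worst_case")))
    stop_invalid("unknown preset '", name[1],
                 "'; valid presets: subject1_like, subject2_like, worst_case")
  name <- match.arg(name)
  args <- switch(name,
    subject1_like = list(
      heart_rate_track = 1.3 * 60, resp_rate_track = 0.3 * 60,
      resp_std = c(10200, 1100, 8500), heart_std = c(1100, 100, 800),
      noise_sigma = c(53.6, 11.2, 64.2),
      offset_level = c(60000, 20000, 90000), drift_sigma = c(102, 11, 85)),
    subject2_like = list(
      heart_rate_track = 1.7 * 60, resp_rate_track = 0.2 * 60,
      resp_std = c(191.2, 4137.1, 5846.5), heart_std = c(70.1, 100, 140),
      noise_sigma = c(6.7, 12.2, 15.6),
      offset_level = c(8000, 40000, 60000), drift_sigma = c(1.9, 41, 58)),
    worst_case = list(
      heart_rate_track = 0.7 * 60, resp_rate_track = 0.35 * 60,
      resp_std = c(1900, 9000, 8000), heart_std = c(700, 90, 80),
      noise_sigma = c(50, 60, 55),
      offset_level = c(50000, 30000, 70000), drift_sigma = c(19, 90, 80))
  )
  do.call(session_spec, utils::modifyList(args, list(...)))
}

#' Generate a synthetic session
#'
#' Each sensor channel is
#' \code{offset + drift random walk + resp_amplitude * waveform(phi_s) +
#' heart_amplitude * sin(phi_f) + white noise}, where the phases integrate
#' the (piecewise-linear) rate tracks by cumulative trapezoidal integration,
#' guaranteeing phase continuity across rate changes. The returned object
#' carries the noise-free components and per-sample true rates as ground
#' truth. The R random-number state is restored on exit.
#'
#' @param spec An \code{"akf_session_spec"}.
#' @return A list of class \code{"akf_session"} with fields \code{t},
#'   \code{sensors} (n x 3 matrix), \code{flow_ref}, \code{ppg_ref},
#'   \code{truth} (true rate tracks, component matrices, offset track and
#'   per-sensor component standard deviations) and \code{spec}.
#' @export
generate_session <- function(spec) {
  validate_session_spec(spec)
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(spec$seed)

  fs <- spec$fs
  n <- round(spec$duration * fs)
  t <- (seq_len(n) - 1) / fs
  f_f <- track_eval(spec$heart_rate_track, t) / 60   # Hz
  f_s <- track_eval(spec$resp_rate_track, t) / 60
  phi_f <- 2 * pi * cumtrapz(f_f, 1 / fs)
  phi_s <- 2 * pi * cumtrapz(f_s, 1 / fs)

  wave <- sin(phi_s)
  for (h in spec$resp_harmonics) wave <- wave + h[2] * sin(h[1] * phi_s)
  heart <- sin(phi_f)

  resp_comp <- outer(wave, spec$resp_amplitude)
  heart_comp <- outer(heart, spec$heart_amplitude)
  offsets <- matrix(spec$offset_level, n, 3, byrow = TRUE)
  for (i in 1:3) {
    if (spec$drift_sigma[i] > 0)
      offsets[, i] <- offsets[, i] +
        cumsum(stats::rnorm(n, 0, spec$drift_sigma[i]))
  }
  noise <- vapply(1:3, function(i) stats::rnorm(n, 0, spec$noise_sigma[i]),
                  numeric(n))
  sensors <- offsets + resp_comp + heart_comp + noise
  colnames(sensors) <- paste0("s", 1:3)

  structure(list(
    t = t, sensors = sensors,
    flow_ref = sin(phi_s), ppg_ref = sin(phi_f),
    truth = list(
      heart_rate_bpm = f_f * 60, resp_rate_permin = f_s * 60,
      phi_f = phi_f, phi_s = phi_s,
      resp_component = resp_comp, heart_component = heart_comp,
      offset_track = offsets,
      sigma_noise = spec$noise_sigma,
      sigma_resp = spec$resp_amplitude * resp_wave_rms(spec$resp_harmonics),
      sigma_heart = spec$heart_amplitude / sqrt(2)
    ),
    spec = spec
  ), class = "akf_session")
}

# Cumulative trapezoidal integral on a uniform grid, starting at 0.
cumtrapz <- function(y, dx) {
  n <- length(y)
  c(0, cumsum((y[-1] + y[-n]) / 2 * dx))
}

#' @export
#' @rdname generate_session
#' @param object An \code{"akf_session_spec"} (for the \code{simulate}
#'   method).
#' @param nsim Number of sessions to simulate.
#' @param seed Optional seed overriding \code{spec$seed}; session j of
#'   \code{nsim} uses \code{seed + j - 1}.
#' @param ... Unused.
simulate.akf_session_spec <- function(object, nsim = 1, seed = NULL, ...) {
  base_seed <- if (is.null(seed)) object$seed else as.integer(seed)
  out <- lapply(seq_len(nsim), function(j) {
    object$seed <- base_seed + j - 1L
    generate_session(object)
  })
  if (nsim == 1L) out[[1]] else out
}

#' @export
print.akf_session <- function(x, ...) {
  cat(sprintf("Synthetic cardiorespiratory session: %.1f s at %g Hz (%d samples)\n",
              x$spec$duration, x$spec$fs, length(x$t)))
  cat(sprintf("  heart rate %.1f-%.1f bpm, respiration %.1f-%.1f /min\n",
              min(x$truth$heart_rate_bpm), max(x$truth$heart_rate_bpm),
              min(x$truth$resp_rate_permin), max(x$truth$resp_rate_permin)))
  cat("  component std  resp:", paste(round(x$truth$sigma_resp, 1), collapse = ", "),
      " heart:", paste(round(x$truth$sigma_heart, 1), collapse = ", "),
      " noise:", paste(round(x$truth$sigma_noise, 1), collapse = ", "), "\n")
  invisible(x)
}

#' Asymptotic adaptation targets from ground truth
#'
#' Applies the adaptation module's windowed standard-deviation definitions
#' to the session's noise-free oscillatory components (respiration plus
#' heart, excluding offset drift), adding the known white-noise variance
#' inside each window, to obtain the asymptotic values the online estimators
#' converge to under the generator model. Used as an independent reference
#' when checking adaptation convergence.
#'
#' @param session An \code{"akf_session"}.
#' @param config An \code{\link{akf_config}} (window lengths and divisors).
#' @return List with per-sensor 3-vectors \code{sigma_noise} (the true noise
#'   level), \code{sigma_resp}, \code{sigma_heart}, \code{sigma_trend} and
#'   fusion gains \code{h_f}, \code{h_s}.
#' @export
adaptation_targets <- function(session, config = akf_config()) {
  clean <- session$truth$resp_component + session$truth$heart_component
  n <- nrow(clean)
  short_len <- round(config$short_window_s * config$fs)
  long_len <- round(config$long_window_s * config$fs)
  starts_s <- seq(1L, n - short_len + 1L, by = short_len)
  starts_l <- seq(1L, n - long_len + 1L, by = max(long_len %/% 4L, 1L))
  sigma_noise <- session$truth$sigma_noise
  ## the online path lowpass-averages per-window standard deviations, so the
  ## asymptotic value is the mean of per-window sqrt(clean var + noise var)
  sigma_heart <- vapply(1:3, function(i) {
    mean(sqrt(vapply(starts_s, function(s)
      stats::var(clean[s:(s + short_len - 1L), i]), numeric(1)) +
      sigma_noise[i]^2))
  }, numeric(1)) / config$heart_std_divisor
  sigma_resp <- vapply(1:3, function(i) {
    mean(sqrt(vapply(starts_l, function(s)
      stats::var(clean[s:(s + long_len - 1L), i]), numeric(1)) +
      sigma_noise[i]^2))
  }, numeric(1))
  h <- compute_h_entries(sigma_heart, sigma_noise, sigma_resp,
                         config$scal_f, config$scal_s,
                         config$noise_floor_factor)
  list(sigma_noise = sigma_noise, sigma_resp = sigma_resp,
       sigma_heart = sigma_heart,
       sigma_trend = estimate_trend_std(sigma_resp),
       h_f = h$h_f, h_s = h$h_s)
}

#' Write / read a session as delimited text
#'
#' The CSV has the header \code{time,s1,s2,s3,flow,ppg} with one row per
#' sample; a JSON sidecar (\code{<path>.json}) records the generating spec
#' and a truth summary so a written session can be re-identified.
#'
#' @param session An \code{"akf_session"}.
#' @param path CSV file path.
#' @param sidecar Write the JSON sidecar alongside?
#' @return \code{write_session}: \code{invisible(path)};
#'   \code{read_session}: a data frame with the CSV columns, with the parsed
#'   sidecar (if present) attached as attribute \code{"sidecar"}.
#' @export
write_session <- function(session, path, sidecar = TRUE) {
  df <- data.frame(time = session$t,
                   s1 = session$sensors[, 1], s2 = session$sensors[, 2],
                   s3 = session$sensors[, 3],
                   flow = session$flow_ref, ppg = session$ppg_ref)
  utils::write.csv(df, path, row.names = FALSE)
  if (sidecar) {
    spec <- unclass(session$spec)
    meta <- list(spec = spec,
                 truth_summary = list(
                   sigma_noise = session$truth$sigma_noise,
                   sigma_resp = session$truth$sigma_resp,
                   sigma_heart = session$truth$sigma_heart,
                   mean_heart_rate_bpm = mean(session$truth$heart_rate_bpm),
                   mean_resp_rate_permin = mean(session$truth$resp_rate_permin)))
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA, dataframe = "columns", pretty = TRUE)
  }
  invisible(path)
}

#' @rdname write_session
#' @export
read_session <- function(path) {
  df <- utils::read.csv(path)
  required <- c("time", "s1", "s2", "s3")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop_invalid("session file ", path, " lacks column(s): ",
                 paste(missing, collapse = ", "))
  for (col in required) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v))
    if (length(bad))
      stop_invalid("non-numeric or missing value in column '", col,
                   "' of ", path, " at data line ", bad[1])
    df[[col]] <- v
  }
  sidecar_path <- paste0(path, ".json")
  if (file.exists(sidecar_path))
    attr(df, "sidecar") <- jsonlite::read_json(sidecar_path,
                                               simplifyVector = TRUE)
  df
}
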