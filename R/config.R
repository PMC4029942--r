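#' Filter configuration
#'
#' Builds the complete parameter set one filter run needs: initialization
#' values for the model matrices, the sensor scaling vectors, buffer lengths,
#' smoother cutoffs, the estimation cadence and the warm-up span. Four named
#' presets reproduce the initialization settings studied on the two recorded
#' subjects:
#' \describe{
#'   \item{SE1, SE2}{"sensor estimation" best case for subject 1 / 2 --
#'     variances estimated from the whole raw recording in post-processing.}
#'   \item{DS}{default settings expected to work adequately in most cases.}
#'   \item{BS}{deliberately bad settings (noise variances far too high,
#'     signal variances far too low), the worst-case misconfiguration.}
#' }
#' Presets are shipped as JSON files under
#' \code{system.file("extdata", "presets", package = "akfvitals")}.
#'
#' @param preset Preset name (\code{"SE1"}, \code{"SE2"}, \code{"DS"},
#'   \code{"BS"}) or \code{NULL} for the DS values.
#' @param adaptive Logical; \code{FALSE} freezes all matrices at their
#'   initialization values (the non-adaptive baseline filter). The
#'   state-transition matrix then keeps the initial frequencies for the
#'   whole run.
#' @param ... Named overrides for any configuration field (see the schema in
#'   \code{system.file("extdata", "config-schema.json", package =
#'   "akfvitals")}).
#' @return A validated list of class \code{"akf_config"}.
#' @examples
#' cfg <- akf_config("SE1", adaptive = TRUE)
#' cfg$f_f0                 # 1.3 Hz initial heart frequency
#' @export
akf_config <- function(preset = NULL, adaptive = TRUE, ...) {
  cfg <- list(
    preset = if (is.null(preset)) "DS" else preset,
    adaptive = isTRUE(adaptive),
    fs = 95,
    cadence = 10L,
    warmup_s = 22.5,
    short_window_s = 0.5,
    long_window_s = 20,
    resp_buffer_s = 20,
    heart_buffer_s = 10,
    estimate_cutoff_hz = 0.1,
    heart_rate_cutoff_hz = 0.1,
    resp_rate_cutoff_hz = 0.05,
    noise_diff_divisor = sqrt(2),
    heart_std_divisor = 2,
    noise_floor_factor = 1e-12,
    heart_band_hz = c(0.6, 3.0),
    resp_band_hz = c(0.05, 0.8),
    heart_min_sep_frac = 0.4,
    resp_min_sep_frac = 0.5,
    heart_swing_frac = 0.25,
    resp_swing_frac = 0.3,
    heart_detrend_s = 1.0,
    resp_detrend_s = 0,
    p0_osc_factor = 10
  )
  cfg <- utils::modifyList(cfg, load_preset(cfg$preset))
  dots <- list(...)
  if (length(dots)) {
    unknown <- setdiff(names(dots), c(names(cfg), "name", "description"))
    if (length(unknown))
      stop_invalid("unknown configuration field(s): ",
                   paste(unknown, collapse = ", "))
    cfg <- utils::modifyList(cfg, dots)
  }
  cfg$cadence <- as.integer(cfg$cadence)
  class(cfg) <- "akf_config"
  validate_config(cfg)
  cfg
}

load_preset <- function(name) {
  dir <- system.file("extdata", "presets", package = "akfvitals")
  path <- file.path(dir, paste0(name, ".json"))
  if (!file.exists(path)) {
    valid <- sub("\\.json$", "", list.files(dir, pattern = "\\.json$"))
    stop_invalid("unknown preset '", name, "'; valid presets: ",
                 paste(valid, collapse = ", "))
  }
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  p$description <- NULL
  p$name <- NULL
  p
}

#' Validate a filter configuration
#'
#' Checks the configuration against the published schema rules (field types,
#' lengths, positivity, band ordering) and stops with a message listing every
#' offending field.
#'
#' @param config An \code{"akf_config"} (or plain list with the same fields).
#' @return \code{invisible(TRUE)} on success.
#' @export
validate_config <- function(config) {
  bad <- character(0)
  pos_scalar <- c("fs", "f_f0", "f_s0", "warmup_s", "short_window_s",
                  "long_window_s", "resp_buffer_s", "heart_buffer_s",
                  "estimate_cutoff_hz", "heart_rate_cutoff_hz",
                  "resp_rate_cutoff_hz", "noise_diff_divisor",
                  "heart_std_divisor", "p0_osc_factor")
  for (f in pos_scalar) {
    v <- config[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) ||
        v <= (if (f == "warmup_s") -1e-9 else 0))
      bad <- c(bad, f)
  }
  for (f in c("sigma_trend0", "sigma_noise0", "sigma_heart0", "sigma_resp0")) {
    v <- config[[f]]
    if (!is.numeric(v) || length(v) != 3L || any(!is.finite(v)) || any(v <= 0))
      bad <- c(bad, f)
  }
  for (f in c("scal_f", "scal_s")) {
    v <- config[[f]]
    if (!is.numeric(v) || length(v) != 3L || any(v <= 0) || any(v > 1))
      bad <- c(bad, f)
  }
  for (f in c("heart_band_hz", "resp_band_hz")) {
    v <- config[[f]]
    if (!is.numeric(v) || length(v) != 2L || any(v <= 0) || v[1] >= v[2])
      bad <- c(bad, f)
  }
  for (f in c("heart_swing_frac", "resp_swing_frac")) {
    v <- config[[f]]
    if (!is.numeric(v) || length(v) != 1L || v < 0 || v >= 1) bad <- c(bad, f)
  }
  for (f in c("heart_detrend_s", "resp_detrend_s")) {
    v <- config[[f]]
    if (!is.numeric(v) || length(v) != 1L || v < 0) bad <- c(bad, f)
  }
  if (!is.numeric(config$cadence) || config$cadence < 1) bad <- c(bad, "cadence")
  if (!is.logical(config$adaptive)) bad <- c(bad, "adaptive")
  if (is.numeric(config$noise_floor_factor) &&
      config$noise_floor_factor < 0) bad <- c(bad, "noise_floor_factor")
  if (length(bad))
    stop_invalid("invalid configuration field(s): ", paste(bad, collapse = ", "))
  invisible(TRUE)
}

#' Read / write a configuration as JSON
#'
#' @param config An \code{"akf_config"}.
#' @param path File path.
#' @return \code{read_config}: a validated \code{"akf_config"};
#'   \code{write_config}: \code{invisible(path)}.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  preset <- if (is.null(raw$preset)) "DS" else raw$preset
  adaptive <- if (is.null(raw$adaptive)) TRUE else raw$adaptive
  raw$preset <- NULL
  raw$adaptive <- NULL
  do.call(akf_config, c(list(preset = preset, adaptive = adaptive), raw))
}

#' @export
print.akf_config <- function(x, ...) {
  cat("Adaptive Kalman filter configuration (preset ", x$preset,
      if (x$adaptive) ", adaptive" else ", non-adaptive", ")\n", sep = "")
  cat(sprintf("  fs = %g Hz, cadence = %d (%.1f Hz estimation), warm-up = %g s\n",
              x$fs, x$cadence, x$fs / x$cadence, x$warmup_s))
  cat(sprintf("  f_f0 = %g Hz, f_s0 = %g Hz\n", x$f_f0, x$f_s0))
  fmt <- function(v) paste(format(v, trim = TRUE), collapse = ", ")
  cat("  sigma_noise0: ", fmt(x$sigma_noise0), "\n", sep = "")
  cat("  sigma_resp0:  ", fmt(x$sigma_resp0), "\n", sep = "")
  cat("  sigma_heart0: ", fmt(x$sigma_heart0), "\n", sep = "")
  cat("  sigma_trend0: ", fmt(x$sigma_trend0), "\n", sep = "")
  cat("  scal_f: ", fmt(x$scal_f), "   scal_s: ", fmt(x$scal_s), "\n", sep = "")
  invisible(x)
}
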