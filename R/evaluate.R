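#' Evaluation metrics and the offline reference rate estimator
#'
#' The online peak-detector rates are judged against a reference track
#' (ground truth for synthetic sessions, or rates derived from the flow/PPG
#' reference channels by \code{\link{spectrum_reference_rate}}) via the mean
#' and standard deviation of the estimation error; offset separation is
#' judged by the residual between each raw channel and its estimated offset.
#' All metrics exclude the warm-up span.
#'
#' @name evaluation
#' @keywords internal
NULL

#' Rate-error metrics
#'
#' @param estimated,reference Time-aligned rate series (bpm for heart,
#'   min^-1 for respiration). Any warm-up exclusion must be applied by the
#'   caller or via \code{t}/\code{warmup_s}.
#' @param t Optional time vector; samples with \code{t < warmup_s} are
#'   dropped.
#' @param warmup_s Warm-up span in seconds (used with \code{t}).
#' @return Named numeric vector \code{c(mean_error, sd_error)} of
#'   \code{estimated - reference}.
#' @export
evaluate_rates <- function(estimated, reference, t = NULL, warmup_s = 0) {
  if (length(estimated) != length(reference))
    stop_invalid("estimated and reference series must be equally long")
  keep <- if (is.null(t)) rep(TRUE, length(estimated)) else t >= warmup_s
  keep <- keep & !is.na(estimated) & !is.na(reference)
  if (!any(keep)) stop_invalid("no overlapping samples to evaluate")
  err <- estimated[keep] - reference[keep]
  c(mean_error = mean(err), sd_error = stats::sd(err))
}

#' Offset-separation metrics
#'
#' Mean and standard deviation of \code{raw - offset} per sensor. A large
#' mean implies the offset estimate deviates systematically from the raw
#' channel; the standard deviation reflects how much oscillatory and noise
#' content remains after offset removal (for a clean separation it
#' approaches the combined respiration + heart + noise level).
#'
#' @param offsets n x 3 matrix of estimated offsets (states C1-C3).
#' @param raw n x 3 matrix of raw sensor channels.
#' @inheritParams evaluate_rates
#' @return List with 3-vectors \code{mean_error} and \code{sd_error}.
#' @export
evaluate_offsets <- function(offsets, raw, t = NULL, warmup_s = 0) {
  offsets <- as.matrix(offsets); raw <- as.matrix(raw)
  if (!all(dim(offsets) == dim(raw)) || ncol(raw) != 3L)
    stop_invalid("offsets and raw must be equally sized n x 3 matrices")
  keep <- if (is.null(t)) rep(TRUE, nrow(raw)) else t >= warmup_s
  if (!any(keep)) stop_invalid("no overlapping samples to evaluate")
  err <- raw[keep, , drop = FALSE] - offsets[keep, , drop = FALSE]
  list(mean_error = colMeans(err), sd_error = apply(err, 2, stats::sd))
}

#' Spectrum-based reference rate estimator
#'
#' Offline, high-resolution rate track for a reference channel (flow or
#' PPG): sliding Hann-windowed DFT, dominant in-band magnitude bin refined
#' by three-point parabolic interpolation. Far more precise than the online
#' peak detector but not real-time capable; used only to produce evaluation
#' references. Each estimate is reported at its window center.
#'
#' @param x Reference signal.
#' @param fs Sampling rate in Hz.
#' @param band Frequency search band in Hz, \code{c(min, max)}; the window
#'   must cover at least 4 periods of \code{band[1]}.
#' @param window_s Window length in seconds.
#' @param hop_s Hop between windows in seconds.
#' @return Data frame with columns \code{t} (window-center time in s) and
#'   \code{rate_hz}; windows with no in-band energy yield \code{NA}.
#' @export
spectrum_reference_rate <- function(x, fs, band, window_s = 30, hop_s = 1) {
  check_scalar(fs, "fs", positive = TRUE)
  if (length(band) != 2L || band[1] <= 0 || band[1] >= band[2])
    stop_invalid("band must be c(min, max) with 0 < min < max")
  if (window_s < 4 / band[1])
    stop_invalid("window (", window_s, " s) must cover at least 4 periods of ",
                 "the band's lower edge (need >= ", 4 / band[1], " s)")
  wlen <- round(window_s * fs)
  hop <- max(1L, round(hop_s * fs))
  n <- length(x)
  if (n < wlen) stop_invalid("signal shorter than one window")
  starts <- seq(1L, n - wlen + 1L, by = hop)
  hann <- 0.5 - 0.5 * cos(2 * pi * (seq_len(wlen) - 1) / (wlen - 1))
  freqs <- (seq_len(wlen) - 1) * fs / wlen
  inband <- which(freqs >= band[1] & freqs <= band[2])
  est <- vapply(starts, function(s) {
    seg <- x[s:(s + wlen - 1L)]
    if (all(seg == 0)) return(NA_real_)
    seg <- (seg - mean(seg)) * hann
    mag <- Mod(stats::fft(seg))
    pk <- inband[which.max(mag[inband])]
    ## three-point parabolic interpolation around the peak bin
    if (pk > 1L && pk < wlen) {
      am <- mag[pk - 1L]; a0 <- mag[pk]; ap <- mag[pk + 1L]
      den <- am - 2 * a0 + ap
      delta <- if (den != 0) 0.5 * (am - ap) / den else 0
    } else delta <- 0
    (pk - 1 + delta) * fs / wlen
  }, numeric(1))
  data.frame(t = (starts - 1 + (wlen - 1) / 2) / fs, rate_hz = est)
}
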