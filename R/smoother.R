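#' First-order recursive lowpass smoother
#'
#' All online estimates (noise/respiration/heart standard deviations and both
#' rates) are smoothed with first-order IIR Butterworth lowpass filters
#' running at the decimated estimation rate (9.5 Hz when the filter runs at
#' 95 Hz with a cadence of 10). \code{lowpass_smoother} designs the filter
#' with \code{signal::butter} and returns a small state object;
#' \code{smooth_step} advances it by one estimation instant. DC gain is
#' exactly 1, so a constant input passes unchanged.
#'
#' @param cutoff Cutoff frequency in Hz; must be below half the estimation
#'   rate.
#' @param rate Estimation rate in Hz at which the smoother is stepped.
#' @param init Initial value; the filter state is primed so that the first
#'   outputs equal \code{init} until real inputs move it (suppresses startup
#'   transients).
#' @return A list of class \code{"akf_smoother"} with coefficients and state.
#' @examples
#' sm <- lowpass_smoother(0.1, 9.5, init = 0)
#' st <- smooth_step(sm, 1)   # first step of the unit-step response
#' st$y
#' @export
lowpass_smoother <- function(cutoff, rate = 9.5, init = 0) {
  check_scalar(cutoff, "cutoff", positive = TRUE)
  check_scalar(rate, "rate", positive = TRUE)
  if (cutoff >= rate / 2)
    stop_invalid("cutoff (", cutoff, " Hz) must be below the Nyquist rate ",
                 rate / 2, " Hz of the estimation cadence")
  ba <- signal::butter(1, cutoff / (rate / 2), type = "low")
  structure(list(b = as.numeric(ba$b), a = as.numeric(ba$a),
                 x1 = init, y1 = init, y = init),
            class = "akf_smoother")
}

#' @rdname lowpass_smoother
#' @param sm An \code{"akf_smoother"}.
#' @param x New input sample.
#' @return \code{smooth_step}: the updated smoother; the current output is in
#'   field \code{y}.
#' @export
smooth_step <- function(sm, x) {
  y <- sm$b[1] * x + sm$b[2] * sm$x1 - sm$a[2] * sm$y1
  sm$x1 <- x
  sm$y1 <- y
  sm$y <- y
  sm
}
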