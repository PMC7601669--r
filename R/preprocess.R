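#' Uniformly sampled ionic-current trace
#'
#' Container for a single-channel current recording. Currents are in amperes,
#' sampling rate in Hz.
#'
#' @param current Numeric vector of current samples (A). Must be finite.
#' @param sampling_rate Sampling rate (Hz), > 0.
#' @param start_time Time of the first sample (s).
#' @return An object of class `current_trace`.
#' @export
current_trace <- function(current, sampling_rate, start_time = 0) {
  stopifnot(is.numeric(current), is.numeric(sampling_rate),
            length(sampling_rate) == 1L)
  if (sampling_rate <= 0 || !is.finite(sampling_rate)) {
    stop_domain("sampling_rate must be a positive scalar (Hz)")
  }
  if (anyNA(current) || any(!is.finite(current))) {
    stop_domain("current samples must all be finite")
  }
  structure(list(current = as.numeric(current),
                 sampling_rate = sampling_rate,
                 start_time = start_time),
            class = "current_trace")
}

#' @export
print.current_trace <- function(x, ...) {
  n <- length(x$current)
  cat(sprintf("Current trace: %d samples at %g kHz (%.3f s), mean %.4g nA\n",
              n, x$sampling_rate / 1e3, n / x$sampling_rate,
              mean(x$current) * 1e9))
  invisible(x)
}

#' Sample times of a trace
#' @param trace A [current_trace()].
#' @return Numeric vector of sample times (s).
#' @export
trace_times <- function(trace) {
  trace$start_time + (seq_along(trace$current) - 1) / trace$sampling_rate
}

#' Zero-phase Butterworth low-pass filter
#'
#' Applies a Butterworth low-pass filter forward and backward (zero phase) so
#' that event onsets are not shifted in time; effective amplitude response is
#' the squared single-pass magnitude, i.e. the gain at the nominal cutoff is
#' 0.5 rather than 1/sqrt(2). DC gain is exactly 1 and the trace length is
#' preserved. Edge transients are suppressed by odd-reflection padding before
#' filtering.
#'
#' @param trace A [current_trace()].
#' @param cutoff Cutoff frequency (Hz); must be below the Nyquist frequency.
#'   Default 2500 Hz.
#' @param order Filter order of each pass. Default 2.
#' @return A filtered [current_trace()] of the same length.
#' @export
lowpass_butterworth <- function(trace, cutoff = 2500, order = 2) {
  stopifnot(inherits(trace, "current_trace"))
  nyq <- trace$sampling_rate / 2
  if (!is.finite(cutoff) || cutoff <= 0 || cutoff >= nyq) {
    stop_domain(sprintf(
      "cutoff must lie in (0, Nyquist = %g Hz)", nyq))
  }
  bf <- signal::butter(order, cutoff / nyq, type = "low")
  x <- trace$current
  n <- length(x)
  # pad long enough for the impulse response to die out; odd reflection keeps
  # the padded signal continuous in value and slope at both ends
  npad <- min(n - 1L, max(512L, ceiling(6 * trace$sampling_rate / cutoff)))
  pre <- 2 * x[1L] - x[(npad + 1L):2L]
  post <- 2 * x[n] - x[(n - 1L):(n - npad)]
  xp <- c(pre, x, post)
  y <- signal::filter(bf$b, bf$a, xp)
  y <- rev(signal::filter(bf$b, bf$a, rev(y)))
  trace$current <- as.numeric(y[(npad + 1L):(npad + n)])
  trace
}

#' Savitzky-Golay baseline estimation and correction
#'
#' Estimates the slowly varying open-pore baseline with a Savitzky-Golay
#' smoother of window `2 * side_points + 1` samples and polynomial order
#' `poly_order`, and returns both the baseline and the *deviation*
#' `baseline - current`, which is positive during current blockades.
#'
#' For `poly_order <= 1` on a symmetric window the Savitzky-Golay estimate is
#' exactly the window mean, which is computed in O(n) with cumulative sums; at
#' the trace edges the window is truncated symmetrically. Baselines of orders
#' <= 1 reproduce any linear drift exactly. The first and last `side_points`
#' samples are edge-affected and flagged so downstream event detection can
#' discard events overlapping them.
#'
#' @param trace A [current_trace()] (normally already low-pass filtered).
#' @param side_points Samples on each side of the window centre; window length
#'   is `2 * side_points + 1`. Default 2400 (window 4801).
#' @param poly_order Polynomial order of the smoother. Default 1.
#' @return An object of class `baseline_model`: list with `baseline` and
#'   `deviation` vectors (same length as the trace), `side_points`,
#'   `poly_order` and `sampling_rate`.
#' @export
estimate_baseline_savgol <- function(trace, side_points = 2400,
                                     poly_order = 1) {
  stopifnot(inherits(trace, "current_trace"))
  side_points <- as.integer(side_points)
  n <- length(trace$current)
  if (side_points < 1L) stop_domain("side_points must be >= 1")
  if (n <= 2L * side_points + 1L) {
    stop_domain(sprintf(
      "trace (%d samples) must be longer than the smoothing window (%d samples)",
      n, 2L * side_points + 1L))
  }
  x <- trace$current
  if (poly_order <= 1) {
    # order-0/1 SG on a symmetric window == running mean; edges use the
    # largest symmetric window that fits
    cs <- cumsum(c(0, x))
    i <- seq_len(n)
    s <- pmin(side_points, i - 1L, n - i)
    baseline <- (cs[i + s + 1L] - cs[i - s]) / (2 * s + 1)
  } else {
    baseline <- signal::sgolayfilt(x, p = poly_order, n = 2L * side_points + 1L)
  }
  structure(list(baseline = baseline,
                 deviation = baseline - x,
                 side_points = side_points,
                 poly_order = poly_order,
                 sampling_rate = trace$sampling_rate),
            class = "baseline_model")
}
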