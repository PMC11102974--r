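#' Uniformly sampled one-dimensional signal
#'
#' Lightweight container for a single channel of uniformly sampled data
#' (dynamometer torque, surface EMG, joint angle, ...). Units travel with the
#' signal so downstream stages can refuse unit mismatches instead of silently
#' multiplying volts by conversion factors meant for newton-metres.
#'
#' @param samples Numeric vector of sample values; must be non-empty and finite.
#' @param rate_hz Sampling frequency in Hz (> 0).
#' @param units Free-text unit label ("V", "Nm", "mV", "deg", "BW", ...).
#' @param label Channel name (e.g. "torque", "VL", "BFL").
#' @param t0_s Start-time offset in seconds (default 0).
#'
#' @return An object of class `sampled_signal`: a list with elements
#'   `samples`, `rate_hz`, `units`, `label`, `t0_s`.
#' @examples
#' s <- sampled_signal(sin(2 * pi * 5 * seq(0, 1, by = 1 / 200)), 200, "Nm")
#' signal_duration(s)
#' @export
sampled_signal <- function(samples, rate_hz, units = "", label = "", t0_s = 0) {
  samples <- as.numeric(samples)
  if (length(samples) == 0L) {
    stop("sampled_signal: `samples` must be non-empty", call. = FALSE)
  }
  if (!all(is.finite(samples))) {
    stop("sampled_signal: all samples must be finite", call. = FALSE)
  }
  if (!is.numeric(rate_hz) || length(rate_hz) != 1L || !is.finite(rate_hz) ||
      rate_hz <= 0) {
    stop("sampled_signal: `rate_hz` must be a single positive number",
         call. = FALSE)
  }
  structure(
    list(samples = samples, rate_hz = as.numeric(rate_hz),
         units = as.character(units), label = as.character(label),
         t0_s = as.numeric(t0_s)),
    class = "sampled_signal"
  )
}

#' @export
print.sampled_signal <- function(x, ...) {
  cat(sprintf("<sampled_signal> %s [%s], %d samples @ %g Hz (%.3f s)\n",
              if (nzchar(x$label)) x$label else "(unnamed)",
              if (nzchar(x$units)) x$units else "unitless",
              length(x$samples), x$rate_hz, signal_duration(x)))
  invisible(x)
}

#' Signal duration in seconds
#'
#' `(n - 1) / rate_hz`; zero for a single sample.
#' @param x A `sampled_signal`.
#' @return Duration in seconds.
#' @export
signal_duration <- function(x) {
  stopifnot(inherits(x, "sampled_signal"))
  (length(x$samples) - 1L) / x$rate_hz
}

#' Sample times of a signal
#'
#' @param x A `sampled_signal`.
#' @return Numeric vector of times in seconds (`t0_s` + index / rate).
#' @export
signal_times <- function(x) {
  stopifnot(inherits(x, "sampled_signal"))
  x$t0_s + (seq_along(x$samples) - 1L) / x$rate_hz
}

#' @export
as.data.frame.sampled_signal <- function(x, ...) {
  data.frame(time_s = signal_times(x), value = x$samples)
}

# Replace samples, keeping metadata; optionally retag units.
signal_with <- function(x, samples, units = x$units) {
  sampled_signal(samples, x$rate_hz, units = units, label = x$label,
                 t0_s = x$t0_s)
}

#' Full-wave rectification
#'
#' Elementwise absolute value, the standard step between band-pass filtering
#' and linear-envelope extraction of surface EMG.
#'
#' @param signal A `sampled_signal`.
#' @return Rectified `sampled_signal` (units unchanged).
#' @export
rectify <- function(signal) {
  stopifnot(inherits(signal, "sampled_signal"))
  signal_with(signal, abs(signal$samples))
}
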