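#' Filter specification
#'
#' Describes one stage of the fixed filter chains used throughout the
#' pipelines: Butterworth low-pass stages for torque smoothing and envelope
#' extraction, Chebyshev type-I high/low-pass stages for the EMG analysis
#' band, and comb notches for mains removal. Filters are designed in
#' normalized frequency at the signal's own sampling rate when applied;
#' resampling is never implicit.
#'
#' @param kind One of `"butterworth_lowpass"`, `"chebyshev_highpass"`,
#'   `"chebyshev_lowpass"`, `"comb_notch"`.
#' @param order Filter order (positive integer). Ignored for `comb_notch`
#'   (second-order sections).
#' @param cutoff_hz Corner frequency in Hz; for `comb_notch` the fundamental
#'   (mains) frequency.
#' @param ripple_db Passband ripple in dB for the Chebyshev stages
#'   (default 0.1).
#' @param zero_phase Apply forward-backward for zero group delay
#'   (default TRUE).
#' @param bandwidth_hz -3 dB width of each notch for `comb_notch`
#'   (default 2).
#' @return A `filter_spec` object.
#' @export
filter_spec <- function(kind, order, cutoff_hz, ripple_db = 0.1,
                        zero_phase = TRUE, bandwidth_hz = 2) {
  kind <- match.arg(kind, c("butterworth_lowpass", "chebyshev_highpass",
                            "chebyshev_lowpass", "comb_notch"))
  if (!is.numeric(order) || length(order) != 1L || order < 1 ||
      order != round(order)) {
    stop("filter_spec: `order` must be a positive integer", call. = FALSE)
  }
  if (!is.numeric(cutoff_hz) || any(cutoff_hz <= 0)) {
    stop("filter_spec: `cutoff_hz` must be positive", call. = FALSE)
  }
  structure(
    list(kind = kind, order = as.integer(order),
         cutoff_hz = as.numeric(cutoff_hz), ripple_db = ripple_db,
         zero_phase = isTRUE(zero_phase), bandwidth_hz = bandwidth_hz),
    class = "filter_spec"
  )
}

# --- internal machinery ------------------------------------------------------

# Steady-state-anchored single-pass IIR filter. The DC component of the input
# is routed around the recursion (response to a constant is exactly
# constant * DC gain), which removes the start-up transient a plain
# zero-initial-state filter would show; the zero-mean remainder is filtered
# with zero initial state.
iir_pass <- function(b, a, x) {
  b <- b / a[1]
  a <- a / a[1]
  x0 <- x[1]
  dc_den <- sum(a)
  dc <- if (abs(dc_den) > .Machine$double.eps) sum(b) / dc_den else 0
  u <- x - x0
  nb <- length(b)
  if (nb > 1L) {
    v <- stats::filter(c(rep(0, nb - 1L), u), b, method = "convolution",
                       sides = 1)
    v <- as.numeric(v)[nb:(length(u) + nb - 1L)]
  } else {
    v <- b * u
  }
  if (length(a) > 1L) {
    v <- as.numeric(stats::filter(v, -a[-1], method = "recursive"))
  }
  v + x0 * dc
}

# Zero-phase (forward-backward) filtering with odd reflective edge padding.
# pad_min is the hard floor (3x the filter length); pad_want the adaptive
# target covering the slowest transient of the filter.
zphase_pass <- function(b, a, x, pad_min, pad_want) {
  n <- length(x)
  if (n - 1L < pad_min) {
    stop(sprintf(paste0("signal too short for zero-phase filtering: ",
                        "%d samples, need > %d for edge padding"),
                 n, pad_min + 1L), call. = FALSE)
  }
  pad <- min(n - 1L, max(pad_min, pad_want))
  pre <- 2 * x[1] - x[(pad + 1L):2L]
  post <- 2 * x[n] - x[(n - 1L):(n - pad)]
  xp <- c(pre, x, post)
  y <- iir_pass(b, a, xp)
  y <- rev(iir_pass(b, a, rev(y)))
  y[(pad + 1L):(pad + n)]
}

# RBJ second-order notch at f0 with given -3 dB bandwidth.
notch_coefs <- function(f0_hz, bw_hz, rate_hz) {
  w0 <- 2 * pi * f0_hz / rate_hz
  alpha <- sin(w0) * bw_hz / (2 * f0_hz)  # Q = f0 / bw
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  list(b = b / a[1], a = a / a[1])
}

check_cutoff <- function(cutoff_hz, rate_hz) {
  nyq <- rate_hz / 2
  if (any(cutoff_hz >= nyq)) {
    stop(sprintf("cutoff %g Hz is at or above the Nyquist frequency (%g Hz)",
                 max(cutoff_hz), nyq), call. = FALSE)
  }
  if (any(cutoff_hz <= 0)) {
    stop("cutoff frequencies must be strictly positive", call. = FALSE)
  }
}

design_filter <- function(spec, rate_hz) {
  check_cutoff(spec$cutoff_hz, rate_hz)
  wn <- spec$cutoff_hz / (rate_hz / 2)
  co <- switch(spec$kind,
    butterworth_lowpass = signal::butter(spec$order, wn, type = "low"),
    chebyshev_lowpass = signal::cheby1(spec$order, spec$ripple_db, wn,
                                       type = "low"),
    chebyshev_highpass = signal::cheby1(spec$order, spec$ripple_db, wn,
                                        type = "high"),
    stop("design_filter: unsupported kind ", spec$kind, call. = FALSE)
  )
  list(b = co$b, a = co$a)
}

#' Apply a filter stage to a signal
#'
#' Zero-phase filters are applied forward-backward with odd reflective edge
#' padding and steady-state DC anchoring, so they introduce no group delay
#' and pass a constant unchanged (times the filter's DC gain). Length, rate
#' and units are preserved.
#'
#' @param signal A `sampled_signal`.
#' @param spec A `filter_spec`.
#' @return Filtered `sampled_signal`.
#' @examples
#' s <- sampled_signal(rep(5, 4000), 2000, "Nm")
#' f <- apply_filter(s, filter_spec("butterworth_lowpass", 4, 20))
#' range(f$samples)  # still 5: unit DC gain
#' @export
apply_filter <- function(signal, spec) {
  stopifnot(inherits(signal, "sampled_signal"), inherits(spec, "filter_spec"))
  rate <- signal$rate_hz
  if (spec$kind == "comb_notch") {
    return(remove_mains(signal, mains_hz = spec$cutoff_hz[1],
                        bandwidth_hz = spec$bandwidth_hz,
                        zero_phase = spec$zero_phase))
  }
  co <- design_filter(spec, rate)
  nf <- max(length(co$b), length(co$a))
  pad_min <- 3L * (nf - 1L)
  # cover ~4 cycles of the lowest corner so low-cutoff transients die in the pad
  pad_want <- as.integer(ceiling(4 * rate / min(spec$cutoff_hz)))
  y <- if (spec$zero_phase) {
    zphase_pass(co$b, co$a, signal$samples, pad_min, pad_want)
  } else {
    iir_pass(co$b, co$a, signal$samples)
  }
  signal_with(signal, y)
}

#' Remove mains interference and its harmonics
#'
#' Cascade of second-order IIR notches at the mains frequency and its integer
#' harmonics, each applied zero-phase by default. Harmonics at or above the
#' Nyquist frequency are skipped with a message.
#'
#' @param signal A `sampled_signal`.
#' @param mains_hz Mains fundamental (default 50 Hz).
#' @param n_harmonics Number of harmonics to target including the fundamental
#'   (default `Inf` = all below Nyquist).
#' @param bandwidth_hz -3 dB notch width in Hz (default 2).
#' @param zero_phase Forward-backward application (default TRUE).
#' @return Notch-filtered `sampled_signal`.
#' @export
remove_mains <- function(signal, mains_hz = 50, n_harmonics = Inf,
                         bandwidth_hz = 2, zero_phase = TRUE) {
  stopifnot(inherits(signal, "sampled_signal"))
  rate <- signal$rate_hz
  nyq <- rate / 2
  if (mains_hz >= nyq) {
    stop(sprintf("mains frequency %g Hz is not below Nyquist (%g Hz)",
                 mains_hz, nyq), call. = FALSE)
  }
  kmax_nyq <- floor((nyq - bandwidth_hz) / mains_hz)
  kmax <- min(kmax_nyq, n_harmonics)
  if (is.finite(n_harmonics) && n_harmonics > kmax_nyq) {
    message(sprintf("remove_mains: harmonics above %g Hz skipped (Nyquist %g Hz)",
                    kmax_nyq * mains_hz, nyq))
  }
  x <- signal$samples
  for (k in seq_len(kmax)) {
    co <- notch_coefs(k * mains_hz, bandwidth_hz, rate)
    pad_want <- as.integer(ceiling(4 * rate / bandwidth_hz))
    x <- if (zero_phase) {
      zphase_pass(co$b, co$a, x, 6L, pad_want)
    } else {
      iir_pass(co$b, co$a, x)
    }
  }
  signal_with(signal, x)
}
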