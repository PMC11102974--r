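#' EMG envelope extraction parameters
#'
#' The published chain: zero-lag 5th-order Chebyshev type-I high-pass at
#' 20 Hz, 8th-order Chebyshev type-I low-pass at 300 Hz, comb-notch removal
#' of 50 Hz mains and harmonics, full-wave rectification, and a zero-lag
#' 4th-order Butterworth low-pass at 2 Hz giving the linear envelope.
#'
#' @param band_hz Analysis band `c(high_pass, low_pass)` (default
#'   `c(20, 300)`).
#' @param hp_order,lp_order Chebyshev orders (defaults 5 and 8).
#' @param envelope_cutoff_hz,envelope_order Envelope Butterworth low-pass
#'   (defaults 2 Hz, order 4).
#' @param mains_hz Mains fundamental (default 50).
#' @param ripple_db Chebyshev passband ripple (default 0.1).
#' @param mains_bandwidth_hz Notch -3 dB width (default 2).
#' @return An `envelope_params` object.
#' @export
envelope_params <- function(band_hz = c(20, 300), hp_order = 5, lp_order = 8,
                            envelope_cutoff_hz = 2, envelope_order = 4,
                            mains_hz = 50, ripple_db = 0.1,
                            mains_bandwidth_hz = 2) {
  stopifnot(length(band_hz) == 2L, band_hz[1] > 0, band_hz[1] < band_hz[2])
  structure(
    list(band_hz = band_hz, hp_order = hp_order, lp_order = lp_order,
         envelope_cutoff_hz = envelope_cutoff_hz,
         envelope_order = envelope_order, mains_hz = mains_hz,
         ripple_db = ripple_db, mains_bandwidth_hz = mains_bandwidth_hz),
    class = "envelope_params"
  )
}

#' Linear envelope of a raw EMG channel
#'
#' @param raw A `sampled_signal` (typically mV at 2000 Hz).
#' @param params An [envelope_params()].
#' @return Non-negative envelope `sampled_signal` (units unchanged).
#' @export
compute_envelope <- function(raw, params = envelope_params()) {
  stopifnot(inherits(raw, "sampled_signal"),
            inherits(params, "envelope_params"))
  if (raw$rate_hz < 2 * params$band_hz[2]) {
    stop(sprintf(paste0("compute_envelope: rate %g Hz too low for the ",
                        "%g Hz low-pass corner"),
                 raw$rate_hz, params$band_hz[2]), call. = FALSE)
  }
  s <- apply_filter(raw, filter_spec("chebyshev_highpass", params$hp_order,
                                     params$band_hz[1],
                                     ripple_db = params$ripple_db))
  s <- apply_filter(s, filter_spec("chebyshev_lowpass", params$lp_order,
                                   params$band_hz[2],
                                   ripple_db = params$ripple_db))
  s <- remove_mains(s, mains_hz = params$mains_hz,
                    bandwidth_hz = params$mains_bandwidth_hz)
  s <- rectify(s)
  s <- apply_filter(s, filter_spec("butterworth_lowpass",
                                   params$envelope_order,
                                   params$envelope_cutoff_hz))
  signal_with(s, pmax(s$samples, 0))
}

#' Normalize an envelope to its task maximum
#'
#' @param env Envelope `sampled_signal` with a strictly positive maximum.
#' @param reference Normalization reference; only `"task_max"` (the maximum
#'   observed during the task) is defined.
#' @return Envelope rescaled to unit maximum; the scale factor applied is
#'   recorded in attribute `"norm_factor"`.
#' @export
normalize_envelope <- function(env, reference = "task_max") {
  stopifnot(inherits(env, "sampled_signal"))
  reference <- match.arg(reference, "task_max")
  m <- max(env$samples)
  if (m <= 0) {
    stop("normalize_envelope: envelope has no positive maximum", call. = FALSE)
  }
  out <- signal_with(env, env$samples / m, units = "")
  attr(out, "norm_factor") <- m
  out
}

#' Co-contraction index (Rudolph form) of an antagonist pair
#'
#' Per sample, with `L = min(a, b)` and `H = max(a, b)` the activations of
#' the less and more active muscle, `CCI = (L / H) * (L + H)`; zero where
#' both are silent. For inputs normalized to `[0, 1]` the CCI ranges from 0
#' to 2, the maximum attained only when both muscles are fully active.
#'
#' @param env_a,env_b Normalized envelopes (equal length and rate). Values
#'   marginally above 1 (zero-phase filtering ripple) are clipped to 1 with
#'   a warning.
#' @return Unitless `sampled_signal` of per-sample CCI, labelled `"CCI"`.
#' @examples
#' a <- sampled_signal(rep(0.25, 101), 101, "")
#' b <- sampled_signal(rep(0.50, 101), 101, "")
#' compute_cci(a, b)$samples[1]  # (0.25/0.5)*(0.75) = 0.375
#' @export
compute_cci <- function(env_a, env_b) {
  stopifnot(inherits(env_a, "sampled_signal"),
            inherits(env_b, "sampled_signal"))
  if (length(env_a$samples) != length(env_b$samples)) {
    stop("compute_cci: envelope lengths differ", call. = FALSE)
  }
  if (env_a$rate_hz != env_b$rate_hz) {
    stop("compute_cci: envelope rates differ", call. = FALSE)
  }
  a <- env_a$samples
  b <- env_b$samples
  if (any(a < 0) || any(b < 0)) {
    stop("compute_cci: envelopes must be non-negative", call. = FALSE)
  }
  n_over <- sum(a > 1) + sum(b > 1)
  if (n_over > 0L) {
    warning(sprintf("compute_cci: %d sample(s) above 1 clipped to 1", n_over),
            call. = FALSE)
    a <- pmin(a, 1)
    b <- pmin(b, 1)
  }
  l <- pmin(a, b)
  h <- pmax(a, b)
  cci <- ifelse(h > 0, (l / h) * (l + h), 0)
  sampled_signal(cci, env_a$rate_hz, units = "", label = "CCI",
                 t0_s = env_a$t0_s)
}

#' Gait-cycle phase boundaries (percent of cycle)
#'
#' Initial double support 0-10%, single support 10-50%, pre-swing 50-60%,
#' swing 60-100%.
#' @return Named list of half-open `[lo, hi)` percent intervals (the swing
#'   interval is closed at 100).
#' @export
gait_phases <- function() {
  list(initial_double_support = c(0, 10), single_support = c(10, 50),
       pre_swing = c(50, 60), swing = c(60, 100))
}

#' Per-phase means of a cycle-resampled CCI series
#'
#' @param series CCI values on the 101-point percent grid (numeric vector of
#'   length 101, a `sampled_signal`, or a [gait_cycle_series()]).
#' @return Named numeric vector: mean CCI per gait phase, intervals
#'   half-open `[lo, hi)` except swing which includes 100%.
#' @export
cci_by_phase <- function(series) {
  v <- if (inherits(series, "gait_cycle_series")) {
    series$values
  } else if (inherits(series, "sampled_signal")) {
    series$samples
  } else {
    as.numeric(series)
  }
  if (length(v) != 101L) {
    stop("cci_by_phase: series must be on the 101-point cycle grid",
         call. = FALSE)
  }
  pct <- 0:100
  phases <- gait_phases()
  out <- vapply(names(phases), function(nm) {
    b <- phases[[nm]]
    sel <- if (nm == "swing") pct >= b[1] & pct <= b[2] else
      pct >= b[1] & pct < b[2]
    mean(v[sel])
  }, numeric(1))
  out
}
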