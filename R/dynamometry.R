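#' Dynamometer voltage-to-torque conversion factors
#'
#' The dynamometer reports torque as a voltage; the vendor chain converts
#' volts to foot-pounds and foot-pounds to newton-metres. At the default
#' factors the combined gain is 138.834 Nm/V.
#'
#' @param volts_to_ftlb Vendor factor, ft-lb per volt (default 102.4).
#' @param ftlb_to_nm Unit conversion, Nm per ft-lb (default 1.3558).
#' @return A `torque_conversion` object with the combined Nm/V gain.
#' @export
torque_conversion <- function(volts_to_ftlb = 102.4, ftlb_to_nm = 1.3558) {
  stopifnot(volts_to_ftlb > 0, ftlb_to_nm > 0)
  structure(
    list(volts_to_ftlb = volts_to_ftlb, ftlb_to_nm = ftlb_to_nm,
         combined = volts_to_ftlb * ftlb_to_nm),
    class = "torque_conversion"
  )
}

#' Convert a raw dynamometer trace from volts to newton-metres
#'
#' @param signal A `sampled_signal` with units `"V"`.
#' @param conv A [torque_conversion()] (default vendor factors).
#' @return The trace in Nm (`units` retagged).
#' @examples
#' v <- sampled_signal(rep(1, 200), 2000, "V")
#' convert_torque(v)$samples[1]  # 138.834
#' @export
convert_torque <- function(signal, conv = torque_conversion()) {
  stopifnot(inherits(signal, "sampled_signal"),
            inherits(conv, "torque_conversion"))
  if (!identical(signal$units, "V")) {
    stop(sprintf("convert_torque: expected units 'V', got '%s'", signal$units),
         call. = FALSE)
  }
  signal_with(signal, signal$samples * conv$combined, units = "Nm")
}

#' Contraction segmentation parameters
#'
#' @param noise_window Integer vector `c(start_idx, end_idx)` (1-based,
#'   inclusive) of a stretch known to contain no contraction.
#' @param k_sigma Threshold multiplier on the noise SD (default 3).
#' @param min_duration_s Minimum contraction length in s (default 1).
#' @param min_gap_s Supra-threshold runs closer than this are merged
#'   (default 0.5).
#' @return A `segmentation_params` object.
#' @export
segmentation_params <- function(noise_window, k_sigma = 3,
                                min_duration_s = 1, min_gap_s = 0.5) {
  stopifnot(length(noise_window) == 2L, noise_window[1] >= 1,
            noise_window[2] > noise_window[1],
            k_sigma > 0, min_duration_s > 0, min_gap_s >= 0)
  structure(
    list(noise_window = as.integer(noise_window), k_sigma = k_sigma,
         min_duration_s = min_duration_s, min_gap_s = min_gap_s),
    class = "segmentation_params"
  )
}

#' Contraction-detection threshold from baseline noise
#'
#' `threshold = mu_noise + k_sigma * sigma_noise`, with mean and SD taken
#' over a window of the trace known to contain no contraction.
#'
#' @param signal A `sampled_signal` in Nm (20 Hz low-pass filtered upstream).
#' @param params A [segmentation_params()].
#' @return Threshold in the signal's units, with attributes `mu` and `sigma`.
#' @export
compute_threshold <- function(signal, params) {
  stopifnot(inherits(signal, "sampled_signal"),
            inherits(params, "segmentation_params"))
  nw <- params$noise_window
  if (nw[2] > length(signal$samples)) {
    stop("compute_threshold: noise window extends past the signal",
         call. = FALSE)
  }
  if (nw[2] - nw[1] + 1L < 100L) {
    stop("compute_threshold: noise window must span at least 100 samples",
         call. = FALSE)
  }
  x <- signal$samples[nw[1]:nw[2]]
  mu <- mean(x)
  sigma <- stats::sd(x)
  # activity check on the interior: the first/last few samples of a
  # zero-phase-filtered trace retain raw-noise amplitude (edge effect)
  margin <- max(3L, round(0.05 * length(x)))
  interior <- x[(margin + 1L):(length(x) - margin)]
  if (sigma <= 1e-8 * max(diff(range(signal$samples)), 1e-300)) {
    message("compute_threshold: (near-)zero-variance noise window; ",
            "threshold degenerates to the window mean")
  } else if (any(interior > mu + 10 * sigma)) {
    warning("compute_threshold: noise window appears to overlap activity ",
            "(samples above mu + 10 sigma)", call. = FALSE)
  }
  structure(mu + params$k_sigma * sigma, mu = mu, sigma = sigma)
}

#' Segment contraction repetitions by threshold crossing
#'
#' Supra-threshold runs of the (20 Hz low-pass filtered) torque trace are the
#' candidate contractions; runs separated by gaps shorter than `min_gap_s`
#' are merged, and runs shorter than `min_duration_s` are discarded.
#'
#' @param signal A `sampled_signal` in Nm, low-pass filtered at 20 Hz.
#' @param threshold Detection threshold (from [compute_threshold()]).
#' @param params A [segmentation_params()].
#' @return A data.frame with one row per contraction: `start_idx`,
#'   `end_idx` (half-open `[start, end)`), `peak_nm`, `peak_time_s`. Zero
#'   rows when nothing crosses the threshold.
#' @export
segment_contractions <- function(signal, threshold, params) {
  stopifnot(inherits(signal, "sampled_signal"),
            inherits(params, "segmentation_params"))
  x <- signal$samples
  rate <- signal$rate_hz
  above <- x > as.numeric(threshold)
  empty <- data.frame(start_idx = integer(), end_idx = integer(),
                      peak_nm = numeric(), peak_time_s = numeric())
  if (!any(above)) return(empty)
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- data.frame(start = starts[r$values], end = ends[r$values] + 1L)
  # merge runs separated by short sub-threshold gaps
  min_gap <- round(params$min_gap_s * rate)
  merged <- runs[1, , drop = FALSE]
  if (nrow(runs) > 1L) {
    for (i in 2:nrow(runs)) {
      if (runs$start[i] - merged$end[nrow(merged)] < min_gap) {
        merged$end[nrow(merged)] <- runs$end[i]
      } else {
        merged <- rbind(merged, runs[i, ])
      }
    }
  }
  min_len <- round(params$min_duration_s * rate)
  merged <- merged[(merged$end - merged$start) >= min_len, , drop = FALSE]
  if (nrow(merged) == 0L) return(empty)
  peak_idx <- vapply(seq_len(nrow(merged)), function(i) {
    seg <- merged$start[i]:(merged$end[i] - 1L)
    seg[which.max(x[seg])]
  }, integer(1))
  data.frame(start_idx = merged$start, end_idx = merged$end,
             peak_nm = x[peak_idx],
             peak_time_s = signal$t0_s + (peak_idx - 1L) / rate)
}

#' Extract the MVIC torque from segmented contractions
#'
#' Within each detected window the torque is smoothed with a zero-phase
#' 4th-order Butterworth low-pass at 2 Hz (so transient bursts do not inflate
#' the maximum) and the per-trial peak is read off; the maximal voluntary
#' isometric contraction (MVIC) is the overall maximum across trials. A
#' retest flag is raised when a third trial exceeds the earlier trials by 5%
#' or more, the protocol's cue to request a fourth trial.
#'
#' @param windows Data.frame from [segment_contractions()] (>= 1 row).
#' @param signal The torque trace in Nm the windows refer to.
#' @param task `"extension"` or `"flexion"` (metadata only; flexion traces
#'   are expected sign-inverted upstream so the peak is a maximum).
#' @param knee_angle_deg Nominal dynamometer angle, 75 or 90 (metadata).
#' @param baseline_nm Baseline offset subtracted before peak extraction
#'   (typically the noise-window mean; default 0).
#' @param smooth_cutoff_hz Smoothing corner (default 2).
#' @param retest_rule `"both"` (third trial must exceed each earlier trial by
#'   >= 5%) or `"max"` (exceed the running maximum).
#' @return An `mvic_result`: `task`, `knee_angle_deg`, `per_trial_peaks_nm`,
#'   `mvic_nm`, `retest_flag`.
#' @export
extract_mvic <- function(windows, signal, task = c("extension", "flexion"),
                         knee_angle_deg = 75, baseline_nm = 0,
                         smooth_cutoff_hz = 2,
                         retest_rule = c("both", "max")) {
  task <- match.arg(task)
  retest_rule <- match.arg(retest_rule)
  stopifnot(inherits(signal, "sampled_signal"))
  if (is.null(windows) || nrow(windows) == 0L) {
    stop("extract_mvic: no contraction windows detected", call. = FALSE)
  }
  spec <- filter_spec("butterworth_lowpass", 4, smooth_cutoff_hz)
  peaks <- vapply(seq_len(nrow(windows)), function(i) {
    seg <- signal$samples[windows$start_idx[i]:(windows$end_idx[i] - 1L)]
    sm <- apply_filter(sampled_signal(seg, signal$rate_hz, signal$units), spec)
    max(sm$samples) - baseline_nm
  }, numeric(1))
  retest <- FALSE
  if (length(peaks) >= 3L) {
    third <- peaks[3]
    prev <- peaks[1:2]
    retest <- if (retest_rule == "both") {
      all(third >= 1.05 * prev)
    } else {
      third >= 1.05 * max(prev)
    }
  }
  structure(
    list(task = task, knee_angle_deg = knee_angle_deg,
         per_trial_peaks_nm = peaks, mvic_nm = max(peaks),
         retest_flag = retest),
    class = "mvic_result"
  )
}

#' @export
print.mvic_result <- function(x, ...) {
  cat(sprintf("<mvic_result> %s @ %g deg: MVIC %.2f Nm over %d trial(s)%s\n",
              x$task, x$knee_angle_deg, x$mvic_nm,
              length(x$per_trial_peaks_nm),
              if (x$retest_flag) " [retest advised]" else ""))
  invisible(x)
}

#' Full dynamometry pipeline: raw trace to MVIC
#'
#' Convenience wrapper chaining the published processing order: 20 Hz
#' zero-phase Butterworth low-pass, volts-to-Nm conversion (when the input is
#' in volts), noise-threshold segmentation, baseline subtraction and 2 Hz
#' smoothed peak extraction.
#'
#' @param signal Raw trace (`units` `"V"` or `"Nm"`).
#' @param params A [segmentation_params()].
#' @param task,knee_angle_deg Passed to [extract_mvic()]; flexion traces are
#'   sign-inverted before analysis so the peak is a maximum.
#' @param conv A [torque_conversion()].
#' @return List with `signal_nm` (filtered, converted, sign-adjusted),
#'   `threshold`, `windows`, `mvic` (an `mvic_result`).
#' @export
mvic_pipeline <- function(signal, params, task = c("extension", "flexion"),
                          knee_angle_deg = 75, conv = torque_conversion()) {
  task <- match.arg(task)
  stopifnot(inherits(signal, "sampled_signal"))
  s <- apply_filter(signal, filter_spec("butterworth_lowpass", 4, 20))
  if (identical(s$units, "V")) s <- convert_torque(s, conv)
  if (task == "flexion") s <- signal_with(s, -s$samples)
  thr <- compute_threshold(s, params)
  windows <- segment_contractions(s, thr, params)
  mvic <- extract_mvic(windows, s, task = task,
                       knee_angle_deg = knee_angle_deg,
                       baseline_nm = attr(thr, "mu"))
  list(signal_nm = s, threshold = thr, windows = windows, mvic = mvic)
}
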