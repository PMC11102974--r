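#' Locate the superimposed-stimulation onset within a contraction
#'
#' During a maximal contraction a doublet of electrical stimuli is delivered
#' once the torque plateau is reached; the evoked twitch rides on top of the
#' voluntary torque. The onset is read from a trigger channel when one is
#' recorded, and otherwise detected as the sample of maximal positive first
#' difference of the 20 Hz-filtered torque within the plateau region of the
#' window. Trials without a detectable stimulus are rejected with an error —
#' unstimulated trials must never be scored.
#'
#' @param signal Torque trace in Nm, 20 Hz low-pass filtered.
#' @param window One row of the data.frame from [segment_contractions()]
#'   (fields `start_idx`, `end_idx`) or a list with those fields.
#' @param trigger Optional trigger-channel `sampled_signal` (same rate); the
#'   onset is its first rising edge inside the window.
#' @param plateau_level_frac The plateau region is where the torque reaches
#'   this fraction of the window's 95th percentile (default 0.95), trimmed
#'   by `trim_s` at each end so the rise and fall ramps are excluded from
#'   the derivative statistics.
#' @param trim_s Trim applied to each end of the plateau region (default
#'   0.1 s).
#' @param k_detect Detection requires the derivative spike to exceed
#'   `k_detect` times the plateau-region derivative SD (default 5).
#' @return A `stimulus_event`: `onset_idx`, `onset_s`, `source`
#'   (`"trigger_channel"` or `"detected"`).
#' @export
detect_stimulus <- function(signal, window, trigger = NULL,
                            plateau_level_frac = 0.95, trim_s = 0.1,
                            k_detect = 5) {
  stopifnot(inherits(signal, "sampled_signal"))
  s0 <- as.integer(window$start_idx)
  e0 <- as.integer(window$end_idx)
  stopifnot(s0 >= 1, e0 > s0, e0 <= length(signal$samples) + 1L)
  rate <- signal$rate_hz
  if (!is.null(trigger)) {
    stopifnot(inherits(trigger, "sampled_signal"))
    if (trigger$rate_hz != rate) {
      stop("detect_stimulus: trigger rate differs from torque rate",
           call. = FALSE)
    }
    tr <- trigger$samples[s0:(e0 - 1L)]
    lev <- (max(tr) + min(tr)) / 2
    if (max(tr) - min(tr) <= 0 || !any(tr[-1] > lev & tr[-length(tr)] <= lev)) {
      stop("detect_stimulus: no rising edge on trigger channel in window",
           call. = FALSE)
    }
    edge <- which(tr[-1] > lev & tr[-length(tr)] <= lev)[1] + 1L
    onset <- s0 + edge - 1L
    src <- "trigger_channel"
  } else {
    xw <- signal$samples[s0:(e0 - 1L)]
    lev <- plateau_level_frac * stats::quantile(xw, 0.95, names = FALSE)
    sel <- which(xw >= lev)
    lo <- s0 + min(sel) - 1L
    hi <- s0 + max(sel) - 1L
    trim <- round(trim_s * rate)
    if (hi - trim > lo + trim + round(0.5 * rate)) {
      lo <- lo + trim
      hi <- hi - trim
    }
    d <- diff(signal$samples[lo:hi])
    sd_d <- stats::sd(d)
    if (sd_d == 0 || max(d) < k_detect * sd_d) {
      stop("detect_stimulus: no stimulus found (derivative spike below ",
           k_detect, " x plateau derivative SD)", call. = FALSE)
    }
    onset <- lo + which.max(d) - 1L
    src <- "detected"
  }
  structure(
    list(onset_idx = onset,
         onset_s = signal$t0_s + (onset - 1L) / rate, source = src),
    class = "stimulus_event"
  )
}

#' Central activation ratio from a superimposed-stimulation trial
#'
#' The voluntary plateau torque (MVC) is the mean over a short window ending
#' at the stimulation onset; the superimposed twitch is the excess of the
#' post-stimulus maximum over that plateau. The central activation ratio is
#' `CAR = MVC / (MVC + twitch)`, 1 (or 100%) meaning full voluntary
#' activation. Both the fraction and the percent form are returned.
#'
#' @param signal Torque trace in Nm, 20 Hz low-pass filtered and
#'   offset-removed.
#' @param event A `stimulus_event` from [detect_stimulus()].
#' @param plateau_window_s Averaging window ending at onset (default 0.1 s).
#' @param twitch_window_s Search horizon after onset for the twitch maximum
#'   (default 0.3 s).
#' @return A `car_result`: `plateau_nm`, `twitch_nm`, `car_fraction`,
#'   `car_percent`, `clamped` (TRUE when a negative twitch estimate was
#'   clamped to zero).
#' @examples
#' # plateau 96 Nm, post-stimulus max 100 Nm -> CAR = 96/100 = 0.96
#' @export
compute_car <- function(signal, event, plateau_window_s = 0.1,
                        twitch_window_s = 0.3) {
  stopifnot(inherits(signal, "sampled_signal"),
            inherits(event, "stimulus_event"))
  rate <- signal$rate_hz
  onset <- event$onset_idx
  n_plat <- max(1L, round(plateau_window_s * rate))
  if (onset - n_plat < 1L) {
    stop("compute_car: plateau window extends before the start of the signal",
         call. = FALSE)
  }
  plateau <- mean(signal$samples[(onset - n_plat):(onset - 1L)])
  if (plateau <= 0) {
    stop("compute_car: non-positive plateau torque", call. = FALSE)
  }
  hi <- min(length(signal$samples), onset + round(twitch_window_s * rate))
  twitch <- max(signal$samples[onset:hi]) - plateau
  clamped <- FALSE
  if (twitch < 0) {
    twitch <- 0
    clamped <- TRUE
  }
  frac <- plateau / (plateau + twitch)
  structure(
    list(plateau_nm = plateau, twitch_nm = twitch, car_fraction = frac,
         car_percent = 100 * frac, clamped = clamped),
    class = "car_result"
  )
}

#' @export
print.car_result <- function(x, ...) {
  cat(sprintf("<car_result> plateau %.2f Nm, twitch %.2f Nm, CAR %.3f (%.1f%%)%s\n",
              x$plateau_nm, x$twitch_nm, x$car_fraction, x$car_percent,
              if (x$clamped) " [twitch clamped to 0]" else ""))
  invisible(x)
}

#' Resting-twitch intensity criterion (MVC25)
#'
#' Stimulation intensity is adequate when the torque evoked at rest reaches
#' at least 25% of the recorded peak voluntary torque.
#'
#' @param twitch_rest_nm Torque evoked by stimulation at rest (Nm, > 0).
#' @param peak_mvic_nm Recorded peak MVIC torque (Nm, > 0).
#' @return TRUE iff `twitch_rest_nm >= 0.25 * peak_mvic_nm`.
#' @export
check_mvc25 <- function(twitch_rest_nm, peak_mvic_nm) {
  stopifnot(twitch_rest_nm > 0, peak_mvic_nm > 0)
  twitch_rest_nm >= 0.25 * peak_mvic_nm
}

#' Full SNMES pipeline: raw trace to CAR
#'
#' 20 Hz zero-phase low-pass, offset removal (noise-window mean),
#' segmentation, stimulus detection and CAR computation on the (single)
#' stimulated contraction.
#'
#' @param signal Raw torque trace (`"V"` or `"Nm"`).
#' @param params A [segmentation_params()].
#' @param trigger Optional trigger channel.
#' @param conv A [torque_conversion()].
#' @param ... Passed to [compute_car()].
#' @return List with `signal_nm`, `windows`, `event`, `car` (a `car_result`).
#' @export
car_pipeline <- function(signal, params, trigger = NULL,
                         conv = torque_conversion(), ...) {
  stopifnot(inherits(signal, "sampled_signal"))
  s <- apply_filter(signal, filter_spec("butterworth_lowpass", 4, 20))
  if (identical(s$units, "V")) s <- convert_torque(s, conv)
  thr <- compute_threshold(s, params)
  s <- signal_with(s, s$samples - attr(thr, "mu"))
  windows <- segment_contractions(s, as.numeric(thr) - attr(thr, "mu"), params)
  if (nrow(windows) == 0L) {
    stop("car_pipeline: no contraction detected", call. = FALSE)
  }
  w <- windows[which.max(windows$peak_nm), ]
  event <- detect_stimulus(s, w, trigger = trigger)
  car <- compute_car(s, event, ...)
  list(signal_nm = s, windows = windows, event = event, car = car)
}
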