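# Seedable generators for every input modality, with ground truth attached.
# Each generator is a pure function of its parameters and seed: the same
# call regenerates the identical data, and the RNG state of the session is
# left untouched.

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

# Trapezoid profile over a sample grid: 0, ramp up, plateau, ramp down, 0.
trapezoid <- function(n, rate_hz, t_on, rise_s, hold_s, fall_s, amplitude) {
  t <- (seq_len(n) - 1L) / rate_hz
  up <- pmin(pmax((t - t_on) / rise_s, 0), 1)
  down <- pmin(pmax((t - (t_on + rise_s + hold_s)) / fall_s, 0), 1)
  amplitude * (up - down)
}

#' Generate a synthetic MVIC dynamometry trace
#'
#' A sequence of trapezoidal contractions (rise, hold at plateau, fall) with
#' additive Gaussian noise, emulating repeated maximal isometric trials with
#' compressed inter-trial rests. Ground truth (true plateau, per-trial
#' on/off times) is returned alongside.
#'
#' @param n_trials Number of contractions (default 3).
#' @param plateau_nm True plateau torque in Nm (scalar or per-trial vector).
#' @param rise_s,hold_s,fall_s Ramp-up, hold and ramp-down durations
#'   (defaults 1, 3, 1 s).
#' @param gap_s Rest between contractions (default 2 s; the experimental
#'   rest is much longer but carries no information).
#' @param lead_s Contraction-free lead-in used as the noise window
#'   (default 2 s).
#' @param noise_sd Additive Gaussian noise SD in Nm (>= 0).
#' @param rate_hz Sampling rate (default 2000).
#' @param units `"Nm"` (default) or `"V"` (divides by the vendor gain so the
#'   conversion stage is exercised).
#' @param seed RNG seed.
#' @return List: `signal` (a [sampled_signal()]), `truth` (list with
#'   `plateau_nm`, `trial_on_s`, `trial_off_s`, `noise_sd`, `seed`).
#' @export
gen_mvic_trace <- function(n_trials = 3, plateau_nm = 210, rise_s = 1,
                           hold_s = 3, fall_s = 1, gap_s = 2, lead_s = 2,
                           noise_sd = 1, rate_hz = 2000,
                           units = c("Nm", "V"), seed = 1) {
  units <- match.arg(units)
  if (noise_sd < 0) stop("gen_mvic_trace: noise_sd must be >= 0",
                         call. = FALSE)
  plateau_nm <- rep_len(plateau_nm, n_trials)
  trial_len <- rise_s + hold_s + fall_s
  total_s <- lead_s + n_trials * trial_len + n_trials * gap_s
  n <- round(total_s * rate_hz) + 1L
  x <- numeric(n)
  on_s <- lead_s + (seq_len(n_trials) - 1L) * (trial_len + gap_s)
  for (i in seq_len(n_trials)) {
    x <- x + trapezoid(n, rate_hz, on_s[i], rise_s, hold_s, fall_s,
                       plateau_nm[i])
  }
  x <- x + with_seed(seed, stats::rnorm(n, 0, noise_sd))
  if (units == "V") x <- x / torque_conversion()$combined
  list(
    signal = sampled_signal(x, rate_hz, units = units, label = "torque"),
    truth = list(plateau_nm = plateau_nm, trial_on_s = on_s,
                 trial_off_s = on_s + trial_len, noise_sd = noise_sd,
                 rate_hz = rate_hz, seed = seed)
  )
}

# Alpha-function twitch transient: peaks at exactly `amplitude`, tau after
# onset, then decays exponentially; ~5 tau wide.
alpha_bump <- function(t_rel, amplitude, tau_s) {
  out <- numeric(length(t_rel))
  pos <- t_rel >= 0
  out[pos] <- amplitude * (t_rel[pos] / tau_s) * exp(1 - t_rel[pos] / tau_s)
  out
}

#' Generate a synthetic superimposed-stimulation (SNMES) trial
#'
#' One trapezoidal maximal contraction with an evoked-twitch transient
#' (alpha-function bump) added at a known onset on the plateau, plus a
#' trigger channel carrying a rectangular pulse at the stimulation instant.
#'
#' @param plateau_nm True voluntary plateau torque (default 96).
#' @param twitch_nm True twitch amplitude (>= 0; default 4).
#' @param onset_s Stimulation time; default mid-plateau.
#' @param rise_s,hold_s,fall_s,lead_s Contraction timing (defaults 1, 4, 1,
#'   2 s).
#' @param twitch_tau_s Alpha-function time-to-peak (default 0.03 s, giving a
#'   ~150 ms transient).
#' @param noise_sd Gaussian noise SD in Nm.
#' @param rate_hz Sampling rate (default 2000).
#' @param seed RNG seed.
#' @return List: `signal`, `trigger` (both [sampled_signal()]), `truth`
#'   (`plateau_nm`, `twitch_nm`, `onset_s`, `car_fraction` =
#'   plateau/(plateau+twitch), `seed`).
#' @export
gen_snmes_trace <- function(plateau_nm = 96, twitch_nm = 4, onset_s = NULL,
                            rise_s = 1, hold_s = 4, fall_s = 1, lead_s = 2,
                            twitch_tau_s = 0.03, noise_sd = 0.96,
                            rate_hz = 2000, seed = 1) {
  if (twitch_nm < 0) stop("gen_snmes_trace: twitch_nm must be >= 0",
                          call. = FALSE)
  if (is.null(onset_s)) onset_s <- lead_s + rise_s + hold_s / 2
  if (onset_s < lead_s + rise_s || onset_s > lead_s + rise_s + hold_s) {
    stop("gen_snmes_trace: onset must lie on the plateau", call. = FALSE)
  }
  total_s <- lead_s + rise_s + hold_s + fall_s + 1
  n <- round(total_s * rate_hz) + 1L
  t <- (seq_len(n) - 1L) / rate_hz
  x <- trapezoid(n, rate_hz, lead_s, rise_s, hold_s, fall_s, plateau_nm)
  x <- x + alpha_bump(t - onset_s, twitch_nm, twitch_tau_s)
  x <- x + with_seed(seed, stats::rnorm(n, 0, noise_sd))
  trig <- as.numeric(t >= onset_s & t < onset_s + 0.010) * 5
  list(
    signal = sampled_signal(x, rate_hz, units = "Nm", label = "torque"),
    trigger = sampled_signal(trig, rate_hz, units = "V", label = "stim"),
    truth = list(plateau_nm = plateau_nm, twitch_nm = twitch_nm,
                 onset_s = onset_s,
                 car_fraction = plateau_nm / (plateau_nm + twitch_nm),
                 noise_sd = noise_sd, seed = seed)
  )
}

#' Generate synthetic surface EMG with known activation profiles
#'
#' Each channel is band-limited (20-300 Hz) Gaussian noise amplitude-
#' modulated by its activation profile, optionally contaminated with a 50 Hz
#' mains sinusoid. The carrier is calibrated so the rectified mean of a
#' unit-activation carrier is 1.0: the linear envelope of the generated
#' signal reads directly in activation units, and the profile itself is the
#' ground-truth envelope.
#'
#' @param profiles Named list of activation profiles, each either a numeric
#'   vector of length `n` or a function of time in seconds, with values in
#'   `[0, 1]`.
#' @param duration_s Trace duration (default 10 s).
#' @param rate_hz Sampling rate (default 2000).
#' @param mains_amp Amplitude of added 50 Hz contamination (default 0).
#' @param band_hz Carrier band (default `c(20, 300)`).
#' @param seed RNG seed.
#' @return List: `signals` (named list of [sampled_signal()], units mV),
#'   `truth` (`profiles` as evaluated vectors, `mains_amp`, `seed`).
#' @export
gen_emg <- function(profiles, duration_s = 10, rate_hz = 2000,
                    mains_amp = 0, band_hz = c(20, 300), seed = 1) {
  n <- round(duration_s * rate_hz) + 1L
  t <- (seq_len(n) - 1L) / rate_hz
  prof_v <- lapply(profiles, function(p) {
    v <- if (is.function(p)) p(t) else rep_len(as.numeric(p), n)
    if (any(v < 0 | v > 1)) {
      stop("gen_emg: activation profiles must lie in [0, 1]", call. = FALSE)
    }
    v
  })
  bp <- signal::butter(4, band_hz / (rate_hz / 2), type = "pass")
  signals <- with_seed(seed, {
    lapply(prof_v, function(v) {
      carrier <- zphase_pass(bp$b, bp$a, stats::rnorm(n), 6L,
                             as.integer(ceiling(4 * rate_hz / band_hz[1])))
      carrier <- carrier / stats::sd(carrier)
      x <- sqrt(pi / 2) * v * carrier + mains_amp * sin(2 * pi * 50 * t)
      sampled_signal(x, rate_hz, units = "mV")
    })
  })
  for (nm in names(signals)) signals[[nm]]$label <- nm
  list(signals = signals,
       truth = list(profiles = prof_v, mains_amp = mains_amp, seed = seed))
}

# Smooth zero-mean Gaussian deviation along the cycle grid: white noise
# convolved with a Gaussian kernel (correlation length ~corr_pct percent
# points), rescaled to the requested SD. Gait-curve trial variability is
# band-limited, not white per grid point.
smooth_cycle_noise <- function(n, sd, corr_pct = 3) {
  if (sd == 0) return(numeric(n))
  half <- ceiling(3 * corr_pct)
  k <- exp(-((-half):half)^2 / (2 * corr_pct^2))
  k <- k / sum(k)
  w <- stats::rnorm(n + 2 * half)
  z <- stats::filter(w, k, method = "convolution", sides = 2)
  z <- z[(half + 1L):(half + n)]
  z / sqrt(sum(k^2)) * sd
}

# Normalized [0, 1] sagittal shape templates over the percent grid.
gait_shape <- function(joint, pct = 0:100) {
  raw <- switch(joint,
    knee = 0.28 * exp(-(pct - 12)^2 / (2 * 7^2)) +
      exp(-(pct - 70)^2 / (2 * 12^2)),
    hip = (1 + cos(2 * pi * (pct - 90) / 100)) / 2,
    ankle = 0.55 * exp(-(pct - 45)^2 / (2 * 12^2)) -
      exp(-(pct - 65)^2 / (2 * 5^2)) + 0.4 * exp(-(pct - 5)^2 / (2 * 8^2)),
    stop("gait_shape: unknown joint ", joint, call. = FALSE)
  )
  (raw - min(raw)) / (max(raw) - min(raw))
}

#' Generate templated gait-cycle curves with known ROM and JCF peaks
#'
#' Smooth sagittal joint-angle curves with exactly the requested range of
#' motion, and a knee contact-force curve (in body weight) whose two
#' characteristic peaks take exactly the requested values at the requested
#' cycle locations, plus per-trial Gaussian noise.
#'
#' @param rom_deg Named vector of sagittal ROM per joint (defaults
#'   hip 40.69, knee 64.07, ankle 31.44 deg).
#' @param angle_offset_deg Named vector of curve minima (default hip -10,
#'   knee 0, ankle -15).
#' @param jcf_peaks_bw First and second contact-force peak values (default
#'   `c(3.08, 3.14)` BW).
#' @param jcf_locs_pct Peak locations in percent of cycle (default
#'   `c(25, 55)`).
#' @param n_trials Trials to generate (default 10).
#' @param noise_frac Per-trial deviation SD as a fraction of each curve's
#'   scale (ROM for angles, maximal force for the JCF; default 0.01).
#'   Deviations are smooth along the cycle (Gaussian, ~3%-of-cycle
#'   correlation length), as band-limited simulation outputs are.
#' @param seed RNG seed.
#' @return List: `trials` (each with `angles`, a named list of
#'   [gait_cycle_series()], and `jcf`), `truth` (`rom_deg`, `jcf_peaks_bw`,
#'   `jcf_locs_pct`, `seed`).
#' @export
gen_gait_curves <- function(rom_deg = c(hip = 40.69, knee = 64.07,
                                        ankle = 31.44),
                            angle_offset_deg = c(hip = -10, knee = 0,
                                                 ankle = -15),
                            jcf_peaks_bw = c(3.08, 3.14),
                            jcf_locs_pct = c(25, 55), n_trials = 10,
                            noise_frac = 0.01, seed = 1) {
  stopifnot(all(rom_deg >= 0), all(jcf_peaks_bw > 0))
  pct <- 0:100
  base <- 0.5
  sg <- 5
  g1 <- exp(-(pct - jcf_locs_pct[1])^2 / (2 * sg^2))
  g2 <- exp(-(pct - jcf_locs_pct[2])^2 / (2 * sg^2))
  cross <- exp(-(diff(jcf_locs_pct))^2 / (2 * sg^2))
  amp <- solve(matrix(c(1, cross, cross, 1), 2),
               jcf_peaks_bw - base)
  jcf_clean <- base + amp[1] * g1 + amp[2] * g2
  angles_clean <- lapply(names(rom_deg), function(j) {
    angle_offset_deg[[j]] + rom_deg[[j]] * gait_shape(j, pct)
  })
  names(angles_clean) <- names(rom_deg)
  trials <- with_seed(seed, {
    lapply(seq_len(n_trials), function(k) {
      angles <- lapply(names(rom_deg), function(j) {
        v <- angles_clean[[j]] +
          smooth_cycle_noise(101, noise_frac * rom_deg[[j]])
        gait_cycle_series(v, "angle_deg", joint = j,
                          trial_id = sprintf("trial%02d", k))
      })
      names(angles) <- names(rom_deg)
      jcf <- gait_cycle_series(
        jcf_clean + smooth_cycle_noise(101, noise_frac * max(jcf_clean)),
        "jcf_bw", joint = "knee", trial_id = sprintf("trial%02d", k))
      list(angles = angles, jcf = jcf)
    })
  })
  list(trials = trials,
       truth = list(rom_deg = rom_deg, jcf_peaks_bw = jcf_peaks_bw,
                    jcf_locs_pct = jcf_locs_pct, noise_frac = noise_frac,
                    seed = seed))
}

#' Generate a straight-line pelvis trajectory with gait-like sway
#'
#' @param speed_m_s Progression speed (default 1.25).
#' @param duration_s Duration (default 5 s).
#' @param rate_hz Sampling rate (default 100).
#' @param sway_m Lateral sway amplitude (default 0.03).
#' @param sway_hz Sway frequency (default 0.9, about one stride).
#' @param bob_m Vertical oscillation amplitude (default 0.02).
#' @return List: `positions` (n x 3, metres; x = progression), `time_s`,
#'   `truth` (`speed_m_s`).
#' @export
gen_pelvis_trajectory <- function(speed_m_s = 1.25, duration_s = 5,
                                  rate_hz = 100, sway_m = 0.03,
                                  sway_hz = 0.9, bob_m = 0.02) {
  t <- seq(0, duration_s, by = 1 / rate_hz)
  pos <- cbind(speed_m_s * t,
               sway_m * sin(2 * pi * sway_hz * t),
               0.95 + bob_m * sin(2 * pi * 2 * sway_hz * t))
  list(positions = pos, time_s = t, truth = list(speed_m_s = speed_m_s))
}
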