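#' A quantity resampled to the 0-100% gait-cycle grid
#'
#' @param values Numeric vector of exactly 101 samples (percent grid
#'   0, 1, ..., 100).
#' @param quantity One of `"angle_deg"`, `"moment_nm"`, `"moment_nm_per_kg"`,
#'   `"jcf_n"`, `"jcf_bw"`.
#' @param joint `"hip"`, `"knee"`, `"ankle"` or NA.
#' @param side `"left"`, `"right"` or NA.
#' @param trial_id Free-text trial identifier.
#' @return A `gait_cycle_series` object.
#' @export
gait_cycle_series <- function(values, quantity, joint = NA_character_,
                              side = NA_character_,
                              trial_id = NA_character_) {
  values <- as.numeric(values)
  if (length(values) != 101L || !all(is.finite(values))) {
    stop("gait_cycle_series: exactly 101 finite samples required",
         call. = FALSE)
  }
  quantity <- match.arg(quantity, c("angle_deg", "moment_nm",
                                    "moment_nm_per_kg", "jcf_n", "jcf_bw"))
  structure(
    list(values = values, percent = 0:100, quantity = quantity,
         joint = joint, side = side, trial_id = trial_id),
    class = "gait_cycle_series"
  )
}

#' @export
print.gait_cycle_series <- function(x, ...) {
  cat(sprintf("<gait_cycle_series> %s %s: 101 points, range [%.3f, %.3f]\n",
              ifelse(is.na(x$joint), "", x$joint), x$quantity,
              min(x$values), max(x$values)))
  invisible(x)
}

#' Normalize simulation outputs by subject size
#'
#' Joint moments are divided by body mass (Nm/kg); joint contact forces by
#' body weight (`mass * g`, unit BW); joint angles pass through unchanged.
#'
#' @param series A [gait_cycle_series()].
#' @param subject_mass_kg Body mass in kg (> 0).
#' @param g Gravitational acceleration (default 9.81 m/s^2).
#' @return The normalized series with its `quantity` retagged.
#' @export
normalize_outputs <- function(series, subject_mass_kg, g = 9.81) {
  stopifnot(inherits(series, "gait_cycle_series"), subject_mass_kg > 0)
  switch(series$quantity,
    angle_deg = series,
    moment_nm = {
      series$values <- series$values / subject_mass_kg
      series$quantity <- "moment_nm_per_kg"
      series
    },
    jcf_n = {
      series$values <- series$values / (subject_mass_kg * g)
      series$quantity <- "jcf_bw"
      series
    },
    stop(sprintf("normalize_outputs: cannot normalize quantity '%s'",
                 series$quantity), call. = FALSE)
  )
}

#' Resample one gait cycle onto the 101-point percent grid
#'
#' Linear interpolation of a time-indexed quantity onto 101 equally spaced
#' points spanning one gait cycle (0-100% in 1% steps); endpoint values are
#' preserved exactly. Linear (not spline) interpolation avoids overshoot on
#' force curves.
#'
#' @param time_s Sample times (seconds, increasing).
#' @param values Sample values (same length).
#' @param events `c(start, end)` of the cycle in seconds; must lie within
#'   the sampled support.
#' @param quantity,joint,side,trial_id Metadata for the output series.
#' @return A [gait_cycle_series()].
#' @export
resample_cycle <- function(time_s, values, events, quantity = "angle_deg",
                           joint = NA_character_, side = NA_character_,
                           trial_id = NA_character_) {
  stopifnot(length(time_s) == length(values), length(events) == 2L)
  if (events[2] <= events[1]) {
    stop("resample_cycle: cycle end must follow cycle start", call. = FALSE)
  }
  if (events[1] < min(time_s) || events[2] > max(time_s)) {
    stop("resample_cycle: cycle events outside the sampled time support",
         call. = FALSE)
  }
  grid <- seq(events[1], events[2], length.out = 101L)
  out <- stats::approx(time_s, values, xout = grid, method = "linear")$y
  gait_cycle_series(out, quantity = quantity, joint = joint, side = side,
                    trial_id = trial_id)
}

#' Heel-strike detection from a vertical ground-reaction force channel
#'
#' Rising crossings of a force threshold (default 20 N) mark foot contact;
#' consecutive crossings delimit gait cycles.
#'
#' @param time_s,force_n Vertical GRF samples.
#' @param threshold_n Contact threshold (default 20 N).
#' @return Numeric vector of heel-strike times (s).
#' @export
detect_heel_strikes <- function(time_s, force_n, threshold_n = 20) {
  stopifnot(length(time_s) == length(force_n))
  above <- force_n > threshold_n
  idx <- which(above[-1] & !above[-length(above)]) + 1L
  time_s[idx]
}

#' Sagittal range of motion of a joint-angle cycle
#'
#' @param curve A [gait_cycle_series()] with quantity `"angle_deg"`.
#' @return `max - min` over the cycle, in degrees.
#' @export
sagittal_rom <- function(curve) {
  stopifnot(inherits(curve, "gait_cycle_series"))
  if (curve$quantity != "angle_deg") {
    stop("sagittal_rom: requires an angle series", call. = FALSE)
  }
  max(curve$values) - min(curve$values)
}

#' Walking speed from a pelvis trajectory
#'
#' Displacement along the progression axis (the net displacement direction)
#' divided by elapsed time over a steady-state window; lateral sway is
#' orthogonal to the progression axis and does not bias the estimate.
#'
#' @param positions n x 3 matrix of pelvis positions (m).
#' @param time_s Sample times (s, length n).
#' @param window `c(t_start, t_end)` of the steady-state stretch; must span
#'   at least 1 s. Default: the whole trajectory.
#' @return Speed in m/s.
#' @export
walking_speed <- function(positions, time_s, window = range(time_s)) {
  positions <- as.matrix(positions)
  stopifnot(ncol(positions) == 3L, nrow(positions) == length(time_s))
  if (diff(window) < 1) {
    stop("walking_speed: steady-state window must span at least 1 s",
         call. = FALSE)
  }
  sel <- time_s >= window[1] & time_s <= window[2]
  if (sum(sel) < 2L) {
    stop("walking_speed: window contains fewer than 2 samples", call. = FALSE)
  }
  p <- positions[sel, , drop = FALSE]
  t <- time_s[sel]
  disp <- p[nrow(p), ] - p[1, ]
  sqrt(sum(disp^2)) / (t[length(t)] - t[1])
}

#' Characteristic first and second peaks of a knee contact-force cycle
#'
#' The first peak is the maximum over the early-stance window and the second
#' over the late-stance/push-off window (defaults 0-50% and 40-70% of the
#' cycle). A curve without two distinct local maxima is flagged unimodal.
#'
#' @param curve A [gait_cycle_series()] with quantity `"jcf_bw"`.
#' @param window1,window2 Percent windows for the two peaks.
#' @return List: `peak1_bw`, `peak2_bw`, `loc1_pct`, `loc2_pct`, `unimodal`.
#' @export
jcf_peaks <- function(curve, window1 = c(0, 50), window2 = c(40, 70)) {
  stopifnot(inherits(curve, "gait_cycle_series"))
  if (curve$quantity != "jcf_bw") {
    stop("jcf_peaks: requires a body-weight-normalized contact-force series",
         call. = FALSE)
  }
  v <- curve$values
  pct <- curve$percent
  s1 <- pct >= window1[1] & pct < window1[2]
  s2 <- pct >= window2[1] & pct <= window2[2]
  i1 <- which(s1)[which.max(v[s1])]
  i2 <- which(s2)[which.max(v[s2])]
  d <- diff(v)
  n_local_max <- sum(d[-length(d)] > 0 & d[-1] <= 0)
  list(peak1_bw = v[i1], peak2_bw = v[i2],
       loc1_pct = pct[i1], loc2_pct = pct[i2],
       unimodal = n_local_max < 2L)
}

#' Point-wise two-group comparison along the gait cycle
#'
#' Two-sample t statistic at each of the 101 cycle points, with family-wise
#' inference by cluster-mass permutation of group labels: supra-threshold
#' clusters (|t| above the pointwise t critical value at `alpha`) are scored
#' by the sum of |t| and compared against the permutation distribution of
#' the maximal cluster mass. Because both tails are examined, each cluster
#' is declared significant at `alpha / 2` (the usual two-sided correction
#' for cluster-permutation tests), which guarantees a family-wise error
#' rate at or below `alpha` rather than exactly at it. This is a
#' permutation-based analogue of 1-D statistical parametric mapping and is
#' labelled as such, not as a random-field-theory implementation.
#'
#' @param group_a,group_b Matrices (subjects/trials x 101) or lists of
#'   [gait_cycle_series()] (>= 2 curves per group).
#' @param n_perm Number of label permutations (default 1000).
#' @param alpha Significance level (default 0.05).
#' @param seed Optional RNG seed for the permutations.
#' @return List: `t` (length-101 statistic), `t_threshold`, `clusters`
#'   (data.frame `start_pct`, `end_pct`, `mass`, `p`, `significant`),
#'   `df`, `n_perm`, `degenerate` (points where variance vanished and the
#'   statistic was set to 0).
#' @export
compare_groups_pointwise <- function(group_a, group_b, n_perm = 1000,
                                     alpha = 0.05, seed = NULL) {
  as_mat <- function(g) {
    if (is.list(g) && !is.matrix(g)) {
      g <- do.call(rbind, lapply(g, function(x) {
        if (inherits(x, "gait_cycle_series")) x$values else as.numeric(x)
      }))
    }
    as.matrix(g)
  }
  a <- as_mat(group_a)
  b <- as_mat(group_b)
  stopifnot(ncol(a) == 101L, ncol(b) == 101L)
  na <- nrow(a)
  nb <- nrow(b)
  if (na < 2L || nb < 2L) {
    stop("compare_groups_pointwise: need >= 2 curves per group",
         call. = FALSE)
  }
  x <- rbind(a, b)
  n <- na + nb
  df <- n - 2L
  t_thr <- stats::qt(1 - alpha / 2, df)

  tstat <- function(idx_a) {
    is_a <- logical(n)
    is_a[idx_a] <- TRUE
    ma <- colMeans(x[is_a, , drop = FALSE])
    mb <- colMeans(x[!is_a, , drop = FALSE])
    va <- colSums(x[is_a, , drop = FALSE]^2) - na * ma^2
    vb <- colSums(x[!is_a, , drop = FALSE]^2) - nb * mb^2
    sp2 <- (va + vb) / df
    se <- sqrt(sp2 * (1 / na + 1 / nb))
    t <- (ma - mb) / se
    t[!is.finite(t)] <- 0
    t
  }
  clusters_of <- function(t) {
    above <- abs(t) > t_thr
    if (!any(above)) return(NULL)
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values
    data.frame(start = starts[keep], end = ends[keep],
               mass = vapply(which(keep), function(i) {
                 sum(abs(t[(ends[i] - r$lengths[i] + 1L):ends[i]]))
               }, numeric(1)))
  }

  t_obs <- tstat(seq_len(na))
  degenerate <- which(t_obs == 0 &
                        apply(x, 2, function(col) stats::var(col) == 0))
  cl <- clusters_of(t_obs)

  if (!is.null(seed)) set.seed(seed)
  max_mass <- numeric(n_perm)
  for (p in seq_len(n_perm)) {
    idx <- sample.int(n, na)
    cp <- clusters_of(tstat(idx))
    max_mass[p] <- if (is.null(cp)) 0 else max(cp$mass)
  }

  if (is.null(cl)) {
    cl_out <- data.frame(start_pct = numeric(), end_pct = numeric(),
                         mass = numeric(), p = numeric(),
                         significant = logical())
  } else {
    pvals <- vapply(cl$mass, function(m) {
      (1 + sum(max_mass >= m)) / (1 + n_perm)
    }, numeric(1))
    cl_out <- data.frame(start_pct = cl$start - 1L, end_pct = cl$end - 1L,
                         mass = cl$mass, p = pvals,
                         significant = pvals <= alpha / 2)
  }
  list(t = t_obs, t_threshold = t_thr, clusters = cl_out, df = df,
       n_perm = n_perm, degenerate = degenerate)
}
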