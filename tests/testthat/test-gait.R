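test_that("mass and body-weight normalization follow the quantity", {
  jcf <- gait_cycle_series(rep(2060.1, 101), "jcf_n", joint = "knee")
  bw <- normalize_outputs(jcf, 70)
  expect_identical(bw$quantity, "jcf_bw")
  expect_equal(bw$values, rep(3, 101), tolerance = 1e-6)
  mom <- gait_cycle_series(rep(70, 101), "moment_nm")
  expect_equal(normalize_outputs(mom, 70)$values, rep(1, 101))
  ang <- gait_cycle_series(sin(0:100 / 10), "angle_deg")
  expect_identical(normalize_outputs(ang, 70)$values, ang$values)
  expect_error(normalize_outputs(bw, 70), "cannot normalize")
  # homogeneity: doubling mass halves the normalized values
  half <- normalize_outputs(jcf, 140)
  expect_equal(half$values, bw$values / 2)
})

test_that("cycle resampling gives exactly 101 points with preserved endpoints", {
  t <- seq(0, 1.2, by = 0.004)
  ramp <- 10 * (t - 0.1) / 1
  g <- resample_cycle(t, ramp, events = c(0.1, 1.1))
  expect_length(g$values, 101)
  expect_identical(g$percent, 0:100)
  expect_equal(g$values, seq(0, 10, by = 0.1), tolerance = 1e-10)
  # smooth curve: interpolation error below 1e-3 with 250 input samples
  t2 <- seq(0, 1, length.out = 250)
  s <- resample_cycle(t2, sin(2 * pi * t2), events = c(0, 1))
  expect_lt(max(abs(s$values - sin(2 * pi * (0:100) / 100))), 1e-3)
  expect_error(resample_cycle(t2, sin(t2), events = c(-0.1, 0.9)),
               "outside")
  expect_error(gait_cycle_series(1:100, "angle_deg"), "101")
})

test_that("resampling preserves ROM within interpolation tolerance", {
  t <- seq(0, 1, length.out = 150)
  v <- 30 + 20 * sin(2 * pi * t) + 5 * cos(4 * pi * t)
  g <- resample_cycle(t, v, events = c(0, 1), quantity = "angle_deg")
  expect_equal(sagittal_rom(g), max(v) - min(v), tolerance = 0.005)
})

test_that("sagittal ROM is max minus min, offset-invariant", {
  flat <- gait_cycle_series(rep(12, 101), "angle_deg")
  expect_identical(sagittal_rom(flat), 0)
  v <- 5 + 64 * gait_cycle_series(rep(0, 101), "angle_deg")$percent / 100
  curve <- gait_cycle_series(v, "angle_deg")
  expect_equal(sagittal_rom(curve), 64)
  shifted <- gait_cycle_series(v + 17.3, "angle_deg")
  expect_equal(sagittal_rom(shifted), sagittal_rom(curve))
  expect_error(sagittal_rom(gait_cycle_series(rep(1, 101), "jcf_bw")),
               "angle")
})

test_that("walking speed projects onto the progression axis", {
  g <- gen_pelvis_trajectory(speed_m_s = 1.25, duration_s = 5, sway_m = 0)
  expect_equal(walking_speed(g$positions, g$time_s), 1.25, tolerance = 1e-9)
  gs <- gen_pelvis_trajectory(speed_m_s = 1.25, duration_s = 5,
                              sway_m = 0.05)
  expect_equal(walking_speed(gs$positions, gs$time_s), 1.25,
               tolerance = 0.0125)
  still <- matrix(rep(c(1, 2, 3), each = 200), ncol = 3)
  expect_equal(walking_speed(still, seq(0, 1.99, by = 0.01)), 0)
  expect_error(walking_speed(still, seq(0, 1.99, by = 0.01),
                             window = c(0, 0.5)), "at least 1 s")
})

test_that("JCF peaks are read from the stance windows; unimodal curves flagged", {
  g <- gen_gait_curves(jcf_peaks_bw = c(3.1, 2.6), jcf_locs_pct = c(25, 55),
                       n_trials = 1, noise_frac = 0, seed = 1)
  pk <- jcf_peaks(g$trials[[1]]$jcf)
  expect_equal(pk$peak1_bw, 3.1, tolerance = 1e-6)
  expect_equal(pk$peak2_bw, 2.6, tolerance = 1e-6)
  expect_equal(pk$loc1_pct, 25)
  expect_equal(pk$loc2_pct, 55)
  expect_false(pk$unimodal)
  expect_lt(pk$loc1_pct, pk$loc2_pct)
  single <- gait_cycle_series(0.5 + 2 * exp(-((0:100) - 30)^2 / 50),
                              "jcf_bw")
  expect_true(jcf_peaks(single)$unimodal)
  flat <- gait_cycle_series(rep(2, 101), "jcf_bw")
  pf <- jcf_peaks(flat)
  expect_true(pf$unimodal)
  expect_equal(pf$peak1_bw, 2)
  expect_equal(pf$peak2_bw, 2)
})

test_that("heel strikes are detected at rising 20 N crossings", {
  t <- seq(0, 3, by = 0.005)
  f <- 800 * pmax(0, sin(2 * pi * (t - 0.2) / 1.1))  # stance bumps
  hs <- detect_heel_strikes(t, f)
  expect_length(hs, 3)
  expect_equal(hs[2] - hs[1], 1.1, tolerance = 0.02)
})

test_that("identical groups produce no significant clusters", {
  set.seed(42)
  base <- sin(2 * pi * (0:100) / 100)
  mk_group <- function(n) t(replicate(n, base + rnorm(101, 0, 0.3)))
  res <- compare_groups_pointwise(mk_group(10), mk_group(10), n_perm = 500,
                                  seed = 1)
  expect_false(any(res$clusters$significant))
})

test_that("a strong localized offset is detected over its interval", {
  set.seed(43)
  base <- sin(2 * pi * (0:100) / 100)
  sd0 <- 0.3
  a <- t(replicate(10, base + rnorm(101, 0, sd0)))
  shift <- ifelse(0:100 >= 20 & 0:100 <= 40, 10 * sd0, 0)
  b <- t(replicate(10, base + shift + rnorm(101, 0, sd0)))
  res <- compare_groups_pointwise(a, b, n_perm = 500, seed = 2)
  sig <- res$clusters[res$clusters$significant, ]
  expect_gte(nrow(sig), 1)
  # the significant cluster covers approximately the offset interval
  expect_lte(min(sig$start_pct), 23)
  expect_gte(max(sig$end_pct), 37)
})

test_that("degenerate zero-variance points yield a zero statistic with a flag", {
  a <- matrix(rnorm(5 * 101), 5, 101)
  b <- matrix(rnorm(5 * 101), 5, 101)
  a[, 7] <- 1
  b[, 7] <- 1
  res <- compare_groups_pointwise(a, b, n_perm = 50, seed = 3)
  expect_identical(res$t[7], 0)
  expect_true(7 %in% res$degenerate)
})
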