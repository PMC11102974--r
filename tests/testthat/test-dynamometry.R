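test_that("torque conversion applies the vendor chain", {
  conv <- torque_conversion()
  expect_equal(conv$combined, 138.834, tolerance = 5e-4 / 138.834)
  one_v <- sampled_signal(rep(1, 300), 2000, "V")
  expect_equal(convert_torque(one_v)$samples, rep(138.834, 300),
               tolerance = 5e-6)
  expect_equal(convert_torque(signal_with(one_v, rep(0, 300)))$samples,
               rep(0, 300))
  half <- convert_torque(signal_with(one_v, rep(0.5, 300)))
  expect_equal(half$samples[1], 0.5 * 102.4 * 1.3558)  # 69.41696
  expect_identical(half$units, "Nm")
  nm <- sampled_signal(1:10, 100, "Nm")
  expect_error(convert_torque(nm), "expected units 'V'")
})

test_that("noise threshold is mu + k * sigma of the noise window", {
  z <- as.numeric(scale(rnorm(200)))  # exactly mean 0, sd 1
  s <- sampled_signal(c(z, rep(10, 50)), 100)
  p <- segmentation_params(c(1, 200))
  expect_equal(as.numeric(compute_threshold(s, p)), 3)
  s2 <- sampled_signal(c(2 + 0.5 * z, rep(10, 50)), 100)
  expect_equal(as.numeric(compute_threshold(s2, p)), 3.5)
  # zero-variance window: threshold degenerates to the mean, with a message
  s3 <- sampled_signal(c(rep(1.5, 200), rep(10, 50)), 100)
  expect_message(thr <- compute_threshold(s3, p), "variance")
  expect_equal(as.numeric(thr), 1.5)
  expect_error(compute_threshold(s, segmentation_params(c(1, 50))),
               "at least 100")
})

test_that("a warm-up train of 8 bursts yields exactly 8 windows", {
  g <- gen_mvic_trace(n_trials = 8, plateau_nm = 100, rise_s = 0.5,
                      hold_s = 3, fall_s = 0.5, gap_s = 2, noise_sd = 2,
                      seed = 21)
  res <- mvic_pipeline(g$signal, std_seg_params())
  expect_identical(nrow(res$windows), 8L)
  expect_true(all(diff(res$windows$start_idx) > 0))
  expect_true(all(res$windows$end_idx[-8] <= res$windows$start_idx[-1]))
})

test_that("an all-noise trace yields zero windows, not an error", {
  set.seed(5)
  s <- sampled_signal(rnorm(10000), 2000, "Nm")
  f <- apply_filter(s, filter_spec("butterworth_lowpass", 4, 20))
  p <- std_seg_params()
  w <- segment_contractions(f, compute_threshold(f, p), p)
  expect_identical(nrow(w), 0L)
})

test_that("bursts closer than min_gap_s are merged", {
  fs <- 2000
  n <- 16000
  x <- numeric(n)
  x[4001:6000] <- 100   # 1 s burst
  x[6401:8400] <- 100   # 0.2 s gap, below min_gap 0.5 s
  x <- x + 0.01 * as.numeric(scale(rnorm(n)))
  s <- sampled_signal(x, fs, "Nm")
  p <- segmentation_params(c(1, 3600), min_gap_s = 0.5)
  w <- segment_contractions(s, 50, p)
  expect_identical(nrow(w), 1L)
  expect_lte(w$start_idx, 4001L)
  expect_gte(w$end_idx, 8400L)
})

test_that("MVIC is the max smoothed peak; third-trial rule raises the retest flag", {
  p <- std_seg_params()
  g1 <- gen_mvic_trace(plateau_nm = c(200, 210, 205), noise_sd = 0.5,
                       seed = 2)
  r1 <- mvic_pipeline(g1$signal, p)
  expect_equal(r1$mvic$mvic_nm, max(r1$mvic$per_trial_peaks_nm))
  expect_equal(r1$mvic$mvic_nm, 210, tolerance = 0.02)
  expect_false(r1$mvic$retest_flag)
  # 216 > 1.05 * 205 and > 1.05 * 200: retest
  g2 <- gen_mvic_trace(plateau_nm = c(200, 205, 216), noise_sd = 0.5,
                       seed = 2)
  r2 <- mvic_pipeline(g2$signal, p)
  expect_true(r2$mvic$retest_flag)
  expect_equal(r2$mvic$mvic_nm, 216, tolerance = 0.02)
  g3 <- gen_mvic_trace(n_trials = 1, plateau_nm = 150, noise_sd = 0.5,
                       seed = 2)
  r3 <- mvic_pipeline(g3$signal, p)
  expect_length(r3$mvic$per_trial_peaks_nm, 1)
  expect_equal(r3$mvic$mvic_nm, 150, tolerance = 0.02 * 150)
  expect_error(extract_mvic(r3$windows[0, ], g3$signal), "no contraction")
})

test_that("flexion trials are analyzed on sign-inverted torque", {
  g <- gen_mvic_trace(plateau_nm = 180, noise_sd = 1, seed = 9)
  neg <- signal_with(g$signal, -g$signal$samples)
  r <- mvic_pipeline(neg, std_seg_params(), task = "flexion")
  expect_equal(r$mvic$mvic_nm, 180, tolerance = 0.02 * 180)
})

test_that("2 Hz smoothing never exceeds the raw in-window maximum on noisy trials", {
  for (seed in 1:10) {
    g <- gen_mvic_trace(noise_sd = 2, seed = seed)
    res <- mvic_pipeline(g$signal, std_seg_params())
    raw_peaks <- vapply(seq_len(nrow(res$windows)), function(i) {
      max(g$signal$samples[res$windows$start_idx[i]:(res$windows$end_idx[i] - 1)])
    }, numeric(1))
    expect_true(all(res$mvic$per_trial_peaks_nm <= raw_peaks))
  }
})

test_that("segmentation count matches generator ground truth across seeds", {
  for (seed in 1:10) {
    g <- gen_mvic_trace(n_trials = 3, plateau_nm = 210, noise_sd = 2,
                        seed = seed)
    res <- mvic_pipeline(g$signal, std_seg_params())
    expect_identical(nrow(res$windows), 3L)
    # detected onsets near the true trial starts
    expect_equal(res$windows$start_idx / 2000, g$truth$trial_on_s,
                 tolerance = 0.2)
  }
})
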