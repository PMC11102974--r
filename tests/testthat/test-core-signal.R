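test_that("sampled_signal validates its contract", {
  expect_error(sampled_signal(numeric(0), 100), "non-empty")
  expect_error(sampled_signal(c(1, NA), 100), "finite")
  expect_error(sampled_signal(1:10, 0), "positive")
  s <- sampled_signal(1:5, 10, units = "Nm", t0_s = 1)
  expect_equal(signal_duration(s), 0.4)
  expect_equal(signal_times(s), 1 + (0:4) / 10)
})

test_that("lowpass passes DC unchanged and highpass blocks it", {
  s <- sampled_signal(rep(5, 4000), 2000, "Nm")
  lp <- apply_filter(s, filter_spec("butterworth_lowpass", 4, 20))
  expect_equal(lp$samples, rep(5, 4000), tolerance = 1e-8)
  hp <- apply_filter(s, filter_spec("chebyshev_highpass", 5, 20))
  expect_lt(max(abs(hp$samples)), 1e-8)
})

test_that("zero-phase lowpass preserves an in-band sinusoid's amplitude and phase", {
  fs <- 2000
  t <- seq(0, 4, by = 1 / fs)
  x <- sin(2 * pi * 1 * t)
  y <- apply_filter(sampled_signal(x, fs), filter_spec("butterworth_lowpass", 4, 20))
  core <- 2000:6000
  # analytic zero-phase Butterworth gain |H|^2 = (1 + (f/fc)^(2n))^-1, f/fc = 0.05
  gain <- 1 / (1 + 0.05^8)
  expect_equal(max(y$samples[core]), gain, tolerance = 1e-3)
  # zero group delay: peak cross-correlation at lag 0
  cc <- stats::ccf(y$samples, x, lag.max = 20, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
})

test_that("filter application is linear", {
  fs <- 2000
  set.seed(11)
  x <- rnorm(4000)
  y <- rnorm(4000)
  spec <- filter_spec("butterworth_lowpass", 4, 20)
  fx <- apply_filter(sampled_signal(x, fs), spec)$samples
  fy <- apply_filter(sampled_signal(y, fs), spec)$samples
  fxy <- apply_filter(sampled_signal(2.3 * x - 1.7 * y, fs), spec)$samples
  expect_equal(fxy, 2.3 * fx - 1.7 * fy, tolerance = 1e-9)
})

test_that("zero-phase filtering of an even-symmetric pulse stays even-symmetric", {
  fs <- 2000
  n <- 4001
  t <- (seq_len(n) - (n + 1) / 2) / fs
  pulse <- exp(-t^2 / (2 * 0.05^2))
  for (spec in list(filter_spec("butterworth_lowpass", 4, 20),
                    filter_spec("chebyshev_highpass", 5, 20))) {
    y <- apply_filter(sampled_signal(pulse, fs), spec)$samples
    expect_lt(max(abs(y - rev(y))), 1e-6)
  }
})

test_that("lowpass does not amplify white-noise energy", {
  set.seed(7)
  for (i in 1:5) {
    x <- rnorm(5000)
    y <- apply_filter(sampled_signal(x, 2000),
                      filter_spec("butterworth_lowpass", 4, 20))$samples
    expect_lte(var(y), var(x))
  }
})

test_that("invalid cutoffs and too-short signals raise explicit errors", {
  s <- sampled_signal(rnorm(1000), 100)
  expect_error(apply_filter(s, filter_spec("butterworth_lowpass", 4, 50)),
               "Nyquist")
  tiny <- sampled_signal(rnorm(10), 2000)
  expect_error(apply_filter(tiny, filter_spec("chebyshev_lowpass", 8, 300)),
               "too short")
})

test_that("mains removal notches 50 Hz and its harmonics, sparing the rest", {
  fs <- 2000
  t <- seq(0, 4, by = 1 / fs)
  core <- 2000:6000
  s50 <- sampled_signal(sin(2 * pi * 50 * t), fs)
  r50 <- remove_mains(s50)
  expect_lt(sd(r50$samples) / sd(s50$samples), 0.1)
  s150 <- sampled_signal(sin(2 * pi * 150 * t), fs)
  expect_lt(sd(remove_mains(s150)$samples[core]) / sd(s150$samples[core]), 0.1)
  s10 <- sampled_signal(sin(2 * pi * 10 * t), fs)
  r10 <- remove_mains(s10)
  expect_equal(max(r10$samples[core]), 1, tolerance = 0.05)
  z <- remove_mains(sampled_signal(rep(0, 4000), fs))
  expect_equal(z$samples, rep(0, 4000))
})

test_that("harmonics above Nyquist are skipped with a message", {
  s <- sampled_signal(rnorm(2000), 200)  # Nyquist 100: only 50 Hz fits
  expect_message(remove_mains(s, n_harmonics = 4), "skipped")
})

test_that("rectification is elementwise absolute value", {
  s <- sampled_signal(c(-1, 2, -3), 10)
  expect_equal(rectify(s)$samples, c(1, 2, 3))
  pos <- sampled_signal(c(0, 1, 2), 10)
  expect_identical(rectify(pos)$samples, pos$samples)
  t <- seq(0, 10, by = 1 / 1000)
  m <- mean(rectify(sampled_signal(sin(2 * pi * 5 * t), 1000))$samples)
  expect_equal(m, 2 / pi, tolerance = 1e-3)
})
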