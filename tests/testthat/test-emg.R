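test_that("envelope of silence is zero and rates below the band are refused", {
  z <- sampled_signal(rep(0, 8000), 2000, "mV")
  expect_equal(compute_envelope(z)$samples, rep(0, 8000))
  slow <- sampled_signal(rnorm(2000), 500, "mV")
  expect_error(compute_envelope(slow), "too low")
})

test_that("an in-band sinusoid yields a near-constant envelope of 2/pi", {
  # 80 Hz: inside the 20-300 Hz band and not a mains harmonic
  fs <- 2000
  t <- seq(0, 6, by = 1 / fs)
  s <- sampled_signal(sin(2 * pi * 80 * t), fs, "mV")
  env <- compute_envelope(s)
  core <- 4000:8000
  expect_equal(mean(env$samples[core]), 2 / pi, tolerance = 0.05)
  expect_lt(sd(env$samples[core]) / mean(env$samples[core]), 0.05)
  expect_true(all(env$samples >= 0))
})

test_that("envelope tracks a trapezoidal activation profile", {
  fs <- 2000
  dur <- 10
  prof <- function(t) pmin(pmax((t - 2) / 1, 0), 1) -
    pmin(pmax((t - 7) / 1, 0), 1)
  g <- gen_emg(list(ch = prof), duration_s = dur, rate_hz = fs, seed = 3)
  env <- compute_envelope(g$signals$ch)
  # peak of the envelope within the profile's plateau (3-7 s)
  tpk <- (which.max(env$samples) - 1) / fs
  expect_gte(tpk, 3 - 0.05)
  expect_lte(tpk, 7 + 0.05)
  # plateau level reads in activation units (generator calibration)
  plateau <- env$samples[(4 * fs):(6 * fs)]
  expect_equal(mean(plateau), 1, tolerance = 0.1)
})

test_that("mains contamination 10x the carrier leaves the envelope intact", {
  fs <- 2000
  g0 <- gen_emg(list(a = 0.5, b = 0.5), duration_s = 8, rate_hz = fs,
                mains_amp = 0, seed = 6)
  g1 <- gen_emg(list(a = 0.5, b = 0.5), duration_s = 8, rate_hz = fs,
                mains_amp = 10 * sqrt(pi / 2) * 0.5, seed = 6)
  core <- (2 * fs):(6 * fs)
  e0 <- compute_envelope(g0$signals$a)$samples[core]
  e1 <- compute_envelope(g1$signals$a)$samples[core]
  expect_equal(mean(e1), mean(e0), tolerance = 0.1)
})

test_that("normalization rescales to unit maximum and records the factor", {
  fs <- 100
  env <- sampled_signal(0.8 * abs(sin(seq(0, 3, by = 0.01))), fs, "mV")
  nrm <- normalize_envelope(env)
  expect_equal(max(nrm$samples), 1)
  expect_equal(attr(nrm, "norm_factor"), max(env$samples))
  again <- normalize_envelope(nrm)
  expect_equal(again$samples, nrm$samples)
  expect_error(normalize_envelope(signal_with(env, rep(0, length(env$samples)))),
               "no positive maximum")
})

test_that("CCI matches the closed form and its stated range", {
  fs <- 100
  mk <- function(v) sampled_signal(v, fs)
  expect_equal(compute_cci(mk(rep(1, 10)), mk(rep(1, 10)))$samples,
               rep(2, 10))
  expect_equal(compute_cci(mk(rep(0, 10)), mk(runif(10)))$samples,
               rep(0, 10))
  expect_equal(compute_cci(mk(0.25), mk(0.5))$samples, 0.375)
  # symmetry is exact
  set.seed(8)
  a <- runif(500)
  b <- runif(500)
  expect_identical(compute_cci(mk(a), mk(b))$samples,
                   compute_cci(mk(b), mk(a))$samples)
  # equal activations: CCI(a, a) = (a/a)(a + a) = 2a on a grid
  g <- seq(0, 1, by = 0.01)
  expect_equal(compute_cci(mk(g), mk(g))$samples, 2 * g)
  # bounds on a dense grid of normalized pairs
  gr <- expand.grid(a = seq(0, 1, by = 0.02), b = seq(0, 1, by = 0.02))
  cci <- compute_cci(mk(gr$a), mk(gr$b))$samples
  expect_true(all(cci >= 0 & cci <= 2))
  expect_warning(compute_cci(mk(c(0.5, 1.004)), mk(c(0.5, 1))), "clipped")
  expect_error(compute_cci(mk(1:5), mk(1:4 / 4)), "lengths differ")
})

test_that("per-phase CCI means use the published phase bounds", {
  expect_equal(unname(cci_by_phase(rep(0.5, 101))), rep(0.5, 4))
  v <- c(rep(1, 10), rep(0, 91))  # 1 on [0,10)%, 0 elsewhere
  bp <- cci_by_phase(v)
  expect_equal(unname(bp["initial_double_support"]), 1)
  expect_equal(unname(bp[c("single_support", "pre_swing", "swing")]),
               c(0, 0, 0))
  # phase sample counts on the 101-point grid: 10 / 40 / 10 / 41
  pct <- 0:100
  ph <- gait_phases()
  counts <- c(sum(pct >= 0 & pct < 10), sum(pct >= 10 & pct < 50),
              sum(pct >= 50 & pct < 60), sum(pct >= 60 & pct <= 100))
  expect_identical(counts, c(10L, 40L, 10L, 41L))
  expect_error(cci_by_phase(rep(0.5, 100)), "101")
})

test_that("resting-baseline channels give a near-zero CCI", {
  fs <- 2000
  g <- gen_emg(list(VL = 0.02, BFL = 0.02), duration_s = 30, rate_hz = fs,
               seed = 12)
  # envelopes in activation units, normalized against the task (MVIC) max of 1
  eA <- compute_envelope(g$signals$VL)
  eB <- compute_envelope(g$signals$BFL)
  cci <- compute_cci(eA, eB)
  expect_lt(mean(cci$samples), 0.05)
})

test_that("co-contraction pipeline recovers the closed form for equal profiles", {
  fs <- 2000
  g <- gen_emg(list(a = 0.5, b = 0.5), duration_s = 8, rate_hz = fs,
               mains_amp = 0.2, seed = 10)
  core <- (2 * fs):(6 * fs)
  # equal half-max profiles: CCI = 2 * 0.5 = 1
  cci <- compute_cci(compute_envelope(g$signals$a),
                     compute_envelope(g$signals$b))
  expect_equal(mean(cci$samples[core]), 1, tolerance = 0.15)
})
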