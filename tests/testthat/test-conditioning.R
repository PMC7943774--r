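test_that("resampling linearly interpolates onto the uniform grid", {
  # a linear ramp is reproduced exactly by linear interpolation
  t143 <- seq(0, 10, by = 1 / 143)
  ramp <- 2 + 3 * t143
  sig <- resample_uniform(t143, ramp, 50)
  expect_equal(sig$rate, 50)
  expect_equal(sig$values, 2 + 3 * signal_time(sig), tolerance = 1e-12)

  # 15 Hz imaging-class input comes out at 50 Hz
  t15 <- seq(0, 10, by = 1 / 15)
  s15 <- resample_uniform(t15, sin(t15), 50)
  expect_equal(s15$rate, 50)
  expect_gt(length(s15$values), length(t15))

  # already-uniform input is unchanged at grid points
  t50 <- seq(0, 5, by = 1 / 50)
  v <- rnorm(length(t50))
  expect_equal(resample_uniform(t50, v, 50)$values, v, tolerance = 1e-12)

  expect_error(resample_uniform(c(0, 1, 1), c(1, 2, 3)), "increasing")
})

test_that("blink detection finds derivative outliers with the 150 ms pad", {
  t <- seq(0, 30, by = 0.02)
  smooth <- vns_signal(sin(2 * pi * 0.2 * t), 50)
  expect_equal(nrow(detect_blinks(smooth, 3)), 0)

  # step artifact at t = 10 s, 20 x the derivative SD
  v <- sin(2 * pi * 0.2 * t)
  step_sd <- sd(diff(v))
  v[t >= 10] <- v[t >= 10] + 20 * step_sd
  iv <- detect_blinks(vns_signal(v, 50), 3)
  expect_equal(nrow(iv), 1)
  expect_lte(t[iv[1, "start"]], 10 - 0.14)   # pad reaches ~150 ms before
  expect_gte(t[iv[1, "end"]], 10 + 0.14)

  # constant signal: zero-variance derivative, no error, no intervals
  expect_equal(nrow(detect_blinks(vns_signal(rep(1, 100), 50), 3)), 0)

  # all samples missing: one interval spanning the signal
  allbad <- vns_signal(rep(0, 100), 50, gap_mask = rep(TRUE, 100))
  expect_equal(detect_blinks(allbad, 3), cbind(start = 1L, end = 100L))
})

test_that("gap interpolation is linear inside, nearest at the edges", {
  sig <- vns_signal(c(2, 2, NA, 4, 4), 1)
  out <- interpolate_gaps(sig, cbind(start = 3L, end = 3L))
  expect_equal(out$values[3], 3)              # midpoint of 2 and 4
  expect_equal(out$gap_mask, c(F, F, T, F, F))

  # leading gap: constant extension of first good value
  lead <- interpolate_gaps(vns_signal(c(NA, NA, 7, 8), 1),
                           cbind(start = integer(0), end = integer(0)))
  expect_equal(lead$values[1:2], c(7, 7))

  # no gaps: identity
  clean <- vns_signal(1:10, 1)
  expect_equal(interpolate_gaps(clean, cbind(start = integer(0),
                                             end = integer(0)))$values,
               as.numeric(1:10))
  expect_error(interpolate_gaps(vns_signal(rep(NA_real_, 5), 1),
                                cbind(start = integer(0), end = integer(0))),
               "no good samples")
})

test_that("zero-phase Butterworth matches its analytic magnitude response", {
  t <- seq(0, 60, by = 0.02)
  # DC gain 1
  const <- lowpass_zero_phase(vns_signal(rep(5, length(t)), 50))
  expect_equal(const$values[500:2500], rep(5, 2001), tolerance = 1e-6)

  gain_at <- function(f_hz) {
    x <- sin(2 * pi * f_hz * t)
    y <- lowpass_zero_phase(vns_signal(x, 50))$values
    mid <- t > 10 & t < 50   # avoid edge transients
    sqrt(sum(y[mid]^2) / sum(x[mid]^2))
  }
  # two-pass response = |H|^2 with |H(f)| = 1/sqrt(1 + (f/3)^6)
  expect_equal(gain_at(0.1), 1 / (1 + (0.1 / 3)^6), tolerance = 0.01)
  expect_lt(gain_at(10), 0.03)   # analytic two-pass gain 7.3e-4

  expect_error(lowpass_zero_phase(vns_signal(rnorm(100), 50),
                                  cutoff_hz = 30), "Nyquist")
})

test_that("channel kinds get their documented conditioning chains", {
  set.seed(2)
  t <- seq(0, 120, by = 1 / 143)
  raw <- 50 + 5 * sin(2 * pi * t / 60) + rnorm(length(t), 0, 0.1)
  cfg <- vns_config()

  pup <- condition_channel(t, raw, "pupil", cfg)
  expect_equal(quantile(pup$values, 0.999, names = FALSE), 100,
               tolerance = 1e-6)
  expect_false(anyNA(pup$values))
  expect_equal(pup$rate, 50)
  expect_match(paste(pup$provenance, collapse = ";"), "butterworth")

  eye <- condition_channel(t, raw, "eye_position", cfg)
  expect_equal(mean(eye$values), 0, tolerance = 1e-9)
  expect_equal(sd(eye$values), 1, tolerance = 1e-9)

  vel <- condition_channel(t, raw, "velocity", cfg)
  expect_false(any(grepl("butterworth", vel$provenance)))

  # calcium: added linear rundown is removed by detrending
  ca_raw <- raw + -0.05 * t
  ca <- condition_channel(t, ca_raw, "calcium", cfg)
  slope <- coef(lm(ca$values ~ signal_time(ca)))[2]
  expect_equal(unname(slope), 0, tolerance = 1e-6)

  expect_error(condition_channel(t, raw, "licking"), "arg")
})

test_that("percentile normalization is idempotent", {
  set.seed(3)
  sig <- vns_signal(abs(rnorm(5000)) + 1, 50)
  once <- vnspupil:::normalize_percentile(sig)
  twice <- vnspupil:::normalize_percentile(once)
  expect_lt(max(abs(twice$values - once$values)), 1e-9)
})

test_that("gap mask covers exactly the interpolated spans", {
  set.seed(4)
  t <- seq(0, 60, by = 1 / 143)
  v <- 50 + rnorm(length(t), 0, 0.05)
  v[t > 20 & t < 20.4] <- NA            # dropout
  cfg <- vns_config()
  sig <- condition_channel(t, v, "pupil", cfg)
  tm <- signal_time(sig)
  # all samples inside the dropout are masked (plus the 150 ms pad)
  expect_true(all(sig$gap_mask[tm > 20.05 & tm < 20.35]))
  # far away from it, the mask is mostly clean
  expect_lt(mean(sig$gap_mask[tm > 40]), 0.2)
})
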