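test_that("outlier detection flags gaps, short beats and jumps only", {
  rr <- rr_series(cumsum(rep(0.8, 50)), rep(0.8, 50))
  expect_false(any(detect_outliers(rr)))

  x <- rep(0.8, 20); x[10] <- 3.0
  rr2 <- rr_series(cumsum(x), x)
  flags <- detect_outliers(rr2, max_rr_s = 2.0)
  expect_identical(which(flags), 10L)

  x <- rep(0.8, 20); x[5] <- 0.2
  rr3 <- rr_series(cumsum(x), x)
  expect_identical(which(detect_outliers(rr3, min_rr_s = 0.3)), 5L)
})

test_that("outlier interpolation fixes flagged beats and leaves the rest", {
  rr <- rr_series(cumsum(rep(0.8, 10)), rep(0.8, 10))
  expect_equal(interpolate_outliers(rr, rep(FALSE, 10))$rr_s, rr$rr_s)

  # flagged beat exactly midway in time between 0.8 and 0.9 neighbours
  times <- c(1, 2, 3)
  vals <- c(0.8, 5, 0.9)
  rr2 <- rr_series(times, vals)
  out <- interpolate_outliers(rr2, c(FALSE, TRUE, FALSE))
  expect_equal(out$rr_s[2], 0.85, tolerance = 1e-12)
  expect_equal(out$rr_s[c(1, 3)], c(0.8, 0.9))

  # flag at the series start: nearest-unflagged extrapolation
  rr3 <- rr_series(c(1, 2, 3, 4), c(9, 0.8, 0.85, 0.9))
  out3 <- interpolate_outliers(rr3, c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(out3$rr_s[1], 0.8, tolerance = 1e-12)

  expect_error(interpolate_outliers(rr2, rep(TRUE, 3)), "clean")
})

test_that("cleaning a constant series is idempotent", {
  x <- rep(0.8, 30); x[c(7, 19)] <- c(2.5, 0.1)
  rr <- rr_series(cumsum(x), x)
  cleaned <- interpolate_outliers(rr, detect_outliers(rr))
  expect_false(any(detect_outliers(cleaned)))
})

test_that("SQI agreement fraction matches its definition", {
  fs <- 250
  a <- peak_annotations(c(100, 300, 500), fs)
  expect_equal(compute_sqi(a, a)$sqi, 1.0)

  b <- peak_annotations(c(1000, 2000, 3000), fs)
  expect_equal(compute_sqi(a, b)$sqi, 0.0)

  # 2 peaks each, exactly one matched pair: 1 / (2 + 2 - 1)
  a2 <- peak_annotations(c(250, 1000), fs)     # 1.0 s, 4.0 s
  b2 <- peak_annotations(c(255, 2000), fs)     # 1.02 s, 8.0 s
  expect_equal(compute_sqi(a2, b2)$sqi, 1 / 3)

  expect_error(compute_sqi(peak_annotations(numeric(0), fs),
                           peak_annotations(numeric(0), fs)), "empty")
})

test_that("SQI is symmetric in the two detectors", {
  for (seed in 1:5) {
    set.seed(seed)
    a <- peak_annotations(sort(sample(10000, 40)), 100)
    b <- peak_annotations(sort(sample(10000, 35)), 100)
    expect_equal(compute_sqi(a, b)$sqi, compute_sqi(b, a)$sqi)
  }
})

test_that("segmentation yields the expected windows and quality gating", {
  rr <- synth_tachogram(1200, noise_sd_s = 0, seed = 1)   # 20 minutes
  segs <- segment_and_gate(rr)
  expect_length(segs, 4)
  expect_true(all(vapply(segs, function(s) s$quality$is_high_quality, logical(1))))

  # per-beat SQI averaging 0.813 marks the segment low-quality
  segs2 <- segment_and_gate(rr, sqi_flags = rep(0.813, nrow(rr)))
  expect_false(any(vapply(segs2, function(s) s$quality$is_high_quality, logical(1))))
  expect_equal(segs2[[1]]$quality$mean_sqi, 0.813)

  short <- synth_tachogram(100, seed = 1)
  expect_warning(out <- segment_and_gate(short), "shorter")
  expect_length(out, 0)
})

test_that("uniform resampling is a 4 Hz interpolant through the beats", {
  rr <- rr_series(cumsum(rep(0.8, 20)), rep(0.8, 20))
  u <- resample_uniform(rr)
  expect_equal(u$sampling_rate_hz, 4)
  expect_true(all(abs(u$values - 0.8) < 1e-9))

  rr2 <- synth_tachogram(120, seed = 4)
  u2 <- resample_uniform(rr2)
  grid <- u2$start_time_s + (seq_along(u2$values) - 1) / u2$sampling_rate_hz
  expect_equal(diff(grid)[1], 0.25)
  # the spline passes through the original nodes
  on_grid <- rr2$time_s[rr2$time_s >= min(grid) & rr2$time_s <= max(grid)]
  f <- stats::splinefun(rr2$time_s, rr2$rr_s, method = "fmm")
  expect_lt(max(abs(f(rr2$time_s) - rr2$rr_s)), 1e-9)

  expect_error(resample_uniform(rr_series(c(1, 2), c(1, 1))), "4 beats")
})

test_that("band-pass keeps HF, kills DC, and attenuates out-of-band tones", {
  t <- seq(0, 300, by = 0.25)
  inband <- uniform_series(sin(2 * pi * 0.25 * t), 0, 4)
  y <- bandpass_hrv(inband)$values
  core <- seq(200, length(t) - 200)          # ignore filter edges
  expect_gt(max(abs(y[core])), 0.95)

  dc <- uniform_series(rep(0.8, length(t)), 0, 4)
  expect_lt(abs(mean(bandpass_hrv(dc)$values)), 1e-6 * 0.8)

  fast <- uniform_series(sin(2 * pi * 1.8 * t), 0, 4)
  yf <- bandpass_hrv(fast)$values
  expect_lt(max(abs(yf[core])), 0.1)

  expect_error(bandpass_hrv(inband, high = 2.5), "Nyquist")
})

test_that("band-pass filtering is linear", {
  set.seed(11)
  t <- seq(0, 100, by = 0.25)
  x <- uniform_series(rnorm(length(t)), 0, 4)
  y <- uniform_series(rnorm(length(t)), 0, 4)
  xy <- uniform_series(x$values + y$values, 0, 4)
  expect_equal(bandpass_hrv(xy)$values,
               bandpass_hrv(x)$values + bandpass_hrv(y)$values,
               tolerance = 1e-9)
})
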