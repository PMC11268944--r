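test_that("sampling_stats matches a uniform grid and detects gaps", {
  ts <- seq(0, by = 0.01, length.out = 1000)
  st <- sampling_stats(ts, 100)
  expect_equal(st$median_freq, 100)
  expect_equal(st$irregularity, 0)
  expect_equal(st$max_gap, 0.01)

  ts2 <- c(ts[1:500], ts[501:1000] + 0.49)  # one 0.5 s gap
  expect_equal(sampling_stats(ts2)$max_gap, 0.5)

  expect_error(sampling_stats(c(0, 1)), "insufficient")
})

test_that("sampling_stats is invariant under a constant time shift", {
  set.seed(7)
  ts <- cumsum(abs(stats::rnorm(200, 0.01, 0.002)))
  a <- sampling_stats(ts)
  b <- sampling_stats(ts + 123.456)
  expect_equal(a$median_freq, b$median_freq)
  expect_equal(a$irregularity, b$irregularity)
  expect_equal(a$max_gap, b$max_gap)
})

test_that("flag_sampling fires on irregular or gapped sampling only", {
  uni <- sampling_stats(seq(0, 9.99, by = 0.01), 100)
  expect_null(flag_sampling(uni, 100))

  gap <- sampling_stats(c(seq(0, 5, 0.01), seq(5.5, 10, 0.01)), 100)
  f <- flag_sampling(gap, 100, task = "sixmwt")
  expect_s3_class(f, "quality_flag")
  expect_identical(f$id, "sixmwt-technical-deviation-sampling_unstable")

  # jittered dt ~ 0.01 +/- 0.002 -> irregularity ~ 0.2
  set.seed(11)
  jit <- cumsum(abs(stats::rnorm(1000, 0.01, 0.002)))
  stj <- sampling_stats(jit)
  expect_gt(stj$irregularity, 0.1)
  expect_lt(abs(stj$irregularity - 0.2), 0.05)
  expect_s3_class(flag_sampling(stj, 100), "quality_flag")
})

test_that("resample_uniform is exact on linear input and idempotent on uniform", {
  ts <- seq(0, 1, by = 0.01)
  v <- 2 * ts + 1
  out <- resample_uniform(ts, v, 100)
  expect_equal(out$timestamps, ts)
  expect_equal(out$values, v, tolerance = 1e-12)

  # linear ramp: midpoints are exact under linear interpolation
  out2 <- resample_uniform(c(0, 1), c(0, 10), 4)
  expect_equal(out2$values, c(0, 2.5, 5, 7.5, 10))

  # 2 Hz sine downsampled 100 -> 50 Hz: small interpolation error
  t100 <- seq(0, 2, by = 0.01)
  res <- resample_uniform(t100, sin(2 * pi * 2 * t100), 50)
  expect_lt(max(abs(res$values - sin(2 * pi * 2 * res$timestamps))), 0.01)
})

test_that("zero-phase band-pass rejects DC, keeps in-band timing, kills out-of-band", {
  fs <- 100
  t <- seq(0, 20, by = 1 / fs)
  dc <- rep(1, length(t))
  out <- bandpass_zero_phase(dc, fs, 0.5, 5)
  # the 0.5 Hz high-pass edge has a seconds-long transient; judge the
  # interior of the record
  inner <- out[(8 * fs):(length(out) - 8 * fs)]
  expect_lt(max(abs(inner)), 1e-6)

  # in-band 2 Hz sine: zero lag at the cross-correlation peak
  s <- sin(2 * pi * 2 * t)
  f <- bandpass_zero_phase(s, fs, 0.5, 5)
  cc <- stats::ccf(f, s, lag.max = 20, plot = FALSE)
  expect_identical(cc$lag[which.max(cc$acf)], 0)

  # out-of-band 20 Hz sine attenuated > 90%
  hi <- sin(2 * pi * 20 * t)
  fh <- bandpass_zero_phase(hi, fs, 0.5, 5)
  expect_lt(max(abs(fh)) / max(abs(hi)), 0.1)
})

test_that("band-pass of the time-reversed signal is the reversed output", {
  set.seed(3)
  x <- stats::rnorm(2000)
  a <- bandpass_zero_phase(rev(x), 100, 0.5, 5)
  b <- rev(bandpass_zero_phase(x, 100, 0.5, 5))
  expect_equal(a, b, tolerance = 1e-9)
})

test_that("gravity_and_norm separates static and dynamic components", {
  n <- 1000
  acc <- cbind(rep(0, n), rep(0, n), rep(9.81, n))
  gn <- gravity_and_norm(acc)
  expect_equal(gn$gravity, c(0, 0, 9.81))
  expect_equal(gn$norm, rep(0, n))

  t <- seq(0, 10, length.out = n)
  A <- 0.7
  acc2 <- cbind(A * sin(2 * pi * 1 * t), rep(0, n), rep(9.81, n))
  gn2 <- gravity_and_norm(acc2)
  expect_lt(abs(max(gn2$norm) - A), 0.01)

  expect_equal(gravity_and_norm(matrix(0, 5, 3))$norm, rep(0, 5))
})

test_that("flag_orientation fires on flipped or weak gravity components", {
  n <- 500
  up <- cbind(rep(0, n), rep(0, n), rep(9.81, n))
  expect_null(flag_orientation(up, "z", 1))
  f <- flag_orientation(-up, "z", 1, task = "sixmwt")
  expect_identical(f$id, "sixmwt-behavioral-deviation-orientation")
  weak <- cbind(rep(0, n), rep(0, n), rep(0.3 * 9.81, n))
  expect_s3_class(flag_orientation(weak, "z", 1), "quality_flag")
})
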