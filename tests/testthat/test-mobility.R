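test_that("detect_steps counts analytic sine peaks and handles silence", {
  fs <- 100
  t <- seq(0, 60, by = 1 / fs)
  s <- 1.0 * sin(2 * pi * 2 * t)  # 2 steps/s for 60 s
  ev <- detect_steps(s, fs)
  expect_equal(ev$count, 120)
  expect_equal(ev$cadence, 120)
  expect_lt(ev$step_time_cv, 0.05)

  zero <- detect_steps(rep(0, 6001), fs)
  expect_equal(zero$count, 0)
  expect_equal(zero$cadence, 0)
  expect_true(is.na(zero$step_time_cv))

  expect_error(detect_steps(rep(0, 100), fs), "insufficient")
})

test_that("detect_steps tolerates additive noise on the walking harmonic", {
  fs <- 100
  t <- seq(0, 60, by = 1 / fs)
  set.seed(5)
  s <- sin(2 * pi * 2 * t) + stats::rnorm(length(t), 0, 0.05)
  ev <- detect_steps(s, fs)
  expect_lte(abs(ev$count - 120), 2)
})

test_that("cadence is recovered within 2 steps/min across the generator grid", {
  for (cad in c(80, 100, 120)) {
    for (seed in 1:3) {
      fx <- gen_walk(cadence = cad, duration = 60, fs = 100,
                     noise_sd = 0.05, seed = seed)
      res <- run_registered(fx$reading)
      est <- level_measure(res$reading, "sixmwt-cadence")
      expect_lte(abs(est - cad), 2)
    }
  }
})

test_that("detect_turns integrates constant-rate blocks to their exact angle", {
  fs <- 100
  w <- c(rep(0, 200), rep(90 * pi / 180, 200), rep(0, 200))  # 90 deg/s, 2 s
  tn <- detect_turns(w, fs)
  expect_length(tn, 1L)
  expect_lt(abs(tn[[1]]$angle - pi), 0.01)
  expect_lt(abs(tn[[1]]$duration - 2), 0.1)

  expect_length(detect_turns(rep(0, 1000), fs), 0L)

  w2 <- c(rep(0, 100), rep(90 * pi / 180, 200), rep(0, 300),
          rep(-90 * pi / 180, 200), rep(0, 100))
  tn2 <- detect_turns(w2, fs)
  expect_length(tn2, 2L)
  expect_lt(abs(tn2[[1]]$angle - pi), 0.01)
  expect_lt(abs(tn2[[2]]$angle + pi), 0.01)
  expect_lt(tn2[[1]]$start, tn2[[2]]$start)
})

test_that("turn angles follow the input sign and negate under time reversal", {
  fs <- 50
  set.seed(9)
  for (i in 1:5) {
    ang <- sample(c(170, 180, 270), 1) * sample(c(-1, 1), 1)
    rate <- sample(c(60, 90, 120), 1)
    fx <- gen_turns(ang, rate, fs = fs)
    w <- fx$reading$levels[[1]]$datasets[["gyro"]]$data$yaw
    tn <- detect_turns(w, fs)
    expect_length(tn, 1L)
    expect_identical(sign(tn[[1]]$angle), sign(ang))
    # playing the recording backwards in time negates the yaw rate
    rev_tn <- detect_turns(-rev(w), fs)
    expect_equal(rev_tn[[1]]$angle, -tn[[1]]$angle, tolerance = 1e-9)
  }
})

test_that("sway metrics match the isotropic Gaussian closed form and scale laws", {
  fs <- 100
  set.seed(21)
  sigma <- 0.05
  ap <- stats::rnorm(6000, 0, sigma)
  ml <- stats::rnorm(6000, 0, sigma)
  sm <- sway_metrics(ap, ml, fs)
  expect_lt(abs(sm$ellipse_area - pi * 5.991 * sigma^2),
            0.1 * pi * 5.991 * sigma^2)

  const <- sway_metrics(rep(1, 2000), rep(-2, 2000), fs)
  expect_equal(const$rms_ap, 0)
  expect_equal(const$rms_ml, 0)
  expect_equal(const$ellipse_area, 0)
  expect_equal(const$jerk_rms, 0)

  sm2 <- sway_metrics(2 * ap, 2 * ml, fs)
  expect_equal(sm2$rms_ap, 2 * sm$rms_ap, tolerance = 1e-12)
  expect_equal(sm2$ellipse_area, 4 * sm$ellipse_area, tolerance = 1e-12)

  expect_error(sway_metrics(ap[1:100], ml[1:100], fs), "insufficient")
})

test_that("sway ellipse area is invariant under rotation of the AP/ML plane", {
  set.seed(33)
  ap <- stats::rnorm(2000, 0, 0.08)
  ml <- stats::rnorm(2000, 0, 0.03)
  base <- sway_metrics(ap, ml, 100)$ellipse_area
  for (th in c(pi / 7, pi / 3, 1.1)) {
    ap2 <- cos(th) * ap - sin(th) * ml
    ml2 <- sin(th) * ap + cos(th) * ml
    rot <- sway_metrics(ap2, ml2, 100)$ellipse_area
    expect_equal(rot, base, tolerance = 1e-9)
  }
})

test_that("sixmwt extraction flags short or flipped recordings but keeps measures", {
  fx <- gen_walk(cadence = 108, duration = 60, fs = 100, noise_sd = 0.05,
                 seed = 2)
  res <- run_registered(fx$reading)
  expect_lte(abs(level_measure(res$reading, "sixmwt-cadence") - 108), 2)
  expect_false("sixmwt-behavioral-invalidation-too_short" %in%
                 all_flag_ids(res$reading))

  short <- corrupt(fx$reading, "truncate", 0.1)
  res_s <- run_registered(short)
  expect_true("sixmwt-behavioral-invalidation-too_short" %in%
                all_flag_ids(res_s$reading))
  expect_gt(length(res_s$reading$levels[[1]]$measures$values), 0L)

  flipped <- corrupt(fx$reading, "flip_orientation")
  res_f <- run_registered(flipped)
  expect_true("sixmwt-behavioral-deviation-orientation" %in%
                all_flag_ids(res_f$reading))
  expect_true("sixmwt-cadence" %in%
                measure_ids(res_f$reading$levels[[1]]$measures))
})

test_that("utt and sbt pipelines emit their measure families with epochs", {
  fx <- gen_turns(c(180, -180), c(90, 90))
  res <- run_registered(fx$reading)
  expect_equal(level_measure(res$reading, "utt-turns"), 2)
  expect_length(res$reading$levels[[1]]$epochs, 2L)
  expect_equal(res$reading$levels[[1]]$epochs[[1]]$payload$angle, pi,
               tolerance = 0.01)

  sw <- gen_sway(seed = 4)
  res2 <- run_registered(sw$reading)
  expect_setequal(measure_ids(res2$reading$levels[[1]]$measures),
                  c("sbt-rms_ap", "sbt-rms_ml", "sbt-ellipse_area",
                    "sbt-jerk_rms"))
})
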