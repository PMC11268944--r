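square_ref <- function() {
  n <- 20
  cbind(c(seq(0, 10, length.out = n), rep(10, n), seq(10, 0, length.out = n),
          rep(0, n)),
        c(rep(0, n), seq(0, 10, length.out = n), rep(10, n),
          seq(10, 0, length.out = n)))
}

test_that("drawing similarity is zero on identity and exact on rigid offsets", {
  ref <- square_ref()
  tr <- data.frame(t = seq_len(nrow(ref)), x = ref[, 1], y = ref[, 2])
  res <- drawing_similarity(tr, ref)
  expect_equal(res$sim, 0, tolerance = 1e-12)
  expect_equal(res$dtw_sim, 0, tolerance = 1e-12)

  tr2 <- data.frame(t = tr$t, x = tr$x + 3, y = tr$y + 4)
  res2 <- drawing_similarity(tr2, ref)
  expect_equal(res2$sim, 5, tolerance = 1e-12)
})

test_that("DTW relaxation never exceeds the index-coupled distance", {
  set.seed(17)
  ref <- square_ref()
  for (i in 1:20) {
    x <- ref[, 1] + stats::rnorm(nrow(ref), 0, 0.5)
    y <- ref[, 2] + stats::rnorm(nrow(ref), 0, 0.5)
    tr <- data.frame(t = seq_len(nrow(ref)), x = x, y = y)
    res <- drawing_similarity(tr, ref)
    expect_lte(res$dtw_sim, res$sim + 1e-12)
  }
})

test_that("the DP alignment total matches a brute-force DTW oracle", {
  set.seed(23)
  for (i in 1:5) {
    a <- cbind(stats::rnorm(8), stats::rnorm(8))
    b <- cbind(stats::rnorm(10), stats::rnorm(10))
    expect_equal(sdmkit:::dtw_align(a, b)$total, brute_dtw_total(a, b),
                 tolerance = 1e-12)
  }
})

test_that("drawing similarity is invariant under a shared rigid transform", {
  set.seed(31)
  ref <- square_ref()
  tr <- data.frame(t = seq_len(nrow(ref)),
                   x = ref[, 1] + stats::rnorm(nrow(ref), 0, 0.3),
                   y = ref[, 2] + stats::rnorm(nrow(ref), 0, 0.3))
  base <- drawing_similarity(tr, ref)
  th <- 0.7; dx <- 12; dy <- -5
  rot <- function(m) cbind(cos(th) * m[, 1] - sin(th) * m[, 2] + dx,
                           sin(th) * m[, 1] + cos(th) * m[, 2] + dy)
  tr2m <- rot(cbind(tr$x, tr$y))
  tr2 <- data.frame(t = tr$t, x = tr2m[, 1], y = tr2m[, 2])
  moved <- drawing_similarity(tr2, rot(ref))
  expect_equal(moved$sim, base$sim, tolerance = 1e-9)
  expect_equal(moved$dtw_sim, base$dtw_sim, tolerance = 1e-9)
})

test_that("pinch attempts, successes and the single-finger flag behave as stated", {
  fx <- gen_pinch(c(TRUE, TRUE, TRUE))
  res <- run_registered(fx$reading)
  expect_equal(level_measure(res$reading, "pinch-attempts"), 3)
  expect_equal(level_measure(res$reading, "pinch-successes"), 3)
  expect_equal(level_measure(res$reading, "pinch-success_rate"), 1.0)

  fx2 <- gen_pinch(c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE, TRUE, FALSE))
  res2 <- run_registered(fx2$reading)
  expect_equal(level_measure(res2$reading, "pinch-success_rate"), 0.5)

  # one contact only throughout
  single <- fx$reading
  ds <- single$levels[[1]]$datasets[["touch"]]
  ds$data$c2 <- 0L
  single$levels[[1]]$datasets[["touch"]] <- ds
  res3 <- run_registered(single)
  expect_equal(level_measure(res3$reading, "pinch-attempts"), 0)
  expect_true("pinch-behavioral-deviation-single_finger" %in%
                all_flag_ids(res3$reading))
})

test_that("symbol-digit scoring counts matches, rates and drift", {
  km <- setNames(1:9, as.character(1:9))
  stim <- rep(1:5, 4)
  resp <- stim
  resp[c(3, 8)] <- resp[c(3, 8)] + 1L  # 18 of 20 correct
  trials <- data.frame(stimulus = stim, response = resp,
                       t_shown = seq(0, by = 1, length.out = 20),
                       t_answered = seq(0, by = 1, length.out = 20) + 0.5)
  res <- cps_measures(trials, km)
  expect_equal(res$n_correct, 18)
  expect_equal(res$accuracy, 0.9)
  expect_equal(res$rt_mean, 0.5)
  expect_equal(res$rt_drift, 0)

  expect_error(cps_measures(trials[0, ], km), "insufficient")

  # linearly slowing RTs -> positive drift
  n <- 30
  tr2 <- data.frame(stimulus = rep(1, n), response = rep(1, n),
                    t_shown = seq_len(n),
                    t_answered = seq_len(n) + seq(0.4, 0.8, length.out = n))
  expect_gt(cps_measures(tr2, km)$rt_drift, 0)
})

test_that("cps accuracy stays in [0, 1] with n_correct <= n_total", {
  for (seed in 1:5) {
    fx <- gen_cps(n_trials = 25, p_correct = stats::runif(1), seed = seed)
    res <- run_registered(fx$reading)
    acc <- level_measure(res$reading, "cps-accuracy")
    expect_gte(acc, 0)
    expect_lte(acc, 1)
    expect_lte(level_measure(res$reading, "cps-n_correct"),
               level_measure(res$reading, "cps-n_total"))
  }
})

test_that("event statistics follow their definitions", {
  es <- event_stats(0:9)
  expect_equal(es$count, 10)
  expect_equal(es$rate, 10 / 9, tolerance = 1e-12)
  expect_equal(es$iei_mean, 1)

  single <- event_stats(2.5)
  expect_equal(single$count, 1)
  expect_true(is.na(single$iei_mean))

  expect_equal(event_stats(numeric())$count, 0)
})

test_that("questionnaire endpoint scores hit the published scale limits", {
  lo <- score_questionnaire("msis29", rep(1, 29))
  hi <- score_questionnaire("msis29", rep(5, 29))
  expect_equal(unname(lo[c("msis29-physical", "msis29-psychological")]),
               c(0, 0))
  expect_equal(unname(hi[c("msis29-physical", "msis29-psychological")]),
               c(100, 100))

  expect_equal(unname(score_questionnaire("alsfrs_r", rep(4, 12))["alsfrs_r-total"]),
               48)

  expect_equal(unname(score_questionnaire("pdq39", rep(0, 39))["pdq39-si"]), 0)
  expect_equal(unname(score_questionnaire("pdq39", rep(4, 39))["pdq39-si"]), 100)

  expect_error(score_questionnaire("msis29", rep(0, 29)), "out of range")
  expect_error(score_questionnaire("msis29", rep(1, 28)), "expects 29")
})

test_that("questionnaire scores are monotone non-decreasing in every answer", {
  set.seed(13)
  for (instr in c("msis29", "alsfrs_r", "pdq39")) {
    cfg <- builtin_questionnaire(instr)
    base <- round(stats::runif(cfg$n_items, cfg$item_range[1],
                               cfg$item_range[2] - 1))
    s0 <- score_questionnaire(cfg, base)
    for (item in sample(cfg$n_items, 5)) {
      bumped <- base
      bumped[item] <- bumped[item] + 1
      s1 <- score_questionnaire(cfg, bumped)
      expect_true(all(s1 >= s0 - 1e-12), info = paste(instr, "item", item))
    }
  }
})
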