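test_that("measure ids are generated from task, modalities, abbr and agg", {
  expect_identical(
    generate_measure_id("draw", c("square", "right", "first"), "sim", "mean"),
    "draw-square_right_first-sim-mean")
  expect_identical(generate_measure_id("sixmwt", character(), "cadence"),
                   "sixmwt-cadence")
  expect_identical(
    generate_measure_id("cps", list(modality("part", "symbol_to_digit")),
                        "rt", "median"),
    "cps-symbol_to_digit-rt-median")
  expect_error(generate_measure_id("six-mwt", character(), "cadence"),
               "invalid slug")
  expect_error(generate_measure_id("draw", c("sq-uare"), "sim"),
               "invalid slug")
})

test_that("measure id generation is injective over dash/underscore-free slugs", {
  set.seed(42)
  syll <- c("ga", "to", "mi", "ra", "zu", "pe", "lo", "ki")
  rand_slug <- function() paste(sample(syll, 3, replace = TRUE), collapse = "")
  seen <- new.env(parent = emptyenv())
  for (i in 1:200) {
    task <- rand_slug()
    mods <- replicate(sample(0:3, 1), rand_slug())
    abbr <- rand_slug()
    agg <- if (stats::runif(1) < 0.5) rand_slug() else NULL
    key <- paste(task, paste(mods, collapse = "|"), abbr,
                 if (is.null(agg)) "" else agg, sep = "#")
    id <- generate_measure_id(task, mods, abbr, agg)
    prior <- mget(id, envir = seen, ifnotfound = list(NULL))[[1]]
    if (!is.null(prior)) expect_identical(prior, key)
    assign(id, key, envir = seen)
  }
  succeed()
})

test_that("add_measure inserts, keeps order deterministic and rejects duplicates", {
  s <- measure_set()
  s <- add_measure(s, measure_value(
    value_definition("cps-rt-mean", unit = "s"), 0.61))
  expect_length(s$values, 1L)
  expect_equal(s$values[["cps-rt-mean"]]$value, 0.61)

  a <- measure_value(value_definition("a"), 1)
  b <- measure_value(value_definition("b"), 2)
  s2 <- add_measure(add_measure(measure_set(), b, "step_b"), a, "step_a")
  expect_identical(measure_ids(s2), c("a", "b"))
  err <- expect_error(add_measure(s2, a, "step_c"), "collision")
  expect_match(conditionMessage(err), "step_a")
  expect_match(conditionMessage(err), "step_c")
})

test_that("attach_flag annotates targets and rejects dangling references", {
  r <- minimal_reading()
  r$levels[["only"]]$measures <- add_measure(
    r$levels[["only"]]$measures,
    measure_value(value_definition("tap-count"), 3))
  f <- quality_flag(flag_id("tap", "behavioral", "deviation", "restless"),
                    targets = "level:only")
  r2 <- attach_flag(r, f)
  expect_length(level_flags(r2, "only"), 1L)
  expect_identical(level_flags(r2, "only")[[1]]$id,
                   "tap-behavioral-deviation-restless")

  fm <- quality_flag(flag_id("tap", "technical", "invalidation", "garbled"),
                     targets = "measure:only/tap-count")
  r3 <- attach_flag(r2, fm)
  m <- r3$levels[["only"]]$measures$values[["tap-count"]]
  expect_length(m$flags, 1L)
  expect_equal(m$value, 3)  # annotated, not deleted

  expect_error(
    attach_flag(r, quality_flag("tap-technical-deviation-x",
                                targets = "level:nope")),
    "does not resolve")
  expect_error(quality_flag("tap-oops-deviation-x"), "grammar|follow")
})

test_that("level and dataset invariants are enforced", {
  expect_error(level(start = 2, end = 1), "start must be <=")
  ds <- minimal_reading()$levels[[1]]$datasets[[1]]
  lv <- level(start = 0, end = 1, datasets = list(ds), id = "l")
  expect_error(level_add_dataset <- sdmkit:::level_add_dataset(lv, ds),
               "already present")
  expect_error(raw_dataset("x!", ds$source, ds$columns, ds$data),
               "invalid slug")
  bad_cols <- list(value_definition("a", data_type = "float"))
  expect_error(raw_dataset("x", ds$source, bad_cols,
                           data.frame(a = 1)), "timestamp")
})

test_that("modalities of a level are queryable and unique per dimension", {
  lv <- level(modalities = list(modality("shape", "square"),
                                modality("hand", "left")),
              start = 0, end = 1)
  expect_identical(lv$id, "square_left")
  expect_identical(level_modality(lv, "hand"), "left")
  expect_true(is.na(level_modality(lv, "attempt")))
  expect_error(level(modalities = list(modality("hand", "left"),
                                       modality("hand", "right"))),
               "duplicate modality")
})
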