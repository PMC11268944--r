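# A tiny two-step pipeline used across these tests: a transform that
# scales the events column, then an extract that counts rows.
scale_step <- function() {
  processing_step("scale_ts", "transform", function(lv, rd, config) {
    ds <- lv$datasets[["events"]]
    d <- ds$data
    d$v <- d$v * 2
    raw_dataset("events_scaled", ds$source, ds$columns, d)
  }, inputs = "events", outputs = "events_scaled")
}

count_step <- function(input = "events_scaled") {
  processing_step("count_rows", "extract", function(lv, rd, config) {
    ds <- lv$datasets[[input]]
    add_measure(measure_set(),
                measure_value(value_definition("tap-count"), nrow(ds$data)))
  }, inputs = input, outputs = "tap-count")
}

test_that("steps run only on levels matching the modality filter", {
  fx <- gen_drawing("all", seed = 1)
  r <- fx$reading
  marker <- processing_step("mark", "extract", function(lv, rd, config) {
    add_measure(measure_set(),
                measure_value(value_definition("draw-marked"), 1))
  }, inputs = "touch", level_filter = c(hand = "right"))
  res <- process_reading(r, list(marker))
  marked <- vapply(res$reading$levels,
                   function(lv) "draw-marked" %in% measure_ids(lv$measures),
                   logical(1))
  expect_equal(sum(marked), 8L)
  expect_true(all(vapply(res$reading$levels[marked],
                         function(lv) level_modality(lv, "hand") == "right",
                         logical(1))))
})

test_that("missing inputs skip the step without raising", {
  r <- minimal_reading()
  steps <- list(count_step(input = "not_there"))
  expect_silent(res <- process_reading(r, steps))
  expect_length(res$reading$levels[[1]]$measures$values, 0L)
  expect_identical(res$trace$steps$status, "skipped_missing_input")
})

test_that("a transform-extract pipeline leaves a raw-to-measure trace path", {
  r <- minimal_reading()
  res <- process_reading(r, list(scale_step(), count_step()))
  expect_equal(res$reading$levels[[1]]$measures$values[["tap-count"]]$value, 3)

  ex <- export_trace(res$trace)
  g <- igraph::graph_from_data_frame(
    ex$edges[ex$edges$relation %in% c("input", "output"), c("from", "to")],
    directed = TRUE, vertices = ex$nodes$id)
  paths <- igraph::shortest_paths(g, from = "dataset:only/events",
                                  to = "measure:only/tap-count",
                                  mode = "out")
  ids <- names(paths$vpath[[1]])
  expect_identical(ids, c("dataset:only/events", "step:only/scale_ts",
                          "dataset:only/events_scaled",
                          "step:only/count_rows", "measure:only/tap-count"))
  expect_true(trace_is_acyclic(res$trace))
})

test_that("cyclic step declarations are rejected before execution", {
  a <- processing_step("a", "transform", function(lv, rd, config) NULL,
                       inputs = "x", outputs = "y")
  b <- processing_step("b", "transform", function(lv, rd, config) NULL,
                       inputs = "y", outputs = "x")
  expect_error(process_reading(minimal_reading(), list(a, b)),
               "configuration error.*cyclic")
})

test_that("stopped_processing flags abort only the flagged level", {
  fx <- gen_drawing("all", seed = 2)
  r <- fx$reading
  stopper <- processing_step("stopper", "flag", function(lv, rd, config) {
    if (level_modality(lv, "hand") == "left") {
      list(quality_flag(flag_id("draw", "behavioral", "invalidation", "bail"),
                        targets = sprintf("level:%s", lv$id),
                        stopped_processing = TRUE))
    }
  }, inputs = "touch")
  extract <- processing_step("extract", "extract", function(lv, rd, config) {
    add_measure(measure_set(),
                measure_value(value_definition("draw-after"), 1))
  }, inputs = "touch")
  res <- process_reading(r, list(stopper, extract))
  got <- vapply(res$reading$levels,
                function(lv) "draw-after" %in% measure_ids(lv$measures),
                logical(1))
  hands <- vapply(res$reading$levels, level_modality, character(1),
                  dimension = "hand")
  expect_true(all(got[hands == "right"]))
  expect_false(any(got[hands == "left"]))
  st <- res$trace$steps
  expect_setequal(st$status[st$step_id == "extract" &
                              grepl("left", st$level_id)],
                  "aborted_by_flag")
})

test_that("processing is deterministic and never mutates raw data", {
  fx <- gen_walk(cadence = 100, duration = 30, fs = 50, seed = 6)
  before <- digest_raw <- fx$reading$levels[[1]]$datasets[["acc"]]$data
  # detect_steps needs >= 5 s; 30 s is plenty
  res1 <- run_registered(fx$reading)
  res2 <- run_registered(fx$reading)
  m1 <- vapply(res1$reading$levels[[1]]$measures$values,
               function(m) m$value, numeric(1))
  m2 <- vapply(res2$reading$levels[[1]]$measures$values,
               function(m) m$value, numeric(1))
  expect_identical(m1, m2)
  expect_identical(export_trace(res1$trace)$edges,
                   export_trace(res2$trace)$edges)
  expect_identical(res1$reading$levels[[1]]$datasets[["acc"]]$data, before)
})

test_that("deleting any single raw dataset only converts steps to skips", {
  suite <- gen_fixture_suite(3)
  for (code in c("sixmwt", "utt", "draw", "cps")) {
    r <- suite[[code]]$reading
    lv <- r$levels[[1]]
    lv$datasets <- list()
    r$levels[[1]] <- lv
    expect_silent(res <- process_reading(r, registry_steps(code)))
    st <- res$trace$steps
    expect_true(all(st$status[st$level_id == names(r$levels)[1]] ==
                      "skipped_missing_input"))
  }
})

test_that("filter_levels subsets by predicate with order preserved", {
  fx <- gen_drawing("all", seed = 1)
  r <- fx$reading
  expect_length(filter_levels(r, c(hand = "left")), 8L)
  expect_length(filter_levels(r, function(lv) TRUE), 16L)
  expect_length(filter_levels(r, function(lv) FALSE), 0L)
  lefts <- filter_levels(r, c(hand = "left"))
  all_ids <- vapply(unname(r$levels), function(l) l$id, character(1))
  left_ids <- vapply(lefts, function(l) l$id, character(1))
  expect_identical(left_ids, all_ids[grepl("_left_", all_ids)])
})

test_that("trace export orders nodes deterministically and keeps step params", {
  r <- minimal_reading()
  res <- process_reading(r, list(
    processing_step("count", "extract", function(lv, rd, config) {
      add_measure(measure_set(),
                  measure_value(value_definition("tap-count"), 1))
    }, inputs = "events", params = list(window = 2.5))))
  ex <- export_trace(res$trace)
  expect_identical(ex$nodes$id, sort(ex$nodes$id))
  expect_match(ex$steps$params, "\"window\":2.5")
  snode <- ex$nodes$id[ex$nodes$kind == "step"]
  flow <- ex$edges[ex$edges$relation %in% c("input", "output"), ]
  expect_equal(sum(flow$to == snode), 1L)   # one declared input
  expect_equal(sum(flow$from == snode), 1L) # one measure out

  empty <- process_reading(r, list())
  ex0 <- export_trace(empty$trace)
  expect_equal(sum(ex0$nodes$kind == "step"), 0L)
  expect_true(all(ex0$nodes$kind %in% c("reading", "level", "dataset")))

  dot <- trace_to_dot(res$trace)
  expect_match(dot, "digraph data_trace")
  expect_match(dot, "measure:only/tap-count", fixed = TRUE)
})
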