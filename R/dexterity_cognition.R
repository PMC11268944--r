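# SDM extraction for handheld-smartphone tests: shape drawing, pinching,
# symbol-digit substitution (processing speed), event-based dexterity
# variants (tapping, typing, grip, sit-to-stand counts) and questionnaire
# scoring.

# Resample a polyline to n points equally spaced in arc length.
arc_length_resample <- function(xy, n_points) {
  xy <- as.matrix(xy)
  if (nrow(xy) == 1L) return(xy[rep(1L, n_points), , drop = FALSE])
  seg <- sqrt(rowSums(diff(xy)^2))
  s <- c(0, cumsum(seg))
  total <- s[length(s)]
  if (total == 0) return(xy[rep(1L, n_points), , drop = FALSE])
  keep <- c(TRUE, seg > 0)       # drop zero-length segments for approx()
  s <- s[keep]; xy <- xy[keep, , drop = FALSE]
  grid <- seq(0, total, length.out = n_points)
  cbind(stats::approx(s, xy[, 1], xout = grid)$y,
        stats::approx(s, xy[, 2], xout = grid)$y)
}

# Full (unconstrained) dynamic-time-warping alignment with Euclidean local
# cost; returns total optimal cost and the optimal path length.
dtw_align <- function(a, b) {
  n <- nrow(a); m <- nrow(b)
  d <- outer(seq_len(n), seq_len(m), function(i, j) {
    sqrt((a[i, 1] - b[j, 1])^2 + (a[i, 2] - b[j, 2])^2)
  })
  D <- matrix(Inf, n, m)
  D[1, 1] <- d[1, 1]
  for (j in 2:m) D[1, j] <- D[1, j - 1] + d[1, j]
  for (i in 2:n) {
    D[i, 1] <- D[i - 1, 1] + d[i, 1]
    for (j in 2:m) {
      D[i, j] <- d[i, j] + min(D[i - 1, j], D[i, j - 1], D[i - 1, j - 1])
    }
  }
  # backtrack for path length
  i <- n; j <- m; len <- 1L
  while (i > 1L || j > 1L) {
    if (i == 1L) j <- j - 1L
    else if (j == 1L) i <- i - 1L
    else {
      k <- which.min(c(D[i - 1, j - 1], D[i - 1, j], D[i, j - 1]))
      if (k == 1L) { i <- i - 1L; j <- j - 1L }
      else if (k == 2L) i <- i - 1L
      else j <- j - 1L
    }
    len <- len + 1L
  }
  list(total = D[n, m], path_length = len)
}

#' Similarity of a drawn trace to its reference shape
#'
#' Both the finger trace and the reference polyline are resampled to
#' `n_points` equally spaced in arc length. `sim` is the mean Euclidean
#' distance between index-coupled points; `dtw_sim` is the dynamic time
#' warping path-averaged distance (full alignment, Euclidean local cost),
#' which is never larger than `sim` because the identity alignment is one
#' admissible warping path. Units are the input screen units.
#'
#' @param trace Data frame with columns `t, x, y` (t non-decreasing).
#' @param reference Two-column matrix/data.frame of reference vertices
#'   (>= 2 rows).
#' @param n_points Resampling size (default 100; traces longer than 2000
#'   points are handled identically since resampling comes first).
#' @return List with `sim`, `dtw_sim` (screen units) and `duration` (s).
#' @export
#' @examples
#' ref <- cbind(c(0, 1, 1, 0, 0), c(0, 0, 1, 1, 0))
#' tr <- data.frame(t = seq_len(5), x = ref[, 1] + 3, y = ref[, 2] + 4)
#' drawing_similarity(tr, ref)$sim   # 5: rigid (3,4) offset
drawing_similarity <- function(trace, reference, n_points = 100) {
  stopifnot(nrow(trace) >= 2L, nrow(reference) >= 2L)
  if (is.unsorted(trace$t)) stop("trace timestamps must be non-decreasing",
                                 call. = FALSE)
  a <- arc_length_resample(cbind(trace$x, trace$y), n_points)
  b <- arc_length_resample(as.matrix(reference), n_points)
  sim <- mean(sqrt(rowSums((a - b)^2)))
  al <- dtw_align(a, b)
  list(sim = sim, dtw_sim = al$total / al$path_length,
       duration = trace$t[nrow(trace)] - trace$t[1])
}

#' Pinch-attempt measures from two-finger touch streams
#'
#' A pinch attempt is a maximal interval during which two simultaneous
#' screen contacts are present; the attempt succeeds when the
#' inter-contact distance shrinks below `target_distance` at any moment of
#' the attempt.
#'
#' @param touch Data frame with columns `ts, x1, y1, c1, x2, y2, c2`
#'   (`c1`, `c2` are 0/1 contact indicators).
#' @param target_distance Success threshold in screen units.
#' @return List with `attempts`, `successes`, `success_rate`
#'   (`NA` with zero attempts), `ipi_mean` (mean inter-pinch interval
#'   between attempt starts, s; `NA` with < 2 attempts) and
#'   `single_finger` (`TRUE` when contacts occurred but never two at
#'   once).
#' @export
pinch_measures <- function(touch, target_distance) {
  both <- touch$c1 > 0 & touch$c2 > 0
  any_contact <- touch$c1 > 0 | touch$c2 > 0
  runs <- rle(both)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  attempt_idx <- which(runs$values)
  attempts <- length(attempt_idx)
  successes <- 0L
  start_times <- numeric(0)
  for (k in attempt_idx) {
    i <- starts[k]:ends[k]
    dist <- sqrt((touch$x1[i] - touch$x2[i])^2 + (touch$y1[i] - touch$y2[i])^2)
    if (any(dist < target_distance)) successes <- successes + 1L
    start_times <- c(start_times, touch$ts[starts[k]])
  }
  list(attempts = attempts, successes = successes,
       success_rate = if (attempts > 0) successes / attempts else NA_real_,
       ipi_mean = if (attempts >= 2) mean(diff(start_times)) else NA_real_,
       single_finger = attempts == 0L && any(any_contact))
}

#' Symbol-digit substitution (processing speed) measures
#'
#' A response is correct when it equals the key mapping of its stimulus.
#' Reaction times are computed over correct trials; the drift is the mean
#' reaction time of the last third of trials minus that of the first third
#' (a positive drift indicates slowing over the test).
#'
#' @param trials Data frame with columns
#'   `stimulus, response, t_shown, t_answered` in presentation order.
#' @param key_map Named vector mapping stimulus (as character) to the
#'   correct response.
#' @return List with `n_correct`, `n_total`, `accuracy`, `rt_mean`,
#'   `rt_median`, `rt_drift` (all reaction times in seconds; RT fields
#'   `NA` when no/too few correct trials).
#' @export
cps_measures <- function(trials, key_map) {
  if (is.null(trials) || nrow(trials) == 0L) {
    stop("insufficient data: empty response log", call. = FALSE)
  }
  stopifnot(all(trials$t_answered >= trials$t_shown))
  correct <- trials$response == unname(key_map[as.character(trials$stimulus)])
  correct[is.na(correct)] <- FALSE
  rt <- (trials$t_answered - trials$t_shown)[correct]
  k <- length(rt) %/% 3L
  drift <- if (k >= 1L) {
    mean(rt[(length(rt) - k + 1L):length(rt)]) - mean(rt[1:k])
  } else NA_real_
  list(n_correct = sum(correct), n_total = nrow(trials),
       accuracy = sum(correct) / nrow(trials),
       rt_mean = if (length(rt)) mean(rt) else NA_real_,
       rt_median = if (length(rt)) stats::median(rt) else NA_real_,
       rt_drift = drift)
}

#' Summary statistics for an event (tap/keystroke/repetition) stream
#'
#' Shared backend for tapping, typing, grip and sit-to-stand style tests:
#' the count, the rate `count / span` with span the time from first to
#' last event, and mean and coefficient of variation of inter-event
#' intervals (absent with fewer than two events).
#'
#' @param events Numeric vector of event timestamps (s), non-decreasing.
#' @return List with `count`, `span`, `rate`, `iei_mean`, `iei_cv`.
#' @export
#' @examples
#' event_stats(0:9)$rate   # 10 events over a 9 s span -> 1.111 /s
event_stats <- function(events) {
  n <- length(events)
  if (n == 0L) {
    return(list(count = 0L, span = NA_real_, rate = NA_real_,
                iei_mean = NA_real_, iei_cv = NA_real_))
  }
  if (is.unsorted(events)) stop("event times must be non-decreasing",
                                call. = FALSE)
  span <- events[n] - events[1]
  iei <- diff(events)
  list(count = n, span = span,
       rate = if (n >= 2 && span > 0) n / span else NA_real_,
       iei_mean = if (n >= 2) mean(iei) else NA_real_,
       iei_cv = if (n >= 3 && mean(iei) > 0) stats::sd(iei) / mean(iei)
                else NA_real_)
}

# ---- questionnaires --------------------------------------------------------

#' Define a questionnaire scoring configuration
#'
#' Scoring is data, not code: an instrument is its item count, per-item
#' range and a set of subscales, each summing a group of items with a
#' transform (`"sum"` for the raw sum, `"scaled_0_100"` for
#' `100 * (sum - n*min) / ((max - min) * n)`). An optional summary rule
#' `"mean_of_subscales"` adds the mean of all subscale scores.
#'
#' @param instrument Instrument slug (e.g. `"msis29"`).
#' @param n_items Number of items.
#' @param item_range `c(min, max)` of admissible answers.
#' @param subscales Named list; each element a list with `items` (integer
#'   indices) and `transform`.
#' @param summary `NULL` or list with `id` and `rule`.
#' @return A `questionnaire_config` object.
#' @export
questionnaire_config <- function(instrument, n_items, item_range,
                                 subscales, summary = NULL) {
  assert_slug(instrument, "instrument")
  for (s in subscales) {
    stopifnot(all(s$items >= 1L), all(s$items <= n_items),
              s$transform %in% c("sum", "scaled_0_100"))
  }
  structure(list(instrument = instrument, n_items = as.integer(n_items),
                 item_range = as.numeric(item_range),
                 subscales = subscales, summary = summary),
            class = "questionnaire_config")
}

#' Built-in questionnaire configurations
#'
#' `msis29`: Multiple Sclerosis Impact Scale, 29 items scored 1--5;
#' physical subscale items 1--20, psychological items 21--29, each scaled
#' 0--100. `alsfrs_r`: ALS Functional Rating Scale (Revised), 12 items
#' scored 0--4, total = sum (0--48). `pdq39`: Parkinson's Disease
#' Questionnaire, 39 items scored 0--4, eight published dimensions each
#' scaled 0--100, summary index = mean of the eight. `mood`, `fatigue`,
#' `qol` are generic placeholder instruments (10/9/5 items, scaled
#' totals) wired through the same engine.
#'
#' @param instrument Instrument slug.
#' @return A [questionnaire_config()].
#' @export
builtin_questionnaire <- function(instrument) {
  switch(instrument,
    msis29 = questionnaire_config("msis29", 29, c(1, 5), list(
      physical = list(items = 1:20, transform = "scaled_0_100"),
      psychological = list(items = 21:29, transform = "scaled_0_100"))),
    alsfrs_r = questionnaire_config("alsfrs_r", 12, c(0, 4), list(
      total = list(items = 1:12, transform = "sum"))),
    pdq39 = questionnaire_config("pdq39", 39, c(0, 4), list(
      mobility = list(items = 1:10, transform = "scaled_0_100"),
      adl = list(items = 11:16, transform = "scaled_0_100"),
      emotional = list(items = 17:22, transform = "scaled_0_100"),
      stigma = list(items = 23:26, transform = "scaled_0_100"),
      social = list(items = 27:29, transform = "scaled_0_100"),
      cognition = list(items = 30:33, transform = "scaled_0_100"),
      communication = list(items = 34:36, transform = "scaled_0_100"),
      bodily_discomfort = list(items = 37:39, transform = "scaled_0_100")),
      summary = list(id = "si", rule = "mean_of_subscales")),
    mood = questionnaire_config("mood", 10, c(0, 4), list(
      total = list(items = 1:10, transform = "scaled_0_100"))),
    fatigue = questionnaire_config("fatigue", 9, c(1, 7), list(
      total = list(items = 1:9, transform = "scaled_0_100"))),
    qol = questionnaire_config("qol", 5, c(0, 4), list(
      total = list(items = 1:5, transform = "scaled_0_100"))),
    stop("unknown questionnaire instrument: ", instrument, call. = FALSE))
}

#' Score a questionnaire
#'
#' @param config A [questionnaire_config()] or instrument slug resolved
#'   through [builtin_questionnaire()].
#' @param answers Numeric vector of item answers, length `n_items`, each
#'   within the instrument's item range (violations are a validation
#'   error).
#' @return Named numeric vector of subscale (and summary) scores, names
#'   `{instrument}-{subscale}`.
#' @export
#' @examples
#' score_questionnaire("alsfrs_r", rep(4, 12))   # total 48
score_questionnaire <- function(config, answers) {
  if (is.character(config)) config <- builtin_questionnaire(config)
  stopifnot(inherits(config, "questionnaire_config"))
  if (length(answers) != config$n_items) {
    stop(sprintf("%s expects %d answers, got %d", config$instrument,
                 config$n_items, length(answers)), call. = FALSE)
  }
  lo <- config$item_range[1]; hi <- config$item_range[2]
  bad <- which(answers < lo | answers > hi | is.na(answers))
  if (length(bad)) {
    stop(sprintf("%s answers out of range [%g, %g] at item(s) %s",
                 config$instrument, lo, hi,
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  scores <- vapply(config$subscales, function(s) {
    n <- length(s$items)
    total <- sum(answers[s$items])
    switch(s$transform,
           sum = total,
           scaled_0_100 = 100 * (total - n * lo) / ((hi - lo) * n))
  }, numeric(1))
  names(scores) <- paste(config$instrument, names(config$subscales), sep = "-")
  if (!is.null(config$summary) && config$summary$rule == "mean_of_subscales") {
    si <- mean(scores)
    names(si) <- paste(config$instrument, config$summary$id, sep = "-")
    scores <- c(scores, si)
  }
  scores
}

# ---- level-based extractors (registry backends) ---------------------------

draw_level_measures <- function(lv, config = sdm_config()) {
  ds <- lv$datasets[["touch"]]
  if (is.null(ds)) stop("draw level has no 'touch' dataset", call. = FALSE)
  ref <- lv$context$reference
  if (is.null(ref)) stop("draw level context lacks 'reference' polyline",
                         call. = FALSE)
  ref <- matrix(unlist(ref), ncol = 2, byrow = FALSE)
  tr <- data.frame(t = ds$data$ts, x = ds$data$x, y = ds$data$y)
  res <- drawing_similarity(tr, ref)
  mid <- function(abbr) generate_measure_id("draw", lv$modalities, abbr)
  ms <- measure_set()
  ms <- add_measure(ms, mv(mid("sim"), res$sim, "px"))
  ms <- add_measure(ms, mv(mid("dtw_sim"), res$dtw_sim, "px"))
  ms <- add_measure(ms, mv(mid("duration"), res$duration, "s"))
  list(measures = ms, flags = list(), epochs = list())
}

pinch_level_measures <- function(lv, config = sdm_config()) {
  ds <- lv$datasets[["touch"]]
  if (is.null(ds)) stop("pinch level has no 'touch' dataset", call. = FALSE)
  target <- lv$context$target_distance
  if (is.null(target)) target <- 50
  res <- pinch_measures(ds$data, target)
  mid <- function(abbr, agg = NULL)
    generate_measure_id("pinch", lv$modalities, abbr, agg)
  ms <- measure_set()
  ms <- add_measure(ms, mv(mid("attempts"), res$attempts, ""))
  ms <- add_measure(ms, mv(mid("successes"), res$successes, ""))
  if (!is.na(res$success_rate)) {
    ms <- add_measure(ms, mv(mid("success_rate"), res$success_rate, ""))
  }
  if (!is.na(res$ipi_mean)) {
    ms <- add_measure(ms, mv(mid("ipi", "mean"), res$ipi_mean, "s"))
  }
  flags <- list()
  if (res$single_finger) {
    flags <- list(quality_flag(
      flag_id("pinch", "behavioral", "deviation", "single_finger"),
      reason = "screen contacts present but never two simultaneously",
      targets = sprintf("level:%s", lv$id)))
  }
  list(measures = ms, flags = flags, epochs = list())
}

cps_level_measures <- function(lv, config = sdm_config()) {
  ds <- lv$datasets[["responses"]]
  if (is.null(ds)) stop("cps level has no 'responses' dataset", call. = FALSE)
  key_map <- unlist(lv$context$key_map)
  trials <- data.frame(stimulus = ds$data$stimulus,
                       response = ds$data$response,
                       t_shown = ds$data$ts,
                       t_answered = ds$data$t_answered)
  res <- cps_measures(trials, key_map)
  mid <- function(abbr, agg = NULL)
    generate_measure_id("cps", lv$modalities, abbr, agg)
  ms <- measure_set()
  ms <- add_measure(ms, mv(mid("n_correct"), res$n_correct, ""))
  ms <- add_measure(ms, mv(mid("n_total"), res$n_total, ""))
  ms <- add_measure(ms, mv(mid("accuracy"), res$accuracy, ""))
  if (!is.na(res$rt_mean)) {
    ms <- add_measure(ms, mv(mid("rt", "mean"), res$rt_mean, "s"))
    ms <- add_measure(ms, mv(mid("rt", "median"), res$rt_median, "s"))
  }
  if (!is.na(res$rt_drift)) {
    ms <- add_measure(ms, mv(mid("rt_drift"), res$rt_drift, "s"))
  }
  list(measures = ms, flags = list(), epochs = list())
}

events_level_measures <- function(task) {
  force(task)
  function(lv, config = sdm_config()) {
    ds <- lv$datasets[["events"]]
    if (is.null(ds)) stop(task, " level has no 'events' dataset", call. = FALSE)
    res <- event_stats(ds$data$ts)
    mid <- function(abbr, agg = NULL)
      generate_measure_id(task, lv$modalities, abbr, agg)
    ms <- measure_set()
    ms <- add_measure(ms, mv(mid("count"), res$count, ""))
    if (!is.na(res$rate)) ms <- add_measure(ms, mv(mid("rate"), res$rate, "1/s"))
    if (!is.na(res$iei_mean)) {
      ms <- add_measure(ms, mv(mid("iei", "mean"), res$iei_mean, "s"))
    }
    if (!is.na(res$iei_cv)) {
      ms <- add_measure(ms, mv(mid("iei", "cv"), res$iei_cv, ""))
    }
    list(measures = ms, flags = list(), epochs = list())
  }
}

questionnaire_level_measures <- function(instrument) {
  force(instrument)
  function(lv, config = sdm_config()) {
    ds <- lv$datasets[["answers"]]
    if (is.null(ds)) stop(instrument, " level has no 'answers' dataset",
                          call. = FALSE)
    ans <- ds$data$answer[order(ds$data$item)]
    scores <- score_questionnaire(instrument, ans)
    ms <- measure_set()
    for (i in seq_along(scores)) {
      ms <- add_measure(ms, mv(names(scores)[i], unname(scores[i]), ""))
    }
    list(measures = ms, flags = list(), epochs = list())
  }
}
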