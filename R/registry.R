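# Test registry: evaluation code -> processing-step factory. The default
# build registers 16 structured tests, 6 of which are questionnaires.

.registry <- new.env(parent = emptyenv())

#' Register a structured test
#'
#' @param code Evaluation code slug (unique).
#' @param category `"test"` or `"questionnaire"`.
#' @param steps_factory `function(config) -> list of` [processing_step()];
#'   must contain at least one extract step.
#' @param description One-line description of the test.
#' @return Invisibly, the code.
#' @export
register_test <- function(code, category = c("test", "questionnaire"),
                          steps_factory, description = "") {
  assert_slug(code, "evaluation code")
  category <- match.arg(category)
  steps <- steps_factory(sdm_config())
  if (!any(vapply(steps, function(s) s$kind == "extract", logical(1)))) {
    stop("every registered test needs at least one extract step",
         call. = FALSE)
  }
  assign(code, list(code = code, category = category,
                    steps_factory = steps_factory,
                    description = description),
         envir = .registry)
  invisible(code)
}

#' Remove all registry entries (mainly for tests of the registry itself)
#' @return Invisibly `NULL`.
#' @export
clear_registry <- function() {
  rm(list = ls(.registry), envir = .registry)
  invisible(NULL)
}

#' Look up the processing steps for an evaluation code
#'
#' @param code Evaluation code.
#' @param config Threshold configuration forwarded to the step factory.
#' @return List of [processing_step()]s.
#' @export
registry_steps <- function(code, config = sdm_config()) {
  if (!exists(code, envir = .registry, inherits = FALSE)) {
    stop(sprintf("unknown evaluation code '%s'; registered: %s", code,
                 paste(sort(ls(.registry)), collapse = ", ")),
         call. = FALSE)
  }
  get(code, envir = .registry)$steps_factory(config)
}

#' List the registered tests
#'
#' @return Data frame with `code`, `category`, `description` and
#'   `n_steps`, ordered by code.
#' @export
list_tests <- function() {
  codes <- sort(ls(.registry))
  out <- do.call(rbind, lapply(codes, function(cd) {
    e <- get(cd, envir = .registry)
    data.frame(code = e$code, category = e$category,
               description = e$description,
               n_steps = length(e$steps_factory(sdm_config())),
               stringsAsFactors = FALSE)
  }))
  if (is.null(out)) {
    out <- data.frame(code = character(), category = character(),
                      description = character(), n_steps = integer(),
                      stringsAsFactors = FALSE)
  }
  out
}

#' Document the measures a registered test emits
#'
#' Runs the test's pipeline on its synthetic fixture and tabulates every
#' emitted measure id with its unit and name, so the documentation always
#' reflects the implementation.
#'
#' @param code Evaluation code.
#' @param seed Seed for the fixture.
#' @return Data frame with `measure_id`, `name`, `unit`.
#' @export
registry_docs <- function(code, seed = 1) {
  fx <- gen_fixture_suite(seed)[[code]]
  if (is.null(fx)) stop("no fixture generator for code ", code, call. = FALSE)
  res <- process_reading(fx$reading, registry_steps(code))
  rows <- list()
  for (lv in res$reading$levels) {
    for (m in lv$measures$values) {
      rows[[length(rows) + 1L]] <- data.frame(
        measure_id = m$definition$id, name = m$definition$name,
        unit = m$definition$unit, stringsAsFactors = FALSE)
    }
  }
  out <- unique(do.call(rbind, rows))
  out[order(out$measure_id), , drop = FALSE]
}

extract_step <- function(step_id, inputs, fn) {
  processing_step(step_id, "extract",
                  function(lv, rd, config) fn(lv, config),
                  inputs = inputs)
}

default_registrations <- function() {
  register_test("sixmwt", "test", function(config) list(
    extract_step("sixmwt_extract", "acc", sixmwt_measures)),
    "Six-minute walk: steps, cadence, step-time variability")
  register_test("utt", "test", function(config) list(
    extract_step("utt_extract", "gyro", utt_measures)),
    "U-turn: turn epochs, angles, durations, peak rates")
  register_test("sbt", "test", function(config) list(
    extract_step("sbt_extract", "acc", sbt_measures)),
    "Static balance: sway RMS, 95% ellipse area, jerk")
  register_test("draw", "test", function(config) list(
    extract_step("draw_extract", "touch", draw_level_measures)),
    "Shape drawing: trace-to-reference similarity (coupled and DTW)")
  register_test("pinch", "test", function(config) list(
    extract_step("pinch_extract", "touch", pinch_level_measures)),
    "Pinch: attempts, successes, success rate")
  register_test("cps", "test", function(config) list(
    extract_step("cps_extract", "responses", cps_level_measures)),
    "Symbol-digit substitution: accuracy, reaction times, drift")
  for (code in c("tap", "typing", "grip", "sts")) {
    local({
      cd <- code
      register_test(cd, "test", function(config) list(
        extract_step(paste0(cd, "_extract"), "events",
                     events_level_measures(cd))),
        sprintf("Event-based test '%s': count, rate, interval stats", cd))
    })
  }
  for (instr in c("msis29", "alsfrs_r", "pdq39", "mood", "fatigue", "qol")) {
    local({
      it <- instr
      register_test(it, "questionnaire", function(config) list(
        extract_step(paste0(it, "_score"), "answers",
                     questionnaire_level_measures(it))),
        sprintf("Questionnaire '%s' scored per its published rule", it))
    })
  }
  invisible(NULL)
}

.onLoad <- function(libname, pkgname) {
  default_registrations()
}
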