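# In-memory model for structured-test recordings: a Reading holds ordered
# Levels (one sub-task attempt each, keyed by modalities); levels hold raw
# columnar sensor datasets, analysis epochs, extracted measures and quality
# flags. All timestamps are seconds (double) relative to reading start.

SLUG_RE <- "^[a-z0-9_]+$"

is_slug <- function(x) {
  is.character(x) && length(x) == 1L && !is.na(x) && grepl(SLUG_RE, x)
}

assert_slug <- function(x, what) {
  if (!is_slug(x)) {
    stop(sprintf("invalid slug for %s: %s (must match [a-z0-9_]+, no '-')",
                 what, deparse(x)), call. = FALSE)
  }
  invisible(x)
}

#' Define a named, unit-carrying value
#'
#' A value definition describes one column of a raw dataset or one
#' sensor-derived measure: a lowercase slug identifier, a human-readable
#' name, a unit string (SI, or `""` for dimensionless values and counts),
#' a data type and an optional valid range.
#'
#' @param id Lowercase slug (`[a-z0-9_]+`, dash-separated segments allowed
#'   for measure ids).
#' @param name Human-readable name.
#' @param unit Unit string; `""` for dimensionless.
#' @param data_type One of `"float"`, `"int"`, `"bool"`, `"string"`,
#'   `"timestamp"`.
#' @param valid_range Optional closed interval `c(lo, hi)`.
#' @return An object of class `value_definition`.
#' @export
#' @examples
#' value_definition("cadence", "Step cadence", "steps/min")
value_definition <- function(id, name = id, unit = "",
                             data_type = "float", valid_range = NULL) {
  if (!is.character(id) || length(id) != 1L ||
      !grepl("^[a-z0-9_]+(-[a-z0-9_]+)*$", id)) {
    stop(sprintf("invalid value-definition id: %s", deparse(id)), call. = FALSE)
  }
  data_type <- match.arg(data_type,
                         c("float", "int", "bool", "string", "timestamp"))
  if (!is.null(valid_range)) {
    stopifnot(is.numeric(valid_range), length(valid_range) == 2L,
              valid_range[1] <= valid_range[2])
    valid_range <- as.numeric(valid_range)
  }
  structure(list(id = id, name = name, unit = unit,
                 data_type = data_type, valid_range = valid_range),
            class = "value_definition")
}

#' Describe the recording device/sensor source
#'
#' @param device_model Free-text device model.
#' @param sensor Sensor kind (e.g. `"accelerometer"`, `"gyroscope"`,
#'   `"touchscreen"`).
#' @param sampling_frequency Nominal sampling frequency in Hz (`NA` for
#'   event streams).
#' @param placement One of `"handheld"`, `"belt"`, `"none"`.
#' @return A `sensor_source` list.
#' @export
sensor_source <- function(device_model = "generic", sensor = "accelerometer",
                          sampling_frequency = NA_real_,
                          placement = c("handheld", "belt", "none")) {
  placement <- match.arg(placement)
  structure(list(device_model = device_model, sensor = sensor,
                 sampling_frequency = as.numeric(sampling_frequency),
                 placement = placement),
            class = "sensor_source")
}

#' Create a raw columnar sensor dataset
#'
#' Rectangular, column-major timestamped data. The first column must have
#' data type `"timestamp"` (seconds, monotone non-decreasing); violations
#' of monotonicity are tolerated at construction (they are flagged at load
#' time) but column lengths must agree and column ids must be unique.
#'
#' @param id Dataset slug.
#' @param source A [sensor_source()].
#' @param columns List of [value_definition()]s, first of type timestamp.
#' @param data A data.frame whose names equal the column ids.
#' @return An object of class `raw_dataset`.
#' @export
raw_dataset <- function(id, source, columns, data) {
  assert_slug(id, "dataset id")
  stopifnot(inherits(source, "sensor_source"), is.list(columns),
            length(columns) >= 1L, is.data.frame(data))
  ids <- vapply(columns, function(c) c$id, character(1))
  if (anyDuplicated(ids)) stop("duplicate column ids in dataset ", id,
                               call. = FALSE)
  if (columns[[1]]$data_type != "timestamp") {
    stop("first column of a raw dataset must be a timestamp", call. = FALSE)
  }
  if (!identical(names(data), ids)) {
    stop("data column names must equal column definition ids", call. = FALSE)
  }
  rownames(data) <- NULL
  structure(list(id = id, source = source, columns = columns, data = data),
            class = "raw_dataset")
}

#' @export
print.raw_dataset <- function(x, ...) {
  cat(sprintf("<raw_dataset '%s'> %s, %d columns x %d rows\n",
              x$id, x$source$sensor, length(x$columns), nrow(x$data)))
  invisible(x)
}

ds_timestamps <- function(ds) ds$data[[1]]

#' Label one dimension of a level
#'
#' Modalities distinguish levels within a test: e.g. the shape drawn, the
#' hand used, the attempt number.
#'
#' @param dimension Dimension name (e.g. `"hand"`).
#' @param value Dimension value (slug; `_` allowed, `-` reserved).
#' @return A `modality` object.
#' @export
modality <- function(dimension, value) {
  stopifnot(is.character(dimension), length(dimension) == 1L)
  assert_slug(value, sprintf("modality value (%s)", dimension))
  structure(list(dimension = dimension, value = value), class = "modality")
}

#' Create an analysis epoch within a level
#'
#' A custom time window of analysis (e.g. one detected turn) with an
#' optional payload of derived quantities.
#'
#' @param definition [value_definition()] naming the epoch kind.
#' @param start,end Window bounds in seconds, `start <= end`.
#' @param payload Optional named list (e.g. turn angle).
#' @return A `level_epoch` object.
#' @export
level_epoch <- function(definition, start, end, payload = NULL) {
  stopifnot(inherits(definition, "value_definition"),
            is.numeric(start), is.numeric(end))
  if (start > end) stop("epoch start must be <= end", call. = FALSE)
  structure(list(definition = definition, start = as.numeric(start),
                 end = as.numeric(end), payload = payload),
            class = "level_epoch")
}

#' Create a level (one sub-task attempt)
#'
#' The level id is the ordered modality values rendered as a slug joined by
#' `_` (or an explicit id for single-level tests).
#'
#' @param modalities List of [modality()] objects (may be empty).
#' @param start,end Level bounds in seconds.
#' @param context Named list of protocol parameters (e.g. reference shape
#'   vertices, expected duration).
#' @param datasets List of [raw_dataset()]s.
#' @param id Optional explicit id; defaults to joined modality values.
#' @return An object of class `level`.
#' @export
level <- function(modalities = list(), start = 0, end = 0,
                  context = list(), datasets = list(), id = NULL) {
  stopifnot(is.list(modalities), is.list(datasets))
  for (m in modalities) stopifnot(inherits(m, "modality"))
  dims <- vapply(modalities, function(m) m$dimension, character(1))
  if (anyDuplicated(dims)) stop("duplicate modality dimensions", call. = FALSE)
  if (is.null(id)) {
    id <- if (length(modalities)) {
      paste(vapply(modalities, function(m) m$value, character(1)),
            collapse = "_")
    } else "all"
  }
  assert_slug(id, "level id")
  if (start > end) stop("level start must be <= end", call. = FALSE)
  lv <- structure(list(id = id, modalities = modalities,
                       start = as.numeric(start), end = as.numeric(end),
                       context = context, datasets = list(),
                       epochs = list(), measures = measure_set(),
                       flags = list()),
                  class = "level")
  for (ds in datasets) lv <- level_add_dataset(lv, ds)
  lv
}

level_add_dataset <- function(lv, ds) {
  stopifnot(inherits(lv, "level"), inherits(ds, "raw_dataset"))
  if (ds$id %in% names(lv$datasets)) {
    stop(sprintf("dataset id '%s' already present in level '%s'",
                 ds$id, lv$id), call. = FALSE)
  }
  lv$datasets[[ds$id]] <- ds
  lv
}

level_add_epoch <- function(lv, ep) {
  stopifnot(inherits(ep, "level_epoch"))
  lv$epochs[[length(lv$epochs) + 1L]] <- ep
  lv
}

#' Look up a modality value on a level
#'
#' @param lv A [level()].
#' @param dimension Dimension name.
#' @return The value, or `NA_character_` if the dimension is absent.
#' @export
level_modality <- function(lv, dimension) {
  for (m in lv$modalities) if (m$dimension == dimension) return(m$value)
  NA_character_
}

#' @export
print.level <- function(x, ...) {
  cat(sprintf("<level '%s'> [%.3f, %.3f] s, %d dataset(s), %d measure(s), %d flag(s)\n",
              x$id, x$start, x$end, length(x$datasets),
              length(x$measures$values), length(x$flags)))
  invisible(x)
}

#' Create an empty measure set
#'
#' A collection of [measure_value()]s keyed by definition id. Duplicate
#' ids are an error; iteration order is deterministic (sorted by id).
#'
#' @return A `measure_set` object.
#' @export
measure_set <- function() {
  structure(list(values = list()), class = "measure_set")
}

#' Create a measure value
#'
#' @param definition A [value_definition()].
#' @param value Scalar value.
#' @param flags Character vector of flag ids annotating this measure.
#' @return A `measure_value` object.
#' @export
measure_value <- function(definition, value, flags = character()) {
  stopifnot(inherits(definition, "value_definition"))
  structure(list(definition = definition, value = value, flags = flags),
            class = "measure_value")
}

#' Add a measure to a measure set
#'
#' @param set A [measure_set()].
#' @param m A [measure_value()].
#' @param provenance Optional label used in the collision error message.
#' @return The augmented set; prior content unchanged.
#' @export
#' @examples
#' s <- add_measure(measure_set(),
#'                  measure_value(value_definition("cps-rt-mean", unit = "s"), 0.61))
#' measure_ids(s)
add_measure <- function(set, m, provenance = NULL) {
  stopifnot(inherits(set, "measure_set"), inherits(m, "measure_value"))
  id <- m$definition$id
  if (id %in% names(set$values)) {
    prior <- attr(set$values[[id]], "provenance")
    stop(sprintf(
      "measure id collision for '%s': already produced by <%s>, now by <%s>",
      id, if (is.null(prior)) "unknown step" else prior,
      if (is.null(provenance)) "unknown step" else provenance), call. = FALSE)
  }
  if (!is.null(provenance)) attr(m, "provenance") <- provenance
  set$values[[id]] <- m
  set$values <- set$values[order(names(set$values))]
  set
}

#' Merge two measure sets
#'
#' Colliding ids are an error (a set holds at most one value per id).
#'
#' @param a,b Measure sets.
#' @return The merged set.
#' @export
merge_measure_sets <- function(a, b) {
  for (m in b$values) a <- add_measure(a, m, provenance = attr(m, "provenance"))
  a
}

#' @export
print.measure_set <- function(x, ...) {
  cat(sprintf("<measure_set> %d measure(s)\n", length(x$values)))
  for (m in x$values) {
    cat(sprintf("  %-40s %s %s%s\n", m$definition$id, format(m$value),
                m$definition$unit,
                if (length(m$flags)) sprintf("  [%d flag(s)]", length(m$flags)) else ""))
  }
  invisible(x)
}

#' Ids of the measures in a set (sorted)
#' @param set A [measure_set()].
#' @return Character vector.
#' @export
measure_ids <- function(set) names(set$values)

#' Generate a standardized measure id
#'
#' Measure names link the task, the level (through its modality values) and
#' the measure abbreviation, with an optional aggregation suffix:
#' `{task}-{modality values joined by "_"}-{abbr}[-{agg}]`. An empty
#' modality list omits that segment. The mapping is deterministic and
#' injective as long as modality values contain no `-` or `_`.
#'
#' @param task Test slug (evaluation code).
#' @param modalities List of [modality()] objects or character vector of
#'   modality values.
#' @param abbr Measure abbreviation slug.
#' @param agg Optional aggregation slug (e.g. `"mean"`).
#' @return The measure id string.
#' @export
#' @examples
#' generate_measure_id("draw", c("square", "right", "first"), "sim", "mean")
#' generate_measure_id("sixmwt", character(), "cadence")
generate_measure_id <- function(task, modalities = character(), abbr,
                                agg = NULL) {
  assert_slug(task, "task")
  assert_slug(abbr, "abbr")
  vals <- if (is.list(modalities)) {
    vapply(modalities, function(m) m$value, character(1))
  } else as.character(modalities)
  for (v in vals) assert_slug(v, "modality value")
  if (!is.null(agg)) assert_slug(agg, "agg")
  parts <- c(task, if (length(vals)) paste(vals, collapse = "_"), abbr, agg)
  paste(parts, collapse = "-")
}

# ---- flags -----------------------------------------------------------------

FLAG_DOMAINS <- c("technical", "behavioral")
FLAG_SEVERITIES <- c("deviation", "invalidation")

#' Build a standardized flag id
#'
#' Flag ids follow the grammar `{task}-{domain}-{severity}-{name}` with
#' domain in `{technical, behavioral}` and severity in
#' `{deviation, invalidation}`.
#'
#' @param task Test slug.
#' @param domain `"technical"` or `"behavioral"`.
#' @param severity `"deviation"` (annotate) or `"invalidation"` (distrust).
#' @param name Short flag name slug.
#' @return Flag id string.
#' @export
flag_id <- function(task, domain, severity, name) {
  assert_slug(task, "task")
  domain <- match.arg(domain, FLAG_DOMAINS)
  severity <- match.arg(severity, FLAG_SEVERITIES)
  assert_slug(name, "flag name")
  paste(task, domain, severity, name, sep = "-")
}

#' Create a quality flag
#'
#' Flags annotate — never remove — data and measures. Targets are string
#' references resolved within one reading: `"reading"`, `"level:<id>"`,
#' `"dataset:<level>/<id>"`, `"epoch:<level>/<index>"`,
#' `"measure:<level or ''>/<id>"`.
#'
#' @param id Flag id from [flag_id()] (or a string obeying its grammar).
#' @param reason Free-text explanation.
#' @param targets Character vector of target references.
#' @param stopped_processing If `TRUE`, downstream processing steps on the
#'   flagged level are aborted (recorded in the trace), though already
#'   computed measures are kept.
#' @return A `quality_flag` object.
#' @export
quality_flag <- function(id, reason = "", targets = "reading",
                         stopped_processing = FALSE) {
  parts <- strsplit(id, "-", fixed = TRUE)[[1]]
  if (length(parts) < 4L || !(parts[2] %in% FLAG_DOMAINS) ||
      !(parts[3] %in% FLAG_SEVERITIES)) {
    stop(sprintf("flag id '%s' does not follow {task}-{domain}-{severity}-{name}",
                 id), call. = FALSE)
  }
  structure(list(id = id, reason = reason,
                 targets = as.character(targets),
                 stopped_processing = isTRUE(stopped_processing)),
            class = "quality_flag")
}

flag_domain <- function(f) strsplit(f$id, "-", fixed = TRUE)[[1]][2]
flag_severity <- function(f) strsplit(f$id, "-", fixed = TRUE)[[1]][3]

# ---- reading ---------------------------------------------------------------

#' Create a reading (one subject, one session, one test)
#'
#' @param evaluation_code Test slug; should be present in the test registry
#'   (see [list_tests()]).
#' @param subject_id,session_id Identifier strings.
#' @param device Device descriptor list (free-form; serialized verbatim).
#' @param levels Ordered list of [level()]s with unique ids.
#' @param schema_version Canonical-format schema version.
#' @param metadata Opaque bag of extra metadata keys (preserved on IO).
#' @return An object of class `reading`.
#' @export
reading <- function(evaluation_code, subject_id = "anon",
                    session_id = "s1", device = list(model = "generic"),
                    levels = list(), schema_version = "1.0",
                    metadata = list()) {
  assert_slug(evaluation_code, "evaluation code")
  ids <- vapply(levels, function(l) l$id, character(1))
  if (anyDuplicated(ids)) stop("duplicate level ids in reading", call. = FALSE)
  names(levels) <- ids
  structure(list(evaluation_code = evaluation_code,
                 subject_id = subject_id, session_id = session_id,
                 device = device, schema_version = schema_version,
                 levels = levels, measures = measure_set(),
                 flags = list(), metadata = metadata),
            class = "reading")
}

#' @export
print.reading <- function(x, ...) {
  nmeas <- length(x$measures$values) +
    sum(vapply(x$levels, function(l) length(l$measures$values), integer(1)))
  cat(sprintf("<reading '%s'> subject %s session %s: %d level(s), %d measure(s), %d reading-level flag(s)\n",
              x$evaluation_code, x$subject_id, x$session_id,
              length(x$levels), nmeas, length(x$flags)))
  invisible(x)
}

# Parse a target reference string into list(type, level, id).
parse_target <- function(ref) {
  if (ref == "reading") return(list(type = "reading"))
  m <- regmatches(ref, regexec("^(level|dataset|epoch|measure):(.*)$", ref))[[1]]
  if (length(m) == 0L) stop("malformed target reference: ", ref, call. = FALSE)
  type <- m[2]; rest <- m[3]
  if (type == "level") return(list(type = "level", level = rest))
  slash <- regexpr("/", rest, fixed = TRUE)
  if (slash < 0) {
    if (type == "measure") return(list(type = "measure", level = "", id = rest))
    stop("malformed target reference: ", ref, call. = FALSE)
  }
  list(type = type, level = substr(rest, 1, slash - 1),
       id = substr(rest, slash + 1, nchar(rest)))
}

resolve_target <- function(r, tgt) {
  p <- parse_target(tgt)
  ok <- switch(p$type,
    reading = TRUE,
    level = p$level %in% names(r$levels),
    dataset = p$level %in% names(r$levels) &&
      p$id %in% names(r$levels[[p$level]]$datasets),
    epoch = p$level %in% names(r$levels) &&
      suppressWarnings(!is.na(as.integer(p$id))) &&
      as.integer(p$id) <= length(r$levels[[p$level]]$epochs),
    measure = if (p$level == "") p$id %in% names(r$measures$values)
      else p$level %in% names(r$levels) &&
        p$id %in% names(r$levels[[p$level]]$measures$values),
    FALSE)
  if (!ok) stop(sprintf("flag target '%s' does not resolve in reading", tgt),
                call. = FALSE)
  p
}

#' Attach a quality flag to a reading
#'
#' The flag becomes visible from the reading and from every target: levels
#' record it in their flag list, measures gain the flag id in their `flags`
#' field. Measures are annotated, never deleted. Dangling targets are a
#' reference error.
#'
#' @param r A [reading()].
#' @param flag A [quality_flag()].
#' @return The augmented reading.
#' @export
attach_flag <- function(r, flag) {
  stopifnot(inherits(r, "reading"), inherits(flag, "quality_flag"))
  parsed <- lapply(flag$targets, function(t) resolve_target(r, t))
  r$flags[[length(r$flags) + 1L]] <- flag
  for (p in parsed) {
    if (p$type == "level") {
      lv <- r$levels[[p$level]]
      lv$flags[[length(lv$flags) + 1L]] <- flag
      r$levels[[p$level]] <- lv
    } else if (p$type %in% c("dataset", "epoch")) {
      lv <- r$levels[[p$level]]
      lv$flags[[length(lv$flags) + 1L]] <- flag
      r$levels[[p$level]] <- lv
    } else if (p$type == "measure") {
      if (p$level == "") {
        m <- r$measures$values[[p$id]]
        m$flags <- union(m$flags, flag$id)
        r$measures$values[[p$id]] <- m
      } else {
        m <- r$levels[[p$level]]$measures$values[[p$id]]
        m$flags <- union(m$flags, flag$id)
        r$levels[[p$level]]$measures$values[[p$id]] <- m
      }
    }
  }
  r
}

#' All flags attached anywhere in a reading
#'
#' @param r A [reading()].
#' @return List of `quality_flag` objects (reading-level list; every flag
#'   attached through [attach_flag()] appears here exactly once).
#' @export
reading_flags <- function(r) r$flags

#' Flags recorded on one level
#' @param r A [reading()].
#' @param level_id Level id.
#' @return List of `quality_flag` objects.
#' @export
level_flags <- function(r, level_id) r$levels[[level_id]]$flags
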