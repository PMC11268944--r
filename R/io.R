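# Canonical reading format (JSON) and measure-collection export. The
# dialect is this package's native format: top-level {metadata, levels[],
# measures[], flags[]}; levels hold {id, modalities, start, end, context,
# datasets[], epochs[], measures[], flags[]}; datasets hold {id, source,
# columns[], values[][]} with column-major values. The schema is published
# at inst/schema/reading.schema.json.

# ---- serialization ---------------------------------------------------------

vd_to_list <- function(vd) {
  out <- list(id = vd$id, name = vd$name, unit = vd$unit,
              data_type = vd$data_type)
  if (!is.null(vd$valid_range)) out$valid_range <- I(vd$valid_range)
  out
}

vd_from_list <- function(x) {
  value_definition(x$id, x$name, x$unit, x$data_type,
                   valid_range = if (!is.null(x$valid_range))
                     unlist(x$valid_range))
}

flag_to_list <- function(f) {
  list(id = f$id, reason = f$reason, targets = I(f$targets),
       stopped_processing = f$stopped_processing)
}

flag_from_list <- function(x) {
  quality_flag(x$id, x$reason, unlist(x$targets),
               isTRUE(x$stopped_processing))
}

measure_to_list <- function(m) {
  list(definition = vd_to_list(m$definition), value = m$value,
       flags = I(m$flags))
}

measure_from_list <- function(x) {
  measure_value(vd_from_list(x$definition), x$value,
                flags = as.character(unlist(x$flags)))
}

dataset_to_list <- function(ds) {
  list(id = ds$id,
       source = unclass(ds$source),
       columns = lapply(ds$columns, vd_to_list),
       values = lapply(ds$data, I))
}

coerce_column <- function(v, data_type) {
  v <- unlist(v)
  if (is.null(v)) v <- vector(mode = "numeric", length = 0L)
  switch(data_type,
         float = as.numeric(v), timestamp = as.numeric(v),
         int = as.integer(v), bool = as.logical(v),
         string = as.character(v))
}

dataset_from_list <- function(x) {
  cols <- lapply(x$columns, vd_from_list)
  src <- x$source
  data <- as.data.frame(
    setNames(lapply(seq_along(cols), function(i) {
      coerce_column(x$values[[i]], cols[[i]]$data_type)
    }), vapply(cols, function(c) c$id, character(1))))
  raw_dataset(x$id,
              sensor_source(src$device_model, src$sensor,
                            if (is.null(src$sampling_frequency)) NA_real_
                            else src$sampling_frequency,
                            src$placement),
              cols, data)
}

# Collapse JSON lists of homogeneous scalars back into atomic vectors so
# context round-trips losslessly.
normalize_bag <- function(x) {
  if (!is.list(x)) return(x)
  x <- lapply(x, normalize_bag)
  scal <- vapply(x, function(e) is.atomic(e) && length(e) == 1L, logical(1))
  kind <- function(e) if (is.numeric(e)) "numeric" else class(e)[1]
  if (length(x) && all(scal) &&
      length(unique(vapply(x, kind, character(1)))) == 1L &&
      is.null(names(x))) {
    v <- unlist(x)
    if (is.integer(v)) v <- as.numeric(v)
    return(v)
  }
  x
}

epoch_to_list <- function(ep) {
  out <- list(definition = vd_to_list(ep$definition),
              start = ep$start, end = ep$end)
  if (!is.null(ep$payload)) out$payload <- ep$payload
  out
}

epoch_from_list <- function(x) {
  level_epoch(vd_from_list(x$definition), x$start, x$end,
              payload = normalize_bag(x$payload))
}

level_to_list <- function(lv) {
  list(id = lv$id,
       modalities = lapply(lv$modalities, function(m)
         list(dimension = m$dimension, value = m$value)),
       start = lv$start, end = lv$end,
       context = lv$context,
       datasets = lapply(unname(lv$datasets), dataset_to_list),
       epochs = lapply(lv$epochs, epoch_to_list),
       measures = lapply(unname(lv$measures$values), measure_to_list),
       flags = lapply(lv$flags, flag_to_list))
}

level_from_list <- function(x) {
  lv <- level(modalities = lapply(x$modalities, function(m)
                modality(m$dimension, m$value)),
              start = x$start, end = x$end,
              context = normalize_bag(x$context),
              id = x$id)
  for (d in x$datasets) lv <- level_add_dataset(lv, dataset_from_list(d))
  for (e in x$epochs) lv <- level_add_epoch(lv, epoch_from_list(e))
  for (m in x$measures) {
    lv$measures <- add_measure(lv$measures, measure_from_list(m))
  }
  lv$flags <- lapply(x$flags, flag_from_list)
  lv
}

#' Serialize a reading to canonical JSON
#'
#' Floats are serialized with 17 significant digits so numeric round trips
#' are lossless to double precision. Inverse of [read_reading()] up to key
#' ordering.
#'
#' @param r A [reading()].
#' @param path Optional file path; when `NULL` the JSON text is returned.
#' @return JSON text (invisibly when writing to a file).
#' @export
write_reading <- function(r, path = NULL) {
  stopifnot(inherits(r, "reading"))
  meta <- c(list(evaluation_code = r$evaluation_code,
                 subject_id = r$subject_id, session_id = r$session_id,
                 schema_version = r$schema_version,
                 device = r$device),
            r$metadata)
  doc <- list(metadata = meta,
              levels = lapply(unname(r$levels), level_to_list),
              measures = lapply(unname(r$measures$values), measure_to_list),
              flags = lapply(r$flags, flag_to_list))
  js <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = I(17),
                         null = "null", na = "null", pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

# ---- structural validation -------------------------------------------------

#' Validate a canonical reading document
#'
#' Structural validation against the published schema
#' (`inst/schema/reading.schema.json`): required keys, types, rectangular
#' datasets. Each problem is reported with the JSON-pointer path of the
#' offending element.
#'
#' @param doc Parsed document (list) or JSON text/path.
#' @return Character vector of error messages; empty when valid.
#' @export
validate_reading_document <- function(doc) {
  if (is.character(doc)) {
    txt <- if (length(doc) == 1L && file.exists(doc))
      paste(readLines(doc, warn = FALSE), collapse = "\n") else doc
    doc <- tryCatch(jsonlite::fromJSON(txt, simplifyVector = FALSE),
                    error = function(e) NULL)
    if (is.null(doc)) return("/: not parseable as JSON")
  }
  errs <- character(0)
  err <- function(path, msg) errs <<- c(errs, sprintf("%s: %s", path, msg))
  if (!is.list(doc)) return("/: document must be a JSON object")
  if (is.null(doc$metadata)) err("/metadata", "missing required object")
  else {
    for (k in c("evaluation_code", "subject_id", "session_id")) {
      v <- doc$metadata[[k]]
      if (is.null(v) || !is.character(v) || length(v) != 1L) {
        err(paste0("/metadata/", k), "missing or not a string")
      }
    }
    if (!is.null(doc$metadata$evaluation_code) &&
        is.character(doc$metadata$evaluation_code) &&
        !grepl(SLUG_RE, doc$metadata$evaluation_code)) {
      err("/metadata/evaluation_code", "not a lowercase slug")
    }
  }
  if (is.null(doc$levels)) err("/levels", "missing required array")
  lids <- character(0)
  for (i in seq_along(doc$levels)) {
    lp <- sprintf("/levels/%d", i - 1L)
    lv <- doc$levels[[i]]
    if (!is.list(lv)) { err(lp, "level must be an object"); next }
    if (is.null(lv$id) || !is.character(lv$id)) {
      err(paste0(lp, "/id"), "missing or not a string")
    } else {
      if (lv$id %in% lids) err(paste0(lp, "/id"), "duplicate level id")
      lids <- c(lids, lv$id)
    }
    for (k in c("start", "end")) {
      if (is.null(lv[[k]]) || !is.numeric(lv[[k]])) {
        err(paste0(lp, "/", k), "missing or not a number")
      }
    }
    if (is.numeric(lv$start) && is.numeric(lv$end) && lv$start > lv$end) {
      err(paste0(lp, "/start"), "start exceeds end")
    }
    dids <- character(0)
    for (j in seq_along(lv$datasets)) {
      dp <- sprintf("%s/datasets/%d", lp, j - 1L)
      ds <- lv$datasets[[j]]
      if (!is.list(ds)) { err(dp, "dataset must be an object"); next }
      if (is.null(ds$id) || !is.character(ds$id)) {
        err(paste0(dp, "/id"), "missing or not a string")
      } else {
        if (ds$id %in% dids) err(paste0(dp, "/id"), "duplicate dataset id")
        dids <- c(dids, ds$id)
      }
      ncol <- length(ds$columns)
      if (ncol == 0L) err(paste0(dp, "/columns"), "missing or empty")
      else {
        dt1 <- ds$columns[[1]]$data_type
        if (is.null(dt1) || dt1 != "timestamp") {
          err(paste0(dp, "/columns/0/data_type"),
              "first column must be a timestamp")
        }
      }
      if (length(ds$values) != ncol) {
        err(paste0(dp, "/values"),
            sprintf("expected %d value columns, found %d",
                    ncol, length(ds$values)))
      } else if (ncol > 0L) {
        lens <- vapply(ds$values, length, integer(1))
        if (length(unique(lens)) > 1L) {
          err(paste0(dp, "/values"), "columns have unequal lengths")
        }
      }
    }
  }
  errs
}

#' Read a reading from canonical JSON
#'
#' Schema violations are a validation error naming the JSON-pointer path
#' of the offending element. Non-monotone timestamps do not fail the load:
#' the reading is loaded and an automatic technical-deviation flag
#' (`{task}-technical-deviation-ts_nonmonotone`) is attached to the
#' affected dataset. Unknown metadata keys are preserved in an opaque
#' metadata bag and written back by [write_reading()].
#'
#' @param x Path to a JSON file, or JSON text.
#' @return A [reading()].
#' @export
read_reading <- function(x) {
  txt <- if (length(x) == 1L && !grepl("[{\n]", x) && file.exists(x)) {
    paste(readLines(x, warn = FALSE), collapse = "\n")
  } else paste(x, collapse = "\n")
  errs <- validate_reading_document(txt)
  if (length(errs)) {
    stop("validation error in reading document:\n  ",
         paste(errs, collapse = "\n  "), call. = FALSE)
  }
  doc <- jsonlite::fromJSON(txt, simplifyVector = FALSE)
  meta <- doc$metadata
  known <- c("evaluation_code", "subject_id", "session_id",
             "schema_version", "device")
  extras <- meta[setdiff(names(meta), known)]
  r <- reading(meta$evaluation_code, meta$subject_id, meta$session_id,
               device = normalize_bag(meta$device),
               levels = lapply(doc$levels, level_from_list),
               schema_version = if (is.null(meta$schema_version)) "1.0"
                                else meta$schema_version,
               metadata = lapply(extras, normalize_bag))
  for (m in doc$measures) {
    r$measures <- add_measure(r$measures, measure_from_list(m))
  }
  r$flags <- lapply(doc$flags, flag_from_list)
  # automatic technical flag on non-monotone timestamps
  for (lv in r$levels) {
    for (ds in lv$datasets) {
      ts <- ds_timestamps(ds)
      if (length(ts) >= 2L && is.unsorted(ts)) {
        r <- attach_flag(r, quality_flag(
          flag_id(r$evaluation_code, "technical", "deviation",
                  "ts_nonmonotone"),
          reason = sprintf("dataset '%s' of level '%s' has non-monotone timestamps",
                           ds$id, lv$id),
          targets = sprintf("dataset:%s/%s", lv$id, ds$id)))
      }
    }
  }
  r
}

#' Compare two readings for semantic equality
#'
#' Field-wise comparison with numeric tolerance (timestamps and values to
#' `tol`); key order and internal attribute differences are ignored.
#'
#' @param a,b Readings.
#' @param tol Absolute numeric tolerance (default 1e-9).
#' @return `TRUE` or a character description of the first difference.
#' @export
reading_equal <- function(a, b, tol = 1e-9) {
  strip <- function(r) {
    r$levels <- lapply(r$levels, function(lv) {
      lv$measures$values <- lapply(lv$measures$values, function(m) {
        attributes(m) <- attributes(m)["class" == names(attributes(m))]
        m
      })
      lv
    })
    r
  }
  res <- all.equal(strip(a), strip(b), tolerance = tol,
                   check.attributes = FALSE)
  if (isTRUE(res)) TRUE else paste(res, collapse = "; ")
}

# ---- measure collections ---------------------------------------------------

MEASURE_COLLECTION_FIELDS <- c("subject_id", "session_id", "evaluation_code",
                               "level_id", "measure_id", "measure_name",
                               "value", "unit", "flag_count", "flag_ids")

#' Collect the measures of one or more readings into a flat table
#'
#' One row per (session, level, measure id); session-level measures carry
#' an empty `level_id`. `flag_count` equals the number of flag ids
#' annotating the measure; `flag_ids` joins them with `;`.
#'
#' @param readings A [reading()] or list of readings.
#' @return A `measure_collection`: a data.frame with columns
#'   `subject_id, session_id, evaluation_code, level_id, measure_id,
#'   measure_name, value, unit, flag_count, flag_ids`.
#' @export
measure_collection <- function(readings) {
  if (inherits(readings, "reading")) readings <- list(readings)
  rows <- list()
  push <- function(r, level_id, m) {
    rows[[length(rows) + 1L]] <<- data.frame(
      subject_id = r$subject_id, session_id = r$session_id,
      evaluation_code = r$evaluation_code, level_id = level_id,
      measure_id = m$definition$id, measure_name = m$definition$name,
      value = as.numeric(m$value), unit = m$definition$unit,
      flag_count = length(m$flags),
      flag_ids = paste(m$flags, collapse = ";"),
      stringsAsFactors = FALSE)
  }
  for (r in readings) {
    for (m in r$measures$values) push(r, "", m)
    for (lv in r$levels) for (m in lv$measures$values) push(r, lv$id, m)
  }
  out <- if (length(rows)) do.call(rbind, rows) else {
    as.data.frame(setNames(
      list(character(), character(), character(), character(), character(),
           character(), numeric(), character(), integer(), character()),
      MEASURE_COLLECTION_FIELDS))
  }
  class(out) <- c("measure_collection", "data.frame")
  out
}

#' Export a measure collection
#'
#' @param collection A [measure_collection()] (plain data.frames with the
#'   same columns are accepted).
#' @param format `"mapping"` (named list keyed `session_id/measure_id`),
#'   `"json"` (record list) or `"csv"` (UTF-8, header row exactly the
#'   collection field list, `.` decimal separator).
#' @param path Output file for json/csv; when `NULL` the artifact is
#'   returned instead.
#' @return The mapping, JSON text or CSV text (invisibly when written to
#'   `path`).
#' @export
export_measures <- function(collection, format = c("mapping", "json", "csv"),
                            path = NULL) {
  format <- match.arg(format)
  df <- as.data.frame(collection)[, MEASURE_COLLECTION_FIELDS, drop = FALSE]
  if (format == "mapping") {
    keys <- paste(df$session_id, df$measure_id, sep = "/")
    return(setNames(lapply(seq_len(nrow(df)), function(i)
      as.list(df[i, ])), keys))
  }
  if (format == "json") {
    js <- jsonlite::toJSON(df, dataframe = "rows", auto_unbox = TRUE,
                           digits = I(17), pretty = TRUE)
    if (!is.null(path)) { writeLines(js, path); return(invisible(js)) }
    return(js)
  }
  # csv
  con <- if (is.null(path)) textConnection("csv_out", "w", local = TRUE)
         else file(path, "w", encoding = "UTF-8")
  df$value <- vapply(df$value, base::format, character(1), digits = 17,
                     trim = TRUE)
  utils::write.csv(df, con, row.names = FALSE, quote = TRUE)
  close(con)
  if (is.null(path)) paste0(paste(csv_out, collapse = "\n"), "\n")
  else invisible(path)
}

#' Re-parse an exported measure CSV
#'
#' @param path CSV file or literal CSV text.
#' @return A [measure_collection()].
#' @export
read_measures_csv <- function(path) {
  df <- if (file.exists(path)) {
    utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  } else {
    utils::read.csv(text = path, stringsAsFactors = FALSE,
                    colClasses = "character")
  }
  df$value <- as.numeric(df$value)
  df$flag_count <- as.integer(df$flag_count)
  for (k in setdiff(MEASURE_COLLECTION_FIELDS, c("value", "flag_count"))) {
    df[[k]] <- as.character(df[[k]])
    df[[k]][is.na(df[[k]])] <- ""
  }
  class(df) <- c("measure_collection", "data.frame")
  df
}
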