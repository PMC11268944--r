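# Declarative processing-step graph. Steps transform datasets, extract
# measures or raise flags; every run records a complete data trace: a DAG
# whose nodes are entities (reading, levels, datasets, epochs, measures,
# step instances) and whose edges connect step inputs to steps and steps
# to their outputs.

#' Declare a processing step
#'
#' @param step_id Step slug (unique within a pipeline).
#' @param kind `"transform"` (produces new datasets), `"extract"`
#'   (produces measures, may raise flags and epochs) or `"flag"` (raises
#'   flags only).
#' @param fn The step body, `function(level, reading, params)`. Transform
#'   steps return a [raw_dataset()] or list of them; extract steps return
#'   a list with `measures` ([measure_set()]) and optional `flags`,
#'   `epochs`; flag steps return a list of [quality_flag()]s (or `NULL`).
#' @param inputs Dataset/measure ids the step consumes. A step whose
#'   inputs are absent on a level is recorded as `skipped_missing_input`
#'   and never raises.
#' @param outputs Ids the step declares to produce (used for the cycle
#'   check; transform outputs must be new dataset ids).
#' @param level_filter `NULL` (all levels), a predicate
#'   `function(level) -> logical`, or a named character vector of
#'   modality constraints (e.g. `c(hand = "right")`).
#' @param params Named list recorded verbatim in the trace; frozen
#'   (copied) at declaration so the trace reflects run-time configuration
#'   exactly.
#' @return A `processing_step` object.
#' @export
processing_step <- function(step_id, kind, fn, inputs = character(),
                            outputs = character(), level_filter = NULL,
                            params = list()) {
  assert_slug(step_id, "step id")
  kind <- match.arg(kind, c("transform", "extract", "flag"))
  stopifnot(is.function(fn))
  structure(list(step_id = step_id, kind = kind, fn = fn,
                 inputs = as.character(inputs),
                 outputs = as.character(outputs),
                 level_filter = level_filter,
                 params = params),   # frozen copy: R copies on assignment
            class = "processing_step")
}

level_matches <- function(lv, filter) {
  if (is.null(filter)) return(TRUE)
  if (is.function(filter)) return(isTRUE(filter(lv)))
  for (dim in names(filter)) {
    if (!identical(level_modality(lv, dim), unname(filter[dim]))) return(FALSE)
  }
  TRUE
}

#' Filter the levels of a reading
#'
#' @param r A [reading()].
#' @param predicate A predicate `function(level) -> logical` or a named
#'   character vector of modality constraints.
#' @return List of matching [level()]s, order preserved (possibly empty).
#' @export
#' @examples
#' # all left-hand levels of a drawing session:
#' # filter_levels(rd, c(hand = "left"))
filter_levels <- function(r, predicate) {
  Filter(function(lv) level_matches(lv, predicate), unname(r$levels))
}

new_trace <- function() {
  structure(list(
    nodes = data.frame(id = character(), kind = character(),
                       label = character(), stringsAsFactors = FALSE),
    edges = data.frame(from = character(), to = character(),
                       relation = character(), stringsAsFactors = FALSE),
    steps = data.frame(step_node = character(), step_id = character(),
                       level_id = character(), status = character(),
                       params = character(), stringsAsFactors = FALSE)),
    class = "data_trace")
}

trace_add_node <- function(tr, id, kind, label = id) {
  if (!(id %in% tr$nodes$id)) {
    tr$nodes <- rbind(tr$nodes, data.frame(id = id, kind = kind,
                                           label = label,
                                           stringsAsFactors = FALSE))
  }
  tr
}

trace_add_edge <- function(tr, from, to, relation = "flow") {
  tr$edges <- rbind(tr$edges, data.frame(from = from, to = to,
                                         relation = relation,
                                         stringsAsFactors = FALSE))
  tr
}

trace_record_status <- function(tr, node, step_id, level_id, status, params) {
  tr$steps <- rbind(tr$steps, data.frame(
    step_node = node, step_id = step_id, level_id = level_id,
    status = status,
    params = as.character(jsonlite::toJSON(params, auto_unbox = TRUE)),
    stringsAsFactors = FALSE))
  tr
}

trace_seed_entities <- function(tr, r) {
  tr <- trace_add_node(tr, "reading", "reading", r$evaluation_code)
  for (lv in r$levels) {
    lnode <- paste0("level:", lv$id)
    tr <- trace_add_node(tr, lnode, "level", lv$id)
    tr <- trace_add_edge(tr, "reading", lnode, "contains")
    for (ds in lv$datasets) {
      dnode <- sprintf("dataset:%s/%s", lv$id, ds$id)
      tr <- trace_add_node(tr, dnode, "dataset", ds$id)
      tr <- trace_add_edge(tr, lnode, dnode, "contains")
    }
  }
  tr
}

# Cycle check over declared input/output ids; configuration error before
# any execution.
check_step_declarations <- function(steps) {
  edges <- character(0)
  for (s in steps) {
    for (i in s$inputs) edges <- c(edges, i, paste0("step#", s$step_id))
    for (o in s$outputs) edges <- c(edges, paste0("step#", s$step_id), o)
  }
  if (!length(edges)) return(invisible(TRUE))
  g <- igraph::make_graph(edges, directed = TRUE)
  if (!igraph::is_dag(g)) {
    stop("configuration error: cyclic step input/output declarations",
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Run a processing pipeline on a reading
#'
#' Steps run in declaration order, independently per matching level. A
#' step whose declared inputs are absent on a level is recorded as
#' `skipped_missing_input` and does not raise; a flag with
#' `stopped_processing = TRUE` aborts downstream steps on the flagged
#' level only (recorded `aborted_by_flag`). Raw data is never mutated:
#' transforms add new datasets, extracts add measures, flags annotate.
#'
#' @param r A [reading()].
#' @param steps List of [processing_step()]s; cyclic input/output
#'   declarations are a configuration error raised before any execution.
#' @param config Threshold configuration passed to step bodies.
#' @return List with the augmented `reading` and the `trace`
#'   (a `data_trace`).
#' @export
process_reading <- function(r, steps, config = sdm_config()) {
  stopifnot(inherits(r, "reading"))
  for (s in steps) stopifnot(inherits(s, "processing_step"))
  check_step_declarations(steps)
  tr <- trace_seed_entities(new_trace(), r)
  aborted <- setNames(rep(FALSE, length(r$levels)), names(r$levels))

  for (lid in names(r$levels)) {
    for (s in steps) {
      lv <- r$levels[[lid]]
      if (!level_matches(lv, s$level_filter)) next
      snode <- sprintf("step:%s/%s", lid, s$step_id)
      tr <- trace_add_node(tr, snode, "step", s$step_id)

      if (aborted[[lid]]) {
        tr <- trace_record_status(tr, snode, s$step_id, lid,
                                  "aborted_by_flag", s$params)
        next
      }
      present <- vapply(s$inputs, function(i) {
        i %in% names(lv$datasets) || i %in% names(lv$measures$values)
      }, logical(1))
      if (length(present) && !all(present)) {
        tr <- trace_record_status(tr, snode, s$step_id, lid,
                                  "skipped_missing_input", s$params)
        next
      }
      for (i in s$inputs) {
        inode <- if (i %in% names(lv$datasets)) {
          sprintf("dataset:%s/%s", lid, i)
        } else sprintf("measure:%s/%s", lid, i)
        tr <- trace_add_edge(tr, inode, snode, "input")
      }

      out <- s$fn(lv, r, config)

      if (s$kind == "transform") {
        dss <- if (inherits(out, "raw_dataset")) list(out) else out
        for (ds in dss) {
          lv <- level_add_dataset(lv, ds)
          dnode <- sprintf("dataset:%s/%s", lid, ds$id)
          tr <- trace_add_node(tr, dnode, "dataset", ds$id)
          tr <- trace_add_edge(tr, snode, dnode, "output")
        }
        r$levels[[lid]] <- lv
      } else if (s$kind == "extract") {
        res <- if (inherits(out, "measure_set")) list(measures = out) else out
        if (!is.null(res$measures)) {
          for (m in res$measures$values) {
            lv$measures <- add_measure(lv$measures, m, provenance = s$step_id)
            mnode <- sprintf("measure:%s/%s", lid, m$definition$id)
            tr <- trace_add_node(tr, mnode, "measure", m$definition$id)
            tr <- trace_add_edge(tr, snode, mnode, "output")
          }
        }
        if (!is.null(res$epochs)) {
          for (ep in res$epochs) {
            lv <- level_add_epoch(lv, ep)
            enode <- sprintf("epoch:%s/%d", lid, length(lv$epochs))
            tr <- trace_add_node(tr, enode, "epoch", ep$definition$id)
            tr <- trace_add_edge(tr, snode, enode, "output")
          }
        }
        r$levels[[lid]] <- lv
        if (!is.null(res$flags)) {
          for (f in res$flags) {
            r <- attach_flag(r, f)
            if (f$stopped_processing) aborted[[lid]] <- TRUE
          }
        }
      } else {  # flag step
        flags <- if (inherits(out, "quality_flag")) list(out) else out
        for (f in flags) {
          if (is.null(f)) next
          r <- attach_flag(r, f)
          if (f$stopped_processing) aborted[[lid]] <- TRUE
        }
      }
      tr <- trace_record_status(tr, snode, s$step_id, lid,
                                "completed", s$params)
    }
  }
  list(reading = r, trace = tr)
}

#' Export a data trace as an adjacency structure
#'
#' @param trace A `data_trace` from [process_reading()].
#' @return List with `nodes` (data.frame, lexicographically ordered ids),
#'   `edges` (data.frame from/to/relation, ordered) and `steps` (status
#'   and frozen params per executed step instance). Suitable for JSON
#'   serialization and DOT rendering.
#' @export
export_trace <- function(trace) {
  stopifnot(inherits(trace, "data_trace"))
  nodes <- trace$nodes[order(trace$nodes$id), , drop = FALSE]
  edges <- trace$edges[order(trace$edges$from, trace$edges$to), , drop = FALSE]
  rownames(nodes) <- NULL
  rownames(edges) <- NULL
  list(nodes = nodes, edges = edges, steps = trace$steps)
}

#' Is a trace acyclic?
#'
#' @param trace A `data_trace`.
#' @return `TRUE` when the trace graph is a DAG (it always should be).
#' @export
trace_is_acyclic <- function(trace) {
  if (nrow(trace$edges) == 0L) return(TRUE)
  g <- igraph::graph_from_data_frame(trace$edges[, c("from", "to")],
                                     directed = TRUE,
                                     vertices = trace$nodes$id)
  igraph::is_dag(g)
}

#' Measure nodes reachable from raw data
#'
#' Checks the completeness property of a finalized trace: every measure
#' node must be reachable from at least one dataset node through the
#' directed input/output edges.
#'
#' @param trace A `data_trace`.
#' @return Logical vector named by measure node id; `TRUE` where
#'   reachable.
#' @export
trace_measures_reachable <- function(trace) {
  meas <- trace$nodes$id[trace$nodes$kind == "measure"]
  if (!length(meas)) return(setNames(logical(0), character(0)))
  flow <- trace$edges[trace$edges$relation %in% c("input", "output"), ]
  g <- igraph::graph_from_data_frame(flow[, c("from", "to")],
                                     directed = TRUE,
                                     vertices = trace$nodes$id)
  roots <- trace$nodes$id[trace$nodes$kind == "dataset"]
  reach <- unique(unlist(lapply(roots, function(rt) {
    names(igraph::subcomponent(g, rt, mode = "out"))
  })))
  setNames(meas %in% reach, meas)
}

#' Render a trace as DOT text
#'
#' @param trace A `data_trace`.
#' @return Character scalar of Graphviz DOT source.
#' @export
trace_to_dot <- function(trace) {
  ex <- export_trace(trace)
  shape <- c(reading = "folder", level = "box", dataset = "cylinder",
             epoch = "note", measure = "ellipse", step = "component")
  lines <- c("digraph data_trace {", "  rankdir=LR;")
  for (i in seq_len(nrow(ex$nodes))) {
    n <- ex$nodes[i, ]
    lines <- c(lines, sprintf('  "%s" [label="%s", shape=%s];',
                              n$id, n$label, shape[[n$kind]]))
  }
  for (i in seq_len(nrow(ex$edges))) {
    e <- ex$edges[i, ]
    style <- if (e$relation == "contains") ' [style=dotted]' else ''
    lines <- c(lines, sprintf('  "%s" -> "%s"%s;', e$from, e$to, style))
  }
  paste(c(lines, "}"), collapse = "\n")
}

#' Serialize a trace to JSON
#'
#' @param trace A `data_trace`.
#' @param path Optional output file; when `NULL` the JSON string is
#'   returned.
#' @return JSON string (invisibly, when writing to a file).
#' @export
trace_to_json <- function(trace, path = NULL) {
  ex <- export_trace(trace)
  js <- jsonlite::toJSON(ex, dataframe = "rows", auto_unbox = TRUE,
                         pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
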