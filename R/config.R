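# Tunable thresholds, collected in one place so a YAML config (and CLI
# flags on top of it) can override any of them.

default_config <- function() {
  list(
    sampling = list(irregularity_max = 0.10, gap_factor = 1.5),
    orientation = list(min_g_fraction = 0.5),
    steps = list(low_hz = 0.5, high_hz = 5, filter_order = 2,
                 min_prominence = 0.3, min_separation = 0.25),
    turns = list(min_angle_deg = 160, rate_threshold_deg_s = 15),
    protocol = list(too_short_fraction = 0.8)
  )
}

merge_lists <- function(base, override) {
  for (k in names(override)) {
    base[[k]] <- if (is.list(base[[k]]) && is.list(override[[k]])) {
      merge_lists(base[[k]], override[[k]])
    } else override[[k]]
  }
  base
}

#' Configuration of extraction thresholds
#'
#' Returns the default thresholds used across the package (sampling
#' irregularity 0.10, gap 1.5 nominal periods, orientation 0.5 g, step
#' band 0.5--5 Hz with prominence 0.3 m/s^2 and separation 0.25 s, turn
#' threshold 15 deg/s with minimum angle 160 deg, too-short rule at 80% of
#' the protocol duration), optionally overridden by a YAML file and/or a
#' named list. Overrides merge recursively; unnamed thresholds keep their
#' defaults.
#'
#' @param yaml_path Optional path to a YAML file mirroring the default
#'   structure.
#' @param overrides Optional named list applied after the YAML file.
#' @return Nested named list of thresholds.
#' @export
#' @examples
#' cfg <- sdm_config(overrides = list(steps = list(min_prominence = 0.5)))
#' cfg$steps$min_prominence
sdm_config <- function(yaml_path = NULL, overrides = NULL) {
  cfg <- default_config()
  if (!is.null(yaml_path)) {
    cfg <- merge_lists(cfg, yaml::read_yaml(yaml_path))
  }
  if (!is.null(overrides)) cfg <- merge_lists(cfg, overrides)
  cfg
}
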