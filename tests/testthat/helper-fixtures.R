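# Shared fixtures and independent oracles.

# Minimal one-level reading with a single 2-column dataset.
minimal_reading <- function(ts = c(0, 0.5, 1), vals = c(1, 2, 3),
                            code = "tap") {
  ds <- raw_dataset(
    "events",
    sensor_source("fixture", "touchscreen", NA, "handheld"),
    list(value_definition("ts", "Time", "s", "timestamp"),
         value_definition("v", "Value", "")),
    data.frame(ts = ts, v = vals))
  reading(code, "subj", "sess",
          levels = list(level(start = min(ts), end = max(ts),
                              datasets = list(ds), id = "only")))
}

# Independent brute-force DTW: plain memoized recursion over the three
# admissible moves, used only as an oracle against the DP implementation.
brute_dtw_total <- function(a, b) {
  n <- nrow(a); m <- nrow(b)
  memo <- array(NA_real_, c(n, m))
  cost <- function(i, j) sqrt(sum((a[i, ] - b[j, ])^2))
  rec <- function(i, j) {
    if (!is.na(memo[i, j])) return(memo[i, j])
    v <- if (i == 1 && j == 1) cost(1, 1)
    else if (i == 1) rec(1, j - 1) + cost(i, j)
    else if (j == 1) rec(i - 1, 1) + cost(i, j)
    else cost(i, j) + min(rec(i - 1, j - 1), rec(i - 1, j), rec(i, j - 1))
    memo[i, j] <<- v
    v
  }
  rec(n, m)
}

# Flag ids attached anywhere on a reading.
all_flag_ids <- function(r) {
  vapply(reading_flags(r), function(f) f$id, character(1))
}

run_registered <- function(r, config = sdm_config()) {
  process_reading(r, registry_steps(r$evaluation_code, config), config)
}

level_measure <- function(r, measure_id, level_index = 1) {
  r$levels[[level_index]]$measures$values[[measure_id]]$value
}
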