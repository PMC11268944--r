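# SDM extraction for the mobility tests: six-minute walk (sixmwt), U-turn
# (utt) and static balance (sbt). The device is belt-worn on the lower
# back; gravity is expected on +z.

# Local maxima of x with topographic prominence >= min_prominence and at
# least min_distance samples between kept peaks (higher peaks win).
find_peaks <- function(x, min_prominence = 0, min_distance = 1L) {
  n <- length(x)
  if (n < 3L) return(integer())
  cand <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
  if (!length(cand)) return(integer())

  prominence <- vapply(cand, function(i) {
    h <- x[i]
    lmin <- h
    j <- i - 1L
    while (j >= 1L && x[j] <= h) { if (x[j] < lmin) lmin <- x[j]; j <- j - 1L }
    rmin <- h
    j <- i + 1L
    while (j <= n && x[j] <= h) { if (x[j] < rmin) rmin <- x[j]; j <- j + 1L }
    h - max(lmin, rmin)
  }, numeric(1))
  cand <- cand[prominence >= min_prominence]
  if (!length(cand)) return(integer())

  # enforce separation: keep higher peaks first
  ord <- cand[order(x[cand], decreasing = TRUE)]
  keep <- logical(n)
  blocked <- logical(n)
  for (i in ord) {
    if (blocked[i]) next
    keep[i] <- TRUE
    lo <- max(1L, i - min_distance + 1L)
    hi <- min(n, i + min_distance - 1L)
    blocked[lo:hi] <- TRUE
  }
  which(keep)
}

#' Detect steps in an acceleration-norm series
#'
#' Band-pass filters the gravity-subtracted acceleration norm (zero phase,
#' 0.5--5 Hz by default, covering physiological step frequencies) and
#' detects local maxima with a topographic-prominence and a minimum
#' temporal-separation constraint. One retained peak is counted as one
#' step.
#'
#' @param acc_norm Dynamic acceleration norm (m/s^2), uniformly sampled.
#' @param fs Sampling frequency (Hz).
#' @param min_prominence Minimum peak prominence (m/s^2, default 0.3).
#' @param min_separation Minimum time between steps (s, default 0.25,
#'   i.e. a 240 steps/min ceiling).
#' @param low_hz,high_hz,order Band-pass settings, see
#'   [bandpass_zero_phase()].
#' @return A `step_events` list: `times` (s), `count`, `cadence`
#'   (steps/min, `60 * count / span`), `step_time_cv` (sd/mean of
#'   successive step intervals; `NA` when fewer than 3 steps).
#' @export
detect_steps <- function(acc_norm, fs, min_prominence = 0.3,
                         min_separation = 0.25,
                         low_hz = 0.5, high_hz = 5, order = 2) {
  n <- length(acc_norm)
  if (n < 5 * fs) {
    stop("insufficient data: detect_steps needs >= 5 s of signal",
         call. = FALSE)
  }
  filtered <- bandpass_zero_phase(acc_norm, fs, low_hz, high_hz, order)
  idx <- find_peaks(filtered, min_prominence,
                    min_distance = max(1L, as.integer(round(min_separation * fs))))
  times <- (idx - 1L) / fs
  span <- (n - 1L) / fs
  count <- length(idx)
  cv <- if (count >= 3L) {
    d <- diff(times)
    stats::sd(d) / mean(d)
  } else NA_real_
  structure(list(times = times, count = count,
                 cadence = 60 * count / span,
                 step_time_cv = cv, span = span),
            class = "step_events")
}

#' Detect turns from a yaw-rate series
#'
#' Integrates the yaw rate (trapezoidal rule) over maximal intervals where
#' the rate magnitude stays at or above `rate_threshold_deg_s` with a
#' constant sign, extending each interval by the half-sample trapezoid to
#' the adjacent sub-threshold samples so a sampled constant-rate block
#' integrates to its exact rectangle area. Intervals whose absolute
#' integrated angle reaches `min_angle_deg` become turn epochs.
#'
#' @param gyro_yaw Calibrated yaw rate (rad/s).
#' @param fs Sampling frequency (Hz).
#' @param min_angle_deg Minimum absolute turn angle in degrees (default
#'   160, capturing U-turns while rejecting path curvature).
#' @param rate_threshold_deg_s Rate magnitude threshold in deg/s (default
#'   15).
#' @return List of turn epochs, ordered and non-overlapping; each a list
#'   with `start`, `end`, `duration` (s), `angle` (rad, signed),
#'   `peak_rate` (rad/s, signed, maximal magnitude).
#' @export
detect_turns <- function(gyro_yaw, fs, min_angle_deg = 160,
                         rate_threshold_deg_s = 15) {
  w <- as.numeric(gyro_yaw)
  n <- length(w)
  if (n < 2L) return(list())
  thr <- rate_threshold_deg_s * pi / 180
  min_angle <- min_angle_deg * pi / 180
  dt <- 1 / fs
  t <- (seq_len(n) - 1L) * dt

  active <- abs(w) >= thr
  sgn <- sign(w)
  # run starts: active and (previous inactive or sign change)
  starts <- which(active & (!c(FALSE, active[-n]) | c(FALSE, sgn[-n] != sgn[-1])))
  ends <- which(active & (!c(active[-1], FALSE) | c(sgn[-n] != sgn[-1], FALSE)))
  out <- list()
  for (k in seq_along(starts)) {
    i0 <- starts[k]; i1 <- ends[k]
    angle <- if (i1 > i0) {
      sum((w[i0:(i1 - 1)] + w[(i0 + 1):i1]) / 2) * dt
    } else 0
    if (i0 > 1L && sgn[i0 - 1L] == sgn[i0] || (i0 > 1L && w[i0 - 1L] == 0)) {
      angle <- angle + (w[i0] + w[i0 - 1L]) / 2 * dt
    } else if (i0 > 1L) {
      # opposite-sign neighbour: only this run's share of the crossing
      angle <- angle + w[i0] / 2 * dt
    }
    if (i1 < n && (sgn[i1 + 1L] == sgn[i1] || w[i1 + 1L] == 0)) {
      angle <- angle + (w[i1] + w[i1 + 1L]) / 2 * dt
    } else if (i1 < n) {
      angle <- angle + w[i1] / 2 * dt
    }
    if (abs(angle) < min_angle) next
    pk <- which.max(abs(w[i0:i1])) + i0 - 1L
    out[[length(out) + 1L]] <- list(
      start = t[i0], end = t[i1],
      duration = t[i1] - t[i0] + dt,
      angle = angle, peak_rate = w[pk])
  }
  out
}

#' Postural sway metrics from AP/ML acceleration
#'
#' Means are removed before any computation. The 95% confidence ellipse
#' area is `pi * chi2(0.95, df = 2) * sqrt(lambda1 * lambda2)` with
#' `lambda_i` the eigenvalues of the 2x2 covariance of the
#' (anteroposterior, mediolateral) accelerations and
#' `chi2(0.95, 2) = 5.991`. Jerk is the first difference divided by the
#' sampling period; `jerk_rms` pools both axes.
#'
#' @param acc_ap,acc_ml Anteroposterior / mediolateral acceleration
#'   (m/s^2), uniformly sampled, >= 10 s.
#' @param fs Sampling frequency (Hz).
#' @return A `sway_metrics` list: `rms_ap`, `rms_ml` (m/s^2),
#'   `ellipse_area` ((m/s^2)^2), `jerk_rms` (m/s^3).
#' @export
sway_metrics <- function(acc_ap, acc_ml, fs) {
  n <- length(acc_ap)
  stopifnot(length(acc_ml) == n)
  if (n < 10 * fs) {
    stop("insufficient data: sway_metrics needs >= 10 s of signal",
         call. = FALSE)
  }
  ap <- acc_ap - mean(acc_ap)
  ml <- acc_ml - mean(acc_ml)
  cv <- stats::cov(cbind(ap, ml))
  ev <- eigen(cv, symmetric = TRUE, only.values = TRUE)$values
  ev[ev < 0] <- 0
  jerk2 <- (diff(ap) * fs)^2 + (diff(ml) * fs)^2
  structure(list(
    rms_ap = sqrt(mean(ap^2)),
    rms_ml = sqrt(mean(ml^2)),
    ellipse_area = pi * 5.991 * sqrt(prod(ev)),
    jerk_rms = sqrt(mean(jerk2))),
    class = "sway_metrics")
}

# Shared helpers for the per-test extractors -------------------------------

acc_matrix <- function(ds) as.matrix(ds$data[, c("acc_x", "acc_y", "acc_z")])

dataset_fs <- function(ds) {
  fs <- ds$source$sampling_frequency
  if (is.na(fs)) {
    ts <- ds_timestamps(ds)
    fs <- 1 / stats::median(diff(ts))
  }
  fs
}

mv <- function(id, value, unit = "", name = id) {
  measure_value(value_definition(id, name = name, unit = unit), value)
}

quality_flags_for_inertial <- function(lv, ds, task, config,
                                       expected_axis = "z") {
  flags <- list()
  ts <- ds_timestamps(ds)
  nominal <- ds$source$sampling_frequency
  if (is.na(nominal)) nominal <- dataset_fs(ds)
  if (length(ts) >= 3L && !is.unsorted(ts)) {
    st <- sampling_stats(ts, nominal)
    f <- flag_sampling(st, nominal, task,
                       targets = sprintf("dataset:%s/%s", lv$id, ds$id),
                       irregularity_max = config$sampling$irregularity_max,
                       gap_factor = config$sampling$gap_factor)
    if (!is.null(f)) flags <- c(flags, list(f))
  }
  if (ds$source$sensor == "accelerometer") {
    f <- flag_orientation(acc_matrix(ds), expected_axis, 1, task,
                          targets = sprintf("dataset:%s/%s", lv$id, ds$id),
                          min_g_fraction = config$orientation$min_g_fraction)
    if (!is.null(f)) flags <- c(flags, list(f))
  }
  flags
}

too_short_flag <- function(lv, ds, task, config) {
  expected <- lv$context$expected_duration
  if (is.null(expected)) return(NULL)
  ts <- ds_timestamps(ds)
  span <- max(ts) - min(ts)
  if (span >= config$protocol$too_short_fraction * expected) return(NULL)
  quality_flag(
    flag_id(task, "behavioral", "invalidation", "too_short"),
    reason = sprintf("recording spans %.1f s; protocol expects %.0f s (min %.0f%%)",
                     span, expected, 100 * config$protocol$too_short_fraction),
    targets = sprintf("level:%s", lv$id))
}

#' Six-minute-walk measures for one level
#'
#' Detects steps on the vertical dynamic acceleration — the signed
#' projection of the gravity-subtracted acceleration onto the estimated
#' gravity axis — of the level's `acc` dataset (the signed projection
#' keeps one peak per step, whereas the Euclidean norm rectifies the
#' oscillation and doubles the peak rate), and emits step count, cadence
#' and step-time variability,
#' plus minute-wise cadence aggregates (half-open windows
#' `[k*60, (k+1)*60)` seconds). Sampling, orientation and too-short flags
#' are raised alongside; flags annotate the level, never suppress measures.
#'
#' @param lv A [level()] holding an `acc` dataset (columns
#'   `ts, acc_x, acc_y, acc_z`).
#' @param config Threshold configuration, see [sdm_config()].
#' @return List with `measures` ([measure_set()]), `flags`
#'   (list of [quality_flag()]), `epochs` (empty).
#' @export
sixmwt_measures <- function(lv, config = sdm_config()) {
  ds <- lv$datasets[["acc"]]
  if (is.null(ds)) stop("sixmwt level has no 'acc' dataset", call. = FALSE)
  fs <- dataset_fs(ds)
  acc <- acc_matrix(ds)
  gn <- gravity_and_norm(acc)
  ghat <- gn$gravity / sqrt(sum(gn$gravity^2))
  vertical <- as.numeric(sweep(acc, 2, gn$gravity) %*% ghat)
  steps <- detect_steps(vertical, fs,
                        min_prominence = config$steps$min_prominence,
                        min_separation = config$steps$min_separation,
                        low_hz = config$steps$low_hz,
                        high_hz = config$steps$high_hz,
                        order = config$steps$filter_order)
  mid <- function(abbr, agg = NULL)
    generate_measure_id("sixmwt", lv$modalities, abbr, agg)
  ms <- measure_set()
  ms <- add_measure(ms, mv(mid("steps"), steps$count, ""))
  ms <- add_measure(ms, mv(mid("cadence"), steps$cadence, "steps/min"))
  if (!is.na(steps$step_time_cv)) {
    ms <- add_measure(ms, mv(mid("step_time_cv"), steps$step_time_cv, ""))
  }
  # minute-wise cadence over half-open windows [k*60, (k+1)*60)
  span <- steps$span
  nwin <- max(1L, ceiling(span / 60))
  win_cad <- vapply(seq_len(nwin) - 1L, function(k) {
    lo <- k * 60
    hi <- min((k + 1) * 60, span)
    if (hi <= lo) return(NA_real_)
    60 * sum(steps$times >= lo & steps$times < hi) / (hi - lo)
  }, numeric(1))
  win_cad <- win_cad[!is.na(win_cad)]
  if (length(win_cad)) {
    ms <- add_measure(ms, mv(mid("cadence", "min"), min(win_cad), "steps/min"))
    ms <- add_measure(ms, mv(mid("cadence", "max"), max(win_cad), "steps/min"))
    ms <- add_measure(ms, mv(mid("cadence", "mean"), mean(win_cad), "steps/min"))
  }
  flags <- quality_flags_for_inertial(lv, ds, "sixmwt", config)
  ts_flag <- too_short_flag(lv, ds, "sixmwt", config)
  if (!is.null(ts_flag)) flags <- c(flags, list(ts_flag))
  list(measures = ms, flags = flags, epochs = list())
}

#' U-turn-test measures for one level
#'
#' Detects turn epochs on the level's `gyro` dataset (column `yaw`,
#' rad/s) and emits the turn count and mean absolute angle, duration and
#' peak rate across turns. Each detected turn becomes a level epoch with
#' its angle, duration and peak rate as payload.
#'
#' @inheritParams sixmwt_measures
#' @return List with `measures`, `flags`, `epochs`.
#' @export
utt_measures <- function(lv, config = sdm_config()) {
  ds <- lv$datasets[["gyro"]]
  if (is.null(ds)) stop("utt level has no 'gyro' dataset", call. = FALSE)
  fs <- dataset_fs(ds)
  turns <- detect_turns(ds$data$yaw, fs,
                        min_angle_deg = config$turns$min_angle_deg,
                        rate_threshold_deg_s = config$turns$rate_threshold_deg_s)
  mid <- function(abbr, agg = NULL)
    generate_measure_id("utt", lv$modalities, abbr, agg)
  ms <- measure_set()
  ms <- add_measure(ms, mv(mid("turns"), length(turns), ""))
  if (length(turns)) {
    ang <- vapply(turns, function(e) abs(e$angle), numeric(1))
    dur <- vapply(turns, function(e) e$duration, numeric(1))
    pk <- vapply(turns, function(e) abs(e$peak_rate), numeric(1))
    ms <- add_measure(ms, mv(mid("turn_angle", "mean"), mean(ang), "rad"))
    ms <- add_measure(ms, mv(mid("turn_duration", "mean"), mean(dur), "s"))
    ms <- add_measure(ms, mv(mid("turn_peak_rate", "mean"), mean(pk), "rad/s"))
  }
  epochs <- lapply(turns, function(e) {
    level_epoch(value_definition("turn", "Detected turn", "s"),
                e$start, e$end,
                payload = list(angle = e$angle, duration = e$duration,
                               peak_rate = e$peak_rate))
  })
  flags <- quality_flags_for_inertial(lv, ds, "utt", config)
  list(measures = ms, flags = flags, epochs = epochs)
}

#' Static-balance-test measures for one level
#'
#' Computes postural sway metrics from the level's `acc` dataset with the
#' device belt-worn (z vertical): anteroposterior sway is the x axis,
#' mediolateral the y axis, after per-axis median gravity removal.
#'
#' @inheritParams sixmwt_measures
#' @return List with `measures`, `flags`, `epochs`.
#' @export
sbt_measures <- function(lv, config = sdm_config()) {
  ds <- lv$datasets[["acc"]]
  if (is.null(ds)) stop("sbt level has no 'acc' dataset", call. = FALSE)
  fs <- dataset_fs(ds)
  acc <- acc_matrix(ds)
  g <- apply(acc, 2, stats::median)
  sm <- sway_metrics(acc[, 1] - g[1], acc[, 2] - g[2], fs)
  mid <- function(abbr) generate_measure_id("sbt", lv$modalities, abbr)
  ms <- measure_set()
  ms <- add_measure(ms, mv(mid("rms_ap"), sm$rms_ap, "m/s^2"))
  ms <- add_measure(ms, mv(mid("rms_ml"), sm$rms_ml, "m/s^2"))
  ms <- add_measure(ms, mv(mid("ellipse_area"), sm$ellipse_area, "(m/s^2)^2"))
  ms <- add_measure(ms, mv(mid("jerk_rms"), sm$jerk_rms, "m/s^3"))
  flags <- quality_flags_for_inertial(lv, ds, "sbt", config)
  list(measures = ms, flags = flags, epochs = list())
}
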