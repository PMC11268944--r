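# Shared preprocessing and technical quality checks for inertial/touch
# time series. Thresholds are defaults surfaced through sdm_config().

GRAVITY_MS2 <- 9.81

#' Sampling statistics of a timestamp vector
#'
#' @param timestamps Non-decreasing numeric vector (seconds), length >= 3.
#' @param nominal_freq Nominal sampling frequency in Hz (recorded in the
#'   result; `NA` if unknown).
#' @return A `sampling_stats` list: `median_freq` (Hz, `1/median(dt)`),
#'   `nominal_freq`, `max_gap` (s), `irregularity` (`sd(dt)/mean(dt)`,
#'   dimensionless).
#' @export
sampling_stats <- function(timestamps, nominal_freq = NA_real_) {
  if (length(timestamps) < 3L) {
    stop("insufficient data: sampling_stats needs >= 3 samples", call. = FALSE)
  }
  if (is.unsorted(timestamps)) {
    stop("timestamps must be non-decreasing", call. = FALSE)
  }
  dt <- diff(timestamps)
  structure(list(median_freq = 1 / stats::median(dt),
                 nominal_freq = as.numeric(nominal_freq),
                 max_gap = max(dt),
                 irregularity = stats::sd(dt) / mean(dt)),
            class = "sampling_stats")
}

#' Flag unstable sampling
#'
#' Raises a technical-deviation flag when the sampling is irregular
#' (`irregularity > irregularity_max`) or has gaps larger than
#' `gap_factor` nominal periods.
#'
#' @param stats A [sampling_stats()] result.
#' @param nominal Nominal sampling frequency in Hz (> 0).
#' @param task Test slug used in the flag id.
#' @param targets Flag target references.
#' @param irregularity_max Threshold on `sd(dt)/mean(dt)` (default 0.10).
#' @param gap_factor Maximum tolerated gap in nominal periods (default 1.5).
#' @return A [quality_flag()] or `NULL` when sampling is acceptable.
#' @export
flag_sampling <- function(stats, nominal, task = "generic",
                          targets = "reading",
                          irregularity_max = 0.10, gap_factor = 1.5) {
  stopifnot(nominal > 0)
  bad_irreg <- stats$irregularity > irregularity_max
  bad_gap <- stats$max_gap > gap_factor / nominal
  if (!bad_irreg && !bad_gap) return(NULL)
  quality_flag(
    flag_id(task, "technical", "deviation", "sampling_unstable"),
    reason = sprintf(
      "unstable sampling: irregularity %.3f (max %.2f), max gap %.3f s (max %.3f s)",
      stats$irregularity, irregularity_max, stats$max_gap, gap_factor / nominal),
    targets = targets)
}

#' Resample a series onto a uniform grid
#'
#' Linear interpolation onto `seq(t[1], t[n], by = 1/target_freq)`; no
#' extrapolation beyond the recorded span. Idempotent on already-uniform
#' input at the same rate.
#'
#' @param timestamps Non-decreasing numeric vector, length >= 2.
#' @param values Numeric vector or data.frame of value columns.
#' @param target_freq Target sampling frequency in Hz.
#' @return List with `timestamps` (uniform grid) and `values` (same shape
#'   class as the input values).
#' @export
resample_uniform <- function(timestamps, values, target_freq) {
  stopifnot(length(timestamps) >= 2L, target_freq > 0)
  grid <- seq(timestamps[1], timestamps[length(timestamps)],
              by = 1 / target_freq)
  interp1 <- function(v) stats::approx(timestamps, v, xout = grid,
                                       ties = "ordered")$y
  out <- if (is.data.frame(values)) {
    as.data.frame(lapply(values, interp1))
  } else interp1(values)
  list(timestamps = grid, values = out)
}

#' Zero-phase band-pass filter
#'
#' Butterworth design applied forward and backward (`signal::filtfilt`),
#' giving zero net phase: in-band components are not delayed, which
#' preserves event timings for peak detection. The forward-backward pass
#' is symmetrized (averaged with its time-reversed counterpart) so the
#' output of a time-reversed input is exactly the time-reversed output,
#' removing the direction dependence of finite-edge transients.
#'
#' @param x Numeric series, uniformly sampled.
#' @param fs Sampling frequency (Hz).
#' @param low_hz,high_hz Pass band, `0 < low < high < fs/2`.
#' @param order Butterworth order per pass (default 2).
#' @return Filtered series.
#' @export
bandpass_zero_phase <- function(x, fs, low_hz = 0.5, high_hz = 5, order = 2) {
  stopifnot(low_hz > 0, high_hz > low_hz, high_hz < fs / 2)
  bf <- signal::butter(order, c(low_hz, high_hz) / (fs / 2), type = "pass")
  fwd <- as.numeric(signal::filtfilt(bf, x))
  bwd <- rev(as.numeric(signal::filtfilt(bf, rev(x))))
  (fwd + bwd) / 2
}

#' Gravity estimate and dynamic-acceleration norm
#'
#' Gravity is estimated per axis as the median (robust to activity bursts);
#' the returned norm is the Euclidean norm of the gravity-subtracted
#' acceleration.
#'
#' @param acc3d n x 3 matrix or data.frame of accelerations (m/s^2).
#' @return List with `gravity` (length-3 vector) and `norm` (length-n
#'   series, m/s^2).
#' @export
gravity_and_norm <- function(acc3d) {
  acc <- as.matrix(acc3d)
  stopifnot(ncol(acc) == 3L)
  g <- apply(acc, 2, stats::median)
  centered <- sweep(acc, 2, g)
  list(gravity = as.numeric(g), norm = sqrt(rowSums(centered^2)))
}

#' Flag wrong device orientation
#'
#' The protocol fixes which body axis should carry gravity (e.g. +z for a
#' belt-worn phone on the lower back). A behavioral-deviation flag is
#' raised when the median of the expected component has the wrong sign or
#' a magnitude below `min_g_fraction` g (device not worn/held as
#' instructed).
#'
#' @param acc3d n x 3 acceleration matrix/data.frame (m/s^2), columns x,y,z.
#' @param expected_axis `"x"`, `"y"` or `"z"`.
#' @param expected_sign `+1` or `-1`.
#' @param task Test slug for the flag id.
#' @param targets Flag target references.
#' @param min_g_fraction Minimum |median| as a fraction of g (default 0.5).
#' @return A [quality_flag()] or `NULL`.
#' @export
flag_orientation <- function(acc3d, expected_axis = "z", expected_sign = 1,
                             task = "generic", targets = "reading",
                             min_g_fraction = 0.5) {
  acc <- as.matrix(acc3d)
  stopifnot(ncol(acc) == 3L, expected_sign %in% c(-1, 1))
  ax <- match(expected_axis, c("x", "y", "z"))
  stopifnot(!is.na(ax))
  med <- stats::median(acc[, ax])
  ok <- sign(med) == expected_sign && abs(med) >= min_g_fraction * GRAVITY_MS2
  if (ok) return(NULL)
  quality_flag(
    flag_id(task, "behavioral", "deviation", "orientation"),
    reason = sprintf(
      "median %s-axis acceleration %.2f m/s^2; expected sign %+d with |median| >= %.2f m/s^2",
      expected_axis, med, expected_sign, min_g_fraction * GRAVITY_MS2),
    targets = targets)
}
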