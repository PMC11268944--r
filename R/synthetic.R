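# Seeded generators producing canonical readings with known ground truth,
# plus corruption operators exercising the quality-flag paths. All
# randomness flows through an explicit seed; regeneration with the same
# seed is identical.

with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
            else suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
    set.seed(seed)
  }
  expr
}

ts_column <- function() value_definition("ts", "Time", "s", "timestamp")

acc_columns <- function() list(
  ts_column(),
  value_definition("acc_x", "Acceleration x", "m/s^2"),
  value_definition("acc_y", "Acceleration y", "m/s^2"),
  value_definition("acc_z", "Acceleration z", "m/s^2"))

ground_truth <- function(measures, seed, params) {
  list(measures = measures, seed = seed, params = params)
}

#' Generate a six-minute-walk reading
#'
#' Single-harmonic walking model: gravity on +z plus a vertical
#' acceleration component `A * sin(2*pi*(cadence/60)*t)` with `A` = 1
#' m/s^2 and additive white noise, belt placement. One sine peak per
#' step, so the true cadence is the sine frequency in steps/min.
#'
#' @param cadence True cadence in steps/min.
#' @param duration Recording duration in s (protocol: 360 s).
#' @param fs Sampling frequency in Hz.
#' @param noise_sd White-noise standard deviation (m/s^2).
#' @param seed Integer seed.
#' @param subject_id,session_id Identifiers.
#' @return List with `reading` and `truth` (measure ground truth, seed,
#'   params).
#' @export
gen_walk <- function(cadence = 100, duration = 360, fs = 100,
                     noise_sd = 0.05, seed = 1,
                     subject_id = "sim", session_id = "s1") {
  with_seed(seed, {
    t <- seq(0, duration, by = 1 / fs)
    n <- length(t)
    z <- 9.81 + 1.0 * sin(2 * pi * (cadence / 60) * t) +
      stats::rnorm(n, 0, noise_sd)
    x <- stats::rnorm(n, 0, noise_sd)
    y <- stats::rnorm(n, 0, noise_sd)
    ds <- raw_dataset("acc",
                      sensor_source("simulated", "accelerometer", fs, "belt"),
                      acc_columns(),
                      data.frame(ts = t, acc_x = x, acc_y = y, acc_z = z))
    lv <- level(start = 0, end = duration,
                context = list(expected_duration = duration),
                datasets = list(ds), id = "walk")
    r <- reading("sixmwt", subject_id, session_id,
                 device = list(model = "simulated", placement = "belt"),
                 levels = list(lv))
    list(reading = r,
         truth = ground_truth(list(`sixmwt-cadence` = cadence,
                                   `sixmwt-steps` = cadence * duration / 60),
                              seed,
                              list(cadence = cadence, duration = duration,
                                   fs = fs, noise_sd = noise_sd)))
  })
}

#' Generate a static-balance reading
#'
#' Quiet standing emulated as iid Gaussian AP (x) and ML (y) acceleration
#' on top of gravity on +z, belt placement.
#'
#' @param sigma_ap,sigma_ml Sway standard deviations (m/s^2).
#' @param duration Duration (s).
#' @param fs Sampling frequency (Hz).
#' @param seed Integer seed.
#' @return List with `reading` and `truth` (true sigmas and the isotropic
#'   closed-form ellipse area `pi * 5.991 * sigma_ap * sigma_ml`).
#' @export
gen_sway <- function(sigma_ap = 0.05, sigma_ml = 0.05, duration = 60,
                     fs = 100, seed = 1) {
  with_seed(seed, {
    t <- seq(0, duration, by = 1 / fs)
    n <- length(t)
    ds <- raw_dataset("acc",
                      sensor_source("simulated", "accelerometer", fs, "belt"),
                      acc_columns(),
                      data.frame(ts = t,
                                 acc_x = stats::rnorm(n, 0, sigma_ap),
                                 acc_y = stats::rnorm(n, 0, sigma_ml),
                                 acc_z = 9.81 + stats::rnorm(n, 0, 0.01)))
    lv <- level(start = 0, end = duration,
                context = list(expected_duration = duration),
                datasets = list(ds), id = "stand")
    r <- reading("sbt", "sim", "s1",
                 device = list(model = "simulated", placement = "belt"),
                 levels = list(lv))
    list(reading = r,
         truth = ground_truth(
           list(`sbt-rms_ap` = sigma_ap, `sbt-rms_ml` = sigma_ml,
                `sbt-ellipse_area` = pi * 5.991 * sigma_ap * sigma_ml),
           seed, list(sigma_ap = sigma_ap, sigma_ml = sigma_ml,
                      duration = duration, fs = fs)))
  })
}

#' Generate a U-turn reading
#'
#' Piecewise-constant yaw rate: for each requested turn, a block of
#' constant rate lasting exactly `angle / rate` seconds, separated by
#' `gap` seconds of zero rate.
#'
#' @param angles_deg Turn angles in degrees (signed).
#' @param rates_deg_s Corresponding rate magnitudes in deg/s.
#' @param fs Sampling frequency (Hz).
#' @param gap Zero-rate gap between turns (s).
#' @param seed Integer seed (kept for interface uniformity; the signal is
#'   deterministic).
#' @return List with `reading` and `truth` (angles in rad).
#' @export
gen_turns <- function(angles_deg = c(180), rates_deg_s = c(90), fs = 100,
                      gap = 2, seed = 1) {
  stopifnot(length(angles_deg) == length(rates_deg_s))
  dt <- 1 / fs
  w <- rep(0, as.integer(gap * fs))
  for (k in seq_along(angles_deg)) {
    dur <- abs(angles_deg[k]) / rates_deg_s[k]
    block <- rep(sign(angles_deg[k]) * rates_deg_s[k] * pi / 180,
                 as.integer(round(dur * fs)))
    w <- c(w, block, rep(0, as.integer(gap * fs)))
  }
  t <- (seq_along(w) - 1L) * dt
  ds <- raw_dataset("gyro",
                    sensor_source("simulated", "gyroscope", fs, "belt"),
                    list(ts_column(),
                         value_definition("yaw", "Yaw rate", "rad/s")),
                    data.frame(ts = t, yaw = w))
  lv <- level(start = 0, end = max(t), datasets = list(ds), id = "turns")
  r <- reading("utt", "sim", "s1",
               device = list(model = "simulated", placement = "belt"),
               levels = list(lv))
  list(reading = r,
       truth = ground_truth(list(`utt-turns` = length(angles_deg),
                                 turn_angles_rad = angles_deg * pi / 180),
                            seed, list(angles_deg = angles_deg,
                                       rates_deg_s = rates_deg_s, fs = fs)))
}

reference_shape <- function(shape, n = 60, size = 300) {
  switch(shape,
    square = {
      s <- size
      cbind(c(seq(0, s, length.out = n), rep(s, n), seq(s, 0, length.out = n),
              rep(0, n)),
            c(rep(0, n), seq(0, s, length.out = n), rep(s, n),
              seq(s, 0, length.out = n)))
    },
    circle = {
      th <- seq(0, 2 * pi, length.out = 4 * n)
      size / 2 * cbind(cos(th), sin(th))
    },
    spiral = {
      th <- seq(0, 6 * pi, length.out = 4 * n)
      (size / 2) * (th / (6 * pi)) * cbind(cos(th), sin(th))
    },
    infinity = {
      th <- seq(0, 2 * pi, length.out = 4 * n)
      cbind(size / 2 * sin(th), size / 4 * sin(th) * cos(th))
    },
    stop("unknown shape: ", shape, call. = FALSE))
}

draw_level <- function(shape, hand, attempt, jitter_sd, fs = 60) {
  ref <- reference_shape(shape)
  n <- nrow(ref)
  t <- seq(0, (n - 1) / fs, by = 1 / fs)
  x <- ref[, 1] + stats::rnorm(n, 0, jitter_sd)
  y <- ref[, 2] + stats::rnorm(n, 0, jitter_sd)
  ds <- raw_dataset("touch",
                    sensor_source("simulated", "touchscreen", fs, "handheld"),
                    list(ts_column(),
                         value_definition("x", "Touch x", "px"),
                         value_definition("y", "Touch y", "px")),
                    data.frame(ts = t, x = x, y = y))
  level(modalities = list(modality("shape", shape), modality("hand", hand),
                          modality("attempt", attempt)),
        start = 0, end = max(t),
        context = list(reference = list(x = ref[, 1], y = ref[, 2])),
        datasets = list(ds))
}

#' Generate a drawing reading
#'
#' A full session asks for four shapes (square, circle, spiral, infinity)
#' drawn twice with both hands: 16 levels, keyed by the shape, hand and
#' attempt modalities. The finger trace is the reference polyline plus
#' Gaussian jitter.
#'
#' @param shape Single shape for a one-level reading, or `"all"` for the
#'   full 16-level session.
#' @param jitter_sd Trace jitter (screen px).
#' @param hand,attempt Modality values for the single-level variant.
#' @param seed Integer seed.
#' @return List with `reading` and `truth`.
#' @export
gen_drawing <- function(shape = "all", jitter_sd = 2, hand = "right",
                        attempt = "first", seed = 1) {
  with_seed(seed, {
    levels <- if (identical(shape, "all")) {
      out <- list()
      for (sh in c("square", "circle", "spiral", "infinity"))
        for (h in c("right", "left"))
          for (a in c("first", "second"))
            out[[length(out) + 1L]] <- draw_level(sh, h, a, jitter_sd)
      out
    } else list(draw_level(shape, hand, attempt, jitter_sd))
    r <- reading("draw", "sim", "s1",
                 device = list(model = "simulated", placement = "handheld"),
                 levels = levels)
    list(reading = r,
         truth = ground_truth(list(n_levels = length(levels),
                                   jitter_sd = jitter_sd),
                              seed, list(shape = shape,
                                         jitter_sd = jitter_sd)))
  })
}

#' Generate a symbol-digit substitution reading
#'
#' Stimuli are symbols 1..9 with the identity key map; exactly
#' `round(p_correct * n_trials)` responses are correct (the rest are off
#' by one), so the true accuracy is attained by construction. Reaction
#' times are Gaussian, truncated at 0.05 s.
#'
#' @param n_trials Number of trials.
#' @param p_correct True proportion correct.
#' @param rt_mean,rt_sd Reaction-time distribution (s).
#' @param seed Integer seed.
#' @return List with `reading` and `truth`.
#' @export
gen_cps <- function(n_trials = 60, p_correct = 0.9, rt_mean = 0.6,
                    rt_sd = 0.1, seed = 1) {
  with_seed(seed, {
    n_correct <- as.integer(round(p_correct * n_trials))
    stim <- sample(1:9, n_trials, replace = TRUE)
    correct <- sample(c(rep(TRUE, n_correct),
                        rep(FALSE, n_trials - n_correct)))
    resp <- ifelse(correct, stim, (stim %% 9) + 1L)
    rt <- pmax(0.05, stats::rnorm(n_trials, rt_mean, rt_sd))
    shown <- cumsum(c(0, rt[-n_trials] + 0.2))
    ds <- raw_dataset("responses",
                      sensor_source("simulated", "touchscreen", NA, "handheld"),
                      list(ts_column(),
                           value_definition("t_answered", "Answer time", "s",
                                            "float"),
                           value_definition("stimulus", "Stimulus", "", "int"),
                           value_definition("response", "Response", "", "int")),
                      data.frame(ts = shown, t_answered = shown + rt,
                                 stimulus = as.integer(stim),
                                 response = as.integer(resp)))
    key_map <- as.list(setNames(1:9, as.character(1:9)))
    lv <- level(start = 0, end = max(shown + rt),
                context = list(key_map = key_map),
                datasets = list(ds), id = "symbol_to_digit")
    r <- reading("cps", "sim", "s1",
                 device = list(model = "simulated", placement = "handheld"),
                 levels = list(lv))
    list(reading = r,
         truth = ground_truth(
           list(`cps-n_correct` = n_correct,
                `cps-accuracy` = n_correct / n_trials),
           seed, list(n_trials = n_trials, p_correct = p_correct,
                      rt_mean = rt_mean, rt_sd = rt_sd)))
  })
}

#' Generate a questionnaire reading
#'
#' @param instrument Instrument slug, see [builtin_questionnaire()].
#' @param answers Item answers; defaults to the instrument's minimum for
#'   every item.
#' @param seed Integer seed (interface uniformity; deterministic given
#'   answers).
#' @return List with `reading` and `truth` (the expected scores).
#' @export
gen_questionnaire <- function(instrument = "msis29", answers = NULL,
                              seed = 1) {
  cfg <- builtin_questionnaire(instrument)
  if (is.null(answers)) answers <- rep(cfg$item_range[1], cfg$n_items)
  scores <- score_questionnaire(cfg, answers)
  n <- length(answers)
  ds <- raw_dataset("answers",
                    sensor_source("simulated", "form", NA, "handheld"),
                    list(ts_column(),
                         value_definition("item", "Item index", "", "int"),
                         value_definition("answer", "Answer", "", "int")),
                    data.frame(ts = as.numeric(seq_len(n) - 1L),
                               item = seq_len(n),
                               answer = as.integer(answers)))
  lv <- level(start = 0, end = n - 1, datasets = list(ds), id = "form")
  r <- reading(instrument, "sim", "s1",
               device = list(model = "simulated", placement = "handheld"),
               levels = list(lv))
  list(reading = r,
       truth = ground_truth(as.list(scores), seed,
                            list(instrument = instrument)))
}

#' Generate an event-stream reading (tap/typing/grip/sit-to-stand)
#'
#' Events at a constant rate with optional Gaussian timing jitter.
#'
#' @param code Evaluation code (`"tap"`, `"typing"`, `"grip"`, `"sts"`).
#' @param n_events Number of events.
#' @param rate Events per second.
#' @param jitter_sd Timing jitter (s).
#' @param seed Integer seed.
#' @return List with `reading` and `truth`.
#' @export
gen_events <- function(code = "tap", n_events = 30, rate = 2,
                       jitter_sd = 0, seed = 1) {
  with_seed(seed, {
    t <- (seq_len(n_events) - 1L) / rate +
      if (jitter_sd > 0) stats::rnorm(n_events, 0, jitter_sd) else 0
    t <- sort(t)
    ds <- raw_dataset("events",
                      sensor_source("simulated", "touchscreen", NA, "handheld"),
                      list(ts_column()),
                      data.frame(ts = t))
    lv <- level(start = 0, end = max(t), datasets = list(ds), id = "events")
    r <- reading(code, "sim", "s1",
                 device = list(model = "simulated", placement = "handheld"),
                 levels = list(lv))
    list(reading = r,
         truth = ground_truth(list(count = n_events, rate = rate), seed,
                              list(code = code, n_events = n_events,
                                   rate = rate)))
  })
}

#' Generate a pinch reading
#'
#' @param outcomes Logical vector, one element per pinch attempt
#'   (`TRUE` = successful squeeze below the target distance).
#' @param target_distance Success threshold (px).
#' @param fs Touch sampling frequency (Hz).
#' @param seed Integer seed.
#' @return List with `reading` and `truth`.
#' @export
gen_pinch <- function(outcomes = c(TRUE, TRUE, TRUE), target_distance = 50,
                      fs = 60, seed = 1) {
  n_per <- as.integer(fs)           # 1 s per attempt
  rows <- list()
  t0 <- 0
  for (ok in outcomes) {
    t <- t0 + (seq_len(n_per) - 1L) / fs
    start_d <- 200
    end_d <- if (ok) target_distance / 2 else target_distance * 1.5
    d <- seq(start_d, end_d, length.out = n_per)
    rows[[length(rows) + 1L]] <- data.frame(
      ts = t, x1 = -d / 2, y1 = 0, c1 = 1, x2 = d / 2, y2 = 0, c2 = 1)
    # fingers lifted between attempts
    tg <- t0 + 1 + (seq_len(n_per %/% 2) - 1L) / fs
    rows[[length(rows) + 1L]] <- data.frame(
      ts = tg, x1 = 0, y1 = 0, c1 = 0, x2 = 0, y2 = 0, c2 = 0)
    t0 <- t0 + 1.5
  }
  df <- do.call(rbind, rows)
  cols <- list(ts_column(),
               value_definition("x1", "Contact 1 x", "px"),
               value_definition("y1", "Contact 1 y", "px"),
               value_definition("c1", "Contact 1 down", "", "int"),
               value_definition("x2", "Contact 2 x", "px"),
               value_definition("y2", "Contact 2 y", "px"),
               value_definition("c2", "Contact 2 down", "", "int"))
  df$c1 <- as.integer(df$c1); df$c2 <- as.integer(df$c2)
  ds <- raw_dataset("touch",
                    sensor_source("simulated", "touchscreen", fs, "handheld"),
                    cols, df)
  lv <- level(start = 0, end = max(df$ts),
              context = list(target_distance = target_distance),
              datasets = list(ds), id = "pinch")
  r <- reading("pinch", "sim", "s1",
               device = list(model = "simulated", placement = "handheld"),
               levels = list(lv))
  list(reading = r,
       truth = ground_truth(list(`pinch-attempts` = length(outcomes),
                                 `pinch-successes` = sum(outcomes)),
                            seed, list(outcomes = outcomes)))
}

#' Generate one fixture per registered test
#'
#' @param seed Integer seed.
#' @return Named list (by evaluation code) of `list(reading, truth)`
#'   fixtures covering the whole registry.
#' @export
gen_fixture_suite <- function(seed = 1) {
  qn <- function(instr) {
    cfg <- builtin_questionnaire(instr)
    gen_questionnaire(instr,
                      answers = rep(cfg$item_range[2], cfg$n_items),
                      seed = seed)
  }
  list(
    sixmwt = gen_walk(cadence = 108, duration = 60, fs = 100,
                      noise_sd = 0.05, seed = seed),
    utt = gen_turns(c(180, -180), c(90, 90), seed = seed),
    sbt = gen_sway(seed = seed),
    draw = gen_drawing("square", jitter_sd = 2, seed = seed),
    pinch = gen_pinch(c(TRUE, FALSE, TRUE, TRUE), seed = seed),
    cps = gen_cps(30, 0.9, seed = seed),
    tap = gen_events("tap", 40, 3, 0.01, seed = seed),
    typing = gen_events("typing", 40, 2, 0.05, seed = seed),
    grip = gen_events("grip", 20, 1, 0.02, seed = seed),
    sts = gen_events("sts", 5, 0.5, 0.05, seed = seed),
    msis29 = qn("msis29"),
    alsfrs_r = qn("alsfrs_r"),
    pdq39 = qn("pdq39"),
    mood = qn("mood"),
    fatigue = qn("fatigue"),
    qol = qn("qol"))
}

#' Corrupt a reading to exercise flag paths
#'
#' Applies one corruption to every dataset of every level: random sample
#' dropping (irregular sampling), vertical-axis flip (wrong orientation),
#' truncation to an initial fraction of the time span, or timestamp
#' shuffling (non-monotone time base).
#'
#' @param r A [reading()].
#' @param mode One of `"drop_samples"`, `"flip_orientation"`,
#'   `"truncate"`, `"shuffle_timestamps"`.
#' @param frac Fraction dropped (`drop_samples`) or kept (`truncate`).
#' @param seed Integer seed for the random modes.
#' @return The corrupted reading.
#' @export
corrupt <- function(r, mode = c("drop_samples", "flip_orientation",
                                "truncate", "shuffle_timestamps"),
                    frac = 0.2, seed = 1) {
  mode <- match.arg(mode)
  with_seed(seed, {
    for (lid in names(r$levels)) {
      lv <- r$levels[[lid]]
      for (did in names(lv$datasets)) {
        ds <- lv$datasets[[did]]
        df <- ds$data
        n <- nrow(df)
        df <- switch(mode,
          drop_samples = df[sort(sample(n, ceiling((1 - frac) * n))), ,
                            drop = FALSE],
          flip_orientation = {
            if ("acc_z" %in% names(df)) df$acc_z <- -df$acc_z
            df
          },
          truncate = {
            span <- df[[1]][n] - df[[1]][1]
            df[df[[1]] <= df[[1]][1] + frac * span, , drop = FALSE]
          },
          shuffle_timestamps = {
            df[[1]] <- sample(df[[1]])
            df
          })
        rownames(df) <- NULL
        ds$data <- df
        lv$datasets[[did]] <- ds
      }
      r$levels[[lid]] <- lv
    }
    r
  })
}
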