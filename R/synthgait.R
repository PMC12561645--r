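# Seeded synthetic wrist-acceleration generator with exact ground truth
# (walking bouts, alternating-foot initial contacts, stride lengths). Stands
# in for a multi-sensor reference system so the whole pipeline is testable
# offline.

#' Walking-segment specification
#'
#' Describes one continuous walking segment for the synthetic generator. The
#' wrist signal is modelled as gravity plus an arm-swing fundamental at step
#' frequency (cosine phase, so swing maxima coincide with initial contacts), a
#' 10 percent stride-frequency subharmonic giving left/right structure,
#' `harmonics` higher cosine harmonics sharpening the per-step peak, a brief
#' negative impact transient at each initial contact (the heel-strike jolt
#' transmitted to the wrist), and white noise. Arm-swing and impact amplitudes
#' scale affinely with walking speed so intensity features carry speed signal:
#' swing = 0.12 + 0.18 x speed (g), impact = 0.25 + 0.35 x speed (g).
#'
#' @param duration_s segment duration in seconds.
#' @param cadence_spm cadence in steps per minute (60-160).
#' @param speed_ms walking speed in m/s.
#' @param arm_swing_g arm-swing amplitude in g; default couples to speed.
#' @param harmonics number of higher harmonics (default 2).
#' @param noise_sd_g white-noise standard deviation per axis in g.
#' @param impact_g impact-transient amplitude in g; default couples to speed.
#' @param drift_deg amplitude of the slow (0.02 Hz) orientation drift in
#'   degrees; 0 disables drift.
#' @param seed optional integer seed for this segment's noise.
#' @return an object of class `wg_walkspec`.
#' @export
walk_spec <- function(duration_s, cadence_spm = 110, speed_ms = 1.0,
                      arm_swing_g = NULL, harmonics = 2L, noise_sd_g = 0.02,
                      impact_g = NULL, drift_deg = 8, seed = NULL) {
  if (cadence_spm < 60 || cadence_spm > 160) stop("cadence must be in [60, 160] steps/min")
  if (speed_ms <= 0) stop("speed must be positive")
  if (is.null(arm_swing_g)) arm_swing_g <- 0.18 + 0.20 * speed_ms
  if (arm_swing_g < 0) stop("arm-swing amplitude must be >= 0")
  if (is.null(impact_g)) impact_g <- 0.60 + 0.50 * speed_ms
  structure(list(duration_s = duration_s, cadence_spm = cadence_spm,
                 speed_ms = speed_ms, arm_swing_g = arm_swing_g,
                 harmonics = as.integer(harmonics), noise_sd_g = noise_sd_g,
                 impact_g = impact_g, drift_deg = drift_deg, seed = seed),
            class = "wg_walkspec")
}

# Slow orientation drift: rotation of the full acceleration vector about the
# y axis (norm-preserving, so norm-based detectors are unaffected).
apply_drift <- function(acc, t, drift_deg) {
  if (drift_deg <= 0) return(acc)
  th <- drift_deg * pi / 180 * sin(2 * pi * 0.02 * t)
  x <- acc[, 1L] * cos(th) + acc[, 3L] * sin(th)
  z <- -acc[, 1L] * sin(th) + acc[, 3L] * cos(th)
  acc[, 1L] <- x
  acc[, 3L] <- z
  acc
}

#' Generate one synthetic walking segment
#'
#' Returns the wrist acceleration for one walking segment together with exact
#' ground truth: initial contacts sit at the arm-swing fundamental's phase
#' zeros (cosine maxima), feet alternate, inter-contact time is exactly one
#' step period, and stride length is exactly speed x stride time.
#'
#' @param spec a [walk_spec()].
#' @param fs sampling frequency in Hz (default 100).
#' @return list with `acc` (N x 3 matrix, g), `ics` (data.frame time_s, foot),
#'   `strides` (data.frame start_ic_s, end_ic_s, length_m, foot), and
#'   `speed_ms`.
#' @export
synth_walk <- function(spec, fs = 100) {
  stopifnot(inherits(spec, "wg_walkspec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  f_step <- spec$cadence_spm / 60
  n_steps <- floor(spec$duration_s * f_step)
  if (n_steps < 6L) {
    stop("segment too short: need at least two consecutive strides of both feet (6 steps)")
  }
  n <- round(spec$duration_s * fs)
  t <- (seq_len(n) - 1L) / fs
  t_ic0 <- 0.5 / f_step
  ic_times <- t_ic0 + (seq_len(n_steps) - 1L) / f_step
  # fundamental at -45 degrees: the swing maximum trails the initial contact
  # by an eighth of a step period, as the arm keeps accelerating briefly after
  # foot strike
  phase <- 2 * pi * f_step * (t - t_ic0) - pi / 4

  a <- spec$arm_swing_g
  w <- a * cos(phase) + 0.1 * a * cos(phase / 2)
  if (spec$harmonics > 0L) {
    for (h in seq_len(spec$harmonics) + 1L) w <- w + (0.1 * a / h) * cos(h * phase)
  }
  # heel-strike jolt: balanced biphasic transient straddling the initial
  # contact -- a brief deceleration dip just before the contact and an equal
  # rebound spike just after, as the impact shock reaches the wrist; the
  # balance keeps the jolt spectrally broadband with no net pull on the
  # arm-swing fundamental
  sig_i <- 0.025
  d_ic <- 0.02
  dip <- rep(0, n)
  for (tc in ic_times) {
    lo <- max(1L, floor((tc - d_ic - 4 * sig_i) * fs) + 1L)
    hi <- min(n, ceiling((tc + d_ic + 4 * sig_i) * fs) + 1L)
    idx <- lo:hi
    dip[idx] <- dip[idx] -
      spec$impact_g * exp(-((t[idx] - (tc - d_ic)) / sig_i)^2 / 2) +
      spec$impact_g * exp(-((t[idx] - (tc + d_ic)) / sig_i)^2 / 2)
  }
  w <- w + dip
  # taper segment edges over 0.25 s so concatenated schedules stay continuous
  ramp <- pmin(1, pmin(t, max(t) - t) / 0.25)
  w <- w * ramp

  acc <- cbind(
    0.4 * a * sin(phase) * ramp,
    0.15 * a * sin(phase / 2) * ramp,
    1 + w
  )
  acc <- apply_drift(acc, t, spec$drift_deg)
  if (spec$noise_sd_g > 0) {
    acc <- acc + matrix(rnorm(3 * n, sd = spec$noise_sd_g), ncol = 3L)
  }

  feet <- rep(c("left", "right"), length.out = n_steps)
  stride_t <- 2 / f_step
  strides <- NULL
  if (n_steps >= 3L) {
    i <- seq_len(n_steps - 2L)
    strides <- data.frame(
      start_ic_s = ic_times[i], end_ic_s = ic_times[i + 2L],
      length_m = spec$speed_ms * stride_t, foot = feet[i],
      stringsAsFactors = FALSE
    )
  }
  list(acc = acc,
       ics = data.frame(time_s = ic_times, foot = feet, stringsAsFactors = FALSE),
       strides = strides, speed_ms = spec$speed_ms)
}

#' Schedule items for the synthetic recorder
#'
#' @param kind `"walk"`, `"rest"` or `"activity"` (non-gait arm movement).
#' @param spec for walks, a [walk_spec()]; ignored otherwise.
#' @param duration_s duration for rest/activity items.
#' @param activity for `kind = "activity"`: one of `"filtered_noise"`
#'   (aperiodic high-variance arm movement), `"arm_wave"` (0.5 Hz),
#'   `"toothbrush"` (3.5 Hz burst) or `"shake"` (high-g shaking).
#' @param intensity_g amplitude of the activity in g.
#' @return an object of class `wg_schedule_item`.
#' @export
schedule_item <- function(kind = c("walk", "rest", "activity"), spec = NULL,
                          duration_s = NULL, activity = "filtered_noise",
                          intensity_g = 0.3) {
  kind <- match.arg(kind)
  if (kind == "walk") {
    stopifnot(inherits(spec, "wg_walkspec"))
    duration_s <- spec$duration_s
  }
  if (is.null(duration_s) || duration_s <= 0) stop("item duration must be positive")
  structure(list(kind = kind, spec = spec, duration_s = duration_s,
                 activity = activity, intensity_g = intensity_g),
            class = "wg_schedule_item")
}

synth_rest <- function(duration_s, fs, noise_sd_g = 0.005) {
  n <- round(duration_s * fs)
  matrix(rnorm(3 * n, sd = noise_sd_g), ncol = 3L) +
    matrix(rep(c(0, 0, 1), each = n), ncol = 3L)
}

synth_activity <- function(duration_s, fs, activity, intensity_g) {
  n <- round(duration_s * fs)
  t <- (seq_len(n) - 1L) / fs
  ramp <- pmin(1, pmin(t, max(t) - t) / 0.25)
  w <- switch(activity,
    filtered_noise = {
      x <- rnorm(n)
      bt <- signal::butter(2, 6 / (fs / 2), type = "low")
      y <- as.numeric(signal::filter(bt, x))
      intensity_g * y / max(sd(y), 1e-12)
    },
    arm_wave = intensity_g * sin(2 * pi * 0.5 * t),
    toothbrush = intensity_g * sin(2 * pi * 3.5 * t),
    shake = intensity_g * sin(2 * pi * 8 * t) * (1 + 0.3 * rnorm(n)),
    stop(sprintf("unknown activity kind '%s'", activity))
  )
  w <- w * ramp
  cbind(0.5 * w + rnorm(n, sd = 0.01),
        rnorm(n, sd = 0.01),
        1 + w + rnorm(n, sd = 0.01))
}

#' Generate a full synthetic recording with ground truth
#'
#' Concatenates schedule items into one 100 Hz wrist recording and the exact
#' reference annotations: walking bouts (with walk segments separated by
#' pauses shorter than 3 s merged into a single bout, matching the bout
#' definition used throughout), foot-labelled initial contacts, stride records
#' and per-bout walking speed. The same seed reproduces the recording
#' byte-for-byte; a different seed changes the noise but never the truth
#' timing.
#'
#' @param schedule list of [schedule_item()]s.
#' @param seed integer seed.
#' @param fs sampling frequency in Hz.
#' @return list with `recording` (a [wg_recording()]) and `reference` (a
#'   `wg_reference`: list of data.frames `bouts`, `ics`, `strides`,
#'   `bout_speed`, plus `schema_version`).
#' @export
synth_recording <- function(schedule, seed = 1L, fs = 100) {
  if (length(schedule) == 0L) stop("schedule must contain at least one item")
  set.seed(seed)
  acc <- NULL
  t_cursor <- 0
  raw_bouts <- list(); ics <- list(); strides <- list(); speeds <- list()
  for (item in schedule) {
    stopifnot(inherits(item, "wg_schedule_item"))
    if (item$kind == "walk") {
      seg <- synth_walk(item$spec, fs = fs)
      raw_bouts[[length(raw_bouts) + 1L]] <-
        c(t_cursor, t_cursor + item$duration_s)
      seg$ics$time_s <- seg$ics$time_s + t_cursor
      ics[[length(ics) + 1L]] <- seg$ics
      if (!is.null(seg$strides)) {
        seg$strides$start_ic_s <- seg$strides$start_ic_s + t_cursor
        seg$strides$end_ic_s <- seg$strides$end_ic_s + t_cursor
        strides[[length(strides) + 1L]] <- seg$strides
      }
      speeds[[length(speeds) + 1L]] <-
        c(t_cursor, t_cursor + item$duration_s, seg$speed_ms)
      a <- seg$acc
    } else if (item$kind == "rest") {
      a <- synth_rest(item$duration_s, fs)
    } else {
      a <- synth_activity(item$duration_s, fs, item$activity, item$intensity_g)
    }
    acc <- rbind(acc, a)
    t_cursor <- t_cursor + item$duration_s
  }
  rec <- wg_recording(acc, fs = fs, unit = "g")

  raw <- do.call(rbind, raw_bouts)
  bouts <- merge_bouts(data.frame(start_s = raw[, 1L], end_s = raw[, 2L]),
                       min_break_s = 3.0)
  bouts$bout_id <- seq_len(nrow(bouts))
  bouts <- bouts[, c("bout_id", "start_s", "end_s")]

  ic_df <- if (length(ics)) do.call(rbind, ics) else
    data.frame(time_s = numeric(0), foot = character(0))
  ic_df$bout_id <- assign_to_bout(ic_df$time_s, bouts)
  st_df <- if (length(strides)) do.call(rbind, strides) else
    data.frame(start_ic_s = numeric(0), end_ic_s = numeric(0),
               length_m = numeric(0), foot = character(0))
  st_df$bout_id <- assign_to_bout(st_df$start_ic_s, bouts)

  sp <- do.call(rbind, speeds)
  bout_speed <- data.frame(bout_id = integer(0), speed_ms = numeric(0))
  if (!is.null(sp)) {
    bid <- assign_to_bout(sp[, 1L], bouts)
    agg <- tapply(seq_len(nrow(sp)), bid, function(i) {
      wdur <- sp[i, 2L] - sp[i, 1L]
      sum(sp[i, 3L] * wdur) / sum(wdur)
    })
    bout_speed <- data.frame(bout_id = as.integer(names(agg)),
                             speed_ms = as.numeric(agg))
  }

  reference <- structure(
    list(bouts = bouts, ics = ic_df, strides = st_df, bout_speed = bout_speed,
         schema_version = 1L),
    class = "wg_reference"
  )
  list(recording = rec, reference = reference)
}

# Map event times onto bout ids (half-open membership); NA outside any bout.
assign_to_bout <- function(times, bouts) {
  if (length(times) == 0L) return(integer(0))
  out <- rep(NA_integer_, length(times))
  for (i in seq_len(nrow(bouts))) {
    inb <- times >= bouts$start_s[i] & times < bouts$end_s[i]
    out[inb] <- bouts$bout_id[i]
  }
  out
}

#' @export
print.wg_reference <- function(x, ...) {
  cat(sprintf("<wg_reference> %d bout(s), %d IC(s), %d stride(s)\n",
              nrow(x$bouts), nrow(x$ics), nrow(x$strides)))
  invisible(x)
}

#' A standard mixed simulation schedule
#'
#' Convenience builder: alternating rest and walking, roughly a target
#' fraction of walking time, with per-bout speeds cycling through a small
#' range. Used by examples and the package's own validation runs.
#'
#' @param total_s total duration in seconds.
#' @param walk_fraction fraction of time spent walking.
#' @param n_bouts number of walking bouts.
#' @param speeds vector of walking speeds recycled across bouts (m/s).
#' @param cadence_spm cadence for all bouts.
#' @param noise_sd_g noise level.
#' @return list of [schedule_item()]s.
#' @export
demo_schedule <- function(total_s = 600, walk_fraction = 0.5, n_bouts = 5L,
                          speeds = c(0.9, 1.0, 1.2, 1.1, 1.3),
                          cadence_spm = 110, noise_sd_g = 0.02) {
  walk_each <- total_s * walk_fraction / n_bouts
  rest_each <- total_s * (1 - walk_fraction) / (n_bouts + 1L)
  sched <- list(schedule_item("rest", duration_s = rest_each))
  for (i in seq_len(n_bouts)) {
    sched <- c(sched, list(
      schedule_item("walk", spec = walk_spec(walk_each, cadence_spm = cadence_spm,
                                             speed_ms = speeds[(i - 1L) %% length(speeds) + 1L],
                                             noise_sd_g = noise_sd_g)),
      schedule_item("rest", duration_s = rest_each)
    ))
  }
  sched
}
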