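# Intensity-based step/stride-length estimation: Weinberg, Kim and Bylemans
# power-law models, each in wrist, foot-length, adaptive-RMS and
# adaptive+foot-length versions. Features are computed in g between
# consecutive initial contacts; outputs are metres.

#' Resolve stride-length model parameters
#'
#' Looks up the registered gain `A` and intercept `B` for a model version and
#' binds the participant's foot length where the version requires it (the
#' foot length is printed in cm and converted to metres before addition).
#'
#' @param method `"weinberg"`, `"kim"` or `"bylemans"`.
#' @param version one of `"wrist"`, `"wrist_footlength"`, `"wrist_adaptive"`,
#'   `"wrist_adaptive_footlength"`.
#' @param foot_length_cm participant foot length in cm (required by the
#'   foot-length versions).
#' @param overrides optional named list of parameter overrides (e.g. `A`).
#' @return list with `A`, `B_m`, `adaptive`, `method`, `version`.
#' @export
sl_params <- function(method, version, foot_length_cm = NULL, overrides = NULL) {
  p <- override_params(default_params(method, version), overrides)
  if (p$family != "sl") stop(sprintf("'%s' is not a stride-length method", method))
  A <- param_value(p, "A")
  if (A <= 0) stop("gain A must be positive")
  b_entry <- p$params$B
  if (identical(b_entry$value, "foot_length")) {
    if (is.null(foot_length_cm) || !is.finite(foot_length_cm)) {
      stop(sprintf("version '%s' requires the participant's foot length (cm)", version))
    }
    B_m <- foot_length_cm / 100
  } else {
    B_m <- as.numeric(b_entry$value)
  }
  list(A = A, B_m = B_m, adaptive = grepl("adaptive", version),
       method = method, version = version)
}

# method-specific preprocessing of the bout norm (input and output in g)
sl_preprocess <- function(bs, method) {
  switch(method,
    weinberg = butterworth(bs$series, "low", 2, order = 4L),
    kim = bs$series,
    bylemans = moving_average(
      butterworth(bs$series, "high", 4, order = 4L), 0.1),
    stop(sprintf("unknown stride-length method '%s'", method))
  )
}

#' Per-step intensity features between consecutive initial contacts
#'
#' One row per consecutive IC pair, computed on the method's preprocessed
#' series over the half-open sample range between the two ICs: `maxmin`
#' (amplitude max - min), `mu` (mean absolute signal), `rms`, and `dt_s`.
#'
#' @param bs a [bout_signal()].
#' @param ic_times_s initial-contact times (recording clock), at least two,
#'   inside the bout.
#' @param method `"weinberg"`, `"kim"` or `"bylemans"`.
#' @return data.frame with columns `maxmin`, `mu`, `rms`, `dt_s`,
#'   `start_ic_s`, `end_ic_s`.
#' @export
extract_step_features <- function(bs, ic_times_s, method = "weinberg") {
  if (length(ic_times_s) < 2L) stop("need at least two initial contacts")
  if (any(ic_times_s < bs$start_s - 1e-9) || any(ic_times_s > bs$end_s + 1e-9)) {
    stop("initial contact outside the bout")
  }
  x <- sl_preprocess(bs, method)$values
  fs <- bs$fs
  idx <- pmin(pmax(round((ic_times_s - bs$start_s) * fs) + 1L, 1L), length(x))
  out <- lapply(seq_len(length(idx) - 1L), function(i) {
    i0 <- idx[i]; i1 <- idx[i + 1L]
    if (i1 <= i0) stop("initial contacts must be strictly increasing")
    v <- x[i0:(i1 - 1L)]
    data.frame(maxmin = max(v) - min(v), mu = mean(abs(v)),
               rms = sqrt(mean(v^2)),
               dt_s = ic_times_s[i + 1L] - ic_times_s[i],
               start_ic_s = ic_times_s[i], end_ic_s = ic_times_s[i + 1L])
  })
  do.call(rbind, out)
}

#' Weinberg step-length model
#'
#' Non-adaptive versions: `A * maxmin^(1/4) + B`; adaptive versions multiply
#' the intensity term by the segment RMS: `A * rms * maxmin^(1/4) + B`.
#'
#' @param f one row (or several) of [extract_step_features()].
#' @param p parameters from [sl_params()].
#' @return step length(s) in metres (uncapped).
#' @export
step_length_weinberg <- function(f, p) {
  term <- abs(f$maxmin)^(1 / 4)
  if (p$adaptive) term <- term * f$rms
  p$A * term + p$B_m
}

#' Kim step-length model
#'
#' Non-adaptive: `A * mu^(1/3) + B`; adaptive: `A * rms * mu^(1/3) + B`.
#'
#' @inheritParams step_length_weinberg
#' @return step length(s) in metres (uncapped).
#' @export
step_length_kim <- function(f, p) {
  term <- abs(f$mu)^(1 / 3)
  if (p$adaptive) term <- term * f$rms
  p$A * term + p$B_m
}

#' Bylemans step-length model
#'
#' Non-adaptive: `A * (mu * (1/dt) * maxmin)^(1/2.7) + B`; adaptive versions
#' multiply the intensity term by the segment RMS.
#'
#' @inheritParams step_length_weinberg
#' @return step length(s) in metres (uncapped).
#' @export
step_length_bylemans <- function(f, p) {
  if (any(f$dt_s <= 0)) stop("dt_s must be positive")
  term <- (abs(f$mu) * (1 / f$dt_s) * abs(f$maxmin))^(1 / 2.7)
  if (p$adaptive) term <- term * f$rms
  p$A * term + p$B_m
}

# physiological step-length cap; out-of-range estimates are clamped and counted
cap_steps <- function(steps, lo = 0.1, hi = 1.5) {
  n_clamped <- sum(steps < lo | steps > hi)
  structure(pmin(pmax(steps, lo), hi), n_clamped = n_clamped)
}

#' Assemble stride records and the per-second stride-length series
#'
#' Stride length over each IC-to-IC interval is twice the step length. Step
#' values are placed at their interval midpoints and linearly interpolated
#' onto a 1 s grid clipped to the bout; the bout-mean stride length is the
#' mean of that per-second series.
#'
#' @param steps step lengths in metres, one per consecutive IC pair.
#' @param ic_times_s the IC times (length `length(steps) + 1`).
#' @param bout_start_s,bout_end_s bout boundaries in seconds.
#' @param bout_id optional id stamped on the outputs.
#' @return list with `strides` (data.frame bout_id, start_ic_s, end_ic_s,
#'   stride_m), `per_second` (data.frame bout_id, second_index, time_s,
#'   stride_m) and `bout_mean_m`.
#' @export
assemble_strides <- function(steps, ic_times_s, bout_start_s, bout_end_s,
                             bout_id = 1L) {
  if (length(steps) == 0L) stop("no steps to assemble")
  if (length(ic_times_s) != length(steps) + 1L) {
    stop("need exactly one more IC than steps")
  }
  stride_m <- 2 * steps
  strides <- data.frame(bout_id = bout_id,
                        start_ic_s = ic_times_s[-length(ic_times_s)],
                        end_ic_s = ic_times_s[-1L], stride_m = stride_m)
  mid <- (strides$start_ic_s + strides$end_ic_s) / 2
  grid <- seq(bout_start_s + 0.5, bout_end_s, by = 1)
  if (length(grid) == 0L) grid <- (bout_start_s + bout_end_s) / 2
  vals <- if (length(mid) == 1L) rep(stride_m, length(grid)) else
    approx(mid, stride_m, xout = grid, rule = 2)$y
  per_second <- data.frame(bout_id = bout_id,
                           second_index = seq_along(grid) - 1L,
                           time_s = grid, stride_m = vals)
  list(strides = strides, per_second = per_second, bout_mean_m = mean(vals))
}

#' Estimate stride length over walking bouts
#'
#' Runs one stride-length model over every bout, using externally supplied
#' initial contacts (typically reference ICs). Step estimates outside the
#' physiological range [0.1, 1.5] m are clamped and counted.
#'
#' @param rec a [wg_recording()].
#' @param bouts data.frame with `bout_id`, `start_s`, `end_s`.
#' @param ics data.frame with `bout_id`, `time_s`.
#' @param method `"weinberg"`, `"kim"` or `"bylemans"`.
#' @param version model version (see [sl_params()]).
#' @param foot_length_cm participant foot length (cm), for foot-length
#'   versions; defaults to `rec$participant_meta$foot_length_cm`.
#' @param overrides optional parameter overrides.
#' @return list with `strides`, `per_second`, `bout_means` (data.frame
#'   bout_id, stride_m), `n_clamped`, `method`, `version`.
#' @export
estimate_stride_length <- function(rec, bouts, ics, method, version = "wrist",
                                   foot_length_cm = NULL, overrides = NULL) {
  if (is.null(foot_length_cm)) foot_length_cm <- rec$participant_meta$foot_length_cm
  p <- sl_params(method, version, foot_length_cm, overrides)
  model <- switch(method, weinberg = step_length_weinberg,
                  kim = step_length_kim, bylemans = step_length_bylemans)
  strides <- NULL; per_sec <- NULL; means <- NULL; n_clamped <- 0L
  for (i in seq_len(nrow(bouts))) {
    bid <- bouts$bout_id[i]
    tt <- sort(ics$time_s[ics$bout_id == bid])
    if (length(tt) < 2L) next
    bsg <- bout_signal(rec, bouts$start_s[i], bouts$end_s[i])
    f <- extract_step_features(bsg, tt, method)
    st <- cap_steps(model(f, p))
    n_clamped <- n_clamped + attr(st, "n_clamped")
    asm <- assemble_strides(as.numeric(st), tt, bouts$start_s[i], bouts$end_s[i],
                            bout_id = bid)
    strides <- rbind(strides, asm$strides)
    per_sec <- rbind(per_sec, asm$per_second)
    means <- rbind(means, data.frame(bout_id = bid, stride_m = asm$bout_mean_m))
  }
  list(strides = strides, per_second = per_sec, bout_means = means,
       n_clamped = n_clamped, method = method, version = version)
}
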