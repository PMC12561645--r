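# Gait-sequence detection: six wrist-adapted detectors mapping a recording to
# a list of walking bouts, plus the 3 s bout merge rule shared with the
# reference bout definition.

#' Merge walking bouts separated by short pauses
#'
#' Bouts separated by a break shorter than `min_break_s` are considered one
#' bout (the pause is part of the bout); breaks of at least `min_break_s`
#' keep bouts separate.
#'
#' @param bouts data.frame with columns `start_s`, `end_s`, sorted and
#'   pairwise disjoint.
#' @param min_break_s minimum break that separates bouts (default 3 s).
#' @return merged data.frame with columns `start_s`, `end_s`.
#' @export
merge_bouts <- function(bouts, min_break_s = 3.0) {
  if (nrow(bouts) == 0L) return(data.frame(start_s = numeric(0), end_s = numeric(0)))
  if (any(bouts$end_s <= bouts$start_s)) stop("bouts must have end_s > start_s")
  if (is.unsorted(bouts$start_s)) stop("bouts must be sorted by start time")
  if (nrow(bouts) > 1L && any(bouts$start_s[-1L] < bouts$end_s[-nrow(bouts)])) {
    stop("bouts must be pairwise disjoint")
  }
  start <- bouts$start_s[1L]
  end <- bouts$end_s[1L]
  out_s <- numeric(0); out_e <- numeric(0)
  for (i in seq_len(nrow(bouts))[-1L]) {
    if (bouts$start_s[i] - end < min_break_s) {
      end <- max(end, bouts$end_s[i])
    } else {
      out_s <- c(out_s, start); out_e <- c(out_e, end)
      start <- bouts$start_s[i]; end <- bouts$end_s[i]
    }
  }
  data.frame(start_s = c(out_s, start), end_s = c(out_e, end))
}

# Boolean flags over a regular grid of interval starts -> bout intervals.
flags_to_bouts <- function(flags, starts, width) {
  if (!any(flags)) return(data.frame(start_s = numeric(0), end_s = numeric(0)))
  iv <- cbind(starts[flags], starts[flags] + width)
  # union of possibly overlapping equal-width intervals
  s <- iv[1L, 1L]; e <- iv[1L, 2L]
  out_s <- numeric(0); out_e <- numeric(0)
  for (i in seq_len(nrow(iv))[-1L]) {
    if (iv[i, 1L] <= e) e <- max(e, iv[i, 2L]) else {
      out_s <- c(out_s, s); out_e <- c(out_e, e)
      s <- iv[i, 1L]; e <- iv[i, 2L]
    }
  }
  data.frame(start_s = c(out_s, s), end_s = c(out_e, e))
}

# Windowed standard deviation via cumulative sums; returns one value per
# window start (indices, not times).
windowed_sd <- function(x, win, starts) {
  cs <- c(0, cumsum(x)); cs2 <- c(0, cumsum(x^2))
  n <- win
  sums <- cs[starts + n] - cs[starts]
  sq <- cs2[starts + n] - cs2[starts]
  v <- pmax(0, (sq - sums^2 / n) / (n - 1L))
  sqrt(v)
}

windowed_max <- function(x, win, starts) {
  vapply(starts, function(s) max(x[s:(s + win - 1L)]), 0)
}

windowed_mean <- function(x, win, starts) {
  cs <- c(0, cumsum(x))
  (cs[starts + win] - cs[starts]) / win
}

# Remove the gravity component from each axis: zero-phase low-pass at 0.25 Hz
# subtracted per axis. Returns an N x 3 matrix in the recording's unit.
remove_gravity_axes <- function(rec) {
  apply(rec$acc, 2L, function(col) {
    s <- wg_series(col, fs = rec$fs, unit = rec$unit)
    col - butterworth(s, "low", 0.25, order = 2L)$values
  })
}

norm_in_g <- function(rec) convert_unit(accel_norm(rec), "g")

# Shared finishing for every detector: 3 s merge, then the minimum-bout rule
# (a bout must span at least four steps; for detectors without explicit steps
# this is a 2 s minimum at the nominal two steps per second).
finish_bouts <- function(bouts, duration_s, min_bout_s = 2.0) {
  if (nrow(bouts) == 0L) return(bouts)
  bouts$start_s <- pmax(0, bouts$start_s)
  bouts$end_s <- pmin(duration_s, bouts$end_s)
  bouts <- bouts[bouts$end_s > bouts$start_s, , drop = FALSE]
  if (nrow(bouts) == 0L) return(bouts)
  bouts <- merge_bouts(bouts, 3.0)
  bouts <- bouts[bouts$end_s - bouts$start_s >= min_bout_s, , drop = FALSE]
  rownames(bouts) <- NULL
  bouts
}

new_gsd_result <- function(method, version, bouts) {
  structure(list(method = method, version = version, bouts = bouts,
                 total_walking_s = sum(bouts$end_s - bouts$start_s)),
            class = "wg_gsd_result")
}

#' @export
print.wg_gsd_result <- function(x, ...) {
  cat(sprintf("<wg_gsd_result> %s/%s: %d bout(s), %.1f s walking\n",
              x$method, x$version, nrow(x$bouts), x$total_walking_s))
  invisible(x)
}

prep_rec <- function(rec) {
  if (rec$fs != 100) {
    # detectors assume 100 Hz; resample each axis
    acc <- apply(rec$acc, 2L, function(col)
      resample_series(wg_series(col, rec$fs, rec$unit), 100)$values)
    rec <- wg_recording(acc, fs = 100, unit = rec$unit, t0 = rec$t0,
                        participant_meta = rec$participant_meta)
  }
  rec
}

#' Hickey gait-sequence detector (wrist)
#'
#' Window-based detector on the gravity-removed acceleration norm: 1 s
#' analysis windows at 0.1 s resolution are walking candidates when the norm
#' standard deviation exceeds `thresholdstill` and the raw-norm activity stays
#' below the `thresholdupright` maximum-activity ceiling (which excludes
#' high-g non-gait movement); contiguous candidate windows merge into bouts.
#'
#' @param rec a [wg_recording()].
#' @param p parameters from [default_params()]; default registry values used
#'   when NULL.
#' @return a `wg_gsd_result`.
#' @export
gsd_hickey <- function(rec, p = NULL) {
  rec <- prep_rec(rec)
  if (is.null(p)) p <- default_params("hickey", "wrist")
  fs <- rec$fs
  win <- round(1.0 * fs); hop <- max(1L, round(0.1 * fs))
  gn <- sqrt(rowSums(remove_gravity_axes(rec)^2))
  if (rec$unit == "m_s2") gn <- gn / WG_GRAVITY
  raw <- norm_in_g(rec)$values
  n <- length(gn)
  if (n < win) stop("recording shorter than one analysis window (1 s)")
  starts <- seq(1L, n - win + 1L, by = hop)
  cand <- windowed_sd(gn, win, starts) > param_value(p, "thresholdstill") &
    windowed_max(raw, win, starts) < param_value(p, "thresholdupright")
  bouts <- flags_to_bouts(cand, (starts - 1L) / fs, win / fs)
  new_gsd_result("hickey", "wrist", finish_bouts(bouts, n / fs))
}

#' Kheirkhahan gait-sequence detector (wrist)
#'
#' Activity-count detector: per-second activity counts are taken as the epoch
#' peak-to-peak amplitude of the rectified 0.25-10 Hz band-passed norm (in g),
#' a robust per-epoch activity magnitude; a sliding window of `win_size`
#' epochs marks its central epoch as walking when the window's mean count
#' exceeds `threshold`.
#'
#' @inheritParams gsd_hickey
#' @return a `wg_gsd_result`.
#' @export
gsd_kheirkhahan <- function(rec, p = NULL) {
  rec <- prep_rec(rec)
  if (is.null(p)) p <- default_params("kheirkhahan", "wrist")
  fs <- rec$fs
  s <- norm_in_g(rec)
  bp <- abs(butterworth(s, "band", c(0.25, 10), order = 4L)$values)
  epoch <- round(fs)  # 1 s epochs
  n_ep <- floor(length(bp) / epoch)
  if (n_ep < 1L) stop("recording shorter than one epoch (1 s)")
  counts <- vapply(seq_len(n_ep), function(i) {
    v <- bp[((i - 1L) * epoch + 1L):(i * epoch)]
    max(v) - min(v)
  }, 0)
  k <- as.integer(param_value(p, "win_size"))
  thr <- param_value(p, "threshold")
  # centered window mean; edge windows truncate to the available epochs
  wsum <- stats::filter(counts, rep(1, k), sides = 2L)
  wn <- stats::filter(rep(1, n_ep), rep(1, k), sides = 2L)
  half <- k %/% 2L
  for (j in seq_len(half)) {
    wsum[j] <- sum(counts[1:min(n_ep, j + half)])
    wn[j] <- min(n_ep, j + half)
    wsum[n_ep - j + 1L] <- sum(counts[max(1L, n_ep - j + 1L - half):n_ep])
    wn[n_ep - j + 1L] <- n_ep - max(1L, n_ep - j + 1L - half) + 1L
  }
  flags <- as.numeric(wsum / wn) > thr
  bouts <- flags_to_bouts(flags, (seq_len(n_ep) - 1L), 1)
  new_gsd_result("kheirkhahan", "wrist", finish_bouts(bouts, length(bp) / fs))
}

#' MacLean gait-sequence detector (wrist)
#'
#' Threshold detector: the band-passed, centered norm is binarised at
#' `threshold_binary`, the binary signal is smoothed (0.5 s moving average and
#' majority vote), inactive gaps shorter than `gap_threshold` whose mean
#' smoothed activity is at least `gap_index` are filled, and candidate bouts
#' are kept when they last at least `walk_threshold` seconds with a mean raw
#' activity fraction of at least `walk_index`.
#'
#' @inheritParams gsd_hickey
#' @return a `wg_gsd_result`.
#' @export
gsd_maclean <- function(rec, p = NULL) {
  rec <- prep_rec(rec)
  if (is.null(p)) p <- default_params("maclean", "wrist")
  fs <- rec$fs
  s <- norm_in_g(rec)
  bp <- abs(butterworth(s, "band", c(0.25, 6), order = 4L)$values)
  b <- as.numeric(bp > param_value(p, "threshold_binary"))
  sm <- conv_same(b, rep(1 / round(0.5 * fs + 1), round(0.5 * fs) + 1L))
  active <- sm >= 0.5
  # fill short, still-somewhat-active gaps
  gap_max <- round(param_value(p, "gap_threshold") * fs)
  gi <- param_value(p, "gap_index")
  r <- rle(active)
  pos <- cumsum(c(1L, r$lengths))
  for (j in seq_along(r$values)) {
    if (!r$values[j] && j > 1L && j < length(r$values) && r$lengths[j] <= gap_max) {
      idx <- pos[j]:(pos[j + 1L] - 1L)
      if (mean(sm[idx]) >= gi) active[idx] <- TRUE
    }
  }
  r <- rle(active)
  pos <- cumsum(c(1L, r$lengths))
  keep_s <- numeric(0); keep_e <- numeric(0)
  min_len <- param_value(p, "walk_threshold") * fs
  wi <- param_value(p, "walk_index")
  for (j in seq_along(r$values)) {
    if (r$values[j] && r$lengths[j] >= min_len) {
      idx <- pos[j]:(pos[j + 1L] - 1L)
      if (mean(b[idx]) >= wi) {
        keep_s <- c(keep_s, (pos[j] - 1L) / fs)
        keep_e <- c(keep_e, (pos[j + 1L] - 1L) / fs)
      }
    }
  }
  bouts <- data.frame(start_s = keep_s, end_s = keep_e)
  new_gsd_result("maclean", "wrist", finish_bouts(bouts, length(b) / fs))
}

#' Keren gait-sequence detector (improved / adaptive)
#'
#' Multi-criterion detector on the detrended norm in overlapping 3 s windows
#' (50 percent overlap): a window passes when it shows (a) at least
#' `min_peaks` peaks above the amplitude threshold (a fixed value in the
#' improved version, the `threshold_percentile`-th percentile of the window's
#' detrended norm in the adaptive version), (b) standard deviation above
#' `threshold_sd`, (c) a dominant frequency inside the 0.5-3 Hz gait band and
#' (d) autocorrelation at the step-period lag above `regularity_floor`.
#' The central half of each passing window is marked as walking.
#'
#' @inheritParams gsd_hickey
#' @param version `"improved"` or `"adaptive"`.
#' @return a `wg_gsd_result`.
#' @export
gsd_keren <- function(rec, p = NULL, version = c("improved", "adaptive")) {
  version <- match.arg(version)
  rec <- prep_rec(rec)
  if (is.null(p)) p <- default_params("keren", version)
  fs <- rec$fs
  x <- detrend_series(norm_in_g(rec), "mean")$values
  win <- round(param_value(p, "window_s") * fs)
  if (length(x) < win) stop("recording shorter than one analysis window")
  hop <- win %/% 2L
  starts <- seq(1L, length(x) - win + 1L, by = hop)
  thr_sd <- param_value(p, "threshold_sd")
  min_pk <- param_value(p, "min_peaks")
  reg_floor <- param_value(p, "regularity_floor")
  flags <- vapply(starts, function(st) {
    w <- x[st:(st + win - 1L)]
    w <- w - mean(w)
    if (sd(w) <= thr_sd) return(FALSE)
    thr <- if (version == "adaptive") {
      as.numeric(quantile(w, param_value(p, "threshold_percentile") / 100))
    } else param_value(p, "threshold")
    pk <- find_peaks(w, min_height = thr, min_dist = round(0.25 * fs))
    if (length(pk) < min_pk) return(FALSE)
    f <- tryCatch(dominant_frequency(wg_series(w, fs), band_hz = c(0.3, 5)),
                  wg_flat_signal = function(e) NA_real_, error = function(e) NA_real_)
    if (is.na(f) || f < 0.5 || f > 3) return(FALSE)
    # regularity: autocorrelation peak near the step-period lag (the spectral
    # lag estimate is bin-quantized, so search +/- 30% around it)
    lags <- round(0.7 * fs / f):min(round(1.3 * fs / f), length(w) - 1L)
    if (length(lags) == 0L) return(FALSE)
    ac <- max(vapply(lags, function(lag)
      sum(w[1:(length(w) - lag)] * w[(lag + 1L):length(w)]) / sum(w^2), 0))
    ac > reg_floor
  }, NA)
  # mark the central half of each passing window
  bouts <- flags_to_bouts(flags, (starts - 1L) / fs + win / fs / 4, win / fs / 2)
  new_gsd_result("keren", version, finish_bouts(bouts, length(x) / fs))
}

# Step grouping shared by the step-based detectors: a run of steps breaks when
# an inter-step interval exceeds 3 s or 2.25x the running median step time,
# whichever is smaller. Returns a list of index vectors.
group_steps <- function(times) {
  if (length(times) == 0L) return(list())
  runs <- list(); cur <- 1L
  for (i in seq_along(times)[-1L]) {
    iv <- times[i] - times[i - 1L]
    med <- median(diff(times[cur:(i - 1L)]))
    lim <- if (is.na(med)) 3.0 else min(3.0, 2.25 * med)
    if (iv > lim) {
      runs[[length(runs) + 1L]] <- cur:(i - 1L)
      cur <- i
    }
  }
  runs[[length(runs) + 1L]] <- cur:length(times)
  runs
}

steps_to_bouts <- function(step_times, min_steps = 4L) {
  runs <- group_steps(step_times)
  out <- lapply(runs, function(idx) {
    if (length(idx) < min_steps) return(NULL)
    tt <- step_times[idx]
    pad <- median(diff(tt)) / 2
    c(tt[1L] - pad, tt[length(tt)] + pad)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) return(data.frame(start_s = numeric(0), end_s = numeric(0)))
  data.frame(start_s = out[, 1L], end_s = out[, 2L])
}

#' Ionescu gait-sequence detector (wrist / wrist_adaptive)
#'
#' Step-based detector: the gravity-removed, low-pass filtered norm is scanned
#' for peaks; peaks above the step threshold are steps, and runs of steps
#' whose inter-step intervals pass an adaptive step-duration rule become
#' bouts. The fixed version thresholds at `active_signal_threshold`; the
#' adaptive version sets the threshold at the `percentile`-th percentile of
#' candidate peak amplitudes, falling back to
#' `active_signal_fallback_threshold` when fewer than 10 candidate peaks
#' exist.
#'
#' @inheritParams gsd_hickey
#' @param version `"wrist"` or `"wrist_adaptive"`.
#' @return a `wg_gsd_result`.
#' @export
gsd_ionescu <- function(rec, p = NULL, version = c("wrist", "wrist_adaptive")) {
  version <- match.arg(version)
  rec <- prep_rec(rec)
  if (is.null(p)) p <- default_params("ionescu", version)
  fs <- rec$fs
  s <- norm_in_g(rec)
  hp <- s$values - butterworth(s, "low", 0.25, order = 2L)$values
  lp <- butterworth(wg_series(hp, fs, "g"), "low",
                    param_value(p, "lowpass_cutoff"), order = 4L)$values
  if (version == "wrist") {
    thr <- param_value(p, "active_signal_threshold")
  } else {
    cand <- find_peaks(lp, min_height = 0.05, min_dist = round(0.25 * fs))
    thr <- if (length(cand) >= 10L) {
      as.numeric(quantile(lp[cand], param_value(p, "percentile") / 100))
    } else param_value(p, "active_signal_fallback_threshold")
  }
  pk <- find_peaks(lp, min_height = thr, min_dist = round(0.25 * fs))
  bouts <- steps_to_bouts((pk - 1L) / fs)
  new_gsd_result("ionescu", version, finish_bouts(bouts, length(lp) / fs))
}

# Sliding normalized (Pearson) cross-correlation of x with a template.
sliding_ncc <- function(x, tmpl) {
  k <- length(tmpl)
  tc <- tmpl - mean(tmpl)
  denom_t <- sqrt(sum(tc^2))
  num <- stats::filter(x, rev(tc), sides = 2L)  # centered dot product
  m <- stats::filter(x, rep(1 / k, k), sides = 2L)
  m2 <- stats::filter(x^2, rep(1 / k, k), sides = 2L)
  sdx <- sqrt(pmax(k * (m2 - m^2), 1e-12))
  out <- as.numeric(num / (sdx * denom_t))
  out[is.na(out)] <- 0
  out
}

#' Iluz gait-sequence detector (wrist)
#'
#' Frequency-based detector: gravity is removed per axis, activity is gated on
#' the norm standard deviation (`std_threshold` over 1 s windows), the norm is
#' band-passed to the gait band and correlated with a single-period sine
#' template; local maxima of the normalized correlation above `step_threshold`
#' inside active regions are steps, grouped into bouts.
#'
#' @inheritParams gsd_hickey
#' @return a `wg_gsd_result`.
#' @export
gsd_iluz <- function(rec, p = NULL) {
  rec <- prep_rec(rec)
  if (is.null(p)) p <- default_params("iluz", "wrist")
  fs <- rec$fs
  gn <- sqrt(rowSums(remove_gravity_axes(rec)^2))
  if (rec$unit == "m_s2") gn <- gn / WG_GRAVITY
  n <- length(gn)
  win <- round(fs)
  if (n < win) stop("recording shorter than one analysis window (1 s)")
  starts <- seq(1L, n - win + 1L, by = win)
  act_win <- windowed_sd(gn, win, starts) > param_value(p, "std_threshold")
  active <- rep(FALSE, n)
  for (j in which(act_win)) active[starts[j]:(starts[j] + win - 1L)] <- TRUE
  if (!any(active)) {
    return(new_gsd_result("iluz", "wrist",
                          data.frame(start_s = numeric(0), end_s = numeric(0))))
  }
  bp <- butterworth(wg_series(gn, fs, "g"), "band", c(0.5, 3), order = 4L)$values
  tmpl <- sin(2 * pi * seq(0, 1, length.out = round(0.5 * fs)))
  ncc <- sliding_ncc(bp, tmpl)
  pk <- find_peaks(ncc, min_height = param_value(p, "step_threshold"),
                   min_dist = round(0.3 * fs))
  pk <- pk[active[pk]]
  bouts <- steps_to_bouts((pk - 1L) / fs)
  new_gsd_result("iluz", "wrist", finish_bouts(bouts, n / fs))
}

#' Run a gait-sequence detector by name
#'
#' @param rec a [wg_recording()].
#' @param method one of `"hickey"`, `"kheirkhahan"`, `"maclean"`, `"keren"`,
#'   `"ionescu"`, `"iluz"`.
#' @param version version identifier (see [list_methods()]).
#' @param params optional named list of parameter overrides.
#' @return a `wg_gsd_result`.
#' @export
detect_gait_sequences <- function(rec, method, version = NULL, params = NULL) {
  reg <- list_methods("gsd")
  if (!method %in% reg$method) {
    stop(sprintf("unknown GSD method '%s'; available: %s",
                 method, paste(unique(reg$method), collapse = ", ")))
  }
  if (is.null(version)) version <- reg$version[reg$method == method][1L]
  p <- override_params(default_params(method, version), params)
  switch(method,
    hickey = gsd_hickey(rec, p),
    kheirkhahan = gsd_kheirkhahan(rec, p),
    maclean = gsd_maclean(rec, p),
    keren = gsd_keren(rec, p, version),
    ionescu = gsd_ionescu(rec, p, version),
    iluz = gsd_iluz(rec, p)
  )
}
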