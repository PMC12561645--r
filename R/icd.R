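# Initial-contact (heel-strike) detection: nine wrist-adapted detectors, each
# mapping a bout-restricted acceleration-norm series to IC timestamps on the
# recording clock.

#' Crop the acceleration norm to one walking bout
#'
#' @param rec a [wg_recording()].
#' @param start_s,end_s bout boundaries in seconds (half-open).
#' @return a `wg_bout_signal`: list with `series` (norm in g), `start_s`,
#'   `end_s`, `fs`.
#' @export
bout_signal <- function(rec, start_s, end_s) {
  stopifnot(end_s > start_s)
  s <- norm_in_g(rec)
  n <- length(s$values)
  i0 <- max(1L, floor(start_s * s$fs) + 1L)
  i1 <- min(n, ceiling(end_s * s$fs))
  if (i1 <= i0) stop("bout lies outside the recording")
  structure(list(series = wg_series(s$values[i0:i1], s$fs, "g"),
                 start_s = (i0 - 1L) / s$fs, end_s = i1 / s$fs, fs = s$fs),
            class = "wg_bout_signal")
}

check_bout_len <- function(bs, min_s = 2) {
  if (length(bs$series$values) < min_s * bs$fs) {
    stop(sprintf("bout too short for IC detection: need >= %g s", min_s))
  }
}

# indices (at rate fs_local) -> recording-clock times, clipped to the bout
idx_to_times <- function(idx, fs_local, bs) {
  t <- bs$start_s + (idx - 1L) / fs_local
  t <- t[t >= bs$start_s & t < bs$end_s]
  sort(unique(t))
}

ic_df <- function(times) data.frame(time_s = times)

#' Ducharme initial-contact detector (wrist)
#'
#' Mean-detrend, resample to 80 Hz, fourth-order 0.25-2.5 Hz Butterworth
#' band-pass, then peaks above `threshold`; peak indices are rescaled back to
#' the original sampling rate.
#'
#' @param bs a [bout_signal()].
#' @param p parameters from [default_params()] (registry defaults when NULL).
#' @return data.frame with column `time_s`, sorted.
#' @export
icd_ducharme <- function(bs, p = NULL) {
  check_bout_len(bs)
  if (is.null(p)) p <- default_params("ducharme", "wrist")
  s <- detrend_series(bs$series, "mean")
  s <- resample_series(s, 80)
  s <- butterworth(s, "band", c(0.25, 2.5), order = 4L)
  pk <- find_peaks(s$values, min_height = param_value(p, "threshold"),
                   min_dist = round(0.25 * 80))
  ic_df(idx_to_times(pk, 80, bs))
}

# running min / max over a centered window of k samples (edge-replicated)
running_extreme <- function(x, k, fun) {
  n <- length(x); half <- k %/% 2L
  vapply(seq_len(n), function(i)
    fun(x[max(1L, i - half):min(n, i + half)]), 0)
}

#' Gu initial-contact detector (improved / adaptive)
#'
#' Local maxima of the norm filtered through a cascade: magnitude (absolute
#' `mag_thres` in the improved version; the `mag_thres`-th percentile of the
#' segment norm in the adaptive version), periodicity (inter-peak interval in
#' `[period_min, period_max]` samples), shape similarity of peak neighbourhoods
#' at least `sim_thres`, local variance at least `var_thres`, and a continuity
#' run-length of at least `k` consecutive surviving peaks.
#'
#' @inheritParams icd_ducharme
#' @param version `"improved"` or `"adaptive"`.
#' @return data.frame with column `time_s`.
#' @export
icd_gu <- function(bs, p = NULL, version = c("improved", "adaptive")) {
  version <- match.arg(version)
  check_bout_len(bs)
  if (is.null(p)) p <- default_params("gu", version)
  fs <- bs$fs
  x <- bs$series$values
  pmin_s <- as.integer(param_value(p, "period_min"))
  pmax_s <- as.integer(param_value(p, "period_max"))
  pk <- find_peaks(x, min_dist = pmin_s)
  if (length(pk) == 0L) return(ic_df(numeric(0)))
  # magnitude
  mag_ok <- if (version == "adaptive") {
    x[pk] > as.numeric(quantile(x, param_value(p, "mag_thres") / 100))
  } else x[pk] > param_value(p, "mag_thres")
  pk <- pk[mag_ok]
  if (length(pk) == 0L) return(ic_df(numeric(0)))
  # periodicity: distance to previous or next surviving peak inside the window
  if (length(pk) > 1L) {
    d <- diff(pk)
    ok_prev <- c(FALSE, d >= pmin_s & d <= pmax_s)
    ok_next <- c(d >= pmin_s & d <= pmax_s, FALSE)
    pk <- pk[ok_prev | ok_next]
  }
  if (length(pk) == 0L) return(ic_df(numeric(0)))
  # shape similarity against the mean peak neighbourhood
  half <- round(0.2 * fs)
  segs <- lapply(pk, function(i) {
    lo <- max(1L, i - half); hi <- min(length(x), i + half)
    v <- x[lo:hi]
    if (length(v) < 2L * half + 1L) v <- c(v, rep(v[length(v)], 2L * half + 1L - length(v)))
    v
  })
  m <- Reduce(`+`, segs) / length(segs)
  sim <- vapply(segs, function(v) {
    if (sd(v) < 1e-12 || sd(m) < 1e-12) return(1)
    suppressWarnings(stats::cor(v, m))
  }, 0)
  sim[is.na(sim)] <- 1
  pk <- pk[sim >= param_value(p, "sim_thres")]
  if (length(pk) == 0L) return(ic_df(numeric(0)))
  # local variance
  vt <- param_value(p, "var_thres",
                    as_unit = if (p$params$var_thres$unit == "m_s2_2") "g2" else NULL)
  vwin <- round(0.25 * fs)
  lv <- vapply(pk, function(i) {
    lo <- max(1L, i - vwin); hi <- min(length(x), i + vwin)
    var(x[lo:hi])
  }, 0)
  pk <- pk[lv >= vt]
  if (length(pk) == 0L) return(ic_df(numeric(0)))
  # continuity: runs of at least k peaks with plausible spacing
  kmin <- as.integer(param_value(p, "k"))
  if (length(pk) > 1L) {
    grp <- cumsum(c(1L, as.integer(diff(pk) > pmax_s)))
    keep <- as.vector(unlist(lapply(split(seq_along(pk), grp), function(idx)
      if (length(idx) >= kmin) idx else integer(0))))
    pk <- pk[keep]
  } else if (kmin > 1L) pk <- integer(0)
  ic_df(idx_to_times(pk, fs, bs))
}

#' Shin initial-contact detector (original)
#'
#' A sliding-window sum reduces noise; a lagged difference acts as a high-pass
#' filter removing gravity; initial contacts are the zero crossings of the
#' differenced signal on the positive slope.
#'
#' @inheritParams icd_ducharme
#' @return data.frame with column `time_s`.
#' @export
icd_shin <- function(bs, p = NULL) {
  check_bout_len(bs)
  if (is.null(p)) p <- default_params("shin", "original")
  fs <- bs$fs
  k <- max(2L, round(param_value(p, "window_s") * fs))
  sm <- conv_same(bs$series$values, rep(1, k))
  lag <- max(1L, round(param_value(p, "lag_s") * fs))
  n <- length(sm)
  d <- c(rep(0, lag), sm[(lag + 1L):n] - sm[1:(n - lag)])
  # three-state sign with a round-off guard band: a crossing is a clearly
  # negative sample followed (possibly across near-zero samples) by a clearly
  # positive one, localised at the midpoint
  eps <- 1e-8 * max(1, max(abs(sm)))
  sgn <- ifelse(d >= eps, 1L, ifelse(d <= -eps, -1L, 0L))
  nz <- which(sgn != 0L)
  up <- integer(0)
  if (length(nz) > 1L) {
    tr <- which(sgn[nz][-length(nz)] == -1L & sgn[nz][-1L] == 1L)
    up <- as.integer(round((nz[tr] + nz[tr + 1L]) / 2))
  }
  ic_df(idx_to_times(up, fs, bs))
}

#' Lee (HKLee) initial-contact detector (original)
#'
#' Low-pass filtering, detrending, Savitzky-Golay and Gaussian smoothing, a
#' continuous wavelet transform to enhance step features, morphological
#' open/close filtering, then maxima between zero-crossings (plateau ties
#' resolve to the earliest sample).
#'
#' @inheritParams icd_ducharme
#' @return data.frame with column `time_s`.
#' @export
icd_hklee <- function(bs, p = NULL) {
  check_bout_len(bs)
  if (is.null(p)) p <- default_params("hklee", "original")
  fs <- bs$fs
  s <- butterworth(bs$series, "low", 10, order = 4L)
  s <- detrend_series(s, "mean")
  v <- signal::sgolayfilt(s$values,
                          p = as.integer(param_value(p, "sgolay_order")),
                          n = as.integer(param_value(p, "sgolay_window")))
  s <- gaussian_smooth(wg_series(v, fs, "g"),
                       window = as.integer(param_value(p, "gauss_window")),
                       sigma = param_value(p, "gauss_sigma"))
  s <- cwt_smooth(s, "adaptive")
  x <- s$values
  # morphological smoothing: opening then closing with a short flat element
  se <- max(3L, round(0.05 * fs))
  x <- running_extreme(running_extreme(x, se, min), se, max)  # open
  x <- running_extreme(running_extreme(x, se, max), se, min)  # close
  # maxima between zero crossings
  sgn <- sign(x)
  zc <- which(sgn[-1L] != sgn[-length(sgn)])
  bounds <- unique(c(1L, zc, length(x)))
  pk <- integer(0)
  for (j in seq_len(length(bounds) - 1L)) {
    idx <- (bounds[j] + 1L):bounds[j + 1L]
    if (length(idx) >= 3L && max(x[idx]) > 0) {
      pk <- c(pk, idx[which.max(x[idx])])
    }
  }
  pk <- find_peaks_keep(pk, x, min_dist = round(0.25 * fs))
  ic_df(idx_to_times(sort(pk), fs, bs))
}

# keep a set of candidate indices subject to a minimum spacing, preferring
# larger values of x (deterministic)
find_peaks_keep <- function(idx, x, min_dist) {
  if (length(idx) <= 1L) return(idx)
  ord <- idx[order(-x[idx], idx)]
  taken <- integer(0)
  for (i in ord) if (all(abs(taken - i) >= min_dist)) taken <- c(taken, i)
  sort(taken)
}

#' Zijlstra initial-contact detector (wrist)
#'
#' Detrending and low-pass Butterworth filtering at `cutoff` Hz, then initial
#' contacts as peak maxima (wrist default) or positive-to-negative zero
#' crossings.
#'
#' @inheritParams icd_ducharme
#' @param mode `"peak"` or `"zero"`; defaults to the registered
#'   `peak_detection_method`.
#' @return data.frame with column `time_s`.
#' @export
icd_zijlstra <- function(bs, p = NULL, mode = NULL) {
  check_bout_len(bs)
  if (is.null(p)) p <- default_params("zijlstra", "wrist")
  if (is.null(mode)) mode <- param_value(p, "peak_detection_method")
  fs <- bs$fs
  s <- detrend_series(bs$series, "mean")
  s <- butterworth(s, "low", param_value(p, "cutoff"), order = 4L)
  x <- s$values
  if (mode == "peak") {
    pk <- find_peaks(x, min_height = 0, min_dist = round(0.25 * fs))
  } else {
    sgn <- x > 0
    pk <- which(sgn[-length(sgn)] & !sgn[-1L]) + 1L
    if (length(pk) > 1L) pk <- pk[c(TRUE, diff(pk) >= round(0.25 * fs))]
  }
  ic_df(idx_to_times(pk, fs, bs))
}

# Dynamic time warping distance with a Sakoe-Chiba band; small inputs only.
dtw_distance <- function(a, b, band_frac = 0.15) {
  n <- length(a); m <- length(b)
  band <- max(1L, round(band_frac * max(n, m)))
  D <- matrix(Inf, n + 1L, m + 1L)
  D[1L, 1L] <- 0
  for (i in seq_len(n)) {
    jlo <- max(1L, i - band); jhi <- min(m, i + band)
    for (j in jlo:jhi) {
      cost <- abs(a[i] - b[j])
      D[i + 1L, j + 1L] <- cost + min(D[i, j + 1L], D[i + 1L, j], D[i, j])
    }
  }
  D[n + 1L, m + 1L] / (n + m)
}

#' Mico-Amigo initial-contact detector (wrist)
#'
#' Estimates the step period from the gravity-removed norm (autocovariance
#' peak cross-checked against the spectral dominant frequency), builds a
#' subject-specific template by averaging step-period segments around
#' prominent acceleration peaks (spaced at least `peakdistance` seconds), and
#' scans the normalized-correlation similarity signal for peaks spaced at
#' least `peakdistance_coef` step periods. Candidates whose dynamic-time-
#' warping distance to the template (warping band `shiftfactor`) exceeds
#' `factorlimit` times the median candidate distance are rejected, and a fixed
#' `event_offset`-sample correction is applied.
#'
#' @inheritParams icd_ducharme
#' @return data.frame with column `time_s`; attribute `template_len_s` carries
#'   the estimated template length.
#' @export
icd_micoamigo <- function(bs, p = NULL) {
  check_bout_len(bs)
  if (is.null(p)) p <- default_params("micoamigo", "wrist")
  fs <- bs$fs
  x <- bs$series$values - butterworth(bs$series, "low", 0.25, order = 2L)$values
  s <- wg_series(x, fs, "g")
  # step period: spectral estimate refined by the autocovariance peak
  f <- tryCatch(dominant_frequency(s, c(0.5, 3)),
                wg_flat_signal = function(e) NA_real_, error = function(e) NA_real_)
  if (is.na(f)) return(ic_df(numeric(0)))
  lag0 <- round(fs / f)
  lags <- max(2L, round(0.7 * lag0)):min(length(x) - 1L, round(1.3 * lag0))
  acv <- vapply(lags, function(L)
    sum(x[1:(length(x) - L)] * x[(L + 1L):length(x)]), 0)
  T_samp <- lags[which.max(acv)]
  tmpl_len <- T_samp
  lp <- butterworth(s, "low", 3, order = 4L)$values
  anchors <- find_peaks(lp, min_height = 0,
                        min_dist = round(param_value(p, "peakdistance") * fs))
  half <- tmpl_len %/% 2L
  anchors <- anchors[anchors > half & anchors <= length(x) - half]
  if (length(anchors) < 2L) return(ic_df(numeric(0)))
  segs <- vapply(anchors, function(i) x[(i - half):(i + half)], numeric(2L * half + 1L))
  tmpl <- rowMeans(segs)
  ncc <- sliding_ncc(x, tmpl)
  min_sp <- max(2L, round(param_value(p, "peakdistance_coef") * T_samp * 0.8))
  cand <- find_peaks(ncc, min_height = 0.3, min_dist = min_sp)
  cand <- cand[cand > half & cand <= length(x) - half]
  if (length(cand) == 0L) return(ic_df(numeric(0)))
  dists <- vapply(cand, function(i)
    dtw_distance(x[(i - half):(i + half)], tmpl,
                 band_frac = param_value(p, "shiftfactor")), 0)
  keep <- dists <= param_value(p, "factorlimit") * median(dists)
  ev <- cand[keep] - as.integer(param_value(p, "event_offset"))
  out <- ic_df(idx_to_times(ev, fs, bs))
  attr(out, "template_len_s") <- tmpl_len / fs
  out
}

prune_mccamley <- function(times, min_gap = 0.25, max_isolation = 2.25, depth = NULL) {
  if (length(times) == 0L) return(times)
  # events closer than min_gap: keep the deeper (or earlier) one
  keep <- rep(TRUE, length(times))
  for (i in seq_along(times)[-1L]) {
    prev <- max(which(keep[seq_len(i - 1L)]))
    if (times[i] - times[prev] < min_gap) {
      if (!is.null(depth) && depth[i] > depth[prev]) keep[prev] <- FALSE else keep[i] <- FALSE
    }
  }
  times <- times[keep]
  if (length(times) <= 1L) return(times)
  gap_prev <- c(Inf, diff(times))
  gap_next <- c(diff(times), Inf)
  iso <- pmin(gap_prev, gap_next) > max_isolation
  times[!iso]
}

#' McCamley initial-contact detector (wrist)
#'
#' Downsampling to 50 Hz, detrending, 20 Hz low-pass, cumulative trapezoidal
#' integration, adaptive-scale continuous wavelet transform, upsampling back
#' to the original rate; initial contacts are local minima. Detected events
#' closer than 0.25 s to a neighbour or further than 2.25 s from both
#' neighbours are pruned.
#'
#' @inheritParams icd_ducharme
#' @return data.frame with column `time_s`.
#' @export
icd_mccamley <- function(bs, p = NULL) {
  check_bout_len(bs)
  if (is.null(p)) p <- default_params("mccamley", "wrist")
  fs <- bs$fs
  s <- resample_series(bs$series, 50)
  s <- detrend_series(s, "mean")
  s <- butterworth(s, "low", 20, order = 4L)
  iv <- pracma::cumtrapz(seq_along(s$values) / 50, s$values)[, 1L]
  s <- wg_series(iv - mean(iv), 50, "g_s")
  mode <- if (identical(param_value(p, "cwt_method"), "adaptive")) "adaptive" else "fixed"
  s <- cwt_smooth(s, mode)
  s <- resample_series(s, fs)
  x <- s$values
  mn <- local_maxima(-x)
  times <- (mn - 1L) / fs
  pruned <- prune_mccamley(times, depth = -x[mn])
  ic_df(idx_to_times(round(pruned * fs) + 1L, fs, bs))
}

#' Pham initial-contact detector (wrist)
#'
#' Upsampling to 128 Hz, detrending, 10 Hz low-pass, cumulative trapezoidal
#' integration, adaptive-scale continuous wavelet transform, re-detrending;
#' local minima are retained when their magnitude exceeds `percentage_thresh`
#' times the mean minimum magnitude, and event times map back to the original
#' rate.
#'
#' @inheritParams icd_ducharme
#' @return data.frame with column `time_s`.
#' @export
icd_pham <- function(bs, p = NULL) {
  check_bout_len(bs)
  if (is.null(p)) p <- default_params("pham", "wrist")
  fs <- bs$fs
  s <- resample_series(bs$series, 128)
  s <- detrend_series(s, "mean")
  s <- butterworth(s, "low", 10, order = 4L)
  iv <- pracma::cumtrapz(seq_along(s$values) / 128, s$values)[, 1L]
  s <- wg_series(iv - mean(iv), 128, "g_s")
  mode <- if (identical(param_value(p, "cwt_method"), "adaptive")) "adaptive" else "fixed"
  s <- cwt_smooth(s, mode)
  s <- detrend_series(s, "linear")
  x <- s$values
  mn <- local_maxima(-x)
  mn <- mn[x[mn] < 0]
  if (length(mn) > 0L) {
    depth <- -x[mn]
    mn <- mn[depth >= param_value(p, "percentage_thresh") * mean(depth)]
    mn <- find_peaks_keep(mn, -x, min_dist = round(0.25 * 128))
  }
  ic_df(idx_to_times(round((mn - 1L) / 128 * fs) + 1L, fs, bs))
}

#' Run an initial-contact detector over reference bouts
#'
#' Applies one ICD method to each walking bout of a recording (the bouts are
#' supplied externally, typically from the reference system or a GSD result).
#'
#' @param rec a [wg_recording()].
#' @param bouts data.frame with `start_s`, `end_s` (and optionally `bout_id`).
#' @param method one of `"ducharme"`, `"gu"`, `"shin"`, `"hklee"`,
#'   `"zijlstra"`, `"micoamigo"`, `"mccamley"`, `"pham"`.
#' @param version version identifier (see [list_methods()]).
#' @param params optional named list of parameter overrides.
#' @return data.frame with columns `bout_id`, `time_s`, `method`, `version`.
#' @export
detect_initial_contacts <- function(rec, bouts, method, version = NULL,
                                    params = NULL) {
  reg <- list_methods("icd")
  if (!method %in% reg$method) {
    stop(sprintf("unknown ICD method '%s'; available: %s",
                 method, paste(unique(reg$method), collapse = ", ")))
  }
  if (is.null(version)) version <- reg$version[reg$method == method][1L]
  p <- override_params(default_params(method, version), params)
  if (is.null(bouts$bout_id)) bouts$bout_id <- seq_len(nrow(bouts))
  out <- lapply(seq_len(nrow(bouts)), function(i) {
    bsg <- bout_signal(rec, bouts$start_s[i], bouts$end_s[i])
    ev <- run_icd(bsg, method, version, p)
    if (nrow(ev) == 0L) return(NULL)
    data.frame(bout_id = bouts$bout_id[i], time_s = ev$time_s,
               method = method, version = version, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) out <- data.frame(bout_id = integer(0), time_s = numeric(0),
                                      method = character(0), version = character(0))
  out
}

run_icd <- function(bs, method, version, p) {
  switch(method,
    ducharme = icd_ducharme(bs, p),
    gu = icd_gu(bs, p, version),
    shin = icd_shin(bs, p),
    hklee = icd_hklee(bs, p),
    zijlstra = icd_zijlstra(bs, p),
    micoamigo = icd_micoamigo(bs, p),
    mccamley = icd_mccamley(bs, p),
    pham = icd_pham(bs, p)
  )
}
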