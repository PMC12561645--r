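# Preprocessing primitives shared by all detectors: filtering, resampling,
# smoothing, single-scale CWT, spectral and RMS utilities.

# Centered convolution with reflection padding; returns a vector the same
# length as x. Used by the CWT and Gaussian smoothing stages.
conv_same <- function(x, kernel) {
  n <- length(x)
  k <- length(kernel)
  half <- k %/% 2L
  pad <- pmin(half, n - 1L)
  xp <- c(rev(x[seq_len(pad) + 1L]), x, rev(x[n - seq_len(pad)]))
  out <- stats::convolve(xp, rev(kernel), type = "open")
  # centre of the full convolution, aligned to the original samples
  start <- pad + half + 1L
  out[start:(start + n - 1L)]
}

# Odd-reflection padding, the standard edge treatment for zero-phase IIR
# filtering: keeps the signal continuous in value at the boundary.
pad_reflect_odd <- function(x, pad) {
  n <- length(x)
  pad <- min(pad, n - 1L)
  if (pad <= 0L) return(list(x = x, pad = 0L))
  left <- 2 * x[1L] - x[pad + 1L - seq_len(pad) + 1L]
  right <- 2 * x[n] - x[n - seq_len(pad)]
  list(x = c(left, x, right), pad = pad)
}

#' Butterworth filter a series
#'
#' Low-, high- or band-pass Butterworth filtering. In zero-phase mode the
#' filter is applied forward and backward (no group delay), with
#' odd-reflection edge padding and mean removal to suppress startup
#' transients; event timing downstream is therefore unbiased by filter phase.
#'
#' @param s a [wg_series()].
#' @param kind `"low"`, `"high"` or `"band"`.
#' @param cutoff_hz scalar cutoff (low/high) or length-2 band edges in Hz.
#' @param order filter order (>= 1).
#' @param zero_phase apply forward-backward filtering (default TRUE).
#' @return the filtered [wg_series()].
#' @export
butterworth <- function(s, kind = c("low", "high", "band"), cutoff_hz,
                        order = 4L, zero_phase = TRUE) {
  kind <- match.arg(kind)
  nyq <- s$fs / 2
  if (any(cutoff_hz <= 0) || any(cutoff_hz >= nyq)) {
    stop(sprintf("cutoff must lie strictly inside (0, %g) Hz (Nyquist)", nyq))
  }
  if (order < 1L) stop("order must be >= 1")
  if (kind == "band" && length(cutoff_hz) != 2L) stop("band kind needs two cutoffs")
  x <- s$values
  n <- length(x)
  ncoef <- order * (if (kind == "band") 2L else 1L) + 1L
  minlen <- 3L * ncoef
  if (n < minlen) {
    stop(sprintf("series too short for filter warm-up: need at least %d samples, got %d",
                 minlen, n))
  }
  bt <- signal::butter(order, sort(cutoff_hz) / nyq,
                       type = if (kind == "band") "pass" else kind)
  mu <- mean(x)
  xc <- x - mu
  if (zero_phase) {
    # pad generously relative to the slowest cutoff so decaying transients
    # never reach the retained samples
    pad <- min(n - 1L, max(minlen, ceiling(3 * s$fs / min(cutoff_hz))))
    pr <- pad_reflect_odd(xc, pad)
    y <- signal::filter(bt, pr$x)
    y <- rev(signal::filter(bt, rev(y)))
    y <- y[(pr$pad + 1L):(pr$pad + n)]
  } else {
    y <- as.numeric(signal::filter(bt, xc))
  }
  if (kind == "low") y <- y + mu
  wg_series(as.numeric(y), fs = s$fs, unit = s$unit)
}

#' Resample a series to a new rate
#'
#' Zero-phase resampling: downsampling applies a zero-phase Butterworth
#' anti-alias filter at 0.45 of the target rate before cubic-spline
#' interpolation onto the new time grid; upsampling interpolates directly.
#' The output length is `round(N * fs_out / fs)` and event timing carries no
#' group delay (sample i of the output sits at the same clock time as the
#' original signal).
#'
#' @param s a [wg_series()].
#' @param fs_out target sampling frequency in Hz.
#' @return the resampled [wg_series()] at `fs_out`.
#' @export
resample_series <- function(s, fs_out) {
  if (fs_out <= 0) stop("fs_out must be positive")
  n <- length(s$values)
  if (s$fs == fs_out) return(s)
  n_out <- round(n * fs_out / s$fs)
  if (n_out < 1L) stop("resampled series would be empty")
  x <- s$values
  if (fs_out < s$fs && n >= 30L) {
    x <- butterworth(s, "low", 0.45 * fs_out, order = 8L)$values
  }
  t_in <- (seq_len(n) - 1L) / s$fs
  t_out <- (seq_len(n_out) - 1L) / fs_out
  y <- if (n >= 4L) stats::spline(t_in, x, xout = t_out, method = "fmm")$y
       else approx(t_in, x, xout = t_out, rule = 2)$y
  wg_series(y, fs = fs_out, unit = s$unit)
}

#' Detrend a series
#'
#' @param s a [wg_series()].
#' @param mode `"mean"` subtracts the mean; `"linear"` removes the
#'   least-squares line.
#' @return the detrended [wg_series()].
#' @export
detrend_series <- function(s, mode = c("mean", "linear")) {
  mode <- match.arg(mode)
  x <- s$values
  if (mode == "mean") {
    y <- x - mean(x)
  } else {
    if (length(x) < 2L) stop("linear detrending needs at least 2 samples")
    t <- seq_along(x)
    y <- as.numeric(residuals(lm(x ~ t)))
  }
  wg_series(y, fs = s$fs, unit = s$unit)
}

#' Centered moving-average smoothing
#'
#' @param s a [wg_series()].
#' @param window_s window length in seconds (converted to an odd sample count).
#' @return the smoothed [wg_series()].
#' @export
moving_average <- function(s, window_s) {
  k <- max(1L, round(window_s * s$fs))
  if (k %% 2L == 0L) k <- k + 1L
  conv_same_series(s, rep(1 / k, k))
}

#' Gaussian smoothing
#'
#' @param s a [wg_series()].
#' @param window samples in the kernel (default 10).
#' @param sigma kernel standard deviation in samples (default 2).
#' @return the smoothed [wg_series()].
#' @export
gaussian_smooth <- function(s, window = 10L, sigma = 2) {
  t <- seq_len(window) - (window + 1) / 2
  w <- exp(-t^2 / (2 * sigma^2))
  conv_same_series(s, w / sum(w))
}

conv_same_series <- function(s, kernel) {
  wg_series(conv_same(s$values, kernel), fs = s$fs, unit = s$unit)
}

# Mexican-hat (second derivative of Gaussian) mother wavelet sampled at fs
# for a scale sigma given in seconds.
mexhat_kernel <- function(sigma_s, fs) {
  half <- max(4L, ceiling(4 * sigma_s * fs))
  t <- (-half:half) / fs
  u <- t / sigma_s
  (1 - u^2) * exp(-u^2 / 2)
}

# Scale (seconds) whose Mexican-hat spectral peak sits at frequency f:
# |Psi(w)| ~ w^2 exp(-sigma^2 w^2 / 2) peaks at w = sqrt(2)/sigma.
mexhat_scale_for_freq <- function(f_hz) sqrt(2) / (2 * pi * f_hz)

#' Single-scale continuous wavelet transform smoothing
#'
#' Convolution of the series with a Mexican-hat wavelet at one scale. In
#' adaptive mode the scale is set so the wavelet's spectral peak matches the
#' signal's dominant frequency in the 0.5-3 Hz gait band, following the
#' lineage of wavelet-based initial-contact detectors. On a flat signal the
#' dominant frequency is undefined; the transform then falls back to the
#' fixed default scale with a warning.
#'
#' @param s a [wg_series()].
#' @param mode `"adaptive"` or `"fixed"`.
#' @param scale_s wavelet scale in seconds for fixed mode; the default
#'   corresponds to a 1.5 Hz center frequency.
#' @return the transformed [wg_series()] (same length).
#' @export
cwt_smooth <- function(s, mode = c("adaptive", "fixed"),
                       scale_s = mexhat_scale_for_freq(1.5)) {
  mode <- match.arg(mode)
  if (length(s$values) < 16L) stop("cwt_smooth needs at least 16 samples")
  sigma <- scale_s
  if (mode == "adaptive") {
    f <- tryCatch(dominant_frequency(s, band_hz = c(0.5, 3)),
                  wg_flat_signal = function(e) NA_real_)
    if (is.na(f)) {
      warning("dominant frequency undefined (flat signal); using fixed default scale")
    } else {
      sigma <- mexhat_scale_for_freq(f)
    }
  }
  kern <- mexhat_kernel(sigma, s$fs)
  wg_series(conv_same(s$values, kern) / s$fs, fs = s$fs, unit = s$unit)
}

#' Dominant frequency via Welch periodogram
#'
#' Welch-averaged periodogram (Hann window, segment length `min(N, 512)`,
#' 50 percent overlap, per-segment mean removal); returns the frequency of the
#' spectral maximum inside `band_hz`. An all-constant series has no defined
#' dominant frequency and raises a condition of class `wg_flat_signal`.
#'
#' @param s a [wg_series()] with at least 64 samples.
#' @param band_hz length-2 search band in Hz, inside (0, fs/2).
#' @return dominant frequency in Hz.
#' @export
dominant_frequency <- function(s, band_hz = c(0.5, 3)) {
  x <- s$values
  n <- length(x)
  if (n < 64L) stop("dominant_frequency needs at least 64 samples")
  if (band_hz[1L] <= 0 || band_hz[2L] >= s$fs / 2 || band_hz[1L] >= band_hz[2L]) {
    stop("band must lie inside (0, fs/2)")
  }
  if (sd(x) < 1e-12) {
    stop(structure(class = c("wg_flat_signal", "error", "condition"),
                   list(message = "dominant frequency undefined on a constant series",
                        call = sys.call())))
  }
  seg <- min(n, 512L)
  hop <- max(1L, seg %/% 2L)
  win <- 0.5 - 0.5 * cos(2 * pi * seq_len(seg) / (seg + 1))  # Hann
  starts <- seq(1L, n - seg + 1L, by = hop)
  psd <- rep(0, seg)
  for (st in starts) {
    xs <- x[st:(st + seg - 1L)]
    xs <- (xs - mean(xs)) * win
    psd <- psd + Mod(fft(xs))^2
  }
  freqs <- (seq_len(seg) - 1L) * s$fs / seg
  keep <- freqs >= band_hz[1L] & freqs <= band_hz[2L]
  if (!any(keep)) stop("band contains no frequency bin; series too short for this band")
  freqs[keep][which.max(psd[keep])]
}

#' Root mean square over a half-open index range
#'
#' RMS of `values[i0:(i1-1)]` for 1-based `i0 < i1 <= N + 1`; this is the RMS
#' feature the adaptive stride-length models compute between two consecutive
#' initial contacts.
#'
#' @param s a [wg_series()].
#' @param i0 start index (1-based, inclusive).
#' @param i1 end index (exclusive).
#' @return scalar RMS.
#' @export
segment_rms <- function(s, i0, i1) {
  n <- length(s$values)
  if (!(i0 >= 1L && i0 < i1 && i1 <= n + 1L)) {
    stop("need 1 <= i0 < i1 <= N + 1 (half-open range, non-empty)")
  }
  v <- s$values[i0:(i1 - 1L)]
  sqrt(mean(v^2))
}

# Local maxima (strictly greater than the previous sample, >= the next, so
# plateau ties resolve to the earliest sample). Returns indices.
local_maxima <- function(x) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  idx <- which(x[2:(n - 1L)] > x[1:(n - 2L)] & x[2:(n - 1L)] >= x[3:n]) + 1L
  # collapse runs created by plateaus: keep the first index of each run
  if (length(idx) > 1L) {
    keep <- c(TRUE, diff(idx) > 1L | x[idx[-1L]] != x[idx[-length(idx)]])
    idx <- idx[keep]
  }
  idx
}

# Peak picking with a minimum height and minimum spacing (samples). Peaks are
# admitted in decreasing height order; later peaks within min_dist of an
# admitted one are suppressed. Deterministic (ties broken by earlier index).
find_peaks <- function(x, min_height = -Inf, min_dist = 1L) {
  cand <- local_maxima(x)
  cand <- cand[x[cand] >= min_height]
  if (length(cand) <= 1L || min_dist <= 1L) return(sort(cand))
  ord <- cand[order(-x[cand], cand)]
  taken <- integer(0)
  for (i in ord) {
    if (all(abs(taken - i) >= min_dist)) taken <- c(taken, i)
  }
  sort(taken)
}
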