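#' @importFrom stats approx coef fft lm median na.omit nls quantile residuals
#'   rnorm runif sd setNames var predict
#' @importFrom utils head read.csv tail write.csv
NULL

# Standard gravity used for all g <-> m/s^2 conversions.
WG_GRAVITY <- 9.81

#' Triaxial accelerometer recording
#'
#' Container for a fixed-rate triaxial wrist acceleration recording. Gyroscope
#' samples may be carried along for provenance but are never consumed by any
#' detector in this package (all algorithms are accelerometer-only).
#'
#' @param acc numeric N x 3 matrix of acceleration samples (columns x, y, z).
#' @param fs sampling frequency in Hz.
#' @param unit acceleration unit, `"g"` or `"m_s2"`.
#' @param t0 recording start time in seconds (default 0).
#' @param gyro optional N x 3 matrix of gyroscope samples (carried, unused).
#' @param participant_meta optional named list of participant metadata; the
#'   stride-length foot-length variants read `foot_length_cm` from here.
#'
#' @return an object of class `wg_recording`.
#' @export
wg_recording <- function(acc, fs, unit = c("g", "m_s2"), t0 = 0,
                         gyro = NULL, participant_meta = NULL) {
  unit <- match.arg(unit)
  acc <- as.matrix(acc)
  if (ncol(acc) != 3L) stop("acc must have exactly 3 columns (x, y, z)")
  if (nrow(acc) < 1L) stop("recording must contain at least one sample")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) stop("fs must be a positive scalar")
  bad <- which(!is.finite(acc))
  if (length(bad) > 0L) {
    stop(sprintf("non-finite acceleration sample at matrix index %d", bad[1L]))
  }
  if (!is.null(gyro)) {
    gyro <- as.matrix(gyro)
    if (nrow(gyro) != nrow(acc)) stop("gyro and acc must have equal length")
  }
  structure(
    list(t0 = t0, fs = fs, acc = acc, unit = unit, gyro = gyro,
         participant_meta = participant_meta),
    class = "wg_recording"
  )
}

#' @export
print.wg_recording <- function(x, ...) {
  cat(sprintf("<wg_recording> %d samples @ %g Hz (%.1f s), unit = %s%s\n",
              nrow(x$acc), x$fs, nrow(x$acc) / x$fs, x$unit,
              if (is.null(x$gyro)) "" else ", gyro carried"))
  invisible(x)
}

#' Duration of a recording in seconds
#' @param rec a [wg_recording()].
#' @return duration in seconds.
#' @export
rec_duration <- function(rec) nrow(rec$acc) / rec$fs

#' One-dimensional signal series
#'
#' A fixed-rate scalar series with a unit tag; the acceleration-norm signal all
#' wrist-adapted detectors operate on is represented this way.
#'
#' @param values numeric vector, all finite.
#' @param fs sampling frequency in Hz.
#' @param unit unit tag (e.g. `"g"`, `"m_s2"`, or any label for derived signals).
#' @return an object of class `wg_series`.
#' @export
wg_series <- function(values, fs, unit = "g") {
  values <- as.numeric(values)
  if (length(values) < 1L) stop("series must contain at least one sample")
  if (!all(is.finite(values))) {
    stop(sprintf("non-finite sample at index %d", which(!is.finite(values))[1L]))
  }
  if (!is.numeric(fs) || fs <= 0) stop("fs must be positive")
  structure(list(fs = fs, values = values, unit = unit), class = "wg_series")
}

#' @export
print.wg_series <- function(x, ...) {
  cat(sprintf("<wg_series> %d samples @ %g Hz, unit = %s\n",
              length(x$values), x$fs, x$unit))
  invisible(x)
}

#' Euclidean norm of the triaxial acceleration
#'
#' Computes the per-sample Euclidean norm of the acceleration, the
#' orientation-invariant scalar signal used by every wrist-adapted algorithm
#' in this package.
#'
#' @param rec a [wg_recording()].
#' @return a [wg_series()] with the recording's unit and sampling rate.
#' @export
accel_norm <- function(rec) {
  stopifnot(inherits(rec, "wg_recording"))
  v <- sqrt(rowSums(rec$acc^2))
  wg_series(v, fs = rec$fs, unit = rec$unit)
}

#' Convert a series between g and m/s^2
#'
#' Multiplies or divides by standard gravity (9.81) exactly once; converting to
#' the unit the series already carries is the identity.
#'
#' @param s a [wg_series()] with unit `"g"` or `"m_s2"`.
#' @param target `"g"` or `"m_s2"`.
#' @return the converted [wg_series()].
#' @export
convert_unit <- function(s, target = c("g", "m_s2")) {
  target <- match.arg(target)
  if (!s$unit %in% c("g", "m_s2")) {
    stop(sprintf("unknown unit tag '%s'; cannot convert", s$unit))
  }
  if (s$unit == target) return(s)
  f <- if (target == "m_s2") WG_GRAVITY else 1 / WG_GRAVITY
  wg_series(s$values * f, fs = s$fs, unit = target)
}

#' Read a wrist IMU recording from CSV
#'
#' Expects a header row with columns `time_s, acc_x, acc_y, acc_z` and
#' optionally `gyr_x, gyr_y, gyr_z`. Irregular timestamps are repaired onto a
#' regular grid at `fs` by linear interpolation, with a warning when the
#' observed jitter exceeds one sample period.
#'
#' @param path CSV file path.
#' @param unit acceleration unit of the file (`"g"` or `"m_s2"`); recorded in
#'   the returned object, typically declared in a sidecar config.
#' @param fs target sampling frequency in Hz.
#' @return a [wg_recording()].
#' @export
read_imu_csv <- function(path, unit = "g", fs = 100) {
  d <- read.csv(path, check.names = TRUE)
  need <- c("time_s", "acc_x", "acc_y", "acc_z")
  if (!all(need %in% names(d))) {
    stop("IMU CSV must have header columns time_s, acc_x, acc_y, acc_z")
  }
  t <- d$time_s
  acc <- as.matrix(d[, c("acc_x", "acc_y", "acc_z")])
  gyro <- NULL
  if (all(c("gyr_x", "gyr_y", "gyr_z") %in% names(d))) {
    gyro <- as.matrix(d[, c("gyr_x", "gyr_y", "gyr_z")])
  }
  dt <- diff(t)
  if (length(dt) > 0L && (max(dt) - min(dt)) > 1 / fs) {
    warning("irregular timestamps (jitter > 1 sample); repairing by linear interpolation")
  }
  tg <- seq(t[1L], t[length(t)], by = 1 / fs)
  if (length(t) > 1L && (length(tg) != length(t) || max(abs(tg - t)) > 1e-9)) {
    acc <- apply(acc, 2L, function(col) approx(t, col, xout = tg)$y)
    if (!is.null(gyro)) gyro <- apply(gyro, 2L, function(col) approx(t, col, xout = tg)$y)
  }
  wg_recording(acc, fs = fs, unit = unit, t0 = t[1L], gyro = gyro)
}

#' Write a recording to the package's IMU CSV dialect
#'
#' @param rec a [wg_recording()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_imu_csv <- function(rec, path) {
  n <- nrow(rec$acc)
  d <- data.frame(
    time_s = rec$t0 + (seq_len(n) - 1L) / rec$fs,
    acc_x = rec$acc[, 1L], acc_y = rec$acc[, 2L], acc_z = rec$acc[, 3L]
  )
  if (!is.null(rec$gyro)) {
    d$gyr_x <- rec$gyro[, 1L]; d$gyr_y <- rec$gyro[, 2L]; d$gyr_z <- rec$gyro[, 3L]
  }
  write.csv(d, path, row.names = FALSE)
  invisible(path)
}
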