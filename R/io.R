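# Readers/writers: reference-annotation JSON (the dialect the synthetic
# generator emits, emulating a multi-sensor reference system's outputs) and
# CSV/JSON result tables.

validate_reference <- function(ref) {
  b <- ref$bouts
  if (is.null(b) || !all(c("bout_id", "start_s", "end_s") %in% names(b))) {
    stop("reference schema violation at bouts: need bout_id, start_s, end_s")
  }
  if (nrow(b) > 0L) {
    if (any(b$end_s <= b$start_s)) stop("reference schema violation at bouts.end_s: end <= start")
    if (is.unsorted(b$start_s)) stop("reference schema violation at bouts.start_s: not sorted")
    if (nrow(b) > 1L && any(b$start_s[-1L] < b$end_s[-nrow(b)])) {
      stop("reference schema violation at bouts: overlapping bouts")
    }
  }
  if (!is.null(ref$ics) && nrow(ref$ics) > 0L) {
    if (!all(c("time_s", "bout_id") %in% names(ref$ics))) {
      stop("reference schema violation at initial_contacts: need time_s, bout_id")
    }
    for (bid in unique(na.omit(ref$ics$bout_id))) {
      tt <- ref$ics$time_s[!is.na(ref$ics$bout_id) & ref$ics$bout_id == bid]
      if (is.unsorted(tt, strictly = TRUE)) {
        stop(sprintf("reference schema violation at initial_contacts.time_s (bout %s): not strictly increasing", bid))
      }
    }
  }
  if (!is.null(ref$strides) && nrow(ref$strides) > 0L) {
    if (any(ref$strides$end_ic_s <= ref$strides$start_ic_s)) {
      stop("reference schema violation at strides: end_ic_s <= start_ic_s")
    }
    if (any(ref$strides$length_m <= 0)) {
      stop("reference schema violation at strides.length_m: non-positive")
    }
  }
  invisible(ref)
}

#' Write reference annotations to JSON
#'
#' @param ref a `wg_reference` (see [synth_recording()]).
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_reference <- function(ref, path) {
  validate_reference(ref)
  obj <- list(schema_version = ref$schema_version %||% 1L,
              bouts = ref$bouts, initial_contacts = ref$ics,
              strides = ref$strides, bout_speed = ref$bout_speed)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read reference annotations from JSON
#'
#' The `strides` (and `bout_speed`) sections may be absent, which is valid for
#' GSD/ICD-only evaluation; malformed time ordering is rejected with the
#' offending field path.
#'
#' @param path JSON file path.
#' @return a `wg_reference`.
#' @export
read_reference <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  as_df <- function(x, cols) {
    if (is.null(x) || (is.data.frame(x) && nrow(x) == 0L) || length(x) == 0L) {
      return(as.data.frame(setNames(rep(list(numeric(0)), length(cols)), cols)))
    }
    as.data.frame(x)
  }
  ref <- structure(list(
    bouts = as_df(obj$bouts, c("bout_id", "start_s", "end_s")),
    ics = as_df(obj$initial_contacts, c("time_s", "foot", "bout_id")),
    strides = as_df(obj$strides, c("start_ic_s", "end_ic_s", "length_m", "foot", "bout_id")),
    bout_speed = as_df(obj$bout_speed, c("bout_id", "speed_ms")),
    schema_version = obj$schema_version %||% 1L
  ), class = "wg_reference")
  validate_reference(ref)
  ref
}

#' Write detected bouts as CSV
#'
#' @param res a `wg_gsd_result`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_bouts_csv <- function(res, path) {
  b <- res$bouts
  d <- data.frame(bout_id = seq_len(nrow(b)), start_s = b$start_s,
                  end_s = b$end_s, duration_s = b$end_s - b$start_s)
  write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' Write detected initial contacts as CSV
#'
#' @param ics data.frame from [detect_initial_contacts()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_ics_csv <- function(ics, path) {
  d <- ics
  d$ic_index <- stats::ave(seq_len(nrow(d)), d$bout_id, FUN = seq_along)
  write.csv(d[, c("bout_id", "ic_index", "time_s", "method", "version")],
            path, row.names = FALSE)
  invisible(path)
}

#' Write stride estimates as CSV
#'
#' @param sl result of [estimate_stride_length()].
#' @param path output CSV path for stride records.
#' @param per_second_path optional CSV path for the per-second series.
#' @return `path`, invisibly.
#' @export
write_strides_csv <- function(sl, path, per_second_path = NULL) {
  d <- sl$strides
  d$method <- sl$method; d$version <- sl$version
  write.csv(d[, c("bout_id", "start_ic_s", "end_ic_s", "stride_m", "method", "version")],
            path, row.names = FALSE)
  if (!is.null(per_second_path)) {
    write.csv(sl$per_second[, c("bout_id", "second_index", "stride_m")],
              per_second_path, row.names = FALSE)
  }
  invisible(path)
}

# report rows with the standard column names used in validation tables
gsd_report_row <- function(r) {
  v <- function(nm) r$metrics[[nm]]$value
  data.frame(
    Method = r$method, Version = r$version,
    `Performance Index` = r$performance_index,
    `Detected Walking Time (s)` = r$detected_walking_s,
    `Reference Walking Time (s)` = r$reference_walking_s,
    Specificity = v("specificity"), Accuracy = v("accuracy"),
    Recall = v("recall"), Precision = v("precision"),
    `Absolute Relative Duration Error (%)` = v("abs_rel_duration_error_pct"),
    ICC = v("icc"), check.names = FALSE, stringsAsFactors = FALSE)
}

icd_report_row <- function(r) {
  v <- function(nm) r$metrics[[nm]]$value
  data.frame(
    Method = r$method, Version = r$version,
    `Performance Index` = r$performance_index,
    Recall = v("recall"), Precision = v("precision"),
    `Absolute Timing Error (s)` = v("abs_timing_error_s"),
    `Relative Timing Error (%)` = v("rel_timing_error_pct"),
    check.names = FALSE, stringsAsFactors = FALSE)
}

sl_report_row <- function(r) {
  v <- function(nm) r$metrics[[nm]]$value
  data.frame(
    Method = r$method, Version = r$version,
    `Performance Index` = r$performance_index,
    `Detected Stride Length (m)` = r$detected_stride_m,
    `Reference Stride Length (m)` = r$reference_stride_m,
    `Absolute Error (m)` = v("abs_error_m"),
    `Relative Error (%)` = v("rel_error_pct"),
    ICC = v("icc"), check.names = FALSE, stringsAsFactors = FALSE)
}

#' Convert metric reports to a results table
#'
#' @param reports list of `wg_metric_report`s of one family.
#' @param family `"gsd"`, `"icd"` or `"sl"`.
#' @return data.frame with the standard validation-table column names, ranked
#'   by performance index.
#' @export
reports_table <- function(reports, family = c("gsd", "icd", "sl")) {
  family <- match.arg(family)
  rower <- switch(family, gsd = gsd_report_row, icd = icd_report_row,
                  sl = sl_report_row)
  d <- do.call(rbind, lapply(reports, rower))
  ranked <- rank_algorithms(reports)
  key_d <- paste(d$Method, d$Version)
  key_r <- paste(ranked$method, ranked$version)
  d <- d[match(key_r, key_d), , drop = FALSE]
  rownames(d) <- NULL
  d
}
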