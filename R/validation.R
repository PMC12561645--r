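# Technical-validation framework: windowed GSD classification, tolerance-based
# IC matching, stride-length errors, ICC(2,1), exponential error-trend fits,
# Bland-Altman tables, and the weighted performance index used to rank
# algorithms.

#' Classify fixed windows against reference and detected bouts
#'
#' Splits `[0, duration_s)` into windows of `window_s` and classifies each by
#' whether its midpoint lies inside a reference and/or detected bout
#' (half-open membership): TP = both walking, TN = neither, FP = detector
#' only, FN = reference only.
#'
#' @param ref_bouts,det_bouts data.frames with `start_s`, `end_s`.
#' @param duration_s recording duration in seconds.
#' @param window_s window length (default 0.1 s).
#' @return list with integer counts `tp`, `fp`, `tn`, `fn`.
#' @export
classify_windows <- function(ref_bouts, det_bouts, duration_s, window_s = 0.1) {
  n_win <- floor(duration_s / window_s + 1e-9)
  if (n_win < 1L) stop("duration shorter than one window")
  mids <- (seq_len(n_win) - 0.5) * window_s
  in_bouts <- function(t, b) {
    out <- rep(FALSE, length(t))
    for (i in seq_len(nrow(b))) out <- out | (t >= b$start_s[i] & t < b$end_s[i])
    out
  }
  r <- in_bouts(mids, ref_bouts)
  d <- in_bouts(mids, det_bouts)
  list(tp = sum(r & d), fp = sum(!r & d), tn = sum(!r & !d), fn = sum(r & !d))
}

#' Window-classification metrics
#'
#' Accuracy, recall (sensitivity), specificity and precision (positive
#' predictive value) from the window confusion counts. Ratios with a zero
#' denominator are returned as `NA` (undefined), never 0.
#'
#' @param cc counts from [classify_windows()].
#' @return named list of metrics.
#' @export
gsd_metrics <- function(cc) {
  total <- cc$tp + cc$fp + cc$tn + cc$fn
  safe <- function(num, den) if (den > 0) num / den else NA_real_
  list(accuracy = safe(cc$tp + cc$tn, total),
       recall = safe(cc$tp, cc$tp + cc$fn),
       specificity = safe(cc$tn, cc$tn + cc$fp),
       precision = safe(cc$tp, cc$tp + cc$fp))
}

#' Absolute relative duration error (percent)
#'
#' @param ref_total_s,det_total_s total accumulated walking durations.
#' @return `100 * |det - ref| / ref`.
#' @export
duration_error <- function(ref_total_s, det_total_s) {
  if (ref_total_s <= 0) stop("reference duration must be positive")
  100 * abs(det_total_s - ref_total_s) / ref_total_s
}

#' ICC(2,1): two-way random effects, absolute agreement, single measure
#'
#' Computed from the two-way ANOVA mean squares of an n x k ratings table
#' (subjects x raters). Absolute agreement penalises systematic offsets
#' between raters, unlike consistency forms.
#'
#' @param ratings numeric matrix or data.frame, n subjects x k raters
#'   (k = 2 for reference vs detector), complete.
#' @return the ICC value; `NA` with a warning when total variance is zero.
#' @export
icc_2_1 <- function(ratings) {
  m <- as.matrix(ratings)
  if (any(!is.finite(m))) stop("ratings table must be complete and finite")
  n <- nrow(m); k <- ncol(m)
  if (n < 3L || k < 2L) stop("need at least 3 subjects and 2 raters")
  grand <- mean(m)
  rm_ <- rowMeans(m); cm_ <- colMeans(m)
  if (sum((m - grand)^2) < 1e-24) {
    warning("zero total variance; ICC undefined")
    return(NA_real_)
  }
  msr <- k * sum((rm_ - grand)^2) / (n - 1)
  msc <- n * sum((cm_ - grand)^2) / (k - 1)
  mse <- sum((m - outer(rm_, rep(1, k)) - outer(rep(1, n), cm_) + grand)^2) /
    ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
}

#' Match detected initial contacts to reference events
#'
#' One-to-one matching within the tolerance window: reference events are
#' processed in time order and take their nearest unmatched detected event;
#' when every candidate is already taken, the previous assignments are
#' re-arranged along an augmenting path, so the matching always reaches
#' maximum cardinality. Remaining detected events are false positives,
#' remaining reference events false negatives.
#'
#' @param ref_s,det_s sorted event times in seconds.
#' @param tol_s matching tolerance (default 0.25 s, i.e. a window of
#'   +/- 0.25 s centered on the reference event).
#' @return list with `pairs` (data.frame ref_s, det_s, error_s = det - ref),
#'   `fp_events`, `fn_events`.
#' @export
match_ics <- function(ref_s, det_s, tol_s = 0.25) {
  if (is.unsorted(ref_s) || is.unsorted(det_s)) stop("event lists must be sorted")
  nr <- length(ref_s); nd <- length(det_s)
  owner <- rep(NA_integer_, nd)  # det index -> ref index
  # candidates of ref i, nearest first
  cands <- lapply(seq_len(nr), function(i) {
    j <- which(abs(det_s - ref_s[i]) <= tol_s)
    j[order(abs(det_s[j] - ref_s[i]), j)]
  })
  try_assign <- function(i, visited) {
    for (j in cands[[i]]) {
      if (visited[j]) next
      visited[j] <- TRUE
      if (is.na(owner[j])) {
        owner[j] <<- i
        return(TRUE)
      }
      prev <- owner[j]
      owner[j] <<- i
      if (Recall(prev, visited)) return(TRUE)
      owner[j] <<- prev
    }
    FALSE
  }
  for (i in seq_len(nr)) try_assign(i, rep(FALSE, nd))
  paired <- which(!is.na(owner))
  ord <- order(owner[paired])
  pd <- det_s[paired][ord]
  pr <- ref_s[owner[paired]][ord]
  list(pairs = data.frame(ref_s = pr, det_s = pd, error_s = pd - pr),
       fp_events = det_s[is.na(owner)],
       fn_events = ref_s[!seq_len(nr) %in% owner])
}

#' Timing errors of matched initial contacts
#'
#' @param m a [match_ics()] result.
#' @param mean_ref_step_s mean reference step duration of the bout, used to
#'   normalise the relative error.
#' @return list with `abs_error_s` (mean absolute signed error) and
#'   `rel_error_pct` (100 x abs / mean step duration); both `NA` when no
#'   pairs matched.
#' @export
ic_timing_errors <- function(m, mean_ref_step_s) {
  if (nrow(m$pairs) == 0L) {
    return(list(abs_error_s = NA_real_, rel_error_pct = NA_real_))
  }
  abs_err <- mean(abs(m$pairs$error_s))
  list(abs_error_s = abs_err, rel_error_pct = 100 * abs_err / mean_ref_step_s)
}

# two-sided 95% t-interval for a mean
ci95 <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 2L) return(c(NA_real_, NA_real_))
  se <- sd(x) / sqrt(length(x))
  mean(x) + c(-1, 1) * stats::qt(0.975, length(x) - 1L) * se
}

#' Bout-level stride-length errors
#'
#' Per-bout absolute (m) and relative (percent) errors of detected vs
#' reference bout-mean stride length, aggregated as means with 95 percent
#' t-intervals, plus ICC(2,1) over the bout pairs.
#'
#' @param ref_bout_means,det_bout_means numeric vectors, paired by bout.
#' @return list with `abs_m`, `abs_ci`, `rel_pct`, `rel_ci`, `icc`,
#'   `per_bout` (data.frame ref_m, det_m, abs_err_m, rel_err_pct).
#' @export
sl_errors <- function(ref_bout_means, det_bout_means) {
  if (length(ref_bout_means) != length(det_bout_means)) stop("length mismatch")
  if (any(ref_bout_means <= 0)) stop("reference bout means must be positive")
  abs_err <- abs(det_bout_means - ref_bout_means)
  rel_err <- 100 * abs_err / ref_bout_means
  icc <- if (length(ref_bout_means) >= 3L) {
    icc_2_1(cbind(ref_bout_means, det_bout_means))
  } else NA_real_
  list(abs_m = mean(abs_err), abs_ci = ci95(abs_err),
       rel_pct = mean(rel_err), rel_ci = ci95(rel_err), icc = icc,
       per_bout = data.frame(ref_m = ref_bout_means, det_m = det_bout_means,
                             abs_err_m = abs_err, rel_err_pct = rel_err))
}

#' Exponential cost-to-benefit transform
#'
#' Maps a non-negative cost metric onto the 0-1 benefit scale as
#' `exp(-cost / scale)`: zero cost maps to 1 and the transform is monotone
#' decreasing; `scale` is the cost magnitude at which the benefit drops to
#' 1/e.
#'
#' @param cost_value non-negative cost.
#' @param scale positive scale of the exponential transform.
#' @return benefit in (0, 1].
#' @export
cost_to_benefit <- function(cost_value, scale) {
  if (any(cost_value < 0, na.rm = TRUE)) stop("cost must be non-negative")
  if (scale <= 0) stop("scale must be positive")
  exp(-cost_value / scale)
}

#' Weight configuration for the performance index
#'
#' Uniform weights by default, with per-cost-metric exponential scales set to
#' each metric's acceptable magnitude. Every ranking output records the weight
#' vector actually used.
#'
#' @param metric_names names of the metrics in the report.
#' @param weights optional named non-negative weights (normalised at use).
#' @param cost_scales optional named scales; defaults are 50 (percent) for
#'   duration error, 0.1 s for absolute timing error, 15 (percent) for
#'   relative timing error, 0.2 m for absolute stride error and 30 (percent)
#'   for relative stride error.
#' @return an object of class `wg_weight_config`.
#' @export
weight_config <- function(metric_names, weights = NULL, cost_scales = NULL) {
  w <- setNames(rep(1, length(metric_names)), metric_names)
  if (!is.null(weights)) {
    if (any(weights < 0)) stop("weights must be non-negative")
    w[names(weights)] <- weights
  }
  if (sum(w) <= 0) stop("at least one weight must be positive")
  defaults <- c(abs_rel_duration_error_pct = 50, abs_timing_error_s = 0.1,
                rel_timing_error_pct = 15, abs_error_m = 0.2,
                rel_error_pct = 30)
  cs <- defaults
  if (!is.null(cost_scales)) cs[names(cost_scales)] <- cost_scales
  structure(list(weights = w, cost_scales = cs), class = "wg_weight_config")
}

#' Weighted performance index
#'
#' Weighted mean of benefit metrics (used directly on the 0-1 scale) and
#' exponentially transformed cost metrics, with weights normalised to sum 1.
#' Undefined (`NA`) metrics are excluded with weight renormalisation and a
#' note recorded on the result.
#'
#' @param metrics named list; each element is `list(value =, kind =)` with
#'   kind `"benefit"` or `"cost"`.
#' @param w a [weight_config()].
#' @return index in [0, 1], with attribute `excluded` naming dropped metrics.
#' @export
performance_index <- function(metrics, w = weight_config(names(metrics))) {
  vals <- vapply(names(metrics), function(nm) {
    m <- metrics[[nm]]
    if (!is.finite(m$value)) return(NA_real_)
    if (m$kind == "benefit") m$value
    else cost_to_benefit(m$value, scale = if (nm %in% names(w$cost_scales))
      w$cost_scales[[nm]] else 1)
  }, 0)
  wts <- w$weights[names(metrics)]
  keep <- is.finite(vals)
  if (!any(keep)) stop("all metrics undefined; no performance index")
  wts <- wts[keep] / sum(wts[keep])
  structure(sum(wts * vals[keep]),
            excluded = names(metrics)[!keep])
}

new_metric_report <- function(method, version, metrics, w) {
  pi <- performance_index(metrics, w)
  structure(list(method = method, version = version, metrics = metrics,
                 performance_index = as.numeric(pi),
                 excluded = attr(pi, "excluded"),
                 weights_used = w$weights[names(metrics)] /
                   sum(w$weights[names(metrics)])),
            class = "wg_metric_report")
}

#' @export
print.wg_metric_report <- function(x, ...) {
  cat(sprintf("<wg_metric_report> %s/%s  index = %.3f\n",
              x$method, x$version, x$performance_index))
  for (nm in names(x$metrics)) {
    m <- x$metrics[[nm]]
    cat(sprintf("  %-28s %8.4f (%s)\n", nm, m$value, m$kind))
  }
  invisible(x)
}

#' Rank algorithm reports by performance index
#'
#' Descending by index; ties broken by accuracy (GSD reports), recall (ICD),
#' ICC (SL), then method/version name — a documented deterministic order.
#'
#' @param reports list of metric reports (from the `evaluate_*` functions).
#' @return data.frame, one row per report, ranked.
#' @export
rank_algorithms <- function(reports) {
  if (length(reports) == 0L) stop("no reports to rank")
  rows <- lapply(reports, function(r) {
    tie <- NA_real_
    for (nm in c("accuracy", "recall", "icc")) {
      if (nm %in% names(r$metrics) && is.finite(r$metrics[[nm]]$value)) {
        tie <- r$metrics[[nm]]$value; break
      }
    }
    data.frame(method = r$method, version = r$version,
               performance_index = r$performance_index, tie_break = tie,
               stringsAsFactors = FALSE)
  })
  d <- do.call(rbind, rows)
  ord <- order(-d$performance_index, -ifelse(is.na(d$tie_break), -Inf, d$tie_break),
               d$method, d$version)
  d <- d[ord, , drop = FALSE]
  d$rank <- seq_len(nrow(d))
  rownames(d) <- NULL
  d
}

#' Fit an exponential error-decay trend
#'
#' Nonlinear least-squares fit of `error = a * exp(-b * x) + c` against a
#' covariate (walking speed or bout duration), returning the parameters,
#' Pearson r between fitted and observed values, R-squared (clipped to
#' [0, 1]) and the raw scatter table.
#'
#' @param per_bout_errors numeric vector of per-bout errors.
#' @param covariate numeric vector (same length): walking speed (m/s) or bout
#'   duration (s).
#' @return list with `a`, `b`, `c`, `pearson_r`, `r_squared`, `fitted`,
#'   `scatter`; parameters are `NA` when fewer than 5 bouts are available or
#'   the fit fails (scatter is always returned).
#' @export
trend_tables <- function(per_bout_errors, covariate) {
  stopifnot(length(per_bout_errors) == length(covariate))
  scatter <- data.frame(x = covariate, error = per_bout_errors)
  empty <- list(a = NA_real_, b = NA_real_, c = NA_real_,
                pearson_r = NA_real_, r_squared = NA_real_,
                fitted = rep(NA_real_, length(covariate)), scatter = scatter)
  if (length(per_bout_errors) < 5L) return(empty)
  y <- per_bout_errors; x <- covariate
  st <- list(a = max(y) - min(y), b = 1, c = min(y))
  if (st$a <= 0) st$a <- max(abs(y), 1e-6)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ a * exp(-b * x) + c,
                      start = st, data = data.frame(x = x, y = y),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(empty)
  cf <- coef(fit)
  yhat <- as.numeric(predict(fit))
  ss_res <- sum((y - yhat)^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) max(0, min(1, 1 - ss_res / ss_tot)) else NA_real_
  pr <- if (sd(yhat) > 1e-12 && sd(y) > 1e-12) stats::cor(y, yhat) else NA_real_
  list(a = unname(cf["a"]), b = unname(cf["b"]), c = unname(cf["c"]),
       pearson_r = pr, r_squared = r2, fitted = yhat, scatter = scatter)
}

#' Bland-Altman agreement table
#'
#' Differences are wearable (detected) minus reference; positive values mean
#' the wearable overestimates.
#'
#' @param det,ref paired measurements.
#' @return list with `table` (mean, diff), `mean_diff`, `loa` (the
#'   +/- 1.96 SD limits of agreement).
#' @export
bland_altman <- function(det, ref) {
  stopifnot(length(det) == length(ref))
  d <- det - ref
  m <- (det + ref) / 2
  list(table = data.frame(mean = m, diff = d),
       mean_diff = mean(d),
       loa = mean(d) + c(-1, 1) * 1.96 * sd(d))
}

#' Evaluate a GSD result against the reference
#'
#' Window classification at 0.1 s plus duration error for one or more
#' recordings ("participants"); ICC(2,1) of total walking duration is computed
#' across recordings when at least three are supplied.
#'
#' @param ref_list list of reference bout data.frames (or a single data.frame).
#' @param det_list list of detected bout data.frames (same length).
#' @param duration_s vector of recording durations.
#' @param method,version identifiers stamped on the report.
#' @param w optional [weight_config()].
#' @return a `wg_metric_report`.
#' @export
evaluate_gsd <- function(ref_list, det_list, duration_s, method = "gsd",
                         version = "", w = NULL) {
  if (is.data.frame(ref_list)) ref_list <- list(ref_list)
  if (is.data.frame(det_list)) det_list <- list(det_list)
  stopifnot(length(ref_list) == length(det_list),
            length(duration_s) == length(ref_list))
  cc <- list(tp = 0L, fp = 0L, tn = 0L, fn = 0L)
  ref_tot <- det_tot <- numeric(length(ref_list))
  for (i in seq_along(ref_list)) {
    c_i <- classify_windows(ref_list[[i]], det_list[[i]], duration_s[i])
    cc <- Map(`+`, cc, c_i)
    ref_tot[i] <- sum(ref_list[[i]]$end_s - ref_list[[i]]$start_s)
    det_tot[i] <- sum(det_list[[i]]$end_s - det_list[[i]]$start_s)
  }
  gm <- gsd_metrics(cc)
  icc <- if (length(ref_tot) >= 3L) icc_2_1(cbind(ref_tot, det_tot)) else NA_real_
  metrics <- list(
    accuracy = list(value = gm$accuracy, kind = "benefit"),
    recall = list(value = gm$recall, kind = "benefit"),
    specificity = list(value = gm$specificity, kind = "benefit"),
    precision = list(value = gm$precision, kind = "benefit"),
    icc = list(value = icc, kind = "benefit"),
    abs_rel_duration_error_pct = list(
      value = mean(vapply(seq_along(ref_tot), function(i)
        duration_error(ref_tot[i], det_tot[i]), 0)), kind = "cost")
  )
  if (is.null(w)) w <- weight_config(names(metrics))
  rep_ <- new_metric_report(method, version, metrics, w)
  rep_$detected_walking_s <- sum(det_tot)
  rep_$reference_walking_s <- sum(ref_tot)
  rep_
}

#' Evaluate detected initial contacts against the reference
#'
#' Matches events per bout within the tolerance window, then aggregates
#' recall, precision and the mean absolute / relative timing errors across
#' bouts (relative errors are normalised to each bout's mean reference step
#' duration).
#'
#' @param ref_ics data.frame with `bout_id`, `time_s` (reference events).
#' @param det_ics data.frame with `bout_id`, `time_s` (detected events).
#' @param tol_s matching tolerance (default 0.25 s).
#' @param method,version identifiers stamped on the report.
#' @param w optional [weight_config()].
#' @return a `wg_metric_report`; `$per_bout` carries bout-level errors.
#' @export
evaluate_icd <- function(ref_ics, det_ics, tol_s = 0.25, method = "icd",
                         version = "", w = NULL) {
  bids <- sort(unique(ref_ics$bout_id))
  tp <- fp <- fn <- 0L
  abs_errs <- rel_errs <- numeric(0)
  per_bout <- NULL
  for (b in bids) {
    r <- sort(ref_ics$time_s[ref_ics$bout_id == b])
    d <- sort(det_ics$time_s[det_ics$bout_id == b])
    m <- match_ics(r, d, tol_s)
    tp <- tp + nrow(m$pairs); fp <- fp + length(m$fp_events)
    fn <- fn + length(m$fn_events)
    if (length(r) >= 2L) {
      te <- ic_timing_errors(m, mean(diff(r)))
      abs_errs <- c(abs_errs, te$abs_error_s)
      rel_errs <- c(rel_errs, te$rel_error_pct)
      per_bout <- rbind(per_bout, data.frame(
        bout_id = b, n_ref = length(r), n_det = length(d),
        abs_error_s = te$abs_error_s, rel_error_pct = te$rel_error_pct))
    }
  }
  # detected events in bouts with no reference events are false positives
  extra <- det_ics$time_s[!det_ics$bout_id %in% bids]
  fp <- fp + length(extra)
  safe <- function(num, den) if (den > 0) num / den else NA_real_
  metrics <- list(
    recall = list(value = safe(tp, tp + fn), kind = "benefit"),
    precision = list(value = safe(tp, tp + fp), kind = "benefit"),
    abs_timing_error_s = list(value = mean(abs_errs, na.rm = TRUE), kind = "cost"),
    rel_timing_error_pct = list(value = mean(rel_errs, na.rm = TRUE), kind = "cost")
  )
  if (is.null(w)) w <- weight_config(names(metrics))
  rep_ <- new_metric_report(method, version, metrics, w)
  rep_$per_bout <- per_bout
  rep_
}

#' Evaluate stride-length estimates against the reference
#'
#' @param ref_bout_means,det_bout_means paired bout-mean stride lengths (m).
#' @param method,version identifiers stamped on the report.
#' @param w optional [weight_config()].
#' @return a `wg_metric_report`; `$errors` carries the [sl_errors()] detail
#'   and `$bland_altman` the agreement table.
#' @export
evaluate_sl <- function(ref_bout_means, det_bout_means, method = "sl",
                        version = "", w = NULL) {
  e <- sl_errors(ref_bout_means, det_bout_means)
  metrics <- list(
    icc = list(value = e$icc, kind = "benefit"),
    abs_error_m = list(value = e$abs_m, kind = "cost"),
    rel_error_pct = list(value = e$rel_pct, kind = "cost")
  )
  if (is.null(w)) w <- weight_config(names(metrics))
  rep_ <- new_metric_report(method, version, metrics, w)
  rep_$errors <- e
  rep_$bland_altman <- bland_altman(det_bout_means, ref_bout_means)
  rep_$detected_stride_m <- mean(det_bout_means)
  rep_$reference_stride_m <- mean(ref_bout_means)
  rep_
}
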