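test_that("window classification matches hand enumeration and an oracle", {
  cc <- classify_windows(data.frame(start_s = 0, end_s = 0.5),
                         data.frame(start_s = 0, end_s = 0.4), 1)
  expect_equal(cc, list(tp = 4L, fp = 0L, tn = 5L, fn = 1L))
  ref <- data.frame(start_s = c(1, 5), end_s = c(3, 8))
  ide <- classify_windows(ref, ref, 10)
  expect_equal(ide$fp + ide$fn, 0L)

  set.seed(31)
  for (rep_i in 1:200) {
    n <- sample(1:4, 1)
    e <- sort(runif(2 * n, 0, 20))
    a <- data.frame(start_s = e[seq(1, 2 * n, 2)], end_s = e[seq(2, 2 * n, 2)])
    e2 <- sort(runif(4, 0, 20))
    b <- data.frame(start_s = e2[c(1, 3)], end_s = e2[c(2, 4)])
    cc <- classify_windows(a, b, 20)
    # brute-force per-window oracle
    mids <- (seq_len(200) - 0.5) * 0.1
    inb <- function(t, d) {
      o <- rep(FALSE, length(t))
      for (i in seq_len(nrow(d))) o <- o | (t >= d$start_s[i] & t < d$end_s[i])
      o
    }
    r <- inb(mids, a); d <- inb(mids, b)
    expect_identical(cc, list(tp = sum(r & d), fp = sum(!r & d),
                              tn = sum(!r & !d), fn = sum(r & !d)))
    expect_equal(cc$tp + cc$fp + cc$tn + cc$fn, 200L)
  }
})

test_that("classification metrics handle zero denominators as undefined", {
  m <- gsd_metrics(list(tp = 4L, fp = 0L, tn = 5L, fn = 1L))
  expect_equal(m, list(accuracy = 0.9, recall = 0.8, specificity = 1, precision = 1))
  m0 <- gsd_metrics(list(tp = 0L, fp = 0L, tn = 10L, fn = 0L))
  expect_equal(m0$accuracy, 1)
  expect_true(is.na(m0$recall) && is.na(m0$precision))
  # swapping (tp,tn) and (fp,fn) swaps recall and specificity
  a <- gsd_metrics(list(tp = 7L, fp = 2L, tn = 9L, fn = 3L))
  b <- gsd_metrics(list(tp = 9L, fp = 3L, tn = 7L, fn = 2L))
  expect_equal(a$recall, b$specificity)
  expect_equal(a$specificity, b$recall)
})

test_that("duration error is the absolute relative percentage", {
  expect_equal(duration_error(1000, 900), 10)
  expect_equal(duration_error(1000, 1000), 0)
  set.seed(32)
  for (i in 1:20) {
    r <- runif(1, 10, 100); d <- runif(1, 0, 200)
    expect_equal(duration_error(r, d), 100 * abs(d - r) / r)
  }
  expect_error(duration_error(0, 5), "positive")
})

test_that("ICC(2,1) matches the ANOVA mean-squares oracle", {
  expect_equal(icc_2_1(cbind(c(1, 2, 3, 4), c(1, 2, 3, 4))), 1)
  tab <- cbind(c(10, 11, 12, 10.5, 11.5, 12.5),
               c(10, 11, 12, 10.5, 11.5, 12.5) + 5)
  # frozen from an aov() decomposition of this 6 x 2 table
  expect_equal(icc_2_1(tab), 0.06542056, tolerance = 1e-7)
  expect_lt(icc_2_1(tab), 0.5)  # absolute agreement penalises the offset
  # oracle recomputed independently via aov
  df <- data.frame(y = c(tab), subj = factor(rep(1:6, 2)),
                   rater = factor(rep(1:2, each = 6)))
  av <- summary(stats::aov(y ~ subj + rater, data = df))[[1]]
  msr <- av["subj", "Mean Sq"]; msc <- av["rater", "Mean Sq"]
  mse <- av["Residuals", "Mean Sq"]
  expect_equal(icc_2_1(tab), (msr - mse) / (msr + mse + 2 * (msc - mse) / 6))
  # permutation invariance
  p <- sample(6)
  expect_equal(icc_2_1(tab[p, ]), icc_2_1(tab))
  expect_warning(v <- icc_2_1(matrix(1, 4, 2)), "zero total variance")
  expect_true(is.na(v))
})

test_that("IC matching achieves maximum cardinality within tolerance", {
  m <- match_ics(c(1.0, 2.0), c(1.1, 2.3))
  expect_equal(m$pairs$ref_s, 1.0)
  expect_equal(m$pairs$det_s, 1.1)
  expect_equal(m$fp_events, 2.3)
  expect_equal(m$fn_events, 2.0)

  r <- c(0.5, 1.0, 1.5)
  m2 <- match_ics(r, r)
  expect_equal(nrow(m2$pairs), 3L)
  expect_true(all(m2$pairs$error_s == 0))

  set.seed(33)
  for (rep_i in 1:300) {
    nr <- sample(0:8, 1); nd <- sample(0:8, 1)
    ref <- sort(runif(nr, 0, 5)); det <- sort(runif(nd, 0, 5))
    m <- match_ics(ref, det, tol_s = 0.25)
    expect_equal(nrow(m$pairs), max_matching_oracle(ref, det, 0.25))
    expect_true(all(abs(m$pairs$error_s) <= 0.25))
    expect_equal(nrow(m$pairs) + length(m$fn_events), nr)
    expect_equal(nrow(m$pairs) + length(m$fp_events), nd)
  }
  expect_error(match_ics(c(2, 1), c(1)), "sorted")
})

test_that("timing errors normalise to the mean step duration", {
  m <- list(pairs = data.frame(ref_s = c(1, 2), det_s = c(1.1, 2.1),
                               error_s = c(0.1, 0.1)))
  te <- ic_timing_errors(m, mean_ref_step_s = 0.5)
  expect_equal(te$abs_error_s, 0.1)
  expect_equal(te$rel_error_pct, 20)
  perfect <- ic_timing_errors(list(pairs = data.frame(ref_s = 1, det_s = 1,
                                                      error_s = 0)), 0.5)
  expect_equal(unlist(perfect), c(abs_error_s = 0, rel_error_pct = 0))
  none <- ic_timing_errors(list(pairs = data.frame()), 0.5)
  expect_true(is.na(none$abs_error_s))
})

test_that("stride-length errors aggregate with ICC over bouts", {
  e <- sl_errors(c(0.76, 1.0, 1.2), c(0.95, 1.0, 1.2))
  expect_equal(e$per_bout$abs_err_m[1], 0.19)
  expect_equal(e$per_bout$rel_err_pct[1], 25)
  eq <- sl_errors(c(0.7, 0.9, 1.1), c(0.7, 0.9, 1.1))
  expect_equal(eq$abs_m, 0)
  expect_equal(eq$icc, 1)
  expect_error(sl_errors(c(0, 1), c(1, 1)), "positive")
})

test_that("the exponential cost transform hits its closed forms", {
  expect_equal(cost_to_benefit(0, 10), 1)
  expect_equal(cost_to_benefit(50, 50), exp(-1))
  set.seed(34)
  c1 <- sort(runif(50, 0, 100))
  b <- cost_to_benefit(c1, 30)
  expect_true(all(diff(b) <= 0))
  expect_true(all(b >= 0 & b <= 1))
  expect_error(cost_to_benefit(-1, 10), "non-negative")
})

test_that("performance index is a weighted mean with NA renormalisation", {
  pm <- list(m1 = list(value = 1, kind = "benefit"),
             m2 = list(value = 0, kind = "cost"))
  expect_equal(as.numeric(performance_index(pm)), 1)
  pm2 <- list(m1 = list(value = 0.8, kind = "benefit"),
              m2 = list(value = 0.4, kind = "benefit"))
  w <- weight_config(c("m1", "m2"), weights = c(m1 = 0.75, m2 = 0.25))
  expect_equal(as.numeric(performance_index(pm2, w)), 0.7)
  pm3 <- list(m1 = list(value = 0.6, kind = "benefit"),
              m2 = list(value = NA_real_, kind = "benefit"))
  pi3 <- performance_index(pm3)
  expect_equal(as.numeric(pi3), 0.6)
  expect_equal(attr(pi3, "excluded"), "m2")
  expect_error(performance_index(list(m = list(value = NA_real_, kind = "benefit"))),
               "undefined")
})

test_that("ranking is deterministic, descending, and order-invariant", {
  mk <- function(method, idx, acc) {
    structure(list(method = method, version = "v",
                   metrics = list(accuracy = list(value = acc, kind = "benefit")),
                   performance_index = idx), class = "wg_metric_report")
  }
  reps <- list(mk("a", 0.76, 0.9), mk("b", 0.75, 0.9), mk("c", 0.73, 0.9))
  rk <- rank_algorithms(reps)
  expect_equal(rk$method, c("a", "b", "c"))
  expect_equal(rank_algorithms(rev(reps))$method, c("a", "b", "c"))
  one <- rank_algorithms(reps[2])
  expect_equal(one$method, "b")
  # tie on index resolved by the tie-break metric then name
  tie <- list(mk("x", 0.5, 0.7), mk("y", 0.5, 0.9))
  expect_equal(rank_algorithms(tie)$method, c("y", "x"))
})

test_that("trend fitting recovers exact exponential-decay parameters", {
  x <- seq(0.3, 2, length.out = 40)
  y <- 10 * exp(-2 * x) + 5
  ft <- trend_tables(y, x)
  expect_equal(ft$a, 10, tolerance = 1e-3)
  expect_equal(ft$b, 2, tolerance = 1e-3)
  expect_equal(ft$c, 5, tolerance = 1e-3)
  expect_gt(ft$r_squared, 0.999)

  flat <- trend_tables(rep(3, 10), seq_len(10))
  expect_true(is.na(flat$b) || abs(flat$b) < 0.1)

  set.seed(35)
  noisy <- trend_tables(10 * exp(-1.5 * x) + 3 + rnorm(40, 0, 0.5), x)
  expect_true(noisy$r_squared >= 0 && noisy$r_squared <= 1)

  few <- trend_tables(c(1, 2, 3), c(1, 2, 3))
  expect_true(is.na(few$a))
  expect_equal(nrow(few$scatter), 3L)
})

test_that("Bland-Altman differences are antisymmetric under system swap", {
  set.seed(36)
  det <- runif(20, 0.5, 1.5); ref <- runif(20, 0.5, 1.5)
  ba1 <- bland_altman(det, ref); ba2 <- bland_altman(ref, det)
  expect_equal(ba1$mean_diff, -ba2$mean_diff)
  expect_equal(ba1$table$diff, -ba2$table$diff)
})
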