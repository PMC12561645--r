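test_that("step features match closed forms and a loop oracle", {
  # constant series: maxmin 0, mu = |c|, rms = |c|, dt exact (kim = raw norm)
  rec <- wg_recording(matrix(rep(c(0, 0, 0.8), each = 500), ncol = 3), 100, "g")
  bs <- bout_signal(rec, 0, 5)
  f <- extract_step_features(bs, c(1, 2), method = "kim")
  expect_equal(f$maxmin, 0)
  expect_equal(f$mu, 0.8)
  expect_equal(f$rms, 0.8)
  expect_equal(f$dt_s, 1)

  # one full period of a unit sine between ICs: maxmin 2, rms ~ 0.707
  # (series built directly, as the feature extractor sees it post-preprocessing)
  t <- (0:499) / 100
  bs2 <- structure(list(series = wg_series(sin(2 * pi * 1 * t), 100, "g"),
                        start_s = 0, end_s = 5, fs = 100),
                   class = "wg_bout_signal")
  f2 <- extract_step_features(bs2, c(1, 2), method = "kim")
  expect_equal(f2$maxmin, 2, tolerance = 0.01)
  expect_equal(f2$rms, 1 / sqrt(2), tolerance = 0.01)

  # random segment vs explicit loops
  set.seed(8)
  acc <- matrix(rnorm(900, 0, 0.3), ncol = 3)
  acc[, 3] <- acc[, 3] + 1
  rec3 <- wg_recording(acc, 100, "g")
  bs3 <- bout_signal(rec3, 0, 3)
  ics <- c(0.5, 1.2, 2.4)
  f3 <- extract_step_features(bs3, ics, method = "kim")
  x <- bs3$series$values
  seg <- x[51:120]
  expect_equal(f3$maxmin[1], max(seg) - min(seg), tolerance = 1e-12)
  expect_equal(f3$mu[1], mean(abs(seg)), tolerance = 1e-12)
  expect_equal(f3$rms[1], sqrt(mean(seg^2)), tolerance = 1e-12)

  expect_error(extract_step_features(bs3, 0.5), "at least two")
  expect_error(extract_step_features(bs3, c(0.5, 5)), "outside")
})

test_that("the three step-length models evaluate their printed closed forms", {
  f1 <- data.frame(maxmin = 1, mu = 1, rms = 1, dt_s = 0.5)
  expect_equal(step_length_weinberg(f1, sl_params("weinberg", "wrist")), 0.62)
  fa <- data.frame(maxmin = 0.8, mu = 1, rms = 1.1, dt_s = 0.5)
  expect_equal(step_length_weinberg(fa, sl_params("weinberg", "wrist_adaptive")),
               0.60 * 1.1 * 0.8^0.25)
  expect_equal(step_length_kim(f1, sl_params("kim", "wrist")), 0.35)
  expect_equal(step_length_kim(data.frame(maxmin = 0, mu = 0.027, rms = 1, dt_s = 1),
                               sl_params("kim", "wrist")), 0.35 * 0.3)
  fb <- data.frame(maxmin = 1, mu = 1, rms = 1, dt_s = 1)
  expect_equal(step_length_bylemans(fb, sl_params("bylemans", "wrist")), 2.30)
  # power law: doubling maxmin scales by 2^(1/2.7)
  fb2 <- fb; fb2$maxmin <- 2
  expect_equal(step_length_bylemans(fb2, sl_params("bylemans", "wrist")) /
                 step_length_bylemans(fb, sl_params("bylemans", "wrist")),
               2^(1 / 2.7))
  # random features vs hand-computed arithmetic
  set.seed(12)
  fr <- data.frame(maxmin = runif(1, 0.2, 1.5), mu = runif(1, 0.5, 1.2),
                   rms = runif(1, 0.8, 1.2), dt_s = runif(1, 0.4, 0.8))
  expect_equal(step_length_bylemans(fr, sl_params("bylemans", "wrist_adaptive")),
               9.15 * fr$rms * (fr$mu / fr$dt_s * fr$maxmin)^(1 / 2.7))
})

test_that("foot-length versions convert cm to metres and require the input", {
  p <- sl_params("weinberg", "wrist_footlength", foot_length_cm = 25)
  f <- data.frame(maxmin = 1, mu = 1, rms = 1, dt_s = 0.5)
  expect_equal(step_length_weinberg(f, p), 0.21 + 0.25)
  # removing B reproduces the bare intensity term
  p0 <- p; p0$B_m <- 0
  expect_equal(step_length_weinberg(f, p) - step_length_weinberg(f, p0), 0.25)
  expect_error(sl_params("weinberg", "wrist_footlength"), "foot length")
})

test_that("adaptive and non-adaptive versions coincide when rms = 1 and A equal", {
  f <- data.frame(maxmin = 0.7, mu = 0.9, rms = 1, dt_s = 0.55)
  pa <- sl_params("kim", "wrist_adaptive")
  pn <- sl_params("kim", "wrist")
  expect_equal(step_length_kim(f, pa), step_length_kim(f, pn))
})

test_that("estimators are strictly increasing in the features they consume", {
  set.seed(13)
  for (rep_i in 1:50) {
    f <- data.frame(maxmin = runif(1, 0.1, 2), mu = runif(1, 0.1, 2),
                    rms = runif(1, 0.5, 1.5), dt_s = runif(1, 0.3, 1))
    f2 <- f; f2$maxmin <- f$maxmin * 1.2
    expect_gt(step_length_weinberg(f2, sl_params("weinberg", "wrist")),
              step_length_weinberg(f, sl_params("weinberg", "wrist")))
    f3 <- f; f3$mu <- f$mu * 1.2
    expect_gt(step_length_kim(f3, sl_params("kim", "wrist")),
              step_length_kim(f, sl_params("kim", "wrist")))
    f4 <- f; f4$rms <- f$rms * 1.2
    expect_gt(step_length_bylemans(f4, sl_params("bylemans", "wrist_adaptive")),
              step_length_bylemans(f, sl_params("bylemans", "wrist_adaptive")))
  }
})

test_that("stride assembly doubles steps and interpolates per second", {
  asm <- assemble_strides(rep(0.5, 10), seq(0, 5, by = 0.5), 0, 5.2)
  expect_true(all(asm$strides$stride_m == 1.0))
  expect_equal(asm$bout_mean_m, 1.0)
  expect_lte(abs(nrow(asm$per_second) - floor(5.2)), 1)

  asm2 <- assemble_strides(c(0.4, 0.6), c(0, 0.5, 1.0), 0, 1.0)
  expect_equal(asm2$bout_mean_m, 1.0, tolerance = 0.2)
  expect_error(assemble_strides(numeric(0), numeric(0), 0, 1), "no steps")
  expect_error(assemble_strides(c(0.5), c(0, 0.5, 1), 0, 1), "one more IC")
})

test_that("bout-mean stride tracks true speed across a sweep (Spearman > 0.8)", {
  speeds <- seq(0.4, 1.6, length.out = 6)
  det_m <- true_m <- numeric(6)
  for (i in seq_along(speeds)) {
    sim <- synth_recording(list(
      schedule_item("rest", duration_s = 5),
      schedule_item("walk", spec = walk_spec(30, cadence_spm = 110,
                                             speed_ms = speeds[i])),
      schedule_item("rest", duration_s = 5)
    ), seed = 100 + i)
    ref <- sim$reference
    est <- estimate_stride_length(sim$recording, ref$bouts,
                                  ref$ics[!is.na(ref$ics$bout_id), ],
                                  "weinberg", "wrist")
    det_m[i] <- est$bout_means$stride_m[1]
    true_m[i] <- ref_bout_mean_stride(ref)$stride_m[1]
  }
  expect_gt(cor(det_m, true_m, method = "spearman"), 0.8)
})

test_that("physiological capping clamps and counts out-of-range steps", {
  sim <- one_walk_sim(walk_s = 20, rest_s = 5, seed = 9)
  ref <- sim$reference
  est <- estimate_stride_length(sim$recording, ref$bouts, ref$ics,
                                "bylemans", "wrist",
                                overrides = list(A = 50))
  expect_gt(est$n_clamped, 0)
  expect_true(all(est$strides$stride_m <= 3.0 + 1e-9))
})
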