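# Shared fixture: 120 s recording, one 60 s walk between two rests.
sim_walk <- one_walk_sim(seed = 1)

test_that("merge_bouts applies the 3 s rule and matches a brute-force oracle", {
  b <- data.frame(start_s = c(0, 12), end_s = c(10, 20))
  expect_equal(merge_bouts(b), data.frame(start_s = 0, end_s = 20))
  b2 <- data.frame(start_s = c(0, 14), end_s = c(10, 20))
  expect_equal(merge_bouts(b2), b2)
  # boundary: exactly 3 s splits
  b3 <- data.frame(start_s = c(0, 13), end_s = c(10, 20))
  expect_equal(nrow(merge_bouts(b3)), 2L)

  oracle <- function(b, min_break) {
    walk <- rep(FALSE, 4000)  # 0.01 s grid over [0, 40)
    tg <- (seq_len(4000) - 0.5) / 100
    for (i in seq_len(nrow(b))) walk <- walk | (tg >= b$start_s[i] & tg < b$end_s[i])
    for (i in seq_len(nrow(b) - 1)) {
      if (b$start_s[i + 1] - b$end_s[i] < min_break) {
        walk <- walk | (tg >= b$end_s[i] & tg < b$start_s[i + 1])
      }
    }
    r <- rle(walk); ends <- cumsum(r$lengths) / 100
    starts <- c(0, head(ends, -1))
    data.frame(start_s = starts[r$values], end_s = ends[r$values])
  }
  set.seed(21)
  for (rep_i in 1:300) {
    n <- sample(1:6, 1)
    edges <- sort(sample(seq(0, 40, by = 0.25), 2 * n))
    b <- data.frame(start_s = edges[seq(1, 2 * n, 2)], end_s = edges[seq(2, 2 * n, 2)])
    b <- b[b$end_s > b$start_s, , drop = FALSE]
    if (nrow(b) == 0) next
    m <- merge_bouts(b, 3)
    o <- oracle(b, 3)
    expect_equal(m, o, tolerance = 1e-9)
    expect_gte(sum(m$end_s - m$start_s), sum(b$end_s - b$start_s))
  }
  expect_error(merge_bouts(data.frame(start_s = c(0, 1), end_s = c(2, 3))),
               "disjoint")
})

test_that("all detectors return no bouts on a still recording", {
  still <- flat_recording(20)
  expect_equal(nrow(gsd_hickey(still)$bouts), 0L)
  expect_equal(nrow(gsd_kheirkhahan(still)$bouts), 0L)
  expect_equal(nrow(gsd_maclean(still)$bouts), 0L)
  expect_equal(nrow(gsd_keren(still)$bouts), 0L)
  expect_equal(nrow(gsd_ionescu(still)$bouts), 0L)
  expect_equal(nrow(gsd_iluz(still)$bouts), 0L)
})

test_that("every detector recovers a clean walk with high overlap", {
  rec <- sim_walk$recording; ref <- sim_walk$reference
  dur <- rec_duration(rec)
  reg <- list_methods("gsd")
  for (i in seq_len(nrow(reg))) {
    res <- detect_gait_sequences(rec, reg$method[i], reg$version[i])
    expect_equal(nrow(res$bouts), 1L, info = reg$method[i])
    expect_gte(bout_jaccard(res$bouts, ref$bouts, dur), 0.8)
    # structural invariants
    expect_true(all(res$bouts$start_s >= 0 & res$bouts$end_s <= dur))
    expect_equal(res$total_walking_s, sum(res$bouts$end_s - res$bouts$start_s),
                 tolerance = 1e-9)
    # determinism
    res2 <- detect_gait_sequences(rec, reg$method[i], reg$version[i])
    expect_identical(res$bouts, res2$bouts)
  }
})

test_that("hickey excludes a high-g shaking burst via the activity ceiling", {
  sim <- synth_recording(list(
    schedule_item("walk", spec = walk_spec(30, speed_ms = 1.1)),
    schedule_item("activity", duration_s = 10, activity = "shake", intensity_g = 12),
    schedule_item("walk", spec = walk_spec(30, speed_ms = 1.1))
  ), seed = 1)
  r <- gsd_hickey(sim$recording)
  mids <- (r$bouts$start_s + r$bouts$end_s) / 2
  # the burst occupies [30, 40); no detected bout midpoint may fall there
  expect_true(all(mids < 30 | mids > 40))
  covered <- sum(pmin(r$bouts$end_s, 40) - pmax(r$bouts$start_s, 30 + 1) > 1)
  expect_equal(covered, 0L)
})

test_that("keren stays quiet on white noise but detects the walk", {
  set.seed(3)
  noise <- wg_recording(matrix(rnorm(3 * 6000, sd = 0.25), ncol = 3) +
                          matrix(rep(c(0, 0, 1), each = 6000), ncol = 3), 100, "g")
  for (v in c("improved", "adaptive")) {
    r <- gsd_keren(noise, version = v)
    expect_lt(r$total_walking_s, 0.05 * 60)
  }
  rec <- sim_walk$recording
  ri <- gsd_keren(rec, version = "improved")
  ra <- gsd_keren(rec, version = "adaptive")
  expect_gte(bout_jaccard(ri$bouts, ra$bouts, rec_duration(rec)), 0.7)
})

test_that("ionescu adaptive outperforms the fixed threshold on weak arm swing", {
  sp <- walk_spec(60, speed_ms = 1.1)
  sp$arm_swing_g <- sp$arm_swing_g / 2
  sp$impact_g <- sp$impact_g / 2
  sim <- synth_recording(list(schedule_item("rest", duration_s = 10),
                              schedule_item("walk", spec = sp),
                              schedule_item("rest", duration_s = 10)), seed = 5)
  recall_of <- function(det) {
    g <- seq(0.05, 80, by = 0.1)
    inb <- function(t, b) {
      o <- rep(FALSE, length(t))
      for (i in seq_len(nrow(b))) o <- o | (t >= b$start_s[i] & t < b$end_s[i])
      o
    }
    a <- inb(g, det); b <- inb(g, sim$reference$bouts)
    sum(a & b) / sum(b)
  }
  rf <- recall_of(gsd_ionescu(sim$recording, version = "wrist")$bouts)
  ra <- recall_of(gsd_ionescu(sim$recording, version = "wrist_adaptive")$bouts)
  expect_gte(ra, rf)
  expect_gte(ra, 0.7)
})

test_that("ionescu detects about one step per true step inside its bouts", {
  sim <- one_walk_sim(seed = 6, cadence = 120)
  r <- gsd_ionescu(sim$recording, version = "wrist")
  # bout at ~2 steps/s: detected span implies step count via grouping rule
  expect_equal(r$total_walking_s, 60, tolerance = 60 * 0.15)
})

test_that("maclean merges brief pauses but rejects isolated blips", {
  w <- synth_walk(walk_spec(20, speed_ms = 1.1, noise_sd_g = 0, seed = 1))
  acc <- w$acc
  acc[1000:1030, ] <- matrix(rep(c(0, 0, 1), each = 31), ncol = 3)  # 0.3 s pause
  rp <- gsd_maclean(wg_recording(acc, 100, "g"))
  expect_equal(nrow(rp$bouts), 1L)

  blip <- matrix(rep(c(0, 0, 1), each = 3000), ncol = 3)
  blip[1500:1530, 3] <- 1 + 0.5 * sin(2 * pi * 2 * (0:30) / 100)
  expect_equal(nrow(gsd_maclean(wg_recording(blip, 100, "g"))$bouts), 0L)
})

test_that("raising activity thresholds never increases walking time", {
  rec <- sim_walk$recording
  base_k <- gsd_kheirkhahan(rec)$total_walking_s
  doub_k <- detect_gait_sequences(rec, "kheirkhahan",
                                  params = list(threshold = 1.16))$total_walking_s
  expect_lte(doub_k, base_k)
  base_i <- gsd_ionescu(rec, version = "wrist")$total_walking_s
  doub_i <- detect_gait_sequences(rec, "ionescu", "wrist",
                                  params = list(active_signal_threshold = 0.62))$total_walking_s
  expect_lte(doub_i, base_i)
  base_m <- gsd_maclean(rec)$total_walking_s
  doub_m <- detect_gait_sequences(rec, "maclean",
                                  params = list(threshold_binary = 0.22))$total_walking_s
  expect_lte(doub_m, base_m)
})

test_that("iluz activity gate dominates periodicity", {
  # periodic but tiny amplitude: below the std gate, no bouts
  t <- (0:1999) / 100
  rec <- wg_recording(cbind(0, 0, 1 + 0.02 * sin(2 * pi * 2 * t)), 100, "g")
  expect_equal(nrow(gsd_iluz(rec)$bouts), 0L)
})
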