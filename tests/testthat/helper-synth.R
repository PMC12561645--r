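# Shared fixtures, built in code.

# recording holding 1 g gravity plus a pure vertical tone (amplitude in g)
tone_recording <- function(freq_hz, duration_s = 10, amp = 0.25, fs = 100) {
  t <- (seq_len(duration_s * fs) - 1L) / fs
  wg_recording(cbind(0, 0, 1 + amp * sin(2 * pi * freq_hz * t)), fs, "g")
}

flat_recording <- function(duration_s = 10, fs = 100) {
  wg_recording(matrix(rep(c(0, 0, 1), each = duration_s * fs), ncol = 3), fs, "g")
}

# Jaccard overlap of two bout sets on a 0.1 s grid
bout_jaccard <- function(a, b, duration_s) {
  g <- seq(0.05, duration_s, by = 0.1)
  inb <- function(t, d) {
    o <- rep(FALSE, length(t))
    for (i in seq_len(nrow(d))) o <- o | (t >= d$start_s[i] & t < d$end_s[i])
    o
  }
  x <- inb(g, a); y <- inb(g, b)
  sum(x & y) / sum(x | y)
}

# a standard one-bout schedule: rest / walk / rest
one_walk_sim <- function(walk_s = 60, rest_s = 30, speed = 1.2, cadence = 120,
                         seed = 1, noise = 0.02) {
  synth_recording(list(
    schedule_item("rest", duration_s = rest_s),
    schedule_item("walk", spec = walk_spec(walk_s, cadence_spm = cadence,
                                           speed_ms = speed, noise_sd_g = noise)),
    schedule_item("rest", duration_s = rest_s)
  ), seed = seed)
}

# exhaustive maximum bipartite matching size under a tolerance (oracle)
max_matching_oracle <- function(ref, det, tol) {
  n <- length(ref)
  best <- 0L
  rec <- function(i, used) {
    if (i > n) { best <<- max(best, sum(used)); return(invisible()) }
    # prune: even matching all remaining refs cannot beat best
    if (sum(used) + (n - i + 1L) <= best) return(invisible())
    cand <- which(!used & abs(det - ref[i]) <= tol)
    for (j in cand) { used[j] <- TRUE; rec(i + 1L, used); used[j] <- FALSE }
    rec(i + 1L, used)
  }
  rec(1L, rep(FALSE, length(det)))
  best
}
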