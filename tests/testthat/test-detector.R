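test_that("thresholds collapse to the constants for degenerate distributions", {
  ft <- make_features(rep(2, 10), rep(3, 10), rep(0.1, 10), rep(500, 10))
  th <- compute_thresholds(ft)
  expect_equal(th$t_energy, 2, tolerance = 1e-12)
  expect_equal(th$t_entropy, 3, tolerance = 1e-12)
  expect_equal(th$t_zcr, 0.1, tolerance = 1e-12)
  expect_equal(th$t_centroid, 500, tolerance = 1e-12)
  expect_error(compute_thresholds(make_features(1, 1, 0.1, 100)), "2 frames")
})

test_that("percentile and mean+sd thresholds follow their stated conventions", {
  ft <- make_features(1:100, rep(1, 100), rep(0.1, 100), 1:100)
  th <- compute_thresholds(ft)
  expect_equal(th$t_energy, 10.9, tolerance = 1e-12)   # linear interpolation
  expect_equal(th$t_centroid, 75.25, tolerance = 1e-12)
  # population sd, not sample sd
  ft2 <- make_features(rep(1, 4), c(0, 0, 2, 2), c(0, 0, 0.2, 0.2),
                       rep(10, 4))
  th2 <- compute_thresholds(ft2)
  expect_equal(th2$t_entropy, 1 + 0.5 * 1, tolerance = 1e-12)
  expect_equal(th2$t_zcr, 0.1 + 0.5 * 0.1, tolerance = 1e-12)
  # large-sample standard normal: mean + 0.5 sd -> 0.5
  h <- withr::with_seed(1, rnorm(1e5))
  th3 <- compute_thresholds(make_features(rep(1, 1e5), h, rep(0.1, 1e5),
                                          rep(10, 1e5)))
  expect_equal(th3$t_entropy, 0.5, tolerance = 0.02)
})

test_that("voting is inclusive at the boundary and matches a per-frame loop", {
  th <- structure(list(t_energy = 1, t_entropy = 2, t_zcr = 0.3,
                       t_centroid = 400, window_index = 0L),
                  class = "threshold_set")
  cfg <- detector_config()
  ft <- make_features(1, 2, 0.3, 400)          # all four exactly on boundary
  fv <- frame_votes(ft, th, cfg)
  expect_identical(fv$votes, 4L)
  expect_true(fv$mask)
  ft0 <- make_features(0.5, 3, 0.5, 500)       # fails all four
  expect_identical(frame_votes(ft0, th, cfg)$votes, 0L)

  n <- 1000
  ft_r <- withr::with_seed(3, make_features(runif(n, 0, 2), runif(n, 0, 4),
                                            runif(n), runif(n, 0, 800)))
  fv_r <- frame_votes(ft_r, th, cfg)
  loop <- integer(n)
  for (i in seq_len(n)) {
    loop[i] <- (ft_r$energy[i] >= 1) + (ft_r$entropy[i] <= 2) +
      (ft_r$zcr[i] <= 0.3) + (ft_r$centroid[i] <= 400)
  }
  expect_identical(fv_r$votes, loop)
  expect_identical(fv_r$mask, loop >= 3L)
})

test_that("invalid (all-zero) frames vote zero and raising the vote threshold shrinks the mask", {
  th <- structure(list(t_energy = 0, t_entropy = 10, t_zcr = 1,
                       t_centroid = 8000, window_index = 0L),
                  class = "threshold_set")
  ft <- make_features(c(1, 1), c(1, 1), c(0.1, 0.1), c(100, 100))
  ft$valid[2] <- FALSE
  fv <- frame_votes(ft, th, detector_config())
  expect_identical(fv$votes, c(4L, 0L))

  n <- 500
  ft_r <- withr::with_seed(5, make_features(runif(n), runif(n, 0, 4),
                                            runif(n), runif(n, 0, 800)))
  th_r <- compute_thresholds(ft_r)
  masks <- lapply(1:4, function(v) {
    frame_votes(ft_r, th_r, detector_config(vote_threshold = v))$mask
  })
  for (v in 2:4) expect_true(all(masks[[v]] <= masks[[v - 1]]))
})

test_that("runs become half-open segments; overlapping runs are unioned", {
  expect_identical(nrow(runs_to_segments(logical(10), (0:9) * 0.01, 0.025)), 0L)
  mask <- rep(FALSE, 40)
  mask[11:20] <- TRUE
  s <- runs_to_segments(mask, (0:39) * 0.01, 0.025)
  expect_equal(s$t_start_s, 0.10, tolerance = 1e-12)
  expect_equal(s$t_end_s, 0.215, tolerance = 1e-12)
  # two runs separated by >= frame length stay apart
  mask2 <- rep(FALSE, 40)
  mask2[c(5:8, 15:18)] <- TRUE
  s2 <- runs_to_segments(mask2, (0:39) * 0.01, 0.025)
  expect_identical(nrow(s2), 2L)
  # a single false frame between runs: the 25 ms frames overlap in time, so
  # the raw intervals are unioned and the output stays disjoint
  mask3 <- rep(FALSE, 40)
  mask3[c(5:8, 10:12)] <- TRUE
  s3 <- runs_to_segments(mask3, (0:39) * 0.01, 0.025)
  expect_identical(nrow(s3), 1L)
  expect_true(all(s3$t_end_s > s3$t_start_s))
})

test_that("gap merging follows the 0.3 s rule and is idempotent", {
  a <- segments(c(0, 0.7), c(0.5, 1.2))
  m <- merge_gaps(a, 0.3)
  expect_identical(nrow(m), 1L)
  expect_equal(c(m$t_start_s, m$t_end_s), c(0, 1.2), tolerance = 1e-12)
  b <- segments(c(0, 0.9), c(0.5, 1.2))
  expect_identical(nrow(merge_gaps(b, 0.3)), 2L)
  for (i in 1:100) {
    k <- withr::with_seed(i, sample(0:8, 1))
    if (k == 0) {
      segs <- segments()
    } else {
      starts <- withr::with_seed(i + 300, sort(runif(k, 0, 30)))
      ends <- starts + withr::with_seed(i + 600, runif(k, 0.01, 1.5))
      ends <- pmin(ends, c(starts[-1], Inf) - 1e-6)
      segs <- segments(starts, ends)
    }
    once <- merge_gaps(segs, 0.3)
    expect_identical(merge_gaps(once, 0.3), once)
  }
  expect_error(merge_gaps(segments(c(1, 0), c(2, 0.5))), "sorted")
})

test_that("minimum-duration filtering keeps the inclusive boundary", {
  segs <- segments(c(0, 2.0, 5.0), c(0.3, 2.2, 5.9))  # 0.3 s exactly: kept
  out <- filter_short(segs, 0.3)
  expect_identical(nrow(out), 2L)
  expect_equal(out$t_start_s, c(0, 5.0), tolerance = 1e-12)
  for (i in 1:50) {
    k <- withr::with_seed(i, sample(1:10, 1))
    starts <- withr::with_seed(i + 50, sort(runif(k, 0, 50)))
    durs <- withr::with_seed(i + 99, runif(k, 0.05, 0.6))
    segs_r <- segments(starts, starts + durs)
    expect_identical(nrow(filter_short(segs_r, 0.3)), sum(durs >= 0.3))
  }
})

test_that("detector output always satisfies the segment-list invariants", {
  for (i in 1:12) {
    dur <- withr::with_seed(i, runif(1, 3, 20))
    rate <- 8000L
    n <- round(dur * rate)
    x <- withr::with_seed(i + 10, rnorm(n, sd = 0.05))
    # plant a couple of loud low-frequency bursts
    nb <- withr::with_seed(i + 20, sample(0:3, 1))
    for (b in seq_len(nb)) {
      t0 <- withr::with_seed(i * 10 + b, runif(1, 0, dur - 1))
      idx <- round(t0 * rate) + seq_len(round(0.6 * rate))
      x[idx] <- x[idx] + 0.5 * sin(2 * pi * 150 * seq_along(idx) / rate)
    }
    cfg <- detector_config(
      vote_threshold = withr::with_seed(i + 30, sample(2:4, 1)),
      gap_s = withr::with_seed(i + 40, runif(1, 0.1, 0.5)),
      min_dur_s = withr::with_seed(i + 50, runif(1, 0.1, 0.5)))
    segs <- detect_snores(audio_signal(x, rate), cfg)
    if (nrow(segs) > 1) {
      gaps <- segs$t_start_s[-1] - segs$t_end_s[-nrow(segs)]
      expect_true(all(gaps >= cfg$gap_s - 1e-9))
    }
    expect_true(all(segs$t_end_s - segs$t_start_s >= cfg$min_dur_s - 1e-9))
    expect_true(all(diff(segs$t_start_s) > 0))
  }
})

test_that("thresholds are per-window: distant content does not alter a window's mask", {
  rate <- 8000L
  win <- detector_config(analysis_window_s = 2, analysis_step_s = 2,
                         denoise = FALSE)
  base <- withr::with_seed(1, rnorm(2 * rate, sd = 0.02))
  burst <- 0.4 * sin(2 * pi * 120 * seq_len(rate) / rate)
  w1 <- base
  w1[1:rate] <- w1[1:rate] + burst
  # same first window, two very different second windows
  s_a <- audio_signal(c(w1, withr::with_seed(2, rnorm(2 * rate, sd = 0.02))),
                      rate)
  s_b <- audio_signal(c(w1, 0.8 * sin(2 * pi * 200 *
                                        seq_len(2 * rate) / rate)), rate)
  d_a <- detect_snores(s_a, win)
  d_b <- detect_snores(s_b, win)
  in_first <- function(d) d[d$t_end_s <= 2, c("t_start_s", "t_end_s")]
  expect_equal(in_first(d_a), in_first(d_b), tolerance = 1e-9)
})

test_that("the mask is invariant to positive amplitude scaling", {
  sim <- cached_sim("denoised", 1, duration_s = 120)
  d1 <- detect_snores(sim$signal, detector_config())
  scaled <- audio_signal(sim$signal$samples * 7.3, sim$signal$sample_rate_hz)
  d2 <- detect_snores(scaled, detector_config())
  expect_equal(d1$t_start_s, d2$t_start_s, tolerance = 1e-9)
  expect_equal(d1$t_end_s, d2$t_end_s, tolerance = 1e-9)
})

test_that("a recording shorter than one analysis window is one window", {
  sig <- cached_sim("denoised", 2, duration_s = 120)$signal
  short <- audio_signal(sig$samples[1:(30 * 16000)], 16000L)
  segs <- detect_snores(short, detector_config())
  expect_gt(nrow(segs), 0L)
  expect_true(all(segs$t_end_s <= 30))
})
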