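# Shared fixtures and independent scalar oracles. Everything is generated in
# code at test time; heavyweight synthetic recordings are memoised so several
# tests can share one realisation per seed.

tone_signal <- function(freq_hz, dur_s = 1, rate = 16000L, amp = 0.5) {
  t <- seq(0, dur_s - 1 / rate, by = 1 / rate)
  audio_signal(amp * sin(2 * pi * freq_hz * t), rate)
}

white_signal <- function(dur_s = 1, rate = 16000L, amp = 0.1, seed = 1) {
  n <- round(dur_s * rate)
  audio_signal(amp * withr::with_seed(seed, rnorm(n)), rate)
}

# independent scalar oracles (plain loops, no vectorised shortcuts)
oracle_energy <- function(x) {
  s <- 0
  for (v in x) s <- s + v * v
  s
}

oracle_zcr <- function(x) {
  n <- length(x)
  s <- 0
  for (i in 2:n) {
    s1 <- if (x[i] >= 0) 1 else -1
    s0 <- if (x[i - 1] >= 0) 1 else -1
    s <- s + abs(s1 - s0)
  }
  s / (2 * n)
}

oracle_entropy <- function(x, eps = 1e-10, n_fft = NULL) {
  if (is.null(n_fft)) {
    n_fft <- 1L
    while (n_fft < length(x)) n_fft <- n_fft * 2L
  }
  padded <- c(x, rep(0, n_fft - length(x)))
  k <- n_fft %/% 2L + 1L
  p <- numeric(k)
  for (j in seq_len(k)) {
    re <- 0; im <- 0
    for (n in seq_along(padded)) {
      ang <- -2 * pi * (j - 1) * (n - 1) / n_fft
      re <- re + padded[n] * cos(ang)
      im <- im + padded[n] * sin(ang)
    }
    p[j] <- re^2 + im^2
  }
  tot <- sum(p)
  if (tot == 0) return(log(k))
  p <- p / tot
  -sum(p * log(p + eps))
}

oracle_centroid <- function(x, rate, n_fft = NULL) {
  if (is.null(n_fft)) {
    n_fft <- 1L
    while (n_fft < length(x)) n_fft <- n_fft * 2L
  }
  mag <- Mod(fft(c(x, rep(0, n_fft - length(x)))))[1:(n_fft %/% 2 + 1)]
  freqs <- (seq_along(mag) - 1) * rate / n_fft
  if (sum(mag) == 0) return(0)
  sum(freqs * mag) / sum(mag)
}

# memoised short synthetic recordings shared by the unit tests (2-minute
# clips; the signals are small enough to keep)
.sim_cache <- new.env(parent = emptyenv())

cached_sim <- function(preset, seed, duration_s = 120) {
  key <- sprintf("%s_%d_%d", preset, seed, duration_s)
  if (is.null(.sim_cache[[key]])) {
    .sim_cache[[key]] <- synth_recording(
      snore_sim_config(duration_s = duration_s, preset = preset, seed = seed))
  }
  .sim_cache[[key]]
}

# memoised *evaluations* of full 10-minute nights for the acceptance tests:
# each night is synthesised once, the detector (and for the clean preset the
# energy+ZCR baseline) run on it, and only the small evaluation objects are
# kept - retaining 40 ten-minute waveforms would dominate memory
eval_night <- function(preset, seed) {
  key <- sprintf("eval_%s_%d", preset, seed)
  if (is.null(.sim_cache[[key]])) {
    sim <- synth_recording(
      snore_sim_config(duration_s = 600, preset = preset, seed = seed))
    amff <- endpoint_accuracy(detect_snores(sim$signal), sim$truth,
                              iou_min = 0.3)
    base <- if (preset == "denoised") {
      cfg <- detector_config(features_used = c("energy", "zcr"),
                             vote_threshold = 2L)
      endpoint_accuracy(detect_snores(sim$signal, cfg), sim$truth,
                        iou_min = 0.3)
    }
    .sim_cache[[key]] <- list(amff = amff, baseline = base)
  }
  .sim_cache[[key]]
}

# small frame-feature table builder for detector unit tests
make_features <- function(energy, entropy, zcr, centroid,
                          times = seq_along(energy) * 0.01) {
  structure(
    data.frame(frame_time_s = times, energy = energy, entropy = entropy,
               zcr = zcr, centroid = centroid, valid = TRUE),
    class = c("frame_features", "data.frame"),
    frame_length_samples = 400L, hop_samples = 160L, sample_rate_hz = 16000L)
}
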