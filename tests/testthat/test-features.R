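test_that("short-time energy matches hand values and scales quadratically", {
  expect_identical(short_time_energy(rep(0, 10)), 0)
  expect_identical(short_time_energy(c(1, -1, 2)), 6)
  for (i in 1:20) {
    x <- withr::with_seed(i, rnorm(64))
    a <- withr::with_seed(i + 50, runif(1, 0.1, 5))
    expect_equal(short_time_energy(a * x), a^2 * short_time_energy(x),
                 tolerance = 1e-12)
  }
  expect_error(short_time_energy(numeric(0)), "empty")
})

test_that("spectral entropy: delta spectrum near 0, flat spectrum near log K, noise above tone", {
  # constant (DC-only) frame concentrates the power spectrum in one bin
  k <- 64 / 2 + 1
  expect_lt(spectral_entropy(rep(1, 64)), 10 * 1e-10 * k + 1e-6)
  # a frame whose FFT is exactly flat: the unit impulse
  imp <- c(1, rep(0, 63))
  expect_equal(spectral_entropy(imp), log(k), tolerance = 1e-6)
  # Monte-Carlo: white-noise frames carry more entropy than pure tones of
  # equal energy
  h_noise <- sapply(1:100, function(s) {
    spectral_entropy(withr::with_seed(s, rnorm(400, sd = 0.1)))
  })
  h_tone <- sapply(1:100, function(s) {
    f <- withr::with_seed(s + 500, runif(1, 100, 7000))
    x <- sin(2 * pi * f * (0:399) / 16000)
    spectral_entropy(x * sqrt(0.01 / mean(x^2)))
  })
  expect_gt(mean(h_noise), mean(h_tone))
})

test_that("zero-crossing rate matches closed forms and a brute-force count", {
  expect_identical(zero_crossing_rate(rep(2, 50)), 0)
  n <- 60
  alt <- rep(c(1, -1), n / 2)
  expect_equal(zero_crossing_rate(alt), (n - 1) / n, tolerance = 1e-12)
  for (i in 1:1000) {
    x <- withr::with_seed(i, rnorm(32))
    expect_identical(zero_crossing_rate(x), oracle_zcr(x))
  }
  expect_error(zero_crossing_rate(1), "length")
})

test_that("spectral centroid: tone location, symmetry, white-noise expectation", {
  rate <- 16000L
  x <- sin(2 * pi * 1000 * (0:4095) / rate)
  expect_equal(spectral_centroid(x, rate), 1000, tolerance = 250)
  # longer frames converge closer to a non-bin-aligned tone frequency
  x2 <- sin(2 * pi * 1003 * (0:16383) / rate)
  err_long <- abs(spectral_centroid(x2, rate) - 1003)
  err_short <- abs(spectral_centroid(sin(2 * pi * 1003 * (0:511) / rate),
                                     rate) - 1003)
  expect_lt(err_long, err_short)
  # magnitude weighting keeps slowly decaying leakage tails, so convergence
  # is to within a few hundred Hz, not to the bin width
  expect_lt(err_long, 500)
  # spectrum symmetric around a centre bin -> centroid at that bin
  n_fft <- 64L
  spec <- rep(0, n_fft)
  spec[c(9, 17, 25)] <- c(1, 2, 1)              # symmetric around bin 17
  x3 <- Re(fft(c(spec[1:33], rev(Conj(spec[2:32]))), inverse = TRUE))
  f0 <- 16 * rate / n_fft
  expect_equal(spectral_centroid(x3, rate, n_fft = n_fft), f0, tolerance = 1)
  # white noise: centroid near Nyquist/2 (flat magnitude), averaged
  cs <- sapply(1:100, function(s) {
    spectral_centroid(withr::with_seed(s, rnorm(400)), rate)
  })
  expect_equal(mean(cs), rate / 4, tolerance = 0.05 * rate / 4)
  expect_identical(spectral_centroid(rep(0, 16), rate), 0)
})

test_that("the vectorised feature table equals the scalar operations", {
  sig <- white_signal(0.6, seed = 9)
  fs <- frame_signal(sig)
  ft <- compute_feature_table(fs)
  expect_identical(nrow(ft), ncol(fs$frames))
  idx <- withr::with_seed(1, sample(nrow(ft), 50))
  for (j in idx) {
    fr <- fs$frames[, j]
    expect_equal(ft$energy[j], short_time_energy(fr), tolerance = 1e-12)
    expect_equal(ft$entropy[j], spectral_entropy(fr), tolerance = 1e-12)
    expect_equal(ft$zcr[j], zero_crossing_rate(fr), tolerance = 1e-12)
    expect_equal(ft$centroid[j],
                 spectral_centroid(fr, sig$sample_rate_hz), tolerance = 1e-9)
  }
})

test_that("an all-zero frame gets the degenerate conventions and a flag", {
  z <- audio_signal(rep(0, 800), 16000L)
  ft <- compute_feature_table(frame_signal(z))
  expect_true(all(!ft$valid))
  expect_true(all(ft$energy == 0))
  expect_true(all(ft$zcr == 0))
  expect_true(all(ft$centroid == 0))
  expect_equal(ft$entropy, rep(log(257), nrow(ft)), tolerance = 1e-12)
})

test_that("feature bounds hold on thousands of fuzzed frames", {
  n <- 160 * 10000 + 400
  sig <- audio_signal(
    withr::with_seed(11, rnorm(n) * rep(runif(10), length.out = n)), 16000L)
  ft <- compute_feature_table(frame_signal(sig))
  expect_gte(nrow(ft), 10000L)
  k <- 257
  expect_true(all(ft$energy >= 0))
  expect_true(all(ft$zcr >= 0 & ft$zcr <= 1))
  expect_true(all(ft$centroid >= 0 & ft$centroid <= 8000))
  expect_true(all(ft$entropy >= 0 & ft$entropy <= log(k) + 1e-9))
})

test_that("Hz-to-Mel variants match their closed forms and are monotone", {
  expect_identical(hz_to_mel(0, "div100"), 0)
  expect_identical(hz_to_mel(0, "htk_standard"), 0)
  expect_equal(hz_to_mel(100, "div100"), 2595 * log10(2), tolerance = 1e-9)
  expect_equal(hz_to_mel(700, "htk_standard"), 2595 * log10(2),
               tolerance = 1e-9)
  f <- seq(0, 24000, by = 10)
  for (v in c("div100", "htk_standard")) {
    expect_true(all(diff(hz_to_mel(f, v)) > 0))
    expect_equal(mel_to_hz(hz_to_mel(f, v), v), f, tolerance = 1e-6)
  }
  expect_error(hz_to_mel(-1), "non-negative")
})

test_that("the Mel filterbank covers the band with no all-zero filter", {
  for (v in c("htk_standard", "div100")) {
    fb <- mel_filterbank(128, 512, 16000, variant = v)
    expect_identical(dim(fb), c(128L, 257L))
    expect_true(all(rowSums(fb) > 0))
    expect_true(all(fb >= 0))
  }
  # complementary triangles: per-bin coverage stays <= 1 when filters are
  # wider than the bin spacing (true of the standard Mel scale here)
  expect_true(all(colSums(mel_filterbank(128, 512, 16000)) <= 1 + 1e-9))
})

test_that("Mel spectrograms are always 128x128 and energy-bounded", {
  for (dur in c(0.5, 1, 3)) {
    m <- mel_spectrogram(white_signal(dur, seed = round(dur * 10)))
    expect_identical(dim(m$matrix), c(128L, 128L))
    expect_true(all(is.finite(m$matrix)))
  }
  # unscaled Mel energy never exceeds total spectral energy
  for (seed in 1:5) {
    clip <- white_signal(1, seed = seed)
    m <- mel_spectrogram(clip, log_scale = FALSE)
    fs <- frame_signal(clip)
    spec <- Mod(stats::mvfft(rbind(fs$frames,
                                   matrix(0, 112, ncol(fs$frames)))))^2
    expect_lte(sum(m$matrix), sum(spec[1:257, ]))
  }
  # a 200 Hz tone and a 4 kHz tone rank their argmax Mel rows correctly
  m_low <- mel_spectrogram(tone_signal(200, 1))
  m_high <- mel_spectrogram(tone_signal(4000, 1))
  expect_lt(which.max(rowSums(m_low$matrix)), which.max(rowSums(m_high$matrix)))
})
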