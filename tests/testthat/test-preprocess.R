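test_that("framing matches the published 25 ms / 10 ms convention", {
  s48 <- audio_signal(rep(0.1, 48000), 48000L)
  fs <- frame_signal(s48)
  expect_identical(fs$frame_length_samples, 1200L)
  expect_identical(fs$hop_samples, 480L)

  s16 <- audio_signal(rep(0.1, 16000), 16000L)
  expect_identical(ncol(frame_signal(s16)$frames), 98L)  # floor((16000-400)/160)+1
})

test_that("frame count and timing follow the closed form for many (len, N, H)", {
  for (i in 1:40) {
    len <- withr::with_seed(i, sample(500:5000, 1))
    rate <- 1000L
    fm <- withr::with_seed(i + 100, sample(5:80, 1))
    hm <- withr::with_seed(i + 200, sample(2:40, 1))
    n_len <- round(fm / 1000 * rate)
    hop <- round(hm / 1000 * rate)
    if (len < n_len || n_len < 1 || hop < 1) next
    fs <- frame_signal(audio_signal(rep(1, len), rate), fm, hm)
    # brute-force enumeration of valid frame starts
    n_expected <- length(seq(0, len - n_len, by = hop))
    expect_identical(ncol(fs$frames), n_expected)
    expect_equal(diff(fs$frame_start_times_s),
                 rep(hop / rate, n_expected - 1))
  }
})

test_that("frames are the signal times a Hamming window, and framing is linear", {
  s <- audio_signal(rep(1, 4000), 16000L)
  fs <- frame_signal(s)
  w <- 0.54 - 0.46 * cos(2 * pi * (0:399) / 399)
  for (j in c(1, 5, ncol(fs$frames))) {
    expect_equal(fs$frames[, j], w, tolerance = 1e-12)
  }
  x <- white_signal(0.25, seed = 4)
  a <- 3.7
  f1 <- frame_signal(x)
  f2 <- frame_signal(audio_signal(a * x$samples, x$sample_rate_hz))
  expect_equal(f2$frames, a * f1$frames, tolerance = 1e-12)
  expect_error(frame_signal(audio_signal(rep(1, 10), 16000L)), "shorter")
})

test_that("noise spectrum estimation behaves on white noise, silence and split signals", {
  # stationary white noise -> approximately flat profile (several seeds)
  cvs <- sapply(1:5, function(seed) {
    s <- white_signal(10, seed = seed)
    np <- estimate_noise_spectrum(s)
    sd(np$mean_magnitude[-1]) / mean(np$mean_magnitude[-1])
  })
  expect_true(all(cvs < 0.2))

  z <- audio_signal(rep(0, 16000), 16000L)
  expect_true(all(estimate_noise_spectrum(z)$mean_magnitude == 0))

  # first half noise-only, second half noise + loud tone: lowest-energy
  # selection should recover the noise-only spectrum within 3 dB
  noise <- white_signal(10, seed = 7)
  tone <- tone_signal(500, 5, amp = 0.5)
  both <- audio_signal(c(noise$samples[1:80000],
                         noise$samples[80001:160000] + tone$samples),
                       16000L)
  np_mix <- estimate_noise_spectrum(both, method = "lowest_energy_frames")
  np_ref <- estimate_noise_spectrum(audio_signal(noise$samples[1:80000], 16000L))
  ratio_db <- 20 * log10((np_mix$mean_magnitude + 1e-12) /
                           (np_ref$mean_magnitude + 1e-12))
  expect_lt(max(abs(ratio_db)), 3)
  expect_error(estimate_noise_spectrum(audio_signal(rep(0.1, 100), 16000L)),
               "shorter")
})

test_that("spectral subtraction: zero profile is identity, stationary noise is cancelled", {
  s <- white_signal(2, seed = 3)
  np0 <- estimate_noise_spectrum(s)
  np0$mean_magnitude[] <- 0
  y <- spectral_subtract(s, np0)
  expect_identical(length(y$samples), length(s$samples))
  expect_lt(max(abs(y$samples - s$samples)), 1e-6)

  # frame-by-frame stationary input (period = hop): profile equals every
  # frame's spectrum, so subtraction removes essentially all energy
  rate <- 16000L
  period <- withr::with_seed(8, rnorm(160))     # one hop at 16 kHz
  x <- audio_signal(rep(period, 100) * 0.1, rate)
  np <- estimate_noise_spectrum(x)
  y2 <- spectral_subtract(x, np)
  core <- seq(2000, length(x$samples) - 2000)   # ignore edge effects
  drop_db <- 10 * log10(sum(y2$samples[core]^2) / sum(x$samples[core]^2))
  expect_lt(drop_db, -20)
})

test_that("spectral subtraction preserves an out-of-profile tone within 1 dB", {
  rate <- 16000L
  noise <- white_signal(4, rate = rate, amp = 0.01, seed = 5)
  tone <- tone_signal(1000, 4, rate = rate, amp = 0.3)
  noisy <- audio_signal(noise$samples + tone$samples, rate)
  np <- estimate_noise_spectrum(noise)          # profile without the tone
  y <- spectral_subtract(noisy, np)
  spec_in <- Mod(fft(noisy$samples))[1:(length(noisy$samples) / 2)]
  spec_out <- Mod(fft(y$samples))[1:(length(y$samples) / 2)]
  bin <- which.max(spec_in)
  expect_lt(abs(20 * log10(spec_out[bin] / spec_in[bin])), 1)
  # off-tone region is attenuated
  off <- setdiff(seq(2000, 18000), (bin - 50):(bin + 50))
  expect_lt(sum(spec_out[off]^2), sum(spec_in[off]^2))
})

test_that("denoising never increases total energy (non-negative profile, reused phase)", {
  for (seed in 1:100) {
    n <- withr::with_seed(seed, sample(2000:6000, 1))
    x <- audio_signal(withr::with_seed(seed, rnorm(n, sd = 0.05)), 16000L)
    np <- estimate_noise_spectrum(x)
    y <- spectral_subtract(x, np)
    core <- seq(400, n - 400)                   # OLA edge samples excluded
    expect_lte(sum(y$samples[core]^2), sum(x$samples[core]^2) * (1 + 1e-10))
  }
})

test_that("mismatched FFT sizes are rejected", {
  s <- white_signal(1, seed = 2)
  np <- estimate_noise_spectrum(s, n_fft = 512)
  expect_error(spectral_subtract(s, np, n_fft = 1024), "match")
})
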