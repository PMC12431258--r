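## Framing, STFT helpers, noise-spectrum estimation and spectral subtraction.
##
## One framing convention is used throughout the package: 25 ms frames,
## 10 ms hop, Hamming window, FFT length = next power of two >= frame length.

next_pow2 <- function(n) {
  p <- 1L
  while (p < n) p <- p * 2L
  p
}

hamming_window <- function(n) {
  if (n == 1L) return(1)
  0.54 - 0.46 * cos(2 * pi * (0:(n - 1L)) / (n - 1L))
}

#' Default preprocessing configuration
#'
#' @param frame_ms analysis frame length in milliseconds.
#' @param hop_ms frame shift in milliseconds.
#' @param noise_method how the background-noise spectrum is estimated:
#'   `"lowest_energy_frames"` averages the magnitude spectra of the
#'   lowest-energy fraction of frames (robust when a recording starts
#'   mid-snore); `"leading_seconds"` averages the first `noise_leading_s`
#'   seconds.
#' @param noise_fraction fraction of lowest-energy frames used (default 0.10).
#' @param noise_leading_s leading seconds used by `"leading_seconds"`.
#' @return a list of preprocessing settings.
#' @export
preprocess_config <- function(frame_ms = 25, hop_ms = 10,
                              noise_method = c("lowest_energy_frames",
                                               "leading_seconds"),
                              noise_fraction = 0.1, noise_leading_s = 2) {
  noise_method <- match.arg(noise_method)
  stopifnot(frame_ms > 0, hop_ms > 0,
            noise_fraction > 0, noise_fraction <= 1, noise_leading_s > 0)
  list(frame_ms = frame_ms, hop_ms = hop_ms, noise_method = noise_method,
       noise_fraction = noise_fraction, noise_leading_s = noise_leading_s)
}

#' Cut a signal into overlapping Hamming-windowed frames
#'
#' Frame i (0-based) is `x(n + i*H) * w(n)` for `0 <= n < N`, where `N` is the
#' frame length, `H` the hop and `w` a Hamming window. The defaults (25 ms
#' frames, 10 ms hop) balance time and frequency resolution for snore
#' analysis.
#'
#' @param signal an [audio_signal].
#' @param frame_ms frame length in milliseconds.
#' @param hop_ms frame shift in milliseconds.
#' @param t0_s absolute time of the first sample (used when framing a window
#'   of a longer recording).
#' @return an object of class `frame_sequence`: windowed frames as an
#'   `N x n_frames` matrix (one column per frame), frame/hop sizes in samples,
#'   window kind and per-frame start times in seconds.
#' @export
frame_signal <- function(signal, frame_ms = 25, hop_ms = 10, t0_s = 0) {
  stopifnot(inherits(signal, "audio_signal"))
  rate <- signal$sample_rate_hz
  n_len <- as.integer(round(frame_ms / 1000 * rate))
  hop <- as.integer(round(hop_ms / 1000 * rate))
  stopifnot(n_len >= 1L, hop >= 1L)
  x <- signal$samples
  if (length(x) < n_len) {
    stop(sprintf("signal (%d samples) shorter than one frame (%d samples)",
                 length(x), n_len), call. = FALSE)
  }
  n_frames <- (length(x) - n_len) %/% hop + 1L
  starts <- (seq_len(n_frames) - 1L) * hop
  idx <- outer(seq_len(n_len), starts, `+`)
  w <- hamming_window(n_len)
  frames <- matrix(x[idx], nrow = n_len) * w
  structure(list(
    frames = frames,
    frame_length_samples = n_len,
    hop_samples = hop,
    window_kind = "hamming",
    window = w,
    frame_start_times_s = t0_s + starts / rate,
    sample_rate_hz = rate
  ), class = "frame_sequence")
}

#' @export
print.frame_sequence <- function(x, ...) {
  cat(sprintf("<frame_sequence> %d frames of %d samples (hop %d) @ %d Hz\n",
              ncol(x$frames), x$frame_length_samples, x$hop_samples,
              x$sample_rate_hz))
  invisible(x)
}

## One-sided magnitude/complex STFT of a frame_sequence, zero-padded to n_fft.
stft_frames <- function(frames, n_fft) {
  n_len <- nrow(frames)
  stopifnot(n_fft >= n_len)
  if (n_fft > n_len) {
    frames <- rbind(frames, matrix(0, n_fft - n_len, ncol(frames)))
  }
  stats::mvfft(frames)
}

#' Estimate the average background-noise magnitude spectrum
#'
#' Averages one-sided magnitude spectra over frames presumed to contain only
#' background noise: either the lowest-energy fraction of frames (default) or
#' the leading seconds of the recording.
#'
#' @param signal an [audio_signal], longer than one frame.
#' @param n_fft FFT length (power of two >= frame length).
#' @param hop_ms,frame_ms framing parameters (must match the framing used for
#'   subtraction).
#' @param method,fraction,leading_s see [preprocess_config()].
#' @return an object of class `noise_profile`: `mean_magnitude`
#'   (length `n_fft/2 + 1`), `n_fft`, `method_tag`.
#' @export
estimate_noise_spectrum <- function(signal, n_fft = NULL, frame_ms = 25,
                                    hop_ms = 10,
                                    method = c("lowest_energy_frames",
                                               "leading_seconds"),
                                    fraction = 0.1, leading_s = 2) {
  method <- match.arg(method)
  fs <- frame_signal(signal, frame_ms = frame_ms, hop_ms = hop_ms)
  if (is.null(n_fft)) n_fft <- next_pow2(fs$frame_length_samples)
  if (n_fft < fs$frame_length_samples) {
    stop("n_fft must be >= frame length", call. = FALSE)
  }
  n_frames <- ncol(fs$frames)
  sel <- if (method == "lowest_energy_frames") {
    e <- colSums(fs$frames^2)
    k <- max(1L, floor(fraction * n_frames))
    order(e)[seq_len(k)]
  } else {
    lim <- leading_s
    which(fs$frame_start_times_s < lim)
  }
  if (length(sel) == 0L) sel <- 1L
  spec <- stft_frames(fs$frames[, sel, drop = FALSE], n_fft)
  k_bins <- n_fft %/% 2L + 1L
  mag <- Mod(spec[seq_len(k_bins), , drop = FALSE])
  structure(list(
    mean_magnitude = rowMeans(mag),
    n_fft = n_fft,
    method_tag = method
  ), class = "noise_profile")
}

#' Spectral-subtraction denoising
#'
#' Per frame, the estimated clean magnitude is
#' `max(|Y(k,l)| - |N(k)|, 0)`: the mean noise magnitude spectrum is
#' subtracted from the observed magnitude spectrum and clamped at zero. The
#' noisy frame's phase is reused and the signal is reconstructed by
#' overlap-add; the output has the same length as the input. No
#' over-subtraction factor or spectral floor is applied.
#'
#' @param signal an [audio_signal].
#' @param noise a `noise_profile` from [estimate_noise_spectrum()].
#' @param n_fft FFT length; must equal `noise$n_fft`.
#' @param frame_ms,hop_ms framing parameters.
#' @return a denoised [audio_signal] of identical length and rate.
#' @export
spectral_subtract <- function(signal, noise, n_fft = noise$n_fft,
                              frame_ms = 25, hop_ms = 10) {
  stopifnot(inherits(signal, "audio_signal"), inherits(noise, "noise_profile"))
  if (n_fft != noise$n_fft) {
    stop(sprintf("n_fft (%d) does not match noise profile n_fft (%d)",
                 n_fft, noise$n_fft), call. = FALSE)
  }
  fs <- frame_signal(signal, frame_ms = frame_ms, hop_ms = hop_ms)
  if (n_fft < fs$frame_length_samples) {
    stop("n_fft must be >= frame length", call. = FALSE)
  }
  spec <- stft_frames(fs$frames, n_fft)
  k_bins <- n_fft %/% 2L + 1L
  ## mirror the one-sided noise profile onto the full FFT grid
  prof <- noise$mean_magnitude
  full_prof <- c(prof, rev(prof[2:(k_bins - 1L)]))
  mag <- Mod(spec)
  new_mag <- pmax(mag - full_prof, 0)
  scale <- ifelse(mag > 0, new_mag / mag, 0)
  spec_hat <- spec * scale
  ## overlap-add with phase reuse; normalise by the summed analysis window
  frames_t <- Re(stats::mvfft(spec_hat, inverse = TRUE)) / n_fft
  hop <- fs$hop_samples
  n_frames <- ncol(frames_t)
  out_len <- length(signal$samples)
  acc <- numeric(out_len + n_fft)
  den <- numeric(out_len + n_fft)
  wpad <- c(fs$window, numeric(n_fft - fs$frame_length_samples))
  for (j in seq_len(n_frames)) {
    pos <- (j - 1L) * hop
    rng <- (pos + 1L):(pos + n_fft)
    acc[rng] <- acc[rng] + frames_t[, j]
    den[rng] <- den[rng] + wpad
  }
  acc <- acc[seq_len(out_len)]
  den <- den[seq_len(out_len)]
  covered <- den > 1e-8
  y <- signal$samples        # uncovered tail samples pass through unchanged
  y[covered] <- acc[covered] / den[covered]
  audio_signal(y, signal$sample_rate_hz)
}
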