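## Frame-level acoustic features used by the endpoint detector, and the
## Mel-spectrogram representation used by the classifier.
##
## Snoring frames, relative to background, show elevated short-time energy,
## low spectral entropy (compact spectrum), low zero-crossing rate (smooth
## waveform) and low spectral centroid (energy in the low-to-mid bands).

#' Short-time energy of one frame
#'
#' Sum of squared samples, `E = sum(x(n)^2)`.
#'
#' @param frame numeric vector (non-empty).
#' @return non-negative scalar.
#' @export
short_time_energy <- function(frame) {
  if (length(frame) < 1L) stop("empty frame", call. = FALSE)
  sum(frame^2)
}

#' Spectral entropy of one frame
#'
#' Shannon entropy (natural log) of the normalised one-sided power spectrum:
#' `H = -sum(P(k) * log(P(k) + eps))` with `P(k) = |X(k)|^2 / sum |X(k)|^2`.
#' An all-zero frame has no spectrum; by convention it maps to the
#' maximum-entropy value `log(K)` so the detector's voting stage stays total
#' (silence is maximally uninformative, and is excluded by a validity flag
#' downstream).
#'
#' @param frame numeric vector (non-empty).
#' @param eps small positive constant guarding the logarithm.
#' @param n_fft FFT length; defaults to the next power of two >= frame length.
#' @return entropy in nats, in `[0, log(K)]` with `K = n_fft/2 + 1`.
#' @export
spectral_entropy <- function(frame, eps = 1e-10, n_fft = NULL) {
  if (length(frame) < 1L) stop("empty frame", call. = FALSE)
  stopifnot(eps > 0)
  if (is.null(n_fft)) n_fft <- next_pow2(length(frame))
  k_bins <- n_fft %/% 2L + 1L
  p <- Mod(stats::fft(c(frame, numeric(n_fft - length(frame)))))[seq_len(k_bins)]^2
  tot <- sum(p)
  if (tot == 0) return(log(k_bins))
  p <- p / tot
  -sum(p * log(p + eps))
}

#' Zero-crossing rate of one frame
#'
#' `ZCR = 1/(2N) * sum |sgn(x(n)) - sgn(x(n-1))|` over the N-1 successive
#' sample pairs, with the convention `sgn(0) = +1`. Lies in `[0, 1]`.
#'
#' @param frame numeric vector of length >= 2.
#' @return scalar in `[0, 1]`.
#' @export
zero_crossing_rate <- function(frame) {
  n <- length(frame)
  if (n < 2L) stop("zero_crossing_rate needs a frame of length >= 2",
                   call. = FALSE)
  s <- ifelse(frame >= 0, 1, -1)
  sum(abs(diff(s))) / (2 * n)
}

#' Spectral centroid of one frame
#'
#' Magnitude-weighted mean frequency over the one-sided spectrum,
#' `C = sum(f * |X(f)|) / sum |X(f)|`, in Hz. An all-zero frame returns 0 by
#' convention (flagged invalid in [compute_feature_table()]).
#'
#' @param frame numeric vector (non-empty).
#' @param sample_rate_hz sample rate in Hz.
#' @param n_fft FFT length; defaults to the next power of two >= frame length.
#' @return centroid in Hz, in `[0, Nyquist]`.
#' @export
spectral_centroid <- function(frame, sample_rate_hz, n_fft = NULL) {
  if (length(frame) < 1L) stop("empty frame", call. = FALSE)
  if (is.null(n_fft)) n_fft <- next_pow2(length(frame))
  k_bins <- n_fft %/% 2L + 1L
  mag <- Mod(stats::fft(c(frame, numeric(n_fft - length(frame)))))[seq_len(k_bins)]
  tot <- sum(mag)
  if (tot == 0) return(0)
  freqs <- (seq_len(k_bins) - 1L) * sample_rate_hz / n_fft
  sum(freqs * mag) / tot
}

#' Compute the per-frame feature table
#'
#' Vectorised computation of the four detector features for every frame of a
#' [frame_signal()] result. All-zero frames get the degenerate-value
#' conventions (E = 0, ZCR = 0, H = log K, C = 0) and `valid = FALSE`.
#'
#' @param frames a `frame_sequence`.
#' @param eps entropy guard constant.
#' @param n_fft FFT length; defaults to next power of two >= frame length.
#' @return a `data.frame` of class `frame_features` with columns
#'   `frame_time_s`, `energy`, `entropy`, `zcr`, `centroid`, `valid`.
#' @export
compute_feature_table <- function(frames, eps = 1e-10, n_fft = NULL) {
  stopifnot(inherits(frames, "frame_sequence"))
  f <- frames$frames
  if (ncol(f) < 1L) stop("no frames", call. = FALSE)
  n_len <- nrow(f)
  if (is.null(n_fft)) n_fft <- next_pow2(n_len)
  energy <- colSums(f^2)
  s <- matrix(1, nrow(f), ncol(f))
  s[f < 0] <- -1
  zcr <- colSums(abs(s[-1L, , drop = FALSE] - s[-n_len, , drop = FALSE])) /
    (2 * n_len)
  spec <- stft_frames(f, n_fft)
  k_bins <- n_fft %/% 2L + 1L
  mag <- Mod(spec[seq_len(k_bins), , drop = FALSE])
  pow <- mag^2
  tot_pow <- colSums(pow)
  valid <- tot_pow > 0
  p_norm <- sweep(pow, 2L, ifelse(valid, tot_pow, 1), `/`)
  entropy <- -colSums(p_norm * log(p_norm + eps))
  entropy[!valid] <- log(k_bins)
  freqs <- (seq_len(k_bins) - 1L) * frames$sample_rate_hz / n_fft
  tot_mag <- colSums(mag)
  centroid <- ifelse(tot_mag > 0, colSums(freqs * mag) / tot_mag, 0)
  structure(
    data.frame(frame_time_s = frames$frame_start_times_s,
               energy = energy, entropy = entropy, zcr = zcr,
               centroid = centroid, valid = valid),
    class = c("frame_features", "data.frame"),
    frame_length_samples = frames$frame_length_samples,
    hop_samples = frames$hop_samples,
    sample_rate_hz = frames$sample_rate_hz
  )
}

#' Write a feature table to TSV
#' @param features a `frame_features` data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(features, path) {
  utils::write.table(features, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

## ---- Mel scale and Mel spectrograms ---------------------------------------

#' Hz to Mel conversion
#'
#' Two variants of the perceptual frequency warping are provided:
#' `"htk_standard"` is the conventional `2595 * log10(1 + f/700)`;
#' `"div100"` uses a denominator of 100, `2595 * log10(1 + f/100)`, which
#' compresses the scale far more aggressively towards low frequencies. Both
#' are strictly increasing; the default is the field-standard variant.
#'
#' @param f frequency in Hz (vectorised, must be >= 0).
#' @param variant `"htk_standard"` or `"div100"`.
#' @return Mel value(s).
#' @export
hz_to_mel <- function(f, variant = c("htk_standard", "div100")) {
  variant <- match.arg(variant)
  if (any(f < 0)) stop("frequencies must be non-negative", call. = FALSE)
  denom <- if (variant == "div100") 100 else 700
  2595 * log10(1 + f / denom)
}

#' Mel to Hz conversion (inverse of [hz_to_mel()])
#' @param m Mel value(s) (>= 0).
#' @inheritParams hz_to_mel
#' @return frequency in Hz.
#' @export
mel_to_hz <- function(m, variant = c("htk_standard", "div100")) {
  variant <- match.arg(variant)
  denom <- if (variant == "div100") 100 else 700
  denom * (10^(m / 2595) - 1)
}

#' Triangular Mel filterbank
#'
#' `n_mels` triangular filters with peaks equally spaced on the Mel scale
#' between 0 Hz and Nyquist, evaluated on the one-sided FFT bin frequencies.
#' With `norm = "none"` (default) each triangle peaks at 1 and, because
#' adjacent triangles are complementary in Mel, the per-bin coverage never
#' exceeds 1 whenever filters span at least one FFT bin - so total Mel-domain
#' energy never exceeds total spectral energy. (Filters narrower than a bin,
#' which arise under the heavily compressed `"div100"` scale, are anchored to
#' their nearest bin instead.) `norm = "area"` rescales each filter to unit
#' sum.
#'
#' @param n_mels number of filters.
#' @param n_fft FFT length.
#' @param sample_rate_hz sample rate in Hz.
#' @param variant Mel-scale variant, see [hz_to_mel()].
#' @param norm `"none"` or `"area"`.
#' @return `n_mels x (n_fft/2 + 1)` non-negative matrix.
#' @export
mel_filterbank <- function(n_mels, n_fft, sample_rate_hz,
                           variant = c("htk_standard", "div100"),
                           norm = c("none", "area")) {
  variant <- match.arg(variant)
  norm <- match.arg(norm)
  k_bins <- n_fft %/% 2L + 1L
  nyq <- sample_rate_hz / 2
  edges_hz <- mel_to_hz(seq(0, hz_to_mel(nyq, variant), length.out = n_mels + 2L),
                        variant)
  bin_hz <- (seq_len(k_bins) - 1L) * sample_rate_hz / n_fft
  fb <- matrix(0, n_mels, k_bins)
  for (m in seq_len(n_mels)) {
    lo <- edges_hz[m]; ce <- edges_hz[m + 1L]; hi <- edges_hz[m + 2L]
    up <- (bin_hz - lo) / max(ce - lo, .Machine$double.eps)
    down <- (hi - bin_hz) / max(hi - ce, .Machine$double.eps)
    fb[m, ] <- pmax(0, pmin(up, down))
    ## guard: very narrow filters can miss every bin centre; anchor at the
    ## nearest bin so no filter is all-zero
    if (all(fb[m, ] == 0)) {
      fb[m, which.min(abs(bin_hz - ce))] <- 1
    }
    if (norm == "area") fb[m, ] <- fb[m, ] / sum(fb[m, ])
  }
  fb
}

#' Log-Mel spectrogram of an audio clip
#'
#' STFT power (25 ms Hamming frames, 10 ms hop by default) pooled through a
#' triangular Mel filterbank, optionally log-compressed as `log(1 + S)`, and
#' resized along time to exactly `target_frames` columns: clips with more
#' frames are linearly interpolated down, clips with fewer are zero-padded on
#' the right. The 128 x 128 result is the classifier's input.
#'
#' @param clip an [audio_signal].
#' @param n_mels number of Mel bands (rows).
#' @param frame_ms,hop_ms STFT framing.
#' @param n_fft FFT length; defaults to next power of two >= frame length.
#' @param target_frames number of time columns after resizing.
#' @param log_scale apply `log1p` compression.
#' @param variant Mel-scale variant, see [hz_to_mel()].
#' @param clip_id,label optional clip metadata (`label` one of `"normal"`,
#'   `"osahs"`, `"unknown"`).
#' @return an object of class `mel_spectrogram` with fields `matrix`
#'   (`n_mels x target_frames`), `n_mels`, `clip_id`, `label`, `config`.
#' @export
mel_spectrogram <- function(clip, n_mels = 128L, frame_ms = 25, hop_ms = 10,
                            n_fft = NULL, target_frames = 128L,
                            log_scale = TRUE,
                            variant = c("htk_standard", "div100"),
                            clip_id = NA_character_, label = "unknown") {
  variant <- match.arg(variant)
  stopifnot(inherits(clip, "audio_signal"))
  label <- match.arg(label, c("normal", "osahs", "unknown"))
  fs <- frame_signal(clip, frame_ms = frame_ms, hop_ms = hop_ms)
  if (is.null(n_fft)) n_fft <- next_pow2(fs$frame_length_samples)
  spec <- stft_frames(fs$frames, n_fft)
  k_bins <- n_fft %/% 2L + 1L
  pow <- Mod(spec[seq_len(k_bins), , drop = FALSE])^2
  fb <- mel_filterbank(n_mels, n_fft, clip$sample_rate_hz, variant)
  mel <- fb %*% pow
  if (log_scale) mel <- log1p(mel)
  n_t <- ncol(mel)
  if (n_t == target_frames) {
    out <- mel
  } else if (n_t > target_frames) {
    at <- seq(1, n_t, length.out = target_frames)
    lo <- floor(at); hi <- pmin(lo + 1L, n_t); wts <- at - lo
    out <- mel[, lo, drop = FALSE] * rep(1 - wts, each = n_mels) +
      mel[, hi, drop = FALSE] * rep(wts, each = n_mels)
  } else {
    out <- cbind(mel, matrix(0, n_mels, target_frames - n_t))
  }
  structure(list(
    matrix = out, n_mels = n_mels, clip_id = clip_id, label = label,
    config = list(frame_ms = frame_ms, hop_ms = hop_ms, n_fft = n_fft,
                  target_frames = target_frames, log_scale = log_scale,
                  variant = variant, sample_rate_hz = clip$sample_rate_hz)
  ), class = "mel_spectrogram")
}

#' @export
print.mel_spectrogram <- function(x, ...) {
  cat(sprintf("<mel_spectrogram> %d x %d, label=%s, clip=%s\n",
              nrow(x$matrix), ncol(x$matrix), x$label, x$clip_id))
  invisible(x)
}
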