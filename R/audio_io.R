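#' Construct an audio signal object
#'
#' A mono waveform plus its sample rate. Samples are dimensionless amplitudes,
#' nominally in \[-1, 1\].
#'
#' @param samples numeric vector of finite amplitudes (length >= 1).
#' @param sample_rate_hz positive integer sample rate in Hz.
#' @return An object of class `audio_signal` with fields `samples` and
#'   `sample_rate_hz`.
#' @export
audio_signal <- function(samples, sample_rate_hz) {
  samples <- as.numeric(samples)
  if (length(samples) < 1L) {
    stop("audio_signal: 'samples' must have length >= 1", call. = FALSE)
  }
  if (!all(is.finite(samples))) {
    stop("audio_signal: all samples must be finite", call. = FALSE)
  }
  sample_rate_hz <- as.integer(sample_rate_hz)
  if (length(sample_rate_hz) != 1L || is.na(sample_rate_hz) || sample_rate_hz <= 0L) {
    stop("audio_signal: 'sample_rate_hz' must be a positive integer", call. = FALSE)
  }
  structure(list(samples = samples, sample_rate_hz = sample_rate_hz),
            class = "audio_signal")
}

#' @export
print.audio_signal <- function(x, ...) {
  dur <- length(x$samples) / x$sample_rate_hz
  cat(sprintf("<audio_signal> %d samples @ %d Hz (%.3f s), peak %.4f\n",
              length(x$samples), x$sample_rate_hz, dur,
              max(abs(x$samples))))
  invisible(x)
}

#' Duration of an audio signal in seconds
#' @param signal an `audio_signal`.
#' @return duration in seconds.
#' @export
duration_s <- function(signal) {
  stopifnot(inherits(signal, "audio_signal"))
  length(signal$samples) / signal$sample_rate_hz
}

## ---- WAV (RIFF) reading/writing -------------------------------------------
## Minimal RIFF/WAVE codec: PCM 16/24-bit integer and IEEE float32, any
## channel count on read; 16-bit PCM or float32 on write.

read_wav <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("cannot read WAV file '%s': no such file", path), call. = FALSE)
  }
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(riff, "RIFF")) {
    stop(sprintf("'%s' is not a RIFF/WAVE file", path), call. = FALSE)
  }
  invisible(readBin(con, "integer", 1L, size = 4L, endian = "little"))
  wave <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(wave, "WAVE")) {
    stop(sprintf("'%s' is not a RIFF/WAVE file", path), call. = FALSE)
  }
  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- readChar(con, 4L, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    sz <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    if (length(sz) == 0L) break
    if (identical(id, "fmt ")) {
      body <- readBin(con, "raw", sz)
      fmt <- list(
        format    = readBin(body[1:2], "integer", 1L, size = 2L,
                            endian = "little", signed = FALSE),
        channels  = readBin(body[3:4], "integer", 1L, size = 2L,
                            endian = "little", signed = FALSE),
        rate      = readBin(body[5:8], "integer", 1L, size = 4L,
                            endian = "little"),
        bits      = readBin(body[15:16], "integer", 1L, size = 2L,
                            endian = "little", signed = FALSE)
      )
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", sz)
    } else {
      invisible(readBin(con, "raw", sz))
    }
    if (sz %% 2L == 1L) invisible(readBin(con, "raw", 1L))  # chunk padding
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) {
    stop(sprintf("corrupt WAV file '%s': missing fmt/data chunk", path),
         call. = FALSE)
  }
  ## WAVE_FORMAT_EXTENSIBLE (0xFFFE) carries the real format in its extension;
  ## we accept it when bit depth disambiguates.
  x <- switch(as.character(fmt$format),
    "1" = , "65534" = {
      if (fmt$bits == 16L) {
        readBin(data_raw, "integer", length(data_raw) %/% 2L, size = 2L,
                endian = "little") / 32768
      } else if (fmt$bits == 24L) {
        n <- length(data_raw) %/% 3L
        b <- matrix(as.integer(data_raw[seq_len(3L * n)]), nrow = 3L)
        v <- b[1L, ] + 256L * b[2L, ] + 65536L * b[3L, ]
        v <- ifelse(v >= 8388608, v - 16777216, v)
        v / 8388608
      } else if (fmt$bits == 32L) {
        readBin(data_raw, "integer", length(data_raw) %/% 4L, size = 4L,
                endian = "little") / 2147483648
      } else {
        stop(sprintf("unsupported PCM bit depth %d in '%s'", fmt$bits, path),
             call. = FALSE)
      }
    },
    "3" = readBin(data_raw, "double", length(data_raw) %/% 4L, size = 4L,
                  endian = "little"),
    stop(sprintf("unsupported WAV format code %d in '%s'", fmt$format, path),
         call. = FALSE)
  )
  if (length(x) == 0L) {
    stop(sprintf("zero-length audio in '%s'", path), call. = FALSE)
  }
  nch <- max(1L, fmt$channels)
  if (nch > 1L) {
    n <- length(x) %/% nch
    x <- matrix(x[seq_len(n * nch)], nrow = nch)
  }
  list(samples = x, sample_rate_hz = fmt$rate, channels = nch)
}

#' Write an audio signal to a WAV file
#'
#' @param signal an `audio_signal`.
#' @param path output file path.
#' @param bits 16 (PCM) or 32 (IEEE float).
#' @return `path`, invisibly.
#' @export
write_wav <- function(signal, path, bits = 16L) {
  stopifnot(inherits(signal, "audio_signal"), bits %in% c(16L, 32L))
  x <- signal$samples
  n <- length(x)
  bytes_per <- bits / 8L
  data_size <- n * bytes_per
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_size), con, size = 4L, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4L, endian = "little")
  writeBin(if (bits == 16L) 1L else 3L, con, size = 2L, endian = "little")
  writeBin(1L, con, size = 2L, endian = "little")  # mono
  writeBin(as.integer(signal$sample_rate_hz), con, size = 4L, endian = "little")
  writeBin(as.integer(signal$sample_rate_hz * bytes_per), con, size = 4L,
           endian = "little")
  writeBin(as.integer(bytes_per), con, size = 2L, endian = "little")
  writeBin(as.integer(bits), con, size = 2L, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, size = 4L, endian = "little")
  if (bits == 16L) {
    q <- as.integer(round(pmax(pmin(x, 1 - 1 / 32768), -1) * 32768))
    writeBin(q, con, size = 2L, endian = "little")
  } else {
    writeBin(as.numeric(x), con, size = 4L, endian = "little")
  }
  invisible(path)
}

#' Load a WAV recording as a mono audio signal
#'
#' Multi-channel recordings are downmixed by channel averaging (the target
#' setting is a single ambient microphone). Optionally resamples to
#' `target_rate_hz` via polyphase resampling.
#'
#' @param path path to a WAV file (PCM 16/24-bit or float32).
#' @param target_rate_hz optional positive integer; when given and different
#'   from the file's rate, the signal is resampled.
#' @return an [audio_signal].
#' @export
load_audio <- function(path, target_rate_hz = NULL) {
  w <- read_wav(path)
  x <- if (is.matrix(w$samples)) colMeans(w$samples) else w$samples
  rate <- w$sample_rate_hz
  if (!is.null(target_rate_hz)) {
    target_rate_hz <- as.integer(target_rate_hz)
    stopifnot(target_rate_hz > 0L)
    if (target_rate_hz != rate) {
      g <- gcd_int(target_rate_hz, rate)
      x <- as.numeric(signal::resample(x, target_rate_hz / g, rate / g))
      rate <- target_rate_hz
    }
  }
  audio_signal(x, rate)
}

gcd_int <- function(a, b) {
  while (b != 0L) {
    t <- b
    b <- a %% b
    a <- t
  }
  a
}
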