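## AMFF-ED: adaptive multi-feature fusion endpoint detection.
##
## Per 2-minute analysis window, statistical thresholds are computed for the
## four frame features; frames vote on four inclusive threshold conditions
## (E >= T_E, H <= T_H, ZCR <= T_ZCR, C <= T_C) and frames with >= 3 votes
## are snore frames. Runs of snore frames become segments; segments closer
## than dt_gap merge and segments shorter than dt_min are discarded.

#' Detector configuration
#'
#' Defaults are the method's published constants: 2-minute analysis windows
#' with step equal to window length, energy threshold at the 10th percentile,
#' centroid threshold at the 75th percentile, entropy and zero-crossing-rate
#' thresholds at mean + 0.5 * sd, vote threshold 3 of 4, and 0.3 s gap-merge /
#' minimum-duration post-processing.
#'
#' @param analysis_window_s sliding-window length in seconds.
#' @param analysis_step_s sliding-window step in seconds.
#' @param vote_threshold minimum number of satisfied feature conditions
#'   (between 1 and the number of features used).
#' @param gap_s segments separated by less than this merge (seconds).
#' @param min_dur_s segments shorter than this are discarded (seconds).
#' @param energy_percentile percentile for the energy threshold.
#' @param centroid_percentile percentile for the centroid threshold.
#' @param spread_coeff multiplier of the standard deviation in the entropy
#'   and ZCR thresholds.
#' @param features_used subset of `c("energy", "entropy", "zcr", "centroid")`;
#'   restricting to `c("energy", "zcr")` with `vote_threshold = 2` gives the
#'   classical short-time-energy + ZCR baseline detector.
#' @param denoise apply spectral subtraction within each analysis window
#'   before feature extraction. Off by default: denoising is a property of
#'   the acoustic condition under study (raw vs. noise-reduced recordings),
#'   so it is applied explicitly, not silently inside the detector.
#' @return a list of class `detector_config`.
#' @export
detector_config <- function(analysis_window_s = 120, analysis_step_s = 120,
                            vote_threshold = 3L, gap_s = 0.3, min_dur_s = 0.3,
                            energy_percentile = 10, centroid_percentile = 75,
                            spread_coeff = 0.5,
                            features_used = c("energy", "entropy", "zcr",
                                              "centroid"),
                            denoise = FALSE) {
  features_used <- match.arg(features_used,
                             c("energy", "entropy", "zcr", "centroid"),
                             several.ok = TRUE)
  stopifnot(analysis_window_s > 0, analysis_step_s > 0,
            gap_s > 0, min_dur_s > 0,
            energy_percentile > 0, energy_percentile < 100,
            centroid_percentile > 0, centroid_percentile < 100,
            vote_threshold >= 1L, vote_threshold <= length(features_used))
  structure(list(
    analysis_window_s = analysis_window_s, analysis_step_s = analysis_step_s,
    vote_threshold = as.integer(vote_threshold), gap_s = gap_s,
    min_dur_s = min_dur_s, energy_percentile = energy_percentile,
    centroid_percentile = centroid_percentile, spread_coeff = spread_coeff,
    features_used = features_used, denoise = denoise
  ), class = "detector_config")
}

## population standard deviation (the thresholds are descriptive statistics
## of the window, not sample estimates)
pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' Per-window adaptive thresholds
#'
#' `T_E` = `energy_percentile`-th percentile of energy, `T_C` =
#' `centroid_percentile`-th percentile of centroid (linear-interpolation
#' percentiles), `T_H` and `T_ZCR` = mean + `spread_coeff` * population sd.
#'
#' @param features a `frame_features` table restricted to one analysis window
#'   (>= 2 frames).
#' @param config a [detector_config()].
#' @param window_index index of the analysis window (metadata).
#' @return a list of class `threshold_set` with `t_energy`, `t_entropy`,
#'   `t_zcr`, `t_centroid`, `window_index`.
#' @export
compute_thresholds <- function(features, config = detector_config(),
                               window_index = 0L) {
  stopifnot(inherits(features, "frame_features"))
  if (nrow(features) < 2L) {
    stop("compute_thresholds needs at least 2 frames", call. = FALSE)
  }
  structure(list(
    t_energy = unname(quantile(features$energy,
                               config$energy_percentile / 100, type = 7)),
    t_entropy = mean(features$entropy) +
      config$spread_coeff * pop_sd(features$entropy),
    t_zcr = mean(features$zcr) + config$spread_coeff * pop_sd(features$zcr),
    t_centroid = unname(quantile(features$centroid,
                                 config$centroid_percentile / 100, type = 7)),
    window_index = as.integer(window_index)
  ), class = "threshold_set")
}

#' Frame-level snore voting
#'
#' Each frame's vote count is the number of satisfied feature conditions
#' (inclusive comparisons): energy >= T_E, entropy <= T_H, ZCR <= T_ZCR,
#' centroid <= T_C, restricted to `config$features_used`. Frames flagged
#' invalid (all-zero) vote 0. The snore-frame mask is
#' `votes >= vote_threshold`.
#'
#' @param features a `frame_features` table.
#' @param thresholds a `threshold_set` computed on the same window.
#' @param config a [detector_config()].
#' @return list with integer `votes` and logical `mask`.
#' @export
frame_votes <- function(features, thresholds, config = detector_config()) {
  stopifnot(inherits(features, "frame_features"),
            inherits(thresholds, "threshold_set"))
  used <- config$features_used
  votes <- integer(nrow(features))
  if ("energy" %in% used)
    votes <- votes + (features$energy >= thresholds$t_energy)
  if ("entropy" %in% used)
    votes <- votes + (features$entropy <= thresholds$t_entropy)
  if ("zcr" %in% used)
    votes <- votes + (features$zcr <= thresholds$t_zcr)
  if ("centroid" %in% used)
    votes <- votes + (features$centroid <= thresholds$t_centroid)
  votes[!features$valid] <- 0L
  list(votes = as.integer(votes), mask = votes >= config$vote_threshold)
}

## ---- segment lists --------------------------------------------------------

#' Construct a segment list
#'
#' Ordered, pairwise-disjoint half-open time intervals `[t_start, t_end)`.
#'
#' @param t_start_s,t_end_s numeric vectors of interval bounds in seconds.
#' @param ... further per-segment columns (e.g. `label`, `mean_vote`).
#' @return a `data.frame` of class `segments`.
#' @export
segments <- function(t_start_s = numeric(0), t_end_s = numeric(0), ...) {
  df <- data.frame(t_start_s = as.numeric(t_start_s),
                   t_end_s = as.numeric(t_end_s), ...)
  if (nrow(df) > 0L && any(df$t_end_s <= df$t_start_s)) {
    stop("segments must satisfy t_end_s > t_start_s", call. = FALSE)
  }
  class(df) <- c("segments", "data.frame")
  df
}

is_sorted_disjoint <- function(segs) {
  n <- nrow(segs)
  n <= 1L || all(segs$t_start_s[-1L] >= segs$t_end_s[-n])
}

#' Convert a frame mask to raw segments
#'
#' Each maximal run of TRUE frames becomes the half-open interval
#' `[time(first), time(last) + frame_len_s)`. Because frames overlap (frame
#' length > hop), intervals of runs separated by very few frames can overlap
#' in time; such intervals are unioned so the result is always disjoint.
#'
#' @param mask logical vector of snore frames.
#' @param frame_times_s frame start times (same length as `mask`).
#' @param frame_len_s frame length in seconds.
#' @param votes optional per-frame vote counts; reported as `mean_vote`.
#' @return a `segments` data frame with `n_frames` (and `mean_vote`) columns.
#' @export
runs_to_segments <- function(mask, frame_times_s, frame_len_s, votes = NULL) {
  stopifnot(length(mask) == length(frame_times_s))
  if (!any(mask)) {
    return(segments(numeric(0), numeric(0), n_frames = integer(0),
                    mean_vote = numeric(0)))
  }
  r <- rle(as.logical(mask))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  first <- starts[keep]
  last <- ends[keep]
  t_start <- frame_times_s[first]
  t_end <- frame_times_s[last] + frame_len_s
  ## union time-overlapping run intervals
  k <- length(first)
  grp <- cumsum(c(1L, as.integer(t_start[-1L] >= t_end[-k])))
  g_first <- which(!duplicated(grp))
  g_last <- c(g_first[-1L] - 1L, k)
  mv <- vapply(seq_along(g_first), function(i) {
    fr <- unlist(lapply(g_first[i]:g_last[i], function(j) first[j]:last[j]))
    if (is.null(votes)) NA_real_ else mean(votes[fr])
  }, numeric(1))
  nf <- vapply(seq_along(g_first), function(i) {
    sum(last[g_first[i]:g_last[i]] - first[g_first[i]:g_last[i]] + 1L)
  }, integer(1))
  segments(t_start[g_first], t_end[g_last], n_frames = nf, mean_vote = mv)
}

#' Merge segments separated by short gaps
#'
#' Consecutive segments whose inter-gap is strictly less than `gap_s` are
#' unioned into one continuous segment. Idempotent.
#'
#' @param segs a sorted, disjoint `segments` data frame.
#' @param gap_s gap threshold in seconds.
#' @return a `segments` data frame.
#' @export
merge_gaps <- function(segs, gap_s) {
  stopifnot(inherits(segs, "segments"))
  if (!is_sorted_disjoint(segs)) {
    stop("merge_gaps requires a sorted, disjoint segment list", call. = FALSE)
  }
  n <- nrow(segs)
  if (n <= 1L) return(segs)
  gaps <- segs$t_start_s[-1L] - segs$t_end_s[-n]
  grp <- cumsum(c(1L, as.integer(gaps >= gap_s)))
  first <- which(!duplicated(grp))
  last <- c(first[-1L] - 1L, n)
  out <- segments(segs$t_start_s[first], segs$t_end_s[last])
  if ("n_frames" %in% names(segs)) {
    out$n_frames <- vapply(seq_along(first),
                           function(i) sum(segs$n_frames[first[i]:last[i]]),
                           integer(1))
  }
  if ("mean_vote" %in% names(segs)) {
    out$mean_vote <- vapply(seq_along(first), function(i) {
      idx <- first[i]:last[i]
      if ("n_frames" %in% names(segs)) {
        sum(segs$mean_vote[idx] * segs$n_frames[idx]) / sum(segs$n_frames[idx])
      } else {
        mean(segs$mean_vote[idx])
      }
    }, numeric(1))
  }
  out
}

#' Discard segments shorter than a minimum duration
#'
#' Keeps exactly the segments with `t_end_s - t_start_s >= min_dur_s`
#' (inclusive boundary).
#'
#' @param segs a sorted `segments` data frame.
#' @param min_dur_s minimum duration in seconds.
#' @return a `segments` data frame.
#' @export
filter_short <- function(segs, min_dur_s) {
  stopifnot(inherits(segs, "segments"))
  keep <- (segs$t_end_s - segs$t_start_s) >= min_dur_s
  out <- segs[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("segments", "data.frame")
  out
}

#' Detect snore segments in a recording
#'
#' Runs the full endpoint-detection pipeline: the recording is processed in
#' `analysis_window_s` windows (window length = step). Within each window the
#' signal is optionally denoised by spectral subtraction (noise spectrum
#' estimated from that window's lowest-energy frames), framed (25 ms / 10 ms
#' Hamming), featurised, thresholded and voted. The per-window snore-frame
#' masks are concatenated over the whole recording before gap merging and
#' minimum-duration filtering, so events straddling a window boundary are
#' preserved. Segment times are absolute seconds on the original timeline.
#'
#' @param signal an [audio_signal] (at least one frame long).
#' @param config a [detector_config()].
#' @param preprocess a [preprocess_config()].
#' @return a `segments` data frame with columns `t_start_s`, `t_end_s`,
#'   `n_frames`, `mean_vote`.
#' @export
detect_snores <- function(signal, config = detector_config(),
                          preprocess = preprocess_config()) {
  stopifnot(inherits(signal, "audio_signal"))
  rate <- signal$sample_rate_hz
  n_len <- as.integer(round(preprocess$frame_ms / 1000 * rate))
  if (length(signal$samples) < n_len) {
    stop("signal shorter than one frame", call. = FALSE)
  }
  win_n <- as.integer(round(config$analysis_window_s * rate))
  step_n <- as.integer(round(config$analysis_step_s * rate))
  starts <- seq(1L, length(signal$samples), by = step_n)
  n_fft <- next_pow2(n_len)
  all_mask <- logical(0)
  all_votes <- integer(0)
  all_times <- numeric(0)
  for (wi in seq_along(starts)) {
    lo <- starts[wi]
    hi <- min(lo + win_n - 1L, length(signal$samples))
    if (hi - lo + 1L < n_len) next
    wsig <- audio_signal(signal$samples[lo:hi], rate)
    if (config$denoise) {
      np <- estimate_noise_spectrum(
        wsig, n_fft = n_fft, frame_ms = preprocess$frame_ms,
        hop_ms = preprocess$hop_ms, method = preprocess$noise_method,
        fraction = preprocess$noise_fraction,
        leading_s = preprocess$noise_leading_s)
      wsig <- spectral_subtract(wsig, np, n_fft = n_fft,
                                frame_ms = preprocess$frame_ms,
                                hop_ms = preprocess$hop_ms)
    }
    fs <- frame_signal(wsig, frame_ms = preprocess$frame_ms,
                       hop_ms = preprocess$hop_ms,
                       t0_s = (lo - 1L) / rate)
    feats <- compute_feature_table(fs, n_fft = n_fft)
    if (nrow(feats) < 2L) next
    th <- compute_thresholds(feats, config, window_index = wi)
    fv <- frame_votes(feats, th, config)
    all_mask <- c(all_mask, fv$mask)
    all_votes <- c(all_votes, fv$votes)
    all_times <- c(all_times, feats$frame_time_s)
  }
  raw <- runs_to_segments(all_mask, all_times, n_len / rate, all_votes)
  out <- filter_short(merge_gaps(raw, config$gap_s), config$min_dur_s)
  attr(out, "config") <- config
  out
}

#' Write segments as TSV (optionally Audacity label format)
#'
#' @param segs a `segments` data frame.
#' @param path output path.
#' @param format `"tsv"` (header + duration column) or `"audacity"`
#'   (tab-separated start, end, label; no header).
#' @return `path`, invisibly.
#' @export
write_segments <- function(segs, path, format = c("tsv", "audacity")) {
  format <- match.arg(format)
  if (format == "tsv") {
    df <- data.frame(t_start_s = segs$t_start_s, t_end_s = segs$t_end_s,
                     duration_s = segs$t_end_s - segs$t_start_s)
    if ("mean_vote" %in% names(segs)) df$mean_vote <- segs$mean_vote
    if ("label" %in% names(segs)) df$label <- segs$label
    utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  } else {
    lab <- if ("label" %in% names(segs)) segs$label else "snore"
    utils::write.table(
      data.frame(segs$t_start_s, segs$t_end_s, lab), path, sep = "\t",
      row.names = FALSE, col.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Read a segment TSV (as written by [write_segments()])
#'
#' Accepts both the headered TSV and the Audacity label format.
#'
#' @param path input path.
#' @return a `segments` data frame.
#' @export
read_segments <- function(path) {
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) return(segments())
  has_header <- grepl("t_start_s", first, fixed = TRUE)
  df <- utils::read.table(path, sep = "\t", header = has_header,
                          stringsAsFactors = FALSE)
  if (!has_header) {
    names(df)[1:2] <- c("t_start_s", "t_end_s")
    if (ncol(df) >= 3L) names(df)[3L] <- "label"
  }
  if (!all(c("t_start_s", "t_end_s") %in% names(df)) ||
      !is.numeric(df$t_start_s) || !is.numeric(df$t_end_s)) {
    stop(sprintf(
      "'%s' is not a segment table (need numeric t_start_s/t_end_s)", path),
      call. = FALSE)
  }
  do.call(segments, df[, c("t_start_s", "t_end_s",
                           intersect("label", names(df))), drop = FALSE])
}
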