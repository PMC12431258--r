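## Evaluation: endpoint-detection accuracy (correct / total detections, with
## IoU-based event matching) and binary classification metrics.

interval_iou <- function(a_start, a_end, b_start, b_end) {
  inter <- pmax(0, pmin(a_end, b_end) - pmax(a_start, b_start))
  uni <- (a_end - a_start) + (b_end - b_start) - inter
  ifelse(uni > 0, inter / uni, 0)
}

#' Endpoint-detection accuracy
#'
#' A detection is correct when it overlaps a reference event with
#' IoU >= `iou_min`; each reference event matches at most one detection
#' (greedy, highest IoU first). Accuracy is the precision-style ratio
#' `100 * f_r / f_a` where `f_r` is the number of correct detections and
#' `f_a` the total number of detections. A companion recall,
#' `f_r / n_reference`, is reported as an extension.
#'
#' @param detected,reference sorted, disjoint `segments` data frames.
#' @param iou_min matching threshold.
#' @return an object of class `detection_eval`: `f_r`, `f_a`,
#'   `accuracy_pct` (`NA` when nothing was detected), `recall`,
#'   `matching_iou`, `n_reference`, `missed`.
#' @export
endpoint_accuracy <- function(detected, reference, iou_min = 0.3) {
  stopifnot(inherits(detected, "segments"), inherits(reference, "segments"))
  if (!is_sorted_disjoint(detected) || !is_sorted_disjoint(reference)) {
    stop("endpoint_accuracy requires sorted, disjoint segment lists",
         call. = FALSE)
  }
  f_a <- nrow(detected)
  n_ref <- nrow(reference)
  f_r <- 0L
  if (f_a > 0L && n_ref > 0L) {
    iou <- outer(seq_len(f_a), seq_len(n_ref), function(i, j) {
      interval_iou(detected$t_start_s[i], detected$t_end_s[i],
                   reference$t_start_s[j], reference$t_end_s[j])
    })
    repeat {
      best <- which.max(iou)
      if (iou[best] < iou_min || iou[best] == 0) break
      f_r <- f_r + 1L
      bi <- (best - 1L) %% f_a + 1L
      bj <- (best - 1L) %/% f_a + 1L
      iou[bi, ] <- -1
      iou[, bj] <- -1
    }
  }
  structure(list(
    f_r = f_r, f_a = f_a,
    accuracy_pct = if (f_a > 0L) 100 * f_r / f_a else NA_real_,
    recall = if (n_ref > 0L) f_r / n_ref else NA_real_,
    matching_iou = iou_min, n_reference = n_ref,
    missed = n_ref - f_r
  ), class = "detection_eval")
}

#' @export
print.detection_eval <- function(x, ...) {
  cat(sprintf(
    "<detection_eval> f_r=%d f_a=%d accuracy=%.1f%% recall=%.3f missed=%d (IoU>=%.2f)\n",
    x$f_r, x$f_a, x$accuracy_pct, x$recall, x$missed, x$matching_iou))
  invisible(x)
}

#' Binary classification metrics
#'
#' Standard confusion-matrix metrics with OSAHS (or the supplied
#' `positive_class`) as the positive class: accuracy, sensitivity
#' (recall of the positive class), specificity, and F1 (harmonic mean of
#' precision and sensitivity).
#'
#' @param predicted,truth equal-length label vectors over exactly two classes.
#' @param positive_class the positive label (default `"osahs"`).
#' @return an object of class `classification_eval`: `accuracy`,
#'   `sensitivity`, `specificity`, `f1`, `precision` and the 2x2 `confusion`
#'   matrix (rows = truth, cols = predicted).
#' @export
classification_metrics <- function(predicted, truth,
                                   positive_class = "osahs") {
  predicted <- as.character(predicted)
  truth <- as.character(truth)
  if (length(predicted) != length(truth)) {
    stop("predicted and truth must have equal length", call. = FALSE)
  }
  classes <- sort(unique(c(predicted, truth)))
  if (length(classes) > 2L) {
    stop("classification_metrics expects binary labels", call. = FALSE)
  }
  if (!positive_class %in% classes) {
    stop(sprintf("positive_class '%s' not among labels (%s)",
                 positive_class, paste(classes, collapse = ", ")),
         call. = FALSE)
  }
  pos <- positive_class
  tp <- sum(predicted == pos & truth == pos)
  fn <- sum(predicted != pos & truth == pos)
  fp <- sum(predicted == pos & truth != pos)
  tn <- sum(predicted != pos & truth != pos)
  n <- tp + fn + fp + tn
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  f1 <- if (!is.na(prec) && !is.na(sens) && prec + sens > 0) {
    2 * prec * sens / (prec + sens)
  } else NA_real_
  confusion <- matrix(c(tp, fn, fp, tn), 2L, 2L,
                      dimnames = list(truth = c(pos, paste0("not_", pos)),
                                      predicted = c(pos, paste0("not_", pos))))
  structure(list(
    accuracy = (tp + tn) / n, sensitivity = sens, specificity = spec,
    f1 = f1, precision = prec, confusion = confusion,
    positive_class = pos
  ), class = "classification_eval")
}

#' @export
print.classification_eval <- function(x, ...) {
  cat(sprintf(
    "<classification_eval> acc=%.4f sens=%.4f spec=%.4f F1=%.4f (positive=%s)\n",
    x$accuracy, x$sensitivity, x$specificity, x$f1, x$positive_class))
  print(x$confusion)
  invisible(x)
}
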