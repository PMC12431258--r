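## Training loop (stratified split, cross-entropy, Adam, early stopping) and
## inference for the snore classifier.

softmax_cols <- function(z) {
  z <- sweep(z, 2L, apply(z, 2L, max))
  e <- exp(z)
  sweep(e, 2L, colSums(e), `/`)
}

## cross-entropy loss + gradient; y: integer class index (1-based) per column
ce_loss <- function(logits, y) {
  p <- softmax_cols(logits)
  n <- ncol(logits)
  idx <- cbind(y, seq_len(n))
  p_true <- p[cbind(y, seq_len(n))]
  loss <- -mean(log(pmax(p_true, 1e-12)))
  dl <- p
  dl[idx] <- dl[idx] - 1
  list(loss = loss, dlogits = dl / n, probs = p)
}

## flatten nested parameter lists for the optimiser
flatten_params <- function(p, prefix = "") {
  out <- list()
  for (nm in names(p)) {
    v <- p[[nm]]
    key <- paste0(prefix, nm)
    if (is.list(v)) {
      out <- c(out, flatten_params(v, paste0(key, ".")))
    } else {
      out[[key]] <- v
    }
  }
  out
}

assign_flat <- function(p, flat) {
  for (key in names(flat)) {
    path <- strsplit(key, ".", fixed = TRUE)[[1L]]
    if (length(path) == 1L) {
      p[[path]] <- flat[[key]]
    } else {
      p[[path[1L]]][[path[2L]]] <- flat[[key]]
    }
  }
  p
}

adam_init <- function(flat) {
  list(m = lapply(flat, function(v) v * 0),
       v = lapply(flat, function(v) v * 0), t = 0L)
}

adam_step <- function(flat, grads_flat, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  b1t <- 1 - beta1^state$t
  b2t <- 1 - beta2^state$t
  for (key in names(flat)) {
    g <- grads_flat[[key]]
    if (is.null(g)) next
    state$m[[key]] <- beta1 * state$m[[key]] + (1 - beta1) * g
    state$v[[key]] <- beta2 * state$v[[key]] + (1 - beta2) * g^2
    flat[[key]] <- flat[[key]] -
      lr * (state$m[[key]] / b1t) / (sqrt(state$v[[key]] / b2t) + eps)
  }
  list(flat = flat, state = state)
}

#' Training configuration
#'
#' @param split_ratios training/validation/test fractions (sum to 1);
#'   default the 6:2:2 split.
#' @param max_epochs maximum training epochs.
#' @param batch_size minibatch size.
#' @param learning_rate Adam learning rate.
#' @param seed integer seed governing the split, shuffling and initial
#'   weights.
#' @param early_stop_patience epochs without validation-loss improvement
#'   before stopping.
#' @param target_train_acc optional early exit once training accuracy reaches
#'   this value (useful for smoke training on separable data).
#' @return a list of class `train_config`.
#' @export
train_config <- function(split_ratios = c(0.6, 0.2, 0.2), max_epochs = 30L,
                         batch_size = 16L, learning_rate = 1e-3, seed = 1L,
                         early_stop_patience = 10L, target_train_acc = NULL) {
  stopifnot(length(split_ratios) == 3L,
            abs(sum(split_ratios) - 1) < 1e-8, max_epochs >= 1L,
            batch_size >= 1L, learning_rate > 0)
  structure(list(split_ratios = split_ratios,
                 max_epochs = as.integer(max_epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, seed = as.integer(seed),
                 early_stop_patience = as.integer(early_stop_patience),
                 target_train_acc = target_train_acc),
            class = "train_config")
}

## dataset (list(spectrograms, labels)) -> x array (H, W, 1, N) + y ints
dataset_to_arrays <- function(dataset) {
  specs <- dataset$spectrograms
  labels <- as.character(dataset$labels)
  n <- length(specs)
  d1 <- dim(specs[[1L]]$matrix)
  x <- array(0, c(d1[1L], d1[2L], 1L, n))
  for (i in seq_len(n)) x[, , 1L, i] <- specs[[i]]$matrix
  classes <- sort(unique(labels))
  list(x = x, y = match(labels, classes), classes = classes)
}

stratified_split <- function(y, ratios) {
  idx_train <- integer(0)
  idx_val <- integer(0)
  idx_test <- integer(0)
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    n <- length(idx)
    n_tr <- round(ratios[1L] * n)
    n_va <- round(ratios[2L] * n)
    idx_train <- c(idx_train, idx[seq_len(n_tr)])
    idx_val <- c(idx_val, idx[n_tr + seq_len(min(n_va, n - n_tr))])
    if (n > n_tr + n_va) idx_test <- c(idx_test, idx[(n_tr + n_va + 1L):n])
  }
  list(train = sort(idx_train), val = sort(idx_val), test = sort(idx_test))
}

model_eval <- function(model, x, y, batch = 8L) {
  n <- dim(x)[4L]
  loss <- 0
  correct <- 0L
  for (start in seq(1L, n, by = batch)) {
    idx <- start:min(start + batch - 1L, n)
    out <- model_fwd(model, x[, , , idx, drop = FALSE], training = FALSE)
    l <- ce_loss(out$logits, y[idx])
    loss <- loss + l$loss * length(idx)
    correct <- correct + sum(apply(out$logits, 2L, which.max) == y[idx])
  }
  list(loss = loss / n, acc = correct / n)
}

#' Train the snore classifier
#'
#' Stratified 6:2:2 split, cross-entropy loss, Adam optimisation, per-epoch
#' accuracy/loss history, early stopping on validation loss, and return of
#' the best-validation checkpoint. Fully reproducible for a fixed
#' `tc$seed` (which also re-seeds the weight initialisation).
#'
#' @param model an untrained `snore_model` from [build_model()]; its
#'   parameters are re-initialised from `tc$seed` so that training is a pure
#'   function of `(dataset, config, seed)`.
#' @param dataset a list with `spectrograms` (list of [mel_spectrogram]) and
#'   `labels`, e.g. from [synth_spectrogram_dataset()].
#' @param tc a [train_config()].
#' @return the trained `snore_model`, with `history` (one row per epoch:
#'   epoch, train_loss, train_acc, val_loss, val_acc), `label_map`, `norm`,
#'   and `split` (the index sets used).
#' @export
train_model <- function(model, dataset, tc = train_config()) {
  stopifnot(inherits(model, "snore_model"), inherits(tc, "train_config"))
  da <- dataset_to_arrays(dataset)
  if (length(da$classes) < 2L) {
    stop("training needs at least two classes", call. = FALSE)
  }
  model <- build_model(model$config, seed = tc$seed)
  with_seed(tc$seed + 1L, {
    sp <- stratified_split(da$y, tc$split_ratios)
    mu <- mean(da$x[, , , sp$train])
    sdv <- stats::sd(da$x[, , , sp$train])
    if (sdv == 0) sdv <- 1
    x <- (da$x - mu) / sdv
    model$norm <- list(mean = mu, sd = sdv)
    model$label_map <- da$classes
    x_tr <- x[, , , sp$train, drop = FALSE]
    y_tr <- da$y[sp$train]
    x_va <- x[, , , sp$val, drop = FALSE]
    y_va <- da$y[sp$val]
    flat <- flatten_params(model$params)
    opt <- adam_init(flat)
    history <- NULL
    best <- list(loss = Inf, params = model$params, bn = model$bn_stats,
                 epoch = 0L)
    stale <- 0L
    for (epoch in seq_len(tc$max_epochs)) {
      ord <- sample(length(y_tr))
      ep_loss <- 0
      ep_correct <- 0L
      for (start in seq(1L, length(ord), by = tc$batch_size)) {
        bi <- ord[start:min(start + tc$batch_size - 1L, length(ord))]
        xb <- x_tr[, , , bi, drop = FALSE]
        yb <- y_tr[bi]
        out <- model_fwd(model, xb, training = TRUE)
        model$bn_stats <- out$bn_stats
        l <- ce_loss(out$logits, yb)
        grads <- model_bwd(model, l$dlogits, out$caches)
        st <- adam_step(flatten_params(model$params), flatten_params(grads),
                        opt, tc$learning_rate)
        opt <- st$state
        model$params <- assign_flat(model$params, st$flat)
        ep_loss <- ep_loss + l$loss * length(bi)
        ep_correct <- ep_correct +
          sum(apply(l$probs, 2L, which.max) == yb)
      }
      tr_loss <- ep_loss / length(y_tr)
      tr_acc <- ep_correct / length(y_tr)
      va <- if (length(y_va) > 0L) model_eval(model, x_va, y_va)
            else list(loss = NA_real_, acc = NA_real_)
      history <- rbind(history, data.frame(
        epoch = epoch, train_loss = tr_loss, train_acc = tr_acc,
        val_loss = va$loss, val_acc = va$acc))
      if (!is.na(va$loss) && va$loss < best$loss) {
        best <- list(loss = va$loss, params = model$params,
                     bn = model$bn_stats, epoch = epoch)
        stale <- 0L
      } else {
        stale <- stale + 1L
      }
      if (!is.null(tc$target_train_acc) && tr_acc >= tc$target_train_acc) {
        ## training-accuracy targeting: keep the final (target-achieving)
        ## parameters instead of rolling back to the best-validation epoch
        best$loss <- Inf
        break
      }
      if (!is.na(va$loss) && stale >= tc$early_stop_patience) break
    }
    if (is.finite(best$loss)) {
      model$params <- best$params
      model$bn_stats <- best$bn
    }
    ## recalibrate batch-norm running statistics on the training set so that
    ## eval-mode inference matches the fitted weights even after very short
    ## trainings (the 0.1-momentum EMA lags badly in a handful of batches);
    ## a 0.5-momentum sweep converges to the training-set statistics fast
    for (pass in 1:3) {
      for (start in seq(1L, length(y_tr), by = tc$batch_size)) {
        bi <- start:min(start + tc$batch_size - 1L, length(y_tr))
        out <- model_fwd(model, x_tr[, , , bi, drop = FALSE],
                         training = TRUE, momentum = 0.5)
        model$bn_stats <- out$bn_stats
      }
    }
    model$history <- history
    model$split <- sp
    model$train_config <- tc
    model
  })
}

#' Classify Mel spectrograms with a trained model
#'
#' @param model a trained `snore_model`.
#' @param mels a single [mel_spectrogram] or a list of them.
#' @return a `data.frame` with one row per clip: `clip_id`, `label`
#'   (predicted), and one probability column per class (softmax, summing
#'   to 1).
#' @export
predict_model <- function(model, mels) {
  stopifnot(inherits(model, "snore_model"))
  if (is.null(model$label_map)) {
    stop("model has not been trained", call. = FALSE)
  }
  if (inherits(mels, "mel_spectrogram")) mels <- list(mels)
  d1 <- dim(mels[[1L]]$matrix)
  expect <- model$config$input_shape
  if (d1[1L] != expect[2L] || d1[2L] != expect[3L]) {
    stop(sprintf("spectrogram shape %dx%d does not match model input %dx%d",
                 d1[1L], d1[2L], expect[2L], expect[3L]), call. = FALSE)
  }
  n <- length(mels)
  x <- array(0, c(d1[1L], d1[2L], 1L, n))
  for (i in seq_len(n)) x[, , 1L, i] <- mels[[i]]$matrix
  x <- (x - model$norm$mean) / model$norm$sd
  logits <- matrix(0, model$config$n_classes, n)
  for (start in seq(1L, n, by = 8L)) {
    idx <- start:min(start + 7L, n)
    logits[, idx] <- model_fwd(model, x[, , , idx, drop = FALSE],
                               training = FALSE)$logits
  }
  probs <- t(softmax_cols(logits))
  colnames(probs) <- paste0("p_", model$label_map)
  data.frame(
    clip_id = vapply(mels, function(m) as.character(m$clip_id), character(1)),
    label = model$label_map[apply(probs, 1L, which.max)],
    probs,
    stringsAsFactors = FALSE
  )
}

#' Detect and classify snore events in a recording
#'
#' Convenience pipeline: run [detect_snores()], cut each detected segment,
#' compute its 128x128 log-Mel spectrogram and classify it.
#'
#' @param model a trained `snore_model`.
#' @param signal an [audio_signal].
#' @param detector a [detector_config()].
#' @return a `data.frame` with segment times, predicted label and class
#'   probabilities.
#' @export
classify_recording <- function(model, signal, detector = detector_config()) {
  segs <- detect_snores(signal, detector)
  if (nrow(segs) == 0L) {
    return(data.frame(t_start_s = numeric(0), t_end_s = numeric(0),
                      label = character(0)))
  }
  rate <- signal$sample_rate_hz
  mels <- lapply(seq_len(nrow(segs)), function(i) {
    i0 <- max(1L, round(segs$t_start_s[i] * rate) + 1L)
    i1 <- min(length(signal$samples), round(segs$t_end_s[i] * rate))
    mel_spectrogram(audio_signal(signal$samples[i0:i1], rate),
                    clip_id = sprintf("seg_%03d", i))
  })
  pred <- predict_model(model, mels)
  cbind(segs[, c("t_start_s", "t_end_s")], pred[, -1L, drop = FALSE])
}

#' Save / load a trained model as an RDS-free checkpoint directory
#'
#' The checkpoint is a directory with `params.bin` (raw doubles), a JSON
#' manifest of parameter shapes, the model configuration and the label map.
#'
#' @param model a `snore_model`.
#' @param path checkpoint directory.
#' @return `path` invisibly (`save_model`); a `snore_model` (`load_model`).
#' @export
save_model <- function(model, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  flat <- flatten_params(model$params)
  shapes <- lapply(flat, function(v) if (is.null(dim(v))) length(v) else dim(v))
  con <- file(file.path(path, "params.bin"), "wb")
  for (v in flat) writeBin(as.numeric(v), con, size = 8L)
  close(con)
  bn_flat <- flatten_params(model$bn_stats)
  con <- file(file.path(path, "bn.bin"), "wb")
  for (v in bn_flat) writeBin(as.numeric(v), con, size = 8L)
  close(con)
  manifest <- list(shapes = shapes,
                   bn_shapes = lapply(bn_flat, length),
                   config = unclass(model$config),
                   label_map = model$label_map,
                   norm = model$norm)
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  manifest <- jsonlite::read_json(file.path(path, "manifest.json"),
                                  simplifyVector = TRUE)
  cfg <- do.call(model_config, manifest$config[
    c("backbone", "eca_stages", "use_bigru", "bigru_hidden", "bigru_layers",
      "n_classes", "eca_gamma", "eca_b", "input_shape")])
  model <- build_model(cfg)
  con <- file(file.path(path, "params.bin"), "rb")
  flat <- list()
  for (key in names(manifest$shapes)) {
    sh <- manifest$shapes[[key]]
    n <- prod(sh)
    v <- readBin(con, "double", n, size = 8L)
    if (length(sh) > 1L) dim(v) <- sh
    flat[[key]] <- v
  }
  close(con)
  model$params <- assign_flat(model$params, flat)
  con <- file(file.path(path, "bn.bin"), "rb")
  bn_flat <- list()
  for (key in names(manifest$bn_shapes)) {
    bn_flat[[key]] <- readBin(con, "double", manifest$bn_shapes[[key]],
                              size = 8L)
  }
  close(con)
  model$bn_stats <- assign_flat(model$bn_stats, bn_flat)
  model$label_map <- manifest$label_map
  model$norm <- manifest$norm
  model
}
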