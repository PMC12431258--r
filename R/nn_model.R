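## The snore classifier: a ResNet backbone for single-channel 128x128
## log-Mel spectrograms, efficient channel attention inside the residual
## blocks of the configured stages, and a bidirectional GRU head over the
## final feature map unfolded along its time (width) axis. All Table-style
## ablation variants (plain ResNet18, ResNet18+BiGRU, ECA-ResNet18,
## ECA-ResNet34+BiGRU, full model) are reachable purely by configuration.

STAGE_NAMES <- c("conv2_x", "conv3_x", "conv4_x", "conv5_x")
STAGE_CHANNELS <- c(64L, 128L, 256L, 512L)

#' Classifier architecture configuration
#'
#' @param backbone `"resnet18"` (2-2-2-2 basic blocks) or `"resnet34"`
#'   (3-4-6-3).
#' @param eca_stages character subset of `c("conv2_x","conv3_x","conv4_x",
#'   "conv5_x")` receiving efficient channel attention inside each residual
#'   block (after the second convolution's batch norm, before the residual
#'   addition); default the two deepest stages. `character(0)` disables ECA.
#' @param use_bigru attach the bidirectional GRU temporal head; when `FALSE`
#'   the head is global average pooling + linear, i.e. a plain ResNet
#'   classifier.
#' @param bigru_hidden hidden state width per direction.
#' @param bigru_layers number of stacked BiGRU layers (1 supported).
#' @param n_classes number of output classes.
#' @param eca_gamma,eca_b kernel-size adaptation hyperparameters for
#'   [eca_kernel_size()].
#' @param input_shape `(channels, height, width)` of the input spectrogram.
#' @return a list of class `model_config`.
#' @export
model_config <- function(backbone = c("resnet18", "resnet34"),
                         eca_stages = c("conv4_x", "conv5_x"),
                         use_bigru = TRUE, bigru_hidden = 128L,
                         bigru_layers = 1L, n_classes = 2L,
                         eca_gamma = 2, eca_b = 1,
                         input_shape = c(1L, 128L, 128L)) {
  backbone <- match.arg(backbone)
  if (length(eca_stages) > 0L) {
    eca_stages <- match.arg(eca_stages, STAGE_NAMES, several.ok = TRUE)
  }
  stopifnot(bigru_hidden >= 1L, bigru_layers == 1L, n_classes >= 2L,
            eca_gamma > 0, length(input_shape) == 3L)
  structure(list(
    backbone = backbone, eca_stages = eca_stages, use_bigru = use_bigru,
    bigru_hidden = as.integer(bigru_hidden),
    bigru_layers = as.integer(bigru_layers),
    n_classes = as.integer(n_classes), eca_gamma = eca_gamma, eca_b = eca_b,
    input_shape = as.integer(input_shape)
  ), class = "model_config")
}

blocks_per_stage <- function(backbone) {
  if (backbone == "resnet18") c(2L, 2L, 2L, 2L) else c(3L, 4L, 6L, 3L)
}

he_conv <- function(kh, kw, cin, cout) {
  array(stats::rnorm(kh * kw * cin * cout) * sqrt(2 / (kh * kw * cin)),
        c(kh, kw, cin, cout))
}

#' Build an untrained classifier
#'
#' Allocates and initialises all parameters for the configured architecture
#' (He-normal convolutions, unit-gamma batch norms, uniform GRU gates). The
#' first convolution accepts single-channel input; no pretraining is used.
#'
#' @param config a [model_config()].
#' @param seed integer seed for the parameter initialisation.
#' @return a list of class `snore_model` with `params`, `bn_stats`, `config`,
#'   `label_map`.
#' @export
build_model <- function(config = model_config(), seed = 1L) {
  stopifnot(inherits(config, "model_config"))
  with_seed(seed, {
    p <- list()
    bn <- list()
    add_bn <- function(name, c_out) {
      p[[paste0(name, "_g")]] <<- rep(1, c_out)
      p[[paste0(name, "_b")]] <<- rep(0, c_out)
      bn[[name]] <<- list(mean = rep(0, c_out), var = rep(1, c_out))
    }
    c_in0 <- config$input_shape[1L]
    p$conv1_w <- he_conv(7L, 7L, c_in0, 64L)
    add_bn("bn1", 64L)
    nb <- blocks_per_stage(config$backbone)
    c_in <- 64L
    for (s in seq_len(4L)) {
      c_out <- STAGE_CHANNELS[s]
      for (b in seq_len(nb[s])) {
        pre <- sprintf("s%d_b%d_", s, b)
        stride <- if (s > 1L && b == 1L) 2L else 1L
        p[[paste0(pre, "conv1_w")]] <- he_conv(3L, 3L, c_in, c_out)
        add_bn(paste0(pre, "bn1"), c_out)
        p[[paste0(pre, "conv2_w")]] <- he_conv(3L, 3L, c_out, c_out)
        add_bn(paste0(pre, "bn2"), c_out)
        if (stride != 1L || c_in != c_out) {
          p[[paste0(pre, "down_w")]] <- he_conv(1L, 1L, c_in, c_out)
          add_bn(paste0(pre, "downbn"), c_out)
        }
        if (STAGE_NAMES[s] %in% config$eca_stages) {
          k <- eca_kernel_size(c_out, config$eca_gamma, config$eca_b)
          p[[paste0(pre, "eca_w")]] <- stats::rnorm(k) * sqrt(2 / k)
        }
        c_in <- c_out
      }
    }
    if (config$use_bigru) {
      h_spatial <- config$input_shape[2L] %/% 32L   # final feature-map height
      d_in <- 512L * h_spatial
      p$gru_f <- new_gru_params(d_in, config$bigru_hidden)
      p$gru_b <- new_gru_params(d_in, config$bigru_hidden)
      d_head <- 2L * config$bigru_hidden
    } else {
      d_head <- 512L
    }
    p$fc_w <- matrix(stats::rnorm(config$n_classes * d_head) *
                       sqrt(2 / d_head), config$n_classes, d_head)
    p$fc_b <- numeric(config$n_classes)
    structure(list(params = p, bn_stats = bn, config = config,
                   label_map = NULL, norm = NULL),
              class = "snore_model")
  })
}

#' @export
print.snore_model <- function(x, ...) {
  cat(sprintf(
    "<snore_model> %s%s%s, %d classes, %s parameters%s\n",
    if (length(x$config$eca_stages)) "ECA-" else "",
    x$config$backbone,
    if (x$config$use_bigru) "+BiGRU" else "",
    x$config$n_classes,
    format(n_params(x), big.mark = ","),
    if (is.null(x$label_map)) " (untrained)" else ""))
  invisible(x)
}

#' Total number of trainable parameters
#' @param model a `snore_model`.
#' @return integer count.
#' @export
n_params <- function(model) {
  cnt <- function(v) if (is.list(v)) sum(vapply(v, cnt, numeric(1))) else length(v)
  sum(vapply(model$params, cnt, numeric(1)))
}

## ---- forward / backward ---------------------------------------------------

## one basic residual block; returns output + cache when training
block_fwd <- function(x, p, bn, pre, stride, training, momentum = 0.1) {
  cache <- list(x = x)
  w1 <- p[[paste0(pre, "conv1_w")]]
  out <- conv2d_fwd(x, w1, stride, 1L)
  b1 <- bn_fwd(out, p[[paste0(pre, "bn1_g")]], p[[paste0(pre, "bn1_b")]],
               bn[[paste0(pre, "bn1")]]$mean, bn[[paste0(pre, "bn1")]]$var,
               training, momentum)
  cache$conv1_in <- x; cache$conv1_out <- out; cache$bn1 <- b1
  a1 <- relu_fwd(b1$y)
  cache$a1 <- a1
  out2 <- conv2d_fwd(a1, p[[paste0(pre, "conv2_w")]], 1L, 1L)
  b2 <- bn_fwd(out2, p[[paste0(pre, "bn2_g")]], p[[paste0(pre, "bn2_b")]],
               bn[[paste0(pre, "bn2")]]$mean, bn[[paste0(pre, "bn2")]]$var,
               training, momentum)
  cache$conv2_out <- out2; cache$bn2 <- b2
  main <- b2$y
  eca_name <- paste0(pre, "eca_w")
  if (!is.null(p[[eca_name]])) {
    ec <- eca_fwd_batch(main, p[[eca_name]])
    cache$eca_in <- main
    cache$eca <- ec
    main <- ec$y
  }
  if (!is.null(p[[paste0(pre, "down_w")]])) {
    sc_conv <- conv2d_fwd(x, p[[paste0(pre, "down_w")]], stride, 0L)
    bd <- bn_fwd(sc_conv, p[[paste0(pre, "downbn_g")]],
                 p[[paste0(pre, "downbn_b")]],
                 bn[[paste0(pre, "downbn")]]$mean,
                 bn[[paste0(pre, "downbn")]]$var, training, momentum)
    cache$down_out <- sc_conv; cache$downbn <- bd
    shortcut <- bd$y
  } else {
    shortcut <- x
  }
  s <- main + shortcut
  cache$sum <- s
  list(y = relu_fwd(s), cache = cache)
}

block_bwd <- function(dy, p, pre, stride, cache, grads) {
  ds <- relu_bwd(dy, cache$sum)
  d_main <- ds
  d_short <- ds
  if (!is.null(cache$downbn)) {
    bb <- bn_bwd(d_short, cache$downbn, p[[paste0(pre, "downbn_g")]])
    grads[[paste0(pre, "downbn_g")]] <- bb$dgamma
    grads[[paste0(pre, "downbn_b")]] <- bb$dbeta
    cb <- conv2d_bwd(cache$x, p[[paste0(pre, "down_w")]], bb$dx, stride, 0L)
    grads[[paste0(pre, "down_w")]] <- cb$dw
    dx_short <- cb$dx
  } else {
    dx_short <- d_short
  }
  if (!is.null(cache$eca)) {
    eb <- eca_bwd_batch(d_main, cache$eca_in, p[[paste0(pre, "eca_w")]],
                        cache$eca)
    grads[[paste0(pre, "eca_w")]] <- eb$dwt
    d_main <- eb$dx
  }
  b2 <- bn_bwd(d_main, cache$bn2, p[[paste0(pre, "bn2_g")]])
  grads[[paste0(pre, "bn2_g")]] <- b2$dgamma
  grads[[paste0(pre, "bn2_b")]] <- b2$dbeta
  c2 <- conv2d_bwd(cache$a1, p[[paste0(pre, "conv2_w")]], b2$dx, 1L, 1L)
  grads[[paste0(pre, "conv2_w")]] <- c2$dw
  da1 <- relu_bwd(c2$dx, cache$bn1$y)
  b1 <- bn_bwd(da1, cache$bn1, p[[paste0(pre, "bn1_g")]])
  grads[[paste0(pre, "bn1_g")]] <- b1$dgamma
  grads[[paste0(pre, "bn1_b")]] <- b1$dbeta
  c1 <- conv2d_bwd(cache$x, p[[paste0(pre, "conv1_w")]], b1$dx, stride, 1L)
  grads[[paste0(pre, "conv1_w")]] <- c1$dw
  list(dx = c1$dx + dx_short, grads = grads)
}

## full forward; x: (H, W, C, N). Returns logits (n_classes x N) and, when
## training, the caches needed for model_bwd. bn_stats are updated in
## training mode and returned.
model_fwd <- function(model, x, training = FALSE, momentum = 0.1) {
  p <- model$params
  bn <- model$bn_stats
  cfg <- model$config
  caches <- list()
  out <- conv2d_fwd(x, p$conv1_w, 2L, 3L)
  b1 <- bn_fwd(out, p$bn1_g, p$bn1_b, bn$bn1$mean, bn$bn1$var, training,
               momentum)
  if (training) {
    bn$bn1$mean <- b1$run_mean; bn$bn1$var <- b1$run_var
  }
  caches$conv1_in <- x; caches$conv1_out <- out; caches$bn1 <- b1
  a <- relu_fwd(b1$y)
  caches$a0 <- a
  mp <- maxpool_fwd(a, 3L, 2L, 1L)
  caches$pool_in_dim <- dim(a); caches$pool <- mp
  a <- mp$y
  nb <- blocks_per_stage(cfg$backbone)
  for (s in seq_len(4L)) {
    for (b in seq_len(nb[s])) {
      pre <- sprintf("s%d_b%d_", s, b)
      stride <- if (s > 1L && b == 1L) 2L else 1L
      res <- block_fwd(a, p, bn, pre, stride, training, momentum)
      if (training) {
        for (nm in c("bn1", "bn2", "downbn")) {
          cc <- res$cache[[nm]]
          if (!is.null(cc)) {
            bn[[paste0(pre, nm)]]$mean <- cc$run_mean
            bn[[paste0(pre, nm)]]$var <- cc$run_var
          }
        }
      }
      caches[[pre]] <- res$cache
      a <- res$y
    }
  }
  d <- dim(a)                                   # (H', W', 512, N)
  caches$feat_dim <- d
  if (cfg$use_bigru) {
    ## unfold along time (width): T = W', feature = H' * C
    x_seq <- aperm(a, c(1L, 3L, 4L, 2L))        # (H', C, N, W')
    dim(x_seq) <- c(d[1L] * d[3L], d[4L], d[2L])
    fw <- gru_seq_fwd(x_seq, p$gru_f)
    x_rev <- x_seq[, , rev(seq_len(d[2L])), drop = FALSE]
    bw <- gru_seq_fwd(x_rev, p$gru_b)
    h_last_f <- matrix(fw$hs[, , d[2L]], cfg$bigru_hidden, d[4L])
    h_last_b <- matrix(bw$hs[, , d[2L]], cfg$bigru_hidden, d[4L])
    feat <- rbind(h_last_f, h_last_b)
    caches$gru <- list(x_seq = x_seq, fw = fw, bw = bw)
  } else {
    a3 <- a
    dim(a3) <- c(d[1L] * d[2L] * 1L, d[3L] * d[4L])
    ## global average pool over H', W' per (C, N)
    x3 <- a
    dim(x3) <- c(d[1L] * d[2L], d[3L], d[4L])
    feat <- matrix(colMeans(x3), d[3L], d[4L])
    caches$gap_in_dim <- d
  }
  caches$head_in <- feat
  logits <- linear_fwd(feat, p$fc_w, p$fc_b)
  list(logits = logits, caches = caches, bn_stats = bn)
}

model_bwd <- function(model, dlogits, caches) {
  p <- model$params
  cfg <- model$config
  grads <- list()
  lb <- linear_bwd(dlogits, caches$head_in, p$fc_w)
  grads$fc_w <- lb$dw
  grads$fc_b <- lb$db
  d <- caches$feat_dim
  if (cfg$use_bigru) {
    h <- cfg$bigru_hidden
    T_len <- d[2L]
    n_b <- d[4L]
    dh_f <- array(0, c(h, n_b, T_len))
    dh_b <- array(0, c(h, n_b, T_len))
    dh_f[, , T_len] <- lb$dx[seq_len(h), , drop = FALSE]
    dh_b[, , T_len] <- lb$dx[h + seq_len(h), , drop = FALSE]
    gf <- gru_seq_bwd(dh_f, p$gru_f, caches$gru$fw)
    gb <- gru_seq_bwd(dh_b, p$gru_b, caches$gru$bw)
    grads$gru_f <- gf$grads
    grads$gru_b <- gb$grads
    dx_seq <- gf$dx_seq + gb$dx_seq[, , rev(seq_len(T_len)), drop = FALSE]
    dim(dx_seq) <- c(d[1L], d[3L], d[4L], d[2L])  # (H', C, N, W')
    da <- aperm(dx_seq, c(1L, 4L, 2L, 3L))        # (H', W', C, N)
  } else {
    hw <- d[1L] * d[2L]
    da <- array(rep(as.vector(lb$dx) / hw, each = hw), d)
  }
  nb <- blocks_per_stage(cfg$backbone)
  for (s in rev(seq_len(4L))) {
    for (b in rev(seq_len(nb[s]))) {
      pre <- sprintf("s%d_b%d_", s, b)
      stride <- if (s > 1L && b == 1L) 2L else 1L
      res <- block_bwd(da, p, pre, stride, caches[[pre]], grads)
      grads <- res$grads
      da <- res$dx
    }
  }
  da <- maxpool_bwd(caches$pool$idx, da, caches$pool_in_dim)
  da <- relu_bwd(da, caches$bn1$y)
  b1 <- bn_bwd(da, caches$bn1, p$bn1_g)
  grads$bn1_g <- b1$dgamma
  grads$bn1_b <- b1$dbeta
  c1 <- conv2d_bwd(caches$conv1_in, p$conv1_w, b1$dx, 2L, 3L)
  grads$conv1_w <- c1$dw
  grads
}
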