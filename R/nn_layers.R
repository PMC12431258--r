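## Neural-network layer primitives (forward + backward) used by the snore
## classifier. Activations are column-major arrays with dim (H, W, C, N);
## convolution and max-pooling run through the Rcpp kernels in src/.

## channel index vector for broadcasting per-channel quantities over (H,W,C,N)
channel_index <- function(dims) {
  rep(rep(seq_len(dims[3L]), each = dims[1L] * dims[2L]), dims[4L])
}

## per-(channel, sample) index for broadcasting (C,N) matrices over (H,W,C,N)
cn_index <- function(dims) {
  rep(seq_len(dims[3L] * dims[4L]), each = dims[1L] * dims[2L])
}

## ---- batch normalisation --------------------------------------------------

bn_fwd <- function(x, gamma, beta, run_mean, run_var, training,
                   momentum = 0.1, eps = 1e-5) {
  d <- dim(x)
  hw <- d[1L] * d[2L]
  x3 <- x
  dim(x3) <- c(hw, d[3L], d[4L])
  if (training) {
    mu_cn <- colMeans(x3)                      # (C, N)
    mu <- rowMeans(matrix(mu_cn, d[3L], d[4L]))
    ex2 <- rowMeans(matrix(colMeans(x3^2), d[3L], d[4L]))
    v <- ex2 - mu^2
    run_mean <- (1 - momentum) * run_mean + momentum * mu
    run_var <- (1 - momentum) * run_var + momentum * v
  } else {
    mu <- run_mean
    v <- run_var
  }
  invstd <- 1 / sqrt(v + eps)
  ch <- channel_index(d)
  xhat <- (as.vector(x) - mu[ch]) * invstd[ch]
  y <- gamma[ch] * xhat + beta[ch]
  dim(y) <- d
  list(y = y, xhat = xhat, invstd = invstd, ch = ch,
       run_mean = run_mean, run_var = run_var)
}

bn_bwd <- function(dy, cache, gamma) {
  d <- dim(dy)
  hw <- d[1L] * d[2L]
  m <- hw * d[4L]                              # elements per channel
  ch <- cache$ch
  dyv <- as.vector(dy)
  per_channel_sum <- function(v) {
    v3 <- v
    dim(v3) <- c(hw, d[3L], d[4L])
    rowSums(matrix(colSums(v3), d[3L], d[4L]))
  }
  dgamma <- per_channel_sum(dyv * cache$xhat)
  dbeta <- per_channel_sum(dyv)
  dx <- (gamma[ch] * cache$invstd[ch]) *
    (dyv - dbeta[ch] / m - cache$xhat * (dgamma[ch] / m))
  dim(dx) <- d
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

## ---- ReLU -----------------------------------------------------------------

relu_fwd <- function(x) {
  y <- x
  y[y < 0] <- 0
  y
}

relu_bwd <- function(dy, x) {
  dy[x <= 0] <- 0
  dy
}

## ---- fully connected ------------------------------------------------------

linear_fwd <- function(x, w, b) {
  w %*% x + b
}

linear_bwd <- function(dy, x, w) {
  list(dx = crossprod(w, dy), dw = tcrossprod(dy, x), db = rowSums(dy))
}

## ---- efficient channel attention ------------------------------------------

#' Kernel size for efficient channel attention
#'
#' The 1-D convolution width adapts to the channel count:
#' `t = round(log2(C)/gamma + b)`, mapped to the nearest odd integer >= 1
#' (an even `t` is bumped up to `t + 1`).
#'
#' @param n_channels number of channels C (>= 1).
#' @param gamma,b adaptation hyperparameters (defaults 2 and 1, the original
#'   ECA settings).
#' @return an odd positive integer kernel width.
#' @export
eca_kernel_size <- function(n_channels, gamma = 2, b = 1) {
  if (n_channels < 1) stop("n_channels must be >= 1", call. = FALSE)
  stopifnot(gamma > 0)
  t <- round(abs(log2(n_channels) / gamma + b))
  k <- ifelse(t %% 2 == 1, t, t + 1)
  as.integer(max(1L, k))
}

## zero-padded same-size 1-D convolution along the rows of y (C x N)
conv1d_channels <- function(y, wt) {
  k <- length(wt)
  p <- (k - 1L) %/% 2L
  cdim <- nrow(y)
  a <- matrix(0, cdim, ncol(y))
  for (j in seq_len(k)) {
    off <- j - 1L - p
    src <- seq_len(cdim) + off
    ok <- src >= 1L & src <= cdim
    a[ok, ] <- a[ok, ] + wt[j] * y[src[ok], , drop = FALSE]
  }
  a
}

## transpose (correlation) of conv1d_channels, for gradients w.r.t. its input
conv1d_channels_t <- function(ds, wt) {
  conv1d_channels(ds, rev(wt))
}

#' Efficient channel attention forward pass
#'
#' Global average pooling per channel, a `k`-wide 1-D convolution across the
#' channel axis (zero-padded, no bias), a sigmoid, and channel-wise rescaling
#' of the input. Output shape equals input shape; all attention weights lie
#' strictly in (0, 1).
#'
#' @param feature_map array with dim `(C, H, W)`.
#' @param weights numeric vector of odd length `k` (the 1-D conv kernel).
#' @return array of the same shape as `feature_map`.
#' @export
eca_forward <- function(feature_map, weights) {
  d <- dim(feature_map)
  if (is.null(d) || length(d) != 3L) {
    stop("feature_map must be a (C, H, W) array", call. = FALSE)
  }
  if (length(weights) %% 2L == 0L) {
    stop("ECA kernel length must be odd", call. = FALSE)
  }
  x <- aperm(feature_map, c(2L, 3L, 1L))       # (H, W, C)
  dim(x) <- c(d[2L], d[3L], d[1L], 1L)
  out <- eca_fwd_batch(x, weights)$y
  dim(out) <- c(d[2L], d[3L], d[1L])
  aperm(out, c(3L, 1L, 2L))
}

## batched ECA on (H,W,C,N) activations
eca_fwd_batch <- function(x, wt) {
  d <- dim(x)
  hw <- d[1L] * d[2L]
  x3 <- x
  dim(x3) <- c(hw, d[3L], d[4L])
  gap <- colMeans(x3)                          # (C, N)
  if (is.null(dim(gap))) gap <- matrix(gap, d[3L], d[4L])
  a <- conv1d_channels(gap, wt)
  w <- 1 / (1 + exp(-a))
  idx <- cn_index(d)
  y <- as.vector(x) * as.vector(w)[idx]
  dim(y) <- d
  list(y = y, gap = gap, w = w, idx = idx)
}

eca_bwd_batch <- function(dy, x, wt, cache) {
  d <- dim(x)
  hw <- d[1L] * d[2L]
  wv <- as.vector(cache$w)[cache$idx]
  dx <- as.vector(dy) * wv
  ## gradient into the attention weights: sum over spatial positions of dy*x
  s <- as.vector(dy) * as.vector(x)
  dim(s) <- c(hw, d[3L], d[4L])
  dw_cn <- colSums(s)                          # (C, N)
  if (is.null(dim(dw_cn))) dw_cn <- matrix(dw_cn, d[3L], d[4L])
  da <- dw_cn * cache$w * (1 - cache$w)
  ## kernel gradient
  k <- length(wt)
  p <- (k - 1L) %/% 2L
  cdim <- d[3L]
  dwt <- numeric(k)
  for (j in seq_len(k)) {
    off <- j - 1L - p
    src <- seq_len(cdim) + off
    ok <- src >= 1L & src <= cdim
    dwt[j] <- sum(da[ok, , drop = FALSE] * cache$gap[src[ok], , drop = FALSE])
  }
  ## gradient into gap, then spread uniformly over H*W
  dgap <- conv1d_channels_t(da, wt) / hw       # (C, N)
  dx <- dx + as.vector(dgap)[cache$idx]
  dim(dx) <- d
  list(dx = dx, dwt = dwt)
}

## ---- gated recurrent unit --------------------------------------------------

sigmoid <- function(z) 1 / (1 + exp(-z))

new_gru_params <- function(d_in, h) {
  lim <- 1 / sqrt(h)
  rmat <- function(r, c) matrix(stats::runif(r * c, -lim, lim), r, c)
  list(Wz = rmat(h, d_in), Wr = rmat(h, d_in), Wn = rmat(h, d_in),
       Uz = rmat(h, h), Ur = rmat(h, h), Un = rmat(h, h),
       bz = numeric(h), br = numeric(h), bn = numeric(h))
}

## one direction over a sequence; x_seq: array (d, N, T); returns all hidden
## states (h, N, T) plus per-step caches for backpropagation through time
gru_seq_fwd <- function(x_seq, p) {
  d <- dim(x_seq)
  n_h <- nrow(p$Wz)
  n_batch <- d[2L]
  T_len <- d[3L]
  h <- matrix(0, n_h, n_batch)
  hs <- array(0, c(n_h, n_batch, T_len))
  caches <- vector("list", T_len)
  for (t in seq_len(T_len)) {
    x_t <- matrix(x_seq[, , t], d[1L], n_batch)
    z <- sigmoid(p$Wz %*% x_t + p$Uz %*% h + p$bz)
    r <- sigmoid(p$Wr %*% x_t + p$Ur %*% h + p$br)
    n_t <- tanh(p$Wn %*% x_t + p$Un %*% (r * h) + p$bn)
    h_new <- (1 - z) * h + z * n_t
    caches[[t]] <- list(x = x_t, h_prev = h, z = z, r = r, n = n_t)
    h <- h_new
    hs[, , t] <- h
  }
  list(hs = hs, caches = caches)
}

## BPTT; dhs: gradient w.r.t. each hidden state (h, N, T) (zeros allowed)
gru_seq_bwd <- function(dhs, p, fwd) {
  T_len <- dim(dhs)[3L]
  grads <- lapply(p, function(q) q * 0)
  dh <- matrix(0, nrow(p$Wz), ncol(fwd$caches[[1L]]$h_prev))
  dx_seq <- array(0, c(ncol(p$Wz), dim(dhs)[2L], T_len))
  for (t in rev(seq_len(T_len))) {
    cc <- fwd$caches[[t]]
    dh <- dh + matrix(dhs[, , t], nrow(dh), ncol(dh))
    dz <- dh * (cc$n - cc$h_prev)
    dn <- dh * cc$z
    dh_prev <- dh * (1 - cc$z)
    dn_pre <- dn * (1 - cc$n^2)
    grads$Wn <- grads$Wn + tcrossprod(dn_pre, cc$x)
    grads$Un <- grads$Un + tcrossprod(dn_pre, cc$r * cc$h_prev)
    grads$bn <- grads$bn + rowSums(dn_pre)
    drh <- crossprod(p$Un, dn_pre)
    dr <- drh * cc$h_prev
    dh_prev <- dh_prev + drh * cc$r
    dz_pre <- dz * cc$z * (1 - cc$z)
    dr_pre <- dr * cc$r * (1 - cc$r)
    grads$Wz <- grads$Wz + tcrossprod(dz_pre, cc$x)
    grads$Uz <- grads$Uz + tcrossprod(dz_pre, cc$h_prev)
    grads$bz <- grads$bz + rowSums(dz_pre)
    grads$Wr <- grads$Wr + tcrossprod(dr_pre, cc$x)
    grads$Ur <- grads$Ur + tcrossprod(dr_pre, cc$h_prev)
    grads$br <- grads$br + rowSums(dr_pre)
    dh_prev <- dh_prev + crossprod(p$Uz, dz_pre) + crossprod(p$Ur, dr_pre)
    dx_seq[, , t] <- crossprod(p$Wz, dz_pre) + crossprod(p$Wr, dr_pre) +
      crossprod(p$Wn, dn_pre)
    dh <- dh_prev
  }
  list(grads = grads, dx_seq = dx_seq)
}

#' Bidirectional GRU forward pass over one sequence
#'
#' Runs a gated-recurrent-unit layer forward (t = 1..T) and backward
#' (t = T..1) over the sequence and concatenates the two hidden states at
#' each step, `h_t = [h_t_fwd ; h_t_bwd]`.
#'
#' @param sequence `T x d` matrix of input feature vectors (one row per step).
#' @param params list with elements `forward` and `backward`, each a GRU
#'   parameter set as produced internally (gate matrices `Wz, Wr, Wn`
#'   `(h x d)`, recurrences `Uz, Ur, Un` `(h x h)`, biases `bz, br, bn`).
#' @return `T x 2h` matrix of concatenated hidden states.
#' @export
bigru_forward <- function(sequence, params) {
  if (!is.matrix(sequence) || nrow(sequence) < 1L) {
    stop("sequence must be a non-empty T x d matrix", call. = FALSE)
  }
  T_len <- nrow(sequence)
  d_in <- ncol(sequence)
  x_seq <- array(t(sequence), c(d_in, 1L, T_len))
  fw <- gru_seq_fwd(x_seq, params$forward)
  x_rev <- x_seq[, , rev(seq_len(T_len)), drop = FALSE]
  bw <- gru_seq_fwd(x_rev, params$backward)
  h_f <- t(matrix(fw$hs[, 1L, ], ncol = T_len))
  h_b <- t(matrix(bw$hs[, 1L, rev(seq_len(T_len))], ncol = T_len))
  cbind(h_f, h_b)
}
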