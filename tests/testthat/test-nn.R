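test_that("ECA kernel size follows the adaptive rule and is always odd", {
  expect_identical(eca_kernel_size(256, 2, 1), 5L)   # log2(256)/2+1 = 5
  expect_identical(eca_kernel_size(512, 2, 1), 7L)   # 5.5 -> 6 -> bump to 7
  k2 <- eca_kernel_size(2, 2, 1)
  expect_true(k2 >= 1L && k2 %% 2L == 1L)
  ks <- vapply(1:4096, eca_kernel_size, integer(1))
  expect_true(all(ks %% 2L == 1L))
  expect_true(all(ks >= 1L))
  expect_error(eca_kernel_size(0), ">= 1")
})

test_that("ECA forward: zero kernel halves the input, shape is preserved", {
  for (d in list(c(16L, 8L, 8L), c(64L, 4L, 4L), c(512L, 4L, 4L))) {
    x <- array(withr::with_seed(d[1], rnorm(prod(d))), d)
    k <- eca_kernel_size(d[1])
    out0 <- eca_forward(x, numeric(k))          # sigmoid(0) = 0.5
    expect_identical(dim(out0), d)
    expect_equal(out0, 0.5 * x, tolerance = 1e-12)
    out <- eca_forward(x, withr::with_seed(d[1] + 1, rnorm(k)))
    expect_identical(dim(out), dim(x))
    w_implied <- out / x
    expect_true(all(w_implied > 0 & w_implied < 1))
  }
  expect_error(eca_forward(array(1, c(4, 2, 2)), c(1, 2)), "odd")
})

test_that("ECA forward matches a scalar-loop oracle", {
  C <- 3L; H <- 2L; W <- 2L
  x <- array(withr::with_seed(5, rnorm(C * H * W)), c(C, H, W))
  wt <- c(0.3, -0.5, 0.8)
  got <- eca_forward(x, wt)
  # oracle: per-channel GAP, zero-padded width-3 conv, sigmoid, rescale
  gap <- numeric(C)
  for (c in 1:C) gap[c] <- mean(x[c, , ])
  att <- numeric(C)
  for (c in 1:C) {
    s <- 0
    for (j in -1:1) {
      cc <- c + j
      if (cc >= 1 && cc <= C) s <- s + wt[j + 2] * gap[cc]
    }
    att[c] <- 1 / (1 + exp(-s))
  }
  oracle <- x
  for (c in 1:C) oracle[c, , ] <- x[c, , ] * att[c]
  expect_equal(got, oracle, tolerance = 1e-6)
})

test_that("BiGRU handles the degenerate single-step sequence", {
  p <- list(forward = snorescreen:::new_gru_params(3, 4),
            backward = snorescreen:::new_gru_params(3, 4))
  x <- matrix(withr::with_seed(2, rnorm(3)), 1, 3)
  h <- bigru_forward(x, p)
  expect_identical(dim(h), c(1L, 8L))
  expect_true(all(abs(h) < 1))
})

test_that("reversing the sequence swaps the forward and backward GRU roles", {
  q <- withr::with_seed(3, snorescreen:::new_gru_params(2, 3))
  p <- list(forward = q, backward = q)        # shared weights
  x <- matrix(withr::with_seed(4, rnorm(10)), 5, 2)
  h <- bigru_forward(x, p)
  h_rev <- bigru_forward(x[5:1, , drop = FALSE], p)
  # forward states on x equal backward states on reversed x, row-aligned
  expect_equal(h[, 1:3], h_rev[5:1, 4:6], tolerance = 1e-12)
  expect_equal(h[, 4:6], h_rev[5:1, 1:3], tolerance = 1e-12)
})

test_that("the GRU matches a step-by-step scalar recurrence oracle", {
  d <- 2L; hdim <- 2L; T_len <- 3L
  p <- withr::with_seed(6, snorescreen:::new_gru_params(d, hdim))
  x <- matrix(withr::with_seed(7, rnorm(T_len * d)), T_len, d)
  got <- bigru_forward(x, list(forward = p, backward = p))
  sig <- function(z) 1 / (1 + exp(-z))
  h <- rep(0, hdim)
  fwd <- matrix(0, T_len, hdim)
  for (t in 1:T_len) {
    xt <- x[t, ]
    z <- sig(p$Wz %*% xt + p$Uz %*% h + p$bz)
    r <- sig(p$Wr %*% xt + p$Ur %*% h + p$br)
    nn <- tanh(p$Wn %*% xt + p$Un %*% (r * h) + p$bn)
    h <- as.vector((1 - z) * h + z * nn)
    fwd[t, ] <- h
  }
  expect_equal(got[, 1:hdim], fwd, tolerance = 1e-6)
  # hidden states are tanh-gated convex combinations, hence inside (-1, 1)
  big <- matrix(withr::with_seed(8, rnorm(40)), 20, 2) * 5
  hb <- bigru_forward(big, list(forward = p, backward = p))
  expect_true(all(abs(hb) < 1))
})

test_that("every ablation variant builds and produces two logits", {
  x <- array(withr::with_seed(9, rnorm(128 * 128)), c(128, 128, 1, 1))
  variants <- list(
    resnet18 = model_config(eca_stages = character(0), use_bigru = FALSE),
    resnet18_bigru = model_config(eca_stages = character(0), use_bigru = TRUE),
    eca_resnet18 = model_config(use_bigru = FALSE),
    eca_resnet34_bigru = model_config(backbone = "resnet34"),
    erbg_net = model_config())
  for (nm in names(variants)) {
    m <- build_model(variants[[nm]], seed = 1)
    lg <- snorescreen:::model_fwd(m, x)$logits
    expect_identical(dim(lg), c(2L, 1L))
    expect_true(all(is.finite(lg)))
  }
})

test_that("parameter counts: ECA adds exactly its kernel widths, BiGRU off gives plain ResNet18", {
  plain <- build_model(model_config(eca_stages = character(0),
                                    use_bigru = FALSE), seed = 1)
  eca <- build_model(model_config(use_bigru = FALSE), seed = 1)
  # conv4_x/conv5_x: 2 blocks each; k(256)=5, k(512)=7
  expect_identical(n_params(eca) - n_params(plain), 2 * 5 + 2 * 7)
  # plain ResNet18 hand count: conv1 + 4 stages of basic blocks + BN + fc
  convs <- 64 * 1 * 49 +
    (64 * 64 * 9 * 4) +
    (64 * 128 * 9 + 128 * 128 * 9 * 3 + 64 * 128) +
    (128 * 256 * 9 + 256 * 256 * 9 * 3 + 128 * 256) +
    (256 * 512 * 9 + 512 * 512 * 9 * 3 + 256 * 512)
  bns <- 2 * (64 + 64 * 4 + 128 * 4 + 128 + 256 * 4 + 256 + 512 * 4 + 512)
  fc <- 512 * 2 + 2
  expect_identical(n_params(plain), convs + bns + fc)
})
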