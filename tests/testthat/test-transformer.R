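make_rt <- function(c2 = 4L, dims = c(1L, 2L, 2L), M = 2L, H = 2L,
                    hidden = 12L, c3 = 8L, seed = 1) {
  set.seed(seed)
  res_trans_module(c2, dims, M = M, n_heads = H, hidden = hidden, c3 = c3)
}

test_that("serialization produces P = D2*H2*W2 tokens of width C3", {
  set.seed(1)
  rt <- res_trans_module(256L, c(4L, 16L, 16L), M = 1L, hidden = 8L)
  x <- array(rnorm(256 * 4 * 16 * 16), c(256, 4, 16, 16))
  ts <- token_serialize(rt, x)
  expect_equal(dim(ts$tokens), c(1024L, 512L))
  expect_equal(ts$dims, c(4L, 16L, 16L))
  expect_equal(ts$stage, "f")

  # degenerate flatten: a single spatial position gives a single token
  rt1 <- make_rt(dims = c(1L, 1L, 1L))
  x1 <- array(rnorm(4), c(4, 1, 1, 1))
  expect_equal(nrow(token_serialize(rt1, x1)$tokens), 1L)
})

test_that("position embedding is exact elementwise addition with shape checks", {
  rt <- make_rt()
  x <- array(rnorm(4 * 4), c(4, 1, 2, 2))
  f <- token_serialize(rt, x)
  z0 <- add_position_embedding(f, matrix(0, 4, 8))
  expect_equal(z0$tokens, f$tokens)
  expect_equal(z0$stage, "z0")
  pe <- matrix(rnorm(32), 4, 8)
  expect_equal(add_position_embedding(f, pe)$tokens, f$tokens + pe)
  expect_error(add_position_embedding(f, matrix(0, 5, 8)), "shape")

  # with distinct PE rows, permuting tokens does not commute with adding PE
  perm <- c(3, 1, 4, 2)
  before <- add_position_embedding(f$tokens[perm, ], pe)
  after <- add_position_embedding(f$tokens, pe)[perm, ]
  expect_false(isTRUE(all.equal(before, after)))
})

test_that("transformer layer has residual structure: zero projections give identity", {
  rt <- make_rt()
  ly <- rt$layers$tl1
  ly$params$Wo <- ly$params$Wo * 0; ly$params$bo <- ly$params$bo * 0
  ly$params$W2 <- ly$params$W2 * 0; ly$params$b2 <- ly$params$b2 * 0
  z <- matrix(rnorm(4 * 8), 4, 8)
  expect_equal(token_transformer_layer(rt, 1, z), z)
})

test_that("attention weights normalize and self-attention is permutation equivariant", {
  set.seed(7)
  ly <- gtvseg:::new_transformer_layer(8L, 2L, 12L)
  Z <- matrix(rnorm(8 * 6), 8, 6)          # 6 tokens as columns
  r <- gtvseg:::tl_fwd(ly, Z)
  expect_length(r$cache$A, 2L)             # one attention map per head
  for (A in r$cache$A) {
    expect_equal(dim(A), c(6L, 6L))
    expect_equal(rowSums(A), rep(1, 6), tolerance = 1e-12)
  }
  # permutation equivariance (no position embedding here)
  perm <- c(4, 2, 6, 1, 3, 5)
  out_perm <- gtvseg:::tl_fwd(ly, Z[, perm])$out
  expect_equal(out_perm, r$out[, perm], tolerance = 1e-10)

  expect_error(gtvseg:::new_transformer_layer(8L, 3L, 12L), "divisible")
})

test_that("single-head layer without LN matches the closed form on two tokens", {
  ly <- gtvseg:::new_transformer_layer(2L, 1L, 3L)
  ly$cfg$use_ln <- FALSE
  p <- ly$params
  Z <- cbind(c(1, 0), c(0, 2))             # two tokens as columns
  Q <- p$Wq %*% Z + p$bq; K <- p$Wk %*% Z + p$bk; V <- p$Wv %*% Z + p$bv
  S <- t(Q) %*% K / sqrt(2)
  A <- exp(S) / rowSums(exp(S))
  zs <- p$Wo %*% (V %*% t(A)) + p$bo + Z
  h1 <- p$W1 %*% zs + p$b1
  a1 <- ifelse(h1 > 0, h1, 0.01 * h1)
  zm <- p$W2 %*% a1 + p$b2 + zs
  expect_equal(gtvseg:::tl_fwd(ly, Z)$out, zm, tolerance = 1e-12)
})

test_that("serialize/deserialize round trip preserves the raster arrangement", {
  rt <- make_rt(c2 = 4L, dims = c(2L, 3L, 2L), c3 = 4L)
  # pin the in/out linear maps to the identity so positions are traceable
  rt$layers$conv_in$params$W <- diag(4)
  rt$layers$conv_in$params$b <- rep(0, 4)
  rt$layers$conv_out$params$W <- diag(4)
  rt$layers$conv_out$params$b <- rep(0, 4)
  d <- c(2L, 3L, 2L)
  x <- array(0, c(4, d))
  # channel 2 tags the (d, h, w) position; channels encode coordinates
  for (dd in 1:d[1]) for (hh in 1:d[2]) for (ww in 1:d[3])
    x[, dd, hh, ww] <- c(dd, hh, ww, 100 * dd + 10 * hh + ww)
  ts <- token_serialize(rt, x)
  # token order: depth fastest, then height, then width
  k <- 0
  for (ww in 1:d[3]) for (hh in 1:d[2]) for (dd in 1:d[1]) {
    k <- k + 1
    expect_equal(ts$tokens[k, ], c(dd, hh, ww, 100 * dd + 10 * hh + ww))
  }
  # identity transformer path: deserialize adds the residual, giving 2x
  out <- token_deserialize(rt, ts, x)
  expect_equal(out, 2 * x)
  expect_error(token_deserialize(rt, ts$tokens[1:5, , drop = FALSE], x), "token count")
})

test_that("the composed bottleneck maps stage-4 features to the stage-5 shape", {
  set.seed(9)
  blkA <- res_se_block_a(16L, 32L, "3D", stride = c(2L, 2L, 2L))
  rt <- res_trans_module(32L, c(2L, 4L, 4L), M = 1L, n_heads = 4L,
                         hidden = 16L, c3 = 32L)
  x <- fmap(matrix(rnorm(16 * 4 * 8 * 8), 16), 1L, c(4L, 8L, 8L))
  h <- module_forward(blkA, x)
  y <- module_forward(rt, h)
  expect_equal(nrow(y$x), 32L)
  expect_equal(y$dims, c(2L, 4L, 4L))
  expect_true(all(is.finite(y$x)))
  # configured-size contract: the wrong spatial size is rejected
  bad <- fmap(matrix(rnorm(32 * 1 * 4 * 4), 32), 1L, c(1L, 4L, 4L))
  expect_error(module_forward(rt, bad), "configured")
})

test_that("gradients reach the position embedding and every transformer layer", {
  set.seed(10)
  rt <- make_rt(c2 = 4L, dims = c(1L, 2L, 2L), M = 2L)
  x <- fmap(matrix(rnorm(4 * 4 * 2), 4), 2L, c(1L, 2L, 2L))
  r <- gtvseg:::module_fwd(rt, x, training = TRUE)
  dy <- r$out; dy$x <- matrix(rnorm(length(dy$x)), nrow(dy$x))
  gtvseg:::module_bwd(rt, dy, r$cache)
  expect_true(any(rt$layers$pe$grads$PE != 0))
  for (m in 1:2) {
    g <- rt$layers[[paste0("tl", m)]]$grads
    for (nm in c("Wq", "Wk", "Wv", "Wo", "W1", "W2"))
      expect_true(any(g[[nm]] != 0), info = sprintf("tl%d$%s", m, nm))
  }
  expect_true(any(rt$layers$conv_in$grads$W != 0))
  expect_true(any(rt$layers$conv_out$grads$W != 0))
})
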