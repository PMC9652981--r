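# Bottleneck global-attention module. The deepest feature map (C2 channels at
# D2 x H2 x W2) is linearly mapped to C3 channels by a 1x1x1 convolution,
# flattened into P = D2*H2*W2 tokens (depth fastest, then height, then width
# -- the same raster order as the fmap layout), augmented with a learnable
# position embedding, passed through M pre-norm transformer layers
#   z*_m = MSA(LN(z_{m-1})) + z_{m-1};   z_m = MLP(LN(z*_m)) + z*_m,
# unflattened in the same order, mapped back to C2 channels and added to the
# module input as a residual.
#
# Internally tokens are kept as columns (C3 x P); the exported token-sequence
# interface presents them in the conventional P x C3 row layout.

new_fc <- function(in_dim, out_dim, init_sd = NULL) {
  sd <- init_sd %||% sqrt(1 / in_dim)
  new_layer("fc", params = list(W = matrix(rnorm(out_dim * in_dim, 0, sd), out_dim, in_dim),
                                b = numeric(out_dim)),
            cfg = list(in_dim = in_dim, out_dim = out_dim))
}

new_pe <- function(c3, p, init_sd = 0.02) {
  new_layer("pe", params = list(PE = matrix(rnorm(c3 * p, 0, init_sd), c3, p)),
            cfg = list(c3 = c3, p = p))
}

new_transformer_layer <- function(c3, n_heads, hidden, slope = 0.01, eps = 1e-5) {
  if (c3 %% n_heads != 0)
    stop_gtv("token width C3 = %d must be divisible by the number of heads H = %d", c3, n_heads)
  sd_attn <- sqrt(1 / c3); sd_mlp1 <- sqrt(1 / c3); sd_mlp2 <- sqrt(1 / hidden)
  mk <- function(s) matrix(rnorm(c3 * c3, 0, s), c3, c3)
  new_layer("tl",
            params = list(ln1_g = rep(1, c3), ln1_b = rep(0, c3),
                          Wq = mk(sd_attn), bq = numeric(c3),
                          Wk = mk(sd_attn), bk = numeric(c3),
                          Wv = mk(sd_attn), bv = numeric(c3),
                          Wo = mk(sd_attn), bo = numeric(c3),
                          ln2_g = rep(1, c3), ln2_b = rep(0, c3),
                          W1 = matrix(rnorm(hidden * c3, 0, sd_mlp1), hidden, c3),
                          b1 = numeric(hidden),
                          W2 = matrix(rnorm(c3 * hidden, 0, sd_mlp2), c3, hidden),
                          b2 = numeric(c3)),
            cfg = list(c3 = c3, n_heads = n_heads, hidden = hidden,
                       slope = slope, eps = eps, use_ln = TRUE))
}

## ---- layer norm over channels, per token (column) --------------------------

ln_fwd <- function(x, g, b, eps) {
  C <- nrow(x)
  mu <- colMeans(x)
  xc <- x - rep(mu, each = C)
  v <- colMeans(xc * xc)
  invstd <- 1 / sqrt(v + eps)
  xhat <- xc * rep(invstd, each = C)
  list(y = xhat * g + b, xhat = xhat, invstd = invstd)
}

ln_bwd <- function(dy, g, cache) {
  C <- nrow(dy)
  xhat <- cache$xhat
  dxh <- dy * g
  dx <- rep(cache$invstd, each = C) *
    (dxh - rep(colMeans(dxh), each = C) - xhat * rep(colMeans(dxh * xhat), each = C))
  list(dx = dx, dg = rowSums(dy * xhat), db = rowSums(dy))
}

## ---- one transformer layer (tokens as columns, C3 x P) ---------------------

tl_fwd <- function(ly, Z) {
  p <- ly$params; cfg <- ly$cfg
  C3 <- cfg$c3; H <- cfg$n_heads; dh <- C3 %/% H
  scl <- 1 / sqrt(dh)

  if (cfg$use_ln) {
    l1 <- ln_fwd(Z, p$ln1_g, p$ln1_b, cfg$eps); Zn1 <- l1$y
  } else { l1 <- NULL; Zn1 <- Z }

  Q <- p$Wq %*% Zn1 + p$bq
  K <- p$Wk %*% Zn1 + p$bk
  V <- p$Wv %*% Zn1 + p$bv
  P <- ncol(Z)
  O <- matrix(0, C3, P)
  A_list <- vector("list", H)
  for (h in seq_len(H)) {
    idx <- ((h - 1) * dh + 1):(h * dh)
    S <- crossprod(Q[idx, , drop = FALSE], K[idx, , drop = FALSE]) * scl  # P x P
    S <- S - apply(S, 1, max)
    E <- exp(S)
    A <- E / rowSums(E)
    A_list[[h]] <- A
    O[idx, ] <- V[idx, , drop = FALSE] %*% t(A)
  }
  attn_out <- p$Wo %*% O + p$bo
  Zs <- attn_out + Z

  if (cfg$use_ln) {
    l2 <- ln_fwd(Zs, p$ln2_g, p$ln2_b, cfg$eps); Zn2 <- l2$y
  } else { l2 <- NULL; Zn2 <- Zs }

  h1 <- p$W1 %*% Zn2 + p$b1
  g1 <- cfg$slope + (1 - cfg$slope) * (h1 > 0)
  a1 <- h1 * g1
  Zout <- p$W2 %*% a1 + p$b2 + Zs

  list(out = Zout,
       cache = list(Z = Z, l1 = l1, Zn1 = Zn1, Q = Q, K = K, V = V, O = O,
                    A = A_list, Zs = Zs, l2 = l2, Zn2 = Zn2, g1 = g1, a1 = a1))
}

tl_bwd <- function(ly, dZout, cache, acc = FALSE) {
  p <- ly$params; cfg <- ly$cfg
  C3 <- cfg$c3; H <- cfg$n_heads; dh <- C3 %/% H
  scl <- 1 / sqrt(dh)
  g <- list()

  # MLP sub-block
  g$W2 <- dZout %*% t(cache$a1); g$b2 <- rowSums(dZout)
  da1 <- crossprod(p$W2, dZout)
  dh1 <- da1 * cache$g1
  g$W1 <- dh1 %*% t(cache$Zn2); g$b1 <- rowSums(dh1)
  dZn2 <- crossprod(p$W1, dh1)
  if (cfg$use_ln) {
    l <- ln_bwd(dZn2, p$ln2_g, cache$l2)
    dZs <- dZout + l$dx; g$ln2_g <- l$dg; g$ln2_b <- l$db
  } else {
    dZs <- dZout + dZn2
    g$ln2_g <- p$ln2_g * 0; g$ln2_b <- p$ln2_b * 0
  }

  # attention sub-block
  g$Wo <- dZs %*% t(cache$O); g$bo <- rowSums(dZs)
  dO <- crossprod(p$Wo, dZs)
  dQ <- matrix(0, C3, ncol(dZs)); dK <- dQ; dV <- dQ
  for (h in seq_len(H)) {
    idx <- ((h - 1) * dh + 1):(h * dh)
    A <- cache$A[[h]]
    dOh <- dO[idx, , drop = FALSE]
    Vh <- cache$V[idx, , drop = FALSE]
    dV[idx, ] <- dOh %*% A
    dA <- crossprod(dOh, Vh)                       # P x P
    dS <- A * (dA - rowSums(dA * A))
    dQ[idx, ] <- cache$K[idx, , drop = FALSE] %*% t(dS) * scl
    dK[idx, ] <- cache$Q[idx, , drop = FALSE] %*% dS * scl
  }
  g$Wq <- dQ %*% t(cache$Zn1); g$bq <- rowSums(dQ)
  g$Wk <- dK %*% t(cache$Zn1); g$bk <- rowSums(dK)
  g$Wv <- dV %*% t(cache$Zn1); g$bv <- rowSums(dV)
  dZn1 <- crossprod(p$Wq, dQ) + crossprod(p$Wk, dK) + crossprod(p$Wv, dV)
  if (cfg$use_ln) {
    l <- ln_bwd(dZn1, p$ln1_g, cache$l1)
    dZ <- dZs + l$dx; g$ln1_g <- l$dg; g$ln1_b <- l$db
  } else {
    dZ <- dZs + dZn1
    g$ln1_g <- p$ln1_g * 0; g$ln1_b <- p$ln1_b * 0
  }

  if (acc && !is.null(ly$grads)) {
    for (nm in names(g)) ly$grads[[nm]] <- ly$grads[[nm]] + g[[nm]]
  } else ly$grads <- g
  dZ
}

## ---- the full bottleneck module --------------------------------------------

#' Residual transformer bottleneck module
#'
#' Serializes a `c2 x D2 x H2 x W2` feature map into `P = D2*H2*W2` tokens of
#' width `c3`, adds a learnable position embedding, applies `M` pre-norm
#' multi-head self-attention layers, deserializes back to `c2` channels and
#' adds the module input (residual merge). The token count `P` is fixed at
#' construction; applying the module to a feature map with other spatial
#' dimensions is an error.
#'
#' @param c2 Input/output channel count (256 in the reference configuration).
#' @param dims Spatial dimensions `c(D2, H2, W2)` of the expected input.
#' @param M Number of transformer layers (default 4).
#' @param n_heads Number of attention heads H (default 8); must divide `c3`.
#' @param hidden MLP hidden width h (default 4096).
#' @param c3 Token width (default 512).
#' @return An `nn_module` of kind `"res_trans"`.
#' @export
res_trans_module <- function(c2, dims, M = 4L, n_heads = 8L, hidden = 4096L,
                             c3 = 512L) {
  dims <- as.integer(dims)
  p <- prod(dims)
  layers <- list(conv_in = new_fc(c2, c3), pe = new_pe(c3, p))
  for (m in seq_len(M)) layers[[paste0("tl", m)]] <- new_transformer_layer(c3, n_heads, hidden)
  layers$conv_out <- new_fc(c3, c2)
  new_module("res_trans", layers,
             cfg = list(c2 = c2, c3 = c3, dims = dims, M = as.integer(M),
                        n_heads = as.integer(n_heads), hidden = as.integer(hidden)))
}

rt_check_dims <- function(mod, dims) {
  if (!all(dims == mod$cfg$dims))
    stop_gtv("bottleneck was configured for a %s feature map but received %s",
             paste(mod$cfg$dims, collapse = "x"), paste(dims, collapse = "x"))
}

rt_fwd <- function(mod, fm, training) {
  cfg <- mod$cfg; ls <- mod$layers
  rt_check_dims(mod, fm$dims)
  if (nrow(fm$x) != cfg$c2)
    stop_gtv("bottleneck expects %d channels, got %d", cfg$c2, nrow(fm$x))
  P <- prod(fm$dims)
  f_all <- ls$conv_in$params$W %*% fm$x + ls$conv_in$params$b  # c3 x (N*P)
  out <- matrix(0, cfg$c2, ncol(fm$x))
  sample_caches <- vector("list", fm$n)
  Z_final <- vector("list", fm$n)
  for (i in seq_len(fm$n)) {
    blk <- ((i - 1) * P + 1):(i * P)
    Z <- f_all[, blk, drop = FALSE] + ls$pe$params$PE
    lc <- vector("list", cfg$M)
    for (m in seq_len(cfg$M)) {
      r <- tl_fwd(ls[[paste0("tl", m)]], Z)
      Z <- r$out; lc[[m]] <- r$cache
    }
    Z_final[[i]] <- Z
    out[, blk] <- ls$conv_out$params$W %*% Z + ls$conv_out$params$b
    sample_caches[[i]] <- lc
  }
  y <- fmap(out + fm$x, fm$n, fm$dims)
  list(out = y, cache = list(x = fm, P = P, sample_caches = sample_caches,
                             Z_final = Z_final))
}

rt_bwd <- function(mod, dy, cache) {
  cfg <- mod$cfg; ls <- mod$layers
  fm <- cache$x; P <- cache$P
  dx <- dy$x                                  # residual path
  d_fall <- matrix(0, cfg$c3, ncol(fm$x))
  gWout <- ls$conv_out$params$W * 0; gbout <- numeric(cfg$c2)
  gPE <- ls$pe$params$PE * 0
  for (i in seq_len(fm$n)) {
    blk <- ((i - 1) * P + 1):(i * P)
    dOut <- dy$x[, blk, drop = FALSE]
    gWout <- gWout + dOut %*% t(cache$Z_final[[i]])
    gbout <- gbout + rowSums(dOut)
    dZ <- crossprod(ls$conv_out$params$W, dOut)
    for (m in rev(seq_len(cfg$M)))
      dZ <- tl_bwd(ls[[paste0("tl", m)]], dZ, cache$sample_caches[[i]][[m]], acc = i > 1)
    gPE <- gPE + dZ
    d_fall[, blk] <- dZ
  }
  ls$conv_out$grads <- list(W = gWout, b = gbout)
  ls$pe$grads <- list(PE = gPE)
  ls$conv_in$grads <- list(W = d_fall %*% t(fm$x), b = rowSums(d_fall))
  dx <- dx + crossprod(ls$conv_in$params$W, d_fall)
  fmap(dx, fm$n, fm$dims)
}

## ---- exported token-sequence interface (single sample) ---------------------

new_token_seq <- function(tokens, dims, stage) {
  structure(list(tokens = tokens, dims = as.integer(dims), stage = stage),
            class = "token_seq")
}

#' Serialize a feature map into a token sequence
#'
#' Applies the module's 1x1x1 linear map (C2 to C3 channels) and flattens the
#' spatial dimensions in raster order (depth fastest, then height, then
#' width) into `P = D2*H2*W2` tokens.
#'
#' @param mod A module from [res_trans_module()].
#' @param x A `c2 x D2 x H2 x W2` array.
#' @return A `token_seq` (stage `"f"`) whose `tokens` field is `P x c3`.
#' @export
token_serialize <- function(mod, x) {
  d <- dim(x)
  rt_check_dims(mod, d[2:4])
  f <- mod$layers$conv_in$params$W %*% matrix(x, d[1]) + mod$layers$conv_in$params$b
  new_token_seq(t(f), d[2:4], "f")
}

#' Add a position embedding to a token sequence
#'
#' Elementwise addition `z0 = f + PE`. A shape mismatch between the tokens
#' and the embedding is a configuration error.
#'
#' @param f A `token_seq` (or bare `P x C3` matrix).
#' @param pe A `P x C3` matrix of position embeddings; defaults to the
#'   module's learnable embedding when `f` came from [token_serialize()] and
#'   `mod` is given.
#' @param mod Optionally, the [res_trans_module()] whose embedding to use.
#' @return A `token_seq` at stage `"z0"` (or a matrix if `f` was a matrix).
#' @export
add_position_embedding <- function(f, pe = NULL, mod = NULL) {
  tok <- if (inherits(f, "token_seq")) f$tokens else f
  if (is.null(pe)) {
    if (is.null(mod)) stop_gtv("either `pe` or `mod` must be supplied")
    pe <- t(mod$layers$pe$params$PE)
  }
  if (!all(dim(tok) == dim(pe)))
    stop_gtv("position embedding shape (%s) does not match token shape (%s)",
             paste(dim(pe), collapse = "x"), paste(dim(tok), collapse = "x"))
  z0 <- tok + pe
  if (inherits(f, "token_seq")) new_token_seq(z0, f$dims, "z0") else z0
}

#' Apply the m-th transformer layer of a bottleneck module
#'
#' @param mod A module from [res_trans_module()].
#' @param m Layer index in `1:M`.
#' @param z A `token_seq` or `P x C3` matrix.
#' @return The transformed tokens, same form as the input.
#' @export
token_transformer_layer <- function(mod, m, z) {
  tok <- if (inherits(z, "token_seq")) z$tokens else z
  out <- t(tl_fwd(mod$layers[[paste0("tl", m)]], t(tok))$out)
  if (inherits(z, "token_seq")) new_token_seq(out, z$dims, "z_m") else out
}

#' Deserialize a token sequence back to a feature map (residual merge)
#'
#' Unflattens in the same raster order used by [token_serialize()], applies
#' the 1x1x1 map back to C2 channels, and adds the original module input.
#'
#' @param mod A module from [res_trans_module()].
#' @param z A `token_seq` or `P x C3` matrix.
#' @param x_in The `c2 x D2 x H2 x W2` array the tokens were serialized from.
#' @return A `c2 x D2 x H2 x W2` array.
#' @export
token_deserialize <- function(mod, z, x_in) {
  tok <- if (inherits(z, "token_seq")) z$tokens else z
  d <- dim(x_in)
  rt_check_dims(mod, d[2:4])
  if (nrow(tok) != prod(d[2:4]))
    stop_gtv("token count %d does not match provenance dims %s",
             nrow(tok), paste(d[2:4], collapse = "x"))
  y <- mod$layers$conv_out$params$W %*% t(tok) + mod$layers$conv_out$params$b
  array(y + matrix(x_in, d[1]), d)
}
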