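# Activation container and parameterised layers with explicit forward /
# backward passes. Every layer is an environment so that gradients and
# optimiser state can be attached by reference during training.
#
# A batch of feature maps ("fmap") is a C x (N*V) matrix (V = D*H*W) whose
# column index inside a sample is d + D*(h + H*w), i.e. the flattening of an
# R array of dim c(C, D, H, W). Depth varies fastest; this raster order is
# also the token order used by the bottleneck serialization.

#' Construct a batched feature-map container
#'
#' @param x A `C x (n * prod(dims))` numeric matrix of activations.
#' @param n Number of samples in the batch.
#' @param dims Integer spatial dimensions `c(depth, height, width)`.
#' @return An object of class `fmap`.
#' @export
fmap <- function(x, n, dims) {
  stopifnot(is.matrix(x), ncol(x) == n * prod(dims))
  structure(list(x = x, n = as.integer(n), dims = as.integer(dims)),
            class = "fmap")
}

#' Wrap a single channels-first array as a feature map
#'
#' @param a A numeric array of dim `c(C, D, H, W)` (or a `C x D x H` 3D array
#'   treated as width 1).
#' @return An `fmap` with one sample.
#' @export
fmap_from_array <- function(a) {
  d <- dim(a)
  if (length(d) == 3) d <- c(d, 1L)
  stopifnot(length(d) == 4)
  fmap(matrix(a, d[1]), 1L, d[2:4])
}

#' Recover the channels-first array of a single-sample feature map
#'
#' @param f An `fmap` with `n = 1`.
#' @return A numeric array of dim `c(C, D, H, W)`.
#' @export
fmap_to_array <- function(f) {
  stopifnot(inherits(f, "fmap"), f$n == 1L)
  array(f$x, c(nrow(f$x), f$dims))
}

.uid_env <- new.env(parent = emptyenv())
.uid_env$n <- 0L
next_uid <- function() {
  .uid_env$n <- .uid_env$n + 1L
  .uid_env$n
}

new_layer <- function(kind, params, buffers = list(), cfg = list()) {
  e <- new.env(parent = emptyenv())
  e$kind <- kind
  e$params <- params
  e$buffers <- buffers
  e$cfg <- cfg
  e$grads <- NULL
  e$opt <- NULL
  e$uid <- next_uid()
  class(e) <- "nn_layer"
  e
}

kaiming_sd <- function(fan_in, slope = 0.01) sqrt(2 / (1 + slope^2)) / sqrt(fan_in)

## ---- convolution -----------------------------------------------------------

new_conv <- function(in_ch, out_ch, kernel, stride = c(1L, 1L, 1L)) {
  kernel <- as.integer(kernel); stride <- as.integer(stride)
  pad <- (kernel - 1L) %/% 2L
  fan_in <- in_ch * prod(kernel)
  W <- matrix(rnorm(out_ch * fan_in, 0, kaiming_sd(fan_in)), out_ch, fan_in)
  new_layer("conv", params = list(W = W, b = numeric(out_ch)),
            cfg = list(in_ch = in_ch, out_ch = out_ch, kernel = kernel,
                       stride = stride, pad = pad))
}

conv_out_dims <- function(dims, kernel, stride, pad) {
  bad <- which(stride > 1L & dims %% stride != 0L)
  if (length(bad))
    stop_gtv("strided convolution requires even input size along the %s axis (got %d)",
             axis_names[bad[1]], dims[bad[1]])
  (dims + 2L * pad - kernel) %/% stride + 1L
}

conv_forward <- function(ly, fm) {
  cfg <- ly$cfg
  od <- conv_out_dims(fm$dims, cfg$kernel, cfg$stride, cfg$pad)
  y <- cpp_conv_fwd(ly$uid, fm$x, ly$params$W, ly$params$b, fm$n, fm$dims,
                    cfg$kernel, cfg$stride, cfg$pad)
  list(out = fmap(y, fm$n, od), cache = list(x = fm))
}

conv_backward <- function(ly, dy, cache) {
  cfg <- ly$cfg; fm <- cache$x
  r <- cpp_conv_bwd(ly$uid, fm$x, ly$params$W, dy$x, fm$n, fm$dims,
                    cfg$kernel, cfg$stride, cfg$pad)
  ly$grads <- list(W = r$dW, b = as.numeric(r$db))
  fmap(r$dx, fm$n, fm$dims)
}

## ---- transpose convolution (kernel = stride, non-overlapping) --------------

new_tconv <- function(in_ch, out_ch, stride) {
  stride <- as.integer(stride)
  K <- prod(stride)
  A <- matrix(rnorm(out_ch * K * in_ch, 0, kaiming_sd(in_ch)), out_ch * K, in_ch)
  new_layer("tconv", params = list(A = A, b = numeric(out_ch)),
            cfg = list(in_ch = in_ch, out_ch = out_ch, stride = stride))
}

tconv_forward <- function(ly, fm) {
  cfg <- ly$cfg
  od <- fm$dims * cfg$stride
  y <- cpp_tconv_fwd(fm$x, ly$params$A, ly$params$b, fm$n, fm$dims, cfg$stride)
  list(out = fmap(y, fm$n, od), cache = list(x = fm))
}

tconv_backward <- function(ly, dy, cache) {
  cfg <- ly$cfg; fm <- cache$x
  r <- cpp_tconv_bwd(fm$x, ly$params$A, dy$x, fm$n, fm$dims, cfg$stride)
  ly$grads <- list(A = r$dA, b = as.numeric(r$db))
  fmap(r$dx, fm$n, fm$dims)
}

## ---- batch normalization ---------------------------------------------------

new_bn <- function(ch, momentum = 0.1, eps = 1e-5) {
  new_layer("bn",
            params = list(gamma = rep(1, ch), beta = rep(0, ch)),
            buffers = list(r_mean = rep(0, ch), r_var = rep(1, ch)),
            cfg = list(ch = ch, momentum = momentum, eps = eps))
}

bn_forward <- function(ly, fm, training) {
  r <- cpp_bn_fwd(fm$x, ly$params$gamma, ly$params$beta,
                  ly$buffers$r_mean, ly$buffers$r_var, training, ly$cfg$eps)
  if (training) {
    m <- ncol(fm$x); mom <- ly$cfg$momentum
    unb <- if (m > 1) m / (m - 1) else 1
    ly$buffers$r_mean <- (1 - mom) * ly$buffers$r_mean + mom * as.numeric(r$mu)
    ly$buffers$r_var <- (1 - mom) * ly$buffers$r_var + mom * as.numeric(r$var) * unb
  }
  list(out = fmap(r$y, fm$n, fm$dims),
       cache = list(x = fm, mu = r$mu, var = r$var, training = training))
}

bn_backward <- function(ly, dy, cache) {
  r <- cpp_bn_bwd(cache$x$x, dy$x, ly$params$gamma, cache$mu, cache$var,
                  cache$training, ly$cfg$eps)
  ly$grads <- list(gamma = as.numeric(r$dgamma), beta = as.numeric(r$dbeta))
  fmap(r$dx, cache$x$n, cache$x$dims)
}

## ---- leaky ReLU ------------------------------------------------------------

new_act <- function(slope = 0.01) new_layer("act", params = list(), cfg = list(slope = slope))

act_forward <- function(ly, fm) {
  list(out = fmap(cpp_lrelu_fwd(fm$x, ly$cfg$slope), fm$n, fm$dims),
       cache = list(x = fm))
}

act_backward <- function(ly, dy, cache) {
  ly$grads <- list()
  fmap(cpp_lrelu_bwd(cache$x$x, dy$x, ly$cfg$slope), cache$x$n, cache$x$dims)
}

## ---- squeeze-and-excitation ------------------------------------------------

new_se <- function(ch, r = 4, slope = 0.01) {
  if (ch %% r != 0)
    stop_gtv("SE block requires channels (%d) divisible by the reduction ratio r = %d", ch, r)
  hid <- ch %/% r
  new_layer("se",
            params = list(W1 = matrix(rnorm(hid * ch, 0, kaiming_sd(ch)), hid, ch),
                          b1 = numeric(hid),
                          W2 = matrix(rnorm(ch * hid, 0, kaiming_sd(hid)), ch, hid),
                          b2 = numeric(ch)),
            cfg = list(ch = ch, r = r, slope = slope, bypass = FALSE))
}

se_forward <- function(ly, fm) {
  if (isTRUE(ly$cfg$bypass))
    return(list(out = fm, cache = list(bypass = TRUE, x = fm)))
  p <- ly$params; V <- prod(fm$dims)
  s <- cpp_block_rowmeans(fm$x, fm$n)
  z1 <- p$W1 %*% s + p$b1
  g1 <- ly$cfg$slope + (1 - ly$cfg$slope) * (z1 > 0)
  a1 <- z1 * g1
  w <- 1 / (1 + exp(-(p$W2 %*% a1 + p$b2)))
  list(out = fmap(cpp_scale_blocks(fm$x, w), fm$n, fm$dims),
       cache = list(x = fm, s = s, g1 = g1, a1 = a1, w = w, V = V))
}

se_backward <- function(ly, dy, cache) {
  if (isTRUE(cache$bypass)) {
    ly$grads <- list(W1 = ly$params$W1 * 0, b1 = ly$params$b1 * 0,
                     W2 = ly$params$W2 * 0, b2 = ly$params$b2 * 0)
    return(dy)
  }
  p <- ly$params; fm <- cache$x; V <- cache$V; n <- fm$n
  dw <- cpp_se_grad_w(fm$x, dy$x, n)         # sum over voxels of dy * x
  dz2 <- dw * cache$w * (1 - cache$w)
  da1 <- crossprod(p$W2, dz2)
  dz1 <- da1 * cache$g1
  ds <- crossprod(p$W1, dz1)
  dx <- cpp_se_grad_x(dy$x, cache$w, ds / V)
  ly$grads <- list(W1 = tcrossprod(dz1, cache$s), b1 = rowSums(dz1),
                   W2 = tcrossprod(dz2, cache$a1), b2 = rowSums(dz2))
  fmap(dx, n, fm$dims)
}

## ---- generic dispatch ------------------------------------------------------

layer_forward <- function(ly, fm, training = FALSE) {
  switch(ly$kind,
         conv = conv_forward(ly, fm),
         tconv = tconv_forward(ly, fm),
         bn = bn_forward(ly, fm, training),
         act = act_forward(ly, fm),
         se = se_forward(ly, fm),
         stop_gtv("unknown layer kind '%s'", ly$kind))
}

layer_backward <- function(ly, dy, cache) {
  switch(ly$kind,
         conv = conv_backward(ly, dy, cache),
         tconv = tconv_backward(ly, dy, cache),
         bn = bn_backward(ly, dy, cache),
         act = act_backward(ly, dy, cache),
         se = se_backward(ly, dy, cache),
         stop_gtv("unknown layer kind '%s'", ly$kind))
}

layer_param_count <- function(ly) sum(vapply(ly$params, length, 1L))
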