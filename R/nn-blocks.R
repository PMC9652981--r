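# Feature-extraction modules. Each module is a list (class "nn_module") of
# layer environments plus a kind tag; module_forward/module_backward give the
# composite passes. Modes: "3D" uses 3x3x3 kernels, "2D" uses 1x3x3 kernels
# (depth extent 1) and requires depth stride 1, so 2D-mode stages only mix
# information in-plane along the convolutional path.

mode_kernel <- function(mode, base = c(3L, 3L, 3L)) {
  if (mode == "2D") c(1L, base[2], base[3]) else base
}

check_mode_stride <- function(mode, stride) {
  if (mode == "2D" && stride[1] != 1L)
    stop_gtv("2D-mode block cannot stride along depth (got stride %d)", stride[1])
}

new_module <- function(kind, layers, cfg = list()) {
  structure(list(kind = kind, layers = layers, cfg = cfg), class = "nn_module")
}

#' Plain convolution module: conv + batch norm + leaky ReLU
#'
#' The building unit of the baseline U-Net variants. Exactly one batch
#' normalization sits between the convolution and its activation.
#'
#' @param in_ch,out_ch Channel counts.
#' @param mode `"2D"` (kernel depth extent 1) or `"3D"`.
#' @param stride Integer stride `c(sD, sH, sW)`; depth stride must be 1 in 2D
#'   mode.
#' @param kernel Base kernel size before the 2D-mode depth collapse.
#' @return An `nn_module`.
#' @export
conv_bn_act <- function(in_ch, out_ch, mode = "3D", stride = c(1L, 1L, 1L),
                        kernel = c(3L, 3L, 3L)) {
  check_mode_stride(mode, stride)
  k <- mode_kernel(mode, as.integer(kernel))
  new_module("conv_bn_act",
             list(conv = new_conv(in_ch, out_ch, k, stride),
                  bn = new_bn(out_ch),
                  act = new_act()),
             cfg = list(mode = mode))
}

#' Res-SE Block-B: shape-preserving residual squeeze-and-excitation block
#'
#' Layout: conv -> BN -> LeakyReLU -> conv -> BN -> SE -> (+ identity skip)
#' -> LeakyReLU. Input and output channels must match; spatial dimensions are
#' unchanged.
#'
#' @param ch Channel count (in = out); must be divisible by `r`.
#' @param mode `"2D"` or `"3D"`.
#' @param r Squeeze-and-excitation reduction ratio (default 4).
#' @return An `nn_module`.
#' @export
res_se_block_b <- function(ch, mode = "3D", r = 4L) {
  k <- mode_kernel(mode)
  new_module("res_se_b",
             list(conv1 = new_conv(ch, ch, k), bn1 = new_bn(ch), act1 = new_act(),
                  conv2 = new_conv(ch, ch, k), bn2 = new_bn(ch),
                  se = new_se(ch, r), act_out = new_act()),
             cfg = list(mode = mode, ch = ch))
}

#' Res-SE Block-A: residual squeeze-and-excitation block changing shape
#'
#' As Block-B, but the first convolution carries the stride and the channel
#' change, and the skip path is a strided 1x1x1 projection convolution + BN so
#' the shapes agree before the residual addition. Strided axes must have even
#' extent; otherwise a shape error names the axis.
#'
#' @param in_ch,out_ch Channel counts; `out_ch` must be divisible by `r`.
#' @param mode `"2D"` or `"3D"`.
#' @param stride Integer stride `c(sD, sH, sW)` applied by the first
#'   convolution and the projection skip.
#' @param r Squeeze-and-excitation reduction ratio (default 4).
#' @return An `nn_module`.
#' @export
res_se_block_a <- function(in_ch, out_ch, mode = "3D", stride = c(1L, 1L, 1L),
                           r = 4L) {
  stride <- as.integer(stride)
  check_mode_stride(mode, stride)
  k <- mode_kernel(mode)
  new_module("res_se_a",
             list(conv1 = new_conv(in_ch, out_ch, k, stride),
                  bn1 = new_bn(out_ch), act1 = new_act(),
                  conv2 = new_conv(out_ch, out_ch, k), bn2 = new_bn(out_ch),
                  se = new_se(out_ch, r),
                  proj = new_conv(in_ch, out_ch, c(1L, 1L, 1L), stride),
                  proj_bn = new_bn(out_ch),
                  act_out = new_act()),
             cfg = list(mode = mode, stride = stride))
}

## ---- forward / backward ----------------------------------------------------

seq_fwd <- function(layers, names, fm, training) {
  caches <- vector("list", length(names)); names(caches) <- names
  for (nm in names) {
    r <- layer_forward(layers[[nm]], fm, training)
    fm <- r$out; caches[[nm]] <- r$cache
  }
  list(out = fm, caches = caches)
}

seq_bwd <- function(layers, names, dy, caches) {
  for (nm in rev(names)) dy <- layer_backward(layers[[nm]], dy, caches[[nm]])
  dy
}

#' Apply a module to a feature map
#'
#' @param mod An `nn_module` (for example from [res_se_block_b()]).
#' @param x An `fmap`, or a single channels-first array `c(C, D, H, W)`.
#' @param training Logical; `TRUE` uses batch statistics in BN layers.
#' @return The output in the same form as the input (`fmap` or array).
#' @export
module_forward <- function(mod, x, training = FALSE) {
  was_array <- !inherits(x, "fmap")
  if (was_array) x <- fmap_from_array(x)
  out <- module_fwd(mod, x, training)$out
  if (was_array) fmap_to_array(out) else out
}

module_fwd <- function(mod, fm, training) {
  ls <- mod$layers
  switch(mod$kind,
    conv_bn_act = {
      r <- seq_fwd(ls, c("conv", "bn", "act"), fm, training)
      list(out = r$out, cache = r$caches)
    },
    res_se_b = {
      r <- seq_fwd(ls, c("conv1", "bn1", "act1", "conv2", "bn2", "se"), fm, training)
      s <- fmap(r$out$x + fm$x, fm$n, fm$dims)
      a <- layer_forward(ls$act_out, s, training)
      list(out = a$out, cache = list(main = r$caches, act_out = a$cache))
    },
    res_se_a = {
      r <- seq_fwd(ls, c("conv1", "bn1", "act1", "conv2", "bn2", "se"), fm, training)
      p <- seq_fwd(ls, c("proj", "proj_bn"), fm, training)
      s <- fmap(r$out$x + p$out$x, r$out$n, r$out$dims)
      a <- layer_forward(ls$act_out, s, training)
      list(out = a$out, cache = list(main = r$caches, proj = p$caches, act_out = a$cache))
    },
    res_trans = rt_fwd(mod, fm, training),
    stop_gtv("unknown module kind '%s'", mod$kind))
}

module_bwd <- function(mod, dy, cache) {
  ls <- mod$layers
  switch(mod$kind,
    conv_bn_act = seq_bwd(ls, c("conv", "bn", "act"), dy, cache),
    res_se_b = {
      ds <- layer_backward(ls$act_out, dy, cache$act_out)
      dmain <- seq_bwd(ls, c("conv1", "bn1", "act1", "conv2", "bn2", "se"), ds, cache$main)
      fmap(dmain$x + ds$x, dmain$n, dmain$dims)
    },
    res_se_a = {
      ds <- layer_backward(ls$act_out, dy, cache$act_out)
      dmain <- seq_bwd(ls, c("conv1", "bn1", "act1", "conv2", "bn2", "se"), ds, cache$main)
      dproj <- seq_bwd(ls, c("proj", "proj_bn"), ds, cache$proj)
      fmap(dmain$x + dproj$x, dmain$n, dmain$dims)
    },
    res_trans = rt_bwd(mod, dy, cache),
    stop_gtv("unknown module kind '%s'", mod$kind))
}

module_layers <- function(mod) mod$layers

module_param_count <- function(mod) sum(vapply(mod$layers, layer_param_count, 1L))
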