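# Five-stage encoder-decoder assembly for all six architecture variants, and
# sliding-window full-volume inference.

VARIANTS <- c("unet2d", "unet25d", "unet3d", "resseunet3d", "resseunet25d",
              "transresseunet25d")

variant_plan <- function(variant) {
  switch(variant,
    unet2d = list(modes = rep("2D", 5), blocks = "plain", trans = FALSE),
    unet25d = list(modes = c("2D", "2D", "3D", "3D", "3D"), blocks = "plain", trans = FALSE),
    unet3d = list(modes = rep("3D", 5), blocks = "plain", trans = FALSE),
    resseunet3d = list(modes = rep("3D", 5), blocks = "resse", trans = FALSE),
    resseunet25d = list(modes = c("2D", "2D", "3D", "3D", "3D"), blocks = "resse", trans = FALSE),
    transresseunet25d = list(modes = c("2D", "2D", "3D", "3D", "3D"), blocks = "resse", trans = TRUE),
    stop_gtv("unknown variant '%s' (expected one of %s)", variant,
             paste(VARIANTS, collapse = ", ")))
}

#' Describe a network architecture variant
#'
#' Defines the five-stage plan: per-stage channels, strides (the first two
#' stages never downsample along depth; 2D-mode stages cannot), the input
#' patch the network is trained on, and the bottleneck transformer geometry.
#' The default reconstruction uses channels (16, 32, 64, 128, 256), strides
#' ((1,1,1), (1,2,2), (2,2,2), (2,2,2), (2,2,2)) and a 32 x 256 x 256 patch,
#' giving a 4 x 16 x 16 bottleneck with P = 1024 tokens of width 512.
#'
#' @param variant One of `"unet2d"`, `"unet25d"`, `"unet3d"`,
#'   `"resseunet3d"`, `"resseunet25d"`, `"transresseunet25d"`.
#' @param stage_channels Integer vector of 5 per-stage channel counts.
#' @param patch Input patch `c(depth, height, width)`; each axis must be
#'   divisible by the cumulative stride along it.
#' @param n_classes Number of output classes (default 2: background, target).
#' @param transformer List with `M` (layers), `H` (heads), `h` (MLP hidden
#'   width) and `c3` (token width) for the bottleneck attention.
#' @param in_channels Input image channels (default 1).
#' @return A `network_config` list, including the derived per-stage strides,
#'   modes, and bottleneck dimensions.
#' @export
network_config <- function(variant = "transresseunet25d",
                           stage_channels = c(16L, 32L, 64L, 128L, 256L),
                           patch = c(32L, 256L, 256L),
                           n_classes = 2L,
                           transformer = list(M = 4L, H = 8L, h = 4096L, c3 = 512L),
                           in_channels = 1L) {
  variant <- match.arg(variant, VARIANTS)
  plan <- variant_plan(variant)
  stage_channels <- as.integer(stage_channels)
  patch <- as.integer(patch)
  stopifnot(length(stage_channels) == 5, length(patch) == 3)
  strides <- list(c(1L, 1L, 1L), c(1L, 2L, 2L), c(2L, 2L, 2L),
                  c(2L, 2L, 2L), c(2L, 2L, 2L))
  for (i in 1:5) if (plan$modes[i] == "2D") strides[[i]][1] <- 1L

  cum <- Reduce(function(a, s) a * s, strides, accumulate = FALSE,
                init = c(1L, 1L, 1L))
  for (ax in 1:3) {
    if (patch[ax] %% cum[ax] != 0L)
      stop_gtv("patch %s axis (%d) is not divisible by the cumulative stride %d",
               axis_names[ax], patch[ax], cum[ax])
  }
  bottleneck_dims <- patch %/% cum
  tr <- utils::modifyList(list(M = 4L, H = 8L, h = 4096L, c3 = 512L), transformer)
  structure(list(variant = variant, stage_channels = stage_channels,
                 patch = patch, n_classes = as.integer(n_classes),
                 strides = strides, modes = plan$modes, blocks = plan$blocks,
                 trans = plan$trans, transformer = tr,
                 in_channels = as.integer(in_channels),
                 bottleneck_dims = bottleneck_dims),
            class = "network_config")
}

collect_layers <- function(net) {
  out <- list()
  for (st in net$enc) for (m in st) out <- c(out, module_layers(m))
  for (u in net$up) out <- c(out, list(u))
  for (st in net$dec) for (m in st) out <- c(out, module_layers(m))
  c(out, list(net$head))
}

#' Build a segmentation network
#'
#' Instantiates the variant-correct module graph with deterministic seeded
#' initialization (Kaiming-style convolution weights, BN gamma = 1, beta = 0,
#' small-Gaussian position embedding).
#'
#' @param cfg A [network_config()].
#' @param seed Integer seed controlling parameter initialization.
#' @return A `gtv_network` list; `net$n_params` reports the parameter count.
#' @export
build_network <- function(cfg, seed = 1L) {
  stopifnot(inherits(cfg, "network_config"))
  ch <- cfg$stage_channels
  with_seed_(seed, {
    enc <- vector("list", 5)
    in_ch <- cfg$in_channels
    for (i in 1:5) {
      mode <- cfg$modes[i]; s <- cfg$strides[[i]]
      if (i == 5 && cfg$trans) {
        enc[[i]] <- list(
          A = res_se_block_a(in_ch, ch[i], mode, s),
          T = res_trans_module(ch[i], cfg$bottleneck_dims,
                               M = cfg$transformer$M, n_heads = cfg$transformer$H,
                               hidden = cfg$transformer$h, c3 = cfg$transformer$c3))
      } else if (cfg$blocks == "resse") {
        enc[[i]] <- list(A = res_se_block_a(in_ch, ch[i], mode, s),
                         B = res_se_block_b(ch[i], mode))
      } else {
        enc[[i]] <- list(A = conv_bn_act(in_ch, ch[i], mode, s),
                         B = conv_bn_act(ch[i], ch[i], mode))
      }
      in_ch <- ch[i]
    }
    up <- vector("list", 4); dec <- vector("list", 4)
    for (i in 4:1) {
      up[[i]] <- new_tconv(ch[i + 1], ch[i], cfg$strides[[i + 1]])
      mode <- cfg$modes[i]
      if (cfg$blocks == "resse") {
        dec[[i]] <- list(fuse = conv_bn_act(2L * ch[i], ch[i], mode,
                                            kernel = c(1L, 1L, 1L)),
                         B = res_se_block_b(ch[i], mode))
      } else {
        dec[[i]] <- list(c1 = conv_bn_act(2L * ch[i], ch[i], mode),
                         c2 = conv_bn_act(ch[i], ch[i], mode))
      }
    }
    head <- new_conv(ch[1], cfg$n_classes, c(1L, 1L, 1L))
    net <- list(cfg = cfg, enc = enc, up = up, dec = dec, head = head,
                seed = as.integer(seed))
    net$layers <- collect_layers(net)
    net$n_params <- sum(vapply(net$layers, layer_param_count, 1L))
    class(net) <- "gtv_network"
    net
  })
}

#' @export
print.gtv_network <- function(x, ...) {
  cat(sprintf("<gtv_network> variant=%s patch=%s channels=%s params=%d\n",
              x$cfg$variant, paste(x$cfg$patch, collapse = "x"),
              paste(x$cfg$stage_channels, collapse = ","), x$n_params))
  invisible(x)
}

softmax_channels <- function(x) {
  C <- nrow(x)
  m <- x[1, ]
  if (C > 1) for (c in 2:C) m <- pmax(m, x[c, ])
  e <- exp(x - rep(m, each = C))
  e / rep(colSums(e), each = C)
}

modules_fwd <- function(mods, fm, training) {
  caches <- vector("list", length(mods)); names(caches) <- names(mods)
  for (nm in names(mods)) {
    r <- module_fwd(mods[[nm]], fm, training)
    fm <- r$out; caches[[nm]] <- r$cache
  }
  list(out = fm, caches = caches)
}

modules_bwd <- function(mods, dy, caches) {
  for (nm in rev(names(mods))) dy <- module_bwd(mods[[nm]], dy, caches[[nm]])
  dy
}

#' Run the network forward on a batch
#'
#' @param net A [build_network()] result.
#' @param x An `fmap` batch or a single `c(1, D, H, W)` array matching the
#'   configured patch size.
#' @param training Logical; `TRUE` uses batch statistics in BN layers and
#'   records the caches needed for a backward pass.
#' @return A list with `probs` (per-voxel class probabilities, channels sum
#'   to 1), `logits`, and (when `training`) `cache` for [net_backward()].
#' @export
net_forward <- function(net, x, training = FALSE) {
  if (!inherits(x, "fmap")) x <- fmap_from_array(x)
  if (!all(x$dims == net$cfg$patch))
    stop_gtv("input patch %s does not match configured patch %s",
             paste(x$dims, collapse = "x"), paste(net$cfg$patch, collapse = "x"))
  enc_out <- vector("list", 5); enc_cache <- vector("list", 5)
  fm <- x
  for (i in 1:5) {
    r <- modules_fwd(net$enc[[i]], fm, training)
    enc_out[[i]] <- r$out; enc_cache[[i]] <- r$caches
    fm <- r$out
  }
  up_cache <- vector("list", 4); dec_cache <- vector("list", 4)
  for (i in 4:1) {
    ru <- layer_forward(net$up[[i]], fm)
    up_cache[[i]] <- ru$cache
    cat_fm <- fmap(rbind(ru$out$x, enc_out[[i]]$x), fm$n, ru$out$dims)
    rd <- modules_fwd(net$dec[[i]], cat_fm, training)
    dec_cache[[i]] <- rd$caches
    fm <- rd$out
  }
  rh <- layer_forward(net$head, fm)
  probs <- fmap(softmax_channels(rh$out$x), rh$out$n, rh$out$dims)
  list(probs = probs, logits = rh$out,
       cache = list(enc = enc_cache, up = up_cache, dec = dec_cache,
                    head = rh$cache, up_ch = net$cfg$stage_channels))
}

#' Backpropagate a gradient with respect to the logits
#'
#' Fills `layer$grads` on every layer of the network (by reference) and
#' returns the gradient with respect to the input.
#'
#' @param net A `gtv_network`.
#' @param dlogits An `fmap` gradient matching the logits shape.
#' @param cache The cache returned by [net_forward()] with `training = TRUE`.
#' @return The input-gradient `fmap`, invisibly.
#' @export
net_backward <- function(net, dlogits, cache) {
  dy <- layer_backward(net$head, dlogits, cache$head)
  denc <- vector("list", 5)
  for (i in 1:4) {
    dcat <- modules_bwd(net$dec[[i]], dy, cache$dec[[i]])
    cu <- net$cfg$stage_channels[i]
    dup <- fmap(dcat$x[seq_len(cu), , drop = FALSE], dcat$n, dcat$dims)
    denc[[i]] <- dcat$x[(cu + 1):(2 * cu), , drop = FALSE]
    dy <- layer_backward(net$up[[i]], dup, cache$up[[i]])
  }
  carry <- dy
  for (i in 5:1) {
    if (i < 5) carry <- fmap(carry$x + denc[[i]], carry$n, carry$dims)
    carry <- modules_bwd(net$enc[[i]], carry, cache$enc[[i]])
  }
  invisible(carry)
}

## ---- sliding-window inference ---------------------------------------------

tile_starts <- function(extent, win) {
  if (extent <= win) return(0L)
  step <- max(1L, win %/% 2L)
  s <- seq.int(0L, extent - win, by = step)
  if (s[length(s)] != extent - win) s <- c(s, extent - win)
  as.integer(s)
}

pad_to_min <- function(a, size) {
  d <- dim(a)
  need <- pmax(size - d, 0L)
  if (all(need == 0L)) return(list(a = a, lo = c(0L, 0L, 0L), d0 = d))
  lo <- need %/% 2L
  out <- array(0, pmax(d, size))
  out[lo[1] + seq_len(d[1]), lo[2] + seq_len(d[2]), lo[3] + seq_len(d[3])] <- a
  list(a = out, lo = lo, d0 = d)
}

#' Segment a whole volume by overlapping sliding windows
#'
#' Tiles the volume with the configured patch at 50% overlap (the final tile
#' is clamped to the volume edge), averages per-voxel softmax probabilities
#' over all windows covering a voxel, and thresholds the target-class
#' probability at 0.5 (ties go to background). Volumes smaller than the patch
#' are symmetrically zero-padded for inference and the padding removed.
#'
#' @param net A trained `gtv_network`.
#' @param volume A `ct_volume` in the normalized (0-1) intensity domain, or a
#'   bare 3D array.
#' @return A `ct_mask` (or bare integer array if the input was an array).
#' @export
predict_volume <- function(net, volume) {
  arr <- if (inherits(volume, "ct_volume")) volume$data else volume
  if (inherits(volume, "ct_volume") && volume$domain != "normalized_0_1")
    stop_gtv("predict_volume expects a normalized_0_1 volume (got %s)", volume$domain)
  win <- net$cfg$patch
  pp <- pad_to_min(arr, win)
  d <- dim(pp$a)
  acc <- array(0, d); cnt <- array(0, d)
  sd_ <- tile_starts(d[1], win[1]); sh <- tile_starts(d[2], win[2]); sw <- tile_starts(d[3], win[3])
  for (a1 in sd_) for (a2 in sh) for (a3 in sw) {
    i1 <- a1 + seq_len(win[1]); i2 <- a2 + seq_len(win[2]); i3 <- a3 + seq_len(win[3])
    patch <- pp$a[i1, i2, i3, drop = FALSE]
    r <- net_forward(net, array(patch, c(1L, win)), training = FALSE)
    ptar <- array(r$probs$x[2, ], win)
    acc[i1, i2, i3] <- acc[i1, i2, i3] + ptar
    cnt[i1, i2, i3] <- cnt[i1, i2, i3] + 1
  }
  m <- (acc / cnt) > 0.5
  m <- m[pp$lo[1] + seq_len(pp$d0[1]), pp$lo[2] + seq_len(pp$d0[2]),
         pp$lo[3] + seq_len(pp$d0[3]), drop = FALSE]
  storage.mode(m) <- "integer"
  if (inherits(volume, "ct_volume")) new_mask(m, volume$spacing_mm) else m
}

## ---- state (checkpointing) -------------------------------------------------

#' Extract or restore the learnable state of a network
#'
#' `net_state()` returns all parameters and BN running statistics as a plain
#' list; `net_load_state()` writes such a list back into a network of the
#' same architecture. Used for best-model checkpointing.
#'
#' @param net A `gtv_network`.
#' @return For `net_state()`, a list of per-layer `params` / `buffers`.
#' @export
net_state <- function(net) {
  lapply(net$layers, function(ly) list(params = ly$params, buffers = ly$buffers))
}

#' @rdname net_state
#' @param state A list previously returned by `net_state()`.
#' @export
net_load_state <- function(net, state) {
  stopifnot(length(state) == length(net$layers))
  for (i in seq_along(state)) {
    net$layers[[i]]$params <- state[[i]]$params
    net$layers[[i]]$buffers <- state[[i]]$buffers
  }
  invisible(net)
}

#' Save / load a model checkpoint
#'
#' The checkpoint is an RDS of the network state plus a JSON sidecar with the
#' architecture configuration and seed, sufficient to rebuild and reload.
#'
#' @param net A `gtv_network`.
#' @param path Path of the `.rds` checkpoint to write or read.
#' @param meta Optional named list stored in the JSON sidecar.
#' @return `load_checkpoint()` returns a rebuilt `gtv_network`.
#' @export
save_checkpoint <- function(net, path, meta = list()) {
  saveRDS(list(state = net_state(net), cfg = unclass(net$cfg), seed = net$seed), path)
  side <- c(list(variant = net$cfg$variant, patch = net$cfg$patch,
                 stage_channels = net$cfg$stage_channels,
                 n_params = net$n_params, seed = net$seed), meta)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  cfg <- do.call(network_config,
                 ck$cfg[c("variant", "stage_channels", "patch", "n_classes",
                          "transformer", "in_channels")])
  net <- build_network(cfg, ck$seed)
  net_load_state(net, ck$state)
  net
}
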