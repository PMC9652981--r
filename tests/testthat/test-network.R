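layer_kinds <- function(net) {
  vapply(net$layers, function(l) l$kind, "")
}

stage_conv_kernels <- function(net, stage) {
  mods <- net$enc[[stage]]
  out <- list()
  for (m in mods) for (ly in m$layers)
    if (ly$kind == "conv") out <- c(out, list(ly$cfg$kernel))
  out
}

test_that("variant factory builds the documented module graphs", {
  u3 <- build_network(tiny_net_cfg("unet3d"), seed = 1)
  expect_false(any(layer_kinds(u3) == "se"))
  expect_false(any(vapply(u3$enc[[5]], function(m) m$kind, "") == "res_trans"))

  r25 <- build_network(tiny_net_cfg("resseunet25d"), seed = 1)
  expect_true(any(layer_kinds(r25) == "se"))
  for (st in 1:2)
    for (k in stage_conv_kernels(r25, st)) expect_equal(k[1], 1L)
  for (k in stage_conv_kernels(r25, 3)) expect_gte(k[1], 1L)
  expect_true(any(vapply(stage_conv_kernels(r25, 3), function(k) k[1] == 3L, TRUE)))
  expect_equal(vapply(r25$enc[[5]], function(m) m$kind, ""),
               c(A = "res_se_a", B = "res_se_b"))

  tr <- build_network(tiny_net_cfg("transresseunet25d"), seed = 1)
  expect_equal(vapply(tr$enc[[5]], function(m) m$kind, ""),
               c(A = "res_se_a", T = "res_trans"))

  u2 <- build_network(tiny_net_cfg("unet2d"), seed = 1)
  for (st in 1:5) {
    for (k in stage_conv_kernels(u2, st)) expect_equal(k[1], 1L)
    expect_equal(u2$cfg$strides[[st]][1], 1L)   # never strides through slices
  }

  expect_error(network_config("resnet"), "should be one of")
  expect_error(network_config("unet3d", patch = c(12L, 32L, 32L)), "depth")
  expect_gt(tr$n_params, 0)
})

test_that("initialization is seed-deterministic", {
  a <- build_network(tiny_net_cfg(), seed = 5)
  b <- build_network(tiny_net_cfg(), seed = 5)
  c3 <- build_network(tiny_net_cfg(), seed = 6)
  expect_identical(net_state(a), net_state(b))
  expect_false(identical(net_state(a), net_state(c3)))
})

test_that("forward pass yields normalized probabilities at the input resolution", {
  set.seed(1)
  for (variant in c("unet2d", "unet25d", "unet3d", "resseunet3d",
                    "resseunet25d", "transresseunet25d")) {
    net <- build_network(tiny_net_cfg(variant), seed = 2)
    x <- array(runif(prod(net$cfg$patch)), c(1L, net$cfg$patch))
    r <- net_forward(net, x)
    expect_equal(r$probs$dims, net$cfg$patch)
    expect_equal(nrow(r$probs$x), 2L)
    expect_lt(max(abs(colSums(r$probs$x) - 1)), 1e-5)
    expect_true(all(is.finite(r$probs$x)))
  }
  net <- build_network(tiny_net_cfg(), seed = 2)
  expect_error(net_forward(net, array(0, c(1, 4, 32, 32))), "patch")
})

test_that("the scaled-down reference configuration runs a finite forward pass", {
  net <- build_network(toy_net_cfg(), seed = 3)
  x <- array(runif(prod(net$cfg$patch)), c(1L, net$cfg$patch))
  r <- net_forward(net, x)
  expect_true(all(is.finite(r$probs$x)))
  expect_equal(r$probs$dims, c(16L, 64L, 64L))
  # declared stage plan: bottleneck at 1/8 depth, 1/16 in-plane
  expect_equal(net$cfg$bottleneck_dims, c(2L, 4L, 4L))
})

test_that("backpropagation matches finite differences through the whole network", {
  cfg <- tiny_net_cfg(patch = c(8L, 16L, 16L))
  net <- build_network(cfg, seed = 7)
  set.seed(8)
  n <- 2L
  x <- fmap(matrix(rnorm(n * prod(cfg$patch)), 1), n, cfg$patch)
  tar <- as.numeric(runif(n * prod(cfg$patch)) < 0.3)
  lossfun <- function() {
    r <- net_forward(net, x, training = TRUE)
    list(r = r, lg = gtvseg:::loss_and_grad(r$probs$x, tar))
  }
  r0 <- lossfun()
  net_backward(net, fmap(r0$lg$dlogits, n, r0$r$logits$dims), r0$r$cache)

  # directional derivative along a random direction over ALL parameters:
  # aggregates every layer's gradient into one high-signal comparison
  set.seed(9)
  dirs <- lapply(net$layers, function(ly)
    lapply(ly$params, function(p) {
      d <- rnorm(length(p)); dim(d) <- dim(p); d
    }))
  analytic <- 0
  for (li in seq_along(net$layers)) {
    ly <- net$layers[[li]]
    for (nm in names(ly$params))
      analytic <- analytic + sum(ly$grads[[nm]] * dirs[[li]][[nm]])
  }
  shift <- function(s) {
    for (li in seq_along(net$layers)) {
      ly <- net$layers[[li]]
      for (nm in names(ly$params))
        ly$params[[nm]] <- ly$params[[nm]] + s * dirs[[li]][[nm]]
    }
  }
  eps <- 1e-4
  shift(eps); lp <- lossfun()$lg$total
  shift(-2 * eps); lm <- lossfun()$lg$total
  shift(eps)
  numeric <- (lp - lm) / (2 * eps)
  # tolerance reflects LeakyReLU kink crossings under a full-parameter
  # perturbation and the single-precision convolution path; a backprop
  # defect shows up as an order-of-magnitude disagreement
  expect_lt(abs(numeric - analytic) / (abs(numeric) + abs(analytic)), 0.05)
})

test_that("all parameters receive gradient in one training step", {
  cfg <- tiny_net_cfg(patch = c(8L, 32L, 32L))   # bottleneck has 4 tokens
  net <- build_network(cfg, seed = 11)
  set.seed(12)
  n <- 2L
  x <- fmap(matrix(rnorm(n * prod(cfg$patch)), 1), n, cfg$patch)
  tar <- as.numeric(runif(n * prod(cfg$patch)) < 0.3)
  r <- net_forward(net, x, training = TRUE)
  lg <- gtvseg:::loss_and_grad(r$probs$x, tar)
  net_backward(net, fmap(lg$dlogits, n, r$logits$dims), r$cache)
  for (li in seq_along(net$layers)) {
    ly <- net$layers[[li]]
    if (length(ly$params) == 0) next
    for (nm in names(ly$grads))
      expect_true(any(ly$grads[[nm]] != 0),
                  info = sprintf("layer %d (%s) %s", li, ly$kind, nm))
  }
})

test_that("sliding-window tiling covers the volume with 50% overlap", {
  expect_equal(gtvseg:::tile_starts(84L, 32L), c(0L, 16L, 32L, 48L, 52L))
  expect_equal(gtvseg:::tile_starts(32L, 32L), 0L)
  expect_equal(gtvseg:::tile_starts(20L, 32L), 0L)

  net <- build_network(tiny_net_cfg(), seed = 13)
  # volume of exactly one window: prediction equals the single-tile argmax
  v <- array(runif(prod(net$cfg$patch)), net$cfg$patch)
  one <- predict_volume(net, v)
  r <- net_forward(net, array(v, c(1L, dim(v))))
  expect_identical(one, array(as.integer(r$probs$x[2, ] > 0.5), dim(v)))

  # larger and smaller volumes keep shape and spacing
  big <- new_volume(array(runif(12 * 40 * 40), c(12, 40, 40)), c(5, 1, 1),
                    "normalized_0_1")
  pm <- predict_volume(net, big)
  expect_s3_class(pm, "ct_mask")
  expect_equal(dim(pm$data), c(12L, 40L, 40L))
  small <- array(runif(4 * 20 * 20), c(4, 20, 20))
  expect_equal(dim(predict_volume(net, small)), c(4L, 20L, 20L))
  expect_error(predict_volume(net, new_volume(v, c(5, 1, 1), "HU")), "normalized")
})

test_that("checkpoints round-trip the full model state", {
  net <- build_network(tiny_net_cfg(), seed = 4)
  x <- array(runif(prod(net$cfg$patch)), c(1L, net$cfg$patch))
  p1 <- net_forward(net, x)$probs$x
  f <- file.path(tempdir(), "ckpt.rds")
  save_checkpoint(net, f, meta = list(epoch = 3L))
  expect_true(file.exists(paste0(f, ".json")))
  side <- jsonlite::read_json(paste0(f, ".json"))
  expect_equal(side$epoch, 3L)
  net2 <- load_checkpoint(f)
  expect_equal(net_forward(net2, x)$probs$x, p1, tolerance = 1e-12)
})
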