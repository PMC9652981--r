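# Shared fixtures and independent oracles used across the suite.

# A network configuration small enough for CPU-second forward passes.
tiny_net_cfg <- function(variant = "transresseunet25d",
                         patch = c(8L, 32L, 32L),
                         transformer = list(M = 2L, H = 2L, h = 12L, c3 = 8L)) {
  network_config(variant, stage_channels = c(4L, 4L, 8L, 8L, 16L),
                 patch = patch, transformer = transformer)
}

# A small phantom that leaves room for random cropping at 8x32x32.
tiny_phantom_spec <- function(noise_sd_hu = 15) {
  phantom_spec(shape_voxels = c(12L, 48L, 48L), spacing_mm = c(5, 1, 1),
               lesion_semiaxes_mm = c(8, 8, 8), noise_sd_hu = noise_sd_hu)
}

# The toy study profile used by the convergence experiments.
toy_phantom_spec <- function() {
  phantom_spec(shape_voxels = c(24L, 80L, 80L), spacing_mm = c(5, 1, 1),
               lesion_semiaxes_mm = c(12, 16, 16), noise_sd_hu = 20)
}

toy_net_cfg <- function(variant = "transresseunet25d") {
  network_config(variant, stage_channels = c(8L, 16L, 32L, 64L, 128L),
                 patch = c(16L, 64L, 64L),
                 transformer = list(M = 2L, H = 4L, h = 256L, c3 = 128L))
}

# ---- brute-force oracles (independent of the package implementation) -------

# Surface voxels by explicit 6-neighbor enumeration.
oracle_surface <- function(m) {
  d <- dim(m)
  fg <- which(m == 1, arr.ind = TRUE)
  on_surface <- logical(nrow(fg))
  for (i in seq_len(nrow(fg))) {
    v <- fg[i, ]
    nb_bg <- FALSE
    for (ax in 1:3) for (s in c(-1L, 1L)) {
      w <- v; w[ax] <- w[ax] + s
      if (w[ax] < 1 || w[ax] > d[ax]) { nb_bg <- TRUE }
      else if (m[w[1], w[2], w[3]] == 0) { nb_bg <- TRUE }
    }
    on_surface[i] <- nb_bg
  }
  fg[on_surface, , drop = FALSE]
}

# O(n^2) HD95: all pairwise surface distances, type-7 percentile.
oracle_hd95 <- function(a, b, spacing) {
  sa <- oracle_surface(a); sb <- oracle_surface(b)
  pa <- sweep(sa, 2, spacing, `*`); pb <- sweep(sb, 2, spacing, `*`)
  dmat <- outer(pa[, 1], pb[, 1], `-`)^2 +
    outer(pa[, 2], pb[, 2], `-`)^2 + outer(pa[, 3], pb[, 3], `-`)^2
  dmat <- sqrt(dmat)
  q_ab <- stats::quantile(apply(dmat, 2, min), 0.95, type = 7, names = FALSE)
  q_ba <- stats::quantile(apply(dmat, 1, min), 0.95, type = 7, names = FALSE)
  0.5 * (q_ab + q_ba)
}

# Random compact blob mask (ellipsoid at random center/semiaxes) with a
# bounded foreground size; guaranteed nonempty.
random_blob_mask <- function(shape = c(10L, 20L, 20L), spacing = c(5, 1, 1)) {
  repeat {
    ctr <- runif(3, 0.3, 0.7) * (shape - 1) * spacing
    semi <- runif(3, 0.15, 0.35) * (shape - 1) * spacing
    q <- lapply(1:3, function(ax)
      (((seq_len(shape[ax]) - 1) * spacing[ax] - ctr[ax]) / semi[ax])^2)
    m <- outer(outer(q[[1]], q[[2]], "+"), q[[3]], "+") <= 1
    n <- sum(m)
    if (n >= 1 && n <= 1000) {
      out <- array(0L, shape); out[m] <- 1L
      return(out)
    }
  }
}

# Set every parameter of a layer to zero (for forced-weight tests).
zero_layer <- function(ly) {
  for (nm in names(ly$params)) ly$params[[nm]] <- ly$params[[nm]] * 0
  invisible(ly)
}
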