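# Intensity windowing, patch extraction and the training augmentation suite.
# Coordinate convention: axis order (depth, height, width); geometric
# augmentation is in-plane only (about the slice axis), since ~5 mm slices
# make through-plane rotation destructive; depth translation is rounded to
# whole slices for the same reason.

#' Window a CT volume to the 0-255 display mapping
#'
#' `out = clip((hu - (level - width/2)) / width, 0, 1) * 255`; monotone
#' nondecreasing in the input. The default width 400 / level 40 is the
#' soft-tissue window used for target delineation.
#'
#' @param volume A `ct_volume` in HU.
#' @param width Window width (> 0), default 400.
#' @param level Window level (center), default 40.
#' @return A `ct_volume` in the `mapped_0_255` domain.
#' @export
window_ct <- function(volume, width = 400, level = 40) {
  if (width <= 0) stop_gtv("window width must be positive (got %g)", width)
  if (volume$domain != "HU")
    stop_gtv("window_ct expects an HU volume (got %s)", volume$domain)
  lo <- level - width / 2
  out <- pmin(pmax((volume$data - lo) / width, 0), 1) * 255
  new_volume(array(out, dim(volume$data)), volume$spacing_mm, "mapped_0_255")
}

#' Rescale a windowed volume to [0, 1]
#'
#' @param volume A `ct_volume` in the `mapped_0_255` domain.
#' @return A `ct_volume` in the `normalized_0_1` domain.
#' @export
normalize_volume <- function(volume) {
  if (volume$domain != "mapped_0_255")
    stop_gtv("normalize_volume expects a mapped_0_255 volume (got %s)", volume$domain)
  new_volume(volume$data / 255, volume$spacing_mm, "normalized_0_1")
}

# Symmetric zero-padding up to `size`; mask padded with 0. Padding value 0
# corresponds to air after windowing/normalization.
pad_pair <- function(varr, marr, size) {
  d <- dim(varr)
  if (all(d >= size)) return(list(v = varr, m = marr))
  nd <- pmax(d, size)
  lo <- (nd - d) %/% 2L
  v <- array(0, nd); m <- array(0L, nd)
  idx1 <- lo[1] + seq_len(d[1]); idx2 <- lo[2] + seq_len(d[2]); idx3 <- lo[3] + seq_len(d[3])
  v[idx1, idx2, idx3] <- varr
  m[idx1, idx2, idx3] <- marr
  list(v = v, m = m)
}

crop_at <- function(varr, marr, start0, size) {
  i1 <- start0[1] + seq_len(size[1]); i2 <- start0[2] + seq_len(size[2])
  i3 <- start0[3] + seq_len(size[3])
  list(v = varr[i1, i2, i3, drop = FALSE], m = marr[i1, i2, i3, drop = FALSE])
}

#' Randomly crop an aligned volume/mask pair to a patch
#'
#' Volumes smaller than `size` on any axis are symmetrically zero-padded
#' first; crop offsets are drawn uniformly and applied identically to volume
#' and mask. Spacing metadata is unchanged.
#'
#' @param volume,mask An aligned `ct_volume` / `ct_mask` pair.
#' @param size Patch size `c(depth, height, width)`, default `c(32, 256, 256)`.
#' @param seed Integer seed for the crop offsets.
#' @return A list with elements `volume` and `mask`.
#' @export
random_crop <- function(volume, mask, size = c(32L, 256L, 256L), seed = 1L) {
  check_aligned(volume, mask)
  size <- as.integer(size)
  p <- pad_pair(volume$data, mask$data, size)
  d <- dim(p$v)
  start0 <- with_seed_(seed, {
    vapply(1:3, function(ax) sample.int(d[ax] - size[ax] + 1L, 1L) - 1L, 1L)
  })
  cr <- crop_at(p$v, p$m, start0, size)
  list(volume = new_volume(cr$v, volume$spacing_mm, volume$domain),
       mask = new_mask(cr$m, mask$spacing_mm))
}

#' Deterministically crop a patch centered on the GTV
#'
#' The patch is centered on the foreground centroid (voxel indices, rounded
#' toward zero), with offsets clamped so the patch lies inside the (padded)
#' volume. Used for validation, where each case is evaluated on the same
#' target-centered block every epoch.
#'
#' @inheritParams random_crop
#' @return A list with elements `volume` and `mask`.
#' @export
center_crop_on_gtv <- function(volume, mask, size = c(32L, 256L, 256L)) {
  check_aligned(volume, mask)
  size <- as.integer(size)
  if (sum(mask$data) == 0)
    stop_gtv("center_crop_on_gtv: mask has no foreground (validation case has no GTV)")
  p <- pad_pair(volume$data, mask$data, size)
  pad_lo <- (dim(p$v) - dim(volume$data)) %/% 2L
  idx <- which(mask$data == 1L, arr.ind = TRUE)
  centroid0 <- trunc(colMeans(idx) - 1) + pad_lo      # 0-based, in padded frame
  start0 <- as.integer(centroid0) - size %/% 2L
  start0 <- pmin(pmax(start0, 0L), dim(p$v) - size)
  cr <- crop_at(p$v, p$m, start0, size)
  list(volume = new_volume(cr$v, volume$spacing_mm, volume$domain),
       mask = new_mask(cr$m, mask$spacing_mm))
}

## ---- augmentation ----------------------------------------------------------

#' Configure the training augmentation suite
#'
#' Defaults (all overridable): mirror probability 0.5 per axis, in-plane
#' rotation up to +/-15 degrees, isotropic in-plane scaling in [0.9, 1.1],
#' translation up to +/-10% per axis (depth rounded to whole slices),
#' additive Gaussian intensity noise with sd 0.02 in normalized units.
#'
#' @param p_mirror Mirror probability per axis (length 3, in `[0, 1]`).
#' @param rotation_deg_max Maximum in-plane rotation magnitude in degrees.
#' @param scale_range In-plane scale range, a subset of (0, 2).
#' @param translate_frac_max Maximum translation per axis as a fraction of
#'   its extent, in `[0, 0.5)`.
#' @param noise_sd Intensity noise standard deviation (volume only).
#' @param enabled Named logical flags: `mirror`, `rotate`, `scale`,
#'   `translate`, `noise`.
#' @return An `augment_config`.
#' @export
augment_config <- function(p_mirror = c(0.5, 0.5, 0.5), rotation_deg_max = 15,
                           scale_range = c(0.9, 1.1), translate_frac_max = 0.1,
                           noise_sd = 0.02,
                           enabled = list(mirror = TRUE, rotate = TRUE,
                                          scale = TRUE, translate = TRUE,
                                          noise = TRUE)) {
  stopifnot(length(p_mirror) == 3, all(p_mirror >= 0 & p_mirror <= 1),
            rotation_deg_max >= 0,
            length(scale_range) == 2, scale_range[1] <= scale_range[2],
            scale_range[1] > 0, scale_range[2] < 2,
            translate_frac_max >= 0, translate_frac_max < 0.5,
            noise_sd >= 0)
  enabled <- utils::modifyList(list(mirror = TRUE, rotate = TRUE, scale = TRUE,
                                    translate = TRUE, noise = TRUE), enabled)
  structure(list(p_mirror = p_mirror, rotation_deg_max = rotation_deg_max,
                 scale_range = scale_range, translate_frac_max = translate_frac_max,
                 noise_sd = noise_sd, enabled = enabled),
            class = "augment_config")
}

# In-plane affine resample of a (D, H, W) array: rotation by `angle_deg`
# about the slice axis, isotropic scale, in-plane translation (voxels).
# `interp` is "linear" for images, "nearest" for masks; out-of-range reads 0.
affine_inplane <- function(arr, angle_deg, scale, t_hw, interp = "linear") {
  d <- dim(arr)
  th <- angle_deg * pi / 180
  ch <- (d[2] + 1) / 2; cw <- (d[3] + 1) / 2
  hr <- matrix(seq_len(d[2]) - ch - t_hw[1], d[2], d[3])
  wr <- matrix(seq_len(d[3]) - cw - t_hw[2], d[2], d[3], byrow = TRUE)
  src_h <- (cos(th) * hr + sin(th) * wr) / scale + ch
  src_w <- (-sin(th) * hr + cos(th) * wr) / scale + cw
  out <- array(if (interp == "nearest") 0L else 0, d)
  if (interp == "nearest") {
    si <- round(src_h); sj <- round(src_w)
    ok <- si >= 1 & si <= d[2] & sj >= 1 & sj <= d[3]
    lin <- cbind(si[ok], sj[ok])
    for (k in seq_len(d[1])) {
      sl <- arr[k, , ]
      o <- matrix(0L, d[2], d[3]); o[ok] <- sl[lin]
      out[k, , ] <- o
    }
  } else {
    i0 <- floor(src_h); j0 <- floor(src_w)
    fi <- src_h - i0; fj <- src_w - j0
    cl <- function(i, lim) pmin(pmax(i, 1), lim)
    w00 <- (1 - fi) * (1 - fj); w01 <- (1 - fi) * fj
    w10 <- fi * (1 - fj); w11 <- fi * fj
    v00 <- i0 >= 1 & i0 <= d[2] & j0 >= 1 & j0 <= d[3]
    v01 <- i0 >= 1 & i0 <= d[2] & j0 + 1 >= 1 & j0 + 1 <= d[3]
    v10 <- i0 + 1 >= 1 & i0 + 1 <= d[2] & j0 >= 1 & j0 <= d[3]
    v11 <- i0 + 1 >= 1 & i0 + 1 <= d[2] & j0 + 1 >= 1 & j0 + 1 <= d[3]
    a00 <- cbind(c(cl(i0, d[2])), c(cl(j0, d[3])))
    a01 <- cbind(c(cl(i0, d[2])), c(cl(j0 + 1, d[3])))
    a10 <- cbind(c(cl(i0 + 1, d[2])), c(cl(j0, d[3])))
    a11 <- cbind(c(cl(i0 + 1, d[2])), c(cl(j0 + 1, d[3])))
    for (k in seq_len(d[1])) {
      sl <- arr[k, , ]
      o <- w00 * (sl[a00] * v00) + w01 * (sl[a01] * v01) +
        w10 * (sl[a10] * v10) + w11 * (sl[a11] * v11)
      out[k, , ] <- o
    }
  }
  out
}

shift_depth <- function(arr, k, fill = 0) {
  if (k == 0) return(arr)
  d <- dim(arr)
  out <- array(fill, d)
  if (abs(k) >= d[1]) return(out)
  if (k > 0) out[(k + 1):d[1], , ] <- arr[1:(d[1] - k), , ]
  else out[1:(d[1] + k), , ] <- arr[(1 - k):d[1], , ]
  out
}

#' Apply a fully specified augmentation to a volume/mask patch
#'
#' The geometric transform is applied identically to the volume (linear
#' interpolation) and the mask (nearest neighbor); noise is applied to the
#' volume only. Exposed so that tests and pipelines can force exact
#' parameters; [augment_patch()] draws the parameters.
#'
#' @param volume,mask An aligned patch pair.
#' @param params List with `mirror` (logical length 3), `angle` (degrees),
#'   `scale`, `translate` (voxels, length 3; depth component rounded),
#'   `noise_sd`, and optionally `noise_seed`.
#' @return A list with elements `volume` and `mask`.
#' @export
augment_apply <- function(volume, mask, params) {
  check_aligned(volume, mask)
  v <- volume$data; m <- mask$data
  p <- utils::modifyList(list(mirror = c(FALSE, FALSE, FALSE), angle = 0,
                              scale = 1, translate = c(0, 0, 0), noise_sd = 0,
                              noise_seed = 1L), params)
  for (ax in 1:3) {
    if (p$mirror[ax]) {
      idx <- rev(seq_len(dim(v)[ax]))
      if (ax == 1) { v <- v[idx, , , drop = FALSE]; m <- m[idx, , , drop = FALSE] }
      if (ax == 2) { v <- v[, idx, , drop = FALSE]; m <- m[, idx, , drop = FALSE] }
      if (ax == 3) { v <- v[, , idx, drop = FALSE]; m <- m[, , idx, drop = FALSE] }
    }
  }
  if (p$angle != 0 || p$scale != 1 || any(p$translate[2:3] != 0)) {
    v <- affine_inplane(v, p$angle, p$scale, p$translate[2:3], "linear")
    m <- affine_inplane(m, p$angle, p$scale, p$translate[2:3], "nearest")
  }
  kd <- round(p$translate[1])
  if (kd != 0) { v <- shift_depth(v, kd); m <- shift_depth(m, kd, 0L) }
  if (p$noise_sd > 0) {
    v <- v + with_seed_(p$noise_seed,
                        array(rnorm(length(v), 0, p$noise_sd), dim(v)))
  }
  storage.mode(m) <- "integer"
  list(volume = new_volume(v, volume$spacing_mm, volume$domain),
       mask = new_mask(m, mask$spacing_mm))
}

#' Randomly augment a volume/mask patch
#'
#' Draws mirror flags, in-plane rotation angle, scale, per-axis translation
#' and noise from `config` under `seed`, then calls [augment_apply()].
#' Deterministic for a fixed `(patch, config, seed)`.
#'
#' @inheritParams augment_apply
#' @param config An [augment_config()].
#' @param seed Integer seed.
#' @return A list with elements `volume` and `mask`.
#' @export
augment_patch <- function(volume, mask, config = augment_config(), seed = 1L) {
  en <- config$enabled
  params <- with_seed_(child_seed(seed, "augment"), {
    d <- dim(volume$data)
    list(mirror = if (en$mirror) runif(3) < config$p_mirror else c(FALSE, FALSE, FALSE),
         angle = if (en$rotate) runif(1, -config$rotation_deg_max,
                                      config$rotation_deg_max) else 0,
         scale = if (en$scale) runif(1, config$scale_range[1],
                                     config$scale_range[2]) else 1,
         translate = if (en$translate)
           runif(3, -config$translate_frac_max, config$translate_frac_max) * d
         else c(0, 0, 0),
         noise_sd = if (en$noise) config$noise_sd else 0,
         noise_seed = child_seed(seed, "augment_noise"))
  })
  augment_apply(volume, mask, params)
}
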