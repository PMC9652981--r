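# Seeded generator of anisotropic CT-like phantoms with exact analytic lesion
# masks. Emulates the thick-slice regime of radiotherapy planning CT (slice
# spacing ~5x the in-plane pixel spacing) with a single soft-tissue lesion on
# an air-like background, so the full pipeline is testable without clinical
# data. Lesion membership is decided at voxel centers in physical mm
# coordinates with no partial-volume antialiasing, keeping the mask
# oracle-checkable against the ellipsoid inequality.

#' Specify a synthetic CT phantom
#'
#' @param shape_voxels Positive integers `c(depth, height, width)`. The
#'   default 32 x 96 x 96 keeps the 5:1 slice anisotropy while staying fast
#'   on a single CPU.
#' @param spacing_mm Positive reals `c(slice, row, col)` in mm; default
#'   `c(5, 1, 1)` (slice thickness about 5x the pixel spacing).
#' @param lesion_kind `"ellipsoid"` or `"lobulated"` (a connected union of
#'   `n_lobes` jittered ellipsoids, mimicking irregular tumor margins).
#' @param lesion_semiaxes_mm Three positive semiaxes in mm (depth, height,
#'   width directions).
#' @param lesion_center_frac Lesion center as a fraction of each axis extent,
#'   each in (0, 1).
#' @param lesion_hu,background_hu Lesion and background intensities in HU
#'   (defaults 40 / -800: soft-tissue lesion in aerated lung).
#' @param noise_sd_hu Additive Gaussian noise standard deviation in HU.
#' @param n_lobes Number of lobes for the lobulated kind.
#' @return A `phantom_spec`.
#' @export
phantom_spec <- function(shape_voxels = c(32L, 96L, 96L),
                         spacing_mm = c(5, 1, 1),
                         lesion_kind = c("ellipsoid", "lobulated"),
                         lesion_semiaxes_mm = c(15, 15, 15),
                         lesion_center_frac = c(0.5, 0.5, 0.5),
                         lesion_hu = 40, background_hu = -800,
                         noise_sd_hu = 20, n_lobes = 3L) {
  lesion_kind <- match.arg(lesion_kind)
  spec <- structure(list(shape_voxels = as.integer(shape_voxels),
                         spacing_mm = as.numeric(spacing_mm),
                         lesion_kind = lesion_kind,
                         lesion_semiaxes_mm = as.numeric(lesion_semiaxes_mm),
                         lesion_center_frac = as.numeric(lesion_center_frac),
                         lesion_hu = lesion_hu, background_hu = background_hu,
                         noise_sd_hu = noise_sd_hu, n_lobes = as.integer(n_lobes)),
                    class = "phantom_spec")
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  with(spec, {
    if (length(shape_voxels) != 3 || any(shape_voxels < 1))
      stop_gtv("shape_voxels must be 3 positive integers")
    if (length(spacing_mm) != 3 || any(spacing_mm <= 0))
      stop_gtv("spacing_mm must be 3 positive reals")
    if (any(lesion_semiaxes_mm <= 0))
      stop_gtv("lesion_semiaxes_mm must be positive")
    if (any(lesion_center_frac <= 0) || any(lesion_center_frac >= 1))
      stop_gtv("lesion_center_frac must lie strictly in (0, 1)")
    if (noise_sd_hu < 0) stop_gtv("noise_sd_hu must be nonnegative")
    if (n_lobes < 1) stop_gtv("n_lobes must be >= 1")
    # the whole lesion (center +/- semiaxes) must fit inside the volume
    extent <- (shape_voxels - 1) * spacing_mm
    ctr <- lesion_center_frac * extent
    for (ax in 1:3) {
      if (ctr[ax] - lesion_semiaxes_mm[ax] < 0 ||
          ctr[ax] + lesion_semiaxes_mm[ax] > extent[ax])
        stop_gtv("lesion does not fit inside the volume along the %s axis",
                 axis_names[ax])
    }
  })
  invisible(spec)
}

# Voxel-center coordinates along one axis, in mm (0-based index * spacing).
axis_coords <- function(n, spacing) (seq_len(n) - 1) * spacing

ellipsoid_mask <- function(shape, spacing, center, semi) {
  q <- lapply(1:3, function(ax) ((axis_coords(shape[ax], spacing[ax]) - center[ax]) / semi[ax])^2)
  outer(outer(q[[1]], q[[2]], "+"), q[[3]], "+") <= 1
}

#' Generate one phantom case
#'
#' Deterministic for a fixed `(spec, seed)`. The master seed spawns separate
#' `"geometry"` and `"noise"` child streams, so changing the noise level
#' never moves the lesion. The mask is the exact analytic lesion support at
#' voxel centers; the volume is `background_hu` plus the lesion contrast
#' inside the mask plus additive Gaussian noise.
#'
#' @param spec A [phantom_spec()].
#' @param seed Integer seed.
#' @return A `phantom_case`: list with `volume` (`ct_volume`, HU), `mask`
#'   (`ct_mask`), `spec`, `seed`.
#' @export
generate_phantom <- function(spec, seed = 1L) {
  validate_phantom_spec(spec)
  shape <- spec$shape_voxels; sp <- spec$spacing_mm
  extent <- (shape - 1) * sp
  ctr <- spec$lesion_center_frac * extent

  mask <- with_seed_(child_seed(seed, "geometry"), {
    if (spec$lesion_kind == "ellipsoid") {
      ellipsoid_mask(shape, sp, ctr, spec$lesion_semiaxes_mm)
    } else {
      # union of n_lobes ellipsoids: offsets <= 0.3 semiaxes, lobe size
      # 0.4-0.7 of the spec semiaxes -> every lobe covers the main center,
      # so the union is connected and stays inside the spec envelope
      m <- array(FALSE, shape)
      for (k in seq_len(spec$n_lobes)) {
        off <- runif(3, -0.3, 0.3) * spec$lesion_semiaxes_mm
        semi <- runif(1, 0.4, 0.7) * spec$lesion_semiaxes_mm
        m <- m | ellipsoid_mask(shape, sp, ctr + off, semi)
      }
      m
    }
  })
  if (!any(mask)) stop_gtv("degenerate phantom: empty lesion mask")

  vol <- array(spec$background_hu, shape)
  vol[mask] <- spec$lesion_hu
  if (spec$noise_sd_hu > 0) {
    vol <- vol + with_seed_(child_seed(seed, "noise"),
                            array(rnorm(prod(shape), 0, spec$noise_sd_hu), shape))
  }
  mask_arr <- array(0L, shape); mask_arr[mask] <- 1L
  structure(list(volume = new_volume(vol, sp, "HU"),
                 mask = new_mask(mask_arr, sp),
                 spec = spec, seed = as.integer(seed)),
            class = "phantom_case")
}

default_jitter <- function() {
  list(semiaxes_scale = c(0.7, 1.2), center_frac = c(0.35, 0.65))
}

#' Generate the i-th case of a phantom dataset
#'
#' Case parameters are drawn within the jitter ranges from an independent
#' per-case child stream of `seed`, so case `i` is reproducible without
#' generating the other cases.
#'
#' @param spec_template A [phantom_spec()] giving the base geometry.
#' @param jitter Named list of ranges: `semiaxes_scale` (multiplier on all
#'   semiaxes) and `center_frac` (per-axis center fraction range).
#'   Zero-width ranges are allowed; inverted (empty) ranges are an error.
#' @param seed Master integer seed of the dataset.
#' @param index Case index (1-based).
#' @return A `phantom_case`.
#' @export
generate_case <- function(spec_template, jitter = default_jitter(), seed = 1L,
                          index = 1L) {
  jitter <- utils::modifyList(default_jitter(), jitter %||% list())
  for (nm in names(jitter)) {
    rg <- jitter[[nm]]
    if (length(rg) != 2 || rg[2] < rg[1])
      stop_gtv("jitter range '%s' is empty or malformed", nm)
  }
  cseed <- child_seed(seed, paste0("case", index))
  spec_i <- with_seed_(child_seed(cseed, "params"), {
    s <- spec_template
    s$lesion_semiaxes_mm <- s$lesion_semiaxes_mm * runif(1, jitter$semiaxes_scale[1],
                                                         jitter$semiaxes_scale[2])
    s$lesion_center_frac <- runif(3, jitter$center_frac[1], jitter$center_frac[2])
    validate_phantom_spec(s)
    s
  })
  generate_phantom(spec_i, cseed)
}

#' Generate a dataset of phantom cases
#'
#' @inheritParams generate_case
#' @param n_cases Number of cases (>= 1).
#' @return A list of `phantom_case` objects.
#' @export
generate_dataset <- function(n_cases, spec_template = phantom_spec(),
                             jitter = default_jitter(), seed = 1L) {
  if (n_cases < 1) stop_gtv("n_cases must be >= 1")
  lapply(seq_len(n_cases), function(i)
    generate_case(spec_template, jitter, seed, i))
}

#' Write a phantom case to NIfTI files
#'
#' @param case A `phantom_case`.
#' @param dir Output directory (created if needed).
#' @param stem File stem; writes `<stem>_volume.nii.gz` and
#'   `<stem>_mask.nii.gz`.
#' @return The two paths, invisibly.
#' @export
write_phantom_case <- function(case, dir, stem = sprintf("case%03d", case$seed)) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pv <- file.path(dir, paste0(stem, "_volume.nii.gz"))
  pm <- file.path(dir, paste0(stem, "_mask.nii.gz"))
  write_volume(case$volume, pv)
  write_mask(case$mask, pm)
  invisible(c(pv, pm))
}
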