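# Volume and mask containers. Arrays are (depth, height, width); spacing is
# (slice, row, col) in mm. Intensity domains track the preprocessing state:
# raw Hounsfield units, the windowed 0-255 mapping, or network-ready [0,1].

INTENSITY_DOMAINS <- c("HU", "mapped_0_255", "normalized_0_1")

#' Construct a CT volume
#'
#' @param data A finite numeric 3D array `(depth, height, width)`.
#' @param spacing_mm Positive spacing `c(slice, row, col)` in mm.
#' @param domain Intensity domain: `"HU"`, `"mapped_0_255"` or
#'   `"normalized_0_1"`.
#' @return A `ct_volume`.
#' @export
new_volume <- function(data, spacing_mm, domain = "HU") {
  domain <- match.arg(domain, INTENSITY_DOMAINS)
  if (!is.array(data) || length(dim(data)) != 3)
    stop_gtv("volume data must be a 3D array (got %s dims)",
             paste(dim(data) %||% length(data), collapse = "x"))
  if (!all(is.finite(data))) stop_gtv("volume data must be finite")
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) != 3 || any(spacing_mm <= 0))
    stop_gtv("spacing_mm must be 3 positive reals")
  structure(list(data = data, spacing_mm = spacing_mm, domain = domain),
            class = "ct_volume")
}

#' Construct a binary mask aligned with a volume
#'
#' @param data A 3D array with values in `{0, 1}`.
#' @param spacing_mm Positive spacing `c(slice, row, col)` in mm.
#' @return A `ct_mask` (integer storage).
#' @export
new_mask <- function(data, spacing_mm) {
  if (!is.array(data) || length(dim(data)) != 3)
    stop_gtv("mask data must be a 3D array")
  if (!all(data %in% c(0, 1)))
    stop_gtv("mask values must be 0 or 1")
  storage.mode(data) <- "integer"
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) != 3 || any(spacing_mm <= 0))
    stop_gtv("spacing_mm must be 3 positive reals")
  structure(list(data = data, spacing_mm = spacing_mm), class = "ct_mask")
}

#' @export
print.ct_volume <- function(x, ...) {
  cat(sprintf("<ct_volume> %s voxels, spacing %s mm, domain %s, range [%.5g, %.5g]\n",
              paste(dim(x$data), collapse = "x"),
              paste(x$spacing_mm, collapse = "x"), x$domain,
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
print.ct_mask <- function(x, ...) {
  cat(sprintf("<ct_mask> %s voxels, spacing %s mm, %d foreground\n",
              paste(dim(x$data), collapse = "x"),
              paste(x$spacing_mm, collapse = "x"), sum(x$data)))
  invisible(x)
}

mask_data <- function(m) if (inherits(m, "ct_mask")) m$data else m

check_aligned <- function(volume, mask) {
  if (!all(dim(volume$data) == dim(mask$data)))
    stop_gtv("volume (%s) and mask (%s) shapes differ",
             paste(dim(volume$data), collapse = "x"),
             paste(dim(mask$data), collapse = "x"))
  if (!isTRUE(all.equal(volume$spacing_mm, mask$spacing_mm)))
    stop_gtv("volume and mask spacing differ")
  invisible(TRUE)
}
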