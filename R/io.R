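# NIfTI interchange. Internally arrays are (depth, height, width) with
# spacing (slice, row, col); on disk the NIfTI axes are (col, row, slice)
# with matching pixdim, so files read correctly in standard viewers.

arr_to_nifti <- function(arr, spacing_mm) {
  im <- RNifti::asNifti(aperm(arr, c(3, 2, 1)))
  RNifti::`pixdim<-`(im, spacing_mm[c(3, 2, 1)])
}

nifti_to_arr <- function(path, what) {
  im <- RNifti::readNifti(path)
  d <- dim(im)
  if (length(d) != 3)
    stop_gtv("%s: expected a 3D image, got %d dimensions", what, length(d))
  sp <- RNifti::pixdim(im)[c(3, 2, 1)]
  if (any(sp <= 0)) stop_gtv("%s: non-positive voxel spacing in header", what)
  list(arr = aperm(as.array(im), c(3, 2, 1)), spacing = sp)
}

#' Read and write volumes and masks as NIfTI
#'
#' Write-then-read round trips preserve the voxel data bitwise (float64
#' volumes, uint8 masks) and the anisotropic spacing. Non-3D images are
#' rejected.
#'
#' @param path A `.nii` / `.nii.gz` file path.
#' @param domain Intensity domain to tag the volume with on read.
#' @return `read_volume()` a `ct_volume`; `read_mask()` a `ct_mask`.
#' @export
read_volume <- function(path, domain = "HU") {
  if (!file.exists(path)) stop_gtv("volume file not found: %s", path)
  r <- nifti_to_arr(path, "read_volume")
  new_volume(r$arr, r$spacing, domain)
}

#' @rdname read_volume
#' @param volume A `ct_volume`.
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "ct_volume"))
  RNifti::writeNifti(arr_to_nifti(volume$data, volume$spacing_mm), path,
                     datatype = "double")
  invisible(path)
}

#' @rdname read_volume
#' @export
read_mask <- function(path) {
  if (!file.exists(path)) stop_gtv("mask file not found: %s", path)
  r <- nifti_to_arr(path, "read_mask")
  if (!all(r$arr %in% c(0, 1)))
    stop_gtv("read_mask: file contains non-binary labels")
  new_mask(r$arr, r$spacing)
}

#' @rdname read_volume
#' @param mask A `ct_mask`.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "ct_mask"))
  RNifti::writeNifti(arr_to_nifti(mask$data, mask$spacing_mm), path,
                     datatype = "uint8")
  invisible(path)
}
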