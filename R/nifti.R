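# NIfTI-1 read/write via RNifti. Internally volumes are indexed [z, y, x];
# NIfTI arrays are [x, y, z], so axes are permuted at the boundary.

#' Read a 3D NIfTI volume
#'
#' @param path a `.nii` or `.nii.gz` file containing a 3D image.
#' @param intensity_scale intensity scale tag to attach; see [ct_volume()].
#' @return A [ct_volume()].
#' @export
read_nifti <- function(path, intensity_scale = "HU") {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L)
    stop_nc("expected a 3D NIfTI volume, got ", length(d), "D")
  arr <- aperm(as.array(img), c(3, 2, 1))
  pd <- RNifti::pixdim(img)
  xf <- try(RNifti::xform(img), silent = TRUE)
  origin <- if (!inherits(xf, "try-error") && is.matrix(xf)) rev(xf[1:3, 4]) else c(0, 0, 0)
  if (intensity_scale == "normalized8bit") {
    arr <- pmin(pmax(arr, 0), 255)
    dim(arr) <- c(d[3], d[2], d[1])
  }
  ct_volume(arr, spacing_mm = rev(pd[1:3]), origin_mm = origin,
            intensity_scale = intensity_scale)
}

nifti_from_volume <- function(arr_zyx, v) {
  img <- RNifti::asNifti(aperm(arr_zyx, c(3, 2, 1)))
  RNifti::pixdim(img) <- rev(v$spacing_mm)
  img
}

#' Write a CT volume as NIfTI
#'
#' @param v a [ct_volume()].
#' @param path output `.nii` or `.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_volume_nifti <- function(v, path) {
  stopifnot(inherits(v, "ct_volume"))
  RNifti::writeNifti(nifti_from_volume(v$intensities, v), path)
  invisible(path)
}

#' Write a binary mask as NIfTI
#'
#' The mask is written as 8-bit integers on the grid of the reference volume.
#'
#' @param mask logical or 0/1 array shaped like `like`, or a [lung mask][extract_lungs].
#' @param like the [ct_volume()] the mask is aligned to.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mask_nifti <- function(mask, like, path) {
  if (inherits(mask, "lung_mask")) mask <- mask$mask
  if (!identical(dim(mask), dim(like$intensities)))
    stop_nc("mask shape does not match reference volume")
  arr <- array(as.integer(mask), dim = dim(mask))
  img <- nifti_from_volume(arr, like)
  RNifti::writeNifti(img, path, datatype = "uint8")
  invisible(path)
}
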