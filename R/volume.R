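#' CT volume container
#'
#' A `ct_volume` holds a 3D intensity grid indexed `[z, y, x]` together with
#' per-axis voxel spacing in mm. Physical coordinates follow the voxel-center
#' convention: the center of voxel `(i, j, k)` (1-based indices along z, y, x)
#' is `origin_mm + (index - 1) * spacing_mm` on each axis.
#'
#' @param intensities numeric 3D array, dimensions `(nz, ny, nx)`.
#' @param spacing_mm positive numeric length 3, `(dz, dy, dx)` in mm.
#' @param origin_mm numeric length 3, `(z0, y0, x0)` in mm.
#' @param intensity_scale `"HU"` (Hounsfield units) or `"normalized8bit"`
#'   (values in `[0, 255]`).
#'
#' @return An object of class `ct_volume`.
#' @export
ct_volume <- function(intensities, spacing_mm, origin_mm = c(0, 0, 0),
                      intensity_scale = c("HU", "normalized8bit")) {
  intensity_scale <- match.arg(intensity_scale)
  if (!is.array(intensities) || length(dim(intensities)) != 3L)
    stop_nc("intensities must be a 3D array")
  if (any(dim(intensities) < 1L)) stop_nc("intensities grid is empty")
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) != 3L || any(!is.finite(spacing_mm)) || any(spacing_mm <= 0))
    stop_nc("spacing_mm must be 3 positive values (dz, dy, dx)")
  if (intensity_scale == "normalized8bit") {
    rng <- range(intensities)
    if (rng[1] < -1e-9 || rng[2] > 255 + 1e-9)
      stop_nc("normalized8bit intensities must lie in [0, 255]")
  }
  structure(
    list(
      intensities = intensities,
      spacing_mm = spacing_mm,
      origin_mm = as.numeric(origin_mm),
      intensity_scale = intensity_scale
    ),
    class = "ct_volume"
  )
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$intensities)
  cat(sprintf(
    "<ct_volume> %d x %d x %d voxels (z,y,x), spacing %.3g x %.3g x %.3g mm, scale %s\n",
    d[1], d[2], d[3], x$spacing_mm[1], x$spacing_mm[2], x$spacing_mm[3],
    x$intensity_scale
  ))
  cat(sprintf("  intensity range [%.4g, %.4g]\n", min(x$intensities), max(x$intensities)))
  invisible(x)
}

#' @export
dim.ct_volume <- function(x) dim(x$intensities)

# mm coordinates of voxel centers given 1-based (z,y,x) index matrix
voxel_centers_mm <- function(idx, v) {
  sweep(sweep(idx - 1, 2, v$spacing_mm, "*"), 2, v$origin_mm, "+")
}

#' Normalize a volume to the 8-bit range
#'
#' Linear min-max rescale of all intensities to `[0, 255]`. A constant volume
#' maps to all zeros. The transform is monotone, so voxel intensity ordering
#' is preserved.
#'
#' @param v a [ct_volume()].
#' @return A `ct_volume` with `intensity_scale = "normalized8bit"`.
#' @export
normalize_volume <- function(v) {
  stopifnot(inherits(v, "ct_volume"))
  rng <- range(v$intensities)
  arr <- if (rng[2] > rng[1]) {
    (v$intensities - rng[1]) / (rng[2] - rng[1]) * 255
  } else {
    array(0, dim = dim(v$intensities))
  }
  ct_volume(arr, v$spacing_mm, v$origin_mm, "normalized8bit")
}
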