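#' 256-bin intensity histogram
#'
#' Bin k (k = 0..255) counts voxels with `floor(intensity) == k`; intensities
#' of exactly 255 fall in the last bin. Counts sum to the voxel count.
#'
#' @param v a [ct_volume()] with intensities in `[0, 255]` (see
#'   [normalize_volume()]).
#' @return Integer vector of length 256 named by bin intensity 0..255.
#' @export
histogram256 <- function(v) {
  stopifnot(inherits(v, "ct_volume"))
  x <- v$intensities
  if (min(x) < -1e-9 || max(x) > 255 + 1e-9)
    stop_nc("histogram256 expects intensities in [0, 255]; normalize first")
  idx <- pmin(floor(x), 255) + 1L
  counts <- tabulate(idx, nbins = 256L)
  names(counts) <- 0:255
  counts
}

# Kittler-Illingworth criterion J(t) for every interior threshold t, where
# class 1 = bins 0..t and class 2 = bins (t+1)..255. Gaussian class models
# with a sigma^2 floor of 1/12 (quantization variance) to keep log finite for
# single-bin classes.
min_error_criterion <- function(hist_counts) {
  stopifnot(length(hist_counts) == 256L)
  g <- 0:255
  c_ <- as.numeric(hist_counts)
  N <- sum(c_)
  cw <- cumsum(c_)
  cm <- cumsum(c_ * g)
  cs <- cumsum(c_ * g^2)
  t <- 0:254
  n1 <- cw[t + 1]; n2 <- N - n1
  P1 <- n1 / N; P2 <- n2 / N
  mu1 <- ifelse(n1 > 0, cm[t + 1] / n1, 0)
  mu2 <- ifelse(n2 > 0, (cm[256] - cm[t + 1]) / n2, 0)
  v1 <- ifelse(n1 > 0, cs[t + 1] / n1 - mu1^2, 0)
  v2 <- ifelse(n2 > 0, (cs[256] - cs[t + 1]) / n2 - mu2^2, 0)
  v1 <- pmax(v1, 1 / 12)
  v2 <- pmax(v2, 1 / 12)
  J <- 1 + 2 * (P1 * log(sqrt(v1)) + P2 * log(sqrt(v2))) -
    2 * (ifelse(P1 > 0, P1 * log(P1), 0) + ifelse(P2 > 0, P2 * log(P2), 0))
  J[n1 == 0 | n2 == 0] <- Inf
  J
}

#' Minimum-error (Kittler-Illingworth) threshold
#'
#' Exhaustively minimizes the minimum-error criterion
#' `J(t) = 1 + 2[P1 ln sigma1 + P2 ln sigma2] - 2[P1 ln P1 + P2 ln P2]`
#' over all interior thresholds of a 256-bin histogram, modeling the two
#' classes as Gaussians. Ties break toward the smaller threshold. The returned
#' cut is `t* + 0.5`: class 1 is all intensities below the cut.
#'
#' @param hist_counts 256 bin counts, e.g. from [histogram256()].
#' @return The threshold cut (numeric scalar, halfway between bins).
#' @export
minimum_error_threshold <- function(hist_counts) {
  if (length(hist_counts) != 256L) stop_nc("expected 256 bin counts")
  if (sum(hist_counts > 0) < 2L)
    stop_nc("histogram has fewer than 2 nonzero bins; no bimodality to threshold")
  J <- min_error_criterion(hist_counts)
  t_star <- which.min(J) - 1L  # which.min takes the first (smallest t) on ties
  t_star + 0.5
}

#' Extract the lungs from a chest volume
#'
#' Implements the lung-extraction stage: (1) binarize at the minimum-error
#' threshold, keeping the dark (air/lung) side; (2) per slice, remove binary
#' components touching the in-plane border (outside air, scanner bed);
#' (3) keep the largest one or two remaining 3D components (26-connectivity) -
#' the second is kept only if at least `second_lung_min_frac` of the largest,
#' since a fused lung region can present as a single component; (4) reconstruct
#' the pleural surface by per-slice morphological closing with a small disc
#' (radius `closing_radius_mm`) followed by slice-wise hole filling, so bright
#' internal structures and pleura-attached nodules are recovered into the
#' mask. Hole filling alone cannot restore a pleural bite that stays open to
#' the chest wall on its widest slices; the closing seals the mouth of such
#' bites first (the rolling-ball idea). The closing radius must stay well
#' below half the inter-lung gap or the mediastinum would be swallowed.
#'
#' @param v a normalized [ct_volume()] (see [normalize_volume()]).
#' @param second_lung_min_frac minimum relative size for keeping a second
#'   component (default 0.1).
#' @param closing_radius_mm structuring-disc radius for pleural reconstruction
#'   (default 3.5 mm; 0 disables the closing).
#' @return An object of class `lung_mask`: list with `mask` (logical array),
#'   `threshold_used`, and `components_kept`.
#' @export
extract_lungs <- function(v, second_lung_min_frac = 0.1, closing_radius_mm = 3.5) {
  stopifnot(inherits(v, "ct_volume"))
  h <- histogram256(v)
  if (sum(h > 0) < 2L) stop_nc("no lungs detected: volume has a single intensity level")
  cut <- minimum_error_threshold(h)

  # dark side = the class holding the lower-intensity histogram mode
  below <- h[as.integer(names(h)) < cut]
  above <- h[as.integer(names(h)) >= cut]
  dark_is_low <- TRUE
  if (length(above) && length(below)) {
    # on CT the air/lung class is the lower mode; assert the convention holds
    dark_is_low <- as.integer(names(which.max(below))) <
      as.integer(names(which.max(above)))
  }
  dark <- if (dark_is_low) v$intensities < cut else v$intensities >= cut

  coords <- which_coords(dark)
  if (nrow(coords) == 0L) stop_nc("no lungs detected: no dark voxels below threshold")

  # (2) drop 2D components touching the in-plane border, slice by slice
  memb2d <- slicewise_components(coords, dim(dark), offsets_2d_8())
  d <- dim(dark)
  on_border <- coords[, 2] == 1L | coords[, 2] == d[2] |
    coords[, 3] == 1L | coords[, 3] == d[3]
  border_comps <- unique(memb2d[on_border])
  keep <- !(memb2d %in% border_comps)
  coords <- coords[keep, , drop = FALSE]
  if (nrow(coords) == 0L) stop_nc("no lungs detected: all dark components touch the border")

  # (3) largest one or two 3D components
  memb3d <- connected_components(coords, d, offsets_3d_26())
  sizes <- sort(table(memb3d), decreasing = TRUE)
  kept_ids <- as.integer(names(sizes)[1])
  if (length(sizes) >= 2 && sizes[2] >= second_lung_min_frac * sizes[1])
    kept_ids <- c(kept_ids, as.integer(names(sizes)[2]))
  coords <- coords[memb3d %in% kept_ids, , drop = FALSE]

  mask <- array(FALSE, dim = d)
  mask[coords] <- TRUE

  # (4) pleural reconstruction: seal bite mouths, then fill enclosed holes
  if (closing_radius_mm > 0) {
    r_px <- round(closing_radius_mm / min(v$spacing_mm[2:3]))
    if (r_px >= 1) {
      brush <- EBImage::makeBrush(2L * r_px + 1L, shape = "disc")
      for (z in seq_len(d[1])) {
        if (!any(mask[z, , ])) next
        closed <- EBImage::closing(mask[z, , ] * 1, brush)
        mask[z, , ] <- closed > 0.5
      }
    }
  }
  mask <- fill_holes_volume(mask)

  structure(
    list(mask = mask, threshold_used = cut, components_kept = length(kept_ids)),
    class = "lung_mask"
  )
}

#' @export
print.lung_mask <- function(x, ...) {
  cat(sprintf("<lung_mask> %s voxels, threshold %.1f, %d component(s) kept\n",
              format(sum(x$mask), big.mark = ","), x$threshold_used,
              x$components_kept))
  invisible(x)
}
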