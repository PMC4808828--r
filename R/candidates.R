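# Candidate segmentation: 2D per-slice structure filtering, then 3D candidate
# formation under 26-connectivity with blob-shape discrimination.

# Otsu threshold of a vector of intensities on the 0-255 scale
otsu_threshold <- function(values) {
  stopifnot(length(values) > 0)
  x <- array(pmin(pmax(values, 0), 255) / 255, dim = c(length(values), 1L))
  EBImage::otsu(x, range = c(0, 1), levels = 256L) * 255
}

#' Label bright structures in one axial slice
#'
#' Connected components (8-connectivity in-plane) of the above-threshold
#' pixels inside the lung mask, with per-structure area and mean intensity.
#' When `threshold` is `NULL`, it is set by Otsu's method on the lung-interior
#' intensities of the slice.
#'
#' @param slice 2D numeric matrix `[y, x]` of intensities.
#' @param lung_mask_slice logical matrix of the same shape.
#' @param threshold intensity above which a pixel is a structure; `NULL` for
#'   Otsu on the in-mask intensities.
#' @param slice_index optional slice index recorded on the output.
#' @return Tibble with `slice_index`, `structure_id`, `pixels` (list of
#'   integer matrices with columns y, x), `area_px`, `mean_intensity`.
#' @export
label_slice_structures <- function(slice, lung_mask_slice, threshold = NULL,
                                   slice_index = NA_integer_) {
  if (!is.matrix(slice) || !identical(dim(slice), dim(lung_mask_slice)))
    stop_nc("slice and lung_mask_slice must be matrices of identical shape")
  mask <- lung_mask_slice != 0
  empty <- tibble::tibble(
    slice_index = integer(0), structure_id = integer(0), pixels = list(),
    area_px = integer(0), mean_intensity = numeric(0)
  )
  if (!any(mask)) return(empty)
  if (is.null(threshold)) threshold <- otsu_threshold(slice[mask])
  bright <- mask & slice > threshold
  coords <- which_coords(bright)
  if (nrow(coords) == 0L) return(empty)
  memb <- connected_components(coords, dim(slice), offsets_2d_8())
  idx <- split(seq_len(nrow(coords)), memb)
  tibble::tibble(
    slice_index = as.integer(slice_index),
    structure_id = as.integer(names(idx)),
    pixels = lapply(idx, function(i) {
      m <- coords[i, , drop = FALSE]
      colnames(m) <- c("y", "x")
      m
    }),
    area_px = lengths(idx),
    mean_intensity = vapply(idx, function(i) mean(slice[coords[i, , drop = FALSE]]), 0)
  )
}

#' Filter slice structures by area and intensity
#'
#' Keeps exactly the structures for which both indicators agree:
#' `area_px >= area_min_px` AND `mean_intensity >= intensity_min`. The removed
#' structures, with the indicator that failed, are attached as the
#' `"removed"` attribute of the result.
#'
#' @param structs tibble from [label_slice_structures()].
#' @param area_min_px minimum pixel area (see [area_floor_from_spacing()]).
#' @param intensity_min minimum mean intensity.
#' @return The surviving rows of `structs`.
#' @export
filter_slice_structures <- function(structs, area_min_px, intensity_min) {
  stopifnot(area_min_px >= 0, intensity_min >= 0)
  ok_area <- structs$area_px >= area_min_px
  ok_int <- structs$mean_intensity >= intensity_min
  keep <- ok_area & ok_int
  removed <- structs[!keep, , drop = FALSE]
  if (nrow(removed)) {
    removed$failed <- dplyr::case_when(
      !ok_area[!keep] & !ok_int[!keep] ~ "area+intensity",
      !ok_area[!keep] ~ "area",
      TRUE ~ "intensity"
    )
  }
  out <- structs[keep, , drop = FALSE]
  attr(out, "removed") <- removed
  out
}

#' Pixel-area floor implied by the minimum nodule diameter
#'
#' The equatorial cross-section of the smallest nodule of interest (default
#' diameter 4 mm, below which malignancy is negligible) covers
#' `ceil(pi * (d/2)^2 / (dy * dx))` pixels; structures smaller than this in
#' every slice cannot be such a nodule.
#'
#' @param spacing_mm voxel spacing; either `(dz, dy, dx)` or `(dy, dx)`.
#' @param min_diameter_mm minimum nodule diameter in mm (0 disables the floor).
#' @return Integer pixel count.
#' @export
area_floor_from_spacing <- function(spacing_mm, min_diameter_mm = 4.0) {
  spacing_mm <- as.numeric(spacing_mm)
  stopifnot(all(spacing_mm > 0), min_diameter_mm >= 0)
  k <- length(spacing_mm)
  if (!k %in% c(2L, 3L)) stop_nc("spacing_mm must have 2 or 3 elements")
  dy <- spacing_mm[k - 1]; dx <- spacing_mm[k]
  as.integer(ceiling(pi * (min_diameter_mm / 2)^2 / (dy * dx)))
}

#' Blob shape scores of a candidate
#'
#' Sphericity is the candidate volume divided by the volume of the sphere
#' whose radius is the maximum distance (mm) from the candidate centroid to
#' any member voxel center, clipped to `(0, 1]`; a compact blob scores near 1,
#' a tube scores near 0. Width is the shortest bounding-box edge in mm. A
#' single-voxel candidate uses half the largest spacing as its radius and has
#' sphericity 1 by convention.
#'
#' @param voxels integer matrix of `(z, y, x)` voxel indices.
#' @param spacing_mm voxel spacing `(dz, dy, dx)`.
#' @return List with `sphericity` and `width_mm`.
#' @export
blob_scores <- function(voxels, spacing_mm) {
  stopifnot(nrow(voxels) >= 1)
  spacing_mm <- as.numeric(spacing_mm)
  ext <- (apply(voxels, 2, max) - apply(voxels, 2, min) + 1) * spacing_mm
  width_mm <- min(ext)
  if (nrow(voxels) == 1L) {
    return(list(sphericity = 1, width_mm = width_mm))
  }
  pts <- sweep(voxels, 2, spacing_mm, "*")
  ctr <- colMeans(pts)
  r_max <- sqrt(max(rowSums(sweep(pts, 2, ctr)^2)))
  if (r_max <= 0) r_max <- max(spacing_mm) / 2
  vol <- nrow(voxels) * prod(spacing_mm)
  sph <- min(1, vol / (4 / 3 * pi * r_max^3))
  list(sphericity = sph, width_mm = width_mm)
}

# build the candidate tibble (geometry, blob scores) from labeled components
candidate_table <- function(components, v) {
  if (nrow(components) == 0L) {
    return(tibble::tibble(
      id = integer(0), voxels = list(), voxel_count = integer(0),
      cx_mm = numeric(0), cy_mm = numeric(0), cz_mm = numeric(0),
      LBB_mm = numeric(0), WBB_mm = numeric(0), HBB_mm = numeric(0),
      width_mm = numeric(0), elongation = numeric(0),
      volume_mm3 = numeric(0), sphericity = numeric(0)
    ))
  }
  sp <- v$spacing_mm
  rows <- purrr::map2(components$voxels, components$id, function(vox, id) {
    ctr <- colMeans(voxel_centers_mm(vox, v))
    ext <- (apply(vox, 2, max) - apply(vox, 2, min) + 1) * sp  # (z, y, x) mm
    bs <- blob_scores(vox, sp)
    tibble::tibble(
      id = id, voxel_count = nrow(vox),
      cx_mm = ctr[3], cy_mm = ctr[2], cz_mm = ctr[1],
      LBB_mm = ext[3], WBB_mm = ext[2], HBB_mm = ext[1],
      width_mm = bs$width_mm, elongation = max(ext) / min(ext),
      volume_mm3 = nrow(vox) * prod(sp), sphericity = bs$sphericity
    )
  })
  out <- dplyr::bind_rows(rows)
  out$voxels <- components$voxels
  dplyr::relocate(out, "id", "voxels", "voxel_count")
}

#' Discriminate candidates by blob shape
#'
#' Keeps candidates with `sphericity >= sphericity_min`,
#' `width_min_mm <= width_mm <= width_max_mm`, and bounding-box elongation
#' (longest edge over shortest) at most `elongation_max`. Rejected candidates,
#' with the failing test, are attached as the `"rejected"` attribute.
#'
#' @param cands candidate tibble from [detect_candidates()].
#' @param sphericity_min minimum sphericity (default 0.3).
#' @param width_min_mm,width_max_mm bounds on the shortest bounding-box edge
#'   in mm (defaults 2 and `Inf`; there is no upper size filter by default so
#'   large masses survive to classification). The lower bound must stay below
#'   the slice thickness: a 4-6 mm nodule legitimately survives the per-slice
#'   area floor in only one slice, making its z-edge a single slice thick.
#' @param elongation_max maximum bounding-box elongation (default 4).
#' @return The surviving rows of `cands`.
#' @export
discriminate_candidates <- function(cands, sphericity_min = 0.3,
                                    width_min_mm = 2.0, width_max_mm = Inf,
                                    elongation_max = 4.0) {
  ok_sph <- cands$sphericity >= sphericity_min
  ok_w <- cands$width_mm >= width_min_mm & cands$width_mm <= width_max_mm
  ok_e <- cands$elongation <= elongation_max
  keep <- ok_sph & ok_w & ok_e
  rejected <- cands[!keep, , drop = FALSE]
  if (nrow(rejected)) {
    rejected$failed <- purrr::pmap_chr(
      list(ok_sph[!keep], ok_w[!keep], ok_e[!keep]),
      function(s, w, e) paste(c("sphericity", "width", "elongation")[!c(s, w, e)],
                              collapse = "+")
    )
  }
  out <- cands[keep, , drop = FALSE]
  attr(out, "rejected") <- rejected
  out
}

#' Detect nodule candidates in a lung-masked volume
#'
#' Runs the candidate-segmentation stage: per-slice labeling of bright
#' structures inside the lung mask, area/intensity filtering (both indicators
#' must agree), 3D candidate formation under 26-connectivity, blob scoring,
#' and sphericity/width/elongation discrimination.
#'
#' @param v normalized [ct_volume()].
#' @param lungs a `lung_mask` from [extract_lungs()].
#' @param config a [pipeline_config()].
#' @return List with `candidates` (surviving candidate tibble), `all_candidates`
#'   (before discrimination), and `stage_counts` (tibble of per-stage structure
#'   counts).
#' @export
detect_candidates <- function(v, lungs, config = pipeline_config()) {
  stopifnot(inherits(v, "ct_volume"), inherits(lungs, "lung_mask"))
  if (!identical(dim(lungs$mask), dim(v$intensities)))
    stop_nc("lung mask shape does not match volume")
  d <- dim(v$intensities)

  in_mask <- v$intensities[lungs$mask]
  thr <- config$structure_threshold %||% otsu_threshold(in_mask)
  intensity_min <- config$intensity_min %||% thr
  area_min <- area_floor_from_spacing(v$spacing_mm, config$min_diameter_mm)

  bright <- lungs$mask & v$intensities > thr
  coords <- which_coords(bright)
  n_structs <- 0L
  if (nrow(coords) > 0L) {
    memb <- slicewise_components(coords, d, offsets_2d_8())
    n_structs <- length(unique(memb))
    # per-structure indicators: both must agree for a structure to survive
    area_px <- tapply(seq_along(memb), memb, length)
    mean_int <- tapply(v$intensities[coords], memb, mean)
    keep_struct <- as.integer(names(mean_int))[area_px >= area_min &
                                                 mean_int >= intensity_min]
    coords <- coords[memb %in% keep_struct, , drop = FALSE]
  }
  surv <- array(FALSE, dim = d)
  if (nrow(coords)) surv[coords] <- TRUE
  n_structs_kept <- if (nrow(coords)) {
    length(unique(slicewise_components(coords, d, offsets_2d_8())))
  } else 0L

  comps <- label_components_26(surv)
  cands <- candidate_table(comps, v)
  kept <- discriminate_candidates(
    cands,
    sphericity_min = config$sphericity_min,
    width_min_mm = config$width_min_mm,
    width_max_mm = config$width_max_mm,
    elongation_max = config$elongation_max
  )

  stage_counts <- tibble::tibble(
    stage = c("slice_structures", "slice_structures_filtered",
              "candidates_3d", "candidates_discriminated"),
    n = c(n_structs, n_structs_kept, nrow(cands), nrow(kept))
  )
  list(candidates = kept, all_candidates = cands, stage_counts = stage_counts,
       structure_threshold = thr, area_min_px = area_min)
}
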