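# Eight-descriptor feature set per candidate (d1..d8) and pairwise-correlation
# feature selection. d1/d2 are 2D descriptors measured on the candidate's
# largest-area axial cross-section; d3..d8 are volumetric.

largest_slice_pixels <- function(voxels) {
  zc <- table(voxels[, 1])
  z_best <- as.integer(names(zc))[which.max(zc)]  # smallest z on ties
  voxels[voxels[, 1] == z_best, c(2, 3), drop = FALSE]
}

#' Area descriptor d1
#'
#' Pixel count of the candidate's largest-area axial cross-section.
#'
#' @param voxels integer matrix of `(z, y, x)` voxel indices.
#' @return Integer pixel count.
#' @export
area_d1 <- function(voxels) {
  stopifnot(nrow(voxels) >= 1)
  nrow(largest_slice_pixels(voxels))
}

# maximum pairwise pixel-center distance + 1 px; a single pixel has diameter 1
pn_diameter_px <- function(pix) {
  if (nrow(pix) < 2) return(1)
  max(dist(pix)) + 1
}

#' Circularity descriptor d2
#'
#' `d2 = d1 / (4 * pi * (D / 2)^2)` on the largest-area axial cross-section,
#' with `D` the maximum pairwise pixel-center distance plus one pixel (so a
#' single pixel has `D = 1` and `d2 = 1/pi`). A large digital disk tends to
#' 1/4; elongated shapes score much lower.
#'
#' @inheritParams area_d1
#' @return Numeric circularity.
#' @export
circularity_d2 <- function(voxels) {
  pix <- largest_slice_pixels(voxels)
  d1 <- nrow(pix)
  D <- pn_diameter_px(pix)
  d1 / (4 * pi * (D / 2)^2)
}

#' Intensity statistics d3, d4, d8
#'
#' Mean (`d3`), population variance (`d4`), and sum (`d8`) of the volume
#' intensities over the candidate's voxels.
#'
#' @param voxels integer matrix of `(z, y, x)` voxel indices.
#' @param v the [ct_volume()] the candidate lives in.
#' @return Named list `d3`, `d4`, `d8`.
#' @export
intensity_stats <- function(voxels, v) {
  d <- dim(v$intensities)
  if (any(voxels < 1L) || any(sweep(voxels, 2, d, ">")))
    stop_nc("candidate voxel outside volume bounds")
  f <- v$intensities[voxels]
  n <- length(f)
  m <- mean(f)
  list(d3 = m, d4 = sum((f - m)^2) / n, d8 = sum(f))
}

#' Skewness descriptor d5
#'
#' Population-moment skewness `m3 / m2^(3/2)` with
#' `mk = mean((x - mean(x))^k)`, exactly as tabulated (no sample correction).
#'
#' @param values numeric vector, `n >= 2` with positive variance.
#' @return Numeric skewness.
#' @export
skewness_d5 <- function(values) {
  mom <- central_moments(values)
  mom$m3 / mom$m2^1.5
}

#' Kurtosis descriptor d6
#'
#' Population-moment kurtosis `m4 / m2^2` (raw, not excess: a normal
#' distribution scores 3, a uniform one 9/5).
#'
#' @inheritParams skewness_d5
#' @return Numeric kurtosis.
#' @export
kurtosis_d6 <- function(values) {
  mom <- central_moments(values)
  mom$m4 / mom$m2^2
}

central_moments <- function(values) {
  n <- length(values)
  if (n < 2) stop_nc("need at least 2 values for moment ratios")
  xc <- values - mean(values)
  m2 <- mean(xc^2)
  if (m2 <= 0) stop_nc("undefined moment ratio: zero variance")
  list(m2 = m2, m3 = mean(xc^3), m4 = mean(xc^4))
}

#' Bounding-box volume descriptor d7
#'
#' Product of the axis-aligned bounding-box edge lengths in mm, each edge
#' being `(index extent + 1) * spacing`.
#'
#' @inheritParams area_d1
#' @param spacing_mm voxel spacing `(dz, dy, dx)`.
#' @return Volume in mm^3.
#' @export
volume_box_d7 <- function(voxels, spacing_mm) {
  stopifnot(nrow(voxels) >= 1)
  ext <- (apply(voxels, 2, max) - apply(voxels, 2, min) + 1) * as.numeric(spacing_mm)
  prod(ext)
}

FEATURE_NAMES <- paste0("d", 1:8)

#' Feature matrix of a candidate set
#'
#' One row per candidate with the eight descriptors in fixed column order
#' d1..d8: largest-slice area (d1) and circularity (d2), mean/variance/sum of
#' intensity (d3, d4, d8), skewness (d5), kurtosis (d6), and bounding-box
#' volume (d7). Columns `id` and, when present on `cands`, `scan_id` and
#' `label` are carried through.
#'
#' @param cands candidate tibble (see [detect_candidates()]).
#' @param v the [ct_volume()] the candidates were segmented from.
#' @return A tibble with attribute `normalization = "raw"`.
#' @export
feature_matrix <- function(cands, v) {
  rows <- purrr::map(seq_len(nrow(cands)), function(i) {
    vox <- cands$voxels[[i]]
    f <- tryCatch({
      st <- intensity_stats(vox, v)
      vals <- v$intensities[vox]
      tibble::tibble(
        d1 = area_d1(vox), d2 = circularity_d2(vox),
        d3 = st$d3, d4 = st$d4,
        d5 = skewness_d5(vals), d6 = kurtosis_d6(vals),
        d7 = volume_box_d7(vox, v$spacing_mm), d8 = st$d8
      )
    }, error = function(e) {
      stop_nc("feature extraction failed for candidate id ", cands$id[i], ": ",
              conditionMessage(e))
    })
    f
  })
  out <- if (length(rows)) dplyr::bind_rows(rows) else
    tibble::as_tibble(stats::setNames(rep(list(numeric(0)), 8), FEATURE_NAMES))
  out <- tibble::add_column(out, id = cands$id %||% integer(0), .before = 1)
  if ("scan_id" %in% names(cands)) out <- tibble::add_column(out, scan_id = cands$scan_id, .before = 1)
  if ("label" %in% names(cands)) out$label <- cands$label
  attr(out, "normalization") <- "raw"
  class(out) <- c("nodule_features", class(out))
  out
}

#' Select features by pairwise correlation
#'
#' Greedy elimination of redundant features: while any pair of features has
#' absolute Pearson correlation above `r_max`, the member of the worst
#' (most-correlated) pair with the larger mean absolute correlation to all
#' other remaining features is dropped. Ties break toward keeping the earlier
#' column. Constant columns are dropped first with a warning since their
#' correlation is undefined.
#'
#' @param m feature matrix tibble (see [feature_matrix()]).
#' @param r_max correlation cutoff in `[0, 1)`; default 0.95. In the limit
#'   `r_max = 0` a single feature survives.
#' @param features character vector of feature column names to consider.
#' @return Character vector of surviving feature names.
#' @export
select_features_by_correlation <- function(m, r_max = 0.95,
                                           features = intersect(FEATURE_NAMES, names(m))) {
  stopifnot(r_max >= 0, r_max < 1)
  if (nrow(m) < 3) stop_nc("need at least 3 rows for correlation analysis")
  X <- as.matrix(m[, features, drop = FALSE])
  const <- apply(X, 2, function(col) sd(col) == 0 || !is.finite(sd(col)))
  if (any(const)) {
    warning("dropping constant feature column(s): ",
            paste(features[const], collapse = ", "), call. = FALSE)
    features <- features[!const]
    X <- X[, !const, drop = FALSE]
  }
  while (length(features) > 1) {
    R <- abs(cor(X))
    diag(R) <- 0
    if (max(R) <= r_max) break
    worst <- which(R == max(R), arr.ind = TRUE)[1, ]  # first = earliest pair
    i <- worst[["row"]]; j <- worst[["col"]]
    mean_abs <- colSums(R) / (ncol(R) - 1)
    drop_j <- if (mean_abs[j] > mean_abs[i]) j else if (mean_abs[i] > mean_abs[j]) i else max(i, j)
    features <- features[-drop_j]
    X <- X[, -drop_j, drop = FALSE]
  }
  features
}
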