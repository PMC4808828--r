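lattice_disk_voxels <- function(radius_px, z = 1L) {
  g <- expand.grid(y = -radius_px:radius_px, x = -radius_px:radius_px)
  g <- g[g$y^2 + g$x^2 <= radius_px^2, ]
  cbind(z = z, y = g$y + radius_px + 1L, x = g$x + radius_px + 1L)
}

test_that("d1 is the largest axial cross-section's pixel count", {
  expect_equal(area_d1(matrix(c(1L, 1L, 1L), 1)), 1L)
  disk <- lattice_disk_voxels(10)
  expect_equal(nrow(disk), 317L)  # lattice points with y^2 + x^2 <= 100
  expect_equal(area_d1(disk), 317L)
  square <- as.matrix(expand.grid(z = 1L, y = 1:5, x = 1:5))[, c("z", "y", "x")]
  expect_equal(area_d1(square), 25L)
  # two slices: the larger one wins
  expect_equal(area_d1(rbind(disk, cbind(z = 2L, square[, 2:3]))), 317L)
})

test_that("d2 evaluates the printed circularity formula", {
  single <- matrix(c(1L, 3L, 3L), 1)
  expect_equal(circularity_d2(single), 1 / pi, tolerance = 1e-12)

  disk <- lattice_disk_voxels(10)
  expect_equal(circularity_d2(disk), 317 / (pi * 21^2), tolerance = 1e-12)

  line <- cbind(z = 1L, y = 1L, x = 1:25)
  expect_equal(circularity_d2(line), 25 / (pi * 625), tolerance = 1e-12)
})

test_that("intensity statistics are exact and bounds-checked", {
  arr <- array(0, dim = c(2, 2, 3))
  arr[1, 1, 1] <- 10; arr[1, 1, 2] <- 20; arr[1, 1, 3] <- 30
  v <- ct_volume(arr, c(1, 1, 1), intensity_scale = "normalized8bit")
  vox <- cbind(z = 1L, y = 1L, x = 1:3)
  st <- intensity_stats(vox, v)
  expect_equal(st$d3, 20)
  expect_equal(st$d8, 60)
  expect_equal(st$d4, 200 / 3)

  cst <- intensity_stats(cbind(z = 2L, y = 2L, x = 1:3), v)
  expect_equal(cst$d4, 0)

  expect_error(intensity_stats(cbind(z = 5L, y = 1L, x = 1L), v), "bounds")

  set.seed(40)
  arr2 <- array(runif(60, 0, 255), dim = c(3, 4, 5))
  v2 <- ct_volume(arr2, c(1, 1, 1), intensity_scale = "normalized8bit")
  vox2 <- unique(cbind(sample(1:3, 12, TRUE), sample(1:4, 12, TRUE), sample(1:5, 12, TRUE)))
  st2 <- intensity_stats(vox2, v2)
  f <- apply(vox2, 1, function(i) arr2[i[1], i[2], i[3]])
  expect_equal(st2$d3, mean(f), tolerance = 1e-9)
  expect_equal(st2$d4, mean((f - mean(f))^2), tolerance = 1e-9)
  expect_equal(st2$d8, sum(f), tolerance = 1e-9)
})

test_that("skewness and kurtosis use population moments exactly as printed", {
  expect_equal(skewness_d5(c(1, 2, 3)), 0)

  x <- c(1, 2, 3, 4, 10)
  expect_equal(skewness_d5(x), 36 / 10^1.5, tolerance = 1e-12)
  expect_equal(kurtosis_d6(x), 278.8 / 100, tolerance = 1e-12)

  expect_error(skewness_d5(c(5, 5, 5)), "zero variance")
  expect_error(kurtosis_d6(7), "at least 2")
})

test_that("kurtosis calibrates to 3 on normal and 9/5 on uniform samples", {
  set.seed(606)
  expect_equal(kurtosis_d6(rnorm(2e5)), 3, tolerance = 0.05)
  expect_equal(kurtosis_d6(runif(2e5)), 1.8, tolerance = 0.05)
})

test_that("d7 is the bounding-box volume in mm^3", {
  expect_equal(volume_box_d7(matrix(c(1L, 1L, 1L), 1), c(2.5, 0.7, 0.7)), 1.225)
  cube <- as.matrix(expand.grid(z = 1:3, y = 1:3, x = 1:3))
  expect_equal(volume_box_d7(cube, c(1, 1, 1)), 27)

  sphere <- digitized_sphere(c(10, 30, 30), c(2.5, 0.7, 0.7), c(10, 10, 12.5), 3)
  ext <- (apply(sphere, 2, max) - apply(sphere, 2, min) + 1) * c(2.5, 0.7, 0.7)
  expect_equal(volume_box_d7(sphere, c(2.5, 0.7, 0.7)), prod(ext))
})

test_that("feature_matrix composes the per-feature operations", {
  ph <- generate_phantom(small_phantom_spec(
    seed = 9, nodules = nodule_truth(20, 33.25, 28.75, 4, "isolated")
  ))
  v <- normalize_volume(ph$volume)
  lungs <- extract_lungs(v)
  det <- detect_candidates(v, lungs)
  m <- feature_matrix(det$candidates, v)
  expect_equal(nrow(m), nrow(det$candidates))
  expect_true(all(paste0("d", 1:8) %in% names(m)))
  expect_false(anyNA(m))

  vox <- det$candidates$voxels[[1]]
  vals <- v$intensities[vox]
  expect_equal(m$d1[1], area_d1(vox))
  expect_equal(m$d2[1], circularity_d2(vox))
  expect_equal(m$d5[1], skewness_d5(vals))
  expect_equal(m$d7[1], volume_box_d7(vox, v$spacing_mm))
  # invariant: d8 = d3 * voxel count
  expect_equal(m$d8, m$d3 * det$candidates$voxel_count, tolerance = 1e-9)

  empty <- feature_matrix(det$candidates[0, ], v)
  expect_equal(nrow(empty), 0L)
  expect_true(all(paste0("d", 1:8) %in% names(empty)))
})

test_that("features respect their invariances", {
  set.seed(77)
  arr <- array(runif(4000, 0, 255), dim = c(10, 20, 20))
  v <- ct_volume(arr, c(2.5, 0.7, 0.7), intensity_scale = "normalized8bit")
  vox <- digitized_sphere(c(10, 20, 20), c(2.5, 0.7, 0.7), c(6, 6, 11), 3.2)
  vals <- arr[vox]

  # voxel-order invariance
  perm <- vox[sample(nrow(vox)), ]
  expect_equal(area_d1(perm), area_d1(vox))
  expect_equal(circularity_d2(perm), circularity_d2(vox))
  expect_equal(volume_box_d7(perm, v$spacing_mm), volume_box_d7(vox, v$spacing_mm))
  expect_equal(intensity_stats(perm, v)$d3, intensity_stats(vox, v)$d3)

  # affine intensity transform: d5/d6 invariant, d3/d8 linear, d1/d7 untouched
  a <- 1.7; b <- 12
  expect_equal(skewness_d5(a * vals + b), skewness_d5(vals), tolerance = 1e-9)
  expect_equal(kurtosis_d6(a * vals + b), kurtosis_d6(vals), tolerance = 1e-9)
  expect_equal(mean(a * vals + b), a * mean(vals) + b, tolerance = 1e-9)
})

test_that("correlation-based selection drops duplicates and respects limits", {
  set.seed(14)
  m <- tibble::as_tibble(stats::setNames(
    as.data.frame(matrix(rnorm(50 * 8), 50, 8)), paste0("d", 1:8)
  ))
  # independent random columns survive at r_max = 0.95
  R <- abs(stats::cor(as.matrix(m))); diag(R) <- 0
  expect_lt(max(R), 0.95)
  expect_setequal(select_features_by_correlation(m, 0.95), paste0("d", 1:8))

  # a duplicated column: exactly one copy survives
  m2 <- m
  m2$d2 <- m2$d1
  kept <- select_features_by_correlation(m2, 0.95)
  expect_equal(sum(c("d1", "d2") %in% kept), 1L)

  # r_max = 0 leaves a single feature
  expect_length(select_features_by_correlation(m, 0), 1L)

  # constant columns are dropped first, with a warning
  m3 <- m
  m3$d5 <- 1
  expect_warning(kept3 <- select_features_by_correlation(m3, 0.95), "constant")
  expect_false("d5" %in% kept3)
})
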