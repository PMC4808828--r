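test_that("slice structure labeling finds separated bright squares", {
  slice <- matrix(0, 20, 20)
  slice[3:5, 3:5] <- 200        # 9 px
  slice[10:13, 12:15] <- 220    # 16 px
  mask <- matrix(TRUE, 20, 20)
  st <- label_slice_structures(slice, mask, threshold = 100, slice_index = 7L)
  expect_equal(nrow(st), 2L)
  expect_setequal(st$area_px, c(9L, 16L))
  expect_true(all(st$slice_index == 7L))
  expect_setequal(round(st$mean_intensity), c(200, 220))
})

test_that("an empty lung mask yields no structures", {
  st <- label_slice_structures(matrix(5, 4, 4), matrix(FALSE, 4, 4))
  expect_equal(nrow(st), 0L)
})

test_that("slice labeling agrees with a BFS flood-fill oracle", {
  set.seed(17)
  for (rep in 1:5) {
    slice <- matrix(runif(30 * 30, 0, 255), 30, 30)
    mask <- matrix(TRUE, 30, 30)
    st <- label_slice_structures(slice, mask, threshold = 180)
    bright <- slice > 180
    lab <- bfs_label(bright, offsets_full_8())
    expect_equal(nrow(st), max(lab))
    # identical partitions: same multiset of pixel sets
    ours <- sort(unname(vapply(st$pixels, function(p) {
      paste(sort(p[, 1] * 1000 + p[, 2]), collapse = ",")
    }, "")))
    theirs <- sort(unname(vapply(seq_len(max(lab)), function(l) {
      w <- which(lab == l, arr.ind = TRUE)
      paste(sort(w[, 1] * 1000 + w[, 2]), collapse = ",")
    }, "")))
    expect_identical(ours, theirs)
  }
})

test_that("structure filtering requires both indicators to agree", {
  st <- tibble::tibble(
    slice_index = 1L, structure_id = 1:3,
    pixels = list(matrix(1L, 3, 2), matrix(1L, 10, 2), matrix(1L, 8, 2)),
    area_px = c(3L, 10L, 8L),
    mean_intensity = c(250, 120, 220)
  )
  kept <- filter_slice_structures(st, area_min_px = 5L, intensity_min = 200)
  expect_equal(kept$structure_id, 3L)
  removed <- attr(kept, "removed")
  expect_setequal(removed$failed, c("area", "intensity"))
})

test_that("structure filtering matches an independent re-implementation", {
  set.seed(8)
  st <- tibble::tibble(
    slice_index = 1L, structure_id = 1:50,
    pixels = replicate(50, matrix(1L, 2, 2), simplify = FALSE),
    area_px = sample(1:60, 50, replace = TRUE),
    mean_intensity = runif(50, 0, 255)
  )
  kept <- filter_slice_structures(st, 20L, 130)
  manual <- st$structure_id[vapply(seq_len(50), function(i) {
    st$area_px[i] >= 20 && st$mean_intensity[i] >= 130
  }, TRUE)]
  expect_identical(kept$structure_id, manual)
})

test_that("the pixel-area floor evaluates its formula", {
  expect_identical(area_floor_from_spacing(c(2.5, 0.7, 0.7)), 26L)
  expect_identical(area_floor_from_spacing(c(2.0, 2.0)), 4L)
  expect_identical(area_floor_from_spacing(c(1, 1), min_diameter_mm = 0), 0L)
})

test_that("26-connectivity joins corners but not gaps", {
  vol <- array(FALSE, dim = c(3, 3, 3))
  vol[1, 1, 1] <- TRUE; vol[2, 2, 2] <- TRUE
  expect_equal(nrow(label_components_26(vol)), 1L)

  vol2 <- array(FALSE, dim = c(1, 1, 3))
  vol2[1, 1, 1] <- TRUE; vol2[1, 1, 3] <- TRUE
  comps <- label_components_26(vol2)
  expect_equal(nrow(comps), 2L)
  expect_equal(comps$id, 1:2)
})

test_that("26-connected labeling equals BFS flood fill and is a partition", {
  set.seed(12)
  for (rep in 1:5) {
    vol <- array(runif(20^3) < 0.2, dim = c(20, 20, 20))
    comps <- label_components_26(vol)
    lab <- bfs_label(vol, offsets_full_26())
    expect_equal(nrow(comps), max(lab))
    all_vox <- do.call(rbind, comps$voxels)
    # partition: disjoint and covering
    expect_equal(nrow(all_vox), sum(vol))
    expect_equal(nrow(unique(as.data.frame(all_vox))), sum(vol))
    # identical grouping
    key <- function(m) sort(unname(vapply(m, function(v) paste(sort(v), collapse = "|"), "")))
    ours <- lapply(comps$voxels, function(m) (m[, 1] - 1) * 400 + (m[, 2] - 1) * 20 + m[, 3])
    theirs <- lapply(seq_len(max(lab)), function(l) {
      w <- which(lab == l, arr.ind = TRUE)
      (w[, 1] - 1) * 400 + (w[, 2] - 1) * 20 + w[, 3]
    })
    expect_identical(key(ours), key(theirs))
  }
})

test_that("component count never increases when adjacent voxels are added", {
  set.seed(3)
  vol <- array(runif(12^3) < 0.15, dim = c(12, 12, 12))
  n0 <- nrow(label_components_26(vol))
  fg <- which(vol, arr.ind = TRUE)
  grown <- vol
  for (i in seq_len(min(20, nrow(fg)))) {
    nb <- fg[i, ] + sample(c(-1L, 0L, 1L), 3, replace = TRUE)
    if (all(nb >= 1) && all(nb <= 12)) grown[matrix(nb, 1)] <- TRUE
  }
  expect_lte(nrow(label_components_26(grown)), n0)
})

test_that("blob scores separate spheres from tubes", {
  sphere <- digitized_sphere(c(11, 11, 11), c(1, 1, 1), c(5, 5, 5), 5)
  s <- blob_scores(sphere, c(1, 1, 1))
  expect_gte(s$sphericity, 0.9)

  tube <- as.matrix(expand.grid(z = 1:30, y = 1:3, x = 1:3))[, c("z", "y", "x")]
  tube <- tube[(tube[, 2] - 2)^2 + (tube[, 3] - 2)^2 <= 1, ]
  s2 <- blob_scores(tube, c(1, 1, 1))
  expect_lt(s2$sphericity, 0.2)

  s3 <- blob_scores(matrix(c(4L, 4L, 4L), 1), c(2.5, 0.7, 0.7))
  expect_equal(s3$sphericity, 1)
  expect_equal(s3$width_mm, 0.7)
})

test_that("discrimination keeps spheres, rejects tubes, logs reasons", {
  ph <- generate_phantom(small_phantom_spec(
    noise_sigma = 0, seed = 4,
    nodules = nodule_truth(20, 33.25, 28.75, 3, "isolated")
  ))
  v <- ph$volume  # raw phantom scale: only the nodule sits above 200
  comps <- label_components_26(v$intensities > 200)
  cands <- nodulecad:::candidate_table(comps, v)
  kept <- discriminate_candidates(cands)
  expect_equal(nrow(kept), 1L)
  expect_gte(kept$sphericity, 0.3)

  tube_vol <- array(FALSE, dim = c(30, 10, 10))
  tube_vol[2:29, 5, 5] <- TRUE
  tv <- ct_volume(array(as.numeric(tube_vol) * 200, dim = dim(tube_vol)), c(1, 1, 1),
                  intensity_scale = "normalized8bit")
  tcands <- nodulecad:::candidate_table(label_components_26(tube_vol), tv)
  tkept <- discriminate_candidates(tcands)
  expect_equal(nrow(tkept), 0L)
  expect_match(attr(tkept, "rejected")$failed, "sphericity|elongation")

  empty <- discriminate_candidates(cands[0, ])
  expect_equal(nrow(empty), 0L)
})

test_that("end-to-end: nodules give one candidate each, plain vessels none", {
  shape <- c(24L, 96L, 96L)
  sp <- c(2.5, 0.7, 0.7)
  geom <- nodulecad:::phantom_geometry(shape, sp)
  L <- geom$lungs$left; R <- geom$lungs$right
  nodules <- dplyr::bind_rows(
    nodule_truth(L$center[1], L$center[2], L$center[3] + 0.4 * L$semi[3], 4, "isolated"),
    nodule_truth(R$center[1], R$center[2] + 0.3 * R$semi[2], R$center[3] - 0.4 * R$semi[3],
                 5, "isolated")
  )
  # three straight vessels, no bifurcations, comfortably below the area floor
  vessels <- list(
    vessel(L$center + c(0, 0, 0.45 * L$semi[3]), L$center - c(0, 0, 0.45 * L$semi[3]), 1.3),
    vessel(R$center + c(1, 2, 0.45 * R$semi[3]), R$center - c(-1, 2, 0.45 * R$semi[3]), 1.3),
    vessel(R$center + c(-4, 0, 0.3 * R$semi[3]), R$center + c(4, 1, -0.3 * R$semi[3]), 1.0)
  )
  ph <- generate_phantom(phantom_spec(shape_voxels = shape, spacing_mm = sp,
                                      noise_sigma = 3, nodules = nodules,
                                      vessels = vessels, seed = 21))
  v <- normalize_volume(ph$volume)
  lungs <- extract_lungs(v)
  det <- detect_candidates(v, lungs)
  cands <- det$candidates

  for (t in seq_len(nrow(nodules))) {
    dd <- sqrt((cands$cx_mm - nodules$cx_mm[t])^2 +
                 (cands$cy_mm - nodules$cy_mm[t])^2 +
                 (cands$cz_mm - nodules$cz_mm[t])^2)
    expect_equal(sum(dd <= nodules$radius_mm[t]), 1L, info = paste("nodule", t))
  }
  expect_equal(nrow(cands), 2L)  # vessels without bifurcation blobs: nothing
})
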