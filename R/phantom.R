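# Synthetic thoracic phantom generator. Produces annotated CT-like volumes
# with the statistical and geometric structure the pipeline assumes: a bright
# body section enclosing two dark lung ellipsoids (two-peak histogram),
# tubular vessels with Y-bifurcations (widened at the junction, the chief
# false-positive source), and spherical or irregular nodules of the
# isolated / juxtapleural / vascular kinds.

#' Ground-truth nodule descriptor
#'
#' @param cx_mm,cy_mm,cz_mm nodule center in mm (volume coordinates).
#' @param radius_mm nodule radius in mm; at least 2.0 for a nodule meant to be
#'   detectable (the 4 mm diameter floor).
#' @param kind `"isolated"`, `"juxtapleural"`, or `"vascular"`.
#' @param irregularity surface perturbation amount in `[0, 1]` (0 = sphere).
#' @return One-row tibble.
#' @export
nodule_truth <- function(cx_mm, cy_mm, cz_mm, radius_mm,
                         kind = c("isolated", "juxtapleural", "vascular"),
                         irregularity = 0) {
  kind <- match.arg(kind)
  if (!is.finite(radius_mm) || radius_mm <= 0)
    stop_nc("invalid nodule radius_mm: must be positive")
  if (irregularity < 0 || irregularity > 1)
    stop_nc("invalid nodule irregularity: must be in [0, 1]")
  tibble::tibble(cx_mm = cx_mm, cy_mm = cy_mm, cz_mm = cz_mm,
                 radius_mm = radius_mm, kind = kind,
                 irregularity = irregularity)
}

#' Vessel (capsule) descriptor
#'
#' A vessel is the set of voxels within `radius_mm` of the segment
#' `from_mm -> to_mm`. Optional children start at `to_mm`, forming a
#' Y-bifurcation; the junction is widened by an ellipsoidal bulge aligned with
#' the parent axis (about 1.75x the parent radius along it), emulating the
#' vessel-ramification points that blob detectors confuse with nodules.
#'
#' @param from_mm,to_mm segment endpoints, `c(x, y, z)` in mm.
#' @param radius_mm vessel radius in mm.
#' @param children list of `vessel()` descriptors starting at `to_mm` (their
#'   `from_mm` is overridden); nonempty list makes this a bifurcation.
#' @param bulge if TRUE (default when there are children) draw the junction
#'   bulge.
#' @return A `vessel` list.
#' @export
vessel <- function(from_mm, to_mm, radius_mm, children = list(),
                   bulge = length(children) > 0) {
  if (!is.finite(radius_mm) || radius_mm <= 0)
    stop_nc("invalid vessel radius_mm: must be positive")
  structure(list(from_mm = as.numeric(from_mm), to_mm = as.numeric(to_mm),
                 radius_mm = radius_mm, children = children, bulge = bulge),
            class = "vessel")
}

#' Phantom specification
#'
#' Defines one synthetic chest volume. Intensities are on an 8-bit-like 0-255
#' scale; the lung/air intensity must be the lowest so the volume histogram
#' has the two-peak structure lung extraction assumes. The default geometry is
#' desk-sized: 128 x 128 in-plane at 0.7 mm, 2.5 mm slices.
#'
#' @param shape_voxels integer `(nz, ny, nx)`, each at least 8.
#' @param spacing_mm positive `(dz, dy, dx)` in mm.
#' @param body_intensity,lung_intensity,structure_intensity material
#'   intensities; `lung_intensity` must be smaller than the other two.
#' @param noise_sigma additive Gaussian noise SD (clipped to `[0, 255]`).
#' @param nodules tibble of [nodule_truth()] rows (or a list of them).
#' @param vessels list of [vessel()] descriptors.
#' @param seed integer seed controlling noise and surface irregularity.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape_voxels = c(48L, 128L, 128L),
                         spacing_mm = c(2.5, 0.7, 0.7),
                         body_intensity = 190, lung_intensity = 60,
                         structure_intensity = 210, noise_sigma = 5,
                         nodules = NULL, vessels = list(), seed = 1L) {
  shape_voxels <- as.integer(shape_voxels)
  if (length(shape_voxels) != 3L || any(shape_voxels < 8L))
    stop_nc("invalid shape_voxels: need (nz, ny, nx) all >= 8")
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) != 3L || any(!is.finite(spacing_mm)) || any(spacing_mm <= 0))
    stop_nc("invalid spacing_mm: need 3 positive values")
  for (nm in c("body_intensity", "lung_intensity", "structure_intensity")) {
    val <- get(nm)
    if (!is.finite(val) || val < 0 || val > 255)
      stop_nc("invalid ", nm, ": must be in [0, 255]")
  }
  if (lung_intensity >= body_intensity || lung_intensity >= structure_intensity)
    stop_nc("invalid lung_intensity: must be below body_intensity and structure_intensity")
  if (!is.finite(noise_sigma) || noise_sigma < 0)
    stop_nc("invalid noise_sigma: must be non-negative")
  if (is.null(nodules)) {
    nodules <- nodule_truth(0, 0, 0, 1)[0, ]
  } else if (is.list(nodules) && !is.data.frame(nodules)) {
    nodules <- dplyr::bind_rows(nodules)
  }
  if (!all(vapply(vessels, inherits, TRUE, "vessel")))
    stop_nc("invalid vessels: must be a list of vessel() descriptors")
  structure(
    list(shape_voxels = shape_voxels, spacing_mm = spacing_mm,
         body_intensity = body_intensity, lung_intensity = lung_intensity,
         structure_intensity = structure_intensity, noise_sigma = noise_sigma,
         nodules = nodules, vessels = vessels, seed = as.integer(seed)),
    class = "phantom_spec"
  )
}

# fixed internal thorax geometry, derived from the grid extents (mm)
phantom_geometry <- function(shape_voxels, spacing_mm) {
  ext <- (shape_voxels - 1) * spacing_mm          # (Ez, Ey, Ex)
  ctr <- ext / 2
  list(
    extent_mm = ext,
    body = list(cx = ctr[3], cy = ctr[2],
                ax = 0.42 * ext[3], ay = 0.32 * ext[2]),
    # the inter-lung gap (0.12 * Ex, i.e. 8 mm on a 96-voxel 0.7 mm grid) must
    # stay above the pleural-reconstruction closing diameter of lung
    # extraction, or the mediastinum would be swallowed into the mask
    lungs = list(
      left = list(center = c(ctr[3] - 0.21 * ext[3], ctr[2], ctr[1]),  # (x,y,z)
                  semi = c(0.15 * ext[3], 0.22 * ext[2], 0.38 * ext[1])),
      right = list(center = c(ctr[3] + 0.21 * ext[3], ctr[2], ctr[1]),
                   semi = c(0.15 * ext[3], 0.22 * ext[2], 0.38 * ext[1]))
    )
  )
}

# coordinate arrays (mm) for a grid, as vectors per axis
axis_mm <- function(n, sp) (seq_len(n) - 1) * sp

# logical mask of an ellipsoid given (x,y,z) center/semi-axes, on the full grid
ellipsoid_mask <- function(shape, spacing, center_xyz, semi_xyz) {
  z <- axis_mm(shape[1], spacing[1]); y <- axis_mm(shape[2], spacing[2])
  x <- axis_mm(shape[3], spacing[3])
  qz <- ((z - center_xyz[3]) / semi_xyz[3])^2
  qy <- ((y - center_xyz[2]) / semi_xyz[2])^2
  qx <- ((x - center_xyz[1]) / semi_xyz[1])^2
  outer(outer(qz, qy, "+"), qx, "+") <= 1
}

# voxel-index bounding box (with margin mm) around a set of mm points
crop_box <- function(points_xyz, margin, shape, spacing) {
  pts <- rbind(points_xyz)
  lo_mm <- apply(pts, 2, min) - margin   # (x, y, z)
  hi_mm <- apply(pts, 2, max) + margin
  # voxel center of index i is (i - 1) * spacing, so index = mm / spacing + 1
  lo_zyx <- c(lo_mm[3] / spacing[1], lo_mm[2] / spacing[2], lo_mm[1] / spacing[3])
  hi_zyx <- c(hi_mm[3] / spacing[1], hi_mm[2] / spacing[2], hi_mm[1] / spacing[3])
  lo <- pmax(1L, as.integer(floor(lo_zyx)) + 1L)
  hi <- pmin(shape, as.integer(ceiling(hi_zyx)) + 1L)
  list(z = lo[1]:hi[1], y = lo[2]:hi[2], x = lo[3]:hi[3])
}

# distance from grid points (cropped box) to a segment; returns logical mask
# of the capsule within the box, plus the box
capsule_mask <- function(shape, spacing, from_xyz, to_xyz, radius) {
  box <- crop_box(rbind(from_xyz, to_xyz), radius + 2, shape, spacing)
  z <- axis_mm(shape[1], spacing[1])[box$z]
  y <- axis_mm(shape[2], spacing[2])[box$y]
  x <- axis_mm(shape[3], spacing[3])[box$x]
  g <- expand.grid(z = z, y = y, x = x, KEEP.OUT.ATTRS = FALSE)
  p <- cbind(g$x, g$y, g$z)
  d <- to_xyz - from_xyz
  len2 <- sum(d^2)
  t <- if (len2 > 0) {
    pmin(1, pmax(0, (sweep(p, 2, from_xyz) %*% d) / len2))
  } else {
    matrix(0, nrow(p), 1)
  }
  closest <- sweep(t %*% rbind(d), 2, from_xyz, "+")
  dist_mm <- sqrt(rowSums((p - closest)^2))
  dims <- c(length(box$z), length(box$y), length(box$x))
  list(box = box,
       mask = array(dist_mm <= radius, dim = dims),
       weight = array(pv_weight(radius - dist_mm), dim = dims))
}

# partial-volume edge profile: linear ramp over ~one in-plane voxel around the
# surface (signed distance > 0 inside). Thin structures (vessels, junction
# bulges) are rendered with it, which is what makes them dimmer and more
# heterogeneous than solid nodules on real CT.
PV_EDGE_MM <- 0.7
pv_weight <- function(signed_inside_mm) {
  pmin(1, pmax(0, signed_inside_mm / PV_EDGE_MM + 0.5))
}

# ellipsoidal bulge aligned with a direction (junction widening)
aligned_bulge_mask <- function(shape, spacing, center_xyz, dir_xyz, a_long, a_perp) {
  box <- crop_box(rbind(center_xyz), a_long + 2, shape, spacing)
  z <- axis_mm(shape[1], spacing[1])[box$z]
  y <- axis_mm(shape[2], spacing[2])[box$y]
  x <- axis_mm(shape[3], spacing[3])[box$x]
  g <- expand.grid(z = z, y = y, x = x, KEEP.OUT.ATTRS = FALSE)
  p <- sweep(cbind(g$x, g$y, g$z), 2, center_xyz)
  u <- dir_xyz / sqrt(sum(dir_xyz^2))
  along <- as.numeric(p %*% u)
  perp2 <- rowSums(p^2) - along^2
  q <- sqrt((along / a_long)^2 + perp2 / a_perp^2)
  dims <- c(length(box$z), length(box$y), length(box$x))
  list(box = box,
       mask = array(q <= 1, dim = dims),
       weight = array(pv_weight((1 - q) * a_perp), dim = dims))
}

# low-order directional perturbation field for irregular nodules; coefficients
# are drawn from the RNG stream, result scaled to |s| <= 1
make_surface_perturbation <- function() {
  co <- rnorm(9)
  co <- co / max(1e-9, sqrt(sum(co^2))) * 1.5
  function(u) {
    s <- co[1] * u[, 1] + co[2] * u[, 2] + co[3] * u[, 3] +
      co[4] * u[, 1] * u[, 2] + co[5] * u[, 2] * u[, 3] + co[6] * u[, 1] * u[, 3] +
      co[7] * (u[, 1]^2 - 1 / 3) + co[8] * (u[, 2]^2 - 1 / 3) + co[9] * (u[, 3]^2 - 1 / 3)
    pmin(1, pmax(-1, s))
  }
}

# nodule membership mask on a cropped box: voxel centers within the (possibly
# perturbed) radius of the center
nodule_mask <- function(shape, spacing, center_xyz, radius, irregularity, perturb) {
  rmax <- radius * (1 + 0.35 * irregularity)
  box <- crop_box(rbind(center_xyz), rmax + 2, shape, spacing)
  z <- axis_mm(shape[1], spacing[1])[box$z]
  y <- axis_mm(shape[2], spacing[2])[box$y]
  x <- axis_mm(shape[3], spacing[3])[box$x]
  g <- expand.grid(z = z, y = y, x = x, KEEP.OUT.ATTRS = FALSE)
  p <- sweep(cbind(g$x, g$y, g$z), 2, center_xyz)
  d <- sqrt(rowSums(p^2))
  if (irregularity > 0) {
    u <- p / pmax(d, 1e-9)
    r_eff <- radius * (1 + 0.35 * irregularity * perturb(u))
  } else {
    r_eff <- radius
  }
  within <- d <= r_eff
  list(box = box, mask = array(within, dim = c(length(box$z), length(box$y), length(box$x))))
}

paint <- function(arr, piece, where, value) {
  sub <- arr[piece$box$z, piece$box$y, piece$box$x, drop = FALSE]
  w <- where[piece$box$z, piece$box$y, piece$box$x, drop = FALSE]
  sub[piece$mask & w] <- value
  arr[piece$box$z, piece$box$y, piece$box$x] <- sub
  arr
}

# blend with partial-volume weights instead of overwriting
paint_soft <- function(arr, piece, where, value) {
  sub <- arr[piece$box$z, piece$box$y, piece$box$x, drop = FALSE]
  w <- piece$weight
  w[!where[piece$box$z, piece$box$y, piece$box$x, drop = FALSE]] <- 0
  sub <- sub * (1 - w) + value * w
  arr[piece$box$z, piece$box$y, piece$box$x] <- sub
  arr
}

flatten_vessels <- function(vessels) {
  out <- list()
  for (v in vessels) {
    out <- c(out, list(v))
    for (ch in v$children) {
      ch$from_mm <- v$to_mm
      out <- c(out, flatten_vessels(list(ch)))
    }
  }
  out
}

#' Generate a synthetic chest phantom
#'
#' Renders the phantom described by `spec`: air background and lung ellipsoids
#' at `lung_intensity`, body ellipse at `body_intensity`, vessels (clipped to
#' the lungs) and nodules at `structure_intensity`, then additive Gaussian
#' noise clipped to `[0, 255]`. Nodules are spheres (voxel centers within
#' `radius_mm` of the center), optionally perturbed radially for
#' `irregularity > 0`; juxtapleural nodules are clipped to the body section.
#' Identical specs (including `seed`) produce bit-identical volumes.
#'
#' @param spec a [phantom_spec()].
#' @return An object of class `ct_phantom`: list with `volume` (a
#'   [ct_volume()]), `truth` (the nodule tibble, returned verbatim), and
#'   `geometry` (body/lung parameters, for oracle checks).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  shape <- spec$shape_voxels
  sp <- spec$spacing_mm
  geom <- phantom_geometry(shape, sp)

  with_seed(spec$seed, {
    arr <- array(spec$lung_intensity, dim = shape)

    # body: elliptical cylinder through all slices
    y <- axis_mm(shape[2], sp[2]); x <- axis_mm(shape[3], sp[3])
    body2d <- outer(((y - geom$body$cy) / geom$body$ay)^2,
                    ((x - geom$body$cx) / geom$body$ax)^2, "+") <= 1
    body <- array(rep(body2d, each = shape[1]), dim = shape)
    arr[body] <- spec$body_intensity

    lungL <- ellipsoid_mask(shape, sp, geom$lungs$left$center, geom$lungs$left$semi)
    lungR <- ellipsoid_mask(shape, sp, geom$lungs$right$center, geom$lungs$right$semi)
    lungs <- lungL | lungR
    arr[lungs] <- spec$lung_intensity

    inside <- body | lungs
    everywhere <- array(TRUE, dim = shape)

    # vessels and junction bulges, clipped to the lung interior
    for (seg in flatten_vessels(spec$vessels)) {
      piece <- capsule_mask(shape, sp, seg$from_mm, seg$to_mm, seg$radius_mm)
      arr <- paint_soft(arr, piece, lungs, spec$structure_intensity)
      if (isTRUE(seg$bulge) && length(seg$children)) {
        dir <- seg$to_mm - seg$from_mm
        piece <- aligned_bulge_mask(shape, sp, seg$to_mm, dir,
                                    a_long = 2.2 * seg$radius_mm,
                                    a_perp = 1.8 * seg$radius_mm)
        arr <- paint_soft(arr, piece, lungs, spec$structure_intensity)
      }
    }

    # nodules: isolated/vascular live in the lungs; juxtapleural spheres are
    # clipped to the body section (their pleural cap merges with the wall)
    if (nrow(spec$nodules)) {
      for (i in seq_len(nrow(spec$nodules))) {
        nd <- spec$nodules[i, ]
        perturb <- make_surface_perturbation()
        piece <- nodule_mask(shape, sp, c(nd$cx_mm, nd$cy_mm, nd$cz_mm),
                             nd$radius_mm, nd$irregularity, perturb)
        clip <- if (nd$kind == "juxtapleural") inside else everywhere
        arr <- paint(arr, piece, clip, spec$structure_intensity)
      }
    }

    if (spec$noise_sigma > 0) {
      arr <- arr + rnorm(length(arr), 0, spec$noise_sigma)
      arr <- pmin(pmax(arr, 0), 255)
      dim(arr) <- shape
    }

    structure(
      list(
        volume = ct_volume(arr, spacing_mm = sp, intensity_scale = "normalized8bit"),
        truth = spec$nodules,
        geometry = geom,
        spec = spec
      ),
      class = "ct_phantom"
    )
  })
}

#' @export
print.ct_phantom <- function(x, ...) {
  cat(sprintf("<ct_phantom> %d nodule(s), %d vessel tree(s)\n",
              nrow(x$truth), length(x$spec$vessels)))
  print(x$volume)
  invisible(x)
}

# default vessel tree for one lung: a main trunk that bifurcates into two
# children, with the junction bulge that mimics a ramification point
lung_vessel_tree <- function(lung, jitter = c(0, 0, 0)) {
  c0 <- lung$center; s <- lung$semi
  top <- c0 + c(jitter[1], jitter[2], 0.45 * s[3])
  mid <- c0 + c(jitter[1] * 0.5, jitter[2] * 0.5, -0.05 * s[3] + jitter[3])
  ch1 <- mid + c(-0.45 * s[1], 0.35 * s[2], -0.5 * s[3])
  ch2 <- mid + c(0.45 * s[1], -0.35 * s[2], -0.5 * s[3])
  vessel(top, mid, radius_mm = 1.6,
         children = list(vessel(mid, ch1, radius_mm = 1.2),
                         vessel(mid, ch2, radius_mm = 1.2)))
}

# sample a nodule of the given kind inside/at the lung, using the current RNG
sample_nodule <- function(kind, lung, radius_mm, irregularity) {
  c0 <- lung$center; s <- lung$semi
  if (kind == "juxtapleural") {
    # seat on the lateral/medial pleural surface, where the boundary is
    # gently curved (like the costal pleura); polar caps and the
    # anterior/posterior extremes of the ellipsoid curve too tightly for a
    # nodule-sized sphere to sit against
    u <- c(sample(c(-1, 1), 1), runif(1, -0.35, 0.35), runif(1, -0.15, 0.15))
    u <- u / sqrt(sum(u^2))
    k <- 1 / sqrt(sum((u / s)^2))
    boundary <- c0 + k * u
    # mostly inside the lung, with the cap merging into the chest wall: deep
    # enough that pleural reconstruction (closing + hole filling) can recover
    # the bite, as in clinical juxtapleural presentations
    d <- runif(1, 0.88, 0.97) * radius_mm
    ctr <- boundary - d * u
  } else if (kind == "vascular") {
    # on the trunk of the lung's vessel tree, clear of the junction bulge
    t <- runif(1, 0.3, 0.6)
    top <- c0 + c(0, 0, 0.45 * s[3])
    mid <- c0 + c(0, 0, -0.05 * s[3])
    ctr <- top + t * (mid - top)
  } else {
    repeat {
      p <- runif(3, -1, 1)
      if (sum(p^2) <= 1) break
    }
    margin <- pmax(s - radius_mm - 1.5, 0.15 * s)
    ctr <- c0 + p * margin
  }
  nodule_truth(ctr[1], ctr[2], ctr[3], radius_mm, kind, irregularity)
}

#' Generate a suite of annotated phantoms
#'
#' Each scan gets a randomized slice count (40-80 at 2.5 mm), zero to two
#' nodules of randomized size (radius 2.5-6 mm), kind, and irregularity, and
#' one bifurcating vessel tree per lung (deliberate false-positive sources).
#' Reproducible from `seed`.
#'
#' @param n_scans number of phantoms (>= 1).
#' @param seed integer seed.
#' @param noise_sigma noise level passed to every [phantom_spec()].
#' @param in_plane in-plane grid size (default 128).
#' @return List of [generate_phantom()] results; each `truth` tibble carries a
#'   `scan_id` column.
#' @export
phantom_suite <- function(n_scans, seed = 1L, noise_sigma = 5, in_plane = 128L) {
  if (n_scans < 1) stop_nc("n_scans must be >= 1")
  purrr::map(seq_len(n_scans), function(i) {
    scan_seed <- derive_seed(seed, i)
    params <- with_seed(scan_seed, {
      nz <- sample(40:80, 1)
      shape <- c(nz, in_plane, in_plane)
      sp <- c(2.5, 0.7, 0.7)
      geom <- phantom_geometry(shape, sp)
      n_nod <- sample(0:2, 1)
      sides <- sample(c("left", "right"), 2)
      nodules <- NULL
      if (n_nod > 0) {
        rows <- purrr::map(seq_len(n_nod), function(j) {
          kind <- sample(c("isolated", "isolated", "juxtapleural", "vascular"), 1)
          sample_nodule(kind, geom$lungs[[sides[j]]],
                        radius_mm = runif(1, 2.5, 6),
                        irregularity = runif(1, 0, 0.4))
        })
        nodules <- dplyr::bind_rows(rows)
      }
      vessels <- list(
        lung_vessel_tree(geom$lungs$left, jitter = runif(3, -2, 2)),
        lung_vessel_tree(geom$lungs$right, jitter = runif(3, -2, 2))
      )
      list(shape = shape, sp = sp, nodules = nodules, vessels = vessels)
    })
    ph <- generate_phantom(phantom_spec(
      shape_voxels = params$shape, spacing_mm = params$sp,
      noise_sigma = noise_sigma, nodules = params$nodules,
      vessels = params$vessels, seed = scan_seed
    ))
    ph$truth <- tibble::add_column(ph$truth, scan_id = i, .before = 1)
    ph
  })
}

#' Write a phantom suite to disk
#'
#' Volumes as NIfTI (`scan_<id>.nii.gz`, affine from spacing) and ground truth
#' as both CSV (`truth.csv`: scan_id, cx_mm, cy_mm, cz_mm, radius_mm, kind)
#' and JSON (`truth.json`).
#'
#' @param suite result of [phantom_suite()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_phantom_suite <- function(suite, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  truth <- purrr::map_dfr(seq_along(suite), function(i) {
    write_volume_nifti(suite[[i]]$volume,
                       file.path(dir, sprintf("scan_%03d.nii.gz", i)))
    tr <- suite[[i]]$truth
    if (!"scan_id" %in% names(tr) && nrow(tr)) tr <- tibble::add_column(tr, scan_id = i, .before = 1)
    tr
  })
  cols <- c("scan_id", "cx_mm", "cy_mm", "cz_mm", "radius_mm", "kind")
  utils::write.csv(truth[, intersect(cols, names(truth))],
                   file.path(dir, "truth.csv"), row.names = FALSE)
  jsonlite::write_json(truth, file.path(dir, "truth.json"), digits = NA)
  invisible(dir)
}
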