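# Connected-component machinery shared by lung extraction and candidate
# segmentation. Components are found by building the voxel adjacency graph for
# a chosen connectivity and taking igraph components; label order is fixed
# lexicographically for reproducibility.

# half-neighborhood offsets (one of each symmetric pair is enough for an
# undirected adjacency graph)
offsets_2d_4 <- function() rbind(c(0L, 1L), c(1L, 0L))
offsets_2d_8 <- function() rbind(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(1L, -1L))
offsets_3d_26 <- function() {
  g <- as.matrix(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1))
  g <- g[!(g[, 1] == 0 & g[, 2] == 0 & g[, 3] == 0), , drop = FALSE]
  # keep one representative of each +/- pair
  keep <- g[, 1] > 0 | (g[, 1] == 0 & g[, 2] > 0) |
    (g[, 1] == 0 & g[, 2] == 0 & g[, 3] > 0)
  storage.mode(g) <- "integer"
  unname(g[keep, , drop = FALSE])
}

# coords: n x k integer matrix of 1-based indices; dims: grid extents.
# Returns component membership (integer), components numbered 1..m in
# ascending lexicographic order of their first voxel.
connected_components <- function(coords, dims, offsets) {
  n <- nrow(coords)
  if (n == 0L) return(integer(0))
  k <- ncol(coords)
  mult <- cumprod(c(1, dims[-k]))
  key <- as.numeric(coords %*% mult)
  edges <- vector("list", nrow(offsets))
  for (r in seq_len(nrow(offsets))) {
    nb <- sweep(coords, 2, offsets[r, ], "+")
    ok <- rep(TRUE, n)
    for (j in seq_len(k)) ok <- ok & nb[, j] >= 1L & nb[, j] <= dims[j]
    if (!any(ok)) next
    nk <- as.numeric(nb[ok, , drop = FALSE] %*% mult)
    m <- match(nk, key)
    hit <- !is.na(m)
    if (any(hit)) edges[[r]] <- cbind(which(ok)[hit], m[hit])
  }
  edges <- do.call(rbind, edges)
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (!is.null(edges) && nrow(edges) > 0)
    g <- igraph::add_edges(g, t(edges))
  memb <- igraph::components(g)$membership
  # renumber by lexicographic order of each component's first voxel
  ord <- do.call(order, lapply(seq_len(k), function(j) coords[, j]))
  lex_pos <- integer(n)
  lex_pos[ord] <- seq_len(n)
  comp_first <- tapply(lex_pos, memb, min)
  new_id <- rank(comp_first, ties.method = "first")
  as.integer(new_id[memb])
}

# coords of TRUE cells of a logical array/matrix as integer index matrix
which_coords <- function(mask) {
  w <- which(mask)
  if (length(w) == 0L) {
    return(matrix(integer(0), 0, length(dim(mask) %||% c(length(mask)))))
  }
  arrayInd(w, .dim = dim(mask))
}

#' Label the 26-connected components of a binary volume
#'
#' Partitions the foreground of a binary 3D grid into maximal 26-connected
#' components (face, edge, and corner adjacency). Component ids are assigned
#' in ascending lexicographic `(z, y, x)` order of each component's first
#' voxel, so labeling is deterministic.
#'
#' @param binary_volume logical (or 0/1) 3D array indexed `[z, y, x]`.
#' @return A tibble with one row per component: `id`, `voxels` (list column of
#'   integer matrices with columns z, y, x) and `voxel_count`.
#' @export
label_components_26 <- function(binary_volume) {
  if (length(dim(binary_volume)) != 3L) stop_nc("binary_volume must be 3D")
  mask <- binary_volume != 0
  coords <- which_coords(mask)
  memb <- connected_components(coords, dim(mask), offsets_3d_26())
  if (length(memb) == 0L) {
    return(tibble::tibble(id = integer(0), voxels = list(), voxel_count = integer(0)))
  }
  split_idx <- split(seq_len(nrow(coords)), memb)
  tibble::tibble(
    id = as.integer(names(split_idx)),
    voxels = lapply(split_idx, function(i) {
      m <- coords[i, , drop = FALSE]
      colnames(m) <- c("z", "y", "x")
      m
    }),
    voxel_count = lengths(split_idx)
  )
}

#' Fill holes in a 2D binary mask
#'
#' Every background region that is not 4-connected to the slice border is set
#' to foreground. The output is always a superset of the input, and the
#' operation is idempotent.
#'
#' @param slice_mask logical (or 0/1) matrix.
#' @return A logical matrix of the same shape.
#' @export
fill_holes <- function(slice_mask) {
  if (!is.matrix(slice_mask)) stop_nc("slice_mask must be a 2D matrix")
  mask <- slice_mask != 0
  bg <- which_coords(!mask)
  if (nrow(bg) == 0L) return(mask)
  memb <- connected_components(bg, dim(mask), offsets_2d_4())
  on_border <- bg[, 1] == 1L | bg[, 1] == nrow(mask) |
    bg[, 2] == 1L | bg[, 2] == ncol(mask)
  border_comps <- unique(memb[on_border])
  hole <- !(memb %in% border_comps)
  if (any(hole)) mask[bg[hole, , drop = FALSE]] <- TRUE
  mask
}

# volume-level slice-wise hole filling, restricted to the in-plane bounding
# box of the mask (everything outside the box is background connected to the
# slice border, so it can never be a hole)
fill_holes_volume <- function(mask3d) {
  out <- mask3d
  fg <- which_coords(mask3d)
  if (nrow(fg) == 0L) return(out)
  y0 <- max(1L, min(fg[, 2]) - 1L); y1 <- min(dim(mask3d)[2], max(fg[, 2]) + 1L)
  x0 <- max(1L, min(fg[, 3]) - 1L); x1 <- min(dim(mask3d)[3], max(fg[, 3]) + 1L)
  for (z in unique(fg[, 1])) {
    sub <- mask3d[z, y0:y1, x0:x1]
    out[z, y0:y1, x0:x1] <- fill_holes(sub)
  }
  out
}

# per-slice 2D components of a 3D foreground in one pass: connectivity is
# in-plane only, so components never span slices
slicewise_components <- function(coords, dims, offsets2d) {
  off <- cbind(0L, offsets2d)
  connected_components(coords, dims, off)
}
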