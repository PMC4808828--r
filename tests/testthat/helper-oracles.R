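# Independent oracles used across the test files. These deliberately avoid the
# package's own code paths: plain BFS flood fills, naive loops over thresholds,
# direct arithmetic.

# BFS flood-fill labeling of a logical array under an explicit full
# neighborhood (list of integer offset vectors). Returns an integer array of
# labels (0 = background), labeled in scan order of R's linear indexing.
bfs_label <- function(mask, offsets) {
  dims <- dim(mask)
  labels <- array(0L, dim = dims)
  coords <- which(mask, arr.ind = TRUE)
  if (nrow(coords) == 0L) return(labels)
  lab <- 0L
  for (s in seq_len(nrow(coords))) {
    start <- coords[s, ]
    if (labels[matrix(start, 1)] != 0L) next
    lab <- lab + 1L
    queue <- list(start)
    labels[matrix(start, 1)] <- lab
    while (length(queue)) {
      cur <- queue[[1]]
      queue <- queue[-1]
      for (off in offsets) {
        nb <- cur + off
        if (any(nb < 1L) || any(nb > dims)) next
        nbm <- matrix(nb, 1)
        if (mask[nbm] && labels[nbm] == 0L) {
          labels[nbm] <- lab
          queue <- c(queue, list(nb))
        }
      }
    }
  }
  labels
}

offsets_full_26 <- function() {
  g <- expand.grid(-1:1, -1:1, -1:1)
  g <- g[rowSums(abs(g)) > 0, ]
  lapply(seq_len(nrow(g)), function(i) as.integer(g[i, ]))
}

offsets_full_8 <- function() {
  g <- expand.grid(-1:1, -1:1)
  g <- g[rowSums(abs(g)) > 0, ]
  lapply(seq_len(nrow(g)), function(i) as.integer(g[i, ]))
}

offsets_full_4 <- function() list(c(1L, 0L), c(-1L, 0L), c(0L, 1L), c(0L, -1L))

# hole filling oracle: flood the background from the border (4-connectivity);
# everything not reached is foreground
fill_holes_oracle <- function(mask) {
  dims <- dim(mask)
  padded <- matrix(FALSE, dims[1] + 2, dims[2] + 2)
  padded[2:(dims[1] + 1), 2:(dims[2] + 1)] <- mask
  bg <- !padded
  reach <- bfs_label(bg, offsets_full_4())
  outside <- unique(c(reach[1, ], reach[nrow(reach), ], reach[, 1], reach[, ncol(reach)]))
  outside <- outside[outside != 0]
  hole <- bg & !matrix(reach %in% outside, nrow(reach))
  filled <- padded | hole
  filled[2:(dims[1] + 1), 2:(dims[2] + 1)]
}

# naive Kittler-Illingworth criterion, evaluated by explicit loops
min_error_oracle <- function(counts) {
  N <- sum(counts)
  g <- 0:255
  best_t <- NA_integer_
  best_J <- Inf
  for (t in 0:254) {
    idx1 <- g <= t
    n1 <- sum(counts[idx1]); n2 <- N - n1
    if (n1 == 0 || n2 == 0) next
    P1 <- n1 / N; P2 <- n2 / N
    mu1 <- sum(counts[idx1] * g[idx1]) / n1
    mu2 <- sum(counts[!idx1] * g[!idx1]) / n2
    v1 <- max(sum(counts[idx1] * (g[idx1] - mu1)^2) / n1, 1 / 12)
    v2 <- max(sum(counts[!idx1] * (g[!idx1] - mu2)^2) / n2, 1 / 12)
    J <- 1 + 2 * (P1 * log(sqrt(v1)) + P2 * log(sqrt(v2))) -
      2 * (P1 * log(P1) + P2 * log(P2))
    if (J < best_J) {
      best_J <- J
      best_t <- t
    }
  }
  best_t + 0.5
}

# random bimodal histogram: two Gaussian classes, Poisson-ish jitter
random_bimodal_hist <- function(seed) {
  set.seed(seed)
  mu <- sort(runif(2, 20, 235))
  while (diff(mu) < 40) mu <- sort(runif(2, 20, 235))
  sd_ <- runif(2, 3, 25)
  w <- runif(1, 0.2, 0.8)
  n <- 20000
  x <- c(rnorm(round(n * w), mu[1], sd_[1]), rnorm(round(n * (1 - w)), mu[2], sd_[2]))
  x <- pmin(pmax(x, 0), 255)
  counts <- tabulate(floor(x) + 1L, nbins = 256L)
  names(counts) <- 0:255
  counts
}

# brute-force digitized sphere: 1-based (z,y,x) indices of voxel centers
# within radius_mm of center (cx, cy, cz in mm)
digitized_sphere <- function(shape, spacing, center_xyz, radius_mm) {
  idx <- which(array(TRUE, shape), arr.ind = TRUE)
  zmm <- (idx[, 1] - 1) * spacing[1]
  ymm <- (idx[, 2] - 1) * spacing[2]
  xmm <- (idx[, 3] - 1) * spacing[3]
  keep <- (xmm - center_xyz[1])^2 + (ymm - center_xyz[2])^2 +
    (zmm - center_xyz[3])^2 <= radius_mm^2
  idx[keep, , drop = FALSE]
}

# two well-separated Gaussian clouds in feature space, labeled, as a tibble
# shaped like a feature matrix (d1, d2 informative, rest noise)
separable_toy_features <- function(n_per_class = 25, seed = 7) {
  set.seed(seed)
  pos <- cbind(rnorm(n_per_class, 0.8, 0.04), rnorm(n_per_class, 0.8, 0.04))
  neg <- cbind(rnorm(n_per_class, 0.2, 0.04), rnorm(n_per_class, 0.2, 0.04))
  tibble::tibble(
    id = seq_len(2 * n_per_class),
    d1 = c(pos[, 1], neg[, 1]),
    d2 = c(pos[, 2], neg[, 2]),
    d3 = runif(2 * n_per_class),
    label = rep(c("nodule", "non-nodule"), each = n_per_class)
  )
}

# small noiseless two-lung phantom helpers -----------------------------------

small_phantom_spec <- function(..., shape = c(24L, 96L, 96L)) {
  phantom_spec(shape_voxels = shape, ...)
}

# the geometric lung mask of a phantom, from its recorded geometry
geometry_lung_mask <- function(ph) {
  shape <- dim(ph$volume$intensities)
  sp <- ph$volume$spacing_mm
  g <- ph$geometry
  m <- array(FALSE, shape)
  for (side in c("left", "right")) {
    lung <- g$lungs[[side]]
    idx <- which(array(TRUE, shape), arr.ind = TRUE)
    zmm <- (idx[, 1] - 1) * sp[1]; ymm <- (idx[, 2] - 1) * sp[2]
    xmm <- (idx[, 3] - 1) * sp[3]
    q <- ((xmm - lung$center[1]) / lung$semi[1])^2 +
      ((ymm - lung$center[2]) / lung$semi[2])^2 +
      ((zmm - lung$center[3]) / lung$semi[3])^2
    m[idx[q <= 1, , drop = FALSE]] <- TRUE
  }
  m
}

# cached 20-phantom suite + end-to-end evaluation shared by acceptance tests
.suite_cache <- new.env(parent = emptyenv())

get_seed11_suite <- function() {
  if (is.null(.suite_cache$suite)) .suite_cache$suite <- phantom_suite(20, seed = 11)
  .suite_cache$suite
}

get_seed11_evaluation <- function() {
  if (is.null(.suite_cache$eval)) {
    .suite_cache$eval <- evaluate_phantom_suite(get_seed11_suite(),
                                                pipeline_config(), seed = 11)
  }
  .suite_cache$eval
}
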