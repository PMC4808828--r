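# RBF-kernel epsilon-SVR used as a nodule/non-nodule classifier (regression on
# +/-1 targets, thresholded at 0), with joint min-max normalization and a
# balanced training matrix.

LABEL_NODULE <- "nodule"
LABEL_NON <- "non-nodule"

as_pm1 <- function(label) ifelse(label == LABEL_NODULE, 1, -1)

#' Build a balanced training matrix
#'
#' Samples `n_per_class` rows of each label ("nodule", "non-nodule") without
#' replacement. Deterministic for a fixed seed.
#'
#' @param m labeled feature matrix tibble (column `label`).
#' @param n_per_class rows per class (the reference protocol uses 20 + 20).
#' @param seed integer seed for the sampling.
#' @return Tibble with exactly `2 * n_per_class` rows.
#' @export
build_balanced_matrix <- function(m, n_per_class = 20L, seed = 1L) {
  if (!"label" %in% names(m)) stop_nc("feature matrix has no label column")
  idx_pos <- which(m$label == LABEL_NODULE)
  idx_neg <- which(m$label == LABEL_NON)
  if (length(idx_pos) < n_per_class || length(idx_neg) < n_per_class)
    stop_nc(sprintf(
      "not enough rows per class: need %d, have %d nodules and %d non-nodules",
      n_per_class, length(idx_pos), length(idx_neg)
    ))
  sel <- with_seed(seed, c(sample(idx_pos, n_per_class), sample(idx_neg, n_per_class)))
  m[sort(sel), , drop = FALSE]
}

#' Joint min-max normalization of training and new data
#'
#' Per-feature min-max over the concatenation of both matrices maps every
#' feature to `[0, 1]`; both matrices are transformed with the same statistics
#' and split back. Constant features map to 0. When `new` is `NULL` or empty,
#' the statistics come from `train` alone (the leakage-free protocol).
#'
#' @param train,new feature matrix tibbles with identical feature columns
#'   (`new` may be `NULL`).
#' @param features feature column names.
#' @return List with `train`, `new`, and `norm_stats` (tibble of feature,
#'   min, max).
#' @export
joint_normalize <- function(train, new = NULL,
                            features = intersect(FEATURE_NAMES, names(train))) {
  if (!is.null(new) && nrow(new) > 0 && !all(features %in% names(new)))
    stop_nc("train and new matrices disagree on feature columns")
  both <- if (!is.null(new) && nrow(new) > 0) {
    rbind(as.matrix(train[, features]), as.matrix(new[, features]))
  } else {
    as.matrix(train[, features])
  }
  lo <- apply(both, 2, min)
  hi <- apply(both, 2, max)
  stats_tbl <- tibble::tibble(feature = features, min = unname(lo), max = unname(hi))
  tr <- apply_norm_stats(train, stats_tbl)
  nw <- if (!is.null(new)) apply_norm_stats(new, stats_tbl) else NULL
  list(train = tr, new = nw, norm_stats = stats_tbl)
}

#' Apply stored normalization statistics to a feature matrix
#'
#' @param m feature matrix tibble.
#' @param norm_stats tibble `(feature, min, max)` as returned by
#'   [joint_normalize()] or stored on a [train_svm()] fit.
#' @return `m` with normalized feature columns and
#'   `normalization = "joint-normalized"`.
#' @export
apply_norm_stats <- function(m, norm_stats) {
  out <- m
  for (i in seq_len(nrow(norm_stats))) {
    f <- norm_stats$feature[i]
    rng <- norm_stats$max[i] - norm_stats$min[i]
    out[[f]] <- if (rng > 0) (m[[f]] - norm_stats$min[i]) / rng else rep(0, nrow(m))
  }
  attr(out, "normalization") <- "joint-normalized"
  out
}

default_cost_grid <- function() 2^seq(-5, 15, by = 2)
default_gamma_grid <- function() 2^seq(-15, 3, by = 2)

#' Train the RBF-kernel epsilon-SVR nodule classifier
#'
#' Fits an epsilon-SVR with RBF kernel on a balanced, normalized training
#' matrix, regressing on targets +1 (nodule) / -1 (non-nodule); predictions
#' are thresholded at `decision_threshold` to classify. Unless `cost` and
#' `gamma` are given, they are chosen by grid search (C in 2^-5..2^15, gamma
#' in 2^-15..2^3, both in multiplicative steps of 4) maximizing k-fold
#' cross-validated accuracy of `sign(prediction)`; ties prefer the smaller
#' cost, then the smaller gamma.
#'
#' @param bt balanced, normalized feature matrix with a `label` column.
#' @param epsilon_p epsilon-insensitive loss width in `[0, 1)` (default 0.4,
#'   the operating point selected by the reference protocol).
#' @param seed integer seed (cross-validation fold assignment).
#' @param norm_stats normalization statistics to store for deployment.
#' @param features feature column names used by the model.
#' @param cost,gamma optional fixed kernel parameters (skips the grid search).
#' @param n_folds folds for the parameter search (default 5).
#' @param decision_threshold score cut for calling a nodule (default 0).
#' @return An object of class `nodule_svm`.
#' @export
train_svm <- function(bt, epsilon_p = 0.4, seed = 1L, norm_stats = NULL,
                      features = intersect(FEATURE_NAMES, names(bt)),
                      cost = NULL, gamma = NULL, n_folds = 5L,
                      decision_threshold = 0) {
  if (!"label" %in% names(bt)) stop_nc("training matrix has no label column")
  if (length(unique(bt$label)) < 2L)
    stop_nc("training labels are degenerate: a single class cannot be learned")
  if (epsilon_p < 0 || epsilon_p >= 1) stop_nc("epsilon_p must be in [0, 1)")
  X <- as.matrix(bt[, features])
  y <- as_pm1(bt$label)

  search <- NULL
  if (is.null(cost) || is.null(gamma)) {
    search <- svm_grid_search(X, y, epsilon_p, seed, n_folds)
    cost <- search$cost[1]
    gamma <- search$gamma[1]
  }
  fit <- e1071::svm(X, y, type = "eps-regression", kernel = "radial",
                    cost = cost, gamma = gamma, epsilon = epsilon_p,
                    scale = FALSE)
  structure(
    list(
      fit = fit, cost = cost, gamma = gamma, epsilon_p = epsilon_p,
      feature_names = features, norm_stats = norm_stats,
      decision_threshold = decision_threshold, search = search,
      n_train = nrow(bt)
    ),
    class = "nodule_svm"
  )
}

# grid search over (cost, gamma) by k-fold CV accuracy of sign(prediction);
# result rows sorted best first with deterministic tie-breaking
svm_grid_search <- function(X, y, epsilon_p, seed, n_folds,
                            cost_grid = default_cost_grid(),
                            gamma_grid = default_gamma_grid()) {
  n <- nrow(X)
  folds <- with_seed(seed, sample(rep_len(seq_len(n_folds), n)))
  grid <- expand.grid(cost = cost_grid, gamma = gamma_grid,
                      KEEP.OUT.ATTRS = FALSE)
  acc <- vapply(seq_len(nrow(grid)), function(i) {
    correct <- 0L
    for (k in seq_len(n_folds)) {
      tr <- folds != k
      if (length(unique(y[tr])) < 2L) next
      f <- e1071::svm(X[tr, , drop = FALSE], y[tr], type = "eps-regression",
                      kernel = "radial", cost = grid$cost[i],
                      gamma = grid$gamma[i], epsilon = epsilon_p, scale = FALSE)
      p <- predict(f, X[!tr, , drop = FALSE])
      correct <- correct + sum(ifelse(p >= 0, 1, -1) == y[!tr])
    }
    correct / n
  }, 0)
  out <- tibble::as_tibble(grid)
  out$accuracy <- acc
  dplyr::arrange(out, dplyr::desc(.data$accuracy), .data$cost, .data$gamma)
}

#' @export
print.nodule_svm <- function(x, ...) {
  cat(sprintf(
    "<nodule_svm> RBF eps-SVR: C = %g, gamma = %g, epsilon = %g, %d SV, %d features\n",
    x$cost, x$gamma, x$epsilon_p, x$fit$tot.nSV, length(x$feature_names)
  ))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the classifier's parameter search
#'
#' @param x a `nodule_svm`.
#' @param ... unused.
#' @return Grid-search results (cost, gamma, cross-validated accuracy), best
#'   first; a single row when the parameters were fixed by the caller.
#' @export
tidy.nodule_svm <- function(x, ...) {
  x$search %||% tibble::tibble(cost = x$cost, gamma = x$gamma, accuracy = NA_real_)
}

#' One-row summary of a fitted nodule classifier
#'
#' @param x a `nodule_svm`.
#' @param ... unused.
#' @export
glance.nodule_svm <- function(x, ...) {
  tibble::tibble(
    cost = x$cost, gamma = x$gamma, epsilon_p = x$epsilon_p,
    n_support_vectors = x$fit$tot.nSV, n_train = x$n_train,
    decision_threshold = x$decision_threshold
  )
}

#' Classify candidates with a trained nodule classifier
#'
#' The SVR regression output is the score; a candidate is called a nodule when
#' `score >= decision_threshold`. The input must already be normalized (with
#' the classifier's stored statistics or jointly with its training data); a
#' warning is raised if values fall outside `[-0.1, 1.1]`.
#'
#' @param clf a [train_svm()] fit.
#' @param new feature matrix tibble (normalized).
#' @param decision_threshold overrides the classifier's stored threshold.
#' @return `new` with `.score` and `.label` columns appended.
#' @export
classify <- function(clf, new, decision_threshold = clf$decision_threshold) {
  stopifnot(inherits(clf, "nodule_svm"))
  if (nrow(new) == 0L) {
    out <- new
    out$.score <- numeric(0)
    out$.label <- character(0)
    return(out)
  }
  X <- as.matrix(new[, clf$feature_names])
  if (min(X) < -0.1 || max(X) > 1.1)
    warning("feature values outside [-0.1, 1.1]: input does not look normalized",
            call. = FALSE)
  score <- unname(predict(clf$fit, X))
  out <- new
  out$.score <- score
  out$.label <- ifelse(score >= decision_threshold, LABEL_NODULE, LABEL_NON)
  out
}
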