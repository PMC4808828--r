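# Scoring detections against ground truth: confusion counts, the three
# headline metrics, false positives per scan, leave-two-out cross-validation,
# and ROC analysis over the epsilon parameter.

#' Confusion counts
#'
#' @param TP,TN,FP,FN non-negative integer counts.
#' @return An object of class `confusion_counts`.
#' @export
confusion_counts <- function(TP = 0L, TN = 0L, FP = 0L, FN = 0L) {
  counts <- c(TP = TP, TN = TN, FP = FP, FN = FN)
  if (any(counts < 0)) stop_nc("confusion counts must be non-negative")
  structure(lapply(as.list(counts), as.integer), class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts> TP = %d, TN = %d, FP = %d, FN = %d\n",
              x$TP, x$TN, x$FP, x$FN))
  invisible(x)
}

#' @export
`+.confusion_counts` <- function(e1, e2) {
  confusion_counts(e1$TP + e2$TP, e1$TN + e2$TN, e1$FP + e2$FP, e1$FN + e2$FN)
}

#' Match classified candidates to ground-truth nodules
#'
#' A predicted-nodule candidate is a true positive if its centroid lies within
#' the ground-truth radius of some truth center; truths are matched at most
#' once, nearest pair first. Unmatched predicted nodules are false positives;
#' unmatched truths are false negatives (whether missed at segmentation or
#' classified as non-nodule); predicted non-nodules overlapping no truth are
#' true negatives.
#'
#' @param cands tibble with `cx_mm`, `cy_mm`, `cz_mm` and predicted labels in
#'   `.label` (or `label`).
#' @param truth tibble with `cx_mm`, `cy_mm`, `cz_mm`, `radius_mm`.
#' @return A [confusion_counts()].
#' @export
match_candidates_to_truth <- function(cands, truth) {
  lab <- cands$.label %||% cands$label
  if (nrow(cands) && is.null(lab)) stop_nc("candidates carry no predicted label")
  pred_pos <- which(lab == LABEL_NODULE)
  pred_neg <- which(lab == LABEL_NON)
  n_truth <- nrow(truth)

  centers <- function(idx) {
    cbind(cands$cx_mm[idx], cands$cy_mm[idx], cands$cz_mm[idx])
  }
  tcenters <- cbind(truth$cx_mm, truth$cy_mm, truth$cz_mm)

  # greedy nearest-first assignment of predicted nodules to truths
  match_greedy <- function(cand_idx, truth_avail) {
    matched_c <- integer(0); matched_t <- integer(0)
    if (length(cand_idx) == 0L || !any(truth_avail)) {
      return(list(c = matched_c, t = matched_t))
    }
    cc <- centers(cand_idx)
    pairs <- expand.grid(ci = seq_along(cand_idx), ti = which(truth_avail))
    d <- sqrt(rowSums((cc[pairs$ci, , drop = FALSE] -
                         tcenters[pairs$ti, , drop = FALSE])^2))
    ok <- d <= truth$radius_mm[pairs$ti]
    pairs <- pairs[ok, , drop = FALSE]; d <- d[ok]
    for (k in order(d)) {
      ci <- pairs$ci[k]; ti <- pairs$ti[k]
      if (cand_idx[ci] %in% matched_c || ti %in% matched_t) next
      matched_c <- c(matched_c, cand_idx[ci])
      matched_t <- c(matched_t, ti)
    }
    list(c = matched_c, t = matched_t)
  }

  avail <- rep(TRUE, n_truth)
  pos_match <- match_greedy(pred_pos, avail)
  TP <- length(pos_match$c)
  FP <- length(pred_pos) - TP
  avail[pos_match$t] <- FALSE
  # predicted non-nodules overlapping a remaining truth are missed detections,
  # not true negatives
  neg_match <- match_greedy(pred_neg, avail)
  TN <- length(pred_neg) - length(neg_match$c)
  FN <- n_truth - TP
  confusion_counts(TP = TP, TN = TN, FP = FP, FN = FN)
}

#' Sensitivity, specificity, and accuracy
#'
#' `sensitivity = TP / (TP + FN)`, `specificity = TN / (TN + FP)`,
#' `accuracy = (TP + TN) / (TP + TN + FP + FN)`, reported as percentages
#' rounded half-up to 2 decimals. A metric with a zero denominator is
#' undefined and reported as `NA`, never as 0.
#'
#' @param cc a [confusion_counts()].
#' @return Tibble with columns `metric`, `value` (exact proportion), and
#'   `percent` (rounded percentage).
#' @export
metrics <- function(cc) {
  stopifnot(inherits(cc, "confusion_counts"))
  safe_div <- function(num, den) if (den > 0) num / den else NA_real_
  vals <- c(
    sensitivity = safe_div(cc$TP, cc$TP + cc$FN),
    specificity = safe_div(cc$TN, cc$TN + cc$FP),
    accuracy = safe_div(cc$TP + cc$TN, cc$TP + cc$TN + cc$FP + cc$FN)
  )
  tibble::tibble(
    metric = names(vals),
    value = unname(vals),
    percent = round_half_up(unname(vals) * 100, 2)
  )
}

#' False positives per scan
#'
#' @param cc a [confusion_counts()].
#' @param n_scans number of scans the counts were pooled over (>= 1).
#' @return FP / n_scans.
#' @export
fp_per_scan <- function(cc, n_scans) {
  stopifnot(inherits(cc, "confusion_counts"))
  if (n_scans < 1) stop_nc("n_scans must be >= 1")
  cc$FP / n_scans
}

# the two-element test sets for leave-two-out CV: exhaustive when feasible,
# otherwise a disjoint cover of all rows plus distinct random extra pairs
lto_pairs <- function(n, max_folds, seed) {
  if (choose(n, 2) <= max_folds) {
    return(t(combn(n, 2)))
  }
  with_seed(seed, {
    perm <- sample(n)
    cover <- matrix(perm[seq_len(2 * (n %/% 2))], ncol = 2, byrow = TRUE)
    key <- function(p) paste(pmin(p[, 1], p[, 2]), pmax(p[, 1], p[, 2]))
    seen <- key(cover)
    extra <- matrix(integer(0), 0, 2)
    while (nrow(cover) + nrow(extra) < max_folds) {
      cand <- matrix(sample(n, 2 * (max_folds - nrow(cover) - nrow(extra)),
                            replace = TRUE), ncol = 2)
      cand <- cand[cand[, 1] != cand[, 2], , drop = FALSE]
      k <- key(cand)
      fresh <- !duplicated(k) & !(k %in% seen)
      extra <- rbind(extra, cand[fresh, , drop = FALSE])
      seen <- c(seen, k[fresh])
    }
    rbind(cover, extra[seq_len(max_folds - nrow(cover)), , drop = FALSE])
  })
}

#' Leave-two-out cross-validation of the nodule classifier
#'
#' Every fold holds out two rows; the remaining rows supply a balanced
#' training matrix which is normalized jointly with the held-out rows
#' (`normalization = "transductive"`) or alone with its statistics applied to
#' them (`"training"`, the leakage-free default), then an RBF epsilon-SVR is
#' trained and the two rows are classified. All `C(n, 2)` pairs are
#' enumerated when there are at most `max_folds` of them; otherwise
#' `max_folds` distinct pairs are sampled so that every row is tested at
#' least once. `C` and `gamma` are tuned once on an initial balanced matrix
#' and reused across folds.
#'
#' @param m labeled feature matrix tibble (raw scale).
#' @param epsilon_p epsilon-insensitive loss width (default 0.4).
#' @param seed integer seed.
#' @param max_folds fold budget (default 500).
#' @param n_per_class balanced-matrix size per class; capped at the available
#'   training rows of the scarcer class (default 20).
#' @param normalization `"training"` (leakage-free) or `"transductive"`
#'   (train and test normalized together).
#' @param decision_threshold score cut for calling a nodule.
#' @return An object of class `lto_cv`: list with `counts`
#'   (aggregated [confusion_counts()] over all test slots), `predictions`
#'   (per-row tibble: `truth`, majority `pred`, `mean_score`, `times_tested`),
#'   `n_folds`, `cost`, `gamma`, `epsilon_p`.
#' @export
leave_two_out_cv <- function(m, epsilon_p = 0.4, seed = 1L, max_folds = 500L,
                             n_per_class = 20L,
                             normalization = c("training", "transductive"),
                             decision_threshold = 0) {
  normalization <- match.arg(normalization)
  if (!"label" %in% names(m)) stop_nc("feature matrix has no label column")
  n <- nrow(m)
  if (n < 4) stop_nc("need at least 4 labeled rows for leave-two-out CV")
  features <- intersect(FEATURE_NAMES, names(m))
  pairs <- lto_pairs(n, max_folds, seed)

  # tune C and gamma once on a balanced matrix drawn from all rows
  npc_all <- min(n_per_class, min(table(m$label)))
  bt0 <- build_balanced_matrix(m, npc_all, seed = derive_seed(seed, 0L))
  nrm0 <- joint_normalize(bt0, features = features)
  clf0 <- train_svm(nrm0$train, epsilon_p = epsilon_p,
                    seed = derive_seed(seed, 1L), features = features,
                    decision_threshold = decision_threshold)

  score_sum <- numeric(n)
  vote_pos <- integer(n)
  tested <- integer(n)
  counts <- confusion_counts()
  skipped <- 0L

  for (f in seq_len(nrow(pairs))) {
    test_idx <- pairs[f, ]
    train_rows <- m[-test_idx, , drop = FALSE]
    tab <- table(factor(train_rows$label, levels = c(LABEL_NODULE, LABEL_NON)))
    if (any(tab < 2)) {
      skipped <- skipped + 1L
      warning("fold skipped: fewer than 2 training rows of a class", call. = FALSE)
      next
    }
    npc <- min(n_per_class, min(tab))
    bt <- build_balanced_matrix(train_rows, npc, seed = derive_seed(seed, f + 1L))
    test_rows <- m[test_idx, , drop = FALSE]
    if (normalization == "transductive") {
      nrm <- joint_normalize(bt, test_rows, features = features)
      tr <- nrm$train; te <- nrm$new
    } else {
      nrm <- joint_normalize(bt, features = features)
      tr <- nrm$train; te <- apply_norm_stats(test_rows, nrm$norm_stats)
    }
    clf <- train_svm(tr, epsilon_p = epsilon_p, seed = derive_seed(seed, f + 1L),
                     features = features, cost = clf0$cost, gamma = clf0$gamma,
                     norm_stats = nrm$norm_stats,
                     decision_threshold = decision_threshold)
    pred <- suppressWarnings(classify(clf, te))
    truth_lab <- test_rows$label
    counts <- counts + confusion_counts(
      TP = sum(pred$.label == LABEL_NODULE & truth_lab == LABEL_NODULE),
      TN = sum(pred$.label == LABEL_NON & truth_lab == LABEL_NON),
      FP = sum(pred$.label == LABEL_NODULE & truth_lab == LABEL_NON),
      FN = sum(pred$.label == LABEL_NON & truth_lab == LABEL_NODULE)
    )
    score_sum[test_idx] <- score_sum[test_idx] + pred$.score
    vote_pos[test_idx] <- vote_pos[test_idx] + (pred$.label == LABEL_NODULE)
    tested[test_idx] <- tested[test_idx] + 1L
  }

  mean_score <- ifelse(tested > 0, score_sum / tested, NA_real_)
  predictions <- tibble::tibble(
    row = seq_len(n),
    truth = m$label,
    pred = dplyr::case_when(
      tested == 0L ~ NA_character_,
      vote_pos * 2L >= tested ~ LABEL_NODULE,
      TRUE ~ LABEL_NON
    ),
    mean_score = mean_score,
    times_tested = tested
  )
  structure(
    list(counts = counts, predictions = predictions,
         n_folds = nrow(pairs) - skipped, cost = clf0$cost, gamma = clf0$gamma,
         epsilon_p = epsilon_p, normalization = normalization),
    class = "lto_cv"
  )
}

#' @export
print.lto_cv <- function(x, ...) {
  cat(sprintf("<lto_cv> %d folds, epsilon = %g, C = %g, gamma = %g (%s normalization)\n",
              x$n_folds, x$epsilon_p, x$cost, x$gamma, x$normalization))
  print(x$counts)
  invisible(x)
}

#' @rdname metrics
#' @param x an `lto_cv` object.
#' @param ... unused.
#' @export
tidy.lto_cv <- function(x, ...) metrics(x$counts)

#' @rdname metrics
#' @export
glance.lto_cv <- function(x, ...) {
  m <- metrics(x$counts)
  tibble::tibble(
    n_folds = x$n_folds, epsilon_p = x$epsilon_p, cost = x$cost,
    gamma = x$gamma,
    sensitivity = m$value[m$metric == "sensitivity"],
    specificity = m$value[m$metric == "specificity"],
    accuracy = m$value[m$metric == "accuracy"]
  )
}

#' ROC analysis over the epsilon parameter
#'
#' Runs leave-two-out cross-validation at each epsilon and reports the
#' operating point (sensitivity vs 1 - specificity at the default score
#' threshold), plus a full curve obtained by sweeping the decision threshold
#' over the cross-validated per-row mean scores.
#'
#' @inheritParams leave_two_out_cv
#' @param epsilons epsilon values, each in `[0, 1)`.
#' @return Tibble with `epsilon`, `threshold`, `sensitivity`,
#'   `one_minus_specificity`, and `operating_point` (TRUE for the default
#'   threshold row of each epsilon).
#' @export
roc_over_epsilon <- function(m, epsilons, seed = 1L, max_folds = 500L,
                             n_per_class = 20L) {
  if (length(epsilons) == 0L) stop_nc("epsilons must be nonempty")
  if (any(epsilons < 0 | epsilons >= 1)) stop_nc("each epsilon must be in [0, 1)")
  purrr::map_dfr(epsilons, function(eps) {
    cv <- leave_two_out_cv(m, epsilon_p = eps, seed = seed,
                           max_folds = max_folds, n_per_class = n_per_class)
    p <- cv$predictions[!is.na(cv$predictions$mean_score), ]
    is_pos <- p$truth == LABEL_NODULE
    thr <- sort(unique(c(0, p$mean_score, max(p$mean_score) + 1e-9)))
    pts <- purrr::map_dfr(thr, function(t) {
      call_pos <- p$mean_score >= t
      tibble::tibble(
        epsilon = eps, threshold = t,
        sensitivity = if (any(is_pos)) mean(call_pos[is_pos]) else NA_real_,
        one_minus_specificity = if (any(!is_pos)) mean(call_pos[!is_pos]) else NA_real_,
        operating_point = t == 0
      )
    })
    pts
  })
}
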