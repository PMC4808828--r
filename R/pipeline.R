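# Pipeline orchestration: configuration, the full detection run on one
# volume, and end-to-end evaluation of a phantom suite.

#' Pipeline configuration
#'
#' All tunable thresholds of the detection pipeline with their defaults.
#' Unknown names are rejected.
#'
#' @param ... named overrides of the defaults: `min_diameter_mm` (4),
#'   `structure_threshold` (NULL = Otsu on lung-interior intensities),
#'   `intensity_min` (NULL = the structure threshold), `sphericity_min` (0.3),
#'   `width_min_mm` (2), `width_max_mm` (Inf), `elongation_max` (4),
#'   `second_lung_min_frac` (0.1), `r_max` (0.95), `epsilon_p` (0.4),
#'   `n_per_class` (20), `max_folds` (500), `normalization` ("training"),
#'   `decision_threshold` (0), `seed` (1).
#' @return Named list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    min_diameter_mm = 4.0,
    structure_threshold = NULL,
    intensity_min = NULL,
    sphericity_min = 0.3,
    width_min_mm = 2.0,
    width_max_mm = Inf,
    elongation_max = 4.0,
    second_lung_min_frac = 0.1,
    r_max = 0.95,
    epsilon_p = 0.4,
    n_per_class = 20L,
    max_folds = 500L,
    normalization = "training",
    decision_threshold = 0,
    seed = 1L
  )
  overrides <- list(...)
  if (length(overrides) == 1L && is.list(overrides[[1]]) && is.null(names(overrides)[1]))
    overrides <- overrides[[1]]
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown))
    stop_nc("unknown pipeline_config field(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, overrides, keep.null = TRUE)
  structure(cfg, class = "pipeline_config")
}

as_volume_input <- function(x) {
  if (inherits(x, "ct_volume")) return(x)
  if (inherits(x, "ct_phantom")) return(x$volume)
  if (is.character(x) && length(x) == 1L) {
    if (!file.exists(x)) stop_nc("input path does not exist: ", x)
    return(read_nifti(x))
  }
  stop_nc("input must be a ct_volume, ct_phantom, or NIfTI path")
}

#' Run the full detection pipeline on one volume
#'
#' Normalizes the volume, extracts the lungs, segments candidates (2D filter,
#' 3D 26-connected components, blob discrimination), computes the eight
#' features, and - when a trained classifier is supplied - classifies
#' candidates into nodules and non-nodules. Every stage's structure counts are
#' recorded in the report. The run is deterministic: the same input, config,
#' and classifier give a byte-identical [report_json()].
#'
#' @param x a [ct_volume()], [generate_phantom()] result, or NIfTI path.
#' @param config a [pipeline_config()].
#' @param classifier optional [train_svm()] fit (with stored `norm_stats`).
#' @param truth optional ground-truth nodule tibble; with a classifier, the
#'   report then carries confusion counts and metrics.
#' @param dry_run validate the inputs and config, touch no data.
#' @return An object of class `nodule_report`.
#' @export
run_pipeline <- function(x, config = pipeline_config(), classifier = NULL,
                         truth = NULL, dry_run = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  if (dry_run) {
    return(structure(list(config = unclass(config), dry_run = TRUE),
                     class = "nodule_report"))
  }
  v <- normalize_volume(as_volume_input(x))
  if (is.null(truth) && inherits(x, "ct_phantom")) truth <- x$truth

  lungs <- extract_lungs(v, second_lung_min_frac = config$second_lung_min_frac)
  det <- detect_candidates(v, lungs, config)
  feats <- feature_matrix(det$candidates, v)

  calls <- NULL
  evaluation <- NULL
  if (!is.null(classifier) && nrow(feats)) {
    if (is.null(classifier$norm_stats))
      stop_nc("classifier has no stored norm_stats; train with joint_normalize statistics")
    normed <- apply_norm_stats(feats, classifier$norm_stats)
    calls <- classify(classifier, normed)
    calls[classifier$feature_names] <- feats[classifier$feature_names]
    if (!is.null(truth)) {
      matched <- dplyr::bind_cols(det$candidates[, c("cx_mm", "cy_mm", "cz_mm")],
                                  tibble::tibble(.label = calls$.label))
      cc <- match_candidates_to_truth(matched, truth)
      evaluation <- list(counts = cc, metrics = metrics(cc))
    }
  }

  stage_counts <- dplyr::bind_rows(
    tibble::tibble(stage = "lung_voxels", n = sum(lungs$mask)),
    det$stage_counts,
    if (!is.null(calls))
      tibble::tibble(stage = "classified_nodules",
                     n = sum(calls$.label == LABEL_NODULE))
  )

  structure(
    list(
      config = unclass(config),
      threshold_used = lungs$threshold_used,
      structure_threshold = det$structure_threshold,
      area_min_px = det$area_min_px,
      stage_counts = stage_counts,
      candidates = dplyr::select(det$candidates, -"voxels"),
      features = feats,
      calls = if (!is.null(calls)) dplyr::select(calls, -dplyr::any_of("voxels")),
      evaluation = evaluation,
      dry_run = FALSE
    ),
    class = "nodule_report"
  )
}

#' @export
print.nodule_report <- function(x, ...) {
  if (isTRUE(x$dry_run)) {
    cat("<nodule_report> dry run: config validated, no data touched\n")
    return(invisible(x))
  }
  cat("<nodule_report>\n")
  cat(sprintf("  lung threshold %.1f, structure threshold %.1f, area floor %d px\n",
              x$threshold_used, x$structure_threshold, x$area_min_px))
  for (i in seq_len(nrow(x$stage_counts)))
    cat(sprintf("  %-28s %d\n", x$stage_counts$stage[i], x$stage_counts$n[i]))
  if (!is.null(x$evaluation)) {
    print(x$evaluation$counts)
    print(x$evaluation$metrics)
  }
  invisible(x)
}

#' Serialize a pipeline report to canonical JSON
#'
#' A deterministic, byte-stable JSON rendering of the report (used by the
#' determinism audit and the CLI).
#'
#' @param report a [run_pipeline()] result.
#' @return A JSON string.
#' @export
report_json <- function(report) {
  stopifnot(inherits(report, "nodule_report"))
  x <- unclass(report)
  x$evaluation$counts <- if (!is.null(x$evaluation)) unclass(x$evaluation$counts)
  as.character(jsonlite::toJSON(x, dataframe = "columns", null = "null",
                                na = "null", auto_unbox = TRUE, digits = 10))
}

#' End-to-end evaluation on a phantom suite
#'
#' Runs lung extraction and candidate segmentation on every phantom, labels
#' each surviving candidate against the planted ground truth (centroid within
#' the truth radius = nodule), pools the labeled feature matrix across scans,
#' cross-validates the classifier leave-two-out, and scores the final
#' per-candidate predictions scan by scan. Ground-truth nodules that produced
#' no surviving candidate count as false negatives, so `sensitivity` is the
#' whole-pipeline detection sensitivity, and `fp_per_scan` counts
#' candidate-level false positives after classification. Candidate-level
#' counts before classification are reported alongside.
#'
#' @param suite a [phantom_suite()] result.
#' @param config a [pipeline_config()].
#' @param seed integer seed for the cross-validation.
#' @return List with `counts` ([confusion_counts()]), `sensitivity`,
#'   `fp_per_scan`, `candidate_fp_per_scan` (before classification),
#'   `n_truth`, `n_missed_at_segmentation`, `features` (pooled labeled
#'   matrix), `cv` (the [leave_two_out_cv()] object), and `per_scan`.
#' @export
evaluate_phantom_suite <- function(suite, config = pipeline_config(), seed = 1L) {
  per_scan <- purrr::map(seq_along(suite), function(i) {
    ph <- suite[[i]]
    v <- normalize_volume(ph$volume)
    lungs <- extract_lungs(v, second_lung_min_frac = config$second_lung_min_frac)
    det <- detect_candidates(v, lungs, config)
    cands <- det$candidates
    truth <- ph$truth
    lab <- rep(LABEL_NON, nrow(cands))
    used <- rep(FALSE, nrow(truth))
    if (nrow(cands) && nrow(truth)) {
      d <- as.matrix(dist(rbind(
        cbind(cands$cx_mm, cands$cy_mm, cands$cz_mm),
        cbind(truth$cx_mm, truth$cy_mm, truth$cz_mm)
      )))[seq_len(nrow(cands)), nrow(cands) + seq_len(nrow(truth)), drop = FALSE]
      ord <- order(d)
      for (k in ord) {
        ci <- (k - 1) %% nrow(cands) + 1
        ti <- (k - 1) %/% nrow(cands) + 1
        if (d[ci, ti] <= truth$radius_mm[ti] && lab[ci] == LABEL_NON && !used[ti]) {
          lab[ci] <- LABEL_NODULE
          used[ti] <- TRUE
        }
      }
    }
    feats <- feature_matrix(cands, v)
    if (nrow(feats)) {
      feats$label <- lab
      feats <- tibble::add_column(feats, scan_id = i, .before = 1)
    }
    list(features = feats, n_truth = nrow(truth), n_detected = sum(used),
         truth = ph$truth, candidates = cands)
  })

  features <- dplyr::bind_rows(purrr::map(per_scan, "features"))
  n_truth <- sum(purrr::map_int(per_scan, "n_truth"))
  n_detected <- sum(purrr::map_int(per_scan, "n_detected"))
  missed <- n_truth - n_detected

  cv <- leave_two_out_cv(
    features, epsilon_p = config$epsilon_p, seed = seed,
    max_folds = config$max_folds, n_per_class = config$n_per_class,
    normalization = config$normalization,
    decision_threshold = config$decision_threshold
  )
  pred <- cv$predictions
  cand_counts <- confusion_counts(
    TP = sum(pred$truth == LABEL_NODULE & pred$pred == LABEL_NODULE, na.rm = TRUE),
    TN = sum(pred$truth == LABEL_NON & pred$pred == LABEL_NON, na.rm = TRUE),
    FP = sum(pred$truth == LABEL_NON & pred$pred == LABEL_NODULE, na.rm = TRUE),
    FN = sum(pred$truth == LABEL_NODULE & pred$pred == LABEL_NON, na.rm = TRUE)
  )
  # nodules lost before classification are false negatives of the pipeline
  counts <- cand_counts + confusion_counts(FN = missed)
  n_scans <- length(suite)
  list(
    counts = counts,
    sensitivity = if (n_truth > 0) counts$TP / (counts$TP + counts$FN) else NA_real_,
    fp_per_scan = counts$FP / n_scans,
    candidate_fp_per_scan = sum(features$label == LABEL_NON) / n_scans,
    n_truth = n_truth,
    n_missed_at_segmentation = missed,
    features = features,
    cv = cv,
    per_scan = per_scan
  )
}
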