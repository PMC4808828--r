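# Diagnostic plots: intensity histogram with the minimum-error cut, feature
# scatter pairs, and ROC curves over epsilon.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Intensity histogram with the minimum-error threshold
#'
#' @param v a normalized [ct_volume()].
#' @return A ggplot.
#' @export
plot_histogram_threshold <- function(v) {
  h <- histogram256(v)
  cut <- minimum_error_threshold(h)
  df <- tibble::tibble(intensity = 0:255, count = as.numeric(h))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$intensity, y = .data$count)) +
    ggplot2::geom_col(width = 1) +
    ggplot2::geom_vline(xintercept = cut, linetype = 2, color = "red") +
    ggplot2::labs(x = "intensity (8-bit)", y = "voxels",
                  title = sprintf("minimum-error threshold at %.1f", cut)) +
    ggplot2::theme_minimal()
}

#' Scatter plots of feature pairs
#'
#' Pairwise scatter of selected feature columns, colored by label when one is
#' present - the visual check that nodules and non-nodules separate.
#'
#' @param object a [feature_matrix()] tibble.
#' @param pairs list of 2-element character vectors of feature names; default
#'   a standard set of informative pairs.
#' @param ... unused.
#' @return A ggplot (facetted over pairs).
#' @export
autoplot.nodule_features <- function(object, pairs = NULL, ...) {
  plot_feature_pairs(object, pairs = pairs)
}

#' @rdname autoplot.nodule_features
#' @param m a [feature_matrix()] tibble.
#' @export
plot_feature_pairs <- function(m, pairs = NULL) {
  pairs <- pairs %||% list(c("d1", "d2"), c("d2", "d3"), c("d3", "d5"),
                           c("d4", "d5"), c("d4", "d6"), c("d7", "d8"))
  df <- purrr::map_dfr(pairs, function(p) {
    tibble::tibble(
      pair = paste(p, collapse = " vs "),
      x = m[[p[1]]], y = m[[p[2]]],
      label = if ("label" %in% names(m)) m$label else "candidate"
    )
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y, color = .data$label)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::facet_wrap(~pair, scales = "free") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' ROC curves over the epsilon parameter
#'
#' @param roc tibble from [roc_over_epsilon()].
#' @return A ggplot; one curve per epsilon, operating points marked.
#' @export
plot_roc <- function(roc) {
  ggplot2::ggplot(roc, ggplot2::aes(x = .data$one_minus_specificity,
                                    y = .data$sensitivity,
                                    color = factor(.data$epsilon))) +
    ggplot2::geom_step(direction = "vh") +
    ggplot2::geom_point(data = roc[roc$operating_point, ], size = 3, shape = 4) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 3, color = "grey") +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "1 - specificity", y = "sensitivity", color = "epsilon") +
    ggplot2::theme_minimal()
}
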