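#' @importFrom ggplot2 ggplot aes geom_line geom_abline geom_point
#'   geom_boxplot geom_jitter labs theme_minimal coord_equal autoplot
NULL

#' @export
#' @rdname roc_analysis
#' @param object An `sdi_roc` object.
#' @param ... Unused.
autoplot.sdi_roc <- function(object, ...) {
  curve <- dplyr::arrange(object$curve, dplyr::desc(.data$specificity))
  ggplot(curve, aes(x = 1 - .data$specificity, y = .data$sensitivity)) +
    geom_line(linewidth = 0.8, colour = "#2c7fb8") +
    geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                colour = "grey60") +
    coord_equal() +
    labs(x = "1 - specificity", y = "Sensitivity",
         title = sprintf("ROC curve (AUC = %.1f%%)", 100 * object$auc)) +
    theme_minimal()
}

#' @export
#' @rdname pcoa_ordination
#' @param object An `sdi_pcoa` object.
#' @param metadata Optional data frame with `sample_id` and `group` used to
#'   colour points.
#' @param ... Unused.
autoplot.sdi_pcoa <- function(object, metadata = NULL, ...) {
  d <- object$coordinates
  ve <- object$variance_explained
  lab <- function(i) sprintf("PC%d (%.1f%%)", i, 100 * ve[i])
  if (!is.null(metadata)) {
    d <- dplyr::left_join(d, metadata[c("sample_id", "group")],
                          by = "sample_id")
    p <- ggplot(d, aes(.data$Axis.1, .data$Axis.2, colour = .data$group))
  } else {
    p <- ggplot(d, aes(.data$Axis.1, .data$Axis.2))
  }
  p + geom_point(size = 2, alpha = 0.8) +
    labs(x = lab(1), y = lab(2), title = "PCoA ordination") +
    theme_minimal()
}

#' Boxplot of index scores by group
#'
#' @param scores Tibble with `sample_id` and `sdi` (see [compute_sdi()]).
#' @param metadata Data frame with `sample_id` and `group`.
#' @return A ggplot object.
#' @export
plot_sdi <- function(scores, metadata) {
  d <- dplyr::left_join(scores, metadata[c("sample_id", "group")],
                        by = "sample_id")
  ggplot(d, aes(.data$group, .data$sdi, fill = .data$group)) +
    geom_boxplot(outlier.shape = NA, alpha = 0.7) +
    geom_jitter(width = 0.15, size = 0.8, alpha = 0.5) +
    labs(x = NULL, y = "Stroke Dysbiosis Index") +
    theme_minimal() +
    ggplot2::theme(legend.position = "none")
}
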