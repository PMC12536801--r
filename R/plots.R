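#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot PCA scores of presence/absence profiles
#'
#' @param object A `spore_pca`.
#' @param colour Column of the score table to colour by (default
#'   `phenotype` when present).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.spore_pca <- function(object, colour = NULL, ...) {
  scores <- object$scores
  colour <- colour %||%
    (if ("phenotype" %in% names(scores)) "phenotype" else NULL)
  p <- ggplot2::ggplot(scores, ggplot2::aes(x = .data$PC1, y = .data$PC2))
  p <- if (is.null(colour)) {
    p + ggplot2::geom_point(alpha = 0.8)
  } else {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data[[colour]]),
                            alpha = 0.8)
  }
  p +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", object$percent_variance[1]),
      y = sprintf("PC2 (%.1f%%)", object$percent_variance[2]),
      title = "PCA of sporulation-gene presence/absence") +
    ggplot2::theme_minimal()
}

#' Plot dispersion distances by group
#'
#' @param object A `spore_dispersion`.
#' @param ... Unused.
#' @return A ggplot (boxplot of distance-to-centroid per group).
#' @export
autoplot.spore_dispersion <- function(object, ...) {
  sub <- if (!is.na(object$p_value)) {
    sprintf("F = %.3g, permutation p = %.3g", object$f_statistic,
            object$p_value)
  } else {
    sprintf("F = %.3g", object$f_statistic)
  }
  ggplot2::ggplot(object$distances,
                  ggplot2::aes(x = .data$group, y = .data$distance)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.6) +
    ggplot2::labs(x = NULL, y = "Distance to group centroid",
                  title = "Multivariate dispersion", subtitle = sub) +
    ggplot2::theme_minimal()
}

#' Plot bootstrap metric summaries
#'
#' @param object A `spore_bootstrap`.
#' @param ... Unused.
#' @return A ggplot (median and 95% CI per metric).
#' @export
autoplot.spore_bootstrap <- function(object, ...) {
  ggplot2::ggplot(object$summary,
                  ggplot2::aes(x = .data$metric, y = .data$median)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$ci_low,
                                          ymax = .data$ci_high)) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "Value (median, 95% CI)",
                  title = sprintf("Bootstrap evaluation (%d iterations)",
                                  object$n_iterations)) +
    ggplot2::theme_minimal()
}

#' Plot ranked consensus-gene importances
#'
#' Bar chart of the per-model mean absolute Shapley values of the
#' consensus genes, in descending ranking order.
#'
#' @param object A `spore_consensus`.
#' @param top_n Number of genes to show (default 20).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.spore_consensus <- function(object, top_n = 20, ...) {
  df <- utils::head(as_tibble(object), top_n) |>
    tidyr::pivot_longer(c("mean_abs_rf", "mean_abs_svm"),
                        names_to = "model", names_prefix = "mean_abs_",
                        values_to = "mean_abs")
  df$gene_symbol <- factor(df$gene_symbol,
                           levels = rev(unique(df$gene_symbol)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mean_abs,
                                   y = .data$gene_symbol,
                                   fill = .data$model)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "Mean |SHAP| toward Sporulating", y = NULL,
                  title = "Dual-model consensus genes") +
    ggplot2::theme_minimal()
}
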