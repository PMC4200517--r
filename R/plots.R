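#' Plot a clade-recovery curve
#'
#' Gene count against the proportion of replicate trees recovering each
#' target clade, one line per clade.
#'
#' @param object A [recovery_curve()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot recovery_curve
#' @export
autoplot.recovery_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$n_genes, y = .data$prop,
                                       colour = .data$clade)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_y_continuous(labels = function(x) paste0(100 * x, "%"),
                                limits = c(0, 1)) +
    ggplot2::labs(x = "Number of genes",
                  y = "Replicates recovering clade",
                  colour = "Clade") +
    ggplot2::theme_minimal()
}

#' Plot a saturation regression
#'
#' Scatter of uncorrected p-distance against patristic distance with the
#' fitted least-squares line; a flat cloud signals saturation.
#'
#' @param object A [saturation_fit()] result (single gene).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot saturation_fit
#' @export
autoplot.saturation_fit <- function(object, ...) {
  pairs <- attr(object, "pairs")
  ggplot2::ggplot(pairs, ggplot2::aes(x = .data$pd, y = .data$p)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_abline(intercept = object$intercept, slope = object$slope,
                         colour = "firebrick") +
    ggplot2::labs(
      x = "Patristic distance (substitutions/site)",
      y = "Uncorrected p-distance",
      title = sprintf("slope = %.3f, R² = %.3f", object$slope, object$r2)
    ) +
    ggplot2::theme_minimal()
}

#' Heatmap of taxon-by-gene LB scores
#'
#' @param object A [taxon_gene_matrix()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
plot_lb_heatmap <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$gene, y = .data$taxon,
                                       fill = .data$lb)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white",
                                  high = "firebrick", midpoint = 0) +
    ggplot2::labs(x = "Gene", y = "Taxon", fill = "LB score") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
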