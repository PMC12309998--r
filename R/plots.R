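#' Plot methods
#'
#' `autoplot()` methods give quick ggplot2 views of the main result types:
#' a change-percent heatmap, a BLUP caterpillar plot with prediction
#' intervals, a PCA biplot of genotype scores, and group response profiles.
#'
#' @param object A result object (`change_matrix`, `blup_tbl`, `trait_pca`).
#' @param ... Unused.
#' @return A ggplot object.
#' @name droughtphen-plots
NULL

#' @rdname droughtphen-plots
#' @export
autoplot.change_matrix <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$genotype, y = .data$trait,
                                       fill = .data$change_pct)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(midpoint = 100, low = "#b2182b",
                                  mid = "white", high = "#2166ac",
                                  name = "% of control") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = paste0("Change % of control (",
                                 attr(object, "treatment"), ")")) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' @rdname droughtphen-plots
#' @export
autoplot.blup_tbl <- function(object, ...) {
  mu <- attr(object, "mu")
  d <- dplyr::mutate(object,
                     genotype = factor(.data$genotype,
                                       levels = rev(.data$genotype)))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$blup, y = .data$genotype,
                                  colour = .data$above_mean)) +
    ggplot2::geom_vline(xintercept = mu, linetype = 2, colour = "grey40") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$lwr,
                                         xmax = .data$upr), height = 0.2) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "#2166ac",
                                            `FALSE` = "#b2182b"),
                                 name = "above mean") +
    ggplot2::labs(x = paste("Predicted", attr(object, "trait")),
                  y = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname droughtphen-plots
#' @export
autoplot.trait_pca <- function(object, ...) {
  sc <- object$scores
  ve <- round(object$var_explained[1:2], 1)
  ggplot2::ggplot(sc, ggplot2::aes(x = .data$PC1, y = .data$PC2,
                                   label = .data$genotype)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey80") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey80") +
    ggplot2::geom_point() +
    ggplot2::geom_text(vjust = -0.6, size = 2.8) +
    ggplot2::labs(x = paste0("PC1 (", ve[1], "%)"),
                  y = paste0("PC2 (", ve[2], "%)")) +
    ggplot2::theme_minimal()
}

#' Group response profile plot
#'
#' Bar chart of the per-group trait profiles (proportion of the panel-wide
#' average change%, 100 = panel average).
#'
#' @param profiles Output of [group_profile()].
#' @return A ggplot object.
#' @export
plot_group_profiles <- function(profiles) {
  ggplot2::ggplot(profiles,
                  ggplot2::aes(x = .data$trait, y = .data$profile,
                               fill = factor(.data$cluster))) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_hline(yintercept = 100, linetype = 2) +
    ggplot2::scale_fill_brewer(palette = "Dark2", name = "Group") +
    ggplot2::labs(x = NULL, y = "% of panel-average change") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}
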