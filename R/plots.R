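# ggplot2 visualizations for the main result types.

#' @importFrom ggplot2 ggplot aes autoplot geom_point geom_line geom_tile
#'   geom_hline geom_vline scale_color_manual scale_fill_gradient2 labs
#'   theme_minimal facet_wrap
NULL

quadrant_colors <- c(
  concordant_class_a = "#1b9e42",
  concordant_class_b = "#d62728",
  shared_or_modest = "grey70",
  discordant = "black",
  missing_expression = "grey90"
)

#' Accessibility-versus-expression quadrant scatter
#'
#' One point per peak: x = differential-accessibility log2 fold-change,
#' y = assigned-gene differential-expression log2 fold-change, colored by
#' quadrant label (concordant toward either class, shared/modest,
#' discordant).
#'
#' @param object A `cre_quadrants` classification from
#'   [classify_quadrants()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cre_quadrants <- function(object, ...) {
  thr <- log2(attr(object, "fold") %||% 4)
  ggplot(object, aes(x = .data$da_log2fc, y = .data$de_log2fc,
                     color = .data$label)) +
    geom_point(size = 0.8, alpha = 0.8) +
    geom_hline(yintercept = c(-thr, thr), linetype = "dashed",
               color = "grey50") +
    geom_vline(xintercept = c(-thr, thr), linetype = "dashed",
               color = "grey50") +
    scale_color_manual(values = quadrant_colors) +
    labs(x = "Accessibility log2 fold-change",
         y = "Expression log2 fold-change", color = "Peak class") +
    theme_minimal()
}

#' Sample correlation heatmap
#'
#' Pairwise Pearson correlations of log-normalized count profiles, with
#' samples ordered by the clustering dendrogram.
#'
#' @param object A `cre_sample_clust` from [cluster_samples()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cre_sample_clust <- function(object, ...) {
  d <- tidy(object) |>
    mutate(
      sample1 = factor(.data$sample1, levels = object$order),
      sample2 = factor(.data$sample2, levels = object$order)
    )
  ggplot(d, aes(x = .data$sample1, y = .data$sample2,
                fill = .data$correlation)) +
    geom_tile() +
    scale_fill_gradient2(low = "#2166ac", mid = "white", high = "#b2182b",
                         midpoint = stats::median(d$correlation)) +
    labs(x = NULL, y = NULL, fill = "Pearson r") +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' MA plot of a differential test
#'
#' @param object A `cre_nb_fit` from [nb_wald_test()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cre_nb_fit <- function(object, ...) {
  d <- tidy(object)
  ggplot(d, aes(x = .data$base_mean, y = .data$log2fc,
                color = .data$called)) +
    geom_point(size = 0.6, alpha = 0.6) +
    ggplot2::scale_x_log10() +
    scale_color_manual(values = c(`FALSE` = "grey60", `TRUE` = "#d62728")) +
    geom_hline(yintercept = c(-object$lfc_threshold, object$lfc_threshold),
               linetype = "dashed", color = "grey40") +
    labs(x = "Mean normalized count", y = "log2 fold-change",
         color = "Called") +
    theme_minimal()
}

#' Plot summit-anchored motif density profiles
#'
#' @param profile Output of [motif_density_profile()].
#' @return A ggplot: density (motifs per bp per 1000 peaks) against offset
#'   from summit, one panel per motif.
#' @export
plot_density_profile <- function(profile) {
  check_columns(profile, c("motif", "bin_mid", "density"), "profile")
  ggplot(profile, aes(x = .data$bin_mid, y = .data$density)) +
    geom_line(color = "#2166ac") +
    facet_wrap(~motif, scales = "free_y") +
    labs(x = "Offset from peak summit (bp)",
         y = "Motifs per bp per 1000 peaks") +
    theme_minimal()
}

#' Plot a motif spacing profile
#'
#' @param profile Output of [spacing_profile()].
#' @return A ggplot: pair density against anchor-relative offset, one line
#'   per orientation.
#' @export
plot_spacing_profile <- function(profile) {
  check_columns(profile, c("orientation", "bin_mid", "density"), "profile")
  ggplot(profile, aes(x = .data$bin_mid, y = .data$density,
                      color = .data$orientation)) +
    geom_line() +
    labs(x = "Offset from anchor motif (bp)",
         y = "Pairs per bp per 1000 anchors", color = "Strand") +
    theme_minimal()
}
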