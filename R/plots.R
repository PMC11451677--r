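#' Plot per-patient pTRT frequencies by tissue
#'
#' @param object A `ptrt_frequency` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ptrt_frequency <- function(object, ...) {
  df <- dplyr::filter(tibble::as_tibble(object), !is.na(.data$frequency))
  ord <- summarize_ptrt_frequency(object)$tissue
  df$tissue <- factor(df$tissue, levels = ord)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$tissue, y = .data$frequency)) +
    ggplot2::geom_boxplot(outlier.shape = NA, fill = "grey90") +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.6, size = 1) +
    ggplot2::labs(x = NULL, y = "pTRT frequency among CD8+ T cells") +
    ggplot2::theme_classic()
}

#' Plot the top trajectory-correlated genes
#'
#' @param object A `moran_table`.
#' @param n Genes to show (default 20).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.moran_table <- function(object, n = 20, ...) {
  df <- head(tibble::as_tibble(object), n)
  df$gene <- factor(df$gene, levels = rev(df$gene))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$moran_i, y = .data$gene)) +
    ggplot2::geom_segment(ggplot2::aes(x = 0, xend = .data$moran_i,
                                       yend = .data$gene), color = "grey70") +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "Moran's I along trajectory", y = NULL) +
    ggplot2::theme_classic()
}

#' Plot a cross-compartment correlation with its OLS fit
#'
#' @param object An `xcorr`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.xcorr <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_abline(intercept = object$intercept, slope = object$slope,
                         color = "firebrick") +
    ggplot2::labs(x = object$x_label, y = object$y_label,
                  subtitle = sprintf("r = %.2f, slope = %.2f, p = %.3g",
                                     object$r, object$slope, object$p_value)) +
    ggplot2::theme_classic()
}

#' Plot region-stratified proximity summaries
#'
#' Paired alpha-SMA+/- nearest-neighbor distances per sample and phenotype
#' pair.
#'
#' @param object A `proximity_stats` tibble (possibly several samples).
#' @param metric Column to plot (default `"mean_nn"`).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.proximity_stats <- function(object, metric = "mean_nn", ...) {
  df <- tibble::as_tibble(object)
  df$pair <- paste(df$query, "→", df$target)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$region_class,
                                   y = .data[[metric]])) +
    ggplot2::geom_boxplot(outlier.shape = NA, fill = "grey90") +
    ggplot2::geom_line(ggplot2::aes(group = .data$sample_id), alpha = 0.4) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::facet_wrap(~pair, scales = "free_y") +
    ggplot2::labs(x = NULL, y = sprintf("%s (µm)", metric)) +
    ggplot2::theme_classic()
}

#' Plot branch subclusters along pseudotime
#'
#' @param object A `branch_clusters` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.branch_clusters <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$pseudotime, fill = .data$state)) +
    ggplot2::geom_histogram(bins = 40, position = "identity", alpha = 0.6) +
    ggplot2::labs(x = "pseudotime", y = "cells", fill = "state") +
    ggplot2::theme_classic()
}

#' Heatmap of differential communication between conditions
#'
#' @param diff A `diff_comm`.
#' @return A ggplot of sender x receiver strength differences.
#' @export
plot_diff_network <- function(diff) {
  stopifnot(inherits(diff, "diff_comm"))
  ggplot2::ggplot(diff$summary,
                  ggplot2::aes(x = .data$receiver, y = .data$sender,
                               fill = .data$delta_strength)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white",
                                  high = "firebrick",
                                  name = sprintf("Δ strength\n(%s - %s)",
                                                 diff$cond_a, diff$cond_b)) +
    ggplot2::labs(x = "receiver", y = "sender") +
    ggplot2::theme_classic() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
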