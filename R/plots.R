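#' Heatmap of clustered signal
#'
#' Rows (regions, grouped by class) by columns (position relative to
#' the peak center) heatmap of the clustered signal matrices, the
#' standard visual for K-means signal classes.
#'
#' @param clusters A `signal_clusters` object.
#' @param matrices The signal matrix (or named list of matrices) the
#'   clustering was run on.
#' @return A ggplot object.
#' @export
plot_signal_clusters <- function(clusters, matrices) {
  if (is.matrix(matrices)) matrices <- list(signal = matrices)
  if (is.null(names(matrices))) {
    names(matrices) <- sprintf("track_%d", seq_along(matrices))
  }
  ord <- arrange(clusters$assignments, .data$class)
  df <- list_rbind(imap(matrices, function(m, nm) {
    flank <- attr(m, "flank") %||% (ncol(m) / 2)
    bw <- attr(m, "bin_width") %||% 1
    long <- as_tibble(as.data.frame(unclass(m)))
    long$region_id <- rownames(m)
    long <- tidyr::pivot_longer(long, -"region_id", names_to = "col",
                                values_to = "signal")
    long$position <- (as.integer(sub("^V", "", long$col)) - 1) * bw - flank
    long$track <- nm
    long
  }))
  df$region_id <- factor(df$region_id, levels = rev(ord$region_id))
  df <- left_join(df, clusters$assignments, by = "region_id")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$region_id,
                                   fill = .data$signal)) +
    ggplot2::geom_raster() +
    ggplot2::facet_grid(class ~ track, scales = "free_y", space = "free_y") +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "position relative to peak center (bp)", y = NULL,
                  fill = "signal") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}

#' @rdname plot_signal_clusters
#' @param object A `signal_clusters` object.
#' @param ... Passed on.
#' @method autoplot signal_clusters
#' @export
autoplot.signal_clusters <- function(object, ...) {
  abort("autoplot(signal_clusters) needs the matrices; use plot_signal_clusters(clusters, matrices)")
}

#' Distribution of enhancer distances to the nearest TSS
#'
#' @param calls Enhancer-call tibble with `tss_distance` and `state`.
#' @param binwidth Histogram bin width in bases.
#' @return A ggplot object.
#' @export
plot_tss_distances <- function(calls, binwidth = 10000) {
  ggplot2::ggplot(calls, ggplot2::aes(x = .data$tss_distance,
                                      fill = .data$state)) +
    ggplot2::geom_histogram(binwidth = binwidth, position = "dodge") +
    ggplot2::labs(x = "distance to nearest TSS (bp)", y = "enhancers",
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' Box plots of expression by gene class and condition
#'
#' @param expr Expression tibble (`gene_id` + condition columns).
#' @param gene_sets Named list of gene-id vectors.
#' @param conditions Condition column names to show.
#' @return A ggplot object.
#' @export
plot_expression_by_class <- function(expr, gene_sets, conditions) {
  sets <- c(list(all = expr$gene_id), gene_sets)
  df <- list_rbind(imap(sets, function(ids, cls) {
    sub <- expr[expr$gene_id %in% ids, c("gene_id", conditions)]
    sub$class <- cls
    sub
  }))
  df <- tidyr::pivot_longer(df, dplyr::all_of(conditions),
                            names_to = "condition", values_to = "fpkm")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$class, y = .data$fpkm + 1,
                                   fill = .data$condition)) +
    ggplot2::geom_boxplot(outlier.size = 0.3) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = NULL, y = "FPKM + 1") +
    ggplot2::theme_minimal()
}

#' Methylation frequency per annotation family
#'
#' @param freq Output of [annotation_methylation_frequency()], possibly
#'   with an added grouping column (e.g. `cell_type`).
#' @return A ggplot object.
#' @export
plot_methylation_frequency <- function(freq) {
  p <- ggplot2::ggplot(freq, ggplot2::aes(x = .data$family,
                                          y = .data$frequency))
  if ("cell_type" %in% names(freq)) {
    p <- p + ggplot2::geom_col(ggplot2::aes(fill = .data$cell_type),
                               position = "dodge")
  } else {
    p <- p + ggplot2::geom_col()
  }
  p + ggplot2::labs(x = NULL, y = "fraction of loci methylated") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
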