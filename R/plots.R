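#' PC1-vs-PC2 scatter of embedded replicates
#'
#' Each dot is one subsampled replicate, colored by donor; dashed ellipses
#' outline the K-means clusters when labels are supplied. Axis labels carry
#' the percent variance explained by each component.
#'
#' @param embedding Matrix from [project_embedding()].
#' @param model Optional `pca_model` supplying variance-explained ratios
#'   (taken from the embedding's attribute if absent).
#' @param clusters Optional labels from [kmeans_cluster()].
#' @return A ggplot object.
#' @export
plot_embedding <- function(embedding, model = NULL, clusters = NULL) {
  ratios <- if (!is.null(model)) model$explained_variance_ratio else
    attr(embedding, "explained_variance_ratio")
  lab <- function(i) {
    if (!is.null(ratios) && length(ratios) >= i) {
      sprintf("PC%d (%.1f%%)", i, 100 * ratios[[i]])
    } else sprintf("PC%d", i)
  }
  df <- data.frame(PC1 = embedding[, 1L], PC2 = embedding[, 2L],
                   donor = attr(embedding, "row_donors") %||% "all")
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$PC1, y = .data$PC2)) +
    ggplot2::geom_point(ggplot2::aes(color = .data$donor), size = 2) +
    ggplot2::labs(x = lab(1L), y = lab(2L), color = "donor") +
    ggplot2::theme_bw()
  if (!is.null(clusters)) {
    df$cluster <- factor(clusters)
    p <- p + ggplot2::stat_ellipse(
      data = df, ggplot2::aes(group = .data$cluster),
      linetype = "dashed", color = "black")
  }
  p
}

#' Heat map of PCA feature weights
#'
#' Features by components tile map of the loading weights from
#' [feature_weights()]; by default only the `top_n` features by absolute
#' weight on the first requested component are shown, since a 306-pair space
#' is unreadable in full.
#'
#' @param weights Data frame from [feature_weights()].
#' @param top_n Number of features displayed (all if `NA`).
#' @return A ggplot object.
#' @export
plot_weight_heatmap <- function(weights, top_n = 30L) {
  pc_cols <- grep("^PC[0-9]+$", names(weights), value = TRUE)
  rank_col <- paste0(pc_cols[[1L]], "_rank")
  keep <- if (is.na(top_n)) weights else weights[weights[[rank_col]] <= top_n, ]
  long <- do.call(rbind, lapply(pc_cols, function(pc) {
    data.frame(feature = keep$feature, component = pc, weight = keep[[pc]],
               stringsAsFactors = FALSE)
  }))
  long$feature <- factor(long$feature, levels = keep$feature[order(keep[[rank_col]])])
  ggplot2::ggplot(long, ggplot2::aes(x = .data$component, y = .data$feature,
                                     fill = .data$weight)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white", high = "firebrick") +
    ggplot2::labs(x = NULL, y = "V-J pair", fill = "weight") +
    ggplot2::theme_minimal()
}

#' Intra- versus inter-cohort distance boxplot
#'
#' One box per pair group (intra-cohort groups and inter) per metric,
#' faceted by metric since the PC distance and the RDI live on different
#' scales.
#'
#' @param records Data frame of distance records (may mix metrics).
#' @return A ggplot object.
#' @export
plot_distance_boxes <- function(records) {
  ggplot2::ggplot(records, ggplot2::aes(x = .data$group, y = .data$value)) +
    ggplot2::geom_boxplot(fill = "grey85") +
    ggplot2::geom_jitter(width = 0.1, alpha = 0.5, size = 1) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "distance") +
    ggplot2::theme_bw()
}
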