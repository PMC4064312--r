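#' Plots
#'
#' ggplot2 views of the main result types: the exon log-ratio profile with
#' fitted segments, the cohort alteration heatmap (samples by genes, in the
#' style of an oncoprint), and the clustering dendrogram cut.
#'
#' @name panelseq-plots
NULL

#' Plot a log-ratio profile with segment means
#'
#' @param profile Exon profile tibble with `lr` (and `exon_index`).
#' @param fit Optional `purity_ploidy_fit`; segment means and fitted copy
#'   numbers are overlaid when given.
#' @return A ggplot.
#' @export
plot_logratio_profile <- function(profile, fit = NULL) {
  profile$exon_index <- profile$exon_index %||% seq_len(nrow(profile))
  p <- ggplot2::ggplot(profile, ggplot2::aes(x = .data$exon_index, y = .data$lr)) +
    ggplot2::geom_point(size = 0.4, alpha = 0.5, colour = "grey40") +
    ggplot2::labs(x = "exon (panel order)", y = "log2 tumor/normal") +
    ggplot2::theme_minimal()
  if (!is.null(fit)) {
    seg <- tidy(fit)
    p <- p + ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$start_index, xend = .data$end_index,
                   y = .data$lr_seg, yend = .data$lr_seg),
      colour = "firebrick", linewidth = 1)
  }
  p
}

#' Alteration heatmap (oncoprint-style)
#'
#' @param matrix Long alteration matrix from [build_alteration_matrix()].
#' @param drop_empty Drop genes altered in no sample.
#' @return A ggplot tile heatmap, samples ordered within group.
#' @export
plot_alteration_matrix <- function(matrix, drop_empty = TRUE) {
  if (drop_empty) {
    keep <- matrix |> group_by(.data$gene) |>
      summarise(any_alt = any(.data$alteration != "none"), .groups = "drop") |>
      filter(.data$any_alt) |> pull(.data$gene)
    matrix <- filter(matrix, .data$gene %in% keep)
  }
  pal <- c(none = "grey92", mutation = "#2c7fb8", amplification = "#d95f02",
           deletion = "#1b9e77", multiple = "#7570b3")
  ggplot2::ggplot(matrix, ggplot2::aes(x = .data$sample, y = .data$gene,
                                       fill = .data$alteration)) +
    ggplot2::geom_tile(colour = "white", linewidth = 0.3) +
    ggplot2::scale_fill_manual(values = pal) +
    ggplot2::facet_grid(~group, scales = "free_x", space = "free_x") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, size = 6))
}

#' @rdname panelseq-plots
#' @param object A `cohort_clustering`.
#' @param ... Unused.
#' @export
autoplot.cohort_clustering <- function(object, ...) {
  hc <- object$hclust
  ord <- hc$order
  df <- tibble(sample = hc$labels[ord], x = seq_along(ord),
               cluster = factor(object$cut[hc$labels[ord]]))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = 0, label = .data$sample,
                                   colour = .data$cluster)) +
    ggplot2::geom_text(angle = 90, hjust = 1, size = 2.5) +
    ggplot2::labs(x = "dendrogram order", y = NULL,
                  title = sprintf("two-group cut purity %.0f%%", 100 * object$purity)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
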