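#' Scatter plot of a group estimate against total expression
#'
#' Log-log scatter of one identifiable group's abundance versus the
#' total-expression proxy, annotated with the Pearson correlation — the
#' per-group diagnostic view of cohort co-overexpression.
#'
#' @param estimate A `group_estimate`.
#' @param proxy A [select_total_proxy()] result.
#' @param file Optional PNG path; if given, the plot is written there.
#' @return The ggplot object, invisibly.
#' @export
plot_group_scatter <- function(estimate, proxy, file = NULL) {
  df <- data.frame(total = proxy$total, group = estimate$abundances,
                   clipped = estimate$clipped)
  r <- if (stats::sd(df$group) > 0)
    stats::cor(df$group, df$total) else NA_real_
  p <- ggplot2::ggplot(df, ggplot2::aes(x = total, y = group,
                                        color = clipped)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::scale_color_manual(values = c(`FALSE` = "grey20",
                                           `TRUE` = "red")) +
    ggplot2::labs(x = "total expression (linear)",
                  y = paste(estimate$group_label, "abundance"),
                  title = sprintf("%s vs total (r = %.3f)",
                                  estimate$group_label, r)) +
    ggplot2::theme_minimal()
  if (!is.null(file)) {
    grDevices::png(file, width = 1200, height = 900, res = 150)
    print(p)
    grDevices::dev.off()
  }
  invisible(p)
}

#' Z-score heat map of exon-level expression
#'
#' Probe sets (rows, grouped by exon) by samples, z-scored per probe set.
#' A plumbing visualization of the exon-level signal structure, not a
#' replication of any clustering software.
#'
#' @param X An [expression_matrix()].
#' @param file Optional PNG path.
#' @return The pheatmap object, invisibly.
#' @export
plot_exon_heatmap <- function(X, file = NULL) {
  V <- t(X$values)
  z <- (V - rowMeans(V)) / apply(V, 1, stats::sd)
  z[!is.finite(z)] <- 0
  ord <- order(X$probe_to_exon)
  ann <- data.frame(exon = factor(X$probe_to_exon[ord]))
  rownames(ann) <- rownames(V)[ord]
  args <- list(mat = z[ord, , drop = FALSE], cluster_rows = FALSE,
               cluster_cols = FALSE, show_colnames = FALSE,
               annotation_row = ann, silent = TRUE)
  if (!is.null(file)) {
    args$filename <- file
    args$width <- 8; args$height <- 6
  }
  invisible(do.call(pheatmap::pheatmap, args))
}
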