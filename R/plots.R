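#' Plot a copy-number profile along the genome
#'
#' Windows are drawn at their genomic midpoints, faceted per chromosome, with
#' guide lines at the diploid CN 2 and the duplication/deletion thresholds.
#'
#' @param object a `cn_profile`.
#' @param dup_thr,del_thr guide-line positions.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.cn_profile <- function(object, dup_thr = 2.5, del_thr = 1.5, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = (.data$start + .data$end) / 2e6, y = .data$cn)) +
    ggplot2::geom_point(size = 0.3, alpha = 0.5) +
    ggplot2::geom_hline(yintercept = 2, linetype = 1, colour = "grey40") +
    ggplot2::geom_hline(yintercept = c(dup_thr, del_thr), linetype = 2,
                        colour = "firebrick") +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::labs(x = "position (Mb)", y = "absolute copy number",
                  title = attr(object, "sample_id")) +
    ggplot2::theme_minimal()
}

#' Plot per-chromosome variant-count residuals
#'
#' @param object a `variant_chisq` object.
#' @param residual_threshold dashed guide lines.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.variant_chisq <- function(object, residual_threshold = 2, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$chrom, y = .data$residual)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = c(-residual_threshold, residual_threshold),
                        linetype = 2, colour = "firebrick") +
    ggplot2::labs(x = NULL, y = "standardized residual (O - E) / sqrt(E)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot the PCA of a repeat-landscape comparison
#'
#' @param object a `landscape_comparison` object.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.landscape_comparison <- function(object, ...) {
  ve <- summary(object$pca)$importance[2, ]
  ggplot2::ggplot(object$scores,
                  ggplot2::aes(x = .data$PC1, y = .data$PC2, colour = .data$group,
                               label = .data$sample_id)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_text(vjust = -0.8, size = 3, show.legend = FALSE) +
    ggplot2::labs(x = sprintf("PC1 (%.1f%%)", 100 * ve[1]),
                  y = sprintf("PC2 (%.1f%%)", 100 * ve[2]),
                  colour = "K-means group") +
    ggplot2::theme_minimal()
}

#' Stacked-bar plot of repeat genome proportions per sample
#'
#' @param abundance wide tibble from [abundance_table()].
#' @return a ggplot object.
#' @export
plot_abundance <- function(abundance) {
  long <- tidyr::pivot_longer(abundance, -"sample_id",
                              names_to = "family", values_to = "percent")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$sample_id, y = .data$percent,
                                     fill = .data$family)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "genome proportion (%)", fill = "repeat family") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Ideogram-style plot of satellite tandem loci
#'
#' Chromosomes are drawn as horizontal bars with tandem loci marked, the
#' in-silico counterpart of a FISH karyotype.
#'
#' @param loci tibble from [call_tandem_loci()] (optionally with a `family`
#'   column to colour by).
#' @param chrom_lengths tibble `chrom`, `length`.
#' @return a ggplot object.
#' @export
plot_satellite_loci <- function(loci, chrom_lengths) {
  cl <- as_chrom_lengths(chrom_lengths)
  if (!"family" %in% names(loci)) loci$family <- "satellite"
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = cl,
                          ggplot2::aes(x = 0, xend = .data$length / 1e6,
                                       y = .data$chrom, yend = .data$chrom),
                          linewidth = 3, colour = "grey80", lineend = "round") +
    ggplot2::geom_point(data = loci,
                        ggplot2::aes(x = (.data$start + .data$end) / 2e6,
                                     y = .data$chrom, colour = .data$family),
                        size = 3, shape = 18) +
    ggplot2::labs(x = "position (Mb)", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}
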