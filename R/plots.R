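# ggplot2 views of the main result types. Each returns a ggplot object the
# caller can style further.

#' Plot per-cluster methylation along the pollen trajectory
#'
#' Boxplots of per-nucleus weighted region methylation by cluster, ordered
#' along the developmental ontology, optionally split by genotype.
#'
#' @param summaries Output of [region_weighted_methylation()] joined with a
#'   `label` column (cluster) and optionally `genotype`.
#' @param ontology Cluster order (default [pollen_ontology()]).
#' @return A ggplot object.
#' @export
plot_trajectory <- function(summaries, ontology = pollen_ontology()) {
  df <- summaries[summaries$n_sites > 0 & summaries$label %in% ontology, , drop = FALSE]
  df$label <- factor(df$label, levels = ontology)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$label, y = .data$avg_me)) +
    ggplot2::geom_boxplot(outlier.size = 0.4) +
    ggplot2::labs(x = NULL, y = "weighted methylation",
                  title = unique(df$region_set)[1],
                  subtitle = paste(unique(df$context), "context")) +
    ggplot2::theme_minimal()
  if ("genotype" %in% names(df)) {
    p <- p + ggplot2::aes(fill = .data$genotype) +
      ggplot2::geom_boxplot(outlier.size = 0.4)
  }
  p
}

#' @describeIn coverage_doublet_filter Autoplot of the doublet trend:
#'   `f_multi` against covered sites with the Theil-Sen fit and flagged
#'   nuclei highlighted.
#' @param object A `doublet_fit`.
#' @param ... Unused.
#' @export
autoplot.doublet_fit <- function(object, ...) {
  df <- object$table
  ggplot2::ggplot(df, ggplot2::aes(x = .data$sites_ge1, y = .data$f_multi)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$flagged_doublet), size = 0.7) +
    ggplot2::geom_abline(intercept = object$intercept, slope = object$slope,
                         linetype = 2) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40", `TRUE` = "red")) +
    ggplot2::labs(x = "sites covered (>= 1 read)",
                  y = "fraction of sites with > 1 read",
                  colour = "flagged doublet") +
    ggplot2::theme_minimal()
}

#' @describeIn signal_vs_density_curve Autoplot of the fitted curve with
#'   its residual-sd band.
#' @param object A `density_curve`.
#' @param ... Unused.
#' @export
autoplot.density_curve <- function(object, ...) {
  cv <- object$curve
  ggplot2::ggplot(cv, ggplot2::aes(x = .data$density, y = .data$fitted)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$fitted - .data$sd_band,
                                      ymax = .data$fitted + .data$sd_band),
                         alpha = 0.2) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "methylation density (summed %)", y = "ChIP signal") +
    ggplot2::theme_minimal()
}

#' @describeIn overlap_with_shuffles Autoplot: true overlap fraction
#'   against the shuffled-control distribution.
#' @param object An `overlap_enrichment`.
#' @param ... Unused.
#' @export
autoplot.overlap_enrichment <- function(object, ...) {
  ggplot2::ggplot(object$shuffled, ggplot2::aes(x = .data$frac_A_overlap)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey70") +
    ggplot2::geom_vline(xintercept = object$summary$true_frac, colour = "red") +
    ggplot2::labs(x = "fraction of peaks overlapping DMRs",
                  y = "shuffles",
                  subtitle = "red line: true peaks") +
    ggplot2::theme_minimal()
}

#' @describeIn classify_rescue Autoplot: row-scaled expression heatmap in
#'   dendrogram order, annotated with the rescue label.
#' @param object A `rescue_classification`.
#' @param tpm The TPM matrix used for the classification.
#' @param samples The sample sheet used for the classification.
#' @param ... Unused.
#' @export
autoplot.rescue_classification <- function(object, tpm = NULL, samples = NULL, ...) {
  if (is.null(tpm) || is.null(samples)) {
    stop("supply the tpm matrix and sample sheet used for classification")
  }
  m <- tpm[object$order, samples$sample, drop = FALSE]
  z <- t(scale(t(m)))
  df <- tibble::as_tibble(z, rownames = "transcript_id") %>%
    tidyr::pivot_longer(-"transcript_id", names_to = "sample", values_to = "z") %>%
    dplyr::mutate(transcript_id = factor(.data$transcript_id, levels = rev(object$order)),
                  sample = factor(.data$sample, levels = samples$sample))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$sample, y = .data$transcript_id,
                                   fill = .data$z)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "navy", mid = "white", high = "firebrick") +
    ggplot2::labs(x = NULL, y = NULL, fill = "row z") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank(),
                   axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}
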