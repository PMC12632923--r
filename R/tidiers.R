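# broom-style tidiers for the package's fitted/classified objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a doublet fit
#'
#' @param x A `doublet_fit` from [coverage_doublet_filter()].
#' @param ... Unused.
#' @return One row per nucleus with residual and flag.
#' @export
tidy.doublet_fit <- function(x, ...) {
  x$table[, c("nucleus", "sites_ge1", "f_multi", "residual", "flagged_doublet")]
}

#' @rdname tidy.doublet_fit
#' @export
glance.doublet_fit <- function(x, ...) {
  tibble::tibble(
    n_nuclei = nrow(x$table), n_flagged = x$n_flagged,
    slope = x$slope, intercept = x$intercept, mad = x$mad, k_mad = x$k_mad
  )
}

#' Tidy a rescue classification
#'
#' @param x A `rescue_classification` from [classify_rescue()].
#' @param ... Unused.
#' @return One row per transcript with cluster, rescue index and label.
#' @export
tidy.rescue_classification <- function(x, ...) {
  x$labels
}

#' @rdname tidy.rescue_classification
#' @export
glance.rescue_classification <- function(x, ...) {
  tab <- table(x$labels$label)
  tibble::tibble(
    n_transcripts = nrow(x$labels),
    n_clusters = nrow(x$clusters),
    n_rescued = sum(x$labels$label == "rescued"),
    n_partially_rescued = sum(x$labels$label == "partially_rescued"),
    n_not_rescued = sum(x$labels$label == "not_rescued"),
    n_omitted = sum(x$labels$label == "omitted"),
    distance = x$params$distance, linkage = x$params$linkage
  )
}

#' Tidy an effect size
#'
#' @param x An `effect_size` from [cohens_d_stars()].
#' @param ... Unused.
#' @return One-row tibble with d, stars, p and group sizes.
#' @export
tidy.effect_size <- function(x, ...) {
  tibble::tibble(d = x$d, stars = x$stars, p = x$p,
                 n_a = x$n_a, n_b = x$n_b, significant = x$significant)
}

#' Tidy a density curve
#'
#' @param x A `density_curve` from [signal_vs_density_curve()].
#' @param ... Unused.
#' @return The fitted curve grid.
#' @export
tidy.density_curve <- function(x, ...) {
  x$curve
}

#' @rdname tidy.density_curve
#' @export
glance.density_curve <- function(x, ...) {
  tibble::tibble(n_bins = x$n_bins, span = x$span, residual_sd = x$residual_sd)
}

#' Tidy an overlap report
#'
#' @param x An `overlap_report` from [reciprocal_overlap()].
#' @param ... Unused.
#' @return One-row tibble of counts and fractions.
#' @export
tidy.overlap_report <- function(x, ...) {
  tibble::tibble(
    n_A = x$n_A, n_B = x$n_B,
    n_A_overlap = x$n_A_overlap, n_B_overlap = x$n_B_overlap,
    frac_A_overlap = x$frac_A_overlap, frac_B_overlap = x$frac_B_overlap,
    min_frac = x$min_frac
  )
}
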