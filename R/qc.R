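# Nucleus-level quality control. Filter order is fixed: basic well filter ->
# organelle RNA filter -> coverage-based doublet filter -> bisulfite
# conversion filter -> (after clustering) marker-ratio reassignment. Each
# filter only narrows the passing set, and every censored nucleus carries
# exactly one primary failure reason (the first filter it failed).

#' Compute per-nucleus QC metrics
#'
#' From a per-nucleus methylation call table and a gene count matrix,
#' derives the quantities every downstream filter consumes:
#' * `rna_reads`, `genes_detected` - transcriptome depth;
#' * `wgbs_bin_frac` - fraction of 1-kb nuclear bins with at least one
#'   covered cytosine (any context);
#' * `organelle_rna_frac` - organelle gene reads over all gene reads;
#' * `sites_ge1` / `sites_eq1` / `sites_gt1` and `f_multi = sites_gt1 /
#'   sites_ge1` - coverage-class site counts over nuclear chromosomes
#'   (organelles are excluded because their copy number breaks the
#'   haploid one-read expectation);
#' * `chloro_me` - weighted mean apparent methylation over all covered
#'   chloroplast cytosines, all contexts (`NA` when none are covered).
#'
#' @param calls Methylation call tibble with a `nucleus` column.
#' @param counts Genes-by-nuclei count matrix.
#' @param genome A [genome_spec()].
#' @param gene_meta Tibble with columns `gene_id` and `is_organelle`
#'   (logical) flagging chloroplast/mitochondrial genes; if `NULL`, no gene
#'   is treated as organellar.
#' @param bin_width Bin width for the WGBS coverage metric (default 1000).
#' @return Tibble, one row per nucleus appearing in either input.
#' @export
compute_nucleus_qc <- function(calls, counts, genome, gene_meta = NULL,
                               bin_width = 1000) {
  assert_genome(genome)
  stopifnot("nucleus" %in% names(calls))
  nuclei <- union(colnames(counts), unique(calls$nucleus))

  rna_reads <- colSums(counts)
  genes_detected <- colSums(counts > 0)
  org_genes <- if (is.null(gene_meta)) character() else
    gene_meta$gene_id[gene_meta$is_organelle]
  org_reads <- colSums(counts[rownames(counts) %in% org_genes, , drop = FALSE])
  organelle_rna_frac <- ifelse(rna_reads > 0, org_reads / rna_reads, 0)

  nuclear <- genome_chroms(genome, "exclude")
  chloro <- genome$chrom[genome$is_organelle &
                           grepl("c$", genome$chrom, ignore.case = TRUE)]
  if (length(chloro) == 0 && any(genome$is_organelle)) {
    chloro <- genome_chroms(genome, "only")[1]
  }
  n_bins_total <- sum(ceiling(genome$length[!genome$is_organelle] / bin_width))

  nuc_calls <- calls[calls$chrom %in% nuclear, , drop = FALSE]
  meth_stats <- nuc_calls %>%
    dplyr::group_by(.data$nucleus) %>%
    dplyr::summarise(
      sites_ge1 = dplyr::n(),
      sites_eq1 = sum(.data$cov == 1L),
      sites_gt1 = sum(.data$cov > 1L),
      bins_covered = dplyr::n_distinct(paste(.data$chrom, bin_index(.data$pos, bin_width))),
      .groups = "drop"
    )
  chloro_stats <- calls[calls$chrom %in% chloro, , drop = FALSE] %>%
    dplyr::group_by(.data$nucleus) %>%
    dplyr::summarise(
      chloro_sites = dplyr::n(),
      chloro_mc = sum(.data$mc),
      chloro_cov = sum(.data$cov),
      chloro_me = sum(.data$mc) / sum(.data$cov),
      .groups = "drop"
    )

  tibble::tibble(nucleus = nuclei) %>%
    dplyr::left_join(meth_stats, by = "nucleus") %>%
    dplyr::left_join(chloro_stats, by = "nucleus") %>%
    dplyr::mutate(
      rna_reads = unname(rna_reads[.data$nucleus]),
      genes_detected = unname(genes_detected[.data$nucleus]),
      organelle_rna_frac = unname(organelle_rna_frac[.data$nucleus]),
      dplyr::across(c("sites_ge1", "sites_eq1", "sites_gt1", "bins_covered",
                      "chloro_sites", "chloro_mc", "chloro_cov"),
                    ~ dplyr::coalesce(.x, 0L)),
      rna_reads = dplyr::coalesce(.data$rna_reads, 0),
      genes_detected = dplyr::coalesce(.data$genes_detected, 0),
      organelle_rna_frac = dplyr::coalesce(.data$organelle_rna_frac, 0),
      wgbs_bin_frac = .data$bins_covered / n_bins_total,
      f_multi = ifelse(.data$sites_ge1 > 0, .data$sites_gt1 / .data$sites_ge1, 0)
    ) %>%
    dplyr::select("nucleus", "rna_reads", "genes_detected", "wgbs_bin_frac",
                  "organelle_rna_frac", "sites_ge1", "sites_eq1", "sites_gt1",
                  "f_multi", "chloro_sites", "chloro_mc", "chloro_cov",
                  "chloro_me")
}

#' Basic well filter
#'
#' Pass iff the nucleus has at least `min_rna_reads` transcriptome reads
#' over at least `min_genes` genes and at least `min_bin_frac` of 1-kb
#' genome bins carry WGBS coverage. All comparisons inclusive ("at least").
#'
#' @param qc QC tibble from [compute_nucleus_qc()].
#' @param min_rna_reads,min_genes,min_bin_frac Thresholds (defaults 1000,
#'   200, 0.10).
#' @return `qc` with logical `pass_basic` and character
#'   `basic_fail_reason` columns.
#' @export
basic_well_filter <- function(qc, min_rna_reads = 1000, min_genes = 200,
                              min_bin_frac = 0.10) {
  for (col in c("rna_reads", "genes_detected", "wgbs_bin_frac")) {
    if (!col %in% names(qc) || anyNA(qc[[col]])) {
      stop("QC metric missing: ", col)
    }
  }
  dplyr::mutate(
    qc,
    pass_basic = .data$rna_reads >= min_rna_reads &
      .data$genes_detected >= min_genes &
      .data$wgbs_bin_frac >= min_bin_frac,
    basic_fail_reason = dplyr::case_when(
      .data$rna_reads < min_rna_reads ~ "rna_reads",
      .data$genes_detected < min_genes ~ "genes_detected",
      .data$wgbs_bin_frac < min_bin_frac ~ "wgbs_bin_frac",
      TRUE ~ NA_character_
    )
  )
}

#' Organelle RNA filter
#'
#' Fail iff strictly more than `max_frac` of gene-assigned reads come from
#' chloroplast or mitochondrial genes (the ">10 percent" rule; exactly 10
#' percent passes).
#'
#' @param qc QC tibble with an `organelle_rna_frac` column.
#' @param max_frac Threshold (default 0.10, strict).
#' @return `qc` with a logical `pass_organelle` column.
#' @export
organelle_rna_filter <- function(qc, max_frac = 0.10) {
  if (!"organelle_rna_frac" %in% names(qc)) stop("QC metric missing: organelle_rna_frac")
  dplyr::mutate(qc, pass_organelle = .data$organelle_rna_frac <= max_frac)
}

theil_sen <- function(x, y) {
  # exact median of pairwise slopes; O(n^2) but vectorized, fine for the
  # nucleus counts seen in practice (thousands)
  n <- length(x)
  i <- rep.int(seq_len(n - 1L), rev(seq_len(n - 1L)))
  j <- sequence(rev(seq_len(n - 1L)), from = seq.int(2L, n))
  dx <- x[j] - x[i]
  dy <- y[j] - y[i]
  ok <- dx != 0
  slope <- if (any(ok)) stats::median(dy[ok] / dx[ok]) else 0
  intercept <- stats::median(y - slope * x)
  list(slope = slope, intercept = intercept)
}

#' Coverage-based doublet filter
#'
#' Post-deduplication, a haploid nucleus should not show more than one read
#' at any site, yet multi-coverage is observed at low rates that grow with
#' total genome coverage. This filter fits a robust trend (Theil-Sen) of
#' `f_multi` (fraction of covered sites with coverage > 1) against
#' `sites_ge1` across nuclei and flags nuclei whose positive residual
#' exceeds `k_mad` times the MAD of all residuals - the signature of two
#' nuclei sorted into one well, whose site-wise coverage sums double-cover
#' every jointly covered site.
#'
#' @param qc QC tibble with `sites_ge1` and `f_multi` columns (>= 20 rows).
#' @param k_mad Flagging multiplier (default 5).
#' @param exempt Optional character vector of nucleus ids never flagged
#'   (e.g. GN nuclei, which can legitimately carry two genome copies after
#'   S phase).
#' @return Object of class `doublet_fit`: `qc` rows with `residual` and
#'   `flagged_doublet` columns in `$table`, plus the fitted trend.
#' @export
coverage_doublet_filter <- function(qc, k_mad = 5, exempt = NULL) {
  stopifnot(all(c("nucleus", "sites_ge1", "f_multi") %in% names(qc)))
  if (nrow(qc) < 20) stop("need at least 20 nuclei for a robust trend fit")
  fit <- theil_sen(qc$sites_ge1, qc$f_multi)
  resid <- qc$f_multi - (fit$intercept + fit$slope * qc$sites_ge1)
  s <- stats::mad(resid)
  flagged <- resid > k_mad * s & resid > 0
  if (!is.null(exempt)) flagged[qc$nucleus %in% exempt] <- FALSE
  out <- list(
    table = dplyr::mutate(qc, residual = resid, flagged_doublet = flagged),
    slope = fit$slope, intercept = fit$intercept,
    mad = s, k_mad = k_mad, n_flagged = sum(flagged)
  )
  class(out) <- "doublet_fit"
  out
}

#' @export
print.doublet_fit <- function(x, ...) {
  cat(sprintf(
    "<doublet_fit> %d/%d nuclei flagged (Theil-Sen slope %.3g, MAD %.3g, k = %g)\n",
    x$n_flagged, nrow(x$table), x$slope, x$mad, x$k_mad
  ))
  invisible(x)
}

#' Bisulfite conversion filter via chloroplast methylation
#'
#' The chloroplast genome is unmethylated, so apparent chloroplast
#' methylation measures bisulfite conversion failure. A nucleus fails when
#' its `chloro_me` strictly exceeds the threshold - either `median + k_mad *
#' MAD` across nuclei (`method = "mad"`, the default) or an absolute cutoff
#' (`method = "fixed"`) - and, when per-nucleus chloroplast read counts are
#' available (`chloro_mc`, `chloro_cov`), its methylated chloroplast read
#' count is also a Bonferroni-significant binomial outlier against the
#' cohort's median error rate. The significance guard stops nuclei with few
#' chloroplast reads from being censored on sampling noise alone: genuine
#' conversion failures exceed the cohort rate by an order of magnitude and
#' pass it at astronomical significance. Nuclei with no covered chloroplast
#' cytosines get status `"indeterminate"`.
#'
#' @param qc QC tibble with `chloro_me` and `chloro_sites` columns
#'   (optionally `chloro_mc` and `chloro_cov` for the significance guard).
#' @param method `"mad"` or `"fixed"`.
#' @param threshold Absolute cutoff for `method = "fixed"` (default 0.02).
#' @param k_mad MAD multiplier for `method = "mad"` (default 5).
#' @param alpha Family-wise level of the binomial outlier guard (default
#'   0.01, Bonferroni-corrected across nuclei).
#' @return `qc` with `conversion_status` in
#'   `{"pass", "fail", "indeterminate"}` and the applied
#'   `conversion_threshold`.
#' @export
conversion_filter <- function(qc, method = c("mad", "fixed"),
                              threshold = 0.02, k_mad = 5, alpha = 0.01) {
  method <- match.arg(method)
  stopifnot(all(c("chloro_me", "chloro_sites") %in% names(qc)))
  have <- qc$chloro_sites > 0 & !is.na(qc$chloro_me)
  thr <- if (method == "mad") {
    if (!any(have)) stop("no nuclei with chloroplast coverage")
    stats::median(qc$chloro_me[have]) + k_mad * stats::mad(qc$chloro_me[have])
  } else {
    threshold
  }
  exceeds <- have & qc$chloro_me > thr
  if (all(c("chloro_mc", "chloro_cov") %in% names(qc)) && any(have)) {
    p0 <- stats::median(qc$chloro_me[have])
    pvals <- rep(1, nrow(qc))
    pvals[have] <- stats::pbinom(qc$chloro_mc[have] - 1, qc$chloro_cov[have],
                                 p0, lower.tail = FALSE)
    exceeds <- exceeds & pvals < alpha / sum(have)
  }
  dplyr::mutate(
    qc,
    conversion_status = dplyr::case_when(
      !have ~ "indeterminate",
      exceeds ~ "fail",
      TRUE ~ "pass"
    ),
    conversion_threshold = thr
  )
}

#' Marker-ratio reassignment of mature VN / SN doublets
#'
#' For every nucleus currently labelled mature VN (VN4, VN5) or SN, computes
#' `r = log2((mean cp10k of SN markers + eps) / (mean cp10k of VN markers +
#' eps))`. Nuclei with `-window <= r <= window` (inclusive) express both
#' marker sets at similar levels and are relabelled `"VN and SN"` - these
#' are physically associated VN+SN pairs sorted together, censored from
#' methylome analyses. Other clusters are untouched.
#'
#' @param counts Genes-by-nuclei raw count matrix.
#' @param labels Tibble with columns `nucleus` and `label`.
#' @param sn_markers,vn_markers Character vectors of marker gene ids (must
#'   be non-empty).
#' @param mature_vn Labels treated as mature VN (default VN4, VN5).
#' @param window Half-width of the relabelling window on r (default 0.2,
#'   endpoints inclusive).
#' @param pseudocount Added to both means on the counts-per-10k scale
#'   (default 1).
#' @return `labels` with columns `marker_log2_ratio` (NA outside scope) and
#'   updated `label`.
#' @export
marker_ratio_reassignment <- function(counts, labels, sn_markers, vn_markers,
                                      mature_vn = c("VN4", "VN5"),
                                      window = 0.2, pseudocount = 1) {
  if (length(sn_markers) == 0 || length(vn_markers) == 0) {
    stop("marker lists must be non-empty")
  }
  stopifnot(all(c("nucleus", "label") %in% names(labels)))
  scope <- labels$label %in% c(mature_vn, "SN")
  libsize <- colSums(counts)
  cp10k <- sweep(counts, 2, pmax(libsize, 1), "/") * 1e4
  sn_mean <- colMeans(cp10k[rownames(cp10k) %in% sn_markers, , drop = FALSE])
  vn_mean <- colMeans(cp10k[rownames(cp10k) %in% vn_markers, , drop = FALSE])
  r <- log2((sn_mean + pseudocount) / (vn_mean + pseudocount))
  out <- labels
  out$marker_log2_ratio <- NA_real_
  idx <- match(out$nucleus, colnames(counts))
  out$marker_log2_ratio[scope] <- r[idx[scope]]
  relabel <- scope & !is.na(out$marker_log2_ratio) &
    out$marker_log2_ratio >= -window & out$marker_log2_ratio <= window
  out$label[relabel] <- "VN and SN"
  out
}

#' Run the full QC filter cascade
#'
#' Applies, in the fixed order, the basic well filter, the organelle RNA
#' filter, the coverage-based doublet filter and the conversion filter, and
#' assigns each nucleus a final status plus exactly one primary failure
#' reason (the first failed filter). Marker-ratio reassignment happens after
#' clustering and is applied separately via
#' [marker_ratio_reassignment()].
#'
#' @param qc QC tibble from [compute_nucleus_qc()].
#' @param thresholds Named list overriding defaults: `min_rna_reads`,
#'   `min_genes`, `min_bin_frac`, `max_organelle_frac`, `k_mad_doublet`,
#'   `conversion_method`, `conversion_threshold`, `k_mad_conversion`.
#' @param exempt_doublet Nucleus ids exempt from doublet flagging.
#' @return `qc` with per-filter columns, `status` (`"pass"`/`"fail"`) and
#'   `fail_reason`.
#' @export
qc_filter_nuclei <- function(qc, thresholds = list(), exempt_doublet = NULL) {
  th <- utils::modifyList(list(
    min_rna_reads = 1000, min_genes = 200, min_bin_frac = 0.10,
    max_organelle_frac = 0.10, k_mad_doublet = 5,
    conversion_method = "mad", conversion_threshold = 0.02,
    k_mad_conversion = 5
  ), thresholds)
  out <- qc %>%
    basic_well_filter(th$min_rna_reads, th$min_genes, th$min_bin_frac) %>%
    organelle_rna_filter(th$max_organelle_frac)
  dfit <- coverage_doublet_filter(out, k_mad = th$k_mad_doublet,
                                  exempt = exempt_doublet)
  out <- dfit$table %>%
    conversion_filter(method = th$conversion_method,
                      threshold = th$conversion_threshold,
                      k_mad = th$k_mad_conversion)
  out <- dplyr::mutate(
    out,
    fail_reason = dplyr::case_when(
      !.data$pass_basic ~ paste0("basic:", .data$basic_fail_reason),
      !.data$pass_organelle ~ "organelle_rna",
      .data$flagged_doublet ~ "coverage_doublet",
      .data$conversion_status == "fail" ~ "conversion",
      TRUE ~ NA_character_
    ),
    status = ifelse(is.na(.data$fail_reason), "pass", "fail")
  )
  attr(out, "doublet_fit") <- dfit[c("slope", "intercept", "mad", "k_mad")]
  attr(out, "thresholds") <- th
  out
}
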