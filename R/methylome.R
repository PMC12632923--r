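# Methylation aggregation math. All averages are weighted methylation levels:
# sum(mc) / sum(cov) over the contributing cytosines, never an average of
# per-region averages. Summaries with no qualifying sites are missing (NA),
# never 0, so absence of data is not mistaken for hypomethylation.

# Logical mask: does each call fall inside the union of the regions?
# Calls are 1-based positions; regions 0-based half-open, so position p lies
# in [start, end) iff start < p <= end.
sites_in_regions <- function(calls, regions) {
  if (nrow(calls) == 0 || nrow(regions) == 0) {
    return(rep(FALSE, nrow(calls)))
  }
  hit <- rep(FALSE, nrow(calls))
  for (chr in unique(regions$chrom)) {
    ci <- which(calls$chrom == chr)
    if (length(ci) == 0) next
    ri <- regions$chrom == chr
    merged <- IRanges::reduce(IRanges::IRanges(
      start = regions$start[ri] + 1L, end = regions$end[ri]
    ))
    q <- IRanges::IRanges(start = calls$pos[ci], width = 1L)
    hit[ci] <- IRanges::overlapsAny(q, merged)
  }
  hit
}

summarise_weighted <- function(calls, by_nucleus) {
  if (by_nucleus) {
    out <- calls %>%
      dplyr::group_by(.data$nucleus) %>%
      dplyr::summarise(
        n_sites = dplyr::n(),
        avg_cov = mean(.data$cov),
        avg_me = sum(.data$mc) / sum(.data$cov),
        .groups = "drop"
      )
  } else {
    out <- tibble::tibble(
      n_sites = nrow(calls),
      avg_cov = if (nrow(calls)) mean(calls$cov) else NA_real_,
      avg_me = if (nrow(calls)) sum(calls$mc) / sum(calls$cov) else NA_real_
    )
  }
  out
}

#' Weighted mean methylation over a region set, per nucleus
#'
#' For each nucleus, pools all cytosines of the requested context with
#' coverage at least `min_cov` that fall inside the union of the regions
#' (a site inside overlapping regions counts once) and reports the weighted
#' mean methylation `sum(mc) / sum(cov)`, the number of contributing sites
#' and the mean coverage per site. Nuclei with no qualifying sites get
#' `n_sites = 0` and `avg_me = NA`.
#'
#' @param calls Methylation call tibble; a `nucleus` column yields one row
#'   per nucleus, otherwise a single pooled row is returned.
#' @param regions Region set tibble (must be non-empty).
#' @param context One of `"CG"`, `"CHG"`, `"CHH"`.
#' @param min_cov Minimum read coverage per site; 1 for single-nucleus data
#'   (coverage is 0/1 after deduplication), 5 is the convention for bulk.
#' @param region_set_id Label recorded in the output.
#' @return Tibble with columns `nucleus` (if present), `region_set`,
#'   `context`, `n_sites`, `avg_cov`, `avg_me`.
#' @export
region_weighted_methylation <- function(calls, regions, context,
                                        min_cov = 1, region_set_id = "regions") {
  context <- match.arg(context, c("CG", "CHG", "CHH"))
  stopifnot(min_cov >= 1)
  if (nrow(regions) == 0) stop("empty region set")
  by_nucleus <- "nucleus" %in% names(calls)
  sel <- calls[calls$context == context & calls$cov >= min_cov, , drop = FALSE]
  sel <- sel[sites_in_regions(sel, regions), , drop = FALSE]
  out <- summarise_weighted(sel, by_nucleus)
  if (by_nucleus) {
    # keep a row (n_sites = 0, avg_me missing) for every nucleus in the input
    all_nuc <- tibble::tibble(nucleus = unique(calls$nucleus))
    out <- dplyr::left_join(all_nuc, out, by = "nucleus") %>%
      dplyr::mutate(n_sites = dplyr::coalesce(.data$n_sites, 0L))
  }
  dplyr::mutate(out, region_set = region_set_id, context = context,
                .before = "n_sites")
}

#' Genome-wide weighted mean methylation
#'
#' Same arithmetic as [region_weighted_methylation()] with the regions being
#' whole chromosomes; by default the chloroplast and mitochondrial
#' chromosomes are excluded.
#'
#' @inheritParams region_weighted_methylation
#' @param genome A [genome_spec()].
#' @param exclude_organelles Drop organellar chromosomes before averaging?
#' @return As [region_weighted_methylation()], with `region_set =
#'   "genome"`.
#' @export
genomewide_methylation <- function(calls, genome, context, min_cov = 1,
                                   exclude_organelles = TRUE) {
  assert_genome(genome)
  g <- if (exclude_organelles) genome[!genome$is_organelle, ] else genome
  regions <- region_set(g$chrom, 0, g$length, id = g$chrom)
  region_weighted_methylation(calls, regions, context, min_cov,
                              region_set_id = "genome")
}

#' Pool per-nucleus methylation calls into pseudobulk tracks
#'
#' Sums (mc, cov) site-wise across all nuclei sharing a label, yielding one
#' pooled track per label. The result is independent of nucleus order.
#'
#' @param calls Methylation call tibble with a `nucleus` column.
#' @param groups Tibble with columns `nucleus` and `label` (e.g. cluster, or
#'   cluster x genotype). Nuclei absent from `groups` are dropped.
#' @return Tibble with columns `label`, `chrom`, `pos`, `strand`, `context`,
#'   `mc`, `cov`, sorted by label, chrom, pos.
#' @export
pseudobulk_pool <- function(calls, groups) {
  stopifnot("nucleus" %in% names(calls),
            all(c("nucleus", "label") %in% names(groups)))
  empty <- setdiff(unique(groups$label), groups$label[groups$nucleus %in% calls$nucleus])
  if (length(empty)) {
    warning("label(s) with no member nuclei produce empty tracks: ",
            paste(empty, collapse = ", "))
  }
  calls %>%
    dplyr::inner_join(groups[, c("nucleus", "label")], by = "nucleus") %>%
    dplyr::group_by(.data$label, .data$chrom, .data$pos, .data$strand, .data$context) %>%
    dplyr::summarise(mc = sum(.data$mc), cov = sum(.data$cov), .groups = "drop") %>%
    dplyr::arrange(.data$label, .data$chrom, .data$pos)
}

#' Tile a genome into fixed-width bins
#'
#' Bins are left-aligned from the chromosome start; the final partial bin is
#' kept, truncated at the chromosome end.
#'
#' @param genome A [genome_spec()].
#' @param bin_width Bin width in bp (> 0).
#' @param exclude_organelles Drop organellar chromosomes?
#' @return Region set tibble with ids `chrom:start-end`.
#' @export
genome_bins <- function(genome, bin_width, exclude_organelles = TRUE) {
  assert_genome(genome)
  stopifnot(bin_width > 0)
  g <- if (exclude_organelles) genome[!genome$is_organelle, ] else genome
  bins <- purrr::map_dfr(seq_len(nrow(g)), function(i) {
    starts <- seq(0, g$length[i] - 1, by = bin_width)
    tibble::tibble(chrom = g$chrom[i], start = starts,
                   end = pmin(starts + bin_width, g$length[i]))
  })
  bins$id <- sprintf("%s:%d-%d", bins$chrom, as.integer(bins$start), as.integer(bins$end))
  bins$score <- NA_real_
  bins
}

bin_index <- function(pos, bin_width) (pos - 1L) %/% bin_width

#' Per-bin methylation fraction
#'
#' Tiles the genome into fixed-width bins and reports, per bin, the fraction
#' of methylated calls in the requested context: `sum(mc) / sum(cov)` over
#' the context cytosines in the bin. Bins with no covered context sites are
#' `NA`, not 0.
#'
#' @param calls Methylation call tibble (single nucleus or pooled track; a
#'   `nucleus` or `label` column, if present, is ignored and all rows are
#'   pooled).
#' @param genome A [genome_spec()].
#' @param bin_width Bin width in bp; the conventions used in practice are
#'   400 (density bins), 1e3 (QC), 25e3 (methylome clustering) and 100e3
#'   (chromosome profiles).
#' @param context One of `"CG"`, `"CHG"`, `"CHH"`.
#' @param exclude_organelles Drop organellar chromosomes?
#' @return Tibble of bins with `n_sites` and `value` (= methylation
#'   fraction) columns.
#' @export
bin_methylation_fraction <- function(calls, genome, bin_width, context,
                                     exclude_organelles = TRUE) {
  context <- match.arg(context, c("CG", "CHG", "CHH"))
  bins <- genome_bins(genome, bin_width, exclude_organelles)
  sel <- calls[calls$context == context & calls$chrom %in% unique(bins$chrom), , drop = FALSE]
  agg <- sel %>%
    dplyr::mutate(start = bin_index(.data$pos, bin_width) * bin_width) %>%
    dplyr::group_by(.data$chrom, .data$start) %>%
    dplyr::summarise(n_sites = dplyr::n(),
                     value = sum(.data$mc) / sum(.data$cov), .groups = "drop")
  out <- dplyr::left_join(bins, agg, by = c("chrom", "start")) %>%
    dplyr::mutate(n_sites = dplyr::coalesce(.data$n_sites, 0L),
                  context = context)
  out
}

#' Per-bin methylation density
#'
#' For bulk data with per-site methylation percentages: tiles the genome
#' into fixed-width bins (default 400 bp) and sums, over all context
#' cytosines with coverage at least `min_cov`, the per-site percent
#' methylation `mc / cov * 100`. The unit is summed percent; bins without
#' qualifying sites have density 0 (a site below `min_cov` contributes
#' nothing).
#'
#' @inheritParams bin_methylation_fraction
#' @param min_cov Minimum aligned reads per cytosine (default 5, the bulk
#'   convention).
#' @return Tibble of bins with `n_sites` and `value` (= density) columns.
#' @export
methylation_density <- function(calls, genome, bin_width = 400, context,
                                min_cov = 5, exclude_organelles = TRUE) {
  context <- match.arg(context, c("CG", "CHG", "CHH"))
  bins <- genome_bins(genome, bin_width, exclude_organelles)
  sel <- calls[calls$context == context & calls$cov >= min_cov &
                 calls$chrom %in% unique(bins$chrom), , drop = FALSE]
  agg <- sel %>%
    dplyr::mutate(start = bin_index(.data$pos, bin_width) * bin_width) %>%
    dplyr::group_by(.data$chrom, .data$start) %>%
    dplyr::summarise(n_sites = dplyr::n(),
                     value = sum(.data$mc / .data$cov * 100), .groups = "drop")
  dplyr::left_join(bins, agg, by = c("chrom", "start")) %>%
    dplyr::mutate(n_sites = dplyr::coalesce(.data$n_sites, 0L),
                  value = dplyr::coalesce(.data$value, 0),
                  context = context)
}

#' TSS-proximal windows
#'
#' Builds the +/- `radius` bp window around each transcription start site,
#' clipped to chromosome bounds: the width-2*radius interval centred on the
#' 0-based TSS position, i.e. a TSS at 1-based position p yields
#' [p - 1 - radius, p - 1 + radius).
#'
#' @param tss Tibble with columns `transcript_id`, `chrom`, `tss` (1-based)
#'   and optionally `strand`.
#' @param genome A [genome_spec()].
#' @param radius Window radius in bp (default 400).
#' @return Region set tibble, ids = transcript ids.
#' @export
tss_windows <- function(tss, genome, radius = 400) {
  assert_genome(genome)
  stopifnot(all(c("transcript_id", "chrom", "tss") %in% names(tss)))
  lens <- chrom_length(genome, tss$chrom)
  if (any(tss$tss < 1 | tss$tss > lens)) stop("TSS outside chromosome bounds")
  start <- pmax(tss$tss - 1 - radius, 0)
  end <- pmin(tss$tss - 1 + radius, lens)
  region_set(tss$chrom, start, end, id = tss$transcript_id, genome = genome)
}

#' Scaled metaprofile of a methylation track over regions
#'
#' The analogue of a compute-matrix + average profile: each region's body is
#' scaled to `n_body_bins` equal bins, flanks are tiled in fixed-width bins,
#' and per profile bin the (mc, cov) pairs of all regions are pooled into a
#' weighted methylation fraction. Minus-strand regions are reversed so all
#' profiles read 5' to 3'; unstranded regions are treated as plus strand.
#'
#' @param calls Methylation call tibble (typically a pseudobulk track for
#'   one label); rows are pooled.
#' @param regions Region set; an optional `strand` column controls
#'   orientation.
#' @param context One of `"CG"`, `"CHG"`, `"CHH"`.
#' @param upstream,downstream Flank sizes in bp.
#' @param n_body_bins Number of bins the region body is scaled into.
#' @param flank_bin_width Width of flank bins in bp.
#' @return Tibble with one row per profile bin: `bin` (index, upstream
#'   first), `zone` (upstream/body/downstream), `offset` (bp or scaled
#'   position), `n_sites`, `value`.
#' @export
metaprofile <- function(calls, regions, context, upstream = 1000,
                        downstream = 1000, n_body_bins = 50,
                        flank_bin_width = 100) {
  context <- match.arg(context, c("CG", "CHG", "CHH"))
  stopifnot(n_body_bins >= 1)
  if (nrow(regions) == 0) stop("empty region set")
  strand <- if ("strand" %in% names(regions)) regions$strand else rep("+", nrow(regions))
  strand[is.na(strand) | !strand %in% c("+", "-")] <- "+"
  n_up <- if (upstream > 0) ceiling(upstream / flank_bin_width) else 0L
  n_down <- if (downstream > 0) ceiling(downstream / flank_bin_width) else 0L
  n_tot <- n_up + n_body_bins + n_down
  sel <- calls[calls$context == context, , drop = FALSE]

  mc_acc <- numeric(n_tot)
  cov_acc <- numeric(n_tot)
  n_acc <- integer(n_tot)
  for (i in seq_len(nrow(regions))) {
    chr <- regions$chrom[i]
    s <- regions$start[i]; e <- regions$end[i]
    minus <- strand[i] == "-"
    lo <- s - (if (minus) downstream else upstream)
    hi <- e + (if (minus) upstream else downstream)
    ci <- which(sel$chrom == chr & sel$pos > lo & sel$pos <= hi)
    if (length(ci) == 0) next
    p0 <- sel$pos[ci] - 1  # 0-based site position
    # signed distance along the profile, 5'->3' of the region
    rel <- numeric(length(ci))
    zone <- integer(length(ci))  # 1 upstream, 2 body, 3 downstream
    if (!minus) {
      zone[p0 < s] <- 1L; zone[p0 >= s & p0 < e] <- 2L; zone[p0 >= e] <- 3L
      bin <- integer(length(ci))
      bin[zone == 1L] <- n_up - 1L - ((s - 1 - p0[zone == 1L]) %/% flank_bin_width)
      frac <- (p0[zone == 2L] - s) / (e - s)
      bin[zone == 2L] <- n_up + pmin(floor(frac * n_body_bins), n_body_bins - 1)
      bin[zone == 3L] <- n_up + n_body_bins + ((p0[zone == 3L] - e) %/% flank_bin_width)
    } else {
      zone[p0 >= e] <- 1L; zone[p0 >= s & p0 < e] <- 2L; zone[p0 < s] <- 3L
      bin <- integer(length(ci))
      bin[zone == 1L] <- n_up - 1L - ((p0[zone == 1L] - e) %/% flank_bin_width)
      frac <- (e - 1 - p0[zone == 2L]) / (e - s)
      bin[zone == 2L] <- n_up + pmin(floor(frac * n_body_bins), n_body_bins - 1)
      bin[zone == 3L] <- n_up + n_body_bins + ((s - 1 - p0[zone == 3L]) %/% flank_bin_width)
    }
    keep <- bin >= 0 & bin < n_tot
    bin1 <- bin[keep] + 1L
    mc_acc <- mc_acc + tabulate_weighted(bin1, sel$mc[ci][keep], n_tot)
    cov_acc <- cov_acc + tabulate_weighted(bin1, sel$cov[ci][keep], n_tot)
    n_acc <- n_acc + tabulate(bin1, n_tot)
  }
  zone_lab <- c(rep("upstream", n_up), rep("body", n_body_bins), rep("downstream", n_down))
  offset <- c(
    if (n_up) -rev(seq_len(n_up)) * flank_bin_width else numeric(),
    (seq_len(n_body_bins) - 0.5) / n_body_bins,
    if (n_down) seq_len(n_down) * flank_bin_width else numeric()
  )
  tibble::tibble(
    bin = seq_len(n_tot), zone = zone_lab, offset = offset,
    n_sites = n_acc,
    value = ifelse(cov_acc > 0, mc_acc / cov_acc, NA_real_),
    context = context
  )
}

tabulate_weighted <- function(bin, w, nbins) {
  out <- numeric(nbins)
  if (length(bin)) {
    agg <- rowsum(as.numeric(w), group = bin)
    out[as.integer(rownames(agg))] <- agg[, 1]
  }
  out
}
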