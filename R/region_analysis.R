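# Interval-level statistics: peak dominance deciles, reciprocal-coverage
# overlap with shuffled controls, and ChIP-signal-vs-methylation-density
# curves.

#' Classify peak dominance by MBD7 signal deciles
#'
#' Ranks the union of MBD6/MBD7 peaks by mean MBD7 ChIP enrichment and
#' labels the top decile MBD7-dominant (strong MBD7, weak MBD6), the bottom
#' decile MBD6-dominant, and the decile centred on the median rank mixed.
#' Everything else is unlabeled. Ties are broken by peak id, so labels are
#' deterministic and invariant to input order.
#'
#' @param peaks Region set of union peaks.
#' @param signal Tibble with columns `id` and `signal` (mean MBD7
#'   enrichment, e.g. log2 IP/control), one row per peak.
#' @param decile Fraction per class (default 0.10).
#' @return Tibble with columns `id`, `signal`, `rank` (1 = highest signal),
#'   `decile` (1..10 by rank), `label`.
#' @export
classify_dominance <- function(peaks, signal, decile = 0.10) {
  stopifnot(all(c("id", "signal") %in% names(signal)))
  n <- nrow(peaks)
  if (n < 30) stop("need at least 30 peaks for decile-based dominance classes")
  if (!all(peaks$id %in% signal$id)) {
    stop("every peak needs a signal value")
  }
  df <- tibble::tibble(id = peaks$id) %>%
    dplyr::left_join(signal[, c("id", "signal")], by = "id")
  ord <- order(-df$signal, df$id)  # descending signal, stable by id
  df <- df[ord, ]
  df$rank <- seq_len(n)
  k <- floor(decile * n)
  lab <- rep("unlabeled", n)
  lab[seq_len(k)] <- "MBD7_dominant"
  lab[seq.int(n - k + 1L, n)] <- "MBD6_dominant"
  mid_centre <- ceiling(n / 2)
  mid_lo <- mid_centre - floor(k / 2) + ifelse(k %% 2 == 0, 1L, 0L)
  mid <- seq.int(mid_lo, length.out = k)
  lab[mid] <- "mixed"
  df$decile <- pmin(ceiling(df$rank / (n / 10)), 10L)
  df$label <- lab
  df
}

merged_coverage_width <- function(query, subject) {
  # bp of each query interval covered by the union (merge) of subject
  out <- numeric(nrow(query))
  for (chr in unique(query$chrom)) {
    qi <- which(query$chrom == chr)
    si <- subject$chrom == chr
    if (!any(si)) next
    q <- IRanges::IRanges(start = query$start[qi] + 1L, end = query$end[qi])
    s <- IRanges::reduce(IRanges::IRanges(start = subject$start[si] + 1L,
                                          end = subject$end[si]))
    ov <- IRanges::findOverlaps(q, s)
    if (length(ov) == 0) next
    inter_w <- pmin(IRanges::end(q)[S4Vectors::queryHits(ov)],
                    IRanges::end(s)[S4Vectors::subjectHits(ov)]) -
      pmax(IRanges::start(q)[S4Vectors::queryHits(ov)],
           IRanges::start(s)[S4Vectors::subjectHits(ov)]) + 1
    cov <- rowsum(inter_w, group = S4Vectors::queryHits(ov))
    out[qi[as.integer(rownames(cov))]] <- cov[, 1]
  }
  out
}

overlap_flags <- function(A, B, min_frac) {
  # A region counts as overlapping if >min_frac of it is covered by merged B,
  # or if it touches a B region that is itself >min_frac covered by merged A
  # (the "either covered by the other" clause).
  covA <- merged_coverage_width(A, B) / (A$end - A$start)
  covB <- merged_coverage_width(B, A) / (B$end - B$start)
  flagA <- covA > min_frac
  flagB <- covB > min_frac
  # propagate via touching pairs
  for (chr in unique(A$chrom)) {
    ai <- which(A$chrom == chr)
    bi <- which(B$chrom == chr)
    if (!length(ai) || !length(bi)) next
    ra <- IRanges::IRanges(start = A$start[ai] + 1L, end = A$end[ai])
    rb <- IRanges::IRanges(start = B$start[bi] + 1L, end = B$end[bi])
    ov <- IRanges::findOverlaps(ra, rb)
    if (length(ov) == 0) next
    qa <- ai[S4Vectors::queryHits(ov)]
    qb <- bi[S4Vectors::subjectHits(ov)]
    flagA[qa] <- flagA[qa] | flagB[qb]
    flagB[qb] <- flagB[qb] | covA[qa] > min_frac
  }
  list(A = flagA, B = flagB)
}

#' Reciprocal >50 percent coverage overlap between two region sets
#'
#' Two regions are considered overlapping if either is more than `min_frac`
#' covered by the other. Coverage is computed against the merged partner set
#' so several abutting partners accumulate; the comparison is strict
#' (exactly 50 percent does not count at the default).
#'
#' @param A,B Region set tibbles.
#' @param min_frac Coverage fraction threshold (strict; default 0.5).
#' @return A list of class `overlap_report`: per-set sizes, counts of
#'   overlapping regions, fractions, and per-region flag tibbles.
#' @export
reciprocal_overlap <- function(A, B, min_frac = 0.5) {
  flags <- overlap_flags(A, B, min_frac)
  out <- list(
    n_A = nrow(A), n_B = nrow(B),
    n_A_overlap = sum(flags$A), n_B_overlap = sum(flags$B),
    frac_A_overlap = if (nrow(A)) mean(flags$A) else NA_real_,
    frac_B_overlap = if (nrow(B)) mean(flags$B) else NA_real_,
    min_frac = min_frac,
    flags_A = tibble::tibble(id = A$id, overlaps = flags$A),
    flags_B = tibble::tibble(id = B$id, overlaps = flags$B)
  )
  class(out) <- "overlap_report"
  out
}

#' @export
print.overlap_report <- function(x, ...) {
  cat(sprintf(
    "<overlap_report> |A| = %d (%.1f%% overlap B), |B| = %d (%.1f%% overlap A), rule: >%.0f%% reciprocal coverage\n",
    x$n_A, 100 * x$frac_A_overlap, x$n_B, 100 * x$frac_B_overlap, 100 * x$min_frac
  ))
  invisible(x)
}

#' Shuffle regions across the genome
#'
#' Places each interval uniformly at random (length preserved), by default
#' on its own chromosome, rejecting placements that overlap an already
#' placed interval (bedtools-shuffle-like). Fully reproducible from `seed`.
#'
#' @param A Region set to shuffle.
#' @param genome A [genome_spec()].
#' @param n_shuffles Number of independent shuffles.
#' @param seed Integer seed.
#' @param same_chrom Keep each interval on its own chromosome? If `FALSE`,
#'   a chromosome is drawn with probability proportional to its length
#'   (organelles excluded).
#' @param max_attempts Rejection-sampling bound per interval.
#' @return List of `n_shuffles` region sets.
#' @export
shuffle_regions <- function(A, genome, n_shuffles = 1, seed = 1,
                            same_chrom = TRUE, max_attempts = 1000) {
  assert_genome(genome)
  lens <- chrom_length(genome, A$chrom)
  if (any(A$end - A$start > lens)) stop("region longer than its chromosome")
  nuclear <- genome[!genome$is_organelle, ]
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  ord <- order(-(A$end - A$start), A$id)  # place long intervals first
  lapply(seq_len(n_shuffles), function(s) {
    placed <- vector("list", nrow(A))
    occ <- list()  # per chrom: matrix of placed [start, end)
    for (i in ord) {
      w <- A$end[i] - A$start[i]
      ok <- FALSE
      for (att in seq_len(max_attempts)) {
        chr <- if (same_chrom) A$chrom[i] else {
          sample(nuclear$chrom, 1, prob = nuclear$length)
        }
        L <- chrom_length(genome, chr)
        if (w > L) next
        start <- floor(stats::runif(1, 0, L - w + 1))
        end <- start + w
        prev <- occ[[chr]]
        clash <- !is.null(prev) && any(start < prev[, 2] & end > prev[, 1])
        if (!clash) {
          occ[[chr]] <- rbind(prev, c(start, end))
          placed[[i]] <- tibble::tibble(chrom = chr, start = start, end = end,
                                        id = A$id[i], score = A$score[i])
          ok <- TRUE
          break
        }
      }
      if (!ok) stop("could not place interval ", A$id[i], " after ",
                    max_attempts, " attempts")
    }
    dplyr::bind_rows(placed) %>%
      dplyr::arrange(.data$chrom, .data$start)
  })
}

#' Overlap of a region set against shuffled controls
#'
#' Convenience wrapper: runs [reciprocal_overlap()] for the true A set and
#' for `n_shuffles` shuffles of A, and reports the true overlap fractions
#' next to the shuffled mean and sd.
#'
#' @inheritParams reciprocal_overlap
#' @inheritParams shuffle_regions
#' @return A list of class `overlap_enrichment` with elements `true`
#'   (overlap_report), `shuffled` (tibble of per-shuffle fractions) and
#'   `summary` (one-row tibble).
#' @export
overlap_with_shuffles <- function(A, B, genome, min_frac = 0.5,
                                  n_shuffles = 100, seed = 1,
                                  same_chrom = TRUE) {
  true <- reciprocal_overlap(A, B, min_frac)
  shufs <- shuffle_regions(A, genome, n_shuffles = n_shuffles, seed = seed,
                           same_chrom = same_chrom)
  per <- purrr::map_dfr(seq_along(shufs), function(i) {
    r <- reciprocal_overlap(shufs[[i]], B, min_frac)
    tibble::tibble(shuffle = i, frac_A_overlap = r$frac_A_overlap,
                   n_A_overlap = r$n_A_overlap)
  })
  out <- list(
    true = true,
    shuffled = per,
    summary = tibble::tibble(
      n_A = true$n_A,
      true_frac = true$frac_A_overlap,
      shuffled_mean = mean(per$frac_A_overlap),
      shuffled_sd = stats::sd(per$frac_A_overlap),
      n_shuffles = n_shuffles
    )
  )
  class(out) <- "overlap_enrichment"
  out
}

#' @export
print.overlap_enrichment <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "<overlap_enrichment> true overlap %.1f%% vs shuffled %.1f%% +/- %.1f%% (%d shuffles)\n",
    100 * s$true_frac, 100 * s$shuffled_mean, 100 * s$shuffled_sd, s$n_shuffles
  ))
  invisible(x)
}

#' Locally weighted regression of ChIP signal on methylation density
#'
#' Fits a loess curve of per-bin ChIP enrichment against per-bin methylation
#' density (as from [methylation_density()]) and evaluates it on an evenly
#' spaced grid across the observed density range, together with a residual
#' standard deviation band.
#'
#' @param bins Tibble with one row per aligned 400-bp bin, columns `signal`
#'   (e.g. log2 IP/control) and `density` (summed percent methylation).
#' @param span Loess span (default 0.75, the usual smoother default).
#' @param n_grid Number of grid points.
#' @param degree Local polynomial degree (default 2).
#' @return Object of class `density_curve`: a list with `curve` (tibble of
#'   `density`, `fitted`, `sd_band`), `residual_sd`, `n_bins`, `span`.
#' @export
signal_vs_density_curve <- function(bins, span = 0.75, n_grid = 100, degree = 2) {
  stopifnot(all(c("signal", "density") %in% names(bins)))
  bins <- bins[is.finite(bins$signal) & is.finite(bins$density), , drop = FALSE]
  if (nrow(bins) < 50) stop("need at least 50 aligned bins")
  fit <- stats::loess(signal ~ density, data = bins, span = span,
                      degree = degree, family = "gaussian",
                      control = stats::loess.control(surface = "direct"))
  grid <- seq(min(bins$density), max(bins$density), length.out = n_grid)
  pred <- stats::predict(fit, newdata = data.frame(density = grid))
  rsd <- stats::sd(stats::residuals(fit))
  out <- list(
    curve = tibble::tibble(density = grid, fitted = as.numeric(pred), sd_band = rsd),
    residual_sd = rsd,
    n_bins = nrow(bins),
    span = span,
    fit = fit
  )
  class(out) <- "density_curve"
  out
}

#' @export
print.density_curve <- function(x, ...) {
  cat(sprintf(
    "<density_curve> loess (span %.2f) over %d bins; residual sd %.4g; fitted range [%.4g, %.4g]\n",
    x$span, x$n_bins, x$residual_sd, min(x$curve$fitted), max(x$curve$fitted)
  ))
  invisible(x)
}
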