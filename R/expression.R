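# Expression-side classifiers: DE threshold selection, hierarchical-
# clustering rescue classification, Cohen's d effect staging, and BLAST
# bitscore homology calls. Differential-expression model fitting and TPM
# estimation happen upstream; this module consumes their tables.

#' Select up/down regulated transcripts by DE thresholds
#'
#' Significance rule: adjusted p-value < 0.05 and |log2 fold change| > 1,
#' both strict. Transcripts with missing `padj` are excluded.
#'
#' @param stats Tibble with columns `transcript_id`, `log2fc`, `padj`.
#' @param padj_max,lfc_min Thresholds (strict comparisons).
#' @return Tibble `stats` with an added `direction` column in
#'   `{"up", "down", "ns"}`.
#' @export
de_threshold_filter <- function(stats, padj_max = 0.05, lfc_min = 1) {
  stopifnot(all(c("transcript_id", "log2fc", "padj") %in% names(stats)))
  sig <- !is.na(stats$padj) & stats$padj < padj_max
  dplyr::mutate(
    tibble::as_tibble(stats),
    direction = dplyr::case_when(
      sig & .data$log2fc > lfc_min ~ "up",
      sig & .data$log2fc < -lfc_min ~ "down",
      TRUE ~ "ns"
    )
  )
}

rescue_index <- function(wt, m56, m567) {
  # rho = 1 when the triple mutant returns to wild type, 0 when it stays at
  # the double-mutant level
  (m56 - m567) / (m56 - wt)
}

#' Classify transcript rescue from TPM by hierarchical clustering
#'
#' Restricts a TPM matrix to the upregulated set, z-scores each transcript
#' across samples, clusters transcripts (correlation distance, average
#' linkage by default), cuts into `k` clusters, and labels each cluster by
#' its centroid rescue index computed on unscaled TPM:
#' `rho = (mean(mbd5/6) - mean(mbd5/6/7)) / (mean(mbd5/6) - mean(WT))`.
#' `rho >= 0.75` is rescued, `0.25 <= rho < 0.75` partially rescued,
#' `rho < 0.25` not rescued. Clusters whose members' per-transcript rho
#' values are too dispersed are labelled omitted.
#'
#' @param tpm Numeric matrix, transcripts x samples.
#' @param samples Tibble with columns `sample` and `genotype`; genotypes
#'   must include `WT`, `mbd5/6` and `mbd5/6/7`, each with >= 2 replicates.
#' @param upregulated Character vector of transcript ids to classify.
#' @param k Number of clusters to cut (default 4).
#' @param distance `"correlation"` or `"euclidean"`.
#' @param linkage Agglomeration method for [stats::hclust()].
#' @param rescued_min,not_rescued_max Rho thresholds (0.75 / 0.25).
#' @param omit_dispersion Clusters whose member rho standard deviation
#'   exceeds this are labelled omitted (default 0.35).
#' @return Object of class `rescue_classification`: tibble `labels`
#'   (transcript_id, cluster, rho, label), tibble `clusters` (per-cluster
#'   centroid rho, dispersion, label), the `hclust` object and the
#'   dendrogram transcript order.
#' @export
classify_rescue <- function(tpm, samples, upregulated, k = 4,
                            distance = c("correlation", "euclidean"),
                            linkage = "average",
                            rescued_min = 0.75, not_rescued_max = 0.25,
                            omit_dispersion = 0.35) {
  distance <- match.arg(distance)
  stopifnot(all(c("sample", "genotype") %in% names(samples)))
  needed <- c("WT", "mbd5/6", "mbd5/6/7")
  absent <- setdiff(needed, unique(samples$genotype))
  if (length(absent)) stop("genotype(s) absent: ", paste(absent, collapse = ", "))
  reps <- table(samples$genotype[samples$genotype %in% needed])
  if (any(reps < 2)) stop("need >= 2 replicates per genotype")
  if (!all(samples$sample %in% colnames(tpm))) stop("samples missing from TPM matrix")
  missing_tx <- setdiff(upregulated, rownames(tpm))
  if (length(missing_tx)) stop("transcript(s) missing from TPM matrix: ",
                               paste(utils::head(missing_tx, 3), collapse = ", "))
  m <- tpm[upregulated, samples$sample, drop = FALSE]

  sds <- apply(m, 1, stats::sd)
  if (any(sds == 0)) {
    warning(sum(sds == 0), " zero-variance transcript row(s) dropped")
    m <- m[sds > 0, , drop = FALSE]
  }
  z <- t(scale(t(m)))  # z-score per transcript across samples
  if (distance == "correlation") {
    d <- stats::as.dist(1 - stats::cor(t(z)))
  } else {
    d <- stats::dist(z)
  }
  hc <- stats::hclust(d, method = linkage)
  cl <- stats::cutree(hc, k = min(k, nrow(m)))

  gmeans <- function(rows) {
    vapply(needed, function(g) {
      mean(m[rows, samples$sample[samples$genotype == g], drop = FALSE])
    }, numeric(1))
  }
  per_tx_rho <- vapply(rownames(m), function(tx) {
    gm <- gmeans(tx)
    rescue_index(gm["WT"], gm["mbd5/6"], gm["mbd5/6/7"])
  }, numeric(1))

  clusters <- purrr::map_dfr(sort(unique(cl)), function(cc) {
    rows <- names(cl)[cl == cc]
    gm <- gmeans(rows)
    rho_c <- rescue_index(gm["WT"], gm["mbd5/6"], gm["mbd5/6/7"])
    disp <- if (length(rows) > 1) stats::sd(per_tx_rho[rows]) else 0
    lab <- if (is.finite(disp) && disp > omit_dispersion) {
      "omitted"
    } else if (rho_c >= rescued_min) {
      "rescued"
    } else if (rho_c >= not_rescued_max) {
      "partially_rescued"
    } else {
      "not_rescued"
    }
    tibble::tibble(cluster = cc, n = length(rows), rho = rho_c,
                   rho_dispersion = disp, label = lab)
  })
  labels <- tibble::tibble(
    transcript_id = rownames(m),
    cluster = unname(cl),
    rho = unname(per_tx_rho)
  ) %>%
    dplyr::left_join(clusters[, c("cluster", "label")], by = "cluster")

  out <- list(labels = labels, clusters = clusters, hclust = hc,
              order = rownames(m)[hc$order],
              params = list(k = k, distance = distance, linkage = linkage,
                            rescued_min = rescued_min,
                            not_rescued_max = not_rescued_max,
                            omit_dispersion = omit_dispersion))
  class(out) <- "rescue_classification"
  out
}

#' @export
print.rescue_classification <- function(x, ...) {
  tab <- table(x$labels$label)
  cat("<rescue_classification> ", nrow(x$labels), " transcripts in ",
      nrow(x$clusters), " clusters: ",
      paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Cohen's d with star-grade effect staging
#'
#' Standardised mean difference `(mean(A) - mean(B)) / pooled sd` with the
#' pooled standard deviation `sqrt(((nA-1) sA^2 + (nB-1) sB^2) / (nA+nB-2))`,
#' binned into star grades by strict |d| thresholds: n.e. (|d| <= 0.2),
#' `*` (> 0.2), `**` (> 0.5), `***` (> 0.9), `****` (> 1.5). A two-sided
#' two-sample t-test p-value accompanies the effect size; `p < 0.001`
#' corresponds to the red-star significance convention.
#'
#' @param a,b Numeric vectors, each of length >= 2.
#' @param welch Use the Welch (unequal variance) t-test?
#' @return Object of class `effect_size`: list with `d`, `stars`, `p`,
#'   `n_a`, `n_b`, `significant` (p < 0.001).
#' @export
cohens_d_stars <- function(a, b, welch = FALSE) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) < 2 || length(b) < 2) stop("each group needs n >= 2")
  na <- length(a); nb <- length(b)
  sp <- sqrt(((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / (na + nb - 2))
  md <- mean(a) - mean(b)
  if (sp == 0) {
    if (md != 0) stop("pooled sd is zero with unequal means; d undefined")
    d <- 0
    p <- 1
  } else {
    d <- md / sp
    p <- stats::t.test(a, b, var.equal = !welch)$p.value
  }
  out <- list(
    d = d,
    stars = d_stars(d),
    p = p,
    n_a = na, n_b = nb,
    significant = is.finite(p) && p < 0.001
  )
  class(out) <- "effect_size"
  out
}

d_stars <- function(d) {
  ad <- abs(d)
  if (ad > 1.5) "****"
  else if (ad > 0.9) "***"
  else if (ad > 0.5) "**"
  else if (ad > 0.2) "*"
  else "n.e."
}

#' @export
print.effect_size <- function(x, ...) {
  cat(sprintf("<effect_size> d = %.3f (%s), p = %.3g (n = %d vs %d)%s\n",
              x$d, x$stars, x$p, x$n_a, x$n_b,
              if (x$significant) " [p < 0.001]" else ""))
  invisible(x)
}

#' Classify locus homology from BLAST bitscores
#'
#' Per query locus, takes the best (maximum) bitscore against the gene
#' annotation and against the TE / TE-gene annotations, and applies:
#' no gene hit and TE bitscore > 100 -> TE; no TE hit and gene bitscore
#' > 100 -> gene; hits to both -> the higher category if its best bitscore
#' is at least 3x the other (inclusive), else ambiguous; no hit above
#' threshold on either side -> neither.
#'
#' @param hits Tibble with columns `query_id`, `subject_class` (one of
#'   `gene`, `TE`, `TEgene`) and `bitscore`, as from [read_blast_hits()].
#'   Queries absent from the table can be supplied via `queries` to receive
#'   the label `neither`.
#' @param queries Optional character vector of all query ids.
#' @param bitscore_min Significance floor for single-sided calls (default
#'   100, strict).
#' @param ratio_min Dominance ratio (default 3, inclusive).
#' @return Tibble with columns `query_id`, `gene_bitscore`, `te_bitscore`,
#'   `label` in `{"gene", "TE", "ambiguous", "neither"}`.
#' @export
homology_classify <- function(hits, queries = NULL, bitscore_min = 100,
                              ratio_min = 3) {
  stopifnot(all(c("query_id", "subject_class", "bitscore") %in% names(hits)))
  if (nrow(hits) == 0) {
    best <- tibble::tibble(query_id = character(), gene = numeric(),
                           TE = numeric())
    if (!is.null(queries)) {
      best <- tibble::tibble(query_id = queries, gene = NA_real_, TE = NA_real_)
    }
    return(tibble::tibble(query_id = best$query_id, gene_bitscore = best$gene,
                          te_bitscore = best$TE,
                          label = rep("neither", nrow(best))))
  }
  best <- hits %>%
    dplyr::mutate(side = ifelse(.data$subject_class == "gene", "gene", "TE")) %>%
    dplyr::group_by(.data$query_id, .data$side) %>%
    dplyr::summarise(bitscore = max(.data$bitscore), .groups = "drop") %>%
    tidyr::pivot_wider(names_from = "side", values_from = "bitscore")
  if (!"gene" %in% names(best)) best$gene <- NA_real_
  if (!"TE" %in% names(best)) best$TE <- NA_real_
  if (!is.null(queries)) {
    best <- dplyr::left_join(tibble::tibble(query_id = queries), best,
                             by = "query_id")
  }
  g <- best$gene
  t <- best$TE
  label <- dplyr::case_when(
    is.na(g) & !is.na(t) & t > bitscore_min ~ "TE",
    is.na(t) & !is.na(g) & g > bitscore_min ~ "gene",
    !is.na(g) & !is.na(t) & g >= ratio_min * t ~ "gene",
    !is.na(g) & !is.na(t) & t >= ratio_min * g ~ "TE",
    !is.na(g) & !is.na(t) ~ "ambiguous",
    TRUE ~ "neither"
  )
  tibble::tibble(query_id = best$query_id, gene_bitscore = g,
                 te_bitscore = t, label = label)
}
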