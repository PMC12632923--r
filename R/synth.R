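# The synthetic snmCT-seq generator. One call to simulate_dataset() yields
# per-nucleus methylation calls, an RNA count matrix, the region bundle and
# ground-truth labels, all reproducible from the config seed.

sim_gene_table <- function(config) {
  rna <- config$rna
  clusters <- config$clusters
  markers <- purrr::map_dfr(clusters, function(cl) {
    tibble::tibble(
      gene_id = sprintf("MK_%s_%d", gsub("[^A-Za-z0-9]", "", cl),
                        seq_len(rna$markers_per_cluster)),
      marker_of = cl, is_organelle = FALSE
    )
  })
  background <- tibble::tibble(
    gene_id = sprintf("BG_%04d", seq_len(rna$n_background_genes)),
    marker_of = NA_character_, is_organelle = FALSE
  )
  organelle <- tibble::tibble(
    gene_id = c(sprintf("CP_%02d", seq_len(rna$n_chloro_genes)),
                sprintf("MT_%02d", seq_len(rna$n_mito_genes))),
    marker_of = NA_character_, is_organelle = TRUE
  )
  dplyr::bind_rows(markers, background, organelle)
}

sim_gene_weights <- function(genes, config, cluster) {
  rna <- config$rna
  w <- rep(1, nrow(genes))
  w[genes$is_organelle] <- rna$organelle_gene_weight
  w[!is.na(genes$marker_of) & genes$marker_of == cluster] <- rna$marker_weight
  w
}

sim_tss_table <- function(config, genes) {
  nuclear <- config$genome[!config$genome$is_organelle, ]
  nuc_genes <- genes$gene_id[!genes$is_organelle]
  n <- length(nuc_genes)
  alloc <- floor(n * nuclear$length / sum(nuclear$length))
  while (sum(alloc) < n) alloc[1] <- alloc[1] + 1
  rows <- purrr::map_dfr(seq_len(nrow(nuclear)), function(i) {
    k <- alloc[i]
    if (k == 0) return(NULL)
    tibble::tibble(chrom = nuclear$chrom[i],
                   tss = as.integer(floor((seq_len(k) - 0.5) / k * nuclear$length[i])) + 1L)
  })
  tibble::tibble(
    transcript_id = nuc_genes,
    chrom = rows$chrom,
    tss = rows$tss,
    strand = rep(c("+", "-"), length.out = n)
  )
}

#' Simulate a pollen snmCT-seq dataset with ground truth
#'
#' Generates singleton nuclei for every cluster x genotype combination:
#' each lattice cytosine is covered with the nucleus's coverage probability
#' (Bernoulli; plastid sites boosted by copy number), covered sites carry
#' one read whose methylation state is Bernoulli in the per-site rate for
#' that (region class, context, cluster, genotype), and a small
#' coverage-proportional fraction of sites receives a residual second read.
#' Conversion-failure nuclei have all apparent rates inflated; RNA counts
#' are multinomial over genes with cluster-specific marker weights and a
#' log-normal library size. When `config$doublet_rate > 0`, mature-VN + SN
#' doublets are injected by site-wise coverage summation via
#' [inject_doublets()].
#'
#' @param config A [sim_config()].
#' @return A list of class `snmct_sim`: `calls` (long methylation call
#'   tibble with `nucleus` column), `counts` (genes x nuclei), `regions`
#'   (named region-set bundle incl. `region_truth`), `truth` (per-nucleus
#'   tibble: cluster, genotype, is_doublet, conversion_failed), `panel`
#'   (marker panel), `genes` (gene metadata), `tss`, `genome`, `config`.
#' @export
simulate_dataset <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  regions <- build_region_layout(config)
  lattice <- build_site_lattice(config, regions)
  genes <- sim_gene_table(config)
  panel <- marker_panel(
    tibble::tibble(cluster = genes$marker_of[!is.na(genes$marker_of)],
                   gene = genes$gene_id[!is.na(genes$marker_of)])
  )

  n_sites <- nrow(lattice)
  combos <- expand.grid(cluster = config$clusters, genotype = config$genotypes,
                        stringsAsFactors = FALSE)
  rate_cache <- lapply(seq_len(nrow(combos)), function(i) {
    site_rates(lattice, config, combos$cluster[i], combos$genotype[i])
  })

  base_cov_mult <- rep(1, n_sites)
  base_cov_mult[lattice$chloro] <- config$plastid_cov_boost

  nuc_meta <- purrr::map_dfr(seq_len(nrow(combos)), function(i) {
    tibble::tibble(
      cluster = combos$cluster[i], genotype = combos$genotype[i],
      rep = seq_len(config$n_per_cluster), combo = i
    )
  })
  nuc_meta$nucleus <- sprintf("N%05d_%s_%s", seq_len(nrow(nuc_meta)),
                              gsub("[^A-Za-z0-9]", "", nuc_meta$cluster),
                              gsub("[^A-Za-z0-9]", "", nuc_meta$genotype))
  n_nuc <- nrow(nuc_meta)
  nuc_meta$coverage <- stats::runif(n_nuc, config$coverage_range[1],
                                    config$coverage_range[2])
  nuc_meta$conversion_failed <- stats::runif(n_nuc) < config$conv_fail_rate
  nuc_meta$conv_magnitude <- ifelse(
    nuc_meta$conversion_failed,
    stats::runif(n_nuc, config$conv_fail_range[1], config$conv_fail_range[2]),
    0
  )

  idx_list <- vector("list", n_nuc)
  mc_list <- vector("list", n_nuc)
  cov_list <- vector("list", n_nuc)
  counts <- matrix(0L, nrow = nrow(genes), ncol = n_nuc,
                   dimnames = list(genes$gene_id, nuc_meta$nucleus))
  for (k in seq_len(n_nuc)) {
    c_n <- nuc_meta$coverage[k]
    p_cov <- pmin(c_n * base_cov_mult, 1)
    if (config$gn_diploid && nuc_meta$cluster[k] == "GN") {
      # two genome copies, each covered independently (post S-phase)
      c1 <- stats::runif(n_sites) < p_cov
      c2 <- stats::runif(n_sites) < p_cov
      covered <- which(c1 | c2)
      copies <- (c1 + c2)[covered]
    } else {
      covered <- which(stats::runif(n_sites) < p_cov)
      copies <- rep(1L, length(covered))
    }
    rate <- rate_cache[[nuc_meta$combo[k]]][covered]
    if (nuc_meta$conv_magnitude[k] > 0) {
      rate <- rate + (1 - rate) * nuc_meta$conv_magnitude[k]
    }
    m <- length(covered)
    mc <- stats::rbinom(m, copies, rate)
    cov <- as.integer(copies)
    dup <- stats::runif(m) < config$residual_multi_rate * c_n
    if (any(dup)) {
      cov[dup] <- cov[dup] + 1L
      mc[dup] <- mc[dup] + stats::rbinom(sum(dup), 1L, rate[dup])
    }
    idx_list[[k]] <- covered
    mc_list[[k]] <- mc
    cov_list[[k]] <- cov

    w <- sim_gene_weights(genes, config, nuc_meta$cluster[k])
    lib <- max(200L, as.integer(round(stats::rlnorm(
      1, config$rna$libsize_meanlog, config$rna$libsize_sdlog))))
    counts[, k] <- as.integer(stats::rmultinom(1, lib, prob = w))
  }

  lens <- lengths(idx_list)
  idx <- unlist(idx_list, use.names = FALSE)
  calls <- tibble::tibble(
    nucleus = rep(nuc_meta$nucleus, lens),
    chrom = lattice$chrom[idx],
    pos = lattice$pos[idx],
    strand = lattice$strand[idx],
    context = lattice$context[idx],
    mc = unlist(mc_list, use.names = FALSE),
    cov = unlist(cov_list, use.names = FALSE)
  )

  truth <- tibble::tibble(
    nucleus = nuc_meta$nucleus,
    cluster = nuc_meta$cluster,
    genotype = nuc_meta$genotype,
    is_doublet = FALSE,
    conversion_failed = nuc_meta$conversion_failed
  )

  out <- list(
    calls = calls, counts = counts, regions = regions, truth = truth,
    panel = panel, genes = genes, tss = sim_tss_table(config, genes),
    genome = config$genome, config = config
  )
  class(out) <- "snmct_sim"
  if (config$doublet_rate > 0) {
    out <- inject_doublets(out, rate = config$doublet_rate,
                           seed = sample.int(.Machine$integer.max - 1, 1))
  }
  out
}

#' @export
print.snmct_sim <- function(x, ...) {
  cat(sprintf(
    "<snmct_sim> %d nuclei (%d doublets, %d conversion failures), %s call records, %d genes\n",
    nrow(x$truth), sum(x$truth$is_doublet), sum(x$truth$conversion_failed),
    format(nrow(x$calls), big.mark = ","), nrow(x$counts)
  ))
  invisible(x)
}

#' Inject mature-VN + SN doublets by coverage summation
#'
#' Picks donor pairs (by default a mature VN and an SN of the same
#' genotype), replaces each pair with one doublet nucleus whose methylation
#' table is the site-wise sum of the donors' (mc, cov) - so sites covered in
#' both donors reach coverage 2, the signature the coverage filter detects -
#' and whose RNA counts are the element-wise sum. Donors are removed and the
#' truth labels updated. Total read counts are conserved per pair.
#'
#' @param sim An `snmct_sim` object.
#' @param rate Fraction of current nuclei to convert into doublets
#'   (`n_doublets = round(rate * n_nuclei)`).
#' @param pair_rule Named list with `from` and `to` cluster label sets; each
#'   pair takes one donor from each side (same genotype).
#' @param seed Integer seed for donor sampling.
#' @return The modified `snmct_sim`.
#' @export
inject_doublets <- function(sim, rate,
                            pair_rule = list(from = c("VN4", "VN5"), to = "SN"),
                            seed = 1) {
  stopifnot(inherits(sim, "snmct_sim"), rate >= 0, rate <= 1)
  if (rate == 0) return(sim)
  n_doub <- round(rate * nrow(sim$truth))
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)

  singles <- sim$truth[!sim$truth$is_doublet, ]
  pairs <- purrr::map_dfr(unique(singles$genotype), function(gt) {
    from_pool <- singles$nucleus[singles$genotype == gt &
                                   singles$cluster %in% pair_rule$from]
    to_pool <- singles$nucleus[singles$genotype == gt &
                                 singles$cluster %in% pair_rule$to]
    k <- min(length(from_pool), length(to_pool))
    tibble::tibble(genotype = gt,
                   from = sample(from_pool, k),
                   to = sample(to_pool, k))
  })
  if (nrow(pairs) < n_doub) {
    stop(sprintf("cannot form %d doublets: only %d donor pairs available",
                 n_doub, nrow(pairs)))
  }
  pairs <- pairs[sample.int(nrow(pairs), n_doub), , drop = FALSE]
  pairs$doublet <- sprintf("DBL%04d_%s", seq_len(n_doub),
                           gsub("[^A-Za-z0-9]", "", pairs$genotype))

  donor_map <- stats::setNames(
    rep(pairs$doublet, 2), c(pairs$from, pairs$to)
  )
  donors <- names(donor_map)

  donor_calls <- sim$calls[sim$calls$nucleus %in% donors, , drop = FALSE]
  donor_calls$nucleus <- unname(donor_map[donor_calls$nucleus])
  doublet_calls <- donor_calls %>%
    dplyr::group_by(.data$nucleus, .data$chrom, .data$pos, .data$strand,
                    .data$context) %>%
    dplyr::summarise(mc = sum(.data$mc), cov = sum(.data$cov), .groups = "drop")

  keep_calls <- sim$calls[!sim$calls$nucleus %in% donors, , drop = FALSE]
  sim$calls <- dplyr::bind_rows(keep_calls, doublet_calls)

  doublet_counts <- sim$counts[, pairs$from, drop = FALSE] +
    sim$counts[, pairs$to, drop = FALSE]
  colnames(doublet_counts) <- pairs$doublet
  sim$counts <- cbind(sim$counts[, !colnames(sim$counts) %in% donors, drop = FALSE],
                      doublet_counts)

  donor_truth <- sim$truth[match(donors, sim$truth$nucleus), ]
  doublet_truth <- tibble::tibble(
    nucleus = pairs$doublet,
    cluster = "VN and SN",
    genotype = pairs$genotype,
    is_doublet = TRUE,
    conversion_failed = donor_truth$conversion_failed[match(pairs$from, donors)] |
      donor_truth$conversion_failed[match(pairs$to, donors)]
  )
  sim$truth <- dplyr::bind_rows(
    sim$truth[!sim$truth$nucleus %in% donors, ], doublet_truth
  )
  sim
}

#' Simulate a bulk pollen TPM matrix with known rescue labels
#'
#' Transcripts upregulated in the double mutant are given a wild-type
#' baseline, an elevated `mbd5/6` level, an `mbd7` level equal to wild type,
#' and an `mbd5/6/7` level equal to wild type (rescued), midway (partially
#' rescued) or equal to `mbd5/6` (not rescued), with multiplicative
#' log-normal noise.
#'
#' @param n_transcripts Number of upregulated transcripts.
#' @param label_probs Named probabilities over
#'   `c(rescued, partially_rescued, not_rescued)`.
#' @param n_reps Replicates per genotype.
#' @param fold `mbd5/6` fold change over wild type.
#' @param noise_sdlog Log-normal noise sd (0 = noise-free).
#' @param seed Integer seed.
#' @return List with `tpm` (matrix), `samples` (tibble `sample`,
#'   `genotype`), `truth` (tibble `transcript_id`, `rescue_label`).
#' @export
simulate_bulk_tpm <- function(n_transcripts = 200,
                              label_probs = c(rescued = 0.5,
                                              partially_rescued = 0.2,
                                              not_rescued = 0.3),
                              n_reps = 3, fold = 8, noise_sdlog = 0.2,
                              seed = 1) {
  stopifnot(abs(sum(label_probs) - 1) < 1e-8, n_reps >= 2)
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  labels <- sample(names(label_probs), n_transcripts, replace = TRUE,
                   prob = label_probs)
  tx <- sprintf("TX_%04d", seq_len(n_transcripts))
  wt <- stats::rlnorm(n_transcripts, log(2), 0.5)
  m56 <- wt * fold
  m567 <- dplyr::case_when(
    labels == "rescued" ~ wt,
    labels == "partially_rescued" ~ (wt + m56) / 2,
    TRUE ~ m56
  )
  genotypes <- c("WT", "mbd5/6", "mbd7", "mbd5/6/7")
  base <- cbind(WT = wt, `mbd5/6` = m56, mbd7 = wt, `mbd5/6/7` = m567)
  samples <- tibble::tibble(
    sample = paste0(rep(gsub("[^A-Za-z0-9]", "", genotypes), each = n_reps),
                    "_r", rep(seq_len(n_reps), length(genotypes))),
    genotype = rep(genotypes, each = n_reps)
  )
  tpm <- base[, samples$genotype, drop = FALSE]
  colnames(tpm) <- samples$sample
  rownames(tpm) <- tx
  if (noise_sdlog > 0) {
    tpm <- tpm * matrix(stats::rlnorm(length(tpm), 0, noise_sdlog),
                        nrow = nrow(tpm))
  }
  list(tpm = tpm, samples = samples,
       truth = tibble::tibble(transcript_id = tx, rescue_label = labels))
}
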