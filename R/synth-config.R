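# Configuration of the synthetic pollen snmCT-seq generator. The defaults
# are the study conditions every recovery experiment in the package runs
# under; they encode the qualitative dynamics of the system (VN-trajectory
# CG/CHG loss at CG-hypo DMRs plateauing mid-trajectory, progressive
# pericentromeric CHH gain, mbd5/6 demethylation at MBD6-bound CG-hypo
# regions in VN with mbd7-dependent rescue at a labelled subset) with
# documented free effect sizes. See the methods vignette for the rationale
# behind each number.

#' Default synthetic genome
#'
#' Two nuclear chromosomes of about a megabase plus chloroplast and
#' mitochondrion at their real Arabidopsis sizes (plastid coverage behaviour
#' matters for conversion QC).
#'
#' @return A [genome_spec()].
#' @export
sim_genome <- function() {
  genome_spec(c(Chr1 = 600000, Chr2 = 500000, ChrC = 154478, ChrM = 366924))
}

#' Build a simulation configuration
#'
#' All randomness in [simulate_dataset()] flows from `seed`. Rates are
#' per-site Bernoulli methylation probabilities; coverage is Bernoulli per
#' site per nucleus (haploid, post-deduplication), with a plastid copy-number
#' boost for the chloroplast and a small coverage-proportional residual
#' multi-coverage rate that gives the doublet filter a realistic null trend.
#'
#' @param seed Integer seed.
#' @param genome A [genome_spec()] with at least two nuclear chromosomes
#'   and a chloroplast.
#' @param n_per_cluster Singleton nuclei per cluster per genotype.
#' @param genotypes Subset of `c("WT", "mbd5/6", "mbd5/6/7", "mbd7")`.
#' @param coverage_range Per-nucleus site coverage probability, drawn
#'   uniformly from this range.
#' @param plastid_cov_boost Multiplier on the coverage probability for
#'   chloroplast sites (plastid copy number).
#' @param residual_multi_rate Baseline for the per-site probability of a
#'   residual second read in a singleton: `rate * coverage_prob`.
#' @param doublet_rate Fraction of nuclei converted into mature-VN + SN
#'   doublets by coverage summation (0 disables).
#' @param conv_fail_rate Fraction of nuclei with failed bisulfite
#'   conversion.
#' @param conv_fail_range Apparent methylation inflation for failed nuclei
#'   (uniform draw per nucleus).
#' @param chloro_background_me Apparent organelle methylation of clean
#'   nuclei (conversion error floor).
#' @param flat_rate If non-`NULL`, overrides every nuclear site rate with
#'   this constant (degenerate configurations for testing).
#' @param gn_diploid Give GN nuclei two independently covered genome copies
#'   (post S-phase)?
#' @param rates Named list of trajectory/background rates; see
#'   `sim_rates()` for the defaults.
#' @param layout Named list of region-layout sizes; see `sim_layout()`.
#' @param rna Named list of RNA parameters; see `sim_rna()`.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       genome = sim_genome(),
                       n_per_cluster = 200,
                       genotypes = c("WT", "mbd5/6", "mbd5/6/7"),
                       coverage_range = c(0.02, 0.08),
                       plastid_cov_boost = 10,
                       residual_multi_rate = 0.05,
                       doublet_rate = 0.05,
                       conv_fail_rate = 0.02,
                       conv_fail_range = c(0.2, 0.4),
                       chloro_background_me = 0.005,
                       flat_rate = NULL,
                       gn_diploid = FALSE,
                       rates = sim_rates(),
                       layout = sim_layout(),
                       rna = sim_rna()) {
  assert_genome(genome)
  if (sum(!genome$is_organelle) < 2) stop("need at least two nuclear chromosomes")
  stopifnot(
    n_per_cluster >= 1,
    all(genotypes %in% c("WT", "mbd5/6", "mbd5/6/7", "mbd7")),
    length(coverage_range) == 2, all(coverage_range > 0), all(coverage_range <= 1),
    doublet_rate >= 0, doublet_rate <= 1,
    conv_fail_rate >= 0, conv_fail_rate <= 1,
    all(conv_fail_range >= 0), all(conv_fail_range <= 1),
    chloro_background_me >= 0, chloro_background_me <= 1
  )
  rate_vals <- unlist(rates[c("cg_hypo_traj", "chg_hypo_traj", "chh_hyper_traj",
                              "chh_peri_traj")])
  stopifnot(all(rate_vals >= 0), all(rate_vals <= 1))
  out <- list(
    seed = as.integer(seed), genome = genome,
    clusters = pollen_ontology(), n_per_cluster = n_per_cluster,
    genotypes = genotypes, coverage_range = coverage_range,
    plastid_cov_boost = plastid_cov_boost,
    residual_multi_rate = residual_multi_rate,
    doublet_rate = doublet_rate, conv_fail_rate = conv_fail_rate,
    conv_fail_range = conv_fail_range,
    chloro_background_me = chloro_background_me,
    flat_rate = flat_rate, gn_diploid = gn_diploid,
    rates = rates, layout = layout, rna = rna
  )
  class(out) <- "sim_config"
  out
}

#' @rdname sim_config
#' @param mbd56_factor Multiplicative reduction of CG/CHG rates at
#'   MBD6-peak-on-CG-hypo-DMR sites in VN clusters for `mbd5/6` (and for
#'   `mbd5/6/7` at not-rescued regions).
#' @export
sim_rates <- function(mbd56_factor = 0.5) {
  cl <- pollen_ontology()
  named <- function(x) stats::setNames(x, cl)
  list(
    # CG at CG-hypo DMRs: active demethylation in immature VN, plateau by VN3
    cg_hypo_traj = named(c(0.80, 0.65, 0.50, 0.40, 0.32, 0.30, 0.30, 0.30, 0.80, 0.85)),
    # CHG follows CG loss at the same regions, more mildly
    chg_hypo_traj = named(c(0.40, 0.34, 0.30, 0.27, 0.25, 0.25, 0.25, 0.25, 0.40, 0.42)),
    # CHH at CHH-hyper DMRs: progressive gain along the VN trajectory
    chh_hyper_traj = named(c(0.05, 0.10, 0.15, 0.20, 0.25, 0.30, 0.35, 0.40, 0.05, 0.04)),
    # pericentromeric CHH background also gains progressively in VN
    chh_peri_traj = named(c(0.08, 0.11, 0.14, 0.17, 0.20, 0.23, 0.26, 0.30, 0.08, 0.06)),
    cg_arm = 0.30, cg_peri = 0.85,
    chg_arm = 0.10, chg_peri = 0.60,
    chh_arm = 0.03,
    mbd56_factor = mbd56_factor,
    vn_clusters = c("VN1", "VN1to2", "VN2", "VN3", "VN4", "VN5")
  )
}

#' @rdname sim_config
#' @export
sim_layout <- function() {
  list(
    peri_frac = 0.30,              # centred fraction of each nuclear chrom
    n_cg_hypo_dmr = 50, cg_hypo_width = 2000,
    n_chh_hyper_dmr = 40, chh_hyper_width = 1500,
    n_mbd6_peaks = 60, mbd6_width = 1000, mbd6_on_dmr_frac = 0.6,
    n_mbd7_peaks = 40, mbd7_width = 800, mbd7_on_mbd6_frac = 0.5,
    rescued_frac = 0.6,            # of MBD6-on-DMR regions
    site_spacing = c(CG = 150, CHG = 150, CHH = 60),
    organelle_spacing = c(ChrC = 500, ChrM = 800)
  )
}

#' @rdname sim_config
#' @export
sim_rna <- function() {
  list(
    n_background_genes = 240,
    markers_per_cluster = 5,
    marker_weight = 20,
    n_chloro_genes = 6, n_mito_genes = 4,
    organelle_gene_weight = 1.2,
    libsize_meanlog = log(3000), libsize_sdlog = 0.3
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "<sim_config> seed %d; %d clusters x %d nuclei x %d genotype(s); doublets %.0f%%, conversion failures %.0f%%\n",
    x$seed, length(x$clusters), x$n_per_cluster, length(x$genotypes),
    100 * x$doublet_rate, 100 * x$conv_fail_rate
  ))
  invisible(x)
}

# ---- region layout -----------------------------------------------------

pericentromere_spans <- function(genome, peri_frac) {
  g <- genome[!genome$is_organelle, ]
  tibble::tibble(
    chrom = g$chrom,
    start = floor(g$length * (1 - peri_frac) / 2),
    end = ceiling(g$length * (1 + peri_frac) / 2),
    id = paste0("peri_", g$chrom),
    score = NA_real_
  )
}

arm_spans <- function(genome, peri) {
  g <- genome[!genome$is_organelle, ]
  purrr::map_dfr(seq_len(nrow(g)), function(i) {
    p <- peri[peri$chrom == g$chrom[i], ]
    tibble::tibble(
      chrom = g$chrom[i],
      start = c(0, p$end),
      end = c(p$start, g$length[i])
    )
  })
}

# Deterministically place n non-overlapping width-w intervals across spans,
# proportionally to span length, each centred in its slot.
place_evenly <- function(spans, n, width, prefix) {
  if (n == 0) {
    return(region_set(character(), numeric(), numeric()))
  }
  lens <- spans$end - spans$start
  alloc <- floor(n * lens / sum(lens))
  while (sum(alloc) < n) alloc[which.max(lens / (alloc + 1))] <- alloc[which.max(lens / (alloc + 1))] + 1
  rows <- purrr::map_dfr(seq_len(nrow(spans)), function(i) {
    k <- alloc[i]
    if (k == 0) return(NULL)
    slot <- lens[i] / k
    if (slot < width) stop("spans too small for requested regions")
    centre <- spans$start[i] + (seq_len(k) - 0.5) * slot
    tibble::tibble(chrom = spans$chrom[i],
                   start = floor(centre - width / 2),
                   end = floor(centre - width / 2) + width)
  })
  region_set(rows$chrom, rows$start, rows$end,
             id = paste0(prefix, "_", seq_len(nrow(rows))))
}

# Gaps of `spans` not covered by `occupied` (with a safety margin).
span_gaps <- function(spans, occupied, margin = 200) {
  purrr::map_dfr(seq_len(nrow(spans)), function(i) {
    occ <- occupied[occupied$chrom == spans$chrom[i] &
                      occupied$end > spans$start[i] &
                      occupied$start < spans$end[i], , drop = FALSE]
    if (nrow(occ) == 0) {
      return(spans[i, c("chrom", "start", "end")])
    }
    occ <- occ[order(occ$start), ]
    starts <- c(spans$start[i], occ$end + margin)
    ends <- c(occ$start - margin, spans$end[i])
    keep <- ends - starts > 0
    tibble::tibble(chrom = spans$chrom[i], start = starts[keep], end = ends[keep])
  })
}

# Build the full region bundle for a config. Deterministic (no RNG).
build_region_layout <- function(config) {
  genome <- config$genome
  lay <- config$layout
  peri <- pericentromere_spans(genome, lay$peri_frac)
  arms <- arm_spans(genome, peri)

  cg_hypo <- place_evenly(arms, lay$n_cg_hypo_dmr, lay$cg_hypo_width, "cghypo")
  chh_hyper <- place_evenly(peri[, c("chrom", "start", "end")],
                            lay$n_chh_hyper_dmr, lay$chh_hyper_width, "chhhyper")

  n_on <- round(lay$n_mbd6_peaks * lay$mbd6_on_dmr_frac)
  n_off <- lay$n_mbd6_peaks - n_on
  host <- cg_hypo[seq_len(min(n_on, nrow(cg_hypo))), ]
  on_centre <- (host$start + host$end) / 2
  mbd6_on <- region_set(host$chrom, floor(on_centre - lay$mbd6_width / 2),
                        floor(on_centre - lay$mbd6_width / 2) + lay$mbd6_width,
                        id = paste0("mbd6_", seq_len(nrow(host))))
  gaps <- span_gaps(arms, cg_hypo)
  gaps <- gaps[gaps$end - gaps$start > 4 * lay$mbd6_width, ]
  mbd6_off <- place_evenly(gaps, n_off, lay$mbd6_width, "mbd6off")
  mbd6_off$id <- paste0("mbd6_", nrow(mbd6_on) + seq_len(nrow(mbd6_off)))
  mbd6 <- dplyr::bind_rows(mbd6_on, mbd6_off)

  n7_on <- round(lay$n_mbd7_peaks * lay$mbd7_on_mbd6_frac)
  host7 <- mbd6[seq_len(min(n7_on, nrow(mbd6))), ]
  c7 <- (host7$start + host7$end) / 2
  mbd7_on <- region_set(host7$chrom, floor(c7 - lay$mbd7_width / 2),
                        floor(c7 - lay$mbd7_width / 2) + lay$mbd7_width,
                        id = paste0("mbd7_", seq_len(nrow(host7))))
  gaps7 <- span_gaps(arms, dplyr::bind_rows(cg_hypo, mbd6))
  gaps7 <- gaps7[gaps7$end - gaps7$start > 4 * lay$mbd7_width, ]
  mbd7_off <- place_evenly(gaps7, lay$n_mbd7_peaks - nrow(mbd7_on),
                           lay$mbd7_width, "mbd7off")
  mbd7_off$id <- paste0("mbd7_", nrow(mbd7_on) + seq_len(nrow(mbd7_off)))
  mbd7 <- dplyr::bind_rows(mbd7_on, mbd7_off)

  # MBD6-peak-on-CG-hypo-DMR regions carry the genotype effect and a rescue
  # label; the first rescued_frac are restored in mbd5/6/7
  mbd6_hypo <- mbd6_on
  n_res <- round(nrow(mbd6_hypo) * lay$rescued_frac)
  rescue <- rep("not_rescued", nrow(mbd6_hypo))
  rescue[seq_len(n_res)] <- "rescued"
  mbd6_hypo$rescue_label <- rescue

  region_truth <- dplyr::bind_rows(
    tibble::tibble(id = cg_hypo$id, class = "cg_hypo_dmr", rescue_label = NA_character_),
    tibble::tibble(id = chh_hyper$id, class = "chh_hyper_dmr", rescue_label = NA_character_),
    tibble::tibble(id = mbd6$id, class = "mbd6_peak", rescue_label = NA_character_),
    tibble::tibble(id = mbd7$id, class = "mbd7_peak", rescue_label = NA_character_),
    tibble::tibble(id = paste0("m6h_", mbd6_hypo$id), class = "mbd6_hypo",
                   rescue_label = mbd6_hypo$rescue_label)
  )

  list(
    pericentromere = peri,
    cg_hypo_dmr = cg_hypo,
    chh_hyper_dmr = chh_hyper,
    mbd6_peaks = mbd6,
    mbd7_peaks = mbd7,
    mbd6_hypo = mbd6_hypo,
    region_truth = region_truth
  )
}

# ---- site lattice ------------------------------------------------------

# Regular lattice of cytosine sites with context, strand and region-class
# annotations used to look up per-site methylation rates.
build_site_lattice <- function(config, regions) {
  genome <- config$genome
  lay <- config$layout
  nuclear <- genome[!genome$is_organelle, ]
  parts <- list()
  for (ctx in c("CG", "CHG", "CHH")) {
    sp <- lay$site_spacing[[ctx]]
    for (i in seq_len(nrow(nuclear))) {
      pos <- seq.int(sp %/% 2 + 1L, nuclear$length[i], by = sp)
      parts[[length(parts) + 1L]] <- tibble::tibble(
        chrom = nuclear$chrom[i], pos = as.integer(pos), context = ctx
      )
    }
  }
  org <- genome[genome$is_organelle, ]
  for (i in seq_len(nrow(org))) {
    sp <- lay$organelle_spacing[[org$chrom[i]]]
    if (is.null(sp) || is.na(sp)) sp <- 500
    for (ctx in c("CG", "CHG", "CHH")) {
      pos <- seq.int(sp %/% 2 + 1L + match(ctx, c("CG", "CHG", "CHH")),
                     org$length[i], by = sp)
      parts[[length(parts) + 1L]] <- tibble::tibble(
        chrom = org$chrom[i], pos = as.integer(pos), context = ctx
      )
    }
  }
  lat <- dplyr::bind_rows(parts) %>% dplyr::arrange(.data$chrom, .data$pos)
  lat$strand <- ifelse(lat$pos %% 2 == 0, "+", "-")
  lat$organelle <- lat$chrom %in% genome$chrom[genome$is_organelle]
  lat$chloro <- lat$chrom %in% genome$chrom[genome$is_organelle &
                                              grepl("c$", genome$chrom, ignore.case = TRUE)]
  lat$peri <- sites_in_regions(lat, regions$pericentromere) & !lat$organelle
  lat$hypo <- sites_in_regions(lat, regions$cg_hypo_dmr)
  lat$chh_dmr <- sites_in_regions(lat, regions$chh_hyper_dmr)
  rescued_regions <- regions$mbd6_hypo[regions$mbd6_hypo$rescue_label == "rescued", ]
  notres_regions <- regions$mbd6_hypo[regions$mbd6_hypo$rescue_label == "not_rescued", ]
  lat$mbd6_hypo_rescued <- sites_in_regions(lat, rescued_regions)
  lat$mbd6_hypo_notres <- sites_in_regions(lat, notres_regions)
  lat
}

# Per-site Bernoulli methylation rate for one (cluster, genotype).
site_rates <- function(lattice, config, cluster, genotype) {
  r <- config$rates
  n <- nrow(lattice)
  rate <- numeric(n)

  cg <- lattice$context == "CG" & !lattice$organelle
  chg <- lattice$context == "CHG" & !lattice$organelle
  chh <- lattice$context == "CHH" & !lattice$organelle
  rate[cg] <- ifelse(lattice$hypo[cg], r$cg_hypo_traj[[cluster]],
                     ifelse(lattice$peri[cg], r$cg_peri, r$cg_arm))
  rate[chg] <- ifelse(lattice$hypo[chg], r$chg_hypo_traj[[cluster]],
                      ifelse(lattice$peri[chg], r$chg_peri, r$chg_arm))
  rate[chh] <- ifelse(lattice$chh_dmr[chh], r$chh_hyper_traj[[cluster]],
                      ifelse(lattice$peri[chh], r$chh_peri_traj[[cluster]], r$chh_arm))

  vn <- cluster %in% r$vn_clusters
  if (vn && genotype %in% c("mbd5/6", "mbd5/6/7")) {
    eff_sites <- (cg | chg) &
      (lattice$mbd6_hypo_notres |
         (genotype == "mbd5/6" & lattice$mbd6_hypo_rescued))
    rate[eff_sites] <- rate[eff_sites] * r$mbd56_factor
  }
  if (!is.null(config$flat_rate)) rate[!lattice$organelle] <- config$flat_rate
  rate[lattice$organelle] <- config$chloro_background_me
  rate
}
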