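# The generator: degenerate configurations, determinism, doublet summation
# semantics, conservation laws, and convergence of empirical rates to the
# configured ones.

test_that("degenerate configurations behave as specified", {
  # rate 1 and full coverage: every covered nuclear site is mc = cov
  cfg <- sim_config(seed = 21, n_per_cluster = 2, genotypes = "WT",
                    doublet_rate = 0, conv_fail_rate = 0,
                    coverage_range = c(1, 1), flat_rate = 1,
                    residual_multi_rate = 0, chloro_background_me = 0)
  sim <- simulate_dataset(cfg)
  nuclear <- sim$calls[!sim$calls$chrom %in% c("ChrC", "ChrM"), ]
  expect_true(all(nuclear$mc == nuclear$cov))
  expect_true(all(sim$calls$mc[sim$calls$chrom %in% c("ChrC", "ChrM")] == 0))

  # no doublets, no conversion failures -> all truth labels clean
  sim2 <- simulate_dataset(small_sim_config(seed = 22))
  expect_true(all(!sim2$truth$is_doublet))
  expect_true(all(!sim2$truth$conversion_failed))
})

test_that("identical seeds give byte-identical datasets; different seeds differ", {
  a <- simulate_dataset(small_sim_config(seed = 23))
  b <- simulate_dataset(small_sim_config(seed = 23))
  expect_identical(a$calls, b$calls)
  expect_identical(a$counts, b$counts)
  expect_identical(a$truth, b$truth)

  c <- simulate_dataset(small_sim_config(seed = 24))
  expect_false(identical(a$calls, c$calls))
})

test_that("doublet injection sums site-wise and conserves read counts", {
  cfg <- sim_config(seed = 25, n_per_cluster = 10, genotypes = "WT",
                    doublet_rate = 0, conv_fail_rate = 0)
  sim <- simulate_dataset(cfg)
  before_mc <- sum(sim$calls$mc); before_cov <- sum(sim$calls$cov)
  before_rna <- sum(sim$counts)

  injected <- inject_doublets(sim, rate = 0.05, seed = 3)
  expect_equal(sum(injected$truth$is_doublet), round(0.05 * nrow(sim$truth)))
  expect_equal(sum(injected$calls$mc), before_mc)
  expect_equal(sum(injected$calls$cov), before_cov)
  expect_equal(sum(injected$counts), before_rna)

  # a site covered in both donors has cov 2
  dbl <- injected$truth$nucleus[injected$truth$is_doublet][1]
  dcalls <- injected$calls[injected$calls$nucleus == dbl, ]
  expect_true(any(dcalls$cov >= 2))

  # doublets carry a higher multi-coverage fraction than any singleton of
  # comparable total coverage (brute force over the dataset)
  qcm <- compute_nucleus_qc(injected$calls, injected$counts, injected$genome,
                            gene_meta = injected$genes)
  merged <- dplyr::inner_join(qcm, injected$truth, by = "nucleus")
  worst_singleton <- max(merged$f_multi[!merged$is_doublet])
  expect_true(all(merged$f_multi[merged$is_doublet] > worst_singleton))

  expect_identical(inject_doublets(sim, 0), sim)
  expect_error(inject_doublets(sim, rate = 0.45, seed = 3), "donor pairs")
})

test_that("empirical pseudobulk methylation converges to the configured rates", {
  # one cluster, many nuclei: empirical rate at CG-hypo DMRs must sit
  # within binomial error of the configured value
  cfg <- sim_config(seed = 26, n_per_cluster = 200, genotypes = "WT",
                    doublet_rate = 0, conv_fail_rate = 0)
  cfg$clusters <- c("MN", "VN2")  # keep runtime small
  sim <- simulate_dataset(cfg)
  groups <- dplyr::rename(sim$truth[, c("nucleus", "cluster")], label = "cluster")
  pooled <- pseudobulk_pool(sim$calls, groups)
  for (cl in c("MN", "VN2")) {
    trk <- pooled[pooled$label == cl, ]
    s <- region_weighted_methylation(trk, sim$regions$cg_hypo_dmr, "CG")
    m_cfg <- sim$config$rates$cg_hypo_traj[[cl]]
    tol <- 4 * sqrt(m_cfg * (1 - m_cfg) / sum(trk$context == "CG"))
    expect_lt(abs(s$avg_me - m_cfg), max(tol, 0.01))
  }
})

test_that("conversion failures show inflated apparent chloroplast methylation", {
  cfg <- sim_config(seed = 27, n_per_cluster = 20, genotypes = "WT",
                    doublet_rate = 0, conv_fail_rate = 0.15)
  sim <- simulate_dataset(cfg)
  qcm <- compute_nucleus_qc(sim$calls, sim$counts, sim$genome,
                            gene_meta = sim$genes)
  merged <- dplyr::inner_join(qcm, sim$truth, by = "nucleus")
  expect_gt(min(merged$chloro_me[merged$conversion_failed]), 0.15)
  expect_lt(max(merged$chloro_me[!merged$conversion_failed]), 0.05)
})

test_that("noise-free bulk TPM obeys the rescue design exactly", {
  sim0 <- simulate_bulk_tpm(n_transcripts = 30, noise_sdlog = 0, seed = 28)
  wt <- sim0$tpm[, sim0$samples$sample[sim0$samples$genotype == "WT"][1]]
  m567 <- sim0$tpm[, sim0$samples$sample[sim0$samples$genotype == "mbd5/6/7"][1]]
  m56 <- sim0$tpm[, sim0$samples$sample[sim0$samples$genotype == "mbd5/6"][1]]
  resc <- sim0$truth$rescue_label == "rescued"
  notr <- sim0$truth$rescue_label == "not_rescued"
  expect_equal(m567[resc], wt[resc])
  expect_equal(m567[notr], m56[notr])

  two_seeds <- simulate_bulk_tpm(n_transcripts = 30, seed = 29)
  expect_false(identical(two_seeds$tpm, simulate_bulk_tpm(n_transcripts = 30,
                                                          seed = 30)$tpm))
})

test_that("region layout is valid against the genome and labels every region once", {
  sim <- simulate_dataset(small_sim_config(seed = 31))
  for (nm in c("cg_hypo_dmr", "chh_hyper_dmr", "mbd6_peaks", "mbd7_peaks")) {
    rs <- sim$regions[[nm]]
    expect_true(all(rs$start >= 0 & rs$start < rs$end))
    lens <- sim$genome$length[match(rs$chrom, sim$genome$chrom)]
    expect_true(all(rs$end <= lens))
    expect_false(anyDuplicated(rs$id) > 0)
  }
  expect_equal(anyDuplicated(sim$regions$region_truth$id), 0L)
  expect_equal(anyDuplicated(sim$truth$nucleus), 0L)
})
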