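# Nucleus QC: boundary semantics of each filter, the Theil-Sen + MAD
# doublet rule on constructed fixtures, conversion censoring, and the
# marker-ratio reassignment window.

qc_row <- function(nucleus = "n1", rna_reads = 5000, genes_detected = 400,
                   wgbs_bin_frac = 0.5, organelle_rna_frac = 0.02,
                   sites_ge1 = 1000L, sites_gt1 = 0L,
                   chloro_sites = 100L, chloro_me = 0.005) {
  tibble::tibble(
    nucleus = nucleus, rna_reads = rna_reads, genes_detected = genes_detected,
    wgbs_bin_frac = wgbs_bin_frac, organelle_rna_frac = organelle_rna_frac,
    sites_ge1 = sites_ge1, sites_eq1 = sites_ge1 - sites_gt1,
    sites_gt1 = sites_gt1, f_multi = sites_gt1 / sites_ge1,
    chloro_sites = chloro_sites,
    chloro_mc = as.integer(round(chloro_me * chloro_sites)),
    chloro_cov = chloro_sites,
    chloro_me = chloro_me
  )
}

test_that("basic well filter is inclusive at its thresholds", {
  at <- qc_row(rna_reads = 1000, genes_detected = 200, wgbs_bin_frac = 0.10)
  expect_true(basic_well_filter(at)$pass_basic)

  low_rna <- basic_well_filter(qc_row(rna_reads = 999, genes_detected = 500,
                                      wgbs_bin_frac = 0.9))
  expect_false(low_rna$pass_basic)
  expect_equal(low_rna$basic_fail_reason, "rna_reads")

  expect_false(basic_well_filter(qc_row(genes_detected = 199))$pass_basic)
  expect_false(basic_well_filter(qc_row(wgbs_bin_frac = 0.0999))$pass_basic)

  broken <- qc_row(); broken$wgbs_bin_frac <- NA_real_
  expect_error(basic_well_filter(broken), "wgbs_bin_frac")
})

test_that("basic filter equals an independent three-clause conjunction on random fixtures", {
  set.seed(201)
  for (i in 1:100) {
    q <- qc_row(rna_reads = sample(0:2000, 1), genes_detected = sample(0:400, 1),
                wgbs_bin_frac = runif(1))
    got <- basic_well_filter(q)$pass_basic
    want <- (q$rna_reads >= 1000) && (q$genes_detected >= 200) &&
      (q$wgbs_bin_frac >= 0.10)
    expect_identical(got, want)
  }
})

test_that("organelle filter is strict at 10 percent", {
  expect_true(organelle_rna_filter(qc_row(organelle_rna_frac = 0.10))$pass_organelle)
  expect_false(organelle_rna_filter(qc_row(organelle_rna_frac = 0.11))$pass_organelle)
  expect_true(organelle_rna_filter(qc_row(organelle_rna_frac = 0))$pass_organelle)
})

test_that("doublet filter flags strong multi-coverage outliers and nothing when clean", {
  clean <- dplyr::bind_rows(lapply(1:30, function(i) {
    qc_row(nucleus = paste0("n", i), sites_ge1 = 1000L + 50L * i, sites_gt1 = 0L)
  }))
  fit <- coverage_doublet_filter(clean)
  expect_equal(fit$n_flagged, 0)

  # background trend: f_multi grows with coverage; one nucleus sits 10x
  # above the trend at its coverage
  set.seed(202)
  n <- 60
  sites <- as.integer(round(seq(2000, 8000, length.out = n)))
  f <- sites / 8000 * 0.002 + rnorm(n, 0, 1e-4)
  f <- pmax(f, 0)
  qcs <- dplyr::bind_rows(lapply(seq_len(n), function(i) {
    qc_row(nucleus = paste0("n", i), sites_ge1 = sites[i],
           sites_gt1 = as.integer(round(f[i] * sites[i])))
  }))
  qcs$f_multi[n] <- 10 * (sites[n] / 8000 * 0.002)
  qcs$sites_gt1[n] <- as.integer(round(qcs$f_multi[n] * sites[n]))
  for (k in c(2, 5)) {
    fit <- coverage_doublet_filter(qcs, k_mad = k)
    expect_true(fit$table$flagged_doublet[n])
  }
  # residual computed by hand against the reported fit
  fit <- coverage_doublet_filter(qcs, k_mad = 5)
  expect_equal(fit$table$residual[n],
               qcs$f_multi[n] - (fit$intercept + fit$slope * qcs$sites_ge1[n]))

  expect_error(coverage_doublet_filter(qcs[1:10, ]), "at least 20")
})

test_that("conversion filter censors inflated chloroplast methylation only", {
  qcs <- dplyr::bind_rows(lapply(1:40, function(i) {
    qc_row(nucleus = paste0("n", i), chloro_me = 0.005)
  }))
  qcs$chloro_me[17] <- 0.30
  qcs$chloro_mc[17] <- 30L
  out <- conversion_filter(qcs, method = "mad")
  expect_equal(which(out$conversion_status == "fail"), 17L)

  zero <- conversion_filter(qc_row(chloro_me = 0), method = "fixed")
  expect_equal(zero$conversion_status, "pass")
  # boundary is strictly greater for the fixed method
  at <- conversion_filter(qc_row(chloro_me = 0.02), method = "fixed",
                          threshold = 0.02)
  expect_equal(at$conversion_status, "pass")

  none <- qc_row(chloro_sites = 0L, chloro_me = NA_real_)
  out2 <- conversion_filter(dplyr::bind_rows(qcs, none), method = "fixed")
  expect_equal(out2$conversion_status[nrow(out2)], "indeterminate")
})

test_that("marker ratio relabels only mature VN/SN nuclei inside the inclusive window", {
  genes <- c("SNm1", "SNm2", "VNm1", "VNm2", "other")
  mk <- function(sn, vn, other = 100) {
    c(SNm1 = sn, SNm2 = sn, VNm1 = vn, VNm2 = vn, other = other)
  }
  counts <- cbind(
    equal = mk(50, 50), sn4x = mk(200, 50), mn_equal = mk(50, 50),
    edge = mk(50, 50)
  )
  rownames(counts) <- genes
  labels <- tibble::tibble(
    nucleus = colnames(counts),
    label = c("VN4", "SN", "MN", "VN5")
  )
  out <- marker_ratio_reassignment(counts, labels, c("SNm1", "SNm2"),
                                   c("VNm1", "VNm2"))
  expect_equal(out$label[out$nucleus == "equal"], "VN and SN")   # r = 0
  expect_equal(out$label[out$nucleus == "edge"], "VN and SN")
  expect_equal(out$label[out$nucleus == "sn4x"], "SN")           # r = 2
  expect_equal(out$label[out$nucleus == "mn_equal"], "MN")       # out of scope
  expect_true(is.na(out$marker_log2_ratio[out$nucleus == "mn_equal"]))
  expect_equal(out$marker_log2_ratio[out$nucleus == "equal"], 0)

  expect_error(marker_ratio_reassignment(counts, labels, character(), "VNm1"),
               "non-empty")
})

test_that("ratio window endpoints are inclusive", {
  # a nucleus whose observed ratio sits exactly at the window edge is
  # relabelled; shrinking the window below that value excludes it
  v <- 100
  s <- (v + 1) * 2^0.2 - 1  # ratio near +0.2 on the cp10k scale
  lib <- 1e4
  counts <- cbind(at = c(SN1 = s, VN1x = v, pad = lib - s - v))
  rownames(counts) <- c("SN1", "VN1x", "pad")
  labels <- tibble::tibble(nucleus = "at", label = "SN")
  probe <- marker_ratio_reassignment(counts, labels, "SN1", "VN1x",
                                     window = 10)
  r <- probe$marker_log2_ratio[1]
  expect_equal(r, 0.2, tolerance = 1e-6)
  at_edge <- marker_ratio_reassignment(counts, labels, "SN1", "VN1x",
                                       window = r)
  expect_equal(at_edge$label[1], "VN and SN")
  inside_only <- marker_ratio_reassignment(counts, labels, "SN1", "VN1x",
                                           window = r * (1 - 1e-9))
  expect_equal(inside_only$label[1], "SN")
})

test_that("the filter cascade assigns one primary reason and only narrows", {
  set.seed(203)
  sim <- simulate_dataset(small_sim_config(seed = 203))
  qcm <- compute_nucleus_qc(sim$calls, sim$counts, sim$genome,
                            gene_meta = sim$genes)
  expect_equal(qcm$sites_eq1 + qcm$sites_gt1, qcm$sites_ge1)
  expect_true(all(qcm$f_multi >= 0 & qcm$f_multi <= 1))
  out <- qc_filter_nuclei(qcm)
  expect_equal(nrow(out), nrow(qcm))
  expect_true(all(is.na(out$fail_reason) == (out$status == "pass")))
  # each censored nucleus has exactly one reason string
  expect_true(all(!grepl(";", stats::na.omit(out$fail_reason))))
})
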