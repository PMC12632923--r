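# Methylome aggregation: weighted means, pooling, binning, density,
# windows and metaprofiles, each checked against a naive per-site oracle.

test_that("region weighted methylation follows the pooled-count formula", {
  g <- tiny_genome()
  calls <- meth_calls(data.frame(
    chrom = "chr1", pos = c(10L, 20L, 30L), strand = "+", context = "CG",
    mc = c(1L, 0L, 2L), cov = c(1L, 1L, 2L)
  ), g)
  regions <- region_set("chr1", 0, 100, id = "r1")
  s <- region_weighted_methylation(calls, regions, "CG")
  expect_equal(s$avg_me, 0.75)
  expect_equal(s$n_sites, 3L)
  expect_equal(s$avg_cov, 4 / 3)

  all_me <- meth_calls(data.frame(chrom = "chr1", pos = c(5L, 6L), strand = "+",
                                  context = "CG", mc = 1L, cov = 1L), g)
  expect_equal(region_weighted_methylation(all_me, regions, "CG")$avg_me, 1.0)

  expect_error(region_weighted_methylation(calls, regions[0, ], "CG"), "empty")
  none <- region_weighted_methylation(calls, region_set("chr2", 0, 50), "CG")
  expect_equal(none$n_sites, 0L)
  expect_true(is.na(none$avg_me))
})

test_that("weighted region methylation matches the brute-force oracle on random fixtures", {
  set.seed(101)
  g <- tiny_genome()
  for (rep in 1:12) {
    calls <- random_calls(50, g)
    regions <- random_regions(sample(2:6, 1), g)
    ctx <- sample(c("CG", "CHG", "CHH"), 1)
    mincov <- sample(1:2, 1)
    got <- region_weighted_methylation(calls, regions, ctx, min_cov = mincov)
    want <- oracle_region_meth(calls, regions, ctx, min_cov = mincov)
    expect_equal(got$n_sites, want$n_sites)
    expect_equal(got$avg_me, want$avg_me)
    expect_equal(got$avg_cov, want$avg_cov)
  }
})

test_that("a site inside overlapping regions is counted once", {
  g <- tiny_genome()
  calls <- meth_calls(data.frame(chrom = "chr1", pos = 50L, strand = "+",
                                 context = "CG", mc = 1L, cov = 1L), g)
  overlapping <- region_set(c("chr1", "chr1"), c(0, 40), c(60, 100))
  s <- region_weighted_methylation(calls, overlapping, "CG")
  expect_equal(s$n_sites, 1L)
})

test_that("genome-wide methylation excludes organelles by request", {
  g <- tiny_genome()
  chloro_only <- meth_calls(data.frame(chrom = "ChrC", pos = 1:10 * 10L,
                                       strand = "+", context = "CG",
                                       mc = 1L, cov = 1L), g)
  s <- genomewide_methylation(chloro_only, g, "CG", exclude_organelles = TRUE)
  expect_equal(s$n_sites, 0L)
  s2 <- genomewide_methylation(chloro_only, g, "CG", exclude_organelles = FALSE)
  expect_equal(s2$avg_me, 1.0)

  set.seed(102)
  mix <- random_calls(80, g, organelles = TRUE)
  got <- genomewide_methylation(mix, g, "CHH", exclude_organelles = FALSE)
  whole <- region_set(g$chrom, 0, g$length, id = g$chrom)
  want <- oracle_region_meth(mix, whole, "CHH")
  expect_equal(got$avg_me, want$avg_me)
})

test_that("pseudobulk pooling sums site-wise and is order-invariant", {
  g <- tiny_genome()
  two <- meth_calls(data.frame(
    nucleus = c("a", "b", "a", "b"), chrom = "chr1",
    pos = c(10L, 10L, 20L, 20L), strand = "+", context = "CG",
    mc = c(1L, 1L, 1L, 0L), cov = c(1L, 1L, 1L, 1L)
  ), g)
  groups <- tibble::tibble(nucleus = c("a", "b"), label = "cl")
  pb <- pseudobulk_pool(two, groups)
  expect_equal(pb$mc[pb$pos == 10], 2)
  expect_equal(pb$cov[pb$pos == 10], 2)
  expect_equal(pb$mc[pb$pos == 20] / pb$cov[pb$pos == 20], 0.5)

  set.seed(103)
  many <- random_calls(40, g, n_nuclei = 20)
  groups <- tibble::tibble(nucleus = unique(many$nucleus),
                           label = rep(c("x", "y"), length.out = 20))
  got <- pseudobulk_pool(many, groups)
  want <- oracle_pseudobulk(many, groups)
  expect_equal(nrow(got), nrow(want))
  expect_equal(got$mc, want$mc)
  expect_equal(got$cov, want$cov)

  shuffled <- many[sample.int(nrow(many)), ]
  got2 <- pseudobulk_pool(shuffled, groups)
  expect_equal(got, got2)
})

test_that("aggregation is linear: pooling then averaging equals averaging pooled counts", {
  set.seed(104)
  g <- tiny_genome()
  calls <- random_calls(60, g, n_nuclei = 8)
  regions <- random_regions(4, g)
  groups <- tibble::tibble(nucleus = unique(calls$nucleus), label = "all")
  pooled <- pseudobulk_pool(calls, groups)
  s_pooled <- region_weighted_methylation(pooled, regions, "CG")
  per_nuc <- region_weighted_methylation(calls, regions, "CG")
  raw <- calls[calls$context == "CG" &
                 pollensnmct:::sites_in_regions(calls, regions), ]
  expect_equal(s_pooled$avg_me, sum(raw$mc) / sum(raw$cov))
  # per-nucleus table carries the same total counts
  expect_equal(sum(per_nuc$n_sites), nrow(raw))
})

test_that("bin methylation fraction distinguishes empty bins from unmethylated", {
  g <- tiny_genome()
  calls <- meth_calls(data.frame(
    chrom = "chr1", pos = c(100L, 200L, 300L), strand = "+", context = "CG",
    mc = c(1L, 1L, 0L), cov = c(1L, 1L, 2L)
  ), g)
  b <- bin_methylation_fraction(calls, g, 1000, "CG")
  first <- b[b$chrom == "chr1" & b$start == 0, ]
  expect_equal(first$value, 0.5)
  expect_true(is.na(b$value[b$chrom == "chr2" & b$start == 0]))

  set.seed(105)
  rand <- random_calls(80, g)
  got <- bin_methylation_fraction(rand, g, 2500, "CHG")
  want <- oracle_bin_fraction(rand, g, 2500, "CHG")
  expect_equal(got$value, want$value)
})

test_that("methylation density sums per-site percentages above the coverage floor", {
  g <- tiny_genome()
  calls <- meth_calls(data.frame(
    chrom = "chr1", pos = c(10L, 20L, 30L, 40L), strand = "+", context = "CG",
    mc = c(5L, 3L, 0L, 2L), cov = c(5L, 6L, 5L, 4L)
  ), g)
  d <- methylation_density(calls, g, 400, "CG", min_cov = 5)
  first <- d[d$chrom == "chr1" & d$start == 0, ]
  expect_equal(first$value, 100 + 50 + 0)  # cov=4 site excluded

  set.seed(106)
  rand <- random_calls(80, g, max_cov = 8)
  got <- methylation_density(rand, g, 2000, "CHH", min_cov = 5)
  want <- oracle_density(rand, g, 2000, "CHH", 5)
  expect_equal(got$value, want$value)
})

test_that("TSS windows use 1-based positions and clip at chromosome bounds", {
  g <- tiny_genome()
  tss <- tibble::tibble(transcript_id = c("t1", "t2"), chrom = "chr1",
                        tss = c(1000L, 100L), strand = "+")
  w <- tss_windows(tss, g, radius = 400)
  expect_equal(w$start[1], 599)
  expect_equal(w$end[1], 1399)
  expect_equal(w$start[2], 0)
  expect_equal(w$end[2], 499)
  expect_error(tss_windows(tibble::tibble(transcript_id = "x", chrom = "nope",
                                          tss = 5L), g),
               "unknown chromosome")

  p <- withr::local_tempfile(fileext = ".bed")
  write_bed(w, p)
  back <- read_bed(p, g)
  expect_equal(back$start, w$start)
  expect_equal(back$end, w$end)
})

test_that("metaprofile is flat on uniform tracks and mirror-symmetric on minus strand", {
  g <- tiny_genome()
  pos <- seq(1001L, 3000L, by = 10L)
  uniform <- meth_calls(data.frame(chrom = "chr1", pos = pos, strand = "+",
                                   context = "CG", mc = 1L, cov = 1L), g)
  region <- region_set("chr1", 1500, 2500, id = "r")
  prof <- metaprofile(uniform, region, "CG", upstream = 300, downstream = 300,
                      n_body_bins = 10, flank_bin_width = 100)
  expect_true(all(prof$value[!is.na(prof$value)] == 1))

  set.seed(107)
  grad <- meth_calls(data.frame(chrom = "chr1", pos = pos, strand = "+",
                                context = "CG",
                                mc = as.integer(pos > 2000), cov = 1L), g)
  plus <- region
  minus <- region; minus$strand <- "-"
  p1 <- metaprofile(grad, plus, "CG", upstream = 200, downstream = 200,
                    n_body_bins = 10, flank_bin_width = 100)
  p2 <- metaprofile(grad, minus, "CG", upstream = 200, downstream = 200,
                    n_body_bins = 10, flank_bin_width = 100)
  expect_equal(p1$value, rev(p2$value))
})

test_that("metaprofile pools counts across regions like a direct per-bin oracle", {
  set.seed(108)
  g <- tiny_genome()
  calls <- random_calls(200, g, contexts = "CG")
  regions <- random_regions(10, g, max_width = 600)
  nb <- 5
  prof <- metaprofile(calls, regions, "CG", upstream = 0, downstream = 0,
                      n_body_bins = nb)
  # oracle: assign each in-region site to a scaled bin and pool
  mc <- numeric(nb); cov <- numeric(nb)
  for (i in seq_len(nrow(regions))) {
    r <- regions[i, ]
    sel <- calls$chrom == r$chrom & calls$pos > r$start & calls$pos <= r$end
    if (!any(sel)) next
    frac <- (calls$pos[sel] - 1 - r$start) / (r$end - r$start)
    b <- pmin(floor(frac * nb), nb - 1) + 1
    for (k in seq_along(b)) {
      mc[b[k]] <- mc[b[k]] + calls$mc[sel][k]
      cov[b[k]] <- cov[b[k]] + calls$cov[sel][k]
    }
  }
  expect_equal(prof$value, ifelse(cov > 0, mc / cov, NA_real_))
})
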