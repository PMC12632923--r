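# Interval statistics: dominance deciles, reciprocal coverage overlap,
# seeded shuffles, and loess signal-density curves.

test_that("dominance deciles partition by rank exactly as stated", {
  g <- genome_spec(c(chr1 = 1e6))
  peaks <- region_set("chr1", (0:99) * 1000, (0:99) * 1000 + 500,
                      id = sprintf("p%03d", 1:100))
  # signal = rank: peak p001 has the highest signal
  sig <- tibble::tibble(id = peaks$id, signal = 100:1)
  lab <- classify_dominance(peaks, sig)
  expect_equal(lab$id[lab$label == "MBD7_dominant"], sprintf("p%03d", 1:10))
  expect_equal(sort(lab$id[lab$label == "MBD6_dominant"]), sprintf("p%03d", 91:100))
  expect_equal(sort(lab$id[lab$label == "mixed"]), sprintf("p%03d", 46:55))
  expect_equal(sum(lab$label == "unlabeled"), 70)

  # degenerate ties resolve purely by id
  tied <- tibble::tibble(id = peaks$id, signal = 1)
  lt <- classify_dominance(peaks, tied)
  expect_equal(lt$id[lt$label == "MBD7_dominant"], sprintf("p%03d", 1:10))

  expect_error(classify_dominance(peaks[1:20, ], sig[1:20, ]), "at least 30")
})

test_that("dominance labels equal a sort-based oracle and ignore input order", {
  set.seed(401)
  for (n in c(40, 73, 100)) {
    ids <- sprintf("pk%03d", seq_len(n))
    sig <- runif(n)
    peaks <- region_set(rep("chr1", n), (seq_len(n) - 1) * 100,
                        (seq_len(n) - 1) * 100 + 50, id = ids)
    got <- classify_dominance(peaks, tibble::tibble(id = ids, signal = sig))
    want <- oracle_dominance(ids, sig)
    expect_equal(got$label, unname(want[got$id]))

    perm <- sample.int(n)
    got2 <- classify_dominance(peaks[perm, ], tibble::tibble(id = ids, signal = sig))
    expect_equal(sort(got2$id[got2$label == "mixed"]),
                 sort(got$id[got$label == "mixed"]))
  }
})

test_that("reciprocal overlap follows the either-direction >50% rule", {
  A <- region_set("chr1", 0, 100, id = "a")
  B <- region_set("chr1", 40, 200, id = "b")
  r <- reciprocal_overlap(A, B)
  expect_equal(r$n_A_overlap, 1)  # 60% of A covered

  # A covered 40% (fails) but B covered 100% (passes) -> both flagged
  B2 <- region_set("chr1", 60, 100, id = "b")
  r2 <- reciprocal_overlap(A, B2)
  expect_equal(r2$n_A_overlap, 1)
  expect_equal(r2$n_B_overlap, 1)

  # exactly 50% does not count
  B3 <- region_set("chr1", 50, 150, id = "b")
  r3 <- reciprocal_overlap(A, B3)
  expect_equal(r3$n_A_overlap, 0)

  disjoint <- reciprocal_overlap(A, region_set("chr1", 500, 600, id = "b"))
  expect_equal(disjoint$n_A_overlap + disjoint$n_B_overlap, 0)

  # abutting partners accumulate through the merge
  Bsplit <- region_set(c("chr1", "chr1"), c(0, 30), c(30, 70), id = c("b1", "b2"))
  rs <- reciprocal_overlap(A, Bsplit)
  expect_equal(rs$n_A_overlap, 1)  # 70% covered jointly
})

test_that("reciprocal overlap matches the pairwise brute-force oracle and is symmetric", {
  set.seed(402)
  g <- tiny_genome()
  for (i in 1:8) {
    A <- random_regions(sample(3:8, 1), g, max_width = 400, prefix = "a")
    B <- random_regions(sample(3:8, 1), g, max_width = 400, prefix = "b")
    got <- reciprocal_overlap(A, B)
    want <- oracle_reciprocal_overlap(A, B)
    expect_equal(got$flags_A$overlaps, want$flagA)
    expect_equal(got$flags_B$overlaps, want$flagB)

    swapped <- reciprocal_overlap(B, A)
    expect_equal(swapped$n_A_overlap, got$n_B_overlap)
    expect_equal(swapped$n_B_overlap, got$n_A_overlap)
  }
})

test_that("shuffles preserve lengths, avoid self-overlap and are seed-reproducible", {
  g <- tiny_genome()
  A <- region_set(c("chr1", "chr1", "chr2"), c(0, 5000, 100),
                  c(1200, 5600, 900), id = c("a", "b", "c"))
  s1 <- shuffle_regions(A, g, n_shuffles = 5, seed = 99)
  s2 <- shuffle_regions(A, g, n_shuffles = 5, seed = 99)
  expect_identical(s1, s2)
  for (s in s1) {
    merged <- dplyr::inner_join(as.data.frame(s), as.data.frame(A), by = "id")
    expect_equal(merged$end.x - merged$start.x, merged$end.y - merged$start.y)
    expect_equal(merged$chrom.x, merged$chrom.y)  # same-chrom default
    # no overlap among placed intervals
    by_chr <- split(s, s$chrom)
    for (ch in by_chr) {
      ch <- ch[order(ch$start), ]
      if (nrow(ch) > 1) expect_true(all(ch$start[-1] >= ch$end[-nrow(ch)]))
    }
  }
  expect_error(shuffle_regions(region_set("ChrC", 0, 5000, id = "too_long"), g),
               "longer than")
})

test_that("shuffled overlap frequency matches exact enumeration for one interval", {
  # one 100-bp interval shuffled on a single 4-kb chromosome vs a fixed DMR
  g <- genome_spec(c(chr1 = 4000))
  A <- region_set("chr1", 0, 100, id = "peak")
  B <- region_set("chr1", c(1000, 2500), c(1400, 2560), id = c("d1", "d2"))
  p_exact <- oracle_shuffle_overlap_prob(100, 4000, as.data.frame(B))
  n_shuf <- 400
  shufs <- shuffle_regions(A, g, n_shuffles = n_shuf, seed = 7)
  hits <- vapply(shufs, function(s) {
    reciprocal_overlap(s, B)$n_A_overlap > 0
  }, logical(1))
  p_hat <- mean(hits)
  se <- sqrt(p_exact * (1 - p_exact) / n_shuf)
  expect_lt(abs(p_hat - p_exact), 3 * se + 1e-9)
})

test_that("planted peaks overlap DMRs far above shuffled controls", {
  sim <- simulate_dataset(small_sim_config(seed = 403))
  enr <- overlap_with_shuffles(sim$regions$mbd6_peaks, sim$regions$cg_hypo_dmr,
                               sim$genome, n_shuffles = 30, seed = 11)
  expect_gt(enr$summary$true_frac, enr$summary$shuffled_mean)
  expect_gte(enr$summary$true_frac, sim$config$layout$mbd6_on_dmr_frac - 1e-9)
})

test_that("the loess curve reproduces linear signal exactly and flags thin input", {
  set.seed(404)
  density <- runif(300, 0, 100)
  linear <- tibble::tibble(density = density, signal = 0.03 * density - 1)
  fit <- signal_vs_density_curve(linear, span = 0.5)
  interior <- fit$curve[fit$curve$density > quantile(density, 0.05) &
                          fit$curve$density < quantile(density, 0.95), ]
  expect_lt(max(abs(interior$fitted - (0.03 * interior$density - 1))), 1e-6)
  expect_lt(fit$residual_sd, 1e-8)

  flat <- tibble::tibble(density = density, signal = rnorm(300, 5, 0.1))
  ffit <- signal_vs_density_curve(flat)
  expect_lt(max(ffit$curve$fitted) - min(ffit$curve$fitted), 4 * 0.1)

  expect_error(signal_vs_density_curve(linear[1:30, ]), "at least 50")
})

test_that("a monotone methylation-affinity relationship yields a monotone fitted curve", {
  set.seed(405)
  density <- runif(400, 0, 150)
  chip <- tibble::tibble(density = density,
                         signal = log1p(density / 20) + rnorm(400, 0, 0.15))
  fit <- signal_vs_density_curve(chip, span = 0.75)
  central <- fit$curve[fit$curve$density >= quantile(density, 0.05) &
                         fit$curve$density <= quantile(density, 0.95), ]
  expect_true(all(diff(central$fitted) > -1e-3))
})
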