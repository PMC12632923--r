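# Shared fixtures: a small genome and random-table generators used across
# the unit and property tests.

tiny_genome <- function() {
  genome_spec(c(chr1 = 10000, chr2 = 8000, ChrC = 2000, ChrM = 1500))
}

# random methylation call table on the nuclear chromosomes of `genome`
random_calls <- function(n, genome = tiny_genome(), n_nuclei = 1,
                         max_cov = 3, contexts = c("CG", "CHG", "CHH"),
                         organelles = FALSE) {
  g <- if (organelles) genome else genome[!genome$is_organelle, ]
  rows <- lapply(seq_len(n_nuclei), function(k) {
    chrom <- sample(g$chrom, n, replace = TRUE)
    pos <- vapply(chrom, function(ch) sample.int(g$length[g$chrom == ch], 1), 1L)
    df <- data.frame(
      nucleus = sprintf("nuc%02d", k), chrom = chrom, pos = pos,
      strand = sample(c("+", "-"), n, replace = TRUE),
      context = sample(contexts, n, replace = TRUE),
      cov = sample.int(max_cov, n, replace = TRUE)
    )
    df$mc <- vapply(df$cov, function(cv) sample.int(cv + 1L, 1) - 1L, 1L)
    df <- df[!duplicated(df[, c("chrom", "pos", "strand")]), ]
    df
  })
  out <- do.call(rbind, rows)
  if (n_nuclei == 1) out$nucleus <- NULL
  meth_calls(out, genome)
}

# random non-overlap-free region set (overlaps allowed unless disjoint)
random_regions <- function(n, genome = tiny_genome(), max_width = 800,
                           prefix = "r") {
  g <- genome[!genome$is_organelle, ]
  chrom <- sample(g$chrom, n, replace = TRUE)
  len <- g$length[match(chrom, g$chrom)]
  width <- sample.int(max_width, n, replace = TRUE)
  start <- floor(runif(n, 0, len - width))
  region_set(chrom, start, start + width, id = paste0(prefix, seq_len(n)),
             genome = genome)
}

# small fast simulation config for tests that only need structure
small_sim_config <- function(seed = 1, ...) {
  sim_config(
    seed = seed,
    n_per_cluster = 12,
    genotypes = "WT",
    doublet_rate = 0,
    conv_fail_rate = 0,
    ...
  )
}
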