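# Independent brute-force oracles. These deliberately avoid the package's
# vectorised/interval-tree code paths: plain per-site loops and pairwise
# scans, kept simple enough to be obviously correct.

oracle_in_any_region <- function(chrom, pos, regions) {
  # 1-based position inside any 0-based half-open interval
  any(regions$chrom == chrom & regions$start < pos & pos <= regions$end)
}

oracle_region_meth <- function(calls, regions, context, min_cov = 1) {
  mc <- 0; cov <- 0; n <- 0; covs <- numeric()
  for (i in seq_len(nrow(calls))) {
    r <- calls[i, ]
    if (r$context != context || r$cov < min_cov) next
    if (!oracle_in_any_region(r$chrom, r$pos, regions)) next
    mc <- mc + r$mc; cov <- cov + r$cov; n <- n + 1
    covs <- c(covs, r$cov)
  }
  list(n_sites = n, avg_cov = if (n) mean(covs) else NA_real_,
       avg_me = if (n) mc / cov else NA_real_)
}

oracle_pseudobulk <- function(calls, groups) {
  # hash-map accumulation, one entry per (label, site)
  env <- new.env(hash = TRUE, parent = emptyenv())
  lab <- setNames(groups$label, groups$nucleus)
  for (i in seq_len(nrow(calls))) {
    r <- calls[i, ]
    if (!r$nucleus %in% names(lab)) next
    key <- paste(lab[[r$nucleus]], r$chrom, r$pos, r$strand, r$context, sep = "\r")
    prev <- if (!is.null(env[[key]])) env[[key]] else c(0, 0)
    env[[key]] <- prev + c(r$mc, r$cov)
  }
  keys <- ls(env)
  parts <- strsplit(keys, "\r", fixed = TRUE)
  out <- data.frame(
    label = vapply(parts, `[[`, "", 1),
    chrom = vapply(parts, `[[`, "", 2),
    pos = as.integer(vapply(parts, `[[`, "", 3)),
    strand = vapply(parts, `[[`, "", 4),
    context = vapply(parts, `[[`, "", 5),
    mc = vapply(keys, function(k) env[[k]][1], 1),
    cov = vapply(keys, function(k) env[[k]][2], 1)
  )
  out[order(out$label, out$chrom, out$pos, out$strand, out$context), ]
}

oracle_bin_fraction <- function(calls, genome, bin_width, context) {
  g <- genome[!genome$is_organelle, ]
  rows <- list()
  for (i in seq_len(nrow(g))) {
    starts <- seq(0, g$length[i] - 1, by = bin_width)
    for (s in starts) {
      e <- min(s + bin_width, g$length[i])
      sel <- calls$chrom == g$chrom[i] & calls$context == context &
        calls$pos > s & calls$pos <= e
      rows[[length(rows) + 1]] <- data.frame(
        chrom = g$chrom[i], start = s, end = e,
        value = if (any(sel)) sum(calls$mc[sel]) / sum(calls$cov[sel]) else NA_real_
      )
    }
  }
  do.call(rbind, rows)
}

oracle_density <- function(calls, genome, bin_width, context, min_cov) {
  g <- genome[!genome$is_organelle, ]
  rows <- list()
  for (i in seq_len(nrow(g))) {
    starts <- seq(0, g$length[i] - 1, by = bin_width)
    for (s in starts) {
      e <- min(s + bin_width, g$length[i])
      sel <- calls$chrom == g$chrom[i] & calls$context == context &
        calls$cov >= min_cov & calls$pos > s & calls$pos <= e
      rows[[length(rows) + 1]] <- data.frame(
        chrom = g$chrom[i], start = s, end = e,
        value = sum(calls$mc[sel] / calls$cov[sel] * 100)
      )
    }
  }
  do.call(rbind, rows)
}

oracle_covered_len <- function(a, others) {
  # bp of interval a covered by the union of `others`, by position scan
  if (nrow(others) == 0) return(0)
  pos <- seq.int(a$start, a$end - 1)
  covered <- vapply(pos, function(p) {
    any(others$chrom == a$chrom & others$start <= p & p < others$end)
  }, logical(1))
  sum(covered)
}

oracle_reciprocal_overlap <- function(A, B, min_frac = 0.5) {
  fracA <- vapply(seq_len(nrow(A)), function(i) {
    oracle_covered_len(A[i, ], B) / (A$end[i] - A$start[i])
  }, numeric(1))
  fracB <- vapply(seq_len(nrow(B)), function(j) {
    oracle_covered_len(B[j, ], A) / (B$end[j] - B$start[j])
  }, numeric(1))
  touches <- function(a, b) {
    a$chrom == b$chrom && a$start < b$end && b$start < a$end
  }
  flagA <- fracA > min_frac
  flagB <- fracB > min_frac
  for (i in seq_len(nrow(A))) {
    for (j in seq_len(nrow(B))) {
      if (touches(A[i, ], B[j, ])) {
        if (fracB[j] > min_frac) flagA[i] <- TRUE
        if (fracA[i] > min_frac) flagB[j] <- TRUE
      }
    }
  }
  list(flagA = flagA, flagB = flagB)
}

oracle_dominance <- function(ids, signal, decile = 0.10) {
  # full sort with id tie-break, then explicit index arithmetic
  ord <- order(-signal, ids)
  n <- length(ids)
  k <- floor(decile * n)
  lab <- rep("unlabeled", n)
  lab[ord[1:k]] <- "MBD7_dominant"
  lab[ord[(n - k + 1):n]] <- "MBD6_dominant"
  centre <- ceiling(n / 2)
  lo <- centre - floor(k / 2) + ifelse(k %% 2 == 0, 1, 0)
  lab[ord[lo:(lo + k - 1)]] <- "mixed"
  setNames(lab, ids)
}

oracle_homology <- function(g, t, bitscore_min = 100, ratio_min = 3) {
  # direct transcription of the rule branches
  if (is.na(g) && is.na(t)) return("neither")
  if (is.na(g)) return(if (t > bitscore_min) "TE" else "neither")
  if (is.na(t)) return(if (g > bitscore_min) "gene" else "neither")
  if (g >= ratio_min * t) return("gene")
  if (t >= ratio_min * g) return("TE")
  "ambiguous"
}

# exact probability that a uniformly placed interval of width w on a
# chromosome of length L counts as overlapping the fixed set B under the
# reciprocal >min_frac rule, by enumeration of every integer start
oracle_shuffle_overlap_prob <- function(w, L, B, min_frac = 0.5) {
  starts <- 0:(L - w)
  hits <- vapply(starts, function(s) {
    a <- data.frame(chrom = B$chrom[1], start = s, end = s + w, id = "a")
    covA <- oracle_covered_len(a, B) / w
    if (covA > min_frac) return(TRUE)
    for (j in seq_len(nrow(B))) {
      if (a$start < B$end[j] && B$start[j] < a$end) {
        covB <- oracle_covered_len(B[j, ], a) / (B$end[j] - B$start[j])
        if (covB > min_frac) return(TRUE)
      }
    }
    FALSE
  }, logical(1))
  mean(hits)
}
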