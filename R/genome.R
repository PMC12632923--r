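#' Define a genome as a set of named chromosomes
#'
#' A genome spec is the coordinate frame every other table in the package is
#' validated against. It records chromosome lengths in bp and which
#' chromosomes are organellar (chloroplast/mitochondrion). Organelles are
#' excluded from genome-wide methylation averages but the chloroplast is used
#' for bisulfite conversion QC, so the distinction is carried everywhere.
#'
#' @param lengths Named numeric vector or a data frame with columns
#'   `chrom` and `length`; lengths are chromosome sizes in bp.
#' @param organelles Character vector of chromosome names to treat as
#'   organellar. Must be a subset of the chromosome names. Defaults to the
#'   TAIR10-style names `"ChrC"` (chloroplast) and `"ChrM"` (mitochondrion);
#'   names absent from `lengths` are dropped silently so the default works
#'   for purely nuclear genomes.
#'
#' @return A tibble of class `genome_spec` with columns `chrom`, `length`,
#'   `is_organelle`.
#' @examples
#' genome_spec(c(Chr1 = 1e6, Chr2 = 8e5, ChrC = 154478))
#' @export
genome_spec <- function(lengths, organelles = c("ChrC", "ChrM")) {
  if (is.data.frame(lengths)) {
    stopifnot(all(c("chrom", "length") %in% names(lengths)))
    chrom <- as.character(lengths$chrom)
    len <- as.numeric(lengths$length)
  } else {
    if (is.null(names(lengths)) || any(names(lengths) == "")) {
      stop("`lengths` must be a named vector or a data frame with chrom/length")
    }
    chrom <- names(lengths)
    len <- as.numeric(lengths)
  }
  if (anyDuplicated(chrom)) stop("chromosome names must be unique")
  if (any(!is.finite(len)) || any(len <= 0)) {
    stop("chromosome lengths must be positive and finite")
  }
  organelles <- intersect(organelles, chrom)
  out <- tibble::tibble(
    chrom = chrom,
    length = len,
    is_organelle = chrom %in% organelles
  )
  class(out) <- c("genome_spec", class(out))
  out
}

#' @export
print.genome_spec <- function(x, ...) {
  cat(sprintf(
    "<genome_spec> %d chromosomes (%d organellar), %.3g Mb total\n",
    nrow(x), sum(x$is_organelle), sum(x$length) / 1e6
  ))
  NextMethod()
}

#' Chromosome names of a genome spec
#'
#' @param genome A [genome_spec()].
#' @param organelles One of `"include"`, `"exclude"`, `"only"`.
#' @return Character vector of chromosome names.
#' @export
genome_chroms <- function(genome, organelles = c("include", "exclude", "only")) {
  organelles <- match.arg(organelles)
  switch(organelles,
    include = genome$chrom,
    exclude = genome$chrom[!genome$is_organelle],
    only = genome$chrom[genome$is_organelle]
  )
}

chrom_length <- function(genome, chrom) {
  idx <- match(chrom, genome$chrom)
  if (anyNA(idx)) {
    stop("unknown chromosome(s): ", paste(unique(chrom[is.na(idx)]), collapse = ", "))
  }
  genome$length[idx]
}

assert_genome <- function(genome) {
  if (!inherits(genome, "genome_spec")) {
    stop("`genome` must be a genome_spec object")
  }
  invisible(genome)
}
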