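#' @importFrom rlang .data
#' @importFrom dplyr %>%
NULL

# Coordinate conventions, fixed repo-wide:
#   * interval tables (region sets, bins, bedGraph) are 0-based half-open [start, end)
#   * per-cytosine positions (allc tables) are 1-based
# Conversion between the two is confined to this file: a BED start equals the
# allc position minus one. CG sites are never strand-collapsed; each cytosine
# is an independent record.

#' Construct and validate a region set
#'
#' A region set is a tibble of genomic intervals in 0-based half-open
#' coordinates (the BED convention) with unique ids.
#'
#' @param chrom,start,end,id,score Vectors of equal length (`id` defaults to
#'   `region_1..n`, `score` to `NA`).
#' @param genome Optional [genome_spec()]; when given, intervals are checked
#'   against chromosome bounds.
#' @return A tibble with columns `chrom`, `start`, `end`, `id`, `score`.
#' @export
region_set <- function(chrom, start, end, id = NULL, score = NULL, genome = NULL) {
  n <- length(chrom)
  if (is.null(id)) id <- paste0("region_", seq_len(max(n, 0)))
  if (is.null(score)) score <- rep(NA_real_, n)
  out <- tibble::tibble(
    chrom = as.character(chrom),
    start = as.numeric(start),
    end = as.numeric(end),
    id = as.character(id),
    score = as.numeric(score)
  )
  validate_region_set(out, genome)
}

validate_region_set <- function(regions, genome = NULL) {
  stopifnot(all(c("chrom", "start", "end", "id") %in% names(regions)))
  if (!"score" %in% names(regions)) regions$score <- NA_real_
  if (nrow(regions) == 0) return(regions)
  bad <- which(!(regions$start >= 0 & regions$start < regions$end))
  if (length(bad)) {
    stop(sprintf(
      "invalid interval(s) (need 0 <= start < end), e.g. row %d: [%s, %s)",
      bad[1], format(regions$start[bad[1]]), format(regions$end[bad[1]])
    ))
  }
  if (anyDuplicated(regions$id)) {
    stop("region ids must be unique within a set")
  }
  if (!is.null(genome)) {
    assert_genome(genome)
    lens <- chrom_length(genome, regions$chrom)
    over <- which(regions$end > lens)
    if (length(over)) {
      stop(sprintf(
        "interval %s exceeds length of %s (%d > %d)",
        regions$id[over[1]], regions$chrom[over[1]],
        as.integer(regions$end[over[1]]), as.integer(lens[over[1]])
      ))
    }
  }
  regions
}

#' Read a BED file into a region set
#'
#' Accepts BED3/BED4/BED6; only chrom, start, end, name and score are
#' consumed. Input is taken as 0-based half-open per the BED standard and is
#' validated against the genome. Malformed records are rejected, never
#' repaired.
#'
#' @param path Path to a BED file (plain text, tab-separated).
#' @param genome A [genome_spec()] used for bounds checking.
#' @return A region set tibble (see [region_set()]).
#' @export
read_bed <- function(path, genome) {
  assert_genome(genome)
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "track") & !startsWith(lines, "#")]
  if (length(lines) == 0) {
    return(region_set(character(), numeric(), numeric()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3)) {
    stop(sprintf("malformed BED line %d: fewer than 3 fields", which(nf < 3)[1]))
  }
  chrom <- vapply(fields, `[[`, character(1), 1L)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 3L)))
  if (anyNA(start) || anyNA(end)) {
    stop(sprintf(
      "malformed BED line %d: non-numeric coordinates",
      which(is.na(start) | is.na(end))[1]
    ))
  }
  id <- ifelse(nf >= 4, vapply(fields, function(f) if (length(f) >= 4) f[[4]] else NA_character_, character(1)), NA_character_)
  if (anyNA(id)) id <- ifelse(is.na(id), paste0("region_", seq_along(id)), id)
  score <- suppressWarnings(as.numeric(
    vapply(fields, function(f) if (length(f) >= 5) f[[5]] else NA_character_, character(1))
  ))
  bad <- which(!(start >= 0 & start < end))
  if (length(bad)) {
    stop(sprintf("invalid interval at BED line %d: empty or negative", bad[1]))
  }
  region_set(chrom, start, end, id = id, score = score, genome = genome)
}

#' Write a region set to a BED file
#'
#' @param regions A region set tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(regions, path) {
  validate_region_set(regions)
  df <- regions
  has_score <- any(!is.na(df$score))
  cols <- c("chrom", "start", "end", "id", if (has_score) "score")
  out <- df[, cols]
  out$start <- format(out$start, scientific = FALSE, trim = TRUE)
  out$end <- format(out$end, scientific = FALSE, trim = TRUE)
  readr::write_tsv(out, path, col_names = FALSE)
  invisible(path)
}

normalize_context <- function(context) {
  ctx <- toupper(as.character(context))
  ctx[ctx == "CGN"] <- "CG"
  known <- ctx %in% c("CG", "CHG", "CHH")
  if (any(!known)) {
    stop("unknown methylation context token(s): ",
         paste(unique(ctx[!known]), collapse = ", "))
  }
  ctx
}

#' Construct and validate a per-cytosine methylation call table
#'
#' The atom of all methylome math: one row per covered cytosine per nucleus,
#' with 1-based positions, strand, context in {CG, CHG, CHH} (CGN is
#' normalised to CG), methylated read count `mc` and total read count `cov`.
#' Only covered sites (`cov >= 1`) are stored.
#'
#' @param df Data frame with columns `chrom`, `pos`, `strand`, `context`,
#'   `mc`, `cov` and optionally `nucleus`.
#' @param genome Optional [genome_spec()] for bounds checking.
#' @return A validated tibble.
#' @export
meth_calls <- function(df, genome = NULL) {
  needed <- c("chrom", "pos", "strand", "context", "mc", "cov")
  missing <- setdiff(needed, names(df))
  if (length(missing)) stop("missing column(s): ", paste(missing, collapse = ", "))
  out <- tibble::as_tibble(df)
  out$chrom <- as.character(out$chrom)
  out$pos <- as.integer(out$pos)
  out$strand <- as.character(out$strand)
  out$context <- normalize_context(out$context)
  out$mc <- as.integer(out$mc)
  out$cov <- as.integer(out$cov)
  if (nrow(out) == 0) return(out)
  if (any(!out$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  if (any(out$cov < 1)) stop("stored methylation records must have cov >= 1")
  if (any(out$mc < 0) || any(out$mc > out$cov)) {
    bad <- which(out$mc < 0 | out$mc > out$cov)[1]
    stop(sprintf("mc must satisfy 0 <= mc <= cov (violated at record %d: mc=%d cov=%d)",
                 bad, out$mc[bad], out$cov[bad]))
  }
  if (!is.null(genome)) {
    assert_genome(genome)
    lens <- chrom_length(genome, out$chrom)
    if (any(out$pos < 1 | out$pos > lens)) {
      stop("position outside chromosome bounds")
    }
  }
  key <- if ("nucleus" %in% names(out)) {
    paste(out$nucleus, out$chrom, out$pos, out$strand)
  } else {
    paste(out$chrom, out$pos, out$strand)
  }
  if (anyDuplicated(key)) {
    stop("(chrom, pos, strand) must be unique per nucleus")
  }
  out
}

#' Read an allc-style per-cytosine methylation table
#'
#' Tab-separated, by default headerless, columns chrom, pos (1-based),
#' strand, context, mc, cov. Contexts are normalised (CGN -> CG); records
#' with `mc > cov` or unknown contexts are rejected. An empty file yields an
#' empty table.
#'
#' @param path Path to the TSV.
#' @param genome A [genome_spec()].
#' @param header Logical; does the file carry a header line?
#' @return A validated methylation call tibble.
#' @export
read_allc <- function(path, genome, header = FALSE) {
  assert_genome(genome)
  cols <- c("chrom", "pos", "strand", "context", "mc", "cov")
  df <- readr::read_tsv(
    path,
    col_names = if (header) TRUE else cols,
    col_types = readr::cols(
      chrom = readr::col_character(),
      pos = readr::col_integer(),
      strand = readr::col_character(),
      context = readr::col_character(),
      mc = readr::col_integer(),
      cov = readr::col_integer()
    ),
    progress = FALSE
  )
  if (header) df <- df[, cols]
  if (nrow(df) == 0) return(meth_calls(df))
  df <- df[df$cov >= 1, , drop = FALSE]
  meth_calls(df, genome)
}

#' Write an allc-style methylation table
#'
#' @param calls A methylation call tibble (a `nucleus` column, if present, is
#'   dropped: allc files are per-nucleus).
#' @param path Output path.
#' @param header Write a header line?
#' @return `path`, invisibly.
#' @export
write_allc <- function(calls, path, header = FALSE) {
  cols <- c("chrom", "pos", "strand", "context", "mc", "cov")
  out <- tibble::as_tibble(calls)[, cols]
  readr::write_tsv(out, path, col_names = header)
  invisible(path)
}

#' Write a per-position track as bedGraph
#'
#' Takes a table of per-position values (1-based `pos`) and writes 0-based
#' half-open bedGraph, run-length merging adjacent positions that share a
#' value. Positions must be sorted within each chromosome.
#'
#' @param track Data frame with columns `chrom`, `pos`, `value`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  stopifnot(all(c("chrom", "pos", "value") %in% names(track)))
  if (nrow(track) == 0) {
    readr::write_lines(character(), path)
    return(invisible(path))
  }
  sorted <- unlist(tapply(track$pos, track$chrom, function(p) !is.unsorted(p, strictly = TRUE)))
  if (!all(sorted)) stop("positions must be strictly sorted within each chromosome")
  rows <- track %>%
    dplyr::group_by(.data$chrom) %>%
    dplyr::mutate(
      new_run = dplyr::row_number() == 1L |
        .data$pos != dplyr::lag(.data$pos) + 1L |
        .data$value != dplyr::lag(.data$value),
      run = cumsum(.data$new_run)
    ) %>%
    dplyr::group_by(.data$chrom, .data$run) %>%
    dplyr::summarise(
      start = min(.data$pos) - 1L,
      end = max(.data$pos),
      value = .data$value[1],
      .groups = "drop"
    ) %>%
    dplyr::arrange(.data$chrom, .data$start)
  lines <- sprintf("%s\t%d\t%d\t%s", rows$chrom, rows$start, rows$end,
                   format(rows$value, trim = TRUE, scientific = FALSE))
  readr::write_lines(lines, path)
  invisible(path)
}

#' Read a bedGraph file back into per-position values
#'
#' Expands run-length merged intervals to one row per position (1-based),
#' the inverse of [write_bedgraph()].
#'
#' @param path Path to a bedGraph file.
#' @return Tibble with columns `chrom`, `pos`, `value`.
#' @export
read_bedgraph <- function(path) {
  df <- readr::read_tsv(path, col_names = c("chrom", "start", "end", "value"),
                        col_types = "cddd", progress = FALSE)
  if (nrow(df) == 0) {
    return(tibble::tibble(chrom = character(), pos = integer(), value = numeric()))
  }
  n <- df$end - df$start
  tibble::tibble(
    chrom = rep(df$chrom, n),
    pos = unlist(purrr::map2(df$start, df$end, ~ seq.int(.x + 1L, .y))),
    value = rep(df$value, n)
  )
}

#' Read a genes-by-nuclei count matrix
#'
#' Dense TSV (first column gene ids, one column per nucleus) or sparse
#' MatrixMarket-style triplets with companion row/column name files.
#'
#' @param path Path to the dense TSV, or the `.mtx` file when `format =
#'   "mtx"`.
#' @param format `"tsv"` or `"mtx"`.
#' @param genes,cells For `format = "mtx"`: paths to plain-text files holding
#'   gene ids and nucleus ids, one per line.
#' @return Numeric matrix, genes in rows, nuclei in columns.
#' @export
read_counts <- function(path, format = c("tsv", "mtx"), genes = NULL, cells = NULL) {
  format <- match.arg(format)
  if (format == "tsv") {
    df <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
    mat <- as.matrix(df[, -1, drop = FALSE])
    rownames(mat) <- as.character(df[[1]])
  } else {
    m <- Matrix::readMM(path)
    mat <- as.matrix(m)
    if (!is.null(genes)) rownames(mat) <- readr::read_lines(genes)
    if (!is.null(cells)) colnames(mat) <- readr::read_lines(cells)
  }
  if (any(mat < 0)) stop("expression values must be nonnegative")
  if (anyDuplicated(rownames(mat)) || anyDuplicated(colnames(mat))) {
    stop("gene and sample ids must be unique")
  }
  mat
}

#' Write a count matrix as dense TSV
#'
#' @param mat Genes-by-samples matrix with dimnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_counts <- function(mat, path) {
  df <- tibble::as_tibble(mat, rownames = "gene_id")
  readr::write_tsv(df, path)
  invisible(path)
}

#' Read a differential-expression statistics table
#'
#' TSV with columns `transcript_id`, `log2fc`, `padj` (additional columns
#' are kept). `padj` outside \[0, 1\] is rejected; missing values are allowed
#' and treated downstream as not significant.
#'
#' @param path Path to the TSV (with header).
#' @return Tibble.
#' @export
read_de_stats <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  needed <- c("transcript_id", "log2fc", "padj")
  missing <- setdiff(needed, names(df))
  if (length(missing)) stop("missing column(s): ", paste(missing, collapse = ", "))
  ok <- is.na(df$padj) | (df$padj >= 0 & df$padj <= 1)
  if (!all(ok)) stop("padj must lie in [0, 1] when present")
  df
}

#' Read BLAST tabular hits (outfmt-6-like)
#'
#' Only the query id, a subject class column and the bitscore are consumed.
#' The subject class must be one of `gene`, `TE`, `TEgene`.
#'
#' @param path Path to a headerless TSV with columns query, class, bitscore,
#'   or a TSV with a header containing `query_id`, `subject_class`,
#'   `bitscore`.
#' @param header Does the file have a header?
#' @return Tibble with columns `query_id`, `subject_class`, `bitscore`.
#' @export
read_blast_hits <- function(path, header = FALSE) {
  if (header) {
    df <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
    df <- df[, c("query_id", "subject_class", "bitscore")]
  } else {
    df <- readr::read_tsv(path, col_names = c("query_id", "subject_class", "bitscore"),
                          col_types = "ccd", progress = FALSE)
  }
  df$bitscore <- as.numeric(df$bitscore)
  if (any(df$bitscore < 0)) stop("bitscores must be >= 0")
  if (any(!df$subject_class %in% c("gene", "TE", "TEgene"))) {
    stop("subject_class must be one of gene, TE, TEgene")
  }
  tibble::as_tibble(df)
}

#' Read a transcription start site table
#'
#' Simple TSV with header and columns `transcript_id`, `chrom`, `tss`
#' (1-based) and `strand`.
#'
#' @param path Path to the TSV.
#' @param genome A [genome_spec()] used to validate positions.
#' @return Tibble.
#' @export
read_tss_table <- function(path, genome) {
  assert_genome(genome)
  df <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  needed <- c("transcript_id", "chrom", "tss", "strand")
  missing <- setdiff(needed, names(df))
  if (length(missing)) stop("missing column(s): ", paste(missing, collapse = ", "))
  lens <- chrom_length(genome, df$chrom)
  if (any(df$tss < 1 | df$tss > lens)) stop("TSS outside chromosome bounds")
  tibble::as_tibble(df)
}
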