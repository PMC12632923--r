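# End-to-end orchestration: simulate -> qc -> assign -> aggregate ->
# pseudobulk -> stats, from a single config, with a machine-readable run
# manifest (content checksums, row counts, wall clock per stage).

#' Validate a pipeline configuration
#'
#' Checks the whole config and reports every violation at once, not just
#' the first.
#'
#' @param config Named list (or path to a YAML file) with optional fields
#'   `seed` (integer), `out_dir` (string), `sim` (overrides passed to
#'   [sim_config()]), `qc` (threshold overrides for
#'   [qc_filter_nuclei()]).
#' @return The normalised config list, invisibly; errors on violations.
#' @export
validate_pipeline_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("config must be a list or a YAML file path")
  problems <- character()
  need_num <- function(x, what, lo = -Inf, hi = Inf) {
    if (!is.null(x) && (!is.numeric(x) || length(x) != 1 || x < lo || x > hi)) {
      problems <<- c(problems, sprintf("%s must be a number in [%s, %s]", what, lo, hi))
    }
  }
  need_num(config$seed, "seed", 1, .Machine$integer.max)
  if (!is.null(config$out_dir) && !is.character(config$out_dir)) {
    problems <- c(problems, "out_dir must be a string")
  }
  sim <- config$sim %||% list()
  need_num(sim$n_per_cluster, "sim.n_per_cluster", 1, 1e6)
  need_num(sim$doublet_rate, "sim.doublet_rate", 0, 1)
  need_num(sim$conv_fail_rate, "sim.conv_fail_rate", 0, 1)
  if (!is.null(sim$genotypes) &&
      !all(sim$genotypes %in% c("WT", "mbd5/6", "mbd5/6/7", "mbd7"))) {
    problems <- c(problems, "sim.genotypes must be a subset of WT, mbd5/6, mbd5/6/7, mbd7")
  }
  qc <- config$qc %||% list()
  need_num(qc$min_rna_reads, "qc.min_rna_reads", 0, Inf)
  need_num(qc$min_genes, "qc.min_genes", 0, Inf)
  need_num(qc$min_bin_frac, "qc.min_bin_frac", 0, 1)
  need_num(qc$max_organelle_frac, "qc.max_organelle_frac", 0, 1)
  need_num(qc$k_mad_doublet, "qc.k_mad_doublet", 0, Inf)
  if (length(problems)) {
    stop("invalid pipeline config:\n  - ", paste(problems, collapse = "\n  - "))
  }
  invisible(config)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stage_output <- function(path) {
  n_rows <- length(readr::read_lines(path, progress = FALSE))
  checksum <- unname(tools::md5sum(path))
  tibble::tibble(path = basename(path), rows = n_rows, md5 = checksum)
}

#' Run the full synthetic-data pipeline
#'
#' Executes the fixed stage order simulate, qc, assign, aggregate,
#' pseudobulk, stats; writes each stage's tables under `out_dir` and
#' returns (and writes) a run manifest with a content checksum per output
#' file. Deterministic stages reproduce identical checksums when rerun with
#' the same config. A stage failure aborts with the stage name; outputs
#' written so far are retained next to a `FAILED` marker.
#'
#' @param config Config list or YAML path (see
#'   [validate_pipeline_config()]).
#' @param out_dir Output directory (overrides `config$out_dir`).
#' @return The manifest, invisibly (also written to
#'   `out_dir/manifest.json`).
#' @export
run_pipeline <- function(config = list(), out_dir = NULL) {
  config <- validate_pipeline_config(config)
  out_dir <- out_dir %||% config$out_dir %||% stop("out_dir required")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(config$seed %||% 1)

  manifest <- list(
    config_hash = digest_config(config), seed = seed,
    package_version = as.character(utils::packageVersion("pollensnmct")),
    stages = list()
  )
  env <- new.env(parent = emptyenv())
  run_stage <- function(name, fun) {
    t0 <- proc.time()[["elapsed"]]
    paths <- tryCatch(fun(), error = function(e) {
      writeLines(paste("stage", name, "failed:", conditionMessage(e)),
                 file.path(out_dir, "FAILED"))
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    manifest$stages[[name]] <<- list(
      status = "ok",
      elapsed_s = round(proc.time()[["elapsed"]] - t0, 3),
      outputs = purrr::map_dfr(paths, stage_output)
    )
  }

  run_stage("simulate", function() {
    sim_args <- lapply(config$sim %||% list(),
                       function(x) if (is.list(x)) unlist(x) else x)
    sim_args$seed <- seed
    env$sim <- do.call(sim_config, sim_args) |> simulate_dataset()
    p1 <- file.path(out_dir, "truth.tsv")
    readr::write_tsv(env$sim$truth, p1)
    p2 <- file.path(out_dir, "counts.tsv")
    write_counts(env$sim$counts, p2)
    p3 <- file.path(out_dir, "calls.tsv")
    readr::write_tsv(env$sim$calls, p3)
    p4 <- file.path(out_dir, "regions_cg_hypo_dmr.bed")
    write_bed(env$sim$regions$cg_hypo_dmr, p4)
    c(p1, p2, p3, p4)
  })

  run_stage("qc", function() {
    sim <- env$sim
    qcm <- compute_nucleus_qc(sim$calls, sim$counts, sim$genome,
                              gene_meta = sim$genes)
    env$qc <- qc_filter_nuclei(qcm, thresholds = config$qc %||% list())
    p <- file.path(out_dir, "qc.tsv")
    readr::write_tsv(env$qc, p)
    p
  })

  run_stage("assign", function() {
    sim <- env$sim
    passing <- env$qc$nucleus[env$qc$status == "pass"]
    asg <- assign_clusters(sim$counts[, passing, drop = FALSE], sim$panel)
    sn <- sim$panel$gene[sim$panel$cluster == "SN"]
    vn <- sim$panel$gene[sim$panel$cluster %in% c("VN4", "VN5")]
    env$labels <- marker_ratio_reassignment(
      sim$counts[, passing, drop = FALSE], asg$labels, sn, vn
    )
    p <- file.path(out_dir, "labels.tsv")
    readr::write_tsv(env$labels, p)
    p
  })

  run_stage("aggregate", function() {
    sim <- env$sim
    usable <- env$labels$nucleus[env$labels$label != "VN and SN"]
    calls <- sim$calls[sim$calls$nucleus %in% usable, , drop = FALSE]
    summaries <- dplyr::bind_rows(
      region_weighted_methylation(calls, sim$regions$cg_hypo_dmr, "CG",
                                  region_set_id = "cg_hypo_dmr"),
      region_weighted_methylation(calls, sim$regions$chh_hyper_dmr, "CHH",
                                  region_set_id = "chh_hyper_dmr"),
      region_weighted_methylation(calls, sim$regions$mbd6_hypo, "CG",
                                  region_set_id = "mbd6_hypo")
    )
    env$summaries <- summaries %>%
      dplyr::left_join(env$labels[, c("nucleus", "label")], by = "nucleus") %>%
      dplyr::left_join(sim$truth[, c("nucleus", "genotype")], by = "nucleus")
    p <- file.path(out_dir, "region_summaries.tsv")
    readr::write_tsv(env$summaries, p)
    p
  })

  run_stage("pseudobulk", function() {
    sim <- env$sim
    groups <- env$labels %>%
      dplyr::filter(.data$label != "VN and SN") %>%
      dplyr::left_join(sim$truth[, c("nucleus", "genotype")], by = "nucleus") %>%
      dplyr::mutate(label = paste(.data$label, .data$genotype, sep = "."))
    pooled <- pseudobulk_pool(sim$calls, groups[, c("nucleus", "label")])
    p1 <- file.path(out_dir, "pseudobulk.tsv")
    readr::write_tsv(pooled, p1)
    # one bedGraph per label would be many files; export the largest label
    top <- names(sort(table(groups$label), decreasing = TRUE))[1]
    track <- pooled %>%
      dplyr::filter(.data$label == top, .data$context == "CG") %>%
      dplyr::arrange(.data$chrom, .data$pos) %>%
      dplyr::mutate(value = .data$mc / .data$cov)
    p2 <- file.path(out_dir, paste0("pseudobulk_", gsub("[^A-Za-z0-9.]", "_", top), "_CG.bedGraph"))
    write_bedgraph(track[, c("chrom", "pos", "value")], p2)
    c(p1, p2)
  })

  run_stage("stats", function() {
    traj <- env$summaries %>%
      dplyr::filter(.data$region_set == "cg_hypo_dmr", .data$genotype == "WT",
                    .data$n_sites > 0, .data$label %in% pollen_ontology()) %>%
      dplyr::group_by(.data$label) %>%
      dplyr::summarise(mean_me = mean(.data$avg_me), n = dplyr::n(),
                       .groups = "drop")
    p <- file.path(out_dir, "trajectory_stats.tsv")
    readr::write_tsv(traj, p)
    p
  })

  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

digest_config <- function(config) {
  # stable content hash of the normalised config (md5 over canonical JSON)
  tmp <- tempfile()
  on.exit(unlink(tmp))
  canonical <- jsonlite::toJSON(config[order(names(config))], auto_unbox = TRUE)
  writeLines(as.character(canonical), tmp)
  unname(tools::md5sum(tmp))
}
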