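Package: pollensnmct
Title: Single-Nucleus Methylome and Transcriptome Analysis of Developing Pollen
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Downstream analysis of joint single-nucleus methylome and
    transcriptome (snmCT-seq) data from developing Arabidopsis pollen.
    Provides readers and writers for allc-style per-cytosine call tables,
    BED interval sets, bedGraph tracks and count matrices; nucleus-level
    quality control including haploid coverage-based doublet detection and
    bisulfite conversion filtering via chloroplast methylation; marker-based
    assignment of nuclei to the pollen cluster ontology; cluster-resolved
    pseudobulk methylation tracks, weighted region methylation, genomic
    binning, metaprofiles and methylation density; interval statistics
    (ChIP peak dominance deciles, reciprocal-coverage overlap with shuffled
    controls, signal-versus-density curves); expression-side classifiers
    (differential-expression thresholding, hierarchical-clustering rescue
    classification, Cohen's d effect staging, BLAST bitscore homology); and
    a synthetic-data generator with ground-truth labels that emulates the
    statistical structure of pollen snmCT-seq so every stage is testable
    without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    stringr,
    ggplot2,
    generics,
    yaml,
    jsonlite,
    Matrix,
    IRanges,
    S4Vectors,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
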