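---
title: "Methods: single-nucleus methylome + transcriptome analysis of developing pollen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: single-nucleus methylome + transcriptome analysis of developing pollen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pollensnmct)
library(dplyr)
```

# The problem

Developing Arabidopsis pollen contains several nucleus types — microspore
nuclei (MN), a maturation trajectory of vegetative nuclei (VN1–VN5 plus the
intermediates "MN to VN" and "VN1 to 2"), generative nuclei (GN) and sperm
nuclei (SN). The vegetative nucleus undergoes dramatic epigenetic
reprogramming: active DNA demethylation by the DME/ROS1 glycosylases removes
CG (and some CHG) methylation at a defined set of regions ("CG hypo DMRs"),
while pericentromeric heterochromatin progressively gains CHH methylation.
The methyl-CpG readers MBD5/6 (a repressive complex) and MBD7 (an
anti-silencing complex) compete over densely CG-methylated loci; losing
MBD5/6 exposes their targets to extra demethylation in the VN, and a subset
of the resulting transcriptional derepression is reversed by additionally
losing MBD7.

Joint single-nucleus methylome + transcriptome sequencing (snmCT-seq)
measures both layers in the same haploid nucleus. This package implements
the downstream analysis for such data: format I/O, nucleus-level quality
control (including doublet and bisulfite-conversion filters that exploit the
haploid, post-deduplication structure of the data), marker-based cluster
assignment, cluster-resolved methylome aggregation, interval statistics for
ChIP peaks and DMRs, and the expression-side classifiers (rescue
classification, effect staging, homology calls). A synthetic-data generator
with full ground truth makes every stage testable without sequencing data.

# Coordinate and aggregation conventions

Two conventions are fixed package-wide and conversions are confined to the
I/O layer:

* interval tables (BED, bins, bedGraph) are **0-based half-open**;
* per-cytosine tables (allc format) are **1-based**; a site at position
  `p` lies in the BED interval `[p-1, p)`.

Every methylation average is a **weighted methylation level**:
`sum(mc) / sum(cov)` over the contributing cytosines — counts are pooled
first and divided once, never averaged per region and re-averaged. A site
inside overlapping regions of one set is counted once (union semantics);
this avoids double-weighting and is stated rather than inherited from any
particular upstream script. Cytosines are **not** strand-collapsed: each is
an independent record, as per-cytosine bisulfite extractors emit them.

Summaries, bins and metaprofile cells with no qualifying sites are
**missing (`NA`), never 0**. Conflating absence of coverage with absence of
methylation would manufacture artifactual hypomethylation, which is the
exact signal this analysis looks for.

TSS-proximal windows are the width-`2*radius` interval centred on the
0-based TSS position (default radius 400 bp), clipped at chromosome ends.
Genomic bins are left-aligned from the chromosome start with the final
partial bin kept; genome-wide averages exclude the chloroplast and
mitochondrial chromosomes unless asked otherwise.

# Quality control

Filters run in a fixed order — basic well filter, organelle RNA filter,
coverage-based doublet filter, conversion filter — and each only narrows
the passing set; every censored nucleus records the first filter it failed
as its single primary reason. Marker-ratio reassignment runs after
clustering.

**Basic well filter.** Pass requires at least 1000 transcriptome reads over
at least 200 genes and WGBS coverage in at least 10% of 1-kb genome bins
(all inclusive comparisons). We count a bin as covered when it contains at
least one covered cytosine, which is derivable from the allc table alone; a
read-based count would need alignments this package deliberately does not
consume.

**Organelle RNA filter.** Fails nuclei with strictly more than 10% of
gene-assigned reads on chloroplast/mitochondrial genes. The fraction is
computed over gene-assigned reads (computable from the count matrix), not
raw reads.

**Coverage-based doublet filter.** A haploid nucleus, after PCR-duplicate
removal, should never show two reads at one site. Real data still shows a
low multi-coverage rate that grows with total coverage, so an absolute rule
would be miscalibrated. We fit a robust trend of `f_multi` (fraction of
covered sites with coverage > 1) on `sites_ge1` across nuclei using
Theil–Sen regression (exact median of pairwise slopes — deterministic and
scale-robust; O(n²) but vectorised and fine for thousands of nuclei) and
flag nuclei whose positive residual exceeds `k_mad = 5` times the MAD of
residuals. Two nuclei sorted into one well produce site-wise coverage sums,
double-covering every jointly covered site, which places them far above the
trend. GN nuclei can legitimately carry two genome copies after S phase;
an `exempt` argument excludes them when cluster labels exist (off by
default, since this filter typically runs before clustering). Coverage-class
counts use nuclear chromosomes only: organelle copy number breaks the
haploid one-read expectation (true of real plastid data as well).

**Conversion filter.** The chloroplast genome is unmethylated, so apparent
chloroplast methylation measures bisulfite conversion failure. The default
rule censors nuclei whose chloroplast methylation exceeds
`median + 5 * MAD` across nuclei (a fixed absolute cutoff, default 0.02, is
the alternative; both strictly greater at the boundary). Because the ratio
alone can exceed the threshold by sampling noise in nuclei with few
chloroplast reads, a censored nucleus must additionally be a
Bonferroni-significant binomial outlier (family-wise level 0.01) against
the cohort's median error rate. Genuine conversion failures run an order of
magnitude above background and pass this guard at astronomical
significance; borderline clean nuclei are retained. Nuclei with no covered
chloroplast cytosines are "indeterminate", not passed.

**Marker-ratio reassignment.** Mature VN and SN physically associate and
co-sort, so VN+SN doublets concentrate in those clusters and evade the
coverage filter when coverage is low. For nuclei labelled VN4, VN5 or SN we
compute `r = log2((mean SN-marker cp10k + 1) / (mean VN-marker cp10k + 1))`
and relabel nuclei with `-0.2 <= r <= 0.2` (inclusive endpoints) to a
"VN and SN" class censored from methylome analyses. The pseudocount of 1 on
the counts-per-10k scale avoids log of zero without distorting expressed
markers.

# Cluster assignment

The package assigns nuclei to the ten-cluster pollen ontology by
nearest-marker-centroid scoring: counts are normalised to counts-per-10k,
log1p-transformed, each cluster scored as the mean normalised expression of
its markers, and the argmax taken (ties broken by ontology order; all-zero
nuclei are "unassigned"). This deterministic stand-in replaces graph
clustering + embedding, which belongs to an upstream interactive toolchain:
the downstream methylome math needs only labels, and the recovery surface
here is agreement with synthetic truth (the default generator yields
≥ 95%, and in practice 100%, agreement). The intermediate clusters
("MN to VN", "VN1 to 2") are defined by intermediacy in real data; the
stand-in requires explicit marker sets for them, which the synthetic panel
provides. The cp10k + log1p normalisation is common single-cell practice
and a free choice here.

# Methylome aggregation

`region_weighted_methylation()` produces the per-nucleus region summaries
(n_sites / avg_cov / avg_me); `pseudobulk_pool()` sums (mc, cov) site-wise
over all nuclei sharing a label, deterministically regardless of order, so
that region averages of a pooled track equal pooling the per-nucleus counts
(aggregation linearity — a tested invariant). `bin_methylation_fraction()`
tiles fixed-width bins (400 bp, 1 kb, 25 kb and 100 kb are the conventional
sizes for density bins, QC, methylome clustering input and chromosome
profiles respectively). `methylation_density()` implements the bulk-data
density: the sum over qualifying cytosines of per-site percent methylation
in 400-bp bins, counting only sites with at least 5 aligned reads — the
minimum-coverage convention for bulk data, versus 1 for single-nucleus data
where post-deduplication coverage is 0/1. `metaprofile()` is a
compute-matrix analogue: region bodies scaled to a fixed number of bins,
fixed-width flanks, minus-strand regions reversed, counts pooled per bin.
Chromosome-wide profiles pool counts (coverage-weighted) rather than
averaging per-nucleus bin values; this is a stated choice.

# Interval statistics

**Dominance deciles.** The union of MBD6/MBD7 peaks is ranked by mean MBD7
enrichment; the top decile is MBD7-dominant, the bottom decile
MBD6-dominant, and the "middle 10%" is interpreted as the decile centred on
the median rank (the precise middle is not otherwise pinned down; the
choice is configurable). Ties break by peak id, so labels are deterministic
and order-invariant.

**Reciprocal overlap.** Two regions overlap when either is strictly more
than 50% covered by the other. Coverage is computed against the merged
partner set, so abutting partners jointly covering 60% count — whether
split partners should merge before the 50% test is not externally
specified; merging is this package's stated choice. Shuffled controls place
each interval uniformly at random on its own chromosome (length preserved,
placements non-overlapping, rejection-sampled with a bounded attempt
count), seeded and reproducible; a cross-chromosome mode draws chromosomes
length-proportionally.

**Signal-vs-density curves.** ChIP enrichment per 400-bp bin is regressed
on methylation density with loess (span 0.75, degree 2, direct surface so
predictions are exact rather than interpolated), evaluated on an even grid
with a residual-sd band. On noise-free linear data the local regression
reproduces the line to numerical precision — a tested exactness property.
Enrichment values are consumed as precomputed log2(IP/control); computing
them from alignments is out of scope.

# Expression classifiers

**DE thresholds.** Upregulated means adjusted p < 0.05 and log2FC > 1
(both strict); missing adjusted p-values are excluded.

**Rescue classification.** Restricted to the upregulated set, TPM rows are
z-scored across samples, clustered (correlation distance, average linkage
by default — the parameters are deliberately exposed rather than fixed,
since no canonical setting exists) and cut into k = 4 clusters. Each
cluster is labelled by its centroid rescue index on unscaled TPM,
`rho = (mean(mbd5/6) - mean(mbd5/6/7)) / (mean(mbd5/6) - mean(WT))`:
rho ≥ 0.75 rescued, 0.25 ≤ rho < 0.75 partially rescued, rho < 0.25 not
rescued; clusters whose members' per-transcript rho dispersion exceeds 0.35
are omitted. The 0.75/0.25 thresholds and the dispersion rule are this
package's operationalisation of a visual clustering; the accuracy surface
is recovery of synthetic truth (≥ 90% at the default noise), not any
particular published split, which depends on raw data.

**Effect staging.** Cohen's d with the pooled standard deviation, binned by
strict |d| thresholds: n.e. (≤ 0.2), `*` (> 0.2), `**` (> 0.5), `***`
(> 0.9), `****` (> 1.5), with a two-sided t-test p-value; p < 0.001 is the
"red star" significance convention. Zero pooled sd with equal means gives
d = 0; with unequal means it is an error rather than an infinity.

**Homology.** Per locus, best gene bitscore g and best TE/TE-gene bitscore
t: a single-sided hit needs bitscore > 100 (strict); with hits on both
sides the higher class wins when its best bitscore is at least 3x the other
(inclusive), otherwise "ambiguous"; no qualifying hit on either side is
"neither". "No significant homology" is operationalised as no hit row
(significance filtering happens in the BLAST step upstream); best hits are
compared, not summed bitscores.

# The synthetic-data generator

`simulate_dataset()` is first-class, tested code, not a fixture: it
generates nuclei with known cluster, genotype, doublet and
conversion-status labels under the statistical structure the analysis
assumes, so recovery of planted truth is the acceptance surface for the
full pipeline.

**What it emulates.**

* Haploid coverage: each lattice cytosine is covered Bernoulli(c) per
  nucleus (c uniform in 0.02–0.08 across nuclei), one read per covered
  site, matching ≤1x post-deduplication data. A small residual
  multi-coverage rate proportional to the nucleus's coverage (baseline
  0.05 · c) reproduces the observed low, coverage-correlated background of
  >1x sites that the doublet trend is fitted against. GN can optionally be
  simulated with two genome copies (post S-phase).
* Chloroplast copy number: plastid sites get a 10x coverage boost, and the
  conversion-error floor puts apparent organelle methylation at 0.005.
  Conversion-failure nuclei (2% by default) have all apparent rates
  inflated by a factor drawn from 0.2–0.4 — an order of magnitude above
  background, as real failed wells are.
* The trajectory: CG at CG-hypo DMRs falls 0.80 → 0.65 → 0.50 → 0.40 →
  0.32 across MN → MNtoVN → VN1 → VN1to2 → VN2 and stays at 0.30 for
  VN3–VN5 (the plateau); CHG falls mildly in parallel; CHH at CHH-hyper
  DMRs and in the pericentromere rises linearly along the trajectory.
  GN/SN sit near somatic levels with slightly higher CG in SN. These
  numbers encode the qualitative timing claims (early active
  demethylation, mid-trajectory plateau, progressive CHH gain) as
  generative defaults; no quantitative effect sizes are published for the
  mutants, so the defaults are free parameters documented here, not
  claimed to match any dataset.
* Genotype effects: in VN clusters, `mbd5/6` multiplies CG/CHG rates at
  MBD6-peak ∩ CG-hypo regions by 0.5; `mbd5/6/7` restores the wild-type
  rate at the 60% of those regions labelled "rescued" and keeps the
  `mbd5/6` rate at the rest.
* Region layout: 50 CG-hypo DMRs (2 kb) in chromosome arms, 40 CHH-hyper
  DMRs (1.5 kb) in the pericentromere (the centred 30% of each nuclear
  chromosome), 60 MBD6 peaks (1 kb, 60% planted on DMRs), 40 MBD7 peaks
  (800 bp, 50% on MBD6 peaks), placed deterministically and evenly so the
  layout is valid by construction; shuffled-control enrichment then
  reflects the planted 60% against a ~9% uniform expectation.
* RNA: 300 genes (5 markers for each of the 10 clusters at 20x weight, 240
  background genes, 10 organelle genes at ~3% of reads), multinomial
  counts with log-normal library sizes around 3000 reads — comfortably
  above the basic-filter thresholds, so QC failures are driven by the
  planted defects, not by depth.
* Doublets: 5% of nuclei become mature-VN + SN pairs (the pairing observed
  in real pollen sorting) by site-wise (mc, cov) summation and RNA-count
  addition, donors removed, totals conserved.

**What it does not emulate,** and hence what passing tests do not show:
read-level error, mapping bias, chimeric reads, barcode collisions beyond
whole-nucleus doublets, genuine biological covariance between methylation
and expression within a nucleus, DMR discovery (region sets are inputs
here), or cluster structure that is only separable by graph methods. The
generator's marker separation makes centroid assignment nearly perfect;
real data is harder, and the assignment module is a labelled stand-in, not
a clustering benchmark.

All randomness flows from the single config seed; identical seed gives
byte-identical datasets (a tested invariant), and the pipeline manifest
checks the same property end-to-end via content checksums.

# Problem sizes and statistical calibration of the checks

The recovery experiments run at: 10 × ~1000 nuclei (doublets, seeds 1–10),
5 × 300 (conversion), 4000 WT nuclei (trajectory), 6000 across three
genotypes (genotype effects), 200 transcripts (rescue), 400 nuclei
(assignment). One calibration is worth stating: between two identical
distributions the sampling sd of an estimated Cohen's d is about
sqrt(2/n) per group, i.e. ~0.10 at 200 nuclei per cluster — not small
against a 0.2 flatness band across three pairwise plateau comparisons. The
trajectory experiment therefore uses 400 nuclei per cluster, putting the
estimator's noise (~0.07) safely inside the band while leaving every
generative rate untouched.

# Known limitations

* Theil–Sen is exact median-of-pairs; beyond ~10⁴ nuclei the O(n²) pair
  set becomes memory-heavy and a subsampled or binned variant would be
  preferable.
* The doublet filter assumes doublets are full coverage sums; partial
  (fragmented) doublets with weaker multi-coverage signatures fall back to
  the marker-ratio filter, which only covers mature VN/SN pairs.
* `classify_rescue` labels clusters, not transcripts; a transcript
  misplaced by the clustering inherits its cluster's label. The per-
  transcript rescue index is reported so such cases can be audited.
* The marker-centroid assigner cannot discover clusters absent from the
  panel, and scores are not calibrated probabilities.
* bedGraph export run-length merges only exactly adjacent equal values; it
  is an exchange format here, not a compression format.
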