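# Marker-based assignment of nuclei to the pollen cluster ontology. This is
# a deterministic nearest-marker-centroid stand-in for graph clustering:
# downstream methylome math needs only labels, and ground-truth recovery on
# synthetic data is the accuracy surface.

#' The pollen nucleus cluster ontology, in trajectory order
#'
#' Microspore nuclei (MN) transition into vegetative nuclei (MN to VN,
#' VN1..VN5 along maturation) while the generative nucleus (GN) divides
#' into sperm nuclei (SN).
#'
#' @return Character vector of the ten cluster labels.
#' @export
pollen_ontology <- function() {
  c("MN", "MNtoVN", "VN1", "VN1to2", "VN2", "VN3", "VN4", "VN5", "GN", "SN")
}

#' Construct a marker panel
#'
#' @param markers Tibble with columns `cluster` and `gene`; every cluster
#'   needs at least one marker.
#' @param ontology Cluster order used for trajectory plots and tie-breaks.
#' @return Validated tibble with the ontology stored as an attribute.
#' @export
marker_panel <- function(markers, ontology = pollen_ontology()) {
  stopifnot(all(c("cluster", "gene") %in% names(markers)))
  counts <- table(markers$cluster)
  missing <- setdiff(unique(markers$cluster), names(counts)[counts >= 1])
  if (length(missing)) stop("cluster(s) without markers: ", paste(missing, collapse = ", "))
  extra <- setdiff(unique(markers$cluster), ontology)
  if (length(extra)) {
    ontology <- c(ontology, sort(extra))
  }
  out <- tibble::as_tibble(markers[, c("cluster", "gene")])
  attr(out, "ontology") <- ontology
  out
}

#' Assign nuclei to clusters by marker-centroid score
#'
#' Normalises raw counts to counts-per-10k, applies log1p, scores each
#' nucleus against each cluster as the mean normalised expression of that
#' cluster's markers, and assigns the argmax label. Ties are broken by
#' ontology order; nuclei with zero total counts (or all-zero scores) are
#' `"unassigned"`. Fully deterministic and invariant to gene or nucleus
#' order.
#'
#' @param counts Genes-by-nuclei raw count matrix.
#' @param panel A [marker_panel()] tibble. Marker genes absent from the
#'   matrix are reported via a warning and ignored.
#' @return List with `labels` (tibble `nucleus`, `label`) and `scores`
#'   (nuclei x clusters matrix) for audit.
#' @export
assign_clusters <- function(counts, panel) {
  ontology <- attr(panel, "ontology")
  if (is.null(ontology)) ontology <- unique(panel$cluster)
  missing <- setdiff(panel$gene, rownames(counts))
  if (length(missing)) {
    warning(length(missing), " marker gene(s) missing from the count matrix")
    panel <- panel[panel$gene %in% rownames(counts), , drop = FALSE]
  }
  if (nrow(panel) == 0) stop("no marker genes present in the count matrix")
  clusters <- intersect(ontology, unique(panel$cluster))
  libsize <- colSums(counts)
  norm <- log1p(sweep(counts, 2, pmax(libsize, 1), "/") * 1e4)
  scores <- vapply(clusters, function(cl) {
    genes <- panel$gene[panel$cluster == cl]
    colMeans(norm[genes, , drop = FALSE])
  }, numeric(ncol(counts)))
  if (is.null(dim(scores))) scores <- matrix(scores, nrow = ncol(counts),
                                             dimnames = list(colnames(counts), clusters))
  best <- apply(scores, 1, function(s) {
    if (all(s == 0)) return(NA_integer_)
    which.max(s)  # first max in column order = ontology order tie-break
  })
  label <- unname(ifelse(is.na(best) | libsize == 0, "unassigned", clusters[best]))
  list(
    labels = tibble::tibble(nucleus = colnames(counts), label = label),
    scores = scores
  )
}
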