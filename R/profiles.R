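## Normalized fold-change expression profiles per cluster, marker
## selection, and signature-based cell-type annotation of metacells.

#' Normalized fold-change expression profiles
#'
#' For each gene and cluster, a regularized geometric mean of the
#' depth-downsampled counts, `exp(mean(ln(1 + u))) - 1`, divided (after
#' adding `eps`) by the per-gene lower median of that statistic across
#' clusters.  A fold change of 1 is therefore attained by an actual
#' cluster for every gene.
#'
#' @param counts Sparse genes x cells count matrix.
#' @param partition A `metacell_partition`, or a named vector of cluster
#'   labels per cell (e.g. cell types).
#' @param eps Regularization constant added to numerator and denominator
#'   (default 0.1).
#' @param downsample Downsample to a common depth first (default TRUE).
#' @param seed Seed for the internal downsampling.
#' @return A `fc_profile` list: `fc` and `geomean` (genes x clusters
#'   matrices), `eps`, `cluster_sizes`.
#' @export
compute_fc <- function(counts, partition, eps = 0.1, downsample = TRUE,
                       seed = 1) {
  labels <- if (inherits(partition, "metacell_partition"))
    partition$assignment else partition
  labels <- labels[colnames(counts)]
  keep <- !is.na(labels)
  if (!any(keep)) input_error("no cells assigned to any cluster")
  m <- counts[, keep, drop = FALSE]
  labels <- labels[keep]
  if (downsample) m <- downsample_cells(m, "auto", seed = seed)
  clusters <- sort(unique(labels))
  if (length(clusters) < 1) input_error("no non-empty cluster")
  lm1 <- log1p(as.matrix(m))
  geomean <- matrix(
    vapply(clusters, function(cl)
      expm1(rowMeans(lm1[, labels == cl, drop = FALSE])),
      numeric(nrow(m))),
    nrow = nrow(m),
    dimnames = list(rownames(m), as.character(clusters)))
  med <- apply(geomean, 1, lower_median)
  if (nrow(m) == 1) med <- unname(med)
  fc <- (geomean + eps) / (med + eps)
  structure(list(fc = fc, geomean = geomean, eps = eps,
                 cluster_sizes = table(labels)),
            class = "fc_profile")
}

#' Select marker genes per cluster
#'
#' Per cluster, genes with fold change at least `min_fc`, ordered by
#' decreasing fold change and truncated at `max_per_cluster`.  The
#' global gene display order follows each gene's argmax cluster (the
#' usual marker-heatmap convention).
#'
#' @param fc A `fc_profile`.
#' @param max_per_cluster Cap on markers per cluster (default 30).
#' @param min_fc Minimum fold change (default 2, inclusive).
#' @return A `marker_table` data.frame with columns `cluster`, `rank`,
#'   `gene`, `fc`, plus attribute `gene_order`.
#' @export
select_markers <- function(fc, max_per_cluster = 30, min_fc = 2) {
  stopifnot(inherits(fc, "fc_profile"))
  F <- fc$fc
  rows <- lapply(colnames(F), function(cl) {
    v <- F[, cl]
    sel <- which(v >= min_fc)
    if (!length(sel)) return(NULL)
    sel <- sel[order(-v[sel], rownames(F)[sel])]
    sel <- sel[seq_len(min(max_per_cluster, length(sel)))]
    data.frame(cluster = cl, rank = seq_along(sel),
               gene = rownames(F)[sel], fc = v[sel],
               stringsAsFactors = FALSE, row.names = NULL)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(cluster = character(0), rank = integer(0),
                      gene = character(0), fc = numeric(0))
  marker_genes <- unique(out$gene)
  if (length(marker_genes)) {
    argmax <- max.col(F[marker_genes, , drop = FALSE], ties.method = "first")
    gene_order <- marker_genes[order(argmax,
                                     -apply(F[marker_genes, , drop = FALSE],
                                            1, max))]
  } else gene_order <- character(0)
  attr(out, "gene_order") <- gene_order
  class(out) <- c("marker_table", "data.frame")
  out
}

#' Annotate metacells to cell types from marker signatures
#'
#' The score of metacell m for type t is the mean `log2` fold change of
#' t's signature genes in m; each metacell is assigned its argmax type
#' when the score reaches `floor`, and left unassigned otherwise.  Ties
#' go to the lexicographically first type label and are flagged.
#'
#' @param fc A `fc_profile`.
#' @param signatures Named list, type -> character vector of gene ids.
#' @param floor Minimum score for assignment (default 0.5).
#' @return A `celltype_annotation` list: `assignment` (data.frame
#'   `metacell`, `type`, `score`, `tied`), `scores` (metacells x types).
#' @export
annotate_cell_types <- function(fc, signatures, floor = 0.5) {
  stopifnot(inherits(fc, "fc_profile"))
  if (!length(signatures) || any(!vapply(signatures, length, 1L)))
    param_error("empty signature set")
  F <- fc$fc
  types <- sort(names(signatures))
  scores <- vapply(types, function(t) {
    genes <- signatures[[t]]
    missing <- setdiff(genes, rownames(F))
    if (length(missing))
      warning(sprintf("signature '%s': %d gene(s) not in profile, skipped",
                      t, length(missing)))
    genes <- intersect(genes, rownames(F))
    if (!length(genes)) param_error(
      sprintf("signature '%s' has no genes in the profile", t))
    colMeans(log2(F[genes, , drop = FALSE]))
  }, numeric(ncol(F)))
  scores <- matrix(scores, nrow = ncol(F),
                   dimnames = list(colnames(F), types))
  best <- apply(scores, 1, max)
  assigned <- apply(scores, 1, function(s) types[which.max(s)])
  tied <- apply(scores, 1, function(s) sum(s == max(s)) > 1)
  assigned[best < floor] <- NA_character_
  assignment <- data.frame(metacell = rownames(scores), type = assigned,
                           score = best, tied = tied,
                           stringsAsFactors = FALSE, row.names = NULL)
  structure(list(assignment = assignment, scores = scores,
                 signatures = signatures, floor = floor),
            class = "celltype_annotation")
}
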