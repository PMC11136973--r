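## Cross-species cell-type comparison: per-type marker statistics
## (rank-sum tests with BH adjustment), shared markers/TFs through
## orthology groups, and Pearson correlation of cell-type fold-change
## profiles.

#' One-sided Wilcoxon rank-sum p-value
#'
#' Tests whether values in `x` tend to be larger than values in `y`.
#' When both groups have at most `exact_max` observations and the pooled
#' values carry no ties, the p-value is computed by exact enumeration of
#' all group assignments; otherwise a normal approximation with tie
#' correction and continuity correction is used.
#'
#' @param x,y Numeric vectors.
#' @param exact_max Largest group size for the exact path (default 10).
#' @return One-sided p-value for `x > y`.
#' @export
rank_sum_p <- function(x, y, exact_max = 10) {
  nx <- length(x); ny <- length(y)
  r <- rank(c(x, y))
  w <- sum(r[seq_len(nx)])
  ties <- anyDuplicated(c(x, y)) > 0
  if (!ties && nx <= exact_max && ny <= exact_max) {
    # exact: enumerate all rank subsets of size nx
    sums <- combn(nx + ny, nx, FUN = sum)
    return(sum(sums >= w) / length(sums))
  }
  mu <- nx * (ny + nx + 1) / 2
  tie_tab <- table(r)
  n <- nx + ny
  sigma2 <- nx * ny / 12 *
    (n + 1 - sum(tie_tab^3 - tie_tab) / (n * (n - 1)))
  if (sigma2 <= 0) return(1)
  pnorm((w - mu - 0.5) / sqrt(sigma2), lower.tail = FALSE)
}

#' Per-gene, per-cell-type marker statistics
#'
#' For every gene and cell type: a one-sided rank-sum test of the type's
#' cells against all other cells on per-10,000 normalized expression, a
#' regularized fold change `(mean in type + eps) / (mean in rest +
#' eps)`, and BH adjustment across genes within each type.
#'
#' @param counts Sparse genes x cells count matrix.
#' @param labels Named cell-type labels per cell.
#' @param eps Regularization on mean normalized expression (default
#'   0.1).
#' @param exact_max Group-size limit for exact rank-sum enumeration.
#' @return A `marker_stats` data.frame: `gene`, `type`, `fc`, `p`,
#'   `p_adj`, plus attribute `small_types` flagging types with fewer
#'   than 3 cells.
#' @export
rank_markers <- function(counts, labels, eps = 0.1, exact_max = 10) {
  labels <- labels[colnames(counts)]
  types <- sort(unique(labels))
  if (length(types) < 2) param_error("need >= 2 cell types")
  small <- types[table(labels)[types] < 3]
  if (length(small))
    warning(sprintf("type(s) with < 3 cells: %s",
                    paste(small, collapse = ", ")))
  norm <- as.matrix(counts) %*%
    diag(1e4 / pmax(Matrix::colSums(counts), 1))
  norm <- as.matrix(norm)
  colnames(norm) <- colnames(counts)
  n_genes <- nrow(norm)
  # ranks per gene across all cells, computed once
  R <- t(apply(norm, 1, rank))
  rows <- list()
  for (t in types) {
    in_t <- labels == t
    nx <- sum(in_t); ny <- sum(!in_t)
    mean_in <- rowMeans(norm[, in_t, drop = FALSE])
    mean_out <- rowMeans(norm[, !in_t, drop = FALSE])
    fc <- (mean_in + eps) / (mean_out + eps)
    if (nx <= exact_max && ny <= exact_max) {
      p <- vapply(seq_len(n_genes), function(g)
        rank_sum_p(norm[g, in_t], norm[g, !in_t], exact_max), numeric(1))
    } else {
      w <- R[, in_t, drop = FALSE] %*% rep(1, nx)
      mu <- nx * (nx + ny + 1) / 2
      n <- nx + ny
      tie_term <- apply(R, 1, function(r) {
        tt <- table(r)
        sum(tt^3 - tt)
      })
      sigma2 <- nx * ny / 12 * (n + 1 - tie_term / (n * (n - 1)))
      z <- (as.vector(w) - mu - 0.5) / sqrt(pmax(sigma2, 1e-12))
      p <- pnorm(z, lower.tail = FALSE)
      p[sigma2 <= 0] <- 1
    }
    rows[[t]] <- data.frame(gene = rownames(norm), type = t, fc = fc,
                            p = p, p_adj = p.adjust(p, "BH"),
                            stringsAsFactors = FALSE, row.names = NULL)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "small_types") <- small
  class(out) <- c("marker_stats", "data.frame")
  out
}

orthology_groups <- function(orthology, species_a = "A", species_b = "B") {
  ga <- orthology[orthology$species == species_a, c("group_id", "gene_id")]
  gb <- orthology[orthology$species == species_b, c("group_id", "gene_id")]
  list(a = split(ga$gene_id, ga$group_id),
       b = split(gb$gene_id, gb$group_id))
}

#' Shared marker genes / TFs between cell types of two species
#'
#' For every cell-type pair, lists the orthology groups with at least
#' one gene passing the significance and fold-change thresholds in each
#' species' type.  With `tf_only`, genes are restricted to those flagged
#' as transcription factors.
#'
#' @param a,b `marker_stats` for species A and B.
#' @param orthology Orthology table (`group_id`, `species`, `gene_id`).
#' @param fc_min Minimum fold change (inclusive; use 1.25 with
#'   `tf_only` per the TF-sharing convention, which requires FC > 1.25 —
#'   the comparison is strict when `tf_only` is set).
#' @param p_max Maximum BH-adjusted p (default 0.05, strict `<`).
#' @param tf_only Restrict to TF-flagged genes.
#' @param tf_flags Named logical vector per gene id (both species).
#' @param species Character vector of the two species labels in
#'   `orthology` (default `c("A", "B")`).
#' @return A `shared_marker_graph` data.frame: `type_a`, `type_b`,
#'   `n_shared`, `shared` (semicolon-collapsed orthogroup ids).
#' @export
shared_features <- function(a, b, orthology, fc_min = 1, p_max = 0.05,
                            tf_only = FALSE, tf_flags = NULL,
                            species = c("A", "B")) {
  if (!nrow(orthology)) {
    warning("empty orthology table")
    return(structure(data.frame(type_a = character(0), type_b = character(0),
                                n_shared = integer(0), shared = character(0)),
                     class = c("shared_marker_graph", "data.frame")))
  }
  og <- orthology_groups(orthology, species[1], species[2])
  pass <- function(stats) {
    ok <- stats$p_adj < p_max &
      (if (tf_only) stats$fc > fc_min else stats$fc >= fc_min)
    if (tf_only) {
      if (is.null(tf_flags)) param_error("tf_only requires tf_flags")
      ok <- ok & stats$gene %in% names(tf_flags)[tf_flags]
    }
    stats[ok, , drop = FALSE]
  }
  pa <- pass(a); pb <- pass(b)
  group_of_a <- setNames(rep(names(og$a), lengths(og$a)), unlist(og$a))
  group_of_b <- setNames(rep(names(og$b), lengths(og$b)), unlist(og$b))
  pa$group <- group_of_a[pa$gene]
  pb$group <- group_of_b[pb$gene]
  pa <- pa[!is.na(pa$group), ]
  pb <- pb[!is.na(pb$group), ]
  rows <- list()
  for (ta in sort(unique(a$type))) {
    ga <- unique(pa$group[pa$type == ta])
    for (tb in sort(unique(b$type))) {
      gb <- unique(pb$group[pb$type == tb])
      common <- sort(intersect(ga, gb))
      if (length(common))
        rows[[length(rows) + 1L]] <- data.frame(
          type_a = ta, type_b = tb, n_shared = length(common),
          shared = paste(common, collapse = ";"),
          stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(type_a = character(0), type_b = character(0),
               n_shared = integer(0), shared = character(0))
  rownames(out) <- NULL
  class(out) <- c("shared_marker_graph", "data.frame")
  out
}

#' Cross-species correlation of cell-type fold-change profiles
#'
#' Many:many orthology groups contribute one meta-gene per species (the
#' mean fold change over member genes); meta-genes with fold change
#' above `fc_floor` in at least one cell type of either species are
#' kept, and the Pearson correlation between every pair of cell types is
#' computed on the linked fold-change vectors.  Pairs with fewer than 3
#' usable meta-genes are reported as missing.
#'
#' @param fc_a,fc_b `fc_profile`s (or genes x types matrices) by cell
#'   type for species A and B.
#' @param orthology Orthology table (`group_id`, `species`, `gene_id`).
#' @param fc_floor Fold-change filter (default 1.05, strict `>`).
#' @param species Species labels in `orthology`.
#' @return A `celltype_correlation` list: `matrix` (A-types x B-types),
#'   `best_match` (data.frame `type_a`, `type_b`, `r`), `n_genes`.
#' @export
celltype_correlation <- function(fc_a, fc_b, orthology, fc_floor = 1.05,
                                 species = c("A", "B")) {
  Fa <- if (inherits(fc_a, "fc_profile")) fc_a$fc else fc_a
  Fb <- if (inherits(fc_b, "fc_profile")) fc_b$fc else fc_b
  og <- orthology_groups(orthology, species[1], species[2])
  groups <- intersect(names(og$a), names(og$b))
  meta <- function(F, members) {
    members <- lapply(members, intersect, rownames(F))
    keep <- lengths(members) > 0
    m <- t(vapply(members[keep], function(g)
      colMeans(F[g, , drop = FALSE]), numeric(ncol(F))))
    rownames(m) <- names(members)[keep]
    m
  }
  Ma <- meta(Fa, og$a[groups])
  Mb <- meta(Fb, og$b[groups])
  groups <- intersect(rownames(Ma), rownames(Mb))
  Ma <- Ma[groups, , drop = FALSE]
  Mb <- Mb[groups, , drop = FALSE]
  use <- apply(Ma, 1, max) > fc_floor | apply(Mb, 1, max) > fc_floor
  Ma <- Ma[use, , drop = FALSE]
  Mb <- Mb[use, , drop = FALSE]
  mat <- matrix(NA_real_, ncol(Fa), ncol(Fb),
                dimnames = list(colnames(Fa), colnames(Fb)))
  if (nrow(Ma) >= 3)
    mat[] <- suppressWarnings(cor(Ma, Mb))
  best <- data.frame(
    type_a = rownames(mat),
    type_b = apply(mat, 1, function(r)
      if (all(is.na(r))) NA_character_ else colnames(mat)[which.max(r)]),
    r = apply(mat, 1, function(r) if (all(is.na(r))) NA_real_ else max(r,
      na.rm = TRUE)),
    stringsAsFactors = FALSE, row.names = NULL)
  structure(list(matrix = mat, best_match = best,
                 n_genes = nrow(Ma), fc_floor = fc_floor),
            class = "celltype_correlation")
}
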