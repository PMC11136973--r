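## Metacell construction: depth downsampling, feature selection, a
## balanced K-nearest-neighbor cell graph, bootstrap co-clustering and
## derivation of high-granularity cell clusters (metacells).

#' Downsample cells to a common UMI depth
#'
#' Cells whose total UMI count exceeds `target_depth` are subsampled
#' without replacement to exactly `target_depth`; shallower cells are
#' kept unchanged.  `"auto"` uses the 5th percentile of per-cell totals.
#'
#' @param counts Sparse genes x cells count matrix.
#' @param target_depth Positive integer or `"auto"`.
#' @param seed Integer seed.
#' @return Sparse matrix of the same shape.
#' @export
downsample_cells <- function(counts, target_depth = "auto", seed = 1) {
  if (nrow(counts) == 0 || ncol(counts) == 0)
    input_error("empty count matrix")
  totals <- Matrix::colSums(counts)
  if (identical(target_depth, "auto"))
    target_depth <- as.integer(floor(quantile(totals, 0.05, type = 1)))
  if (target_depth < 1) param_error("target_depth must be >= 1")
  with_seed(substream_seed(seed, "downsample"), {
    m <- methods::as(counts, "CsparseMatrix")
    out_x <- m@x
    for (j in which(totals > target_depth)) {
      idx <- (m@p[j] + 1L):m@p[j + 1L]
      cnt <- m@x[idx]
      # multivariate hypergeometric draw: sample positions in the
      # concatenated UMI multiset, bin by gene
      pos <- sample.int(totals[j], target_depth)
      bins <- findInterval(pos - 0.5, c(0, cumsum(cnt)))
      out_x[idx] <- tabulate(bins, nbins = length(cnt))
    }
    m@x <- out_x
    Matrix::drop0(m)
  })
}

#' Select informative genes for clustering
#'
#' A gene is selected when it passes all enabled filters: total UMI count
#' strictly above `t_tot`; more than `t_prev_umi` UMIs in at least
#' `t_prev_cells` cells; a size correlation (Pearson correlation between
#' the gene's depth-downsampled counts and the cells' pre-downsampling
#' totals) strictly below `t_szcor`; and a niche score (the fraction of
#' the gene's downsampled UMIs found in its top-5%-expressing cells,
#' minus 0.05) strictly above `t_niche`.  Set `t_szcor` or `t_niche` to
#' `NA` to disable that filter.
#'
#' @param counts Sparse genes x cells count matrix (raw).
#' @param t_tot Total-UMI threshold (default 30, strict `>`).
#' @param t_prev_cells Minimum number of cells for the prevalence rule.
#' @param t_prev_umi Per-cell UMI threshold for the prevalence rule
#'   (strict `>`).
#' @param t_szcor Size-correlation threshold (select below; `NA`
#'   disables).
#' @param t_niche Niche-score threshold (select above; `NA` disables).
#' @param downsampled Optional pre-computed downsampled matrix; computed
#'   with [downsample_cells()] otherwise.
#' @param seed Seed for the internal downsampling.
#' @return A `feature_set` list: `gene_ids` (selected genes) and `stats`
#'   (per-gene statistics for all genes).
#' @export
select_features <- function(counts, t_tot = 30, t_prev_cells = 3,
                            t_prev_umi = 2, t_szcor = -0.1, t_niche = 0.01,
                            downsampled = NULL, seed = 1) {
  if (nrow(counts) == 0 || ncol(counts) == 0)
    input_error("empty count matrix")
  if (is.null(downsampled))
    downsampled <- downsample_cells(counts, "auto", seed = seed)
  totals_pre <- Matrix::colSums(counts)
  tot <- Matrix::rowSums(counts)
  prev <- Matrix::rowSums(counts > t_prev_umi)
  ds <- as.matrix(downsampled)
  szcor <- suppressWarnings(as.vector(cor(t(ds), totals_pre)))
  n_top <- floor(0.05 * ncol(counts))
  gene_tot_ds <- rowSums(ds)
  niche <- apply(ds, 1, function(v) {
    if (n_top == 0) return(-0.05)
    s <- sum(sort(v, decreasing = TRUE)[seq_len(n_top)])
    tt <- sum(v)
    if (tt == 0) -0.05 else s / tt - 0.05
  })
  sel <- tot > t_tot & prev >= t_prev_cells
  if (!is.na(t_szcor)) sel <- sel & !is.na(szcor) & szcor < t_szcor
  if (!is.na(t_niche)) sel <- sel & niche > t_niche
  stats <- data.frame(
    gene = rownames(counts), total_umi = as.vector(tot),
    prevalence_cells = as.vector(prev), size_correlation = szcor,
    niche_score = niche, selected = as.vector(sel),
    stringsAsFactors = FALSE, row.names = NULL
  )
  structure(list(gene_ids = rownames(counts)[sel], stats = stats),
            class = "feature_set")
}

#' Build a balanced K-nearest-neighbor cell graph
#'
#' Cell-cell similarity is the Pearson correlation of
#' `log2(1 + downsampled counts)` over the feature genes.  Each cell
#' ranks all others (rank lists truncated at `3K`); the undirected edge
#' (i, j) is kept iff the rank product `r_ij * r_ji <= K^2`, with weight
#' `1 / (1 + sqrt(r_ij * r_ji))`.  Each node then retains at most `2K`
#' incident edges (strongest first; an edge survives only if both
#' endpoints retain it).  Ties in similarity are broken by cell order.
#'
#' @param counts Sparse genes x cells count matrix (raw).
#' @param features A `feature_set` or character vector of gene ids.
#' @param K Neighborhood size (default 100).
#' @param downsampled Optional pre-computed downsampled matrix.
#' @param seed Seed for the internal downsampling.
#' @return A `cell_graph` list: `nodes` (cell ids), `edges` (data.frame
#'   `i`, `j`, `weight` with integer node indices, i < j), `K`.
#' @export
build_balanced_knn <- function(counts, features, K = 100,
                               downsampled = NULL, seed = 1) {
  gene_ids <- if (inherits(features, "feature_set")) features$gene_ids
              else features
  if (length(gene_ids) < 2) param_error("need >= 2 feature genes")
  n <- ncol(counts)
  if (n < K + 1)
    param_error(sprintf(
      "need at least K + 1 = %d cells (got %d); lower K", K + 1, n))
  if (is.null(downsampled))
    downsampled <- downsample_cells(counts, "auto", seed = seed)
  X <- log2(1 + as.matrix(downsampled[gene_ids, , drop = FALSE]))
  S <- suppressWarnings(cor(X))
  S[is.na(S)] <- -1
  diag(S) <- -Inf
  cap <- min(3L * K, n - 1L)
  # ranks: r[i, j] = position of j in i's descending-similarity order
  R <- matrix(NA_integer_, n, n)
  for (i in seq_len(n)) {
    o <- order(S[i, ], decreasing = TRUE)
    R[i, o[seq_len(cap)]] <- seq_len(cap)
  }
  Rd <- R
  Rd[is.na(Rd)] <- Inf
  rp <- Rd * t(Rd)
  keep <- rp <= K^2
  keep[lower.tri(keep, diag = TRUE)] <- FALSE
  idx <- which(keep, arr.ind = TRUE)
  if (nrow(idx) == 0)
    return(structure(list(nodes = colnames(counts),
                          edges = data.frame(i = integer(0), j = integer(0),
                                             weight = numeric(0)),
                          K = K), class = "cell_graph"))
  w <- 1 / (1 + sqrt(rp[keep & upper.tri(keep)]))
  edges <- data.frame(i = idx[, 1], j = idx[, 2],
                      weight = 1 / (1 + sqrt(rp[idx])))
  # degree cap: each node keeps its 2K strongest edges; an edge must be
  # kept by both endpoints
  maxdeg <- 2L * K
  eid <- seq_len(nrow(edges))
  inc <- c(split(eid, edges$i), split(eid, edges$j))
  keep_edge <- rep(0L, nrow(edges))
  node_keep <- lapply(split(
    data.frame(eid = c(eid, eid), node = c(edges$i, edges$j),
               w = c(edges$weight, edges$weight)),
    c(edges$i, edges$j)),
    function(d) d$eid[order(-d$w, d$eid)][seq_len(min(maxdeg, nrow(d)))])
  votes <- tabulate(unlist(node_keep), nbins = nrow(edges))
  edges <- edges[votes == 2L, , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(nodes = colnames(counts), edges = edges, K = K),
            class = "cell_graph")
}

louvain_partition <- function(edges, n_nodes) {
  g <- igraph::graph_from_edgelist(as.matrix(edges[, c("i", "j")]),
                                   directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, n_nodes - igraph::vcount(g)))
  igraph::membership(igraph::cluster_louvain(g, weights = edges$weight))
}

#' Bootstrap co-clustering of a cell graph
#'
#' Repeatedly samples a fraction of the cells without replacement, runs
#' modularity-based community detection (Louvain) on the induced
#' subgraph, and counts, for every cell pair, how often the two cells
#' were sampled together (`cosample`) and clustered together
#' (`cocount`).
#'
#' @param graph A `cell_graph`.
#' @param n_iter Number of bootstrap iterations.
#' @param fraction Fraction of cells sampled per iteration, in `(0, 1]`.
#' @param seed Integer seed.
#' @return A `coclustering` list: `cocount` (sparse symmetric),
#'   `cosample` (dense symmetric), `n_iter`, `fraction`, `cell_ids`.
#' @export
bootstrap_cocluster <- function(graph, n_iter = 1000, fraction = 0.75,
                                seed = 1) {
  if (fraction <= 0 || fraction > 1)
    param_error("fraction must be in (0, 1]")
  n <- length(graph$nodes)
  if (n == 0 || nrow(graph$edges) == 0)
    input_error("graph has no nodes or no edges")
  m_samp <- as.integer(ceiling(fraction * n))
  e_i <- graph$edges$i
  e_j <- graph$edges$j
  e_w <- graph$edges$weight
  with_seed(substream_seed(seed, "bootstrap"), {
    # all cell samples drawn up front, so that the per-iteration
    # community-detection seed (a function of the sampled set) cannot
    # perturb the sampling stream; identical sampled sets then yield
    # identical partitions
    samples <- lapply(seq_len(n_iter), function(it)
      sort(sample.int(n, m_samp)))
    Smat <- matrix(0, n, n_iter)
    zi <- vector("list", n_iter)
    zj <- vector("list", n_iter)
    clust_base <- 0L
    for (it in seq_len(n_iter)) {
      samp <- samples[[it]]
      Smat[samp, it] <- 1
      in_samp <- logical(n)
      in_samp[samp] <- TRUE
      keep <- in_samp[e_i] & in_samp[e_j]
      if (!any(keep)) next
      map <- integer(n)
      map[samp] <- seq_along(samp)
      sub <- data.frame(i = map[e_i[keep]], j = map[e_j[keep]],
                        weight = e_w[keep])
      it_seed <- substream_seed(seed + sum(samp) %% 1000003,
                                "bootstrap_iter")
      memb <- with_seed(it_seed, louvain_partition(sub, length(samp)))
      zi[[it]] <- samp
      zj[[it]] <- as.integer(memb) + clust_base
      clust_base <- clust_base + max(memb)
    }
    Z <- Matrix::sparseMatrix(i = unlist(zi), j = unlist(zj), x = 1,
                              dims = c(n, clust_base))
    cocount <- Matrix::tcrossprod(Z)
    cosample <- tcrossprod(Smat)
    structure(list(cocount = cocount, cosample = cosample,
                   n_iter = n_iter, fraction = fraction,
                   cell_ids = graph$nodes),
              class = "coclustering")
  })
}

#' Derive metacells from bootstrap co-clustering frequencies
#'
#' Builds a graph on co-clustering frequencies `f_ij = cocount /
#' cosample`, keeps each cell's `K_cc` strongest partners, removes edges
#' whose frequency falls below `f_max / alpha` for both endpoints
#' (`f_max` being each endpoint's strongest frequency), partitions by
#' community detection, and dissolves clusters smaller than `min_size`
#' by reassigning members to the cluster with the largest summed
#' frequency (cells with no such cluster become outliers).
#'
#' @param cocluster A `coclustering`.
#' @param K_cc Partners kept per cell (default 30).
#' @param alpha Edge-filtering ratio (default 2); `Inf` disables.
#' @param min_size Minimum metacell size (default 15; 10 is used for
#'   subclustering runs).
#' @return A `metacell_partition`: `assignment` (named integer vector,
#'   `NA` = outlier), `min_size`, `params`.
#' @export
derive_metacells <- function(cocluster, K_cc = 30, alpha = 2,
                             min_size = 15) {
  n <- length(cocluster$cell_ids)
  tri <- Matrix::summary(methods::as(
    methods::as(cocluster$cocount, "generalMatrix"), "TsparseMatrix"))
  tri <- tri[tri$i < tri$j, , drop = FALSE]
  if (nrow(tri) == 0) input_error("degenerate co-clustering: no co-sampled pair")
  cs <- cocluster$cosample[cbind(tri$i, tri$j)]
  f <- tri$x / cs
  edges <- data.frame(i = tri$i, j = tri$j, f = f)
  edges <- edges[edges$f > 0, , drop = FALSE]
  # per-cell top-K_cc partners (an edge survives if either endpoint keeps it)
  eid <- seq_len(nrow(edges))
  long <- data.frame(eid = c(eid, eid), node = c(edges$i, edges$j),
                     f = c(edges$f, edges$f))
  kept <- unlist(lapply(split(long, long$node), function(d)
    d$eid[order(-d$f, d$eid)][seq_len(min(K_cc, nrow(d)))]))
  edges <- edges[sort(unique(kept)), , drop = FALSE]
  # alpha filter
  if (is.finite(alpha)) {
    fmax <- rep(0, n)
    agg <- tapply(c(edges$f, edges$f), c(edges$i, edges$j), max)
    fmax[as.integer(names(agg))] <- agg
    weak <- edges$f < fmax[edges$i] / alpha & edges$f < fmax[edges$j] / alpha
    edges <- edges[!weak, , drop = FALSE]
  }
  assignment <- rep(NA_integer_, n)
  names(assignment) <- cocluster$cell_ids
  if (nrow(edges) == 0) {
    warning("all co-clustering edges removed; every cell is an outlier")
    return(structure(list(assignment = assignment, min_size = min_size,
                          params = list(K_cc = K_cc, alpha = alpha)),
                     class = "metacell_partition"))
  }
  memb <- with_seed(substream_seed(1, "derive_metacells"),
                    louvain_partition(
                      data.frame(i = edges$i, j = edges$j,
                                 weight = edges$f), n))
  memb <- as.integer(memb)
  sizes <- tabulate(memb)
  big <- which(sizes >= min_size)
  if (length(big) == 0) {
    warning("no cluster reaches min_size; every cell is an outlier")
    return(structure(list(assignment = assignment, min_size = min_size,
                          params = list(K_cc = K_cc, alpha = alpha)),
                     class = "metacell_partition"))
  }
  final <- ifelse(memb %in% big, memb, NA_integer_)
  small_cells <- which(is.na(final))
  if (length(small_cells)) {
    # summed frequency from each dissolved cell to every surviving cluster
    tgt_i <- final[edges$i]
    tgt_j <- final[edges$j]
    cand <- rbind(
      data.frame(cell = edges$i[!is.na(tgt_j)], clust = tgt_j[!is.na(tgt_j)],
                 f = edges$f[!is.na(tgt_j)]),
      data.frame(cell = edges$j[!is.na(tgt_i)], clust = tgt_i[!is.na(tgt_i)],
                 f = edges$f[!is.na(tgt_i)]))
    cand <- cand[cand$cell %in% small_cells, , drop = FALSE]
    if (nrow(cand)) {
      sums <- stats::aggregate(f ~ cell + clust, cand, sum)
      best <- do.call(rbind, lapply(split(sums, sums$cell), function(d)
        d[order(-d$f, d$clust)[1], ]))
      final[best$cell] <- best$clust
    }
  }
  # renumber surviving clusters in order of first-member appearance
  ids <- unique(final[!is.na(final)])
  assignment[] <- match(final, ids)
  structure(list(assignment = assignment, min_size = min_size,
                 params = list(K_cc = K_cc, alpha = alpha)),
            class = "metacell_partition")
}

#' Remove metacells with low transcriptomic information
#'
#' A metacell is marked outlier when it has more than `min_cells` cells
#' and a median per-cell total UMI strictly below `min_median_umi`.
#'
#' @param partition A `metacell_partition`.
#' @param counts The raw genes x cells count matrix.
#' @param min_cells Size condition (strict `>`).
#' @param min_median_umi Median-depth condition (strict `<`).
#' @return The filtered `metacell_partition`.
#' @export
filter_low_quality_metacells <- function(partition, counts,
                                         min_cells = 50,
                                         min_median_umi = 500) {
  stopifnot(all(names(partition$assignment) %in% colnames(counts)))
  totals <- Matrix::colSums(counts)[names(partition$assignment)]
  a <- partition$assignment
  for (mc in unique(a[!is.na(a)])) {
    cells <- which(!is.na(a) & a == mc)
    if (length(cells) > min_cells &&
        median(totals[cells]) < min_median_umi)
      a[cells] <- NA_integer_
  }
  partition$assignment <- a
  partition
}

#' Force-directed 2D layout of the metacell co-clustering graph
#'
#' Metacells are embedded by a Fruchterman-Reingold layout of the
#' metacell-level co-clustering graph (mean cell-pair frequency between
#' metacells); cells are jittered around their metacell's position.
#'
#' @param cocluster A `coclustering`.
#' @param partition A `metacell_partition` over the same cells.
#' @param seed Integer seed.
#' @return List of data.frames `metacells` (`metacell`, `x`, `y`) and
#'   `cells` (`cell_id`, `metacell`, `x`, `y`; outliers omitted).
#' @export
layout_2d <- function(cocluster, partition, seed = 1) {
  a <- partition$assignment
  mcs <- sort(unique(a[!is.na(a)]))
  if (length(mcs) == 0) input_error("no metacells to lay out")
  with_seed(substream_seed(seed, "layout"), {
    if (length(mcs) == 1) {
      coords <- matrix(0, 1, 2)
    } else {
      tri <- Matrix::summary(methods::as(
        methods::as(cocluster$cocount, "generalMatrix"), "TsparseMatrix"))
      tri <- tri[tri$i < tri$j, , drop = FALSE]
      cs <- cocluster$cosample[cbind(tri$i, tri$j)]
      f <- tri$x / cs
      mi <- a[tri$i]
      mj <- a[tri$j]
      ok <- !is.na(mi) & !is.na(mj) & mi != mj
      g <- igraph::make_empty_graph(length(mcs), directed = FALSE)
      if (any(ok)) {
        agg <- stats::aggregate(
          f ~ mi + mj, data.frame(mi = pmin(mi[ok], mj[ok]),
                                  mj = pmax(mi[ok], mj[ok]), f = f[ok]),
          mean)
        g <- igraph::add_edges(
          g, rbind(match(agg$mi, mcs), match(agg$mj, mcs)))
        igraph::E(g)$weight <- agg$f
      }
      coords <- igraph::layout_with_fr(g)
    }
    metacells <- data.frame(metacell = mcs, x = coords[, 1], y = coords[, 2])
    cells_in <- which(!is.na(a))
    pos <- coords[match(a[cells_in], mcs), , drop = FALSE]
    cells <- data.frame(
      cell_id = names(a)[cells_in], metacell = a[cells_in],
      x = pos[, 1] + rnorm(length(cells_in), 0, 0.05),
      y = pos[, 2] + rnorm(length(cells_in), 0, 0.05),
      stringsAsFactors = FALSE)
    list(metacells = metacells, cells = cells)
  })
}

#' Label cells by their metacell's majority truth type
#'
#' @param partition A `metacell_partition`.
#' @param labels Named truth labels per cell.
#' @return Named character vector of predicted labels (`NA` for
#'   outliers).
#' @export
metacell_majority_labels <- function(partition, labels) {
  a <- partition$assignment
  labels <- labels[names(a)]
  out <- rep(NA_character_, length(a))
  names(out) <- names(a)
  for (mc in unique(a[!is.na(a)])) {
    cells <- !is.na(a) & a == mc
    tab <- sort(table(labels[cells]), decreasing = TRUE)
    out[cells] <- names(tab)[1]
  }
  out
}

#' Run the full metacell clustering pipeline on a count matrix
#'
#' Downsampling, feature selection, balanced KNN graph, bootstrap
#' co-clustering, metacell derivation and the low-quality filter in one
#' call.  Defaults follow the reference analysis (K = 100, K_cc = 30,
#' 1000 x 75% bootstrap, alpha = 2, min_size = 15); pass `min_size = 10`
#' for subclustering runs on cell subsets.
#'
#' @param counts Sparse genes x cells count matrix.
#' @param K,K_cc,n_iter,fraction,alpha,min_size Clustering parameters.
#' @param t_tot,t_prev_cells,t_prev_umi,t_szcor,t_niche Feature-selection
#'   thresholds (see [select_features()]).
#' @param min_cells,min_median_umi Low-quality metacell filter.
#' @param seed Integer seed.
#' @return List with `partition`, `features`, `graph`, `cocluster`,
#'   `downsampled`.
#' @export
cluster_cells <- function(counts, K = 100, K_cc = 30, n_iter = 1000,
                          fraction = 0.75, alpha = 2, min_size = 15,
                          t_tot = 30, t_prev_cells = 3, t_prev_umi = 2,
                          t_szcor = -0.1, t_niche = 0.01,
                          min_cells = 50, min_median_umi = 500, seed = 1) {
  ds <- downsample_cells(counts, "auto", seed = seed)
  feats <- select_features(counts, t_tot, t_prev_cells, t_prev_umi,
                           t_szcor, t_niche, downsampled = ds)
  graph <- build_balanced_knn(counts, feats, K = K, downsampled = ds)
  cocl <- bootstrap_cocluster(graph, n_iter = n_iter, fraction = fraction,
                              seed = seed)
  part <- derive_metacells(cocl, K_cc = K_cc, alpha = alpha,
                           min_size = min_size)
  part <- filter_low_quality_metacells(part, counts, min_cells,
                                       min_median_umi)
  list(partition = part, features = feats, graph = graph,
       cocluster = cocl, downsampled = ds)
}
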