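## Synthetic expression ground truth: planted cell types with marker
## programs, and multinomial UMI sampling at realistic depths.

#' Default per-cell sequencing depth law
#'
#' Log-normal depths with a median of 1,000 UMIs per cell, truncated to
#' `[200, 20000]` — the shallow plate-based scRNA-seq regime the rest of
#' the pipeline is tuned for.
#'
#' @param median Median UMIs per cell.
#' @param sdlog Log-scale standard deviation.
#' @param min,max Truncation bounds.
#' @return A depth-law specification list.
#' @export
depth_law_lognormal <- function(median = 1000, sdlog = 0.45,
                                min = 200, max = 20000) {
  list(type = "lognormal", median = median, sdlog = sdlog,
       min = min, max = max)
}

#' Constant depth law
#' @param depth UMIs per cell.
#' @return A depth-law specification list.
#' @export
depth_law_constant <- function(depth) {
  list(type = "constant", depth = depth)
}

draw_depths <- function(law, n) {
  d <- switch(law$type,
    constant = rep(as.integer(law$depth), n),
    lognormal = {
      x <- rlnorm(n, meanlog = log(law$median), sdlog = law$sdlog)
      as.integer(round(pmin(pmax(x, law$min), law$max)))
    },
    param_error(sprintf("unknown depth law type '%s'", law$type))
  )
  if (any(d < 1)) param_error("depth law produced non-positive depths")
  d
}

#' Plant a cell-type expression ground truth
#'
#' Builds a genes x types program matrix (columns sum to 1) over a shared
#' symmetric-Dirichlet baseline, planting `markers_per_type` distinct
#' marker genes per type whose within-type program value exceeds the value
#' in every other type by exactly the requested fold factor.  Marker genes
#' share a common baseline mass so that the fold factor survives column
#' normalization exactly.
#'
#' @param n_types Number of cell types (>= 2).
#' @param n_genes Total number of genes.
#' @param markers_per_type Distinct marker genes planted per type.
#' @param fold_levels Positive fold factors, recycled across each type's
#'   markers.
#' @param seed Integer seed.
#' @return A `truth_atlas` list with `n_types`, `types`, `program_matrix`
#'   (genes x types), `marker_map` (data.frame of `type`, `gene`, `fold`)
#'   and `baseline`.
#' @export
make_expression_truth <- function(n_types, n_genes, markers_per_type,
                                  fold_levels = 8, seed = 1) {
  if (n_types < 2) param_error("n_types must be >= 2")
  if (markers_per_type < 1) param_error("markers_per_type must be >= 1")
  if (n_genes < n_types * markers_per_type + 1)
    param_error("n_genes too small for the requested markers")
  if (any(fold_levels <= 0)) param_error("fold_levels must be positive")
  with_seed(substream_seed(seed, "expression_truth"), {
    genes <- sprintf("g%04d", seq_len(n_genes))
    types <- sprintf("type%02d", seq_len(n_types))
    n_mark <- n_types * markers_per_type
    marker_genes <- sample(genes, n_mark)
    # shared baseline: Dirichlet(1) over non-marker genes, a fixed equal
    # mass for marker genes so planted ratios are exact after normalization
    base <- numeric(n_genes)
    names(base) <- genes
    non_mark <- setdiff(genes, marker_genes)
    w <- stats::rexp(length(non_mark))
    base[non_mark] <- w / sum(w) * (1 - n_mark / n_genes)
    base[marker_genes] <- 1 / n_genes
    folds <- rep_len(fold_levels, markers_per_type)
    program <- matrix(base, nrow = n_genes, ncol = n_types,
                      dimnames = list(genes, types))
    marker_map <- data.frame(
      type = rep(types, each = markers_per_type),
      gene = marker_genes,
      fold = rep(folds, n_types),
      stringsAsFactors = FALSE
    )
    for (i in seq_len(nrow(marker_map)))
      program[marker_map$gene[i], marker_map$type[i]] <-
        base[marker_map$gene[i]] * marker_map$fold[i]
    program <- sweep(program, 2, colSums(program), "/")
    structure(
      list(n_types = n_types, types = types, program_matrix = program,
           marker_map = marker_map, baseline = base),
      class = "truth_atlas"
    )
  })
}

#' Sample a UMI count matrix from a planted truth
#'
#' Each cell's counts are a multinomial draw from its type's program
#' column, at a depth drawn from `depth_law`.
#'
#' @param truth A `truth_atlas` from [make_expression_truth()].
#' @param cells_per_type Cells sampled per type.
#' @param depth_law Depth specification, see [depth_law_lognormal()].
#' @param seed Integer seed.
#' @return List with `counts` (sparse genes x cells dgCMatrix), `labels`
#'   (named character vector, cell -> type) and `depths`.
#' @export
sample_umi_matrix <- function(truth, cells_per_type,
                              depth_law = depth_law_lognormal(), seed = 1) {
  if (!inherits(truth, "truth_atlas")) input_error("truth must be a truth_atlas")
  if (cells_per_type < 1) param_error("cells_per_type must be >= 1")
  with_seed(substream_seed(seed, "umi_sampling"), {
    n_cells <- cells_per_type * truth$n_types
    depths <- draw_depths(depth_law, n_cells)
    labels <- rep(truth$types, each = cells_per_type)
    cells <- sprintf("c%05d", seq_len(n_cells))
    counts <- matrix(0L, nrow = nrow(truth$program_matrix), ncol = n_cells)
    for (j in seq_len(n_cells))
      counts[, j] <- rmultinom(1, depths[j], truth$program_matrix[, labels[j]])
    counts <- Matrix::Matrix(counts, sparse = TRUE)
    dimnames(counts) <- list(rownames(truth$program_matrix), cells)
    names(labels) <- cells
    names(depths) <- cells
    list(counts = counts, labels = labels, depths = depths)
  })
}
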