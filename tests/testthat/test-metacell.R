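test_that("downsampling hits the target exactly and never inflates", {
  m <- make_toy_counts(30, 12, lambda = 50)
  ds <- downsample_cells(m, 100, seed = 1)
  before <- Matrix::colSums(m)
  after <- Matrix::colSums(ds)
  expect_true(all(after[before > 100] == 100))
  expect_true(all(after[before <= 100] == before[before <= 100]))
  expect_true(all(as.matrix(ds) <= as.matrix(m)))
  expect_identical(as.matrix(downsample_cells(m, 100, seed = 1)),
                   as.matrix(ds))
  # auto = 5th percentile of totals
  auto <- downsample_cells(m, "auto", seed = 1)
  tgt <- floor(quantile(before, 0.05, type = 1))
  expect_true(all(Matrix::colSums(auto) <= tgt))
  expect_error(downsample_cells(m[, 0]), class = "mcatlas_input_error")
})

test_that("feature selection applies the four thresholds", {
  # hand-built matrix: gene totals straddling the strict > 30 rule
  m <- matrix(0L, 4, 10,
              dimnames = list(c("tot30", "tot31", "sparse", "rich"),
                              sprintf("c%02d", 1:10)))
  m["tot30", ] <- 3L          # total exactly 30 -> excluded
  m["tot31", 1:9] <- 3L
  m["tot31", 10] <- 4L        # total 31, 3 UMI in >= 3 cells -> passes counts
  m["sparse", 1] <- 40L       # total 40 but 1 cell -> fails prevalence
  m["rich", ] <- c(10L, rep(3L, 9))
  fs <- select_features(Matrix::Matrix(m, sparse = TRUE),
                        t_szcor = NA, t_niche = NA)
  expect_false("tot30" %in% fs$gene_ids)
  expect_true("tot31" %in% fs$gene_ids)
  expect_false("sparse" %in% fs$gene_ids)
  expect_equal(nrow(fs$stats), 4)
  expect_true(all(c("total_umi", "prevalence_cells", "size_correlation",
                    "niche_score") %in% names(fs$stats)))
})

test_that("niche score is minimal for a uniformly expressed gene", {
  # 10x10 homogeneous toy: every gene identical in all cells
  m <- Matrix::Matrix(matrix(5L, 10, 10,
                             dimnames = list(sprintf("g%02d", 1:10),
                                             sprintf("c%02d", 1:10))),
                      sparse = TRUE)
  fs <- select_features(m, t_tot = 0, t_prev_cells = 0, t_prev_umi = 0,
                        t_szcor = NA, t_niche = 0.01)
  # brute force: top floor(0.05*10) = 0 cells hold fraction 0 -> score -0.05
  expect_true(all(fs$stats$niche_score == -0.05))
  expect_length(fs$gene_ids, 0)
})

test_that("balanced knn graph links identical cells at weight 1/2", {
  set.seed(2)
  base <- stats::rpois(40, 10)
  m <- Matrix::Matrix(cbind(base, base, sample(base), sample(base),
                            stats::rpois(40, 10)), sparse = TRUE)
  dimnames(m) <- list(sprintf("g%02d", 1:40), sprintf("c%02d", 1:5))
  g <- build_balanced_knn(m, rownames(m), K = 2, downsampled = m)
  e12 <- g$edges[g$edges$i == 1 & g$edges$j == 2, ]
  expect_equal(nrow(e12), 1)
  expect_equal(e12$weight, 0.5)
  # graph invariants: positive weights, no self edges, degree <= 2K
  expect_true(all(g$edges$weight > 0))
  expect_true(all(g$edges$i < g$edges$j))
  deg <- tabulate(c(g$edges$i, g$edges$j), nbins = 5)
  expect_true(all(deg <= 2 * g$K))
  expect_error(build_balanced_knn(m, rownames(m), K = 10),
               class = "mcatlas_param_error")
})

test_that("bootstrap co-clustering counts are consistent and bounded", {
  truth <- make_expression_truth(2, 80, 5, 8, seed = 3)
  umi <- sample_umi_matrix(truth, 30, depth_law_constant(600), seed = 3)
  g <- build_balanced_knn(umi$counts, rownames(umi$counts), K = 10,
                          downsampled = umi$counts)
  cc <- bootstrap_cocluster(g, n_iter = 50, fraction = 0.75, seed = 3)
  co <- as.matrix(cc$cocount)
  cs <- cc$cosample
  off <- upper.tri(co)
  expect_true(all(co[off] <= cs[off]))
  expect_true(all(cs <= cc$n_iter))
  expect_identical(co, t(co))
  # co-sample counts approx n_iter * fraction^2 (3 sigma binomial)
  p2 <- 0.75^2
  expected <- 50 * p2
  tol <- 3 * sqrt(50 * p2 * (1 - p2))
  expect_true(mean(abs(cs[off] - expected) <= tol + 6) > 0.95)
  expect_error(bootstrap_cocluster(g, 10, fraction = 1.5),
               class = "mcatlas_param_error")
})

test_that("full-sample bootstrap with a deterministic subroutine repeats", {
  truth <- make_expression_truth(2, 60, 5, 8, seed = 5)
  umi <- sample_umi_matrix(truth, 20, depth_law_constant(500), seed = 5)
  g <- build_balanced_knn(umi$counts, rownames(umi$counts), K = 5,
                          downsampled = umi$counts)
  cc <- bootstrap_cocluster(g, n_iter = 2, fraction = 1, seed = 9)
  f <- as.matrix(cc$cocount) / pmax(cc$cosample, 1)
  expect_true(all(f %in% c(0, 1)))
})

test_that("metacell derivation recovers planted cliques and applies min_size", {
  # two 20-cell cliques, within-frequency 1, between 0
  n <- 40
  blocks <- list(1:20, 21:40)
  pairs <- do.call(rbind, lapply(blocks, function(b)
    t(combn(b, 2))))
  cocount <- Matrix::sparseMatrix(i = pairs[, 1], j = pairs[, 2], x = 1,
                                  dims = c(n, n), symmetric = TRUE)
  cosample <- matrix(1, n, n)
  cc <- structure(list(cocount = cocount, cosample = cosample,
                       n_iter = 1, fraction = 1,
                       cell_ids = sprintf("c%02d", 1:n)),
                  class = "coclustering")
  part <- derive_metacells(cc, K_cc = 30, alpha = 2, min_size = 15)
  a <- part$assignment
  expect_equal(length(unique(a)), 2)
  expect_equal(length(unique(a[1:20])), 1)
  expect_equal(length(unique(a[21:40])), 1)
  expect_false(a[1] == a[21])
  # a 10-cell clique with min_size 15 and no outside edges -> all outliers
  small_pairs <- t(combn(1:10, 2))
  cc10 <- structure(list(
    cocount = Matrix::sparseMatrix(i = small_pairs[, 1],
                                   j = small_pairs[, 2], x = 1,
                                   dims = c(10, 10), symmetric = TRUE),
    cosample = matrix(1, 10, 10), n_iter = 1, fraction = 1,
    cell_ids = sprintf("c%02d", 1:10)), class = "coclustering")
  expect_warning(p10 <- derive_metacells(cc10, min_size = 15),
                 "outlier")
  expect_true(all(is.na(p10$assignment)))
  # alpha = Inf disables alpha-based edge removal but keeps the partition
  pinf <- derive_metacells(cc, K_cc = 30, alpha = Inf, min_size = 15)
  expect_equal(as.integer(table(pinf$assignment)), c(20L, 20L))
})

test_that("increasing min_size never increases the number of metacells", {
  truth <- make_expression_truth(4, 200, 8, 8, seed = 13)
  umi <- sample_umi_matrix(truth, 40, depth_law_constant(800), seed = 13)
  g <- build_balanced_knn(umi$counts, rownames(umi$counts), K = 15,
                          downsampled = umi$counts)
  cc <- bootstrap_cocluster(g, n_iter = 30, fraction = 0.75, seed = 13)
  n_mc <- sapply(c(5, 15, 30, 60), function(ms) {
    p <- suppressWarnings(derive_metacells(cc, min_size = ms))
    length(unique(stats::na.omit(p$assignment)))
  })
  expect_true(all(diff(n_mc) <= 0))
})

test_that("low-quality metacell filter applies both conditions strictly", {
  mk <- function(n, depth) {
    m <- Matrix::Matrix(matrix(rep(depth, n), nrow = 1), sparse = TRUE)
    m
  }
  # 60 cells at depth 400 (remove), 40 cells at 400 (keep),
  # 60 cells at 500 (keep: strict <)
  counts <- Matrix::Matrix(matrix(c(rep(400L, 60), rep(400L, 40),
                                    rep(500L, 60)), nrow = 1), sparse = TRUE)
  dimnames(counts) <- list("g1", sprintf("c%03d", 1:160))
  part <- structure(list(assignment = setNames(
    rep(1:3, c(60, 40, 60)), colnames(counts)),
    min_size = 15, params = list()), class = "metacell_partition")
  out <- filter_low_quality_metacells(part, counts, 50, 500)
  a <- out$assignment
  expect_true(all(is.na(a[1:60])))
  expect_true(all(a[61:100] == 2))
  expect_true(all(a[101:160] == 3))
})

test_that("2d layout is deterministic and separates metacells", {
  truth <- make_expression_truth(2, 80, 5, 8, seed = 21)
  umi <- sample_umi_matrix(truth, 30, depth_law_constant(600), seed = 21)
  g <- build_balanced_knn(umi$counts, rownames(umi$counts), K = 10,
                          downsampled = umi$counts)
  cc <- bootstrap_cocluster(g, n_iter = 20, seed = 21)
  part <- derive_metacells(cc, min_size = 10)
  l1 <- layout_2d(cc, part, seed = 2)
  l2 <- layout_2d(cc, part, seed = 2)
  expect_identical(l1, l2)
  expect_equal(nrow(l1$metacells), length(unique(na.omit(part$assignment))))
  if (nrow(l1$metacells) > 1) {
    d <- dist(l1$metacells[, c("x", "y")])
    expect_true(all(d > 0))
  }
  # single metacell at the origin
  one <- part
  one$assignment[] <- 1L
  l3 <- layout_2d(cc, one, seed = 1)
  expect_equal(unlist(l3$metacells[1, c("x", "y")]), c(x = 0, y = 0))
})

test_that("partition is total: member or outlier for every cell", {
  truth <- make_expression_truth(3, 150, 6, 8, seed = 17)
  umi <- sample_umi_matrix(truth, 50, depth_law_constant(700), seed = 17)
  res <- cluster_cells(umi$counts, K = 20, n_iter = 30, min_size = 10,
                       t_szcor = NA, seed = 17)
  a <- res$partition$assignment
  expect_setequal(names(a), colnames(umi$counts))
  expect_true(all(is.na(a) | a >= 1))
})

test_that("adjusted Rand index matches the mclust reference", {
  set.seed(8)
  for (i in 1:5) {
    a <- sample(1:4, 60, replace = TRUE)
    b <- sample(1:3, 60, replace = TRUE)
    expect_equal(adjusted_rand_index(a, b),
                 mclust::adjustedRandIndex(a, b), tolerance = 1e-12)
  }
  expect_equal(adjusted_rand_index(1:10, rep(1:5, 2) * 7), 0,
               tolerance = 1)  # bounded sanity on arbitrary labels
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(5, 5, 9, 9)), 1)
})
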