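one_hot_ppm <- function(bases, id = "onehot") {
  idx <- match(strsplit(bases, "")[[1]], c("A", "C", "G", "T"))
  m <- matrix(0, length(idx), 4)
  m[cbind(seq_along(idx), idx)] <- 1
  colnames(m) <- c("A", "C", "G", "T")
  motif_ppm(id, m, "de_novo")
}

test_that("column information content has the right closed forms", {
  expect_equal(column_ic(matrix(0.25, 1, 4)), 0)
  expect_equal(column_ic(matrix(c(1, 0, 0, 0), 1, 4)), 2)
  expect_equal(column_ic(matrix(c(0.5, 0.5, 0, 0), 1, 4)), 1)
  m <- rbind(c(0.25, 0.25, 0.25, 0.25), c(1, 0, 0, 0))
  expect_equal(unname(column_ic(m)), c(0, 2))
  expect_true(all(column_ic(make_motif_families(2, 2, seed = 1)$
                              motifs[[1]]$matrix) >= 0))
  expect_error(column_ic(matrix(c(0.5, 0.5, 0.5, 0.5), 1, 4)),
               class = "mcatlas_input_error")
})

test_that("contiguous IC filter applies the run and block rules", {
  mk <- function(ics, id) {
    # build a PPM whose per-column IC approximates the requested pattern:
    # IC 0 -> uniform, IC 1 -> two bases at 0.5, IC 2 -> one-hot
    rows <- lapply(ics, function(ic) {
      if (ic >= 2) c(1, 0, 0, 0)
      else if (ic >= 1) c(0.5, 0.5, 0, 0)
      else rep(0.25, 4)
    })
    motif_ppm(id, do.call(rbind, rows))
  }
  lib <- motif_library(list(
    mk(rep(0, 8), "uniform"),
    mk(c(2, 2, 2, 2), "run4"),
    mk(c(1, 1, 1, 0, 1, 1, 1), "blocks"),
    mk(c(1, 1, 0, 1, 1, 0, 1), "short_runs")))
  kept <- motif_ids(contiguous_ic_filter(lib))
  expect_setequal(kept, c("run4", "blocks"))
})

test_that("motif similarity is reflexive, rc-aware and symmetric", {
  m <- make_motif_families(1, 1, width = 8, seed = 2)$motifs[[1]]
  expect_equal(motif_similarity(m, m), 1, tolerance = 1e-12)
  rc <- motif_ppm("rc", mcatlas:::reverse_complement_ppm(m$matrix))
  expect_equal(motif_similarity(m, rc), 1, tolerance = 1e-12)
  other <- make_motif_families(1, 1, width = 8, seed = 99)$motifs[[1]]
  expect_equal(motif_similarity(m, other), motif_similarity(other, m),
               tolerance = 1e-12)
  # overlap shorter than min_overlap yields the -1 sentinel
  a4 <- one_hot_ppm("ACGT", "a4")
  b4 <- one_hot_ppm("TGCA", "b4")
  expect_equal(motif_similarity(a4, b4, min_overlap = 6), -1)
})

test_that("dedupe collapses planted copies and keeps the best IC", {
  base <- one_hot_ppm("ACGTACGT", "exact1")
  copies <- list(base,
                 motif_ppm("exact2", base$matrix),
                 motif_ppm("exact3", base$matrix),
                 motif_ppm("exact4", base$matrix),
                 motif_ppm("exact5", base$matrix),
                 make_motif_families(1, 1, width = 8, seed = 123)$motifs[[1]])
  lib <- dedupe_library(motif_library(copies))
  expect_equal(length(lib$motifs), 2)
  # 5 exact copies tie on IC; lexicographically first id is kept
  expect_true("exact1" %in% motif_ids(lib))
  expect_equal(nrow(lib$clusters), 6)
  # singleton library unchanged
  one <- motif_library(list(base))
  expect_equal(motif_ids(dedupe_library(one)), "exact1")
  # retained pairwise similarity below the threshold
  ids <- motif_ids(lib)
  for (i in seq_along(lib$motifs)[-1])
    expect_lt(motif_similarity(lib$motifs[[1]], lib$motifs[[i]]), 0.95)
})

test_that("scanning matches the brute-force scorer and finds planted sites", {
  set.seed(7)
  motif <- one_hot_ppm("ACGTAC", "m1")
  seq <- paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE),
               collapse = "")
  substr(seq, 21, 26) <- "ACGTAC"
  hits <- scan_regions(setNames(seq, "r1"),
                       motif_library(list(motif)),
                       score_fraction_min = 1)
  expect_true(any(hits$offset == 20 & hits$strand == "+"))
  expect_true(all(abs(hits$score_fraction - 1) < 1e-9))
  # every reported hit reproduces under the brute-force scorer, and the
  # brute-force scorer finds no additional hit above threshold
  oracle <- oracle_scan(seq, motif$matrix)
  max_score <- sum(log2(pmax(apply(motif$matrix, 1, max), 1e-3) / 0.25))
  want <- oracle[oracle$score >= max_score - 1e-9, ]
  expect_equal(nrow(hits), nrow(want))
  expect_setequal(paste(hits$offset, hits$strand),
                  paste(want$offset, want$strand))
  # lowering the threshold never removes a hit
  lo <- scan_regions(setNames(seq, "r1"), motif_library(list(motif)), 0.8)
  expect_true(all(paste(hits$offset, hits$strand) %in%
                    paste(lo$offset, lo$strand)))
  # N-runs never match; short regions yield no hits without error
  expect_equal(nrow(scan_regions(c(rN = strrep("N", 40)),
                                 motif_library(list(motif)), 0.8)), 0)
  expect_equal(nrow(scan_regions(c(rS = "ACG"),
                                 motif_library(list(motif)), 0.8)), 0)
})

test_that("scan scores agree numerically with the oracle at low threshold", {
  set.seed(17)
  fam <- make_motif_families(1, 1, width = 7, seed = 31)
  seq <- paste(sample(c("A", "C", "G", "T"), 50, replace = TRUE),
               collapse = "")
  hits <- scan_regions(setNames(seq, "r"), fam, score_fraction_min = 0)
  oracle <- oracle_scan(seq, fam$motifs[[1]]$matrix)
  oracle <- oracle[is.finite(oracle$score) & oracle$score >= -1e-9, ]
  merged <- merge(hits, oracle, by = c("offset", "strand"))
  hits_pos <- hits[hits$score >= 0, ]
  expect_equal(nrow(merged), nrow(hits_pos))
  expect_equal(merged$score.x, merged$score.y, tolerance = 1e-9)
})

test_that("best-only scanning keeps one leftmost top hit per region", {
  motif <- one_hot_ppm("ACGTAC", "m1")
  seq <- paste0(strrep("T", 5), "ACGTAC", strrep("T", 5), "ACGTAC",
                strrep("T", 4))
  hits <- scan_regions(setNames(seq, "r"), motif_library(list(motif)),
                       score_fraction_min = 1, best_only = TRUE)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$offset, 5)
  expect_equal(hits$strand, "+")
})

test_that("matched background reproduces GC, length and counts", {
  g <- make_genome(5, 3e5, gc_target = 0.45, min_spacing = 20000, seed = 5)
  reg <- make_peaks(g, 4, offset_law_uniform(-8000, 8000), seed = 5)
  std <- standardize_peaks(reg$peaks, 125,
                           setNames(Biostrings::width(g$seqs),
                                    names(g$seqs)))
  std <- reduce_overlaps(std)
  bg <- sample_matched_background(std, g$seqs, multiple = 2,
                                  n_gc_bins = 5, seed = 5)
  expect_equal(nrow(bg), 2 * nrow(std))
  expect_true(all(bg$end - bg$start == 250))
  # no overlap with any foreground region
  for (i in seq_len(nrow(bg)))
    expect_false(any(std$chrom == bg$chrom[i] &
                       std$start < bg$end[i] & bg$start[i] < std$end))
  # determinism
  bg2 <- sample_matched_background(std, g$seqs, 2, 5, seed = 5)
  expect_identical(bg, bg2)
  # GC matching: per-bin background GC within the bin's foreground range
  fg_gc <- gc_content(peak_sequences(std, g$seqs))
  bins <- ceiling(rank(fg_gc, ties.method = "first") /
                    (length(fg_gc) / 5))
  for (b in unique(bg$bin)) {
    rng <- range(fg_gc[bins == b])
    expect_true(all(bg$gc[bg$bin == b] >= rng[1] - 1e-9 &
                      bg$gc[bg$bin == b] <= rng[2] + 1e-9))
  }
})

test_that("binomial enrichment matches closed forms and BH", {
  # k = n = 10 hits in foreground, 0/20 in background
  fg_sets <- list(tA = list(high = sprintf("f%02d", 1:10)))
  bg_ids <- sprintf("b%02d", 1:20)
  hits <- data.frame(region = sprintf("f%02d", 1:10), motif = "m1",
                     stringsAsFactors = FALSE)
  enr <- binned_enrichment(fg_sets, bg_ids, hits)
  p0 <- 0.5 / 21
  expect_equal(enr$p0, p0)
  expect_equal(enr$p, oracle_binom_tail(10, 10, p0), tolerance = 1e-12)
  expect_equal(enr$log2fc, log2((10.5 / 11) / p0), tolerance = 1e-12)
  # identical fg/bg hit rates: log2FC ~ 0, p not significant
  hits2 <- data.frame(region = c(sprintf("f%02d", 1:5),
                                 sprintf("b%02d", 1:10)),
                      motif = "m1", stringsAsFactors = FALSE)
  enr2 <- binned_enrichment(fg_sets, bg_ids, hits2)
  expect_lt(abs(enr2$log2fc), 0.2)
  expect_gt(enr2$p, 0.1)
  # BH across motifs within a bin
  fg3 <- list(tA = list(high = sprintf("f%02d", 1:10)))
  hits3 <- rbind(
    data.frame(region = sprintf("f%02d", 1:9), motif = "mA"),
    data.frame(region = sprintf("f%02d", 1:8), motif = "mB"),
    data.frame(region = sprintf("f%02d", 1:7), motif = "mC"))
  enr3 <- binned_enrichment(fg3, bg_ids, hits3)
  expect_equal(enr3$p_adj, oracle_bh(enr3$p), tolerance = 1e-12)
  expect_true(all(enr3$p_adj >= enr3$p - 1e-15))
  expect_true(all(enr3$p_adj <= 1))
})

test_that("BH of (0.01, 0.02, 0.03) is (0.03, 0.03, 0.03)", {
  expect_equal(oracle_bh(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(p.adjust(c(0.01, 0.02, 0.03), "BH"), rep(0.03, 3))
})

test_that("empirical p follows the rank formula and flags empty bins", {
  fg <- data.frame(region = c("r1", "r2"), score = c(101, -5),
                   gc = c(0.4, 0.41))
  bg <- data.frame(score = seq_len(100), gc = rep(c(0.4, 0.41), 50))
  out <- empirical_hit_pvalue(fg, bg, n_gc_bins = 1)
  expect_equal(out$empirical_p[1], 1 / 101)
  expect_equal(out$empirical_p[2], 1)
  # empty bin: background GC far away still maps into a fg bin by range,
  # so force emptiness with no background at all
  expect_warning(
    out2 <- empirical_hit_pvalue(fg, bg[0, , drop = FALSE], 1),
    "no background")
  expect_true(all(is.na(out2$empirical_p)))
})

test_that("MEME round trip preserves motifs", {
  lib <- make_motif_families(3, 2, width = 9, seed = 77)
  path <- tempfile(fileext = ".meme")
  write_meme(lib, path)
  back <- read_meme(path, source = "de_novo")
  expect_equal(motif_ids(back), motif_ids(lib))
  for (i in seq_along(lib$motifs))
    expect_equal(back$motifs[[i]]$matrix, lib$motifs[[i]]$matrix,
                 tolerance = 2e-6)
})
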