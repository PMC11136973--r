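write_np <- function(peaks, path = tempfile(fileext = ".narrowPeak")) {
  write_narrowpeak(peaks, path)
  path
}

toy_peaks <- function(starts, neglog10_q = 10, summit_offset = 125,
                      width = 250, chrom = "chr1") {
  n <- length(starts)
  starts <- as.integer(starts)
  width <- as.integer(width)
  data.frame(chrom = chrom, start = starts, end = starts + width,
             name = sprintf("p%03d", seq_len(n)), score = 0L,
             strand = ".", signal = 1,
             neglog10_p = 12,
             neglog10_q = rep_len(neglog10_q, n),
             summit_offset = as.integer(rep_len(summit_offset, n)),
             stringsAsFactors = FALSE)
}

test_that("narrowPeak loading applies the q-value filter", {
  p <- toy_peaks(c(100, 500, 900), neglog10_q = c(6.5, 5.9, 6.0))
  path <- write_np(p)
  got <- load_and_filter_peaks(path, min_neglog10_q = 6)
  expect_setequal(got$name, c("p001", "p003"))
  # round-trip of retained fields
  expect_equal(got$start[got$name == "p001"], 100)
  expect_equal(got$summit_offset[got$name == "p001"], 125)
  # empty file warns and returns an empty set
  empty <- tempfile()
  file.create(empty)
  expect_warning(e <- load_and_filter_peaks(empty), "empty")
  expect_equal(nrow(e), 0)
  # malformed line rejected with its line number
  bad <- tempfile()
  writeLines(c(paste(rep("x", 10), collapse = "\t"), "too\tfew"), bad)
  expect_error(load_and_filter_peaks(bad), "2",
               class = "mcatlas_input_error")
})

test_that("standardization centers 250 bp on the summit with truncation", {
  p <- toy_peaks(c(400, 0), summit_offset = c(100, 50), width = 300)
  std <- standardize_peaks(p, 125, c(chr1 = 10000))
  # summit at 500 -> [375, 625)
  expect_equal(std$start[1], 375)
  expect_equal(std$end[1], 625)
  expect_false(std$truncated[1])
  expect_equal(std$end[1] - std$start[1], 250)
  # summit at 50 -> [0, 175), truncated
  expect_equal(std$start[2], 0)
  expect_equal(std$end[2], 175)
  expect_true(std$truncated[2])
  # summit outside the interval is rejected
  bad <- toy_peaks(100, summit_offset = 400, width = 250)
  expect_warning(out <- standardize_peaks(bad, 125, c(chr1 = 10000)),
                 "summit")
  expect_equal(nrow(out), 0)
})

test_that("overlap reduction merges transitively, keeping the best summit", {
  p <- toy_peaks(c(0, 1000), width = 250)
  expect_equal(nrow(reduce_overlaps(p)), 2)  # disjoint unchanged
  dup <- toy_peaks(c(100, 100), neglog10_q = c(5, 9))
  r <- reduce_overlaps(dup)
  expect_equal(nrow(r), 1)
  expect_equal(r$name, "p002")  # highest q member wins
  # chain A-B-C with A and C disjoint merges into one record
  chain <- toy_peaks(c(0, 200, 400), neglog10_q = c(1, 9, 2))
  rc <- reduce_overlaps(chain)
  expect_equal(nrow(rc), 1)
  expect_equal(rc$start, 0)
  expect_equal(rc$end, 650)
  expect_equal(rc$start + rc$summit_offset, 200 + 125)
})

test_that("promoter windows are strand-aware and accept external intervals", {
  genes <- data.frame(gene_id = c("gp", "gm"), chrom = "chr1",
                      tss = c(1000, 1000), strand = c("+", "-"),
                      stringsAsFactors = FALSE)
  pr <- define_promoters(genes, 50, 200)
  expect_equal(pr$start[pr$gene_id == "gp"], 950)
  expect_equal(pr$end[pr$gene_id == "gp"], 1200)
  expect_equal(pr$start[pr$gene_id == "gm"], 800)
  expect_equal(pr$end[pr$gene_id == "gm"], 1050)
  # external H3K4me3-style evidence overlapping the window is attributed
  ext <- toy_peaks(1100, width = 250)
  pre <- define_promoters(genes[1, ], 50, 200, external = ext)
  expect_equal(nrow(pre), 2)
  expect_setequal(pre$source, c("tss_window", "external"))
  # unknown strand treated as + with a warning
  gu <- data.frame(gene_id = "gu", chrom = "chr1", tss = 500,
                   strand = "?", stringsAsFactors = FALSE)
  expect_warning(pu <- define_promoters(gu), "strand")
  expect_equal(pu$start, 450)
})

test_that("assignment rules: both sides, shadowing, distance cap, promoters", {
  genes <- data.frame(gene_id = c("gA", "gB"), chrom = "chr1",
                      tss = c(1000, 5000), strand = "+",
                      stringsAsFactors = FALSE)
  promoters <- define_promoters(genes, 50, 200)
  # summit 3000: links to both genes, nothing intervening
  p1 <- toy_peaks(3000 - 125)
  a1 <- assign_peaks(p1, genes, promoters)
  expect_setequal(a1$gene_id, c("gA", "gB"))
  expect_true(all(!a1$is_promoter))
  # summit 12000 with TSSs at 10000 and 1000: only the proximal gene
  genes2 <- data.frame(gene_id = c("gNear", "gFar"), chrom = "chr1",
                       tss = c(10000, 1000), strand = "+",
                       stringsAsFactors = FALSE)
  a2 <- assign_peaks(toy_peaks(12000 - 125), genes2,
                     define_promoters(genes2))
  expect_equal(a2$gene_id, "gNear")
  # summit 35000, nearest TSS 10000: beyond 20 kbp, no link
  a3 <- assign_peaks(toy_peaks(35000 - 125), genes2,
                     define_promoters(genes2))
  expect_equal(nrow(a3), 0)
  # promoter overlap: exclusive single link
  a4 <- assign_peaks(toy_peaks(1000 - 125), genes, promoters)
  expect_equal(a4$gene_id, "gA")
  expect_true(a4$is_promoter)
  expect_false(a4$ambiguous)
  # two overlapping promoters: nearest TSS wins, flagged ambiguous
  genes3 <- data.frame(gene_id = c("g1", "g2"), chrom = "chr1",
                       tss = c(1000, 1100), strand = "+",
                       stringsAsFactors = FALSE)
  a5 <- assign_peaks(toy_peaks(1040 - 125), genes3,
                     define_promoters(genes3))
  expect_equal(nrow(a5), 1)
  expect_equal(a5$gene_id, "g1")
  expect_true(a5$ambiguous)
  # unknown chromosome: unassigned, message
  pX <- toy_peaks(1000)
  pX$chrom <- "chrX"
  expect_message(aX <- assign_peaks(pX, genes, promoters), "unassigned")
  expect_equal(nrow(aX), 0)
})

test_that("assignment matches the exhaustive oracle on random toys", {
  for (s in 1:60) {
    toy <- random_assignment_toy(s)
    prom <- define_promoters(toy$genes, 50, 200)
    got <- assign_peaks(toy$peaks, toy$genes, prom, 20000)
    want <- oracle_assign(toy$peaks, toy$genes, prom, 20000)
    got_df <- as.data.frame(got)
    attr(got_df, "class") <- "data.frame"
    expect_identical(
      got_df[, c("peak_id", "gene_id", "distance", "is_promoter",
                 "ambiguous")],
      want[, c("peak_id", "gene_id", "distance", "is_promoter",
               "ambiguous")],
      info = sprintf("toy seed %d", s))
  }
})

test_that("coordinates survive a 0-based/1-based round trip", {
  p <- toy_peaks(c(100, 400))
  gr <- mcatlas:::peaks_to_granges(p)
  back_start <- GenomicRanges::start(gr) - 1L
  back_end <- GenomicRanges::end(gr)
  expect_identical(back_start, p$start)
  expect_identical(back_end, p$end)
})

test_that("cell-type peak sets honor the FC bins and stay disjoint", {
  asg <- data.frame(peak_id = c("p1", "p2", "p3", "p4"),
                    gene_id = c("g1", "g2", "g3", "g4"),
                    distance = 0L, is_promoter = FALSE, ambiguous = FALSE,
                    stringsAsFactors = FALSE)
  F <- matrix(c(1.6, 1.3, 1.0, 1.05), 4, 1,
              dimnames = list(sprintf("g%d", 1:4), "typeA"))
  sets <- celltype_peak_sets(asg, F)
  expect_equal(sets$typeA$high, "p1")
  expect_equal(sets$typeA$mild, "p2")
  expect_equal(sets$typeA$background, "p3")
  # FC 1.05 falls in no bin; sets are pairwise disjoint
  all_ids <- unlist(sets$typeA)
  expect_false("p4" %in% all_ids)
  expect_equal(anyDuplicated(all_ids), 0L)
  # per-gene peak count distribution on synthetic data: median 2 with
  # peaks_per_gene = 2
  g <- make_genome(12, 6e5, min_spacing = 40000, seed = 3)
  reg <- make_peaks(g, peaks_per_gene = 2,
                    offset_law = offset_law_uniform(-9000, 9000), seed = 3)
  std <- standardize_peaks(reg$peaks, 125,
                           setNames(Biostrings::width(g$seqs),
                                    names(g$seqs)))
  asg2 <- assign_peaks(std, g$genes, define_promoters(g$genes))
  per_gene <- table(asg2$gene_id[!duplicated(paste(asg2$peak_id,
                                                   asg2$gene_id))])
  expect_equal(unname(median(per_gene[g$genes$gene_id[
    g$genes$gene_id %in% names(per_gene)]])), 2)
})

test_that("narrowPeak coordinates agree with the rtracklayer importer", {
  p <- toy_peaks(c(100, 900), neglog10_q = c(8, 12))
  path <- write_np(p)
  gr <- rtracklayer::import(path, format = "BED",
    extraCols = c(signalValue = "numeric", pValue = "numeric",
                  qValue = "numeric", peak = "integer"))
  got <- load_and_filter_peaks(path, 0)
  expect_equal(got$start, GenomicRanges::start(gr) - 1L)
  expect_equal(got$end, GenomicRanges::end(gr))
  expect_equal(got$summit_offset, gr$peak)
  expect_equal(got$neglog10_q, gr$qValue)
})
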