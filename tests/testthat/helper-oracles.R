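# Independent brute-force oracles used to cross-check the package's
# vectorized implementations.  These deliberately re-derive each
# quantity from its definition with plain loops.

# regularized geometric mean / fold change, straight from the formula
oracle_fc <- function(dense_counts, labels, eps) {
  clusters <- sort(unique(labels))
  gm <- sapply(clusters, function(cl) {
    cols <- which(labels == cl)
    apply(dense_counts[, cols, drop = FALSE], 1, function(u)
      exp(mean(log(1 + u))) - 1)
  })
  gm <- matrix(gm, nrow = nrow(dense_counts),
               dimnames = list(rownames(dense_counts), clusters))
  med <- apply(gm, 1, function(v) {
    s <- sort(v)
    s[ceiling(length(s) / 2)]
  })
  (gm + eps) / (med + eps)
}

# exhaustive peak-to-gene rule application: for one peak, loop over all
# genes and apply the three rules literally
oracle_assign_one <- function(summit, chrom, peak_start, peak_end,
                              genes, promoters, max_distance) {
  # promoter overlaps
  hits <- character(0)
  for (i in seq_len(nrow(promoters))) {
    if (promoters$chrom[i] == chrom &&
        peak_start < promoters$end[i] && promoters$start[i] < peak_end)
      hits <- c(hits, promoters$gene_id[i])
  }
  hits <- unique(hits)
  if (length(hits) >= 1) {
    d <- sapply(hits, function(g)
      abs(summit - genes$tss[genes$gene_id == g]))
    pick <- hits[order(d, hits)][1]
    return(data.frame(gene_id = pick,
                      distance = genes$tss[genes$gene_id == pick] - summit,
                      is_promoter = TRUE,
                      ambiguous = length(hits) > 1,
                      stringsAsFactors = FALSE))
  }
  eligible <- genes[genes$chrom == chrom &
                      abs(genes$tss - summit) <= max_distance, ,
                    drop = FALSE]
  if (!nrow(eligible)) return(NULL)
  keep <- logical(nrow(eligible))
  for (k in seq_len(nrow(eligible))) {
    lo <- min(summit, eligible$tss[k])
    hi <- max(summit, eligible$tss[k])
    blocked <- FALSE
    for (j in seq_len(nrow(eligible))) {
      if (j == k) next
      if (eligible$tss[j] > lo && eligible$tss[j] < hi) blocked <- TRUE
    }
    keep[k] <- !blocked
  }
  eligible <- eligible[keep, , drop = FALSE]
  if (!nrow(eligible)) return(NULL)
  data.frame(gene_id = eligible$gene_id,
             distance = eligible$tss - summit,
             is_promoter = FALSE, ambiguous = FALSE,
             stringsAsFactors = FALSE)
}

oracle_assign <- function(peaks, genes, promoters, max_distance) {
  rows <- list()
  for (p in seq_len(nrow(peaks))) {
    if (!peaks$chrom[p] %in% genes$chrom) next
    r <- oracle_assign_one(peaks$start[p] + peaks$summit_offset[p],
                           peaks$chrom[p], peaks$start[p], peaks$end[p],
                           genes, promoters, max_distance)
    if (!is.null(r))
      rows[[length(rows) + 1L]] <- cbind(peak_id = peaks$name[p], r,
                                         stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(peak_id = character(0), gene_id = character(0),
               distance = integer(0), is_promoter = logical(0),
               ambiguous = logical(0))
  out <- out[order(out$peak_id, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# exact upper binomial tail by term-wise summation
oracle_binom_tail <- function(k, n, p) {
  if (k <= 0) return(1)
  if (k > n) return(0)
  sum(sapply(k:n, function(x) choose(n, x) * p^x * (1 - p)^(n - x)))
}

# Benjamini-Hochberg from the definition
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}

# brute-force log-odds scan of one motif over one sequence (both strands)
oracle_scan <- function(seq, ppm, floor = 1e-3) {
  score_at <- function(s, m) {
    chars <- strsplit(s, "")[[1]]
    total <- 0
    for (k in seq_len(nrow(m))) {
      b <- chars[k]
      if (!b %in% c("A", "C", "G", "T")) return(-Inf)
      total <- total + log2(max(m[k, b], floor) / 0.25)
    }
    total
  }
  rc <- function(s) as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(s)))
  w <- nrow(ppm)
  n_off <- nchar(seq) - w + 1
  if (n_off < 1)
    return(data.frame(offset = integer(0), strand = character(0),
                      score = numeric(0)))
  rows <- list()
  for (o in seq_len(n_off)) {
    sub <- substr(seq, o, o + w - 1)
    rows[[length(rows) + 1L]] <- data.frame(
      offset = o - 1L, strand = "+", score = score_at(sub, ppm))
    rows[[length(rows) + 1L]] <- data.frame(
      offset = o - 1L, strand = "-", score = score_at(rc(sub), ppm))
  }
  do.call(rbind, rows)
}

# small random toy genome + peaks for assignment fuzzing
random_assignment_toy <- function(seed) {
  set.seed(seed)
  n_genes <- sample(1:10, 1)
  L <- 100000L
  genes <- data.frame(
    gene_id = sprintf("g%02d", seq_len(n_genes)),
    chrom = "chr1",
    tss = sort(sample.int(L, n_genes)),
    strand = sample(c("+", "-"), n_genes, replace = TRUE),
    stringsAsFactors = FALSE)
  n_peaks <- sample(1:30, 1)
  summit <- sample.int(L, n_peaks)
  peaks <- data.frame(
    chrom = "chr1", start = pmax(summit - 125L, 0L),
    end = pmin(summit + 125L, L),
    name = sprintf("p%03d", seq_len(n_peaks)),
    score = 0L, strand = ".", signal = 1, neglog10_p = 10,
    neglog10_q = 10, stringsAsFactors = FALSE)
  peaks$summit_offset <- summit - peaks$start
  list(genes = genes, peaks = peaks)
}
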