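## ATAC peak handling: narrowPeak loading and q-value filtering, 250 bp
## summit standardization, non-overlap reduction, promoter definition,
## the distance-based peak-to-gene assignment rules, and derivation of
## cell-type-specific regulatory-region sets from expression fold
## changes.  Interval arithmetic goes through IRanges/GenomicRanges; all
## coordinates are 0-based half-open.

peaks_to_granges <- function(peaks) {
  GenomicRanges::GRanges(
    peaks$chrom,
    IRanges::IRanges(start = peaks$start + 1L, end = peaks$end),
    name = peaks$name)
}

#' Load and q-value-filter a narrowPeak file
#'
#' Reads 10-column MACS2 narrowPeak records and keeps peaks whose
#' `-log10(q)` (column 9) is at least `min_neglog10_q`; well-supported
#' peaks in the reference analysis use `min_neglog10_q = 6`
#' (q < 1e-6).  Malformed lines are rejected with their line numbers.
#'
#' @param path narrowPeak file.
#' @param min_neglog10_q Minimum `-log10(q)`.
#' @return A `peak_set` data.frame (narrowPeak columns; `summit_offset`
#'   is the offset of the summit from `start`).
#' @export
load_and_filter_peaks <- function(path, min_neglog10_q = 6) {
  lines <- readLines(path)
  if (!length(lines)) {
    warning("empty narrowPeak file")
    return(empty_peak_set())
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf != 10L)
  if (length(bad))
    input_error(sprintf(
      "malformed narrowPeak lines (expected 10 columns): %s",
      paste(head(bad, 10), collapse = ", ")))
  m <- do.call(rbind, fields)
  peaks <- data.frame(
    chrom = m[, 1], start = as.integer(m[, 2]), end = as.integer(m[, 3]),
    name = m[, 4], score = as.integer(m[, 5]), strand = m[, 6],
    signal = as.numeric(m[, 7]), neglog10_p = as.numeric(m[, 8]),
    neglog10_q = as.numeric(m[, 9]), summit_offset = as.integer(m[, 10]),
    stringsAsFactors = FALSE)
  if (anyNA(peaks$summit_offset))
    input_error("missing or non-numeric summit column")
  keep <- peaks$neglog10_q >= min_neglog10_q
  peaks <- peaks[keep, , drop = FALSE]
  rownames(peaks) <- NULL
  class(peaks) <- c("peak_set", "data.frame")
  peaks
}

empty_peak_set <- function() {
  p <- data.frame(chrom = character(0), start = integer(0), end = integer(0),
                  name = character(0), score = integer(0),
                  strand = character(0), signal = numeric(0),
                  neglog10_p = numeric(0), neglog10_q = numeric(0),
                  summit_offset = integer(0))
  class(p) <- c("peak_set", "data.frame")
  p
}

#' Standardize peaks to a fixed width around their summits
#'
#' Each peak becomes `[summit - half_width, summit + half_width)`,
#' truncated at chromosome bounds (truncation flagged in a `truncated`
#' column).  Records whose summit lies outside the original interval are
#' rejected with a warning.
#'
#' @param peaks A `peak_set`.
#' @param half_width Bases each side of the summit (default 125, i.e.
#'   250 bp standardized peaks).
#' @param chrom_sizes Named vector of chromosome lengths.
#' @return The standardized `peak_set`.
#' @export
standardize_peaks <- function(peaks, half_width = 125, chrom_sizes) {
  summit <- peaks$start + peaks$summit_offset
  bad <- summit < peaks$start | summit >= peaks$end
  if (any(bad)) {
    warning(sprintf("%d peak(s) with summit outside interval rejected",
                    sum(bad)))
    peaks <- peaks[!bad, , drop = FALSE]
    summit <- summit[!bad]
  }
  L <- chrom_sizes[peaks$chrom]
  if (anyNA(L)) input_error("chromosome missing from chrom_sizes")
  start <- pmax(summit - half_width, 0L)
  end <- pmin(summit + half_width, as.integer(L))
  peaks$truncated <- start != summit - half_width | end != summit + half_width
  peaks$start <- as.integer(start)
  peaks$end <- as.integer(end)
  peaks$summit_offset <- as.integer(summit - start)
  rownames(peaks) <- NULL
  peaks
}

#' Merge overlapping peaks into non-overlapping regions
#'
#' Overlapping records are merged into a single record spanning their
#' union (transitively), keeping the summit of the member with the
#' highest `-log10(q)`.
#'
#' @param peaks A `peak_set`.
#' @return A `peak_set` with pairwise-disjoint intervals per chromosome.
#' @export
reduce_overlaps <- function(peaks) {
  if (!nrow(peaks)) return(peaks)
  gr <- peaks_to_granges(peaks)
  red <- GenomicRanges::reduce(gr, with.revmap = TRUE)
  revmap <- S4Vectors::mcols(red)$revmap
  rows <- lapply(seq_along(red), function(k) {
    members <- revmap[[k]]
    best <- members[which.max(peaks$neglog10_q[members])]
    out <- peaks[best, , drop = FALSE]
    out$start <- GenomicRanges::start(red)[k] - 1L
    out$end <- GenomicRanges::end(red)[k]
    out$summit_offset <-
      peaks$start[best] + peaks$summit_offset[best] - out$start
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("peak_set", "data.frame")
  out
}

#' Define promoter windows around TSSs
#'
#' Strand-aware windows `[TSS - upstream, TSS + downstream)` on the plus
#' strand, mirrored on the minus strand.  External intervals (e.g.
#' H3K4me3 peaks) overlapping a gene's window are unioned in and
#' attributed to that gene.
#'
#' @param genes Gene table (`gene_id`, `chrom`, `tss`, `strand`).
#' @param upstream,downstream Window extent in bases (defaults 50/200).
#' @param external Optional `peak_set` of external promoter evidence.
#' @return A `promoter_set` data.frame (`gene_id`, `chrom`, `start`,
#'   `end`, `source`).
#' @export
define_promoters <- function(genes, upstream = 50, downstream = 200,
                             external = NULL) {
  strand <- genes$strand
  unknown <- !strand %in% c("+", "-")
  if (any(unknown)) {
    warning(sprintf("%d gene(s) without strand treated as '+'",
                    sum(unknown)))
    strand[unknown] <- "+"
  }
  start <- ifelse(strand == "+", genes$tss - upstream,
                  genes$tss - downstream)
  end <- ifelse(strand == "+", genes$tss + downstream,
                genes$tss + upstream)
  prom <- data.frame(gene_id = genes$gene_id, chrom = genes$chrom,
                     start = as.integer(start), end = as.integer(end),
                     source = "tss_window", stringsAsFactors = FALSE)
  if (!is.null(external) && nrow(external)) {
    pg <- GenomicRanges::GRanges(prom$chrom,
      IRanges::IRanges(prom$start + 1L, prom$end))
    eg <- peaks_to_granges(external)
    ov <- GenomicRanges::findOverlaps(eg, pg)
    if (length(ov)) {
      extra <- data.frame(
        gene_id = prom$gene_id[S4Vectors::subjectHits(ov)],
        chrom = external$chrom[S4Vectors::queryHits(ov)],
        start = external$start[S4Vectors::queryHits(ov)],
        end = external$end[S4Vectors::queryHits(ov)],
        source = "external", stringsAsFactors = FALSE)
      prom <- rbind(prom, extra)
    }
  }
  rownames(prom) <- NULL
  class(prom) <- c("promoter_set", "data.frame")
  prom
}

#' Assign peaks to genes by summit-to-TSS distance rules
#'
#' A peak overlapping exactly one gene's promoter is linked to that gene
#' alone (promoter-flagged).  A peak overlapping several promoters is
#' linked to the one with the nearest TSS (tie: smaller gene id) and
#' flagged ambiguous.  Any other peak is linked to every gene whose TSS
#' lies within `max_distance` of the summit, except genes "beyond a more
#' proximal gene": gene g is excluded when another eligible gene's TSS
#' lies strictly between the summit and g's TSS.
#'
#' @param peaks A standardized `peak_set`.
#' @param genes Gene table (`gene_id`, `chrom`, `tss`, `strand`).
#' @param promoters A `promoter_set` from [define_promoters()].
#' @param max_distance Maximum |summit - TSS| (default 20000).
#' @return A `peak_gene_assignment` data.frame: `peak_id`, `gene_id`,
#'   `distance` (signed TSS - summit), `is_promoter`, `ambiguous`.
#' @export
assign_peaks <- function(peaks, genes, promoters, max_distance = 20000) {
  if (!nrow(peaks)) {
    out <- data.frame(peak_id = character(0), gene_id = character(0),
                      distance = integer(0), is_promoter = logical(0),
                      ambiguous = logical(0))
    class(out) <- c("peak_gene_assignment", "data.frame")
    return(out)
  }
  summit <- peaks$start + peaks$summit_offset
  known <- peaks$chrom %in% genes$chrom
  if (any(!known))
    message(sprintf("%d peak(s) on chromosomes absent from gene table left unassigned",
                    sum(!known)))
  pk_gr <- peaks_to_granges(peaks)
  pr_gr <- GenomicRanges::GRanges(promoters$chrom,
    IRanges::IRanges(promoters$start + 1L, promoters$end))
  ov <- suppressWarnings(GenomicRanges::findOverlaps(pk_gr, pr_gr))
  prom_hits <- split(promoters$gene_id[S4Vectors::subjectHits(ov)],
                     factor(S4Vectors::queryHits(ov),
                            levels = seq_len(nrow(peaks))))
  tss_of <- setNames(genes$tss, genes$gene_id)
  rows <- vector("list", nrow(peaks))
  for (p in seq_len(nrow(peaks))) {
    if (!known[p]) next
    hit_genes <- unique(prom_hits[[p]])
    if (length(hit_genes) >= 1) {
      d <- abs(summit[p] - tss_of[hit_genes])
      pick <- hit_genes[order(d, hit_genes)][1]
      rows[[p]] <- data.frame(
        peak_id = peaks$name[p], gene_id = pick,
        distance = as.integer(tss_of[pick] - summit[p]),
        is_promoter = TRUE, ambiguous = length(hit_genes) > 1,
        stringsAsFactors = FALSE)
      next
    }
    cand <- genes[genes$chrom == peaks$chrom[p] &
                    abs(genes$tss - summit[p]) <= max_distance, ,
                  drop = FALSE]
    if (!nrow(cand)) next
    keep <- vapply(seq_len(nrow(cand)), function(k) {
      lo <- min(summit[p], cand$tss[k])
      hi <- max(summit[p], cand$tss[k])
      !any(cand$tss > lo & cand$tss < hi)
    }, logical(1))
    cand <- cand[keep, , drop = FALSE]
    if (!nrow(cand)) next
    rows[[p]] <- data.frame(
      peak_id = peaks$name[p], gene_id = cand$gene_id,
      distance = as.integer(cand$tss - summit[p]),
      is_promoter = FALSE, ambiguous = FALSE, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(peak_id = character(0), gene_id = character(0),
                      distance = integer(0), is_promoter = logical(0),
                      ambiguous = logical(0))
  out <- out[order(out$peak_id, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("peak_gene_assignment", "data.frame")
  out
}

#' Cell-type-specific regulatory-region sets from fold changes
#'
#' A region enters a cell type's high, mild or background set according
#' to the maximum expression fold change among its assigned genes in
#' that type: high when `FC >= hi`, mild when `mid <= FC < hi`,
#' background when `FC <= bg`.  The sets are disjoint by construction
#' (precedence high > mild > background); regions whose maximum FC falls
#' strictly between `bg` and `mid` enter no set.
#'
#' @param assignment A `peak_gene_assignment`.
#' @param fc Genes x cell-types fold-change matrix (or `fc_profile`).
#' @param hi,mid,bg Thresholds (defaults 1.5 / 1.1 / 1.0).
#' @return Named list, cell type -> list of character vectors `high`,
#'   `mild`, `background` of peak ids.
#' @export
celltype_peak_sets <- function(assignment, fc, hi = 1.5, mid = 1.1,
                               bg = 1.0) {
  F <- if (inherits(fc, "fc_profile")) fc$fc else fc
  asg <- assignment[assignment$gene_id %in% rownames(F), , drop = FALSE]
  if (!nrow(asg)) return(setNames(list(), character(0)))
  out <- lapply(colnames(F), function(ct) {
    v <- F[asg$gene_id, ct]
    mx <- tapply(v, asg$peak_id, max)
    list(high = names(mx)[mx >= hi],
         mild = names(mx)[mx >= mid & mx < hi],
         background = names(mx)[mx <= bg])
  })
  names(out) <- colnames(F)
  out
}

#' Extract peak sequences from a genome
#'
#' @param peaks A `peak_set`.
#' @param seqs Named [Biostrings::DNAStringSet] of chromosomes.
#' @return A [Biostrings::DNAStringSet] named by peak id.
#' @export
peak_sequences <- function(peaks, seqs) {
  out <- Biostrings::DNAStringSet(vapply(seq_len(nrow(peaks)), function(i)
    as.character(Biostrings::subseq(seqs[[peaks$chrom[i]]],
                                    start = peaks$start[i] + 1L,
                                    end = peaks$end[i])),
    character(1)))
  names(out) <- peaks$name
  out
}
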