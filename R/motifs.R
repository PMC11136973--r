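## Motif toolkit: position probability matrices, information content,
## redundancy reduction by weighted-Pearson similarity clustering,
## log-odds scanning, GC/length-matched background sampling, binomial
## enrichment testing and empirical hit p-values.

#' Construct a position probability matrix motif
#'
#' @param id Motif identifier.
#' @param matrix Width x 4 matrix of probabilities over A, C, G, T; rows
#'   must sum to 1.
#' @param source Source tag (`"de_novo"` or `"known"`).
#' @return A `motif_ppm` list.
#' @export
motif_ppm <- function(id, matrix, source = "known") {
  if (ncol(matrix) != 4 || nrow(matrix) < 1)
    input_error("PPM must be width x 4")
  if (any(matrix < 0) || any(abs(rowSums(matrix) - 1) > 1e-6))
    input_error("PPM rows must be non-negative and sum to 1")
  colnames(matrix) <- BASES
  structure(list(id = id, matrix = matrix, source = source),
            class = "motif_ppm")
}

#' Bundle motifs into a library
#' @param motifs List of `motif_ppm` objects.
#' @return A `motif_library` list with `motifs` and `clusters` (NULL
#'   until [dedupe_library()]).
#' @export
motif_library <- function(motifs) {
  ids <- vapply(motifs, `[[`, character(1), "id")
  if (anyDuplicated(ids)) input_error("duplicate motif ids")
  structure(list(motifs = motifs, clusters = NULL),
            class = "motif_library")
}

#' Motif identifiers of a library
#' @param library A `motif_library`.
#' @return Character vector of motif ids.
#' @export
motif_ids <- function(library) vapply(library$motifs, `[[`, character(1), "id")

#' Per-column information content of a PPM, in bits
#'
#' `IC_j = 2 + sum_b p_jb log2 p_jb` against a uniform background, with
#' `0 log 0 = 0`; values lie in `[0, 2]`.
#'
#' @param ppm A `motif_ppm` or a width x 4 probability matrix.
#' @return Numeric vector of per-column IC.
#' @export
column_ic <- function(ppm) {
  m <- if (inherits(ppm, "motif_ppm")) ppm$matrix else ppm
  if (any(m < 0) || any(abs(rowSums(m) - 1) > 1e-6))
    input_error("PPM rows must be non-negative and sum to 1")
  apply(m, 1, function(p) {
    p <- p[p > 0]
    2 + sum(p * log2(p))
  })
}

total_ic <- function(ppm) sum(column_ic(ppm))

#' Filter motifs by contiguous information content
#'
#' Retains motifs with at least one run of `run_len` consecutive columns
#' at `IC >= ic_min`, or at least `n_blocks` disjoint runs of at least
#' `block_len` such columns.
#'
#' @param library A `motif_library`.
#' @param ic_min IC threshold per column (default 0.5 bits).
#' @param run_len Length of a single qualifying run (default 4).
#' @param block_len Minimum length of each block (default 3).
#' @param n_blocks Number of qualifying blocks (default 2).
#' @return The filtered `motif_library`.
#' @export
contiguous_ic_filter <- function(library, ic_min = 0.5, run_len = 4,
                                 block_len = 3, n_blocks = 2) {
  keep <- vapply(library$motifs, function(m) {
    ok <- column_ic(m) >= ic_min
    r <- rle(ok)
    runs <- r$lengths[r$values]
    any(runs >= run_len) || sum(runs >= block_len) >= n_blocks
  }, logical(1))
  motif_library(library$motifs[keep])
}

reverse_complement_ppm <- function(m) {
  m[rev(seq_len(nrow(m))), c("T", "G", "C", "A"), drop = FALSE]
}

weighted_pearson <- function(x, y, w) {
  if (sum(w) <= 0) w <- rep(1, length(x))
  w <- w / sum(w)
  mx <- sum(w * x); my <- sum(w * y)
  vx <- sum(w * (x - mx)^2); vy <- sum(w * (y - my)^2)
  if (vx < 1e-12 || vy < 1e-12)
    return(if (max(abs(x - y)) < 1e-9) 1 else 0)
  sum(w * (x - mx) * (y - my)) / sqrt(vx * vy)
}

#' Weighted-Pearson similarity between two motifs
#'
#' Maximizes, over all relative offsets with at least `min_overlap`
#' aligned columns and over the reverse complement of `b`, the weighted
#' Pearson correlation of the flattened aligned probability columns;
#' each aligned column pair is weighted by the mean of the two columns'
#' information contents.  Returns -1 when no alignment reaches
#' `min_overlap` (such pairs are never merged).
#'
#' @param a,b `motif_ppm` objects.
#' @param min_overlap Minimum aligned columns (default 6).
#' @return Similarity in `[-1, 1]`.
#' @export
motif_similarity <- function(a, b, min_overlap = 6) {
  ma <- if (inherits(a, "motif_ppm")) a$matrix else a
  mb <- if (inherits(b, "motif_ppm")) b$matrix else b
  best <- -1
  for (mb2 in list(mb, reverse_complement_ppm(mb))) {
    wa <- nrow(ma); wb <- nrow(mb2)
    ica <- column_ic(ma); icb <- column_ic(mb2)
    for (d in (-wb + 1):(wa - 1)) {
      ia <- max(1, 1 + d):min(wa, wb + d)
      ib <- ia - d
      if (length(ia) < min_overlap) next
      w <- rep((ica[ia] + icb[ib]) / 2, each = 4)
      r <- weighted_pearson(as.vector(t(ma[ia, , drop = FALSE])),
                            as.vector(t(mb2[ib, , drop = FALSE])), w)
      if (r > best) best <- r
    }
  }
  best
}

#' Collapse a motif library to non-redundant representatives
#'
#' Average-linkage hierarchical clustering on `1 - similarity`, cut so
#' that merged clusters have average similarity at least `threshold`;
#' the member with the highest total IC represents each cluster (ties:
#' lexicographically first id).  A final pass merges any remaining
#' representative pair at or above the threshold, so retained motifs are
#' pairwise dissimilar.
#'
#' @param library A `motif_library`.
#' @param threshold Similarity threshold (default 0.95).
#' @param min_overlap Minimum alignment overlap (default 6 bp).
#' @return A `motif_library` of representatives, with `clusters` mapping
#'   every input motif id to its cluster representative.
#' @export
dedupe_library <- function(library, threshold = 0.95, min_overlap = 6) {
  n <- length(library$motifs)
  ids <- motif_ids(library)
  if (n <= 1) {
    library$clusters <- data.frame(motif = ids, representative = ids)
    return(library)
  }
  sim <- diag(1, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    sim[i, j] <- sim[j, i] <-
      motif_similarity(library$motifs[[i]], library$motifs[[j]],
                       min_overlap)
  cl <- stats::cutree(
    stats::hclust(stats::as.dist(1 - sim), method = "average"),
    h = 1 - threshold)
  # enforce pairwise dissimilarity of representatives
  repeat {
    reps <- vapply(split(seq_len(n), cl), function(members) {
      tic <- vapply(library$motifs[members], total_ic, numeric(1))
      members[order(-tic, ids[members])][1]
    }, integer(1))
    done <- TRUE
    if (length(reps) > 1) {
      for (i in seq_along(reps)[-length(reps)]) {
        for (j in (i + 1):length(reps)) {
          if (sim[reps[i], reps[j]] >= threshold) {
            cl[cl == cl[reps[j]]] <- cl[reps[i]]
            done <- FALSE
            break
          }
        }
        if (!done) break
      }
    }
    if (done) break
  }
  out <- motif_library(library$motifs[sort(unname(reps))])
  out$clusters <- data.frame(motif = ids,
                             representative = ids[reps[as.character(cl)]],
                             row.names = NULL)
  out
}

encode_dna <- function(seq) {
  code <- match(strsplit(toupper(seq), "")[[1]], c(BASES, "N"))
  code[is.na(code)] <- 5L
  code
}

ppm_score_lookup <- function(m, floor = 1e-3) {
  lo <- log2(pmax(m, floor) / 0.25)
  rbind(t(lo), N = rep(-1e9, nrow(m)))  # 5 x width, row 5 = N
}

scan_one <- function(code, lookup) {
  w <- ncol(lookup)
  n_off <- length(code) - w + 1L
  if (n_off < 1L) return(numeric(0))
  sc <- numeric(n_off)
  for (k in seq_len(w))
    sc <- sc + lookup[code[k:(k + n_off - 1L)] + (k - 1L) * 5L]
  sc
}

#' Scan region sequences for motif occurrences
#'
#' Log2-odds scoring against a uniform background with a per-cell
#' probability floor of `1e-3`; both strands are scanned and positions
#' whose score reaches `score_fraction_min` times the motif's maximum
#' achievable score are reported.  Windows containing N never match.
#'
#' @param regions Named character vector or
#'   [Biostrings::DNAStringSet] of region sequences.
#' @param library A `motif_library`.
#' @param score_fraction_min Fraction of the maximum achievable score
#'   (default 0.8, inclusive).
#' @param best_only Keep only the best hit per region per motif (ties:
#'   leftmost, then plus strand).
#' @return A `motif_hits` data.frame: `region`, `motif`, `offset`
#'   (0-based within the region), `strand`, `score`, `score_fraction`.
#' @export
scan_regions <- function(regions, library, score_fraction_min = 0.8,
                         best_only = FALSE) {
  if (inherits(regions, "DNAStringSet"))
    regions <- setNames(as.character(regions), names(regions))
  if (is.null(names(regions)))
    names(regions) <- sprintf("region%05d", seq_along(regions))
  codes <- lapply(regions, encode_dna)
  rows <- list()
  for (m in library$motifs) {
    lu_f <- ppm_score_lookup(m$matrix)
    lu_r <- ppm_score_lookup(reverse_complement_ppm(m$matrix))
    max_score <- sum(apply(lu_f[1:4, , drop = FALSE], 2, max))
    thr <- score_fraction_min * max_score - 1e-9
    for (r in names(codes)) {
      for (st in c("+", "-")) {
        sc <- scan_one(codes[[r]], if (st == "+") lu_f else lu_r)
        hit <- which(sc >= thr)
        if (length(hit))
          rows[[length(rows) + 1L]] <- data.frame(
            region = r, motif = m$id, offset = hit - 1L, strand = st,
            score = sc[hit],
            score_fraction = if (max_score > 0) sc[hit] / max_score else 1,
            stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(region = character(0), motif = character(0),
               offset = integer(0), strand = character(0),
               score = numeric(0), score_fraction = numeric(0))
  if (best_only && nrow(out)) {
    out <- out[order(out$region, out$motif, -out$score, out$offset,
                     out$strand), , drop = FALSE]
    out <- out[!duplicated(out[, c("region", "motif")]), , drop = FALSE]
  }
  rownames(out) <- NULL
  class(out) <- c("motif_hits", "data.frame")
  out
}

#' GC content of sequences
#' @param seqs Named character vector or [Biostrings::DNAStringSet].
#' @return Numeric vector of GC fractions.
#' @export
gc_content <- function(seqs) {
  if (!inherits(seqs, "DNAStringSet"))
    seqs <- Biostrings::DNAStringSet(seqs)
  as.vector(Biostrings::letterFrequency(seqs, "GC")) /
    Biostrings::width(seqs)
}

#' Sample GC- and length-matched background regions
#'
#' Splits the foreground regions into `n_gc_bins` equal-size bins by GC
#' content and samples, per bin, `multiple` times as many non-overlapping
#' genomic regions of the same length whose GC falls within the bin's
#' range, excluding any overlap with the foreground.  If a bin cannot be
#' satisfied after bounded retries its GC range is relaxed stepwise with
#' a warning.
#'
#' @param foreground A `peak_set` (standardized regions).
#' @param seqs Named [Biostrings::DNAStringSet] of chromosomes.
#' @param multiple Background regions per foreground region (default 2).
#' @param n_gc_bins Number of GC bins (default 10).
#' @param seed Integer seed.
#' @return A data.frame `name`, `chrom`, `start`, `end`, `gc`, `bin`.
#' @export
sample_matched_background <- function(foreground, seqs, multiple = 2,
                                      n_gc_bins = 10, seed = 1) {
  n_fg <- nrow(foreground)
  if (!n_fg) input_error("empty foreground")
  fg_seq <- peak_sequences(foreground, seqs)
  fg_gc <- gc_content(fg_seq)
  n_gc_bins <- min(n_gc_bins, n_fg)
  bin <- ceiling(rank(fg_gc, ties.method = "first") / (n_fg / n_gc_bins))
  chrom_len <- setNames(Biostrings::width(seqs), names(seqs))
  with_seed(substream_seed(seed, "matched_background"), {
    taken_start <- foreground$start
    taken_end <- foreground$end
    taken_chrom <- foreground$chrom
    rows <- list()
    for (b in sort(unique(bin))) {
      members <- which(bin == b)
      lo <- min(fg_gc[members]); hi <- max(fg_gc[members])
      len <- foreground$end[members[1]] - foreground$start[members[1]]
      need <- multiple * length(members)
      got <- 0L
      relax <- 0
      tries <- 0L
      while (got < need) {
        tries <- tries + 1L
        if (tries > 200L * need) {
          relax <- relax + 0.02
          tries <- 0L
          warning(sprintf(
            "GC bin %d unsatisfiable; relaxing range by %.2f", b, relax))
          if (relax > 1) input_error("cannot sample matched background")
        }
        chrom <- sample(names(seqs), 1,
                        prob = as.numeric(chrom_len) / sum(chrom_len))
        if (chrom_len[[chrom]] < len) next
        s <- sample.int(chrom_len[[chrom]] - len + 1L, 1L) - 1L
        e <- s + len
        ovl <- taken_chrom == chrom & taken_start < e & taken_end > s
        if (any(ovl)) next
        g <- gc_content(as.character(
          Biostrings::subseq(seqs[[chrom]], s + 1L, e)))
        if (g < lo - relax || g > hi + relax) next
        got <- got + 1L
        taken_chrom <- c(taken_chrom, chrom)
        taken_start <- c(taken_start, s)
        taken_end <- c(taken_end, e)
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = chrom, start = s, end = e, gc = g, bin = b,
          stringsAsFactors = FALSE)
      }
    }
    out <- do.call(rbind, rows)
    out <- cbind(name = sprintf("bg%05d", seq_len(nrow(out))), out,
                 stringsAsFactors = FALSE)
    rownames(out) <- NULL
    out
  })
}

#' Binned motif enrichment with a binomial test
#'
#' For each (cell type, bin, motif): `k` foreground regions with at
#' least one hit out of `n`; background hit probability `p0 =
#' (background hits + 0.5) / (n_bg + 1)`; one-sided binomial tail
#' `P(X >= k | n, p0)`; `log2FC = log2(((k + 0.5) / (n + 1)) / p0)`;
#' Benjamini-Hochberg adjustment across motifs within each (cell type,
#' bin).
#'
#' @param fg_sets Named list, cell type -> named list of bins -> peak id
#'   vectors (as from [celltype_peak_sets()]).
#' @param bg_ids Character vector of background region ids.
#' @param hits A `motif_hits` table over foreground and background
#'   regions (same scanning threshold).
#' @param motifs Motif ids to report (default: all motifs in `hits`).
#' @return An `enrichment_table` data.frame: `celltype`, `bin`, `motif`,
#'   `k`, `n`, `p0`, `log2fc`, `p`, `p_adj`.
#' @export
binned_enrichment <- function(fg_sets, bg_ids, hits, motifs = NULL) {
  if (is.null(motifs)) motifs <- sort(unique(hits$motif))
  hit_pairs <- unique(hits[, c("region", "motif")])
  n_bg <- length(bg_ids)
  rows <- list()
  for (ct in names(fg_sets)) {
    for (bn in names(fg_sets[[ct]])) {
      ids <- fg_sets[[ct]][[bn]]
      n <- length(ids)
      if (n == 0) {
        warning(sprintf("empty foreground set %s/%s skipped", ct, bn))
        next
      }
      for (mo in motifs) {
        hr <- hit_pairs$region[hit_pairs$motif == mo]
        k <- sum(ids %in% hr)
        kb <- sum(bg_ids %in% hr)
        p0 <- (kb + 0.5) / (n_bg + 1)
        p <- pbinom(k - 1, n, p0, lower.tail = FALSE)
        log2fc <- log2(((k + 0.5) / (n + 1)) / p0)
        rows[[length(rows) + 1L]] <- data.frame(
          celltype = ct, bin = bn, motif = mo, k = k, n = n, p0 = p0,
          log2fc = log2fc, p = p, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(celltype = character(0), bin = character(0),
                      motif = character(0), k = integer(0), n = integer(0),
                      p0 = numeric(0), log2fc = numeric(0), p = numeric(0),
                      p_adj = numeric(0)))
  out$p_adj <- NA_real_
  for (g in split(seq_len(nrow(out)),
                  paste(out$celltype, out$bin, sep = "\r")))
    out$p_adj[g] <- p.adjust(out$p[g], method = "BH")
  rownames(out) <- NULL
  class(out) <- c("enrichment_table", "data.frame")
  out
}

#' Empirical per-region hit p-values against GC-matched backgrounds
#'
#' Foreground regions are split into `n_gc_bins` equal-size bins by GC;
#' background scores are assigned to bins by the foreground bins' GC
#' boundaries.  Within a region's bin, `p = (1 + #background best scores
#' >= observed) / (1 + n_background_in_bin)`.
#'
#' @param fg Data frame with `region`, `score`, `gc` (best score per
#'   region for one motif).
#' @param bg Data frame with `score`, `gc` (best score per background
#'   region).
#' @param n_gc_bins Number of GC bins (default 10).
#' @return `fg` with added `bin` and `empirical_p` columns (`NA` with a
#'   warning for regions whose bin has no background).
#' @export
empirical_hit_pvalue <- function(fg, bg, n_gc_bins = 10) {
  n <- nrow(fg)
  if (!n) return(cbind(fg, bin = integer(0), empirical_p = numeric(0)))
  n_gc_bins <- min(n_gc_bins, n)
  o <- rank(fg$gc, ties.method = "first")
  fg$bin <- ceiling(o / (n / n_gc_bins))
  # bin boundaries for assigning background regions
  bounds <- tapply(fg$gc, fg$bin, max)
  cuts <- c(-Inf, bounds[-length(bounds)], Inf)
  bg_bin <- findInterval(bg$gc, cuts, left.open = TRUE)
  fg$empirical_p <- NA_real_
  for (b in sort(unique(fg$bin))) {
    bs <- bg$score[bg_bin == b]
    idx <- which(fg$bin == b)
    if (!length(bs)) {
      warning(sprintf("GC bin %d has no background; p undefined", b))
      next
    }
    fg$empirical_p[idx] <- vapply(fg$score[idx], function(s)
      (1 + sum(bs >= s)) / (1 + length(bs)), numeric(1))
  }
  fg
}

## ---- synthetic motif generators (planted ground truth) ----

#' Random high-information motif families with perturbed copies
#'
#' Generates `n_families` sharp random PPMs and, for each, `copies - 1`
#' redundant variants: probability-jittered, shifted by uniform flanks,
#' and/or reverse-complemented.  Used to exercise redundancy reduction
#' with known ground truth.
#'
#' @param n_families Number of distinct families.
#' @param copies Motifs per family (including the original).
#' @param width Motif width.
#' @param sharp Probability of the consensus base per column.
#' @param jitter Log-normal sdlog of the probability jitter.
#' @param seed Integer seed.
#' @return A `motif_library`; ids are `famXX_cY` so the planted family
#'   is recoverable from the id.
#' @export
make_motif_families <- function(n_families = 6, copies = 5, width = 10,
                                sharp = 0.85, jitter = 0.1, seed = 1) {
  with_seed(substream_seed(seed, "motif_families"), {
    motifs <- list()
    for (f in seq_len(n_families)) {
      cons <- sample.int(4, width, replace = TRUE)
      base <- matrix((1 - sharp) / 3, width, 4)
      base[cbind(seq_len(width), cons)] <- sharp
      colnames(base) <- BASES
      for (cpy in seq_len(copies)) {
        m <- base
        if (cpy > 1) {
          m <- m * matrix(rlnorm(length(m), 0, jitter), nrow(m))
          m <- m / rowSums(m)
          if (cpy %% 2 == 0)  # shifted variant: one uniform flank column
            m <- rbind(rep(0.25, 4), m)[seq_len(width + 1), , drop = FALSE]
          if (cpy %% 3 == 0)
            m <- reverse_complement_ppm(m)
        }
        colnames(m) <- BASES
        motifs[[length(motifs) + 1L]] <-
          motif_ppm(sprintf("fam%02d_c%d", f, cpy), m, "de_novo")
      }
    }
    motif_library(motifs)
  })
}

#' A single random sharp PPM
#' @param width Motif width.
#' @param sharp Consensus-base probability per column.
#' @param seed Integer seed.
#' @return A `motif_ppm`.
#' @export
random_motif <- function(width = 10, sharp = 0.85, seed = 1) {
  with_seed(substream_seed(seed, "random_motif"), {
    cons <- sample.int(4, width, replace = TRUE)
    m <- matrix((1 - sharp) / 3, width, 4)
    m[cbind(seq_len(width), cons)] <- sharp
    colnames(m) <- BASES
    motif_ppm(sprintf("rand_w%d_s%d", width, seed), m, "de_novo")
  })
}
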