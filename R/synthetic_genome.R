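## Synthetic genome, peaks and planted motif occurrences: the ground
## truth behind the regulatory-assignment and motif-enrichment stages.

BASES <- c("A", "C", "G", "T")

#' Generate a random genome with annotated TSSs
#'
#' A single random chromosome at a target GC content, with `n_genes`
#' transcription start sites spaced at least `min_spacing` bases apart and
#' random strands.
#'
#' @param n_genes Number of genes.
#' @param chrom_length Chromosome length in bases.
#' @param gc_target Target GC fraction in `[0, 1]`.
#' @param min_spacing Minimum distance between consecutive TSSs.
#' @param seed Integer seed.
#' @return A `synthetic_genome` list: `seqs` (named
#'   [Biostrings::DNAStringSet]), `genes` (data.frame `gene_id`, `chrom`,
#'   `tss` 0-based, `strand`), `gc_target`.
#' @export
make_genome <- function(n_genes, chrom_length, gc_target = 0.4,
                        min_spacing = 3000, seed = 1) {
  if (n_genes < 1 || chrom_length < 1) param_error("counts must be positive")
  if (gc_target < 0 || gc_target > 1) param_error("gc_target must be in [0,1]")
  if (n_genes * min_spacing >= chrom_length)
    param_error("infeasible TSS spacing: n_genes * min_spacing >= chrom_length")
  with_seed(substream_seed(seed, "genome"), {
    p <- c(A = (1 - gc_target) / 2, C = gc_target / 2,
           G = gc_target / 2, T = (1 - gc_target) / 2)
    seq <- paste(sample(BASES, chrom_length, replace = TRUE, prob = p),
                 collapse = "")
    seqs <- Biostrings::DNAStringSet(seq)
    names(seqs) <- "chr1"
    # TSSs: sorted uniforms in the slack, shifted by the required spacing
    slack <- chrom_length - n_genes * min_spacing
    u <- sort(runif(n_genes, 0, slack))
    tss <- as.integer(floor(u) + (seq_len(n_genes) - 1) * min_spacing +
                        min_spacing %/% 2)
    genes <- data.frame(
      gene_id = sprintf("g%04d", seq_len(n_genes)),
      chrom = "chr1",
      tss = tss,
      strand = sample(c("+", "-"), n_genes, replace = TRUE),
      stringsAsFactors = FALSE
    )
    structure(list(seqs = seqs, genes = genes, gc_target = gc_target),
              class = "synthetic_genome")
  })
}

#' Realized GC content of a synthetic genome
#' @param genome A `synthetic_genome`.
#' @return GC fraction.
#' @export
genome_gc <- function(genome) {
  f <- Biostrings::letterFrequency(genome$seqs, c("G", "C"))
  sum(f) / sum(Biostrings::width(genome$seqs))
}

#' Uniform peak-offset law
#' @param min,max Offset bounds (summit position relative to TSS).
#' @return An offset-law specification list.
#' @export
offset_law_uniform <- function(min = -10000, max = 10000) {
  list(type = "uniform", min = min, max = max)
}

#' Constant peak-offset law
#' @param offset Fixed summit-to-TSS offset.
#' @return An offset-law specification list.
#' @export
offset_law_constant <- function(offset) {
  list(type = "constant", offset = offset)
}

draw_offsets <- function(law, n) {
  switch(law$type,
    constant = rep(as.integer(law$offset), n),
    uniform = as.integer(round(runif(n, law$min, law$max))),
    param_error(sprintf("unknown offset law type '%s'", law$type))
  )
}

#' Place synthetic ATAC peaks around TSSs, plus orphan peaks
#'
#' Each gene receives `peaks_per_gene` peaks whose summits are placed at
#' offsets drawn from `offset_law`; `extra_orphans` peaks are placed at
#' least 20 kbp from every TSS and carry no true assignment.  All peaks
#' are 250 bp (125 bp each side of the summit) and clamped to the
#' chromosome.
#'
#' @param genome A `synthetic_genome`.
#' @param peaks_per_gene Peaks per gene.
#' @param offset_law Summit-offset law, see [offset_law_uniform()].
#' @param extra_orphans Number of gene-free peaks.
#' @param half_width Half peak width in bases.
#' @param seed Integer seed.
#' @return A `truth_regulome` list: `peaks` (narrowPeak-style data.frame),
#'   `true_assignment` (`peak_id`, `gene_id`; orphans absent),
#'   `planted_motifs` (empty until [plant_motifs()]).
#' @export
make_peaks <- function(genome, peaks_per_gene = 2,
                       offset_law = offset_law_uniform(),
                       extra_orphans = 0, half_width = 125, seed = 1) {
  with_seed(substream_seed(seed, "peaks"), {
    genes <- genome$genes
    L <- Biostrings::width(genome$seqs)[1L]
    n <- nrow(genes) * peaks_per_gene
    summit <- rep(genes$tss, each = peaks_per_gene) +
      draw_offsets(offset_law, n)
    summit <- pmin(pmax(summit, half_width), L - half_width)
    assignment <- data.frame(
      peak_id = sprintf("peak%05d", seq_len(n)),
      gene_id = rep(genes$gene_id, each = peaks_per_gene),
      stringsAsFactors = FALSE
    )
    if (extra_orphans > 0) {
      orph <- integer(0)
      tries <- 0
      while (length(orph) < extra_orphans && tries < 1000) {
        cand <- as.integer(round(runif(extra_orphans * 4, half_width,
                                       L - half_width)))
        ok <- vapply(cand, function(s) all(abs(s - genes$tss) >= 20000),
                     logical(1))
        orph <- c(orph, cand[ok])
        tries <- tries + 1
      }
      if (length(orph) < extra_orphans)
        param_error("could not place orphan peaks >= 20 kbp from all TSSs")
      summit <- c(summit, orph[seq_len(extra_orphans)])
    }
    n_all <- length(summit)
    peaks <- data.frame(
      chrom = "chr1",
      start = summit - half_width,
      end = summit + half_width,
      name = sprintf("peak%05d", seq_len(n_all)),
      score = 0L,
      strand = ".",
      signal = round(runif(n_all, 1, 50), 3),
      neglog10_p = round(runif(n_all, 8, 120), 3),
      neglog10_q = round(runif(n_all, 7, 100), 3),
      summit_offset = half_width,
      stringsAsFactors = FALSE
    )
    structure(list(peaks = peaks, true_assignment = assignment,
                   planted_motifs = NULL, fg_rate = NA_real_,
                   bg_rate = NA_real_),
              class = "truth_regulome")
  })
}

sample_ppm_sequence <- function(ppm) {
  paste(apply(ppm, 1, function(p) sample(BASES, 1, prob = p)), collapse = "")
}

#' Plant motif occurrences into peak sequences
#'
#' For every peak whose truly-assigned gene belongs to a motif's target
#' cell type, a sequence sampled column-wise from the motif's PPM is
#' written over the reference bases at a uniform position on a random
#' strand with probability `fg_rate`; all other peaks receive insertions
#' with probability `bg_rate`.  Insertions overwrite bases, so peak and
#' TSS coordinates are preserved.
#'
#' @param regulome A `truth_regulome` from [make_peaks()].
#' @param genome A `synthetic_genome`; its sequences are mutated.
#' @param motif_ppms A `motif_library` (see [motif_library()]).
#' @param celltype_map Named character vector, motif id -> target type.
#' @param gene_types Named character vector, gene id -> cell type.
#' @param fg_rate,bg_rate Insertion probabilities per peak.
#' @param seed Integer seed.
#' @return List with mutated `genome` and `regulome` whose
#'   `planted_motifs` logs every insertion (`motif_id`, `peak_id`,
#'   `offset` within peak, `strand`).
#' @export
plant_motifs <- function(regulome, genome, motif_ppms, celltype_map,
                         gene_types, fg_rate, bg_rate, seed = 1) {
  if (fg_rate < 0 || fg_rate > 1 || bg_rate < 0 || bg_rate > 1)
    param_error("rates must be in [0,1]")
  widths <- vapply(motif_ppms$motifs, function(m) nrow(m$matrix), integer(1))
  peak_w <- regulome$peaks$end - regulome$peaks$start
  if (any(widths > min(peak_w))) param_error("motif wider than a peak")
  with_seed(substream_seed(seed, "plant_motifs"), {
    peaks <- regulome$peaks
    asg <- regulome$true_assignment
    peak_type <- setNames(rep(NA_character_, nrow(peaks)), peaks$name)
    hit <- match(asg$peak_id, peaks$name)
    peak_type[hit] <- unname(gene_types[asg$gene_id])
    log <- list()
    seqchar <- as.character(genome$seqs[["chr1"]])
    for (m in motif_ppms$motifs) {
      target <- celltype_map[[m$id]]
      w <- nrow(m$matrix)
      is_fg <- !is.na(peak_type) & peak_type == target
      rate <- ifelse(is_fg, fg_rate, bg_rate)
      doit <- runif(nrow(peaks)) < rate
      for (i in which(doit)) {
        off <- sample.int(peak_w[i] - w + 1L, 1L) - 1L
        strand <- sample(c("+", "-"), 1L)
        ins <- sample_ppm_sequence(m$matrix)
        if (strand == "-")
          ins <- as.character(
            Biostrings::reverseComplement(Biostrings::DNAString(ins)))
        at <- peaks$start[i] + off  # 0-based genome position
        substr(seqchar, at + 1L, at + w) <- ins
        log[[length(log) + 1L]] <- data.frame(
          motif_id = m$id, peak_id = peaks$name[i], offset = off,
          strand = strand, stringsAsFactors = FALSE)
      }
    }
    new_seqs <- Biostrings::DNAStringSet(seqchar)
    names(new_seqs) <- "chr1"
    genome$seqs <- new_seqs
    regulome$planted_motifs <- if (length(log)) do.call(rbind, log) else
      data.frame(motif_id = character(0), peak_id = character(0),
                 offset = integer(0), strand = character(0))
    regulome$fg_rate <- fg_rate
    regulome$bg_rate <- bg_rate
    list(genome = genome, regulome = regulome)
  })
}

#' Derive a second species related through orthology groups
#'
#' Species-B genes descend from species-A genes as a mixture of 1:1 and
#' 1:2 orthology groups; conserved cell types copy A's expression
#' programs with multiplicative log-normal noise, and a UMI matrix for B
#' is sampled as in [sample_umi_matrix()].
#'
#' @param truth A `truth_atlas` for species A.
#' @param one2one_frac Fraction of A genes with exactly one B ortholog.
#' @param dup_frac Fraction of A genes with two B orthologs.
#' @param divergence_noise Log-normal sdlog of per-(gene,type)
#'   multiplicative noise on conserved programs.
#' @param conserved_types Character vector of A types whose programs are
#'   conserved in B (default: all).
#' @param cells_per_type,depth_law Passed to the B matrix sampling.
#' @param seed Integer seed.
#' @return List with `pair_truth` (orthology table, conserved types,
#'   noise scale, B truth atlas) and `umi_b` (the sampled B matrix as in
#'   [sample_umi_matrix()]).
#' @export
make_orthology_pair <- function(truth, one2one_frac = 0.7, dup_frac = 0.2,
                                divergence_noise = 0.1,
                                conserved_types = NULL,
                                cells_per_type = 200,
                                depth_law = depth_law_lognormal(),
                                seed = 1) {
  if (one2one_frac < 0 || dup_frac < 0 || one2one_frac + dup_frac > 1)
    param_error("orthology fractions must be in [0,1] and sum <= 1")
  if (is.null(conserved_types)) conserved_types <- truth$types
  with_seed(substream_seed(seed, "orthology_pair"), {
    genes_a <- rownames(truth$program_matrix)
    u <- runif(length(genes_a))
    n_copies <- ifelse(u < one2one_frac, 1L,
                       ifelse(u < one2one_frac + dup_frac, 2L, 0L))
    grouped <- which(n_copies > 0)
    group_id <- sprintf("OG%05d", seq_along(grouped))
    rows <- list()
    b_of_a <- vector("list", length(genes_a))
    k <- 0L
    for (idx in seq_along(grouped)) {
      i <- grouped[idx]
      bs <- sprintf("bg%05d", k + seq_len(n_copies[i]))
      k <- k + n_copies[i]
      b_of_a[[i]] <- bs
      rows[[idx]] <- data.frame(
        group_id = group_id[idx],
        species = c("A", rep("B", length(bs))),
        gene_id = c(genes_a[i], bs),
        stringsAsFactors = FALSE)
    }
    orthology_table <- do.call(rbind, rows)
    genes_b <- unlist(b_of_a)
    prog_b <- matrix(0, nrow = length(genes_b), ncol = truth$n_types,
                     dimnames = list(genes_b, truth$types))
    for (i in which(n_copies > 0)) {
      bs <- b_of_a[[i]]
      share <- truth$program_matrix[genes_a[i], ] / length(bs)
      for (b in bs) prog_b[b, ] <- share
    }
    # conserved types keep A's (split) program up to noise; the rest are
    # replaced with a fresh exchangeable baseline
    for (t in truth$types) {
      if (t %in% conserved_types) {
        if (divergence_noise > 0)
          prog_b[, t] <- prog_b[, t] *
            rlnorm(length(genes_b), 0, divergence_noise)
      } else {
        w <- stats::rexp(length(genes_b))
        prog_b[, t] <- w
      }
      prog_b[, t] <- prog_b[, t] / sum(prog_b[, t])
    }
    marker_b <- truth$marker_map[truth$marker_map$type %in% conserved_types, ]
    marker_b <- do.call(rbind, lapply(seq_len(nrow(marker_b)), function(i) {
      bs <- b_of_a[[match(marker_b$gene[i], genes_a)]]
      if (is.null(bs)) return(NULL)
      data.frame(type = marker_b$type[i], gene = bs, fold = marker_b$fold[i],
                 stringsAsFactors = FALSE)
    }))
    truth_b <- structure(
      list(n_types = truth$n_types, types = truth$types,
           program_matrix = prog_b,
           marker_map = if (is.null(marker_b))
             data.frame(type = character(0), gene = character(0),
                        fold = numeric(0)) else marker_b,
           baseline = NULL),
      class = "truth_atlas")
    umi_b <- sample_umi_matrix(truth_b, cells_per_type, depth_law,
                               seed = substream_seed(seed, "species_b_umi"))
    pair_truth <- list(orthology_table = orthology_table,
                       conserved_types = conserved_types,
                       divergence_noise = divergence_noise,
                       truth_b = truth_b)
    list(pair_truth = pair_truth, umi_b = umi_b)
  })
}
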