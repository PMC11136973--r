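#!/usr/bin/env Rscript
# Stage 1 — generate the synthetic study inputs with planted ground
# truth: an 8-type UMI matrix (3,000 cells, median depth 1,000), a toy
# genome with TSS annotation, ATAC-like peaks with known gene
# assignments, planted motif occurrences, and a diverged sister
# species related through an orthology table.

suppressPackageStartupMessages(library(mcatlas))

seed <- 1
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

truth <- make_expression_truth(8, 800, markers_per_type = 20,
                               fold_levels = 8, seed = seed)
umi <- sample_umi_matrix(truth, 375, seed = seed)
write_mtx_dir(umi$counts, file.path(out, "umi"))
write_truth_json(list(labels = as.list(umi$labels),
                      marker_map = truth$marker_map),
                 file.path(out, "truth.json"))
message(sprintf("expression: %d genes x %d cells, median depth %g",
                nrow(umi$counts), ncol(umi$counts),
                median(Matrix::colSums(umi$counts))))

genome <- make_genome(40, 2e6, gc_target = 0.4, min_spacing = 45000,
                      seed = seed)
regulome <- make_peaks(genome, peaks_per_gene = 2,
                       offset_law_uniform(-9000, 9000),
                       extra_orphans = 5, seed = seed)
lib <- make_motif_families(6, 5, width = 10, seed = seed)
gene_types <- setNames(rep(truth$types, length.out = 40),
                       genome$genes$gene_id)
planted <- plant_motifs(regulome, genome,
                        motif_library(lib$motifs[c(1, 6)]),
                        setNames(truth$types[1:2],
                                 motif_ids(lib)[c(1, 6)]),
                        gene_types, fg_rate = 0.4, bg_rate = 0.05,
                        seed = seed)
write_fasta(planted$genome$seqs, file.path(out, "genome.fa"))
write_gene_table(genome$genes, file.path(out, "genes.tsv"))
write_narrowpeak(planted$regulome$peaks,
                 file.path(out, "peaks.narrowPeak"))
write_meme(lib, file.path(out, "motifs.meme"))
write_truth_json(list(gene_types = as.list(gene_types),
                      planted = planted$regulome$planted_motifs),
                 file.path(out, "regulome_truth.json"))
message(sprintf("genome: %g bp, %d genes, %d peaks (%d planted motif insertions)",
                2e6, 40, nrow(planted$regulome$peaks),
                nrow(planted$regulome$planted_motifs)))

pair <- make_orthology_pair(truth, one2one_frac = 0.7, dup_frac = 0.2,
                            divergence_noise = 0.1,
                            cells_per_type = 100, seed = seed)
write_mtx_dir(pair$umi_b$counts, file.path(out, "umi_speciesB"))
write_orthology_table(pair$pair_truth$orthology_table,
                      file.path(out, "orthology.tsv"))
write_truth_json(list(labels = as.list(pair$umi_b$labels)),
                 file.path(out, "truth_speciesB.json"))
message(sprintf("species B: %d genes in %d orthology groups",
                sum(pair$pair_truth$orthology_table$species == "B"),
                length(unique(pair$pair_truth$orthology_table$group_id))))
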