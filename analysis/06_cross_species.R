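#!/usr/bin/env Rscript
# Stage 6 — cross-species comparison: per-type marker statistics in
# both species, shared markers through orthology groups, and Pearson
# correlation of cell-type fold-change profiles with best-match
# recovery of the planted conserved types.

suppressPackageStartupMessages(library(mcatlas))

seed <- 1
out <- "results/xspecies"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

counts_a <- read_mtx_dir("results/data/umi")
labels_a <- unlist(jsonlite::read_json("results/data/truth.json")$labels)
counts_b <- read_mtx_dir("results/data/umi_speciesB")
labels_b <- unlist(jsonlite::read_json(
  "results/data/truth_speciesB.json")$labels)
orth <- read_orthology_table("results/data/orthology.tsv")

stats_a <- rank_markers(counts_a, labels_a)
stats_b <- rank_markers(counts_b, labels_b)
write.table(stats_a, file.path(out, "marker_stats_A.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(stats_b, file.path(out, "marker_stats_B.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

shared <- shared_features(stats_a, stats_b, orth, fc_min = 1)
write.table(shared, file.path(out, "shared_markers.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
self <- shared[shared$type_a == shared$type_b, ]
message(sprintf("shared-marker edges: %d; mean shared orthogroups on the diagonal: %.1f",
                nrow(shared), mean(self$n_shared)))

fc_a <- compute_fc(counts_a, labels_a, seed = seed)
fc_b <- compute_fc(counts_b, labels_b, seed = seed)
cc <- celltype_correlation(fc_a, fc_b, orth, fc_floor = 1.05)
write.table(data.frame(type_a = rownames(cc$matrix), cc$matrix,
                       check.names = FALSE),
            file.path(out, "correlation.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(cc$best_match, file.path(out, "best_match.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
hit <- mean(cc$best_match$type_b == cc$best_match$type_a)
message(sprintf("correlation on %d orthogroup meta-genes; best-match recovery %.0f%%",
                cc$n_genes, 100 * hit))
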