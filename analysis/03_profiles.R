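#!/usr/bin/env Rscript
# Stage 3 — normalized fold-change profiles per metacell, marker
# selection (up to 30 per cluster at FC >= 2), and cell-type annotation
# of metacells from the planted marker signatures.

suppressPackageStartupMessages(library(mcatlas))

seed <- 1
out <- "results/profiles"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

counts <- read_mtx_dir("results/data/umi")
part_tab <- read.table("results/cluster/partition.tsv", header = TRUE,
                       sep = "\t", colClasses = "character")
assignment <- setNames(
  suppressWarnings(as.integer(part_tab$metacell)), part_tab$cell_id)

fc <- compute_fc(counts, assignment, eps = 0.1, seed = seed)
markers <- select_markers(fc, max_per_cluster = 30, min_fc = 2)
write.table(data.frame(gene = rownames(fc$fc), fc$fc,
                       check.names = FALSE),
            file.path(out, "fc_profiles.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(as.data.frame(markers), file.path(out, "markers.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
message(sprintf("fold-change matrix: %d genes x %d metacells; %d marker entries",
                nrow(fc$fc), ncol(fc$fc), nrow(markers)))

# annotate metacells from the planted marker signatures
truth <- jsonlite::read_json("results/data/truth.json",
                             simplifyVector = TRUE)
signatures <- split(truth$marker_map$gene, truth$marker_map$type)
ann <- annotate_cell_types(fc, signatures, floor = 0.5)
write.table(ann$assignment, file.path(out, "annotation.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
n_ok <- sum(!is.na(ann$assignment$type))
message(sprintf("annotated %d/%d metacells to a planted type",
                n_ok, nrow(ann$assignment)))
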