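#!/usr/bin/env Rscript
# Stage 4 — peak processing and gene assignment: q-value filter, 250 bp
# summit standardization, overlap reduction, promoter definition and
# the distance-rule assignment, evaluated against the planted truth.

suppressPackageStartupMessages(library(mcatlas))

out <- "results/regulatory"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

peaks <- load_and_filter_peaks("results/data/peaks.narrowPeak",
                               min_neglog10_q = 6)
genes <- read_gene_table("results/data/genes.tsv")
seqs <- read_fasta("results/data/genome.fa")
sizes <- setNames(Biostrings::width(seqs), names(seqs))

std0 <- standardize_peaks(peaks, half_width = 125, chrom_sizes = sizes)
message(sprintf("standardized width: all %d non-truncated regions are %d bp",
                sum(!std0$truncated),
                unique((std0$end - std0$start)[!std0$truncated])))
std <- reduce_overlaps(std0)
message(sprintf("%d peaks after q-filter, %d after overlap reduction",
                nrow(peaks), nrow(std)))

prom <- define_promoters(genes, upstream = 50, downstream = 200)
asg <- assign_peaks(std, genes, prom, max_distance = 20000)
write.table(as.data.frame(asg), file.path(out, "assignment.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

links <- unique(asg[, c("peak_id", "gene_id")])
per_gene <- table(links$gene_id)
message(sprintf("%d links, %d genes linked, median %.0f peaks/gene, %d promoter peaks",
                nrow(asg), length(per_gene), median(per_gene),
                sum(asg$is_promoter)))
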