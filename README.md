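# mcatlas

Tools for building developmental single-cell expression atlases and
dissecting their regulatory logic, of the kind used for whole-embryo
atlases of invertebrate chordates (e.g. the amphioxus neurula): sparse
plate-based scRNA-seq UMI counts are partitioned into *metacells*
(small, transcriptionally coherent cell clusters), summarized as
normalized fold-change profiles with marker tables, connected to the
epigenome by rule-based assignment of ATAC-seq peaks to genes,
interrogated for transcription-factor motif enrichment against GC- and
length-matched genomic backgrounds, and compared across species through
orthology groups. A synthetic-data generator plants known cell types,
markers, peaks, motif occurrences and a diverged sister species, so the
entire pipeline is testable end-to-end with ground truth and no
downloads.

The intended users are computational biologists who want the atlas
methodology as reusable, tested functions rather than a one-off
analysis.

## Methods at a glance

- **Metacells.** Cells are downsampled to a common depth; informative
  genes pass total-UMI (> 30), prevalence (> 2 UMI in ≥ 3 cells),
  size-correlation (< −0.1) and niche-score (> 0.01) filters. A
  balanced K-nearest-neighbor graph (K = 100) keeps edge (i, j) iff the
  rank product r\_ij·r\_ji ≤ K², with weight 1/(1+√(r\_ij·r\_ji)).
  Bootstrap resampling (75% of cells, 1,000 iterations by default) with
  community detection yields co-clustering frequencies f\_ij =
  co-clustered / co-sampled; a graph on each cell's 30 strongest
  partners, α = 2 edge filtering, community extraction and dissolution
  of clusters under 15 cells gives the metacell partition.
- **Profiles.** Expression of gene g in cluster m is the regularized
  geometric mean exp(mean ln(1 + u)) − 1; the normalized fold change is
  FC(g, m) = (geomean + ε) / (median over clusters + ε), ε = 0.1.
  Markers: up to 30 genes per cluster at FC ≥ 2.
- **Peak assignment.** narrowPeak records with −log10(q) ≥ 6 are
  standardized to 250 bp around summits, reduced to non-overlapping
  regions, and linked to genes by summit-to-TSS distance: promoter
  overlaps (TSS −50/+200 bp, strand-aware) link exclusively; other
  peaks link to every gene within 20 kbp not shadowed by a more
  proximal gene's TSS. Regions are binned per cell type by assigned
  gene FC: high (≥ 1.5), mild (1.1–1.5), background (≤ 1).
- **Motifs.** PPM information content IC\_j = 2 + Σ p log2 p;
  contiguous-IC filtering (IC ≥ 0.5 over a run of 4, or two blocks of
  3); redundancy reduction by weighted-Pearson similarity (IC-weighted,
  offset- and reverse-complement-maximized, ≥ 6 bp overlap) with
  average-linkage clustering at 0.95 and best-IC representatives.
  Scanning is log2-odds with hits above 80% of each motif's maximum
  score; enrichment is a one-sided binomial test of foreground hit
  counts against a pseudocounted background rate from 2× GC/
  length-matched sampled regions, BH-adjusted within each (cell type,
  bin); per-region empirical p-values are rank-based within 10 GC bins.
- **Cross-species.** Per-type one-sided Wilcoxon rank-sum marker tests
  (exact by enumeration for small tie-free groups) with BH adjustment;
  shared markers/TFs through orthology groups (FC ≥ 1, TFs at
  FC > 1.25, adjusted p < 0.05); Pearson correlation of cell-type FC
  profiles over orthogroup meta-genes with FC > 1.05, with best-match
  reporting.

## Worked example

```r
library(mcatlas)

truth <- make_expression_truth(n_types = 4, n_genes = 300,
                               markers_per_type = 10, fold_levels = 8,
                               seed = 1)
umi <- sample_umi_matrix(truth, cells_per_type = 100, seed = 1)
dim(umi$counts)
#> [1] 300 400
median(Matrix::colSums(umi$counts))
#> [1] 984

res <- cluster_cells(umi$counts, K = 30, n_iter = 60, t_szcor = NA,
                     seed = 1)
table(res$partition$assignment)
#>   1   2   3   4
#> 100 100 100 100

pred <- metacell_majority_labels(res$partition, umi$labels)
adjusted_rand_index(pred, umi$labels)
#> [1] 1

fc <- compute_fc(umi$counts, res$partition, seed = 1)
mk <- select_markers(fc, max_per_cluster = 30, min_fc = 2)
head(as.data.frame(mk), 5)
#>   cluster rank  gene       fc
#> 1       1    1 g0091 9.617816
#> 2       1    2 g0146 9.210243
#> 3       1    3 g0129 8.999114
#> 4       1    4 g0010 8.902728
#> 5       1    5 g0176 8.851163
```

The 400 cells fall into 4 metacells that coincide exactly with the
planted types (adjusted Rand index 1), and the marker table recovers
all 40 planted markers near the planted fold of 8 (the top fold changes
exceed 8 because the denominator — the cross-cluster median — sits
slightly below the baseline for sampled counts).

The `analysis/` directory holds the same workflow as numbered narrative
scripts (`01_simulate.R` … `06_cross_species.R`), each writing its
tables under `results/`; `run_pipeline(validate_config())` runs the
stages programmatically from a single validated configuration.

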