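## End-to-end orchestration: a validated configuration with the
## reference analysis' parameters as defaults, staged execution on
## synthetic data, and a JSON run manifest.

default_config <- function() {
  list(
    seed = 1,
    outdir = "results/run",
    stages = list(simulate = TRUE, cluster = TRUE, profile = TRUE,
                  regmap = TRUE, motifs = TRUE, xspecies = TRUE),
    simulate = list(n_types = 8, n_genes = 800, markers_per_type = 20,
                    fold = 8, cells_per_type = 375,
                    genome_length = 2e6, genome_genes = 40,
                    peaks_per_gene = 2, orphan_peaks = 10,
                    fg_rate = 0.4, bg_rate = 0.05,
                    one2one_frac = 0.7, dup_frac = 0.2,
                    divergence_noise = 0.1),
    cluster = list(K = 100, K_cc = 30, n_iter = 1000, fraction = 0.75,
                   alpha = 2, min_size = 15, t_tot = 30,
                   t_prev_cells = 3, t_prev_umi = 2, t_szcor = -0.1,
                   t_niche = 0.01, min_cells = 50, min_median_umi = 500),
    profile = list(eps = 0.1, max_markers = 30, min_fc = 2),
    regmap = list(min_neglog10_q = 6, half_width = 125,
                  promoter_up = 50, promoter_down = 200,
                  max_distance = 20000, fc_hi = 1.5, fc_mid = 1.1,
                  fc_bg = 1.0),
    motifs = list(ic_min = 0.5, run_len = 4, block_len = 3, n_blocks = 2,
                  sim_threshold = 0.95, min_overlap = 6,
                  score_fraction_min = 0.8, bg_multiple = 2,
                  n_gc_bins = 10),
    xspecies = list(fc_min = 1, tf_fc_min = 1.25, p_max = 0.05,
                    fc_floor = 1.05)
  )
}

check_range <- function(cfg, path, lo, hi, open_lo = FALSE) {
  v <- cfg
  for (k in path) v <- v[[k]]
  bad <- if (open_lo) v <= lo || v > hi else v < lo || v > hi
  if (is.na(bad) || bad)
    param_error(sprintf("config key '%s' = %s out of range",
                        paste(path, collapse = "."), format(v)))
}

merge_config <- function(base, user, prefix = character(0)) {
  for (k in names(user)) {
    if (!k %in% names(base))
      param_error(sprintf("unknown config key '%s'",
                          paste(c(prefix, k), collapse = ".")))
    base[[k]] <- if (is.list(base[[k]]) && is.list(user[[k]]))
      merge_config(base[[k]], user[[k]], c(prefix, k)) else user[[k]]
  }
  base
}

#' Validate a pipeline configuration
#'
#' Reads a YAML file (or takes a list), merges it over the default
#' preset — whose numeric parameters are the reference analysis'
#' published values (K = 100, K_cc = 30, alpha = 2, min_size = 15, 1000
#' x 75% bootstrap, q-filter 1e-6, 250 bp peaks, 20 kbp assignment
#' window, FC bins 1.5/1.1/1.0, IC and similarity thresholds, ...) —
#' rejects unknown keys and range-checks the result.  An empty input
#' yields the full default preset.
#'
#' @param config Path to a YAML file, a list, or `NULL` for defaults.
#' @return A validated `run_config` list.
#' @export
validate_config <- function(config = NULL) {
  user <- if (is.null(config)) list()
    else if (is.character(config)) {
      if (!file.exists(config)) input_error(sprintf("no such file: %s",
                                                    config))
      y <- yaml::read_yaml(config)
      if (is.null(y)) list() else y
    } else config
  cfg <- merge_config(default_config(), user)
  check_range(cfg, c("cluster", "fraction"), 0, 1, open_lo = TRUE)
  check_range(cfg, c("cluster", "K"), 1, Inf)
  check_range(cfg, c("cluster", "min_size"), 1, Inf)
  check_range(cfg, c("simulate", "fg_rate"), 0, 1)
  check_range(cfg, c("simulate", "bg_rate"), 0, 1)
  check_range(cfg, c("simulate", "n_types"), 2, Inf)
  check_range(cfg, c("motifs", "score_fraction_min"), 0, 1)
  check_range(cfg, c("xspecies", "p_max"), 0, 1, open_lo = TRUE)
  class(cfg) <- "run_config"
  cfg
}

write_tsv <- function(d, path) {
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full synthetic-data pipeline
#'
#' Executes the enabled stages in dependency order — simulate, cluster,
#' profile, peak-to-gene assignment, motif curation/enrichment,
#' cross-species comparison — writing each stage's tables under
#' `config$outdir` and a JSON run manifest (resolved configuration,
#' output inventory with checksums, stage timings, package version)
#' last.
#'
#' @param config A `run_config` from [validate_config()].
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config = validate_config()) {
  if (!inherits(config, "run_config")) config <- validate_config(config)
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed
  timings <- list()
  outputs <- character(0)
  state <- new.env()
  stage <- function(name, enabled, deps, fun) {
    if (!enabled) return(invisible(NULL))
    missing <- setdiff(deps, ls(state))
    if (length(missing))
      stop(sprintf("stage '%s' needs upstream stage(s): %s — enable or run them first",
                   name, paste(missing, collapse = ", ")))
    t0 <- proc.time()[["elapsed"]]
    fun()
    timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    assign(name, TRUE, state)
  }

  stage("simulate", config$stages$simulate, character(0), function() {
    sc <- config$simulate
    truth <- make_expression_truth(sc$n_types, sc$n_genes,
                                   sc$markers_per_type, sc$fold, seed)
    umi <- sample_umi_matrix(truth, sc$cells_per_type, seed = seed)
    genome <- make_genome(sc$genome_genes, sc$genome_length, seed = seed)
    regulome <- make_peaks(genome, sc$peaks_per_gene,
                           extra_orphans = sc$orphan_peaks, seed = seed)
    fams <- make_motif_families(2, 1, seed = seed)
    gene_types <- setNames(
      rep(truth$types, length.out = nrow(genome$genes)),
      genome$genes$gene_id)
    planted <- plant_motifs(regulome, genome, fams,
                            setNames(truth$types[seq_along(fams$motifs)],
                                     motif_ids(fams)),
                            gene_types, sc$fg_rate, sc$bg_rate, seed)
    pair <- make_orthology_pair(truth, sc$one2one_frac, sc$dup_frac,
                                sc$divergence_noise, seed = seed)
    assign("truth", truth, state)
    assign("umi", umi, state)
    assign("genome", planted$genome, state)
    assign("regulome", planted$regulome, state)
    assign("motif_fams", fams, state)
    assign("gene_types", gene_types, state)
    assign("pair", pair, state)
    write_mtx_dir(umi$counts, file.path(config$outdir, "umi"))
    write_fasta(state$genome$seqs, file.path(config$outdir, "genome.fa"))
    write_narrowpeak(state$regulome$peaks,
                     file.path(config$outdir, "peaks.narrowPeak"))
    write_gene_table(state$genome$genes,
                     file.path(config$outdir, "genes.tsv"))
    write_orthology_table(pair$pair_truth$orthology_table,
                          file.path(config$outdir, "orthology.tsv"))
    write_truth_json(list(labels = as.list(umi$labels),
                          marker_map = truth$marker_map),
                     file.path(config$outdir, "truth.json"))
    outputs <<- c(outputs, "umi/matrix.mtx", "genome.fa",
                  "peaks.narrowPeak", "genes.tsv", "orthology.tsv",
                  "truth.json")
  })

  stage("cluster", config$stages$cluster, "simulate", function() {
    cc <- config$cluster
    res <- cluster_cells(state$umi$counts, K = cc$K, K_cc = cc$K_cc,
                         n_iter = cc$n_iter, fraction = cc$fraction,
                         alpha = cc$alpha, min_size = cc$min_size,
                         t_tot = cc$t_tot, t_prev_cells = cc$t_prev_cells,
                         t_prev_umi = cc$t_prev_umi, t_szcor = cc$t_szcor,
                         t_niche = cc$t_niche, min_cells = cc$min_cells,
                         min_median_umi = cc$min_median_umi, seed = seed)
    assign("clustering", res, state)
    part <- res$partition$assignment
    write_tsv(data.frame(cell_id = names(part),
                         metacell = ifelse(is.na(part), "outlier", part)),
              file.path(config$outdir, "partition.tsv"))
    write_tsv(res$features$stats, file.path(config$outdir,
                                            "feature_stats.tsv"))
    outputs <<- c(outputs, "partition.tsv", "feature_stats.tsv")
  })

  stage("profile", config$stages$profile, "cluster", function() {
    pc <- config$profile
    fc <- compute_fc(state$umi$counts, state$clustering$partition,
                     eps = pc$eps, seed = seed)
    markers <- select_markers(fc, pc$max_markers, pc$min_fc)
    assign("fc", fc, state)
    assign("markers", markers, state)
    write_tsv(data.frame(gene = rownames(fc$fc), fc$fc,
                         check.names = FALSE),
              file.path(config$outdir, "fc_profiles.tsv"))
    write_tsv(as.data.frame(markers), file.path(config$outdir,
                                                "markers.tsv"))
    outputs <<- c(outputs, "fc_profiles.tsv", "markers.tsv")
  })

  stage("regmap", config$stages$regmap, "simulate", function() {
    rc <- config$regmap
    peaks <- load_and_filter_peaks(
      file.path(config$outdir, "peaks.narrowPeak"), rc$min_neglog10_q)
    sizes <- setNames(Biostrings::width(state$genome$seqs),
                      names(state$genome$seqs))
    peaks <- standardize_peaks(peaks, rc$half_width, sizes)
    peaks <- reduce_overlaps(peaks)
    prom <- define_promoters(state$genome$genes, rc$promoter_up,
                             rc$promoter_down)
    asg <- assign_peaks(peaks, state$genome$genes, prom, rc$max_distance)
    # gene-level cell-type FC: planted gene types give each genome gene
    # the expression profile of its type's markers
    type_fc <- vapply(state$truth$types, function(t)
      ifelse(state$gene_types == t, config$simulate$fold, 1),
      numeric(length(state$gene_types)))
    rownames(type_fc) <- names(state$gene_types)
    sets <- celltype_peak_sets(asg, type_fc, rc$fc_hi, rc$fc_mid, rc$fc_bg)
    assign("peaks_std", peaks, state)
    assign("assignment", asg, state)
    assign("ct_sets", sets, state)
    write_tsv(as.data.frame(asg), file.path(config$outdir,
                                            "peak_gene_assignment.tsv"))
    outputs <<- c(outputs, "peak_gene_assignment.tsv")
  })

  stage("motifs", config$stages$motifs, "regmap", function() {
    mc <- config$motifs
    lib <- contiguous_ic_filter(state$motif_fams, mc$ic_min, mc$run_len,
                                mc$block_len, mc$n_blocks)
    lib <- dedupe_library(lib, mc$sim_threshold, mc$min_overlap)
    fg_seq <- peak_sequences(state$peaks_std, state$genome$seqs)
    bg <- sample_matched_background(state$peaks_std, state$genome$seqs,
                                    mc$bg_multiple, mc$n_gc_bins, seed)
    bg_peaks <- data.frame(chrom = bg$chrom, start = bg$start,
                           end = bg$end, name = bg$name)
    bg_seq <- peak_sequences(bg_peaks, state$genome$seqs)
    hits <- scan_regions(c(fg_seq, bg_seq), lib, mc$score_fraction_min)
    enr <- binned_enrichment(state$ct_sets, bg$name, hits,
                             motifs = motif_ids(lib))
    assign("enrichment", enr, state)
    write_tsv(as.data.frame(enr), file.path(config$outdir,
                                            "motif_enrichment.tsv"))
    outputs <<- c(outputs, "motif_enrichment.tsv")
  })

  stage("xspecies", config$stages$xspecies, "simulate", function() {
    xc <- config$xspecies
    fc_a <- compute_fc(state$umi$counts, state$umi$labels, seed = seed)
    fc_b <- compute_fc(state$pair$umi_b$counts, state$pair$umi_b$labels,
                       seed = seed)
    corr <- celltype_correlation(
      fc_a, fc_b, state$pair$pair_truth$orthology_table,
      fc_floor = xc$fc_floor)
    assign("xcorr", corr, state)
    write_tsv(data.frame(type_a = rownames(corr$matrix), corr$matrix,
                         check.names = FALSE),
              file.path(config$outdir, "celltype_correlation.tsv"))
    write_tsv(corr$best_match, file.path(config$outdir,
                                         "best_match.tsv"))
    outputs <<- c(outputs, "celltype_correlation.tsv", "best_match.tsv")
  })

  paths <- file.path(config$outdir, outputs)
  manifest <- list(
    config = unclass(config),
    outputs = data.frame(file = outputs,
                         md5 = unname(tools::md5sum(paths)),
                         stringsAsFactors = FALSE),
    timings = timings,
    package_version = as.character(utils::packageVersion("mcatlas"))
  )
  jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(manifest)
}
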