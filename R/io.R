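## Readers/writers for the plain-text interchange formats the pipeline
## consumes and produces.  Sparse matrices go through the Matrix package
## (MatrixMarket), sequences through Biostrings (FASTA); narrowPeak and
## MEME-minimal are simple line formats handled here directly.

#' Write a UMI matrix as MatrixMarket plus label tables
#'
#' Writes `matrix.mtx`, `genes.tsv` and `barcodes.tsv` under `dir`.
#'
#' @param counts Sparse genes x cells matrix with dimnames.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_mtx_dir <- function(counts, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(methods::as(counts, "CsparseMatrix"),
                  file.path(dir, "matrix.mtx"))
  writeLines(rownames(counts), file.path(dir, "genes.tsv"))
  writeLines(colnames(counts), file.path(dir, "barcodes.tsv"))
  invisible(dir)
}

#' Read a UMI matrix written by [write_mtx_dir()]
#' @param dir Directory holding `matrix.mtx`, `genes.tsv`, `barcodes.tsv`.
#' @return Sparse genes x cells dgCMatrix.
#' @export
read_mtx_dir <- function(dir) {
  m <- methods::as(Matrix::readMM(file.path(dir, "matrix.mtx")),
                   "CsparseMatrix")
  dimnames(m) <- list(readLines(file.path(dir, "genes.tsv")),
                      readLines(file.path(dir, "barcodes.tsv")))
  m
}

#' Write genome sequences as wrapped FASTA
#' @param seqs A [Biostrings::DNAStringSet].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(seqs, path, width = 60L)
  invisible(path)
}

#' Read FASTA sequences
#' @param path FASTA file.
#' @return A [Biostrings::DNAStringSet].
#' @export
read_fasta <- function(path) Biostrings::readDNAStringSet(path)

narrowpeak_cols <- c("chrom", "start", "end", "name", "score", "strand",
                     "signal", "neglog10_p", "neglog10_q", "summit_offset")

#' Write peaks in MACS2 narrowPeak format
#'
#' Ten-column BED dialect, 0-based half-open, summit as an offset from
#' `start` in the tenth column.
#'
#' @param peaks Data frame with the ten narrowPeak columns (as produced
#'   by [make_peaks()] or [load_and_filter_peaks()]).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_narrowpeak <- function(peaks, path) {
  stopifnot(all(narrowpeak_cols %in% names(peaks)))
  write.table(peaks[, narrowpeak_cols], path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a gene/TSS annotation table
#' @param genes Data frame with `gene_id`, `chrom`, `tss`, `strand`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_gene_table <- function(genes, path) {
  write.table(genes[, c("gene_id", "chrom", "tss", "strand")], path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene/TSS annotation table
#' @param path Tab-separated file with header
#'   `gene_id chrom tss strand`.
#' @return Data frame.
#' @export
read_gene_table <- function(path) {
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' Write an orthology-group table
#' @param table Data frame with `group_id`, `species`, `gene_id`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_orthology_table <- function(table, path) {
  write.table(table[, c("group_id", "species", "gene_id")], path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an orthology-group table
#' @param path Tab-separated file with header `group_id species gene_id`.
#' @return Data frame.
#' @export
read_orthology_table <- function(path) {
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' Write a motif library in MEME minimal format
#'
#' @param library A `motif_library`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_meme <- function(library, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "strands: + -", "",
               "Background letter frequencies",
               "A 0.25000 C 0.25000 G 0.25000 T 0.25000", ""), con)
  for (m in library$motifs) {
    writeLines(sprintf("MOTIF %s", m$id), con)
    writeLines(sprintf(
      "letter-probability matrix: alength= 4 w= %d nsites= 20 E= 0",
      nrow(m$matrix)), con)
    for (i in seq_len(nrow(m$matrix)))
      writeLines(paste(sprintf("%.6f", m$matrix[i, ]), collapse = " "), con)
    writeLines("", con)
  }
  invisible(path)
}

#' Read a MEME minimal format motif file
#'
#' Parses `MOTIF` blocks with `letter-probability matrix:` sections into
#' a `motif_library`; other sections are ignored.
#'
#' @param path MEME file.
#' @param source Source tag attached to every motif.
#' @return A `motif_library`.
#' @export
read_meme <- function(path, source = "known") {
  lines <- readLines(path)
  motifs <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (grepl("^MOTIF\\s", lines[i])) {
      id <- strsplit(trimws(lines[i]), "\\s+")[[1]][2]
      j <- i + 1L
      while (j <= length(lines) &&
             !grepl("^letter-probability matrix:", lines[j])) j <- j + 1L
      if (j > length(lines)) input_error(
        sprintf("MOTIF %s lacks a letter-probability matrix", id))
      w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", lines[j]))
      rows <- lines[(j + 1L):(j + w)]
      mat <- do.call(rbind, lapply(rows, function(r)
        as.numeric(strsplit(trimws(r), "\\s+")[[1]])))
      mat <- mat / rowSums(mat)  # absorb fixed-precision rounding
      colnames(mat) <- BASES
      motifs[[length(motifs) + 1L]] <- motif_ppm(id, mat, source)
      i <- j + w + 1L
    } else i <- i + 1L
  }
  motif_library(motifs)
}

#' Serialize a synthetic ground truth to JSON
#' @param truth Any list of plain-data truth components.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}
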