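# shared small fixtures built in code

make_toy_counts <- function(n_genes = 20, n_cells = 10, seed = 1,
                            lambda = 5) {
  set.seed(seed)
  m <- matrix(stats::rpois(n_genes * n_cells, lambda), n_genes, n_cells)
  dimnames(m) <- list(sprintf("g%02d", seq_len(n_genes)),
                      sprintf("c%02d", seq_len(n_cells)))
  Matrix::Matrix(m, sparse = TRUE)
}
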