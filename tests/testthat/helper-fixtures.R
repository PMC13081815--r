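# Shared fixtures and small oracles used across the suite.

# Hand-derivation of fixtures/qc_fixture.tsv under thresholds
# (min_genes 3, max_genes 6, min_counts 10, min_cells_per_gene 2):
#   c1: 6 genes expressed, 10 UMIs  -> retained (both bounds inclusive)
#   c2: 6 genes, 12 UMIs            -> retained
#   c3: 7 genes > 6                 -> removed (gene-range rule)
#   c4: 2 genes < 3                 -> removed (gene-range rule)
#   c5: 4 genes, 11 UMIs            -> retained
#   c6: 3 genes, 9 UMIs < 10        -> removed (min-counts rule)
# gene filter on {c1, c2, c5}: g01..g04 expressed in c1+c2, g05/g06 in
# c1+c5, g07 in c2+c5 (all >= 2 cells); g08 and g09 in one cell; g10..g12
# in none -> 7 genes survive. Expected shape: 3 cells x 7 genes.
qc_fixture_path <- function() test_path("fixtures", "qc_fixture.tsv")

qc_fixture_thresholds <- function() {
  qc_thresholds(min_genes = 3, max_genes = 6, min_counts = 10,
                min_cells_per_gene = 2)
}

# a count_matrix from a dense integer matrix with default ids
make_cm <- function(m, meta = NULL) {
  count_matrix(m, cell_ids = paste0("c", seq_len(nrow(m))),
               gene_ids = paste0("g", seq_len(ncol(m))), cell_meta = meta)
}

# hand-constructed spectral_decomposition with prescribed scores;
# U is taken orthonormal by construction of the caller
make_decomp <- function(U, s, V = NULL, meta = NULL) {
  K <- length(s)
  if (is.null(V)) V <- diag(max(K, 3))[, seq_len(K)]
  structure(list(U = U, s = s, V = V,
                 total_variance = sum(s^2), centered = FALSE, K = K,
                 method = "manual", gene_ids = NULL, cell_ids = NULL,
                 cell_meta = meta),
            class = "spectral_decomposition")
}

# independent brute-force plug-in MI (bits): naive double loop
brute_force_mi <- function(tab) {
  N <- sum(tab)
  rs <- rowSums(tab)
  cs <- colSums(tab)
  mi <- 0
  for (i in seq_len(nrow(tab))) {
    for (j in seq_len(ncol(tab))) {
      if (tab[i, j] > 0) {
        p <- tab[i, j] / N
        mi <- mi + p * log2((tab[i, j] * N) / (rs[i] * cs[j]))
      }
    }
  }
  mi
}

# align the signs of singular-vector columns to a reference (for SVD
# comparisons; signs are arbitrary per component)
align_signs <- function(A, ref) {
  for (k in seq_len(ncol(A))) {
    if (sum(A[, k] * ref[, k]) < 0) A[, k] <- -A[, k]
  }
  A
}

# a small expression_table built directly from a log2-CPM matrix
make_expr_table <- function(log2_cpm, expressed = NULL) {
  if (is.null(expressed)) expressed <- rep(TRUE, nrow(log2_cpm))
  structure(list(log2_cpm = log2_cpm, pseudocount = 1,
                 expressed = expressed, min_cpm = 1,
                 n_replicates = NULL),
            class = "expression_table")
}
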