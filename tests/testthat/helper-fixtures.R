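# Shared synthetic fixtures, built once per test run.

fixture_spec <- synthetic_spec(seed = 20260107L)
fixture_centroids <- make_centroids(fixture_spec)
fixture_centroid_matrix <- local({
  m <- as.matrix(fixture_centroids[, -1])
  rownames(m) <- fixture_centroids$gene_id
  m
})

# small random expression tibble
random_expression_tbl <- function(n_genes, n_samples, seed = 1) {
  set.seed(seed)
  m <- matrix(runif(n_genes * n_samples, 0, 10), nrow = n_genes,
              dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                              sprintf("s%03d", seq_len(n_samples))))
  dplyr::bind_cols(tibble::tibble(gene_id = rownames(m)), tibble::as_tibble(m))
}

# a centroid pair that is exactly symmetric under reversing gene order
# (an involution), so the 50/50 value mix has identical rho to both
symmetric_centroid_pair <- function(n_genes = 21, seed = 5) {
  set.seed(seed)
  c1 <- runif(n_genes, 0, 10)
  tibble::tibble(gene_id = sprintf("g%02d", seq_len(n_genes)),
                 A = c1, B = rev(c1))
}

# n replicate values with exact sample mean m and sample sd s
replicates_with_moments <- function(n, m, s, seed = 1) {
  set.seed(seed)
  z <- rnorm(n)
  z <- (z - mean(z)) / sd(z)
  m + s * z
}

# repeated-measures set from a value matrix
rm_from_matrix <- function(m, archetype_id, subtype) {
  colnames(m) <- sprintf("rep%02d", seq_len(ncol(m)))
  tb <- dplyr::bind_cols(tibble::tibble(gene_id = rownames(m)),
                         tibble::as_tibble(m))
  repeated_measures(tb, archetype_id = archetype_id, subtype = subtype)
}
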