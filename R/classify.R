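#' Spearman's rank correlation
#'
#' Spearman's rho between two vectors: Pearson correlation of the
#' average-rank (fractional rank) transformed values. This is the similarity
#' measure of the nearest-centroid classifier; ties receive average ranks.
#' Although historically described as a "distance", rho is a similarity and
#' the classifier maximizes it.
#'
#' @param x,y Numeric vectors of equal length >= 3, all values finite.
#' @return A single correlation in `[-1, 1]`.
#' @details If either vector has zero rank variance (all values tied) the
#'   correlation is undefined and an error is raised.
#' @examples
#' spearman_rho(c(1, 2, 3), c(10, 20, 30))   # 1
#' spearman_rho(c(1, 2, 2, 4), c(1, 3, 2, 4))
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) abort("x and y must have equal length")
  if (length(x) < 3L) abort("need at least 3 observations")
  if (!all(is.finite(x)) || !all(is.finite(y))) abort("values must be finite")
  rx <- rank(x)
  ry <- rank(y)
  rx <- rx - mean(rx)
  ry <- ry - mean(ry)
  dx <- sqrt(sum(rx^2))
  dy <- sqrt(sum(ry^2))
  if (dx == 0 || dy == 0) {
    abort("undefined correlation: a vector has zero rank variance (all values tied)")
  }
  r <- sum(rx * ry) / (dx * dy)
  min(1, max(-1, r))
}

# Spearman rho of every column of `m` against every centroid column.
# Returns an n_centroids x n_samples matrix. Vectorized: rank each column,
# center, normalize, then one crossprod.
rho_against_centroids <- function(m, centroid_ranks) {
  rk <- apply(m, 2L, rank)
  if (is.null(dim(rk))) rk <- matrix(rk, ncol = ncol(m))
  rk <- sweep(rk, 2L, colMeans(rk))
  nrm <- sqrt(colSums(rk^2))
  if (any(nrm == 0)) {
    abort("undefined correlation: a sample has zero rank variance (all values tied)")
  }
  rk <- sweep(rk, 2L, nrm, "/")
  crossprod(centroid_ranks, rk)
}

# centroid matrix (genes x subtypes) -> centered, unit-norm rank matrix
centroid_rank_matrix <- function(cm) {
  rk <- apply(cm, 2L, rank)
  rk <- sweep(rk, 2L, colMeans(rk))
  nrm <- sqrt(colSums(rk^2))
  if (any(nrm == 0)) {
    abort(sprintf("centroid '%s' has zero rank variance",
                  colnames(cm)[which(nrm == 0)[1]]))
  }
  sweep(rk, 2L, nrm, "/")
}

# argmax with deterministic tie handling: first subtype in declared order
# among those within tol of the max; flags the tie.
assign_subtype <- function(rho, tol = 1e-12) {
  top <- max(rho)
  hits <- which(rho >= top - tol)
  list(subtype = names(rho)[hits[1]], is_tie = length(hits) > 1L)
}

#' Classify one sample against a centroid set
#'
#' Computes Spearman's rho between the sample and every centroid and assigns
#' the subtype whose centroid attains the maximum. Exact ties (to 1e-12) are
#' resolved deterministically in favor of the earlier subtype in the centroid
#' set's declared column order and flagged via `is_tie`.
#'
#' @inheritParams align_genes
#' @return A one-row tibble: `sample_id`, `assigned_subtype`, `is_tie`,
#'   `n_genes_used`, and one `rho_<subtype>` column per centroid.
#' @examples
#' cen <- tibble::tibble(gene_id = paste0("g", 1:5),
#'                       A = c(5, 4, 3, 2, 1), B = c(1, 2, 3, 4, 5))
#' classify_sample(c(g1 = 0.9, g2 = 2, g3 = 3.2, g4 = 4, g5 = 5.5), cen)
#' @export
classify_sample <- function(values, centroids, sample_id = "sample") {
  al <- align_genes(values, centroids)
  if (length(al$genes) < 3L) abort("need >= 3 shared genes to classify")
  cr <- centroid_rank_matrix(al$centroids)
  rho <- drop(rho_against_centroids(matrix(al$sample, ncol = 1L), cr))
  names(rho) <- colnames(al$centroids)
  asg <- assign_subtype(rho)
  out <- tibble::tibble(sample_id = sample_id,
                        assigned_subtype = asg$subtype,
                        is_tie = asg$is_tie,
                        n_genes_used = length(al$genes))
  for (s in names(rho)) out[[paste0("rho_", s)]] <- unname(rho[s])
  out
}

#' @param samples Expression tibble of one or more samples (columns).
#' @param strict If `TRUE` (default) a per-sample failure aborts the batch;
#'   if `FALSE` failed samples are returned with `assigned_subtype = NA` and
#'   the error message in an `error` column.
#' @param sample_id Identifier used for a single profile given as a named
#'   vector.
#' @rdname classify_sample
#' @details `classify()` applies [classify_sample()] to every sample column,
#'   preserving input order. A sample matrix whose columns are the centroids
#'   themselves classifies each to its own subtype with rho 1.
#' @export
classify <- function(samples, centroids, strict = TRUE) {
  if (is.data.frame(samples) && ncol(samples) == 1L &&
      names(samples)[1] == "gene_id") {
    return(tibble::tibble(sample_id = character(),
                          assigned_subtype = character(),
                          is_tie = logical(), n_genes_used = integer()))
  }
  samples <- as_expression_tbl(samples, "sample matrix")
  ids <- names(samples)[-1]
  rows <- purrr::map(ids, function(sid) {
    v <- setNames(samples[[sid]], samples$gene_id)
    if (strict) return(classify_sample(v, centroids, sample_id = sid))
    tryCatch(
      dplyr::mutate(classify_sample(v, centroids, sample_id = sid), error = NA_character_),
      error = function(e) tibble::tibble(sample_id = sid,
                                         assigned_subtype = NA_character_,
                                         is_tie = NA, n_genes_used = NA_integer_,
                                         error = conditionMessage(e)))
  })
  dplyr::bind_rows(rows)
}
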