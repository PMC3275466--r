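#' Specification for synthetic fixtures
#'
#' Bundles the parameters of the synthetic data generator, which emulates the
#' statistical structure the method assumes: K well-separated subtype
#' centroids over a log-scale expression range, archetypal samples lying
#' essentially on a centroid, "gray-area" samples between two centroids, and
#' heteroscedastic per-gene Gaussian measurement noise whose standard
#' deviation depends on expression level and subtype (weakly expressed genes
#' are noisier, and subtypes differ in how much).
#'
#' @param n_genes Number of genes (default 50, a PAM50-sized panel).
#' @param subtypes Subtype names (default the five intrinsic breast-cancer
#'   subtypes).
#' @param seed Integer master seed for all generator randomness.
#' @param expression_range Range of log-scale expression values (default
#'   `c(0, 10)`, matching the magnitude of qPCR-style relative expression).
#' @param sigma_funs Named list (by subtype) of functions expression -> sigma
#'   used for replicate noise; the default is affine and decreasing in
#'   expression with subtype-specific intercepts (the "HER2-enriched"-like
#'   subtype noisiest at low expression), floored at 0.05.
#' @param archetype_jitter SD of the jitter separating an archetypal sample
#'   from its centroid (default 0.1 = 1% of the dynamic range).
#' @param n_replicates Replicates per repeated-measures set (default 12).
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_genes = 50L,
                           subtypes = c("Luminal A", "Luminal B",
                                        "HER2-enriched", "Basal-like",
                                        "Normal-like"),
                           seed = 20260101L,
                           expression_range = c(0, 10),
                           sigma_funs = NULL,
                           archetype_jitter = 0.01 * diff(expression_range),
                           n_replicates = 12L) {
  stopifnot(n_genes >= 3L, length(subtypes) >= 2L, !anyDuplicated(subtypes),
            n_replicates >= 3L)
  if (is.null(sigma_funs)) sigma_funs <- default_sigma_funs(subtypes)
  structure(list(n_genes = as.integer(n_genes), subtypes = subtypes,
                 seed = as.integer(seed),
                 expression_range = expression_range,
                 sigma_funs = sigma_funs,
                 archetype_jitter = archetype_jitter,
                 n_replicates = as.integer(n_replicates)),
            class = "synthetic_spec")
}

# Affine, decreasing sigma(e) with subtype-specific intercepts: the i-th
# subtype ranges from noisier to cleaner, floored so sigma stays positive
# over [0, 10]. Mimics higher qPCR variability at low template abundance.
default_sigma_funs <- function(subtypes) {
  intercepts <- seq(0.35, 0.15, length.out = length(subtypes))
  # put the largest low-expression noise on a HER2-like subtype if present
  ord <- seq_along(subtypes)
  her2 <- grep("HER2", subtypes)
  if (length(her2)) {
    ord <- c(her2[1], setdiff(ord, her2[1]))
  }
  funs <- vector("list", length(subtypes))
  names(funs) <- subtypes
  for (k in seq_along(subtypes)) {
    a <- intercepts[which(ord == k)]
    funs[[subtypes[k]]] <- local({
      a0 <- a
      function(e) pmax(a0 - 0.02 * e, 0.05)
    })
  }
  funs
}

#' Generate well-separated synthetic centroids
#'
#' Draws each centroid's gene values uniformly over the expression range and
#' resamples until every centroid pair has Spearman rho at or below
#' `max_rho`, so the subtypes are genuinely distinct profiles.
#'
#' @param spec A [synthetic_spec()].
#' @param max_rho Pairwise separation threshold (default 0.3).
#' @param max_attempts Resampling budget (default 1000).
#' @return A centroid set: expression tibble with one column per subtype.
#' @examples
#' cen <- make_centroids(synthetic_spec(n_genes = 10, seed = 7))
#' @export
make_centroids <- function(spec, max_rho = 0.3, max_attempts = 1000L) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(derive_seed(spec$seed, "centroids"))
  K <- length(spec$subtypes)
  rng <- spec$expression_range
  genes <- sprintf("gene%02d", seq_len(spec$n_genes))
  draw <- function() runif(spec$n_genes, rng[1], rng[2])
  m <- replicate(K, draw())
  for (attempt in seq_len(max_attempts)) {
    rho <- cor(apply(m, 2L, rank))
    diag(rho) <- 0
    worst <- which(abs(rho) == max(abs(rho)), arr.ind = TRUE)[1, ]
    if (max(abs(rho)) <= max_rho) {
      colnames(m) <- spec$subtypes
      rownames(m) <- genes
      return(matrix_to_tbl(m))
    }
    m[, worst[2]] <- draw()
  }
  abort(sprintf("could not reach pairwise |rho| <= %.2f in %d attempts",
                max_rho, max_attempts))
}

#' Synthetic archetypal and borderline samples
#'
#' `make_archetype()` returns a profile equal to one centroid plus small
#' seeded jitter, so it classifies to its own subtype with rho near 1.
#' `make_borderline()` returns the value-wise convex combination
#' `lambda * c1 + (1 - lambda) * c2` of two centroids plus jitter -- a
#' "gray-area" sample whose classification can flip under measurement error
#' (at `lambda = 0.5` it sits near the decision boundary).
#'
#' Because Spearman's rho is computed on ranks, the equal-rho point along
#' the value segment between two centroids is generally not at the value
#' midpoint. With `balance = TRUE` (the default) the requested `lambda` is
#' mapped monotonically onto the segment so that `lambda = 0.5` lands on the
#' empirical decision boundary (the mixing weight where rho to both
#' centroids is equal), while `lambda = 0` and `lambda = 1` still give the
#' pure centroids; with `balance = FALSE` the raw weight is used.
#'
#' @param centroids Centroid set (expression tibble).
#' @param subtype,subtype1,subtype2 Subtype column names.
#' @param spec A [synthetic_spec()] (supplies jitter SD and seed).
#' @param lambda Mixing weight toward `subtype1`, in `[0, 1]`.
#' @param jitter_sd Override the spec's jitter SD.
#' @param id Sample name used in seed derivation.
#' @param balance Recalibrate `lambda` so 0.5 sits at the equal-rho point
#'   (default TRUE).
#' @return Named numeric vector (gene -> expression).
#' @export
make_archetype <- function(centroids, subtype, spec, jitter_sd = NULL,
                           id = paste0("arch_", subtype)) {
  centroids <- as_expression_tbl(centroids, "centroid set")
  if (!subtype %in% names(centroids)) abort(sprintf("unknown subtype '%s'", subtype))
  jitter_sd <- jitter_sd %||% spec$archetype_jitter
  set.seed(derive_seed(spec$seed, "archetype", id))
  v <- centroids[[subtype]] + rnorm(nrow(centroids), sd = jitter_sd)
  setNames(v, centroids$gene_id)
}

#' @rdname make_archetype
#' @export
make_borderline <- function(centroids, subtype1, subtype2, lambda, spec,
                            jitter_sd = NULL,
                            id = sprintf("mix_%s_%s_%.2f", subtype1, subtype2, lambda),
                            balance = TRUE) {
  centroids <- as_expression_tbl(centroids, "centroid set")
  stopifnot(lambda >= 0, lambda <= 1)
  for (s in c(subtype1, subtype2)) {
    if (!s %in% names(centroids)) abort(sprintf("unknown subtype '%s'", s))
  }
  jitter_sd <- jitter_sd %||% spec$archetype_jitter
  c1 <- centroids[[subtype1]]; c2 <- centroids[[subtype2]]
  lam <- if (balance) {
    remap_lambda(lambda, boundary_lambda(c1, c2))
  } else lambda
  set.seed(derive_seed(spec$seed, "borderline", id))
  v <- lam * c1 + (1 - lam) * c2 + rnorm(nrow(centroids), sd = jitter_sd)
  setNames(v, centroids$gene_id)
}

# mixing weight at which rho(mix, c1) == rho(mix, c2); the rho gap is a
# step function of the weight, so bisection lands within one rank step
boundary_lambda <- function(c1, c2) {
  gap <- function(l) {
    m <- l * c1 + (1 - l) * c2
    spearman_rho(m, c1) - spearman_rho(m, c2)
  }
  if (gap(0) >= 0 || gap(1) <= 0) return(0.5)
  stats::uniroot(gap, c(0, 1), tol = 1e-6)$root
}

# piecewise-linear monotone map [0,1]->[0,1] sending 0.5 to the boundary
remap_lambda <- function(lambda, lstar) {
  if (lambda <= 0.5) 2 * lambda * lstar else lstar + (2 * lambda - 1) * (1 - lstar)
}

#' Synthetic repeated measures of a parent sample
#'
#' Draws `n_replicates` noisy copies of the parent profile, each gene
#' perturbed by `Normal(0, sigma_fun(value))` -- the heteroscedastic error
#' structure the error-characterization stage is meant to recover.
#'
#' @param values Named numeric parent profile.
#' @param sigma_fun Function expression -> sigma (>= 0).
#' @param n_replicates Number of replicates (default 12).
#' @param seed Integer seed.
#' @param archetype_id,subtype Metadata for the resulting set.
#' @return A [repeated_measures] tibble.
#' @export
make_repeated_measures <- function(values, sigma_fun, n_replicates = 12L,
                                   seed = 1L, archetype_id = "archetype",
                                   subtype = "unknown") {
  stopifnot(is.function(sigma_fun), n_replicates >= 3L)
  sig <- sigma_fun(values)
  if (any(sig < 0)) abort("sigma_fun returned negative sigma")
  set.seed(seed)
  m <- matrix(rnorm(length(values) * n_replicates,
                    mean = rep(values, times = n_replicates),
                    sd = rep(sig, times = n_replicates)),
              nrow = length(values))
  rownames(m) <- names(values)
  colnames(m) <- sprintf("rep%02d", seq_len(n_replicates))
  repeated_measures(matrix_to_tbl(m), archetype_id = archetype_id,
                    subtype = subtype)
}

#' Synthetic cohort with truth manifest
#'
#' Builds a labeled mixture of archetypal samples (one per subtype, cycled)
#' and borderline samples (random subtype pairs at mixing weight `lambda`),
#' together with a truth manifest recording how each sample was generated --
#' the ground truth for parameter-recovery tests.
#'
#' @param spec A [synthetic_spec()].
#' @param n_archetypal,n_borderline Sample counts of each kind.
#' @param centroids Optional pre-built centroid set (defaults to
#'   [make_centroids()] under the spec's seed).
#' @param lambda Mixing weight for borderline samples (default 0.5).
#' @return List with `samples` (expression tibble), `centroids`, and
#'   `truth` (tibble: `sample_id`, `kind`, `subtype`, `subtype2`, `lambda`).
#' @export
make_cohort <- function(spec, n_archetypal, n_borderline,
                        centroids = NULL, lambda = 0.5) {
  stopifnot(inherits(spec, "synthetic_spec"),
            n_archetypal >= 0, n_borderline >= 0,
            n_archetypal + n_borderline >= 1)
  centroids <- centroids %||% make_centroids(spec)
  K <- length(spec$subtypes)
  cols <- list(); truth <- list()
  for (i in seq_len(n_archetypal)) {
    s <- spec$subtypes[((i - 1L) %% K) + 1L]
    sid <- sprintf("arch%03d_%s", i, gsub("[^A-Za-z0-9]", "", s))
    cols[[sid]] <- make_archetype(centroids, s, spec, id = sid)
    truth[[sid]] <- tibble::tibble(sample_id = sid, kind = "archetypal",
                                   subtype = s, subtype2 = NA_character_,
                                   lambda = 1)
  }
  set.seed(derive_seed(spec$seed, "cohort_pairs"))
  for (i in seq_len(n_borderline)) {
    pair <- sample(spec$subtypes, 2L)
    sid <- sprintf("border%03d", i)
    cols[[sid]] <- make_borderline(centroids, pair[1], pair[2], lambda, spec,
                                   id = sid)
    truth[[sid]] <- tibble::tibble(sample_id = sid, kind = "borderline",
                                   subtype = pair[1], subtype2 = pair[2],
                                   lambda = lambda)
  }
  m <- do.call(cbind, cols)
  rownames(m) <- centroids$gene_id
  colnames(m) <- names(cols)
  list(samples = matrix_to_tbl(m), centroids = centroids,
       truth = dplyr::bind_rows(truth))
}

#' Synthetic archetype panel: repeated measures for every subtype
#'
#' Convenience wrapper producing, for each subtype that has an archetype
#' (all but an optional excluded one, mirroring panels where no archetype
#' exists for the normal-tissue class), an archetypal sample and its
#' repeated-measures set under the spec's heteroscedastic noise.
#'
#' @param spec A [synthetic_spec()].
#' @param centroids Optional centroid set.
#' @param exclude Subtypes without an archetype (default "Normal-like" when
#'   present).
#' @return List with `centroids` and `measures` (named list of
#'   [repeated_measures] sets).
#' @export
make_archetype_panel <- function(spec, centroids = NULL,
                                 exclude = intersect("Normal-like", spec$subtypes)) {
  centroids <- centroids %||% make_centroids(spec)
  subtypes <- setdiff(spec$subtypes, exclude)
  measures <- lapply(subtypes, function(s) {
    parent <- make_archetype(centroids, s, spec)
    make_repeated_measures(parent, spec$sigma_funs[[s]],
                           n_replicates = spec$n_replicates,
                           seed = derive_seed(spec$seed, "rm", s),
                           archetype_id = paste0("arch_", gsub("[^A-Za-z0-9]", "", s)),
                           subtype = s)
  })
  names(measures) <- subtypes
  list(centroids = centroids, measures = measures)
}
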