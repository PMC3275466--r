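#' Derive a per-parent random seed from the master seed
#'
#' Seeds for individual parents (and scenarios) are derived from the master
#' seed and the parent's identity by a deterministic string hash, so each
#' parent consumes its own random substream. Results are therefore identical
#' whatever the batch composition, processing order, or parallel split.
#'
#' @param master_seed Integer master seed.
#' @param ... Character/numeric components identifying the substream
#'   (parent sample id, scenario, ...).
#' @return A single integer in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(master_seed, ...) {
  key <- paste(c(as.character(master_seed), vapply(list(...), as.character, "")),
               collapse = "\r")
  p <- 2147483647
  h <- 0
  for (code in utf8ToInt(key)) h <- (h * 31 + code) %% p
  as.integer(max(1, (h * 48271) %% p))
}

#' Perturb an expression profile with per-gene Gaussian error
#'
#' Draws each gene's value independently from
#' `Normal(parent value, sigma_gene)`. Because every draw is centered on the
#' parent's own value, co-regulation between genes in the parent is
#' preserved; only the measurement error is independent across genes.
#' Simulated values are not clipped to the parent's expression range.
#'
#' @param values Named numeric vector (parent profile).
#' @param sigma Per-gene standard deviations: a single number, or a vector
#'   named by gene covering every gene of the parent. All >= 0.
#' @return Named numeric vector over the same genes.
#' @examples
#' set.seed(1)
#' simulate_profile(c(ACTR3B = 1.94), sigma = 0.085)
#' @export
simulate_profile <- function(values, sigma) {
  sigma <- align_sigma(values, sigma)
  setNames(rnorm(length(values), mean = values, sd = sigma), names(values))
}

align_sigma <- function(values, sigma) {
  if (length(sigma) == 1L && is.null(names(sigma))) {
    sigma <- setNames(rep(sigma, length(values)), names(values))
  }
  if (is.null(names(sigma)) && length(sigma) == length(values)) {
    names(sigma) <- names(values)
  }
  missing <- setdiff(names(values), names(sigma))
  if (length(missing)) {
    abort(sprintf("no sigma for gene(s): %s",
                  paste(head(missing, 5), collapse = ", ")))
  }
  sigma <- sigma[names(values)]
  if (any(!is.finite(sigma)) || any(sigma < 0)) {
    abort("sigma values must be finite and >= 0")
  }
  sigma
}

#' Monte Carlo reproducibility of one parent sample
#'
#' Generates `n_sims` perturbed copies of the parent profile (independent
#' per-gene Gaussian error), classifies each against the centroid set, and
#' tallies assignments by subtype. `prop_identical` -- the fraction of
#' simulated samples assigned the parent's subtype -- is the reproducibility
#' estimate reported throughout.
#'
#' @inheritParams simulate_profile
#' @param parent_subtype The parent's (original) subtype; if `NULL` it is
#'   obtained by classifying the parent against `centroids`.
#' @param centroids Centroid set (expression tibble, columns = subtypes).
#' @param n_sims Number of simulated samples (default 100000).
#' @param seed Integer seed for this parent's substream.
#' @param scenario Label recorded with the result (`"average"`, `"best"`,
#'   `"worst"`, or `NA` for archetype mode / explicit sigma).
#' @param sample_id Parent identifier recorded with the result.
#' @param chunk_size Simulated samples classified per block (memory bound).
#' @return A one-row tibble: `parent_sample_id`, `parent_subtype`,
#'   `scenario`, `n_sims`, `seed`, `prop_identical`, and one `n_<subtype>`
#'   count column per subtype. Counts always sum to `n_sims`.
#' @examples
#' cen <- tibble::tibble(gene_id = paste0("g", 1:6),
#'                       A = c(6, 5, 4, 3, 2, 1), B = c(1, 2, 3, 4, 5, 6))
#' parent <- setNames(c(6, 5, 4, 3, 2, 1) + 0.05, paste0("g", 1:6))
#' run_reproducibility(parent, centroids = cen, sigma = 0.1,
#'                     n_sims = 1000, seed = 42)
#' @export
run_reproducibility <- function(values, centroids, sigma,
                                parent_subtype = NULL,
                                n_sims = 100000L, seed = 1L,
                                scenario = NA_character_,
                                sample_id = "sample",
                                chunk_size = 20000L) {
  stopifnot(n_sims >= 1L)
  al <- align_genes(values, centroids)
  if (length(al$genes) < 3L) abort("need >= 3 shared genes to classify")
  sigma <- align_sigma(al$sample, align_sigma(values, sigma)[al$genes])
  subtypes <- colnames(al$centroids)
  if (is.null(parent_subtype)) {
    parent_subtype <- classify_sample(values, centroids,
                                      sample_id = sample_id)$assigned_subtype
  }
  cr <- centroid_rank_matrix(al$centroids)
  counts <- setNames(integer(length(subtypes)), subtypes)
  set.seed(seed)
  left <- as.integer(n_sims)
  ng <- length(al$sample)
  while (left > 0L) {
    k <- min(left, as.integer(chunk_size))
    noise <- matrix(rnorm(ng * k, sd = rep(sigma, times = k)), nrow = ng)
    sims <- noise + al$sample
    rho <- rho_against_centroids(sims, cr)
    idx <- max.col(t(rho), ties.method = "first")
    tab <- tabulate(idx, nbins = length(subtypes))
    counts <- counts + tab
    left <- left - k
  }
  out <- tibble::tibble(parent_sample_id = sample_id,
                        parent_subtype = parent_subtype,
                        scenario = scenario,
                        n_sims = as.integer(n_sims),
                        seed = as.integer(seed),
                        prop_identical =
                          unname(counts[parent_subtype]) / n_sims)
  for (s in subtypes) out[[paste0("n_", s)]] <- unname(counts[s])
  out
}

#' Monte Carlo reproducibility over a cohort
#'
#' For every sample column: classify it to obtain its original subtype, look
#' up that subtype's error curve in the sigma model, predict each gene's
#' sigma from its expression value under the requested scenario(s), and run
#' the per-parent simulation. Each (parent, scenario) pair gets its own
#' random substream derived from `master_seed` (see [derive_seed()]), so
#' results do not depend on cohort composition or processing order.
#'
#' Parents whose original subtype has no curve in the model (typically
#' Normal-like, for which no archetypal sample exists) are skipped with a
#' warning unless `fallback = TRUE`, in which case the pooled
#' across-subtypes curve is used.
#'
#' @param samples Expression tibble of parent samples.
#' @param centroids Centroid set.
#' @param model A [fit_sigma_model()] fit.
#' @param scenarios Character vector among `"best"`, `"average"`, `"worst"`.
#' @param n_sims Simulations per parent per scenario (default 100000).
#' @param master_seed Master seed for substream derivation.
#' @param fallback Use the pooled curve for unknown subtypes (default FALSE).
#' @param chunk_size Passed to [run_reproducibility()].
#' @return Tibble with one row per parent per scenario (skipped parents are
#'   absent; they are listed in the `skipped` attribute).
#' @export
run_cohort <- function(samples, centroids, model,
                       scenarios = "average", n_sims = 100000L,
                       master_seed = 1L, fallback = FALSE,
                       chunk_size = 20000L) {
  stopifnot(inherits(model, "sigma_model"))
  bad <- setdiff(scenarios, c("best", "average", "worst"))
  if (length(bad)) abort(sprintf("unknown scenario(s): %s", paste(bad, collapse = ", ")))
  samples <- as_expression_tbl(samples, "sample matrix")
  original <- classify(samples, centroids)
  rows <- list(); skipped <- character()
  for (i in seq_len(nrow(original))) {
    sid <- original$sample_id[i]
    sub <- original$assigned_subtype[i]
    v <- setNames(samples[[sid]], samples$gene_id)
    known <- sub %in% names(model$fits)
    if (!known && !fallback) {
      warn(sprintf("skipping '%s': no error curve for subtype '%s'", sid, sub))
      skipped <- c(skipped, sid)
      next
    }
    for (sc in scenarios) {
      sig <- if (known) {
        predict_sigma(model, v, subtype = sub, scenario = sc)
      } else {
        suppressWarnings(predict_sigma(model, v, subtype = sub,
                                       scenario = sc, fallback = TRUE))
      }
      rows[[length(rows) + 1L]] <- run_reproducibility(
        v, centroids, sigma = setNames(sig, names(v)),
        parent_subtype = sub, n_sims = n_sims,
        seed = derive_seed(master_seed, sid, sc),
        scenario = sc, sample_id = sid, chunk_size = chunk_size)
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "skipped") <- skipped
  out
}

#' Pivot reproducibility counts to long form
#'
#' @param results Tibble of [run_reproducibility()] rows (wide `n_<subtype>`
#'   count columns).
#' @return Long tibble: `parent_sample_id`, `parent_subtype`, `scenario`,
#'   `n_sims`, `assigned_subtype`, `count`.
#' @export
result_counts <- function(results) {
  cols <- grep("^n_", names(results), value = TRUE)
  cols <- setdiff(cols, "n_sims")
  if (!length(cols)) abort("no count columns (n_<subtype>) found")
  results |>
    dplyr::select(dplyr::all_of(c("parent_sample_id", "parent_subtype",
                                  "scenario", "n_sims", cols))) |>
    tidyr::pivot_longer(dplyr::all_of(cols), names_to = "assigned_subtype",
                        names_prefix = "n_", values_to = "count")
}
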