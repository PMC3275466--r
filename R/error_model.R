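#' Per-gene Gaussian error from repeated measures
#'
#' Fits one Gaussian per gene to the replicate measurements of an archetypal
#' sample: `mu` is the sample mean and `sigma` the sample standard deviation
#' (n-1 denominator) of that gene's replicates. These per-gene, per-archetype
#' distributions drive the archetype-mode Monte Carlo simulation.
#'
#' @param rm A [repeated_measures] set (genes x replicates).
#' @return A tibble with one row per gene: `gene_id`, `archetype_id`,
#'   `subtype`, `mu`, `sigma`, `n`.
#' @examples
#' reps <- tibble::tibble(gene_id = "ACTR3B",
#'                        r1 = 1.9, r2 = 2.0, r3 = 1.92)
#' fit_gene_gaussians(repeated_measures(reps, "lumB", "Luminal B"))
#' @export
fit_gene_gaussians <- function(rm) {
  stopifnot(inherits(rm, "repeated_measures"))
  m <- expr_matrix(rm)
  tibble::tibble(
    gene_id = rownames(m),
    archetype_id = attr(rm, "archetype_id"),
    subtype = attr(rm, "subtype"),
    mu = unname(rowMeans(m)),
    sigma = unname(apply(m, 1L, sd)),
    n = ncol(m)
  )
}

#' Pool median-centered replicate values across archetypes
#'
#' Twelve replicates per archetype are too few to judge a gene's error
#' distribution shape, so each archetype's replicate values are centered by
#' that archetype's per-gene median and then concatenated across archetypes.
#' With four archetypes of 12/12/12/11 replicates this yields the pooled
#' 47-point error distribution per gene whose approximate Gaussianity
#' justifies the normal error model.
#'
#' @param rms List of [repeated_measures] sets sharing one gene list.
#' @return A tibble in long form: `gene_id`, `archetype_id`, `value`
#'   (median-centered expression). Row count = sum of replicate counts x
#'   number of genes.
#' @export
pool_median_centered <- function(rms) {
  stopifnot(is.list(rms), length(rms) >= 1L,
            all(purrr::map_lgl(rms, inherits, "repeated_measures")))
  genes <- rms[[1]]$gene_id
  for (rm in rms[-1]) {
    if (!identical(sort(rm$gene_id), sort(genes))) {
      abort(sprintf("repeated-measures set '%s' has a different gene set",
                    attr(rm, "archetype_id")))
    }
  }
  purrr::map_dfr(rms, function(rm) {
    m <- expr_matrix(rm)[genes, , drop = FALSE]
    centered <- m - apply(m, 1L, median)
    tibble::tibble(gene_id = rep(genes, times = ncol(m)),
                   archetype_id = attr(rm, "archetype_id"),
                   value = as.vector(centered))
  })
}

#' Normality diagnostics for pooled error distributions
#'
#' Descriptive diagnostics of the pooled, median-centered error values per
#' gene: moment skewness and excess kurtosis plus the Shapiro-Wilk p-value.
#' The diagnostics are informational only -- approximate Gaussianity is
#' accepted by inspection, and nothing downstream gates on these values.
#'
#' @param pooled Long tibble from [pool_median_centered()] (or any tibble
#'   with `gene_id` and `value` columns).
#' @return A tibble per gene: `gene_id`, `n`, `skewness`, `kurtosis`
#'   (excess), `shapiro_p`.
#' @export
normality_summary <- function(pooled) {
  stopifnot(all(c("gene_id", "value") %in% names(pooled)))
  pooled |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(
      n = dplyr::n(),
      skewness = moment_skewness(.data$value),
      kurtosis = moment_kurtosis(.data$value),
      shapiro_p = shapiro.test(.data$value)$p.value,
      .groups = "drop"
    )
}

moment_skewness <- function(x) {
  if (length(x) < 8L) abort("need >= 8 points for normality diagnostics")
  s <- sd(x)
  if (s == 0) abort("degenerate input: zero variance")
  mean((x - mean(x))^3) / (mean((x - mean(x))^2))^1.5
}

moment_kurtosis <- function(x) {
  m2 <- mean((x - mean(x))^2)
  if (m2 == 0) abort("degenerate input: zero variance")
  mean((x - mean(x))^4) / m2^2 - 3
}

#' Model measurement sigma as a function of expression level and subtype
#'
#' Repeated measures show that the standard deviation of a gene's
#' measurement depends on its expression level and on the sample subtype
#' (weakly expressed genes are harder to quantify, and subtypes differ in
#' which genes they express weakly). `fit_sigma_model()` fits one locally
#' weighted linear regression (loess, span 0.75, degree 1, direct surface so
#' queries beyond the training range extrapolate the boundary fit, robust
#' "symmetric" bisquare reweighting) of sigma on expression per subtype, and
#' attaches a pointwise 95% confidence band obtained by a seeded
#' nonparametric bootstrap over the training points (percentile band on an
#' evaluation grid, linearly interpolated between grid points). The bands are
#' reordered pointwise so lower <= fit <= upper everywhere.
#'
#' The three bands define the simulation scenarios: `"best"` uses the lower
#' band (least error), `"average"` the fitted curve, `"worst"` the upper
#' band.
#'
#' @param points Tibble with columns `expression` (mean expression of a
#'   gene), `sigma` (its replicate standard deviation, >= 0), and `subtype`.
#'   Typically `fit_gene_gaussians()` output renamed, one point per gene per
#'   archetype. At least 10 points per subtype are required.
#' @param span,degree,family Loess parameters (defaults 0.75, 1,
#'   "symmetric").
#' @param n_boot Bootstrap resamples for the confidence band (default 500).
#' @param grid_n Evaluation grid size per subtype (default 100).
#' @param level Confidence level of the band (default 0.95).
#' @param sigma_floor Hard lower bound on every predicted sigma (default
#'   1e-6 expression units); direct-surface extrapolation of a local linear
#'   fit can go negative, and a positive floor keeps Gaussian sampling valid.
#' @param seed Integer seed for the bootstrap (default 1).
#' @return A `sigma_model` object with [predict_sigma()], [tidy()],
#'   [glance()] and [autoplot()] methods.
#' @export
fit_sigma_model <- function(points, span = 0.75, degree = 1,
                            family = "symmetric", n_boot = 500,
                            grid_n = 100, level = 0.95,
                            sigma_floor = 1e-6, seed = 1) {
  stopifnot(all(c("expression", "sigma", "subtype") %in% names(points)))
  if (any(points$sigma < 0)) abort("sigma values must be >= 0")
  if (!all(is.finite(points$expression)) || !all(is.finite(points$sigma))) {
    abort("points must be finite")
  }
  counts <- table(points$subtype)
  short <- names(counts)[counts < 10L]
  if (length(short)) {
    abort(sprintf("too few points (< 10) for subtype(s): %s",
                  paste(short, collapse = ", ")))
  }
  subtypes <- unique(points$subtype)
  alpha <- (1 - level) / 2

  fit_one <- function(df) {
    loess(sigma ~ expression, data = df, span = span, degree = degree,
          family = family, surface = "direct")
  }

  fits <- list(); grids <- list()
  for (i in seq_along(subtypes)) {
    s <- subtypes[i]
    df <- points[points$subtype == s, c("expression", "sigma")]
    fit <- suppressWarnings(fit_one(df))
    grid_x <- seq(min(df$expression), max(df$expression), length.out = grid_n)
    fit_y <- suppressWarnings(predict(fit, tibble::tibble(expression = grid_x)))

    set.seed((seed + 7L * i) %% .Machine$integer.max)
    boot <- matrix(NA_real_, nrow = n_boot, ncol = grid_n)
    for (b in seq_len(n_boot)) {
      idx <- sample.int(nrow(df), replace = TRUE)
      bf <- try(suppressWarnings(fit_one(df[idx, ])), silent = TRUE)
      if (!inherits(bf, "try-error")) {
        boot[b, ] <- suppressWarnings(
          predict(bf, tibble::tibble(expression = grid_x)))
      }
    }
    lo <- apply(boot, 2L, quantile, probs = alpha, na.rm = TRUE)
    hi <- apply(boot, 2L, quantile, probs = 1 - alpha, na.rm = TRUE)
    # pointwise reorder so best <= average <= worst, then floor
    lower <- pmax(pmin(lo, fit_y), sigma_floor)
    upper <- pmax(pmax(hi, fit_y), sigma_floor)
    fit_y <- pmax(fit_y, sigma_floor)

    fits[[s]] <- fit
    grids[[s]] <- tibble::tibble(subtype = s, expression = grid_x,
                                 lower = lower, fit = fit_y, upper = upper)
  }

  # pooled curve across subtypes: optional fallback for subtypes with no
  # archetype of their own (e.g. Normal-like)
  pooled_fit <- suppressWarnings(fit_one(points[, c("expression", "sigma")]))

  structure(list(
    fits = fits,
    pooled_fit = pooled_fit,
    grid = dplyr::bind_rows(grids),
    points = tibble::as_tibble(points[, c("expression", "sigma", "subtype")]),
    params = list(span = span, degree = degree, family = family,
                  n_boot = n_boot, grid_n = grid_n, level = level,
                  sigma_floor = sigma_floor, seed = seed)
  ), class = "sigma_model")
}

#' Predict measurement sigma under a scenario
#'
#' @param model A `sigma_model` from [fit_sigma_model()].
#' @param expression Numeric vector of expression values to query.
#' @param subtype Subtype whose error curve to use (the parent sample's
#'   original classification).
#' @param scenario One of `"average"` (fitted curve), `"best"` (lower 95%
#'   band) or `"worst"` (upper band).
#' @param fallback If `TRUE`, a subtype absent from the model falls back to
#'   the pooled-across-subtypes curve with a warning (its band offsets come
#'   from the pooled training points' full grid); default `FALSE` errors.
#' @return Numeric vector of sigma values, each >= the model's sigma floor.
#' @details The fitted curve is evaluated by the loess fit itself (direct
#'   surface, so extrapolation uses the boundary's local linear fit); the
#'   `best`/`worst` bands add the bootstrap band offset interpolated on the
#'   evaluation grid (held constant beyond the training range).
#' @export
predict_sigma <- function(model, expression, subtype,
                          scenario = c("average", "best", "worst"),
                          fallback = FALSE) {
  stopifnot(inherits(model, "sigma_model"))
  scenario <- match.arg(scenario)
  floor_v <- model$params$sigma_floor
  if (!subtype %in% names(model$fits)) {
    if (!fallback) {
      abort(sprintf("no error curve for subtype '%s' (known: %s); set fallback=TRUE to use the pooled curve",
                    subtype, paste(names(model$fits), collapse = ", ")))
    }
    warn(sprintf("subtype '%s' not in sigma model; using pooled curve", subtype))
    y <- unname(suppressWarnings(
      predict(model$pooled_fit, tibble::tibble(expression = expression))))
    return(pmax(y, floor_v))
  }
  fit <- model$fits[[subtype]]
  y <- unname(suppressWarnings(
    predict(fit, tibble::tibble(expression = expression))))
  if (scenario != "average") {
    g <- model$grid[model$grid$subtype == subtype, ]
    band <- if (scenario == "best") g$lower - g$fit else g$upper - g$fit
    off <- approx(g$expression, band, xout = expression, rule = 2)$y
    y <- y + off
    # preserve band ordering around the (floored) fit after interpolation
    yfit <- pmax(unname(suppressWarnings(
      predict(fit, tibble::tibble(expression = expression)))), floor_v)
    y <- if (scenario == "best") pmin(y, yfit) else pmax(y, yfit)
  }
  pmax(y, floor_v)
}

#' @rdname fit_sigma_model
#' @param x,object A `sigma_model`.
#' @param ... Unused.
#' @export
tidy.sigma_model <- function(x, ...) x$grid

#' @rdname fit_sigma_model
#' @export
glance.sigma_model <- function(x, ...) {
  x$points |>
    dplyr::group_by(.data$subtype) |>
    dplyr::summarise(n_points = dplyr::n(),
                     expression_min = min(.data$expression),
                     expression_max = max(.data$expression),
                     .groups = "drop") |>
    dplyr::mutate(span = x$params$span, degree = x$params$degree,
                  family = x$params$family, level = x$params$level)
}

#' @rdname fit_sigma_model
#' @export
print.sigma_model <- function(x, ...) {
  cat(sprintf("<sigma_model> %d subtype curve(s): %s\n",
              length(x$fits), paste(names(x$fits), collapse = ", ")))
  cat(sprintf("  loess span=%.2f degree=%d family=%s; %g%% bootstrap band (B=%d)\n",
              x$params$span, x$params$degree, x$params$family,
              100 * x$params$level, x$params$n_boot))
  invisible(x)
}

#' @rdname fit_sigma_model
#' @export
autoplot.sigma_model <- function(object, ...) {
  ggplot2::ggplot(object$grid, ggplot2::aes(x = .data$expression)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
                         fill = "steelblue", alpha = 0.25) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fit), color = "steelblue") +
    ggplot2::geom_point(data = object$points,
                        ggplot2::aes(y = .data$sigma), size = 0.6, alpha = 0.6) +
    ggplot2::facet_wrap(ggplot2::vars(.data$subtype)) +
    ggplot2::labs(x = "mean expression (log scale)",
                  y = expression(sigma ~ "(measurement SD)"),
                  title = "Measurement error vs expression level, by subtype") +
    ggplot2::theme_minimal()
}
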