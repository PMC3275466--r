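#' Confidence-interval half-width for a simulated proportion
#'
#' For a dichotomous outcome (a simulated sample is misclassified or not),
#' the half-width of the normal-approximation confidence interval around the
#' observed proportion is `W = z * sqrt(theta * (1 - theta) / n)`. It
#' justifies the number of Monte Carlo simulations: with z = 1.96 (95%
#' confidence), an expected misclassification proportion theta = 0.02 and
#' n = 100000 simulations the half-width is +/- 0.00087, small enough that
#' simulation noise is negligible against the reported percentages.
#'
#' @param z Normal quantile (e.g. 1.96 for 95%).
#' @param theta Expected proportion, in `[0, 1]`.
#' @param n Number of simulations, >= 1.
#' @return The half-width `W` (same scale as `theta`).
#' @examples
#' ci_width(1.96, 0.02, 100000)  # ~0.00087
#' @export
ci_width <- function(z, theta, n) {
  if (!is.numeric(theta) || any(theta < 0 | theta > 1)) {
    abort("theta must lie in [0, 1]")
  }
  if (!is.numeric(n) || any(n < 1)) abort("n must be >= 1")
  z * sqrt(theta * (1 - theta) / n)
}

#' Confusion summary: original vs simulated subtype, as percentages
#'
#' Aggregates per-parent Monte Carlo tallies by the parents' original
#' subtype: each cell is 100 x (simulated samples with that (original,
#' assigned) pair) / (all simulated samples whose parent had that original
#' subtype). Rows therefore sum to 100 (within rounding); the diagonal is
#' the per-subtype reproducibility. Cells are rendered to 2 decimals;
#' internal math is full precision.
#'
#' @param results Reproducibility tibble ([run_reproducibility()] /
#'   [run_cohort()] rows).
#' @param scenario If given, filter to that scenario first; otherwise all
#'   rows must already share one scenario (mixing scenarios is an error).
#' @param digits Decimals for rendering (default 2); `NA` for full precision.
#' @return A `confusion_summary` tibble: `original_subtype`,
#'   `n_sims_total`, one percentage column per assigned subtype.
#' @export
confusion_table <- function(results, scenario = NULL, digits = 2) {
  if (!nrow(results)) abort("no results to summarize")
  if (!is.null(scenario)) {
    results <- dplyr::filter(results, .data$scenario %in% .env$scenario)
    if (!nrow(results)) abort(sprintf("no results for scenario '%s'", scenario))
  }
  scen <- unique(results$scenario)
  if (length(scen) > 1L) {
    abort(sprintf("mixed scenarios in results (%s); pass scenario=",
                  paste(scen, collapse = ", ")))
  }
  totals <- results |>
    dplyr::group_by(original_subtype = .data$parent_subtype) |>
    dplyr::summarise(n_sims_total = sum(.data$n_sims), .groups = "drop")
  long <- result_counts(results)
  wide <- long |>
    dplyr::group_by(.data$parent_subtype, .data$assigned_subtype) |>
    dplyr::summarise(count = sum(.data$count), .groups = "drop") |>
    dplyr::left_join(totals, by = c(parent_subtype = "original_subtype")) |>
    dplyr::mutate(pct = 100 * .data$count / .data$n_sims_total)
  out <- wide |>
    dplyr::select(original_subtype = "parent_subtype",
                  "assigned_subtype", "pct") |>
    tidyr::pivot_wider(names_from = "assigned_subtype", values_from = "pct") |>
    dplyr::left_join(totals, by = "original_subtype") |>
    dplyr::relocate("n_sims_total", .after = "original_subtype")
  if (!is.na(digits)) {
    out <- dplyr::mutate(out, dplyr::across(-c(1, 2), ~ round(.x, digits)))
  }
  structure(out, scenario = scen, class = c("confusion_summary", class(out)))
}

#' Histogram of per-parent classification change
#'
#' Buckets parents by the percentage of their simulated samples that changed
#' subtype, `100 * (1 - prop_identical)`, per original subtype. Buckets are
#' `[0, w), [w, 2w), ...` with the last bucket closed, `[100 - w, 100]`;
#' `w` must divide 100. Parents whose simulations never change all fall in
#' the first bucket.
#'
#' @inheritParams confusion_table
#' @param bucket_width Bucket width in percentage points (default 5).
#' @return A `change_histogram` tibble: `original_subtype`, `bucket_lo`,
#'   `bucket_hi`, `n_parents`. Bucket counts sum to the number of parents
#'   per subtype.
#' @export
change_histogram <- function(results, bucket_width = 5) {
  if (!nrow(results)) abort("no results to summarize")
  if (100 %% bucket_width != 0) abort("bucket_width must divide 100")
  nb <- as.integer(100 / bucket_width)
  counts <- results |>
    dplyr::mutate(pct_changed = 100 * (1 - .data$prop_identical),
                  bucket = pmin(floor(.data$pct_changed / bucket_width), nb - 1L)) |>
    dplyr::count(original_subtype = .data$parent_subtype, .data$bucket,
                 name = "n_parents")
  out <- tidyr::expand_grid(original_subtype = unique(results$parent_subtype),
                            bucket = seq(0L, nb - 1L)) |>
    dplyr::left_join(counts, by = c("original_subtype", "bucket")) |>
    dplyr::mutate(n_parents = dplyr::coalesce(.data$n_parents, 0L),
                  bucket_lo = .data$bucket * bucket_width,
                  bucket_hi = (.data$bucket + 1L) * bucket_width) |>
    dplyr::select("original_subtype", "bucket_lo", "bucket_hi", "n_parents")
  structure(out, class = c("change_histogram", class(out)))
}

#' Fraction of parents that never change subtype
#'
#' A parent "never changes" when every one of its simulated samples was
#' assigned the parent's own subtype (all tally mass on `parent_subtype`,
#' i.e. `prop_identical == 1`).
#'
#' @inheritParams confusion_table
#' @return Tibble per original subtype: `n_never`, `n_parents`, `fraction`.
#' @export
never_change_summary <- function(results) {
  if (!nrow(results)) abort("no results to summarize")
  results |>
    dplyr::group_by(original_subtype = .data$parent_subtype) |>
    dplyr::summarise(n_never = sum(.data$prop_identical == 1),
                     n_parents = dplyr::n(),
                     fraction = .data$n_never / .data$n_parents,
                     .groups = "drop")
}

#' Clinician-facing scorecard for one sample
#'
#' Turns one parent's Monte Carlo tally into subtype-assignment
#' probabilities: `100 * count / n_sims` per subtype, sorted descending and
#' rendered to 1 decimal. The top line is the parent's reported subtype with
#' the probability that a re-measurement of the same sample would reproduce
#' it under the assay's intrinsic error.
#'
#' @param result A single reproducibility row ([run_reproducibility()]).
#' @param drop_zero Drop subtypes with zero probability (default TRUE).
#' @return A `scorecard` tibble (`subtype`, `probability` in percent) with
#'   attributes `sample_id`, `original_subtype`, `scenario`, `n_sims`.
#' @export
scorecard <- function(result, drop_zero = TRUE) {
  if (nrow(result) != 1L) abort("scorecard() takes exactly one result row")
  long <- result_counts(result)
  out <- long |>
    dplyr::mutate(probability = round(100 * .data$count / .data$n_sims, 1)) |>
    dplyr::arrange(dplyr::desc(.data$probability)) |>
    dplyr::select(subtype = "assigned_subtype", "probability")
  if (drop_zero) out <- dplyr::filter(out, .data$probability > 0)
  structure(out,
            sample_id = result$parent_sample_id,
            original_subtype = result$parent_subtype,
            scenario = result$scenario,
            n_sims = result$n_sims,
            class = c("scorecard", class(out)))
}

#' @rdname scorecard
#' @param x A `scorecard`.
#' @param ... Unused.
#' @export
print.scorecard <- function(x, ...) {
  cat(format_scorecard_md(x), sep = "\n")
  invisible(x)
}

#' Render a scorecard as Markdown or JSON
#'
#' @param x A [scorecard()].
#' @return `format_scorecard_md()` a character vector of Markdown lines;
#'   `format_scorecard_json()` a JSON string.
#' @rdname scorecard_format
#' @export
format_scorecard_md <- function(x) {
  stopifnot(inherits(x, "scorecard"))
  c(sprintf("### Subtype uncertainty scorecard: %s", attr(x, "sample_id")),
    sprintf("Reported subtype: **%s** (%s simulated replicates%s)",
            attr(x, "original_subtype"),
            format(attr(x, "n_sims"), big.mark = ","),
            if (is.na(attr(x, "scenario"))) ""
            else sprintf(", %s-case error model", attr(x, "scenario"))),
    "",
    "| Subtype | Probability |",
    "|---|---|",
    sprintf("| %s | %.1f%% |", x$subtype, x$probability))
}

#' @rdname scorecard_format
#' @export
format_scorecard_json <- function(x) {
  stopifnot(inherits(x, "scorecard"))
  jsonlite::toJSON(list(
    sample_id = attr(x, "sample_id"),
    original_subtype = attr(x, "original_subtype"),
    scenario = attr(x, "scenario"),
    n_sims = attr(x, "n_sims"),
    probability_by_subtype = setNames(as.list(x$probability), x$subtype)
  ), auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

#' @rdname scorecard
#' @param object A `scorecard` or `change_histogram`.
#' @export
autoplot.scorecard <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$subtype <- factor(df$subtype, levels = rev(df$subtype))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$probability, y = .data$subtype)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.1f%%", .data$probability)),
                       hjust = -0.1, size = 3) +
    ggplot2::xlim(0, 105) +
    ggplot2::labs(title = sprintf("Subtype probabilities under measurement error: %s",
                                  attr(object, "sample_id")),
                  x = "probability (%)", y = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname change_histogram
#' @param object A `change_histogram`.
#' @param ... Unused.
#' @export
autoplot.change_histogram <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$bucket_lo + (.data$bucket_hi - .data$bucket_lo) / 2,
                               y = .data$n_parents)) +
    ggplot2::geom_col(fill = "steelblue",
                      width = object$bucket_hi[1] - object$bucket_lo[1]) +
    ggplot2::facet_wrap(ggplot2::vars(.data$original_subtype)) +
    ggplot2::labs(x = "% of simulated samples that changed subtype",
                  y = "number of parent samples") +
    ggplot2::theme_minimal()
}
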