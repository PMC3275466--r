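#' Expression tables
#'
#' `classirep` represents a genes-by-samples expression matrix as a tibble
#' whose first column is `gene_id` and whose remaining columns are numeric,
#' one per sample (log-scale relative expression, unitless). A centroid set
#' uses the identical layout with one column per subtype. All functions in
#' the package accept and return this shape.
#'
#' @param x A data frame in the expression layout.
#' @param what Label used in error messages (e.g. "expression matrix").
#' @return `as_expression_tbl()` returns the validated tibble (invisibly
#'   unchanged apart from class coercion to tibble).
#' @details Validation enforces: first column named `gene_id`; unique,
#'   non-missing gene ids; at least one value column; every value column
#'   numeric; all entries finite (no `NA`/`NaN`/`Inf` -- missing values are
#'   not permitted); unique column names.
#' @examples
#' m <- tibble::tibble(gene_id = c("g1", "g2", "g3"), s1 = 1:3, s2 = c(2, 1, 5))
#' as_expression_tbl(m)
#' @export
as_expression_tbl <- function(x, what = "expression matrix") {
  if (!is.data.frame(x)) {
    abort(sprintf("%s must be a data frame, got <%s>", what, class(x)[1]))
  }
  x <- tibble::as_tibble(x)
  if (ncol(x) < 2L) {
    abort(sprintf("%s needs a gene_id column plus at least one value column", what))
  }
  if (names(x)[1] != "gene_id") {
    abort(sprintf("first column of %s must be named 'gene_id', got '%s'",
                  what, names(x)[1]))
  }
  if (anyDuplicated(names(x))) {
    abort(sprintf("%s has duplicated column names: %s", what,
                  paste(unique(names(x)[duplicated(names(x))]), collapse = ", ")))
  }
  ids <- x$gene_id
  if (!is.character(ids)) ids <- as.character(ids)
  if (anyNA(ids) || any(ids == "")) {
    abort(sprintf("%s has missing or empty gene ids", what))
  }
  if (anyDuplicated(ids)) {
    abort(sprintf("%s has duplicated gene ids: %s", what,
                  paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  for (j in seq(2L, ncol(x))) {
    col <- x[[j]]
    if (!is.numeric(col)) {
      abort(sprintf("column '%s' of %s is not numeric", names(x)[j], what))
    }
    bad <- which(!is.finite(col))
    if (length(bad)) {
      abort(sprintf(
        "non-finite value in %s at gene '%s', column '%s' (missing values are not permitted)",
        what, ids[bad[1]], names(x)[j]))
    }
  }
  x$gene_id <- ids
  x
}

# tibble (gene_id + value cols) -> numeric matrix with gene_id rownames
expr_matrix <- function(x) {
  m <- as.matrix(x[, -1, drop = FALSE])
  rownames(m) <- x$gene_id
  m
}

# numeric matrix with dimnames -> expression tibble
matrix_to_tbl <- function(m) {
  stopifnot(!is.null(rownames(m)), !is.null(colnames(m)))
  dplyr::bind_cols(tibble::tibble(gene_id = rownames(m)),
                   tibble::as_tibble(m))
}

#' Read and write expression/centroid TSV files
#'
#' Tab-separated, UTF-8, `.` decimal separator. The header row holds sample
#' (or subtype) names and its first cell must be the literal `gene_id`; the
#' first column holds gene identifiers. Lines starting with `#` before the
#' header are treated as comments (used by repeated-measures files to carry
#' metadata). Any non-numeric or missing cell is an error that names the
#' offending gene and column; duplicated gene or column ids are errors.
#' Matching of gene names elsewhere in the package is exact and
#' case-sensitive, so files must use consistent identifiers.
#'
#' @param path Path to a TSV file.
#' @param x An expression tibble (see [as_expression_tbl()]).
#' @return `read_expression_tsv()` returns an expression tibble with ids in
#'   file order. `write_expression_tsv()` returns `path` invisibly.
#' @details Values are written with 15 significant digits so that a
#'   read/write round trip preserves them to at least 10 significant digits.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' m <- tibble::tibble(gene_id = c("a", "b", "c"), s1 = c(1.5, 2, 3))
#' write_expression_tsv(m, tf)
#' read_expression_tsv(tf)
#' @export
read_expression_tsv <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readr::read_lines(path)
  lines <- lines[!grepl("^#", lines)]
  if (!length(lines)) abort(sprintf("empty file: %s", path))
  raw <- readr::read_tsv(I(lines), col_types = readr::cols(.default = "c"),
                         progress = FALSE, name_repair = "minimal")
  if (!ncol(raw) || names(raw)[1] != "gene_id") {
    abort(sprintf("header of %s must start with 'gene_id' (got '%s')",
                  path, if (ncol(raw)) names(raw)[1] else ""))
  }
  if (ncol(raw) < 2L) abort(sprintf("%s has no sample columns", path))
  out <- tibble::tibble(gene_id = as.character(raw[[1]]))
  for (j in seq(2L, ncol(raw))) {
    v <- suppressWarnings(as.numeric(raw[[j]]))
    bad <- which(is.na(v))
    if (length(bad)) {
      abort(sprintf("cannot parse value '%s' at row %d (gene '%s'), column '%s' of %s",
                    raw[[j]][bad[1]], bad[1], out$gene_id[bad[1]], names(raw)[j], path))
    }
    out[[names(raw)[j]]] <- v
  }
  as_expression_tbl(out)
}

#' @rdname read_expression_tsv
#' @export
write_expression_tsv <- function(x, path) {
  x <- as_expression_tbl(x)
  num <- lapply(x[-1], function(v) formatC(v, digits = 15, format = "g"))
  out <- c(paste(names(x), collapse = "\t"),
           do.call(paste, c(list(x$gene_id), num, sep = "\t")))
  readr::write_lines(out, path)
  invisible(path)
}

#' @rdname read_expression_tsv
#' @details `read_centroids_tsv()` applies the same parsing and additionally
#'   requires at least two subtype columns.
#' @export
read_centroids_tsv <- function(path) {
  x <- read_expression_tsv(path)
  if (ncol(x) < 3L) {
    abort(sprintf("centroid file %s must define at least 2 subtypes", path))
  }
  x
}

#' Repeated-measures files
#'
#' A repeated-measures set holds the replicate measurements of one archetypal
#' sample: a genes-by-replicates expression tibble plus two attributes,
#' `archetype_id` and `subtype`. On disk it is an expression TSV whose
#' columns are replicate ids, preceded by comment lines
#' `#archetype=<id>` and `#subtype=<name>`.
#'
#' @param path Path to a repeated-measures TSV.
#' @param rm A `repeated_measures` object (or an expression tibble plus the
#'   `archetype_id`/`subtype` arguments).
#' @param archetype_id,subtype Metadata; taken from the file's comment header
#'   when reading, required when constructing.
#' @param x Expression tibble of replicates (one column per replicate).
#' @return A `repeated_measures` tibble (genes x replicates) with attributes
#'   `archetype_id` and `subtype`.
#' @details At least 3 replicates are required and every replicate covers the
#'   identical gene set by construction of the tabular layout.
#' @examples
#' reps <- tibble::tibble(gene_id = c("g1", "g2", "g3"),
#'                        r1 = c(1, 2, 3), r2 = c(1.1, 2, 2.9), r3 = c(0.9, 2.1, 3))
#' rm <- repeated_measures(reps, archetype_id = "arch1", subtype = "Luminal A")
#' n_replicates(rm)
#' @export
repeated_measures <- function(x, archetype_id, subtype) {
  x <- as_expression_tbl(x, what = "repeated-measures set")
  if (ncol(x) - 1L < 3L) {
    abort(sprintf("repeated-measures set '%s' needs >= 3 replicates, got %d",
                  archetype_id, ncol(x) - 1L))
  }
  stopifnot(is.character(archetype_id), length(archetype_id) == 1L,
            is.character(subtype), length(subtype) == 1L)
  structure(x, archetype_id = archetype_id, subtype = subtype,
            class = c("repeated_measures", class(x)))
}

#' @rdname repeated_measures
#' @export
read_repeated_measures_tsv <- function(path, archetype_id = NULL, subtype = NULL) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  hdr <- grep("^#", readr::read_lines(path, n_max = 10L), value = TRUE)
  meta <- function(key) {
    hit <- grep(sprintf("^#%s=", key), hdr, value = TRUE)
    if (length(hit)) sub(sprintf("^#%s=", key), "", hit[1]) else NULL
  }
  archetype_id <- archetype_id %||% meta("archetype") %||%
    sub("\\.tsv$", "", basename(path))
  subtype <- subtype %||% meta("subtype")
  if (is.null(subtype)) {
    abort(sprintf("no subtype for %s: add a '#subtype=<name>' header line or pass subtype=", path))
  }
  repeated_measures(read_expression_tsv(path), archetype_id, subtype)
}

#' @rdname repeated_measures
#' @export
write_repeated_measures_tsv <- function(rm, path) {
  stopifnot(inherits(rm, "repeated_measures"))
  readr::write_lines(c(sprintf("#archetype=%s", attr(rm, "archetype_id")),
                       sprintf("#subtype=%s", attr(rm, "subtype"))), path)
  num <- lapply(rm[-1], function(v) formatC(v, digits = 15, format = "g"))
  out <- c(paste(names(rm), collapse = "\t"),
           do.call(paste, c(list(rm$gene_id), num, sep = "\t")))
  readr::write_lines(out, path, append = TRUE)
  invisible(path)
}

#' @rdname repeated_measures
#' @export
n_replicates <- function(rm) ncol(rm) - 1L

#' Align a sample's genes with a centroid set
#'
#' Restricts a sample profile and a centroid set to their common genes,
#' ordered by the sorted gene-id intersection (so the result does not depend
#' on input row order). Genes present on only one side are dropped and
#' counted; dropping more than half of the sample's genes raises a warning,
#' an empty intersection is an error.
#'
#' @param values Named numeric vector of the sample's expression values
#'   (names are gene ids), or a single-sample expression tibble.
#' @param centroids Centroid set as an expression tibble (columns = subtypes).
#' @return A list with `genes` (character, sorted), `sample` (numeric vector,
#'   aligned), `centroids` (genes x subtypes matrix, aligned), and
#'   `n_dropped` (genes discarded from either side).
#' @examples
#' cen <- tibble::tibble(gene_id = c("a", "b", "c"), s1 = c(1, 2, 3), s2 = c(3, 1, 2))
#' align_genes(c(b = 1.0, a = 2.0, c = 0.5, d = 9), cen)$n_dropped
#' @export
align_genes <- function(values, centroids) {
  if (is.data.frame(values)) {
    values <- as_expression_tbl(values, "sample profile")
    if (ncol(values) != 2L) abort("align_genes() expects a single-sample profile")
    values <- setNames(values[[2]], values$gene_id)
  }
  if (is.null(names(values)) || anyDuplicated(names(values))) {
    abort("sample values must be named by unique gene ids")
  }
  centroids <- as_expression_tbl(centroids, "centroid set")
  common <- sort(intersect(names(values), centroids$gene_id))
  if (!length(common)) abort("no genes shared between sample and centroids")
  n_dropped <- (length(values) - length(common)) +
    (nrow(centroids) - length(common))
  if (length(common) < length(values) / 2) {
    warn(sprintf("more than 50%% of sample genes dropped during alignment (%d kept of %d)",
                 length(common), length(values)))
  }
  cm <- expr_matrix(centroids)[common, , drop = FALSE]
  list(genes = common, sample = values[common], centroids = cm,
       n_dropped = as.integer(n_dropped))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
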