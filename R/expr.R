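#' Expression tables
#'
#' The pipeline carries gene-by-sample log2-ratio matrices as wide tibbles in
#' the PCL shape: a `gene_id` column, optional annotation columns
#' (`clone_id`, `unigene_id`, `symbol`), and one numeric column per sample.
#' Missing measurements are `NA`. These helpers convert between the tibble
#' form and a plain numeric matrix with `gene_id` rownames.
#'
#' @param expr A wide expression tibble.
#' @name expr-table
NULL

# annotation columns recognised in a wide expression tibble
.annot_cols <- c("gene_id", "clone_id", "unigene_id", "symbol")

#' @describeIn expr-table Names of the sample (numeric) columns.
#' @export
sample_ids <- function(expr) {
  setdiff(names(expr), .annot_cols)
}

#' @describeIn expr-table Extract the numeric gene x sample matrix
#'   (rownames = `gene_id`).
#' @export
expr_matrix <- function(expr) {
  stopifnot(is.data.frame(expr), "gene_id" %in% names(expr))
  ids <- sample_ids(expr)
  m <- as.matrix(expr[, ids, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- expr$gene_id
  m
}

#' @describeIn expr-table Annotation columns of the tibble.
#' @export
expr_annotation <- function(expr) {
  expr[, intersect(.annot_cols, names(expr)), drop = FALSE]
}

#' Build a wide expression tibble from a matrix
#'
#' @param m Numeric gene x sample matrix with rownames.
#' @param annotation Optional tibble of gene annotations with a `gene_id`
#'   column aligned to `rownames(m)`.
#' @return A wide expression tibble.
#' @export
as_expr_tibble <- function(m, annotation = NULL) {
  stopifnot(is.matrix(m), !is.null(rownames(m)))
  out <- tibble(gene_id = rownames(m))
  if (!is.null(annotation)) {
    stopifnot("gene_id" %in% names(annotation))
    out <- left_join(out, as_tibble(annotation), by = "gene_id")
  }
  vals <- as_tibble(as.data.frame(m, stringsAsFactors = FALSE))
  names(vals) <- colnames(m)
  dplyr::bind_cols(out, vals)
}

# replace the sample columns of `expr` by the columns of matrix `m`
set_expr_values <- function(expr, m) {
  stopifnot(all(rownames(m) == expr$gene_id))
  keep <- expr[, intersect(.annot_cols, names(expr)), drop = FALSE]
  dplyr::bind_cols(keep, as_tibble(as.data.frame(m)))
}

#' Filter report attached to pipeline outputs
#'
#' Filtering steps return their input tibble with rows removed and attach a
#' small report (`n_input`, per-rule removal counts, `n_retained`).
#'
#' @param x An object returned by a filtering step.
#' @return A tibble with columns `rule` and `n`, or `NULL` if absent.
#' @export
filter_report <- function(x) attr(x, "filter_report")

make_filter_report <- function(n_input, removed, n_retained) {
  rep <- tibble(
    rule = c("input", names(removed), "retained"),
    n = c(n_input, unname(unlist(removed)), n_retained)
  )
  stopifnot(n_input == sum(unlist(removed)) + n_retained)
  rep
}

with_filter_report <- function(x, report) {
  attr(x, "filter_report") <- report
  x
}
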