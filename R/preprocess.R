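#' Library-size normalization of a count matrix
#'
#' Scales every column (cell) by its total count, multiplies by a common
#' scaling factor and applies `log2(v + 1)`, so a zero count maps to zero.
#' This is the standard counts-per-scaled-total transform used for UMI and
#' read-count single-cell matrices.
#'
#' @param x An [ExpressionMatrix()] with `norm_state = "raw_counts"` and
#'   non-negative values.
#' @param scale Common scaling factor applied after dividing by the column
#'   total (default `1e4`).
#' @return An [ExpressionMatrix()] with `norm_state = "log2_normalized"`.
#' @export
log_normalize_counts <- function(x, scale = 1e4) {
  .check_state(x, "raw_counts", "log_normalize_counts")
  if (any(x$values < 0)) stop("counts must be non-negative")
  if (!is.numeric(scale) || length(scale) != 1L || scale <= 0)
    stop("'scale' must be a positive number")
  totals <- colSums(x$values)
  if (any(totals == 0))
    stop("column(s) with zero total count: ",
         paste(colnames(x$values)[totals == 0], collapse = ", "))
  v <- log2(sweep(x$values, 2, totals, "/") * scale + 1)
  ExpressionMatrix(v, column_labels = x$column_labels,
                   norm_state = "log2_normalized")
}

#' Log-transform already-normalized intensities
#'
#' Elementwise `log2(v + 1)` for TPM/FPKM-style matrices, so that zero
#' intensity maps to zero on the transformed scale.
#'
#' @param x An [ExpressionMatrix()] with non-negative raw values.
#' @return An [ExpressionMatrix()] with `norm_state = "log2_normalized"`.
#' @export
log_transform_fpkm <- function(x) {
  .check_state(x, "raw_counts", "log_transform_fpkm")
  if (any(x$values < 0)) stop("values must be non-negative")
  ExpressionMatrix(log2(x$values + 1), column_labels = x$column_labels,
                   norm_state = "log2_normalized")
}

#' Remove low-coverage cells
#'
#' Retains the columns whose total count is at least `min_total`; cells
#' with total strictly below the threshold are removed (a cell exactly at
#' the threshold is kept). Column order is preserved and the number of
#' removed cells is recorded in the `"n_removed"` attribute.
#'
#' @param x An [ExpressionMatrix()] with `norm_state = "raw_counts"`.
#' @param min_total Minimum total count per cell (default 2400).
#' @return Filtered [ExpressionMatrix()].
#' @export
qc_filter_cells <- function(x, min_total = 2400) {
  .check_state(x, "raw_counts", "qc_filter_cells")
  totals <- colSums(x$values)
  keep <- totals >= min_total
  if (!any(keep)) stop("all cells removed at min_total = ", min_total)
  out <- ExpressionMatrix(x$values[, keep, drop = FALSE],
                          column_labels = x$column_labels[keep],
                          norm_state = x$norm_state)
  attr(out, "n_removed") <- sum(!keep)
  message(sum(!keep), " cell(s) removed (total count < ", min_total, ")")
  out
}

.row_sds <- function(m) {
  # sample SD (divisor n - 1) per row
  n <- ncol(m)
  if (n < 2) stop("need at least 2 columns to compute a row SD")
  mu <- rowMeans(m)
  sqrt(rowSums((m - mu)^2) / (n - 1))
}

#' Filter genes by expression variability
#'
#' Keeps rows whose sample standard deviation across columns is strictly
#' greater than `sd_min`, removing genes with no meaningful expression
#' variation before network inference.
#'
#' @param x An [ExpressionMatrix()] with `norm_state = "log2_normalized"`.
#' @param sd_min SD threshold (strict; default 0.25).
#' @return Filtered [ExpressionMatrix()]; row order preserved.
#' @export
variance_filter <- function(x, sd_min = 0.25) {
  .check_state(x, "log2_normalized", "variance_filter")
  keep <- .row_sds(x$values) > sd_min
  if (!any(keep)) stop("no genes with SD > ", sd_min)
  ExpressionMatrix(x$values[keep, , drop = FALSE],
                   column_labels = x$column_labels,
                   norm_state = x$norm_state)
}

#' Z-score genes across columns
#'
#' Centers every gene and scales it to unit sample SD. Constant genes
#' (SD = 0) carry no information for the downstream regression and would
#' corrupt the design, so they are dropped; their identifiers are recorded
#' in the `"dropped_genes"` attribute.
#'
#' @param x An [ExpressionMatrix()] with `norm_state = "log2_normalized"`
#'   and at least 3 columns.
#' @return An [ExpressionMatrix()] with `norm_state = "zscored"`.
#' @export
zscore_rows <- function(x) {
  .check_state(x, c("log2_normalized", "zscored"), "zscore_rows")
  if (ncol(x$values) < 3)
    stop("z-scoring requires at least 3 columns")
  sds <- .row_sds(x$values)
  dropped <- rownames(x$values)[sds == 0]
  keep <- sds > 0
  if (!any(keep)) stop("all genes are constant; nothing to z-score")
  v <- (x$values[keep, , drop = FALSE] - rowMeans(x$values[keep, , drop = FALSE])) /
    sds[keep]
  out <- ExpressionMatrix(v, column_labels = x$column_labels,
                          norm_state = "zscored")
  attr(out, "dropped_genes") <- dropped
  out
}

#' Match regulon genes to a data matrix's gene universe
#'
#' Exact string matching after case normalization; unmatched identifiers
#' are not an error but are counted, so callers can report regulon
#' coverage.
#'
#' @param query Character vector of gene ids to look up.
#' @param universe Character vector of gene ids present in the data.
#' @return Integer vector of indices into `universe` (NA when unmatched),
#'   with attribute `"unmatched"` listing the query ids not found.
#' @keywords internal
match_gene_ids <- function(query, universe) {
  idx <- match(toupper(query), toupper(universe))
  attr(idx, "unmatched") <- query[is.na(idx)]
  idx
}
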