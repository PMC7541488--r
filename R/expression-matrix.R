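#' Expression matrix container
#'
#' A light S3 container for a genes x samples (or genes x cells) expression
#' matrix. Rows are genes, columns are samples/cells; both must carry unique
#' identifiers. The container tracks its normalization state so that
#' downstream operations can refuse inputs on the wrong scale.
#'
#' @param values Numeric matrix with unique, non-empty rownames (gene ids)
#'   and colnames (sample/cell ids). Missing values are an error: expression
#'   inputs must be complete, absent measurements are not silently filled.
#' @param column_labels Optional character/factor vector of per-column
#'   labels (tissue type, phenotype, timepoint), length `ncol(values)`.
#' @param norm_state One of `"raw_counts"`, `"log2_normalized"`,
#'   `"zscored"`.
#'
#' @return An object of class `ExpressionMatrix`: a list with elements
#'   `values`, `column_labels` and `norm_state`.
#' @export
ExpressionMatrix <- function(values,
                             column_labels = NULL,
                             norm_state = c("raw_counts", "log2_normalized",
                                            "zscored")) {
  norm_state <- match.arg(norm_state)
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must have rownames (gene ids) and colnames (column ids)")
  dup_g <- unique(rownames(values)[duplicated(rownames(values))])
  if (length(dup_g))
    stop("duplicate gene ids: ", paste(dup_g, collapse = ", "))
  dup_c <- unique(colnames(values)[duplicated(colnames(values))])
  if (length(dup_c))
    stop("duplicate column ids: ", paste(dup_c, collapse = ", "))
  if (anyNA(values))
    stop("expression matrix contains missing values; refusing to fill")
  if (!is.null(column_labels)) {
    if (length(column_labels) != ncol(values))
      stop("'column_labels' must have one entry per column")
    column_labels <- as.character(column_labels)
    names(column_labels) <- colnames(values)
  }
  structure(list(values = values,
                 column_labels = column_labels,
                 norm_state = norm_state),
            class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d genes x %d columns [%s]\n",
              nrow(x$values), ncol(x$values), x$norm_state))
  if (!is.null(x$column_labels)) {
    tab <- table(x$column_labels)
    cat("column labels:",
        paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' @export
as.matrix.ExpressionMatrix <- function(x, ...) x$values

#' Gene and column identifiers
#' @param x An `ExpressionMatrix`.
#' @return Character vector of identifiers.
#' @export
gene_ids <- function(x) rownames(x$values)

#' @rdname gene_ids
#' @export
column_ids <- function(x) colnames(x$values)

.check_state <- function(x, state, op) {
  if (!inherits(x, "ExpressionMatrix"))
    stop(op, " expects an ExpressionMatrix")
  if (!x$norm_state %in% state)
    stop(op, " requires norm_state in {", paste(state, collapse = ", "),
         "}, got '", x$norm_state, "'")
  invisible(TRUE)
}

#' Read an expression matrix from disk
#'
#' Dense TSV (first column gene id, first row column ids, tab-separated,
#' no quoting) or MatrixMarket MTX with sidecar `genes.tsv` / `barcodes.tsv`
#' files in the same directory holding the row and column identifiers, one
#' per line.
#'
#' @param path File path (`.tsv` table or `.mtx` coordinate file).
#' @param format `"tsv"` or `"mtx"`.
#' @param column_labels,norm_state Passed to [ExpressionMatrix()]; files
#'   carry no normalization metadata so the state defaults to raw counts.
#' @return An [ExpressionMatrix()].
#' @export
read_expression <- function(path, format = c("tsv", "mtx"),
                            column_labels = NULL,
                            norm_state = "raw_counts") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "tsv") {
    nf <- utils::count.fields(path, sep = "\t", quote = "")
    if (length(unique(nf)) > 1) {
      bad <- which(nf != nf[1])[1]
      stop("malformed TSV '", path, "': line ", bad,
           " has ", nf[bad], " fields, expected ", nf[1])
    }
    tab <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                             row.names = NULL, check.names = FALSE,
                             stringsAsFactors = FALSE)
    ids <- as.character(tab[[1]])
    dup <- unique(ids[duplicated(ids)])
    if (length(dup))
      stop("duplicate gene ids in '", path, "': ",
           paste(dup, collapse = ", "))
    vals <- as.matrix(tab[, -1, drop = FALSE])
    if (!is.numeric(vals))
      stop("malformed TSV '", path, "': non-numeric expression values")
    rownames(vals) <- ids
  } else {
    d <- dirname(path)
    gf <- file.path(d, "genes.tsv")
    bf <- file.path(d, "barcodes.tsv")
    if (!file.exists(gf) || !file.exists(bf))
      stop("MTX sidecar files 'genes.tsv'/'barcodes.tsv' not found in ", d)
    m <- Matrix::readMM(path)
    genes <- readLines(gf)
    cells <- readLines(bf)
    if (nrow(m) != length(genes) || ncol(m) != length(cells))
      stop("MTX dimensions (", nrow(m), " x ", ncol(m),
           ") do not match sidecar files (", length(genes), " genes, ",
           length(cells), " barcodes)")
    dup <- unique(genes[duplicated(genes)])
    if (length(dup))
      stop("duplicate gene ids in '", gf, "': ", paste(dup, collapse = ", "))
    vals <- as.matrix(m)
    dimnames(vals) <- list(genes, cells)
  }
  ExpressionMatrix(vals, column_labels = column_labels,
                   norm_state = norm_state)
}

#' Write an expression matrix to disk
#'
#' Values are written with 17 significant digits (TSV) so that doubles
#' round-trip exactly; MTX writing goes through [Matrix::writeMM()], which
#' is also full-precision.
#'
#' @param x An [ExpressionMatrix()].
#' @param path Output path.
#' @param format `"tsv"` or `"mtx"`.
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path, format = c("tsv", "mtx")) {
  format <- match.arg(format)
  stopifnot(inherits(x, "ExpressionMatrix"))
  v <- x$values
  if (format == "tsv") {
    body <- matrix(formatC(v, digits = 17, format = "g"),
                   nrow = nrow(v))
    lines <- c(paste(c("gene_id", colnames(v)), collapse = "\t"),
               paste(rownames(v), apply(body, 1, paste, collapse = "\t"),
                     sep = "\t"))
    writeLines(lines, path)
  } else {
    d <- dirname(path)
    Matrix::writeMM(methods::as(Matrix::Matrix(v, sparse = TRUE),
                                "generalMatrix"), path)
    writeLines(rownames(v), file.path(d, "genes.tsv"))
    writeLines(colnames(v), file.path(d, "barcodes.tsv"))
  }
  invisible(path)
}
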