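#' Signed target profile of a TF over a gene universe
#'
#' Builds the regulon indicator vector used as the covariate in the
#' activity regression: +1 for activating regulon members, -1 for
#' inhibitory members, 0 for all other genes. Alignment is by gene id
#' (case-insensitive), never by position; regulon genes absent from the
#' universe are counted and reported, not an error. The TF's own
#' transcript is always 0 -- activity must be estimable when the TF
#' itself drops out.
#'
#' @param net A `RegulatoryNetwork`.
#' @param tf A TF id present in `net`.
#' @param gene_universe Character vector of gene ids in the expression
#'   data.
#' @return Named numeric vector over `gene_universe` with attributes
#'   `tf_id`, `n_matched` (nonzero entries after matching) and
#'   `unmatched` (regulon ids not found).
#' @export
make_target_profile <- function(net, tf, gene_universe) {
  tfs <- network_tfs(net)
  if (!tf %in% tfs) stop("TF '", tf, "' not in network")
  col <- net$adjacency[, tf]
  members <- rownames(net$adjacency)[col != 0]
  idx <- match_gene_ids(members, gene_universe)
  profile <- numeric(length(gene_universe))
  names(profile) <- gene_universe
  hit <- !is.na(idx)
  profile[idx[hit]] <- col[col != 0][hit]
  self <- match_gene_ids(tf, gene_universe)
  if (!is.na(self[1])) profile[self[1]] <- 0
  n_matched <- sum(profile != 0)
  if (n_matched < 3)
    stop("regulon of TF '", tf, "' has fewer than 3 genes in the data (",
         n_matched, " matched)")
  attr(profile, "tf_id") <- tf
  attr(profile, "n_matched") <- n_matched
  attr(profile, "unmatched") <- attr(idx, "unmatched")
  profile
}

#' Regulatory activity of one TF in one cell
#'
#' The activity score is the t-statistic of the slope from the simple
#' linear regression (with intercept) of the cell's z-scored expression
#' profile on the TF's signed target profile, computed over the whole
#' gene universe. With `n` genes and Pearson correlation `r` between the
#' two vectors this equals `r * sqrt((n - 2) / (1 - r^2))`.
#'
#' @param cell_profile Numeric vector of z-scored expression over genes
#'   (length >= 10).
#' @param profile Signed target profile from [make_target_profile()].
#' @return The slope t-statistic. An exact fit (`r^2 = 1`) returns the
#'   signed cap `1e6` with attribute `capped = TRUE`.
#' @export
estimate_tfa <- function(cell_profile, profile) {
  if (length(cell_profile) != length(profile))
    stop("cell profile and target profile have different lengths")
  n <- length(profile)
  if (n < 10) stop("gene universe too small (need >= 10 genes)")
  if (stats::sd(profile) == 0)
    stop("target profile is constant; activity undefined")
  if (stats::sd(cell_profile) == 0) return(0)
  r <- stats::cor(cell_profile, profile)
  .r_to_t(r, n)
}

.TFA_CAP <- 1e6

.r_to_t <- function(r, n) {
  capped <- abs(r) >= 1 - 1e-15
  t <- ifelse(capped, sign(r) * .TFA_CAP,
              r * sqrt((n - 2) / (1 - r^2)))
  if (any(capped)) attr(t, "capped") <- TRUE
  t
}

#' TF activity matrix over all cells
#'
#' Z-scores the genes of the single-cell matrix, then scores every
#' (TF, cell) pair: `method = "regression_t"` applies [estimate_tfa()]
#' with the signed target profile; `method = "auc"` applies
#' [auc_activity_score()] using the positively-signed regulon members.
#' Cells are independent work units, so results do not depend on how the
#' computation is scheduled. TFs whose regulon has fewer than 3 genes in
#' the data are dropped with a warning.
#'
#' @param sc Log2-normalized single-cell [ExpressionMatrix()].
#' @param net A `RegulatoryNetwork`.
#' @param method `"regression_t"` (default) or `"auc"`.
#' @return A `TFActivityMatrix`: list with `values` (TFs x cells),
#'   `method`, and `coverage` (per-TF matched regulon size).
#' @export
estimate_tfa_matrix <- function(sc, net,
                                method = c("regression_t", "auc")) {
  method <- match.arg(method)
  .check_state(sc, c("log2_normalized", "zscored"), "estimate_tfa_matrix")
  z <- if (sc$norm_state == "zscored") sc else zscore_rows(sc)
  universe <- gene_ids(z)
  tfs <- network_tfs(net)
  profiles <- matrix(0, length(universe), length(tfs),
                     dimnames = list(universe, tfs))
  coverage <- integer(length(tfs)); names(coverage) <- tfs
  ok <- logical(length(tfs)); names(ok) <- tfs
  for (tf in tfs) {
    p <- tryCatch(make_target_profile(net, tf, universe),
                  error = function(e) NULL)
    if (is.null(p)) next
    profiles[, tf] <- p
    coverage[tf] <- attr(p, "n_matched")
    ok[tf] <- TRUE
  }
  if (!any(ok)) stop("no TF has >= 3 regulon genes in the data")
  if (any(!ok))
    warning("dropping TF(s) with < 3 matched regulon genes: ",
            paste(tfs[!ok], collapse = ", "))
  profiles <- profiles[, ok, drop = FALSE]

  if (method == "regression_t") {
    vals <- .tfa_from_profiles(z$values, profiles)
  } else {
    vals <- t(apply(profiles, 2, function(p)
      apply(sc$values, 2, auc_activity_score,
            regulon_genes = universe[p > 0])))
    dimnames(vals) <- list(colnames(profiles), colnames(sc$values))
  }
  structure(list(values = vals, method = method,
                 coverage = coverage[ok],
                 cell_labels = sc$column_labels),
            class = "TFActivityMatrix")
}

# Correlation of each signed profile (genes x TFs) with each z-scored
# cell (genes x cells), mapped to slope t-statistics. Shared by the
# estimator and the Monte-Carlo regulon null.
.tfa_from_profiles <- function(zvals, profiles) {
  n <- nrow(zvals)
  r <- stats::cor(profiles, zvals)
  r[is.na(r)] <- 0  # constant cell column
  vals <- matrix(.r_to_t(as.vector(r), n), nrow(r), ncol(r),
                 dimnames = dimnames(r))
  vals
}

#' @export
print.TFActivityMatrix <- function(x, ...) {
  cat(sprintf("TFActivityMatrix [%s]: %d TFs x %d cells\n",
              x$method, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' @export
dim.TFActivityMatrix <- function(x) dim(x$values)

#' @export
as.matrix.TFActivityMatrix <- function(x, ...) x$values

#' Threshold-free Wilcoxon-AUC regulon score
#'
#' Genes are ranked by expression (decreasing order of expression at the
#' top; ties get midranks) and the score is the Wilcoxon rank-sum AUC
#' comparing the regulon genes' ranks against all other genes: 1 when
#' the regulon occupies the most-expressed positions, 0 when it occupies
#' the least-expressed, 0.5 under exchangeability.
#'
#' @param x Named numeric vector of expression (counts or log scale) over
#'   genes.
#' @param regulon_genes Non-empty strict subset of `names(x)`
#'   (positively-signed regulon members).
#' @return AUC in \[0, 1\].
#' @export
auc_activity_score <- function(x, regulon_genes) {
  if (is.null(names(x))) stop("'x' must be a named vector over genes")
  idx <- match_gene_ids(regulon_genes, names(x))
  idx <- idx[!is.na(idx)]
  if (length(idx) == 0) stop("no regulon gene present in 'x'")
  n1 <- length(idx)
  n2 <- length(x) - n1
  if (n2 == 0) stop("regulon must be a strict subset of the genes")
  if (length(unique(x)) == 1L) {
    warning("all expression values identical; AUC = 0.5")
    return(0.5)
  }
  rk <- rank(x, ties.method = "average")
  (sum(rk[idx]) - n1 * (n1 + 1) / 2) / (n1 * n2)
}
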