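#' Marginal correlation screen between TFs and candidate targets
#'
#' First stage of regulon inference: Pearson correlations between every
#' annotated transcription factor and every other (target) gene across the
#' bulk samples. An edge is retained when (i) its two-sided p-value from
#' the t-transform `t = r * sqrt((n - 2) / (1 - r^2))` with `n - 2` df is
#' at most `sigth`, and (ii) its |r| ranks within the top `spTH` fraction
#' of all TF-target pairs. Genes not annotated as TFs are the putative
#' targets, so TF-TF edges are never formed. TFs left with fewer than
#' `minNtgts` candidate targets are dropped.
#'
#' @param bulk Variance-filtered, log2-normalized [ExpressionMatrix()] of
#'   multi-tissue bulk data (needs at least 4 samples).
#' @param tf_ids Character vector of TF gene ids (subset of the matrix's
#'   genes; matching is case-insensitive).
#' @param sigth Two-sided p-value threshold on the marginal correlation
#'   (default `1e-6`).
#' @param spTH Fraction of all TF-target pairs retained, ranked by |r|
#'   (default 0.01). Caps the size of the candidate edge set.
#' @param minNtgts Minimum number of surviving targets per TF (default 10).
#' @return A `CandidateEdgeSet`: list with `edges` (data.frame `tf`,
#'   `target`, `r`, `p`), `tf_ids`, and screen parameters.
#' @export
marginal_screen <- function(bulk, tf_ids, sigth = 1e-6, spTH = 0.01,
                            minNtgts = 10) {
  .check_state(bulk, "log2_normalized", "marginal_screen")
  n <- ncol(bulk$values)
  if (n < 4) stop("marginal screen needs at least 4 samples")
  if (length(tf_ids) == 0) stop("'tf_ids' is empty")
  idx <- match_gene_ids(tf_ids, gene_ids(bulk))
  if (anyNA(idx))
    stop("TF ids not present in the data: ",
         paste(attr(idx, "unmatched"), collapse = ", "))
  tf_rows <- gene_ids(bulk)[idx]
  tgt_rows <- setdiff(gene_ids(bulk), tf_rows)
  if (length(tgt_rows) == 0) stop("no target genes left after removing TFs")

  r <- stats::cor(t(bulk$values[tgt_rows, , drop = FALSE]),
                  t(bulk$values[tf_rows, , drop = FALSE]))
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)

  keep <- p <= sigth
  if (spTH < 1) {
    k <- ceiling(spTH * length(r))
    if (k < length(r)) {
      cutoff <- sort(abs(r), decreasing = TRUE)[k]
      keep <- keep & abs(r) >= cutoff
    }
  }

  ij <- which(keep, arr.ind = TRUE)
  edges <- data.frame(tf = tf_rows[ij[, 2]],
                      target = tgt_rows[ij[, 1]],
                      r = r[ij], p = p[ij],
                      stringsAsFactors = FALSE)
  counts <- table(edges$tf)
  ok_tfs <- names(counts)[counts >= minNtgts]
  edges <- edges[edges$tf %in% ok_tfs, , drop = FALSE]
  structure(list(edges = edges,
                 tf_ids = ok_tfs,
                 params = list(sigth = sigth, spTH = spTH,
                               minNtgts = minNtgts, n_samples = n)),
            class = "CandidateEdgeSet")
}

#' @export
print.CandidateEdgeSet <- function(x, ...) {
  cat(sprintf("CandidateEdgeSet: %d edges over %d TFs (sigth = %g, spTH = %g)\n",
              nrow(x$edges), length(x$tf_ids),
              x$params$sigth, x$params$spTH))
  invisible(x)
}

#' Partial correlation of a target with each candidate regulator
#'
#' For one target gene g with candidate regulators f, forms the
#' (1 + nf) x (1 + nf) covariance matrix of [g, regulators], inverts it to
#' Omega, and returns `rho_gf = -Omega_gf / sqrt(Omega_gg * Omega_ff)`.
#' @keywords internal
.partial_cor_target <- function(vals, target, regs) {
  S <- stats::cov(t(vals[c(target, regs), , drop = FALSE]))
  kap <- kappa(S, exact = FALSE)
  if (kap > 1e10)
    warning("ill-conditioned covariance for target '", target,
            "' (condition number ", format(kap, digits = 3), ")")
  O <- tryCatch(solve(S), error = function(e)
    stop("singular covariance for target '", target,
         "'; collinear regulators among: ", paste(regs, collapse = ", "),
         call. = FALSE))
  -O[1, -1] / sqrt(O[1, 1] * diag(O)[-1])
}

#' Greedy partial-correlation network construction
#'
#' For each target gene independently, the partial correlation with each
#' of its candidate regulators is computed from the inverse of the
#' covariance matrix of the target and its regulators (conditioning only
#' on that target's candidate-regulator set -- the "greedy" scheme that
#' keeps every inversion well defined when the number of regulators per
#' target is far below the sample count). Edges with |partial r| at or
#' above `pcorth` are retained; the edge sign (+1 activating, -1
#' inhibitory) is the sign of the retained partial correlation. TFs
#' falling below `minNtgts` retained targets are dropped.
#'
#' @param bulk The same [ExpressionMatrix()] used for the screen.
#' @param cands A `CandidateEdgeSet` from [marginal_screen()].
#' @param pcorth Threshold on |partial correlation| (default 0.2).
#' @param minNtgts Minimum retained targets per TF (defaults to the value
#'   recorded in `cands`).
#' @return A `RegulatoryNetwork`: list with `adjacency` (targets x TFs,
#'   entries -1/0/+1), `weights` (matching partial correlations) and
#'   `params`.
#' @export
greedy_partial_correlation <- function(bulk, cands, pcorth = 0.2,
                                       minNtgts = cands$params$minNtgts) {
  stopifnot(inherits(cands, "CandidateEdgeSet"))
  .check_state(bulk, "log2_normalized", "greedy_partial_correlation")
  edges <- cands$edges
  if (nrow(edges) == 0) stop("empty candidate edge set")
  n <- ncol(bulk$values)

  targets <- unique(edges$target)
  tfs <- sort(unique(edges$tf))
  adjacency <- matrix(0L, length(targets), length(tfs),
                      dimnames = list(targets, tfs))
  weights <- matrix(0, length(targets), length(tfs),
                    dimnames = list(targets, tfs))
  reg_list <- split(edges$tf, edges$target)
  for (g in targets) {
    regs <- reg_list[[g]]
    if (length(regs) >= n)
      stop("target '", g, "' has as many candidate regulators as samples")
    pc <- .partial_cor_target(bulk$values, g, regs)
    sel <- abs(pc) >= pcorth
    if (any(sel)) {
      weights[g, regs[sel]] <- pc[sel]
      adjacency[g, regs[sel]] <- as.integer(sign(pc[sel]))
    }
  }
  keep_tf <- colSums(adjacency != 0) >= minNtgts
  adjacency <- adjacency[, keep_tf, drop = FALSE]
  weights <- weights[, keep_tf, drop = FALSE]
  keep_tgt <- rowSums(adjacency != 0) > 0
  RegulatoryNetwork(adjacency[keep_tgt, , drop = FALSE],
                    weights[keep_tgt, , drop = FALSE],
                    params = c(cands$params, list(pcorth = pcorth)))
}

#' Signed regulatory network container
#'
#' @param adjacency Integer matrix targets x TFs with entries -1/0/+1.
#' @param weights Numeric matrix of matching partial correlations; signs
#'   must agree with `adjacency` wherever nonzero.
#' @param params Named list of inference parameters (provenance record).
#' @return An object of class `RegulatoryNetwork`.
#' @export
RegulatoryNetwork <- function(adjacency, weights = NULL, params = list()) {
  if (is.null(weights)) weights <- adjacency + 0
  stopifnot(identical(dim(adjacency), dim(weights)))
  if (!all(adjacency %in% c(-1L, 0L, 1L)))
    stop("adjacency entries must be -1, 0 or +1")
  if (any(sign(weights[adjacency != 0]) != adjacency[adjacency != 0]))
    stop("weight signs disagree with adjacency")
  structure(list(adjacency = adjacency, weights = weights, params = params),
            class = "RegulatoryNetwork")
}

#' @export
print.RegulatoryNetwork <- function(x, ...) {
  cat(sprintf("RegulatoryNetwork: %d TFs, %d targets, %d signed edges\n",
              ncol(x$adjacency), nrow(x$adjacency), sum(x$adjacency != 0)))
  invisible(x)
}

#' TF identifiers of a network
#' @param net A `RegulatoryNetwork`.
#' @return Character vector.
#' @export
network_tfs <- function(net) colnames(net$adjacency)

#' Empirical-Bayes moderated two-group t-test
#'
#' Per-gene two-group comparison in which the gene-wise pooled variances
#' are shrunk toward a common prior: the posterior variance is
#' `(d0 * s0^2 + d_g * s_g^2) / (d0 + d_g)` and the moderated t-statistic
#' uses `d0 + d_g` degrees of freedom. The prior degrees of freedom `d0`
#' and prior variance `s0^2` are estimated by moment matching on the log
#' gene-wise variances (matching the mean and variance of log s^2 under a
#' scaled-F model). `prior_df = 0` recovers the ordinary equal-variance
#' t-test; `prior_df = Inf` forces every gene to the common variance.
#'
#' @param bulk A log2-normalized [ExpressionMatrix()].
#' @param group1,group2 Disjoint column index vectors (or column ids),
#'   each of size >= 2.
#' @param prior_df Optional fixed `d0` overriding the moment-matching
#'   estimate.
#' @param adjust Multiple-testing adjustment: `"BH"` (default) or
#'   `"bonferroni"`.
#' @return Data frame with per-gene `lfc` (group1 minus group2 mean),
#'   `t`, `p`, `p_adj`; hyperparameters in attributes `d0` and `s0sq`.
#' @export
moderated_t_test <- function(bulk, group1, group2, prior_df = NULL,
                             adjust = c("BH", "bonferroni")) {
  adjust <- match.arg(adjust)
  v <- bulk$values
  if (is.character(group1)) group1 <- match(group1, colnames(v))
  if (is.character(group2)) group2 <- match(group2, colnames(v))
  if (length(intersect(group1, group2))) stop("groups must be disjoint")
  n1 <- length(group1); n2 <- length(group2)
  if (n1 < 2 || n2 < 2) stop("both groups need at least 2 columns")
  x1 <- v[, group1, drop = FALSE]
  x2 <- v[, group2, drop = FALSE]
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  ss1 <- rowSums((x1 - m1)^2)
  ss2 <- rowSums((x2 - m2)^2)
  if (all(ss1 == 0) || all(ss2 == 0))
    stop("a group has zero variance in every gene")
  dg <- n1 + n2 - 2
  s2 <- (ss1 + ss2) / dg

  fit <- .fit_variance_prior(s2, dg)
  d0 <- if (is.null(prior_df)) fit$d0 else prior_df
  s0sq <- fit$s0sq
  if (is.infinite(d0)) {
    s2_post <- rep(s0sq, length(s2))
    df_post <- Inf
  } else {
    s2_post <- (d0 * s0sq + dg * s2) / (d0 + dg)
    df_post <- d0 + dg
  }
  lfc <- m1 - m2
  tstat <- lfc / sqrt(s2_post * (1 / n1 + 1 / n2))
  p <- 2 * stats::pt(-abs(tstat), df = df_post)
  out <- data.frame(gene = rownames(v), lfc = lfc, t = tstat, p = p,
                    p_adj = stats::p.adjust(p, method = adjust),
                    row.names = rownames(v), stringsAsFactors = FALSE)
  attr(out, "d0") <- d0
  attr(out, "s0sq") <- s0sq
  class(out) <- c("ModeratedTestResult", "data.frame")
  out
}

# Moment matching of (d0, s0^2) on log gene-wise variances: under a
# scaled-F model, var(log s^2) = trigamma(dg/2) + trigamma(d0/2) and
# E[log s^2] = log s0^2 + digamma(d0/2) - log(d0/2) + digamma-corrections
# for dg. trigamma is inverted by uniroot on a bracketed interval.
.fit_variance_prior <- function(s2, dg) {
  pos <- s2[s2 > 0]
  z <- log(pos)
  e <- z - digamma(dg / 2) + log(dg / 2)
  ev <- stats::var(e)
  tri <- ev - trigamma(dg / 2)
  if (!is.finite(tri) || tri <= 0)
    return(list(d0 = Inf, s0sq = exp(mean(e))))
  # trigamma is decreasing; bracket the root of trigamma(x) = tri
  f <- function(x) trigamma(x) - tri
  lo <- 1e-6; hi <- 1e8
  if (f(lo) < 0) return(list(d0 = 1e-6 * 2, s0sq = exp(mean(e))))
  if (f(hi) > 0) return(list(d0 = Inf, s0sq = exp(mean(e))))
  half_d0 <- stats::uniroot(f, c(lo, hi), tol = 1e-10)$root
  d0 <- 2 * half_d0
  s0sq <- exp(mean(e) + digamma(half_d0) - log(half_d0))
  list(d0 = d0, s0sq = s0sq)
}

#' Restrict a network to tissue-specific TFs
#'
#' Selects TFs significantly overexpressed in the tissue of interest.
#' Comparison A contrasts the tissue of interest against all other
#' tissues (adjusted p < `degth[1]` and log2 fold change > `lfcth[1]`).
#' When confounding tissues are supplied (tissues whose cells infiltrate
#' the tissue of interest, e.g. blood/spleen immune cells), comparison B
#' additionally contrasts the tissue of interest against those tissues
#' only (adjusted p < `degth[2]`, log2 fold change > `lfcth[2]`, strict),
#' ensuring selected TFs are not driven by differential infiltration.
#'
#' @param bulk Log2-normalized [ExpressionMatrix()] with tissue labels in
#'   `column_labels`.
#' @param net A `RegulatoryNetwork` over candidate TFs.
#' @param toi Tissue-of-interest label.
#' @param cft Optional character vector of confounding tissue labels.
#' @param degth Adjusted-p thresholds for comparisons A and B
#'   (default `c(0.05, 0.05)`).
#' @param lfcth Log2 fold-change thresholds for comparisons A and B
#'   (default `c(log2(1.5), 0)`).
#' @param adjust Multiplicity adjustment passed to [moderated_t_test()].
#' @return The network restricted to TFs passing all required
#'   comparisons; per-TF statistics in attribute `"selection"`.
#' @export
select_tissue_specific_tfs <- function(bulk, net, toi, cft = NULL,
                                       degth = c(0.05, 0.05),
                                       lfcth = c(log2(1.5), 0),
                                       adjust = "BH") {
  if (is.null(bulk$column_labels)) stop("bulk data has no tissue labels")
  labels <- bulk$column_labels
  if (!toi %in% labels) stop("tissue of interest '", toi, "' not in labels")
  toi_cols <- which(labels == toi)
  if (length(toi_cols) < 2)
    stop("fewer than 2 samples labeled '", toi, "'")
  tfs <- network_tfs(net)
  present <- tfs[tfs %in% gene_ids(bulk)]

  resA <- moderated_t_test(bulk, toi_cols, which(labels != toi),
                           adjust = adjust)
  passA <- with(resA[present, ], p_adj < degth[1] & lfc > lfcth[1])
  pass <- passA
  resB <- NULL
  if (!is.null(cft) && length(cft)) {
    missing_cft <- setdiff(cft, labels)
    if (length(missing_cft))
      stop("confounding tissue label(s) not found: ",
           paste(missing_cft, collapse = ", "))
    cft_cols <- which(labels %in% cft)
    resB <- moderated_t_test(bulk, toi_cols, cft_cols, adjust = adjust)
    passB <- with(resB[present, ], p_adj < degth[2] & lfc > lfcth[2])
    pass <- pass & passB
  }
  sel_tfs <- present[pass]
  adjacency <- net$adjacency[, sel_tfs, drop = FALSE]
  keep_tgt <- rowSums(adjacency != 0) > 0
  out <- RegulatoryNetwork(adjacency[keep_tgt, , drop = FALSE],
                           net$weights[keep_tgt, sel_tfs, drop = FALSE],
                           params = c(net$params,
                                      list(toi = toi, cft = cft,
                                           degth = degth, lfcth = lfcth)))
  attr(out, "selection") <- list(comparison_all = resA[present, ],
                                 comparison_cft = if (is.null(resB)) NULL
                                                  else resB[present, ])
  out
}

#' Full tissue-specific regulon inference pipeline
#'
#' Composition of [variance_filter()], [marginal_screen()],
#' [greedy_partial_correlation()] and [select_tissue_specific_tfs()] with
#' the method's default parameter surface (`sdth = 0.25, sigth = 1e-6,
#' pcorth = 0.2, spTH = 0.01, minNtgts = 10, degth = c(0.05, 0.05),
#' lfcth = c(log2(1.5), 0)`). All parameters are recorded in the returned
#' network's `params` provenance record.
#'
#' @param bulk Log2-normalized multi-tissue [ExpressionMatrix()] with
#'   tissue labels.
#' @param tf_ids Character vector of TF gene ids.
#' @param toi Tissue-of-interest label.
#' @param cft Optional confounding tissue labels.
#' @param sdth,sigth,pcorth,spTH,minNtgts,degth,lfcth Stage parameters;
#'   see the stage functions.
#' @return A tissue-specific `RegulatoryNetwork`.
#' @export
infer_network <- function(bulk, tf_ids, toi, cft = NULL,
                          sdth = 0.25, sigth = 1e-6, pcorth = 0.2,
                          spTH = 0.01, minNtgts = 10,
                          degth = c(0.05, 0.05),
                          lfcth = c(log2(1.5), 0)) {
  filt <- variance_filter(bulk, sd_min = sdth)
  tf_keep <- tf_ids[toupper(tf_ids) %in% toupper(gene_ids(filt))]
  if (!length(tf_keep)) stop("no TFs survive the variance filter")
  cands <- marginal_screen(filt, tf_keep, sigth = sigth, spTH = spTH,
                           minNtgts = minNtgts)
  if (!length(cands$tf_ids))
    stop("no TFs with at least ", minNtgts, " candidate targets")
  net <- greedy_partial_correlation(filt, cands, pcorth = pcorth,
                                    minNtgts = minNtgts)
  net <- select_tissue_specific_tfs(filt, net, toi = toi, cft = cft,
                                    degth = degth, lfcth = lfcth)
  net$params <- utils::modifyList(net$params, list(sdth = sdth))
  net
}

#' Write / read a signed network as TSV
#'
#' The adjacency is written as a TSV with first column `target` and one
#' column of -1/0/+1 per TF; partial-correlation weights go to a
#' companion `<name>.weights.tsv` and all inference parameters to
#' `<name>.params.json`.
#'
#' @param net A `RegulatoryNetwork`.
#' @param path Path of the adjacency TSV.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path) {
  base <- sub("\\.tsv$", "", path)
  adj <- data.frame(target = rownames(net$adjacency), net$adjacency,
                    check.names = FALSE)
  utils::write.table(adj, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  w <- data.frame(target = rownames(net$weights),
                  formatC(net$weights, digits = 17, format = "g"),
                  check.names = FALSE)
  utils::write.table(w, paste0(base, ".weights.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (length(net$params))
    jsonlite::write_json(net$params, paste0(base, ".params.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path) {
  base <- sub("\\.tsv$", "", path)
  adj <- utils::read.delim(path, check.names = FALSE)
  a <- as.matrix(adj[, -1, drop = FALSE])
  rownames(a) <- adj[[1]]
  storage.mode(a) <- "integer"
  wpath <- paste0(base, ".weights.tsv")
  w <- NULL
  if (file.exists(wpath)) {
    wt <- utils::read.delim(wpath, check.names = FALSE)
    w <- as.matrix(wt[, -1, drop = FALSE])
    rownames(w) <- wt[[1]]
  }
  ppath <- paste0(base, ".params.json")
  params <- if (file.exists(ppath))
    jsonlite::read_json(ppath, simplifyVector = TRUE) else list()
  RegulatoryNetwork(a, w, params = params)
}
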