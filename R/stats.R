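#' Differential activity between two cell groups
#'
#' Per-TF two-sided test of activity (or expression) between two groups
#' of cells, with Bonferroni adjustment over the number of TFs tested.
#' `test = "t"` uses the two-sample t-test; `test = "wilcoxon"` the
#' Wilcoxon rank-sum test, reporting the AUC as the statistic. The
#' direction call is relative to the second factor level of `groups`
#' ("case"): `UP` means higher activity in the case group, `DN` lower,
#' `NC` not significant at `alpha` after Bonferroni.
#'
#' @param tfa A `TFActivityMatrix` (or plain TFs x cells matrix).
#' @param groups Binary labels per cell (factor or coercible); both
#'   groups need at least 3 cells.
#' @param test `"t"` or `"wilcoxon"`.
#' @param alpha Significance level on the Bonferroni-adjusted p-value
#'   (default 0.05).
#' @return A `DiffActivityTable` data frame with columns `tf`, `stat`,
#'   `p`, `p_bonf`, `z`, `direction`.
#' @export
diff_activity_binary <- function(tfa, groups, test = c("t", "wilcoxon"),
                                 alpha = 0.05) {
  test <- match.arg(test)
  vals <- if (inherits(tfa, "TFActivityMatrix")) tfa$values else tfa
  groups <- factor(groups)
  if (nlevels(groups) != 2)
    stop("'groups' must have exactly 2 levels, got ", nlevels(groups))
  if (length(groups) != ncol(vals))
    stop("'groups' must have one label per cell")
  g1 <- groups == levels(groups)[1]
  g2 <- groups == levels(groups)[2]
  if (sum(g1) < 3 || sum(g2) < 3) stop("both groups need at least 3 cells")

  res <- t(apply(vals, 1, function(x) {
    if (test == "t") {
      tt <- stats::t.test(x[g2], x[g1])
      stat <- unname(tt$statistic)
      p <- tt$p.value
      z <- pvalue_to_z(p, direction_stat = stat)
    } else {
      wt <- suppressWarnings(stats::wilcox.test(x[g2], x[g1]))
      auc <- unname(wt$statistic) / (sum(g1) * sum(g2))
      stat <- auc
      p <- wt$p.value
      z <- pvalue_to_z(p, direction_stat = auc - 0.5)
    }
    c(stat = stat, p = p, z = z)
  }))
  .diff_table(rownames(vals), res[, "stat"], res[, "p"], res[, "z"],
              alpha = alpha, test = test,
              null_stat = if (test == "wilcoxon") 0.5 else 0)
}

#' Differential activity along an ordinal phenotype
#'
#' Per-TF Spearman rank correlation of activity against an ordinal stage
#' (timepoint) vector, two-sided, Bonferroni-adjusted over the TFs
#' tested. `UP` means activity increasing with stage.
#'
#' @param tfa A `TFActivityMatrix` or TFs x cells matrix.
#' @param stage Ordinal labels per cell (numeric, ordered factor, or
#'   coercible), with at least 3 distinct values.
#' @param alpha Bonferroni significance level (default 0.05).
#' @return A `DiffActivityTable` with `stat` = Spearman rho.
#' @export
diff_activity_ordinal <- function(tfa, stage, alpha = 0.05) {
  vals <- if (inherits(tfa, "TFActivityMatrix")) tfa$values else tfa
  if (is.factor(stage)) stage <- as.numeric(stage)
  if (length(stage) != ncol(vals))
    stop("'stage' must have one value per cell")
  if (length(unique(stage)) < 3)
    stop("ordinal phenotype needs at least 3 distinct stages")
  res <- t(apply(vals, 1, function(x) {
    ct <- suppressWarnings(
      stats::cor.test(x, stage, method = "spearman"))
    c(stat = unname(ct$estimate), p = ct$p.value)
  }))
  z <- mapply(pvalue_to_z, res[, "p"], res[, "stat"])
  .diff_table(rownames(vals), res[, "stat"], res[, "p"], z,
              alpha = alpha, test = "spearman", null_stat = 0)
}

.diff_table <- function(tf, stat, p, z, alpha, test, null_stat = 0) {
  p_bonf <- pmin(1, p * length(p))
  direction <- ifelse(p_bonf >= alpha, "NC",
                      ifelse(stat > null_stat, "UP", "DN"))
  out <- data.frame(tf = tf, stat = stat, p = p, p_bonf = p_bonf,
                    z = unname(z), direction = direction,
                    row.names = tf, stringsAsFactors = FALSE)
  attr(out, "alpha") <- alpha
  attr(out, "test") <- test
  class(out) <- c("DiffActivityTable", "data.frame")
  out
}

#' Convert a two-sided p-value into a signed z-statistic
#'
#' `z = qnorm(1 - p / 2)`, signed positive when the direction statistic
#' indicates the "up" direction (AUC > 0.5 passed as `auc - 0.5`, or a
#' positive rho / t), negative otherwise. `p = 1` maps to `z = 0`;
#' `p = 0` is capped at |z| = 38 with attribute `capped = TRUE`.
#'
#' @param p Two-sided p-value in \[0, 1\].
#' @param direction_stat Signed direction statistic (rho, t, or
#'   `AUC - 0.5`).
#' @return Signed z.
#' @export
pvalue_to_z <- function(p, direction_stat) {
  if (is.na(p) || p < 0 || p > 1) stop("'p' must be in [0, 1]")
  s <- if (direction_stat >= 0) 1 else -1
  z <- s * stats::qnorm(p / 2, lower.tail = FALSE)
  if (!is.finite(z)) {
    z <- s * 38
    attr(z, "capped") <- TRUE
  }
  z
}

#' One-tailed binomial test for a skew toward inactivation
#'
#' Exact tail probability `P(X >= n_down)` for
#' `X ~ Binomial(n_down + n_up, 1/2)`: the chance of observing at least
#' this many inactivated TFs among all significant calls if direction
#' were a fair coin.
#'
#' @param n_down,n_up Non-negative counts of significant down/up calls,
#'   with `n_down + n_up >= 1`.
#' @return One-tailed p-value.
#' @export
binomial_skew_test <- function(n_down, n_up) {
  if (n_down < 0 || n_up < 0) stop("counts must be non-negative")
  n <- n_down + n_up
  if (n < 1) stop("need at least one significant call")
  stats::pbinom(n_down - 1, size = n, prob = 0.5, lower.tail = FALSE)
}

#' Monte-Carlo regulon randomization null
#'
#' Assesses whether the observed fraction of significantly inactivated
#' TFs could arise by chance: in each run, every TF's regulon is
#' replaced by a uniformly random gene set of identical size and sign
#' composition (excluding the TF's own gene), activity is re-estimated,
#' and the fraction of TFs called `DN` at Bonferroni-adjusted
#' `p < alpha` is recorded. The empirical p-value uses the add-one
#' estimator `(1 + #\{null >= observed\}) / (1 + n_runs)`, so it is never
#' zero.
#'
#' @param sc Log2-normalized single-cell [ExpressionMatrix()].
#' @param net A `RegulatoryNetwork`.
#' @param groups Binary labels per cell (passed to
#'   [diff_activity_binary()]).
#' @param n_runs Number of randomizations (default 1000).
#' @param alpha Bonferroni significance level (default 0.05).
#' @param test Test used for differential activity (default `"t"`).
#' @param seed Optional RNG seed for reproducible nulls.
#' @return A `MonteCarloNull`: list with `observed`, `null_fractions`,
#'   `p` and `n_runs`.
#' @export
montecarlo_regulon_null <- function(sc, net, groups, n_runs = 1000,
                                    alpha = 0.05, test = "t",
                                    seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  z <- zscore_rows(sc)
  universe <- gene_ids(z)
  sizes <- colSums(net$adjacency != 0)
  if (max(sizes) > length(universe) - 1)
    stop("gene universe smaller than the largest regulon")

  observed_tfa <- estimate_tfa_matrix(z, net)
  obs_tab <- diff_activity_binary(observed_tfa, groups, test = test,
                                  alpha = alpha)
  observed <- mean(obs_tab$direction == "DN")

  tfs <- network_tfs(net)
  signs <- lapply(tfs, function(tf) {
    col <- net$adjacency[, tf]
    col[col != 0]
  })
  names(signs) <- tfs

  null_fractions <- vapply(seq_len(n_runs), function(run) {
    profiles <- matrix(0, length(universe), length(tfs),
                       dimnames = list(universe, tfs))
    for (tf in tfs) {
      pool <- setdiff(seq_along(universe),
                      match_gene_ids(tf, universe)[1])
      pool <- pool[!is.na(pool)]
      pick <- sample(pool, length(signs[[tf]]))
      profiles[pick, tf] <- sample(unname(signs[[tf]]))
    }
    vals <- .tfa_from_profiles(z$values, profiles)
    tab <- diff_activity_binary(vals, groups, test = test, alpha = alpha)
    mean(tab$direction == "DN")
  }, numeric(1))

  p <- (1 + sum(null_fractions >= observed)) / (1 + n_runs)
  structure(list(observed = observed, null_fractions = null_fractions,
                 p = p, n_runs = n_runs, alpha = alpha),
            class = "MonteCarloNull")
}

#' @export
print.MonteCarloNull <- function(x, ...) {
  cat(sprintf(
    "MonteCarloNull: observed fraction %.3f, empirical p = %.4g (%d runs)\n",
    x$observed, x$p, x$n_runs))
  invisible(x)
}

#' Sensitivity and FDR against a gold standard
#'
#' Benchmark metrics over a gold-standard TF set with known expected
#' directions: sensitivity (SE) is the fraction of gold TFs called
#' significant in the expected direction; the FDR is the fraction of all
#' significant calls that are in the biologically contrary direction
#' (precision = 1 - FDR). When no TF is significant the FDR is undefined
#' and reported as `NA`.
#'
#' @param table A `DiffActivityTable`.
#' @param gold_direction Named character vector (`"UP"`/`"DN"`) of
#'   expected directions for the gold-standard TFs.
#' @param conf_level Level for the binomial confidence intervals
#'   (default 0.95).
#' @return A `BenchmarkResult` list with `se`, `fdr`, counts, and
#'   confidence intervals.
#' @export
sensitivity_fdr <- function(table, gold_direction, conf_level = 0.95) {
  if (!length(gold_direction)) stop("gold-standard set is empty")
  if (is.null(names(gold_direction)))
    stop("'gold_direction' must be named by TF")
  gold <- names(gold_direction)
  sub <- table[table$tf %in% gold, , drop = FALSE]
  expected <- gold_direction[sub$tf]
  sig <- sub$direction != "NC"
  tp <- sum(sig & sub$direction == expected)
  fp <- sum(sig & sub$direction != expected)
  se <- tp / length(gold)
  n_sig <- sum(sig)
  fdr <- if (n_sig == 0) NA_real_ else fp / n_sig
  ci <- function(k, n) if (n == 0) c(NA, NA) else
    stats::binom.test(k, n, conf.level = conf_level)$conf.int
  structure(list(se = se, fdr = fdr,
                 n_gold = length(gold), n_significant = n_sig,
                 true_positives = tp, false_positives = fp,
                 se_ci = ci(tp, length(gold)),
                 fdr_ci = if (n_sig == 0) c(NA, NA) else ci(fp, n_sig)),
            class = "BenchmarkResult")
}

#' @export
print.BenchmarkResult <- function(x, ...) {
  cat(sprintf("BenchmarkResult: SE = %.3f (%d/%d), FDR = %s (%d/%d)\n",
              x$se, x$true_positives, x$n_gold,
              if (is.na(x$fdr)) "undefined" else sprintf("%.3f", x$fdr),
              x$false_positives, x$n_significant))
  invisible(x)
}

#' Paired method comparison across tissues
#'
#' For each tissue, compares two methods' per-TF success indicators with
#' an exact one-tailed binomial test on the discordant pairs
#' (method A succeeds where B fails vs. the reverse, p = 1/2), and
#' combines the per-tissue p-values with Fisher's statistic
#' `-2 * sum(log p) ~ chi-square(2k)`.
#'
#' @param outcomes_a,outcomes_b Named lists (one element per tissue) of
#'   logical vectors of per-TF success, paired within tissue.
#' @return List with `per_tissue` (named p-values) and `combined_p`.
#' @export
method_comparison_meta <- function(outcomes_a, outcomes_b) {
  if (length(outcomes_a) != length(outcomes_b))
    stop("outcome lists must have the same number of tissues")
  per <- mapply(function(a, b) {
    if (length(a) != length(b)) stop("unpaired outcome vectors")
    n10 <- sum(a & !b)
    n01 <- sum(!a & b)
    if (n10 + n01 == 0) return(1)
    stats::pbinom(n10 - 1, n10 + n01, 0.5, lower.tail = FALSE)
  }, outcomes_a, outcomes_b)
  chisq <- -2 * sum(log(per))
  combined <- stats::pchisq(chisq, df = 2 * length(per),
                            lower.tail = FALSE)
  list(per_tissue = per, fisher_stat = chisq, combined_p = combined)
}

#' Per-TF inactivation frequency across patients
#'
#' Fraction of patients in which each TF is called `DN`, with patients
#' lacking the TF excluded from that TF's denominator. TFs absent from
#' every table are reported as `NA`.
#'
#' @param per_patient_tables List of `DiffActivityTable`s, one per
#'   patient.
#' @return Named numeric vector of inactivation frequencies.
#' @export
inactivation_frequency <- function(per_patient_tables) {
  if (!length(per_patient_tables)) stop("need at least one table")
  tfs <- unique(unlist(lapply(per_patient_tables, function(t) t$tf)))
  vapply(tfs, function(tf) {
    hits <- vapply(per_patient_tables, function(t) {
      if (!tf %in% t$tf) return(NA)
      t$direction[t$tf == tf] == "DN"
    }, logical(1))
    if (all(is.na(hits))) return(NA_real_)
    mean(hits, na.rm = TRUE)
  }, numeric(1))
}
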