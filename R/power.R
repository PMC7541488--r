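#' Parameters of the bulk-detection power model
#'
#' Bundles the quantities governing the sensitivity to detect a
#' tissue-specific TF in a two-group bulk comparison: sample sizes of the
#' tissue of interest (`n1`) and of all other tissues (`n2`, or derived
#' as `n_total - n1`), the average linear fold change `FC` in the
#' expressing cell type, the minor cell fraction `w` (proportion of
#' cells within the tissue in which the TF is highly expressed), the
#' pooled SD `sigma` on the log2 scale, and the significance threshold
#' `t` on the t-statistic scale. The threshold may instead be given as a
#' two-sided level `alpha` with a multiplicity count `m`, in which case
#' `t = qt(1 - alpha / (2 m), n1 + n2 - 2)`.
#'
#' @param n1 Samples in the tissue of interest (>= 2).
#' @param n2 Samples in all other tissues (>= 2); omit if `n_total`
#'   given.
#' @param n_total Total sample count; `n2 = n_total - n1`.
#' @param FC Average linear fold change (>= 1).
#' @param w Minor cell fraction in \[0, 1\].
#' @param sigma Pooled SD on the log2 scale (default 1).
#' @param t Positive significance threshold on the t scale.
#' @param alpha,m Alternative threshold specification: two-sided level
#'   and number of tests (Bonferroni), used when `t` is missing.
#' @return A `PowerParams` list.
#' @export
power_params <- function(n1, n2 = NULL, n_total = NULL, FC, w,
                         sigma = 1, t = NULL, alpha = NULL, m = 1) {
  if (is.null(n2)) {
    if (is.null(n_total)) stop("supply 'n2' or 'n_total'")
    n2 <- n_total - n1
  }
  if (n1 < 2 || n2 < 2) stop("both group sizes must be >= 2")
  if (FC < 1) stop("'FC' must be >= 1 (model defined for overexpression)")
  if (w < 0 || w > 1) stop("'w' must be in [0, 1]")
  if (sigma <= 0) stop("'sigma' must be positive")
  df <- n1 + n2 - 2
  if (is.null(t)) {
    if (is.null(alpha)) stop("supply 't' or 'alpha'")
    t <- stats::qt(1 - alpha / (2 * m), df = df)
  }
  if (t <= 0) stop("'t' must be a positive critical value")
  structure(list(n1 = n1, n2 = n2, FC = FC, w = w, sigma = sigma,
                 t = t, df = df),
            class = "PowerParams")
}

#' Standardized effect size of a TF expressed in a minor cell fraction
#'
#' A TF overexpressed at linear fold change `FC` in a fraction `w` of
#' the cells of a bulk tissue shifts the bulk log2 mean by
#' `log2(FC * w + (1 - w))`; dividing by the pooled SD gives the
#' standardized effect `e = log2(FC * w + (1 - w)) / sigma`.
#'
#' @param FC Average linear fold change (>= 1).
#' @param w Minor cell fraction in \[0, 1\].
#' @param sigma Pooled SD on the log2 scale (default 1).
#' @return Effect size `e`.
#' @export
effect_size <- function(FC, w, sigma = 1) {
  if (any(FC < 1)) stop("'FC' must be >= 1 (model defined for overexpression)")
  if (any(w < 0 | w > 1)) stop("'w' must be in [0, 1]")
  if (sigma <= 0) stop("'sigma' must be positive")
  log2(FC * w + (1 - w)) / sigma
}

#' Non-centrality parameter of the two-group comparison
#'
#' `mu = sqrt(n1 * n2 / (n1 + n2)) * e`: the mean of the t-statistic's
#' non-central t distribution under the alternative.
#'
#' @param n1,n2 Group sizes (>= 2).
#' @param e Standardized effect size from [effect_size()].
#' @return Non-centrality `mu`.
#' @export
noncentrality <- function(n1, n2, e) {
  if (any(n1 < 2) || any(n2 < 2)) stop("group sizes must be >= 2")
  sqrt(n1 * n2 / (n1 + n2)) * e
}

#' Sensitivity to detect a tissue-specific TF at a t threshold
#'
#' Probability that the two-group t-statistic exceeds the significance
#' threshold under the alternative, where the statistic follows a
#' non-central t with `df = n1 + n2 - 2` and non-centrality
#' [noncentrality()]. `mode = "exact_two_sided"` (default) is the exact
#' two-sided rejection probability
#' `1 - F(t; df, mu) + F(-t; df, mu)`; `mode = "paper_approx"` is the
#' one-sided approximation `2 * (1 - F(t; df, mu))` clipped to \[0, 1\]
#' (the two coincide whenever the lower tail at `-t` is negligible).
#'
#' @param params A [power_params()] object.
#' @param mode `"exact_two_sided"` or `"paper_approx"`.
#' @return Sensitivity SE in \[0, 1\].
#' @export
sensitivity_at_threshold <- function(params,
                                     mode = c("exact_two_sided",
                                              "paper_approx")) {
  mode <- match.arg(mode)
  stopifnot(inherits(params, "PowerParams"))
  e <- effect_size(params$FC, params$w, params$sigma)
  mu <- noncentrality(params$n1, params$n2, e)
  upper <- stats::pt(params$t, df = params$df, ncp = mu,
                     lower.tail = FALSE)
  if (mode == "paper_approx") {
    se <- 2 * upper
  } else {
    se <- upper + stats::pt(-params$t, df = params$df, ncp = mu)
  }
  min(1, max(0, se))
}

#' Sensitivity curve over one varied parameter
#'
#' Evaluates [sensitivity_at_threshold()] on a grid of one parameter
#' (`t`, `w`, `n1`, or `FC`) holding the others fixed. When `n1` is
#' varied and the threshold was specified as an alpha level, the
#' critical value is recomputed at each grid point.
#'
#' @param vary One of `"t"`, `"w"`, `"n1"`, `"FC"`.
#' @param grid Non-empty sorted numeric vector of values for the varied
#'   parameter.
#' @param fixed A [power_params()] object for the fixed parameters.
#' @param mode Passed to [sensitivity_at_threshold()].
#' @param alpha,m If given, re-derive the t threshold from this level at
#'   every grid point (needed when varying `n1`).
#' @return A `PowerCurve` data frame with columns `value` and `se`.
#' @export
power_curve <- function(vary = c("t", "w", "n1", "FC"), grid, fixed,
                        mode = "exact_two_sided",
                        alpha = NULL, m = 1) {
  vary <- match.arg(vary)
  if (!length(grid)) stop("'grid' is empty")
  if (is.unsorted(grid)) stop("'grid' must be sorted increasing")
  se <- vapply(grid, function(v) {
    args <- list(n1 = fixed$n1, n2 = fixed$n2, FC = fixed$FC,
                 w = fixed$w, sigma = fixed$sigma, t = fixed$t)
    args[[vary]] <- v
    if (!is.null(alpha)) {
      args$t <- NULL
      args$alpha <- alpha
      args$m <- m
    }
    sensitivity_at_threshold(do.call(power_params, args), mode = mode)
  }, numeric(1))
  out <- data.frame(value = grid, se = se)
  attr(out, "vary") <- vary
  attr(out, "fixed") <- fixed
  class(out) <- c("PowerCurve", "data.frame")
  out
}
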