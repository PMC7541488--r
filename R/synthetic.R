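#' Random signed regulatory network with disjoint regulons
#'
#' Generates a ground-truth network for simulations: `n_tfs` TFs
#' (`TF1..`), each with `n_targets_per_tf` disjoint targets (`G1..`)
#' carrying activating (+1) or inhibitory (-1) signs drawn with
#' probability `prop_activating`.
#'
#' @param n_tfs Number of TFs.
#' @param n_targets_per_tf Regulon size.
#' @param prop_activating Probability of an activating edge
#'   (default 0.7).
#' @param seed Optional RNG seed.
#' @return A `RegulatoryNetwork`.
#' @export
simulate_regulatory_network <- function(n_tfs, n_targets_per_tf,
                                        prop_activating = 0.7,
                                        seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tfs <- paste0("TF", seq_len(n_tfs))
  n_tgt <- n_tfs * n_targets_per_tf
  targets <- paste0("G", seq_len(n_tgt))
  adjacency <- matrix(0L, n_tgt, n_tfs, dimnames = list(targets, tfs))
  for (j in seq_len(n_tfs)) {
    rows <- (j - 1) * n_targets_per_tf + seq_len(n_targets_per_tf)
    adjacency[rows, j] <- ifelse(
      stats::runif(n_targets_per_tf) < prop_activating, 1L, -1L)
  }
  RegulatoryNetwork(adjacency,
                    params = list(simulated = TRUE,
                                  prop_activating = prop_activating))
}

#' Synthetic multi-tissue bulk expression data with planted regulons
#'
#' Emulates the data regime of tissue-specific regulon inference:
#' log2-scale Gaussian baseline expression (pooled SD `sigma`), planted
#' tissue-specific TFs whose bulk mean in their assigned tissue is
#' shifted by `log2(fc * w + (1 - w))` (a TF overexpressed at fold
#' change `fc` in a fraction `w` of the tissue's cells), plus null TFs
#' with regulons but no tissue shift. Each regulon target tracks its TF
#' linearly (`target = sign * beta * TF + noise`) so that the
#' partial-correlation structure is recoverable.
#'
#' @param n_tissues Number of tissue types (labels `Tissue1..`; planted
#'   TFs sit in `Tissue1` unless `tf_tissue` says otherwise).
#' @param n_per_tissue Samples per tissue.
#' @param n_genes Total genes including TFs and targets.
#' @param n_specific_tfs Planted tissue-specific TFs.
#' @param n_null_tfs TFs with regulons but no tissue shift.
#' @param n_targets_per_tf Regulon size (disjoint regulons).
#' @param fc Average linear fold change of planted TFs in their tissue
#'   (default 4; `fc = 1` is the null model).
#' @param w Minor cell fraction (default 1: every cell of the tissue
#'   expresses the TF at `fc`).
#' @param sigma Baseline log2-scale SD (default 1).
#' @param beta Linear regulon effect size (default 1).
#' @param noise_sd SD of target-level residual noise (default 1).
#' @param prop_activating Probability of an activating edge.
#' @param tf_tissue Optional integer vector assigning each specific TF
#'   to a tissue (default all 1).
#' @param seed Optional RNG seed; the output is a pure function of the
#'   configuration and seed.
#' @return List with `expr` (an [ExpressionMatrix()], log2-normalized,
#'   tissue labels attached) and `truth` (a `SyntheticTruth` list:
#'   planted TFs with tissue assignment, regulons with signs, `fc`, `w`,
#'   the true network, and the seed).
#' @export
simulate_bulk_multitissue <- function(n_tissues = 5, n_per_tissue = 60,
                                      n_genes = 2000,
                                      n_specific_tfs = 8, n_null_tfs = 8,
                                      n_targets_per_tf = 20,
                                      fc = 4, w = 1, sigma = 1,
                                      beta = 1, noise_sd = 1,
                                      prop_activating = 0.7,
                                      tf_tissue = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n_tfs <- n_specific_tfs + n_null_tfs
  n_regulon <- n_tfs * n_targets_per_tf
  if (n_tfs + n_regulon > n_genes)
    stop("more planted genes (", n_tfs + n_regulon,
         ") than n_genes (", n_genes, ")")
  if (is.null(tf_tissue)) tf_tissue <- rep(1L, n_specific_tfs)
  if (length(tf_tissue) != n_specific_tfs || any(tf_tissue > n_tissues))
    stop("'tf_tissue' must assign each specific TF to a tissue")

  net <- simulate_regulatory_network(n_tfs, n_targets_per_tf,
                                     prop_activating = prop_activating)
  tfs <- network_tfs(net)
  targets <- rownames(net$adjacency)
  n_bg <- n_genes - n_tfs - n_regulon
  bg <- if (n_bg > 0) paste0("BG", seq_len(n_bg)) else character(0)
  genes <- c(tfs, targets, bg)

  n_samples <- n_tissues * n_per_tissue
  tissue <- rep(paste0("Tissue", seq_len(n_tissues)), each = n_per_tissue)
  samples <- paste0("S", seq_len(n_samples))

  base_mean <- stats::runif(length(genes), 4, 8)
  names(base_mean) <- genes
  vals <- matrix(stats::rnorm(length(genes) * n_samples, sd = sigma),
                 length(genes), n_samples,
                 dimnames = list(genes, samples)) + base_mean

  shift <- log2(fc * w + (1 - w))
  for (j in seq_len(n_specific_tfs)) {
    in_toi <- tissue == paste0("Tissue", tf_tissue[j])
    vals[tfs[j], in_toi] <- vals[tfs[j], in_toi] + shift
  }
  # regulon targets: linear response to the (centered) TF signal
  for (tf in tfs) {
    members <- rownames(net$adjacency)[net$adjacency[, tf] != 0]
    tf_centered <- vals[tf, ] - base_mean[tf]
    for (g in members) {
      s <- net$adjacency[g, tf]
      vals[g, ] <- base_mean[g] + s * beta * tf_centered +
        stats::rnorm(n_samples, sd = noise_sd)
    }
  }

  expr <- ExpressionMatrix(vals, column_labels = tissue,
                           norm_state = "log2_normalized")
  truth <- structure(list(
    specific_tfs = tfs[seq_len(n_specific_tfs)],
    null_tfs = if (n_null_tfs > 0) tfs[n_specific_tfs + seq_len(n_null_tfs)]
               else character(0),
    tf_tissue = stats::setNames(paste0("Tissue", tf_tissue),
                                tfs[seq_len(n_specific_tfs)]),
    network = net, fc = fc, w = w, sigma = sigma, beta = beta,
    noise_sd = noise_sd, seed = seed), class = "SyntheticTruth")
  list(expr = expr, truth = truth)
}

.logistic_dropout <- function(x, k, x0) 1 / (1 + exp(k * (x - x0)))

#' Synthetic single-cell expression with expression-dependent dropout
#'
#' Generates log-scale single-cell expression from a known network and
#' per-(TF, cell) activity states: each regulon gene follows
#' `baseline + sum_f sign_gf * beta * state_fc + noise`, the TF's own
#' transcript tracks its activity, and technical zeros are injected with
#' a probability that decreases with underlying expression
#' (logistic: `p_drop = 1 / (1 + exp(k * (x - x0)))`). Setting
#' `tf_dropout = TRUE` forces the TF transcripts themselves to a 100%
#' dropout rate -- the regime in which transcript-based activity
#' estimates are blind but regulon-based estimates are not.
#'
#' @param n_cells Number of cells.
#' @param net A `RegulatoryNetwork` (truth).
#' @param activity_states Numeric matrix TFs x cells of activity levels
#'   (rownames must cover the network's TFs).
#' @param n_bg_genes Unregulated background genes to append (default 0).
#' @param beta Linear activity effect size (default 1).
#' @param noise_sd Log-scale residual SD (default 1).
#' @param baseline_range Range of per-gene baseline means
#'   (default `c(1, 5)`).
#' @param dropout Either `NULL` (no dropout), a list with `k` and `x0`
#'   for the logistic model (default `list(k = 1, x0 = 1)`), or a
#'   function mapping expression to dropout probability.
#' @param tf_dropout Force 100% dropout of the TF transcripts
#'   (default `FALSE`).
#' @param cell_labels Optional per-cell labels.
#' @param seed Optional RNG seed.
#' @return List with `expr` (log2-normalized [ExpressionMatrix()]) and
#'   `truth` (`SyntheticTruth` with states and dropout settings).
#' @export
simulate_scrnaseq <- function(n_cells, net, activity_states,
                              n_bg_genes = 0, beta = 1, noise_sd = 1,
                              baseline_range = c(1, 5),
                              dropout = list(k = 1, x0 = 1),
                              tf_dropout = FALSE,
                              cell_labels = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tfs <- network_tfs(net)
  if (is.null(rownames(activity_states)) ||
      !all(tfs %in% rownames(activity_states)))
    stop("'activity_states' must have one row per network TF")
  if (ncol(activity_states) != n_cells)
    stop("'activity_states' must have one column per cell")
  states <- activity_states[tfs, , drop = FALSE]

  targets <- rownames(net$adjacency)
  bg <- if (n_bg_genes > 0) paste0("BG", seq_len(n_bg_genes))
        else character(0)
  genes <- c(tfs, targets, bg)
  cells <- paste0("C", seq_len(n_cells))

  base_mean <- stats::runif(length(genes), baseline_range[1],
                            baseline_range[2])
  names(base_mean) <- genes
  signal <- matrix(0, length(genes), n_cells,
                   dimnames = list(genes, cells))
  signal[tfs, ] <- beta * states
  signal[targets, ] <- net$adjacency %*% (beta * states)
  vals <- base_mean + signal +
    matrix(stats::rnorm(length(genes) * n_cells, sd = noise_sd),
           length(genes), n_cells)
  dimnames(vals) <- list(genes, cells)

  drop_fn <- NULL
  if (is.function(dropout)) drop_fn <- dropout
  else if (is.list(dropout))
    drop_fn <- function(x) .logistic_dropout(x, dropout$k, dropout$x0)
  realized_dropout <- 0
  if (!is.null(drop_fn)) {
    p <- drop_fn(vals)
    zero <- matrix(stats::runif(length(vals)) < p, nrow(vals), ncol(vals))
    vals[zero] <- 0
    realized_dropout <- mean(zero)
  }
  if (tf_dropout) vals[tfs, ] <- 0

  expr <- ExpressionMatrix(vals, column_labels = cell_labels,
                           norm_state = "log2_normalized")
  truth <- structure(list(network = net, activity_states = states,
                          beta = beta, noise_sd = noise_sd,
                          dropout = dropout, tf_dropout = tf_dropout,
                          realized_dropout = realized_dropout,
                          seed = seed),
                     class = "SyntheticTruth")
  list(expr = expr, truth = truth)
}

#' Synthetic differentiation time course
#'
#' Simulates a staged differentiation experiment: the activity of the
#' `ramp_tfs` increases linearly with stage from 0 to `amp`, all other
#' TFs stay flat, and cells are generated per stage with
#' [simulate_scrnaseq()]. This is the end-to-end fixture for the
#' sensitivity / FDR benchmark of the activity pipeline.
#'
#' @param n_stages Number of ordinal stages (default 5).
#' @param cells_per_stage Cells per stage (default 50).
#' @param net A `RegulatoryNetwork`.
#' @param ramp_tfs Character vector of TFs whose activity ramps up
#'   (subset of the network's TFs).
#' @param amp Activity at the final stage (default 2).
#' @param flat_level Constant activity of non-ramp TFs (default 1).
#' @param seed Optional RNG seed.
#' @param ... Passed to [simulate_scrnaseq()] (dropout, noise, ...).
#' @return List with `expr`, `stage` (integer vector per cell) and
#'   `truth`.
#' @export
simulate_timecourse <- function(n_stages = 5, cells_per_stage = 50, net,
                                ramp_tfs, amp = 2, flat_level = 1,
                                seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  tfs <- network_tfs(net)
  if (!all(ramp_tfs %in% tfs))
    stop("'ramp_tfs' must be a subset of the network's TFs")
  n_cells <- n_stages * cells_per_stage
  stage <- rep(seq_len(n_stages), each = cells_per_stage)
  states <- matrix(flat_level, length(tfs), n_cells,
                   dimnames = list(tfs, NULL))
  ramp <- amp * (stage - 1) / (n_stages - 1)
  if (length(ramp_tfs))
    states[ramp_tfs, ] <- matrix(ramp, length(ramp_tfs), n_cells,
                                 byrow = TRUE)
  sim <- simulate_scrnaseq(n_cells, net, states,
                           cell_labels = as.character(stage), ...)
  sim$truth$ramp_tfs <- ramp_tfs
  sim$truth$stage <- stage
  list(expr = sim$expr, stage = stage, truth = sim$truth)
}
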