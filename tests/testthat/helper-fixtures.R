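# Small fixture builders shared across test files. Everything is built in
# code; no data files.

make_expr <- function(values, labels = NULL, state = "log2_normalized") {
  if (is.null(rownames(values)))
    rownames(values) <- paste0("G", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- paste0("S", seq_len(ncol(values)))
  ExpressionMatrix(values, column_labels = labels, norm_state = state)
}

rand_expr <- function(n_genes, n_cols, seed = 1, state = "log2_normalized") {
  set.seed(seed)
  make_expr(matrix(rnorm(n_genes * n_cols, mean = 5), n_genes, n_cols),
            state = state)
}

# network with a single TF and an explicit signed regulon
single_tf_net <- function(targets, signs, tf = "TF1") {
  adjacency <- matrix(as.integer(signs), length(targets), 1,
                      dimnames = list(targets, tf))
  RegulatoryNetwork(adjacency)
}

# residual-regression definition of partial correlation: correlate the
# residuals of g and f after regressing both on the remaining regulators
pcor_residual_oracle <- function(dat, g, f, others) {
  if (length(others) == 0) return(cor(dat[, g], dat[, f]))
  rg <- resid(lm(dat[, g] ~ dat[, others]))
  rf <- resid(lm(dat[, f] ~ dat[, others]))
  cor(rg, rf)
}

# all permutations of 1:8, for the exact Spearman oracle
gtools_permutations_8 <- function() {
  perm <- function(v) {
    if (length(v) == 1) return(matrix(v, 1, 1))
    out <- vector("list", length(v))
    for (i in seq_along(v)) {
      rest <- perm(v[-i])
      out[[i]] <- cbind(v[i], rest)
    }
    do.call(rbind, out)
  }
  perm(1:8)
}

run_cli <- function(args) {
  script <- system.file("scripts", "scregact.R", package = "scregact")
  rscript <- file.path(R.home("bin"), "Rscript")
  out <- suppressWarnings(
    system2(rscript, c(script, args), stdout = TRUE, stderr = TRUE,
            env = paste0("R_LIBS=", paste(.libPaths(), collapse = ":"))))
  list(status = attr(out, "status") %||% 0L, output = out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
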