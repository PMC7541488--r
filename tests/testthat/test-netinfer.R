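test_that("marginal screen correlations and p-values match cor.test", {
  x <- rand_expr(30, 20, seed = 5)
  tfs <- paste0("G", 1:4)
  cand <- marginal_screen(x, tfs, sigth = 1, spTH = 1, minNtgts = 1)
  # every TF x target pair retained in the no-filter limit
  expect_equal(nrow(cand$edges), 4 * 26)
  for (k in sample(nrow(cand$edges), 10)) {
    e <- cand$edges[k, ]
    ct <- cor.test(x$values[e$tf, ], x$values[e$target, ])
    expect_equal(e$r, unname(ct$estimate), tolerance = 1e-12)
    expect_equal(e$p, ct$p.value, tolerance = 1e-12)
  }
})

test_that("screen thresholds: significance, top-|r| cap, min targets", {
  set.seed(8)
  n <- 40
  tf <- rnorm(n)
  m <- rbind(TF1 = tf,
             hit1 = tf + rnorm(n, sd = 0.2),
             hit2 = -tf + rnorm(n, sd = 0.2),
             matrix(rnorm(5 * n), 5, n,
                    dimnames = list(paste0("null", 1:5), NULL)))
  colnames(m) <- paste0("s", 1:n)
  x <- make_expr(m)
  cand <- marginal_screen(x, "TF1", sigth = 1e-6, spTH = 1, minNtgts = 1)
  expect_setequal(cand$edges$target, c("hit1", "hit2"))

  # the |r| cap keeps only the single strongest pair at spTH = 1/7
  cand1 <- marginal_screen(x, "TF1", sigth = 1, spTH = 1 / 7, minNtgts = 1)
  expect_equal(nrow(cand1$edges), 1L)
  expect_equal(cand1$edges$target,
               cand$edges$target[which.max(abs(cand$edges$r))])

  # minNtgts removes TFs with too few surviving targets
  cand2 <- marginal_screen(x, "TF1", sigth = 1e-6, spTH = 1, minNtgts = 3)
  expect_length(cand2$tf_ids, 0)

  expect_error(marginal_screen(rand_expr(5, 3), "G1"), "at least 4 samples")
  expect_error(marginal_screen(x, character(0)), "empty")
})

test_that("planted-block candidate edges are recovered exactly", {
  sim <- simulate_bulk_multitissue(
    n_tissues = 5, n_per_tissue = 100, n_genes = 600,
    n_specific_tfs = 10, n_null_tfs = 0, n_targets_per_tf = 30,
    fc = 1, seed = 101)
  truth <- sim$truth$network
  cand <- marginal_screen(sim$expr, network_tfs(truth),
                          sigth = 1e-6, spTH = 1, minNtgts = 10)
  planted <- paste(rep(network_tfs(truth), each = 30),
                   rownames(truth$adjacency)[apply(
                     truth$adjacency != 0, 2, which)], sep = "->")
  found <- paste(cand$edges$tf, cand$edges$target, sep = "->")
  expect_setequal(found, planted)
})

test_that("partial correlation with one regulator equals marginal r", {
  set.seed(21)
  n <- 200
  f <- rnorm(n)
  g <- 0.5 * f + rnorm(n)
  dat <- rbind(TF1 = f, G1 = g)
  colnames(dat) <- paste0("s", 1:n)
  pc <- scregact:::.partial_cor_target(dat, "G1", "TF1")
  expect_equal(unname(pc), cor(g, f), tolerance = 1e-12)
})

test_that("inverse-covariance partial correlations match the residual oracle", {
  for (s in 1:20) {
    set.seed(s)
    n <- 60
    A <- matrix(rnorm(36), 6, 6)
    dat <- matrix(rnorm(n * 6), n, 6) %*% A
    colnames(dat) <- c("g", paste0("f", 1:5))
    pc <- scregact:::.partial_cor_target(t(dat), "g", paste0("f", 1:5))
    for (j in 1:5) {
      oracle <- pcor_residual_oracle(dat, "g", paste0("f", j),
                                     paste0("f", setdiff(1:5, j)))
      expect_equal(unname(pc[j]), oracle, tolerance = 1e-8)
    }
  }
})

test_that("a mediated regulator is pruned by the partial correlation", {
  # TF1 -> TF2 -> G_far, TF1 -> G_mid: conditioning on TF2 should kill
  # the TF1 -> G_far edge while TF1 -> G_mid survives
  pruned <- 0; kept <- 0
  for (rep in 1:20) {
    set.seed(300 + rep)
    n <- 1000
    tf1 <- rnorm(n)
    tf2 <- tf1 + rnorm(n, sd = 0.5)
    g_mid <- tf1 + rnorm(n, sd = 0.5)
    g_far <- tf2 + rnorm(n, sd = 0.5)
    m <- rbind(TF1 = tf1, TF2 = tf2, G_mid = g_mid, G_far = g_far)
    colnames(m) <- paste0("s", 1:n)
    x <- make_expr(m)
    cand <- marginal_screen(x, c("TF1", "TF2"), sigth = 1e-6, spTH = 1,
                            minNtgts = 1)
    net <- greedy_partial_correlation(x, cand, pcorth = 0.2, minNtgts = 1)
    adj <- net$adjacency
    if (!"TF1" %in% colnames(adj) || adj["G_far", "TF1"] == 0)
      pruned <- pruned + 1
    if ("TF1" %in% colnames(adj) && adj["G_mid", "TF1"] != 0)
      kept <- kept + 1
  }
  expect_gte(pruned, 19)
  expect_gte(kept, 19)
})

test_that("network container enforces signs, bounds and target counts", {
  sim <- simulate_bulk_multitissue(n_per_tissue = 40, n_genes = 800,
                                   seed = 77)
  cand <- marginal_screen(sim$expr, network_tfs(sim$truth$network),
                          sigth = 1e-6, spTH = 1, minNtgts = 10)
  net <- greedy_partial_correlation(sim$expr, cand, pcorth = 0.2)
  expect_true(all(net$adjacency %in% c(-1L, 0L, 1L)))
  expect_true(all(abs(net$weights) <= 1))
  nz <- net$adjacency != 0
  expect_true(all(sign(net$weights[nz]) == net$adjacency[nz]))
  expect_true(all(abs(net$weights[nz]) >= 0.2))
  expect_true(all(colSums(nz) >= 10))
})

test_that("moderated t reduces to the ordinary t at d0 = 0 and to the
           common-variance statistic at d0 = Inf", {
  x <- rand_expr(40, 12, seed = 9)
  g1 <- 1:6; g2 <- 7:12
  res0 <- moderated_t_test(x, g1, g2, prior_df = 0)
  ref <- apply(x$values, 1, function(v)
    t.test(v[g1], v[g2], var.equal = TRUE)$statistic)
  expect_equal(res0$t, unname(ref), tolerance = 1e-10)

  resInf <- moderated_t_test(x, g1, g2, prior_df = Inf)
  s0 <- sqrt(attr(resInf, "s0sq"))
  expect_equal(resInf$t, resInf$lfc / (s0 * sqrt(1 / 6 + 1 / 6)),
               tolerance = 1e-10)
})

test_that("moderated t is calibrated under the null and agrees with limma", {
  set.seed(14)
  m <- matrix(rnorm(2000 * 16, 5), 2000, 16,
              dimnames = list(paste0("g", 1:2000), paste0("s", 1:16)))
  x <- make_expr(m)
  res <- moderated_t_test(x, 1:8, 9:16)
  expect_gt(ks.test(res$p, "punif")$p.value, 0.01)
  expect_true(all(res$p_adj >= res$p))

  # limma's empirical-Bayes fit is an independent implementation of the
  # same shrinkage model; hyperparameter estimators differ in finite-n
  # detail, so agreement is close but not bitwise
  design <- cbind(1, rep(c(1, 0), each = 8))
  fit <- limma::eBayes(limma::lmFit(m, design))
  expect_equal(res$t, fit$t[, 2], tolerance = 0.01, ignore_attr = TRUE)
  expect_equal(res$p, fit$p.value[, 2], tolerance = 0.01,
               ignore_attr = TRUE)
  expect_equal(attr(res, "d0"), fit$df.prior, tolerance = 0.2)
  expect_gt(cor(res$t, fit$t[, 2]), 0.9999)
})

test_that("tissue-specific selection finds planted TFs and honours the
           confounding-tissue comparison", {
  sim <- simulate_bulk_multitissue(
    n_tissues = 5, n_per_tissue = 60, n_genes = 2000,
    n_specific_tfs = 8, n_null_tfs = 8, n_targets_per_tf = 20,
    fc = 4, seed = 55)
  net <- infer_network(sim$expr, network_tfs(sim$truth$network),
                       toi = "Tissue1")
  expect_setequal(network_tfs(net), sim$truth$specific_tfs)

  # a TF equally high in the confounding tissue passes comparison A but
  # must be rejected by comparison B
  sim2 <- simulate_bulk_multitissue(
    n_tissues = 4, n_per_tissue = 50, n_genes = 900,
    n_specific_tfs = 2, n_null_tfs = 0, n_targets_per_tf = 15,
    fc = 4, tf_tissue = c(1L, 1L), seed = 56)
  v <- sim2$expr$values
  labs <- sim2$expr$column_labels
  v["TF2", labs == "Tissue2"] <- v["TF2", labs == "Tissue2"] + 2
  contaminated <- ExpressionMatrix(v, column_labels = labs,
                                   norm_state = "log2_normalized")
  cand <- marginal_screen(contaminated, c("TF1", "TF2"),
                          sigth = 1e-6, spTH = 1, minNtgts = 10)
  full <- greedy_partial_correlation(contaminated, cand, pcorth = 0.2)
  selA <- select_tissue_specific_tfs(contaminated, full, toi = "Tissue1")
  selB <- select_tissue_specific_tfs(contaminated, full, toi = "Tissue1",
                                     cft = "Tissue2")
  expect_true(all(c("TF1", "TF2") %in% network_tfs(selA)))
  expect_identical(network_tfs(selB), "TF1")

  expect_error(select_tissue_specific_tfs(contaminated, full,
                                          toi = "NoSuchTissue"),
               "not in labels")
})

test_that("network inference is deterministic, threshold-monotone and
           invariant to sample order", {
  sim <- simulate_bulk_multitissue(n_per_tissue = 40, n_genes = 800,
                                   seed = 31)
  tfs <- network_tfs(sim$truth$network)
  net1 <- infer_network(sim$expr, tfs, toi = "Tissue1")
  net2 <- infer_network(sim$expr, tfs, toi = "Tissue1")
  expect_identical(net1$adjacency, net2$adjacency)

  loose <- infer_network(sim$expr, tfs, toi = "Tissue1", pcorth = 0.1)
  strict_edges <- which(net1$adjacency != 0, arr.ind = TRUE)
  strict_keys <- paste(rownames(net1$adjacency)[strict_edges[, 1]],
                       colnames(net1$adjacency)[strict_edges[, 2]])
  loose_edges <- which(loose$adjacency != 0, arr.ind = TRUE)
  loose_keys <- paste(rownames(loose$adjacency)[loose_edges[, 1]],
                      colnames(loose$adjacency)[loose_edges[, 2]])
  expect_true(all(strict_keys %in% loose_keys))

  set.seed(99)
  perm <- sample(ncol(sim$expr$values))
  shuffled <- ExpressionMatrix(sim$expr$values[, perm],
                               column_labels = sim$expr$column_labels[perm],
                               norm_state = "log2_normalized")
  net3 <- infer_network(shuffled, tfs, toi = "Tissue1")
  expect_identical(net3$adjacency, net1$adjacency)
})

test_that("edge recovery degrades monotonically with noise", {
  recall <- vapply(c(0.5, 1.5, 3), function(ns) {
    sim <- simulate_bulk_multitissue(
      n_tissues = 3, n_per_tissue = 40, n_genes = 500,
      n_specific_tfs = 5, n_null_tfs = 0, n_targets_per_tf = 15,
      fc = 1, noise_sd = ns, seed = 500)
    cand <- marginal_screen(sim$expr, network_tfs(sim$truth$network),
                            sigth = 1e-6, spTH = 1, minNtgts = 1)
    net <- greedy_partial_correlation(sim$expr, cand, pcorth = 0.2,
                                      minNtgts = 1)
    truth_adj <- sim$truth$network$adjacency
    hits <- 0
    for (tf in intersect(colnames(truth_adj), colnames(net$adjacency))) {
      tgts <- rownames(truth_adj)[truth_adj[, tf] != 0]
      tgts <- intersect(tgts, rownames(net$adjacency))
      hits <- hits + sum(net$adjacency[tgts, tf] != 0)
    }
    hits / sum(truth_adj != 0)
  }, numeric(1))
  expect_true(all(diff(recall) <= 0))
  expect_gt(recall[1], 0.9)
})

test_that("network TSV round-trip preserves adjacency, weights and params", {
  sim <- simulate_bulk_multitissue(n_per_tissue = 40, n_genes = 800,
                                   seed = 61)
  net <- infer_network(sim$expr, network_tfs(sim$truth$network),
                       toi = "Tissue1")
  d <- withr::local_tempdir()
  p <- file.path(d, "net.tsv")
  write_network(net, p)
  back <- read_network(p)
  expect_identical(back$adjacency, net$adjacency)
  expect_equal(back$weights, net$weights, tolerance = 1e-15)
  expect_equal(back$params$pcorth, net$params$pcorth)
})
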