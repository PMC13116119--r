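test_that("inferred regulons recover planted driver targets", {
  for (s in 1:5) {
    gt <- simulate_grn(seed = s)
    ds <- lognormalize(simulate_cells(gt, 334, n_background = 20, seed = s))
    regs <- infer_modules(ds, rownames(gt$grn_weights))
    for (lin in gt$lineages) {
      d <- gt$driver_map[[lin]]
      true_pos <- names(which(gt$grn_weights[d, gt$target_block[[lin]]] > 0))
      recovered <- intersect(regs$regulons[[d]]$target, true_pos)
      expect_gte(length(recovered) / length(true_pos), 0.5)
    }
  }
})

test_that("edge calibration under a null GRN stays near the nominal rate", {
  null_importances <- function(seed) {
    gt <- simulate_grn(seed = seed)
    gt$grn_weights[] <- 0
    ds <- lognormalize(simulate_cells(gt, 334, n_background = 20,
                                      seed = seed))
    regs <- infer_modules(ds, rownames(gt$grn_weights), min_importance = 0)
    ## per-gene maximum importance over TFs
    imp <- vapply(setdiff(rownames(ds), rownames(gt$grn_weights)),
                  function(g) {
                    w <- unlist(lapply(regs$regulons, function(df) {
                      abs(df$weight[df$target == g])
                    }))
                    if (length(w)) max(w) else 0
                  }, numeric(1))
    imp
  }
  thr <- unname(quantile(null_importances(101), 0.95))
  imp2 <- null_importances(102)
  expect_lte(mean(imp2 >= thr), 0.10)
})

test_that("a prior-edge mask excluding a TF drops its regulon", {
  sim <- shared_sim()
  tfs <- rownames(sim$gt$grn_weights)
  prior <- expand.grid(tf = setdiff(tfs, "TF1"),
                       target = colnames(sim$gt$grn_weights),
                       stringsAsFactors = FALSE)
  expect_warning(
    regs <- infer_modules(sim$ds, tfs, prior_edges = prior,
                          min_importance = 0.05),
    "TF1"
  )
  expect_false("TF1" %in% names(regs$regulons))
  expect_error(infer_modules(sim$ds, character(0)), "empty")
})

test_that("AUC matches the brute-force recovery-curve oracle", {
  set.seed(10)
  n_cells <- 50; n_genes <- 200
  norm <- matrix(rnorm(n_cells * n_genes), n_cells, n_genes)
  colnames(norm) <- paste0("g", seq_len(n_genes))
  ds <- sce_from_norm(norm)
  regs <- as_regulon_set(setNames(lapply(1:20, function(m) {
    data.frame(target = paste0("g", sample(n_genes, m)), weight = 1)
  }), paste0("R", 1:20)))
  act <- aucell_scores(ds, regs, top_frac = 0.05)
  cutoff <- ceiling(0.05 * n_genes)
  for (r in seq_len(20)) {
    idx <- match(regs$regulons[[r]]$target, colnames(norm))
    for (i in seq_len(n_cells)) {
      expect_equal(act$auc[i, r], auc_oracle(norm[i, ], idx, cutoff),
                   tolerance = 1e-9)
    }
  }
  expect_true(all(act$auc >= 0 & act$auc <= 1))
  expect_equal(max(abs(colMeans(act$zauc))), 0, tolerance = 1e-9)
})

test_that("AUC closed forms: top-ranked block and out-of-cutoff regulons", {
  ## 100 genes, cutoff 5; a cell whose regulon occupies ranks 1..3
  norm <- rbind(c(seq(100, 1)), c(seq(1, 100)))
  colnames(norm) <- paste0("g", 1:100)
  ds <- sce_from_norm(norm)
  regs <- as_regulon_set(list(R = data.frame(target = c("g1", "g2", "g3"),
                                             weight = 1)))
  act <- aucell_scores(ds, regs, top_frac = 0.05)
  m <- 3; cutoff <- 5
  expect_equal(unname(act$auc[1, "R"]), 1 - (m - 1) / (2 * cutoff),
               tolerance = 1e-12)
  ## in the reversed cell the regulon sits at ranks 98..100: AUC 0
  expect_identical(unname(act$auc[2, "R"]), 0)
  ## determinism under ties
  tie <- matrix(1, 3, 100, dimnames = list(NULL, paste0("g", 1:100)))
  act_tie1 <- aucell_scores(sce_from_norm(tie), regs, top_frac = 0.05)
  act_tie2 <- aucell_scores(sce_from_norm(tie), regs, top_frac = 0.05)
  expect_identical(act_tie1$auc, act_tie2$auc)
})

test_that("RSS attains its analytic limits and closed form", {
  n <- 40
  type <- rep(c("A", "B"), each = n / 2)
  ind <- as.numeric(type == "A")
  act <- as_activity(cbind(match_A = ind, outside_A = 1 - ind,
                           uniform = rep(1, n)))
  rss <- regulon_specificity(act, type)
  expect_equal(unname(rss$rss["A", "match_A"]), 1, tolerance = 1e-12)
  expect_equal(unname(rss$rss["A", "outside_A"]), 0, tolerance = 1e-12)
  ## closed form for uniform activity vs a half-size type
  p <- rep(1 / n, n)
  q <- ind / sum(ind)
  expect_equal(unname(rss$rss["A", "uniform"]),
               1 - sqrt(jsd_oracle(p, q)), tolerance = 1e-12)
  ## scale invariance in the activity vector
  act2 <- as_activity(cbind(match_A = 7.3 * ind, outside_A = 1 - ind,
                            uniform = rep(2, n)))
  expect_equal(regulon_specificity(act2, type)$rss, rss$rss,
               tolerance = 1e-12)
  ## all-zero activity is an error naming the regulon
  act0 <- as_activity(cbind(dead = rep(0, n), uniform = rep(1, n)))
  expect_error(regulon_specificity(act0, type), "dead")
})

test_that("marker selection is deterministic and permutation-equivariant", {
  rss <- structure(list(rss = rbind(
    A = c(x = 0.9, y = 0.5, z = 0.9),
    B = c(x = 0.1, y = 0.8, z = 0.2)
  )), class = "rss_matrix")
  mk <- select_markers(rss, n_top = 2)
  expect_identical(mk$A, c("x", "z"))   # tie broken lexicographically
  expect_identical(mk$B, c("y", "z"))
  ## full ranking when n_top equals the number of regulons
  expect_identical(select_markers(rss, n_top = 3)$B, c("y", "z", "x"))
  ## permuting regulon columns leaves the selection unchanged
  rss_perm <- structure(list(rss = rss$rss[, c(3, 1, 2)]),
                        class = "rss_matrix")
  expect_identical(select_markers(rss_perm, 2), mk)
  expect_error(select_markers(rss, 5), "exceeds")
})

test_that("planted drivers surface as markers of their committed population", {
  sim <- shared_sim()
  sa <- shared_activity()
  committed <- c(ME = "MEP", GM = "GMP", LY = "CLP")
  mk <- select_markers(sa$rss, n_top = 3)
  for (lin in names(committed)) {
    expect_true(sim$gt$driver_map[[lin]] %in% mk[[committed[[lin]]]])
  }
})

test_that("the GMM edge filter separates a planted weight mixture", {
  for (s in 1:5) {
    set.seed(s)
    w <- c(rnorm(500, 0, 0.1), rnorm(50, 1, 0.1))
    truth <- rep(c(FALSE, TRUE), c(500, 50))
    regs <- as_regulon_set(list(TFX = data.frame(
      target = paste0("g", seq_along(w)), weight = w)))
    kept <- filter_edges_gmm(regs, "TFX", seed = s)
    retained <- paste0("g", seq_along(w)) %in% kept$target
    expect_gte(mean(retained == truth), 0.95)
    ## deterministic rerun
    kept2 <- filter_edges_gmm(regs, "TFX", seed = s)
    expect_identical(kept$target, kept2$target)
  }
  ## degenerate weights: keep everything, with a warning
  regs_flat <- as_regulon_set(list(TFY = data.frame(
    target = paste0("g", 1:6), weight = rep(0.5, 6))))
  expect_warning(kept <- filter_edges_gmm(regs_flat, "TFY"), "degenerate")
  expect_identical(nrow(kept), 6L)
  expect_error(filter_edges_gmm(regs_flat, "TFZ"), "no regulon")
})

test_that("network export round-trips through standard readers", {
  regs <- as_regulon_set(list(
    TF1 = data.frame(target = c("a", "b", "c"), weight = c(1, -2, 0.5)),
    TF2 = data.frame(target = c("a", "b", "c"), weight = c(3, 4, 5))
  ))
  act <- as_activity(matrix(runif(20), 10, 2,
                            dimnames = list(NULL, c("TF1", "TF2"))))
  dir <- withr::local_tempdir()
  gml <- file.path(dir, "net.graphml")
  export_network(regs, list(P = c("TF1", "TF2")), act, gml, "graphml")
  g <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::vcount(g), 5)
  expect_equal(igraph::ecount(g), 6)
  expect_equal(sort(igraph::E(g)$weight), sort(c(1, -2, 0.5, 3, 4, 5)),
               tolerance = 1e-9)
  expect_setequal(igraph::V(g)$role, c("tf", "target"))

  sif <- file.path(dir, "net.sif")
  export_network(regs, list(P = c("TF1", "TF2")), act, sif, "sif")
  lines <- readLines(sif)
  expect_length(lines, 6L)
  expect_true(all(grepl("^TF[12] regulates [abc]$", lines)))
  expect_error(export_network(regs, list(P = "TF9"), act, sif, "sif"),
               "TF9")
})
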