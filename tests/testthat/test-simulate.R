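test_that("simulate_grn plants one positive driver block per lineage", {
  gt <- simulate_grn(n_tfs = 3, n_targets = 30, lineages = c("A", "B", "C"),
                     density = 0.1, seed = 0)
  expect_setequal(unlist(gt$driver_map), c("TF1", "TF2", "TF3"))
  for (lin in c("A", "B", "C")) {
    w <- gt$grn_weights[gt$driver_map[[lin]], gt$target_block[[lin]]]
    expect_length(w, 10L)
    expect_true(all(w > 0))
  }
  ## zero density: only driver edges remain
  gt0 <- simulate_grn(n_tfs = 5, n_targets = 30, lineages = c("A", "B", "C"),
                      density = 0, seed = 0)
  expect_identical(sum(gt0$grn_weights != 0), 30L)
  expect_error(simulate_grn(n_tfs = 2, lineages = c("A", "B", "C")),
               "lineages")
})

test_that("simulation is seed-deterministic", {
  g1 <- simulate_grn(seed = 1)
  g2 <- simulate_grn(seed = 1)
  g3 <- simulate_grn(seed = 2)
  expect_identical(g1$grn_weights, g2$grn_weights)
  expect_false(identical(g1$grn_weights, g3$grn_weights))

  d1 <- simulate_cells(g1, 60, timepoints = "D0", n_background = 40, seed = 7)
  d2 <- simulate_cells(g1, 60, timepoints = "D0", n_background = 40, seed = 7)
  d3 <- simulate_cells(g1, 60, timepoints = "D0", n_background = 40, seed = 8)
  expect_identical(assay(d1, "counts"), assay(d2, "counts"))
  expect_identical(reducedDim(d1, "embedding"), reducedDim(d2, "embedding"))
  expect_false(identical(assay(d1, "counts"), assay(d3, "counts")))
})

test_that("population allocation follows the abundance multipliers", {
  gt <- simulate_grn(seed = 3)
  ds <- simulate_cells(gt, 500, timepoints = c("D0", "D3"),
                       n_background = 20, seed = 3)
  tab <- table(ds$population, ds$timepoint)
  for (tp in c("D0", "D3")) {
    m <- gt$abundance_multiplier[, tp]
    expected <- 500 * m / sum(m)
    observed <- as.vector(tab[names(m), tp])
    ## each population within 4 binomial standard deviations of expectation
    sdv <- sqrt(expected * (1 - m / sum(m)))
    expect_true(all(abs(observed - expected) <= 4 * sdv + 1))
    expect_identical(sum(observed), 500L)
  }
  ## GMP carries multiplier 3 at D3: observed enrichment reflects it
  expect_gt(tab["GMP", "D3"] / tab["GMP", "D0"], 2)
})

test_that("driver TFs activate along pseudotime in their own lineage", {
  sim <- shared_sim()
  lc <- as.matrix(assay(sim$ds, "logcounts"))
  for (lin in sim$gt$lineages) {
    d <- sim$gt$driver_map[[lin]]
    in_lin <- sim$ds$lineage == lin
    late <- in_lin & sim$ds$pseudotime > 0.8
    early <- in_lin & sim$ds$pseudotime < 0.2
    expect_gt(mean(lc[d, late]), mean(lc[d, early]))
  }
})

test_that("planted driver-target signal is recoverable across seeds", {
  ## at the generator defaults (full gene panel): the planted contract
  for (s in 1:5) {
    gt <- simulate_grn(seed = s)
    ds <- lognormalize(simulate_cells(gt, 334, seed = s))
    lc <- as.matrix(assay(ds, "logcounts"))
    for (lin in gt$lineages) {
      d <- gt$driver_map[[lin]]
      blk <- names(which(gt$grn_weights[d, gt$target_block[[lin]]] > 0))
      r <- cor(lc[d, ], base::t(lc[blk, , drop = FALSE]))
      expect_gt(min(r), 0.3)
    }
  }
})

test_that("a zeroed-out GRN leaves targets uncorrelated with TFs", {
  gt <- simulate_grn(seed = 11)
  gt$grn_weights[] <- 0
  ds <- lognormalize(simulate_cells(gt, 334, n_background = 20,
                                    noise_dispersion = Inf, seed = 11))
  lc <- as.matrix(assay(ds, "logcounts"))
  r <- cor(lc["TF1", ], base::t(lc[gt$target_block$ME, , drop = FALSE]))
  expect_lt(max(abs(r)), 0.1)
})

test_that("inject_mito_and_outliers flags exactly the requested cells", {
  gt <- simulate_grn(seed = 5)
  ds <- simulate_cells(gt, 100, timepoints = "D0", seed = 5)
  out <- inject_mito_and_outliers(ds, frac_low = 0.1, min_genes = 500,
                                  seed = 2)
  expressed <- Matrix::colSums(assay(out, "counts") > 0)
  expect_identical(sum(expressed < 500), 10L)
  expect_identical(sum(out$qc_injected == "low_genes"), 10L)

  ## all fractions zero: identity
  same <- inject_mito_and_outliers(ds, 0, 0, 0, seed = 2)
  expect_equal(as.matrix(assay(same, "counts")),
               as.matrix(assay(ds, "counts")))

  ## determinism of the flagged set
  rerun <- inject_mito_and_outliers(ds, frac_mito = 0.05, seed = 9)
  rerun2 <- inject_mito_and_outliers(ds, frac_mito = 0.05, seed = 9)
  expect_identical(which(rerun$qc_injected == "mito"),
                   which(rerun2$qc_injected == "mito"))

  ## impossible violations error (panel smaller than the high threshold)
  expect_error(inject_mito_and_outliers(ds, frac_high = 0.1,
                                        max_genes = 5000),
               "only")
  expect_error(inject_mito_and_outliers(ds[1:5, ], frac_low = 0.1),
               "fewer than 10 genes")
})

test_that("fixtures round-trip losslessly through disk", {
  gt <- simulate_grn(seed = 6)
  ds <- simulate_cells(gt, 60, timepoints = c("D0", "D3"),
                       n_background = 30, seed = 6)
  dir <- withr::local_tempdir()
  write_fixture(ds, gt, file.path(dir, "fx"))
  back <- read_fixture(file.path(dir, "fx"))
  expect_equal(as.matrix(assay(back$dataset, "counts")),
               as.matrix(assay(ds, "counts")))
  expect_identical(colnames(back$dataset), colnames(ds))
  expect_equal(unname(reducedDim(back$dataset, "embedding")),
               unname(reducedDim(ds, "embedding")))
  expect_equal(back$truth$grn_weights, gt$grn_weights)
  expect_equal(back$truth$abundance_multiplier, gt$abundance_multiplier)
  expect_identical(back$truth$driver_map, gt$driver_map)

  ## refuse to clobber, refuse empty datasets
  expect_error(write_fixture(ds, gt, file.path(dir, "fx")), "not empty")
  expect_error(write_fixture(ds[, integer(0)], gt, file.path(dir, "fx2")),
               "0 cells")
})
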