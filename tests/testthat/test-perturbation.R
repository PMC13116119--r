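## tiny hand-made linear system: TF1 -> G1 with coefficient c
.chain_fixture <- function(c_coef = 0.8, n = 30) {
  set.seed(1)
  tf <- runif(n, 1, 2)
  g1 <- 5 + c_coef * tf  # large offset so clamping never binds
  norm <- cbind(TF1 = tf, G1 = g1, G2 = rnorm(n, 10))
  ds <- sce_from_norm(norm, embedding = cbind(rnorm(n), rnorm(n)),
                      meta = list(population = rep("P", n),
                                  pseudotime = runif(n)))
  edges <- data.frame(tf = "TF1", target = "G1")
  list(ds = ds, edges = edges)
}

test_that("knock-in values follow the max(1, 2 x 95th percentile) rule", {
  expect_identical(knockin_value(rep(0, 100)), 1)
  expect_equal(knockin_value(rep(0.8, 50)), 1.6, tolerance = 1e-12)
  expect_identical(knockin_value(rep(0.4, 50)), 1)
  x <- seq(0, 1, length.out = 101)  # 95th percentile = 0.95
  expect_equal(knockin_value(x), 1.9, tolerance = 1e-12)
  expect_error(knockin_value(numeric(0)), "non-empty")
  expect_error(knockin_value(c(1, -1)), "non-negative")
})

test_that("the linear GRN fit recovers the chain coefficient", {
  fx <- .chain_fixture(0.8)
  grn <- fit_linear_grn(fx$ds, fx$edges, ridge_alpha = 1e-6,
                        stratify = "global")
  expect_equal(unname(grn$coef$global["G1", "TF1"]), 0.8, tolerance = 1e-3)
  ## cross-check the near-unpenalized fit against ordinary least squares
  lc <- base::t(as.matrix(assay(fx$ds, "logcounts")))
  ref <- stats::lm(lc[, "G1"] ~ lc[, "TF1"])
  expect_equal(unname(grn$coef$global["G1", "TF1"]), unname(coef(ref)[2]),
               tolerance = 1e-6)
  ## heavier ridge shrinks the coefficient norm monotonically
  grn_heavy <- fit_linear_grn(fx$ds, fx$edges, ridge_alpha = 1e3,
                              stratify = "global")
  expect_lt(abs(grn_heavy$coef$global["G1", "TF1"]),
            abs(grn$coef$global["G1", "TF1"]))
  ## permuting cells leaves coefficients unchanged
  perm <- sample(ncol(fx$ds))
  grn_perm <- fit_linear_grn(fx$ds[, perm], fx$edges, ridge_alpha = 1e-6,
                             stratify = "global")
  expect_equal(as.matrix(grn_perm$coef$global),
               as.matrix(grn$coef$global), tolerance = 1e-9)
})

test_that("shift propagation follows the pin-multiply-clamp contract", {
  fx <- .chain_fixture(0.8)
  grn <- fit_linear_grn(fx$ds, fx$edges, ridge_alpha = 1e-6,
                        stratify = "global")
  c_hat <- grn$coef$global["G1", "TF1"]
  spec <- perturbation_spec("TF1", "KO", n_propagation = 3)
  shift <- simulate_shift(grn, fx$ds, spec)
  x_tf <- as.numeric(assay(fx$ds, "logcounts")["TF1", ])
  ## the TF coordinate stays pinned at its seed
  expect_equal(unname(shift[, "TF1"]), -x_tf, tolerance = 1e-12)
  ## one-step chain: target shift = c * delta0 after any >= 1 iterations
  expect_equal(unname(shift[, "G1"]), c_hat * (-x_tf), tolerance = 1e-9)
  ## genes outside the GRN universe never move (they are not even carried)
  expect_false("G2" %in% colnames(shift))

  ## null perturbation: pinning the TF at its current value does nothing
  x_const <- fx$ds
  assay(x_const, "logcounts")["TF1", ] <- 1.5
  null_spec <- structure(list(tf = "TF1", mode = "KI", target_value = 1.5,
                              n_propagation = 3L),
                         class = "perturbation_spec")
  expect_true(all(simulate_shift(grn, x_const, null_spec) == 0))

  ## a TF with no outgoing edges only moves itself
  edges2 <- data.frame(tf = c("TF1", "G2"), target = c("G1", "G1"))
  grn2 <- fit_linear_grn(fx$ds, edges2, stratify = "global")
  grn2$edges <- grn2$edges[grn2$edges$tf != "G2", ]
  grn2$coef$global["G1", "G2"] <- 0
  spec2 <- structure(list(tf = "G2", mode = "KO", target_value = 0,
                          n_propagation = 2L), class = "perturbation_spec")
  expect_warning(s2 <- simulate_shift(grn2, fx$ds, spec2), "no outgoing")
  expect_true(all(s2[, c("TF1", "G1")] == 0))
})

test_that("unclamped propagation is linear in the seed shift", {
  sim <- shared_sim()
  sub <- sim$ds[, 1:200]
  grn <- fit_linear_grn(sub, sim$gt, stratify = "global")
  spec1 <- structure(list(tf = "TF1", mode = "KI", target_value = 3,
                          n_propagation = 3L), class = "perturbation_spec")
  s1 <- simulate_shift(grn, sub, spec1, clamp = FALSE)
  ## independent closed form: iterate the coefficient matrix directly
  genes <- grn$genes
  Ct <- base::t(as.matrix(grn$coef$global))
  X <- base::t(as.matrix(assay(sub, "logcounts")[genes, ]))
  D <- matrix(0, nrow(X), length(genes), dimnames = list(NULL, genes))
  D[, "TF1"] <- 3 - X[, "TF1"]
  for (k in 1:3) {
    D <- D %*% Ct
    D[, "TF1"] <- 3 - X[, "TF1"]
  }
  expect_equal(unname(s1), unname(D), tolerance = 1e-9)
  ## doubling the seed doubles the response (restrict to a zero-expression
  ## synthetic TF so the seed is uniform)
  spec2 <- structure(list(tf = "TF1", mode = "KI", target_value = 6,
                          n_propagation = 3L), class = "perturbation_spec")
  s2 <- simulate_shift(grn, sub, spec2, clamp = FALSE)
  seed1 <- 3 - X[, "TF1"]; seed2 <- 6 - X[, "TF1"]
  ## linearity: response difference equals the propagated seed difference
  D2 <- matrix(0, nrow(X), length(genes), dimnames = list(NULL, genes))
  D2[, "TF1"] <- seed2 - seed1
  for (k in 1:3) { D2 <- D2 %*% Ct; D2[, "TF1"] <- seed2 - seed1 }
  expect_equal(unname(s2 - s1), unname(D2), tolerance = 1e-9)
})

test_that("flow projection points toward the matching neighbour", {
  ## a center cell ringed by 8 symmetric neighbours
  set.seed(6)
  angles <- seq(0, 2 * pi, length.out = 9)[-9]
  E <- rbind(c(0, 0), cbind(cos(angles), sin(angles)))
  norm <- matrix(rnorm(9 * 12), 9, 12)
  ds <- sce_from_norm(norm, embedding = E)
  g <- build_cell_graph(ds, k = 8)
  jstar <- 4L
  shift <- matrix(0, 9, 12, dimnames = list(NULL, rownames(ds)))
  shift[1, ] <- norm[jstar, ] - norm[1, ]
  V <- project_flow(shift, ds, g, kernel_scale = 1e-4)
  dir <- E[jstar, ] - E[1, ]
  cosine <- sum(V[1, ] * dir) / sqrt(sum(V[1, ]^2) * sum(dir^2))
  expect_gt(cosine, 0.9)
  ## zero shifts give zero vectors
  expect_true(all(V[-1, ] == 0))
  V0 <- project_flow(shift * 0, ds, g)
  expect_true(all(V0 == 0))
})

test_that("flow vectors are equivariant under embedding rotation", {
  set.seed(7)
  n <- 80
  E <- cbind(rnorm(n), rnorm(n))
  norm <- matrix(rnorm(n * 10), n, 10)
  ds <- sce_from_norm(norm, embedding = E)
  g <- build_cell_graph(ds, k = 10)
  shift <- matrix(rnorm(n * 10), n, 10, dimnames = list(NULL, rownames(ds)))
  V <- project_flow(shift, ds, g)
  th <- pi / 5
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  ds_rot <- sce_from_norm(norm, embedding = E %*% R)
  g_rot <- build_cell_graph(ds_rot, k = 10)
  V_rot <- project_flow(shift, ds_rot, g_rot, kernel_scale = 0.05)
  expect_equal(unname(V_rot), unname(V %*% R), tolerance = 1e-6)
})

test_that("developmental flow follows the pseudotime gradient", {
  set.seed(8)
  n <- 1000
  E <- cbind(runif(n, 0, 10), runif(n, 0, 10))
  ds <- sce_from_norm(matrix(rnorm(n * 2), n, 2), embedding = E,
                      meta = list(pseudotime = E[, 1] / 10))
  dev <- development_flow(ds, grid_bins = 10)
  lens <- sqrt(rowSums(dev$vectors^2))
  cosx <- dev$vectors[, 1] / lens
  expect_true(all(cosx > 0.99))
  ## constant pseudotime: no flow
  ds_const <- ds; colData(ds_const)$pseudotime <- rep(0.5, n)
  dev_const <- development_flow(ds_const, grid_bins = 10)
  expect_equal(max(abs(dev_const$vectors)), 0, tolerance = 1e-9)
  ## reversing pseudotime negates the field
  ds_rev <- ds; colData(ds_rev)$pseudotime <- 1 - E[, 1] / 10
  dev_rev <- development_flow(ds_rev, grid_bins = 10)
  expect_equal(dev_rev$vectors, -dev$vectors, tolerance = 1e-9)
})

test_that("perturbation scores have the inner-product sign laws", {
  set.seed(9)
  n <- 1000
  E <- cbind(runif(n, 0, 10), runif(n, 0, 10))
  lin <- ifelse(E[, 2] > 5, "A", "B")
  ds <- sce_from_norm(matrix(rnorm(n * 2), n, 2), embedding = E,
                      meta = list(pseudotime = E[, 1] / 10, lineage = lin))
  dev <- development_flow(ds, grid_bins = 10)
  ## perturbed flow identical to the developmental flow: PS >= 0 everywhere
  cell_dev <- dev$vectors[match(
    .bincode_like <- {
      gs <- dev$grid_spec
      bx <- pmin(gs$bins, 1L + floor((E[, 1] - gs$xlim[1]) / diff(gs$xlim) * gs$bins))
      by <- pmin(gs$bins, 1L + floor((E[, 2] - gs$ylim[1]) / diff(gs$ylim) * gs$bins))
      (by - 1L) * gs$bins + bx
    }, dev$grid$bin), ]
  cell_dev[is.na(cell_dev[, 1]), ] <- 0
  ff <- perturbation_score(cell_dev, dev, ds, lin)
  expect_true(all(ff$grid$ps >= -1e-12))
  expect_true(all(ff$ps_per_lineage >= 0))
  ## antisymmetry: negating the flow negates every score exactly
  ff_neg <- perturbation_score(-cell_dev, dev, ds, lin)
  expect_equal(ff_neg$grid$ps, -ff$grid$ps, tolerance = 1e-12)
  expect_equal(ff_neg$ps_per_lineage, -ff$ps_per_lineage, tolerance = 1e-12)
  ## a null perturbation scores zero for every lineage
  ff0 <- perturbation_score(cell_dev * 0, dev, ds, lin)
  expect_true(all(abs(ff0$ps_per_lineage) < 1e-12))
})
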