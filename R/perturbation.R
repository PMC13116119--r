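## In silico transcription-factor perturbation.
##
## A linear gene regulatory network is fitted by ridge regression on the
## allowed (TF, target) edges; a knock-in or knock-out shift is seeded at
## the perturbed TF and propagated through the network; the resulting
## per-cell expression shift is projected onto the 2-D embedding as a
## transition-probability flow; and the perturbation score (PS) of a grid
## point is the inner product of that perturbed flow with the
## developmental flow (the gradient of kernel-smoothed pseudotime).
## Positive lineage-mean PS means the perturbation pushes cells along the
## lineage's differentiation direction.

.base_edges <- function(base) {
  if (is(base, "regulon_set")) {
    do.call(rbind, lapply(names(base$regulons), function(tf) {
      data.frame(tf = tf, target = base$regulons[[tf]]$target,
                 stringsAsFactors = FALSE)
    }))
  } else if (is(base, "ground_truth")) {
    .base_edges(regulons_from_truth(base))
  } else if (is.data.frame(base)) {
    stopifnot(all(c("tf", "target") %in% names(base)))
    base[, c("tf", "target")]
  } else {
    stop("base must be a regulon_set, ground_truth or an edge data frame")
  }
}

#' Fit a linear GRN on allowed edges
#'
#' Per stratum (population, or globally) and per target gene, fits a
#' ridge regression of the gene's log-normalized expression on its allowed
#' regulators (centered covariates, intercept absorbed). Strata with
#' fewer than `min_stratum_cells` cells fall back to the global fit.
#'
#' @param ds A `SingleCellExperiment` with `logcounts` and, for
#'   population stratification, a `population` column.
#' @param base Allowed edges: a `regulon_set`, a `ground_truth`, or a
#'   data frame with columns `tf`, `target`.
#' @param ridge_alpha Ridge penalty (default 1).
#' @param stratify `"population"` (default) or `"global"`.
#' @param min_stratum_cells Minimum stratum size before the global
#'   fallback (default 20).
#' @return A `linear_grn` with `coef` (named list of sparse genes x genes
#'   coefficient matrices, `C[target, regulator]`), `genes` (the GRN gene
#'   universe), `stratum_of_pop`, `edges`, `ridge_alpha`.
#' @export
fit_linear_grn <- function(ds, base, ridge_alpha = 1,
                           stratify = c("population", "global"),
                           min_stratum_cells = 20L) {
  stratify <- match.arg(stratify)
  edges <- .base_edges(base)
  genes <- union(unique(edges$tf), unique(edges$target))
  missing <- setdiff(genes, rownames(ds))
  if (length(missing)) {
    stop("base edges reference genes absent from the dataset: ",
         paste(head(missing, 5), collapse = ", "))
  }
  lc <- as.matrix(Matrix::t(.logcounts(ds)[genes, , drop = FALSE]))

  regulators_of <- split(edges$tf, edges$target)

  fit_stratum <- function(rows) {
    X <- lc[rows, , drop = FALSE]
    X <- sweep(X, 2L, colMeans(X), "-")
    trip_i <- integer(0); trip_j <- integer(0); trip_x <- numeric(0)
    for (tg in names(regulators_of)) {
      regs <- unique(regulators_of[[tg]])
      Xr <- X[, regs, drop = FALSE]
      y <- X[, tg]
      beta <- tryCatch(
        solve(crossprod(Xr) + diag(ridge_alpha, length(regs)),
              crossprod(Xr, y)),
        error = function(e) matrix(0, length(regs), 1L)
      )
      trip_i <- c(trip_i, rep(match(tg, genes), length(regs)))
      trip_j <- c(trip_j, match(regs, genes))
      trip_x <- c(trip_x, as.vector(beta))
    }
    sparseMatrix(i = trip_i, j = trip_j, x = trip_x,
                 dims = c(length(genes), length(genes)),
                 dimnames = list(genes, genes))
  }

  all_rows <- seq_len(ncol(ds))
  coefs <- list(global = fit_stratum(all_rows))
  stratum_of_pop <- character(0)
  if (stratify == "population") {
    pop <- colData(ds)$population
    if (is.null(pop)) stop("stratify='population' needs colData(ds)$population")
    for (p in unique(pop)) {
      rows <- which(pop == p)
      if (length(rows) >= min_stratum_cells) {
        coefs[[p]] <- fit_stratum(rows)
        stratum_of_pop[p] <- p
      } else {
        message("population '", p, "' has ", length(rows),
                " cells; using the global fit")
        stratum_of_pop[p] <- "global"
      }
    }
  }
  structure(
    list(coef = coefs, genes = genes, stratum_of_pop = stratum_of_pop,
         edges = edges, ridge_alpha = ridge_alpha, stratify = stratify),
    class = "linear_grn"
  )
}

#' @export
print.linear_grn <- function(x, ...) {
  cat("linear_grn:", length(x$genes), "genes,", nrow(x$edges), "edges,",
      length(x$coef), "strata (", x$stratify, ")\n")
  invisible(x)
}

#' Knock-in expression value for a TF
#'
#' The value a knocked-in TF is pinned to: the greater of 1 or twice the
#' empirical 95th percentile of its observed expression (percentile by
#' linear interpolation, [stats::quantile()] type 7). A TF silent in every
#' cell therefore gets exactly 1.
#'
#' @param tf_expression Non-empty, non-negative per-cell expression.
#' @return A scalar knock-in value (>= 1).
#' @examples
#' knockin_value(rep(0, 100)) # 1
#' @export
knockin_value <- function(tf_expression) {
  if (length(tf_expression) == 0L) stop("tf_expression must be non-empty")
  if (any(tf_expression < 0)) stop("tf_expression must be non-negative")
  max(1, 2 * unname(quantile(tf_expression, 0.95, type = 7)))
}

#' Describe a single-TF perturbation
#'
#' @param tf TF gene id.
#' @param mode `"KI"` (knock-in) or `"KO"` (knock-out).
#' @param ds Dataset used to derive the knock-in value from the TF's
#'   log-normalized expression (required for KI).
#' @param n_propagation Signal propagation iterations (default 3).
#' @return A `perturbation_spec` with `tf`, `mode`, `target_value`
#'   (0 for KO, `>= 1` for KI) and `n_propagation`.
#' @export
perturbation_spec <- function(tf, mode = c("KI", "KO"), ds = NULL,
                              n_propagation = 3L) {
  mode <- match.arg(mode)
  if (n_propagation < 1L) stop("n_propagation must be >= 1")
  value <- if (mode == "KO") {
    0
  } else {
    if (is.null(ds)) stop("KI needs the dataset to derive the target value")
    if (!tf %in% rownames(ds)) stop("TF '", tf, "' absent from the dataset")
    knockin_value(as.numeric(.logcounts(ds)[tf, ]))
  }
  structure(list(tf = tf, mode = mode, target_value = value,
                 n_propagation = n_propagation),
            class = "perturbation_spec")
}

#' Simulate the expression shift of a TF perturbation
#'
#' Seeds a per-cell shift `delta0 = target_value - x[tf]` on the TF
#' coordinate and propagates it `n_propagation` times through the fitted
#' coefficient matrix; after each multiplication the TF coordinate is
#' re-pinned to `delta0` and the simulated expression `x + delta` is
#' clamped at 0 from below. Cells use their population stratum's
#' coefficients (global fallback).
#'
#' @param grn A `linear_grn`.
#' @param ds The dataset the GRN was fitted on (`logcounts` used).
#' @param spec A `perturbation_spec`.
#' @param clamp Clamp simulated expression at 0 (default `TRUE`; disable
#'   only for linearity diagnostics).
#' @return Cells x GRN-genes matrix of expression shifts.
#' @export
simulate_shift <- function(grn, ds, spec, clamp = TRUE) {
  stopifnot(is(grn, "linear_grn"), is(spec, "perturbation_spec"))
  genes <- grn$genes
  tf <- spec$tf
  if (!tf %in% genes) stop("TF '", tf, "' is not in the GRN gene universe")
  X <- as.matrix(Matrix::t(.logcounts(ds)[genes, , drop = FALSE]))
  n <- nrow(X)
  out_deg <- sum(grn$edges$tf == tf)
  if (out_deg == 0L) {
    warning("TF '", tf, "' has no outgoing edges; shift confined to the TF")
  }

  delta0_tf <- spec$target_value - X[, tf]
  delta <- matrix(0, n, length(genes), dimnames = list(rownames(X), genes))
  delta[, tf] <- delta0_tf

  pop <- colData(ds)$population
  groups <- if (grn$stratify == "population" && !is.null(pop)) {
    split(seq_len(n), vapply(as.character(pop), function(p) {
      s <- grn$stratum_of_pop[p]
      if (is.na(s) || is.null(s)) "global" else s
    }, character(1)))
  } else {
    list(global = seq_len(n))
  }
  for (g in names(groups)) {
    rows <- groups[[g]]
    Ct <- Matrix::t(grn$coef[[g]])
    D <- delta[rows, , drop = FALSE]
    for (k in seq_len(spec$n_propagation)) {
      D <- as.matrix(D %*% Ct)
      D[, tf] <- delta0_tf[rows]
      if (clamp) D <- pmax(D, -X[rows, , drop = FALSE])
    }
    delta[rows, ] <- D
  }
  delta
}

#' Project an expression shift onto the embedding as a flow
#'
#' For each cell, the Pearson correlation between its shift vector and
#' the expression difference to each kNN neighbour (over the GRN genes)
#' is turned into transition probabilities by a temperature-scaled
#' softmax; the cell's flow vector is the probability-weighted mean of
#' unit vectors toward its neighbours, minus the uniform-neighbour mean
#' (drift correction). Cells with a zero (or constant) shift get a zero
#' vector.
#'
#' @param shift Cells x genes shift matrix from [simulate_shift()].
#' @param ds The dataset (supplies `logcounts` and the embedding).
#' @param graph A `cell_graph` built on the same cells.
#' @param kernel_scale Softmax temperature (default 0.05; smaller is
#'   closer to argmax).
#' @return Cells x 2 matrix of flow vectors.
#' @export
project_flow <- function(shift, ds, graph, kernel_scale = 0.05) {
  stopifnot(is(graph, "cell_graph"))
  if (!identical(rownames(shift), graph$cell_ids) &&
      nrow(shift) != length(graph$cell_ids)) {
    stop("graph was built on different cells than the shift matrix")
  }
  genes <- colnames(shift)
  X <- as.matrix(Matrix::t(.logcounts(ds)[genes, , drop = FALSE]))
  E <- .embedding(ds)
  n <- nrow(X)
  k <- graph$k
  V <- matrix(0, n, 2L, dimnames = list(rownames(E), c("x", "y")))
  for (i in seq_len(n)) {
    d <- shift[i, ]
    sd_d <- sd(d)
    if (!is.finite(sd_d) || sd_d == 0) next
    nb <- graph$knn_indices[i, ]
    D <- X[nb, , drop = FALSE] - matrix(X[i, ], k, ncol(X), byrow = TRUE)
    dc <- d - mean(d)
    Dc <- D - rowMeans(D)
    denom <- sqrt(sum(dc^2)) * sqrt(rowSums(Dc^2))
    cc <- as.vector(Dc %*% dc) / denom
    cc[!is.finite(cc)] <- 0
    p <- exp((cc - max(cc)) / kernel_scale)
    p <- p / sum(p)
    U <- E[nb, , drop = FALSE] - matrix(E[i, ], k, 2L, byrow = TRUE)
    len <- sqrt(rowSums(U^2))
    ok <- len > 0
    U[ok, ] <- U[ok, , drop = FALSE] / len[ok]
    U[!ok, ] <- 0
    V[i, ] <- colSums(p * U) - colMeans(U)
  }
  V
}

## assign cells to grid bins; returns list(bin index per cell, grid spec)
.grid_bins <- function(E, bins, min_occupancy) {
  xlim <- range(E[, 1L]); ylim <- range(E[, 2L])
  bx <- pmin(bins, 1L + floor((E[, 1L] - xlim[1]) / diff(xlim) * bins))
  by <- pmin(bins, 1L + floor((E[, 2L] - ylim[1]) / diff(ylim) * bins))
  list(bin = (by - 1L) * bins + bx, bx = bx, by = by,
       spec = list(bins = bins, xlim = xlim, ylim = ylim,
                   min_occupancy = min_occupancy))
}

#' Developmental flow from pseudotime
#'
#' Kernel-smooths pseudotime onto a square lattice over the embedding
#' bounding box (Gaussian weights with bandwidth `smooth_sigma`) and takes
#' the finite-difference gradient, pointing toward increasing pseudotime.
#' Grid points whose cell occupancy falls below `min_occupancy` carry no
#' vector.
#'
#' @param ds A `SingleCellExperiment` with an embedding and a
#'   `pseudotime` column in `colData`.
#' @param grid_bins Lattice resolution per axis (default 40).
#' @param smooth_sigma Gaussian bandwidth in embedding units; default 1.5
#'   grid cells.
#' @param min_occupancy Minimum cells per grid point (default 3).
#' @return A `dev_flow` with `grid` (occupied-point table: bin, x, y,
#'   occupancy), `vectors` (per occupied point), `pt_smooth`, and
#'   `grid_spec`.
#' @export
development_flow <- function(ds, grid_bins = 40L, smooth_sigma = NULL,
                             min_occupancy = 3L) {
  E <- .embedding(ds)
  pt <- colData(ds)$pseudotime
  if (is.null(pt)) stop("colData(ds)$pseudotime is required")
  gb <- .grid_bins(E, grid_bins, min_occupancy)
  occ <- tabulate(gb$bin, nbins = grid_bins^2)
  if (sum(occ > 0) < 2L) {
    stop("all cells fall into one grid bin; use a finer grid")
  }
  hx <- diff(gb$spec$xlim) / grid_bins
  hy <- diff(gb$spec$ylim) / grid_bins
  if (is.null(smooth_sigma)) smooth_sigma <- 1.5 * max(hx, hy)
  if (smooth_sigma <= 0) stop("smooth_sigma must be positive")

  cx <- gb$spec$xlim[1] + (seq_len(grid_bins) - 0.5) * hx
  cy <- gb$spec$ylim[1] + (seq_len(grid_bins) - 0.5) * hy
  ## smoothed pseudotime on the full lattice (rows = x index, cols = y)
  Kx <- outer(cx, E[, 1L], function(a, b) dnorm(a - b, sd = smooth_sigma))
  Ky <- outer(cy, E[, 2L], function(a, b) dnorm(a - b, sd = smooth_sigma))
  Kyp <- sweep(Ky, 2L, pt, "*")
  num <- Kx %*% base::t(Kyp)
  den <- Kx %*% base::t(Ky)
  pts <- num / den

  ## central-difference gradient with one-sided edges
  gx <- matrix(0, grid_bins, grid_bins)
  gy <- matrix(0, grid_bins, grid_bins)
  gx[2:(grid_bins - 1L), ] <-
    (pts[3:grid_bins, ] - pts[1:(grid_bins - 2L), ]) / (2 * hx)
  gx[1L, ] <- (pts[2L, ] - pts[1L, ]) / hx
  gx[grid_bins, ] <- (pts[grid_bins, ] - pts[grid_bins - 1L, ]) / hx
  gy[, 2:(grid_bins - 1L)] <-
    (pts[, 3:grid_bins] - pts[, 1:(grid_bins - 2L)]) / (2 * hy)
  gy[, 1L] <- (pts[, 2L] - pts[, 1L]) / hy
  gy[, grid_bins] <- (pts[, grid_bins] - pts[, grid_bins - 1L]) / hy

  keep <- which(occ >= min_occupancy)
  ix <- (keep - 1L) %% grid_bins + 1L
  iy <- (keep - 1L) %/% grid_bins + 1L
  grid <- data.frame(bin = keep, x = cx[ix], y = cy[iy],
                     occupancy = occ[keep])
  vectors <- cbind(x = gx[cbind(ix, iy)], y = gy[cbind(ix, iy)])
  vectors[!is.finite(vectors)] <- 0
  structure(
    list(grid = grid, vectors = vectors,
         pt_smooth = pts, grid_spec = gb$spec),
    class = "dev_flow"
  )
}

#' Perturbation scores on the grid and per lineage
#'
#' Averages per-cell perturbation-flow vectors within each occupied grid
#' point of the developmental flow's lattice; the perturbation score (PS)
#' of a grid point is the raw inner product of its aggregated perturbed
#' vector and the developmental vector. Each grid point is assigned the
#' majority lineage of its occupant cells, and the lineage PS is the mean
#' over that lineage's grid points. Positive PS: the perturbation promotes
#' differentiation along the lineage; negative: it reverses it.
#'
#' @param cell_vectors Cells x 2 flow from [project_flow()].
#' @param dev A `dev_flow` from [development_flow()] on the same cells.
#' @param ds The dataset (for the embedding).
#' @param lineage_of_cell Lineage label per cell.
#' @return A `flow_field` with `grid` (per occupied point: coordinates,
#'   occupancy, majority lineage, perturbed and developmental vectors,
#'   `ps`), `ps_per_lineage` (named means; lineages without an occupied
#'   grid point are `NA`), and `cell_vectors`.
#' @export
perturbation_score <- function(cell_vectors, dev, ds, lineage_of_cell) {
  stopifnot(is(dev, "dev_flow"))
  E <- .embedding(ds)
  if (nrow(cell_vectors) != nrow(E) ||
      length(lineage_of_cell) != nrow(E)) {
    stop("cell_vectors and lineage_of_cell must align with the cells")
  }
  spec <- dev$grid_spec
  gb <- .grid_bins(E, spec$bins, spec$min_occupancy)
  grid <- dev$grid
  vx <- tapply(cell_vectors[, 1L], gb$bin, mean)
  vy <- tapply(cell_vectors[, 2L], gb$bin, mean)
  maj <- tapply(as.character(lineage_of_cell), gb$bin, function(l) {
    tt <- sort(table(l), decreasing = TRUE)
    names(tt)[1L]
  })
  key <- as.character(grid$bin)
  grid$pvx <- unname(vx[key])
  grid$pvy <- unname(vy[key])
  grid$dvx <- dev$vectors[, 1L]
  grid$dvy <- dev$vectors[, 2L]
  grid$lineage <- unname(maj[key])
  grid$ps <- grid$pvx * grid$dvx + grid$pvy * grid$dvy
  lineages <- unique(as.character(lineage_of_cell))
  ps_lin <- vapply(lineages, function(l) {
    rows <- which(grid$lineage == l & is.finite(grid$ps))
    if (!length(rows)) return(NA_real_)
    mean(grid$ps[rows])
  }, numeric(1))
  missing <- lineages[is.na(ps_lin)]
  if (length(missing)) {
    message("lineage(s) without occupied grid points: ",
            paste(missing, collapse = ", "))
  }
  structure(
    list(grid = grid, ps_per_lineage = ps_lin,
         cell_vectors = cell_vectors, grid_spec = spec),
    class = "flow_field"
  )
}

#' @export
print.flow_field <- function(x, ...) {
  cat("flow_field:", nrow(x$grid), "occupied grid points; lineage PS:\n")
  print(round(x$ps_per_lineage, 4))
  invisible(x)
}

#' End-to-end perturbation run for one TF
#'
#' Convenience wrapper: builds the spec, simulates the shift, projects it
#' onto the embedding, and scores it against a developmental flow.
#'
#' @inheritParams simulate_shift
#' @inheritParams project_flow
#' @param tf TF gene id.
#' @param mode `"KI"` or `"KO"`.
#' @param dev A `dev_flow`; computed from `ds` when `NULL`.
#' @param n_propagation Propagation iterations.
#' @return A `flow_field`.
#' @export
perturb_tf <- function(grn, ds, graph, tf, mode = c("KI", "KO"),
                       dev = NULL, n_propagation = 3L,
                       kernel_scale = 0.05) {
  mode <- match.arg(mode)
  spec <- perturbation_spec(tf, mode, ds = ds, n_propagation = n_propagation)
  shift <- simulate_shift(grn, ds, spec)
  vec <- project_flow(shift, ds, graph, kernel_scale = kernel_scale)
  if (is.null(dev)) dev <- development_flow(ds)
  perturbation_score(vec, dev, ds, colData(ds)$lineage)
}
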