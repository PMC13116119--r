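## Graph-diffusion estimation of per-cell relative sample likelihood and
## response-mode classification.
##
## The estimator compares the manifold density of a post-exposure sample
## with the baseline sample on a shared cell-cell kNN graph: one-hot sample
## indicators are smoothed by repeated application of the graph's Markov
## operator, each smoothed signal is normalized to a density, and the
## relative likelihood of a cell is the post density's share at that cell.

#' Build a cell-cell kNN affinity graph
#'
#' Nearest neighbours are found in either the stored 2-D embedding or a
#' PCA of the log-normalized expression. Affinities use an adaptive
#' Gaussian kernel whose per-cell bandwidth is the distance to the
#' `ceiling(k/3)`-th neighbour; the affinity matrix is symmetrized by
#' averaging and row-normalized into a Markov transition matrix.
#'
#' @param ds A `SingleCellExperiment`; needs `logcounts` when
#'   `representation = "pca"`.
#' @param k Number of neighbours (default 30).
#' @param n_pcs Number of principal components for `representation="pca"`.
#' @param representation `"embedding"` (default) or `"pca"`.
#' @return A `cell_graph` with `knn_indices` (cells x k, no self-loops),
#'   `weights` (symmetric sparse affinity), `markov` (row-stochastic),
#'   `k`, `bandwidth_rule` and `cell_ids`.
#' @export
build_cell_graph <- function(ds, k = 30L, n_pcs = 30L,
                             representation = c("embedding", "pca")) {
  representation <- match.arg(representation)
  n <- ncol(ds)
  if (k >= n) stop("k (", k, ") must be smaller than the number of cells")
  X <- if (representation == "embedding") {
    .embedding(ds)
  } else {
    lc <- as.matrix(Matrix::t(.logcounts(ds)))
    rank <- min(n_pcs, ncol(lc), n - 1L)
    prcomp(lc, rank. = rank, center = TRUE, scale. = FALSE)$x
  }
  nn <- BiocNeighbors::findKNN(X, k = k)
  sigma <- nn$distance[, ceiling(k / 3)]
  sigma[sigma == 0] <- min(sigma[sigma > 0], 1e-8)
  aff <- exp(-(nn$distance / sigma)^2)
  W <- sparseMatrix(i = rep(seq_len(n), k), j = as.vector(nn$index),
                    x = as.vector(aff), dims = c(n, n))
  W <- (W + Matrix::t(W)) / 2
  P <- Diagonal(x = 1 / Matrix::rowSums(W)) %*% W
  structure(
    list(knn_indices = nn$index, weights = W, markov = P, k = k,
         bandwidth_rule = "adaptive_gaussian_k3",
         representation = representation,
         cell_ids = colnames(ds)),
    class = "cell_graph"
  )
}

#' @export
print.cell_graph <- function(x, ...) {
  cat("cell_graph:", length(x$cell_ids), "cells, k =", x$k,
      ", representation =", x$representation, "\n")
  invisible(x)
}

#' Relative likelihood of a post-exposure sample versus baseline
#'
#' Diffuses the one-hot indicators of the two samples over the graph
#' (`smoothing_steps` applications of the Markov matrix), normalizes each
#' smoothed signal to a density summing to 1 over cells, and returns
#' `l = dens_post / (dens_post + dens_baseline)` per cell. Cells where
#' both densities vanish (below 1e-12) get `l = 0.5`. Swapping the two
#' samples maps `l` to `1 - l` exactly.
#'
#' @param graph A `cell_graph`.
#' @param sample_of_cell Sample label per cell (aligned with the graph).
#' @param post,baseline The two sample labels to compare (must differ and
#'   both be present).
#' @param smoothing_steps Diffusion steps (default 10; 0 returns the raw
#'   indicator ratio).
#' @return A `relative_likelihood` with `values` in `[0, 1]` (named by
#'   cell), `comparison` and `smoothing_steps`.
#' @export
relative_likelihood <- function(graph, sample_of_cell, post, baseline,
                                smoothing_steps = 10L) {
  stopifnot(is(graph, "cell_graph"))
  n <- length(graph$cell_ids)
  if (length(sample_of_cell) != n) {
    stop("sample_of_cell must have one label per graph cell")
  }
  if (identical(post, baseline)) stop("post and baseline labels must differ")
  ind_p <- as.numeric(sample_of_cell == post)
  ind_b <- as.numeric(sample_of_cell == baseline)
  if (sum(ind_p) == 0) stop("no cells with post label '", post, "'")
  if (sum(ind_b) == 0) stop("no cells with baseline label '", baseline, "'")
  if (smoothing_steps < 0) stop("smoothing_steps must be >= 0")

  P <- graph$markov
  sp <- ind_p; sb <- ind_b
  for (i in seq_len(smoothing_steps)) {
    sp <- as.vector(P %*% sp)
    sb <- as.vector(P %*% sb)
  }
  dens_p <- sp / sum(sp)
  dens_b <- sb / sum(sb)
  tot <- dens_p + dens_b
  l <- ifelse(tot < 1e-12, 0.5, dens_p / tot)
  l[tot < 1e-12] <- 0.5
  names(l) <- graph$cell_ids
  structure(
    list(values = l, comparison = c(post = post, baseline = baseline),
         smoothing_steps = smoothing_steps),
    class = "relative_likelihood"
  )
}

#' Classify cells into down / N.S. / up response modes
#'
#' The fixed thresholds are authoritative: `l < t_down` is "down",
#' `l > t_up` is "up", anything else "N.S." (both inequalities strict). A
#' seeded 3-cluster k-means on `l` is fitted alongside and its ordered
#' centroids reported as a diagnostic concordance check only; it never
#' changes a label.
#'
#' @param rl A `relative_likelihood` (or a bare numeric vector in `[0,1]`).
#' @param t_down,t_up Mode thresholds (defaults 0.45 / 0.55;
#'   `t_down < t_up` required).
#' @param seed Seed for the diagnostic k-means.
#' @return A `response_modes` object with `mode` (factor levels
#'   down / N.S. / up), `thresholds` and `kmeans_centroids` (sorted;
#'   `NA` when fewer than 3 distinct values exist).
#' @export
assign_response_modes <- function(rl, t_down = 0.45, t_up = 0.55, seed = 1L) {
  l <- if (is(rl, "relative_likelihood")) rl$values else rl
  if (any(l < 0 | l > 1)) stop("relative likelihood values must lie in [0, 1]")
  if (t_down >= t_up) stop("t_down must be < t_up")
  mode <- factor(ifelse(l < t_down, "down", ifelse(l > t_up, "up", "N.S.")),
                 levels = c("down", "N.S.", "up"))
  names(mode) <- names(l)
  centroids <- rep(NA_real_, 3L)
  if (length(unique(l)) > 3L) {
    set.seed(seed)
    km <- tryCatch(kmeans(l, centers = 3L, nstart = 10L),
                   error = function(e) NULL)
    if (!is.null(km)) centroids <- sort(as.vector(km$centers))
  }
  structure(
    list(mode = mode, thresholds = c(t_down = t_down, t_up = t_up),
         kmeans_centroids = centroids),
    class = "response_modes"
  )
}

#' Summarize response modes per population and timepoint
#'
#' @param modes A `response_modes` object (or a factor/character vector of
#'   modes).
#' @param population,timepoint Labels aligned with the cells.
#' @return A data frame with one row per non-empty (population, timepoint)
#'   stratum: `frac_down`, `frac_ns`, `frac_up` (summing to 1) and
#'   `n_cells`.
#' @export
summarize_modes <- function(modes, population, timepoint) {
  m <- if (is(modes, "response_modes")) modes$mode else modes
  m <- factor(as.character(m), levels = c("down", "N.S.", "up"))
  if (length(m) != length(population) || length(m) != length(timepoint)) {
    stop("population and timepoint must align with the cells")
  }
  strata <- interaction(population, timepoint, drop = TRUE, sep = "\r")
  out <- do.call(rbind, lapply(levels(strata), function(s) {
    idx <- strata == s
    tab <- table(m[idx])
    parts <- strsplit(s, "\r", fixed = TRUE)[[1]]
    data.frame(population = parts[1], timepoint = parts[2],
               frac_down = unname(tab["down"]) / sum(idx),
               frac_ns = unname(tab["N.S."]) / sum(idx),
               frac_up = unname(tab["up"]) / sum(idx),
               n_cells = sum(idx), stringsAsFactors = FALSE)
  }))
  empty <- setdiff(
    as.vector(outer(unique(population), unique(timepoint), paste, sep = "\r")),
    levels(strata)
  )
  if (length(empty)) {
    message(length(empty), " empty population-timepoint strata omitted")
  }
  rownames(out) <- NULL
  out
}
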