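#' Column z-score with a zero-variance guard
#'
#' Standardizes each feature column of a cells-by-features matrix to mean 0
#' and unit standard deviation (population convention, i.e. dividing by the
#' root mean squared deviation, so `c(1, 2, 3)` maps to ±1.2247). Columns
#' with zero variance are mapped to all-zeros rather than `NaN`, so
#' downstream ranking and AUC computations never see non-finite values.
#'
#' @param x Numeric matrix, cells in rows, features in columns.
#' @param axis Standardization axis; only `"feature"` (per column) is
#'   supported.
#' @return A numeric matrix of the same dimensions and dimnames.
#' @examples
#' zscore_genes(cbind(a = c(1, 2, 3), b = c(5, 5, 5)))
#' @export
zscore_genes <- function(x, axis = c("feature")) {
  axis <- match.arg(axis)
  x <- as.matrix(x)
  if (nrow(x) < 2L) {
    stop("zscore_genes() needs at least 2 rows; got ", nrow(x))
  }
  mu <- colMeans(x)
  z <- sweep(x, 2L, mu, "-")
  sdv <- sqrt(colMeans(z^2))
  keep <- sdv > 0
  z[, keep] <- sweep(z[, keep, drop = FALSE], 2L, sdv[keep], "/")
  z[, !keep] <- 0
  z
}

## counts accessor tolerant of plain and sparse matrices
.counts <- function(ds) {
  stopifnot(is(ds, "SingleCellExperiment"))
  assay(ds, "counts")
}

.logcounts <- function(ds) {
  if (!"logcounts" %in% assayNames(ds)) {
    stop("dataset has no 'logcounts' assay; run lognormalize() first")
  }
  assay(ds, "logcounts")
}

.embedding <- function(ds) {
  if (!"embedding" %in% reducedDimNames(ds)) {
    stop("dataset has no 'embedding' in reducedDims")
  }
  reducedDim(ds, "embedding")
}

## deterministic descending ranking: ties broken by original (gene) order.
## Returns the rank position of every element.
.rank_desc <- function(x) {
  ord <- order(-x, seq_along(x))
  pos <- integer(length(x))
  pos[ord] <- seq_along(x)
  pos
}

.stop_if_not_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x >= 1) {
    stop(name, " must be a fraction in [0, 1); got ", x)
  }
}
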