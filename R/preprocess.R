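#' Filter low-quality cells
#'
#' Removes cells that have fewer than `min_genes` or more than `max_genes`
#' expressed genes (genes with count > 0), or more than `max_mito_frac` of
#' their UMIs from mitochondrial genes. All three rules are applied
#' simultaneously and tallied independently, so a cell failing two rules
#' contributes to both counters but is removed once. Boundaries are
#' inclusive on the retained side: exactly `min_genes` expressed genes or a
#' mitochondrial fraction of exactly `max_mito_frac` is retained.
#'
#' @param ds A `SingleCellExperiment` with a `counts` assay and an
#'   `is_mito` column in `rowData` (may be all-`FALSE`).
#' @param min_genes,max_genes Retained expressed-gene range (default
#'   500-5000).
#' @param max_mito_frac Maximum mitochondrial UMI fraction (default 0.20).
#' @return A list with `dataset` (the filtered object) and `report`, a
#'   `qc_report` with fields `n_input_cells`, `n_retained`,
#'   `n_failed_low_genes`, `n_failed_high_genes`, `n_failed_mito` and
#'   `thresholds`.
#' @examples
#' gt <- simulate_grn(seed = 1)
#' ds <- simulate_cells(gt, 60, "D0", n_background = 300, seed = 1)
#' res <- filter_cells(ds, min_genes = 50, max_genes = 400)
#' res$report
#' @export
filter_cells <- function(ds, min_genes = 500L, max_genes = 5000L,
                         max_mito_frac = 0.20) {
  cnt <- .counts(ds)
  if (is.null(rowData(ds)$is_mito)) {
    stop("rowData(ds)$is_mito is required (may be all FALSE)")
  }
  expressed <- Matrix::colSums(cnt > 0)
  total <- Matrix::colSums(cnt)
  mt <- rowData(ds)$is_mito
  mito_frac <- ifelse(total > 0,
                      Matrix::colSums(cnt[mt, , drop = FALSE]) / total, 0)

  fail_low <- expressed < min_genes
  fail_high <- expressed > max_genes
  fail_mito <- mito_frac > max_mito_frac
  keep <- !(fail_low | fail_high | fail_mito)
  if (!any(keep)) {
    stop("quality-control removed every cell; check thresholds (",
         min_genes, ", ", max_genes, ", ", max_mito_frac, ")")
  }
  report <- structure(
    list(n_input_cells = ncol(ds),
         n_retained = sum(keep),
         n_failed_low_genes = sum(fail_low),
         n_failed_high_genes = sum(fail_high),
         n_failed_mito = sum(fail_mito),
         thresholds = list(min_genes = min_genes, max_genes = max_genes,
                           max_mito_frac = max_mito_frac)),
    class = "qc_report"
  )
  list(dataset = ds[, keep], report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("qc_report:", x$n_retained, "/", x$n_input_cells, "cells retained\n")
  cat("  failed <", x$thresholds$min_genes, "genes:", x$n_failed_low_genes,
      "| >", x$thresholds$max_genes, "genes:", x$n_failed_high_genes,
      "| mito >", x$thresholds$max_mito_frac, ":", x$n_failed_mito, "\n")
  invisible(x)
}

#' Library-size log-normalization
#'
#' Adds a `logcounts` assay with
#' `log(1 + scale * counts[g, i] / total_counts[i])`, the monotone
#' variance-stabilized layer every downstream stage consumes.
#'
#' @param ds A `SingleCellExperiment` with a `counts` assay.
#' @param scale Library-size scale factor (default `1e4`).
#' @return The dataset with a `logcounts` assay added.
#' @export
lognormalize <- function(ds, scale = 1e4) {
  stopifnot(is.numeric(scale), scale > 0)
  cnt <- as(as(.counts(ds), "CsparseMatrix"), "generalMatrix")
  total <- Matrix::colSums(cnt)
  if (any(total == 0)) {
    bad <- colnames(ds)[total == 0]
    stop("cells with zero total counts cannot be normalized: ",
         paste(head(bad, 5), collapse = ", "),
         if (length(bad) > 5) " ..." else "")
  }
  norm <- cnt %*% Diagonal(x = scale / total)
  norm@x <- log1p(norm@x)
  dimnames(norm) <- dimnames(cnt)
  assay(ds, "logcounts") <- norm
  ds
}
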