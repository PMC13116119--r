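## Regulon inference and activity scoring.
##
## A regulon is a transcription factor together with its inferred target
## genes. Inference uses the magnitude of standardized ridge coefficients
## of each candidate target on all TFs jointly (optionally masked by a
## prior edge list); per-cell activity is the area under the recovery
## curve of the regulon's genes within the top fraction of that cell's
## expression ranking; specificity relates a regulon's activity
## distribution to a cell-type indicator via Jensen-Shannon divergence.

.new_regulon_set <- function(regulons, provenance) {
  regulons <- regulons[vapply(regulons, nrow, integer(1)) > 0L]
  structure(list(regulons = regulons, provenance = provenance),
            class = "regulon_set")
}

#' @export
print.regulon_set <- function(x, ...) {
  sizes <- vapply(x$regulons, nrow, integer(1))
  cat("regulon_set (", x$provenance, "): ", length(sizes), " regulons, ",
      sum(sizes), " edges\n", sep = "")
  invisible(x)
}

#' Build a regulon set from ground-truth GRN weights
#'
#' @param truth A `ground_truth` from [simulate_grn()].
#' @return A `regulon_set` with provenance `"ground_truth"` holding every
#'   nonzero true edge.
#' @export
regulons_from_truth <- function(truth) {
  stopifnot(is(truth, "ground_truth"))
  W <- truth$grn_weights
  regs <- lapply(rownames(W), function(tf) {
    nz <- which(W[tf, ] != 0)
    data.frame(target = colnames(W)[nz], weight = unname(W[tf, nz]),
               stringsAsFactors = FALSE)
  })
  names(regs) <- rownames(W)
  .new_regulon_set(regs, "ground_truth")
}

#' Infer TF-target co-expression modules
#'
#' For every non-TF gene, fits a ridge regression of its standardized
#' log-normalized expression on all standardized TF expressions jointly;
#' the per-TF importance of the gene is the magnitude of the standardized
#' coefficient. Edges with importance at or above `min_importance` (and,
#' if supplied, present in `prior_edges`) are kept; each TF's retained
#' targets form its regulon. TFs left without targets are dropped with a
#' warning.
#'
#' @param ds A `SingleCellExperiment` with `logcounts`.
#' @param tf_list Character vector of TF gene ids (subset of the genes).
#' @param prior_edges Optional data frame with columns `tf` and `target`
#'   restricting the admissible edges (the motif-prior stand-in).
#' @param min_importance Minimum absolute standardized coefficient (default 0.25, a moderate standardized effect).
#' @param ridge_alpha Ridge penalty (default 1).
#' @return A `regulon_set` with provenance `"inferred"` (or `"prior"` when
#'   a prior mask was applied); edge `weight` is the signed standardized
#'   coefficient.
#' @export
infer_modules <- function(ds, tf_list, prior_edges = NULL,
                          min_importance = 0.25, ridge_alpha = 1) {
  if (length(tf_list) == 0L) stop("tf_list must not be empty")
  missing <- setdiff(tf_list, rownames(ds))
  if (length(missing)) {
    stop("TFs not in the dataset: ", paste(head(missing, 5), collapse = ", "))
  }
  lc <- .logcounts(ds)
  X <- zscore_genes(as.matrix(Matrix::t(lc[tf_list, , drop = FALSE])))
  genes <- setdiff(rownames(ds), tf_list)
  Y <- zscore_genes(as.matrix(Matrix::t(lc[genes, , drop = FALSE])))
  ## batch ridge: coefficients of every gene on all TFs at once
  XtX <- crossprod(X) + diag(ridge_alpha, ncol(X))
  B <- solve(XtX, crossprod(X, Y)) # TFs x genes
  rownames(B) <- tf_list

  allowed <- abs(B) >= min_importance
  if (!is.null(prior_edges)) {
    stopifnot(all(c("tf", "target") %in% names(prior_edges)))
    mask <- matrix(FALSE, length(tf_list), length(genes),
                   dimnames = list(tf_list, genes))
    pe <- prior_edges[prior_edges$tf %in% tf_list &
                        prior_edges$target %in% genes, ]
    mask[cbind(pe$tf, pe$target)] <- TRUE
    allowed <- allowed & mask
  }
  regs <- lapply(tf_list, function(tf) {
    nz <- which(allowed[tf, ])
    data.frame(target = genes[nz], weight = unname(B[tf, nz]),
               stringsAsFactors = FALSE)
  })
  names(regs) <- tf_list
  dropped <- tf_list[vapply(regs, nrow, integer(1)) == 0L]
  if (length(dropped)) {
    warning("TFs with empty regulons dropped: ",
            paste(dropped, collapse = ", "))
  }
  .new_regulon_set(regs, if (is.null(prior_edges)) "inferred" else "prior")
}

#' Per-cell regulon activity (recovery-curve AUC)
#'
#' For each cell, genes are ranked by log-normalized expression in
#' descending order (ties broken by fixed gene order). The activity of a
#' regulon is the area under its recovery curve — the number of regulon
#' genes found among the top `r` ranks, accumulated for
#' `r = 1 .. ceiling(top_frac * n_genes)` — divided by
#' `regulon_size * cutoff`, so a regulon entirely outside the cutoff
#' scores 0 and one occupying ranks `1..m` scores
#' `1 - (m - 1) / (2 * cutoff)`.
#'
#' @param ds A `SingleCellExperiment` with `logcounts`.
#' @param regs A `regulon_set`; all regulon genes must be in the dataset.
#' @param top_frac Fraction of the ranking used as cutoff (default 0.05).
#' @return An `activity_matrix` with `auc` (cells x regulons in `[0,1]`),
#'   `zauc` (per-regulon z-scored) and `top_frac`.
#' @export
aucell_scores <- function(ds, regs, top_frac = 0.05) {
  stopifnot(is(regs, "regulon_set"))
  if (!(top_frac > 0 && top_frac < 1)) stop("top_frac must be in (0, 1)")
  if (length(regs$regulons) == 0L) stop("regulon set is empty")
  lc <- as.matrix(.logcounts(ds))
  genes <- rownames(ds)
  cutoff <- as.integer(ceiling(top_frac * length(genes)))
  reg_idx <- lapply(regs$regulons, function(df) {
    idx <- match(df$target, genes)
    if (anyNA(idx)) {
      stop("regulon genes absent from the dataset: ",
           paste(head(df$target[is.na(idx)], 5), collapse = ", "))
    }
    idx
  })
  sizes <- lengths(reg_idx)
  if (any(sizes == 0L)) stop("empty regulon in the set")
  if (any(sizes > cutoff)) {
    warning("regulons larger than the rank cutoff (", cutoff, "): ",
            paste(names(which(sizes > cutoff)), collapse = ", "))
  }
  n_cells <- ncol(lc)
  auc <- matrix(0, n_cells, length(reg_idx),
                dimnames = list(colnames(ds), names(reg_idx)))
  for (i in seq_len(n_cells)) {
    pos <- .rank_desc(lc[, i])
    for (r in seq_along(reg_idx)) {
      p <- pos[reg_idx[[r]]]
      auc[i, r] <- sum(pmax(0L, cutoff - p + 1L)) / (sizes[r] * cutoff)
    }
  }
  structure(list(auc = auc, zauc = zscore_genes(auc), top_frac = top_frac),
            class = "activity_matrix")
}

#' @export
print.activity_matrix <- function(x, ...) {
  cat("activity_matrix:", nrow(x$auc), "cells x", ncol(x$auc),
      "regulons (top_frac =", x$top_frac, ")\n")
  invisible(x)
}

## Jensen-Shannon divergence in bits between two probability vectors
.jsd_bits <- function(p, q) {
  m <- (p + q) / 2
  kl <- function(a, b) {
    nz <- a > 0
    sum(a[nz] * log2(a[nz] / b[nz]))
  }
  ## clamp away floating-point drift outside the theoretical [0, 1] range
  min(1, max(0, (kl(p, m) + kl(q, m)) / 2))
}

#' Regulon specificity scores
#'
#' For regulon `R` and cell type `C`, the activity vector and the type
#' indicator are each normalized to probability distributions over cells;
#' the score is `1 - sqrt(JSD)` with the Jensen-Shannon divergence in bits
#' (base-2, bounded by 1). A regulon whose activity exactly matches the
#' indicator scores 1; disjoint support scores 0.
#'
#' @param act An `activity_matrix` (the raw `auc` layer is used).
#' @param cell_type Cell-type label per cell (at least 2 types).
#' @return An `rss_matrix`: cell-types x regulons matrix in `[0, 1]`.
#' @export
regulon_specificity <- function(act, cell_type) {
  stopifnot(is(act, "activity_matrix"))
  auc <- act$auc
  if (length(cell_type) != nrow(auc)) {
    stop("cell_type must have one label per cell")
  }
  types <- sort(unique(as.character(cell_type)))
  if (length(types) < 2L) stop("at least 2 cell types are required")
  zero <- colSums(auc) == 0
  if (any(zero)) {
    stop("all-zero activity; RSS undefined for regulon(s): ",
         paste(colnames(auc)[zero], collapse = ", "))
  }
  p_reg <- sweep(auc, 2L, colSums(auc), "/")
  rss <- matrix(NA_real_, length(types), ncol(auc),
                dimnames = list(types, colnames(auc)))
  for (ct in types) {
    q <- as.numeric(cell_type == ct)
    q <- q / sum(q)
    rss[ct, ] <- apply(p_reg, 2L, function(p) 1 - sqrt(.jsd_bits(p, q)))
  }
  structure(list(rss = rss), class = "rss_matrix")
}

#' @export
print.rss_matrix <- function(x, ...) {
  cat("rss_matrix:", nrow(x$rss), "cell types x", ncol(x$rss), "regulons\n")
  invisible(x)
}

#' Select top cell-type marker regulons
#'
#' @param rss An `rss_matrix`.
#' @param n_top Regulons per cell type (default 10, the standard marker
#'   count; must not exceed the number of regulons).
#' @return Named list mapping each cell type to its `n_top` regulon (TF)
#'   names by descending RSS, ties broken lexicographically.
#' @export
select_markers <- function(rss, n_top = 10L) {
  stopifnot(is(rss, "rss_matrix"))
  m <- rss$rss
  if (n_top > ncol(m)) stop("n_top exceeds the number of regulons")
  out <- lapply(rownames(m), function(ct) {
    v <- m[ct, ]
    colnames(m)[order(-v, colnames(m))][seq_len(n_top)]
  })
  setNames(out, rownames(m))
}

#' Filter a regulon's edges with a Gaussian mixture model
#'
#' Fits an `n_components` Gaussian mixture to the magnitudes of the
#' regulon's edge weights and retains the edges whose posterior
#' probability of belonging to the highest-mean component exceeds 0.5.
#' Zero-variance (or otherwise degenerate) weight sets retain every edge
#' with a warning.
#'
#' @param regs A `regulon_set`.
#' @param tf The TF whose regulon to filter (needs at least
#'   `2 * n_components` edges).
#' @param n_components Mixture components (default 2).
#' @param seed Seed (the EM fit is deterministic, kept for interface
#'   stability).
#' @return Data frame of retained edges: `target`, `weight`,
#'   `posterior_high`.
#' @export
filter_edges_gmm <- function(regs, tf, n_components = 2L, seed = 1L) {
  stopifnot(is(regs, "regulon_set"))
  if (!tf %in% names(regs$regulons)) stop("no regulon for TF '", tf, "'")
  df <- regs$regulons[[tf]]
  if (nrow(df) < 2L * n_components) {
    stop("regulon of '", tf, "' needs at least ", 2L * n_components,
         " edges for a ", n_components, "-component mixture")
  }
  w <- abs(df$weight)
  if (sd(w) == 0) {
    warning("degenerate (zero-variance) weights for '", tf,
            "': all edges retained")
    df$posterior_high <- 1
    return(df)
  }
  set.seed(seed)
  ## Mclust resolves mclustBIC in the calling frame; bind it locally so the
  ## fit works without attaching mclust
  mclustBIC <- mclust::mclustBIC
  fit <- tryCatch(mclust::Mclust(w, G = n_components, verbose = FALSE),
                  error = function(e) NULL)
  if (is.null(fit)) {
    warning("mixture fit failed for '", tf, "': all edges retained")
    df$posterior_high <- 1
    return(df)
  }
  high <- which.max(fit$parameters$mean)
  post <- fit$z[, high]
  out <- df[post > 0.5, , drop = FALSE]
  out$posterior_high <- post[post > 0.5]
  rownames(out) <- NULL
  out
}

#' Export a marker-regulon network
#'
#' Writes the directed, weighted TF-target graph of the marker regulons.
#' Nodes carry a `role` attribute (`"tf"` or `"target"`) and, for TFs,
#' their mean z-scored activity; GraphML round-trips through standard
#' graph readers, SIF uses one `"TF regulates target"` line per edge.
#'
#' @param regs A `regulon_set`.
#' @param markers Marker map from [select_markers()] (or a character
#'   vector of TFs); all must have regulons.
#' @param act An `activity_matrix` supplying mean zAUC per TF (optional
#'   for SIF).
#' @param path Output file path.
#' @param format `"graphml"` or `"sif"`.
#' @return The path, invisibly.
#' @export
export_network <- function(regs, markers, act = NULL, path,
                           format = c("graphml", "sif")) {
  format <- match.arg(format)
  stopifnot(is(regs, "regulon_set"))
  tfs <- unique(unlist(markers, use.names = FALSE))
  missing <- setdiff(tfs, names(regs$regulons))
  if (length(missing)) {
    stop("markers without regulons: ", paste(missing, collapse = ", "))
  }
  edges <- do.call(rbind, lapply(tfs, function(tf) {
    df <- regs$regulons[[tf]]
    data.frame(from = tf, to = df$target, weight = df$weight,
               stringsAsFactors = FALSE)
  }))
  if (format == "sif") {
    writeLines(paste(edges$from, "regulates", edges$to), path)
    return(invisible(path))
  }
  nodes <- data.frame(name = unique(c(edges$from, edges$to)),
                      stringsAsFactors = FALSE)
  nodes$role <- ifelse(nodes$name %in% tfs, "tf", "target")
  nodes$mean_zauc <- 0
  if (!is.null(act)) {
    mz <- colMeans(act$zauc)
    hit <- nodes$name %in% names(mz)
    nodes$mean_zauc[hit] <- mz[nodes$name[hit]]
  }
  g <- igraph::graph_from_data_frame(edges, directed = TRUE,
                                     vertices = nodes)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
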