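## Adaptive sliding-window smoothing of TF activity along pseudotime.
##
## Cells are ordered by (lineage-wise min-max normalized) pseudotime and
## partitioned into fixed-size windows. The step between consecutive
## window starts begins at a default cell spacing and is adapted so the
## pseudotime distance between starts falls inside a target interval:
## in dense regions the step inflates to avoid near-duplicate windows,
## in sparse regions it shrinks (to a single cell if necessary) to avoid
## abrupt jumps.

#' Min-max normalize pseudotime per lineage
#'
#' @param pt Numeric pseudotime per cell.
#' @param scope Lineage label per cell; normalization is independent per
#'   lineage (each attains 0 and 1).
#' @return Numeric vector in `[0, 1]`.
#' @export
normalize_pseudotime <- function(pt, scope = rep("all", length(pt))) {
  if (length(pt) != length(scope)) stop("pt and scope must align")
  out <- numeric(length(pt))
  for (lin in unique(scope)) {
    idx <- scope == lin
    rng <- range(pt[idx])
    if (diff(rng) == 0) {
      stop("constant pseudotime in lineage '", lin, "'; cannot normalize")
    }
    out[idx] <- (pt[idx] - rng[1]) / diff(rng)
  }
  names(out) <- names(pt)
  out
}

#' Sliding-window smoothing of TF activity along pseudotime
#'
#' Sorts cells by normalized pseudotime and emits windows of exactly
#' `window` cells. From a window start `i` the candidate step is `step0`
#' cells; if the pseudotime distance to the candidate next start is below
#' `interval[1]` the step is increased to the smallest step reaching it,
#' and if above `interval[2]` decreased to the largest step within it
#' (falling back to a single cell when even that overshoots). Iteration
#' stops when a full window no longer fits.
#'
#' @param zauc Cells-by-TF matrix of z-scored activity.
#' @param pt_norm Normalized pseudotime per cell, in `[0, 1]`.
#' @param window Cells per window (default 300).
#' @param step0 Default cell spacing between window starts (default 100).
#' @param interval Admissible pseudotime distance between consecutive
#'   window starts, `c(d_min, d_max)` (default `c(0.03, 0.06)`).
#' @param lineage,condition Labels carried through to the result.
#' @return A `dynamic_activity` with `window_means` (windows x TF),
#'   `window_pseudotime` (per-window mean, strictly increasing),
#'   `window_start_pt` (pseudotime at each window's start cell),
#'   `step_cells` (realized steps), `window_size`, `interval`, `lineage`
#'   and `condition`.
#' @export
sliding_window_activity <- function(zauc, pt_norm, window = 300L,
                                    step0 = 100L,
                                    interval = c(0.03, 0.06),
                                    lineage = NA_character_,
                                    condition = NA_character_) {
  zauc <- as.matrix(zauc)
  n <- nrow(zauc)
  if (length(pt_norm) != n) stop("pt_norm must align with zauc rows")
  if (window < 1L) stop("window must be >= 1")
  if (n < window) {
    stop("only ", n, " cells but window = ", window,
         "; use a smaller window")
  }
  if (any(pt_norm < 0 | pt_norm > 1)) stop("pt_norm must lie in [0, 1]")
  if (interval[1] >= interval[2]) stop("interval must satisfy d_min < d_max")
  d_min <- interval[1]; d_max <- interval[2]

  ord <- order(pt_norm)
  pt <- pt_norm[ord]
  z <- zauc[ord, , drop = FALSE]

  starts <- integer(0)
  steps <- integer(0)
  i <- 1L
  repeat {
    starts <- c(starts, i)
    s <- step0
    if (i + s <= n) {
      d <- pt[i + s] - pt[i]
      if (d < d_min) {
        cand <- which(pt[(i + 1L):n] - pt[i] >= d_min)
        s <- if (length(cand)) cand[1L] else n - i + 1L
      } else if (d > d_max) {
        cand <- which(pt[(i + 1L):n] - pt[i] <= d_max)
        s <- if (length(cand)) max(cand) else 1L
      }
    } else {
      s <- n - i + 1L
    }
    i <- i + s
    if (i + window - 1L > n) break
    steps <- c(steps, s)
  }
  wm <- do.call(rbind, lapply(starts, function(st) {
    colMeans(z[st:(st + window - 1L), , drop = FALSE])
  }))
  rownames(wm) <- paste0("w", seq_along(starts))
  structure(
    list(window_means = wm,
         window_pseudotime = vapply(starts, function(st) {
           mean(pt[st:(st + window - 1L)])
         }, numeric(1)),
         window_start_pt = pt[starts],
         step_cells = steps,
         window_size = window, step0 = step0, interval = interval,
         lineage = lineage, condition = condition),
    class = "dynamic_activity"
  )
}

#' @export
print.dynamic_activity <- function(x, ...) {
  cat("dynamic_activity:", nrow(x$window_means), "windows x",
      ncol(x$window_means), "TFs (window =", x$window_size, ")\n")
  invisible(x)
}

#' Select lineage transcription factors by maximum RSS
#'
#' Scores every regulon by its maximum RSS over the cell types that make
#' up a lineage (e.g. GM = MPP3 and GMP) and returns the top `n_top`.
#'
#' @param rss An `rss_matrix`.
#' @param lineage_types Cell types defining the lineage (subset of the RSS
#'   rows, non-empty).
#' @param n_top TFs to return (default 30).
#' @return Character vector of TF names by descending score, ties broken
#'   lexicographically.
#' @export
select_lineage_tfs <- function(rss, lineage_types, n_top = 30L) {
  stopifnot(is(rss, "rss_matrix"))
  if (length(lineage_types) == 0L) stop("lineage_types must not be empty")
  missing <- setdiff(lineage_types, rownames(rss$rss))
  if (length(missing)) {
    stop("cell types not in the RSS matrix: ",
         paste(missing, collapse = ", "))
  }
  score <- apply(rss$rss[lineage_types, , drop = FALSE], 2L, max)
  n_top <- min(n_top, length(score))
  names(score)[order(-score, names(score))][seq_len(n_top)]
}

#' Compare a TF's dynamic activity between two conditions
#'
#' Returns both window series on their own normalized-pseudotime
#' coordinates (no interpolation) together with each condition's overall
#' mean and the mean difference.
#'
#' @param da_a,da_b `dynamic_activity` objects from the same lineage.
#' @param tf TF present in both.
#' @return A list with `table` (long data frame: condition, window,
#'   pseudotime, activity), `mean_a`, `mean_b`, `mean_difference`
#'   (`mean_a - mean_b`).
#' @export
compare_conditions <- function(da_a, da_b, tf) {
  stopifnot(is(da_a, "dynamic_activity"), is(da_b, "dynamic_activity"))
  if (!identical(da_a$lineage, da_b$lineage)) {
    stop("conditions come from different lineages: ",
         da_a$lineage, " vs ", da_b$lineage)
  }
  for (da in list(da_a, da_b)) {
    if (!tf %in% colnames(da$window_means)) {
      stop("TF '", tf, "' absent from a condition's activity matrix")
    }
  }
  row_of <- function(da) {
    data.frame(condition = da$condition,
               window = seq_len(nrow(da$window_means)),
               pseudotime = da$window_pseudotime,
               activity = da$window_means[, tf],
               stringsAsFactors = FALSE, row.names = NULL)
  }
  tab <- rbind(row_of(da_a), row_of(da_b))
  mean_a <- mean(da_a$window_means[, tf])
  mean_b <- mean(da_b$window_means[, tf])
  list(table = tab, mean_a = mean_a, mean_b = mean_b,
       mean_difference = mean_a - mean_b)
}

#' Rank-based single-sample gene-set score per cell
#'
#' A single-sample enrichment statistic: per cell, genes are ranked by
#' log-normalized expression (descending, ties by gene order) and the
#' score is the sum over ranks of the difference between the weighted
#' cumulative hit fraction (weights `(n_genes - rank + 1)^weight_exponent`)
#' and the uniform cumulative miss fraction. Cells whose set genes sit at
#' the very top of the ranking attain the maximal score.
#'
#' @param ds A `SingleCellExperiment` with `logcounts`.
#' @param gene_set Character vector of gene ids; genes absent from the
#'   dataset are dropped with a warning (an empty effective set errors).
#' @param weight_exponent Rank-weight exponent (default 0.25).
#' @return Named numeric score per cell.
#' @seealso [summarize_population_scores()] for the population-level
#'   z-scored summary.
#' @export
gene_set_score <- function(ds, gene_set, weight_exponent = 0.25) {
  lc <- as.matrix(.logcounts(ds))
  genes <- rownames(ds)
  present <- intersect(gene_set, genes)
  if (length(present) < length(gene_set)) {
    warning(length(gene_set) - length(present),
            " gene-set genes absent from the dataset; dropped")
  }
  if (length(present) == 0L) stop("no gene-set genes present in the dataset")
  G <- length(genes)
  member <- genes %in% present
  n_miss <- G - sum(member)
  scores <- vapply(seq_len(ncol(lc)), function(i) {
    pos <- .rank_desc(lc[, i])
    ord_member <- logical(G)
    ord_member[pos[member]] <- TRUE
    w <- (G - seq_len(G) + 1)^weight_exponent
    w[!ord_member] <- 0
    p_hit <- cumsum(w) / sum(w)
    p_miss <- cumsum(!ord_member) / n_miss
    sum(p_hit - p_miss)
  }, numeric(1))
  setNames(scores, colnames(ds))
}

#' Population-level summary of per-cell scores
#'
#' Averages a per-cell score within each (population, timepoint) stratum
#' and then z-scores across timepoints within each population, so every
#' population's temporal profile has mean 0 and unit variance
#' (zero-variance profiles map to 0).
#'
#' @param scores Named numeric per-cell score.
#' @param population,timepoint Labels aligned with the cells.
#' @return Matrix populations x timepoints of z-scored mean scores
#'   (timepoints ordered as first encountered).
#' @export
summarize_population_scores <- function(scores, population, timepoint) {
  stopifnot(length(scores) == length(population),
            length(scores) == length(timepoint))
  pops <- unique(as.character(population))
  tps <- unique(as.character(timepoint))
  m <- matrix(NA_real_, length(pops), length(tps),
              dimnames = list(pops, tps))
  for (p in pops) for (tp in tps) {
    idx <- population == p & timepoint == tp
    if (any(idx)) m[p, tp] <- mean(scores[idx])
  }
  t(apply(m, 1L, function(v) {
    ok <- !is.na(v)
    if (sum(ok) >= 2L && sd(v[ok]) > 0) {
      v[ok] <- (v[ok] - mean(v[ok])) / sd(v[ok])
    } else {
      v[ok] <- 0
    }
    v
  }))
}

#' Read gene sets from a GMT file
#'
#' @param path Path to a tab-separated GMT file (set name, description,
#'   genes...).
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(fields, function(f) f[-c(1L, 2L)])
  names(sets) <- vapply(fields, `[`, character(1), 1L)
  sets
}
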