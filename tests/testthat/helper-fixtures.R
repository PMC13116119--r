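## Shared fixtures and independent oracles. Everything is generated in
## code at test time; the medium simulation is cached per test run.

suppressPackageStartupMessages({
  library(SingleCellExperiment)
  library(Matrix)
})

.fixture_cache <- new.env(parent = emptyenv())

## one medium synthetic dataset (~2000 cells) shared across test files
shared_sim <- function() {
  if (!exists("sim", envir = .fixture_cache)) {
    gt <- simulate_grn(seed = 42)
    ds <- lognormalize(simulate_cells(gt, n_cells_per_timepoint = 334,
                                      seed = 42))
    assign("sim", list(gt = gt, ds = ds), envir = .fixture_cache)
  }
  get("sim", envir = .fixture_cache)
}

## regulons, activity and RSS inferred from the shared simulation
shared_activity <- function() {
  if (!exists("act", envir = .fixture_cache)) {
    sim <- shared_sim()
    regs <- infer_modules(sim$ds, rownames(sim$gt$grn_weights))
    act <- aucell_scores(sim$ds, regs)
    rss <- regulon_specificity(act, sim$ds$population)
    assign("act", list(regs = regs, act = act, rss = rss),
           envir = .fixture_cache)
  }
  get("act", envir = .fixture_cache)
}

## build a SingleCellExperiment from a cells-by-genes matrix of
## "normalized" values (logcounts = the matrix, counts = rounded copy)
sce_from_norm <- function(norm_cells_by_genes, embedding = NULL,
                          meta = NULL) {
  m <- base::t(as.matrix(norm_cells_by_genes))
  if (is.null(rownames(m))) rownames(m) <- paste0("g", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- paste0("c", seq_len(ncol(m)))
  sce <- SingleCellExperiment(
    assays = list(counts = Matrix(round(pmax(m, 0)), sparse = TRUE),
                  logcounts = Matrix(m, sparse = TRUE)),
    rowData = DataFrame(gene_id = rownames(m),
                        is_mito = grepl("^mt-", rownames(m)),
                        row.names = rownames(m))
  )
  if (!is.null(embedding)) {
    rownames(embedding) <- colnames(sce)
    reducedDim(sce, "embedding") <- embedding
  }
  if (!is.null(meta)) {
    for (nm in names(meta)) colData(sce)[[nm]] <- meta[[nm]]
  }
  sce
}

## brute-force recovery-curve AUC: walk the ranking step by step
auc_oracle <- function(expr, regulon_positions_in_gene_order, cutoff) {
  ord <- order(-expr, seq_along(expr))
  in_reg <- seq_along(expr) %in% regulon_positions_in_gene_order
  hits_at_rank <- cumsum(in_reg[ord])
  sum(hits_at_rank[seq_len(cutoff)]) /
    (length(regulon_positions_in_gene_order) * cutoff)
}

## brute-force GSEA enrichment score: explicit running sum
gsea_es_oracle <- function(stats_named, gene_set, weight_exponent = 1) {
  ord <- order(-stats_named, seq_along(stats_named))
  s <- stats_named[ord]
  member <- names(s) %in% gene_set
  m <- sum(member)
  G <- length(s)
  w_hit <- abs(s)^weight_exponent
  sum_w <- sum(w_hit[member])
  running <- 0
  maxP <- -Inf
  minP <- Inf
  for (i in seq_len(G)) {
    running <- running +
      if (member[i]) {
        if (sum_w > 0) w_hit[i] / sum_w else 1 / m
      } else {
        -1 / (G - m)
      }
    if (running > maxP) maxP <- running
    if (running < minP) minP <- running
  }
  ## same extreme-selection rule as the implementation contract:
  ## larger magnitude wins, exact ties resolve positive
  unname(if (maxP + minP >= -1e-12) maxP else minP)
}

## analytic base-2 Jensen-Shannon divergence between two prob vectors
jsd_oracle <- function(p, q) {
  m <- (p + q) / 2
  kl <- function(a, b) sum(ifelse(a > 0, a * log2(a / b), 0))
  (kl(p, m) + kl(q, m)) / 2
}

## wrap a plain cells x regulons activity matrix in the class the RSS and
## marker functions expect
as_activity <- function(auc, top_frac = 0.05) {
  structure(list(auc = auc, zauc = zscore_genes(auc), top_frac = top_frac),
            class = "activity_matrix")
}

## minimal regulon_set from a named list of data.frame(target, weight)
as_regulon_set <- function(regs, provenance = "prior") {
  structure(list(regulons = regs, provenance = provenance),
            class = "regulon_set")
}
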