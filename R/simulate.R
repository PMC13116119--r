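## Synthetic single-cell data with a known regulatory ground truth.
##
## The generator emulates a bone-marrow HSPC compartment profiled at a
## homeostatic baseline (D0) and five post-exposure timepoints
## (D1, D3, D7, D14, D21): eight progenitor subpopulations, three branching
## lineages (ME, GM, LY) with pseudotime, timepoint-dependent abundance
## shifts, and target-gene expression causally driven by transcription
## factors through a known weighted GRN under negative-binomial count noise.

.default_timepoints <- c("D0", "D1", "D3", "D7", "D14", "D21")

## Canonical population pairs (progenitor, committed) per lineage label.
.canonical_pops <- list(
  ME = c("MPP2", "MEP"),
  GM = c("MPP3", "GMP"),
  LY = c("MPP4", "CLP")
)

## Relative abundance trajectories over D0..D21, baseline = 1. Chosen once
## to mirror the compartment's published temporal remodeling: HSC/MPP
## depletion, a synchronized committed-progenitor burst at D1, MEP/CLP
## dip-and-recover, and a persistent GMP expansion from D3 onward.
.abundance_profiles <- list(
  `LT-HSC`   = c(1, 1.0, 0.50, 0.40, 0.35, 0.30),
  `ST-HSC`   = c(1, 0.6, 0.45, 0.40, 0.35, 0.30),
  progenitor = c(1, 0.6, 0.50, 0.45, 0.40, 0.40),
  MEP        = c(1, 2.0, 0.50, 0.80, 1.20, 1.00),
  GMP        = c(1, 2.0, 3.00, 3.50, 4.00, 4.50),
  CLP        = c(1, 2.0, 0.50, 0.70, 1.00, 1.20),
  committed  = c(1, 2.0, 0.50, 0.80, 1.20, 1.00)
)

#' Simulate a ground-truth gene regulatory network
#'
#' Builds the `ground_truth` object that drives [simulate_cells()]: a signed
#' TF-by-target weight matrix with one dedicated driver TF per lineage
#' wired positively onto a disjoint lineage-specific target block, plus
#' random signed background edges at the requested density, a population
#' roster (two root populations and a progenitor/committed pair per
#' lineage), and a population-by-timepoint abundance-multiplier table
#' (baseline timepoint = 1).
#'
#' @param n_tfs Number of transcription factors (must be at least the
#'   number of lineages; the first `length(lineages)` TFs are the drivers).
#' @param n_targets Number of GRN target genes, split into equal
#'   lineage-specific blocks.
#' @param lineages Character vector of lineage labels. The canonical
#'   `c("ME","GM","LY")` get their standard population names
#'   (MPP2/MEP, MPP3/GMP, MPP4/CLP).
#' @param density Probability of a background (non-driver) signed edge for
#'   each remaining TF-target pair, in (0, 1].
#' @param seed Integer seed; identical seeds give identical networks.
#' @return A `ground_truth` list with elements `grn_weights` (TF x target),
#'   `driver_map`, `target_block`, `lineages`, `populations`,
#'   `pop_lineage`, `pop_stage`, `timepoints`, `abundance_multiplier`
#'   and `seed`.
#' @examples
#' gt <- simulate_grn(n_tfs = 6, n_targets = 30, seed = 1)
#' gt$driver_map
#' @export
simulate_grn <- function(n_tfs = 9L, n_targets = 90L,
                         lineages = c("ME", "GM", "LY"),
                         density = 0.1, seed = 1L) {
  n_lin <- length(lineages)
  if (n_tfs < n_lin) {
    stop("n_tfs (", n_tfs, ") must be >= number of lineages (", n_lin, ")")
  }
  if (!(density >= 0 && density <= 1)) stop("density must be in [0, 1]")
  set.seed(seed)

  tfs <- paste0("TF", seq_len(n_tfs))
  targets <- paste0("G", seq_len(n_targets))
  driver_map <- setNames(tfs[seq_len(n_lin)], lineages)

  block_size <- n_targets %/% n_lin
  target_block <- lapply(seq_len(n_lin), function(i) {
    targets[seq.int((i - 1L) * block_size + 1L, i * block_size)]
  })
  names(target_block) <- lineages

  W <- matrix(0, n_tfs, n_targets, dimnames = list(tfs, targets))
  for (lin in lineages) {
    blk <- target_block[[lin]]
    W[driver_map[[lin]], blk] <- runif(length(blk), 1.2, 2.0)
  }
  ## background edges: signed, moderate magnitude, never overwriting a
  ## driver edge
  free <- W == 0
  draw <- matrix(runif(n_tfs * n_targets) < density, n_tfs, n_targets) & free
  n_bg <- sum(draw)
  if (n_bg > 0L) {
    W[draw] <- runif(n_bg, 0.2, 0.5) * sample(c(-1, 1), n_bg, replace = TRUE)
  }

  ## population roster: two root populations plus a progenitor/committed
  ## pair per lineage
  pops <- c("LT-HSC", "ST-HSC")
  pop_lineage <- c(`LT-HSC` = NA_character_, `ST-HSC` = NA_character_)
  pop_stage <- c(`LT-HSC` = "root", `ST-HSC` = "root")
  for (lin in lineages) {
    pair <- if (lin %in% names(.canonical_pops)) {
      .canonical_pops[[lin]]
    } else {
      c(paste0("MPP_", lin), paste0("P_", lin))
    }
    pops <- c(pops, pair)
    pop_lineage[pair] <- lin
    pop_stage[pair] <- c("progenitor", "committed")
  }

  tp <- .default_timepoints
  mult <- matrix(NA_real_, length(pops), length(tp),
                 dimnames = list(pops, tp))
  for (p in pops) {
    prof <- if (p %in% names(.abundance_profiles)) {
      .abundance_profiles[[p]]
    } else if (pop_stage[[p]] == "progenitor") {
      .abundance_profiles$progenitor
    } else {
      .abundance_profiles$committed
    }
    mult[p, ] <- prof
  }

  structure(
    list(grn_weights = W, driver_map = as.list(driver_map),
         target_block = target_block, lineages = lineages,
         populations = pops, pop_lineage = pop_lineage,
         pop_stage = pop_stage, timepoints = tp,
         abundance_multiplier = mult, seed = seed),
    class = "ground_truth"
  )
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("ground_truth GRN:", nrow(x$grn_weights), "TFs x",
      ncol(x$grn_weights), "targets;",
      sum(x$grn_weights != 0), "edges\n")
  cat("lineages:", paste(x$lineages, collapse = ", "),
      "| drivers:", paste(unlist(x$driver_map), collapse = ", "), "\n")
  invisible(x)
}

## pseudotime range per population stage; committed populations reach the
## branch tip, roots sit near the origin
.stage_pt_range <- list(
  root = c(0.00, 0.20),
  progenitor = c(0.25, 0.70),
  committed = c(0.55, 1.00)
)

## driver activation curve: low baseline everywhere, linear rise with
## pseudotime inside the driver's own lineage
.driver_mu <- function(pt, in_lineage, base = 0.2, amp = 5.0) {
  base + ifelse(in_lineage, amp * pt, 0)
}

#' Simulate cells from a ground-truth network
#'
#' Draws a cells-by-genes count matrix at each requested timepoint. Cells
#' are allocated to populations by a multinomial draw with probabilities
#' proportional to the abundance multipliers; each cell gets a lineage
#' (root populations are split evenly across lineages), a true pseudotime
#' drawn within its population's stage range, TF mean expression following
#' lineage- and pseudotime-dependent activation curves, and target means
#' given by a clamped-linear function of the TF means through the true GRN.
#' Counts are negative binomial; a block of unregulated background genes
#' and a small mitochondrial gene set give realistic per-cell complexity.
#' The 2-D embedding is a deterministic branch layout (root at origin,
#' one fixed angle per lineage, radius proportional to pseudotime) plus
#' Gaussian jitter.
#'
#' @param truth A `ground_truth` from [simulate_grn()].
#' @param n_cells_per_timepoint Cells drawn at each timepoint (>= 50).
#' @param timepoints Timepoints to simulate; must be columns of
#'   `truth$abundance_multiplier`.
#' @param noise_dispersion Negative-binomial size parameter (`size` in
#'   [stats::rnbinom()]); larger is less overdispersed, `Inf` gives the
#'   Poisson limit. Must be positive.
#' @param n_background Number of unregulated background genes.
#' @param embed_jitter Standard deviation of the embedding jitter.
#' @param seed Integer seed; identical seeds give bit-identical output.
#' @return A [SingleCellExperiment::SingleCellExperiment] with a `counts`
#'   assay (genes x cells), `colData` columns `cell_id`, `sample_id`,
#'   `timepoint`, `population`, `lineage`, `pseudotime`, a `reducedDim`
#'   named `"embedding"`, and `rowData` columns `gene_id`, `gene_type`
#'   and `is_mito`.
#' @examples
#' gt <- simulate_grn(seed = 1)
#' ds <- simulate_cells(gt, n_cells_per_timepoint = 60,
#'                      timepoints = "D0", n_background = 50, seed = 1)
#' table(ds$population)
#' @export
simulate_cells <- function(truth, n_cells_per_timepoint = 500L,
                           timepoints = truth$timepoints,
                           noise_dispersion = 8, n_background = 1500L,
                           embed_jitter = 0.6, seed = 1L) {
  stopifnot(is(truth, "ground_truth"))
  if (n_cells_per_timepoint < 50L) {
    stop("n_cells_per_timepoint must be >= 50")
  }
  if (!is.numeric(noise_dispersion) || noise_dispersion <= 0) {
    stop("noise_dispersion must be positive")
  }
  missing_tp <- setdiff(timepoints, colnames(truth$abundance_multiplier))
  if (length(missing_tp)) {
    stop("timepoints not in the abundance table: ",
         paste(missing_tp, collapse = ", "))
  }
  set.seed(seed)

  W <- truth$grn_weights
  tfs <- rownames(W)
  targets <- colnames(W)
  lineages <- truth$lineages
  pops <- truth$populations

  ## per-cell population / lineage / pseudotime
  meta <- do.call(rbind, lapply(timepoints, function(tp) {
    m <- truth$abundance_multiplier[, tp]
    alloc <- as.vector(rmultinom(1L, n_cells_per_timepoint, m / sum(m)))
    data.frame(timepoint = tp,
               population = rep(pops, alloc),
               stringsAsFactors = FALSE)
  }))
  n <- nrow(meta)
  stage <- truth$pop_stage[meta$population]
  lin <- truth$pop_lineage[meta$population]
  root <- is.na(lin)
  ## root cells are the shared trajectory origin: split evenly by draw
  lin[root] <- sample(lineages, sum(root), replace = TRUE)
  lo <- vapply(.stage_pt_range[stage], `[`, numeric(1), 1L)
  hi <- vapply(.stage_pt_range[stage], `[`, numeric(1), 2L)
  pt <- runif(n, lo, hi)

  ## TF means: drivers follow the activation curve of their lineage;
  ## other TFs vary by population (fixed lognormal draw per TF x pop)
  mu_tf <- matrix(0, n, length(tfs), dimnames = list(NULL, tfs))
  for (l in lineages) {
    d <- truth$driver_map[[l]]
    mu_tf[, d] <- .driver_mu(pt, lin == l)
  }
  other <- setdiff(tfs, unlist(truth$driver_map))
  if (length(other)) {
    pop_mu <- matrix(exp(rnorm(length(other) * length(pops), -0.2, 0.5)),
                     length(other), length(pops),
                     dimnames = list(other, pops))
    mu_tf[, other] <- Matrix::t(pop_mu[, meta$population, drop = FALSE])
  }

  ## target means: clamped-linear link through the true GRN
  mu_tg <- pmax(mu_tf %*% W + 0.3, 0)

  ## background + mitochondrial genes
  bg <- if (n_background > 0L) paste0("B", seq_len(n_background)) else character()
  mu_bg <- exp(rnorm(n_background, log(0.8), 0.8))
  mito <- c("mt-Nd1", "mt-Nd2", "mt-Co1", "mt-Co2", "mt-Co3",
            "mt-Atp6", "mt-Cytb", "mt-Nd4", "mt-Rnr1", "mt-Rnr2")
  mu_mt <- runif(length(mito), 4, 10)

  mu <- cbind(mu_tf, mu_tg,
              matrix(mu_bg, n, n_background, byrow = TRUE),
              matrix(mu_mt, n, length(mito), byrow = TRUE))
  genes <- c(tfs, targets, bg, mito)
  colnames(mu) <- genes

  counts <- if (is.finite(noise_dispersion)) {
    matrix(rnbinom(length(mu), mu = as.vector(mu), size = noise_dispersion),
           n, ncol(mu))
  } else {
    matrix(stats::rpois(length(mu), as.vector(mu)), n, ncol(mu))
  }
  dimnames(counts) <- list(NULL, genes)
  ## shuffle gene order so deterministic rank tie-breaks carry no
  ## systematic relationship to the planted signal (feature files of real
  ## runs are not ordered by biology either)
  gene_type <- rep(c("tf", "target", "background", "mito"),
                   c(length(tfs), length(targets), n_background,
                     length(mito)))
  gene_perm <- sample(length(genes))
  counts <- counts[, gene_perm, drop = FALSE]
  genes <- genes[gene_perm]
  gene_type <- gene_type[gene_perm]

  ## deterministic branch layout: fixed angle per lineage, radius ~ pt
  angle <- setNames(2 * pi * (seq_along(lineages) - 1L) / length(lineages) +
                      pi / 2, lineages)
  radius <- 10
  emb <- cbind(
    x = radius * pt * cos(angle[lin]) + rnorm(n, 0, embed_jitter),
    y = radius * pt * sin(angle[lin]) + rnorm(n, 0, embed_jitter)
  )

  cell_id <- sprintf("cell_%05d", seq_len(n))
  rownames(emb) <- cell_id
  cd <- DataFrame(
    cell_id = cell_id,
    sample_id = paste0("S_", meta$timepoint),
    timepoint = meta$timepoint,
    population = meta$population,
    lineage = unname(lin),
    pseudotime = pt,
    row.names = cell_id
  )
  rd <- DataFrame(
    gene_id = genes,
    gene_type = gene_type,
    is_mito = genes %in% mito,
    row.names = genes
  )
  sce <- SingleCellExperiment(
    assays = list(counts = Matrix::t(Matrix(counts, sparse = TRUE))),
    colData = cd, rowData = rd
  )
  reducedDim(sce, "embedding") <- emb
  metadata(sce)$simulation <- list(seed = seed,
                                   noise_dispersion = noise_dispersion,
                                   n_cells_per_timepoint = n_cells_per_timepoint,
                                   timepoints = timepoints)
  sce
}

#' Inject QC-violating cells into a dataset
#'
#' Rewrites the count profiles of randomly chosen, disjoint cell subsets so
#' that each violates exactly one quality-control rule: fewer than
#' `min_genes` expressed genes, more than `max_genes` expressed genes, or a
#' mitochondrial UMI fraction above `mito_frac`. The injected class of
#' every cell is recorded in `colData(ds)$qc_injected`
#' (`"none"`, `"low_genes"`, `"high_genes"` or `"mito"`).
#'
#' @param ds A `SingleCellExperiment` with a `counts` assay.
#' @param frac_low,frac_high,frac_mito Fractions of cells (in `[0, 1)`,
#'   summing to < 1) to convert into each violation class.
#' @param min_genes,max_genes,mito_frac QC thresholds the violations are
#'   constructed against (defaults are the standard 500 / 5000 / 20%).
#' @param seed Integer seed controlling which cells are flagged.
#' @return The modified dataset.
#' @export
inject_mito_and_outliers <- function(ds, frac_low = 0, frac_high = 0,
                                     frac_mito = 0, min_genes = 500L,
                                     max_genes = 5000L, mito_frac = 0.2,
                                     seed = 1L) {
  .stop_if_not_fraction(frac_low, "frac_low")
  .stop_if_not_fraction(frac_high, "frac_high")
  .stop_if_not_fraction(frac_mito, "frac_mito")
  if (frac_low + frac_high + frac_mito >= 1) {
    stop("violation fractions must sum to < 1")
  }
  if (nrow(ds) < 10L) {
    stop("dataset has fewer than 10 genes; cannot construct QC violations")
  }
  n <- ncol(ds)
  n_low <- round(frac_low * n)
  n_high <- round(frac_high * n)
  n_mito <- round(frac_mito * n)
  if (n_high > 0L && nrow(ds) <= max_genes) {
    stop("cannot construct >", max_genes, " expressed-gene violations: ",
         "dataset has only ", nrow(ds), " genes")
  }
  if (n_mito > 0L && !any(rowData(ds)$is_mito)) {
    stop("cannot construct mitochondrial violations: no is_mito genes")
  }
  set.seed(seed)
  picked <- sample(n, n_low + n_high + n_mito)
  idx_low <- picked[seq_len(n_low)]
  idx_high <- picked[n_low + seq_len(n_high)]
  idx_mito <- picked[n_low + n_high + seq_len(n_mito)]

  cnt <- as(.counts(ds), "CsparseMatrix")
  dense <- as.matrix(cnt)

  keep_n <- max(1L, min_genes %/% 2L)
  for (i in idx_low) {
    x <- dense[, i]
    keep <- head(order(-x, seq_along(x)), keep_n)
    x[-keep] <- 0
    dense[, i] <- x
  }
  for (i in idx_high) {
    dense[, i] <- pmax(dense[, i], 1)
  }
  mt <- rowData(ds)$is_mito
  target_frac <- min(0.95, 1.5 * mito_frac)
  for (i in idx_mito) {
    non_mt_total <- sum(dense[!mt, i])
    need <- ceiling(target_frac / (1 - target_frac) * max(non_mt_total, 1))
    per_gene <- ceiling(need / sum(mt))
    dense[mt, i] <- per_gene
  }

  assay(ds, "counts") <- Matrix(dense, sparse = TRUE)
  flag <- rep("none", n)
  flag[idx_low] <- "low_genes"
  flag[idx_high] <- "high_genes"
  flag[idx_mito] <- "mito"
  colData(ds)$qc_injected <- flag
  ds
}
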