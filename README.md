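# hspcflow

Regulatory dynamics and in silico transcription-factor perturbation in
stressed hematopoietic progenitors.

## What this package is for

After an acute insult such as total-body irradiation, the bone-marrow
hematopoietic stem and progenitor cell (HSPC) compartment remodels: some
subpopulations collapse, others — classically the granulocyte–macrophage
progenitors (GMP) — expand, and the transcription-factor (TF) programs
steering the megakaryocyte–erythroid (ME), granulocyte–macrophage (GM)
and lymphoid (LY) lineages shift. `hspcflow` provides, as composable R
functions on a `SingleCellExperiment`, the computational workflow for
analyzing such a time course (baseline D0 plus post-exposure timepoints)
and for screening TFs in silico:

* **Response modes** — a per-cell relative likelihood
  `ℓ = dens_post / (dens_post + dens_baseline)` of a post-exposure sample
  versus baseline, estimated by diffusing sample indicators over a kNN
  cell graph (adaptive Gaussian kernel, row-stochastic Markov operator),
  classified *down* (ℓ < 0.45) / *N.S.* / *up* (ℓ > 0.55).
* **Regulons** — TF→target modules from standardized ridge regression;
  per-cell activity as the area under the regulon's recovery curve within
  the top 5% of each cell's expression ranking (AUC); regulon specificity
  scores `RSS = 1 − √JSD₂(p_regulon, p_celltype)`; Gaussian-mixture edge
  filtering; GraphML/SIF export.
* **Dynamic activity** — sliding windows of 300 cells along per-lineage
  min–max-normalized pseudotime, with an adaptive step (initially 100
  cells) constrained so consecutive window starts are 0.03–0.06
  pseudotime apart; top-30 lineage TFs by maximum RSS.
* **Enrichment** — a rank-based single-sample gene-set score with
  population × timepoint z-scored summaries, and preranked GSEA (weighted
  Kolmogorov–Smirnov ES, gene-label permutation null, BH FDR).
* **In silico perturbation** — knock-out (TF pinned to 0) or knock-in
  (pinned to `max(1, 2 × 95th percentile)` of observed expression) on a
  ridge-fitted linear GRN, iterative signal propagation, projection of
  the expression shift onto the embedding as a flow field, and a
  perturbation score `PS = ⟨perturbed flow, developmental flow⟩` per
  lineage — positive PS means the perturbation pushes cells along that
  lineage's differentiation direction.

A seeded synthetic-data generator (`simulate_grn()`, `simulate_cells()`)
with a known ground-truth GRN, branching lineages, pseudotime and
timepoint-dependent abundance shifts makes the entire chain testable
end to end; `run_pipeline()` orchestrates all stages from a validated
configuration and writes every artifact plus a manifest.

## Worked example

```r
library(hspcflow)

gt <- simulate_grn(seed = 1)          # ground truth: drivers TF1 (ME), TF2 (GM), TF3 (LY)
ds <- simulate_cells(gt, n_cells_per_timepoint = 334, seed = 1)

qc <- filter_cells(ds)                # 500/5000 expressed genes, 20% mito
print(qc$report)
#> qc_report: 2004 / 2004 cells retained
#>   failed < 500 genes: 0 | > 5000 genes: 0 | mito > 0.2 : 0

ds    <- lognormalize(qc$dataset)
graph <- build_cell_graph(ds, k = 30)
rl    <- relative_likelihood(graph, ds$timepoint, post = "D3", baseline = "D0")
modes <- assign_response_modes(rl)    # thresholds 0.45 / 0.55
keep  <- ds$timepoint %in% c("D0", "D3")
summarize_modes(modes$mode[keep], ds$population[keep], ds$timepoint[keep])
#>    population timepoint frac_down frac_ns frac_up n_cells
#> 9         CLP        D3     0.522  0.4783   0.000      23
#> 10        GMP        D3     0.000  0.0192   0.981     156
#> 12        MEP        D3     1.000  0.0000   0.000      28
```

The generator plants a persistent GMP expansion from D3 on and an
MEP/CLP contraction; the likelihood estimator reads exactly that out of
the counts: 98% of D3 GMP cells are "up", every D3 MEP cell is "down".

```r
regs <- infer_modules(ds, rownames(gt$grn_weights))
act  <- aucell_scores(ds, regs)
rss  <- regulon_specificity(act, ds$population)
select_markers(rss, n_top = 3)$GMP
#> [1] "TF2" "TF1" "TF3"                    # the planted GM driver ranks first

grn <- fit_linear_grn(ds, gt)             # ridge fit on the true edge mask
dev <- development_flow(ds)               # pseudotime gradient on a 40x40 grid
perturb_tf(grn, ds, graph, "TF2", mode = "KI", dev = dev)
#> flow_field: 230 occupied grid points; lineage PS:
#>      LY      GM      ME
#> -0.0042  0.0089 -0.0051
```

Knock-in of the GM driver yields a positive perturbation score on the GM
lineage only — in-silico promotion of granulocyte–macrophage
differentiation — and knock-out (mode `"KO"`) flips the sign.

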