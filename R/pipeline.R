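## Configuration and end-to-end orchestration: simulate (or read) ->
## QC -> normalize -> graph -> relative likelihood & response modes ->
## regulons -> dynamics -> in silico perturbation, writing every
## intermediate artifact plus a manifest.

#' Default pipeline configuration
#'
#' All stage parameters with their standard values: QC thresholds
#' 500 / 5000 / 20% mitochondrial, response-mode thresholds 0.45 / 0.55,
#' graph k = 30 with 10 smoothing steps, AUC top fraction 0.05 with
#' top-10 markers, window 300 / step 100 / pseudotime interval
#' 0.03-0.06 with top-30 lineage TFs, ridge alpha 1, grid 40 with
#' 3 propagation iterations, and the canonical lineage definitions
#' (ME: MPP2+MEP, GM: MPP3+GMP, LY: MPP4+CLP).
#'
#' @return Nested named list of parameters.
#' @export
default_config <- function() {
  list(
    simulate = list(n_tfs = 9L, n_targets = 90L, n_cells_per_timepoint = 500L,
                    density = 0.1, noise_dispersion = 8, n_background = 1500L,
                    seed = 1L),
    qc = list(min_genes = 500L, max_genes = 5000L, max_mito_frac = 0.20),
    normalize = list(scale = 1e4),
    graph = list(k = 30L, n_pcs = 30L, representation = "embedding"),
    abundance = list(baseline = "D0", smoothing_steps = 10L,
                     t_down = 0.45, t_up = 0.55, seed = 1L),
    regulons = list(top_frac = 0.05, min_importance = 0.25, n_top_markers = 10L),
    dynamics = list(window = 300L, step0 = 100L,
                    interval = c(0.03, 0.06), n_top_tfs = 30L),
    perturbation = list(ridge_alpha = 1, n_propagation = 3L,
                        grid_bins = 40L, min_occupancy = 3L,
                        kernel_scale = 0.05, tfs = NULL, modes = c("KI", "KO")),
    lineages = list(ME = c("MPP2", "MEP"), GM = c("MPP3", "GMP"),
                    LY = c("MPP4", "CLP")),
    paths = list(input = NULL, out = NULL)
  )
}

.check_range <- function(value, name, lo = -Inf, hi = Inf,
                         strict_lo = FALSE, strict_hi = FALSE) {
  bad <- if (strict_lo) value <= lo else value < lo
  bad <- bad | if (strict_hi) value >= hi else value > hi
  if (any(bad)) stop("config: ", name, " out of range [", lo, ", ", hi, "]")
}

#' Validate and complete a pipeline configuration
#'
#' Unknown keys (at the section or parameter level) are an error rather
#' than silently ignored; missing parameters are filled from
#' [default_config()] and reported.
#'
#' @param config Possibly partial nested list (e.g. from a YAML file via
#'   [yaml::read_yaml()]); `NULL` or empty gives the full defaults.
#' @param quiet Suppress the filled-defaults message.
#' @return The completed, validated configuration.
#' @export
validate_config <- function(config = list(), quiet = FALSE) {
  defaults <- default_config()
  if (is.null(config)) config <- list()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown)) {
    stop("unknown config section(s): ", paste(unknown, collapse = ", "))
  }
  filled <- character(0)
  out <- defaults
  for (sec in names(defaults)) {
    if (!sec %in% names(config)) {
      filled <- c(filled, sec)
      next
    }
    if (sec %in% c("lineages", "paths")) {
      out[[sec]] <- config[[sec]]
      next
    }
    unknown_par <- setdiff(names(config[[sec]]), names(defaults[[sec]]))
    if (length(unknown_par)) {
      stop("unknown config key(s) in '", sec, "': ",
           paste(unknown_par, collapse = ", "))
    }
    for (par in names(defaults[[sec]])) {
      if (par %in% names(config[[sec]])) {
        out[[sec]][[par]] <- config[[sec]][[par]]
      } else {
        filled <- c(filled, paste0(sec, "$", par))
      }
    }
  }
  with(out$qc, {
    .check_range(min_genes, "qc$min_genes", 0)
    if (min_genes >= max_genes) stop("config: qc min_genes >= max_genes")
    .check_range(max_mito_frac, "qc$max_mito_frac", 0, 1)
  })
  if (out$abundance$t_down >= out$abundance$t_up) {
    stop("config: abundance t_down must be < t_up")
  }
  .check_range(out$regulons$top_frac, "regulons$top_frac", 0, 1,
               strict_lo = TRUE, strict_hi = TRUE)
  if (out$dynamics$window < 1L) stop("config: dynamics window must be >= 1")
  if (out$dynamics$step0 < 1L) stop("config: dynamics step0 must be >= 1")
  iv <- out$dynamics$interval
  if (length(iv) != 2L || iv[1] >= iv[2]) {
    stop("config: dynamics interval must be (d_min, d_max) with d_min < d_max")
  }
  .check_range(out$perturbation$n_propagation, "perturbation$n_propagation", 1)
  if (length(filled) && !quiet) {
    message("config defaults filled: ", paste(filled, collapse = ", "))
  }
  out
}

#' Run the full workflow
#'
#' Executes simulate (or load) -> QC -> log-normalization -> cell graph ->
#' relative likelihood and response modes per post-baseline timepoint ->
#' regulon inference, activity, RSS and markers -> sliding-window dynamic
#' activity per lineage -> in silico KI/KO of the chosen TFs with
#' perturbation scores per lineage. Every table is written as CSV/JSON
#' under `out_dir` together with a `manifest.json` recording the complete
#' configuration and seeds; a rerun from the manifest reproduces every
#' artifact.
#'
#' @param config Configuration (validated via [validate_config()]).
#' @param out_dir Output directory; overrides `config$paths$out`.
#' @return Invisible list with the main in-memory results (`dataset`,
#'   `qc_report`, `modes`, `activity`, `rss`, `markers`, `dynamics`,
#'   `ps_table`, `truth`).
#' @export
run_pipeline <- function(config = list(), out_dir = NULL) {
  cfg <- validate_config(config, quiet = TRUE)
  if (!is.null(out_dir)) cfg$paths$out <- out_dir
  out <- cfg$paths$out
  if (is.null(out)) stop("an output directory is required (paths$out)")
  dir.create(out, showWarnings = FALSE, recursive = TRUE)

  stage <- "simulate"
  res <- tryCatch({
    ## --- input ---------------------------------------------------------
    if (is.null(cfg$paths$input)) {
      truth <- simulate_grn(n_tfs = cfg$simulate$n_tfs,
                            n_targets = cfg$simulate$n_targets,
                            lineages = names(cfg$lineages),
                            density = cfg$simulate$density,
                            seed = cfg$simulate$seed)
      ds <- simulate_cells(truth,
                           n_cells_per_timepoint =
                             cfg$simulate$n_cells_per_timepoint,
                           noise_dispersion = cfg$simulate$noise_dispersion,
                           n_background = cfg$simulate$n_background,
                           seed = cfg$simulate$seed)
    } else {
      loaded <- read_fixture(cfg$paths$input)
      ds <- loaded$dataset
      truth <- loaded$truth
    }
    message("[simulate] ", nrow(ds), " genes x ", ncol(ds), " cells")

    stage <- "qc"
    qc <- filter_cells(ds, cfg$qc$min_genes, cfg$qc$max_genes,
                       cfg$qc$max_mito_frac)
    ds <- qc$dataset
    jsonlite::write_json(unclass(qc$report),
                         file.path(out, "qc_report.json"),
                         auto_unbox = TRUE, digits = NA)
    message("[qc] retained ", ncol(ds), " cells")

    stage <- "normalize"
    ds <- lognormalize(ds, scale = cfg$normalize$scale)

    stage <- "graph"
    graph <- build_cell_graph(ds, k = cfg$graph$k, n_pcs = cfg$graph$n_pcs,
                              representation = cfg$graph$representation)
    message("[graph] k = ", cfg$graph$k)

    stage <- "abundance"
    base_tp <- cfg$abundance$baseline
    tps <- setdiff(unique(ds$timepoint), base_tp)
    mode_rows <- list()
    lik_rows <- list()
    for (tp in tps) {
      rl <- relative_likelihood(graph, ds$timepoint, post = tp,
                                baseline = base_tp,
                                smoothing_steps = cfg$abundance$smoothing_steps)
      rm_ <- assign_response_modes(rl, cfg$abundance$t_down,
                                   cfg$abundance$t_up,
                                   seed = cfg$abundance$seed)
      keep <- ds$timepoint %in% c(tp, base_tp)
      lik_rows[[tp]] <- data.frame(cell_id = colnames(ds),
                                   comparison = tp,
                                   likelihood = unname(rl$values),
                                   mode = as.character(rm_$mode))
      mode_rows[[tp]] <- cbind(comparison = tp,
                               summarize_modes(rm_$mode[keep],
                                               ds$population[keep],
                                               ds$timepoint[keep]))
    }
    lik_tab <- do.call(rbind, lik_rows)
    mode_tab <- do.call(rbind, mode_rows)
    write.csv(lik_tab, file.path(out, "relative_likelihood.csv"),
              row.names = FALSE)
    write.csv(mode_tab, file.path(out, "response_modes.csv"),
              row.names = FALSE)
    message("[abundance] ", length(tps), " comparisons vs ", base_tp)

    stage <- "regulons"
    tf_list <- if (!is.null(truth)) rownames(truth$grn_weights) else {
      rownames(ds)[rowData(ds)$gene_type == "tf"]
    }
    regs <- infer_modules(ds, tf_list,
                          min_importance = cfg$regulons$min_importance)
    act <- aucell_scores(ds, regs, top_frac = cfg$regulons$top_frac)
    rss <- regulon_specificity(act, ds$population)
    markers <- select_markers(rss, n_top = min(cfg$regulons$n_top_markers,
                                               ncol(rss$rss)))
    reg_tab <- do.call(rbind, lapply(names(regs$regulons), function(tf) {
      data.frame(tf = tf, regs$regulons[[tf]])
    }))
    write.table(reg_tab, file.path(out, "regulons.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.csv(data.frame(cell_type = rownames(rss$rss),
                         as.data.frame(rss$rss), check.names = FALSE),
              file.path(out, "rss.csv"), row.names = FALSE)
    jsonlite::write_json(markers, file.path(out, "markers.json"))
    export_network(regs, markers, act,
                   file.path(out, "network.graphml"), format = "graphml")
    message("[regulons] ", length(regs$regulons), " regulons")

    stage <- "dynamics"
    dyn_rows <- list()
    n_top_tfs <- min(cfg$dynamics$n_top_tfs, ncol(rss$rss))
    for (lin in names(cfg$lineages)) {
      lin_types <- intersect(cfg$lineages[[lin]], rownames(rss$rss))
      if (!length(lin_types)) next
      tfs_lin <- select_lineage_tfs(rss, lin_types, n_top = n_top_tfs)
      in_lin <- ds$lineage == lin & !is.na(ds$pseudotime)
      if (sum(in_lin) < cfg$dynamics$window) {
        message("[dynamics] lineage ", lin, " has too few cells; skipped")
        next
      }
      ptn <- normalize_pseudotime(ds$pseudotime[in_lin])
      da <- sliding_window_activity(
        act$zauc[in_lin, tfs_lin, drop = FALSE], ptn,
        window = cfg$dynamics$window, step0 = cfg$dynamics$step0,
        interval = cfg$dynamics$interval, lineage = lin, condition = "all"
      )
      dyn_rows[[lin]] <- do.call(rbind, lapply(tfs_lin, function(tf) {
        data.frame(lineage = lin, tf = tf,
                   window = seq_len(nrow(da$window_means)),
                   pseudotime = da$window_pseudotime,
                   mean_zauc = da$window_means[, tf])
      }))
    }
    dyn_tab <- do.call(rbind, dyn_rows)
    if (!is.null(dyn_tab)) {
      write.csv(dyn_tab, file.path(out, "dynamic_activity.csv"),
                row.names = FALSE)
    }
    message("[dynamics] ", length(dyn_rows), " lineages windowed")

    stage <- "perturbation"
    base <- if (!is.null(truth)) truth else regs
    grn <- fit_linear_grn(ds, base, ridge_alpha = cfg$perturbation$ridge_alpha)
    dev <- development_flow(ds, grid_bins = cfg$perturbation$grid_bins,
                            min_occupancy = cfg$perturbation$min_occupancy)
    perturb_tfs <- cfg$perturbation$tfs
    if (is.null(perturb_tfs)) {
      perturb_tfs <- if (!is.null(truth)) unlist(truth$driver_map) else
        head(names(regs$regulons), 3L)
    }
    ps_rows <- list()
    for (tf in perturb_tfs) for (md in cfg$perturbation$modes) {
      ff <- perturb_tf(grn, ds, graph, tf, mode = md, dev = dev,
                       n_propagation = cfg$perturbation$n_propagation,
                       kernel_scale = cfg$perturbation$kernel_scale)
      ps_rows[[paste(tf, md)]] <- data.frame(
        tf = tf, mode = md,
        lineage = names(ff$ps_per_lineage),
        ps = unname(ff$ps_per_lineage), row.names = NULL
      )
    }
    ps_tab <- do.call(rbind, ps_rows)
    rownames(ps_tab) <- NULL
    write.csv(ps_tab, file.path(out, "perturbation_scores.csv"),
              row.names = FALSE)
    message("[perturbation] ", length(perturb_tfs), " TFs x ",
            length(cfg$perturbation$modes), " modes")

    manifest <- list(package_version = as.character(utils::packageVersion("hspcflow")),
                     config = cfg,
                     artifacts = list.files(out))
    jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    list(dataset = ds, qc_report = qc$report, likelihood = lik_tab,
         modes = mode_tab, regulons = regs, activity = act, rss = rss,
         markers = markers, dynamics = dyn_tab, ps_table = ps_tab,
         truth = truth)
  }, error = function(e) {
    jsonlite::write_json(list(failed_stage = stage,
                              error = conditionMessage(e)),
                         file.path(out, "manifest.json"),
                         auto_unbox = TRUE)
    stop("pipeline failed at stage '", stage, "': ",
         conditionMessage(e), call. = FALSE)
  })
  invisible(res)
}
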