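## Readers and writers for the on-disk exchange formats: 10x-style
## MatrixMarket (genes x cells) with features/barcodes TSVs, plain CSV
## matrices, cell metadata and embedding CSVs, and a ground-truth JSON.

#' Write a dataset (and its ground truth) as a plain-text fixture
#'
#' Writes `matrix.mtx` (genes x cells, 10x convention), `features.tsv`,
#' `barcodes.tsv`, `cell_meta.csv`, `embedding.csv` and, when a ground
#' truth is given, `ground_truth.json`. The files round-trip losslessly
#' through [read_fixture()] / [read_matrix()].
#'
#' @param ds A `SingleCellExperiment` with at least a `counts` assay.
#' @param truth Optional `ground_truth`.
#' @param dir Output directory (created if needed).
#' @param overwrite Allow writing into a non-empty directory.
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(ds, truth = NULL, dir, overwrite = FALSE) {
  if (ncol(ds) == 0L) stop("refusing to write a dataset with 0 cells")
  if (dir.exists(dir) && length(list.files(dir)) > 0L && !overwrite) {
    stop("directory '", dir, "' is not empty; set overwrite = TRUE")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cnt <- as(as(.counts(ds), "CsparseMatrix"), "generalMatrix")
  Matrix::writeMM(cnt, file.path(dir, "matrix.mtx"))
  rd <- rowData(ds)
  feat <- data.frame(gene_id = rownames(ds),
                     gene_name = rownames(ds),
                     gene_type = if (!is.null(rd$gene_type)) rd$gene_type
                                 else "Gene Expression")
  write.table(feat, file.path(dir, "features.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  writeLines(colnames(ds), file.path(dir, "barcodes.tsv"))
  write.csv(as.data.frame(colData(ds)), file.path(dir, "cell_meta.csv"),
            row.names = FALSE)
  emb <- .embedding(ds)
  write.csv(data.frame(cell_id = colnames(ds), x = emb[, 1L], y = emb[, 2L]),
            file.path(dir, "embedding.csv"), row.names = FALSE)
  if (!is.null(truth)) {
    stopifnot(is(truth, "ground_truth"))
    obj <- list(
      tfs = rownames(truth$grn_weights),
      targets = colnames(truth$grn_weights),
      grn_weights = unname(truth$grn_weights),
      driver_map = truth$driver_map,
      target_block = truth$target_block,
      lineages = truth$lineages,
      populations = truth$populations,
      pop_lineage = as.list(truth$pop_lineage),
      pop_stage = as.list(truth$pop_stage),
      timepoints = truth$timepoints,
      abundance_multiplier = unname(truth$abundance_multiplier),
      seed = truth$seed
    )
    jsonlite::write_json(obj, file.path(dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

#' Read a ground truth written by [write_fixture()]
#'
#' @param path Path to `ground_truth.json`.
#' @return A `ground_truth`.
#' @export
read_ground_truth <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  ## rectangular JSON arrays come back as row-major matrices
  W <- matrix(as.numeric(t(obj$grn_weights)), length(obj$tfs),
              length(obj$targets), byrow = TRUE,
              dimnames = list(obj$tfs, obj$targets))
  mult <- matrix(as.numeric(t(obj$abundance_multiplier)),
                 length(obj$populations), length(obj$timepoints),
                 byrow = TRUE,
                 dimnames = list(obj$populations, obj$timepoints))
  pl <- unlist(lapply(obj$pop_lineage, function(v) {
    if (is.null(v)) NA_character_ else v
  }))
  structure(
    list(grn_weights = W,
         driver_map = obj$driver_map,
         target_block = obj$target_block,
         lineages = obj$lineages,
         populations = obj$populations,
         pop_lineage = pl[obj$populations],
         pop_stage = unlist(obj$pop_stage)[obj$populations],
         timepoints = obj$timepoints,
         abundance_multiplier = mult,
         seed = obj$seed),
    class = "ground_truth"
  )
}

#' Read an expression dataset from disk
#'
#' `format = "mtx_10x"` expects a directory with `matrix.mtx` (genes x
#' cells), `features.tsv` and `barcodes.tsv`, plus optional
#' `cell_meta.csv` and `embedding.csv` which are joined automatically.
#' `format = "csv"` expects a dense CSV with gene/cell identifiers;
#' `orientation` declares the on-disk layout, and the returned object is
#' always genes x cells. Mitochondrial genes are flagged by a `mt-`/`MT-`
#' prefix when no explicit annotation is present.
#'
#' @param path Directory (mtx_10x) or CSV file path.
#' @param format `"mtx_10x"` or `"csv"`.
#' @param orientation For CSV: `"genes_by_cells"` (default) or
#'   `"cells_by_genes"`.
#' @return A `SingleCellExperiment`.
#' @export
read_matrix <- function(path, format = c("mtx_10x", "csv"),
                        orientation = c("genes_by_cells",
                                        "cells_by_genes")) {
  format <- match.arg(format)
  orientation <- match.arg(orientation)
  if (format == "csv") {
    df <- read.csv(path, row.names = 1L, check.names = FALSE)
    m <- as.matrix(df)
    if (orientation == "cells_by_genes") m <- base::t(m)
    if (any(m < 0)) stop("counts must be non-negative in '", path, "'")
    sce <- SingleCellExperiment(
      assays = list(counts = Matrix(m, sparse = TRUE)),
      rowData = DataFrame(gene_id = rownames(m),
                          is_mito = grepl("^mt-", rownames(m),
                                          ignore.case = TRUE),
                          row.names = rownames(m))
    )
    return(sce)
  }
  mtx_file <- file.path(path, "matrix.mtx")
  feat_file <- file.path(path, "features.tsv")
  bc_file <- file.path(path, "barcodes.tsv")
  for (f in c(mtx_file, feat_file, bc_file)) {
    if (!file.exists(f)) stop("required file missing: ", f)
  }
  cnt <- as(Matrix::readMM(mtx_file), "CsparseMatrix")
  feat <- read.delim(feat_file, header = FALSE, stringsAsFactors = FALSE)
  barcodes <- readLines(bc_file)
  if (nrow(feat) != nrow(cnt)) {
    stop("features.tsv has ", nrow(feat), " rows but matrix.mtx has ",
         nrow(cnt), " (file: ", feat_file, ")")
  }
  if (length(barcodes) != ncol(cnt)) {
    stop("barcodes.tsv has ", length(barcodes), " entries but matrix.mtx ",
         "has ", ncol(cnt), " columns (file: ", bc_file, ")")
  }
  dimnames(cnt) <- list(feat[[1L]], barcodes)
  rd <- DataFrame(gene_id = feat[[1L]],
                  is_mito = grepl("^mt-", feat[[1L]], ignore.case = TRUE),
                  row.names = feat[[1L]])
  if (ncol(feat) >= 3L) rd$gene_type <- feat[[3L]]
  sce <- SingleCellExperiment(assays = list(counts = cnt), rowData = rd)

  meta_file <- file.path(path, "cell_meta.csv")
  if (file.exists(meta_file)) {
    meta <- read.csv(meta_file, stringsAsFactors = FALSE)
    if (!"cell_id" %in% names(meta) || !all(barcodes %in% meta$cell_id)) {
      stop("cell_meta.csv does not cover every barcode (file: ",
           meta_file, ")")
    }
    meta <- meta[match(barcodes, meta$cell_id), , drop = FALSE]
    colData(sce) <- DataFrame(meta, row.names = barcodes)
  }
  emb_file <- file.path(path, "embedding.csv")
  if (file.exists(emb_file)) {
    emb <- read.csv(emb_file, stringsAsFactors = FALSE)
    emb <- emb[match(barcodes, emb$cell_id), , drop = FALSE]
    m <- as.matrix(emb[, c("x", "y")])
    rownames(m) <- barcodes
    reducedDim(sce, "embedding") <- m
  }
  sce
}

#' Read a complete fixture directory
#'
#' @param dir Directory written by [write_fixture()].
#' @return List with `dataset` and (when present) `truth`.
#' @export
read_fixture <- function(dir) {
  ds <- read_matrix(dir, format = "mtx_10x")
  gt_file <- file.path(dir, "ground_truth.json")
  truth <- if (file.exists(gt_file)) read_ground_truth(gt_file) else NULL
  list(dataset = ds, truth = truth)
}
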