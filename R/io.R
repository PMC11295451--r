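#' Read one dataset from MatrixMarket + annotation files
#'
#' Expects the conventional triplet layout: a genes x cells integer MTX
#' matrix, one gene id per line, one cell barcode per line, and a TSV
#' annotation with header and at least \code{cell_id} and \code{cluster}
#' columns (optionally \code{main_type}, \code{fine_type}, \code{umap_1},
#' \code{umap_2}).
#'
#' @param mtxPath path to the MatrixMarket coordinate file.
#' @param genesPath path to the gene id file (one symbol per line).
#' @param cellsPath path to the barcode file (one id per line).
#' @param annotationPath path to the annotation TSV; \code{NULL} to skip.
#' @param transpose set \code{TRUE} when the MTX is stored cells x genes.
#' @return a \code{SingleCellExperiment} with a \code{counts} assay,
#'   annotation columns in \code{colData} and, when coordinates are
#'   present, a \code{"UMAP"} \code{reducedDim}.
#' @seealso \code{\link{writeDataset}}
#' @export
readDataset <- function(mtxPath, genesPath, cellsPath,
                        annotationPath = NULL, transpose = FALSE) {
  m <- Matrix::readMM(mtxPath)
  if (transpose) m <- Matrix::t(m)
  genes <- readLines(genesPath)
  cells <- readLines(cellsPath)
  if (anyDuplicated(genes)) stop("duplicate gene ids in ", genesPath)
  if (anyDuplicated(cells)) stop("duplicate cell ids in ", cellsPath)
  if (nrow(m) != length(genes) || ncol(m) != length(cells))
    stop(sprintf("matrix is %d x %d but %d genes / %d cells listed",
                 nrow(m), ncol(m), length(genes), length(cells)))
  v <- m@x
  if (any(v != round(v)) || any(v < 0))
    stop("counts must be nonnegative integers")
  cnt <- as.matrix(m)
  storage.mode(cnt) <- "integer"
  dimnames(cnt) <- list(genes, cells)
  cd <- S4Vectors::DataFrame(cell_id = cells, row.names = cells)
  um <- NULL
  if (!is.null(annotationPath)) {
    ann <- utils::read.delim(annotationPath, stringsAsFactors = FALSE)
    if (!"cell_id" %in% colnames(ann)) stop("annotation lacks cell_id column")
    missing <- setdiff(cells, ann$cell_id)
    if (length(missing))
      stop("annotation missing cell(s): ", paste(utils::head(missing, 5),
                                                 collapse = ", "))
    extra <- setdiff(ann$cell_id, cells)
    if (length(extra))
      stop("annotation has cell(s) absent from the matrix: ",
           paste(utils::head(extra, 5), collapse = ", "))
    ann <- ann[match(cells, ann$cell_id), , drop = FALSE]
    if ("cluster" %in% colnames(ann)) ann$cluster <- factor(ann$cluster)
    if (all(c("umap_1", "umap_2") %in% colnames(ann)) &&
        !anyNA(ann$umap_1)) {
      um <- cbind(umap_1 = ann$umap_1, umap_2 = ann$umap_2)
      rownames(um) <- cells
    }
    cd <- S4Vectors::DataFrame(ann, row.names = cells)
  }
  sce <- SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = cnt), colData = cd)
  if (!is.null(um)) SingleCellExperiment::reducedDim(sce, "UMAP") <- um
  sce
}

#' Write one dataset as MTX + TSV files
#'
#' Inverse of \code{\link{readDataset}}: writes \code{matrix.mtx},
#' \code{genes.tsv}, \code{barcodes.tsv}, \code{annotation.tsv} and, when
#' the object carries a planted-marker truth table, \code{truth.tsv}.
#'
#' @param sce a \code{SingleCellExperiment} with a \code{counts} assay.
#' @param dir output directory (created if missing).
#' @return \code{dir}, invisibly.
#' @export
writeDataset <- function(sce, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cnt <- .counts(sce)
  Matrix::writeMM(methods::as(Matrix::Matrix(cnt, sparse = TRUE), "generalMatrix"),
                  file.path(dir, "matrix.mtx"))
  writeLines(rownames(cnt), file.path(dir, "genes.tsv"))
  writeLines(colnames(cnt), file.path(dir, "barcodes.tsv"))
  ann <- as.data.frame(SummarizedExperiment::colData(sce))
  if ("UMAP" %in% SingleCellExperiment::reducedDimNames(sce)) {
    um <- SingleCellExperiment::reducedDim(sce, "UMAP")
    ann$umap_1 <- um[, 1]
    ann$umap_2 <- um[, 2]
  }
  writeTSV(ann, file.path(dir, "annotation.tsv"))
  truth <- S4Vectors::metadata(sce)$truth
  if (!is.null(truth) && nrow(truth) > 0)
    writeTSV(truth, file.path(dir, "truth.tsv"))
  invisible(dir)
}

#' Log-normalize counts (CP10K convention)
#'
#' Adds a \code{logcounts} assay with value
#' \code{log(1 + scale * count / cellTotal)}: counts-per-\code{scale}
#' normalization followed by a natural-log transform, the convention the
#' Seurat-dialect DE metrics assume.  Zero counts map to zero exactly.
#'
#' @param sce a \code{SingleCellExperiment} with a \code{counts} assay.
#' @param scale scale factor (default 10,000).
#' @return \code{sce} with a \code{logcounts} assay added.
#' @export
logNormalize <- function(sce, scale = 10000) {
  cnt <- .counts(sce)
  tot <- colSums(cnt)
  if (any(tot == 0))
    stop("all-zero cell(s): ",
         paste(utils::head(colnames(cnt)[tot == 0], 5), collapse = ", "))
  lc <- log1p(sweep(cnt, 2, scale / tot, "*"))
  SummarizedExperiment::assay(sce, "logcounts") <- lc
  sce
}

#' Assign clusters by K-means on principal components
#'
#' Fallback for datasets arriving without cluster labels: K-means (10
#' restarts) on the top principal components of the log-normalized matrix.
#'
#' @param sce a \code{SingleCellExperiment}.
#' @param k number of clusters (>= 2).
#' @param seed integer seed.
#' @param nPCs number of principal components (capped by data dimensions).
#' @return \code{sce} with \code{colData(sce)$cluster} set to factors
#'   \code{"cl1"}, ..., \code{"clk"}.
#' @export
assignClusters <- function(sce, k, seed = 1L, nPCs = 50) {
  if (k < 2) stop("k must be >= 2")
  if (k > ncol(sce)) stop("k exceeds number of cells")
  if (!"logcounts" %in% SummarizedExperiment::assayNames(sce))
    sce <- logNormalize(sce)
  lc <- .logcounts(sce)
  pcs <- .topPCs(t(lc), nPCs, seed)
  set.seed(seed)
  km <- stats::kmeans(pcs, centers = k, nstart = 10)
  SummarizedExperiment::colData(sce)$cluster <-
    factor(paste0("cl", km$cluster), levels = paste0("cl", seq_len(k)))
  sce
}
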