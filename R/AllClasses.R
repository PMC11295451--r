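#' @import methods
#' @importFrom S4Vectors DataFrame
#' @importClassesFrom S4Vectors DataFrame
#' @importFrom stats rnbinom rlnorm runif pnorm kmeans p.adjust cor median prcomp
NULL

#' Simulation configuration for multi-dataset scRNA-seq marker benchmarks
#'
#' A \code{SimConfig} describes a collection of synthetic single-cell
#' RNA-seq datasets sharing one gene universe and one cell-type tree, but
#' differing in cell-type proportions and (optionally) in marker stability.
#' Counts follow a negative-binomial model: the expected count of gene
#' \eqn{g} in cell \eqn{c} is \eqn{L_c \, p_g \, f_{g,t(c)}}, where
#' \eqn{L_c} is a log-normal library size, \eqn{p_g} a relative expression
#' level shared across datasets, and \eqn{f} a per-type fold factor encoding
#' the planted markers.
#'
#' @slot nDatasets number of datasets to generate.
#' @slot nCellsPerDataset cells per dataset.
#' @slot nGenes genes per dataset (shared universe).
#' @slot typeTree named list mapping each main cell type to a character
#'   vector of fine cell types; fine types are globally unique.
#' @slot proportions numeric matrix (datasets x fine types); each row sums
#'   to one and gives that dataset's fine-type composition.
#' @slot libSizeMeanlog,libSizeSdlog parameters of the log-normal per-cell
#'   library-size distribution (natural-log scale).
#' @slot nbDispersion negative-binomial dispersion (variance =
#'   mu + dispersion * mu^2); shared by all genes.
#' @slot markerSpecs data.frame of planted markers; see
#'   \code{\link{markerSpec}}.
#' @slot structureGenesPerType number of background "expression program"
#'   genes per fine type.  Real cell types differ in large gene programs,
#'   not only in their markers; these genes (moderately enriched in one
#'   fine type each, never part of the marker catalog) give embeddings the
#'   tight, well-separated clusters the downstream screens assume.
#' @slot structureFoldChange fold elevation of structure genes in their type.
#' @slot seed master integer seed; per-dataset substreams are derived from
#'   it deterministically.
#'
#' @seealso \code{\link{simConfig}}, \code{\link{defaultSimConfig}},
#'   \code{\link{simulateDatasets}}
#' @export
setClass("SimConfig", slots = c(
  nDatasets = "integer",
  nCellsPerDataset = "integer",
  nGenes = "integer",
  typeTree = "list",
  proportions = "matrix",
  libSizeMeanlog = "numeric",
  libSizeSdlog = "numeric",
  nbDispersion = "numeric",
  markerSpecs = "data.frame",
  structureGenesPerType = "integer",
  structureFoldChange = "numeric",
  seed = "integer"
))

.markerSpecCols <- c("gene", "level", "target_type", "quality",
                     "fold_change", "baseline", "off_target_types",
                     "dropout_extra", "second_frac", "unstable_datasets")

.splitList <- function(x) {
  if (is.na(x) || !nzchar(x)) character(0) else strsplit(x, ",", fixed = TRUE)[[1]]
}

setValidity("SimConfig", function(object) {
  msg <- character(0)
  fine <- unlist(object@typeTree, use.names = FALSE)
  if (anyDuplicated(fine))
    msg <- c(msg, "fine types must be unique across main types")
  if (object@nDatasets < 1L || object@nCellsPerDataset < 1L)
    msg <- c(msg, "nDatasets and nCellsPerDataset must be positive")
  if (!identical(dim(object@proportions),
                 c(object@nDatasets, length(fine))) ||
      !identical(colnames(object@proportions), fine)) {
    msg <- c(msg, "proportions must be an nDatasets x nFineTypes matrix with fine-type column names")
  } else {
    rs <- rowSums(object@proportions)
    if (any(abs(rs - 1) > 1e-9))
      msg <- c(msg, sprintf("proportions must sum to 1 per dataset (got %s)",
                            paste(format(rs), collapse = ", ")))
    if (any(object@proportions < 0))
      msg <- c(msg, "proportions must be nonnegative")
  }
  if (object@nbDispersion <= 0)
    msg <- c(msg, "nbDispersion must be > 0")
  if (object@libSizeSdlog < 0)
    msg <- c(msg, "libSizeSdlog must be >= 0")
  ms <- object@markerSpecs
  if (!all(.markerSpecCols %in% colnames(ms))) {
    msg <- c(msg, paste("markerSpecs must have columns:",
                        paste(.markerSpecCols, collapse = ", ")))
  } else if (nrow(ms) > 0) {
    if (anyDuplicated(ms$gene))
      msg <- c(msg, "duplicate marker gene symbols in markerSpecs")
    nReserved <- nrow(ms) +
      object@structureGenesPerType * length(fine)
    if (object@nGenes < nReserved)
      msg <- c(msg, "nGenes must be >= planted markers + structure genes")
    if (!all(ms$quality %in% c("specific", "diffuse", "bimodal", "unstable")))
      msg <- c(msg, "marker quality must be specific, diffuse, bimodal or unstable")
    if (any(ms$fold_change < 1))
      msg <- c(msg, "fold_change must be >= 1")
    if (any(ms$baseline <= 0))
      msg <- c(msg, "marker baseline must be > 0")
    if (any(ms$dropout_extra < 0 | ms$dropout_extra > 1))
      msg <- c(msg, "dropout_extra must be in [0, 1]")
    valid_targets <- c(fine, names(object@typeTree))
    if (!all(ms$target_type %in% valid_targets))
      msg <- c(msg, "marker target_type must name a fine or main type of the tree")
    for (i in seq_len(nrow(ms))) {
      off <- .splitList(ms$off_target_types[i])
      if (ms$quality[i] == "specific" && length(off) > 0)
        msg <- c(msg, sprintf("specific marker %s must have empty off_target_types", ms$gene[i]))
      if (length(off) > 0 && !all(off %in% fine))
        msg <- c(msg, sprintf("off_target_types of %s must be fine types", ms$gene[i]))
      ud <- suppressWarnings(as.integer(.splitList(ms$unstable_datasets[i])))
      if (length(ud) > 0 && (anyNA(ud) || any(ud < 1) || any(ud > object@nDatasets)))
        msg <- c(msg, sprintf("unstable_datasets of %s out of range", ms$gene[i]))
    }
  }
  if (length(msg)) msg else TRUE
})

#' Catalog of candidate cell-type marker genes
#'
#' A \code{MarkerCatalog} stores candidate marker genes, each tied to a
#' cell type at a level (\code{"main"} for coarse lineages such as
#' epithelial/stromal/immune, \code{"fine"} for subtypes such as
#' luminal or endothelial) with a provenance tag.
#'
#' @slot entries a \code{DataFrame} with columns \code{level},
#'   \code{cell_type}, \code{gene}, \code{source}.
#'
#' @seealso \code{\link{markerCatalog}}, \code{\link{prostateMarkerCatalog}},
#'   \code{\link{markerGenes}}
#' @export
setClass("MarkerCatalog", slots = c(entries = "DataFrame"))

setValidity("MarkerCatalog", function(object) {
  e <- object@entries
  msg <- character(0)
  need <- c("level", "cell_type", "gene", "source")
  if (!all(need %in% colnames(e)))
    return(paste("entries must have columns:", paste(need, collapse = ", ")))
  if (!all(e$level %in% c("main", "fine")))
    msg <- c(msg, "level must be 'main' or 'fine'")
  if (any(e$gene != toupper(e$gene)))
    msg <- c(msg, "gene symbols must be uppercase")
  key <- paste(e$level, e$cell_type, e$gene)
  if (anyDuplicated(key))
    msg <- c(msg, "(level, cell_type, gene) entries must be unique")
  if (length(msg)) msg else TRUE
})

#' @describeIn SimConfig-class compact display.
#' @param object a \code{SimConfig}.
#' @export
setMethod("show", "SimConfig", function(object) {
  cat("SimConfig:", object@nDatasets, "datasets x",
      object@nCellsPerDataset, "cells x", object@nGenes, "genes\n")
  cat("  main types:", paste(names(object@typeTree), collapse = ", "), "\n")
  cat("  fine types:", paste(unlist(object@typeTree), collapse = ", "), "\n")
  cat("  planted markers:", nrow(object@markerSpecs),
      sprintf("(%s)", paste(sprintf("%d %s", table(object@markerSpecs$quality),
                                    names(table(object@markerSpecs$quality))),
                            collapse = ", ")), "\n")
  cat("  NB dispersion:", object@nbDispersion,
      " library size: lognormal(", object@libSizeMeanlog, ",",
      object@libSizeSdlog, ")  seed:", object@seed, "\n")
})

#' @describeIn MarkerCatalog-class compact display.
#' @param object a \code{MarkerCatalog}.
#' @export
setMethod("show", "MarkerCatalog", function(object) {
  e <- object@entries
  cat("MarkerCatalog with", nrow(e), "entries\n")
  for (lv in unique(e$level)) {
    sub <- e[e$level == lv, , drop = FALSE]
    cat(sprintf("  %s: %d genes across %d cell types\n", lv,
                length(unique(sub$gene)), length(unique(sub$cell_type))))
  }
})
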