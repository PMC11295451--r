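#' Specify one planted marker gene
#'
#' Helper building one row of the \code{markerSpecs} table of a
#' \code{\link{SimConfig}}.  A planted marker's expected count is
#' \code{baseline} (at the average library size) outside its target type
#' and \code{baseline * fold_change} inside it; the four quality classes
#' modulate that pattern:
#' \describe{
#'   \item{specific}{elevated in the target type only.}
#'   \item{diffuse}{elevated in the target type and in every
#'     \code{off_target_types} entry, blurring its specificity.}
#'   \item{bimodal}{elevated in the target type and, in a small fraction
#'     (\code{second_frac}) of cells, in a second embedding-distant type —
#'     producing the scattered positive clumps that the LOF screen is
#'     designed to flag.}
#'   \item{unstable}{behaves like a specific marker except in
#'     \code{unstable_datasets}, where its fold change is replaced by 1.}
#' }
#'
#' @param gene gene symbol (uppercase).
#' @param target_type fine- or main-type name the marker is supposed to mark.
#' @param quality one of \code{"specific"}, \code{"diffuse"},
#'   \code{"bimodal"}, \code{"unstable"}.
#' @param fold_change mean fold elevation in the target type (>= 1).
#' @param baseline expected off-target count at the average library size.
#' @param level \code{"main"} or \code{"fine"}; inferred from the type tree
#'   at configuration time when \code{NA}.
#' @param off_target_types fine types also elevated (diffuse markers); for a
#'   bimodal marker, a single entry naming the second type (chosen at
#'   simulation time if empty).
#' @param dropout_extra extra Bernoulli dropout applied to this gene's
#'   counts, in [0, 1].
#' @param second_frac fraction of second-type cells carrying the bimodal
#'   elevation.
#' @param unstable_datasets integer dataset indices where an unstable
#'   marker loses its elevation.
#' @return one-row \code{data.frame}; rows can be \code{rbind}-ed.
#' @examples
#' markerSpec("LUM1", "luminal", "specific", fold_change = 32)
#' @export
markerSpec <- function(gene, target_type, quality = "specific",
                       fold_change = 8, baseline = 0.25, level = NA_character_,
                       off_target_types = character(0), dropout_extra = 0,
                       second_frac = 0.015, unstable_datasets = integer(0)) {
  if (length(gene) == 0) {
    out <- data.frame(gene = character(0), level = character(0),
                      target_type = character(0), quality = character(0),
                      fold_change = numeric(0), baseline = numeric(0),
                      off_target_types = character(0),
                      dropout_extra = numeric(0), second_frac = numeric(0),
                      unstable_datasets = character(0),
                      stringsAsFactors = FALSE)
    return(out)
  }
  data.frame(gene = gene, level = level, target_type = target_type,
             quality = quality, fold_change = fold_change,
             baseline = baseline,
             off_target_types = paste(off_target_types, collapse = ","),
             dropout_extra = dropout_extra, second_frac = second_frac,
             unstable_datasets = paste(unstable_datasets, collapse = ","),
             stringsAsFactors = FALSE)
}

#' Build a simulation configuration
#'
#' @param nDatasets,nCellsPerDataset,nGenes dimensions of the simulation.
#' @param typeTree named list: main type -> character vector of fine types.
#' @param proportions numeric matrix (datasets x fine types, columns named
#'   by fine type) of per-dataset composition; rows must sum to 1.
#' @param libSizeMeanlog,libSizeSdlog log-normal library-size parameters
#'   (natural log of total counts per cell).
#' @param nbDispersion shared negative-binomial dispersion.
#' @param markerSpecs data.frame of \code{\link{markerSpec}} rows.
#' @param structureGenesPerType background expression-program genes per
#'   fine type (moderately elevated in that type only, never in the marker
#'   catalog); they supply the type-specific transcriptome that makes
#'   embedding clusters well separated.
#' @param structureFoldChange fold elevation of structure genes.
#' @param seed master integer seed.
#' @return a validated \code{\link{SimConfig}}.
#' @seealso \code{\link{defaultSimConfig}} for the packaged benchmark
#'   configuration.
#' @export
simConfig <- function(nDatasets, nCellsPerDataset, nGenes, typeTree,
                      proportions, libSizeMeanlog = 8.5, libSizeSdlog = 0.35,
                      nbDispersion = 0.3,
                      markerSpecs = markerSpec(character(0), character(0)),
                      structureGenesPerType = 40L, structureFoldChange = 4,
                      seed = 1L) {
  if (is.list(proportions) && !is.matrix(proportions))
    proportions <- do.call(rbind, proportions)
  fine <- unlist(typeTree, use.names = FALSE)
  proportions <- as.matrix(proportions)
  if (is.null(colnames(proportions)) && ncol(proportions) == length(fine))
    colnames(proportions) <- fine
  colnames(proportions) <- unname(colnames(proportions))
  ms <- as.data.frame(markerSpecs)
  if (nrow(ms) > 0) {
    f2m <- fineToMain(typeTree)
    inferred <- ifelse(ms$target_type %in% names(typeTree), "main", "fine")
    ms$level <- ifelse(is.na(ms$level), inferred, ms$level)
  }
  methods::new("SimConfig",
               nDatasets = as.integer(nDatasets),
               nCellsPerDataset = as.integer(nCellsPerDataset),
               nGenes = as.integer(nGenes),
               typeTree = typeTree,
               proportions = proportions,
               libSizeMeanlog = libSizeMeanlog,
               libSizeSdlog = libSizeSdlog,
               nbDispersion = nbDispersion,
               markerSpecs = ms,
               structureGenesPerType = as.integer(structureGenesPerType),
               structureFoldChange = structureFoldChange,
               seed = as.integer(seed))
}

#' Packaged benchmark configuration
#'
#' Four datasets of 5,000 cells and 2,000 genes over a two-level prostate-like
#' type tree (epithelial: luminal, basal, club; stromal: fibroblast,
#' endothelial; immune), with per-dataset composition differing the way
#' tissue strata do, 40 background program genes per fine type, and 18
#' planted markers covering every quality class.  Defaults (library size
#' lognormal(8.5, 0.35), dispersion 0.3, fold change 64 over a 0.05
#' baseline for main-level specifics, 32 over a 0.10 baseline for fine
#' specifics, 32 over a 0.25 baseline for diffuse/unstable markers, 250
#' over a 0.002 baseline for bimodal markers) are the package's fixed
#' study conditions; the methods vignette motivates each choice.
#'
#' @param seed master seed.
#' @return a \code{\link{SimConfig}}.
#' @export
defaultSimConfig <- function(seed = 1L) {
  tree <- list(epithelial = c("luminal", "basal", "club"),
               stromal = c("fibroblast", "endothelial"),
               immune = "immune")
  props <- rbind(
    c(0.25, 0.18, 0.07, 0.20, 0.15, 0.15),
    c(0.35, 0.12, 0.05, 0.13, 0.10, 0.25),
    c(0.18, 0.22, 0.10, 0.22, 0.13, 0.15),
    c(0.22, 0.15, 0.08, 0.10, 0.25, 0.20))
  colnames(props) <- unlist(tree, use.names = FALSE)
  nonEpi <- c("fibroblast", "endothelial", "immune")
  nonStro <- c("luminal", "basal", "club", "immune")
  specs <- rbind(
    markerSpec("EPI_SPEC1", "epithelial", "specific", 64, baseline = 0.05),
    markerSpec("EPI_SPEC2", "epithelial", "specific", 64, baseline = 0.05),
    markerSpec("EPI_SPEC3", "epithelial", "specific", 64, baseline = 0.05),
    markerSpec("STRO_SPEC1", "stromal", "specific", 64, baseline = 0.05),
    markerSpec("STRO_SPEC2", "stromal", "specific", 64, baseline = 0.05),
    markerSpec("EPI_DIFF1", "epithelial", "diffuse", 32,
               off_target_types = nonEpi),
    markerSpec("EPI_DIFF2", "epithelial", "diffuse", 32,
               off_target_types = nonEpi),
    markerSpec("STRO_DIFF1", "stromal", "diffuse", 32,
               off_target_types = nonStro),
    markerSpec("LUM_SPEC1", "luminal", "specific", 32, baseline = 0.10),
    markerSpec("LUM_SPEC2", "luminal", "specific", 32, baseline = 0.10),
    markerSpec("BAS_SPEC1", "basal", "specific", 32, baseline = 0.10),
    markerSpec("FIB_SPEC1", "fibroblast", "specific", 32, baseline = 0.10),
    markerSpec("END_SPEC1", "endothelial", "specific", 32, baseline = 0.10),
    markerSpec("LUM_BIMOD1", "luminal", "bimodal", 250, baseline = 0.002,
               second_frac = 0.02, off_target_types = "endothelial"),
    markerSpec("BAS_BIMOD1", "basal", "bimodal", 250, baseline = 0.002,
               second_frac = 0.02, off_target_types = "fibroblast"),
    markerSpec("LUM_UNST1", "luminal", "unstable", 32,
               unstable_datasets = c(2L, 4L)),
    markerSpec("FIB_UNST1", "fibroblast", "unstable", 32,
               unstable_datasets = c(1L, 3L)))
  simConfig(4L, 5000L, 2000L, tree, props, markerSpecs = specs, seed = seed)
}

# integer cell counts per fine type matching proportions (largest remainder)
.typeCounts <- function(props, n) {
  raw <- props * n
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  base
}

# target fine types of a marker spec row
.targetFine <- function(spec, typeTree) {
  if (spec$target_type %in% names(typeTree)) typeTree[[spec$target_type]]
  else spec$target_type
}

#' Simulate multi-dataset scRNA-seq counts with planted markers
#'
#' Draws one shared gene universe (log-normal relative expression, with
#' marker genes pinned to their declared baselines) and then, per dataset,
#' negative-binomial counts with per-cell log-normal library sizes and the
#' configured fold elevations.  Deterministic for a fixed
#' \code{config@seed}: per-dataset substreams are derived from the master
#' seed, so datasets are reproducible individually.
#'
#' @param config a \code{\link{SimConfig}}.
#' @return list of \code{SingleCellExperiment}s, one per dataset, with a
#'   \code{counts} assay, colData columns \code{cell_id}, \code{cluster}
#'   (one cluster per fine type), \code{main_type}, \code{fine_type}, and
#'   metadata \code{truth} (the marker-spec table), \code{dataset_id} and
#'   \code{lib_size} (the drawn per-cell library sizes).
#' @examples
#' cfg <- simConfig(2, 300, 100,
#'                  list(A = "a", B = "b"),
#'                  rbind(c(0.5, 0.5), c(0.3, 0.7)),
#'                  markerSpecs = markerSpec("M1", "a", "specific", 8),
#'                  seed = 7)
#' sims <- simulateDatasets(cfg)
#' @export
simulateDatasets <- function(config) {
  methods::validObject(config)
  tree <- config@typeTree
  fine <- unlist(tree, use.names = FALSE)
  f2m <- fineToMain(tree)
  ms <- config@markerSpecs
  nG <- config@nGenes
  nC <- config@nCellsPerDataset
  expLib <- exp(config@libSizeMeanlog + config@libSizeSdlog^2 / 2)

  geneIds <- sprintf("G%04d", seq_len(nG))
  if (nrow(ms) > 0) geneIds[seq_len(nrow(ms))] <- ms$gene
  if (anyDuplicated(geneIds)) stop("duplicate gene symbols")

  # shared gene universe: relative expression, drawn once
  set.seed(deriveSeed(config@seed, "simulate", 0L))
  rel <- stats::rlnorm(nG, meanlog = 0, sdlog = 1)
  if (nrow(ms) > 0) {
    # pin marker baselines: off-target mean count = baseline at mean library
    rel[seq_len(nrow(ms))] <- 0     # placeholder, rescaled below
  }
  p <- rel / sum(rel)
  if (nrow(ms) > 0)
    p[seq_len(nrow(ms))] <- ms$baseline / expLib

  # per-type fold factors shared across datasets (unstable handled per ds)
  foldBase <- matrix(1, nG, length(fine), dimnames = list(geneIds, fine))
  # background expression programs: each fine type gets a block of
  # moderately elevated genes, drawn from the ordinary gene universe
  nStruct <- config@structureGenesPerType
  if (nStruct > 0) {
    for (t in seq_along(fine)) {
      rows <- nrow(ms) + (t - 1L) * nStruct + seq_len(nStruct)
      foldBase[rows, fine[t]] <- config@structureFoldChange
    }
  }
  for (j in seq_len(nrow(ms))) {
    tgt <- .targetFine(ms[j, ], tree)
    foldBase[j, tgt] <- ms$fold_change[j]
    if (ms$quality[j] == "diffuse") {
      off <- .splitList(ms$off_target_types[j])
      foldBase[j, off] <- ms$fold_change[j]
    }
  }

  lapply(seq_len(config@nDatasets), function(i) {
    set.seed(deriveSeed(config@seed, "simulate", i))
    counts <- .typeCounts(config@proportions[i, ], nC)
    cellFine <- rep(fine, counts)
    L <- stats::rlnorm(nC, config@libSizeMeanlog, config@libSizeSdlog)

    fold <- foldBase
    for (j in seq_len(nrow(ms))) {
      if (ms$quality[j] == "unstable") {
        ud <- as.integer(.splitList(ms$unstable_datasets[j]))
        if (i %in% ud) fold[j, .targetFine(ms[j, ], tree)] <- 1
      }
      if (ms$quality[j] == "bimodal") {
        # second type carries the elevation in a small cell fraction only
        fold[j, ] <- 1
        fold[j, .targetFine(ms[j, ], tree)] <- ms$fold_change[j]
      }
    }

    mu <- fold[, cellFine, drop = FALSE] * p       # genes x cells
    mu <- sweep(mu, 2, L, "*")

    for (j in seq_len(nrow(ms))) {
      if (ms$quality[j] == "bimodal") {
        second <- .splitList(ms$off_target_types[j])
        if (length(second) == 0) {
          # pick an embedding-distant second type: different main lineage
          tgtMain <- f2m[[.targetFine(ms[j, ], tree)[1]]]
          second <- sample(fine[f2m[fine] != tgtMain], 1L)
        }
        for (ty in second) {
          idx <- which(cellFine == ty)
          nSel <- max(1L, floor(ms$second_frac[j] * length(idx)))
          sel <- sample(idx, nSel)
          mu[j, sel] <- mu[j, sel] * ms$fold_change[j]
        }
      }
    }

    cnt <- matrix(stats::rnbinom(length(mu), mu = mu,
                                 size = 1 / config@nbDispersion),
                  nrow = nG, dimnames = list(geneIds, NULL))
    storage.mode(cnt) <- "integer"
    for (j in seq_len(nrow(ms))) {
      if (ms$dropout_extra[j] > 0) {
        drop <- stats::runif(nC) < ms$dropout_extra[j]
        cnt[j, drop] <- 0L
      }
    }

    cellIds <- sprintf("DS%d_C%05d", i, seq_len(nC))
    colnames(cnt) <- cellIds
    cd <- S4Vectors::DataFrame(
      cell_id = cellIds,
      cluster = factor(paste0("cl", match(cellFine, fine))),
      main_type = unname(f2m[cellFine]),
      fine_type = cellFine)
    sce <- SingleCellExperiment::SingleCellExperiment(
      assays = list(counts = cnt), colData = cd)
    S4Vectors::metadata(sce) <- list(truth = ms, dataset_id = i, lib_size = L)
    sce
  })
}

#' Attach a 2-D UMAP embedding to a dataset
#'
#' Log-normalizes counts if needed (\code{\link{logNormalize}}), takes the
#' top principal components and runs UMAP on them.  Deterministic for a
#' fixed seed (single-threaded UMAP with scaled-PCA initialization).
#'
#' @param sce a \code{SingleCellExperiment} with a \code{counts} assay.
#' @param nNeighbors UMAP neighborhood size.
#' @param seed integer seed.
#' @param nPCs number of principal components (capped by data dimensions).
#' @param nEpochs UMAP optimization epochs.
#' @return \code{sce} with \code{reducedDim(sce, "UMAP")} set.
#' @export
embedCells <- function(sce, nNeighbors = 15, seed = 1L, nPCs = 50,
                       nEpochs = 200) {
  if (ncol(sce) < nNeighbors + 1)
    stop("fewer cells (", ncol(sce), ") than nNeighbors + 1")
  if (!"logcounts" %in% SummarizedExperiment::assayNames(sce))
    sce <- logNormalize(sce)
  lc <- .logcounts(sce)
  pcs <- .topPCs(t(lc), nPCs, seed)
  um <- uwot::umap(pcs, n_neighbors = nNeighbors, init = "spca",
                   n_epochs = nEpochs, n_threads = 1, n_sgd_threads = 0,
                   seed = seed)
  dimnames(um) <- list(colnames(sce), c("umap_1", "umap_2"))
  SingleCellExperiment::reducedDim(sce, "UMAP") <- um
  sce
}
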