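#' Build a pipeline configuration
#'
#' @param outDir output directory for stage TSVs and the report.
#' @param datasetDirs character vector of dataset directories (each laid
#'   out as written by \code{\link{writeDataset}}); ignored when
#'   \code{synthetic = TRUE}.
#' @param catalogPath marker-catalog TSV; \code{NULL} with
#'   \code{synthetic = TRUE} uses the truth-derived catalog.
#' @param synthetic when \code{TRUE} the datasets are simulated from
#'   \code{simCfg}.
#' @param simCfg a \code{\link{SimConfig}} (default
#'   \code{defaultSimConfig(seed)}).
#' @param seed master seed; stage seeds are derived from it.
#' @param alpha,lfcMin up-regulation screen parameters.
#' @param kNeighbors,tol LOF parameters.
#' @param f1MainMin,f1FineMin,coverageMin,f1FracMin validation thresholds.
#' @param threshold expression-positivity threshold for F1.
#' @param skipEmbedding reuse embeddings already present; do not compute.
#' @param makePlots also write PNG figures.
#' @return a validated config list of class \code{"markerPipelineConfig"}.
#' @seealso \code{\link{runPipeline}}, \code{\link{readPipelineConfig}}
#' @export
pipelineConfig <- function(outDir, datasetDirs = character(0),
                           catalogPath = NULL, synthetic = FALSE,
                           simCfg = NULL, seed = 1L, alpha = 0.05,
                           lfcMin = 0.25, kNeighbors = 20, tol = 0.05,
                           f1MainMin = 0.8, f1FineMin = 0.6,
                           coverageMin = 0.6, f1FracMin = 0.8,
                           threshold = 0, skipEmbedding = FALSE,
                           makePlots = FALSE) {
  cfg <- list(outDir = outDir, datasetDirs = datasetDirs,
              catalogPath = catalogPath, synthetic = synthetic,
              simCfg = simCfg, seed = as.integer(seed), alpha = alpha,
              lfcMin = lfcMin, kNeighbors = kNeighbors, tol = tol,
              f1MainMin = f1MainMin, f1FineMin = f1FineMin,
              coverageMin = coverageMin, f1FracMin = f1FracMin,
              threshold = threshold, skipEmbedding = skipEmbedding,
              makePlots = makePlots)
  class(cfg) <- "markerPipelineConfig"
  validatePipelineConfig(cfg)
  cfg
}

#' @rdname pipelineConfig
#' @param cfg a pipeline configuration.
#' @export
validatePipelineConfig <- function(cfg) {
  if (!cfg$synthetic) {
    if (length(cfg$datasetDirs) == 0)
      stop("config error: no dataset directories and synthetic = FALSE")
    missing <- cfg$datasetDirs[!dir.exists(cfg$datasetDirs)]
    if (length(missing))
      stop("config error: dataset dir(s) not found: ",
           paste(missing, collapse = ", "))
    if (is.null(cfg$catalogPath))
      stop("config error: catalogPath required for non-synthetic runs")
  }
  if (!is.null(cfg$catalogPath) && !file.exists(cfg$catalogPath))
    stop("config error: catalog not found: ", cfg$catalogPath)
  if (!is.null(cfg$catalogPath)) {
    cat0 <- readMarkerCatalog(cfg$catalogPath)
    if (nrow(catalogEntries(cat0)) == 0)
      stop("config error: empty marker catalog")
  }
  invisible(TRUE)
}

#' Read a pipeline configuration from YAML
#'
#' Recognized keys mirror the \code{\link{pipelineConfig}} arguments
#' (snake_case accepted: \code{out_dir}, \code{dataset_dirs},
#' \code{catalog_path}, ...).
#'
#' @param path YAML file.
#' @return a validated config list.
#' @export
readPipelineConfig <- function(path) {
  y <- yaml::read_yaml(path)
  pick <- function(a, b, default = NULL) {
    v <- if (!is.null(y[[a]])) y[[a]] else y[[b]]
    if (is.null(v)) default else v
  }
  pipelineConfig(
    outDir = pick("outDir", "out_dir", stop("config error: out_dir missing")),
    datasetDirs = unlist(pick("datasetDirs", "dataset_dirs", character(0))),
    catalogPath = pick("catalogPath", "catalog_path"),
    synthetic = isTRUE(pick("synthetic", "run_synthetic", FALSE)),
    seed = pick("seed", "seed", 1L),
    alpha = pick("alpha", "alpha", 0.05),
    lfcMin = pick("lfcMin", "lfc_min", 0.25),
    kNeighbors = pick("kNeighbors", "k_neighbors", 20),
    tol = pick("tol", "tol", 0.05),
    f1MainMin = pick("f1MainMin", "f1_main_min", 0.8),
    f1FineMin = pick("f1FineMin", "f1_fine_min", 0.6),
    coverageMin = pick("coverageMin", "coverage_min", 0.6),
    f1FracMin = pick("f1FracMin", "f1_frac_min", 0.8),
    threshold = pick("threshold", "threshold", 0),
    skipEmbedding = isTRUE(pick("skipEmbedding", "skip_embedding", FALSE)),
    makePlots = isTRUE(pick("makePlots", "make_plots", FALSE)))
}

#' Expected pipeline verdict for a planted marker
#'
#' Maps the simulator's marker quality classes onto the final report
#' statuses the pipeline should assign when it works: specific markers
#' should come out robust (main level) or validated (fine level), bimodal
#' markers should be removed by the LOF screen, and diffuse or unstable
#' markers should fail screening or validation.
#'
#' @param specs a marker-spec \code{data.frame}
#'   (\code{markerSpecs(config)}).
#' @return named character vector, gene -> expected status.
#' @export
plantedStatus <- function(specs) {
  status <- ifelse(specs$quality == "specific",
                   ifelse(specs$level == "main", "robust-main",
                          "stable-fine-validated"),
                   ifelse(specs$quality == "bimodal", "removed-unstable",
                          "failed"))
  names(status) <- specs$gene
  status
}

# majority-main-type clusters for one dataset
.clustersOfMainType <- function(sce, mainType) {
  cd <- SummarizedExperiment::colData(sce)
  cl <- droplevels(factor(cd$cluster))
  maj <- vapply(levels(cl), function(k)
    names(which.max(table(cd$main_type[cl == k]))), character(1))
  levels(cl)[maj == mainType]
}

#' Run the marker-evaluation pipeline
#'
#' Executes the four-stage analysis over all datasets: (1) DE metrics and
#' up-regulation screening of main-level markers, (2) entropy profiling,
#' cross-dataset ranking and dataset correlation per main panel, (3) panel
#' validation of main markers by K-means regrouping and F1 scores, and
#' (4) LOF screening plus F1 validation of fine-level markers.  All stage
#' outputs are written as TSVs under \code{cfg$outDir}; a rerun with the
#' same config reproduces them byte for byte.
#'
#' @param cfg a \code{\link{pipelineConfig}} (or path to a YAML config).
#' @return invisibly, a list with the per-stage tables and the final
#'   \code{report} (one row per catalog entry with columns \code{gene},
#'   \code{level}, \code{cell_type}, \code{status} and stage summaries).
#' @export
runPipeline <- function(cfg) {
  if (is.character(cfg)) cfg <- readPipelineConfig(cfg)
  validatePipelineConfig(cfg)
  dir.create(cfg$outDir, recursive = TRUE, showWarnings = FALSE)
  manifest <- character(0)
  note <- function(...) {
    manifest <<- c(manifest, paste0(...))
    writeLines(manifest, file.path(cfg$outDir, "MANIFEST"))
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      note("INCOMPLETE at stage ", name, ": ", conditionMessage(e))
      stop("stage ", name, ": ", conditionMessage(e), call. = FALSE)
    })
  }

  ## stage: load ----------------------------------------------------------
  datasets <- stage("load", {
    if (cfg$synthetic) {
      simCfg <- if (is.null(cfg$simCfg)) defaultSimConfig(cfg$seed) else cfg$simCfg
      simulateDatasets(simCfg)
    } else {
      lapply(cfg$datasetDirs, function(d)
        readDataset(file.path(d, "matrix.mtx"), file.path(d, "genes.tsv"),
                    file.path(d, "barcodes.tsv"),
                    file.path(d, "annotation.tsv")))
    }
  })
  catalog <- stage("load", {
    if (!is.null(cfg$catalogPath)) readMarkerCatalog(cfg$catalogPath)
    else if (cfg$synthetic) {
      simCfg <- if (is.null(cfg$simCfg)) defaultSimConfig(cfg$seed) else cfg$simCfg
      syntheticCatalog(simCfg)
    } else stop("no catalog")
  })
  if (nrow(catalogEntries(catalog)) == 0) stop("config error: empty catalog")
  nD <- length(datasets)
  note("datasets: ", nD)

  datasets <- stage("preprocess", lapply(seq_len(nD), function(i) {
    sce <- datasets[[i]]
    if (!"logcounts" %in% SummarizedExperiment::assayNames(sce))
      sce <- logNormalize(sce)
    hasUM <- "UMAP" %in% SingleCellExperiment::reducedDimNames(sce)
    if (!hasUM && !cfg$skipEmbedding)
      sce <- embedCells(sce, seed = deriveSeed(cfg$seed, "embed", i))
    sce
  }))

  e <- catalogEntries(catalog)
  mainE <- e[e$level == "main", , drop = FALSE]
  fineE <- e[e$level == "fine", , drop = FALSE]
  present <- Reduce(intersect, lapply(datasets, rownames))
  absent <- setdiff(e$gene, present)
  if (length(absent))
    note("catalog genes absent from data (statuses set to failed): ",
         paste(absent, collapse = ", "))

  ## stage: DE + screen ---------------------------------------------------
  mainGenes <- intersect(unique(mainE$gene), present)
  deList <- list(); screened <- list()
  if (nrow(mainE) > 0 && length(mainGenes) > 0) {
    deList <- stage("de_metrics", lapply(seq_len(nD), function(i) {
      de <- deTable(datasets[[i]], mainGenes)
      writeDETable(de, file.path(cfg$outDir, sprintf("de_dataset%d.tsv", i)))
      de
    }))
    screened <- stage("screen", {
      out <- list()
      for (ty in unique(mainE$cell_type)) {
        passAll <- rep(TRUE, length(mainGenes)); names(passAll) <- mainGenes
        for (i in seq_len(nD)) {
          tc <- .clustersOfMainType(datasets[[i]], ty)
          if (length(tc) == 0) { passAll[] <- FALSE; next }
          kept <- screenUpregulated(deList[[i]], tc, cfg$alpha, cfg$lfcMin)
          passAll[!(mainGenes %in% kept)] <- FALSE
        }
        cand <- intersect(mainE$gene[mainE$cell_type == ty], mainGenes)
        out[[ty]] <- cand[passAll[cand]]
      }
      writeTSV(data.frame(
        cell_type = rep(names(out), lengths(out)),
        gene = unlist(out, use.names = FALSE)),
        file.path(cfg$outDir, "screened_main.tsv"))
      out
    })
  }

  ## stage: entropy -------------------------------------------------------
  entropySummaries <- list(); correlations <- list(); allProfiles <- list()
  if (length(deList)) stage("entropy", {
    for (ty in unique(mainE$cell_type)) {
      panel <- intersect(mainE$gene[mainE$cell_type == ty], mainGenes)
      if (length(panel) < 2) next
      profs <- lapply(seq_len(nD), function(i) {
        de <- deList[[i]]
        entropyProfiles(de[de$gene %in% panel, , drop = FALSE], i)
      })
      allProfiles[[ty]] <- do.call(rbind, lapply(profs, as.data.frame))
      entropySummaries[[ty]] <- entropySummary(profs)
      writeTSV(as.data.frame(entropySummaries[[ty]]),
               file.path(cfg$outDir, sprintf("entropy_summary_%s.tsv", ty)))
      if (length(panel) >= 3) {
        correlations[[ty]] <- datasetCorrelation(profs)
        cm <- correlations[[ty]]
        writeTSV(data.frame(dataset = rownames(cm), cm, check.names = FALSE),
                 file.path(cfg$outDir,
                           sprintf("dataset_correlation_%s.tsv", ty)))
      }
    }
    if (length(allProfiles))
      writeTSV(do.call(rbind, unname(allProfiles)),
               file.path(cfg$outDir, "entropy_profiles.tsv"))
  })

  ## stage: main validation ----------------------------------------------
  regroups <- list(); f1Main <- NULL
  if (length(screened)) stage("panel_validation", {
    rows <- list()
    for (ty in names(screened)) {
      panel <- screened[[ty]]
      if (length(panel) == 0) next
      for (i in seq_len(nD)) {
        rr <- regroupClusters(datasets[[i]], panel, ty,
                              seed = deriveSeed(cfg$seed, "kmeans", i),
                              datasetId = i)
        regroups[[paste(ty, i)]] <- rr
        rows[[paste(ty, i)]] <- data.frame(
          cell_type = ty, dataset_id = i, n_panel = length(panel),
          purity = rr$purity, separated = rr$separated)
      }
    }
    if (length(rows))
      writeTSV(do.call(rbind, unname(rows)),
               file.path(cfg$outDir, "regroup.tsv"))
    f1rows <- list()
    for (j in seq_len(nrow(mainE))) {
      g <- mainE$gene[j]
      if (!g %in% present) next
      for (i in seq_len(nD))
        f1rows[[paste(j, i)]] <- as.data.frame(
          markerF1(datasets[[i]], g, mainE$cell_type[j], "main",
                   cfg$threshold, i))
    }
    if (length(f1rows)) {
      f1Main <- do.call(rbind, unname(f1rows))
      writeTSV(f1Main, file.path(cfg$outDir, "f1_main.tsv"))
    }
  })

  ## stage: fine (LOF + F1) ----------------------------------------------
  tallies <- NULL; fineVerdicts <- NULL
  fineGenes <- intersect(unique(fineE$gene), present)
  if (nrow(fineE) > 0 && length(fineGenes) > 0 && !cfg$skipEmbedding)
    stage("embedding_lof", {
      lofRows <- list()
      for (g in fineGenes) for (i in seq_len(nD))
        lofRows[[paste(g, i)]] <- markerLOF(datasets[[i]], g,
                                            k = cfg$kNeighbors,
                                            tol = cfg$tol, datasetId = i)
      lofRes <- do.call(rbind, unname(lofRows))
      writeTSV(as.data.frame(lofRes), file.path(cfg$outDir, "lof_results.tsv"))
      tallies <- lofTally(lofRes)
      writeTSV(as.data.frame(tallies), file.path(cfg$outDir, "lof_tally.tsv"))
      fineVerdicts <- fineMarkerWorkflow(
        datasets, catalog, tallies, cfg$f1FineMin, cfg$coverageMin,
        cfg$f1FracMin, cfg$threshold)
      writeTSV(as.data.frame(fineVerdicts),
               file.path(cfg$outDir, "fine_verdicts.tsv"))
    })

  ## stage: report --------------------------------------------------------
  report <- stage("report", {
    rows <- lapply(seq_len(nrow(e)), function(j) {
      g <- e$gene[j]; lv <- e$level[j]; ty <- e$cell_type[j]
      rank_sum <- NA_real_; entropy_sum <- NA_real_
      pct_gt1 <- NA_real_; med_f1 <- NA_real_
      if (!g %in% present) {
        status <- "failed"
      } else if (lv == "main") {
        scr <- !is.null(screened[[ty]]) && g %in% screened[[ty]]
        es <- entropySummaries[[ty]]
        if (!is.null(es) && g %in% es$gene) {
          rank_sum <- es$rank_sum[es$gene == g]
          entropy_sum <- es$total_entropy_sum[es$gene == g]
        }
        if (!is.null(f1Main)) {
          f1s <- f1Main$f1[f1Main$gene == g & f1Main$target_type == ty &
                             f1Main$defined]
          med_f1 <- if (length(f1s)) stats::median(f1s) else NA_real_
          f1ok <- length(f1s) > 0 && mean(f1s >= cfg$f1MainMin) >= cfg$f1FracMin
        } else f1ok <- FALSE
        status <- if (scr && f1ok) "robust-main" else "failed"
      } else {
        fv <- fineVerdicts[fineVerdicts$gene == g &
                             fineVerdicts$cell_type == ty, , drop = FALSE]
        if (!is.null(tallies) && g %in% tallies$gene)
          pct_gt1 <- tallies$pct_gt1[tallies$gene == g]
        if (is.null(fineVerdicts) || nrow(fv) == 0) {
          status <- "failed"
        } else {
          med_f1 <- fv$median_f1[1]
          status <- switch(fv$verdict[1],
                           validated = "stable-fine-validated",
                           `removed-unstable` = "removed-unstable",
                           `insufficient-coverage` = "insufficient-coverage",
                           "failed")
        }
      }
      data.frame(gene = g, level = lv, cell_type = ty, status = status,
                 rank_sum = rank_sum, total_entropy_sum = entropy_sum,
                 pct_gt1 = pct_gt1, median_f1 = med_f1,
                 stringsAsFactors = FALSE)
    })
    rep <- do.call(rbind, rows)
    writeTSV(rep, file.path(cfg$outDir, "marker_report.tsv"))
    rep
  })

  if (cfg$makePlots) stage("plots", {
    for (ty in names(correlations))
      plotDatasetCorrelation(correlations[[ty]],
        file.path(cfg$outDir, sprintf("dataset_correlation_%s.png", ty)))
    if (!is.null(tallies))
      plotLOFTally(tallies, file.path(cfg$outDir, "lof_tally.png"))
    for (nm in names(regroups))
      plotRegroup(regroups[[nm]],
        file.path(cfg$outDir, paste0("regroup_", gsub(" ", "_", nm), ".png")))
  })

  note("complete")
  invisible(list(report = report, screened = screened,
                 entropySummaries = entropySummaries,
                 correlations = correlations, tallies = tallies,
                 fineVerdicts = fineVerdicts, f1Main = f1Main,
                 regroups = regroups, datasets = datasets,
                 catalog = catalog))
}
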