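#' Regroup clusters by panel-average expression
#'
#' Computes each cluster's mean log-normalized expression over a marker
#' panel, z-standardizes per gene across clusters, and splits the clusters
#' into two groups by K-means (K = 2, 10 restarts).  The split is scored
#' by purity against the binary labelling "cluster's majority main type is
#' \code{targetMainType}" vs rest: purity is the best achievable agreement
#' over the two group-to-class assignments, and \code{separated} means the
#' panel isolates the target clusters perfectly (purity 1).
#'
#' @param sce a \code{SingleCellExperiment} with \code{logcounts},
#'   \code{cluster} and \code{main_type} colData columns.
#' @param panel character vector of panel genes.
#' @param targetMainType the main type the panel is supposed to mark.
#' @param seed integer seed for K-means.
#' @param datasetId identifier recorded in the output.
#' @return list with elements \code{dataset_id}, \code{panel},
#'   \code{cluster_ids}, \code{cluster_panel_means} (clusters x panel),
#'   \code{kmeans_group} (named integer), \code{purity}, \code{separated}.
#' @export
regroupClusters <- function(sce, panel, targetMainType, seed = 1L,
                            datasetId = 1L) {
  if (length(panel) == 0) stop("panel must be nonempty")
  .assertGene(panel, rownames(sce))
  cd <- SummarizedExperiment::colData(sce)
  if (is.null(cd$cluster)) stop("no 'cluster' column in colData")
  if (is.null(cd$main_type) || anyNA(cd$main_type))
    stop("main_type labels required for every cell")
  cl <- droplevels(factor(cd$cluster))
  if (nlevels(cl) < 2) stop("need at least 2 clusters")
  lc <- .logcounts(sce)[panel, , drop = FALSE]

  clusters <- levels(cl)
  means <- matrix(0, length(clusters), length(panel),
                  dimnames = list(clusters, panel))
  for (k in clusters)
    means[k, ] <- rowMeans(lc[, cl == k, drop = FALSE])

  z <- scale(means)
  z[, !is.finite(colSums(z)) | attr(z, "scaled:scale") == 0] <- 0

  majority <- vapply(clusters, function(k) {
    names(which.max(table(cd$main_type[cl == k])))
  }, character(1))
  isTarget <- majority == targetMainType

  grp <- tryCatch({
    set.seed(seed)
    stats::kmeans(z, centers = 2, nstart = 10)$cluster
  }, error = function(e) rep(1L, length(clusters)))  # degenerate panel
  names(grp) <- clusters

  acc <- function(map) mean(ifelse(grp == 1L, map[1], map[2]) == isTarget)
  purity <- max(acc(c(TRUE, FALSE)), acc(c(FALSE, TRUE)))

  list(dataset_id = datasetId, panel = panel, cluster_ids = clusters,
       cluster_panel_means = means, kmeans_group = grp,
       purity = purity, separated = purity == 1)
}

#' F1 score of one marker as a cell-type classifier
#'
#' Treats "normalized expression above \code{threshold}" as a prediction
#' that a cell belongs to \code{targetType} and scores it against the
#' annotation at the requested level.
#'
#' @param sce a \code{SingleCellExperiment} with \code{logcounts} and
#'   \code{main_type} / \code{fine_type} colData columns.
#' @param gene gene symbol.
#' @param targetType cell type the marker should predict.
#' @param level \code{"main"} or \code{"fine"}.
#' @param threshold positivity threshold on log-normalized expression
#'   (default 0: any expression counts as positive).
#' @param datasetId identifier recorded in the output.
#' @return one-row \code{DataFrame}: \code{gene}, \code{dataset_id},
#'   \code{target_type}, \code{level}, \code{precision}, \code{recall},
#'   \code{f1}, \code{n_target_cells}, \code{defined}.  \code{defined} is
#'   \code{FALSE} when the dataset has no cells of the target type;
#'   a marker positive in no cell gets precision \code{NA} and f1 0.
#' @export
markerF1 <- function(sce, gene, targetType, level = c("main", "fine"),
                     threshold = 0, datasetId = 1L) {
  level <- match.arg(level)
  .assertGene(gene, rownames(sce))
  labels <- SummarizedExperiment::colData(sce)[[paste0(level, "_type")]]
  if (is.null(labels)) stop("no '", level, "_type' column in colData")
  actual <- !is.na(labels) & labels == targetType
  nTarget <- sum(actual)
  if (nTarget == 0) {
    return(S4Vectors::DataFrame(gene = gene, dataset_id = datasetId,
                                target_type = targetType, level = level,
                                precision = NA_real_, recall = NA_real_,
                                f1 = NA_real_, n_target_cells = 0L,
                                defined = FALSE))
  }
  pred <- .logcounts(sce)[gene, ] > threshold
  tp <- sum(pred & actual)
  prec <- if (sum(pred) == 0) NA_real_ else tp / sum(pred)
  rec <- tp / nTarget
  f1 <- if (is.na(prec) || prec + rec == 0) 0 else
    2 * prec * rec / (prec + rec)
  S4Vectors::DataFrame(gene = gene, dataset_id = datasetId,
                       target_type = targetType, level = level,
                       precision = prec, recall = rec, f1 = f1,
                       n_target_cells = nTarget, defined = TRUE)
}

#' Fine-marker screening and validation workflow
#'
#' Applies the two fine-marker rules across datasets: markers flagged
#' unstable by the LOF tally are removed outright; the rest are validated
#' by F1 score in the datasets where their target type occurs.  A marker
#' is \code{"validated"} when its type occurs in at least
#' \code{coverageMin} of the datasets and its F1 reaches \code{f1Min} in
#' at least \code{f1FracMin} of those, \code{"insufficient-coverage"} when
#' the type is too rare, and \code{"failed"} otherwise.
#'
#' @param datasets list of \code{SingleCellExperiment}s with
#'   \code{logcounts} and \code{fine_type} labels.
#' @param catalog a \code{\link{MarkerCatalog}}; its \code{fine}-level
#'   entries are evaluated.
#' @param tallies a \code{\link{lofTally}} result covering the fine markers.
#' @param f1Min minimum F1 (default 0.6).
#' @param coverageMin minimum fraction of datasets containing the type.
#' @param f1FracMin fraction of covered datasets that must reach
#'   \code{f1Min}.
#' @param threshold positivity threshold passed to \code{\link{markerF1}}.
#' @return \code{DataFrame} with one row per fine catalog entry:
#'   \code{gene}, \code{cell_type}, \code{verdict}, \code{coverage},
#'   \code{n_covered}, \code{median_f1}, \code{frac_f1_pass}.
#' @export
fineMarkerWorkflow <- function(datasets, catalog, tallies, f1Min = 0.6,
                               coverageMin = 0.6, f1FracMin = 0.8,
                               threshold = 0) {
  e <- catalogEntries(catalog)
  e <- e[e$level == "fine", , drop = FALSE]
  if (nrow(e) == 0) stop("catalog has no fine-level entries")
  nD <- length(datasets)
  typePresent <- lapply(datasets, function(d)
    unique(SummarizedExperiment::colData(d)$fine_type))
  rows <- lapply(seq_len(nrow(e)), function(i) {
    g <- e$gene[i]; ty <- e$cell_type[i]
    covered <- vapply(typePresent, function(tp) ty %in% tp, logical(1))
    coverage <- mean(covered)
    tl <- tallies[tallies$gene == g, , drop = FALSE]
    unstable <- nrow(tl) > 0 && isTRUE(tl$unstable_flag[1])
    if (unstable) {
      verdict <- "removed-unstable"
      f1s <- numeric(0)
    } else if (coverage < coverageMin) {
      verdict <- "insufficient-coverage"
      f1s <- numeric(0)
    } else {
      f1s <- vapply(which(covered), function(j)
        markerF1(datasets[[j]], g, ty, level = "fine",
                 threshold = threshold, datasetId = j)$f1, numeric(1))
      verdict <- if (mean(f1s >= f1Min) >= f1FracMin) "validated" else "failed"
    }
    S4Vectors::DataFrame(gene = g, cell_type = ty, verdict = verdict,
                         coverage = coverage, n_covered = sum(covered),
                         median_f1 = if (length(f1s)) stats::median(f1s)
                                     else NA_real_,
                         frac_f1_pass = if (length(f1s)) mean(f1s >= f1Min)
                                        else NA_real_)
  })
  do.call(rbind, rows)
}
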