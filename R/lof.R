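#' Local outlier factor scores
#'
#' Standard LOF (k-distance neighborhoods, reachability distances, local
#' reachability density, mean density ratio over neighbors).  The
#' neighborhood of a point is all points within its k-distance, so tied
#' distances enlarge neighborhoods as in the original definition.  Zero
#' inter-point distances (duplicate points) are replaced by machine
#' epsilon so densities stay finite.
#'
#' Scores are about 1 for points whose local density matches their
#' neighbors', and grow above 1 for points sitting in sparser surroundings
#' than their neighbors — the signature of scattered "outlier" positives.
#'
#' @param points numeric matrix (n x 2, or n x d) of coordinates.
#' @param k neighborhood size (default 20); requires \code{n >= k + 1}.
#' @return numeric vector of n positive LOF scores.
#' @examples
#' set.seed(1)
#' pts <- matrix(rnorm(100), ncol = 2)
#' summary(lofScores(pts, k = 10))
#' @export
lofScores <- function(points, k = 20) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (!all(is.finite(points))) stop("coordinates must be finite")
  if (n <= k) stop("need more than k = ", k, " points, got ", n)
  eps <- .Machine$double.eps

  # k-distance via fast k-NN, then widen neighborhoods to include ties
  kn <- FNN::get.knn(points, k = min(k + 10L, n - 1L))
  kdist <- pmax(kn$nn.dist[, k], eps)
  nnIdx <- vector("list", n)
  nnDist <- vector("list", n)
  for (i in seq_len(n)) {
    d <- kn$nn.dist[i, ]
    keep <- which(d <= kdist[i] + eps * kdist[i])
    if (length(keep) == ncol(kn$nn.dist) && ncol(kn$nn.dist) < n - 1L) {
      # tie block may extend past the widened search: fall back to full scan
      dd <- sqrt(colSums((t(points) - points[i, ])^2))
      dd[i] <- Inf
      keep2 <- which(dd <= kdist[i] + eps * kdist[i])
      nnIdx[[i]] <- keep2
      nnDist[[i]] <- pmax(dd[keep2], eps)
    } else {
      nnIdx[[i]] <- kn$nn.index[i, keep]
      nnDist[[i]] <- pmax(d[keep], eps)
    }
  }

  lrd <- numeric(n)
  for (i in seq_len(n)) {
    reach <- pmax(kdist[nnIdx[[i]]], nnDist[[i]])
    lrd[i] <- length(reach) / sum(reach)
  }
  vapply(seq_len(n), function(i) mean(lrd[nnIdx[[i]]]) / lrd[i], numeric(1))
}

#' LOF screen of one marker on a dataset's embedding
#'
#' Collects the marker's positive cells (raw count > 0, or normalized
#' expression above \code{exprThreshold} when given), computes LOF scores
#' within that positive-cell point set on the 2-D embedding, and
#' classifies the marker by its mean score: \code{"gt1"} if above
#' \code{1 + tol} (dispersed positives), \code{"lt1"} if below
#' \code{1 - tol}, \code{"eq1"} otherwise, or \code{"insufficient"} when
#' fewer than \code{k + 1} cells are positive.
#'
#' @param sce a \code{SingleCellExperiment} with a \code{"UMAP"}
#'   \code{reducedDim} covering all cells.
#' @param gene gene symbol.
#' @param k LOF neighborhood size.
#' @param tol half-width of the "score = 1" band.
#' @param exprThreshold optional positivity threshold on \code{logcounts}
#'   instead of the raw-count rule.
#' @param datasetId identifier recorded in the output.
#' @return one-row \code{DataFrame}: \code{gene}, \code{dataset_id},
#'   \code{n_positive_cells}, \code{lof_score} (NA when insufficient),
#'   \code{classification}.
#' @export
markerLOF <- function(sce, gene, k = 20, tol = 0.05, exprThreshold = NULL,
                      datasetId = 1L) {
  .assertGene(gene, rownames(sce))
  if (!"UMAP" %in% SingleCellExperiment::reducedDimNames(sce))
    stop("no 'UMAP' reducedDim; run embedCells() or supply coordinates")
  um <- SingleCellExperiment::reducedDim(sce, "UMAP")
  if (nrow(um) != ncol(sce) || anyNA(um))
    stop("embedding must cover all cells")
  pos <- if (is.null(exprThreshold)) {
    .counts(sce)[gene, ] > 0
  } else {
    .logcounts(sce)[gene, ] > exprThreshold
  }
  nPos <- sum(pos)
  if (nPos < k + 1) {
    return(S4Vectors::DataFrame(gene = gene, dataset_id = datasetId,
                                n_positive_cells = nPos,
                                lof_score = NA_real_,
                                classification = "insufficient"))
  }
  score <- mean(lofScores(um[pos, , drop = FALSE], k = k))
  cls <- if (score > 1 + tol) "gt1" else if (score < 1 - tol) "lt1" else "eq1"
  S4Vectors::DataFrame(gene = gene, dataset_id = datasetId,
                       n_positive_cells = nPos, lof_score = score,
                       classification = cls)
}

#' Tally LOF classifications across datasets
#'
#' For each gene, the fractions of datasets (among those with a defined
#' score) classified below, at, and above 1, plus the instability flag:
#' a marker dispersed (\code{gt1}) in every dataset with a defined score
#' is considered to have an unstable typing ability.
#'
#' @param results \code{DataFrame} rbind of \code{\link{markerLOF}} rows
#'   across genes and datasets (or a list of such tables).
#' @return \code{DataFrame} with columns \code{gene}, \code{n_defined},
#'   \code{pct_lt1}, \code{pct_eq1}, \code{pct_gt1}, \code{unstable_flag},
#'   \code{all_insufficient}.
#' @export
lofTally <- function(results) {
  if (is.list(results) && !methods::is(results, "DataFrame"))
    results <- do.call(rbind, results)
  genes <- unique(results$gene)
  rows <- lapply(genes, function(g) {
    sub <- results[results$gene == g, , drop = FALSE]
    def <- sub$classification != "insufficient"
    nd <- sum(def)
    if (nd == 0) {
      return(S4Vectors::DataFrame(gene = g, n_defined = 0L, pct_lt1 = NA_real_,
                                  pct_eq1 = NA_real_, pct_gt1 = NA_real_,
                                  unstable_flag = FALSE,
                                  all_insufficient = TRUE))
    }
    cls <- sub$classification[def]
    S4Vectors::DataFrame(gene = g, n_defined = nd,
                         pct_lt1 = mean(cls == "lt1"),
                         pct_eq1 = mean(cls == "eq1"),
                         pct_gt1 = mean(cls == "gt1"),
                         unstable_flag = all(cls == "gt1"),
                         all_insufficient = FALSE)
  })
  do.call(rbind, rows)
}
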