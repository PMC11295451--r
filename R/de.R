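#' Two-sided Wilcoxon rank-sum test
#'
#' Rank-sum test used by \code{\link{deTable}}.  When both groups have at
#' most \code{exactMax} observations the p-value comes from the exact null
#' distribution of the rank sum, computed for the observed (possibly tied)
#' midrank multiset by a generating-function convolution — so exact
#' p-values remain correct under ties.  Larger samples use the normal
#' approximation with tie and continuity corrections.
#'
#' @param x,y numeric samples.
#' @param exactMax exact-path threshold on both group sizes.
#' @return list with \code{statistic} (rank sum of \code{x}) and
#'   \code{p.value}.
#' @examples
#' rankSumTest(c(5, 6, 7), c(1, 2, 3))$p.value  # 0.1
#' @export
rankSumTest <- function(x, y, exactMax = 25) {
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  if (n1 == 0 || n2 == 0) stop("both groups must be nonempty")
  r <- rank(c(x, y))
  W <- sum(r[seq_len(n1)])
  if (n1 <= exactMax && n2 <= exactMax) {
    p <- .exactRankSumP(r, n1, W)
  } else {
    p <- .normalRankSumP(r, n1, W)
  }
  list(statistic = W, p.value = p)
}

# Exact two-sided p for the rank sum W of a size-n1 subset of midranks r.
# Counts subsets by dynamic programming on the doubled (integer) midranks;
# counts stay below 2^53 for N <= 50.
.exactRankSumP <- function(r, n1, W) {
  v <- as.integer(round(2 * r))
  S <- sum(v)
  # f[j+1, s+1] = number of subsets of size j with doubled-rank sum s
  f <- matrix(0, n1 + 1, S + 1)
  f[1, 1] <- 1
  for (val in v) {
    jmax <- n1
    for (j in jmax:1) {
      src <- f[j, 1:(S + 1 - val)]
      if (any(src != 0))
        f[j + 1, (val + 1):(S + 1)] <- f[j + 1, (val + 1):(S + 1)] + src
    }
  }
  dist <- f[n1 + 1, ]
  total <- sum(dist)
  w2 <- as.integer(round(2 * W))
  pLe <- sum(dist[seq_len(w2 + 1)]) / total
  pGe <- sum(dist[(w2 + 1):(S + 1)]) / total
  min(1, 2 * min(pLe, pGe))
}

# Normal approximation with tie correction and continuity correction.
.normalRankSumP <- function(r, n1, W) {
  N <- length(r); n2 <- N - n1
  mu <- n1 * (N + 1) / 2
  ties <- table(r)
  sigma2 <- n1 * n2 / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
  if (sigma2 <= 0) return(1)
  d <- W - mu
  z <- (d - sign(d) * 0.5) / sqrt(sigma2)
  if (d == 0) return(1)
  min(1, 2 * stats::pnorm(-abs(z)))
}

#' Seurat-convention average log2 fold change
#'
#' \code{log2((mean(expm1(in)) + pseudocount) /
#' (mean(expm1(out)) + pseudocount))} on log-normalized values, the
#' convention behind the \code{avg_log2FC} column of cluster-marker
#' tables.
#'
#' @param inVals,outVals log-normalized expression inside / outside the
#'   cluster.
#' @param pseudocount stabilizer added to both de-logged means (default 1;
#'   with 0 the statistic negates exactly under group swap).
#' @return numeric scalar.
#' @export
avgLog2FC <- function(inVals, outVals, pseudocount = 1) {
  log2((mean(expm1(inVals)) + pseudocount) /
       (mean(expm1(outVals)) + pseudocount))
}

#' Per-gene, per-cluster differential-expression metrics
#'
#' For every requested gene and every cluster, computes the four metrics
#' the entropy ranking consumes, in the Seurat column dialect:
#' \code{pct.1} (fraction of in-cluster cells with a nonzero count),
#' \code{pct.2} (same outside), \code{diff_pct = pct.1 - pct.2},
#' \code{avg_log2FC} (see \code{\link{avgLog2FC}}), the two-sided Wilcoxon
#' \code{p_val} on log-normalized values (cluster vs all other cells), and
#' \code{p_val_adj}, Bonferroni-corrected over all tested gene x cluster
#' pairs and capped at 1.
#'
#' @param sce a \code{SingleCellExperiment} with \code{counts} and
#'   \code{logcounts} assays and a \code{cluster} colData column.
#' @param genes genes to test (default: all).
#' @param adjust \code{"bonferroni"} (default) or \code{"BH"}.
#' @return \code{DataFrame} with columns \code{gene}, \code{cluster},
#'   \code{avg_log2FC}, \code{pct.1}, \code{pct.2}, \code{diff_pct},
#'   \code{p_val}, \code{p_val_adj}.
#' @export
deTable <- function(sce, genes = rownames(sce), adjust = c("bonferroni", "BH")) {
  adjust <- match.arg(adjust)
  .assertGene(genes, rownames(sce))
  cl <- SummarizedExperiment::colData(sce)$cluster
  if (is.null(cl)) stop("no 'cluster' column in colData")
  cl <- droplevels(factor(cl))
  if (nlevels(cl) < 2) stop("need at least 2 clusters")
  sizes <- table(cl)
  if (any(sizes < 3))
    stop("cluster(s) with fewer than 3 cells: ",
         paste(names(sizes)[sizes < 3], collapse = ", "))
  if (!"logcounts" %in% SummarizedExperiment::assayNames(sce))
    sce <- logNormalize(sce)
  cnt <- .counts(sce)[genes, , drop = FALSE]
  lc <- .logcounts(sce)[genes, , drop = FALSE]
  clusters <- levels(cl)
  n <- ncol(cnt)
  idx <- lapply(clusters, function(k) which(cl == k))
  names(idx) <- clusters

  res <- vector("list", length(genes) * length(clusters))
  pos <- 0L
  for (g in seq_along(genes)) {
    vals <- lc[g, ]
    posCell <- cnt[g, ] > 0
    r <- rank(vals)
    ties <- table(r)
    tieTerm <- sum(ties^3 - ties) / (n * (n - 1))
    expm1Vals <- expm1(vals)
    for (k in clusters) {
      ii <- idx[[k]]
      n1 <- length(ii); n2 <- n - n1
      pct1 <- mean(posCell[ii]); pct2 <- mean(posCell[-ii])
      lfc <- log2((mean(expm1Vals[ii]) + 1) / (mean(expm1Vals[-ii]) + 1))
      if (n1 <= 25 && n2 <= 25) {
        p <- .exactRankSumP(r, n1, sum(r[ii]))
      } else {
        W <- sum(r[ii])
        mu <- n1 * (n + 1) / 2
        sigma2 <- n1 * n2 / 12 * ((n + 1) - tieTerm)
        d <- W - mu
        p <- if (d == 0 || sigma2 <= 0) 1 else
          min(1, 2 * stats::pnorm(-abs((d - sign(d) * 0.5) / sqrt(sigma2))))
      }
      pos <- pos + 1L
      res[[pos]] <- data.frame(gene = genes[g], cluster = k,
                               avg_log2FC = lfc, pct.1 = pct1, pct.2 = pct2,
                               diff_pct = pct1 - pct2, p_val = p,
                               stringsAsFactors = FALSE, check.names = FALSE)
    }
  }
  out <- do.call(rbind, res)
  out$p_val_adj <- if (adjust == "bonferroni")
    pmin(1, out$p_val * nrow(out)) else stats::p.adjust(out$p_val, "BH")
  S4Vectors::DataFrame(out, check.names = FALSE)
}

#' Screen markers significantly up-regulated in target clusters
#'
#' Keeps the genes whose adjusted p-value is below \code{alpha} and whose
#' \code{avg_log2FC} exceeds \code{lfcMin} in the target clusters — in
#' every target cluster by default (\code{mode = "all"}), or in at least
#' one (\code{mode = "any"}).
#'
#' @param de a \code{\link{deTable}} result.
#' @param targetClusters clusters the marker should be up-regulated in.
#' @param alpha significance level on \code{p_val_adj}.
#' @param lfcMin minimum \code{avg_log2FC}.
#' @param mode \code{"all"} or \code{"any"}.
#' @return character vector of retained genes, input order preserved.
#' @export
screenUpregulated <- function(de, targetClusters, alpha = 0.05,
                              lfcMin = 0.25, mode = c("all", "any")) {
  mode <- match.arg(mode)
  if (length(targetClusters) == 0) stop("targetClusters must be nonempty")
  obs <- unique(de$cluster)
  bad <- setdiff(targetClusters, obs)
  if (length(bad))
    stop("target cluster(s) not in DE table: ", paste(bad, collapse = ", "))
  genes <- unique(de$gene)
  keep <- vapply(genes, function(g) {
    sub <- de[de$gene == g & de$cluster %in% targetClusters, , drop = FALSE]
    hits <- sub$p_val_adj < alpha & sub$avg_log2FC > lfcMin
    if (mode == "all") all(hits) else any(hits)
  }, logical(1))
  genes[keep]
}

#' Write / read a DE table TSV
#'
#' Column dialect mirrors Seurat's \code{FindMarkers} output
#' (\code{gene}, \code{cluster}, \code{avg_log2FC}, \code{pct.1},
#' \code{pct.2}, \code{diff_pct}, \code{p_val}, \code{p_val_adj}).
#'
#' @param de a \code{\link{deTable}} result.
#' @param path file path.
#' @return \code{readDETable}: a \code{DataFrame}; \code{writeDETable}:
#'   the path, invisibly.
#' @export
writeDETable <- function(de, path) writeTSV(as.data.frame(de), path)

#' @rdname writeDETable
#' @export
readDETable <- function(path) {
  S4Vectors::DataFrame(utils::read.delim(path, check.names = FALSE),
                       check.names = FALSE)
}
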