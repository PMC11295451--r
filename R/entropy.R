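#' Normalized entropy of a marker's per-cluster evidence
#'
#' Converts one DE metric's per-cluster values into nonnegative evidence
#' weights, then returns the Shannon entropy of the normalized weight
#' distribution divided by \code{log(C)} (C = number of clusters), so the
#' result lies in [0, 1]: 0 when all evidence sits in one cluster (a
#' perfectly specific marker), 1 when evidence is spread uniformly.
#'
#' Weight transforms by metric kind: \code{avg_log2FC} and
#' \code{diff_pct} are clipped at 0 (down-regulation is not evidence of
#' marking a type); \code{pct1} is used as is; \code{p_val_adj} enters as
#' \code{-log10(max(p, 1e-300))} so small p-values contribute concentrated
#' weight.  An all-zero weight vector returns 1 (maximally uninformative).
#'
#' @param values per-cluster metric values (length >= 2, finite).
#' @param kind one of \code{"avg_log2FC"}, \code{"pct1"},
#'   \code{"diff_pct"}, \code{"p_val_adj"}.
#' @return normalized entropy in [0, 1].
#' @examples
#' metricEntropy(c(1, 0, 0), "avg_log2FC")      # 0: one-hot
#' metricEntropy(c(0.5, 0.5, 0.5), "pct1")      # 1: uniform
#' @export
metricEntropy <- function(values, kind = c("avg_log2FC", "pct1", "diff_pct",
                                           "p_val_adj")) {
  kind <- match.arg(kind)
  if (length(values) < 2) stop("need values for at least 2 clusters")
  if (any(!is.finite(values))) stop("non-finite metric values")
  w <- switch(kind,
              avg_log2FC = pmax(values, 0),
              diff_pct = pmax(values, 0),
              pct1 = values,
              p_val_adj = -log10(pmax(values, 1e-300)))
  if (kind == "pct1" && any(w < 0)) stop("pct1 values must be nonnegative")
  s <- sum(w)
  if (s == 0) return(1)
  p <- w / s
  p <- p[p > 0]
  -sum(p * log(p)) / log(length(values))
}

#' Per-marker entropy profiles within one dataset
#'
#' Computes the four metric entropies for every gene of a DE table,
#' their sum (\code{total_entropy}, in [0, 4]), and the within-dataset
#' rank by ascending total entropy (rank 1 = most cluster-specific;
#' ties share the mean rank).
#'
#' A cluster counts as carrying evidence for a marker only where the
#' marker is significantly up-regulated (\code{p_val_adj < gateAlpha} and
#' \code{avg_log2FC > 0}); other clusters contribute zero weight to all
#' four metrics.  Without the gate, two artifacts corrupt the ranking:
#' sampling noise around zero makes a uniformly expressed marker's clipped
#' fold changes look spuriously concentrated, and the two-sided rank-sum
#' test hands strong \code{-log10(p)} weight to clusters where the marker
#' is significantly \emph{down}.  A marker with no evidence in any cluster
#' gets all four entropies equal to 1 (maximally uninformative).  Set
#' \code{gateAlpha = NULL} to feed the raw metric values through.
#'
#' @param de a \code{\link{deTable}} result covering all clusters for each
#'   gene.
#' @param datasetId identifier recorded in the output.
#' @param gateAlpha significance gate on \code{p_val_adj} (default 0.05).
#' @return \code{DataFrame} with columns \code{gene}, \code{dataset_id},
#'   \code{h_avg_log2FC}, \code{h_pct1}, \code{h_diff_pct}, \code{h_padj},
#'   \code{total_entropy}, \code{rank}.
#' @export
entropyProfiles <- function(de, datasetId = 1L, gateAlpha = 0.05) {
  genes <- sort(unique(de$gene))
  clusters <- sort(unique(de$cluster))
  h <- t(vapply(genes, function(g) {
    sub <- de[de$gene == g, , drop = FALSE]
    miss <- setdiff(clusters, sub$cluster)
    if (length(miss))
      stop("gene ", g, " missing cluster(s): ", paste(miss, collapse = ", "))
    sub <- sub[match(clusters, sub$cluster), , drop = FALSE]
    lfc <- sub$avg_log2FC
    pct1 <- sub$`pct.1`
    dpct <- sub$diff_pct
    padj <- sub$p_val_adj
    if (!is.null(gateAlpha)) {
      evid <- padj < gateAlpha & lfc > 0
      lfc[!evid] <- 0
      pct1[!evid] <- 0
      dpct[!evid] <- 0
      padj[!evid] <- 1        # -log10 weight 0
    }
    c(metricEntropy(lfc, "avg_log2FC"),
      metricEntropy(pct1, "pct1"),
      metricEntropy(dpct, "diff_pct"),
      metricEntropy(padj, "p_val_adj"))
  }, numeric(4)))
  rownames(h) <- NULL
  total <- rowSums(h)
  S4Vectors::DataFrame(gene = genes, dataset_id = datasetId,
                       h_avg_log2FC = h[, 1], h_pct1 = h[, 2],
                       h_diff_pct = h[, 3], h_padj = h[, 4],
                       total_entropy = total,
                       rank = rank(total, ties.method = "average"))
}

#' Cross-dataset entropy summary
#'
#' Aggregates per-dataset \code{\link{entropyProfiles}} into per-marker
#' totals: \code{rank_sum} (sum of within-dataset ranks) and
#' \code{total_entropy_sum}.  Markers are ordered by ascending
#' \code{rank_sum}, then ascending \code{total_entropy_sum}, then gene
#' symbol — so the first row is the most robust marker across datasets.
#'
#' @param profiles list of \code{\link{entropyProfiles}} results (one per
#'   dataset) sharing the same marker panel.
#' @return \code{DataFrame} with columns \code{gene},
#'   \code{total_entropy_sum}, \code{rank_sum}, \code{n_datasets}.
#' @export
entropySummary <- function(profiles) {
  if (!length(profiles)) stop("no profiles supplied")
  genes <- sort(unique(profiles[[1]]$gene))
  for (pr in profiles) {
    miss <- setdiff(genes, pr$gene)
    extra <- setdiff(pr$gene, genes)
    if (length(miss) || length(extra))
      stop("marker panel mismatch across datasets: ",
           paste(c(miss, extra), collapse = ", "))
  }
  rs <- rowSums(vapply(profiles,
                       function(pr) pr$rank[match(genes, pr$gene)],
                       numeric(length(genes))))
  es <- rowSums(vapply(profiles,
                       function(pr) pr$total_entropy[match(genes, pr$gene)],
                       numeric(length(genes))))
  out <- S4Vectors::DataFrame(gene = genes, total_entropy_sum = es,
                              rank_sum = rs,
                              n_datasets = length(profiles))
  out[order(out$rank_sum, out$total_entropy_sum, out$gene), , drop = FALSE]
}

#' Pearson correlation of entropy profiles between datasets
#'
#' Correlates datasets by their per-marker total-entropy vectors; high
#' correlation means the marker panel behaves consistently in both
#' datasets.
#'
#' @param profiles list of \code{\link{entropyProfiles}} results sharing
#'   one marker panel of at least 3 genes.
#' @return symmetric correlation matrix (unit diagonal); entries involving
#'   a constant entropy vector are \code{NA}.
#' @export
datasetCorrelation <- function(profiles) {
  genes <- sort(unique(profiles[[1]]$gene))
  if (length(genes) < 3) stop("need at least 3 markers")
  mat <- vapply(profiles,
                function(pr) pr$total_entropy[match(genes, pr$gene)],
                numeric(length(genes)))
  ids <- vapply(profiles, function(pr) as.character(pr$dataset_id[1]),
                character(1))
  colnames(mat) <- ids
  r <- suppressWarnings(stats::cor(mat))
  diag(r) <- 1
  r
}
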