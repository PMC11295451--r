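#' Heatmap of between-dataset entropy correlations
#'
#' @param mat a \code{\link{datasetCorrelation}} matrix.
#' @param file optional PNG path; when \code{NULL}, plots to the current
#'   device.
#' @return \code{file}, invisibly.
#' @export
plotDatasetCorrelation <- function(mat, file = NULL) {
  if (!is.null(file)) grDevices::png(file, 640, 600)
  op <- graphics::par(mar = c(6, 6, 2, 2))
  on.exit({ graphics::par(op); if (!is.null(file)) grDevices::dev.off() })
  n <- nrow(mat)
  graphics::image(seq_len(n), seq_len(n), t(mat[n:1, , drop = FALSE]),
                  zlim = c(-1, 1), axes = FALSE, xlab = "", ylab = "",
                  col = grDevices::hcl.colors(51, "Blue-Red 3", rev = TRUE),
                  main = "Between-dataset entropy correlation")
  graphics::axis(1, seq_len(n), colnames(mat), las = 2)
  graphics::axis(2, seq_len(n), rev(rownames(mat)), las = 2)
  for (i in seq_len(n)) for (j in seq_len(n))
    graphics::text(j, n - i + 1, sprintf("%.2f", mat[i, j]), cex = 0.8)
  invisible(file)
}

#' Stacked-bar summary of LOF classifications per marker
#'
#' Three bands per marker: the fraction of datasets with mean LOF below,
#' at, and above 1.
#'
#' @param tally a \code{\link{lofTally}} result.
#' @param file optional PNG path.
#' @return \code{file}, invisibly.
#' @export
plotLOFTally <- function(tally, file = NULL) {
  t2 <- tally[!tally$all_insufficient, , drop = FALSE]
  if (nrow(t2) == 0) stop("no defined LOF tallies to plot")
  if (!is.null(file)) grDevices::png(file, 160 + 40 * nrow(t2), 520)
  op <- graphics::par(mar = c(8, 4, 2, 1))
  on.exit({ graphics::par(op); if (!is.null(file)) grDevices::dev.off() })
  m <- rbind(lt1 = t2$pct_lt1, eq1 = t2$pct_eq1, gt1 = t2$pct_gt1)
  colnames(m) <- t2$gene
  graphics::barplot(m, col = c("#4575b4", "#bdbdbd", "#d73027"), las = 2,
                    ylab = "fraction of datasets",
                    legend.text = c("LOF < 1", "LOF = 1", "LOF > 1"),
                    args.legend = list(x = "topright", bty = "n", cex = 0.8))
  invisible(file)
}

#' Scatter of regrouped clusters on panel-mean principal components
#'
#' Projects the cluster x panel mean-expression matrix onto its first two
#' principal components and colors clusters by K-means group.
#'
#' @param rr a \code{\link{regroupClusters}} result.
#' @param file optional PNG path.
#' @return \code{file}, invisibly.
#' @export
plotRegroup <- function(rr, file = NULL) {
  if (!is.null(file)) grDevices::png(file, 600, 560)
  if (!is.null(file)) on.exit(grDevices::dev.off())
  m <- scale(rr$cluster_panel_means)
  m[, !is.finite(colSums(m))] <- 0
  pc <- stats::prcomp(m)$x
  xy <- if (ncol(pc) >= 2) pc[, 1:2] else cbind(pc[, 1], 0)
  graphics::plot(xy, col = c("#d73027", "#4575b4")[rr$kmeans_group],
                 pch = 19, cex = 1.6, xlab = "PC1 of panel means",
                 ylab = "PC2 of panel means",
                 main = sprintf("dataset %s: purity %.2f",
                                rr$dataset_id, rr$purity))
  graphics::text(xy, labels = rr$cluster_ids, pos = 3, cex = 0.8)
  invisible(file)
}
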