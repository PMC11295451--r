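library(SingleCellExperiment)

# small three-fine-type world used by most unit tests
tinyTree <- function() {
  list(epithelial = c("luminal", "basal"), stromal = "fibroblast")
}

tinyProps <- function(nDatasets = 2) {
  p <- rbind(c(0.40, 0.30, 0.30), c(0.30, 0.30, 0.40),
             c(0.35, 0.25, 0.40), c(0.25, 0.40, 0.35))[seq_len(nDatasets), ,
                                                       drop = FALSE]
  colnames(p) <- unlist(tinyTree(), use.names = FALSE)
  p
}

tinyConfig <- function(seed = 11, nDatasets = 2, nCells = 600, nGenes = 300,
                       markers = NULL, nStruct = 20) {
  if (is.null(markers))
    markers <- rbind(
      markerSpec("EPI1", "epithelial", "specific", 8),
      markerSpec("LUM1", "luminal", "specific", 32),
      markerSpec("DIF1", "epithelial", "diffuse", 8,
                 off_target_types = "fibroblast"))
  simConfig(nDatasets, nCells, nGenes, tinyTree(), tinyProps(nDatasets),
            markerSpecs = markers, structureGenesPerType = nStruct,
            seed = seed)
}

# one normalized tiny dataset, cached per helper load
.tinyCache <- new.env()
tinyDataset <- function() {
  if (is.null(.tinyCache$sce)) {
    sims <- simulateDatasets(tinyConfig())
    .tinyCache$sce <- logNormalize(sims[[1]])
  }
  .tinyCache$sce
}

# independent naive LOF: straight transcription of the definition,
# O(n^2) distances, plain loops
oracleLOF <- function(points, k) {
  n <- nrow(points)
  d <- as.matrix(stats::dist(points))
  eps <- .Machine$double.eps
  d[d < eps] <- eps
  diag(d) <- Inf
  kdist <- numeric(n)
  nbrs <- vector("list", n)
  for (i in 1:n) {
    ds <- sort(d[i, ])
    kdist[i] <- max(ds[k], eps)
    nbrs[[i]] <- which(d[i, ] <= kdist[i] + eps * kdist[i])
  }
  lrd <- numeric(n)
  for (i in 1:n) {
    reach <- numeric(length(nbrs[[i]]))
    for (j in seq_along(nbrs[[i]])) {
      o <- nbrs[[i]][j]
      reach[j] <- max(kdist[o], d[i, o])
    }
    lrd[i] <- length(reach) / sum(reach)
  }
  out <- numeric(n)
  for (i in 1:n) out[i] <- mean(lrd[nbrs[[i]]]) / lrd[i]
  out
}

# independent exact two-sided rank-sum p by full subset enumeration
oracleRankSumP <- function(x, y) {
  n1 <- length(x)
  r <- rank(c(x, y))
  W <- sum(r[seq_len(n1)])
  sums <- combn(r, n1, sum)
  pLe <- mean(sums <= W + 1e-9)
  pGe <- mean(sums >= W - 1e-9)
  min(1, 2 * min(pLe, pGe))
}
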