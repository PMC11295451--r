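## Internal helpers shared across stages.

# Deterministic substream seeds: stage seeds are derived from one master
# seed so individual stages can be rerun in isolation.  Kept below 2^31.
deriveSeed <- function(master, stage, index = 0L) {
  stopifnot(is.numeric(master), length(master) == 1L)
  offs <- c(simulate = 1e6, embed = 2e6, cluster = 3e6, kmeans = 4e6,
            pipeline = 5e6)
  if (!stage %in% names(offs)) stop("unknown stage: ", stage)
  as.integer((as.numeric(master) + offs[[stage]] + 997 * index) %% 2147483647)
}

# fine type -> main type lookup from a type tree
fineToMain <- function(typeTree) {
  map <- rep(names(typeTree), lengths(typeTree))
  names(map) <- unlist(typeTree, use.names = FALSE)
  map
}

.assertGene <- function(gene, geneIds) {
  missing <- setdiff(gene, geneIds)
  if (length(missing))
    stop("gene(s) not present in matrix: ", paste(missing, collapse = ", "))
}

# logcounts accessor that insists normalization happened
.logcounts <- function(sce) {
  if (!"logcounts" %in% SummarizedExperiment::assayNames(sce))
    stop("no 'logcounts' assay; run logNormalize() first")
  SummarizedExperiment::assay(sce, "logcounts")
}

.counts <- function(sce) {
  SummarizedExperiment::assay(sce, "counts")
}

# top principal components of a cells x features matrix; truncated SVD
# for the usual case, exact SVD when most components are requested
# (irlba is neither efficient nor quiet there)
.topPCs <- function(x, nPCs, seed) {
  nPCs <- min(nPCs, nrow(x) - 1L, ncol(x) - 1L)
  set.seed(seed)
  if (nPCs > min(dim(x)) / 3) {
    p <- stats::prcomp(x, center = TRUE, scale. = FALSE)
    p$x[, seq_len(nPCs), drop = FALSE]
  } else {
    irlba::prcomp_irlba(x, n = nPCs, center = TRUE, scale. = FALSE)$x
  }
}

# fixed-format TSV writer so pipeline reruns are byte-identical
writeTSV <- function(df, path) {
  df <- as.data.frame(df)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
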