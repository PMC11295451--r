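test_that("simulation is deterministic and validates its configuration", {
  cfg <- tinyConfig(seed = 42)
  a <- simulateDatasets(cfg)
  b <- simulateDatasets(cfg)
  expect_identical(assay(a[[1]], "counts"), assay(b[[1]], "counts"))
  expect_identical(assay(a[[2]], "counts"), assay(b[[2]], "counts"))
  expect_length(a, 2)

  badProps <- tinyProps(2); badProps[1, 1] <- badProps[1, 1] + 0.05
  expect_error(simConfig(2, 100, 50, tinyTree(), badProps,
                         structureGenesPerType = 0),
               "sum to 1")
  dupSpecs <- rbind(markerSpec("M1", "luminal"), markerSpec("M1", "basal"))
  expect_error(tinyConfig(markers = dupSpecs), "duplicate")
  expect_error(simConfig(2, 100, 50, tinyTree(), tinyProps(2),
                         nbDispersion = -1, structureGenesPerType = 0),
               "nbDispersion")
})

test_that("a specific marker's mean-count ratio matches its fold change", {
  # fold_change 8, no extra dropout: target/off-target mean ratio ~ 8
  cfg <- simConfig(1, 2000, 200, tinyTree(), tinyProps(1),
                   markerSpecs = markerSpec("MK1", "luminal", "specific", 8),
                   structureGenesPerType = 0, seed = 5)
  sce <- simulateDatasets(cfg)[[1]]
  cnt <- assay(sce, "counts")["MK1", ]
  tgt <- sce$fine_type == "luminal"
  ratio <- mean(cnt[tgt]) / mean(cnt[!tgt])
  expect_gt(ratio, 6)
  expect_lt(ratio, 10)
})

test_that("per-cell totals track the drawn library sizes", {
  sce <- tinyDataset()
  L <- metadata(sce)$lib_size
  expect_gt(cor(colSums(assay(sce, "counts")), L), 0.9)
})

test_that("planted specific markers separate pct.1 from pct.2", {
  cfg <- simConfig(1, 1200, 150, tinyTree(), tinyProps(1),
                   markerSpecs = markerSpec("MK1", "luminal", "specific", 4),
                   structureGenesPerType = 0, seed = 9)
  sce <- logNormalize(simulateDatasets(cfg)[[1]])
  de <- deTable(sce, "MK1")
  lum <- de[de$cluster == "cl1", ]  # luminal is first fine type
  expect_gt(lum$diff_pct, 0.3)
})

test_that("unstable markers lose their fold change in unstable datasets", {
  ratio <- function(sce) {
    cnt <- assay(sce, "counts")["UNS1", ]
    tgt <- sce$fine_type == "luminal"
    mean(cnt[tgt]) / mean(cnt[!tgt])
  }
  stableR <- unstableR <- numeric(3)
  for (s in 1:3) {
    specs <- markerSpec("UNS1", "luminal", "unstable", 32,
                        unstable_datasets = 2L)
    sims <- simulateDatasets(tinyConfig(markers = specs, nCells = 2000,
                                        seed = s))
    stableR[s] <- ratio(sims[[1]])
    unstableR[s] <- ratio(sims[[2]])
  }
  expect_gt(min(stableR), 10)        # stable datasets keep the elevation
  expect_gte(mean(unstableR), 0.8)   # unstable datasets ~ flat on average
  expect_lte(mean(unstableR), 1.25)
})

test_that("embedding separates well-separated types and is reproducible", {
  skip_if_not_installed("cluster")
  # two types differing in 50 genes at fold change 8
  tree <- list(A = "a", B = "b")
  props <- matrix(c(0.5, 0.5), 1, dimnames = list(NULL, c("a", "b")))
  cfg <- simConfig(1, 500, 200, tree, props, structureGenesPerType = 50,
                   structureFoldChange = 8, seed = 2)
  sce <- embedCells(simulateDatasets(cfg)[[1]], seed = 1)
  um <- reducedDim(sce, "UMAP")
  sil <- cluster::silhouette(as.integer(factor(sce$fine_type)),
                             stats::dist(um))
  expect_gt(mean(sil[, "sil_width"]), 0.25)

  sce2 <- embedCells(simulateDatasets(cfg)[[1]], seed = 1)
  expect_identical(um, reducedDim(sce2, "UMAP"))

  # degenerate single-type input still embeds
  cfg1 <- simConfig(1, 120, 60, list(A = "a"),
                    matrix(1, 1, dimnames = list(NULL, "a")),
                    structureGenesPerType = 0, seed = 4)
  expect_no_error(emb1 <- embedCells(simulateDatasets(cfg1)[[1]], seed = 1))
  expect_identical(dim(reducedDim(emb1, "UMAP")), c(120L, 2L))
  expect_error(embedCells(simulateDatasets(cfg1)[[1]], nNeighbors = 200),
               "nNeighbors")
})
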