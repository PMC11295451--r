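test_that("regrouping separates a cleanly marked lineage", {
  sce <- tinyDataset()
  rr <- regroupClusters(sce, c("EPI1"), "epithelial", seed = 1)
  expect_identical(rr$purity, 1)
  expect_true(rr$separated)
  expect_identical(sort(rr$cluster_ids), c("cl1", "cl2", "cl3"))

  # purity is invariant to cluster order and k-means label swap
  perm <- sce[, rev(seq_len(ncol(sce)))]
  rr2 <- regroupClusters(perm, c("EPI1"), "epithelial", seed = 9)
  expect_identical(rr2$purity, 1)

  # constant panel: degenerate, purity falls to the majority fraction
  const <- sce
  cnt <- assay(const, "counts"); cnt["G0060", ] <- 1L
  assay(const, "counts") <- cnt
  const <- logNormalize(const)
  rr3 <- regroupClusters(const, "G0060", "epithelial", seed = 1)
  expect_false(rr3$separated)
  expect_equal(rr3$purity, 2 / 3)   # 2 epithelial clusters of 3

  expect_error(regroupClusters(sce, character(0), "epithelial"), "nonempty")
})

test_that("marker F1 follows confusion-matrix arithmetic", {
  # 20-cell fixture: TP = 8, FP = 2, FN = 2
  cnt <- matrix(1L, 2, 20, dimnames = list(c("mk", "base"), paste0("c", 1:20)))
  cnt["mk", ] <- 0L
  cnt["mk", c(1:8, 11:12)] <- 5L    # positives: 8 target + 2 non-target
  sce <- SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = cnt),
    colData = S4Vectors::DataFrame(
      cluster = rep(c("k1", "k2"), each = 10),
      fine_type = rep(c("T", "other"), each = 10)))
  sce <- logNormalize(sce)
  r <- markerF1(sce, "mk", "T", level = "fine")
  expect_equal(r$precision, 0.8, tolerance = 1e-12)
  expect_equal(r$recall, 0.8, tolerance = 1e-12)
  expect_equal(r$f1, 0.8, tolerance = 1e-12)

  # relabelling non-target types does not move F1
  sce2 <- sce
  colData(sce2)$fine_type <- c(rep("T", 10), paste0("z", 1:10))
  expect_equal(markerF1(sce2, "mk", "T", level = "fine")$f1, r$f1)

  # perfect marker; silent marker; absent target type
  cnt2 <- cnt; cnt2["mk", ] <- 0L; cnt2["mk", 1:10] <- 2L
  perf <- logNormalize(SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = cnt2), colData = colData(sce)))
  expect_identical(markerF1(perf, "mk", "T", level = "fine")$f1, 1)
  cnt3 <- cnt; cnt3["mk", ] <- 0L
  silent <- logNormalize(SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = cnt3), colData = colData(sce)))
  rs <- markerF1(silent, "mk", "T", level = "fine")
  expect_identical(rs$f1, 0)
  expect_true(is.na(rs$precision))
  rabs <- markerF1(sce, "mk", "ghost", level = "fine")
  expect_false(rabs$defined)

  # raising the threshold weakly decreases recall; extreme threshold -> 0
  th <- c(0, 1, 2, 10)
  recs <- vapply(th, function(t)
    markerF1(sce, "mk", "T", level = "fine", threshold = t)$recall,
    numeric(1))
  expect_true(all(diff(recs) <= 0))
  expect_identical(markerF1(sce, "mk", "T", level = "fine",
                            threshold = 1e6)$f1, 0)
})

test_that("fine-marker workflow routes every verdict path", {
  sims <- simulateDatasets(tinyConfig(seed = 21))
  sims <- lapply(sims, logNormalize)
  catalog <- markerCatalog(data.frame(
    level = "fine", cell_type = c("luminal", "luminal", "ghost"),
    gene = c("LUM1", "EPI1", "LUM1"), source = "planted"))
  tally <- S4Vectors::DataFrame(
    gene = c("LUM1", "EPI1"), n_defined = 2L, pct_lt1 = 0, pct_eq1 = 1,
    pct_gt1 = c(0, 1), unstable_flag = c(FALSE, TRUE),
    all_insufficient = FALSE)
  v <- fineMarkerWorkflow(sims, catalog, tally)
  expect_identical(v$verdict[v$gene == "LUM1" & v$cell_type == "luminal"],
                   "validated")
  # flagged marker is removed before any F1 is computed
  expect_identical(v$verdict[v$gene == "EPI1"], "removed-unstable")
  # type absent from every dataset -> insufficient coverage
  expect_identical(v$verdict[v$cell_type == "ghost"],
                   "insufficient-coverage")
  expect_identical(nrow(v), 3L)
})
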