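test_that("rank-sum test reproduces textbook exact p-values", {
  # in {5,6,7} vs out {1,2,3}: the most extreme of 20 assignments
  expect_equal(rankSumTest(c(5, 6, 7), c(1, 2, 3))$p.value, 0.1,
               tolerance = 1e-12)
  # symmetric case is maximally non-significant
  expect_equal(rankSumTest(c(1, 3), c(2, 2))$p.value, 1, tolerance = 1e-12)
})

test_that("exact path matches brute-force enumeration with ties", {
  set.seed(71)
  for (rep in 1:60) {
    n1 <- sample(2:8, 1); n2 <- sample(2:8, 1)
    x <- sample(0:4, n1, replace = TRUE)
    y <- sample(0:4, n2, replace = TRUE)
    expect_equal(rankSumTest(x, y)$p.value, oracleRankSumP(x, y),
                 tolerance = 1e-12)
  }
})

test_that("approximate path matches R's corrected normal approximation", {
  set.seed(72)
  for (rep in 1:25) {
    x <- rpois(40, 3); y <- rpois(35, 4)
    mine <- rankSumTest(x, y)$p.value
    ref <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                               correct = TRUE))$p.value
    expect_equal(mine, ref, tolerance = 1e-10)
  }
})

test_that("DE metrics follow their closed forms", {
  # 6 in-cluster cells expressing, 6 out-cluster silent
  cnt <- matrix(0L, 2, 12, dimnames = list(c("g1", "g2"), paste0("c", 1:12)))
  cnt[1, 1:6] <- 3L
  cnt[2, ] <- 1L               # keeps every cell total nonzero
  sce <- SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = cnt),
    colData = S4Vectors::DataFrame(cluster = rep(c("in", "out"), each = 6)))
  de <- deTable(sce, c("g1", "g2"))
  g1in <- de[de$gene == "g1" & de$cluster == "in", ]
  expect_identical(g1in$`pct.1`, 1)
  expect_identical(g1in$`pct.2`, 0)
  expect_identical(g1in$diff_pct, 1)
  expect_true(all(de$p_val_adj >= de$p_val))
  expect_true(all(de$p_val_adj <= 1))

  # avg_log2FC closed form: in-values ln(2), out-values 0 -> exactly 1
  expect_equal(avgLog2FC(c(log(2), log(2)), c(0, 0)), 1, tolerance = 1e-12)
  # without the pseudocount it negates exactly on dense positive data
  a <- log1p(c(2.3, 1.1, 4.2)); b <- log1p(c(0.5, 0.8, 1.9))
  expect_equal(avgLog2FC(a, b, pseudocount = 0),
               -avgLog2FC(b, a, pseudocount = 0), tolerance = 1e-12)

  expect_error(deTable(sce, "nope"), "nope")
  one <- sce[, 1:6]
  expect_error(deTable(one, "g1"), "2 clusters")
})

test_that("up-regulation screen keeps planted markers and drops nulls", {
  sce <- tinyDataset()
  de <- deTable(sce, c("EPI1", "LUM1", "DIF1", "G0100"))
  epiClusters <- c("cl1", "cl2")     # luminal + basal clusters
  kept <- screenUpregulated(de, epiClusters)
  expect_true("EPI1" %in% kept)
  expect_false("DIF1" %in% kept)
  expect_false("G0100" %in% kept)

  # vacuous thresholds return every gene, input order preserved
  all4 <- screenUpregulated(de, epiClusters, alpha = 1.01, lfcMin = -Inf)
  expect_identical(all4, unique(de$gene))
  expect_error(screenUpregulated(de, character(0)), "nonempty")
  expect_error(screenUpregulated(de, "cl9"), "cl9")
})

test_that("null genes are screened out at close to the nominal rate", {
  # fold_change 1 everywhere: Bonferroni screening should almost never keep
  kept <- 0L
  for (s in 1:20) {
    cfg <- simConfig(1, 240, 40, tinyTree(), tinyProps(1),
                     markerSpecs = markerSpec("NULL1", "luminal",
                                              "specific", 1),
                     structureGenesPerType = 0, seed = 100 + s)
    sce <- logNormalize(simulateDatasets(cfg)[[1]])
    de <- deTable(sce, "NULL1")
    kept <- kept + ("NULL1" %in% screenUpregulated(de, "cl1"))
  }
  expect_lte(kept / 20, 0.05)
})

test_that("DE tables round-trip through their TSV dialect", {
  sce <- tinyDataset()
  de <- deTable(sce, c("EPI1", "LUM1"))
  path <- withr::local_tempfile(fileext = ".tsv")
  writeDETable(de, path)
  hdr <- strsplit(readLines(path, n = 1), "\t")[[1]]
  expect_identical(hdr, c("gene", "cluster", "avg_log2FC", "pct.1", "pct.2",
                          "diff_pct", "p_val", "p_val_adj"))
  back <- readDETable(path)
  expect_equal(back$avg_log2FC, de$avg_log2FC, tolerance = 1e-12)
})
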