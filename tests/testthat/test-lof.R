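test_that("LOF matches a naive reference implementation", {
  set.seed(31)
  pts <- matrix(rnorm(100), ncol = 2)
  expect_lt(max(abs(lofScores(pts, k = 10) - oracleLOF(pts, k = 10))), 1e-9)
  pts2 <- matrix(runif(160), ncol = 2)
  expect_lt(max(abs(lofScores(pts2, k = 20) - oracleLOF(pts2, k = 20))), 1e-9)
})

test_that("LOF anchors: homogeneous grids, far outliers, duplicates", {
  g <- as.matrix(expand.grid(x = 1:15, y = 1:15))
  lof <- lofScores(g, k = 8)
  interior <- g[, 1] %in% 5:11 & g[, 2] %in% 5:11
  expect_true(all(lof[interior] >= 0.9 & lof[interior] <= 1.1))

  set.seed(32)
  cloud <- matrix(rnorm(400), ncol = 2)
  far <- rbind(cloud, c(100, 0))
  expect_gt(lofScores(far, k = 20)[201], 2)

  dup <- rbind(matrix(rnorm(60), ncol = 2), c(0, 0), c(0, 0))
  expect_true(all(is.finite(lofScores(dup, k = 5))))

  expect_error(lofScores(matrix(rnorm(20), ncol = 2), k = 20), "more than")
  expect_error(lofScores(matrix(c(1, NA), 1, 2), k = 1), "finite")
})

test_that("LOF is invariant under rigid motion and uniform scaling", {
  set.seed(33)
  pts <- matrix(rnorm(240), ncol = 2)
  base <- lofScores(pts, k = 15)
  th <- 0.7
  rot <- pts %*% matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  moved <- sweep(rot, 2, c(5, -3), "+")
  expect_equal(lofScores(moved, k = 15), base, tolerance = 1e-8)
  expect_equal(lofScores(pts * 37.5, k = 15), base, tolerance = 1e-8)
})

test_that("mean LOF of an isotropic cloud stays near 1 across seeds", {
  for (s in 1:3) {
    set.seed(40 + s)
    cloud <- matrix(rnorm(600), ncol = 2)
    m <- mean(lofScores(cloud, k = 20))
    expect_gte(m, 0.95)
    expect_lte(m, 1.15)
  }
})

test_that("adding scattered positives raises the mean LOF monotonically", {
  # scattered counts stay below k: above that, scattered points start to
  # supply each other's neighborhoods and the score saturates
  set.seed(34)
  blob <- matrix(rnorm(800, sd = 1), ncol = 2)
  scatter <- cbind(runif(60, -25, 25), runif(60, -25, 25))
  means <- vapply(c(0, 5, 12, 20), function(s)
    mean(lofScores(rbind(blob, scatter[seq_len(s), , drop = FALSE]), k = 20)),
    numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("marker LOF classifies and tallies per its contracts", {
  sce <- tinyDataset()
  sce <- embedCells(sce, seed = 2)
  r <- markerLOF(sce, "LUM1", k = 20, datasetId = 3)
  expect_identical(r$dataset_id, 3)
  expect_gt(r$n_positive_cells, 20)
  expect_true(r$classification %in% c("lt1", "eq1", "gt1"))

  # too few positive cells -> insufficient, score undefined
  rare <- sce
  cnt <- assay(rare, "counts")
  cnt["G0050", ] <- 0L; cnt["G0050", 1:5] <- 1L
  assay(rare, "counts") <- cnt
  r2 <- markerLOF(rare, "G0050", k = 20)
  expect_identical(r2$classification, "insufficient")
  expect_true(is.na(r2$lof_score))
  expect_error(markerLOF(sce, "NOPE"), "NOPE")

  mk <- function(g, cls, id) S4Vectors::DataFrame(
    gene = g, dataset_id = id, n_positive_cells = 100L,
    lof_score = 1, classification = cls)
  res <- rbind(mk("A", "gt1", 1), mk("A", "gt1", 2), mk("A", "gt1", 3),
               mk("A", "gt1", 4),
               mk("B", "gt1", 1), mk("B", "gt1", 2), mk("B", "gt1", 3),
               mk("B", "eq1", 4),
               mk("C", "lt1", 1), mk("C", "eq1", 2), mk("C", "gt1", 3),
               mk("C", "gt1", 4),
               mk("D", "insufficient", 1))
  tl <- lofTally(res)
  expect_identical(tl$pct_gt1[tl$gene == "A"], 1)
  expect_true(tl$unstable_flag[tl$gene == "A"])
  expect_identical(tl$pct_gt1[tl$gene == "B"], 0.75)
  expect_false(tl$unstable_flag[tl$gene == "B"])   # strict all-datasets rule
  expect_equal(unlist(tl[tl$gene == "C", c("pct_lt1", "pct_eq1", "pct_gt1")]),
               c(pct_lt1 = 0.25, pct_eq1 = 0.25, pct_gt1 = 0.5))
  expect_true(tl$all_insufficient[tl$gene == "D"])
})
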