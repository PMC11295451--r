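test_that("normalized entropy hits its analytic anchors", {
  # one-hot evidence is perfectly specific
  expect_identical(metricEntropy(c(1, 0, 0), "avg_log2FC"), 0)
  # uniform evidence is maximally uninformative, any C
  for (C in c(2, 3, 7, 15)) {
    expect_equal(metricEntropy(rep(0.4, C), "pct1"), 1, tolerance = 1e-12)
  }
  # worked 3-cluster case: weights (1, 1, 2)
  expect_equal(metricEntropy(c(1, 1, 2), "diff_pct"),
               -(0.25 * log(0.25) * 2 + 0.5 * log(0.5)) / log(3),
               tolerance = 1e-12)
  expect_equal(metricEntropy(c(1, 1, 2), "diff_pct"), 0.9464,
               tolerance = 1e-4)
  # all-zero weights: maximally uninformative by convention
  expect_identical(metricEntropy(c(0, 0, 0), "avg_log2FC"), 1)
  expect_identical(metricEntropy(c(1, 1, 1), "p_val_adj"), 1)  # -log10(1)=0

  expect_error(metricEntropy(1, "pct1"), "2 clusters")
  expect_error(metricEntropy(c(1, NA), "pct1"), "non-finite")
})

test_that("entropy is scale invariant and monotone under concentration", {
  w <- c(0.2, 1.3, 0.5, 0.01)
  expect_equal(metricEntropy(w, "pct1"), metricEntropy(17 * w, "pct1"),
               tolerance = 1e-12)
  # zero-weight clusters still count in the log(C) denominator
  expect_equal(metricEntropy(c(1, 1, 0), "pct1"), log(2) / log(3),
               tolerance = 1e-12)
  # concentrating fixed total weight into fewer clusters lowers H
  hs <- c(metricEntropy(c(4, 0, 0, 0), "pct1"),
          metricEntropy(c(2, 2, 0, 0), "pct1"),
          metricEntropy(c(2, 1, 1, 0), "pct1"),
          metricEntropy(c(1, 1, 1, 1), "pct1"))
  expect_true(all(diff(hs) > 0))
})

test_that("profiles rank specific markers below diffuse ones", {
  sce <- tinyDataset()
  de <- deTable(sce, c("EPI1", "LUM1", "DIF1"))
  pr <- entropyProfiles(de, datasetId = 1)
  expect_equal(pr$total_entropy,
               pr$h_avg_log2FC + pr$h_pct1 + pr$h_diff_pct + pr$h_padj,
               tolerance = 1e-12)
  expect_lt(pr$total_entropy[pr$gene == "EPI1"],
            pr$total_entropy[pr$gene == "DIF1"])
  expect_lt(pr$total_entropy[pr$gene == "LUM1"],
            pr$total_entropy[pr$gene == "DIF1"])

  # order invariance: permuting DE rows changes nothing
  pr2 <- entropyProfiles(de[rev(seq_len(nrow(de))), ], datasetId = 1)
  expect_equal(as.data.frame(pr), as.data.frame(pr2))

  # identical metric vectors share the mean rank
  de3 <- S4Vectors::DataFrame(
    gene = rep(c("A", "B", "C"), each = 2),
    cluster = rep(c("k1", "k2"), 3),
    avg_log2FC = rep(c(2, 0), 3), `pct.1` = rep(c(0.9, 0.1), 3),
    `pct.2` = rep(c(0.1, 0.9), 3), diff_pct = rep(c(0.8, -0.8), 3),
    p_val = rep(c(1e-10, 1), 3), p_val_adj = rep(c(1e-9, 1), 3),
    check.names = FALSE)
  pr3 <- entropyProfiles(de3, datasetId = 1)
  expect_identical(pr3$rank, rep(2, 3))

  expect_error(entropyProfiles(de[de$cluster != "cl1" | de$gene != "EPI1", ]),
               "EPI1")
})

test_that("cross-dataset summary orders by rank sum with documented ties", {
  mk <- function(genes, totals, id) {
    S4Vectors::DataFrame(gene = genes, dataset_id = id,
                         h_avg_log2FC = 0, h_pct1 = 0, h_diff_pct = 0,
                         h_padj = 0, total_entropy = totals,
                         rank = rank(totals))
  }
  # marker A dominates everywhere: rank_sum = n_datasets, first row
  s <- entropySummary(list(mk(c("A", "B"), c(1, 2), 1),
                           mk(c("A", "B"), c(1, 3), 2)))
  expect_identical(s$gene[1], "A")
  expect_identical(s$rank_sum[1], 2)
  # reversed rankings tie on rank_sum; total entropy breaks the tie
  s2 <- entropySummary(list(mk(c("A", "B"), c(1, 2), 1),
                            mk(c("A", "B"), c(4, 1), 2)))
  expect_identical(s2$rank_sum, c(3, 3))
  expect_identical(s2$gene[1], "B")   # 2 + 1 < 1 + 4
  expect_error(entropySummary(list(mk(c("A", "B"), c(1, 2), 1),
                                   mk(c("A", "C"), c(1, 2), 2))),
               "mismatch")
})

test_that("dataset correlation matrix behaves at its anchors", {
  mk <- function(totals, id) {
    S4Vectors::DataFrame(gene = paste0("g", seq_along(totals)),
                         dataset_id = id, h_avg_log2FC = 0, h_pct1 = 0,
                         h_diff_pct = 0, h_padj = 0,
                         total_entropy = totals, rank = rank(totals))
  }
  x <- c(0.2, 1.5, 3.1, 0.7)
  r <- datasetCorrelation(list(mk(x, "d1"), mk(x, "d2"), mk(5 - x, "d3")))
  expect_equal(unname(diag(r)), rep(1, 3))
  expect_equal(r["d1", "d2"], 1, tolerance = 1e-12)
  expect_equal(r["d1", "d3"], -1, tolerance = 1e-12)
  expect_identical(r, t(r))
  # constant profile is flagged as undefined, not fabricated
  rc <- datasetCorrelation(list(mk(x, "d1"), mk(rep(2, 4), "d2")))
  expect_true(is.na(rc["d1", "d2"]))
  expect_error(datasetCorrelation(list(mk(x[1:2], "d1"), mk(x[1:2], "d2"))),
               "3 markers")
})
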