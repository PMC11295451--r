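# scMarkerEval

Evaluates how **stable** and **specific** candidate cell-type marker genes
are across multiple single-cell RNA-seq datasets. Different studies of the
same tissue routinely type the same cells with different markers;
scMarkerEval replaces per-study threshold picking with an objective,
multi-dataset performance analysis. It ships a curated catalog of human
prostate cell-type markers (main level: epithelial, stromal; fine level:
luminal, basal, club, hillock, endothelial, fibroblast, smooth muscle,
pericyte) and a negative-binomial multi-dataset simulator with planted
markers of known quality for calibration and testing.

For each marker and each dataset the pipeline computes:

- **DE metrics** (Seurat dialect): `avg_log2FC` — log2 ratio of de-logged
  mean CP10K expression inside vs outside a cluster (pseudocount 1);
  `pct.1` / `pct.2` — fraction of expressing cells inside / outside;
  `diff_pct = pct.1 − pct.2`; a two-sided Wilcoxon rank-sum p-value
  (exact, tie-aware, when both groups ≤ 25 cells) with Bonferroni
  adjustment. Candidate main markers must be significantly up-regulated
  in every cluster of their lineage.
- **Information entropy**: per metric, the marker's per-cluster evidence
  weights are normalized and scored by Shannon entropy / ln(C) ∈ [0, 1];
  the four entropies are summed (total ∈ [0, 4]) and markers are ranked
  within each dataset, then by **rank sum** across datasets. Low entropy
  = evidence concentrated in few clusters = specific; a low rank sum
  means that concentration is reproduced across datasets. Datasets are
  compared by Pearson correlation of their per-marker entropy vectors.
- **Local outlier factor (LOF)**: for fine markers, the positive cells
  (count > 0) are scored by LOF (k = 20) among themselves on the UMAP;
  mean LOF > 1.05 means dispersed positives. A marker dispersed in
  **all** datasets is flagged unstable and removed.
- **Validation**: K-means (K = 2) regrouping of clusters on panel-average
  expression, scored by purity against target-vs-rest; per-marker F1 of
  expression-positivity as a classifier of the target type (main
  markers ≥ 0.8, fine markers ≥ 0.6, in ≥ 80% of covering datasets).

## Worked example

Simulate two datasets with four planted markers — a specific epithelial
marker, a diffuse one, a specific luminal marker, and a bimodal marker
whose second expression site is embedding-distant — and run the full
pipeline:

```r
library(scMarkerEval)

cfg <- simConfig(
  nDatasets = 2, nCellsPerDataset = 800, nGenes = 300,
  typeTree = list(epithelial = c("luminal", "basal"), stromal = "fibroblast"),
  proportions = rbind(c(0.40, 0.30, 0.30), c(0.30, 0.30, 0.40)),
  markerSpecs = rbind(
    markerSpec("EPI1", "epithelial", "specific", 64, baseline = 0.05),
    markerSpec("DIF1", "epithelial", "diffuse", 8, off_target_types = "fibroblast"),
    markerSpec("LUM1", "luminal", "specific", 32),
    markerSpec("BIM1", "luminal", "bimodal", 250, baseline = 0.002,
               second_frac = 0.03, off_target_types = "fibroblast")),
  structureGenesPerType = 30, seed = 42)

res <- runPipeline(pipelineConfig(outDir = tempfile(), synthetic = TRUE,
                                  simCfg = cfg, seed = 42))
res$report[, c("gene", "level", "cell_type", "status", "rank_sum", "median_f1")]
#>   gene level  cell_type                status rank_sum median_f1
#> 1 EPI1  main epithelial           robust-main        2 0.9206316
#> 2 DIF1  main epithelial                failed        4 0.6978905
#> 3 LUM1  fine    luminal stable-fine-validated       NA 0.8249300
#> 4 BIM1  fine    luminal      removed-unstable       NA        NA
```

Each planted class lands where it should: the specific epithelial marker
is screened, best-ranked by entropy (rank sum 2 of 2 datasets) and
validated with median F1 0.92 (`robust-main`); the diffuse marker shows
no cluster-specific up-regulation and fails screening; the specific
luminal marker is validated at the fine level (F1 0.82); and the bimodal
marker's scattered positives give it mean LOF > 1 in both datasets, so
it is removed before F1 is ever computed. The aggregated entropies
behind the ranking:

```r
as.data.frame(res$entropySummaries$epithelial)
#>   gene total_entropy_sum rank_sum n_datasets
#> 1 EPI1              4.98        2          2
#> 2 DIF1              8.00        4          2
```

A diffuse marker carries no significant up-regulation in any cluster, so
all four of its metric entropies are maximally uninformative (total 4
per dataset); the specific marker's evidence concentrates in its two
epithelial clusters (total ≈ 2.5 per dataset).

The packaged prostate catalog is available as
`prostateMarkerCatalog()`; `markerGenes(cat, level = "main",
source = "screened")` returns the 34 screened main-panel genes
(8 epithelial + 26 stromal). All stage outputs (DE tables, entropy
profiles and summaries, LOF results and tallies, regrouping purities, F1
tables, the marker report) are written as TSVs under the configured
output directory, and reruns from the same config are byte-identical. A
thin command-line wrapper with `simulate` / `run` / `report` verbs is in
`inst/scripts/marker_pipeline.R`; pipeline configs can be YAML files
(see `readPipelineConfig`).

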