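# mucospat

Integrative analysis of paired single-cell RNA-seq and single-cell
spatial transcriptomics of human colonic mucosa.

Inflamed intestinal tissue (Crohn's disease, ulcerative colitis) is
highly heterogeneous between patients, and understanding that
heterogeneity requires knowing not just *which* cell states are present
— resident and inflammatory macrophages, neutrophil states,
inflammatory fibroblasts — but *where* they sit in the tissue and which
cells they sit next to. `mucospat` implements, as a tested and reusable
R pipeline, the analysis pattern used for such studies: a droplet
scRNA-seq reference is quality-controlled, normalized and annotated;
its labels are transferred to an imaging-based spatial dataset (a
~1000-gene panel with per-cell centroids and fields of view); and the
annotated tissue map is interrogated with spatial statistics. A
negative-binomial simulator generates paired datasets with planted
ground truth, so every stage is testable without any external download.

It is aimed at computational biologists who want the individual stages
as composable, documented functions rather than a monolithic pipeline.

## What it computes

* **Quality control.** Spatial cells are removed when the mean count of
  negative-control probes exceeds 0.5 (strict) or fewer than 20
  biological features are detected. Reference cells are filtered on
  mitochondrial percentage (a laxer 65% cap for epithelial cells) and
  detected genes; cross-lineage "doublets" (e.g. an epithelial cell
  expressing *C1QA* or *MS4A1*) are removed by a compartment-specific
  forbidden-marker table, and immunoglobulin genes are dropped outside
  the B/plasma compartment.
* **Normalization and feature selection.** Library-size
  log-normalization, `log(1 + c·s/ℓ)`; size factors rescaling every
  sample to the lowest-coverage sample; per-sample mean–variance
  modelling with a loess technical trend, selecting genes with a
  positive biological variance component (HVGs).
* **Cluster entropy.** `H = 1 − Σ pᵢ²` over a cluster's per-sample
  proportions; sample-private (batch-driven) clusters score near 0.
* **Markers and DEGs.** Per-cluster two-sided Wilcoxon rank-sum tests
  (tie-corrected normal approximation; exact enumeration when both
  groups have ≤ 8 cells) with `min.pct = 0.25` and log-FC 0.25
  pre-filters and Benjamini–Hochberg control; "regulated" genes are
  those with FDR < 0.05 and FC > 1.2 or FC < 0.83. Jaccard matching of
  marker lists and expression-bin-matched module scores support
  cross-dataset comparison.
* **Label transfer.** Spearman correlation of each query cell with
  every reference cell on the union of per-label top-100 markers; the
  per-label score is the 0.8 quantile of correlations and the argmax
  wins. A two-pass scheme assigns one of five compartments
  (epithelium, stroma, T cells, B/plasma, myeloid) first, then subtypes
  within the compartment.
* **Spatial statistics.** Co-localization score = Pearson correlation
  of two cell types' 2-D Gaussian KDEs on a shared 64×64 grid per
  sample and FoV (pairs need > 10 cells of each type); Euclidean
  distance of each cell to the mucosal-surface polyline with per
  cluster × group summaries; neighborhoods via k-NN composition
  vectors clustered by k-means; Pearson correlation of per-patient
  cell-type abundances with BH-adjusted p-values.

## Worked example

```r
library(mucospat)

design <- simulation_design(seed = 1)   # 10 types, 5 compartments, 3 groups
pair <- simulate_paired(design)

qc <- filter_spatial_cells(pair$spatial$counts, pair$spatial$meta)
qc$report$retained_fraction
#> [1] 1

norm_ref <- lognormalize(pair$reference$counts)
panel <- pair$spatial$counts[!pair$spatial$counts$is_negative_probe, ]
norm_sp <- lognormalize(panel[, cell_ids(qc$counts)])
ann <- two_pass_annotation(norm_ref, pair$reference$meta, norm_sp)
mean(ann$subtype == pair$spatial$truth$true_type[ann$cell_id])
#> [1] 0.9535

meta <- qc$meta
meta$subtype <- ann$subtype[match(meta$cell_id, ann$cell_id)]
rec <- colocalization_scores(meta)
head(summarize_colocalization(rec, setNames(meta$group, meta$sample_id)), 3)
#>     group type_a type_b n_fov mean_score median_score   sd_score
#> 106    CD type08 type09     8  0.7859037    0.7554542 0.09101091
#> 79     CD type06 type08     8  0.7601667    0.7806814 0.05039668
#> 82     CD type07 type08     8  0.7562330    0.7806729 0.09211051
```

Every simulated spatial cell is retained by QC (no failures were
planted), 95.4% of the 6000 spatial cells recover their true subtype
through the two-pass transfer, and the most co-localized pairs are
types whose simulated depth offsets place them in the same tissue
stratum. `distance_to_surface()` on the same metadata summarises each
subtype's depth below the mucosal surface, and
`run_pipeline(default_config(seed = 1, design = list()), "out")` runs
all of the above end to end, writing CSV tables and a JSON manifest
whose file hashes reproduce exactly under a fixed seed.

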