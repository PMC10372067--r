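---
title: "Methods and design notes for mucospat"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for mucospat}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`mucospat` couples a droplet scRNA-seq reference of colonic mucosa with
an imaging-based single-cell spatial dataset and asks two families of
questions: *what* is each spatial cell (quality control, normalization,
markers, label transfer) and *how is the tissue organised*
(co-localization, depth below the mucosal surface, neighborhoods,
cross-patient abundance structure). This vignette documents the models,
the tunable parameters, and the design decisions that were genuinely
open, in the package's own words.

## Quality control

Spatial (targeted-panel) cells carry counts for negative-control
probes, which target no transcript and estimate background. A cell is
removed when its mean negative-probe count is **strictly greater than
0.5** or it detects **fewer than 20** biological features
(`filter_spatial_cells()`). The two criteria are combined with OR: a
cell failing either is discarded. An AND reading exists, but OR is the
conservative choice — a cell with high background *or* almost no signal
is unusable for annotation — and is what the package implements and
tests. Both cut-offs are strict inequalities; cells sitting exactly on
a boundary (probe mean 0.5, 20 features) are retained, and the test
suite pins this.

Reference cells are filtered on mitochondrial percentage and detected
genes (`filter_reference_cells()`). Epithelial cells are fragile during
dissociation and legitimately carry high mitochondrial content, so they
receive a laxer cap (default 65% of counts); all other cells default to
25% and at least 200 detected genes. The non-epithelial defaults are
package choices following common droplet-QC practice — they are
configuration values, not claims about any particular dataset, and the
tests validate behaviour against planted ground truth rather than the
defaults themselves.

Cross-lineage contamination is handled by a forbidden-marker table
(`default_lineage_rules()`): within a compartment, any cell with
normalized expression of a marker that belongs unambiguously to another
lineage (T-cell receptor complex genes, *C1QA*, *DERL3*, *MS4A1*,
*EPCAM*, *CD79A*, *THY1*, depending on the compartment) above
`lineage_expr_min` is removed as a putative doublet. The default
threshold is 0 — any detection counts — because ambient detection of a
hard lineage marker inside the wrong compartment is already suspect at
panel depth. Immunoglobulin genes (prefixes IGH/IGK/IGL) are removed
from every compartment except B/plasma cells to suppress ambient
background (`remove_ig_genes()`).

## Normalization and variance modelling

`lognormalize()` computes `log(1 + c · s / ℓ)` with scale target
`s = 10⁴` (counts per ten thousand) and the natural logarithm; the base
is configurable. `rescale_to_lowest_coverage()` produces per-cell size
factors `ℓ_cell / min_sample(mean ℓ)`, after which every sample's mean
normalized coverage equals that of the lowest-coverage sample — the
standard way to make unequal-depth samples comparable without
inflating the shallow ones.

`model_gene_variance()` fits, per sample, a loess curve (span 0.3,
degree 2, symmetric family) of per-gene variance against per-gene mean
of log-normalized expression, clamped at zero. The fitted value is the
technical component; variance minus trend is the biological component;
components are averaged unweighted across samples and genes with a
positive combined component are the HVGs, ranked by component size. The
contract here is deliberately loose — *a smooth non-negative trend with
positive-residual selection* — because the published fitters differ in
detail; the tests assert the contract's observable consequences
(planted fold-4 markers recalled at ≥ 0.8; a pure-noise matrix selects
≈ 50% of genes; a zero-variance gene is never selected).

Cluster entropy is `H = 1 − Σ pᵢ²` over the per-sample proportions
`pᵢ` of a cluster, i.e. the complement of the Simpson index: 0 when a
cluster is private to one sample (a batch-artifact signature), at most
`1 − 1/S` when all `S` samples contribute equally. Clusters below a
configurable flag threshold (default 0.2) are reported as candidate
artifacts. Batch *correction* itself (Harmony-style integration,
clustering, embeddings) is outside the package: entropy and markers
operate on any given assignment.

## Markers, fold changes and multiple testing

`find_markers()` compares each cluster against all remaining cells.
Genes enter testing only if detected in ≥ 25% of either group
(`min_pct`) and |log₂ FC| ≥ 0.25, mirroring the conventional
marker-detection thresholds. The test is a two-sided Wilcoxon rank-sum:
a tie-corrected normal approximation in general, and exact enumeration
of all `C(n₁+n₂, n₁)` label assignments (midranks for ties) when both
groups have at most 8 cells — in the fully separated 4 vs 4 case this
yields the textbook `p = 2/70`. No continuity correction is applied;
the permutation-null uniformity of the resulting p-values is tested
with a Kolmogorov–Smirnov check at 2000 genes.

Fold changes are ratios of de-logged normalized means with pseudocount
0.01 in numerator and denominator. The regulated-gene rule — adjusted
`p < 0.05` and `FC > 1.2` or `FC < 0.83` — only makes sense on the
ratio scale (1.2 and 0.83 are near-reciprocal), so the ratio scale is
the implemented and documented choice. Benjamini–Hochberg adjustment is
delegated to `stats::p.adjust` and applied within each cluster over its
tested genes; the step-up definition is re-derived independently in the
test suite as an oracle.

When `block_by_sample = TRUE` the rank-sum z statistic is computed per
sample and combined by Stouffer's method weighted by sample size.
Stouffer was chosen over Fisher because it preserves the direction of
the effect and is the simplest combination satisfying the
uniform-under-null property that the tests check; samples contributing
fewer than 2 cells to either group are skipped.

## Label transfer

`transfer_labels()` follows the correlation-based annotation recipe:
top-100 markers per reference label (positive log-FC, optionally
sample-blocked), working gene space = union of the lists intersected
with the query panel (at least 20 genes, else an error points at panel
compatibility), Spearman correlation of every query cell with every
reference cell on that space, per-label score = 0.8 quantile of the
label's correlations, argmax label with lexicographic tie-break. The
iterative fine-tuning step that some annotators add is deliberately
omitted: the contract exercised here is final-label accuracy on
ground-truthed data, and the single-pass aggregation meets it (the
acceptance checks require ≥ 90% subtype and ≥ 95% compartment accuracy
on the default synthetic pair). Rank correlation makes the result
invariant to any monotone per-cell transform, so whether the query side
is raw or log-scale is immaterial — a property the tests assert
directly. Query cells with zero variance on the working space are
labelled `unassigned` with a reason rather than silently assigned.

The "top ranked" ordering for the 100 markers is the package's marker
rank: ascending adjusted p, then descending |log₂ FC|, then gene id —
deterministic under ties.

`two_pass_annotation()` assigns one of five compartments first, then
re-runs marker detection and transfer within each compartment.
Subtypes can therefore never cross their compartment, which is both a
correctness property (tested) and the main reason the two-pass scheme
beats a flat one on closely related subtypes. A compartment with fewer
than two reference subtypes contributes its own name as the subtype.

## Spatial statistics

**Co-localization.** For each sample, FoV and unordered pair of types
with more than 10 cells each, both types' centroids are smoothed with a
Gaussian product kernel and evaluated on a shared 64×64 grid; the score
is the Pearson correlation of the two flattened grids. The evaluation
window is the *union* bounding box of the two point sets, padded by one
bandwidth per side — union rather than intersection so that both
densities are supported everywhere on the grid. Bandwidths default to
Silverman's rule per type and axis, floored at 1 µm (a degenerate,
zero-spread pattern triggers the floor with a warning). Identical
patterns score exactly 1; independently placed clustered types score
near 0; mutually exclusive placement scores negative. The score's
bounded Pearson definition is what the package implements; descriptions
of scores "> 1" that circulate for such analyses are inconsistent with
a correlation and are not reproduced.

Two numerical caveats are documented deliberately. First, the grid is
axis-aligned, so the score is exactly invariant under translations and
rotations by multiples of 90° (tested at 1e-6) but only approximately
invariant under arbitrary rotation angles, whose rotated bounding box
samples the densities differently. Second, when the bandwidth is an
appreciable fraction of the window — which Silverman's rule produces
for sparse, near-uniform patterns — both KDEs share the same boundary
attenuation, and that common envelope inflates the correlation of even
independent patterns (with ~60 uniform points per type and a
Silverman-scale bandwidth the null mean is ≈ 0.6, not 0). The score is
therefore a *relative* measure at a given bandwidth; the
complete-spatial-randomness calibration test fixes a shared 10 µm
bandwidth, well below the window scale, where the null mean is ≈ 0.
Tightly clustered biological patterns (the regime the statistic is used
in) keep Silverman bandwidths small and are unaffected.

**Surface distance.** The mucosal surface is an ordered polyline;
per-cell distance is the minimum over segments of the clamped
point-to-segment Euclidean distance, exact for all configurations
(perpendicular feet and endpoint clamps are tested analytically, and
1000 random points agree with a 10,000-point dense-sampling oracle
within 0.5 µm). Zero-length segments are skipped. Summaries (min,
mean, median, max, sd) are reported per cluster × disease group, only
for strata with at least 10 cells.

**Neighborhoods.** The methods literature this package follows reports
recurring multicellular domains ("neighborhood I–IV") without
specifying an algorithm, so the procedure here is an explicit package
design decision: each cell's composition vector is the type frequency
among its k = 20 nearest neighbours within its own FoV; vectors are
pooled across samples and clustered by k-means (K = 6 default, 10
restarts, seeded). This is the simplest widely used neighborhood
recipe, deterministic under a fixed seed, and it recovers constructed
two-block fixtures exactly and planted niches at adjusted Rand ≥ 0.7.
FoVs with ≤ k cells cannot furnish k neighbours; their cells are left
unassigned with a warning rather than padded.

**Abundance correlation.** Per-patient abundances of each type are
correlated across patients (Pearson; two-sided p from the t
distribution with n − 2 df; BH over all pairs). The default abundance
is the per-patient *proportion*, which is robust to per-patient cell
yield; a raw-count mode is available and matches the literal
"aggregating the cell counts" description. Zero-variance vectors yield
a missing correlation rather than an error; types absent everywhere
are dropped with a warning.

## The synthetic-data generator

`simulation_design()` fixes the benchmark conditions; its defaults are
the package's study conditions, not tuning knobs. Counts are negative
binomial with a single shared dispersion (0.5): gene g in a type-t cell
has mean `baseline_mean · marker_fold^[g ∈ markers(t)]`, scaled by a
log-normal per-cell library factor (sdlog 0.3). Defaults: 10 types in
5 compartments, 20 markers per type at fold 4, a 2000-gene reference
with a 300-gene panel containing all markers plus 20 negative probes
(Poisson mean 0.05), 3 disease groups × 2 samples × 400 reference
cells, and 6 spatial samples × 4 FoVs × 250 cells in 500×500 µm FoVs
with the mucosal surface at y = 0. `baseline_mean` 0.5 with panel
down-sampling 0.6 gives spatial cells a median of ~80 detected
features — comfortably above the 20-feature QC floor, as in real
imaging panels, so QC failures occur only where planted.

Spatially, each FoV receives `niche_count` uniformly placed niche
centres whose anchor types cycle through the type list. A cell draws
its type from its sample's composition vector, then a niche with
weight `niche_floor + attraction[type, anchor]` (floor 0.05), and a
position at the niche centre plus isotropic Gaussian jitter (σ 40 µm).
Choosing the niche *given* the type (rather than the type given the
niche) keeps the realised composition equal to the design composition
— an invariant the tests rely on — and makes the attraction matrix
interpretable: identity attraction places each anchored type almost
exclusively (≈ 91%) at its own niches, while `attraction[a, b] = 0.9`
spreads a and b over each other's niches and plants a strong positive
co-localization score. The y coordinate is then blended with weight
`surface_weight = 0.3` towards the type's `surface_offset_by_type`, so
depth below the surface is type-structured without destroying niche
coherence; offsets default to an even ladder across the FoV height.

What the generator deliberately does **not** emulate: transcript-level
spot positions and segmentation errors, cell-size and cell-shape
effects, gene–gene correlation beyond the type structure, realistic
(skewed) gene-mean distributions, spatial gradients within a niche,
and batch effects needing integration. Passing tests therefore
demonstrate correctness of the statistics under a clean generative
model, not robustness to every artifact of real tissue data.

## Problem sizes and determinism

The shipped benchmarks use 2400 reference cells × 2000 genes and 6000
spatial cells × 320 panel features, with the co-localization benchmark
at 21 FoVs × 800 cells; these sizes make every planted effect
detectable at comfortable margins while the full suite and the
acceptance script each run in a few minutes on a single core. All
stochastic stages (simulation, control-gene sampling, k-means) draw
their seeds from one global seed via `derive_seed(seed, stage)`, a
stage-name hash fan-out, so inserting a stage never shifts another
stage's random stream and identical (config, seed) runs produce
byte-identical outputs — `run_pipeline()` records md5 hashes in its
manifest and the tests assert they reproduce.

## Known limitations

* Clustering, embedding and batch integration are out of scope; the
  package consumes assignments, it does not produce them.
* The neighborhood procedure is a documented invention (see above);
  other reasonable choices (graph community detection on spatial
  k-NN graphs, Gaussian mixtures on composition vectors) would give
  different domain boundaries.
* Co-localization scores depend on the bandwidth rule (see the
  boundary-attenuation caveat); comparisons are meaningful within a
  fixed rule, not across rules.
* The exact Wilcoxon path enumerates combinations and is only engaged
  when both groups have ≤ 8 cells; larger groups use the tie-corrected
  normal approximation without continuity correction.
* Label-transfer accuracy on real panels depends on marker coverage of
  the panel; the `min_overlap` guard (20 genes) catches outright
  incompatibility but not graded marker loss.
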