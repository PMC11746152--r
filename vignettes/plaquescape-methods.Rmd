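---
title: "Methods: plaque-proximity analysis of MERFISH brain sections"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: plaque-proximity analysis of MERFISH brain sections}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(plaquescape)
```

This vignette documents the models, conventions, and numerical choices
behind `plaquescape`, in the order an analysis runs. Every empirical claim
made here is one the package's test suite or `scripts/acceptance.R`
computes; nothing is quoted from elsewhere.

## The setting

A MERFISH experiment on coronal sections from amyloid mouse cohorts yields,
per 10-μm section: a cell-by-gene integer count matrix over a targeted panel
of ~300 genes, cell centroids and volumes, sample/batch labels, a genotype
per animal, a polygonal map of major brain regions, and — because dense
fibrillar amyloid binds DAPI — plaque centroids and areas from image
segmentation. The four genotypes are wild type (`WT`), the Trem2 R47H point
mutant (`R47H`), the 5xFAD amyloid model (`FAD`), and the double mutant
(`R47H_FAD`); only the latter two develop plaques. Sections are treated as
planar; the 10-μm thickness is used only to convert areas into volumes.

All thresholds live in one `analysis_thresholds()` object that is serialized
into the run manifest, so a run is reproducible from the manifest plus a
seed. The defaults: QC at volume ≤ 1800 μm³ and ≥ 50 transcripts (both
boundaries retained), gene detection ≥ 15% of cells, ≥ 50 cells per
pseudobulk replicate, significance at BH-adjusted p < 0.05 with
|log2FC| ≥ 0.35, subclusters below 5% of a type excluded, single-genotype
bias above 33% and pair bias above 60%, proximal/distal radii 100/500 μm,
25-μm annuli, 50-μm neighborhoods for per-type areas, alpha-shape
α = 0.015 μm⁻¹, and the 5th nearest neighbor for outlier removal.

## The synthetic cohort generator

Real data of this kind cannot ship with a package, so `sim_config()` /
`simulate_cohort()` generate virtual cohorts with the statistical structure
the analyses assume. Cells are drawn from independent Poisson processes per
region and cell type; the default layout is four 500 × 500 μm rectangles
standing in for cortex, hippocampus, corpus callosum, and thalamus, with
excitatory neurons enriched in cortex and oligodendrocytes in the white
matter. Default densities put roughly 200 cells of each type in a section —
deliberately desk-scale; the acceptance checks state the sizes they use.

Plaques are drawn (amyloid genotypes only) from region-dependent Poisson
fields, densest in the corpus callosum, with log-normal areas (median
300 μm², about a 19.5 μm equivalent diameter). Microglial attraction to
plaques is modeled by thinning: an extra microglial process at
(multiplier − 1) × density is kept only within the proximal radius, giving
exactly the configured density ratio (2.0 by default).

Counts are negative binomial with
log μ = log(baseline) + batch effect + genotype effects + distance effects +
library factor. The per-type baseline carries a marker block per cell type
(8× elevation of 12 genes) so clustering has honest signal, and is scaled so
the mean library is 250 transcripts regardless of panel size — this keeps
the 50-transcript QC boundary meaningful for reduced test panels. Batch
effects are per-batch, per-gene log-normal offsets (σ = 0.1) drawn once per
cohort so that sections of one batch share them; the library factor is
log-normal with σ = 0.3; dispersion defaults to 0.3.

Planted effects come in three kinds, all recorded in a ground-truth object
for recovery testing: genotype fold changes (gene, type, genotype set, log2
effect); distance effects, either `amp_decay`
(Δlog2 μ = A·exp(−d/λ), an elevation near plaques that relaxes to baseline)
or `log_linear` (Δln μ = ln2·A + s·d, an exponential decay of the mean with
distance, the form the continuous-distance regression estimates); and
biased subpopulations, which reassign a target fraction of one type, in the
enriched genotypes only, to a latent subtype with shifted marker means.

What the generator does **not** emulate: transcript-level spot noise,
segmentation errors and expression spillover between neighboring cells,
anterior–posterior gradients, cell-type-correlated spatial clustering
beyond the region structure, and optical artifacts. Tests passing on this
generator therefore show the procedures are correct and calibrated under
the stated model — not that real tissue satisfies that model.

All randomness flows from one root seed through a documented linear
derivation (`seed × 10007 + 101 × index + 17 mod 2³¹−1`), and every
generator and analysis function restores the caller's RNG state.

## Typing pipeline

Normalization scales each cell to the median library and applies
log2(1 + x); the median target is this package's choice. The embedding
regresses each gene on total transcripts (ordinary least squares), scales
residuals per gene, and takes the top principal components. Batch
integration is a pluggable `integrate` hook with identity default —
integration algorithms are third-party methodology, and the synthetic
cohorts' batch effects are handled by the mixed models downstream.

Clustering is a contract, not a reproduction of any specific tool: an exact
k-nearest-neighbor graph (k = 15), Jaccard-weighted shared-nearest-neighbor
edges with weak links pruned (< 1/15), and seeded Louvain. The default
resolution (0.1) is deliberately coarse: disconnected populations can never
be merged by modularity optimization, so well-separated types stay apart,
while homogeneous clouds are not shattered. Marker ranking is a two-sided
Wilcoxon rank-sum (normal approximation with tie correction, as large-scale
single-cell rankers use), BH-adjusted within cluster.

Subclusters are excluded as contaminated when ≥ 2 of their top-10
upregulated markers are atlas-annotated as exclusive to a different major
type. The "≥ 2 of 10" quantification is ours — one foreign marker can be a
ranking accident, two are systematic — and both numbers are arguments.

## Plaque detection and validation

The detector is a transparent stand-in for a trained segmentation model,
used to exercise the validation machinery: threshold, label 8-connected
components, drop components smaller than `min_diameter` (10 μm — nuclei
average 8.5 μm, plaques 22.4 μm), and optionally drop components rounder
than `max_circularity`. Two numerical choices matter:

* **Threshold.** A fixed intensity quantile is content-dependent: the same
  quantile lands below the nuclei band in a plaque-free field and inside
  the plaque intensity band in a plaque-dense one. The default is therefore
  an automatic Otsu threshold between the background/nuclei mode and the
  bright fibrillar mode, with a bimodality guard (threshold must exceed the
  image median by 8 MAD, else the mask is empty — this is what makes blank
  and plaque-free images yield zero detections). An explicit
  `intensity_quantile` remains available.
* **Circularity.** Digital perimeter estimates run above the ideal for
  compact objects (small blobs can exceed circularity 1), so a ceiling near
  1 silently deletes genuine compact plaques. The filter ships off
  (`Inf`) and is exercised in tests with an explicit ceiling; it is meant
  for aggressive low-threshold configurations where round somata survive.

Validation matches predicted to annotated objects greedily by pixel
overlap; an annotated object is a true positive when a predicted object
covers ≥ 50% of its area (the overlap fraction is an argument — the notion
of "significant overlap" has no canonical value), predicted objects
touching no annotated pixel are false positives. F1 is
2·tp/(2·tp + fp + fn). The false-positive rate is returned under both
conventions in circulation — fp/(fp + tp) and fp per annotated object —
because validation reports differ in their denominator. Volumes are area ×
10 μm thickness, a convention this package fixes explicitly.

The renderer draws nuclei as Gaussian blobs (mean diameter 8.5 μm) and
plaques as multi-lobed super-Gaussian plateaus (a bright core at 0.44 d
with four satellite lobes), about four-fold brighter than nuclei, over
Gaussian background noise. The plateau profile is what real dense
aggregates look like at these scales and has the property that the
thresholded extent barely depends on the threshold, which keeps the
detector's size filter meaningful. The paired ground-truth mask is the
union of the lobes' supports.

## Spatial statistics

Distances are measured to plaque **centroids** (boundary distance is a
configurable alternative): centroids are deterministic, and for the
proximal radius (100 μm) the difference is second-order. Zones: proximal
d < 100 strictly; distal 100 ≤ d ≤ 500 (closed at 500, a convention this
package fixes). Annulus composition reports raw per-annulus type fractions
and an abundance-normalized version (annulus count over the type's
**section-wide** total, renormalized within annulus); section-wide is one
of two defensible readings of "normalize by the group total" and is flagged
in the output metadata.

Disk-union areas (the denominators of proximal/distal densities) use seeded
Monte Carlo with 10⁶ points by default: the sampling error for areas of
this scale is well under 1%, the estimate handles arbitrary clipping
polygons, and the seed makes it reproducible. Alpha-shape areas sum
Delaunay triangles with circumradius < 1/α (α = 0 keeps all triangles, i.e.
the convex hull); triangulation comes from `deldir`. Before a per-type area
is computed, spatial outliers are removed by the 5th-nearest-neighbor rule
(outside median ± 1.5 IQR). One boundary choice: points **at** the interval
ends are retained — on a perfectly regular grid the IQR collapses to zero,
and an exclusive rule would delete every point.

## Differential expression

Pseudobulk replicates are per (cell type, sample) sums — optionally further
split by zone or region — with two filters: replicates need ≥ 50 cells, and
genes must be detected in ≥ 15% of the analyzed cells of the type, computed
across all analyzed cells rather than per sample (the per-sample variant is
noisier for no benefit at these sizes).

The response for the mixed models is `log2(1 + count / size factor)` with a
**median-of-ratios** size factor (each replicate's median ratio to the
per-gene geometric mean). This deviates from the more obvious
counts-per-million response for a measured reason: when a strongly induced
program sits on abundant genes, per-million scaling deflates every other
gene in the affected group and manufactures fold changes that pass the 0.35
gate — on one simulated recovery cohort the empirical FDR reached 0.72
under CPM and 0 under median-of-ratios. The group coefficient remains the
base-2 log fold change.

The model is `y ~ group + (1 | batch)`, REML via `lme4`, refitted per gene
on a prebuilt structure for speed. Inference uses a t-test on
**Satterthwaite** degrees of freedom, computed by a small dedicated routine
(2 × 2 REML information in (θ, σ²) by central differences, delta method for
the variance of the squared standard error) that the test suite verifies
against `lmerTest` to ~10⁻⁵. A normal reference was rejected: with three
batches the residual degrees of freedom are ~2–4, and a normal Wald test is
anti-conservative enough to break the package's own null-calibration
guarantee (≤ 1% significant rows on effect-free cohorts). When the batch
variance is inestimable — one batch, a singular fit, or a convergence
failure — the gene falls back to ordinary least squares with a
residual-degrees-of-freedom t-test, and the row is flagged.

Pairwise genotype comparisons (FAD–WT, R47H_FAD–R47H, R47H–WT,
R47H_FAD–FAD, R47H_FAD–WT) subset replicates to the two genotypes involved,
because batches are not balanced across genotypes. Region-vs-rest contrasts
each region against the pooled others within one genotype and — following
the convention for that analysis — flags significance at the **unadjusted**
p < 0.05 with the fold-change gate, marking rows `nominal`; cell types with
a single surviving region are skipped with a warning (the replicate filter
can eliminate sparse types from whole regions). Proximal-vs-distal pools
amyloid-genotype samples and contrasts the two zones.

Continuous-distance regression works at single-cell level on
amyloid-genotype cells within the distal radius: per gene, a
negative-binomial GLM of counts on distance with a log link and a library
offset, dispersion by method of moments (floored at 10⁻⁸), Wald test on the
distance coefficient, BH across genes, and only the adjusted p-value (no
fold-change gate) for significance; the reported effect is the expected
log2 change per μm. Genotype is not a model factor — at these sample sizes
it cannot be estimated alongside distance. The library offset is computed
in **two passes**: distance-associated genes found in the first pass are
excluded from the library for the second, because a plaque-proximal
program occupying a visible share of a targeted panel otherwise imposes a
spurious distance trend on every null gene (measured: ~12% BH-positive null
genes with one pass, 0 with two).

BH adjustment family: all tested genes within one (cell type, comparison),
flagged in output metadata; the wider choices (across types or comparisons)
would mix tests with different power.

Post-hoc filters address expression spillover between neighboring cells:
glial results are restricted to genes atlas-annotated as expressed in the
cell type; neuronal results drop atlas-exclusive glial genes and supplied
disease-program markers; an explicit exclusion list (e.g. genes predictive
of anterior–posterior position) is honored in both modes. Unfiltered
results are preserved alongside.

## Genotype-biased subclusters

Genotype proportions per subcluster are normalized in two steps:
n(g, s)/N(g) with N(g) the type's total from genotype g — computed within
the analyzed cell type, the reading under which exchangeable genotypes give
exactly 0.25 — then row-normalized. Bias calls: a single genotype above
33% (uniform 25%) takes precedence over pair calls; otherwise an allowed
pair above 60% (uniform 50%). Allowed pairs are the four interpretable
mutation axes ({WT, R47H}, {FAD, R47H_FAD}, {R47H, R47H_FAD}, {WT, FAD});
the two diagonal pairs are never called, since co-enrichment in, say, WT
and the double mutant has no single-mutation reading. Precedence and tie
order (the canonical genotype order) are this package's choices; each
subcluster receives at most one call. The classifier is verified against
brute-force enumeration of all 176,851 compositions on a 0.01 grid.

Regional subtype composition (e.g. disease-associated vs homeostatic
microglia per region) attaches a permutation p-value: the statistic is the
largest absolute difference in per-sample mean class proportion between two
genotype groups, with sample-to-group assignments permuted (seeded, 10⁴ by
default). A permutation test was chosen over parametric models because
cell-level proportions within a sample are not independent observations.

## Problem sizes and determinism

The shipped checks run at desk scale, chosen once: cohorts of 4 genotypes ×
3 batches (null calibration, per the stated study conditions) or × 4–5
batches (recovery conditions, mirroring a multi-batch study of ~19
sections; with only 3 batches the mixed-model contrast has ~2 residual
degrees of freedom and no honest test attains high sensitivity), ~200
cells per type per section, 300-gene panels, 20 rendered 200 × 200 μm
validation windows, and 10⁶-point Monte Carlo areas. Every pipeline stage
is deterministic given its seed; the end-to-end check runs the full
pipeline twice and requires bit-identical tables.

## Known limitations

The detector is a threshold method and is expected to degrade where plaques
touch or nuclei form dense clumps; the trained-model route it stands in for
is out of scope. Alpha-shape areas underestimate for sparse point sets
(spacing approaching 1/α). The mixed model tests one coefficient per gene
and does not share information across genes. The generator's independence
assumptions (no spillover, no gradients) bound what the recovery tests can
demonstrate about real tissue.
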