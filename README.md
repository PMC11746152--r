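# plaquescape

Spatial-transcriptomics analysis of amyloid pathology in MERFISH coronal
brain sections.

MERFISH imaging of mouse models of amyloidosis produces, per section, a
cell-by-gene count matrix for a targeted panel (~300 genes), cell centroids
in micrometers, region annotations, and — because dense fibrillar amyloid is
visible in the DAPI channel — the positions and sizes of Aβ plaques.
`plaquescape` implements the downstream analysis such a study needs, for
cohorts with four genotypes (wild type, Trem2 R47H, 5xFAD, and
R47H;5xFAD double mutants, the latter two plaque-bearing):

* **Cell-level processing** — QC (volume ≤ 1800 μm³, ≥ 50 transcripts),
  median-library log normalization, depth-regressed scaled PCA, seeded
  shared-nearest-neighbor Louvain clustering, Wilcoxon marker ranking, and
  exclusion of contaminated subclusters by atlas-exclusive foreign markers.
* **Plaque detection and validation** — a transparent threshold detector for
  DAPI-like images (automatic Otsu threshold, 8-connected components, size
  and circularity filters), mask geometry, and confusion-count validation
  with `f1 = 2·tp / (2·tp + fp + fn)`, false-negative rate, and both
  false-positive-rate conventions.
* **Plaque-relative spatial statistics** — distance to the nearest plaque
  with proximal (< 100 μm) / distal (100–500 μm) zones, closest-cell
  composition, 25-μm annulus composition with abundance normalization,
  Monte Carlo disk-union areas, alpha-shape region areas (Delaunay circum-
  radius < 1/α, α = 0.015 μm⁻¹) with 5th-nearest-neighbor outlier removal,
  and per-region density estimates.
* **Differential expression** — pseudobulk construction (≥ 50 cells per
  replicate, genes detected in ≥ 15% of cells), linear mixed models
  `y ~ group + (1 | batch)` with Satterthwaite t-tests for the five pairwise
  genotype contrasts, region-vs-rest, and proximal-vs-distal comparisons
  (significance: BH-adjusted p < 0.05 and |log2FC| ≥ 0.35), single-cell
  negative-binomial regression on distance to plaque (effect in log2 per
  μm), and atlas-based post-hoc filtering of spillover artifacts.
* **Genotype-biased subclusters** — per-type subclustering, the two-step
  genotype-proportion normalization, and the 33% single-genotype / 60%
  allowed-pair bias classifier.
* **A synthetic-cohort generator** that emulates the statistical structure
  of such a study — regionalized Poisson cell fields, genotype-dependent
  plaque fields, negative-binomial counts with library and batch variation,
  and planted genotype, plaque-distance, and subpopulation effects recorded
  as ground truth — plus a DAPI-like renderer for exercising the detector.

## Worked example

Simulate a four-genotype, three-batch cohort with a planted disease-associated
microglial program decaying with distance to plaque, then recover it:

```r
library(plaquescape)

decay <- data.frame(gene = "g020", cell_type = "microglia",
                    form = "amp_decay", amplitude_log2 = 3, decay_um = 50,
                    slope_ln = NA)
cfg <- sim_config(distance_effects = decay)
sim <- simulate_cohort(cfg, cohort_design(batches = paste0("b", 1:5)), seed = 8)

qc <- qc_filter_cells(sim$dataset$cells, sim$dataset$counts)
cells <- qc$cells
for (sid in unique(cells$sample_id)) {
  plq <- sim$dataset$plaques[sim$dataset$plaques$sample_id == sid, ]
  if (nrow(plq) == 0) next
  sel <- cells$sample_id == sid
  ann <- nearest_plaque_distance(cells[sel, ], plq)
  cells$zone[sel] <- as.character(ann$zone)
}

pb <- build_pseudobulk(qc$counts, cells, stratify_by = "zone")
de <- proximal_vs_distal_de(pb, cell_types = "microglia")
subset(de, gene == "g020",
       select = c(gene, log2fc, p_adj, significant))
#>    gene   log2fc       p_adj significant
#> 20 g020 1.205795 3.96135e-06        TRUE
```

The planted program (8-fold at the plaque, 50 μm decay length) appears as a
~1.2 log2-fold elevation of plaque-proximal microglial pseudobulk expression,
significant after BH adjustment; the remaining ~250 genes stay quiet.

The detector side works the same way:

```r
sec <- simulate_section(cfg, "FAD", "b1", seed = 42)
roi <- render_dapi_image(sec$cells, sec$plaques, pixel_size = 0.5,
                         window = c(0, 400, 0, 400), seed = 1)
det <- detect_plaques_threshold(roi$image, pixel_size = 0.5)
detection_metrics(match_predictions(det, roi$mask, 0.5))$f1
```

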