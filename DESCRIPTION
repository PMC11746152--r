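Package: plaquescape
Title: Plaque-Proximity Spatial Transcriptomics Analysis for MERFISH Brain Sections
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for MERFISH coronal brain sections from amyloid
    mouse models. Simulates virtual sections with planted genotype, plaque-distance
    and subpopulation effects; performs cell-level quality control, normalization,
    graph clustering and marker ranking; detects amyloid plaques in DAPI-like
    images with a transparent threshold detector and validates detections with
    confusion-count metrics; computes plaque-relative spatial statistics
    (nearest-plaque distances, annulus composition, disk-union and alpha-shape
    densities); runs pseudobulk mixed-effects differential expression across
    genotypes, regions and plaque-proximity zones plus single-cell
    negative-binomial regression on distance to plaque; and classifies
    genotype-biased subclusters.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    lme4,
    lmerTest,
    MASS,
    igraph,
    deldir,
    EBImage,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
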