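#' Analysis thresholds
#'
#' Container for every numeric threshold used by the pipeline: cell-level QC
#' cutoffs, pseudobulk and differential-expression significance thresholds,
#' subcluster genotype-bias thresholds, and the spatial radii and geometry
#' parameters used for plaque-proximity analysis.
#'
#' @param max_cell_volume Maximum cell volume retained by QC (um^3). Cells with
#'   volume strictly greater are removed.
#' @param min_transcripts_per_cell Minimum transcript count retained by QC.
#'   Cells with strictly fewer transcripts are removed.
#' @param min_gene_cell_fraction Minimum fraction of cells of a type in which a
#'   gene must be detected to enter differential expression.
#' @param min_cells_per_pseudobulk Minimum number of cells for a
#'   (cell type, sample) pseudobulk replicate to be kept.
#' @param abs_log2fc Absolute log2 fold-change threshold for DE significance.
#' @param alpha_fdr Adjusted p-value threshold for DE significance.
#' @param min_subcluster_fraction Subclusters holding less than this fraction
#'   of a cell type are excluded from analysis.
#' @param single_genotype_bias Normalized proportion above which a subcluster
#'   is called biased toward a single genotype (uniform would be 0.25).
#' @param pair_bias Combined normalized proportion above which a subcluster is
#'   called biased toward an allowed genotype pair (uniform would be 0.5).
#' @param proximal_radius Plaque-proximal zone radius (um).
#' @param distal_radius Outer radius of the plaque-distal zone (um).
#' @param annulus_width Width of distance annuli around plaques (um).
#' @param neighborhood_radius Radius used to collect cells around a cell type
#'   when estimating per-type occupied area (um).
#' @param alpha_shape_alpha Alpha parameter of the alpha shape (1/um).
#' @param knn_k Neighbor index used for k-nearest-neighbor outlier removal.
#' @param section_thickness Section thickness used to convert areas to volumes
#'   (um).
#'
#' @return An object of class `analysis_thresholds` (a validated named list).
#' @examples
#' th <- analysis_thresholds()
#' th$proximal_radius
#' @export
analysis_thresholds <- function(max_cell_volume = 1800,
                                min_transcripts_per_cell = 50,
                                min_gene_cell_fraction = 0.15,
                                min_cells_per_pseudobulk = 50,
                                abs_log2fc = 0.35,
                                alpha_fdr = 0.05,
                                min_subcluster_fraction = 0.05,
                                single_genotype_bias = 1 / 3,
                                pair_bias = 0.60,
                                proximal_radius = 100,
                                distal_radius = 500,
                                annulus_width = 25,
                                neighborhood_radius = 50,
                                alpha_shape_alpha = 0.015,
                                knn_k = 5,
                                section_thickness = 10) {
  th <- list(
    max_cell_volume = max_cell_volume,
    min_transcripts_per_cell = min_transcripts_per_cell,
    min_gene_cell_fraction = min_gene_cell_fraction,
    min_cells_per_pseudobulk = min_cells_per_pseudobulk,
    abs_log2fc = abs_log2fc,
    alpha_fdr = alpha_fdr,
    min_subcluster_fraction = min_subcluster_fraction,
    single_genotype_bias = single_genotype_bias,
    pair_bias = pair_bias,
    proximal_radius = proximal_radius,
    distal_radius = distal_radius,
    annulus_width = annulus_width,
    neighborhood_radius = neighborhood_radius,
    alpha_shape_alpha = alpha_shape_alpha,
    knn_k = knn_k,
    section_thickness = section_thickness
  )
  validate_thresholds(th)
  structure(th, class = "analysis_thresholds")
}

validate_thresholds <- function(th) {
  num <- vapply(th, function(x) is.numeric(x) && length(x) == 1L && is.finite(x), logical(1))
  if (!all(num)) {
    stop("all thresholds must be finite numeric scalars: ",
         paste(names(th)[!num], collapse = ", "))
  }
  if (any(unlist(th) <= 0)) {
    stop("all thresholds must be strictly positive: ",
         paste(names(th)[unlist(th) <= 0], collapse = ", "))
  }
  if (th$proximal_radius >= th$distal_radius) {
    stop("proximal_radius must be smaller than distal_radius")
  }
  fr <- c("min_gene_cell_fraction", "min_subcluster_fraction",
          "single_genotype_bias", "pair_bias", "alpha_fdr")
  bad <- fr[unlist(th[fr]) >= 1]
  if (length(bad)) stop("fractions must lie in (0,1): ", paste(bad, collapse = ", "))
  invisible(th)
}

#' @export
print.analysis_thresholds <- function(x, ...) {
  cat("Analysis thresholds:\n")
  for (nm in names(x)) cat(sprintf("  %-26s %g\n", nm, x[[nm]]))
  invisible(x)
}

#' Genotype codes
#'
#' The four-level genotype factor used throughout: wild type (`WT`), the Trem2
#' R47H point mutant (`R47H`), the 5xFAD amyloid model (`FAD`), and the double
#' mutant (`R47H_FAD`). Only the two genotypes carrying the 5xFAD transgenes
#' develop amyloid plaques.
#'
#' @return `genotype_levels()` returns the canonical ordering of the codes.
#' @export
genotype_levels <- function() c("WT", "R47H", "FAD", "R47H_FAD")

#' @rdname genotype_levels
#' @param genotype Character vector of genotype codes.
#' @return `is_amyloid()` returns a logical vector: `TRUE` iff the genotype
#'   carries the 5xFAD transgenes.
#' @export
is_amyloid <- function(genotype) {
  as_genotype(genotype) %in% c("FAD", "R47H_FAD")
}

#' @rdname genotype_levels
#' @details `as_genotype()` also accepts the common long-form strain labels
#'   ("5xFAD", "Trem2R47H", "Trem2R47H;5xFAD" and minor punctuation variants)
#'   and maps them onto the four codes.
#' @export
as_genotype <- function(genotype) {
  g <- gsub("[[:space:]]", "", as.character(genotype))
  key <- toupper(g)
  map <- c(
    "WT" = "WT", "WILDTYPE" = "WT", "WILD-TYPE" = "WT",
    "R47H" = "R47H", "TREM2R47H" = "R47H",
    "FAD" = "FAD", "5XFAD" = "FAD",
    "R47H_FAD" = "R47H_FAD", "R47H;FAD" = "R47H_FAD",
    "5XFAD;TREM2R47H" = "R47H_FAD", "TREM2R47H;5XFAD" = "R47H_FAD"
  )
  out <- unname(map[key])
  if (anyNA(out)) {
    stop("unknown genotype string(s): ",
         paste(unique(g[is.na(out)]), collapse = ", "))
  }
  factor(out, levels = genotype_levels())
}
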