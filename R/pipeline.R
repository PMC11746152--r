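#' Run the full analysis pipeline on a simulated cohort
#'
#' Convenience wrapper chaining the standard analysis on a virtual cohort:
#' simulation, cell QC, plaque-distance assignment, pseudobulk construction,
#' pairwise genotype differential expression, proximal-vs-distal
#' differential expression, annulus composition, and microglial subcluster
#' genotype-bias classification. All randomness derives from `seed`, so two
#' runs with identical arguments produce identical tables.
#'
#' @param config A [sim_config()] object.
#' @param design Cohort design (see [cohort_design()]).
#' @param seed Root seed.
#' @param bias_cell_type Cell type to subcluster for the bias analysis
#'   (skipped when too few cells).
#' @return Named list of result tables.
#' @export
run_pipeline <- function(config, design = cohort_design(), seed = 1L,
                         bias_cell_type = "microglia") {
  th <- config$thresholds
  sim <- simulate_cohort(config, design, seed)
  ds <- sim$dataset
  qc <- qc_filter_cells(ds$cells, ds$counts, th)
  cells <- qc$cells
  counts <- qc$counts

  # plaque-distance zones per amyloid sample
  cells$distance_to_plaque <- NA_real_
  cells$zone <- NA_character_
  for (sid in unique(cells$sample_id)) {
    plq <- ds$plaques[ds$plaques$sample_id == sid, , drop = FALSE]
    if (nrow(plq) == 0) next
    sel <- cells$sample_id == sid
    ann <- nearest_plaque_distance(cells[sel, , drop = FALSE], plq, th)
    cells$distance_to_plaque[sel] <- ann$distance_to_plaque
    cells$zone[sel] <- as.character(ann$zone)
  }

  pb <- build_pseudobulk(counts, cells, th)
  de_pairwise <- pairwise_genotype_de(pb, th)

  de_zone <- NULL
  amy <- cells$zone %in% c("proximal", "distal")
  if (any(amy)) {
    pbz <- tryCatch(build_pseudobulk(counts, cells, th, stratify_by = "zone"),
                    error = function(e) NULL)
    if (!is.null(pbz)) {
      de_zone <- tryCatch(proximal_vs_distal_de(pbz, th), error = function(e) NULL)
    }
  }

  annuli <- NULL
  amy_samples <- unique(cells$sample_id[is_amyloid(cells$genotype)])
  if (length(amy_samples)) {
    sid <- amy_samples[1]
    plq <- ds$plaques[ds$plaques$sample_id == sid, , drop = FALSE]
    if (nrow(plq)) {
      annuli <- annulus_composition(plq, cells[cells$sample_id == sid, , drop = FALSE], th)
    }
  }

  bias <- NULL
  n_type <- sum(cells$cell_type == bias_cell_type, na.rm = TRUE)
  if (n_type >= 2 * th$min_cells_per_pseudobulk) {
    sc <- subcluster_cell_type(counts, cells, bias_cell_type,
                               seed = derive_seed(seed, 31L), thresholds = th)
    props <- genotype_proportion_matrix(sc$labels, sc$cells)
    bias <- classify_bias(props, th)
  }

  out <- list(cells = cells, plaques = ds$plaques,
              de_pairwise = de_pairwise)
  if (!is.null(de_zone)) out$de_zone <- de_zone
  if (!is.null(annuli)) out$annuli <- annuli
  if (!is.null(bias)) out$bias <- bias
  out
}
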