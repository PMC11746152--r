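#' Simulation configuration
#'
#' Builds the configuration for the virtual-section generator. The generator
#' emulates the statistical structure of a MERFISH coronal half-section from
#' amyloid mouse cohorts: a ~300-gene panel, polygonal regions with
#' region-dependent cell-type densities, amyloid plaques present only in the
#' plaque-bearing genotypes with region-dependent intensity, negative-binomial
#' counts with library-size and batch variation, and optional planted effects
#' (genotype fold changes, plaque-distance decay programs, genotype-biased
#' subpopulations, microglial attraction to plaques).
#'
#' @param n_genes Number of genes in the panel.
#' @param region_layout Named list of polygons (n x 2 matrices, um). The
#'   default is four 500 x 500 um rectangles standing for cortex, hippocampus,
#'   corpus callosum and thalamus.
#' @param cell_types Character vector of major cell types.
#' @param cell_type_densities Region x cell-type matrix of intensities
#'   (cells/um^2).
#' @param genotype_plaque_intensity Region x genotype matrix of plaque
#'   intensities (plaques/um^2); must be zero for non-amyloid genotypes.
#' @param plaque_area_meanlog,plaque_area_sdlog Log-normal parameters of
#'   plaque areas (um^2).
#' @param nb_dispersion Per-gene negative-binomial dispersion (scalar or
#'   length `n_genes`); variance = mu + dispersion * mu^2.
#' @param library_size_lognormal_sigma Std. dev. of the per-cell log-normal
#'   library factor (natural-log scale).
#' @param batch_effect_sigma Std. dev. of the per-batch, per-gene
#'   multiplicative log-normal effect (natural-log scale).
#' @param genotype_effects Data frame with columns `gene`, `cell_type`,
#'   `genotype` (one code or a `;`-separated set), `log2fc`. Empty by default.
#' @param distance_effects Data frame with columns `gene`, `cell_type`,
#'   `form` (`"amp_decay"` or `"log_linear"`), `amplitude_log2`, `decay_um`,
#'   `slope_ln`. For `amp_decay`, log2 mean gains
#'   `amplitude_log2 * exp(-d / decay_um)`; for `log_linear`, the natural-log
#'   mean gains `log(2) * amplitude_log2 + slope_ln * d`, i.e. an exponential
#'   decay of the mean with distance. Empty by default.
#' @param biased_subpopulations Data frame with columns `cell_type`,
#'   `genotypes` (`;`-separated), `marker_genes` (`;`-separated), `fraction`,
#'   `shift_log2`. Empty by default.
#' @param microglia_plaque_attraction Multiplier of microglia intensity within
#'   `proximal_radius` of a plaque centroid.
#' @param volume_exceed_fraction Fraction of cell volumes exceeding the QC
#'   cutoff `max_cell_volume`.
#' @param volume_sdlog Log-normal sd of cell volumes.
#' @param target_library Mean per-cell transcript count the panel baseline is
#'   scaled to (before library-size variation).
#' @param thresholds [analysis_thresholds()] (supplies the proximal radius and
#'   the QC volume cutoff used above).
#' @param seed Seed used to lay down the fixed gene-panel baseline (marker
#'   structure and per-gene means); independent of the per-section seeds.
#'
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_genes = 300,
                       region_layout = default_region_layout(),
                       cell_types = c("excitatory", "inhibitory", "astrocyte",
                                      "microglia", "oligodendrocyte"),
                       cell_type_densities = NULL,
                       genotype_plaque_intensity = NULL,
                       plaque_area_meanlog = log(300),
                       plaque_area_sdlog = 0.5,
                       nb_dispersion = 0.3,
                       library_size_lognormal_sigma = 0.3,
                       batch_effect_sigma = 0.1,
                       genotype_effects = NULL,
                       distance_effects = NULL,
                       biased_subpopulations = NULL,
                       microglia_plaque_attraction = 2.0,
                       volume_exceed_fraction = 0.05,
                       volume_sdlog = 0.35,
                       target_library = 250,
                       thresholds = analysis_thresholds(),
                       seed = 1L) {
  regions <- names(region_layout)
  if (is.null(regions) || any(!nzchar(regions))) stop("region_layout must be named")
  if (is.null(cell_type_densities)) {
    cell_type_densities <- matrix(2e-4, length(regions), length(cell_types),
                                  dimnames = list(regions, cell_types))
    # crude regional structure: neurons enriched in grey matter,
    # oligodendrocytes in white matter
    if (all(c("cortex", "corpus_callosum") %in% regions)) {
      if ("excitatory" %in% cell_types) {
        cell_type_densities["cortex", "excitatory"] <- 4e-4
        cell_type_densities["corpus_callosum", "excitatory"] <- 0.5e-4
      }
      if ("oligodendrocyte" %in% cell_types) {
        cell_type_densities["corpus_callosum", "oligodendrocyte"] <- 5e-4
      }
    }
  }
  if (is.null(genotype_plaque_intensity)) {
    genotype_plaque_intensity <- matrix(0, length(regions), 4,
                                        dimnames = list(regions, genotype_levels()))
    genotype_plaque_intensity[, c("FAD", "R47H_FAD")] <- 4e-5
    if ("corpus_callosum" %in% regions) {
      genotype_plaque_intensity["corpus_callosum", c("FAD", "R47H_FAD")] <- 8e-5
    }
  }
  stopifnot(all(rownames(cell_type_densities) == regions),
            all(rownames(genotype_plaque_intensity) == regions))
  if (any(cell_type_densities < 0) || any(genotype_plaque_intensity < 0)) {
    stop("densities and intensities must be nonnegative")
  }
  non_amyloid <- setdiff(genotype_levels(), c("FAD", "R47H_FAD"))
  if (any(genotype_plaque_intensity[, non_amyloid] > 0)) {
    stop("plaque intensity must be zero for non-amyloid genotypes")
  }
  nb_dispersion <- rep_len(nb_dispersion, n_genes)
  if (any(nb_dispersion <= 0)) stop("nb_dispersion must be strictly positive")

  genes <- sprintf("g%03d", seq_len(n_genes))
  baseline <- with_seed(derive_seed(seed, 990001L), {
    base <- exp(stats::rnorm(n_genes, log(0.4), 0.8))
    m <- matrix(rep(base, each = length(cell_types)),
                length(cell_types), n_genes,
                dimnames = list(cell_types, genes))
    # give every type a dedicated block of markers so clustering has signal
    per <- max(1L, min(12L, n_genes %/% (length(cell_types) + 1L)))
    for (i in seq_along(cell_types)) {
      idx <- ((i - 1L) * per + 1L):(i * per)
      m[i, idx] <- m[i, idx] * 8
    }
    # normalize to the target mean library so QC behaves the same for any
    # panel size
    m * target_library / rowSums(m)
  })

  empty_geno <- data.frame(gene = character(), cell_type = character(),
                           genotype = character(), log2fc = numeric())
  empty_dist <- data.frame(gene = character(), cell_type = character(),
                           form = character(), amplitude_log2 = numeric(),
                           decay_um = numeric(), slope_ln = numeric())
  empty_sub <- data.frame(cell_type = character(), genotypes = character(),
                          marker_genes = character(), fraction = numeric(),
                          shift_log2 = numeric())
  cfg <- list(
    n_genes = n_genes, genes = genes, cell_types = cell_types,
    region_layout = region_layout,
    cell_type_densities = cell_type_densities,
    genotype_plaque_intensity = genotype_plaque_intensity,
    plaque_area_meanlog = plaque_area_meanlog,
    plaque_area_sdlog = plaque_area_sdlog,
    nb_baseline = baseline,
    nb_dispersion = nb_dispersion,
    library_size_lognormal_sigma = library_size_lognormal_sigma,
    batch_effect_sigma = batch_effect_sigma,
    genotype_effects = if (is.null(genotype_effects)) empty_geno else genotype_effects,
    distance_effects = if (is.null(distance_effects)) empty_dist else distance_effects,
    biased_subpopulations = if (is.null(biased_subpopulations)) empty_sub else biased_subpopulations,
    microglia_plaque_attraction = microglia_plaque_attraction,
    volume_exceed_fraction = volume_exceed_fraction,
    volume_sdlog = volume_sdlog,
    target_library = target_library,
    thresholds = thresholds,
    seed = seed
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  for (tab in c("genotype_effects", "distance_effects")) {
    ef <- cfg[[tab]]
    if (nrow(ef)) {
      if (!all(ef$gene %in% cfg$genes)) stop(tab, " references unknown gene(s)")
      if (!all(ef$cell_type %in% cfg$cell_types)) stop(tab, " references unknown cell type(s)")
    }
  }
  de <- cfg$distance_effects
  if (nrow(de) && any(de$form == "amp_decay" & !(de$decay_um > 0))) {
    stop("decay lengths must be strictly positive")
  }
  sub <- cfg$biased_subpopulations
  if (nrow(sub)) {
    if (!all(sub$cell_type %in% cfg$cell_types)) stop("biased_subpopulations references unknown cell type(s)")
    mg <- unlist(strsplit(sub$marker_genes, ";"))
    if (!all(mg %in% cfg$genes)) stop("biased_subpopulations references unknown marker gene(s)")
    if (any(sub$fraction <= 0 | sub$fraction >= 1)) stop("subpopulation fractions must be in (0,1)")
  }
  invisible(cfg)
}

#' @rdname sim_config
#' @export
default_region_layout <- function() {
  rect <- function(x0, y0, w, h) {
    cbind(x = c(x0, x0 + w, x0 + w, x0), y = c(y0, y0, y0 + h, y0 + h))
  }
  list(cortex = rect(0, 500, 500, 500),
       hippocampus = rect(500, 500, 500, 500),
       corpus_callosum = rect(0, 0, 500, 500),
       thalamus = rect(500, 0, 500, 500))
}

# sample a Poisson number of points uniformly inside a polygon
sample_poisson_points <- function(poly, intensity) {
  area <- polygon_area(poly)
  n <- stats::rpois(1, intensity * area)
  if (n == 0) return(cbind(x = numeric(), y = numeric()))
  bb <- bbox_of(poly)
  out <- matrix(NA_real_, 0, 2)
  while (nrow(out) < n) {
    m <- max(2L * (n - nrow(out)), 16L)
    cand <- cbind(stats::runif(m, bb["xmin"], bb["xmax"]),
                  stats::runif(m, bb["ymin"], bb["ymax"]))
    keep <- point_in_polygon(cand[, 1], cand[, 2], poly)
    out <- rbind(out, cand[keep, , drop = FALSE])
  }
  out <- out[seq_len(n), , drop = FALSE]
  colnames(out) <- c("x", "y")
  out
}

#' Simulate one virtual coronal section
#'
#' Draws cells from inhomogeneous Poisson processes per region and cell type,
#' draws plaques (amyloid genotypes only) with region-dependent intensity,
#' boosts microglia intensity near plaques, plants the configured genotype,
#' distance and subpopulation effects, and draws negative-binomial counts.
#'
#' @param config A [sim_config()] object.
#' @param genotype One genotype code (see [genotype_levels()]).
#' @param batch Batch label.
#' @param seed Integer seed for this section.
#' @param sample_id Sample label used in all output tables.
#' @param batch_effects Optional per-batch gene effect matrix
#'   (batches x genes, natural-log scale); drawn from `seed` when `NULL`.
#'   [simulate_cohort()] passes a shared matrix so batch effects are common
#'   across sections of the same batch.
#'
#' @return A list with `cells`, `counts`, `plaques`, `regions` and `truth`
#'   (the planted ground-truth record used by recovery tests).
#' @export
simulate_section <- function(config, genotype, batch, seed,
                             sample_id = "S01", batch_effects = NULL) {
  stopifnot(inherits(config, "sim_config"))
  genotype <- as.character(as_genotype(genotype))
  if (!genotype %in% colnames(config$genotype_plaque_intensity)) {
    stop("no plaque intensity entry for genotype ", genotype)
  }
  if (is.null(batch_effects)) {
    batch_effects <- draw_batch_effects(config, batch, seed = derive_seed(seed, 7L))
  }
  if (!batch %in% rownames(batch_effects)) stop("batch_effects lacks batch ", batch)

  with_seed(seed, {
    th <- config$thresholds
    genes <- config$genes
    G <- length(genes)

    # -- plaques ------------------------------------------------------------
    plq <- list()
    if (is_amyloid(genotype)) {
      for (rg in names(config$region_layout)) {
        pts <- sample_poisson_points(config$region_layout[[rg]],
                                     config$genotype_plaque_intensity[rg, genotype])
        if (nrow(pts)) plq[[rg]] <- pts
      }
    }
    plq <- if (length(plq)) do.call(rbind, plq) else cbind(x = numeric(), y = numeric())
    n_plq <- nrow(plq)
    areas <- if (n_plq) stats::rlnorm(n_plq, config$plaque_area_meanlog,
                                      config$plaque_area_sdlog) else numeric()
    plaques <- data.frame(
      plaque_id = if (n_plq) sprintf("%s_p%04d", sample_id, seq_len(n_plq)) else character(),
      x = plq[, 1], y = plq[, 2], area = areas,
      equivalent_diameter = 2 * sqrt(areas / pi),
      volume = areas * th$section_thickness,
      sample_id = rep(sample_id, n_plq),
      stringsAsFactors = FALSE
    )

    # -- cells --------------------------------------------------------------
    xs <- ys <- numeric(); type <- region <- character()
    for (rg in names(config$region_layout)) {
      poly <- config$region_layout[[rg]]
      for (ct in config$cell_types) {
        pts <- sample_poisson_points(poly, config$cell_type_densities[rg, ct])
        # extra microglia near plaques: thinned Poisson at (mult-1) x density
        if (ct == "microglia" && n_plq > 0 && config$microglia_plaque_attraction > 1) {
          extra <- sample_poisson_points(
            poly, (config$microglia_plaque_attraction - 1) * config$cell_type_densities[rg, ct])
          if (nrow(extra)) {
            d2 <- outer(extra[, 1], plq[, 1], "-")^2 + outer(extra[, 2], plq[, 2], "-")^2
            keep <- sqrt(apply(d2, 1, min)) < th$proximal_radius
            pts <- rbind(pts, extra[keep, , drop = FALSE])
          }
        }
        if (nrow(pts)) {
          xs <- c(xs, pts[, 1]); ys <- c(ys, pts[, 2])
          type <- c(type, rep(ct, nrow(pts)))
          region <- c(region, rep(rg, nrow(pts)))
        }
      }
    }
    n <- length(xs)
    if (n == 0) stop("simulated section contains no cells; increase densities")
    cell_id <- sprintf("%s_c%05d", sample_id, seq_len(n))

    dist_plaque <- rep(NA_real_, n)
    if (n_plq > 0) {
      d2 <- outer(xs, plq[, 1], "-")^2 + outer(ys, plq[, 2], "-")^2
      dist_plaque <- sqrt(apply(d2, 1, min))
    }

    # -- latent subpopulations ----------------------------------------------
    subtype <- type
    sub <- config$biased_subpopulations
    if (nrow(sub)) {
      for (i in seq_len(nrow(sub))) {
        enriched <- strsplit(sub$genotypes[i], ";")[[1]]
        if (!genotype %in% enriched) next
        idx <- which(type == sub$cell_type[i])
        take <- idx[stats::runif(length(idx)) < sub$fraction[i]]
        subtype[take] <- paste0(sub$cell_type[i], "_biased", i)
      }
    }

    # -- counts -------------------------------------------------------------
    logmu <- log(config$nb_baseline)[match(type, config$cell_types), , drop = FALSE]
    logmu <- sweep(logmu, 2, batch_effects[batch, ], "+")
    libf <- stats::rnorm(n, 0, config$library_size_lognormal_sigma)
    logmu <- logmu + libf
    ln2 <- log(2)
    ge <- config$genotype_effects
    if (nrow(ge)) {
      for (i in seq_len(nrow(ge))) {
        gset <- strsplit(ge$genotype[i], ";")[[1]]
        if (!genotype %in% gset) next
        idx <- type == ge$cell_type[i]
        logmu[idx, ge$gene[i]] <- logmu[idx, ge$gene[i]] + ln2 * ge$log2fc[i]
      }
    }
    de <- config$distance_effects
    if (nrow(de) && n_plq > 0) {
      for (i in seq_len(nrow(de))) {
        idx <- type == de$cell_type[i]
        d <- dist_plaque[idx]
        delta <- if (de$form[i] == "log_linear") {
          ln2 * de$amplitude_log2[i] + de$slope_ln[i] * d
        } else {
          ln2 * de$amplitude_log2[i] * exp(-d / de$decay_um[i])
        }
        logmu[idx, de$gene[i]] <- logmu[idx, de$gene[i]] + delta
      }
    }
    if (nrow(sub)) {
      for (i in seq_len(nrow(sub))) {
        idx <- subtype == paste0(sub$cell_type[i], "_biased", i)
        if (!any(idx)) next
        for (gn in strsplit(sub$marker_genes[i], ";")[[1]]) {
          logmu[idx, gn] <- logmu[idx, gn] + ln2 * sub$shift_log2[i]
        }
      }
    }
    mu <- exp(logmu)
    counts <- matrix(stats::rnbinom(n * G, mu = mu,
                                    size = rep(1 / config$nb_dispersion, each = n)),
                     n, G, dimnames = list(cell_id, genes))
    storage.mode(counts) <- "integer"

    # volumes calibrated so volume_exceed_fraction of cells fail the QC cutoff
    vol_meanlog <- log(th$max_cell_volume) -
      stats::qnorm(1 - config$volume_exceed_fraction) * config$volume_sdlog
    volume <- stats::rlnorm(n, vol_meanlog, config$volume_sdlog)

    cells <- data.frame(
      cell_id = cell_id, x = xs, y = ys, volume = volume,
      total_transcripts = as.integer(rowSums(counts)),
      sample_id = sample_id, batch_id = as.character(batch),
      genotype = factor(genotype, levels = genotype_levels()),
      cell_type = type, subcluster = NA_character_, region = region,
      stringsAsFactors = FALSE
    )
    truth <- list(
      genotype_effects = ge, distance_effects = de,
      subpopulations = data.frame(cell_id = cell_id, subtype = subtype,
                                  stringsAsFactors = FALSE),
      cell_types = stats::setNames(type, cell_id),
      regions = stats::setNames(region, cell_id),
      distance_to_plaque = stats::setNames(dist_plaque, cell_id),
      plaques = plaques
    )
    list(cells = cells, counts = counts, plaques = plaques,
         regions = stats::setNames(list(config$region_layout), sample_id)[[1]],
         truth = truth)
  })
}

draw_batch_effects <- function(config, batches, seed) {
  batches <- unique(as.character(batches))
  with_seed(seed, {
    matrix(stats::rnorm(length(batches) * config$n_genes, 0, config$batch_effect_sigma),
           length(batches), config$n_genes,
           dimnames = list(batches, config$genes))
  })
}

#' Simulate a cohort of sections
#'
#' One section per design row, with per-section seeds derived from the root
#' seed and shared per-batch gene effects, concatenated into one [dataset]
#' with unique sample ids.
#'
#' @param config A [sim_config()] object.
#' @param design Data frame with columns `genotype` and `batch`; one row per
#'   section.
#' @param seed Root seed; all randomness derives from it.
#' @return A list with `dataset` (class `dataset`) and `truth` (per-sample
#'   ground-truth records).
#' @export
simulate_cohort <- function(config, design, seed) {
  stopifnot(inherits(config, "sim_config"))
  design <- as.data.frame(design)
  if (nrow(design) == 0) stop("design must contain at least one section")
  if (!all(c("genotype", "batch") %in% names(design))) {
    stop("design needs 'genotype' and 'batch' columns")
  }
  batch_effects <- draw_batch_effects(config, design$batch, derive_seed(seed, 7L))
  sections <- vector("list", nrow(design))
  for (i in seq_len(nrow(design))) {
    sections[[i]] <- simulate_section(
      config, design$genotype[i], as.character(design$batch[i]),
      seed = derive_seed(seed, i), sample_id = sprintf("S%02d", i),
      batch_effects = batch_effects)
  }
  cells <- do.call(rbind, lapply(sections, `[[`, "cells"))
  counts <- do.call(rbind, lapply(sections, `[[`, "counts"))
  plaques <- do.call(rbind, lapply(sections, `[[`, "plaques"))
  rownames(cells) <- rownames(plaques) <- NULL
  regions <- stats::setNames(
    rep(list(config$region_layout), nrow(design)),
    sprintf("S%02d", seq_len(nrow(design))))
  ds <- new_dataset(cells, counts, plaques, regions,
                    atlas = NULL, thresholds = config$thresholds)
  truth <- stats::setNames(lapply(sections, `[[`, "truth"),
                           sprintf("S%02d", seq_len(nrow(design))))
  list(dataset = ds, truth = truth)
}

#' Standard cohort design
#'
#' Crossed design: every genotype in every batch, mirroring a multi-batch
#' imaging study with all four genotypes represented.
#'
#' @param genotypes Genotype codes.
#' @param batches Batch labels.
#' @return Data frame with `genotype` and `batch` columns.
#' @export
cohort_design <- function(genotypes = genotype_levels(),
                          batches = c("b1", "b2", "b3")) {
  expand.grid(genotype = genotypes, batch = batches,
              KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
}

#' Render a DAPI-like image of a window of a section
#'
#' Nuclei are rendered as round Gaussian blobs (mean diameter ~8.5 um) and
#' plaques as brighter, larger, multi-lobed blobs (default equivalent
#' diameter 22.4 um), over additive Gaussian background noise. A paired
#' ground-truth label mask marks, for each plaque, the union of its lobes'
#' 2-sigma supports.
#'
#' @param cells Cell table (positions in um).
#' @param plaques Plaque table (positions and equivalent diameters in um);
#'   may be empty.
#' @param pixel_size um per pixel.
#' @param window Numeric `c(xmin, xmax, ymin, ymax)` in um.
#' @param seed Seed for background noise and lobe placement.
#' @param background,noise_sd Background level and noise sd (a.u.).
#' @param nucleus_peak,plaque_peak Peak amplitudes above background; plaques
#'   are several-fold brighter than nuclei by default, as dense fibrillar
#'   material outshines chromatin.
#' @param nucleus_diameter Mean rendered nucleus diameter (um).
#' @return List with `image` (numeric matrix, x by y), `mask` (integer label
#'   matrix: 0 background, k the k-th plaque), `pixel_size`, `window`, and
#'   `plaque_ids` mapping mask labels to plaque ids.
#' @export
render_dapi_image <- function(cells, plaques, pixel_size = 0.5,
                              window, seed = 1L,
                              background = 100, noise_sd = 5,
                              nucleus_peak = 80, plaque_peak = 600,
                              nucleus_diameter = 8.5) {
  stopifnot(pixel_size > 0, length(window) == 4)
  if (window[2] <= window[1] || window[4] <= window[3]) stop("empty window")
  nx <- max(1L, round((window[2] - window[1]) / pixel_size))
  ny <- max(1L, round((window[4] - window[3]) / pixel_size))
  img <- matrix(0, nx, ny)
  mask <- matrix(0L, nx, ny)

  add_blob <- function(img, cx, cy, sigma, amp, plateau = FALSE) {
    # pixel-center coordinates; render on a +/-3 sigma patch
    ix <- (cx - window[1]) / pixel_size + 0.5
    iy <- (cy - window[3]) / pixel_size + 0.5
    r <- 3 * sigma / pixel_size
    x0 <- max(1L, floor(ix - r)); x1 <- min(nx, ceiling(ix + r))
    y0 <- max(1L, floor(iy - r)); y1 <- min(ny, ceiling(iy + r))
    if (x0 > x1 || y0 > y1) return(img)
    dx2 <- ((x0:x1 - ix) * pixel_size)^2
    dy2 <- ((y0:y1 - iy) * pixel_size)^2
    r2 <- outer(dx2, dy2, "+") / sigma^2
    # plateau profile: dense fibrillar aggregate with a sharp edge, so the
    # apparent size barely depends on the detection threshold
    prof <- if (plateau) exp(-0.5 * r2^2) else exp(-0.5 * r2)
    img[x0:x1, y0:y1] <- img[x0:x1, y0:y1] + amp * prof
    img
  }
  mark_disk <- function(mask, cx, cy, radius, label) {
    ix <- (cx - window[1]) / pixel_size + 0.5
    iy <- (cy - window[3]) / pixel_size + 0.5
    r <- radius / pixel_size
    x0 <- max(1L, floor(ix - r)); x1 <- min(nx, ceiling(ix + r))
    y0 <- max(1L, floor(iy - r)); y1 <- min(ny, ceiling(iy + r))
    if (x0 > x1 || y0 > y1) return(mask)
    dd <- outer((x0:x1 - ix)^2, (y0:y1 - iy)^2, "+")
    patch <- mask[x0:x1, y0:y1]
    patch[dd <= r^2] <- label
    mask[x0:x1, y0:y1] <- patch
    mask
  }

  with_seed(seed, {
    if (nrow(cells)) {
      for (i in seq_len(nrow(cells))) {
        img <- add_blob(img, cells$x[i], cells$y[i],
                        sigma = nucleus_diameter / 4, amp = nucleus_peak)
      }
    }
    plaque_ids <- character(0)
    if (nrow(plaques)) {
      diam <- plaques$equivalent_diameter
      diam[!is.finite(diam) | diam <= 0] <- 22.4
      for (k in seq_len(nrow(plaques))) {
        cx <- plaques$x[k]; cy <- plaques$y[k]; d <- diam[k]
        # bright plateau core plus satellite lobes give the irregular,
        # fibrillar look; the paired mask is the union of the lobe supports
        lobes <- data.frame(x = cx, y = cy, sigma = 0.44 * d, amp = plaque_peak)
        nl <- 4L
        ang <- stats::runif(1, 0, 2 * pi) + 2 * pi * seq_len(nl) / nl
        lobes <- rbind(lobes, data.frame(
          x = cx + 0.48 * d * cos(ang), y = cy + 0.48 * d * sin(ang),
          sigma = 0.1 * d, amp = 0.9 * plaque_peak))
        for (j in seq_len(nrow(lobes))) {
          img <- add_blob(img, lobes$x[j], lobes$y[j], lobes$sigma[j],
                          lobes$amp[j], plateau = TRUE)
          mask <- mark_disk(mask, lobes$x[j], lobes$y[j], 1.1 * lobes$sigma[j], k)
        }
        plaque_ids <- c(plaque_ids, as.character(plaques$plaque_id[k]))
      }
    }
    img <- img + background + matrix(stats::rnorm(nx * ny, 0, noise_sd), nx, ny)
    img[img < 0] <- 0
    list(image = img, mask = mask, pixel_size = pixel_size,
         window = window, plaque_ids = plaque_ids)
  })
}
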