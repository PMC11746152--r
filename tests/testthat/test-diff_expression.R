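make_cells <- function(n, type = "t", sample = "S01", batch = "b1",
                       genotype = "WT") {
  data.frame(cell_id = paste0(sample, "_", type, seq_len(n)), x = 0, y = 0,
             volume = 1000, sample_id = sample, batch_id = batch,
             genotype = genotype, cell_type = type,
             stringsAsFactors = FALSE)
}

test_that("pseudobulk sums counts and applies the replicate and gene filters", {
  th <- analysis_thresholds(min_cells_per_pseudobulk = 3)
  cells <- make_cells(3)
  counts <- matrix(c(1L, 2L, 3L, 0L, 0L, 1L), 3, 2,
                   dimnames = list(cells$cell_id, c("gA", "gB")))
  pb <- build_pseudobulk(counts, cells, th)
  expect_equal(unname(pb$counts[1, "gA"]), 6)
  # a 49-cell stratum is dropped at the default 50-cell threshold
  c49 <- make_cells(49, sample = "S01")
  c60 <- make_cells(60, sample = "S02")
  cells2 <- rbind(c49, c60)
  counts2 <- matrix(5L, nrow(cells2), 2,
                    dimnames = list(cells2$cell_id, c("gA", "gB")))
  pb2 <- build_pseudobulk(counts2, cells2, analysis_thresholds())
  expect_equal(pb2$meta$sample_id, "S02")
  expect_true(any(grepl("S01", pb2$dropped_strata)))
  # a gene detected in 10 of 100 cells is excluded for the type
  c100 <- make_cells(100)
  counts3 <- matrix(0L, 100, 2, dimnames = list(c100$cell_id, c("gA", "gB")))
  counts3[, "gA"] <- 1L
  counts3[1:10, "gB"] <- 1L
  pb3 <- build_pseudobulk(counts3, c100, analysis_thresholds())
  expect_equal(pb3$genes_use[["t"]], "gA")
  expect_error(build_pseudobulk(counts, cells, analysis_thresholds()),
               "no stratum")
})

test_that("pseudobulk counts are conserved exactly", {
  cohort <- null_cohort()
  pb <- build_pseudobulk(cohort$counts, cohort$cells)
  in_kept <- paste(cohort$cells$cell_type, cohort$cells$sample_id) %in%
    paste(pb$meta$cell_type, pb$meta$sample_id)
  expect_equal(sum(pb$counts), sum(cohort$counts[in_kept, ]))
  # per-stratum check on one stratum
  s <- pb$meta$cell_type == "microglia" & pb$meta$sample_id == "S01"
  manual <- colSums(cohort$counts[cohort$cells$cell_type == "microglia" &
                                    cohort$cells$sample_id == "S01", ])
  expect_equal(unname(pb$counts[which(s), ]), unname(manual))
})

test_that("identical groups give zero fold change; swapping groups negates it", {
  cells <- rbind(make_cells(60, sample = "S01", batch = "b1", genotype = "WT"),
                 make_cells(60, sample = "S02", batch = "b2", genotype = "WT"),
                 make_cells(60, sample = "S03", batch = "b1", genotype = "FAD"),
                 make_cells(60, sample = "S04", batch = "b2", genotype = "FAD"))
  set.seed(2)
  counts <- matrix(rpois(240 * 20, 5), 240, 20,
                   dimnames = list(cells$cell_id, paste0("g", 1:20)))
  th <- analysis_thresholds()
  pb <- build_pseudobulk(counts, cells, th)
  # duplicate every replicate as a fake second group: the groups then hold
  # identical observations
  pbx <- pb
  pbx$counts <- rbind(pb$counts, pb$counts)
  meta_a <- transform(pb$meta, genotype = "WT")
  meta_b <- transform(pb$meta, genotype = "R47H",
                      sample_id = paste0(sample_id, "x"))
  pbx$meta <- rbind(meta_a, meta_b)
  same <- suppressWarnings(fit_group_de(pbx, "t", "genotype", "R47H", "WT", th))
  expect_true(all(abs(same$log2fc) < 1e-6))
  expect_false(any(same$significant))
  ab <- suppressWarnings(fit_group_de(pb, "t", "genotype", "FAD", "WT", th))
  ba <- suppressWarnings(fit_group_de(pb, "t", "genotype", "WT", "FAD", th))
  expect_equal(ab$log2fc, -ba$log2fc, tolerance = 1e-8)
  expect_equal(ab$p, ba$p, tolerance = 1e-6)
})

test_that("a single batch falls back to ordinary least squares with a flag", {
  cells <- rbind(make_cells(60, sample = "S01", genotype = "WT"),
                 make_cells(60, sample = "S02", genotype = "WT"),
                 make_cells(60, sample = "S03", genotype = "FAD"),
                 make_cells(60, sample = "S04", genotype = "FAD"))
  set.seed(3)
  counts <- matrix(rpois(240 * 10, 5), 240, 10,
                   dimnames = list(cells$cell_id, paste0("g", 1:10)))
  pb <- build_pseudobulk(counts, cells)
  de <- fit_group_de(pb, "t", "genotype", "FAD", "WT")
  expect_true(all(de$model_flag == "ols_single_batch"))
  expect_error(fit_group_de(pb, "t", "genotype", "R47H", "WT"), "R47H")
})

test_that("planted genotype effects are recovered with controlled error", {
  set.seed(0)
  genes <- sprintf("g%03d", 1:300)
  planted <- sample(genes, 20)
  ge <- data.frame(gene = planted, cell_type = "excitatory", genotype = "FAD",
                   log2fc = sample(c(-1.5, 1.5), 20, replace = TRUE))
  cfg <- sim_config(genotype_effects = ge)
  sim <- simulate_cohort(cfg, cohort_design(batches = paste0("b", 1:5)),
                         seed = 11)
  qc <- qc_filter_cells(sim$dataset$cells, sim$dataset$counts)
  pb <- build_pseudobulk(qc$counts, qc$cells)
  de <- suppressWarnings(fit_group_de(pb, "excitatory", "genotype", "FAD", "WT"))
  sub <- de[de$gene %in% planted, ]
  truth <- ge$log2fc[match(sub$gene, ge$gene)]
  expect_gt(mean(abs(sub$log2fc - truth) < 0.4), 0.9)
  hits <- de$gene[de$significant]
  expect_gte(mean(sub$gene %in% hits), 0.8)
  if (length(hits)) expect_lte(mean(!hits %in% planted), 0.1)
})

test_that("pairwise genotype DE covers the five studied contrasts", {
  cohort <- null_cohort()
  pb <- build_pseudobulk(cohort$counts, cohort$cells)
  de <- suppressWarnings(pairwise_genotype_de(pb, cell_types = "astrocyte"))
  expect_setequal(unique(de$comparison),
                  c("FAD_vs_WT", "R47H_FAD_vs_R47H", "R47H_vs_WT",
                    "R47H_FAD_vs_FAD", "R47H_FAD_vs_WT"))
  # missing genotype: its comparisons are skipped with warnings
  keep <- cohort$cells$genotype != "R47H"
  pb2 <- build_pseudobulk(cohort$counts[keep, ], cohort$cells[keep, ])
  w <- testthat::capture_warnings(
    de2 <- pairwise_genotype_de(pb2, cell_types = "astrocyte"))
  expect_true(any(grepl("skipping", w)))
  expect_false(any(grepl("R47H_vs_WT", unique(de2$comparison))))
})

test_that("region-vs-rest finds planted spatial genes at nominal thresholds", {
  # expression raised in one region for one gene, one genotype cohort
  cfg0 <- sim_config(n_genes = 60)
  # plant by hand: simulate, then scale counts of g010 inside the cortex
  sim <- simulate_cohort(cfg0, cohort_design(genotypes = "WT",
                                             batches = c("b1", "b2", "b3")),
                         seed = 14)
  qc <- qc_filter_cells(sim$dataset$cells, sim$dataset$counts)
  cells <- qc$cells; counts <- qc$counts
  boost <- cells$region == "cortex" & cells$cell_type == "excitatory"
  counts[boost, "g010"] <- counts[boost, "g010"] * 3L
  pbr <- build_pseudobulk(counts, cells, stratify_by = "region")
  de <- suppressWarnings(region_vs_rest_de(pbr))  # sparse types skipped
  row <- de[de$gene == "g010" & de$comparison == "cortex_vs_rest" &
              de$cell_type == "excitatory", ]
  expect_true(row$significant)
  expect_gt(row$log2fc, 0.35)
  expect_true(all(de$nominal))
  # the cortex stratum is small for oligodendrocytes in this layout: any
  # stratum under 50 cells must be absent from the pseudobulk
  expect_true(all(pbr$meta$n_cells >= 50))
})

test_that("proximal-vs-distal DE recovers a planted plaque program", {
  de_cfg <- data.frame(gene = "g020", cell_type = "microglia",
                       form = "amp_decay", amplitude_log2 = 3, decay_um = 50,
                       slope_ln = NA)
  cfg <- sim_config(distance_effects = de_cfg)
  sim <- simulate_cohort(cfg, cohort_design(batches = paste0("b", 1:5)),
                         seed = 8)
  qc <- qc_filter_cells(sim$dataset$cells, sim$dataset$counts)
  cells <- annotate_zones(qc$cells, sim$dataset$plaques)
  pbz <- build_pseudobulk(qc$counts, cells, stratify_by = "zone")
  # cells beyond the distal radius play no part
  expect_false("beyond" %in% pbz$meta$zone[is_amyloid(pbz$meta$genotype) &
                                             pbz$meta$cell_type == "microglia"])
  de <- suppressWarnings(proximal_vs_distal_de(pbz, cell_types = "microglia"))
  row <- de[de$gene == "g020", ]
  expect_true(row$significant)
  expect_gt(row$log2fc, 0.35)
  expect_lte(mean(de$significant[de$gene != "g020"]), 0.01)
})

test_that("continuous-distance regression estimates per-um slopes", {
  set.seed(0)
  genes <- sprintf("g%03d", 1:300)
  planted <- sample(genes, 10)
  de_cfg <- data.frame(gene = planted, cell_type = "microglia",
                       form = "log_linear", amplitude_log2 = 3, decay_um = NA,
                       slope_ln = -0.02)
  cfg <- sim_config(distance_effects = de_cfg)
  sim <- simulate_cohort(cfg, cohort_design(), seed = 5)
  qc <- qc_filter_cells(sim$dataset$cells, sim$dataset$counts)
  cells <- annotate_zones(qc$cells, sim$dataset$plaques)
  res <- continuous_distance_de(qc$counts, cells, "microglia")
  pl <- res[res$gene %in% planted, ]
  expect_gte(mean(abs(pl$log2fc_per_um + 0.0289) < 0.3 * 0.0289), 0.9)
  expect_gte(mean(pl$significant & pl$log2fc_per_um < 0), 0.9)
  np <- res[!res$gene %in% planted & !is.na(res$p_adj), ]
  expect_lte(mean(np$significant), 0.05)
  expect_error(continuous_distance_de(qc$counts, cells, "microglia",
                                      max_distance = 0.5),
               "at least 30")
})

test_that("BH adjustment is exact, monotone, and order-preserving", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.05), 0.05)
  expect_error(bh_adjust(c(0.1, 1.2)), "0, 1")
  brute_bh <- function(p) {
    n <- length(p); o <- order(p)
    adj <- p[o] * n / seq_len(n)
    for (i in (n - 1):1) adj[i] <- min(adj[i], adj[i + 1])
    out <- numeric(n); out[o] <- pmin(adj, 1)
    out
  }
  set.seed(6)
  for (i in 1:25) {
    p <- runif(sample(3:40, 1))
    a <- bh_adjust(p)
    expect_equal(a, brute_bh(p), tolerance = 1e-12)
    expect_true(all(a >= p - 1e-12))
    expect_true(all(diff(a[order(p)]) >= -1e-12))
  }
})

test_that("the Satterthwaite routine agrees with the reference implementation", {
  set.seed(7)
  checked <- 0
  for (i in 1:30) {
    nb <- sample(3:5, 1)
    d <- data.frame(grp = factor(rep(c("b", "a"), nb * 2), levels = c("b", "a")),
                    batch = factor(rep(seq_len(nb), each = 4)))
    y <- rnorm(nrow(d)) + 0.5 * rep(rnorm(nb), each = 4) + 0.4 * (d$grp == "a")
    mt <- suppressMessages(lmerTest::lmer(y ~ grp + (1 | batch), data = d))
    if (lme4::isSingular(mt)) next
    ref <- coef(summary(mt))["grpa", "df"]
    own <- plaquescape:::satterthwaite_df(
      y, model.matrix(~grp, d), model.matrix(~ 0 + batch, d),
      theta = mt@theta, s2 = sigma(mt)^2, coef_index = 2L)
    expect_equal(own, ref, tolerance = 1e-3)
    checked <- checked + 1
  }
  expect_gte(checked, 10)
})

test_that("post-hoc filters enforce atlas expression and exclusion lists", {
  atlas <- data.frame(
    gene = c("Gfap", "Cx3cr1", "Slc17a7"),
    expressed_in = c("astrocyte", "microglia", "neuron"),
    exclusive_to = c("astrocyte", "microglia", ""),
    stringsAsFactors = FALSE)
  res <- data.frame(cell_type = c("neuron", "microglia", "neuron"),
                    comparison = "FAD_vs_WT",
                    gene = c("Gfap", "Cx3cr1", "Slc17a7"),
                    log2fc = 1, se = 0.1, p = 0.001, p_adj = 0.01,
                    significant = TRUE, stringsAsFactors = FALSE)
  neu <- filter_de_results(res, atlas, mode = "neuronal")
  expect_false("Gfap" %in% neu$gene)        # astrocyte-exclusive, removed
  expect_true("Slc17a7" %in% neu$gene)
  gli <- filter_de_results(res[2, ], atlas, mode = "glial")
  expect_true("Cx3cr1" %in% gli$gene)       # annotated in microglia, kept
  ap <- filter_de_results(res, atlas, mode = "neuronal",
                          exclusion_genes = "Slc17a7")
  expect_false("Slc17a7" %in% ap$gene)
  expect_error(filter_de_results(res, NULL, mode = "glial"), "atlas")
  expect_equal(nrow(attr(neu, "raw")), nrow(res))
})
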