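# Shared simulated fixtures, built once per test run.
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtures)) assign(name, builder(), envir = .fixtures)
  get(name, envir = .fixtures)
}

# a plain cohort with no planted effects (4 genotypes x 3 batches)
null_cohort <- function() {
  fixture("null_cohort", function() {
    cfg <- sim_config()
    sim <- simulate_cohort(cfg, cohort_design(), seed = 101)
    qc <- qc_filter_cells(sim$dataset$cells, sim$dataset$counts)
    list(cfg = cfg, sim = sim, cells = qc$cells, counts = qc$counts)
  })
}

# cells of one amyloid cohort annotated with plaque distances and zones
annotate_zones <- function(cells, plaques, thresholds = analysis_thresholds()) {
  cells$distance_to_plaque <- NA_real_
  cells$zone <- NA_character_
  for (sid in unique(cells$sample_id)) {
    plq <- plaques[plaques$sample_id == sid, , drop = FALSE]
    if (nrow(plq) == 0) next
    sel <- cells$sample_id == sid
    ann <- nearest_plaque_distance(cells[sel, , drop = FALSE], plq, thresholds)
    cells$distance_to_plaque[sel] <- ann$distance_to_plaque
    cells$zone[sel] <- as.character(ann$zone)
  }
  cells
}

# a rendered validation ROI: window of a simulated amyloid section that
# contains at least one plaque, plus its ground-truth mask
render_validation_roi <- function(s, base = 300, cfg = sim_config()) {
  sec <- simulate_section(cfg, "FAD", "b1", seed = base + s)
  repeat {
    w0 <- c(stats::runif(1, 0, 800), stats::runif(1, 0, 800))
    win <- c(w0[1], w0[1] + 200, w0[2], w0[2] + 200)
    inw <- sec$plaques[sec$plaques$x > win[1] + 12 & sec$plaques$x < win[2] - 12 &
                         sec$plaques$y > win[3] + 12 & sec$plaques$y < win[4] - 12, ]
    if (nrow(inw) >= 1) break
  }
  cells <- sec$cells[sec$cells$x > win[1] - 15 & sec$cells$x < win[2] + 15 &
                       sec$cells$y > win[3] - 15 & sec$cells$y < win[4] + 15, ]
  list(roi = render_dapi_image(cells, inw, pixel_size = 0.5, window = win, seed = s),
       cells = cells, plaques = inw)
}

# convex hull area oracle built on chull(), independent of the alpha-shape path
chull_area <- function(pts) {
  h <- grDevices::chull(pts)
  hp <- pts[h, , drop = FALSE]
  abs(sum(hp[, 1] * c(hp[-1, 2], hp[1, 2]) - c(hp[-1, 1], hp[1, 1]) * hp[, 2])) / 2
}

# brute-force k-th nearest neighbour distances (row includes self at 0)
brute_knn_dist <- function(pts, k) {
  apply(as.matrix(dist(pts)), 1, function(r) sort(r)[k + 1])
}
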