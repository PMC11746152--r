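test_that("nearest-plaque distances and zones follow the conventions", {
  th <- analysis_thresholds()
  cells <- data.frame(cell_id = c("a", "b", "c"), x = c(0, 0, 100), y = c(0, 0, 0),
                      cell_type = "microglia")
  plq <- data.frame(plaque_id = "p", x = 30, y = 40, area = 100,
                    equivalent_diameter = 11.3, volume = 1000, sample_id = "S01")
  ann <- nearest_plaque_distance(cells[1, ], plq, th)
  expect_equal(ann$distance_to_plaque, 50)           # 3-4-5 triangle
  expect_equal(as.character(ann$zone), "proximal")
  two <- rbind(plq, data.frame(plaque_id = "q", x = 6, y = 8, area = 100,
                               equivalent_diameter = 11.3, volume = 1000,
                               sample_id = "S01"))
  expect_equal(nearest_plaque_distance(cells[1, ], two, th)$distance_to_plaque, 10)
  # exactly 100 um is distal (proximal is strict), exactly 500 still distal
  at100 <- data.frame(cell_id = "z", x = 130, y = 40, cell_type = "x")
  expect_equal(as.character(nearest_plaque_distance(at100, plq, th)$zone), "distal")
  at500 <- data.frame(cell_id = "w", x = 530, y = 40, cell_type = "x")
  expect_equal(as.character(nearest_plaque_distance(at500, plq, th)$zone), "distal")
  expect_error(nearest_plaque_distance(cells, plq[0, ], th), "no plaques")
})

test_that("closest-cell composition enumerates nearest typed cells", {
  cells <- data.frame(cell_id = c("c1", "c2", "c3"),
                      x = c(0, 10, 100), y = 0,
                      cell_type = c("A", "A", "B"))
  plq <- data.frame(x = c(1, 9, 99), y = 0)
  prop <- closest_cell_composition(plq, cells)
  expect_equal(unname(prop[c("A", "B")]), c(2 / 3, 1 / 3))
  expect_equal(sum(prop), 1)
  allA <- closest_cell_composition(plq, transform(cells, cell_type = "A"))
  expect_equal(unname(allA), 1)
  # tie broken toward the lower cell_id
  tie <- data.frame(cell_id = c("c2", "c1"), x = c(5, 5), y = c(1, -1),
                    cell_type = c("B", "A"))
  expect_equal(names(closest_cell_composition(data.frame(x = 5, y = 0), tie)), "A")
  expect_error(closest_cell_composition(plq[0, ], cells), "no plaques")
})

test_that("annulus composition applies the two-step abundance normalization", {
  th <- analysis_thresholds()
  # annulus [0,25): types A:30, B:10; section totals A:300, B:50
  set.seed(4)
  mk <- function(n, type, rmin, rmax) {
    r <- sqrt(runif(n, (rmin / 500)^2, (rmax / 500)^2)) * 500
    a <- runif(n, 0, 2 * pi)
    data.frame(cell_id = paste0(type, rmin, "_", seq_len(n)),
               x = r * cos(a), y = r * sin(a), cell_type = type)
  }
  cells <- rbind(mk(30, "A", 0, 24.9), mk(10, "B", 0, 24.9),
                 mk(270, "A", 30, 490), mk(40, "B", 30, 490))
  plq <- data.frame(x = 0, y = 0)
  res <- annulus_composition(plq, cells, th)
  first <- res[res$annulus == 0, ]
  expect_equal(first$proportion[first$cell_type == "A"], 0.75)
  expect_equal(first$proportion[first$cell_type == "B"], 0.25)
  expect_equal(first$proportion_normalized[first$cell_type == "A"], 1 / 3,
               tolerance = 1e-12)
  expect_equal(first$proportion_normalized[first$cell_type == "B"], 2 / 3,
               tolerance = 1e-12)
  # proportions are simplexes in every annulus
  sums <- tapply(res$proportion, res$annulus, sum)
  expect_true(all(abs(sums - 1) < 1e-9))
  one <- annulus_composition(plq, transform(cells, cell_type = "A"), th)
  expect_true(all(one$proportion == 1))
})

test_that("union disk areas agree with closed forms within 1 percent", {
  big <- cbind(c(-1e4, 1e4, 1e4, -1e4), c(-1e4, -1e4, 1e4, 1e4))
  one <- union_disk_area(cbind(0, 0), 100, clip = big, seed = 2)
  expect_lt(abs(one - pi * 1e4) / (pi * 1e4), 0.01)
  two <- union_disk_area(rbind(c(0, 0), c(400, 0)), 100, seed = 2)
  expect_lt(abs(two - 2 * pi * 1e4) / (2 * pi * 1e4), 0.01)
  co <- union_disk_area(rbind(c(0, 0), c(0, 0)), 100, seed = 2)
  expect_lt(abs(co - pi * 1e4) / (pi * 1e4), 0.01)
  expect_equal(union_disk_area(cbind(numeric(), numeric()), 100), 0)
  # monotone in radius, subadditive over center sets
  centers <- rbind(c(0, 0), c(120, 40), c(60, 180))
  a1 <- union_disk_area(centers, 80, seed = 3)
  a2 <- union_disk_area(centers, 120, seed = 3)
  expect_gt(a2, a1)
  part <- union_disk_area(centers[1:2, ], 80, seed = 3) +
    union_disk_area(centers[3, , drop = FALSE], 80, seed = 3)
  expect_lte(a1, part * 1.01)
})

test_that("proximal and distal densities are estimated per unit union area", {
  th <- analysis_thresholds()
  # uniform cells: proximal and distal densities agree within 20%
  set.seed(8)
  cells <- data.frame(cell_id = paste0("c", 1:3000),
                      x = runif(3000, 0, 1500), y = runif(3000, 0, 1500))
  plq <- data.frame(x = c(300, 900, 1200), y = c(300, 1100, 500))
  poly <- cbind(c(0, 1500, 1500, 0), c(0, 0, 1500, 1500))
  d <- proximal_distal_density(cells, plq, poly, th, n_points = 2e5, seed = 1)
  expect_lt(abs(d$proximal / d$distal - 1), 0.2)
  # plain division
  expect_equal(d$proximal, d$n_proximal / d$area_proximal)
  expect_error(proximal_distal_density(cells, plq[0, ], poly, th), "no plaques")
})

test_that("knn outlier filtering matches a brute-force oracle", {
  # regular grid: interior points share one 5th-neighbor distance (the IQR is
  # zero), so exactly the four corners, whose 5th neighbor sits farther out,
  # are flagged -- the brute-force oracle agrees
  grid <- as.matrix(expand.grid(x = seq(0, 90, 10), y = seq(0, 90, 10)))
  d5 <- brute_knn_dist(grid, 5)
  oracle <- which(!(d5 >= median(d5) - 1.5 * IQR(d5) &
                      d5 <= median(d5) + 1.5 * IQR(d5)))
  kept <- knn_outlier_filter(grid, 5)
  expect_equal(sort(attr(kept, "removed")), sort(oracle))
  expect_equal(nrow(kept), 96)
  # a far-away point is always removed
  with_out <- rbind(grid, c(1000, 1000))
  kept2 <- knn_outlier_filter(with_out, 5)
  expect_true(101L %in% attr(kept2, "removed"))
  # oracle agreement on an irregular cloud
  set.seed(3)
  pts <- cbind(runif(60, 0, 100), runif(60, 0, 100))
  d5 <- brute_knn_dist(pts, 5)
  med <- median(d5); iqr <- IQR(d5)
  oracle_keep <- d5 >= med - 1.5 * iqr & d5 <= med + 1.5 * iqr
  expect_equal(nrow(knn_outlier_filter(pts, 5)), sum(oracle_keep))
  expect_error(knn_outlier_filter(grid[1:5, ], 5), "more than k")
})

test_that("alpha-shape areas match geometric references", {
  tri <- rbind(c(0, 0), c(100, 0), c(0, 100))
  expect_equal(alpha_shape_area(tri, 0), 5000)
  grid <- as.matrix(expand.grid(seq(0, 100, length.out = 50),
                                seq(0, 100, length.out = 50)))
  expect_lt(abs(alpha_shape_area(grid, 0.015) - 10000) / 10000, 0.05)
  set.seed(2)
  pts <- cbind(runif(200, 0, 100), runif(200, 0, 100))
  expect_equal(alpha_shape_area(pts, 0), chull_area(pts), tolerance = 1e-9)
  expect_error(alpha_shape_area(rbind(c(0, 0), c(1, 1)), 0.015), "3 distinct")
  expect_error(alpha_shape_area(rbind(c(0, 0), c(1, 1), c(2, 2)), 0),
               "collinear")
})

test_that("regional densities divide counts by the right areas", {
  th <- analysis_thresholds()
  poly <- list(box = cbind(c(0, 1000, 1000, 0), c(0, 0, 1000, 1000)))
  set.seed(5)
  cells <- data.frame(cell_id = paste0("c", 1:100),
                      x = runif(100, 0, 1000), y = runif(100, 0, 1000),
                      cell_type = "neuron")
  res <- regional_density(cells, poly, by = "all", thresholds = th)
  expect_equal(res$density, 1e-4)
  # empty region reports density 0 for a named type
  far <- list(empty = cbind(c(5000, 6000, 6000, 5000), c(0, 0, 1000, 1000)))
  res0 <- regional_density(cells, far, by = "neuron", thresholds = th)
  expect_equal(res0$density, 0)
  # planted density recovered within 15% via the alpha-shape route
  dense <- data.frame(cell_id = paste0("d", 1:1000),
                      x = runif(1000, 0, 1000), y = runif(1000, 0, 1000),
                      cell_type = "neuron")
  resd <- regional_density(dense, poly, by = "neuron", thresholds = th)
  expect_lt(abs(resd$density - 1e-3) / 1e-3, 0.15)
})

test_that("plaque-to-neuron distances exceed neuron spacing on a grid", {
  neurons <- expand.grid(x = seq(0, 100, 20), y = seq(0, 100, 20))
  cells <- data.frame(cell_id = seq_len(nrow(neurons)), neurons,
                      cell_type = "excitatory")
  plq <- data.frame(x = c(10, 30), y = c(10, 30))   # grid cell centers
  res <- plaque_neuron_distance_contrast(plq, cells)
  expect_equal(res$plaque_to_neuron, rep(sqrt(200), 2), tolerance = 1e-9)
  expect_true(all(res$neuron_to_neuron == 20))
  # grid spacing is constant, so the t-test degenerates to NA here
  co <- plaque_neuron_distance_contrast(data.frame(x = 0, y = 0), cells)
  expect_equal(co$plaque_to_neuron, 0)
  expect_error(plaque_neuron_distance_contrast(plq, cells[1, ]), "2 neurons")
})

test_that("densities are invariant to rigid motions of the coordinates", {
  th <- analysis_thresholds()
  set.seed(12)
  cells <- data.frame(cell_id = paste0("c", 1:800),
                      x = runif(800, 0, 800), y = runif(800, 0, 800))
  plq <- data.frame(x = c(200, 600), y = c(200, 500))
  poly <- cbind(c(0, 800, 800, 0), c(0, 0, 800, 800))
  base <- proximal_distal_density(cells, plq, poly, th, n_points = 2e5, seed = 4)
  # rotate everything by 30 degrees about the origin and translate
  th30 <- pi / 6
  rot <- function(x, y) cbind(x * cos(th30) - y * sin(th30) + 250,
                              x * sin(th30) + y * cos(th30) - 40)
  rc <- rot(cells$x, cells$y); rp <- rot(plq$x, plq$y); rpoly <- rot(poly[, 1], poly[, 2])
  cells2 <- transform(cells, x = rc[, 1], y = rc[, 2])
  plq2 <- data.frame(x = rp[, 1], y = rp[, 2])
  moved <- proximal_distal_density(cells2, plq2, rpoly, th, n_points = 2e5, seed = 4)
  expect_equal(moved$n_proximal, base$n_proximal)
  expect_lt(abs(moved$proximal / base$proximal - 1), 0.05)
  expect_lt(abs(moved$distal / base$distal - 1), 0.05)
})
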