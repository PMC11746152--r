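#' Distance to nearest plaque and proximity zones
#'
#' Euclidean distance from each cell to the nearest plaque centroid, with a
#' zone label: proximal (`d < proximal_radius`), distal
#' (`proximal_radius <= d <= distal_radius`, closed at the outer boundary) or
#' beyond.
#'
#' @param cells Cell table of one sample.
#' @param plaques Plaque table of the same sample.
#' @param thresholds [analysis_thresholds()].
#' @return `cells` with added columns `distance_to_plaque` and `zone`.
#' @export
nearest_plaque_distance <- function(cells, plaques,
                                    thresholds = analysis_thresholds()) {
  if (nrow(plaques) == 0) stop("no plaques in sample; distances are undefined")
  d2 <- outer(cells$x, plaques$x, "-")^2 + outer(cells$y, plaques$y, "-")^2
  d <- sqrt(apply(d2, 1, min))
  zone <- ifelse(d < thresholds$proximal_radius, "proximal",
                 ifelse(d <= thresholds$distal_radius, "distal", "beyond"))
  cells$distance_to_plaque <- d
  cells$zone <- factor(zone, levels = c("proximal", "distal", "beyond"))
  cells
}

#' Cell-type composition of the plaque-closest cells
#'
#' For each plaque, the nearest cell by centroid distance is identified (ties
#' broken toward the lower `cell_id`), and the proportions of the resulting
#' cell types are returned.
#'
#' @param plaques Plaque table (>= 1 row).
#' @param cells Cell table with `cell_type` set.
#' @return Named numeric vector of proportions summing to 1.
#' @export
closest_cell_composition <- function(plaques, cells) {
  if (nrow(plaques) == 0) stop("no plaques")
  typed <- cells[!is.na(cells$cell_type), , drop = FALSE]
  if (nrow(typed) == 0) stop("no typed cells")
  typed <- typed[order(typed$cell_id), , drop = FALSE]
  d2 <- outer(plaques$x, typed$x, "-")^2 + outer(plaques$y, typed$y, "-")^2
  nearest <- apply(d2, 1, which.min)  # which.min takes the first = lowest id
  tab <- table(typed$cell_type[nearest])
  prop <- as.numeric(tab) / sum(tab)
  stats::setNames(prop, names(tab))
}

#' Cell-type composition in distance annuli around plaques
#'
#' Cells are binned by distance to the nearest plaque into annuli of width
#' `annulus_width` up to `distal_radius`. Raw proportions are per-annulus
#' cell-type fractions. The abundance-normalized version divides each type's
#' annulus count by that type's section-wide total and renormalizes within
#' the annulus, so types are compared against their overall abundance.
#'
#' @param plaques,cells Tables of one sample; `cells` needs `cell_type`.
#' @param thresholds [analysis_thresholds()].
#' @return Data frame with `annulus` (inner edge, um), `cell_type`, `n`,
#'   `proportion`, `proportion_normalized`.
#' @export
annulus_composition <- function(plaques, cells,
                                thresholds = analysis_thresholds()) {
  if (nrow(plaques) == 0) stop("no plaques")
  cells <- nearest_plaque_distance(cells, plaques, thresholds)
  cells <- cells[!is.na(cells$cell_type), , drop = FALSE]
  edges <- seq(0, thresholds$distal_radius, by = thresholds$annulus_width)
  cells <- cells[cells$distance_to_plaque < thresholds$distal_radius, , drop = FALSE]
  bin <- findInterval(cells$distance_to_plaque, edges, rightmost.closed = FALSE)
  totals <- table(cells$cell_type)
  out <- list()
  for (b in sort(unique(bin))) {
    sel <- bin == b
    tab <- table(cells$cell_type[sel])
    tab <- tab[tab > 0]
    raw <- as.numeric(tab) / sum(tab)
    norm_w <- as.numeric(tab) / as.numeric(totals[names(tab)])
    out[[length(out) + 1L]] <- data.frame(
      annulus = edges[b], cell_type = names(tab), n = as.integer(tab),
      proportion = raw, proportion_normalized = norm_w / sum(norm_w),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "normalization") <- "section-wide type totals"
  res
}

#' Area of a union of disks
#'
#' Seeded Monte Carlo estimate (relative error well under 1% at the default
#' sample size) of the area of the union of equal-radius disks, optionally
#' clipped to a polygon.
#'
#' @param centers Matrix or data frame of disk centers (x, y in um).
#' @param radius Disk radius (um).
#' @param clip Optional clipping polygon (n x 2 matrix, um).
#' @param n_points Monte Carlo sample size.
#' @param seed Seed for the Monte Carlo draw.
#' @return Area in um^2 (0 for no centers).
#' @export
union_disk_area <- function(centers, radius, clip = NULL,
                            n_points = 1e6, seed = 1L) {
  stopifnot(radius > 0)
  centers <- as.matrix(centers)
  if (nrow(centers) == 0) return(0)
  in_union <- function(x, y) {
    inside <- rep(FALSE, length(x))
    for (i in seq_len(nrow(centers))) {
      inside <- inside | ((x - centers[i, 1])^2 + (y - centers[i, 2])^2 <= radius^2)
    }
    inside
  }
  mc_region_area(in_union,
                 bbox = union_bbox(centers, radius, clip),
                 clip = clip, n_points = n_points, seed = seed)
}

union_bbox <- function(centers, radius, clip = NULL) {
  bb <- c(xmin = min(centers[, 1]) - radius, xmax = max(centers[, 1]) + radius,
          ymin = min(centers[, 2]) - radius, ymax = max(centers[, 2]) + radius)
  if (!is.null(clip)) {
    cb <- bbox_of(clip)
    bb <- c(xmin = max(bb["xmin"], cb["xmin"]), xmax = min(bb["xmax"], cb["xmax"]),
            ymin = max(bb["ymin"], cb["ymin"]), ymax = min(bb["ymax"], cb["ymax"]))
    names(bb) <- c("xmin", "xmax", "ymin", "ymax")
  }
  bb
}

mc_region_area <- function(predicate, bbox, clip = NULL, n_points = 1e6, seed = 1L) {
  if (bbox["xmax"] <= bbox["xmin"] || bbox["ymax"] <= bbox["ymin"]) return(0)
  with_seed(seed, {
    x <- stats::runif(n_points, bbox["xmin"], bbox["xmax"])
    y <- stats::runif(n_points, bbox["ymin"], bbox["ymax"])
    keep <- predicate(x, y)
    if (!is.null(clip)) keep <- keep & point_in_polygon(x, y, clip)
    mean(keep) * (bbox["xmax"] - bbox["xmin"]) * (bbox["ymax"] - bbox["ymin"])
  })
}

#' Cell density proximal and distal to plaques
#'
#' Counts the cells of interest in the proximal zone (within
#' `proximal_radius` of a plaque centroid) and the distal zone (between
#' `proximal_radius` and `distal_radius`) and divides by the respective
#' union areas (union of proximal disks; union of distal disks minus the
#' proximal union), optionally clipped to the section polygon.
#'
#' @param cells Cell table (already subset to the type of interest).
#' @param plaques Plaque table (>= 1 row).
#' @param section Optional section polygon for clipping.
#' @param thresholds [analysis_thresholds()].
#' @param n_points,seed Monte Carlo controls passed to the area estimate.
#' @return List with `proximal`, `distal` (cells/um^2), counts and areas.
#' @export
proximal_distal_density <- function(cells, plaques, section = NULL,
                                    thresholds = analysis_thresholds(),
                                    n_points = 1e6, seed = 1L) {
  if (nrow(plaques) == 0) stop("no plaques")
  cells <- nearest_plaque_distance(cells, plaques, thresholds)
  n_prox <- sum(cells$zone == "proximal")
  n_dist <- sum(cells$zone == "distal")
  centers <- as.matrix(plaques[, c("x", "y")])
  rp <- thresholds$proximal_radius; rd <- thresholds$distal_radius
  min_d2 <- function(x, y) {
    m <- rep(Inf, length(x))
    for (i in seq_len(nrow(centers))) {
      m <- pmin(m, (x - centers[i, 1])^2 + (y - centers[i, 2])^2)
    }
    m
  }
  bb <- union_bbox(centers, rd, section)
  area_prox <- mc_region_area(function(x, y) min_d2(x, y) < rp^2,
                              bb, section, n_points, seed = derive_seed(seed, 1L))
  area_dist <- mc_region_area(function(x, y) {
    d2 <- min_d2(x, y); d2 >= rp^2 & d2 <= rd^2
  }, bb, section, n_points, seed = derive_seed(seed, 2L))
  if (area_prox <= 0) stop("proximal zone has zero area")
  if (area_dist <= 0) stop("distal zone has zero area")
  list(proximal = n_prox / area_prox, distal = n_dist / area_dist,
       n_proximal = n_prox, n_distal = n_dist,
       area_proximal = area_prox, area_distal = area_dist)
}

#' k-nearest-neighbor spatial outlier removal
#'
#' Computes each point's distance to its k-th nearest neighbor and removes
#' points whose value falls outside
#' `(median - 1.5*IQR, median + 1.5*IQR)`, retaining only densely packed
#' regions.
#'
#' @param points Matrix or data frame of coordinates (x, y in um).
#' @param k Neighbor index (default: the 5th nearest neighbor).
#' @return The retained points, with attribute `"removed"` (row indices).
#' @export
knn_outlier_filter <- function(points, k = 5L) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (n <= k) stop("need more than k = ", k, " points (got ", n, ")")
  d <- as.matrix(stats::dist(points))
  diag(d) <- Inf
  kth <- apply(d, 1, function(r) sort.int(r, partial = k)[k])
  med <- stats::median(kth)
  iqr <- stats::IQR(kth)
  # points strictly outside the interval are removed; boundary values stay,
  # so a perfectly regular pattern (IQR = 0) is not wiped out
  keep <- kth >= med - 1.5 * iqr & kth <= med + 1.5 * iqr
  out <- points[keep, , drop = FALSE]
  attr(out, "removed") <- which(!keep)
  out
}

#' Alpha-shape area of a point set
#'
#' Area of the alpha complex: the union of Delaunay triangles whose
#' circumradius is below `1/alpha`. `alpha = 0` keeps every triangle and
#' degenerates to the convex hull.
#'
#' @param points Matrix or data frame of coordinates (x, y in um).
#' @param alpha Alpha parameter (1/um).
#' @return Area in um^2.
#' @export
alpha_shape_area <- function(points, alpha = 0.015) {
  points <- as.matrix(points)
  points <- unique(points)
  if (nrow(points) < 3) stop("need at least 3 distinct points")
  if (nrow(points) == 3) {
    tri <- matrix(1:3, 1, 3)
  } else {
    dd <- tryCatch(
      deldir::deldir(points[, 1], points[, 2], suppressMsge = TRUE),
      error = function(e) stop("triangulation failed (collinear points?): ",
                               conditionMessage(e)))
    tri <- tryCatch(deldir::triMat(dd), error = function(e) NULL)
  }
  if (is.null(tri) || !is.matrix(tri) || nrow(tri) == 0 || anyNA(tri)) {
    stop("points are collinear; area undefined")
  }
  p1 <- points[tri[, 1], , drop = FALSE]
  p2 <- points[tri[, 2], , drop = FALSE]
  p3 <- points[tri[, 3], , drop = FALSE]
  a <- sqrt(rowSums((p2 - p3)^2))
  b <- sqrt(rowSums((p1 - p3)^2))
  cc <- sqrt(rowSums((p1 - p2)^2))
  area2 <- abs((p2[, 1] - p1[, 1]) * (p3[, 2] - p1[, 2]) -
                 (p3[, 1] - p1[, 1]) * (p2[, 2] - p1[, 2])) / 2
  circum <- ifelse(area2 > 0, a * b * cc / (4 * area2), Inf)
  keep <- if (alpha <= 0) rep(TRUE, length(circum)) else circum < 1 / alpha
  out <- sum(area2[keep])
  if (nrow(points) == 3 && out == 0) stop("points are collinear; area undefined")
  out
}

#' Cell density per region
#'
#' For `by = "all"`: cells inside each region polygon divided by the polygon
#' area. For a single cell type: the occupied area is estimated from all
#' cells within `neighborhood_radius` of any cell of the type, after
#' [knn_outlier_filter()], via [alpha_shape_area()]; the density is the
#' type's cell count over that area.
#'
#' @param cells Cell table of one sample.
#' @param regions Named list of region polygons for the sample.
#' @param by `"all"` or a single cell type.
#' @param thresholds [analysis_thresholds()].
#' @return Data frame with `region`, `n`, `area`, `density`.
#' @export
regional_density <- function(cells, regions, by = "all",
                             thresholds = analysis_thresholds()) {
  out <- list()
  for (rg in names(regions)) {
    poly <- regions[[rg]]
    area_poly <- polygon_area(poly)
    if (area_poly <= 0) {
      warning("region ", rg, " has zero area; excluded")
      next
    }
    inside <- point_in_polygon(cells$x, cells$y, poly)
    sub <- cells[inside, , drop = FALSE]
    if (by == "all") {
      n <- nrow(sub); area <- area_poly
    } else {
      of_type <- sub[!is.na(sub$cell_type) & sub$cell_type == by, , drop = FALSE]
      n <- nrow(of_type)
      if (n == 0) {
        out[[rg]] <- data.frame(region = rg, n = 0L, area = NA_real_, density = 0)
        next
      }
      d2 <- outer(sub$x, of_type$x, "-")^2 + outer(sub$y, of_type$y, "-")^2
      near <- sqrt(apply(d2, 1, min)) <= thresholds$neighborhood_radius
      pts <- cbind(sub$x[near], sub$y[near])
      if (nrow(pts) > thresholds$knn_k) pts <- knn_outlier_filter(pts, thresholds$knn_k)
      if (nrow(pts) < 3) {
        out[[rg]] <- data.frame(region = rg, n = n, area = NA_real_, density = NA_real_)
        next
      }
      area <- alpha_shape_area(pts, thresholds$alpha_shape_alpha)
    }
    out[[rg]] <- data.frame(region = rg, n = as.integer(n), area = area,
                            density = n / area, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Plaque-to-neuron vs neuron-to-neuron distance contrast
#'
#' Per-plaque minimum distance to a neuron, per-neuron distance to its
#' nearest neuronal neighbor, and a two-sided t-test of the difference.
#'
#' @param plaques Plaque table (>= 1 row).
#' @param cells Cell table; neurons are rows whose `cell_type` is in
#'   `neuron_types`.
#' @param neuron_types Cell types counted as neurons.
#' @return List with `plaque_to_neuron`, `neuron_to_neuron` (um vectors) and
#'   `p`.
#' @export
plaque_neuron_distance_contrast <- function(plaques, cells,
                                            neuron_types = c("excitatory", "inhibitory")) {
  neurons <- cells[!is.na(cells$cell_type) & cells$cell_type %in% neuron_types, , drop = FALSE]
  if (nrow(neurons) < 2) stop("need at least 2 neurons")
  if (nrow(plaques) == 0) stop("no plaques")
  d2 <- outer(plaques$x, neurons$x, "-")^2 + outer(plaques$y, neurons$y, "-")^2
  p2n <- sqrt(apply(d2, 1, min))
  nd <- as.matrix(stats::dist(cbind(neurons$x, neurons$y)))
  diag(nd) <- Inf
  n2n <- apply(nd, 1, min)
  p <- tryCatch(two_sample_contrast(p2n, n2n, "t")$p,
                error = function(e) NA_real_)   # degenerate: constant samples
  list(plaque_to_neuron = p2n, neuron_to_neuron = n2n, p = p)
}
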