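#' Threshold-based plaque detection in DAPI-like images
#'
#' Transparent stand-in for a trained segmentation model: thresholds the image
#' (automatic Otsu threshold by default, or a fixed intensity quantile),
#' labels connected components (8-connectivity), and rejects components that
#' are too small (nuclei-sized) or too circular (round cell somata), keeping
#' large bright irregular objects.
#'
#' @param image Numeric matrix (x by y).
#' @param pixel_size um per pixel.
#' @param intensity_quantile Threshold quantile of the intensity distribution,
#'   or `NULL` (default) for an automatic Otsu threshold. A fixed quantile is
#'   content-dependent — the same value means different things in plaque-dense
#'   and plaque-free fields — so the automatic threshold, which separates the
#'   bright fibrillar plaque intensity mode from the background/nuclei mode,
#'   is the default.
#' @param min_diameter Minimum equivalent diameter retained (um).
#' @param max_circularity Maximum circularity `4*pi*area/perimeter^2`
#'   retained. Off (`Inf`) by default: the digital perimeter estimate runs
#'   above the ideal for compact objects, so a ceiling near 1 would discard
#'   genuine compact plaques. Set it (e.g. 0.8) to reject round somata when
#'   thresholding close to background.
#' @return A plaque mask: integer label matrix (0 background, 1..K plaques)
#'   with attribute `"pixel_size"`.
#' @export
detect_plaques_threshold <- function(image, pixel_size,
                                     intensity_quantile = NULL,
                                     min_diameter = 10,
                                     max_circularity = Inf) {
  stopifnot(is.matrix(image), all(is.finite(image)), pixel_size > 0)
  thr <- if (is.null(intensity_quantile)) {
    rng <- range(image)
    if (rng[2] <= rng[1]) {
      rng[2]
    } else {
      t0 <- EBImage::otsu(EBImage::Image((image - rng[1]) / (rng[2] - rng[1])),
                          range = c(0, 1), levels = 256) * (rng[2] - rng[1]) + rng[1]
      # bimodality guard: without a bright fibrillar mode well separated from
      # the background/nuclei band, there is nothing to segment
      if (t0 - stats::median(image) < 8 * stats::mad(image)) Inf else t0
    }
  } else {
    stats::quantile(image, intensity_quantile, names = FALSE)
  }
  bw <- image > thr
  if (!any(bw)) return(new_plaque_mask(matrix(0L, nrow(image), ncol(image)), pixel_size))
  lab <- label_components8(bw)
  if (max(lab) == 0) return(new_plaque_mask(lab, pixel_size))
  feats <- mask_shape_features(lab)
  eq_diam <- 2 * sqrt(feats$area * pixel_size^2 / pi)
  circ <- ifelse(feats$perimeter > 0, 4 * pi * feats$area / feats$perimeter^2, 1)
  keep <- which(eq_diam >= min_diameter & circ <= max_circularity)
  relabel <- integer(max(lab))
  relabel[keep] <- seq_along(keep)
  out <- matrix(0L, nrow(lab), ncol(lab))
  nz <- lab > 0
  out[nz] <- relabel[lab[nz]]
  new_plaque_mask(out, pixel_size)
}

new_plaque_mask <- function(lab, pixel_size) {
  storage.mode(lab) <- "integer"
  attr(lab, "pixel_size") <- pixel_size
  lab
}

# 8-connected labeling: EBImage::bwlabel is 4-connected, so labels touching
# diagonally are merged through a label graph.
label_components8 <- function(bw) {
  lab <- EBImage::bwlabel(bw)
  lab <- matrix(as.integer(EBImage::imageData(lab)), nrow(bw), ncol(bw))
  K <- max(lab)
  if (K < 2) return(lab)
  nr <- nrow(lab); nc <- ncol(lab)
  a <- lab[-nr, -nc]; b <- lab[-1, -1]   # down-right diagonals
  c2 <- lab[-nr, -1]; d <- lab[-1, -nc]  # down-left diagonals
  pairs <- rbind(cbind(a[a > 0 & b > 0 & a != b], b[a > 0 & b > 0 & a != b]),
                 cbind(c2[c2 > 0 & d > 0 & c2 != d], d[c2 > 0 & d > 0 & c2 != d]))
  if (nrow(pairs) == 0) return(lab)
  g <- igraph::graph_from_edgelist(pairs, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, K - igraph::vcount(g)))
  comp <- igraph::components(g)$membership[seq_len(K)]
  # contiguous labels in first-appearance order
  relabel <- match(comp, unique(comp))
  out <- lab
  nz <- lab > 0
  out[nz] <- relabel[lab[nz]]
  out
}

mask_shape_features <- function(lab) {
  K <- max(lab)
  area <- tabulate(lab[lab > 0], nbins = K)
  f <- EBImage::computeFeatures.shape(EBImage::Image(lab))
  perim <- rep(0, K)
  if (!is.null(f)) perim[seq_len(nrow(f))] <- f[, "s.perimeter"]
  list(area = area, perimeter = perim)
}

#' Convert a plaque mask to a plaque table
#'
#' One row per label with centroid (mean pixel position times pixel size),
#' area (pixel count times pixel size squared), equivalent diameter
#' `2*sqrt(area/pi)` and volume `area * section_thickness`.
#'
#' @param mask Label matrix from [detect_plaques_threshold()] (or any integer
#'   label matrix with a `"pixel_size"` attribute, which `pixel_size` can
#'   override).
#' @param sample_id Sample label for the output rows.
#' @param thresholds [analysis_thresholds()] (supplies `section_thickness`).
#' @param pixel_size um per pixel; defaults to the mask attribute.
#' @param origin `c(x, y)` of the lower-left image corner in um.
#' @return A plaque table data frame (possibly empty).
#' @export
mask_to_table <- function(mask, sample_id = "S01",
                          thresholds = analysis_thresholds(),
                          pixel_size = attr(mask, "pixel_size"),
                          origin = c(0, 0)) {
  if (is.null(pixel_size)) stop("pixel_size missing")
  K <- max(mask)
  if (K == 0) return(empty_plaque_table())
  idx <- which(mask > 0, arr.ind = TRUE)
  labv <- mask[mask > 0]
  area_px <- tabulate(labv, nbins = K)
  cx <- tapply((idx[, 1] - 0.5) * pixel_size, labv, mean) + origin[1]
  cy <- tapply((idx[, 2] - 0.5) * pixel_size, labv, mean) + origin[2]
  area <- area_px * pixel_size^2
  data.frame(
    plaque_id = sprintf("%s_p%04d", sample_id, seq_len(K)),
    x = as.numeric(cx), y = as.numeric(cy), area = area,
    equivalent_diameter = 2 * sqrt(area / pi),
    volume = area * thresholds$section_thickness,
    sample_id = sample_id, stringsAsFactors = FALSE
  )
}

#' Confusion counts between predicted and annotated plaque masks
#'
#' An annotated object is a true positive when a predicted object covers at
#' least `min_overlap_fraction` of its area (each predicted object is matched
#' to at most one annotated object, greedily by overlap, ties broken toward
#' lower labels); unmatched annotated objects are false negatives; predicted
#' objects overlapping no annotated pixel at all are false positives.
#'
#' @param predicted,annotated Integer label matrices of identical shape.
#' @param min_overlap_fraction Fraction of the annotated object's area that
#'   must be covered.
#' @return List of class `confusion_counts` with `tp`, `fp`, `fn`.
#' @export
match_predictions <- function(predicted, annotated, min_overlap_fraction = 0.5) {
  if (!all(dim(predicted) == dim(annotated))) stop("masks must share shape")
  n_ann <- max(annotated)
  n_pred <- max(predicted)
  if (n_ann == 0 && n_pred == 0) {
    return(structure(list(tp = 0L, fp = 0L, fn = 0L), class = "confusion_counts"))
  }
  ann_area <- tabulate(annotated[annotated > 0], nbins = n_ann)
  both <- annotated > 0 & predicted > 0
  overlaps <- if (any(both)) {
    as.data.frame(table(ann = annotated[both], pred = predicted[both]),
                  stringsAsFactors = FALSE)
  } else data.frame(ann = character(), pred = character(), Freq = integer())
  overlaps$ann <- as.integer(overlaps$ann)
  overlaps$pred <- as.integer(overlaps$pred)
  pred_touching <- unique(overlaps$pred)
  fp <- n_pred - length(pred_touching)

  cand <- overlaps[overlaps$Freq >= min_overlap_fraction * ann_area[overlaps$ann], , drop = FALSE]
  cand <- cand[order(-cand$Freq, cand$ann, cand$pred), , drop = FALSE]
  used_ann <- logical(n_ann); used_pred <- logical(max(1L, n_pred))
  tp <- 0L
  for (i in seq_len(nrow(cand))) {
    a <- cand$ann[i]; p <- cand$pred[i]
    if (!used_ann[a] && !used_pred[p]) {
      used_ann[a] <- TRUE; used_pred[p] <- TRUE
      tp <- tp + 1L
    }
  }
  structure(list(tp = tp, fp = as.integer(fp), fn = as.integer(n_ann - tp)),
            class = "confusion_counts")
}

#' Detection metrics from confusion counts
#'
#' `f1 = 2*tp / (2*tp + fp + fn)`; `fnr = fn / (tp + fn)`. The false-positive
#' rate is reported under two conventions, since validation studies differ in
#' the denominator they use: `fpr_of_predictions = fp / (fp + tp)` and
#' `fpr_per_annotated = fp / (tp + fn)`.
#'
#' @param conf A `confusion_counts` object or list with `tp`, `fp`, `fn`.
#' @return List with `f1`, `fnr`, `fpr_of_predictions`, `fpr_per_annotated`.
#' @export
detection_metrics <- function(conf) {
  tp <- conf$tp; fp <- conf$fp; fn <- conf$fn
  if (any(c(tp, fp, fn) < 0)) stop("confusion counts must be nonnegative")
  if (tp + fp + fn == 0) stop("all confusion counts are zero")
  list(
    f1 = 2 * tp / (2 * tp + fp + fn),
    fnr = if (tp + fn > 0) fn / (tp + fn) else 0,
    fpr_of_predictions = if (fp + tp > 0) fp / (fp + tp) else 0,
    fpr_per_annotated = if (tp + fn > 0) fp / (tp + fn) else NA_real_
  )
}

#' Two-sample location contrast
#'
#' Two-sided test of a difference between two samples: Welch t-test or
#' Wilcoxon rank-sum. The rank-sum test is exact when both samples have at
#' most 20 observations and no ties cross the samples.
#'
#' @param values_a,values_b Numeric vectors.
#' @param test `"t"` or `"rank_sum"`.
#' @return List with `statistic` and `p`.
#' @export
two_sample_contrast <- function(values_a, values_b, test = c("t", "rank_sum")) {
  test <- match.arg(test)
  if (length(values_a) == 0 || length(values_b) == 0) stop("samples must be nonempty")
  if (test == "t") {
    ht <- stats::t.test(values_a, values_b)
  } else {
    exact <- length(values_a) <= 20 && length(values_b) <= 20
    ht <- suppressWarnings(stats::wilcox.test(values_a, values_b, exact = exact))
  }
  list(statistic = unname(ht$statistic), p = ht$p.value)
}

#' Per-object transcript density in a labeled image
#'
#' Sums the transcripts of cells whose centroid falls inside each labeled
#' object and divides by the object's area, supporting the contrast that
#' plaque objects carry far lower transcript density than cell objects.
#'
#' @param mask Integer label matrix with `"pixel_size"` attribute.
#' @param cells Cell table with `x`, `y`, `total_transcripts` (um).
#' @param window `c(xmin, xmax, ymin, ymax)` of the image in um.
#' @param pixel_size um per pixel; defaults to the mask attribute.
#' @return Data frame with `label`, `area` (um^2), `transcripts`,
#'   `density` (transcripts/um^2).
#' @export
object_transcript_density <- function(mask, cells, window,
                                      pixel_size = attr(mask, "pixel_size")) {
  K <- max(mask)
  if (K == 0) return(data.frame(label = integer(), area = numeric(),
                                transcripts = numeric(), density = numeric()))
  area <- tabulate(mask[mask > 0], nbins = K) * pixel_size^2
  ix <- floor((cells$x - window[1]) / pixel_size) + 1L
  iy <- floor((cells$y - window[3]) / pixel_size) + 1L
  ok <- ix >= 1 & ix <= nrow(mask) & iy >= 1 & iy <= ncol(mask)
  lab <- rep(0L, nrow(cells))
  lab[ok] <- mask[cbind(ix[ok], iy[ok])]
  tx <- vapply(seq_len(K), function(k) {
    sum(cells$total_transcripts[lab == k])
  }, numeric(1))
  data.frame(label = seq_len(K), area = area, transcripts = tx,
             density = tx / area)
}
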