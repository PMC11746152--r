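#' Build pseudobulk replicates
#'
#' Sums counts per (cell type, sample) stratum — optionally further split by
#' additional metadata columns such as `zone` or `region` — and applies the
#' replicate-level filters: strata with fewer than `min_cells_per_pseudobulk`
#' cells are dropped, and, per cell type, genes detected in fewer than
#' `min_gene_cell_fraction` of that type's analyzed cells are excluded from
#' differential expression.
#'
#' @param counts Count matrix (cells x genes) aligned with `cells`.
#' @param cells Cell table with `cell_type`, `sample_id`, `batch_id`,
#'   `genotype` set.
#' @param thresholds [analysis_thresholds()].
#' @param stratify_by Extra column names of `cells` to stratify by.
#' @return An object of class `pseudobulk`: list with `counts` (strata x
#'   genes), `meta` (per-stratum metadata incl. `n_cells`) and `genes_use`
#'   (per cell type, the genes passing the detection filter).
#' @export
build_pseudobulk <- function(counts, cells, thresholds = analysis_thresholds(),
                             stratify_by = NULL) {
  stopifnot(nrow(counts) == nrow(cells))
  keep_cells <- !is.na(cells$cell_type)
  if (!is.null(stratify_by)) {
    for (col in stratify_by) keep_cells <- keep_cells & !is.na(cells[[col]])
  }
  cells <- cells[keep_cells, , drop = FALSE]
  counts <- counts[keep_cells, , drop = FALSE]
  keys <- c("cell_type", "sample_id", stratify_by)
  key <- do.call(paste, c(lapply(keys, function(k) as.character(cells[[k]])), sep = "||"))
  groups <- unique(key)
  n_cells <- as.integer(table(key)[groups])
  ok <- n_cells >= thresholds$min_cells_per_pseudobulk
  if (!any(ok)) {
    stop("no stratum reaches ", thresholds$min_cells_per_pseudobulk,
         " cells; failed strata: ", paste(groups, collapse = ", "))
  }
  dropped <- groups[!ok]
  groups <- groups[ok]; n_cells <- n_cells[ok]

  gidx <- match(key, groups)
  in_kept <- !is.na(gidx)
  pbm <- rowsum(counts[in_kept, , drop = FALSE], gidx[in_kept])
  pbm <- as.matrix(pbm)
  rownames(pbm) <- groups

  parts <- do.call(rbind, strsplit(groups, "||", fixed = TRUE))
  meta <- data.frame(parts, stringsAsFactors = FALSE)
  names(meta) <- keys
  first <- match(meta$sample_id, cells$sample_id)
  meta$genotype <- as.character(cells$genotype[first])
  meta$batch_id <- as.character(cells$batch_id[first])
  meta$n_cells <- n_cells

  # per-type gene detection filter over all analyzed cells of the type
  genes_use <- list()
  for (ct in unique(meta$cell_type)) {
    of_type <- in_kept & cells$cell_type == ct
    frac <- colMeans(counts[of_type, , drop = FALSE] > 0)
    genes_use[[ct]] <- colnames(counts)[frac >= thresholds$min_gene_cell_fraction]
  }
  structure(list(counts = pbm, meta = meta, genes_use = genes_use,
                 dropped_strata = dropped),
            class = "pseudobulk")
}

#' @export
print.pseudobulk <- function(x, ...) {
  cat(sprintf("pseudobulk: %d strata x %d genes (%d strata dropped by cell filter)\n",
              nrow(x$counts), ncol(x$counts), length(x$dropped_strata)))
  invisible(x)
}

# log2 of median-of-ratios-normalized pseudobulk counts. A plain
# counts-per-million response is confounded by composition: a strongly
# induced program inflates the library of the affected group and shifts the
# apparent fold change of every other gene. Size factors computed against
# the per-gene geometric mean anchor on the unchanged majority.
log2_norm_counts <- function(m) {
  logm <- log(m)
  loggeo <- colMeans(logm)
  usable <- is.finite(loggeo)
  sf <- apply(m, 1, function(r) {
    v <- log(r[usable]) - loggeo[usable]
    v <- v[is.finite(v)]
    if (length(v) == 0) 1 else exp(stats::median(v))
  })
  sf[!is.finite(sf) | sf <= 0] <- 1
  log2(1 + m / sf)
}

#' Mixed-effects differential expression between two groups of pseudobulk
#' replicates
#'
#' For each gene, the response is the log2 of the pseudobulk count normalized
#' by a median-of-ratios size factor (composition-robust, so a strongly
#' induced program in one group does not masquerade as down-regulation of
#' everything else), modeled as `y ~ group + (1 | batch)` by REML; the group
#' coefficient (the log2 fold change of `group_a` over `group_b`) is tested
#' with a t-test on Satterthwaite degrees of freedom. When the
#' batch variance is inestimable — a single batch, a singular fit, or a
#' convergence failure — the gene falls back to ordinary least squares and
#' the row is flagged. P-values are BH-adjusted across the genes of the
#' comparison; a gene is significant when the adjusted (or, with
#' `nominal = TRUE`, unadjusted) p-value is below `alpha_fdr` and
#' `|log2fc| >= abs_log2fc`.
#'
#' @param pb A [build_pseudobulk()] object.
#' @param cell_type Cell type stratum to analyze.
#' @param group_col Metadata column defining the groups.
#' @param group_a,group_b Values of `group_col` forming the two groups
#'   (vectors pool several values).
#' @param thresholds [analysis_thresholds()].
#' @param label Comparison label written to the result.
#' @param nominal Use unadjusted p for the significance flag (the
#'   region-vs-rest convention); such rows carry `nominal = TRUE`.
#' @return A `DEResult` data frame: `cell_type`, `comparison`, `gene`,
#'   `log2fc`, `se`, `p`, `p_adj`, `significant`, `model_flag`, `nominal`.
#' @export
fit_group_de <- function(pb, cell_type, group_col, group_a, group_b,
                         thresholds = analysis_thresholds(),
                         label = NULL, nominal = FALSE) {
  stopifnot(inherits(pb, "pseudobulk"))
  if (length(intersect(group_a, group_b))) stop("groups must be disjoint")
  meta <- pb$meta
  sel <- meta$cell_type == cell_type & meta[[group_col]] %in% c(group_a, group_b)
  if (!any(sel)) stop("no pseudobulk replicates for cell type ", cell_type)
  meta <- meta[sel, , drop = FALSE]
  grp <- factor(ifelse(meta[[group_col]] %in% group_a, "a", "b"), levels = c("b", "a"))
  if (sum(grp == "a") < 2) stop("group_a (", paste(group_a, collapse = "+"), ") has <2 replicates")
  if (sum(grp == "b") < 2) stop("group_b (", paste(group_b, collapse = "+"), ") has <2 replicates")
  genes <- pb$genes_use[[cell_type]]
  if (is.null(genes) || length(genes) == 0) stop("no genes pass the detection filter")
  y <- log2_norm_counts(pb$counts[sel, , drop = FALSE])[, genes, drop = FALSE]
  batch <- factor(meta$batch_id)
  if (is.null(label)) {
    label <- paste0(paste(group_a, collapse = "+"), "_vs_", paste(group_b, collapse = "+"))
  }

  est <- se <- p <- rep(NA_real_, length(genes))
  flag <- rep("lmm", length(genes))
  single_batch <- nlevels(droplevels(batch)) < 2
  dat <- data.frame(grp = grp, batch = batch)
  X <- stats::model.matrix(~grp, dat)
  m0 <- NULL
  if (!single_batch) {
    Zmat <- stats::model.matrix(~ 0 + batch, dat)
    m0 <- tryCatch(
      suppressMessages(suppressWarnings(
        lme4::lmer(v ~ grp + (1 | batch), data = cbind(dat, v = y[, 1]),
                   control = lme4::lmerControl(check.conv.singular = "ignore",
                                               calc.derivs = FALSE)))),
      error = function(e) NULL)
  }
  ols <- function(v) {
    fit <- stats::lm(v ~ grp, data = dat)
    co <- stats::coef(summary(fit))["grpa", ]
    c(co[["Estimate"]], co[["Std. Error"]], co[["Pr(>|t|)"]])
  }
  for (j in seq_along(genes)) {
    v <- y[, j]
    done <- FALSE
    if (!is.null(m0)) {
      res <- tryCatch({
        m <- suppressMessages(suppressWarnings(lme4::refit(m0, v)))
        if (lme4::isSingular(m)) NULL else {
          b <- lme4::fixef(m)[["grpa"]]
          sdev <- sqrt(as.matrix(stats::vcov(m))["grpa", "grpa"])
          df <- satterthwaite_df(v, X, Zmat, theta = m@theta,
                                 s2 = stats::sigma(m)^2, coef_index = 2L)
          if (!is.finite(df) || df <= 0) NULL else {
            c(b, sdev, 2 * stats::pt(-abs(b / sdev), df))
          }
        }
      }, error = function(e) NULL)
      if (!is.null(res) && all(is.finite(res))) {
        est[j] <- res[1]; se[j] <- res[2]; p[j] <- res[3]
        done <- TRUE
      }
    }
    if (!done) {
      res <- ols(v)
      est[j] <- res[1]; se[j] <- res[2]; p[j] <- res[3]
      flag[j] <- if (single_batch) "ols_single_batch" else "ols_fallback"
    }
  }
  p_adj <- bh_adjust(p)
  crit_p <- if (nominal) p else p_adj
  data.frame(
    cell_type = cell_type, comparison = label, gene = genes,
    log2fc = est, se = se, p = p, p_adj = p_adj,
    significant = crit_p < thresholds$alpha_fdr & abs(est) >= thresholds$abs_log2fc,
    model_flag = flag, nominal = nominal, stringsAsFactors = FALSE
  )
}

# Satterthwaite degrees of freedom for one fixed-effect contrast of a
# random-intercept mixed model, from the 2x2 REML information in
# (theta, sigma^2) where theta is the lme4 variance ratio sd_batch/sd_resid.
# Numeric derivatives on the exact REML criterion; the design is tiny
# (pseudobulk replicates), so dense linear algebra is immediate.
satterthwaite_df <- function(y, X, Zmat, theta, s2, coef_index) {
  if (!is.finite(s2) || s2 <= 1e-10) return(NA_real_)
  n <- nrow(X); pX <- ncol(X)
  ZZt <- tcrossprod(Zmat)
  reml <- function(th, s2) {
    V <- diag(n) + th^2 * ZZt
    cV <- chol(V)
    Vi <- chol2inv(cV)
    XtViX <- crossprod(X, Vi %*% X)
    beta <- solve(XtViX, crossprod(X, Vi %*% y))
    r <- y - X %*% beta
    (n - pX) * log(s2) + 2 * sum(log(diag(cV))) +
      determinant(XtViX, logarithm = TRUE)$modulus[1] +
      drop(crossprod(r, Vi %*% r)) / s2
  }
  sevar <- function(th, s2) {
    V <- diag(n) + th^2 * ZZt
    Vi <- chol2inv(chol(V))
    s2 * solve(crossprod(X, Vi %*% X))[coef_index, coef_index]
  }
  h1 <- max(1e-4, 1e-3 * abs(theta))
  h2 <- max(1e-6, 1e-3 * s2)
  # Hessian of the -2*logLik REML criterion
  H <- matrix(NA_real_, 2, 2)
  f0 <- reml(theta, s2)
  H[1, 1] <- (reml(theta + h1, s2) - 2 * f0 + reml(theta - h1, s2)) / h1^2
  H[2, 2] <- (reml(theta, s2 + h2) - 2 * f0 + reml(theta, s2 - h2)) / h2^2
  H[1, 2] <- H[2, 1] <- (reml(theta + h1, s2 + h2) - reml(theta + h1, s2 - h2) -
                           reml(theta - h1, s2 + h2) + reml(theta - h1, s2 - h2)) /
    (4 * h1 * h2)
  A <- tryCatch(2 * solve(H), error = function(e) NULL)
  if (is.null(A)) return(NA_real_)
  g <- c((sevar(theta + h1, s2) - sevar(theta - h1, s2)) / (2 * h1),
         (sevar(theta, s2 + h2) - sevar(theta, s2 - h2)) / (2 * h2))
  f <- sevar(theta, s2)
  denom <- drop(t(g) %*% A %*% g)
  if (!is.finite(denom) || denom <= 0) return(NA_real_)
  2 * f^2 / denom
}

genotype_comparisons <- function() {
  list(c("FAD", "WT"), c("R47H_FAD", "R47H"), c("R47H", "WT"),
       c("R47H_FAD", "FAD"), c("R47H_FAD", "WT"))
}

#' Pairwise genotype differential expression
#'
#' Runs [fit_group_de()] for the five studied genotype contrasts (5xFAD vs
#' WT, double mutant vs R47H, R47H vs WT, double mutant vs 5xFAD, double
#' mutant vs WT), separately per cell type, restricting the replicates to the
#' two compared genotypes each time. Comparisons lacking two replicates per
#' group are skipped with a warning.
#'
#' @param pb A [build_pseudobulk()] object.
#' @param thresholds [analysis_thresholds()].
#' @param cell_types Cell types to analyze (default: all in `pb`).
#' @return Combined `DEResult` data frame.
#' @export
pairwise_genotype_de <- function(pb, thresholds = analysis_thresholds(),
                                 cell_types = NULL) {
  if (is.null(cell_types)) cell_types <- unique(pb$meta$cell_type)
  out <- list()
  for (ct in cell_types) {
    for (cmp in genotype_comparisons()) {
      res <- tryCatch(
        fit_group_de(pb, ct, "genotype", cmp[1], cmp[2], thresholds,
                     label = paste0(cmp[1], "_vs_", cmp[2])),
        error = function(e) {
          warning("skipping ", cmp[1], " vs ", cmp[2], " for ", ct, ": ",
                  conditionMessage(e), call. = FALSE)
          NULL
        })
      if (!is.null(res)) out[[length(out) + 1L]] <- res
    }
  }
  do.call(rbind, out)
}

#' Region-versus-rest differential expression
#'
#' Within each genotype and cell type, compares pseudobulk expression in each
#' region against the pooled remaining regions to identify spatially variable
#' genes. Following the region-analysis convention, significance uses the
#' unadjusted p-value (flagged `nominal` in the output) together with the
#' fold-change threshold.
#'
#' @param pb A [build_pseudobulk()] built with `stratify_by = "region"`.
#' @param thresholds [analysis_thresholds()].
#' @return Combined `DEResult` data frame with a `genotype` column.
#' @export
region_vs_rest_de <- function(pb, thresholds = analysis_thresholds()) {
  if (!"region" %in% names(pb$meta)) stop("pseudobulk lacks a region stratification")
  out <- list()
  for (gt in unique(pb$meta$genotype)) {
    sub <- subset_pseudobulk(pb, pb$meta$genotype == gt)
    for (ct in unique(sub$meta$cell_type)) {
      regions <- unique(sub$meta$region[sub$meta$cell_type == ct])
      if (length(regions) < 2) {
        # mirrors the replicate-count exclusions: a cell type confined to a
        # single surviving region cannot be contrasted
        warning("cell type ", ct, " in genotype ", gt,
                " has a single surviving region; skipped", call. = FALSE)
        next
      }
      for (rg in regions) {
        res <- tryCatch(
          fit_group_de(sub, ct, "region", rg, setdiff(regions, rg), thresholds,
                       label = paste0(rg, "_vs_rest"), nominal = TRUE),
          error = function(e) NULL)
        if (!is.null(res)) {
          res$genotype <- gt
          out[[length(out) + 1L]] <- res
        }
      }
    }
  }
  if (length(out) == 0) stop("no cell type has two or more surviving regions")
  do.call(rbind, out)
}

subset_pseudobulk <- function(pb, sel) {
  structure(list(counts = pb$counts[sel, , drop = FALSE],
                 meta = pb$meta[sel, , drop = FALSE],
                 genes_use = pb$genes_use,
                 dropped_strata = pb$dropped_strata),
            class = "pseudobulk")
}

#' Plaque-proximal versus plaque-distal differential expression
#'
#' Pseudobulk comparison of the plaque-proximal zone against the distal zone
#' within a cell type, pooling the amyloid-genotype samples; cells beyond the
#' distal radius take no part.
#'
#' @param pb A [build_pseudobulk()] built with `stratify_by = "zone"`.
#' @param thresholds [analysis_thresholds()].
#' @param cell_types Cell types to analyze (default: all with both zones).
#' @return Combined `DEResult` data frame.
#' @export
proximal_vs_distal_de <- function(pb, thresholds = analysis_thresholds(),
                                  cell_types = NULL) {
  if (!"zone" %in% names(pb$meta)) stop("pseudobulk lacks a zone stratification")
  sub <- subset_pseudobulk(pb, is_amyloid(pb$meta$genotype) &
                             pb$meta$zone %in% c("proximal", "distal"))
  if (is.null(cell_types)) {
    # analyze the cell types represented in both zones
    cell_types <- Filter(function(ct) {
      all(c("proximal", "distal") %in% sub$meta$zone[sub$meta$cell_type == ct])
    }, unique(sub$meta$cell_type))
    if (length(cell_types) == 0) stop("no cell type has both zones represented")
  }
  out <- list()
  for (ct in cell_types) {
    zones <- unique(sub$meta$zone[sub$meta$cell_type == ct])
    for (z in c("proximal", "distal")) {
      if (!z %in% zones) stop("zone '", z, "' absent for cell type ", ct)
    }
    out[[length(out) + 1L]] <-
      fit_group_de(sub, ct, "zone", "proximal", "distal", thresholds,
                   label = "proximal_vs_distal")
  }
  do.call(rbind, out)
}

#' Continuous plaque-distance differential expression
#'
#' Single-cell negative-binomial regression of each gene on distance to the
#' nearest plaque, restricted to amyloid-genotype samples:
#' `log mu = intercept + beta * distance + log(size factor)`, with the
#' per-cell size factor the library size over the median library size and
#' per-gene dispersion estimated by the method of moments (floored at 1e-8).
#' The Wald test on `beta` is BH-adjusted across genes; only the adjusted
#' p-value (no fold-change threshold) defines significance. The reported
#' effect is the expected log2 expression change per um of distance.
#'
#' @param counts Count matrix (cells x genes).
#' @param cells Cell table with `distance_to_plaque` set (see
#'   [nearest_plaque_distance()]).
#' @param cell_type Cell type to analyze.
#' @param thresholds [analysis_thresholds()].
#' @param max_distance Cells farther than this from a plaque are excluded
#'   (default: the distal radius).
#' @param two_pass Composition-robust normalization: after a first pass,
#'   genes called distance-associated are excluded from the library used for
#'   the size factors and every gene is refitted. Plaque-proximal activation
#'   programs can make up a visible share of a targeted panel's counts, and
#'   a raw library-size factor would then impose a spurious distance trend
#'   on every other gene.
#' @return `DEResult` data frame with `log2fc_per_um` as the effect column.
#' @export
continuous_distance_de <- function(counts, cells, cell_type,
                                   thresholds = analysis_thresholds(),
                                   max_distance = NULL, two_pass = TRUE) {
  if (is.null(max_distance)) max_distance <- thresholds$distal_radius
  if (is.null(cells$distance_to_plaque)) {
    stop("cells lack distance_to_plaque; run nearest_plaque_distance() first")
  }
  sel <- !is.na(cells$cell_type) & cells$cell_type == cell_type &
    is_amyloid(cells$genotype) & is.finite(cells$distance_to_plaque) &
    cells$distance_to_plaque <= max_distance
  n_prox <- sum(sel & cells$distance_to_plaque < thresholds$proximal_radius)
  if (n_prox < 30) {
    stop("only ", n_prox, " cells of type ", cell_type,
         " within the proximal radius; need at least 30")
  }
  cnt <- counts[sel, , drop = FALSE]
  d <- cells$distance_to_plaque[sel]
  genes <- colnames(cnt)

  fit_all <- function(exclude_genes) {
    lib <- rowSums(cnt[, setdiff(genes, exclude_genes), drop = FALSE])
    sf <- lib / stats::median(lib)
    sf[sf <= 0] <- min(sf[sf > 0])
    off <- log(sf)
    est <- se <- p <- rep(NA_real_, length(genes))
    for (j in seq_along(genes)) {
      v <- cnt[, j]
      z <- v / sf
      m <- mean(z)
      if (m == 0) next
      disp <- max((stats::var(z) - m) / m^2, 1e-8)
      fit <- tryCatch(
        suppressWarnings(stats::glm(v ~ d + offset(off),
                                    family = MASS::negative.binomial(theta = 1 / disp))),
        error = function(e) NULL)
      if (is.null(fit) || !fit$converged) next
      co <- stats::coef(summary(fit, dispersion = 1))
      if (!"d" %in% rownames(co)) next
      est[j] <- co["d", "Estimate"] / log(2)
      se[j] <- co["d", "Std. Error"] / log(2)
      p[j] <- co["d", "Pr(>|z|)"]
    }
    ok <- !is.na(p)
    p_adj <- rep(NA_real_, length(genes))
    p_adj[ok] <- bh_adjust(p[ok])
    list(est = est, se = se, p = p, p_adj = p_adj)
  }
  res <- fit_all(character())
  if (two_pass) {
    assoc <- genes[!is.na(res$p_adj) & res$p_adj < thresholds$alpha_fdr]
    if (length(assoc) && length(assoc) < length(genes)) {
      res <- fit_all(assoc)
    }
  }
  est <- res$est; se <- res$se; p <- res$p; p_adj <- res$p_adj
  data.frame(
    cell_type = cell_type, comparison = "distance_to_plaque", gene = genes,
    log2fc_per_um = est, se = se, p = p, p_adj = p_adj,
    significant = !is.na(p_adj) & p_adj < thresholds$alpha_fdr,
    n_cells = sum(sel), stringsAsFactors = FALSE
  )
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment of a p-value vector, returned in
#' the original order.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values.
#' @export
bh_adjust <- function(p) {
  if (any(!is.na(p) & (p < 0 | p > 1))) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Post-hoc filtering of differential-expression results
#'
#' Glial mode keeps only genes the atlas annotates as expressed in the
#' result's cell type; neuronal mode removes genes exclusive to glial types
#' and known disease-associated glial program markers, which spill into
#' neuronal segmentations. Genes on `exclusion_genes` (e.g. anterior-
#' posterior gradient genes or spatial-subcluster markers) are removed in
#' both modes. The unfiltered input is preserved in attribute `"raw"`.
#'
#' @param results `DEResult` data frame.
#' @param atlas Atlas annotation (`gene`, `expressed_in`, `exclusive_to`).
#' @param mode `"glial"` or `"neuronal"`.
#' @param exclusion_genes Genes removed regardless of significance.
#' @param disease_markers Extra marker genes removed in neuronal mode (e.g.
#'   DAM/DAA program genes).
#' @return Filtered `DEResult` with a `filtered_reason` column on removed
#'   rows available via `attr(, "removed")`.
#' @export
filter_de_results <- function(results, atlas = NULL,
                              mode = c("glial", "neuronal"),
                              exclusion_genes = character(),
                              disease_markers = character()) {
  mode <- match.arg(mode)
  reason <- rep(NA_character_, nrow(results))
  if (mode == "glial") {
    if (is.null(atlas)) stop("glial mode requires an atlas annotation")
    expressed <- strsplit(atlas$expressed_in, ";")
    names(expressed) <- atlas$gene
    ok <- mapply(function(g, ct) {
      !is.null(expressed[[g]]) && ct %in% expressed[[g]]
    }, results$gene, results$cell_type)
    reason[!ok] <- "not_expressed_in_cell_type"
  } else {
    glial_exclusive <- character()
    if (!is.null(atlas)) {
      excl <- atlas$exclusive_to
      excl[is.na(excl)] <- ""
      glial_exclusive <- atlas$gene[nzchar(excl)]
    }
    bad <- results$gene %in% c(glial_exclusive, disease_markers)
    reason[bad] <- "glial_or_disease_marker"
  }
  reason[results$gene %in% exclusion_genes] <- "exclusion_list"
  keep <- is.na(reason)
  removed <- results[!keep, , drop = FALSE]
  removed$filtered_reason <- reason[!keep]
  out <- results[keep, , drop = FALSE]
  attr(out, "raw") <- results
  attr(out, "removed") <- removed
  out
}
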