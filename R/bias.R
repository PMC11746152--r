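#' Subcluster one cell type
#'
#' Subsets to the cell type and reruns the typing pipeline (normalize, embed,
#' cluster) on the subset. Subclusters holding less than
#' `min_subcluster_fraction` of the type's cells are marked excluded.
#'
#' @param counts Count matrix aligned with `cells`.
#' @param cells Cell table with `cell_type` set.
#' @param cell_type Type to subcluster.
#' @param seed Clustering seed.
#' @param thresholds [analysis_thresholds()].
#' @param n_pcs,resolution,k Embedding/clustering controls.
#' @return List with `cells` (the subset), `labels` (subcluster factor),
#'   `excluded` (labels failing the size rule).
#' @export
subcluster_cell_type <- function(counts, cells, cell_type, seed = 1L,
                                 thresholds = analysis_thresholds(),
                                 n_pcs = 10, resolution = 0.1, k = 15L) {
  sel <- !is.na(cells$cell_type) & cells$cell_type == cell_type
  n_min <- 2 * thresholds$min_cells_per_pseudobulk
  if (sum(sel) < n_min) {
    stop("only ", sum(sel), " cells of type ", cell_type,
         "; need at least ", n_min)
  }
  sub_cells <- cells[sel, , drop = FALSE]
  sub_counts <- counts[sel, , drop = FALSE]
  if (is.null(sub_cells$total_transcripts)) {
    sub_cells$total_transcripts <- as.integer(rowSums(sub_counts))
  }
  norm <- normalize_log(sub_counts)
  emb <- embed_cells(norm, sub_cells, n_pcs = n_pcs)
  labels <- cluster_cells(emb, seed = seed, resolution = resolution, k = k)
  frac <- table(labels) / length(labels)
  excluded <- names(frac)[frac < thresholds$min_subcluster_fraction]
  list(cells = sub_cells, labels = labels, excluded = excluded)
}

#' Genotype proportion matrix of subclusters
#'
#' Two-step normalization that corrects for unequal genotype representation:
#' per subcluster s and genotype g, `r(g,s) = n(g,s) / N(g)` with `N(g)` the
#' type's total cell count from genotype g, then each subcluster row is
#' normalized to sum to one. Under genotype exchangeability every entry is
#' 0.25.
#'
#' @param labels Subcluster labels aligned with `cells`.
#' @param cells Cell table (rows = the subclustered cells) with `genotype`.
#' @return Matrix (subclusters x genotypes) of normalized proportions; rows
#'   sum to 1.
#' @export
genotype_proportion_matrix <- function(labels, cells) {
  g <- factor(as.character(cells$genotype), levels = genotype_levels())
  if (anyNA(g)) stop("every cell needs a genotype")
  N <- table(g)
  present <- N > 0
  if (!all(present)) {
    warning("genotype(s) with no cells dropped: ",
            paste(names(N)[!present], collapse = ", "))
  }
  tab <- table(labels, g)[, present, drop = FALSE]
  r <- sweep(unclass(tab), 2, as.numeric(N[present]), "/")
  p <- r / rowSums(r)
  p[is.nan(p)] <- 0
  p
}

default_allowed_pairs <- function() {
  list(c("WT", "R47H"), c("FAD", "R47H_FAD"),
       c("R47H", "R47H_FAD"), c("WT", "FAD"))
}

#' Classify genotype bias of subclusters
#'
#' A subcluster is called biased toward a single genotype when that
#' genotype's normalized proportion exceeds `single_genotype_bias` (uniform
#' would be 0.25; single calls take precedence, ties broken by the canonical
#' genotype order). Otherwise it is called biased toward a genotype pair when
#' an allowed pair's combined proportion exceeds `pair_bias` (uniform 0.5);
#' the two diagonal pairs (WT with the double mutant, and R47H with 5xFAD)
#' are never called, restricting pair calls to interpretable mutation axes.
#'
#' @param props Proportion matrix from [genotype_proportion_matrix()]; rows
#'   must sum to 1.
#' @param thresholds [analysis_thresholds()].
#' @param allowed_pairs List of genotype pairs eligible for pair calls.
#' @return Data frame with `subcluster`, `call` (`none`/`single`/`pair`),
#'   `genotypes` (`;`-separated) and `proportion` (the triggering value).
#' @export
classify_bias <- function(props, thresholds = analysis_thresholds(),
                          allowed_pairs = default_allowed_pairs()) {
  props <- as.matrix(props)
  if (any(abs(rowSums(props) - 1) > 1e-6)) stop("proportion rows must sum to 1")
  glev <- colnames(props)
  n <- nrow(props)
  call <- rep("none", n)
  genos <- rep("", n)
  trig <- rep(NA_real_, n)

  best <- max.col(props, ties.method = "first")
  single <- props[cbind(seq_len(n), best)] > thresholds$single_genotype_bias
  call[single] <- "single"
  genos[single] <- glev[best[single]]
  trig[single] <- props[cbind(seq_len(n), best)][single]

  rest <- which(!single)
  if (length(rest)) {
    pair_ok <- vapply(allowed_pairs, function(pr) all(pr %in% glev), logical(1))
    pairs <- allowed_pairs[pair_ok]
    if (length(pairs)) {
      sums <- vapply(pairs, function(pr) {
        rowSums(props[rest, pr, drop = FALSE])
      }, numeric(length(rest)))
      sums <- matrix(sums, nrow = length(rest))
      bestp <- max.col(sums, ties.method = "first")
      hit <- sums[cbind(seq_along(rest), bestp)] > thresholds$pair_bias
      idx <- rest[hit]
      call[idx] <- "pair"
      genos[idx] <- vapply(pairs[bestp[hit]], paste, character(1), collapse = ";")
      trig[idx] <- sums[cbind(seq_along(rest), bestp)][hit]
    }
  }
  data.frame(subcluster = rownames(props) %||% as.character(seq_len(n)),
             call = call, genotypes = genos, proportion = trig,
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Regional composition of subtype classes
#'
#' Maps subclusters to classes (e.g. disease-associated vs homeostatic
#' microglia), computes per-region class proportions, and attaches a
#' permutation p-value per region for a difference between two genotype
#' groups: the test statistic is the largest absolute difference in
#' per-sample mean class proportion between the groups, and sample-to-group
#' assignments are permuted.
#'
#' @param labels Subcluster labels aligned with `cells`.
#' @param cells Cell table (the subclustered cells) with `region`,
#'   `sample_id`, `genotype`.
#' @param grouping Named character vector mapping subcluster -> class; must
#'   cover every non-`NA` label.
#' @param group_a,group_b Genotype codes forming the contrasted groups
#'   (default: amyloid vs non-amyloid).
#' @param n_perm Number of permutations.
#' @param seed Permutation seed.
#' @return Data frame with `region`, `class`, `n`, `proportion`, `p_perm`.
#' @export
regional_subtype_composition <- function(labels, cells, grouping,
                                         group_a = c("FAD", "R47H_FAD"),
                                         group_b = c("WT", "R47H"),
                                         n_perm = 10000, seed = 1L) {
  lab <- as.character(labels)
  keep <- !is.na(lab)
  miss <- setdiff(unique(lab[keep]), names(grouping))
  if (length(miss)) stop("grouping lacks subcluster(s): ", paste(miss, collapse = ", "))
  cls <- grouping[lab[keep]]
  sub <- cells[keep, , drop = FALSE]
  classes <- sort(unique(grouping))
  regions <- unique(sub$region[!is.na(sub$region)])
  samples <- unique(sub$sample_id)
  sample_group <- ifelse(sub$genotype[match(samples, sub$sample_id)] %in% group_a,
                         "a", ifelse(sub$genotype[match(samples, sub$sample_id)] %in% group_b,
                                     "b", NA))
  out <- list()
  for (rg in regions) {
    in_rg <- sub$region == rg
    if (!any(in_rg)) {
      warning("region ", rg, " has no cells of the type; omitted")
      next
    }
    tab <- table(factor(cls[in_rg], levels = classes))
    prop <- as.numeric(tab) / sum(tab)
    # per-sample class-proportion matrix for the permutation test
    pm <- prop.table(table(sub$sample_id[in_rg],
                           factor(cls[in_rg], levels = classes)), 1)
    pm <- pm[rowSums(is.na(pm)) == 0, , drop = FALSE]
    grp <- sample_group[match(rownames(pm), samples)]
    p_perm <- NA_real_
    ok <- !is.na(grp)
    if (sum(grp[ok] == "a") >= 2 && sum(grp[ok] == "b") >= 2) {
      pm2 <- pm[ok, , drop = FALSE]; g2 <- grp[ok]
      stat <- function(gv) max(abs(colMeans(pm2[gv == "a", , drop = FALSE]) -
                                     colMeans(pm2[gv == "b", , drop = FALSE])))
      obs <- stat(g2)
      p_perm <- with_seed(derive_seed(seed, match(rg, regions)), {
        null <- replicate(n_perm, stat(sample(g2)))
        (1 + sum(null >= obs - 1e-12)) / (n_perm + 1)
      })
    }
    out[[length(out) + 1L]] <- data.frame(
      region = rg, class = classes, n = as.integer(tab),
      proportion = prop, p_perm = p_perm, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
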