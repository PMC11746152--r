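#' Cell-level quality control
#'
#' Removes cells with volume strictly greater than `max_cell_volume` or with
#' strictly fewer than `min_transcripts_per_cell` transcripts; boundary values
#' are retained. Idempotent.
#'
#' @param cells Cell table.
#' @param counts Count matrix aligned with `cells` (rows = cells).
#' @param thresholds [analysis_thresholds()].
#' @return List with filtered `cells` and `counts`.
#' @export
qc_filter_cells <- function(cells, counts, thresholds = analysis_thresholds()) {
  stopifnot(nrow(cells) == nrow(counts))
  total <- rowSums(counts)
  keep <- cells$volume <= thresholds$max_cell_volume &
    total >= thresholds$min_transcripts_per_cell
  cells <- cells[keep, , drop = FALSE]
  rownames(cells) <- NULL
  cells$total_transcripts <- as.integer(total[keep])
  list(cells = cells, counts = counts[keep, , drop = FALSE])
}

#' Library-size normalization and log transform
#'
#' Scales each cell to the median library size of the dataset, then applies
#' `log2(1 + x)`. All-zero cells map to all-zero rows.
#'
#' @param counts Count matrix (cells x genes).
#' @return Normalized matrix of the same shape.
#' @export
normalize_log <- function(counts) {
  lib <- rowSums(counts)
  if (all(lib == 0)) stop("all counts are zero; nothing to normalize")
  med <- stats::median(lib[lib > 0])
  scale <- ifelse(lib > 0, med / lib, 0)
  log2(1 + counts * scale)
}

#' Depth-regressed, scaled PCA embedding
#'
#' Regresses each gene on per-cell sequencing depth (total transcripts),
#' standard-scales the residuals per gene, and projects onto the top principal
#' components. An optional `integrate` hook (default identity) may adjust the
#' embedding using cell metadata, e.g. per batch.
#'
#' @param norm Normalized matrix from [normalize_log()].
#' @param cells Cell table aligned with `norm` (supplies `total_transcripts`).
#' @param n_pcs Number of principal components.
#' @param integrate Function `(embedding, cells) -> embedding` applied last.
#' @return Embedding matrix (cells x `n_pcs`) with attribute `"sdev"` (the
#'   component standard deviations).
#' @export
embed_cells <- function(norm, cells, n_pcs = 20, integrate = NULL) {
  if (n_pcs < 1) stop("n_pcs must be at least 1")
  n_pcs <- min(n_pcs, ncol(norm), nrow(norm) - 1L)
  depth <- cells$total_transcripts
  if (is.null(depth)) stop("cells must carry total_transcripts")
  X <- qr.resid(qr(cbind(1, depth)), as.matrix(norm))
  sds <- apply(X, 2, stats::sd)
  sds[sds == 0] <- 1
  X <- sweep(X, 2, sds, "/")
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE, rank. = n_pcs)
  emb <- pc$x[, seq_len(n_pcs), drop = FALSE]
  rownames(emb) <- cells$cell_id
  attr(emb, "sdev") <- pc$sdev[seq_len(n_pcs)]
  if (!is.null(integrate)) emb <- integrate(emb, cells)
  emb
}

# chunked exact k-nearest neighbours (indices), memory-bounded
knn_index <- function(X, k, chunk = 1024L) {
  n <- nrow(X)
  k <- min(k, n - 1L)
  idx <- matrix(0L, n, k)
  sq <- rowSums(X^2)
  for (start in seq(1L, n, by = chunk)) {
    rows <- start:min(start + chunk - 1L, n)
    d2 <- outer(sq[rows], sq, "+") - 2 * X[rows, , drop = FALSE] %*% t(X)
    for (j in seq_along(rows)) {
      d2[j, rows[j]] <- Inf
      idx[rows[j], ] <- order(d2[j, ])[seq_len(k)]
    }
  }
  idx
}

#' Graph-based clustering of an embedding
#'
#' Builds a k-nearest-neighbor graph on the embedding and partitions it with
#' seeded Louvain modularity optimization.
#'
#' @param embedding Numeric matrix (cells x dims).
#' @param seed Integer seed (the partition is deterministic given it).
#' @param resolution Louvain resolution; higher gives more clusters. The
#'   default is deliberately coarse: it keeps disconnected populations apart
#'   while not shattering homogeneous ones.
#' @param k Number of nearest neighbors for the graph.
#' @return Integer factor of cluster labels (length = cells).
#' @export
cluster_cells <- function(embedding, seed = 1L, resolution = 0.1, k = 15L) {
  if (nrow(embedding) < 2) stop("need at least 2 cells to cluster")
  if (!all(is.finite(embedding))) stop("embedding must be finite")
  k <- min(k, nrow(embedding) - 1L)
  nn <- knn_index(embedding, k)
  n <- nrow(embedding)
  # shared-nearest-neighbor graph: edges weighted by the Jaccard overlap of
  # neighborhoods, weak links pruned, then seeded Louvain
  nb <- lapply(seq_len(n), function(i) c(i, nn[i, ]))
  edges <- cbind(rep(seq_len(n), k), as.vector(nn))
  edges <- edges[edges[, 1] < edges[, 2], , drop = FALSE]
  edges <- unique(edges)
  w <- vapply(seq_len(nrow(edges)), function(e) {
    a <- nb[[edges[e, 1]]]; b <- nb[[edges[e, 2]]]
    ov <- length(intersect(a, b))
    ov / (2 * (k + 1) - ov)
  }, numeric(1))
  keep <- w >= 1 / 15
  g <- igraph::graph_from_edgelist(edges[keep, , drop = FALSE], directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, n - igraph::vcount(g)))
  part <- with_seed(seed, igraph::cluster_louvain(g, weights = w[keep],
                                                  resolution = resolution))
  factor(igraph::membership(part))
}

#' Rank cluster markers by Wilcoxon rank-sum test
#'
#' For each cluster and gene, a two-sided rank-sum test of the cluster versus
#' all other cells on normalized expression (normal approximation with tie
#' correction), BH adjustment within cluster, genes ranked by the signed
#' z statistic (rank 1 = strongest upregulated marker).
#'
#' @param norm Normalized matrix (cells x genes).
#' @param labels Cluster labels (length = cells).
#' @return Data frame with columns `cluster`, `gene`, `statistic`, `p`,
#'   `p_adj`, `direction`, `rank`.
#' @export
rank_markers <- function(norm, labels) {
  labels <- as.factor(labels)
  if (nlevels(labels) < 2) stop("need at least 2 clusters to rank markers")
  n <- nrow(norm)
  ranks <- apply(norm, 2, rank)
  # tie correction per gene for the rank-sum variance
  tie_term <- apply(norm, 2, function(v) {
    t <- table(v); sum(t^3 - t)
  })
  out <- vector("list", nlevels(labels))
  for (li in seq_len(nlevels(labels))) {
    in_cl <- labels == levels(labels)[li]
    n1 <- sum(in_cl); n2 <- n - n1
    W <- colSums(ranks[in_cl, , drop = FALSE])
    mu <- n1 * (n + 1) / 2
    sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term / (n * (n - 1)))
    z <- ifelse(sigma2 > 0, (W - mu) / sqrt(sigma2), 0)
    p <- 2 * stats::pnorm(-abs(z))
    df <- data.frame(cluster = levels(labels)[li], gene = colnames(norm),
                     statistic = z, p = p,
                     p_adj = stats::p.adjust(p, method = "BH"),
                     direction = ifelse(z >= 0, "up", "down"),
                     stringsAsFactors = FALSE)
    df$rank <- rank(-df$statistic, ties.method = "first")
    out[[li]] <- df
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Exclude contaminated subclusters
#'
#' A subcluster is excluded when at least `min_hits` of its top-`top_n`
#' upregulated markers are atlas-annotated as exclusive to a major cell type
#' other than the host type, indicating contamination by spillover from
#' neighboring cells of that type.
#'
#' @param labels Subcluster labels.
#' @param markers Marker table from [rank_markers()].
#' @param atlas Atlas annotation data frame with columns `gene`,
#'   `expressed_in` (`;`-separated types), `exclusive_to` (type or empty).
#' @param host_type The cell type whose subclusters are being screened.
#' @param top_n,min_hits The rule's window and trigger count.
#' @return List with `labels` (excluded subclusters set to `NA`) and `report`
#'   (excluded subclusters and their triggering genes).
#' @export
drop_contaminated_subclusters <- function(labels, markers, atlas, host_type,
                                          top_n = 10L, min_hits = 2L) {
  known_types <- unique(unlist(strsplit(atlas$expressed_in, ";")))
  if (!host_type %in% known_types) {
    stop("host type '", host_type, "' is absent from the atlas annotation")
  }
  excl <- atlas$exclusive_to
  excl[is.na(excl)] <- ""
  foreign <- atlas$gene[nzchar(excl) & excl != host_type]
  labels <- as.factor(labels)
  report <- list()
  dropped <- character()
  for (cl in levels(labels)) {
    top <- markers[markers$cluster == cl & markers$rank <= top_n &
                     markers$direction == "up", "gene"]
    hits <- intersect(top, foreign)
    if (length(hits) >= min_hits) {
      dropped <- c(dropped, cl)
      report[[cl]] <- hits
    }
  }
  out <- as.character(labels)
  out[out %in% dropped] <- NA_character_
  list(labels = factor(out), report = report)
}
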