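#' Load a dataset from disk
#'
#' Reads the cell metadata table, count matrix, and optional plaque table,
#' region map and atlas annotation, validates their mutual consistency, and
#' returns them as a single `dataset` list. Rows of the count matrix are
#' reordered to match the cell table after canonical sorting by `cell_id`, so
#' loading is invariant to the on-disk row order.
#'
#' @param paths Named list of file paths. Required: `cells` (CSV) and `counts`
#'   (dense CSV whose first column is `cell_id`, or a Matrix Market `.mtx`
#'   file with `counts_cells` and `counts_genes` plain-text sidecars, one name
#'   per line). Optional: `plaques` (CSV), `regions` (JSON region map),
#'   `atlas` (CSV).
#' @param thresholds An [analysis_thresholds()] object stored with the dataset.
#'
#' @return A list of class `dataset` with elements `cells`, `counts`,
#'   `plaques`, `regions`, `atlas`, `thresholds`.
#' @seealso [save_results()], [simulate_cohort()]
#' @export
load_dataset <- function(paths, thresholds = analysis_thresholds()) {
  stopifnot(is.list(paths))
  if (is.null(paths$cells) || is.null(paths$counts)) {
    stop("paths must name at least 'cells' and 'counts' files")
  }
  cells <- utils::read.csv(paths$cells, stringsAsFactors = FALSE)
  required <- c("cell_id", "x", "y", "volume", "sample_id", "batch_id", "genotype")
  missing <- setdiff(required, names(cells))
  if (length(missing)) {
    stop("cell table is missing required column(s): ", paste(missing, collapse = ", "))
  }
  cells$cell_id <- as.character(cells$cell_id)
  if (anyDuplicated(cells$cell_id)) stop("cell_id values must be unique")
  cells$genotype <- as_genotype(cells$genotype)

  counts <- read_counts(paths)
  if (!setequal(rownames(counts), cells$cell_id) ||
      nrow(counts) != nrow(cells)) {
    stop("cell ids in counts and cell table do not match 1:1 (",
         nrow(counts), " count rows vs ", nrow(cells), " metadata rows)")
  }
  cells <- cells[order(cells$cell_id), , drop = FALSE]
  rownames(cells) <- NULL
  counts <- counts[cells$cell_id, , drop = FALSE]
  cells$total_transcripts <- as.integer(rowSums(counts))

  plaques <- empty_plaque_table()
  if (!is.null(paths$plaques) && file.exists(paths$plaques)) {
    plaques <- utils::read.csv(paths$plaques, stringsAsFactors = FALSE)
    need <- c("plaque_id", "x", "y", "area", "sample_id")
    miss <- setdiff(need, names(plaques))
    if (length(miss)) stop("plaque table missing column(s): ", paste(miss, collapse = ", "))
    unknown <- setdiff(plaques$sample_id, cells$sample_id)
    if (length(unknown)) {
      stop("plaque sample id(s) absent from cell table: ", paste(unknown, collapse = ", "))
    }
  }
  regions <- if (!is.null(paths$regions)) read_region_map(paths$regions) else NULL
  atlas <- if (!is.null(paths$atlas)) read_atlas(paths$atlas) else NULL

  new_dataset(cells, counts, plaques, regions, atlas, thresholds)
}

new_dataset <- function(cells, counts, plaques, regions = NULL, atlas = NULL,
                        thresholds = analysis_thresholds()) {
  structure(list(cells = cells, counts = counts, plaques = plaques,
                 regions = regions, atlas = atlas, thresholds = thresholds),
            class = "dataset")
}

#' @export
print.dataset <- function(x, ...) {
  cat(sprintf("dataset: %d cells x %d genes, %d sample(s), %d plaque(s)\n",
              nrow(x$cells), ncol(x$counts),
              length(unique(x$cells$sample_id)), nrow(x$plaques)))
  invisible(x)
}

read_counts <- function(paths) {
  path <- paths$counts
  if (grepl("\\.mtx$", path)) {
    if (is.null(paths$counts_cells) || is.null(paths$counts_genes)) {
      stop("MTX counts require 'counts_cells' and 'counts_genes' sidecar paths")
    }
    m <- as.matrix(Matrix::readMM(path))
    rn <- readLines(paths$counts_cells)
    cn <- readLines(paths$counts_genes)
    if (length(rn) != nrow(m) || length(cn) != ncol(m)) {
      stop("MTX sidecar lengths do not match matrix dimensions")
    }
    dimnames(m) <- list(rn, cn)
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
    if (names(df)[1] != "cell_id") stop("dense counts CSV must have 'cell_id' as first column")
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- as.character(df$cell_id)
  }
  storage.mode(m) <- "integer"
  if (any(m < 0)) stop("counts must be nonnegative")
  if (anyDuplicated(colnames(m))) stop("gene names must be unique")
  m
}

empty_plaque_table <- function() {
  data.frame(plaque_id = character(), x = numeric(), y = numeric(),
             area = numeric(), equivalent_diameter = numeric(),
             volume = numeric(), sample_id = character(),
             stringsAsFactors = FALSE)
}

#' Read and write region maps
#'
#' A region map is a per-sample set of named simple polygons (vertex lists in
#' um). On disk it is a JSON object `sample -> region -> [[x, y], ...]`.
#'
#' @param path JSON file path.
#' @return `read_region_map()` returns a nested list
#'   `sample -> region -> matrix(n, 2)`.
#' @export
read_region_map <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(raw, function(sample) {
    lapply(sample, function(poly) {
      m <- matrix(as.numeric(unlist(poly)), ncol = 2, byrow = !is.matrix(poly))
      if (is.matrix(poly)) m <- as.matrix(poly)
      colnames(m) <- c("x", "y")
      if (nrow(m) < 3) stop("region polygon needs at least 3 vertices")
      m
    })
  })
}

#' @rdname read_region_map
#' @param regions Nested region-map list as returned by `read_region_map()`.
#' @export
write_region_map <- function(regions, path) {
  out <- lapply(regions, function(sample) {
    lapply(sample, function(poly) unname(apply(poly, 1, as.numeric, simplify = FALSE)))
  })
  jsonlite::write_json(out, path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

read_atlas <- function(path) {
  atlas <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("gene", "expressed_in", "exclusive_to")
  miss <- setdiff(need, names(atlas))
  if (length(miss)) stop("atlas table missing column(s): ", paste(miss, collapse = ", "))
  atlas
}

#' Save result tables with a run manifest
#'
#' Writes each table as CSV with a stable column order and writes
#' `manifest.json` recording file names, row counts, the configuration hash
#' and the random seed, so a run is reproducible from manifest plus seed.
#'
#' @param results Named list of data frames.
#' @param out_dir Output directory (created if needed).
#' @param thresholds The [analysis_thresholds()] used for the run.
#' @param seed The root random seed of the run.
#' @return Invisibly, the manifest list.
#' @export
save_results <- function(results, out_dir, thresholds = analysis_thresholds(),
                         seed = NA_integer_) {
  stopifnot(is.list(results), !is.null(names(results)), all(nzchar(names(results))))
  ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!ok || file.access(out_dir, mode = 2) != 0) {
    stop("output directory is not writable: ", out_dir)
  }
  files <- list()
  for (nm in names(results)) {
    tab <- as.data.frame(results[[nm]])
    fn <- file.path(out_dir, paste0(nm, ".csv"))
    utils::write.csv(tab, fn, row.names = FALSE)
    files[[nm]] <- list(file = basename(fn), row_count = nrow(tab))
  }
  manifest <- list(files = files,
                   config_hash = config_hash(thresholds),
                   seed = seed)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

# 32-bit polynomial rolling hash over the deparsed config; stable across
# sessions for plain lists of numbers and strings.
config_hash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(unclass(x)), collapse = "\n"))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Read back a saved result table
#'
#' @param out_dir Directory written by [save_results()].
#' @param name Table name (without `.csv`).
#' @return The table as a data frame.
#' @export
load_result <- function(out_dir, name) {
  utils::read.csv(file.path(out_dir, paste0(name, ".csv")), stringsAsFactors = FALSE)
}
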