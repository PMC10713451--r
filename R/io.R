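#' Read a Matrix Market count triplet (matrix + barcodes + features)
#'
#' Reads the standard 10x-style triplet: an MTX file with features in rows
#' and cells in columns (transposed internally to cells x features), a
#' barcodes TSV and a features TSV. Dimensions are validated against the
#' matrix header; non-integer entries are rejected.
#'
#' @param mtx,barcodes,features File paths. `barcodes`/`features` default to
#'   the conventional names next to `mtx`.
#' @param modality `"rna"` or `"atac"`.
#' @return A [cell_matrix()].
#' @export
read_counts_mtx <- function(mtx, barcodes = NULL, features = NULL,
                            modality = "rna") {
  dir <- dirname(mtx)
  barcodes <- barcodes %||% file.path(dir, "barcodes.tsv")
  features <- features %||% file.path(dir, "features.tsv")
  for (f in c(mtx, barcodes, features)) {
    if (!file.exists(f)) abort(sprintf("file not found: %s", f))
  }
  m <- Matrix::readMM(mtx)
  m <- as(as(as(m, "dMatrix"), "generalMatrix"), "CsparseMatrix")
  bc <- readr::read_tsv(barcodes, col_names = FALSE, show_col_types = FALSE)[[1]]
  ft <- readr::read_tsv(features, col_names = FALSE, show_col_types = FALSE)[[1]]
  if (ncol(m) != length(bc) || nrow(m) != length(ft)) {
    abort(sprintf("dimension mismatch: matrix is %d features x %d cells but %d features / %d barcodes given",
                  nrow(m), ncol(m), length(ft), length(bc)))
  }
  m <- Matrix::t(m)
  if (length(m@x) && any(m@x != floor(m@x))) {
    abort("matrix entries must be integer counts")
  }
  cell_matrix(m, cell_ids = bc, feature_ids = ft, modality = modality)
}

#' Write a count matrix as an MTX triplet
#'
#' Inverse of [read_counts_mtx()]: writes `matrix.mtx`, `barcodes.tsv` and
#' `features.tsv` (features x cells orientation) into `dir`. Round trips are
#' lossless.
#'
#' @param counts A [cell_matrix()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the three paths.
#' @export
write_counts_mtx <- function(counts, dir) {
  stopifnot(is(counts, "cell_matrix"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("matrix.mtx", "barcodes.tsv", "features.tsv"))
  Matrix::writeMM(Matrix::t(as_dgc(counts)), paths[1])
  readr::write_lines(rownames(counts), paths[2])
  readr::write_lines(colnames(counts), paths[3])
  invisible(paths)
}

#' Read an ATAC fragments file
#'
#' Tab-separated `chrom start end barcode [count]` records with 0-based
#' half-open coordinates (the 10x fragments dialect); plain or gzip
#' compressed. Malformed records abort with their line number.
#'
#' @param path File path.
#' @return Fragment tibble with a `count` column (1 for the 4-column
#'   dialect).
#' @export
read_fragments <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  raw <- suppressWarnings(
    readr::read_tsv(path,
                    col_names = c("chrom", "start", "end", "barcode", "count"),
                    col_types = "ciici", comment = "#",
                    show_col_types = FALSE))
  if (!"count" %in% names(raw)) raw$count <- 1L
  if (all(is.na(raw$count))) raw$count <- 1L
  bad <- which(is.na(raw$start) | is.na(raw$end))
  if (length(bad)) {
    abort(sprintf("non-numeric coordinates at line %d", bad[1]))
  }
  bad <- which(raw$end <= raw$start)
  if (length(bad)) {
    abort(sprintf("end <= start at line %d", bad[1]))
  }
  raw
}

#' Write fragments as a tab-separated file
#'
#' @param fragments Fragment tibble.
#' @param path Output path (`.gz` writes gzip-compressed).
#' @return Invisibly, `path`.
#' @export
write_fragments <- function(fragments, path) {
  check_fragments(fragments)
  readr::write_tsv(fragments, path, col_names = FALSE)
  invisible(path)
}

#' Read a peak set: BED3 plus a GC-content sidecar
#'
#' @param bed BED3 file (chrom, start, end; 0-based half-open).
#' @param gc Optional TSV sidecar with columns `peak` and `gc`, or a numeric
#'   vector aligned with the BED rows.
#' @return Peak tibble: `peak`, `chrom`, `start`, `end`, and `gc` when
#'   available.
#' @export
read_peaks_bed <- function(bed, gc = NULL) {
  raw <- readr::read_tsv(bed, col_names = c("chrom", "start", "end"),
                         col_types = "cii", show_col_types = FALSE)
  if (any(raw$end <= raw$start)) abort("peak with end <= start")
  out <- tibble(peak = sprintf("peak_%05d", seq_len(nrow(raw))),
                chrom = raw$chrom, start = raw$start, end = raw$end)
  if (!is.null(gc)) {
    out$gc <- if (is.character(gc)) {
      readr::read_tsv(gc, show_col_types = FALSE)$gc
    } else as.numeric(gc)
  }
  out
}

#' Export a sparse matrix as 3-column TSV (i, j, value)
#'
#' @param m A sparse matrix.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_sparse_tsv <- function(m, path) {
  tm <- as(as(m, "generalMatrix"), "TsparseMatrix")
  readr::write_tsv(tibble(i = tm@i + 1L, j = tm@j + 1L, value = tm@x), path)
  invisible(path)
}

#' Default run configuration
#'
#' All pipeline defaults in one provenance-ready record: graph and kernel
#' parameters, metacell heuristics, ATAC toolkit constants and cohort test
#' settings.
#'
#' @param ... Overrides of any default field.
#' @return A `run_config` list.
#' @export
run_config <- function(...) {
  cfg <- list(
    seed = 0,
    modality = "rna",
    k = 50,
    l = 15,
    n_components_rna = 50,
    n_components_atac = 30,
    n_hvg = 2500,
    n_dcs = 10,
    cells_per_metacell = 75,
    trivial_threshold = 0.05,
    max_iter = 150,
    tol = 1e-5,
    nfr_max_length = 147,
    peak_width = 500,
    eff_length_multiplier = 5000,
    open_peak_p = 0.01,
    peak_gene_window_kb = 100,
    n_background_peaks = 100,
    n_matching_bins = 100,
    peak_gene_p = 0.1,
    tf_lasso_folds = 10,
    meta2_ratio = 10,
    da_permutations = 5000,
    da_alpha = 0.1)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) abort(sprintf("unknown config field(s): %s",
                                     paste(unknown, collapse = ", ")))
  cfg[names(over)] <- over
  structure(cfg, class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config>\n")
  for (nm in names(x)) cat(sprintf("  %-24s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

# provenance sidecar written next to any CLI output
write_provenance <- function(dir, cfg, extra = list()) {
  payload <- c(list(tool = "metacellkit",
                    version = as.character(utils::packageVersion("metacellkit")),
                    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
               list(config = unclass(cfg)), extra)
  jsonlite::write_json(payload, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE)
}
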