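#' Single-cell count container
#'
#' A `CellMatrix` bundles a genes x cells integer count matrix with per-cell
#' metadata (donor, condition, optional cell type / cluster) and the derived
#' per-cell quality statistics used by the QC filters: number of detected
#' features, total counts, and mitochondrial fraction (genes whose name
#' starts with `"MT-"`).
#'
#' @param counts genes x cells matrix of non-negative integer counts (dense
#'   or any [Matrix::Matrix] class; stored sparse). Must carry rownames
#'   (gene ids) and colnames (cell ids).
#' @param cell_meta data.frame with one row per cell, in the column order of
#'   `counts`; must contain `donor_id` and `condition` (factor with levels
#'   `young`, `aged`), optionally `cell_type` and `cluster`.
#' @param condition_levels the two condition labels, reference first.
#'
#' @return An object of class `CellMatrix`: a list with elements `counts`
#'   (dgCMatrix), `cell_meta` (data.frame, with derived columns
#'   `n_features`, `total_counts`, `mito_fraction` appended), and
#'   `logcounts` (`NULL` until [normalize_log1p()] is applied).
#' @seealso [filter_cells()], [normalize_log1p()], [pseudobulk()]
#' @export
CellMatrix <- function(counts, cell_meta,
                       condition_levels = c("young", "aged")) {
  counts <- as_counts(counts, "counts")
  if (!is.data.frame(cell_meta)) stop_arg("cell_meta", "must be a data.frame")
  if (nrow(cell_meta) != ncol(counts)) {
    stop_arg("cell_meta", "must have one row per cell")
  }
  for (f in c("donor_id", "condition")) {
    if (is.null(cell_meta[[f]])) stop_arg("cell_meta", paste("missing", f))
  }
  cond <- as.character(cell_meta$condition)
  if (!all(cond %in% condition_levels)) {
    stop_arg("cell_meta",
             sprintf("condition must take values in {%s}",
                     paste(condition_levels, collapse = ", ")))
  }
  cell_meta$condition <- factor(cond, levels = condition_levels)
  cell_meta$cell_id <- colnames(counts)
  rownames(cell_meta) <- colnames(counts)
  obj <- structure(
    list(counts = counts, cell_meta = cell_meta, logcounts = NULL),
    class = "CellMatrix")
  refresh_cell_stats(obj)
}

as_counts <- function(counts, name) {
  if (is.matrix(counts)) {
    counts <- Matrix::Matrix(counts, sparse = TRUE)
  }
  if (!methods::is(counts, "Matrix")) {
    stop_arg(name, "must be a matrix or sparse Matrix")
  }
  counts <- methods::as(methods::as(counts, "generalMatrix"),
                        "CsparseMatrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop_arg(name, "must have gene rownames and cell/spot colnames")
  }
  if (any(counts@x < 0) || any(counts@x != round(counts@x))) {
    stop_arg(name, "must contain non-negative integer counts")
  }
  counts
}

refresh_cell_stats <- function(x) {
  mito <- startsWith(rownames(x$counts), "MT-")
  tot <- col_totals(x$counts)
  x$cell_meta$n_features <- as.integer(col_features(x$counts))
  x$cell_meta$total_counts <- as.numeric(tot)
  mt <- if (any(mito)) col_totals(x$counts[mito, , drop = FALSE]) else 0
  x$cell_meta$mito_fraction <- ifelse(tot > 0, as.numeric(mt) / tot, 0)
  x
}

#' @export
print.CellMatrix <- function(x, ...) {
  cat(sprintf("CellMatrix: %d genes x %d cells\n",
              nrow(x$counts), ncol(x$counts)))
  cat(sprintf("  donors: %d | conditions: %s | normalized: %s\n",
              length(unique(x$cell_meta$donor_id)),
              paste(table(x$cell_meta$condition), collapse = "/"),
              !is.null(x$logcounts)))
  invisible(x)
}

#' @export
dim.CellMatrix <- function(x) dim(x$counts)

#' Subset the cells (columns) of a CellMatrix
#'
#' Keeps counts, metadata, any normalized values and the derived QC
#' statistics in step.
#'
#' @param x a [CellMatrix].
#' @param idx cell indices, logical mask, or cell ids.
#' @return the subset [CellMatrix].
#' @export
subset_cells <- function(x, idx) {
  if (is.character(idx)) idx <- match(idx, colnames(x$counts))
  x$counts <- x$counts[, idx, drop = FALSE]
  x$cell_meta <- x$cell_meta[idx, , drop = FALSE]
  if (!is.null(x$logcounts)) x$logcounts <- x$logcounts[, idx, drop = FALSE]
  refresh_cell_stats(x)
}

subset_genes <- function(x, idx) {
  x$counts <- x$counts[idx, , drop = FALSE]
  if (!is.null(x$logcounts)) x$logcounts <- x$logcounts[idx, , drop = FALSE]
  refresh_cell_stats(x)
}

#' Spatial spot count container
#'
#' A `SpotMatrix` bundles a genes x spots count matrix with Visium-style
#' array coordinates. The hexagonal layout follows the Visium convention
#' that `array_row + array_col` is even for every spot, so the six
#' neighbours of `(r, c)` sit at `(r, c +/- 2)` and `(r +/- 1, c +/- 1)`.
#'
#' @param counts genes x spots count matrix with dimnames.
#' @param positions data.frame with columns `barcode`, `in_tissue` (0/1),
#'   `array_row`, `array_col`; one row per spot, matched by barcode.
#' @return An object of class `SpotMatrix` with elements `counts`,
#'   `positions`, `logcounts`.
#' @seealso [filter_spots()], [hex_neighbors()]
#' @export
SpotMatrix <- function(counts, positions) {
  counts <- as_counts(counts, "counts")
  req <- c("barcode", "in_tissue", "array_row", "array_col")
  if (!is.data.frame(positions) || !all(req %in% names(positions))) {
    stop_arg("positions",
             "must be a data.frame with barcode, in_tissue, array_row, array_col")
  }
  positions <- positions[match(colnames(counts), positions$barcode), , drop = FALSE]
  if (anyNA(positions$barcode)) {
    stop_arg("positions", "every spot in counts needs a position row")
  }
  par_ok <- (positions$array_row + positions$array_col) %% 2 == 0
  if (!all(par_ok[positions$in_tissue == 1])) {
    stop_arg("positions", "in-tissue spots must satisfy (row + col) even")
  }
  rownames(positions) <- positions$barcode
  structure(list(counts = counts, positions = positions, logcounts = NULL),
            class = "SpotMatrix")
}

#' @export
print.SpotMatrix <- function(x, ...) {
  cat(sprintf("SpotMatrix: %d genes x %d spots (%d in tissue)\n",
              nrow(x$counts), ncol(x$counts), sum(x$positions$in_tissue == 1)))
  invisible(x)
}

#' @export
dim.SpotMatrix <- function(x) dim(x$counts)

subset_spots <- function(x, idx) {
  x$counts <- x$counts[, idx, drop = FALSE]
  x$positions <- x$positions[idx, , drop = FALSE]
  if (!is.null(x$logcounts)) x$logcounts <- x$logcounts[, idx, drop = FALSE]
  x
}
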