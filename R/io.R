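# Reading and writing the standard on-disk formats (10x MTX dialect,
# tissue_positions CSV, GMT signatures, ligand-receptor resource CSV).

#' Write a CellMatrix as a 10x-style directory
#'
#' Writes `matrix.mtx` (MatrixMarket), `genes.tsv`, `barcodes.tsv` and a
#' flat `metadata.tsv` (cell_id, donor_id, condition, cell_type if
#' present).
#'
#' @param m a [CellMatrix].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sc_10x <- function(m, dir) {
  stopifnot(inherits(m, "CellMatrix"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(m$counts, file.path(dir, "matrix.mtx"))
  writeLines(rownames(m$counts), file.path(dir, "genes.tsv"))
  writeLines(colnames(m$counts), file.path(dir, "barcodes.tsv"))
  keep <- intersect(c("cell_id", "donor_id", "condition", "cell_type",
                      "cluster"), names(m$cell_meta))
  utils::write.table(m$cell_meta[keep], file.path(dir, "metadata.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read a CellMatrix from a 10x-style directory
#'
#' Expects the files written by [write_sc_10x()].
#'
#' @param dir directory containing `matrix.mtx`, `genes.tsv`,
#'   `barcodes.tsv`, `metadata.tsv`.
#' @return a [CellMatrix].
#' @export
read_sc_10x <- function(dir) {
  counts <- methods::as(Matrix::readMM(file.path(dir, "matrix.mtx")),
                        "CsparseMatrix")
  rownames(counts) <- readLines(file.path(dir, "genes.tsv"))
  colnames(counts) <- readLines(file.path(dir, "barcodes.tsv"))
  meta <- utils::read.delim(file.path(dir, "metadata.tsv"),
                            stringsAsFactors = FALSE)
  meta <- meta[match(colnames(counts), meta$cell_id), , drop = FALSE]
  CellMatrix(counts, meta)
}

#' Write a SpotMatrix as MTX + tissue positions
#'
#' Writes `matrix.mtx`, `genes.tsv`, `barcodes.tsv` and a
#' `tissue_positions.csv` with columns `barcode`, `in_tissue`,
#' `array_row`, `array_col`.
#'
#' @param s a [SpotMatrix].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_spatial_10x <- function(s, dir) {
  stopifnot(inherits(s, "SpotMatrix"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(s$counts, file.path(dir, "matrix.mtx"))
  writeLines(rownames(s$counts), file.path(dir, "genes.tsv"))
  writeLines(colnames(s$counts), file.path(dir, "barcodes.tsv"))
  utils::write.csv(
    s$positions[c("barcode", "in_tissue", "array_row", "array_col")],
    file.path(dir, "tissue_positions.csv"), row.names = FALSE,
    quote = FALSE)
  invisible(dir)
}

#' Read a SpotMatrix from an MTX + tissue positions directory
#'
#' @param dir directory written by [write_spatial_10x()].
#' @return a [SpotMatrix].
#' @export
read_spatial_10x <- function(dir) {
  counts <- methods::as(Matrix::readMM(file.path(dir, "matrix.mtx")),
                        "CsparseMatrix")
  rownames(counts) <- readLines(file.path(dir, "genes.tsv"))
  colnames(counts) <- readLines(file.path(dir, "barcodes.tsv"))
  pos <- utils::read.csv(file.path(dir, "tissue_positions.csv"),
                         stringsAsFactors = FALSE)
  SpotMatrix(counts, pos)
}

#' Read gene signatures from a GMT file
#'
#' @param path GMT file (set name, description, tab-separated genes).
#' @return named list of gene sets.
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}

#' Write gene signatures to a GMT file
#'
#' @param sets named list of gene sets.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  lines <- vapply(names(sets), function(s) {
    paste(c(s, "na", sets[[s]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a ligand-receptor resource table from CSV
#'
#' Expects columns `ligand`, `receptor`, `curation_effort`,
#' `n_references`, `n_resources`.
#'
#' @param path CSV file.
#' @return an `LRResource` data.frame.
#' @export
read_lr_resource <- function(path) {
  res <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("ligand", "receptor", "curation_effort")
  if (!all(req %in% names(res))) {
    stop_arg("path", paste("resource CSV needs columns:",
                           paste(req, collapse = ", ")))
  }
  class(res) <- c("LRResource", "data.frame")
  res
}

#' Write a ligand-receptor resource (or any result table) to CSV
#'
#' @param x a data.frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_result_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
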