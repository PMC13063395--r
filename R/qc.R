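#' Quality-control filtering of cells and genes
#'
#' Removes low-complexity and high-mitochondrial cells, then lowly detected
#' genes. A cell is kept when it has strictly more than `min_features`
#' detected genes and a mitochondrial fraction at most `max_mito`; after
#' cell filtering, a gene is kept when it is detected in strictly more than
#' `min_cells_per_gene` of the remaining cells. The order is fixed: cells
#' first, then genes. The filter is idempotent.
#'
#' @param m a [CellMatrix].
#' @param min_features keep cells with `n_features > min_features`.
#' @param max_mito keep cells with `mito_fraction <= max_mito`.
#' @param min_cells_per_gene keep genes detected in more than this many
#'   cells (after cell filtering).
#' @return the filtered [CellMatrix].
#' @export
filter_cells <- function(m, min_features = 200, max_mito = 0.10,
                         min_cells_per_gene = 3) {
  stopifnot(inherits(m, "CellMatrix"))
  if (ncol(m$counts) == 0) stop_arg("m", "matrix has no cells")
  min_features <- check_count(min_features, "min_features", min = 0)
  max_mito <- check_fraction(max_mito, "max_mito")
  min_cells_per_gene <- check_count(min_cells_per_gene,
                                    "min_cells_per_gene", min = 0)
  feat_ok <- m$cell_meta$n_features > min_features
  mito_ok <- m$cell_meta$mito_fraction <= max_mito
  keep_cells <- feat_ok & mito_ok
  if (!any(keep_cells)) {
    binding <- if (!any(feat_ok)) "min_features" else
      if (!any(mito_ok)) "max_mito" else "min_features + max_mito"
    stop(sprintf("all cells removed by QC (binding filter: %s)", binding),
         call. = FALSE)
  }
  m <- subset_cells(m, which(keep_cells))
  detected_in <- Matrix::rowSums(m$counts > 0)
  m <- subset_genes(m, which(detected_in > min_cells_per_gene))
  m
}

#' Quality-control filtering of spatial spots
#'
#' Keeps spots with at least `min_umi` total counts and at least
#' `min_features` detected genes (a spot failing either threshold is
#' removed), and optionally drops immunoglobulin genes, identified by the
#' gene-name prefixes `IGH`, `IGK` and `IGL`.
#'
#' @param s a [SpotMatrix].
#' @param min_umi minimum total counts per spot.
#' @param min_features minimum detected genes per spot.
#' @param drop_ig drop immunoglobulin-named genes?
#' @return the filtered [SpotMatrix].
#' @export
filter_spots <- function(s, min_umi = 200, min_features = 150,
                         drop_ig = TRUE) {
  stopifnot(inherits(s, "SpotMatrix"))
  if (ncol(s$counts) == 0) stop_arg("s", "matrix has no spots")
  min_umi <- check_count(min_umi, "min_umi", min = 0)
  min_features <- check_count(min_features, "min_features", min = 0)
  umi_ok <- col_totals(s$counts) >= min_umi
  feat_ok <- col_features(s$counts) >= min_features
  keep <- umi_ok & feat_ok
  if (!any(keep)) {
    binding <- if (!any(umi_ok)) "min_umi" else
      if (!any(feat_ok)) "min_features" else "min_umi + min_features"
    stop(sprintf("all spots removed by QC (binding filter: %s)", binding),
         call. = FALSE)
  }
  s <- subset_spots(s, which(keep))
  if (isTRUE(drop_ig)) {
    ig <- startsWith(rownames(s$counts), "IGH") |
      startsWith(rownames(s$counts), "IGK") |
      startsWith(rownames(s$counts), "IGL")
    if (any(ig)) {
      s$counts <- s$counts[!ig, , drop = FALSE]
      if (!is.null(s$logcounts)) {
        s$logcounts <- s$logcounts[!ig, , drop = FALSE]
      }
    }
  }
  s
}

#' Library-size normalization (counts-per-`scale`, log1p)
#'
#' Computes `log(1 + scale * count / column_total)` for every entry and
#' stores it alongside the raw counts in the `logcounts` slot. This is a
#' fully specified, reproducible normalization; raw counts are retained.
#'
#' @param m a [CellMatrix] or [SpotMatrix].
#' @param scale target library size (default 10,000).
#' @return `m` with `logcounts` filled in.
#' @export
normalize_log1p <- function(m, scale = 10000) {
  stopifnot(inherits(m, "CellMatrix") || inherits(m, "SpotMatrix"))
  scale <- check_positive(scale, "scale")
  tot <- col_totals(m$counts)
  if (any(tot == 0)) {
    stop("zero-total columns present; filter before normalizing",
         call. = FALSE)
  }
  cpm <- m$counts %*% Matrix::Diagonal(x = scale / tot)
  lc <- cpm
  lc@x <- log1p(lc@x)
  dimnames(lc) <- dimnames(m$counts)
  m$logcounts <- methods::as(lc, "CsparseMatrix")
  m
}

#' Donor-level pseudobulk aggregation
#'
#' Sums raw counts over groups of cells — by default one group per
#' `(donor_id, cell_type)` combination — yielding a genes x groups matrix
#' of exact integer sums that can be treated as bulk replicates. Groups
#' with fewer than `min_cells` cells are kept but flagged.
#'
#' @param m a [CellMatrix].
#' @param group_by character vector of `cell_meta` columns defining groups.
#' @param min_cells groups below this size are flagged in `small_group`.
#' @return a `PseudobulkMatrix`: list with `counts` (genes x groups),
#'   `groups` (data.frame: the grouping columns, `n_cells`, `small_group`).
#' @export
pseudobulk <- function(m, group_by = c("donor_id", "cell_type"),
                       min_cells = 10) {
  stopifnot(inherits(m, "CellMatrix"))
  missing_f <- setdiff(group_by, names(m$cell_meta))
  if (length(missing_f)) {
    stop_arg("group_by", paste("missing metadata field(s):",
                               paste(missing_f, collapse = ", ")))
  }
  min_cells <- check_count(min_cells, "min_cells", min = 1)
  key <- interaction(m$cell_meta[group_by], drop = TRUE, sep = "|")
  design <- Matrix::sparseMatrix(
    i = seq_along(key), j = as.integer(key), x = 1,
    dims = c(length(key), nlevels(key)))
  counts <- m$counts %*% design
  colnames(counts) <- levels(key)
  n_cells <- as.integer(table(key))
  groups <- do.call(rbind, strsplit(levels(key), "|", fixed = TRUE))
  groups <- stats::setNames(as.data.frame(groups), group_by)
  groups$group <- levels(key)
  groups$n_cells <- n_cells
  groups$small_group <- n_cells < min_cells
  structure(list(counts = methods::as(counts, "CsparseMatrix"),
                 groups = groups),
            class = "PseudobulkMatrix")
}

#' @export
print.PseudobulkMatrix <- function(x, ...) {
  cat(sprintf("PseudobulkMatrix: %d genes x %d groups (%d flagged small)\n",
              nrow(x$counts), ncol(x$counts), sum(x$groups$small_group)))
  invisible(x)
}
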