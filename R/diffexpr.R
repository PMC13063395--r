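# Marker / condition differential expression and over-representation.

#' Threshold presets for DE calling
#'
#' `"markers"`: cluster-vs-rest marker calling (`min_pct = 0.25`,
#' `min_abs_log2fc = 1`). `"age"`: aged-vs-young DE calling
#' (`min_pct = 0.25`, `min_abs_log2fc = 0.5`). Both use Bonferroni-adjusted
#' p < 0.05.
#'
#' @param preset `"markers"` or `"age"`.
#' @return list with `min_pct`, `min_abs_log2fc`, `alpha`.
#' @export
de_preset <- function(preset = c("markers", "age")) {
  preset <- match.arg(preset)
  list(min_pct = 0.25,
       min_abs_log2fc = if (preset == "markers") 1 else 0.5,
       alpha = 0.05)
}

#' Wilcoxon rank-sum differential expression with detection thresholds
#'
#' Tests each gene between two disjoint cell groups on the normalized
#' (log1p) values using the rank-sum test with normal approximation and
#' tie correction. A gene is tested only when its detection fraction
#' exceeds `min_pct` in at least one group. The fold change is
#' `log2FC = log2((mean_a' + eps) / (mean_b' + eps))` where `mean'` is the
#' group mean of `expm1(normalized)` and `eps = 1e-9`. p-values are
#' Bonferroni-adjusted over the tested genes; a gene passes when
#' `p_adj < alpha` and `|log2FC| > min_abs_log2fc`.
#'
#' @param m a normalized [CellMatrix] (see [normalize_log1p()]).
#' @param group_a,group_b cell ids or column indices of the two groups
#'   (must not overlap; both of size >= 2).
#' @param min_pct detection-fraction gate (in either group).
#' @param min_abs_log2fc fold-change threshold of the `pass` flag.
#' @param alpha adjusted-p threshold of the `pass` flag.
#' @return a `DEResult` data.frame per tested gene: `gene`, `log2FC`,
#'   `pct_1`, `pct_2`, `p`, `p_adj`, `pass`.
#' @export
rank_sum_de <- function(m, group_a, group_b, min_pct = 0.25,
                        min_abs_log2fc = 1, alpha = 0.05) {
  stopifnot(inherits(m, "CellMatrix"))
  if (is.null(m$logcounts)) {
    stop("normalize with normalize_log1p() first", call. = FALSE)
  }
  min_pct <- check_fraction(min_pct, "min_pct")
  ia <- resolve_cells(m, group_a, "group_a")
  ib <- resolve_cells(m, group_b, "group_b")
  if (length(intersect(ia, ib)) > 0) {
    stop_arg("group_b", "groups must not overlap")
  }
  if (length(ia) < 2 || length(ib) < 2) {
    stop("both groups need at least 2 cells", call. = FALSE)
  }
  xa <- m$logcounts[, ia, drop = FALSE]
  xb <- m$logcounts[, ib, drop = FALSE]
  pct1 <- Matrix::rowSums(xa > 0) / length(ia)
  pct2 <- Matrix::rowSums(xb > 0) / length(ib)
  test_idx <- which(pmax(pct1, pct2) > min_pct)
  if (!length(test_idx)) {
    return(empty_de_result())
  }
  eps <- 1e-9
  mean_a <- Matrix::rowSums(expm1_sparse(xa)) / length(ia)
  mean_b <- Matrix::rowSums(expm1_sparse(xb)) / length(ib)
  log2fc <- log2((mean_a[test_idx] + eps) / (mean_b[test_idx] + eps))
  av <- as.matrix(xa[test_idx, , drop = FALSE])
  bv <- as.matrix(xb[test_idx, , drop = FALSE])
  p <- vapply(seq_along(test_idx), function(i) {
    suppressWarnings(
      stats::wilcox.test(av[i, ], bv[i, ], exact = FALSE,
                         correct = TRUE)$p.value)
  }, numeric(1))
  p[is.na(p)] <- 1   # all-tied gene: no evidence
  p_adj <- pmin(1, p * length(test_idx))
  res <- data.frame(gene = rownames(m$counts)[test_idx],
                    log2FC = log2fc,
                    pct_1 = pct1[test_idx], pct_2 = pct2[test_idx],
                    p = p, p_adj = p_adj,
                    pass = p_adj < alpha & abs(log2fc) > min_abs_log2fc,
                    stringsAsFactors = FALSE, row.names = NULL)
  class(res) <- c("DEResult", "data.frame")
  res
}

empty_de_result <- function() {
  res <- data.frame(gene = character(0), log2FC = numeric(0),
                    pct_1 = numeric(0), pct_2 = numeric(0),
                    p = numeric(0), p_adj = numeric(0), pass = logical(0))
  class(res) <- c("DEResult", "data.frame")
  res
}

resolve_cells <- function(m, g, name) {
  if (is.character(g)) {
    idx <- match(g, colnames(m$counts))
    if (anyNA(idx)) stop_arg(name, "unknown cell id(s)")
    idx
  } else if (is.logical(g)) {
    which(g)
  } else {
    as.integer(g)
  }
}

expm1_sparse <- function(x) {
  x@x <- expm1(x@x)
  x
}

#' Pseudobulk log2 fold changes and single-cell concordance
#'
#' Converts a [pseudobulk()] matrix to counts-per-million, takes
#' `log2(CPM + 1)` per donor group, averages donors within each condition
#' and reports the aged-minus-young difference per gene. If reference
#' effect sizes are supplied (e.g. single-cell log2FCs or planted ground
#' truth), the Spearman concordance over those genes is returned.
#'
#' @param pb a `PseudobulkMatrix` whose groups are (donor, ...) columns.
#' @param condition_map named character vector donor_id -> condition
#'   (`young`/`aged`).
#' @param reference_log2fc optional named numeric vector of per-gene
#'   effects to correlate with.
#' @return list with `log2FC` (named per gene), `n_young`, `n_aged`
#'   (donors), and `concordance_rho` (or `NA` if no reference given).
#' @export
pseudobulk_log2fc <- function(pb, condition_map, reference_log2fc = NULL) {
  stopifnot(inherits(pb, "PseudobulkMatrix"))
  donors <- pb$groups$donor_id
  if (is.null(donors)) stop_arg("pb", "groups must carry donor_id")
  cond <- unname(condition_map[donors])
  if (anyNA(cond)) stop_arg("condition_map", "must cover every donor")
  if (sum(unique(data.frame(donors, cond))$cond == "young") < 2 ||
      sum(unique(data.frame(donors, cond))$cond == "aged") < 2) {
    stop("need >= 2 donors per condition for pseudobulk replicates",
         call. = FALSE)
  }
  tot <- col_totals(pb$counts)
  if (any(tot == 0)) stop_arg("pb", "zero-total pseudobulk column")
  cpm <- sweep(as.matrix(pb$counts), 2, tot / 1e6, `/`)
  lg <- log2(cpm + 1)
  mean_y <- rowMeans(lg[, cond == "young", drop = FALSE])
  mean_a <- rowMeans(lg[, cond == "aged", drop = FALSE])
  lfc <- mean_a - mean_y
  rho <- NA_real_
  if (!is.null(reference_log2fc)) {
    genes <- intersect(names(reference_log2fc), names(lfc))
    if (length(genes) >= 3) {
      rho <- suppressWarnings(
        stats::cor(reference_log2fc[genes], lfc[genes],
                   method = "spearman"))
    }
  }
  list(log2FC = lfc,
       n_young = length(unique(donors[cond == "young"])),
       n_aged = length(unique(donors[cond == "aged"])),
       concordance_rho = rho)
}

#' Hypergeometric over-representation analysis
#'
#' For each gene set, tests whether its overlap with the query gene list
#' is larger than expected given the universe:
#' `hyper_p = P(X >= k)` for `X ~ Hypergeometric(N, K, n)` with `N` the
#' universe size, `K` the (universe-intersected) set size, `n` the query
#' size and `k` the overlap. p-values are BH-adjusted across sets.
#'
#' @param query character vector of genes (subset of `universe`).
#' @param sets named list of gene sets.
#' @param universe character vector of background genes.
#' @return an `ORAResult` data.frame: `set`, `k`, `K`, `n`, `N`,
#'   `hyper_p`, `p_adj`.
#' @export
hypergeom_ora <- function(query, sets, universe) {
  if (!length(universe)) stop_arg("universe", "must be non-empty")
  universe <- unique(universe)
  query <- unique(query)
  if (!all(query %in% universe)) {
    stop_arg("query", "must be a subset of the universe")
  }
  if (!length(sets) || is.null(names(sets))) {
    stop_arg("sets", "must be a named list of gene sets")
  }
  N <- length(universe)
  n <- length(query)
  rows <- lapply(names(sets), function(s) {
    set_u <- intersect(unique(sets[[s]]), universe)
    K <- length(set_u)
    k <- length(intersect(set_u, query))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set = s, k = k, K = K, n = n, N = N, hyper_p = p,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$p_adj <- stats::p.adjust(res$hyper_p, method = "BH")
  class(res) <- c("ORAResult", "data.frame")
  res
}
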