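# Spot deconvolution, dual-rank labeling, hex adjacency, co-localization.

#' Reference-based spot deconvolution by non-negative least squares
#'
#' Estimates per-spot cell-type fractions by regressing each spot's
#' counts-per-million vector on reference per-type mean profiles under a
#' non-negativity constraint (NNLS, via [pracma::lsqnonneg()]), then
#' renormalizing the coefficients to sum to 1. Spots with an all-zero
#' solution are assigned uniform fractions and flagged.
#'
#' @param s a [SpotMatrix].
#' @param reference genes x types matrix of non-negative mean profiles
#'   (>= 2 types); rows are matched to the spot matrix by gene name.
#' @return a `DeconvMatrix`: spots x types matrix of fractions with
#'   attributes `mean_fraction` (per-type mean, the p-bar used by
#'   [label_spots()]) and `degenerate` (spot ids with all-zero NNLS
#'   solutions).
#' @export
nnls_deconvolve <- function(s, reference) {
  stopifnot(inherits(s, "SpotMatrix"))
  if (!is.matrix(reference) || ncol(reference) < 2 ||
      is.null(colnames(reference)) || any(reference < 0)) {
    stop_arg("reference",
             "must be a non-negative genes x types matrix (>= 2 types)")
  }
  genes <- intersect(rownames(s$counts), rownames(reference))
  if (length(genes) < ncol(reference)) {
    stop_arg("reference", "too few shared genes with the spot matrix")
  }
  A <- reference[genes, , drop = FALSE]
  A <- sweep(A, 2, colSums(A), `/`) * 1e6  # profile CPM
  if (qr(A)$rank < ncol(A)) {
    warning("reference profiles are rank deficient; fractions degenerate")
  }
  tot <- col_totals(s$counts)
  if (any(tot == 0)) stop_arg("s", "zero-total spot; filter first")
  cpm <- sweep(as.matrix(s$counts[genes, , drop = FALSE]), 2,
               tot / 1e6, `/`)
  n_types <- ncol(A)
  out <- matrix(0, ncol(cpm), n_types,
                dimnames = list(colnames(cpm), colnames(A)))
  degenerate <- character(0)
  for (j in seq_len(ncol(cpm))) {
    coefs <- tryCatch(pracma::lsqnonneg(A, cpm[, j])$x,
                      error = function(e) rep(0, n_types))
    if (sum(coefs) <= 0) {
      out[j, ] <- 1 / n_types
      degenerate <- c(degenerate, colnames(cpm)[j])
    } else {
      out[j, ] <- coefs / sum(coefs)
    }
  }
  structure(out, mean_fraction = colMeans(out), degenerate = degenerate,
            class = c("DeconvMatrix", class(out)))
}

#' Dual-rank spot labeling: golden / high / low / rest
#'
#' Labels each spot for a given cell type from two independent descending
#' rankings — signature AUC and deconvolved fraction (ties broken by spot
#' id). With `p_bar` the mean deconvolved fraction of the type over all
#' spots, `n_top = ceiling(p_bar * n_spots)` and
#' `n_high = ceiling(2 * p_bar * n_spots)`:
#' \itemize{
#'   \item \strong{rest}: AUC = 0, regardless of the deconvolution rank
#'     (takes precedence over every other rule);
#'   \item \strong{golden}: within the top `n_top` of both rankings;
#'   \item \strong{high}: within the top `n_high` of both rankings and not
#'     golden;
#'   \item \strong{low}: everything else.
#' }
#'
#' @param deconv a `DeconvMatrix` (spots x types fractions).
#' @param scores a `SignatureScoreMatrix` (spots x signatures) whose
#'   column for `cell_type` holds the AUC scores.
#' @param cell_type the type (column name present in both inputs).
#' @return a `SpotLabelTable` data.frame: `spot`, `cell_type`, `label`
#'   (factor golden/high/low/rest), `auc`, `fraction`, `auc_rank`,
#'   `deconv_rank`.
#' @export
label_spots <- function(deconv, scores, cell_type) {
  if (is.null(colnames(deconv)) || !cell_type %in% colnames(deconv)) {
    stop_arg("cell_type", "not a column of the deconvolution matrix")
  }
  if (is.null(colnames(scores)) || !cell_type %in% colnames(scores)) {
    stop_arg("cell_type", "not a column of the score matrix")
  }
  spots <- rownames(deconv)
  if (is.null(spots) || !setequal(spots, rownames(scores))) {
    stop_arg("scores", "must cover the same spots as the deconvolution")
  }
  frac <- deconv[, cell_type]
  auc <- scores[spots, cell_type]
  n <- length(spots)
  p_bar <- mean(frac)
  auc_rank <- rank_desc(auc, spots)
  dec_rank <- rank_desc(frac, spots)
  label <- rep("low", n)
  if (p_bar > 0) {
    n_top <- ceiling(p_bar * n)
    n_high <- ceiling(2 * p_bar * n)
    golden <- auc_rank <= n_top & dec_rank <= n_top
    high <- auc_rank <= n_high & dec_rank <= n_high & !golden
    label[high] <- "high"
    label[golden] <- "golden"
  } else {
    warning("mean fraction is 0; no golden/high spots possible")
  }
  label[auc == 0] <- "rest"   # precedence over all other rules
  res <- data.frame(spot = spots, cell_type = cell_type,
                    label = factor(label,
                                   levels = c("golden", "high", "low",
                                              "rest")),
                    auc = unname(auc), fraction = unname(frac),
                    auc_rank = auc_rank, deconv_rank = dec_rank,
                    stringsAsFactors = FALSE, row.names = NULL)
  class(res) <- c("SpotLabelTable", "data.frame")
  res
}

# Descending rank with deterministic lexicographic tie-break on spot id.
rank_desc <- function(x, ids) {
  ord <- order(-x, ids)
  r <- integer(length(x))
  r[ord] <- seq_along(x)
  r
}

#' Hexagonal neighbour graph of Visium-style spots
#'
#' Under the parity convention (`array_row + array_col` even), the six
#' neighbours of spot `(r, c)` are `(r, c - 2)`, `(r, c + 2)`,
#' `(r - 1, c - 1)`, `(r - 1, c + 1)`, `(r + 1, c - 1)`, `(r + 1, c + 1)`
#' — whichever are present. The graph is symmetric and interior spots
#' have exactly six neighbours.
#'
#' @param s a [SpotMatrix].
#' @return a `HexNeighborGraph`: named list mapping each spot id to the
#'   character vector of its neighbours' ids.
#' @export
hex_neighbors <- function(s) {
  stopifnot(inherits(s, "SpotMatrix"))
  pos <- s$positions
  key <- paste(pos$array_row, pos$array_col)
  if (anyDuplicated(key)) {
    stop_arg("s", "duplicate array coordinates")
  }
  lookup <- stats::setNames(pos$barcode, key)
  offs <- rbind(c(0, -2), c(0, 2), c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))
  out <- lapply(seq_len(nrow(pos)), function(i) {
    nk <- paste(pos$array_row[i] + offs[, 1], pos$array_col[i] + offs[, 2])
    unname(lookup[nk[nk %in% names(lookup)]])
  })
  names(out) <- pos$barcode
  structure(out, class = "HexNeighborGraph")
}

#' Co-localization of two cell-type signatures over spots of interest
#'
#' Restricts to the golden spots of `type_a` and correlates (Spearman) the
#' AUC of `type_a` with either the AUC of `type_b` in the same spots
#' (`mode = "same_spot"`) or the mean AUC of `type_b` over each golden
#' spot's present hex neighbours (`mode = "neighbor"`). Significance is
#' the standard large-sample t approximation; for `n <= 9` spots the
#' exact permutation distribution is used.
#'
#' @param scores a `SignatureScoreMatrix` with columns for both types.
#' @param labels a `SpotLabelTable` for `type_a` (see [label_spots()]).
#' @param graph a `HexNeighborGraph` (required for `mode = "neighbor"`).
#' @param type_a,type_b signature columns to correlate.
#' @param mode `"same_spot"` or `"neighbor"`.
#' @return list with `rho`, `p`, `n` (spots used) and `mode`.
#' @export
colocalization <- function(scores, labels, graph = NULL, type_a, type_b,
                           mode = c("same_spot", "neighbor")) {
  mode <- match.arg(mode)
  stopifnot(inherits(labels, "SpotLabelTable"))
  if (!all(c(type_a, type_b) %in% colnames(scores))) {
    stop_arg("scores", "must contain both signature columns")
  }
  golden <- labels$spot[labels$label == "golden" &
                          labels$cell_type == type_a]
  if (length(golden) < 4) {
    stop(sprintf("need >= 4 golden spots for %s (found %d)",
                 type_a, length(golden)), call. = FALSE)
  }
  xa <- scores[golden, type_a]
  if (mode == "same_spot") {
    xb <- scores[golden, type_b]
  } else {
    if (is.null(graph)) stop_arg("graph", "required for neighbor mode")
    xb <- vapply(golden, function(sp) {
      nb <- graph[[sp]]
      nb <- nb[nb %in% rownames(scores)]
      if (!length(nb)) return(NA_real_)
      mean(scores[nb, type_b])
    }, numeric(1))
    keep <- !is.na(xb)
    xa <- xa[keep]; xb <- xb[keep]
    if (length(xa) < 4) {
      stop("fewer than 4 golden spots with neighbours", call. = FALSE)
    }
  }
  if (stats::var(xa) == 0 || stats::var(xb) == 0) {
    stop("zero variance in a score vector; correlation undefined",
         call. = FALSE)
  }
  ct <- suppressWarnings(
    stats::cor.test(xa, xb, method = "spearman",
                    exact = length(xa) <= 9))
  list(rho = unname(ct$estimate), p = ct$p.value, n = length(xa),
       mode = mode)
}
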