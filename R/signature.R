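# AUC-based gene-signature scoring (recovery-curve area per cell/spot).

# Seeded tie-breaking permutation over genes, fixed once per matrix.
tie_break_order <- function(n_genes, seed) {
  with_seed(seed, sample.int(n_genes))
}

auc_from_ranks <- function(sig_ranks, T, n_sig) {
  hit <- sig_ranks[sig_ranks <= T]
  if (!length(hit)) return(0)
  sum(T - hit + 0.5) / (T * n_sig)
}

#' Signature activity of one expression vector (recovery-curve AUC)
#'
#' Ranks all genes by decreasing expression (ties broken by a fixed,
#' seeded random gene permutation), takes the top
#' `T = ceiling(top_fraction * n_genes)` ranks, and scores the signature
#' by the normalized area under its left-step recovery curve:
#' `AUC = sum over signature genes at rank r <= T of (T - r + 0.5)`
#' divided by `T * |signature in universe|` (1-based ranks). The score
#' lies in `[0, 1]`, is 0 when no signature gene reaches the top block,
#' and is invariant under strictly monotone transforms of the expression
#' values.
#'
#' @param expr named numeric vector of expression values (one cell/spot).
#' @param signature character vector of gene ids.
#' @param top_fraction fraction of the ranking treated as "expressed"
#'   (in `(0, 1]`).
#' @param tie_break integer permutation of the genes used to break ties
#'   (default: seeded from `seed`).
#' @param seed seed for the tie-breaking permutation when `tie_break` is
#'   not supplied.
#' @return the AUC (single number in `[0, 1]`).
#' @export
auc_score <- function(expr, signature, top_fraction = 0.05,
                      tie_break = NULL, seed = 0L) {
  if (is.null(names(expr))) stop_arg("expr", "must be a named vector")
  top_fraction <- check_fraction(top_fraction, "top_fraction",
                                 lo_open = TRUE)
  n <- length(expr)
  sig <- intersect(unique(signature), names(expr))
  if (!length(sig)) {
    warning("signature shares no genes with the universe; score 0")
    return(0)
  }
  if (is.null(tie_break)) tie_break <- tie_break_order(n, seed)
  ord <- order(-expr, tie_break)
  ranks <- integer(n)
  ranks[ord] <- seq_len(n)
  names(ranks) <- names(expr)
  T <- ceiling(top_fraction * n)
  auc_from_ranks(ranks[sig], T, length(sig))
}

#' Signature scores for every column of a normalized matrix
#'
#' Applies [auc_score()] column-wise for each gene set; one tie-breaking
#' permutation (seeded) is drawn per matrix and shared by all columns, so
#' scoring is deterministic given the seed.
#'
#' @param m a normalized [CellMatrix] / [SpotMatrix], or a genes x
#'   columns numeric matrix.
#' @param sets named list of gene signatures.
#' @param top_fraction see [auc_score()].
#' @param seed seed for the tie-breaking permutation.
#' @return a `SignatureScoreMatrix`: columns (cells/spots) x gene sets
#'   numeric matrix of AUC values, with attribute `top_fraction`.
#' @export
score_matrix <- function(m, sets, top_fraction = 0.05, seed = 0L) {
  x <- if (inherits(m, "CellMatrix") || inherits(m, "SpotMatrix")) {
    if (is.null(m$logcounts)) {
      stop("normalize with normalize_log1p() first", call. = FALSE)
    }
    m$logcounts
  } else m
  if (is.null(names(sets)) || !length(sets)) {
    stop_arg("sets", "must be a named list of signatures")
  }
  top_fraction <- check_fraction(top_fraction, "top_fraction",
                                 lo_open = TRUE)
  genes <- rownames(x)
  n <- length(genes)
  T <- ceiling(top_fraction * n)
  tie_break <- tie_break_order(n, seed)
  sig_idx <- lapply(sets, function(s) {
    idx <- match(intersect(unique(s), genes), genes)
    idx[!is.na(idx)]
  })
  empty <- vapply(sig_idx, length, 1L) == 0
  if (any(empty)) {
    warning(sprintf("signature(s) with no genes in the universe: %s",
                    paste(names(sets)[empty], collapse = ", ")))
  }
  xd <- as.matrix(x)
  out <- matrix(0, ncol(xd), length(sets),
                dimnames = list(colnames(xd), names(sets)))
  for (j in seq_len(ncol(xd))) {
    ord <- order(-xd[, j], tie_break)
    ranks <- integer(n)
    ranks[ord] <- seq_len(n)
    for (s in seq_along(sets)) {
      if (empty[s]) next
      out[j, s] <- auc_from_ranks(ranks[sig_idx[[s]]], T,
                                  length(sig_idx[[s]]))
    }
  }
  structure(out, top_fraction = top_fraction, class = c("SignatureScoreMatrix",
                                                        class(out)))
}
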