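# Differential cell-type abundance between two conditions.

# Extract a (condition x type) count table from a CellMatrix or a
# metadata-like data.frame with condition / cell_type columns.
abundance_counts <- function(m, type_col = "cell_type") {
  meta <- if (inherits(m, "CellMatrix")) m$cell_meta else m
  if (!is.data.frame(meta) || is.null(meta$condition) ||
      is.null(meta[[type_col]])) {
    stop_arg("m", "needs per-cell `condition` and cell-type labels")
  }
  cond <- factor(as.character(meta$condition), levels = c("young", "aged"))
  if (anyNA(cond)) stop_arg("m", "condition must be young/aged")
  if (nlevels(droplevels(cond)) < 2) {
    stop("both conditions must be present", call. = FALSE)
  }
  type <- as.character(meta[[type_col]])
  tab <- table(type, cond)
  empty <- rowSums(tab) == 0
  if (any(empty)) {
    warning(sprintf("dropping type(s) absent from both conditions: %s",
                    paste(rownames(tab)[empty], collapse = ", ")))
    tab <- tab[!empty, , drop = FALSE]
  }
  tab
}

# log2 of the aged/young proportion ratio with a 0.5 add-on to BOTH counts
# of a ratio whose numerator or denominator count is zero.
log2fd_from_counts <- function(n_aged, n_young, N_aged, N_young) {
  corr <- n_aged == 0 | n_young == 0
  na <- ifelse(corr, n_aged + 0.5, n_aged)
  ny <- ifelse(corr, n_young + 0.5, n_young)
  list(log2fd = log2((na / N_aged) / (ny / N_young)), corrected = corr)
}

#' Permutation test for differential cell-type abundance
#'
#' For every cell type, compares its proportion between aged and young
#' cells via the log2 fold difference
#' `log2FD = log2((n_aged/N_aged) / (n_young/N_young))` and a permutation
#' null obtained by reassigning condition labels across all cells while
#' preserving the two condition sizes. The two-sided p-value uses the
#' add-one estimator `p = (1 + #{|log2FD*| >= |log2FD|}) / (1 + n_perm)`,
#' so p is never exactly zero; p-values are BH-adjusted across types, and
#' a type is flagged significant when `FDR < 0.05` and `|log2FD| > 1`.
#' Types with a zero count in one condition get a 0.5 continuity add-on
#' (both counts of that ratio) and are flagged in `zero_corrected`.
#'
#' The null is sampled exactly, type by type, through nested hypergeometric
#' draws of the permuted aged counts — the marginal distribution of a label
#' shuffle with fixed condition sizes.
#'
#' @param m a [CellMatrix], or a data.frame with `condition` and
#'   `cell_type` columns.
#' @param n_perm number of label permutations.
#' @param seed integer seed (`NULL` = use current RNG state).
#' @param fdr_alpha,log2fd_cut thresholds of the significance rule.
#' @return an `AbundanceTable` data.frame with one row per type:
#'   `n_young`, `n_aged`, `prop_young`, `prop_aged`, `log2FD`, `perm_p`,
#'   `FDR`, `OR`, `OR_CI_low`, `OR_CI_high`, `zero_corrected`,
#'   `significant`.
#' @export
permutation_abundance <- function(m, n_perm = 1000, seed = NULL,
                                  fdr_alpha = 0.05, log2fd_cut = 1) {
  n_perm <- check_count(n_perm, "n_perm")
  tab <- abundance_counts(m)
  n_young <- as.numeric(tab[, "young"])
  n_aged <- as.numeric(tab[, "aged"])
  N_young <- sum(n_young)
  N_aged <- sum(n_aged)
  totals <- n_young + n_aged
  obs <- log2fd_from_counts(n_aged, n_young, N_aged, N_young)

  with_seed(seed, {
    perm_aged <- rmvhyper_counts(n_perm, totals, N_aged)  # types x n_perm
  })
  perm_young <- totals - perm_aged
  perm_fd <- log2fd_from_counts(perm_aged, perm_young, N_aged, N_young)
  exceed <- rowSums(matrix(abs(perm_fd$log2fd), nrow = length(totals)) >=
                      abs(obs$log2fd) - 1e-12)
  perm_p <- (1 + exceed) / (1 + n_perm)
  fdr <- stats::p.adjust(perm_p, method = "BH")

  or <- t(vapply(seq_along(totals), function(k) {
    unlist(odds_ratio(n_aged[k], N_aged - n_aged[k],
                      n_young[k], N_young - n_young[k])[
                        c("OR", "CI_low", "CI_high")])
  }, numeric(3)))

  res <- data.frame(
    cell_type = rownames(tab),
    n_young = n_young, n_aged = n_aged,
    prop_young = n_young / N_young, prop_aged = n_aged / N_aged,
    log2FD = obs$log2fd, perm_p = perm_p, FDR = fdr,
    OR = or[, 1], OR_CI_low = or[, 2], OR_CI_high = or[, 3],
    zero_corrected = obs$corrected,
    significant = fdr < fdr_alpha & abs(obs$log2fd) > log2fd_cut,
    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  class(res) <- c("AbundanceTable", "data.frame")
  res
}

#' Condition-balanced bootstrap intervals for type proportions
#'
#' In each iteration an equal number of cells —
#' `min(N_young, N_aged)` — is resampled from each condition
#' (with replacement by default, i.e. a bootstrap), per-type proportions
#' and the log2 fold difference are recomputed, and 95% intervals are the
#' 2.5/97.5 linear-interpolation percentiles across iterations.
#'
#' @param m a [CellMatrix] or metadata data.frame (see
#'   [permutation_abundance()]).
#' @param n_iter bootstrap iterations (>= 2).
#' @param seed integer seed.
#' @param replace resample with replacement (`TRUE`, bootstrap) or draw a
#'   subsample without replacement (`FALSE`).
#' @param conf confidence level of the percentile interval.
#' @return data.frame per type: `prop_young_lo/hi`, `prop_aged_lo/hi`,
#'   `log2FD_lo`, `log2FD_hi`, plus the point `log2FD` on the full data.
#' @export
donor_balanced_bootstrap <- function(m, n_iter = 100, seed = NULL,
                                     replace = TRUE, conf = 0.95) {
  if (length(n_iter) != 1 || n_iter < 2) {
    stop_arg("n_iter", "must be >= 2")
  }
  n_iter <- check_count(n_iter, "n_iter", min = 2)
  conf <- check_fraction(conf, "conf", lo_open = TRUE, hi_open = TRUE)
  meta <- if (inherits(m, "CellMatrix")) m$cell_meta else m
  tab <- abundance_counts(meta)
  types <- rownames(tab)
  type <- factor(as.character(meta$cell_type), levels = types)
  cond <- as.character(meta$condition)
  keep <- !is.na(type)
  type <- type[keep]; cond <- cond[keep]
  iy <- which(cond == "young")
  ia <- which(cond == "aged")
  n_bal <- min(length(iy), length(ia))

  obs <- log2fd_from_counts(as.numeric(tab[, "aged"]),
                            as.numeric(tab[, "young"]),
                            sum(tab[, "aged"]), sum(tab[, "young"]))

  k <- length(types)
  py <- pa <- fd <- matrix(NA_real_, n_iter, k)
  with_seed(seed, {
    for (b in seq_len(n_iter)) {
      sy <- tabulate(type[sample(iy, n_bal, replace = replace)], nbins = k)
      sa <- tabulate(type[sample(ia, n_bal, replace = replace)], nbins = k)
      py[b, ] <- sy / n_bal
      pa[b, ] <- sa / n_bal
      fd[b, ] <- log2fd_from_counts(sa, sy, n_bal, n_bal)$log2fd
    }
  })
  a <- (1 - conf) / 2
  qs <- function(x) stats::quantile(x, c(a, 1 - a), type = 7, names = FALSE)
  ql <- apply(fd, 2, qs)
  qy <- apply(py, 2, qs)
  qa <- apply(pa, 2, qs)
  data.frame(cell_type = types,
             log2FD = obs$log2fd,
             log2FD_lo = ql[1, ], log2FD_hi = ql[2, ],
             prop_young_lo = qy[1, ], prop_young_hi = qy[2, ],
             prop_aged_lo = qa[1, ], prop_aged_hi = qa[2, ],
             n_balanced = n_bal,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Odds ratio of type membership, aged vs young
#'
#' `OR = (n_k_aged / n_other_aged) / (n_k_young / n_other_young)` with a
#' Woolf (log-normal) confidence interval
#' `exp(ln OR +/- z * sqrt(sum of reciprocal cells))`. If any cell of the
#' 2x2 table is zero, the Haldane-Anscombe correction adds 0.5 to all four
#' cells (flagged in `corrected`).
#'
#' @param n_k_aged,n_other_aged,n_k_young,n_other_young the 2x2 counts:
#'   cells of the type / of all other types, in aged / young.
#' @param conf confidence level.
#' @return list with `OR`, `CI_low`, `CI_high`, `corrected`.
#' @export
odds_ratio <- function(n_k_aged, n_other_aged, n_k_young, n_other_young,
                       conf = 0.95) {
  cells <- c(n_k_aged, n_other_aged, n_k_young, n_other_young)
  if (any(!is.finite(cells)) || any(cells < 0)) {
    stop_arg("counts", "must be non-negative")
  }
  if ((n_k_aged + n_k_young == 0) || (n_other_aged + n_other_young == 0) ||
      (n_k_aged + n_other_aged == 0) || (n_k_young + n_other_young == 0)) {
    stop("odds ratio undefined: a margin of the 2x2 table is zero",
         call. = FALSE)
  }
  corrected <- any(cells == 0)
  if (corrected) cells <- cells + 0.5
  or <- (cells[1] / cells[2]) / (cells[3] / cells[4])
  z <- stats::qnorm(1 - (1 - conf) / 2)
  se <- sqrt(sum(1 / cells))
  list(OR = or,
       CI_low = exp(log(or) - z * se),
       CI_high = exp(log(or) + z * se),
       corrected = corrected)
}
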