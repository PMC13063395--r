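# Internal helpers shared across modules.

#' @importFrom withr local_seed
#' @importFrom methods as is
#' @importFrom stats quantile rgamma rlnorm rpois runif rhyper p.adjust
#'   phyper pbeta wilcox.test cor.test prcomp kmeans rbinom setNames
#'   qnorm uniroot cor var
#' @importFrom utils read.delim write.table read.csv write.csv head
NULL

# Evaluate `expr` under a fixed RNG state without disturbing the caller's
# stream; seed = NULL leaves the RNG alone.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
    withr::local_seed(as.integer(seed))
  }
  expr
}

stop_arg <- function(name, msg) {
  stop(sprintf("invalid `%s`: %s", name, msg), call. = FALSE)
}

check_count <- function(x, name, min = 1) {
  if (length(x) != 1L || !is.numeric(x) || !is.finite(x) ||
      x < min || x != round(x)) {
    stop_arg(name, sprintf("must be a single integer >= %s", min))
  }
  as.integer(x)
}

check_fraction <- function(x, name, lo = 0, hi = 1,
                           lo_open = FALSE, hi_open = FALSE) {
  ok <- length(x) == 1L && is.numeric(x) && is.finite(x) &&
    (if (lo_open) x > lo else x >= lo) &&
    (if (hi_open) x < hi else x <= hi)
  if (!ok) {
    stop_arg(name, sprintf("must be a single number in %s%s, %s%s",
                           if (lo_open) "(" else "[", lo, hi,
                           if (hi_open) ")" else "]"))
  }
  as.numeric(x)
}

check_positive <- function(x, name) {
  if (!is.numeric(x) || !all(is.finite(x)) || any(x <= 0)) {
    stop_arg(name, "must be finite and strictly positive")
  }
  as.numeric(x)
}

# Sparse column sums / per-column detected-gene counts on a dgCMatrix.
col_totals <- function(m) Matrix::colSums(m)
col_features <- function(m) Matrix::colSums(m > 0)

# Counts of condition-k cells per type under random reassignment of
# `n_draw` "aged" labels among all cells, marginally per type: nested
# hypergeometric sampling, exact equivalent of a label permutation.
# Returns a matrix of n_types x n_perm aged counts.
rmvhyper_counts <- function(n_perm, type_totals, n_draw) {
  k <- length(type_totals)
  out <- matrix(0L, nrow = k, ncol = n_perm)
  remaining_pop <- sum(type_totals)
  remaining_draw <- rep.int(n_draw, n_perm)
  for (i in seq_len(k - 1L)) {
    m_i <- type_totals[i]
    out[i, ] <- stats::rhyper(n_perm, m = m_i,
                              n = remaining_pop - m_i, k = remaining_draw)
    remaining_draw <- remaining_draw - out[i, ]
    remaining_pop <- remaining_pop - m_i
  }
  out[k, ] <- remaining_draw
  out
}

# Dirichlet draws: n x length(alpha) matrix of simplex rows.
rdirichlet <- function(n, alpha) {
  g <- matrix(stats::rgamma(n * length(alpha), shape = alpha, rate = 1),
              nrow = n, byrow = TRUE)
  g / rowSums(g)
}
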