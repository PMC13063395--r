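# In-code fixtures shared across test files.

# Tiny CellMatrix with explicit counts and metadata.
toy_cell_matrix <- function(counts, donor = NULL, condition = NULL,
                            cell_type = NULL) {
  n <- ncol(counts)
  meta <- data.frame(
    donor_id = donor %||% rep("d1", n),
    condition = condition %||% rep(c("young", "aged"), length.out = n),
    stringsAsFactors = FALSE)
  if (!is.null(cell_type)) meta$cell_type <- cell_type
  CellMatrix(counts, meta)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# A metadata-only data.frame for abundance tests: counts per type and
# condition expand into one row per cell.
abundance_meta <- function(young_counts, aged_counts) {
  types <- names(young_counts)
  data.frame(
    donor_id = "d",
    condition = rep(c("young", "aged"),
                    c(sum(young_counts), sum(aged_counts))),
    cell_type = c(rep(types, young_counts), rep(types, aged_counts)),
    stringsAsFactors = FALSE)
}

# Dense random count matrix with dimnames.
random_counts <- function(n_genes, n_cells, lambda = 2, seed = 1) {
  withr::with_seed(seed, {
    m <- matrix(rpois(n_genes * n_cells, lambda), n_genes, n_cells)
  })
  dimnames(m) <- list(sprintf("g%03d", seq_len(n_genes)),
                      sprintf("c%03d", seq_len(n_cells)))
  m
}

# Two clearly separated expression groups for clustering tests: types
# differ in disjoint high-expression gene blocks.
separated_types_matrix <- function(n_per_type = 60, n_genes = 60,
                                   n_donors = 3, boost = 30, seed = 7) {
  withr::with_seed(seed, {
    half <- n_genes %/% 2
    mk <- function(hot) {
      mu <- rep(1, n_genes)
      mu[hot] <- boost
      matrix(rpois(n_genes * n_per_type, mu), n_genes, n_per_type)
    }
    counts <- cbind(mk(seq_len(half)), mk(half + seq_len(n_genes - half)))
    dimnames(counts) <- list(sprintf("g%02d", seq_len(n_genes)),
                             sprintf("c%03d", seq_len(2 * n_per_type)))
    toy_cell_matrix(
      counts,
      donor = rep(sprintf("d%d", seq_len(n_donors)),
                  length.out = 2 * n_per_type),
      condition = "young",
      cell_type = rep(c("A", "B"), each = n_per_type))
  })
}

# Brute-force recovery-curve AUC: trapezoidal integration of the step
# curve y(t) = #signature genes with rank <= t on the integer grid 0..T,
# normalized by T * |signature|. Independent of the package formula.
brute_force_auc <- function(expr, signature, top_fraction, tie_break) {
  n <- length(expr)
  ord <- order(-expr, tie_break)
  ranks <- integer(n)
  ranks[ord] <- seq_len(n)
  names(ranks) <- names(expr)
  T <- ceiling(top_fraction * n)
  sig <- intersect(signature, names(expr))
  y <- vapply(0:T, function(t) sum(ranks[sig] <= t), numeric(1))
  pracma::trapz(0:T, y) / (T * length(sig))
}
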