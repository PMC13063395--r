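# Clustering stability via donor-balanced downsampling.

#' Donor-balanced downsampling of cells
#'
#' Samples `min(cells_per_donor, n_donor)` cells without replacement from
#' every donor; donors with fewer than `cells_per_donor` cells contribute
#' all their cells and are flagged in the `short_donors` attribute.
#'
#' @param m a [CellMatrix].
#' @param cells_per_donor target cells per donor (>= 1).
#' @param seed integer seed.
#' @return the downsampled [CellMatrix]; attribute `short_donors` lists
#'   donors that could not supply `cells_per_donor` cells.
#' @export
donor_balanced_downsample <- function(m, cells_per_donor, seed = NULL) {
  stopifnot(inherits(m, "CellMatrix"))
  cells_per_donor <- check_count(cells_per_donor, "cells_per_donor")
  donors <- split(seq_len(ncol(m$counts)), m$cell_meta$donor_id)
  with_seed(seed, {
    picked <- lapply(donors, function(idx) {
      if (length(idx) <= cells_per_donor) idx
      else sample(idx, cells_per_donor)
    })
  })
  short <- names(donors)[vapply(donors, length, 1L) < cells_per_donor]
  out <- subset_cells(m, sort(unlist(picked, use.names = FALSE)))
  attr(out, "short_donors") <- short
  out
}

#' Default reclustering backend: PCA + k-means on variable genes
#'
#' A deterministic, pluggable clustering contract: given a seed it returns
#' one integer label per cell. The default pipeline is log1p-CPM
#' normalization, selection of the 2,000 most variable genes, PCA to
#' `n_pcs` components, and seeded k-means with `k` centers. Any function
#' `(m, k, seed) -> labels` honouring the contract may replace it in
#' [cluster_stability()].
#'
#' @param m a [CellMatrix] (raw counts suffice; normalized internally).
#' @param k number of clusters (`k = 1` returns a single label).
#' @param n_pcs number of principal components.
#' @param n_var_genes number of most-variable genes retained.
#' @param seed integer seed.
#' @return integer vector of cluster labels, named by cell id.
#' @export
recluster <- function(m, k, n_pcs = 20, n_var_genes = 2000, seed = NULL) {
  stopifnot(inherits(m, "CellMatrix"))
  k <- check_count(k, "k")
  n_cells <- ncol(m$counts)
  if (k > n_cells) stop_arg("k", "cannot exceed the number of cells")
  if (k == 1) {
    return(stats::setNames(rep(1L, n_cells), colnames(m$counts)))
  }
  mm <- normalize_log1p(m)
  x <- as.matrix(mm$logcounts)
  v <- apply(x, 1, stats::var)
  keep <- order(v, decreasing = TRUE)[seq_len(min(n_var_genes, nrow(x)))]
  x <- t(x[keep, , drop = FALSE])
  n_pcs <- min(n_pcs, ncol(x) - 1L, nrow(x) - 1L)
  pcs <- stats::prcomp(x, rank. = n_pcs, center = TRUE, scale. = FALSE)$x
  with_seed(seed, {
    km <- stats::kmeans(pcs, centers = k, nstart = 10, iter.max = 50)
  })
  stats::setNames(as.integer(km$cluster), colnames(m$counts))
}

#' Best-match Jaccard similarity per original cluster
#'
#' For each cluster of the original partition, the maximum Jaccard index
#' `|A intersect B| / |A union B|` over all clusters of the recomputed
#' partition. Both labelings must cover the same cells (matched by name
#' when named).
#'
#' @param original,recomputed label vectors over the same cell universe.
#' @return named numeric vector: best-match Jaccard per original cluster.
#' @export
jaccard_match <- function(original, recomputed) {
  al <- align_partitions(original, recomputed)
  tab <- table(al$u, al$v)
  size_u <- rowSums(tab)
  size_v <- colSums(tab)
  jac <- tab / (outer(size_u, size_v, `+`) - tab)
  apply(jac, 1, max)
}

#' Adjusted Rand Index between two partitions
#'
#' Chance-corrected pair-counting agreement under the permutation model:
#' `(Index - Expected) / (Max - Expected)` from the contingency table of
#' the two labelings. 1 means identical partitions up to relabeling;
#' independent partitions score near 0.
#'
#' @param original,recomputed label vectors over the same cell universe.
#' @return the ARI (a single number in `[-1, 1]`).
#' @export
adjusted_rand <- function(original, recomputed) {
  al <- align_partitions(original, recomputed)
  n <- length(al$u)
  if (n < 2) stop("ARI undefined for fewer than 2 items", call. = FALSE)
  tab <- table(al$u, al$v)
  a <- sum(choose(tab, 2))
  b <- sum(choose(rowSums(tab), 2))
  cc <- sum(choose(colSums(tab), 2))
  nn <- choose(n, 2)
  expected <- b * cc / nn
  maximum <- (b + cc) / 2
  if (maximum == expected) return(1)  # both partitions trivial
  (a - expected) / (maximum - expected)
}

align_partitions <- function(u, v) {
  if (!is.null(names(u)) && !is.null(names(v))) {
    common <- intersect(names(u), names(v))
    if (!length(common)) {
      stop("partitions share no cells", call. = FALSE)
    }
    u <- u[common]; v <- v[common]
  } else if (length(u) != length(v)) {
    stop("unnamed partitions must have equal length", call. = FALSE)
  }
  list(u = as.character(u), v = as.character(v))
}

#' Clustering-stability analysis over balanced downsampling iterations
#'
#' Repeats, `n_iter` times: donor-balanced downsampling
#' ([donor_balanced_downsample()]), reclustering of the subset, and
#' comparison of the recomputed partition with the original labels on the
#' downsampled cells via per-cluster best-match Jaccard and the ARI.
#'
#' @param m a [CellMatrix] with a label column in `cell_meta`.
#' @param label_col metadata column holding the original cluster labels.
#' @param cells_per_donor cells sampled per donor each iteration.
#' @param n_iter number of iterations.
#' @param k clusters for reclustering (default: number of original labels).
#' @param cluster_fun clustering backend `(m, k, seed) -> labels`
#'   (default [recluster()]).
#' @param seed integer seed; iteration `b` uses `seed + b`.
#' @return a `StabilityReport` list: `jaccard` (data.frame iteration x
#'   cluster long form), `ari` (per-iteration vector), `summary`
#'   (per-cluster mean/min Jaccard and mean ARI).
#' @export
cluster_stability <- function(m, label_col = "cell_type",
                              cells_per_donor = 50, n_iter = 100,
                              k = NULL, cluster_fun = recluster,
                              seed = 0L) {
  stopifnot(inherits(m, "CellMatrix"))
  labels <- m$cell_meta[[label_col]]
  if (is.null(labels)) stop_arg("label_col", "not found in cell_meta")
  labels <- stats::setNames(as.character(labels), colnames(m$counts))
  if (is.null(k)) k <- length(unique(labels))
  n_iter <- check_count(n_iter, "n_iter")
  seed <- check_count(seed, "seed", min = 0)

  jac_rows <- vector("list", n_iter)
  ari <- numeric(n_iter)
  for (b in seq_len(n_iter)) {
    sub <- donor_balanced_downsample(m, cells_per_donor, seed = seed + b)
    new_lab <- cluster_fun(sub, k = k, seed = seed + b)
    orig_sub <- labels[colnames(sub$counts)]
    jj <- jaccard_match(orig_sub, new_lab)
    ari[b] <- adjusted_rand(orig_sub, new_lab)
    jac_rows[[b]] <- data.frame(iteration = b, cluster = names(jj),
                                jaccard = unname(jj),
                                stringsAsFactors = FALSE)
  }
  jac <- do.call(rbind, jac_rows)
  summ <- do.call(rbind, lapply(split(jac$jaccard, jac$cluster), function(x) {
    data.frame(mean_jaccard = mean(x), min_jaccard = min(x))
  }))
  summ$cluster <- rownames(summ)
  rownames(summ) <- NULL
  structure(list(jaccard = jac, ari = ari,
                 summary = list(per_cluster = summ, mean_ari = mean(ari))),
            class = "StabilityReport")
}

#' @export
print.StabilityReport <- function(x, ...) {
  cat(sprintf("StabilityReport: %d iterations | mean ARI %.3f\n",
              length(x$ari), x$summary$mean_ari))
  invisible(x)
}
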