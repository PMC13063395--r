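# Bootstrapped ligand-receptor prioritization: balanced subsampling, three
# scoring methods, robust rank aggregation, frequency + curation filters.

#' Cell-type-balanced subsampling
#'
#' Downsamples every cell type, without replacement, to the minimum type
#' count, removing abundance biases before ligand-receptor scoring. Types
#' listed in `types` but absent from the data are dropped with a warning.
#'
#' @param m a [CellMatrix] with `cell_type` metadata.
#' @param seed integer seed.
#' @param types optional subset of cell types to keep.
#' @return the balanced [CellMatrix] (equal cells per type).
#' @export
balanced_subsample <- function(m, seed = NULL, types = NULL) {
  stopifnot(inherits(m, "CellMatrix"))
  ct <- as.character(m$cell_meta$cell_type)
  if (is.null(ct)) stop_arg("m", "cell_type metadata required")
  if (!is.null(types)) {
    missing_t <- setdiff(types, unique(ct))
    if (length(missing_t)) {
      warning(sprintf("dropping type(s) with 0 cells: %s",
                      paste(missing_t, collapse = ", ")))
    }
    keep <- ct %in% types
    m <- subset_cells(m, which(keep))
    ct <- ct[keep]
  }
  groups <- split(seq_along(ct), ct)
  if (length(groups) < 2) stop("need >= 2 cell types", call. = FALSE)
  n_min <- min(vapply(groups, length, 1L))
  with_seed(seed, {
    picked <- lapply(groups, function(idx) {
      if (length(idx) == n_min) idx else sample(idx, n_min)
    })
  })
  subset_cells(m, sort(unlist(picked, use.names = FALSE)))
}

# Split complex names ("A_B") into member genes.
complex_members <- function(x) strsplit(x, "_", fixed = TRUE)

#' Ligand-receptor scores for every (sender, receiver, pair) triple
#'
#' Computes three fully specified interaction scores on a normalized,
#' type-balanced cell matrix, for all ordered sender-receiver type pairs
#' and every resource pair whose genes are present:
#' \itemize{
#'   \item `perm_p`: mean-rank permutation p-value of
#'     `stat = (mean ligand in sender + mean receptor in receiver) / 2`
#'     under `n_perm` cell-type-label shuffles (add-one estimator);
#'   \item `specificity`:
#'     `(mean_L,sender / sum_types mean_L) * (mean_R,receiver / sum_types mean_R)`;
#'   \item `lr_score`: `sqrt(l r) / (sqrt(l r) + mu)` with `l`, `r` the
#'     group means and `mu` the global mean of the normalized matrix.
#' }
#' Multi-subunit complexes (members separated by `"_"`) use the minimum
#' over member genes at the group-mean level. Resource pairs with absent
#' genes are dropped and reported in the `dropped_pairs` attribute.
#'
#' @param m a normalized [CellMatrix] (see [balanced_subsample()]).
#' @param resource an `LRResource` data.frame (`ligand`, `receptor`, ...).
#' @param n_perm label permutations (>= 10).
#' @param seed integer seed.
#' @return data.frame per (sender, receiver, ligand, receptor):
#'   `perm_p`, `specificity`, `lr_score`.
#' @export
score_lr_methods <- function(m, resource, n_perm = 500, seed = NULL) {
  stopifnot(inherits(m, "CellMatrix"))
  if (is.null(m$logcounts)) {
    stop("normalize with normalize_log1p() first", call. = FALSE)
  }
  if (n_perm < 10) stop_arg("n_perm", "must be >= 10")
  n_perm <- check_count(n_perm, "n_perm")
  genes <- rownames(m$logcounts)
  lig_mem <- complex_members(resource$ligand)
  rec_mem <- complex_members(resource$receptor)
  present <- vapply(seq_len(nrow(resource)), function(i) {
    all(c(lig_mem[[i]], rec_mem[[i]]) %in% genes)
  }, logical(1))
  dropped <- resource[!present, c("ligand", "receptor")]
  resource <- resource[present, , drop = FALSE]
  lig_mem <- lig_mem[present]; rec_mem <- rec_mem[present]
  if (!nrow(resource)) stop("no resource pair has genes in the matrix",
                            call. = FALSE)

  ct <- factor(as.character(m$cell_meta$cell_type))
  types <- levels(ct)
  K <- length(types)
  n_per_type <- as.numeric(table(ct))
  used_genes <- unique(unlist(c(lig_mem, rec_mem)))
  X <- m$logcounts[used_genes, , drop = FALSE]
  mu_global <- mean(m$logcounts@x) * length(m$logcounts@x) /
    prod(dim(m$logcounts))

  group_means <- function(labels_int) {
    ind <- Matrix::sparseMatrix(i = seq_along(labels_int), j = labels_int,
                                x = 1, dims = c(length(labels_int), K))
    as.matrix(X %*% ind) %*% diag(1 / n_per_type, K)
  }
  # minimum over complex members, rows = unique complexes; single-member
  # complexes are a plain row lookup
  complex_means <- function(gm, members, keys) {
    u <- which(!duplicated(keys))
    sizes <- lengths(members[u])
    if (all(sizes == 1L)) {
      out <- gm[unlist(members[u]), , drop = FALSE]
    } else {
      out <- t(vapply(u, function(i) {
        rows <- gm[members[[i]], , drop = FALSE]
        apply(rows, 2, min)
      }, numeric(K)))
    }
    rownames(out) <- keys[u]
    out
  }

  lig_key <- resource$ligand
  rec_key <- resource$receptor
  pairs <- expand.grid(sender = types, receiver = types,
                       pair = seq_len(nrow(resource)),
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  obs_gm <- group_means(as.integer(ct))
  rownames(obs_gm) <- used_genes
  Lm <- complex_means(obs_gm, lig_mem, lig_key)
  Rm <- complex_means(obs_gm, rec_mem, rec_key)
  s_i <- match(pairs$sender, types)
  r_i <- match(pairs$receiver, types)
  l_obs <- Lm[cbind(match(lig_key[pairs$pair], rownames(Lm)), s_i)]
  r_obs <- Rm[cbind(match(rec_key[pairs$pair], rownames(Rm)), r_i)]
  stat_obs <- (l_obs + r_obs) / 2

  l_tot <- rowSums(Lm)[match(lig_key[pairs$pair], rownames(Lm))]
  r_tot <- rowSums(Rm)[match(rec_key[pairs$pair], rownames(Rm))]
  spec <- ifelse(l_tot > 0, l_obs / l_tot, 0) *
    ifelse(r_tot > 0, r_obs / r_tot, 0)
  g <- sqrt(l_obs * r_obs)
  lr_score <- ifelse(g > 0, g / (g + mu_global), 0)

  exceed <- numeric(nrow(pairs))
  with_seed(seed, {
    labels_int <- as.integer(ct)
    li <- match(lig_key[pairs$pair], rownames(Lm))
    ri <- match(rec_key[pairs$pair], rownames(Rm))
    for (b in seq_len(n_perm)) {
      gm <- group_means(sample(labels_int))
      rownames(gm) <- used_genes
      Lb <- complex_means(gm, lig_mem, lig_key)
      Rb <- complex_means(gm, rec_mem, rec_key)
      stat_b <- (Lb[cbind(li, s_i)] + Rb[cbind(ri, r_i)]) / 2
      exceed <- exceed + (stat_b >= stat_obs - 1e-12)
    }
  })
  res <- data.frame(sender = pairs$sender, receiver = pairs$receiver,
                    ligand = lig_key[pairs$pair],
                    receptor = rec_key[pairs$pair],
                    perm_p = (1 + exceed) / (1 + n_perm),
                    specificity = spec, lr_score = lr_score,
                    stringsAsFactors = FALSE)
  attr(res, "dropped_pairs") <- dropped
  res
}

#' Robust rank aggregation of method scores
#'
#' Ranks all interactions per method (ascending `perm_p`; descending
#' `specificity` and `lr_score`), converts ranks to normalized ranks in
#' `(0, 1]`, and combines them with the robust-rank-aggregation order
#' statistic: for sorted normalized ranks `r_(1) <= ... <= r_(m)`,
#' `rho = m * min_k BetaCDF(r_(k); k, m - k + 1)`, capped at 1.
#' Interactions ranked consistently well by all methods get small `rho`.
#'
#' @param scores output of [score_lr_methods()].
#' @param methods score columns to aggregate (prefix `perm_p` ascending).
#' @return `scores` with an `aggregate_rank` column appended.
#' @export
aggregate_rank <- function(scores,
                           methods = c("perm_p", "specificity",
                                       "lr_score")) {
  if (!is.data.frame(scores) || !nrow(scores)) {
    stop_arg("scores", "must be a non-empty data.frame")
  }
  methods <- intersect(methods, names(scores))
  if (!length(methods)) stop_arg("methods", "none present in scores")
  n <- nrow(scores)
  rank_mat <- vapply(methods, function(mth) {
    x <- scores[[mth]]
    r <- if (mth == "perm_p") rank(x, ties.method = "average")
         else rank(-x, ties.method = "average")
    r / n
  }, numeric(n))
  rank_mat <- matrix(rank_mat, nrow = n)
  m <- ncol(rank_mat)
  rho <- apply(rank_mat, 1, function(r) {
    r <- sort(r)
    min(stats::pbeta(r, seq_len(m), m - seq_len(m) + 1))
  })
  scores$aggregate_rank <- pmin(1, rho * m)
  scores
}

lr_key <- function(df) {
  paste(df$sender, df$receiver, df$ligand, df$receptor, sep = "|")
}

#' Bootstrapped ligand-receptor prioritization
#'
#' Repeats, for `n_iter` bootstrap iterations: cell-type-balanced
#' subsampling ([balanced_subsample()]), method scoring
#' ([score_lr_methods()]), rank aggregation ([aggregate_rank()]), and
#' recording of every interaction with `aggregate_rank < rank_cut`. The
#' bootstrap frequency of each ever-recovered interaction is its fraction
#' of recovering iterations; interactions at or above the
#' `freq_percentile` quantile (linear interpolation) of the frequency
#' distribution are retained as robust.
#'
#' @param m a normalized [CellMatrix] with `cell_type` metadata.
#' @param resource an `LRResource`.
#' @param n_iter bootstrap iterations.
#' @param rank_cut aggregate-rank specificity cutoff.
#' @param freq_percentile percentile of the bootstrap-frequency
#'   distribution used as the robustness threshold (`>=` semantics, so
#'   ties at the maximum frequency are never all discarded).
#' @param n_perm label permutations inside each iteration.
#' @param seed integer seed; iteration `b` uses `seed + b`.
#' @return an `LRTable` data.frame over ever-recovered interactions:
#'   `sender`, `receiver`, `ligand`, `receptor`, `bootstrap_frequency`,
#'   `mean_aggregate_rank`, `retained`; attribute `freq_threshold`.
#' @export
bootstrap_prioritize <- function(m, resource, n_iter = 100,
                                 rank_cut = 0.01, freq_percentile = 0.95,
                                 n_perm = 500, seed = 0L) {
  n_iter <- check_count(n_iter, "n_iter")
  rank_cut <- check_fraction(rank_cut, "rank_cut", lo_open = TRUE)
  freq_percentile <- check_fraction(freq_percentile, "freq_percentile")
  seed <- check_count(seed, "seed", min = 0)
  hits <- list()
  rho_sum <- list()
  for (b in seq_len(n_iter)) {
    sub <- balanced_subsample(m, seed = seed + b)
    sc <- score_lr_methods(sub, resource, n_perm = n_perm,
                           seed = seed + b)
    sc <- aggregate_rank(sc)
    rec <- sc[sc$aggregate_rank < rank_cut, , drop = FALSE]
    if (!nrow(rec)) next
    keys <- lr_key(rec)
    for (i in seq_along(keys)) {
      k <- keys[i]
      hits[[k]] <- (hits[[k]] %||% 0L) + 1L
      rho_sum[[k]] <- (rho_sum[[k]] %||% 0) + rec$aggregate_rank[i]
    }
  }
  if (!length(hits)) {
    warning("no interaction recovered in any iteration")
    res <- data.frame(sender = character(0), receiver = character(0),
                      ligand = character(0), receptor = character(0),
                      bootstrap_frequency = numeric(0),
                      mean_aggregate_rank = numeric(0),
                      retained = logical(0))
    class(res) <- c("LRTable", "data.frame")
    return(res)
  }
  keys <- names(hits)
  parts <- do.call(rbind, strsplit(keys, "|", fixed = TRUE))
  freq <- vapply(hits, function(x) x / n_iter, numeric(1))
  thr <- freq_threshold(freq, freq_percentile)
  res <- data.frame(sender = parts[, 1], receiver = parts[, 2],
                    ligand = parts[, 3], receptor = parts[, 4],
                    bootstrap_frequency = unname(freq),
                    mean_aggregate_rank =
                      unname(unlist(rho_sum)[keys]) / unname(unlist(hits)[keys]),
                    retained = unname(freq) >= thr,
                    stringsAsFactors = FALSE)
  res <- res[order(-res$bootstrap_frequency, res$mean_aggregate_rank), ]
  rownames(res) <- NULL
  attr(res, "freq_threshold") <- thr
  class(res) <- c("LRTable", "data.frame")
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Robustness cutoff: the freq_percentile quantile (linear interpolation)
# of the bootstrap-frequency distribution; retention uses >=, so the
# maximum observed frequency always survives.
freq_threshold <- function(freq, freq_percentile) {
  stats::quantile(freq, freq_percentile, type = 7, names = FALSE)
}

#' Age stratification and curation filtering of prioritized interactions
#'
#' Classifies interactions retained in the young and aged analyses as
#' `young_specific`, `aged_specific` or `shared` by set algebra on the
#' (sender, receiver, ligand, receptor) keys, annotates each with the
#' resource's curation flag (`curation_effort >= 1`), and keeps curated
#' interactions only.
#'
#' @param young,aged `LRTable`s from [bootstrap_prioritize()] run on the
#'   young / aged cells with the same resource.
#' @param resource the `LRResource` both tables were scored against.
#' @return an `LRTable` of curated interactions with `age_class` and the
#'   per-condition bootstrap frequencies (`NA` where not recovered).
#' @export
stratify_and_filter <- function(young, aged, resource) {
  ky <- lr_key(young[young$retained, , drop = FALSE])
  ka <- lr_key(aged[aged$retained, , drop = FALSE])
  all_keys <- union(ky, ka)
  parts <- do.call(rbind, strsplit(all_keys, "|", fixed = TRUE))
  if (!length(all_keys)) {
    res <- data.frame(sender = character(0), receiver = character(0),
                      ligand = character(0), receptor = character(0),
                      age_class = character(0), curated = logical(0),
                      freq_young = numeric(0), freq_aged = numeric(0))
    class(res) <- c("LRTable", "data.frame")
    return(res)
  }
  age_class <- ifelse(all_keys %in% ky & all_keys %in% ka, "shared",
                      ifelse(all_keys %in% ka, "aged_specific",
                             "young_specific"))
  res <- data.frame(sender = parts[, 1], receiver = parts[, 2],
                    ligand = parts[, 3], receptor = parts[, 4],
                    age_class = age_class, stringsAsFactors = FALSE)
  res_key <- paste(res$ligand, res$receptor, sep = "|")
  cur_key <- paste(resource$ligand, resource$receptor, sep = "|")
  res$curated <- res_key %in% cur_key[resource$curation_effort >= 1]
  fy <- stats::setNames(young$bootstrap_frequency, lr_key(young))
  fa <- stats::setNames(aged$bootstrap_frequency, lr_key(aged))
  res$freq_young <- unname(fy[all_keys])
  res$freq_aged <- unname(fa[all_keys])
  res <- res[res$curated, , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("LRTable", "data.frame")
  res
}
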