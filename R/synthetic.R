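#' Configuration for the single-cell simulator
#'
#' Defines a multi-donor, two-condition (young/aged) cell population with
#' known ground truth: condition-shifted cell-type composition, per-type
#' marker genes, per-type age-DE genes, gene-wise multiplicative donor
#' random effects, log-normal library sizes, and named mitochondrial
#' (`MT-`) and immunoglobulin (`IGH`/`IGK`/`IGL`) gene blocks so that
#' name-based QC filters are exercised.
#'
#' Counts are Gamma-Poisson: a Gamma(shape 2, mean 1) baseline per gene
#' gives marginally negative-binomial counts with the overdispersion
#' typical of droplet data. Aged cell-type probabilities are obtained by
#' multiplying each type's young odds `p/(1-p)` by `aged_odds_multiplier`,
#' back-transforming, and renormalizing.
#'
#' @param n_donors_young,n_donors_aged donors per condition.
#' @param cells_per_donor cells simulated for every donor.
#' @param n_genes total genes, including marker/DE/mito/IG blocks.
#' @param cell_types character vector of type names.
#' @param base_proportions young-condition type probabilities (sum to 1).
#' @param aged_odds_multiplier positive per-type odds ratio of membership
#'   in aged vs young (recycled).
#' @param n_markers_per_type,marker_log2fc marker genes per type and their
#'   log2 boost in that type.
#' @param n_de_genes_per_type,de_log2fc age-DE genes per type and their
#'   log2 effect in aged cells; `de_log2fc` may be a signed vector,
#'   recycled over a type's DE genes.
#' @param donor_effect_sd sd (log scale) of gene-wise log-normal donor
#'   factors.
#' @param type_effect_sd sd (log scale) of per-gene, per-type log-normal
#'   factors shared by both conditions (default 0). Positive values give
#'   every gene mild cell-type structure beyond the planted markers, the
#'   background against which condition-specific signal must be picked
#'   out in communication analyses.
#' @param library_size_mean,library_size_sd log-normal library sizes:
#'   median `library_size_mean` counts, sdlog `library_size_sd`.
#' @param mito_fraction_range per-cell mitochondrial fraction is uniform
#'   on this interval.
#' @param n_mito_genes,n_ig_genes sizes of the named QC gene blocks.
#' @param seed integer seed; identical configs generate identical data.
#' @return an `ScSimConfig` list.
#' @export
sc_sim_config <- function(n_donors_young = 4, n_donors_aged = 5,
                          cells_per_donor = 400, n_genes = 1000,
                          cell_types = c("EC_sinusoidal", "EC_arterial",
                                         "EC_venous", "MSC_THY1",
                                         "MSC_adipo"),
                          base_proportions = c(0.30, 0.15, 0.20, 0.20, 0.15),
                          aged_odds_multiplier = 1,
                          n_markers_per_type = 10, marker_log2fc = 2,
                          n_de_genes_per_type = 10, de_log2fc = 1,
                          donor_effect_sd = 0.15, type_effect_sd = 0,
                          library_size_mean = 2500, library_size_sd = 0.3,
                          mito_fraction_range = c(0.02, 0.08),
                          n_mito_genes = 10, n_ig_genes = 6,
                          seed = 1L) {
  n_types <- length(cell_types)
  if (n_types < 1 || anyDuplicated(cell_types)) {
    stop_arg("cell_types", "must be distinct, non-empty names")
  }
  if (length(base_proportions) != n_types ||
      any(base_proportions <= 0) ||
      abs(sum(base_proportions) - 1) > 1e-9) {
    stop_arg("base_proportions",
             "must be positive, one per type, summing to 1 (tol 1e-9)")
  }
  aged_odds_multiplier <- rep_len(check_positive(aged_odds_multiplier,
                                                 "aged_odds_multiplier"),
                                  n_types)
  cfg <- list(
    n_donors_young = check_count(n_donors_young, "n_donors_young"),
    n_donors_aged = check_count(n_donors_aged, "n_donors_aged"),
    cells_per_donor = check_count(cells_per_donor, "cells_per_donor"),
    n_genes = check_count(n_genes, "n_genes"),
    cell_types = cell_types,
    base_proportions = as.numeric(base_proportions),
    aged_odds_multiplier = aged_odds_multiplier,
    n_markers_per_type = check_count(n_markers_per_type,
                                     "n_markers_per_type", min = 0),
    marker_log2fc = check_fraction(marker_log2fc, "marker_log2fc",
                                   lo = -Inf, hi = Inf),
    n_de_genes_per_type = check_count(n_de_genes_per_type,
                                      "n_de_genes_per_type", min = 0),
    de_log2fc = as.numeric(de_log2fc),
    donor_effect_sd = check_fraction(donor_effect_sd, "donor_effect_sd",
                                     lo = 0, hi = Inf),
    type_effect_sd = check_fraction(type_effect_sd, "type_effect_sd",
                                    lo = 0, hi = Inf),
    library_size_mean = check_positive(library_size_mean,
                                       "library_size_mean"),
    library_size_sd = check_fraction(library_size_sd, "library_size_sd",
                                     lo = 0, hi = Inf),
    mito_fraction_range = mito_fraction_range,
    n_mito_genes = check_count(n_mito_genes, "n_mito_genes", min = 1),
    n_ig_genes = check_count(n_ig_genes, "n_ig_genes", min = 0),
    seed = check_count(seed, "seed", min = 0))
  if (!is.numeric(de_log2fc) || !all(is.finite(de_log2fc))) {
    stop_arg("de_log2fc", "must be finite")
  }
  if (length(mito_fraction_range) != 2 ||
      any(mito_fraction_range < 0) || any(mito_fraction_range >= 1) ||
      diff(mito_fraction_range) < 0) {
    stop_arg("mito_fraction_range", "must be an increasing interval in [0,1)")
  }
  reserved <- n_types * (cfg$n_markers_per_type + cfg$n_de_genes_per_type) +
    cfg$n_mito_genes + cfg$n_ig_genes
  if (reserved > cfg$n_genes) {
    stop_arg("n_genes", sprintf(
      "too small: %d genes reserved for marker/DE/mito/IG blocks", reserved))
  }
  structure(cfg, class = "ScSimConfig")
}

#' True cell-type proportions implied by a simulator configuration
#'
#' Young proportions are `base_proportions`; aged proportions multiply each
#' type's odds by `aged_odds_multiplier` and renormalize.
#'
#' @param config an [sc_sim_config()].
#' @return list with `young`, `aged` (named probability vectors) and
#'   `log2_ratio` (`log2(aged/young)` per type).
#' @export
planted_proportions <- function(config) {
  stopifnot(inherits(config, "ScSimConfig"))
  p <- config$base_proportions
  odds <- p / (1 - p) * config$aged_odds_multiplier
  q <- odds / (1 + odds)
  q <- q / sum(q)
  names(p) <- names(q) <- config$cell_types
  list(young = p, aged = q, log2_ratio = log2(q / p))
}

#' Odds multiplier that plants a given aged/young proportion ratio
#'
#' Solves for the `aged_odds_multiplier` of one type (all other types at 1)
#' such that the renormalized aged proportion of that type is `ratio` times
#' its young proportion.
#'
#' @param base_proportions young type probabilities (sum to 1).
#' @param type_index which type carries the effect.
#' @param ratio target aged/young proportion ratio (> 0).
#' @return the scalar odds multiplier.
#' @export
odds_multiplier_for_ratio <- function(base_proportions, type_index, ratio) {
  check_positive(ratio, "ratio")
  p <- base_proportions
  ratio_max <- 1 / (p[type_index] * (2 - p[type_index]))
  if (ratio >= ratio_max) {
    stop_arg("ratio", sprintf(
      "unattainable: a type at base proportion %.3f can reach at most %.3f-fold",
      p[type_index], ratio_max))
  }
  f <- function(m) {
    mult <- rep(1, length(p))
    mult[type_index] <- m
    odds <- p / (1 - p) * mult
    q <- odds / (1 + odds)
    q <- q / sum(q)
    q[type_index] / p[type_index] - ratio
  }
  stats::uniroot(f, c(1e-8, 1e8), tol = 1e-12)$root
}

# Gene-name layout for a configuration: marker/DE blocks per type, then a
# contiguous mito block and an IG-named block, then filler genes.
sc_gene_layout <- function(cfg) {
  n_types <- length(cfg$cell_types)
  ids <- character(cfg$n_genes)
  pos <- 1L
  take <- function(n) {
    idx <- seq.int(pos, length.out = n)
    pos <<- pos + n
    idx
  }
  markers <- de <- vector("list", n_types)
  names(markers) <- names(de) <- cfg$cell_types
  for (t in seq_len(n_types)) {
    markers[[t]] <- take(cfg$n_markers_per_type)
    de[[t]] <- take(cfg$n_de_genes_per_type)
  }
  mito <- take(cfg$n_mito_genes)
  ig <- take(cfg$n_ig_genes)
  rest <- if (pos <= cfg$n_genes) seq.int(pos, cfg$n_genes) else integer(0)
  for (t in seq_len(n_types)) {
    ids[markers[[t]]] <- sprintf("MK%s-%02d", t, seq_along(markers[[t]]))
    ids[de[[t]]] <- sprintf("DE%s-%02d", t, seq_along(de[[t]]))
  }
  ids[mito] <- sprintf("MT-G%02d", seq_along(mito))
  if (length(ig)) {
    ids[ig] <- paste0(rep_len(c("IGH", "IGK", "IGL"), length(ig)),
                      "S", seq_along(ig))
  }
  ids[rest] <- sprintf("G%04d", rest)
  list(ids = ids, markers = markers, de = de, mito = mito, ig = ig)
}

#' Simulate a multi-donor two-condition single-cell dataset
#'
#' Draws cells donor by donor: each donor belongs to one condition, each
#' cell's type follows the condition-specific probabilities of
#' [planted_proportions()], gene means combine a Gamma baseline with the
#' marker, age-DE and donor-effect multipliers of the configuration, and
#' counts are Poisson at log-normal per-cell library sizes. A per-cell
#' mitochondrial fraction drawn uniformly on `mito_fraction_range` is
#' allocated to the `MT-` gene block. Optionally, ligand/receptor genes of
#' `planted_interactions` are boosted in the sender/receiver cell types of
#' one (or both) conditions, creating condition-specific communication
#' signal for recovery tests.
#'
#' Gene means are scaled by a constant baseline total, so a marker with
#' `marker_log2fc = x` has exactly `2^x` times the generative mean in its
#' own type relative to all others.
#'
#' @param config an [sc_sim_config()].
#' @param planted_interactions optional data.frame with columns `sender`,
#'   `receiver` (cell types), `ligand`, `receptor` (gene ids), `condition`
#'   (`young`, `aged` or `shared`) and optionally `log2_boost` (default 3)
#'   and `off_target` (multiplier on the gene's baseline outside the
#'   sender/receiver type; default `0.01`). Planted communication
#'   genes are thus cell-type restricted — strongly expressed in the
#'   sender (ligand) / receiver (receptor) and depleted elsewhere, the
#'   situation the specificity-based scoring methods are designed to
#'   detect.
#' @return list with elements `matrix` (a [CellMatrix]) and `truth` (a
#'   `GroundTruth` list: per-cell `true_cell_type`, `true_donor`,
#'   `true_condition`; `true_marker_genes`, `true_de_genes` with signed
#'   effects; `true_proportions`; `type_mean_profiles` — genes x types
#'   young-condition generative means usable as a deconvolution reference;
#'   `planted_interactions`).
#' @export
generate_sc <- function(config, planted_interactions = NULL) {
  stopifnot(inherits(config, "ScSimConfig"))
  cfg <- config
  layout <- sc_gene_layout(cfg)
  n_types <- length(cfg$cell_types)
  props <- planted_proportions(cfg)

  donors <- c(sprintf("young_d%d", seq_len(cfg$n_donors_young)),
              sprintf("aged_d%d", seq_len(cfg$n_donors_aged)))
  donor_cond <- rep(c("young", "aged"),
                    c(cfg$n_donors_young, cfg$n_donors_aged))
  n_cells <- length(donors) * cfg$cells_per_donor

  if (!is.null(planted_interactions)) {
    pi_req <- c("sender", "receiver", "ligand", "receptor", "condition")
    if (!is.data.frame(planted_interactions) ||
        !all(pi_req %in% names(planted_interactions))) {
      stop_arg("planted_interactions",
               "needs columns sender, receiver, ligand, receptor, condition")
    }
    if (is.null(planted_interactions$log2_boost)) {
      planted_interactions$log2_boost <- 3
    }
    if (is.null(planted_interactions$off_target)) {
      planted_interactions$off_target <- 0.01
    }
    pg <- c(planted_interactions$ligand, planted_interactions$receptor)
    if (!all(pg %in% layout$ids)) {
      stop_arg("planted_interactions",
               "ligand/receptor genes must exist in the simulated universe")
    }
    if (!all(planted_interactions$sender %in% cfg$cell_types) ||
        !all(planted_interactions$receiver %in% cfg$cell_types)) {
      stop_arg("planted_interactions", "sender/receiver must be cell types")
    }
  }

  with_seed(cfg$seed, {
    baseline <- stats::rgamma(cfg$n_genes, shape = 2, rate = 2)
    baseline <- pmax(baseline, 1e-6)
    type_fac <- matrix(
      stats::rlnorm(cfg$n_genes * n_types, 0, cfg$type_effect_sd),
      cfg$n_genes, n_types)
    if (!is.null(planted_interactions)) {
      # planted communication genes carry exactly the planted pattern:
      # no additional random type structure
      pg <- match(c(planted_interactions$ligand,
                    planted_interactions$receptor), layout$ids)
      type_fac[pg, ] <- 1
      baseline[pg] <- 1    # unit baseline: the planted fold changes are
                           # the gene's whole expression pattern
    }

    # genes x types x condition mean multipliers (before donor effects)
    type_mult <- function(cond) {
      mm <- matrix(type_fac, cfg$n_genes, n_types,
                   dimnames = list(layout$ids, cfg$cell_types))
      for (t in seq_len(n_types)) {
        mm[layout$markers[[t]], t] <- 2^cfg$marker_log2fc
        if (cond == "aged" && cfg$n_de_genes_per_type > 0) {
          eff <- rep_len(cfg$de_log2fc, cfg$n_de_genes_per_type)
          mm[layout$de[[t]], t] <- mm[layout$de[[t]], t] * 2^eff
        }
      }
      if (!is.null(planted_interactions)) {
        for (r in seq_len(nrow(planted_interactions))) {
          pi_r <- planted_interactions[r, ]
          if (pi_r$condition %in% c(cond, "shared")) {
            b <- 2^pi_r$log2_boost
            off <- pi_r$off_target
            # cell-type-restricted communication genes: boosted in the
            # sender/receiver type, suppressed elsewhere
            mm[pi_r$ligand, ] <- mm[pi_r$ligand, ] * off
            mm[pi_r$ligand, pi_r$sender] <-
              mm[pi_r$ligand, pi_r$sender] / off * b
            mm[pi_r$receptor, ] <- mm[pi_r$receptor, ] * off
            mm[pi_r$receptor, pi_r$receiver] <-
              mm[pi_r$receptor, pi_r$receiver] / off * b
          }
        }
      }
      mm * baseline
    }
    mean_young <- type_mult("young")
    mean_aged <- type_mult("aged")

    donor_fac <- matrix(
      stats::rlnorm(cfg$n_genes * length(donors),
                    meanlog = 0, sdlog = cfg$donor_effect_sd),
      nrow = cfg$n_genes)

    nonmito <- setdiff(seq_len(cfg$n_genes), layout$mito)
    s_base <- sum(baseline[nonmito])          # constant scale denominator
    s_mito <- sum(baseline[layout$mito])

    cell_donor <- rep(donors, each = cfg$cells_per_donor)
    cell_cond <- rep(donor_cond, each = cfg$cells_per_donor)
    cell_type <- character(n_cells)
    lib <- stats::rlnorm(n_cells, meanlog = log(cfg$library_size_mean),
                         sdlog = cfg$library_size_sd)
    mito_f <- stats::runif(n_cells, cfg$mito_fraction_range[1],
                           cfg$mito_fraction_range[2])

    counts <- matrix(0L, cfg$n_genes, n_cells)
    for (d in seq_along(donors)) {
      idx <- which(cell_donor == donors[d])
      cond <- donor_cond[d]
      p_t <- if (cond == "young") props$young else props$aged
      tt <- sample.int(n_types, length(idx), replace = TRUE, prob = p_t)
      cell_type[idx] <- cfg$cell_types[tt]
      base_mean <- if (cond == "young") mean_young else mean_aged
      mu_types <- base_mean * donor_fac[, d]   # genes x types for this donor
      mu <- mu_types[, tt, drop = FALSE]
      mu[nonmito, ] <- sweep(mu[nonmito, , drop = FALSE], 2,
                             lib[idx] * (1 - mito_f[idx]) / s_base, `*`)
      mu[layout$mito, ] <- sweep(mu[layout$mito, , drop = FALSE], 2,
                                 lib[idx] * mito_f[idx] / s_mito, `*`)
      counts[, idx] <- stats::rpois(length(mu), as.vector(mu))
    }
    dimnames(counts) <- list(layout$ids, sprintf("cell_%05d", seq_len(n_cells)))

    meta <- data.frame(donor_id = cell_donor,
                       condition = cell_cond,
                       cell_type = cell_type,
                       stringsAsFactors = FALSE)
    m <- CellMatrix(counts, meta)

    de_truth <- lapply(seq_len(n_types), function(t) {
      if (cfg$n_de_genes_per_type == 0) return(numeric(0))
      stats::setNames(rep_len(cfg$de_log2fc, cfg$n_de_genes_per_type),
                      layout$ids[layout$de[[t]]])
    })
    names(de_truth) <- cfg$cell_types
    marker_truth <- lapply(layout$markers, function(i) layout$ids[i])

    truth <- list(
      true_cell_type = stats::setNames(cell_type, colnames(counts)),
      true_donor = stats::setNames(cell_donor, colnames(counts)),
      true_condition = stats::setNames(cell_cond, colnames(counts)),
      true_marker_genes = marker_truth,
      true_de_genes = de_truth,
      true_proportions = props,
      type_mean_profiles = mean_young,
      mito_genes = layout$ids[layout$mito],
      ig_genes = layout$ids[layout$ig],
      planted_interactions = planted_interactions)
    list(matrix = m, truth = truth)
  })
}

#' Configuration for the spatial simulator
#'
#' Spots are laid on a Visium-dialect hexagonal grid (`array_col` parity
#' equals `array_row` parity); each spot's cell-type composition is a
#' Dirichlet draw, optionally biased per horizontal region band so that
#' chosen types co-localize; observed counts are Poisson around a mixture
#' of type expression profiles at a target sequencing depth.
#'
#' @param n_rows,n_cols grid dimensions (spots per row = `n_cols`).
#' @param dirichlet_alpha positive Dirichlet concentration, one per cell
#'   type (recycled).
#' @param region_bias optional matrix (regions x types) of positive
#'   multipliers on alpha; the grid is split into `nrow(region_bias)`
#'   horizontal bands.
#' @param depth_per_spot expected total counts per spot.
#' @param seed integer seed.
#' @return a `SpatialSimConfig` list.
#' @export
spatial_sim_config <- function(n_rows = 20, n_cols = 20,
                               dirichlet_alpha = 1,
                               region_bias = NULL,
                               depth_per_spot = 5000, seed = 1L) {
  cfg <- list(n_rows = check_count(n_rows, "n_rows"),
              n_cols = check_count(n_cols, "n_cols"),
              dirichlet_alpha = check_positive(dirichlet_alpha,
                                               "dirichlet_alpha"),
              region_bias = region_bias,
              depth_per_spot = check_positive(depth_per_spot,
                                              "depth_per_spot"),
              seed = check_count(seed, "seed", min = 0))
  if (!is.null(region_bias)) {
    if (!is.matrix(region_bias) || any(region_bias <= 0)) {
      stop_arg("region_bias", "must be a positive matrix (regions x types)")
    }
  }
  structure(cfg, class = "SpatialSimConfig")
}

#' Simulate a Visium-style spatial dataset from cell-type profiles
#'
#' @param config a [spatial_sim_config()].
#' @param type_profiles genes x types matrix of non-negative expression
#'   profiles (e.g. `truth$type_mean_profiles` from [generate_sc()]); each
#'   column is normalized internally to a composition.
#' @return list with `matrix` (a [SpotMatrix]) and `truth` (list:
#'   `true_spot_proportions` spots x types, `region` per spot).
#' @export
generate_spatial <- function(config, type_profiles) {
  stopifnot(inherits(config, "SpatialSimConfig"))
  cfg <- config
  if (!is.matrix(type_profiles) || is.null(colnames(type_profiles)) ||
      any(type_profiles < 0)) {
    stop_arg("type_profiles",
             "must be a non-negative genes x types matrix with type colnames")
  }
  n_types <- ncol(type_profiles)
  alpha <- rep_len(cfg$dirichlet_alpha, n_types)
  if (!is.null(cfg$region_bias) && ncol(cfg$region_bias) != n_types) {
    stop_arg("region_bias", "one column per cell type required")
  }
  rows <- rep(seq_len(cfg$n_rows) - 1L, each = cfg$n_cols)
  cols <- unlist(lapply(seq_len(cfg$n_rows) - 1L, function(r) {
    seq(r %% 2L, by = 2L, length.out = cfg$n_cols)
  }))
  barcodes <- sprintf("spot_r%02d_c%03d", rows, cols)
  n_regions <- if (is.null(cfg$region_bias)) 1L else nrow(cfg$region_bias)
  region <- pmin(n_regions, 1L + (rows * n_regions) %/% cfg$n_rows)

  W <- sweep(type_profiles, 2, colSums(type_profiles), `/`)
  with_seed(cfg$seed, {
    n_spots <- length(barcodes)
    P <- matrix(0, n_spots, n_types)
    for (g in seq_len(n_regions)) {
      idx <- which(region == g)
      a <- alpha * (if (is.null(cfg$region_bias)) 1 else cfg$region_bias[g, ])
      P[idx, ] <- rdirichlet(length(idx), a)
    }
    mu <- W %*% t(P) * cfg$depth_per_spot    # genes x spots
    counts <- matrix(stats::rpois(length(mu), as.vector(mu)),
                     nrow = nrow(mu),
                     dimnames = list(rownames(type_profiles), barcodes))
    pos <- data.frame(barcode = barcodes, in_tissue = 1L,
                      array_row = rows, array_col = cols)
    dimnames(P) <- list(barcodes, colnames(type_profiles))
    list(matrix = SpotMatrix(counts, pos),
         truth = list(true_spot_proportions = P,
                      region = stats::setNames(region, barcodes)))
  })
}

#' Simulate a ligand-receptor resource table
#'
#' Draws `n_pairs` distinct ligand-receptor gene pairs from a gene
#' universe, annotated with curation metadata: exactly `n_curated` pairs
#' get `curation_effort >= 1`, the rest 0. Specific pairs (e.g. planted
#' interactions) can be forced into the table via `include`; they occupy
#' curated slots first.
#'
#' @param genes gene universe to draw from.
#' @param n_pairs number of pairs.
#' @param n_curated number of pairs with `curation_effort >= 1`
#'   (`<= n_pairs`).
#' @param include optional data.frame with `ligand`, `receptor` columns of
#'   pairs that must be present (their genes need not belong to `genes`,
#'   so planted interaction genes can be kept out of the random pairs).
#' @param seed integer seed.
#' @return an `LRResource` data.frame: `ligand`, `receptor`,
#'   `curation_effort`, `n_references`, `n_resources`.
#' @export
generate_lr_resource <- function(genes, n_pairs, n_curated,
                                 include = NULL, seed = 1L) {
  n_pairs <- check_count(n_pairs, "n_pairs")
  n_curated <- check_count(n_curated, "n_curated", min = 0)
  if (n_curated > n_pairs) {
    stop_arg("n_curated", "must be <= n_pairs")
  }
  if (!is.null(include)) {
    stopifnot(is.data.frame(include),
              all(c("ligand", "receptor") %in% names(include)))
    if (nrow(include) > n_pairs) stop_arg("include", "more rows than n_pairs")
  }
  with_seed(seed, {
    n_inc <- if (is.null(include)) 0L else nrow(include)
    pairs <- data.frame(ligand = character(0), receptor = character(0))
    if (n_inc > 0) {
      pairs <- include[, c("ligand", "receptor")]
    }
    while (nrow(pairs) < n_pairs) {
      need <- n_pairs - nrow(pairs)
      cand <- data.frame(ligand = sample(genes, need, replace = TRUE),
                         receptor = sample(genes, need, replace = TRUE))
      pairs <- unique(rbind(pairs, cand[cand$ligand != cand$receptor, ]))
    }
    pairs <- pairs[seq_len(n_pairs), ]
    effort <- integer(n_pairs)
    curated_idx <- c(seq_len(min(n_inc, n_curated)),
                     if (n_curated > n_inc) {
                       n_inc + sample.int(n_pairs - n_inc,
                                          n_curated - n_inc)
                     })
    effort[curated_idx] <- sample.int(5, n_curated, replace = TRUE)
    res <- data.frame(
      ligand = pairs$ligand, receptor = pairs$receptor,
      curation_effort = effort,
      n_references = effort + stats::rpois(n_pairs, 1),
      n_resources = 1L + stats::rpois(n_pairs, 2),
      stringsAsFactors = FALSE)
    rownames(res) <- NULL
    class(res) <- c("LRResource", "data.frame")
    res
  })
}
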