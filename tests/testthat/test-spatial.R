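make_spot_matrix <- function(counts) {
  n <- ncol(counts)
  rows <- rep(0:((n - 1) %/% 4), each = 4, length.out = n)
  cols <- unlist(lapply(split(seq_len(n), rows), function(i) {
    r <- rows[i[1]]
    seq(r %% 2, by = 2, length.out = length(i))
  }))
  pos <- data.frame(barcode = colnames(counts), in_tissue = 1,
                    array_row = rows, array_col = cols)
  SpotMatrix(counts, pos)
}

test_that("NNLS recovers exact and noiseless mixed profiles", {
  ref <- cbind(A = c(10, 0, 5, 1), B = c(0, 10, 1, 5))
  rownames(ref) <- paste0("g", 1:4)
  pure <- matrix(round(ref[, "A"] * 20), 4, 1,
                 dimnames = list(paste0("g", 1:4), "s1"))
  mix <- 0.3 * ref[, "A"] / sum(ref[, "A"]) +
    0.7 * ref[, "B"] / sum(ref[, "B"])
  mixed <- matrix(round(mix * 1e6), 4, 1,
                  dimnames = list(paste0("g", 1:4), "s1"))
  d_pure <- nnls_deconvolve(make_spot_matrix(pure), ref)
  expect_equal(unname(d_pure["s1", "A"]), 1, tolerance = 1e-9)
  d_mix <- nnls_deconvolve(make_spot_matrix(mixed), ref)
  expect_equal(unname(d_mix["s1", ]), c(0.3, 0.7), tolerance = 1e-6)
})

test_that("NNLS fractions recover Poisson-noised synthetic mixtures", {
  cfg <- sc_sim_config(n_donors_young = 2, n_donors_aged = 2,
                       cells_per_donor = 50, n_genes = 300,
                       cell_types = c("A", "B", "C", "D"),
                       base_proportions = rep(0.25, 4),
                       n_markers_per_type = 20, marker_log2fc = 3,
                       seed = 31)
  sim <- generate_sc(cfg)
  sp <- generate_spatial(
    spatial_sim_config(n_rows = 20, n_cols = 20, dirichlet_alpha = 1,
                       depth_per_spot = 5000, seed = 32),
    sim$truth$type_mean_profiles)
  d <- nnls_deconvolve(sp$matrix, sim$truth$type_mean_profiles)
  P <- sp$truth$true_spot_proportions[rownames(d), colnames(d)]
  expect_lt(mean(abs(d - P)), 0.05)
  expect_true(all(abs(rowSums(d) - 1) < 1e-6))
})

test_that("dual-rank labeling reproduces the hand-enumerated toy", {
  spots <- paste0("s", sprintf("%02d", 1:10))
  frac <- c(.9, .8, .7, .6, .5, .4, .3, .2, .1, 0)
  auc <- c(.50, .40, .45, .10, .20, .05, .30, .25, .15, 0)
  deconv <- cbind(X = frac, Y = 1 - frac)
  rownames(deconv) <- spots
  scores <- cbind(X = auc)
  rownames(scores) <- spots
  lab <- label_spots(deconv, scores, "X")
  got <- split(lab$spot, lab$label)
  expect_setequal(got$golden, paste0("s0", 1:3))
  expect_setequal(got$high, paste0("s0", 4:9))
  expect_setequal(got$rest, "s10")
  expect_length(got$low, 0)
})

test_that("an AUC of zero forces the rest label regardless of fractions", {
  spots <- paste0("s", 1:6)
  deconv <- cbind(X = c(.9, .8, .7, .3, .2, .1), Y = 0)
  deconv[, "Y"] <- 1 - deconv[, "X"]
  rownames(deconv) <- spots
  scores <- cbind(X = rep(0, 6))
  rownames(scores) <- spots
  lab <- label_spots(deconv, scores, "X")
  expect_true(all(lab$label == "rest"))
})

test_that("labels always partition the spots", {
  withr::with_seed(17, {
    for (i in 1:100) {
      n <- sample(5:60, 1)
      spots <- sprintf("s%03d", seq_len(n))
      fr <- runif(n); fr <- fr * rbinom(n, 1, 0.9)
      au <- runif(n) * rbinom(n, 1, 0.8)
      deconv <- cbind(X = fr / max(sum(fr), 1e-9),
                      Y = 1 - fr / max(sum(fr), 1e-9))
      rownames(deconv) <- spots
      scores <- cbind(X = au)
      rownames(scores) <- spots
      lab <- label_spots(deconv, scores, "X")
      expect_equal(nrow(lab), n)
      expect_equal(sum(table(lab$label)), n)
      expect_false(anyNA(lab$label))
    }
  })
})

test_that("hex neighbourhoods follow the parity offsets", {
  counts <- matrix(5L, 2, 12,
                   dimnames = list(c("g1", "g2"), sprintf("s%02d", 1:12)))
  rows <- rep(0:2, each = 4)
  cols <- c(seq(0, 6, 2), seq(1, 7, 2), seq(0, 6, 2))
  pos <- data.frame(barcode = colnames(counts), in_tissue = 1,
                    array_row = rows, array_col = cols)
  s <- SpotMatrix(counts, pos)
  g <- hex_neighbors(s)
  corner <- g[["s01"]]  # spot (0,0): neighbours (0,2) and (1,1)
  expect_setequal(corner, c("s02", "s05"))
  interior <- g[["s06"]] # spot (1,3): six neighbours
  expect_length(interior, 6)
  # symmetry
  for (a in names(g)) {
    for (b in g[[a]]) expect_true(a %in% g[[b]])
  }
  pos$array_col[2] <- pos$array_col[1]
  pos$array_row[2] <- pos$array_row[1]
  expect_error(hex_neighbors(SpotMatrix(counts[, c(1, 1)] |>
    (\(x) {colnames(x) <- c("a", "b"); x})(), pos[1:2, ] |>
    (\(p) {p$barcode <- c("a", "b"); p})())), "duplicate")
})

# Four cell types: A/B carry the signal of interest, C is an independent
# bystander and D a high-alpha filler emulating the hematopoietic
# background that dominates marrow spots (and dilutes the compositional
# anticorrelation inherent to Dirichlet mixtures). For the planted case,
# A and B share a smooth row-band abundance gradient.
coloc_fixture <- function(seed, planted = FALSE, n_rows = 26, n_cols = 26,
                          alpha = 2 * c(60, 30, 10, 40)) {
  cfg <- sc_sim_config(n_donors_young = 2, n_donors_aged = 2,
                       cells_per_donor = 60, n_genes = 240,
                       cell_types = c("A", "B", "C", "D"),
                       base_proportions = c(0.3, 0.25, 0.2, 0.25),
                       n_markers_per_type = 20, marker_log2fc = 3,
                       seed = seed)
  sim <- generate_sc(cfg)
  bias <- NULL
  if (planted) {
    g <- pmax(0.8^(0:(n_rows - 1)), 0.25)
    bias <- cbind(A = g, B = g, C = 1, D = 1)
  }
  sp <- generate_spatial(
    spatial_sim_config(n_rows = n_rows, n_cols = n_cols,
                       dirichlet_alpha = alpha, region_bias = bias,
                       depth_per_spot = 8000, seed = seed + 1),
    sim$truth$type_mean_profiles)
  sm <- normalize_log1p(sp$matrix)
  scores <- score_matrix(sm, sim$truth$true_marker_genes,
                         top_fraction = 0.1, seed = seed)
  deconv <- nnls_deconvolve(sp$matrix, sim$truth$type_mean_profiles)
  list(scores = scores, deconv = deconv, graph = hex_neighbors(sp$matrix),
       P = sp$truth$true_spot_proportions)
}

test_that("co-localization detects a planted shared abundance gradient", {
  fx <- coloc_fixture(seed = 51, planted = TRUE)
  lab <- label_spots(fx$deconv, fx$scores, "A")
  expect_gt(sum(lab$label == "golden"), 100)
  same <- colocalization(fx$scores, lab, type_a = "A", type_b = "B",
                         mode = "same_spot")
  expect_gt(same$rho, 0)
  expect_lt(same$p, 0.05)
  nb <- colocalization(fx$scores, lab, graph = fx$graph,
                       type_a = "A", type_b = "B", mode = "neighbor")
  expect_gt(nb$rho, 0)
  expect_lt(nb$p, 0.05)
  # self-correlation is exactly 1
  self <- colocalization(fx$scores, lab, type_a = "A", type_b = "A")
  expect_equal(self$rho, 1)
})

test_that("independently placed types show no systematic co-localization", {
  rhos <- vapply(1:20, function(i) {
    fx <- coloc_fixture(seed = 300 + 13 * i, n_rows = 40, n_cols = 40,
                        alpha = c(6, 6, 6, 48))
    lab <- label_spots(fx$deconv, fx$scores, "A")
    colocalization(fx$scores, lab, type_a = "A", type_b = "C")$rho
  }, numeric(1))
  expect_lt(mean(abs(rhos)), 0.1)
})

test_that("golden/high labels capture truly enriched spots", {
  fx <- coloc_fixture(seed = 71, n_rows = 30, n_cols = 30,
                      alpha = c(8, 8, 8, 40))
  P <- fx$P
  lab <- label_spots(fx$deconv, fx$scores, "A")
  p_bar <- mean(fx$deconv[, "A"])
  hot <- rownames(P)[P[, "A"] > stats::quantile(P[, "A"], 1 - p_bar)]
  called <- lab$spot[lab$label %in% c("golden", "high")]
  expect_gte(mean(hot %in% called), 0.8)
  # fraction/AUC agreement is positive for every type
  for (tp in c("A", "B", "C", "D")) {
    expect_gt(stats::cor(fx$deconv[, tp],
                         fx$scores[rownames(fx$deconv), tp],
                         method = "spearman"), 0)
  }
})
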