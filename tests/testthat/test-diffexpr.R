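de_toy <- function(n_genes = 40, n_a = 20, n_b = 20, seed = 1) {
  counts <- random_counts(n_genes, n_a + n_b, lambda = 4, seed = seed)
  normalize_log1p(toy_cell_matrix(counts, condition = "young"))
}

test_that("duplicated groups give zero fold change and null p-values", {
  counts <- random_counts(30, 15, lambda = 4, seed = 2)
  both <- cbind(counts, counts)
  colnames(both) <- sprintf("c%03d", seq_len(30))
  m <- normalize_log1p(toy_cell_matrix(both, condition = "young"))
  res <- rank_sum_de(m, 1:15, 16:30, min_pct = 0, min_abs_log2fc = 0.5)
  expect_true(all(abs(res$log2FC) < 1e-12))
  expect_true(all(res$p > 0.9))
  expect_false(any(res$pass))
})

test_that("complete separation is called at the marker thresholds", {
  counts <- matrix(0L, 5, 40,
                   dimnames = list(paste0("g", 1:5), sprintf("c%02d", 1:40)))
  counts[1, 1:20] <- 50L           # expressed only in group a
  counts[2:5, ] <- matrix(rpois(4 * 40, 5), 4)
  m <- normalize_log1p(toy_cell_matrix(counts, condition = "young"))
  preset <- de_preset("markers")
  res <- rank_sum_de(m, 1:20, 21:40, min_pct = preset$min_pct,
                     min_abs_log2fc = preset$min_abs_log2fc,
                     alpha = preset$alpha)
  g1 <- res[res$gene == "g1", ]
  expect_lt(g1$p_adj, 0.05)
  expect_gt(g1$log2FC, 1)
  expect_true(g1$pass)
})

test_that("presets carry the marker and age-DE thresholds", {
  expect_equal(de_preset("markers")$min_abs_log2fc, 1)
  expect_equal(de_preset("age")$min_abs_log2fc, 0.5)
  expect_equal(de_preset("age")$min_pct, 0.25)
})

test_that("swapping groups negates log2FC and preserves p", {
  m <- de_toy(seed = 3)
  ab <- rank_sum_de(m, 1:20, 21:40, min_pct = 0)
  ba <- rank_sum_de(m, 21:40, 1:20, min_pct = 0)
  expect_equal(ab$log2FC, -ba$log2FC, tolerance = 1e-12)
  expect_equal(ab$p, ba$p, tolerance = 1e-12)
  expect_equal(ab$pct_1, ba$pct_2)
})

test_that("overlapping groups and unnormalized input are rejected", {
  m <- de_toy()
  expect_error(rank_sum_de(m, 1:20, 20:40), "overlap")
  raw <- toy_cell_matrix(random_counts(10, 10))
  expect_error(rank_sum_de(raw, 1:5, 6:10), "normalize")
})

test_that("under exchangeability the raw p-values are calibrated", {
  m <- de_toy(n_genes = 400, n_a = 30, n_b = 30, seed = 5)
  res <- rank_sum_de(m, 1:30, 31:60, min_pct = 0)
  frac <- mean(res$p < 0.05)
  env <- qbinom(c(0.005, 0.995), nrow(res), 0.05) / nrow(res)
  expect_gte(frac, env[1])
  expect_lte(frac, env[2])
})

test_that("detection gating uses the better-detected group", {
  counts <- matrix(0L, 2, 20,
                   dimnames = list(c("g1", "g2"), sprintf("c%02d", 1:20)))
  counts[1, 1:10] <- 5L   # 100% in group a, 0% in group b
  counts[2, ] <- 1L
  m <- normalize_log1p(toy_cell_matrix(counts, condition = "young"))
  res <- rank_sum_de(m, 1:10, 11:20, min_pct = 0.25)
  expect_true("g1" %in% res$gene)
})

test_that("pseudobulk fold changes match hand-computed CPM arithmetic", {
  counts <- rbind(g1 = c(10, 20, 30, 40),
                  g2 = c(90, 80, 70, 60))
  colnames(counts) <- paste0("c", 1:4)
  m <- toy_cell_matrix(counts, donor = paste0("d", 1:4),
                       condition = c("young", "young", "aged", "aged"),
                       cell_type = "A")
  pb <- pseudobulk(m, group_by = "donor_id", min_cells = 1)
  cmap <- c(d1 = "young", d2 = "young", d3 = "aged", d4 = "aged")
  out <- pseudobulk_log2fc(pb, cmap)
  cpm <- sweep(counts, 2, colSums(counts) / 1e6, `/`)
  lg <- log2(cpm + 1)
  expect_equal(unname(out$log2FC["g1"]),
               mean(lg[1, 3:4]) - mean(lg[1, 1:2]), tolerance = 1e-12)
  # identical donor columns across conditions: all zero
  same <- counts[, c(1, 1, 1, 1)]
  colnames(same) <- paste0("c", 1:4)
  m0 <- toy_cell_matrix(same, donor = paste0("d", 1:4),
                        condition = c("young", "young", "aged", "aged"),
                        cell_type = "A")
  out0 <- pseudobulk_log2fc(pseudobulk(m0, "donor_id", min_cells = 1), cmap)
  expect_true(all(abs(out0$log2FC) < 1e-12))
  expect_error(
    pseudobulk_log2fc(pb, c(d1 = "young", d2 = "aged", d3 = "aged",
                            d4 = "aged")),
    "2 donors")
})

test_that("pseudobulk effects recover planted DE with high concordance", {
  effects <- c(-2, -1.2, -0.6, 0.6, 1.2, 2)
  cfg <- sc_sim_config(n_donors_young = 4, n_donors_aged = 4,
                       cells_per_donor = 250, n_genes = 200,
                       cell_types = c("A", "B"),
                       base_proportions = c(0.5, 0.5),
                       n_markers_per_type = 4, marker_log2fc = 1,
                       n_de_genes_per_type = 6, de_log2fc = effects,
                       donor_effect_sd = 0.1, seed = 21)
  sim <- generate_sc(cfg)
  m <- sim$matrix
  a_cells <- m$cell_meta$cell_type == "A"
  mA <- bmniche:::subset_cells(m, which(a_cells))
  pb <- pseudobulk(mA, group_by = "donor_id", min_cells = 5)
  cmap <- with(unique(mA$cell_meta[c("donor_id", "condition")]),
               stats::setNames(as.character(condition), donor_id))
  truth <- sim$truth$true_de_genes[["A"]]
  out <- pseudobulk_log2fc(pb, cmap, reference_log2fc = truth)
  expect_gte(out$concordance_rho, 0.8)
  # direction agrees for the strongest planted effects
  strong <- names(truth)[abs(truth) >= 1.2]
  expect_true(all(sign(out$log2FC[strong]) == sign(truth[strong])))
})

test_that("hypergeometric ORA matches the exact tail and BH identities", {
  universe <- paste0("g", 1:20)
  sets <- list(hit = paste0("g", 1:5))
  # N=20, K=5, n=5, overlap 4
  res <- hypergeom_ora(paste0("g", c(1:4, 10)), sets, universe)
  expect_equal(res$hyper_p, 76 / 15504, tolerance = 1e-12)
  expect_equal(res$p_adj, res$hyper_p)  # single set: BH identity
  # zero overlap: p = 1
  res0 <- hypergeom_ora(paste0("g", 10:14), sets, universe)
  expect_equal(res0$hyper_p, 1)
  # monotone decreasing in the overlap at fixed margins
  ps <- vapply(1:5, function(k) {
    q <- paste0("g", c(seq_len(k), 10 + seq_len(5 - k)))
    hypergeom_ora(q, sets, universe)$hyper_p
  }, numeric(1))
  expect_true(all(diff(ps) < 0))
  expect_error(hypergeom_ora("g1", sets, character(0)), "universe")
  expect_error(hypergeom_ora("absent", sets, universe), "query")
})
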