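lr_toy_matrix <- function(seed = 1) {
  counts <- random_counts(40, 120, lambda = 3, seed = seed)
  m <- toy_cell_matrix(counts,
                       donor = rep(c("d1", "d2"), 60),
                       condition = "young",
                       cell_type = rep(c("A", "B", "C"), c(50, 40, 30)))
  normalize_log1p(m)
}

test_that("balanced subsampling equalizes cell-type counts", {
  m <- lr_toy_matrix()
  sub <- balanced_subsample(m, seed = 1)
  expect_equal(ncol(sub$counts), 90)
  expect_true(all(table(sub$cell_meta$cell_type) == 30))
  # sizes (100, 40, 60) -> 40 each, 120 total
  m2 <- toy_cell_matrix(random_counts(10, 200, seed = 2),
                        condition = "young",
                        cell_type = rep(c("A", "B", "C"), c(100, 40, 60)))
  sub2 <- balanced_subsample(m2, seed = 3)
  expect_equal(ncol(sub2$counts), 120)
  expect_warning(balanced_subsample(m, types = c("A", "B", "ghost")),
                 "ghost")
})

test_that("method scores obey their closed forms", {
  m <- lr_toy_matrix()
  res <- data.frame(ligand = c("g001", "g002"),
                    receptor = c("g003", "g004"),
                    curation_effort = 1L)
  sc <- score_lr_methods(m, res, n_perm = 50, seed = 4)
  expect_equal(nrow(sc), 2 * 9)  # 3x3 sender-receiver pairs per resource pair
  expect_true(all(sc$perm_p > 0 & sc$perm_p <= 1))
  expect_true(all(sc$specificity >= 0 & sc$specificity <= 1))
  expect_true(all(sc$lr_score >= 0 & sc$lr_score < 1))
  expect_error(score_lr_methods(m, res, n_perm = 5), "n_perm")

  # ligand expressed in the sender only: specificity ligand term is 1,
  # so specificity equals the receptor term alone
  counts <- matrix(0L, 3, 60, dimnames = list(c("L", "R", "H"),
                                              sprintf("c%02d", 1:60)))
  counts["L", 1:20] <- 10L          # only type A
  counts["R", ] <- 5L               # everywhere
  counts["H", ] <- rep(c(3L, 4L, 5L), 20)
  m2 <- normalize_log1p(toy_cell_matrix(
    counts, condition = "young",
    cell_type = rep(c("A", "B", "C"), each = 20)))
  sc2 <- score_lr_methods(m2, data.frame(ligand = "L", receptor = "R"),
                          n_perm = 20, seed = 5)
  ab <- sc2[sc2$sender == "A" & sc2$receiver == "B", ]
  gm <- function(type) mean(m2$logcounts["R", m2$cell_meta$cell_type == type])
  expect_equal(ab$specificity, gm("B") / (gm("A") + gm("B") + gm("C")),
               tolerance = 1e-12)
  # l = 0 outside the sender: lr_score = 0 there
  cb <- sc2[sc2$sender == "C", ]
  expect_true(all(cb$lr_score == 0))
  # l * r = mu^2 would give 1/2 by the saturation form
  mu <- mean(as.matrix(m2$logcounts))
  expect_equal(mu / (mu + mu), 0.5)

  # dropped pairs with absent genes are reported
  sc3 <- score_lr_methods(m2, data.frame(ligand = c("L", "nope"),
                                         receptor = c("R", "R")),
                          n_perm = 20, seed = 6)
  expect_equal(attr(sc3, "dropped_pairs")$ligand, "nope")
})

test_that("robust rank aggregation matches the beta order statistics", {
  # m = 1: identity on the normalized rank
  one <- data.frame(perm_p = c(0.2, 0.5, 0.9, 0.1, 0.4))
  agg <- aggregate_rank(one, methods = "perm_p")
  expect_equal(agg$aggregate_rank, rank(one$perm_p) / 5, tolerance = 1e-12)
  # m = 2 with normalized ranks (0.1, 0.2) for the top interaction:
  # rho = 2 * min(1 - 0.9^2, 0.2^2) = 0.08
  ten <- data.frame(perm_p = (1:10) / 10,
                    specificity = c(0.9, 1, seq(0.8, 0.1, length.out = 8)))
  agg2 <- aggregate_rank(ten, methods = c("perm_p", "specificity"))
  expect_equal(agg2$aggregate_rank[1], 0.08, tolerance = 1e-12)
  # unanimity dominance: ranked first by all methods beats ranked last
  both <- data.frame(perm_p = c(0.01, 0.99, runif(8, 0.02, 0.98)),
                     specificity = c(0.99, 0.01, runif(8, 0.02, 0.98)),
                     lr_score = c(0.99, 0.01, runif(8, 0.02, 0.98)))
  agg3 <- aggregate_rank(both)
  expect_lt(agg3$aggregate_rank[1], agg3$aggregate_rank[2])
  expect_error(aggregate_rank(both[0, ]), "non-empty")
})

test_that("duplicating a method leaves the aggregate ordering intact", {
  df <- data.frame(perm_p = runif(20), specificity = runif(20))
  a <- aggregate_rank(df, methods = c("perm_p", "specificity"))
  df$specificity2 <- df$specificity
  b <- aggregate_rank(df, methods = c("perm_p", "specificity",
                                      "specificity2"))
  expect_gt(stats::cor(a$aggregate_rank, b$aggregate_rank,
                       method = "spearman"), 0.9)
  expect_equal(which.min(a$aggregate_rank), which.min(b$aggregate_rank))
})

test_that("the frequency threshold uses >= so maxima always survive", {
  thr <- bmniche:::freq_threshold(c(1.0, 1.0, 0.1, 0.05), 0.95)
  expect_equal(thr, 1.0)
  # with >= semantics the two at 1.0 are retained
  expect_equal(sum(c(1.0, 1.0, 0.1, 0.05) >= thr), 2)
})

test_that("age stratification and curation compose as set algebra", {
  tab <- function(keys, retained = TRUE) {
    parts <- do.call(rbind, strsplit(keys, ":"))
    df <- data.frame(sender = parts[, 1], receiver = parts[, 2],
                     ligand = parts[, 3], receptor = parts[, 4],
                     bootstrap_frequency = 1,
                     mean_aggregate_rank = 0.001,
                     retained = retained)
    class(df) <- c("LRTable", "data.frame")
    df
  }
  res <- data.frame(ligand = c("l1", "l2", "l3"),
                    receptor = c("r1", "r2", "r3"),
                    curation_effort = c(2L, 0L, 1L))
  young <- tab(c("A:B:l1:r1", "A:B:l2:r2"))
  aged <- tab(c("A:B:l1:r1", "C:D:l3:r3"))
  out <- stratify_and_filter(young, aged, res)
  expect_setequal(out$age_class[out$ligand == "l1"], "shared")
  expect_setequal(out$age_class[out$ligand == "l3"], "aged_specific")
  # l2 is young-specific but uncurated: filtered out
  expect_false("l2" %in% out$ligand)
  # identical tables: everything shared; disjoint: no shared
  all_shared <- stratify_and_filter(young, young, res)
  expect_true(all(all_shared$age_class == "shared"))
  disjoint <- stratify_and_filter(tab("A:B:l1:r1"), tab("C:D:l3:r3"), res)
  expect_false(any(disjoint$age_class == "shared"))
})

test_that("a planted aged-specific interaction is recovered end to end", {
  study <- simulate_lr_study(seed = 917)
  ty <- bootstrap_prioritize(study$young, study$resource, n_iter = 25,
                             n_perm = 100, seed = 918)
  ta <- bootstrap_prioritize(study$aged, study$resource, n_iter = 25,
                             n_perm = 100, seed = 919)
  out <- stratify_and_filter(ty, ta, study$resource)
  ag <- out[out$age_class == "aged_specific", ]
  hit <- ag$sender == study$planted$sender &
    ag$receiver == study$planted$receiver &
    ag$ligand == study$planted$ligand &
    ag$receptor == study$planted$receptor
  expect_true(any(hit))
  # the planted pair is recovered in (nearly) every aged iteration
  expect_gte(ag$freq_aged[hit], 0.9)
  # the aged-specific call list stays clean
  expect_lte(nrow(ag), 3)
})

test_that("a null study yields empty or balanced age-specific sets", {
  counts <- c(young = 0, aged = 0)
  for (i in 1:6) {
    study <- simulate_lr_study(seed = 2000 + 101 * i, planted = FALSE)
    ty <- bootstrap_prioritize(study$young, study$resource, n_iter = 20,
                               n_perm = 100, seed = 2001 + 101 * i)
    ta <- bootstrap_prioritize(study$aged, study$resource, n_iter = 20,
                               n_perm = 100, seed = 2002 + 101 * i)
    out <- stratify_and_filter(ty, ta, study$resource)
    counts["young"] <- counts["young"] +
      sum(out$age_class == "young_specific")
    counts["aged"] <- counts["aged"] + sum(out$age_class == "aged_specific")
  }
  if (sum(counts) > 0) {
    expect_gt(binom.test(counts["aged"], sum(counts), 0.5)$p.value, 0.01)
  } else {
    expect_equal(sum(counts), 0)
  }
})
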