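# Ready-made simulation scenario for ligand-receptor recovery studies.

#' Simulate a two-condition communication study with one planted
#' aged-specific interaction
#'
#' Builds the study design used to benchmark the bootstrapped
#' ligand-receptor prioritization end to end: a four-type cell population
#' with skewed abundances (so type-balanced subsampling actually
#' resamples), cell-type-structured background expression (every gene
#' carries mild type-specific signal in both conditions, the shared
#' biology the age stratification must cancel), and a single planted
#' interaction — a cell-type-restricted ligand in the sender and receptor
#' in the receiver, boosted only in aged cells. The resource mixes
#' curated and uncurated random pairs (drawn from genes not involved in
#' the planted interaction) plus the planted pair, which is curated.
#'
#' With `planted = FALSE` no interaction is planted (a null study in
#' which both conditions share the same expression law), for checking
#' that the age-specific call sets stay empty or balanced.
#'
#' @param seed integer seed.
#' @param n_resource_pairs size of the ligand-receptor resource.
#' @param n_curated curated pairs among them (planted pair included).
#' @param log2_boost planted boost (default 3, an 8-fold increase).
#' @param cells_per_donor,n_genes scale of the simulated data.
#' @param planted plant the aged-specific interaction? (`FALSE` = null
#'   study).
#' @return list with `young`, `aged` (normalized [CellMatrix] per
#'   condition), `resource` (`LRResource`), and `planted` (the planted
#'   interaction row — sender `A`, receiver `B` — or `NULL`).
#' @export
simulate_lr_study <- function(seed, n_resource_pairs = 50,
                              n_curated = 30, log2_boost = 3,
                              cells_per_donor = 150, n_genes = 300,
                              planted = TRUE) {
  planted0 <- data.frame(sender = "A", receiver = "B",
                         condition = "aged", log2_boost = log2_boost)
  cfg <- sc_sim_config(n_donors_young = 2, n_donors_aged = 2,
                       cells_per_donor = cells_per_donor,
                       n_genes = n_genes,
                       cell_types = c("A", "B", "C", "D"),
                       base_proportions = c(0.10, 0.15, 0.25, 0.50),
                       n_markers_per_type = 10, marker_log2fc = 2,
                       n_de_genes_per_type = 0, donor_effect_sd = 0.15,
                       type_effect_sd = 1.0, seed = seed)
  # the planted genes take the last two filler gene slots
  layout <- sc_gene_layout(cfg)
  filler <- layout$ids[startsWith(layout$ids, "G")]
  planted_df <- if (isTRUE(planted)) {
    data.frame(sender = planted0$sender, receiver = planted0$receiver,
               ligand = filler[length(filler) - 1L],
               receptor = filler[length(filler)],
               condition = planted0$condition,
               log2_boost = planted0$log2_boost)
  }
  sim <- generate_sc(cfg, planted_interactions = planted_df)
  m <- normalize_log1p(sim$matrix)
  pool <- setdiff(rownames(m$counts),
                  c(unlist(sim$truth$true_marker_genes),
                    sim$truth$mito_genes, sim$truth$ig_genes,
                    planted_df$ligand, planted_df$receptor))
  resource <- generate_lr_resource(
    pool, n_resource_pairs, n_curated,
    include = planted_df[c("ligand", "receptor")], seed = seed + 1)
  list(young = subset_cells(m, which(m$cell_meta$condition == "young")),
       aged = subset_cells(m, which(m$cell_meta$condition == "aged")),
       resource = resource,
       planted = planted_df)
}
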