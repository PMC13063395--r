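---
title: "Methods and design notes for bmniche"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for bmniche}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

bmniche implements the statistical core of an aging study of the human
bone-marrow niche: differential cell-type abundance between young and
aged donors, clustering robustness, marker and age differential
expression, gene-signature activity, spatial spot annotation and
co-localization, and ligand-receptor prioritization. This vignette
records the models behind each procedure, the tunable parameters and
their defaults, what the synthetic-data generator does and does not
emulate, and the design choices made where more than one reasonable
option existed.

## The synthetic-data generator

Every procedure in the package is exercised against data with known
ground truth, produced by `generate_sc()`, `generate_spatial()` and
`generate_lr_resource()`.

**Single-cell counts are Gamma-Poisson.** Each gene receives a
Gamma(shape 2, mean 1) baseline; cell-level counts are Poisson around a
product of multipliers, so counts are marginally negative binomial with
the overdispersion droplet data exhibit, without an extra fitted
parameter. The multipliers are:

* a marker effect: `2^marker_log2fc` (default 4-fold) on each type's
  marker block;
* an age effect: `2^de_log2fc` in aged cells on each type's DE block —
  `de_log2fc` may be a signed vector, recycled over the block, because
  recovery checks need graded effects, not a single magnitude;
* a per-donor, per-gene log-normal factor (`donor_effect_sd`, default
  0.15) — the simplest structure that makes donor-balanced procedures
  non-trivial;
* optionally a per-type, per-gene log-normal factor (`type_effect_sd`,
  default 0) giving every gene mild cell-type structure; it is off by
  default so the planted marker effects are the only type signal, and
  switched on for communication studies (below).

Cell-type membership is drawn per donor with condition-specific
probabilities: aged probabilities multiply each type's young odds
`p/(1-p)` by `aged_odds_multiplier` and renormalize.
`planted_proportions()` reports the implied truth and
`odds_multiplier_for_ratio()` inverts it — note a type at base
proportion *p* can shift at most `1/(p(2-p))`-fold, so large planted
ratios need rare types.

Gene means are scaled by a constant baseline total rather than each
cell's realized total, so a marker with `marker_log2fc = 2` has exactly
4 times the generative mean in its type; library sizes
(log-normal, median 2,500) are therefore expected values, not exact
column sums. A contiguous `MT-` block receives a per-cell mitochondrial
fraction drawn uniformly on `mito_fraction_range`, and an
immunoglobulin-named block exists purely so the name-based QC filters
have something to act on. The default cohort (4 young, 5 aged donors)
mirrors the scale of the motivating study.

**What the generator does not emulate:** batch effects requiring
integration, doublets, ambient RNA, zero inflation beyond
Gamma-Poisson, or donor-specific composition shifts (donor effects act
on expression only, so type proportions are exactly multinomial within
a condition). Tests passing on these data therefore say nothing about
robustness to those artefacts.

**Spatial spots** sit on a Visium-parity hexagonal grid
(`array_row + array_col` even; six neighbours at `(r, c±2)`,
`(r±1, c±1)`). Spot compositions are Dirichlet draws — optionally
biased per horizontal row band to plant co-localized types — and counts
are Poisson around the composition-weighted mixture of type profiles at
a target depth, so observed depth is conserved in expectation.

## Quality control and normalization

Cells are kept with strictly more than 200 detected features (a cell
with exactly 200 is removed) and mitochondrial fraction at most 10%;
genes afterwards if detected in strictly more than 3 cells. Spots are
kept with at least 200 UMIs **and** at least 150 features — failing
either threshold removes the spot, the conservative reading when the
two thresholds are stated jointly — and `IGH`/`IGK`/`IGL` genes are
dropped. Mitochondrial genes are identified by the `MT-` prefix.
Normalization is counts-per-10k log1p: a fully specified, reproducible
transform (variance-stabilizing alternatives are deliberately out of
scope, as their output depends on fitted parameters). Pseudobulk
aggregation sums raw counts per (donor, cell type) and flags groups
under 10 cells.

## Differential abundance

The permutation test fixes the two condition sizes and reassigns labels;
the per-type null is sampled exactly by nested hypergeometric draws,
which is the marginal distribution of a label shuffle (a literal shuffle
is kept as the oracle in the test suite). Two details matter
numerically: the add-one estimator `p = (1 + #extreme)/(1 + n_perm)`
never returns 0 at finite `n_perm`, and a zero count in either condition
adds 0.5 to both counts of that ratio before the log (flagged in
`zero_corrected`). Significance requires FDR < 0.05 **and**
|log2FD| > 1 — a minimal-p type with a modest fold change is not called
(the worked README example shows exactly this).

The condition-balanced interval resamples `min(N_young, N_aged)` cells
from each condition **with replacement** and takes 2.5/97.5
linear-interpolation percentiles over (default) 100 iterations.
Sampling with replacement is a genuine bootstrap: a without-replacement
subsample of size `min(N_young, N_aged)` degenerates to the identity
when the conditions are equal in size and its variance carries a
finite-population factor otherwise, so the resulting interval cannot
attain nominal coverage; the bootstrap attains 95–97% coverage under
the generator (slightly conservative for the larger condition). The
`replace = FALSE` variant remains available.

The odds ratio uses the Woolf (log-normal) interval
`exp(ln OR ± z · sqrt(Σ 1/cell))` — chosen for its closed form — with
the Haldane-Anscombe 0.5 correction when any cell is zero.

## Differential expression

The rank-sum test with normal approximation and tie correction is used
per gene, gated on detection in more than 25% of cells in *either*
group (the common single-cell convention; the max-of-groups choice is
ours). Fold changes are computed on `expm1` of the normalized values
with a `1e-9` pseudocount. Marker calling uses |log2FC| > 1, age DE
0.5, both at Bonferroni-adjusted p < 0.05. The donor-level route
converts pseudobulk to CPM, takes `log2(CPM + 1)`, averages donors per
condition and differences; on generator data with graded planted
effects its Spearman concordance with the truth exceeds 0.95. This
pseudobulk route is also the package's answer to donor covariates: the
cell-level test ignores them by design.

## Clustering stability

`cluster_stability()` repeats donor-balanced downsampling (default 50
cells per donor, 100 iterations), reclusters with a pluggable backend,
and scores each iteration with per-original-cluster best-match Jaccard
(computed on the downsampled cells, where the recomputed partition
exists) and the ARI. The default backend — top-2,000 variable genes,
PCA, seeded k-means with k equal to the number of original clusters —
is a deterministic stand-in for graph-based pipelines whose results
are not reproducible from a written description; any
`(m, k, seed) -> labels` function can replace it. Best-match (rather
than globally matched) Jaccard is used because a per-cluster score is
the quantity of interest.

## Signature scoring

For one cell or spot, genes are ranked by decreasing expression with
ties broken by a single seeded permutation fixed per matrix (average
ranks would collapse the zero block of sparse data to one rank);
with `T = ceiling(top_fraction × n_genes)` the score is

    AUC = Σ_{g in S, r_g ≤ T} (T − r_g + 0.5) / (T · |S ∩ universe|)

the exact area of the left-closed recovery step curve (the `+0.5` is
the trapezoid midpoint, which makes the independent integration oracle
in the tests unambiguous). The score is invariant under monotone
transforms of expression. `top_fraction` defaults to 0.05, the
established convention for this family of scores.

## Spot labeling and co-localization

With `p̄_c` the mean deconvolved fraction of type *c* over spots
(e.g. around 0.3 for MSC and 0.16 for EC in marrow sections),
`n_top = ceiling(p̄_c · n_spots)` and `n_high = ceiling(2 p̄_c ·
n_spots)`; golden spots are in the top `n_top` of **both** the AUC and
fraction rankings, high in the top `n_high` of both (the both-rankings
reading parallels the golden rule), and AUC = 0 forces *rest*
regardless of the deconvolution rank. Ranking ties break by spot id so
labels are deterministic. Percentages are interpreted as fractions of
the spot count. NNLS deconvolution regresses spot CPM on reference
profile CPM and renormalizes; all-zero solutions get uniform fractions
and a flag.

Co-localization restricts to the golden spots of the anchor type and
Spearman-correlates its AUC against the partner's AUC in the same spot
or averaged over present hex neighbours (exact permutation p at
n ≤ 9). Two properties of compositional data shaped the test design
and should inform interpretation: among spots selected for a high
anchor fraction, any other type's fraction is mechanically depressed
(Dirichlet components are negatively correlated, about −1/(K−1) for K
symmetric types), so a mild negative same-spot correlation is the null
expectation unless a shared spatial gradient overrides it; and the
per-spot AUC is a noisy proxy whose sampling floor is roughly
`1/sqrt(n_golden)`. The test fixtures therefore include a high-alpha
"background" type standing in for the hematopoietic mass that
dominates real spots, and plant co-localization as a smooth shared
abundance gradient across row bands.

## Ligand-receptor prioritization

Each age group is analyzed separately: per bootstrap iteration the
types are downsampled to the minimum type count, three scores are
computed for every (sender, receiver, ligand, receptor) — the
permutation p of `(mean ligand in sender + mean receptor in
receiver)/2` under type-label shuffles, the specificity product
`(mean_L,sender/Σ_t mean_L,t)(mean_R,receiver/Σ_t mean_R,t)`, and the
saturating magnitude `sqrt(lr)/(sqrt(lr) + μ)` with `μ` the global
matrix mean — and combined by robust rank aggregation: with sorted
normalized ranks `r_(1..m)`, `rho = m · min_k BetaCDF(r_(k); k,
m−k+1)`, capped at 1. Multi-subunit complexes take the minimum over
members. Interactions with `rho < 0.01` are recorded; bootstrap
frequency is tallied over ever-recovered interactions (tallying over
the full resource would drive the later percentile threshold to
zero), and retention keeps frequencies at or above the 95th percentile
of that distribution — `≥`, so ties at the maximum are never all
discarded. Age classes follow by set algebra on the retained keys and
only curated interactions (`curation_effort ≥ 1`) survive.

Because `rho` behaves like a p-value, the rank cut admits roughly 1% of
the interaction table in *every* iteration, signal or not; the
procedure's specificity therefore rests on the frequency filter and the
age stratification, and `simulate_lr_study()` freezes the study design
under which those two stages can work:

* **skewed type abundances** (0.10/0.15/0.25/0.50): with equal types
  the balanced subsample is the identity and every noise interaction
  repeats at frequency 1;
* **type-structured background** (`type_effect_sd = 1`, shared by the
  conditions): the stably top-ranked background interactions are then
  genuinely specific in both age groups and cancel as *shared*;
* **a cell-type-restricted planted pair**: ligand and receptor at unit
  baseline, boosted 8-fold in the sender/receiver type and depleted to
  1% of baseline elsewhere, in aged cells only. Restriction is
  essential, not cosmetic — with baseline-level off-target expression
  the two magnitude-driven scores rank wrong-sender/receiver versions
  of the pair above all noise and attribution fails;
* **a 60% curated resource** whose random pairs avoid the planted
  genes (a pair reusing the boosted receptor would be genuinely
  aged-specific), with the planted pair curated, so the curation
  filter actively removes calls.

Under this design the aged-specific curated set recovers the planted
interaction with precision and recall above 0.9 in the test suite.

## Numerical conventions and degenerate inputs

Seeds are threaded explicitly through every stochastic function
(`withr::local_seed`, restoring the caller's RNG); identical inputs and
seeds give identical outputs, byte for byte. Percentile-type quantities
(bootstrap CIs, the frequency threshold) use R's default
linear-interpolation quantile. Empty results fail loudly: QC that
removes everything names the binding filter, a zero-margin 2×2 table
and a zero-variance correlation are errors rather than silent zeros or
ones, and an all-`rest` labeling or an empty prioritization table warns.

## Problem sizes

The test suite and acceptance script run at desk scale, chosen so each
statistical property is measurable with comfortable margin: abundance
calibration over 120–200 null cohorts of 2,000 cells, power and
coverage over 40–100 cohorts, 400–1,600-spot grids for spatial
recovery, and 8–20 communication studies of 600 cells each. These sizes
are stated in the corresponding test blocks and in
`scripts/acceptance.R`.

## Known limitations

The clustering backend is a stand-in, not a reimplementation of
graph-based pipelines; MAST-style hurdle models, variance-stabilizing
normalization, CARD's spatially-aware deconvolution, regulon inference
and composition clustering are out of scope. The GLMM sometimes used to
relate subtype membership to chronological age
(`cell_type ~ age + (1|donor)`, binomial family) is documented here for
completeness but delegated to any mixed-model engine and not part of
the tested surface. Abundance inference treats cells as exchangeable
within a condition given the donor-balancing step; strong
donor-composition effects beyond those the generator emulates would
require the GLMM route.
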