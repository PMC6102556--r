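---
title: "Spatial phylogenetic diversity, endemism and multi-taxon concordance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatial phylogenetic diversity, endemism and multi-taxon concordance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phylospat)
library(dplyr)
```

phylospat implements grid-based spatial phylogenetics for one or several
co-registered taxonomic groups: per-cell diversity and endemism surfaces, a
constrained randomization null with CANAPE endemism categories,
phylogenetic (phylo-jaccard) beta diversity, and a cross-taxon layer that
standardizes, averages and fuzzily compares surfaces across groups. This
vignette is the package's own account of the models, conventions and
numerical choices, and of what the synthetic-data generators do and do not
emulate.

## Data model

Everything runs on two objects per taxonomic group:

* a **rooted phylogenetic tree** with branch lengths (`phylo`, read with
  `read_tree()`), whose tips are taxon names;
* a **cell-by-taxon presence–absence matrix** (`pa_matrix`), built by
  binning point occurrence records (planar meters, assumed already in an
  equal-area projection — the package performs no reprojection) into
  square grid cells, 25 km by default. Cells are half-open intervals
  `[low, high)` with floor binning, so a record exactly on a cell boundary
  belongs to the higher-index cell, bit-reproducibly. The grid origin
  defaults to the data minimum floored to a cell multiple and is
  configurable, and an optional polygon mask (boundary-inclusive
  point-in-polygon) restricts the domain.

Row sums of the matrix are per-cell taxon richness; column sums are
per-taxon range sizes $r_i$ in cells. Cells without records are not
materialized: absence from the matrix means *unsampled*, not richness
zero — a distinction the cross-taxon layer relies on. Name reconciliation
between matrix and tree is exact string matching with either a `strict`
policy (error on any mismatch) or `prune-both` (intersect and prune);
taxonomic synonymy is out of scope.

## Per-cell metrics

For a cell $c$ with taxon set $S_c$:

* **TR** (taxon richness): $|S_c|$.
* **WE** (weighted endemism): $\sum_{i \in S_c} 1/r_i$. Summed over all
  cells, WE equals the number of taxa.
* **PD** (phylogenetic diversity): the total branch length of the tree
  subgraph spanned by $S_c$. The central structure is the
  `branch_incidence()`: per branch $b$, its length $L_b$ and the set of
  cells containing at least one descendant tip, computed in a single
  post-order pass; the branch range $R_b$ is the size of that set.
* **PE** (phylogenetic endemism):
  $\sum_{b \ni c} L_b / R_b$ — PD with every branch down-weighted by how
  widespread it is. Summed over all cells, PE equals the total counted
  tree length; both conservation identities are asserted to $10^{-9}$
  relative tolerance in the tests.
* **RPD / RPE**: the ratio of PD (or PE) on the actual tree to the same
  quantity on a *comparison tree* of identical topology in which every
  counted branch is set to (total length)/(number of branches)
  (`equalize_branch_lengths()`), so total length is preserved. Ratios
  above 1 flag concentrations of unusually long branches, below 1 of
  unusually short ones. Because topology and occupancy are unchanged by
  equalization, the comparison PE reuses the same branch cell sets and
  ranges; only the lengths differ.

**Path convention.** By default PD and PE follow the tips-to-root
convention: a cell's branch set is the union of the tip-to-root paths of
its taxa, excluding only a root stem if the newick carries one. This is
the dominant convention in spatial phylogenetics software. A crown-only
variant (`convention = "crown"`), which additionally removes the shared
root-to-MRCA path, is available on every metric; under it a single-taxon
cell scores PD 0, and relative metrics are undefined wherever the
comparison value is 0 (an error lists the offending cells). On a star
tree with unit branches the two conventions coincide and PD reduces to TR
and PE to WE, which the tests assert. Polytomies are accepted as-is;
zero-length branches are retained and contribute zero.

## The randomization null and CANAPE

Observed PD and RPD are tested two-tailed, and CANAPE's step one
one-tailed, against a **fixed-margin null**: taxa are reassigned to cells
with every cell's richness and every taxon's range held exactly constant,
which amounts to handing each cell a random selection of the same number
of terminals. The sampler is curveball trading (random pairs of cells
exchange their exchangeable taxa), run as one sequential chain with a
burn-in of `burn_in_swaps_factor` (default 5) times the number of
presences before the first emitted matrix and a thinning of
`thin_swaps_factor` (default 1) times the presences between matrices.
A sequential thinned chain was chosen over independent chains per
replicate because it buys the same stationary draws at a fraction of the
trades; burn-in and thinning are expressed in presences so they scale
with the matrix. The whole ensemble is a pure function of (matrix, tree,
seed), and every emitted matrix satisfies the margin constraints exactly
(hard-asserted in the tests).

P-values are rank-based and never zero:
$p_{high} = (1 + \#\{\text{null} \ge \text{obs}\})/(1 + n_{reps})$, with
$p_{low}$ symmetric; ties count into both tails, which is deliberately
conservative. Two-tailed tests split $\alpha$ evenly per tail. Defaults
are 999 randomizations and $\alpha = 0.05$.

**CANAPE** classifies each cell in two steps: step one requires
significantly high PE (one-tailed, $\alpha$); step two reads the
two-tailed RPE test — significantly high RPE means the endemism is
carried by rare *long* branches (paleo-endemism), significantly low RPE
by rare *short* branches (neo-endemism), and otherwise the cell holds a
mixture (mixed-endemism), upgraded to super-endemism when the step-one
p-value is at or below the stricter `alpha_super` (default 0.01). The
categories are mutually exclusive and exhaustive. Step one defaults to PE
on the actual tree; `step_one = "either"` passes a cell if PE on either
the actual or the comparison tree is significantly high, with the
step-one p taken as the smaller of the two. The either-tree rule matters
in practice: a concentration of rare *short*-branched taxa barely moves
actual-tree PE (its branches are short by construction) but moves
comparison-tree PE strongly (each rare branch counts at full average
length), so neo-endemism is mainly detectable through the comparison
tree. The recovery experiments below therefore use the either-tree rule.

### Calibration and its limits

`calibrate_null_rates()` measures the empirical type-I behaviour: one
64-tip pure-birth tree is held fixed; per outer replicate a fresh
disc-model matrix over a 20 × 10 grid of 25-km cells is drawn and
replaced by a fixed-margin draw (so the null holds by construction), and
the 999-trial tests run on every cell. Twenty outer replicates are the
default problem size; the one-tailed PE pass rate and the stricter
0.01-level rate land on their nominal levels (≈ 0.05 and ≈ 0.01).

The two-tailed PD test, however, is *structurally conservative* on
sparse cells, and the package reports this honestly rather than hiding
it: with the tie-inclusive rank convention, a cell of richness 1 has a
null PD distribution with at most as many atoms as there are taxa, the
extreme atoms carry more than $\alpha/2$ mass, and the attainable
rejection probability is exactly zero; richness 2–3 cells attain about
half the nominal two-tailed level. Averaged over the disc-model richness
distribution the empirical two-tailed rate is about 0.03–0.035 against a
nominal 0.05 — a property of the stated convention on discrete nulls,
verified against a direct enumeration of attainable tail masses, not a
sampler defect (the one-tailed rates, which face milder discreteness,
are on target).

### Scenario recovery

`inject_endemism_scenario()` grafts rare taxa onto an existing dataset
without touching it otherwise, so the base data remain a control. Paleo
scenarios add single tips whose subtending branch is the base tree's mean
tip branch length times `branch_scale` (default 10) with a range of 1
cell; such branches land in the top branch-length decile by construction.
Neo scenarios add a star cladelet of sisters (default 5 tips at scale
0.1, ranges of 2 cells) — a caricature of a recent, range-restricted
radiation. `scenario_recovery()` injects at a cell of *median* richness
(a cell whose endemism signal the injected taxa dominate; injecting into
the single richest cell instead tests dilution by the base assemblage,
where a mixed/super call is the scientifically right answer) and checks
the CANAPE category at the target over 20 independent datasets: paleo
counts as recovered when classified paleo or super, neo when classified
neo.

## Phylogenetic beta diversity

`phylo_jaccard()` is one minus the shared fraction of branch length:
with $A$ the length present in both cells and $B, C$ the lengths unique
to each, $(B + C)/(A + B + C)$, using the same path convention as PD so
shared ancestral branches count as shared signal. Two cells with
identical branch sets score 0, cells sharing nothing score 1, and two
empty branch sets (possible only under the crown convention) are defined
as distance 0. Cells are clustered by unweighted average linkage
(UPGMA); items are sorted lexicographically before clustering so tied
merges resolve deterministically, `cut_clusters()` removes the $k-1$
highest merges, and dendrograms export to newick with cophenetic
distances preserved. The number of clusters $k$ is a user parameter.

## Cross-taxon layer

Comparisons run on observed TR, WE, PD and PE surfaces. Each group is
first standardized to $[0,1]$ by its own min and max
(`standardize_groups(mode = "per-group")`); the sentence defining the
standardization in the methods literature is ambiguous between per-group
and pooled min/max, so `mode = "pooled"` is also provided, and a
constant surface maps to all zeros with a warning. Two summary surfaces
follow:

* **mean-all**: per cell, the mean over the groups *materialized* there.
  Cells missing a group average over the present groups — imputing 0
  would conflate "unsampled" with "zero diversity". This is an
  interpretation, documented as such.
* **mean-concordant**: restricted to cells where *every* group has a
  nonzero standardized value; the concordant set is exactly the
  intersection of the groups' nonzero cells, so dropping a group
  (`leave_group_out()`) can only grow it — the sensitivity analysis for
  groups of restricted coverage such as fish.

`fuzzy_numerical_similarity()` compares two surfaces with spatial
tolerance: per cell, the local similarity
$s(u, v) = 1 - |u - v| / \max(|u|, |v|)$ (1 when both are 0) is
maximized over neighbor cells within a radius (default 100 km, i.e. a
200-km-diameter circle) under a linear distance decay, in both
directions; the cell score is the minimum of the directions and the
scalar score the mean over mutually materialized cells. This transparent
formula is a stand-in for proprietary fuzzy map-comparison software and
is documented as *not* a replica of any of them. Group-by-group scalar
dissimilarities feed the same average-linkage clustering, giving one
group dendrogram per metric with heights in $[0,1]$.

## Synthetic data: what it emulates, what it does not

No generative model underlies the real analyses this package supports —
they run on herbarium and survey records with published phylogenies — so
the generators are stand-ins designed to reproduce the *statistical
structure* the method assumes, not the biology:

* `simulate_tree()`: pure-birth (Yule) trees. Chosen over birth–death
  because the analysis needs branch-length heterogeneity, not realism.
* `simulate_occurrences()`: disc ranges with lognormal radius (defaults:
  median radius 2 cells, log-sd 0.6 — a 25-km-cell caricature of
  clustered regional ranges) around centers drawn from a 3-component
  Gaussian mixture when `center_clustering > 0`, giving the spatially
  autocorrelated composition the beta-diversity stage assumes. Every
  taxon occupies at least one cell.
* `simulate_null_dataset()`: exact-margin matrices from given richness
  and range vectors — Gale–Ryser feasibility check, greedy construction,
  curveball burn-in.

Not emulated: climate- or niche-based ranges, abundance, sampling bias,
coalescent history, taxonomic error. Passing tests on these generators
show the machinery is correct and calibrated under its own assumptions;
they do not show that real data meet those assumptions.

## Numerical choices and limitations

* All generators and the ensemble are pure functions of their integer
  seeds; the pipeline derives per-stage seeds from one global seed.
* Conservation identities are asserted at $10^{-9}$ relative tolerance;
  oracle-equivalence tests at $10^{-12}$.
* Degenerate inputs: all-zero trees refuse equalization; single-cell
  matrices refuse pairwise dissimilarity; infeasible margins refuse
  sampling; an all-ones matrix is its own (unique) randomization.
* The two-tailed randomization test is conservative on cells of richness
  1–3 (see Calibration); interpret sparse-cell significance accordingly.
* No multiple-testing correction is applied across cells, matching
  standard practice for these maps.
* Problem sizes used by the shipped experiments — 64-tip trees, 200-cell
  grids, 999 randomizations, 20 outer replicates — were chosen as the
  smallest sizes at which the calibration quantities stabilize.

## A one-group run

```{r example, eval = FALSE}
tree <- simulate_tree(64, seed = 7)
pa <- simulate_occurrences(tree, range_model(), seed = 3)
surfaces <- diversity_metrics(pa, tree, group = "demo")
ens <- build_null_ensemble(pa, tree, randomization_config(seed = 11))
canape_map <- canape(ens)
table(canape_map$category)
autoplot(surfaces)
autoplot(canape_map)
```
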