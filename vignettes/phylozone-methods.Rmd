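---
title: "Phylogeny-weighted spatial prioritization: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phylogeny-weighted spatial prioritization: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phylozone)
library(dplyr)
```

## The problem

Reserve networks are usually judged, and expanded, by how many species they
cover. phylozone implements the complementary view: protect the *tree of
life*, i.e. as much summed branch length of a phylogeny as possible. Every
branch of the tree is treated as a spatial feature — present in a cell
whenever any of its descendant species occurs there — and weighted by its
length, so that ranking cells for protection trades off species exactly in
proportion to the unique evolutionary history they carry.

The package covers the whole workflow at desk scale: simulating landscapes
with the statistical structure the analysis assumes, a stand-in suitability
model with the standard evaluation/ensembling/clipping chain, branch
feature construction and Faith's PD, an iterative marginal-loss cell
ranking with protected-area lock-in, and the protection accounting used to
judge a reserve system (gap analysis, branch coverage, human pressure,
novel climate).

## The prioritizer

Given binary feature-by-cell occurrences $a_{ji}$, weights $w_j > 0$ and
cell costs $c_i > 0$, define the proportional occurrence
$q_{ji} = a_{ji} / \sum_{i' \in R} a_{ji'}$ over the remaining landscape
$R$. The marginal loss of removing cell $i$ is

* core-area zonation (CAZ): $\max_j w_j q_{ji} / c_i$;
* additive benefit function (ABF): $\sum_j w_j q_{ji} / c_i$.

Cells are removed one at a time, always the cell of minimum loss,
recomputing $q$ as totals shrink; the removal order (scaled to `priority =
order / n`) is the rank map, and the top fraction $f$ of the landscape is
the $\lceil f n \rceil$ cells removed last. CAZ is the default because a
cell's value is driven by the most irreplaceable branch it holds — losing
the last cell of a long branch is the worst possible loss of evolutionary
history, which is precisely the quantity being protected.

Numerical choices:

* Cells are removed strictly one at a time (no batched removal): grids of
  a few thousand cells need no acceleration, and the exact greedy is the
  cleanest behaviour to verify against an independently coded oracle
  (which the test suite does exhaustively on small instances).
* Ties in marginal loss are broken by a seeded uniform random key per
  cell, so a run is a pure function of (features, rule, seed); on a
  landscape of identical cells the ranking is a seeded uniform
  permutation.
* The removal loop recomputes every remaining cell's loss each iteration
  in compiled code; the ABF sum uses extended-precision accumulation so
  that the compiled path and the base-R oracle agree bitwise.
* Locked-in cells (the protected-area mask) form a second stratum removed
  only after every free cell: existing reserves are pinned to the top of
  the ranking and expansion is chosen purely among free cells.
* Multiplying all weights by a positive constant leaves the order
  unchanged (both rules), so branch lengths need no normalisation.

ABF is implemented as the plain weighted sum. An exponentiated benefit
function would be a generalisation, but the plain sum is the form used for
the headline comparisons, so no exponent parameter is exposed.

## Branch features and Faith's PD

A branch (the edge above each non-root node) occupies the union of its
descendant tips' cells and weighs its branch length; the edge above the
root carries no length and is excluded. Local PD of a cell is the sum of
weights of branches reaching it, which is identical to the induced-subtree
definition *including the path to the root* — the convention under which a
single-species cell has nonzero PD (its tip-to-root path). Branch
identifiers are content hashes of the sorted descendant tip set, stable
across runs and topologically equivalent trees.

Polytomy resolution when grafting species onto a genus backbone samples a
birth–death subtree per genus and scales its crown depth to a uniform
fraction (default 0.2–0.8) of the genus terminal branch. This preserves
ultrametricity and positive branch lengths while leaving the within-genus
node heights diffuse; the published workflows that randomly resolve
polytomies report rank correlations near 0.98 between repeated
resolutions, so a single resolved tree is the default pipeline input and
repeated resolution is left to the caller (the generator is seeded, so
`lapply(seeds, ...)` reproduces any ensemble).

## The stand-in suitability model

The five classification/regression algorithms and the circulation-model
ensembles of large SDM studies are external tools; everything this package
asserts is the surrounding protocol, which is implemented in full:

* stratified 80/20 train/test splits, repeated 10 times;
* evaluation by the true skill statistic
  $\mathrm{TSS} = \mathrm{sensitivity} + \mathrm{specificity} - 1$ at the
  max-TSS threshold (candidates: all unique observed scores plus the 0/1
  endpoints; `score >= threshold`; smallest maximizer on ties);
* retention of replicates with $\mathrm{TSS} \ge 0.5$ (inclusive); species
  whose replicates all fail are flagged unmodellable and dropped with a
  log entry;
* cell-wise median ensembling of the retained maps (even counts average
  the two middle values);
* clipping of the binarized current range to the 200 km buffered minimum
  convex polygon of the occurrences (planar km on the equal-area grid;
  one or two occurrences degrade to a buffered point/segment);
* three future-dispersal scenarios: full (unconstrained), none
  (intersection with the current range), limited (future cells within
  200 km — 20 km per decade over a century — of the current range). These
  nest: none ⊆ limited ⊆ full.

The scorer itself is a quadratic logistic regression on the standardized
predictors (linear plus squared terms), which recovers unimodal
(Gaussian-niche) responses and is deterministic. Pseudo-absences are drawn
uniformly from unoccupied cells at a 1:1 presence:absence ratio (the ratio
is configurable since published calibration protocols often leave it
unstated). Species occupying nearly the whole landscape leave no
background to contrast against and are flagged unmodellable.

## The synthetic landscape generator

The generator is first-class, tested code; its defaults are the study
conditions for every property the package asserts about itself.

* **Grid**: 30 × 30 cells of 20 × 20 km (400 km²). The scale keeps a full
  pipeline run in minutes on one CPU while leaving ~900 cells, enough for
  spatial structure.
* **Climate**: six standardized variables, Gaussian-smoothed white noise
  with kernel sd `corr_len − 1` (so `corr_len = 1` is exactly white
  noise); default `corr_len = 3` gives fields whose lag-1 autocorrelation
  sits in the range typical of gridded bioclimate at this resolution.
  Future climate adds a constant shift (default +0.5 sd) per variable plus
  small iid noise — a deterministic, tunable range-shift driver.
* **Phylogeny**: constant-rate birth–death (defaults birth 1, death 0)
  with 150 tips.
* **Ranges**: niche optima evolve on the tree by Brownian motion (variance
  1 root-to-tip on the depth-rescaled tree), species-specific breadths are
  log-normal (median 0.9 sd, log-sd 0.5), and a species occupies cells
  with Gaussian suitability ≥ 0.5. This yields the two properties the
  analysis depends on — closely related species have correlated ranges
  (so PD has spatial structure) and range sizes are right-skewed — both of
  which are verified by simulation tests. Tips falling below the
  20-occurrence floor are nudged toward the climate centre up to 10 times,
  then dropped with a count.
* **Protected areas and human pressure**: HMI is a rank-uniform blend of a
  designated climate variable and noise (warm/lowland cells carry more
  pressure); reserves grow as clusters from seeded cells with selection
  weight $e^{-8 \cdot \mathrm{bias} \cdot \mathrm{HMI}}$, reproducing the
  historical bias of reserve systems toward low-pressure land. The
  realized protected share matches the requested fraction up to rounding.

What the generator does **not** emulate: real geography (coastlines,
elevation, spatial barriers), observation error in occurrence data,
non-climatic range limits (dispersal history, biotic interactions), land
cover dynamics, and any particular country's reserve system. Passing tests
therefore demonstrate the correctness and the qualitative behaviour of the
methods — e.g. that strategically chosen expansion beats random expansion
— not quantitative predictions for any real flora.

## Protection accounting

* A cell is protected when reserve polygons cover **more than** 30% of its
  area (strict inequality, following the 30%-by-2030 framing).
* Representation targets scale log-linearly with range area from 100%
  (≤ 1000 km²) down to 10% (≥ 250 000 km²); the endpoints and floor are
  config keys. Branches use the same function as species, applied to the
  branch's occupied area.
* Gap classes compare achieved protection against the target:
  `unprotected` (no protected cell), `gap` (≤ 20% of target),
  `partial_gap` (20–90%], `covered` (> 90%).
* Habitat-change vulnerability: CSH = (future − current)/current cells;
  `lost` when no future habitat, `greatly_expanded` when CSH > 0.8.
* HMI classes: low < 0.1 ≤ moderate < 0.4 ≤ high (left-closed).
* Novel climate: variables standardized by the reference stack; a
  projected cell's dissimilarity is its nearest-neighbour distance to the
  reference cells scaled by the mean pairwise reference distance; novel if
  above the 0.95 quantile of the reference cells' own leave-one-out
  dissimilarities. On exchangeable data the flag rate is ≈ 5% by
  construction. Note that exchangeability is a cell-level property: for a
  spatially autocorrelated reference every cell has a near-twin from its
  own field, so an independent projection drawn from the same distribution
  of *fields* is flagged above 5% — the calibration checks therefore use
  white-noise stacks.
* Group pressure summaries (existing reserves / selected expansion /
  unprotected land) are deliberately descriptive — mean, sd, n, class
  shares — rather than inferential; the qualitative contrasts the pipeline
  asserts are verified by seeded simulation instead of ANOVA.

## Design decisions that were genuinely open

* **Rank semantics.** The priority of a cell is `removal_order / n_cells`
  (higher = removed later = more important) so that "top fraction f" is
  simply `priority > 1 − f`. The alternative — labelling cells by the
  landscape fraction remaining at their removal — inverts the scale and
  makes the lock-in semantics awkward.
* **Hull buffer timing.** The convex-hull clip is applied after
  ensembling, to the binarized ensemble map; applying it per replicate
  would multiply geometry work without changing the result materially,
  since the hull depends only on the occurrences.
* **Threshold provenance for future maps.** Future projections are
  binarized with the threshold fitted on current data: a threshold is a
  property of the calibrated model, and refitting it on projected scores
  would let the future map drift from the model's calibration.
* **Near-ubiquitous species** (fewer than two background cells) cannot be
  evaluated and are treated as unmodellable rather than silently assumed
  present everywhere.
* **Problem sizes in tests.** Oracle-equivalence checks run on hundreds of
  small random instances (≤ 6 cells, ≤ 4 features; trees ≤ 12 tips) where
  exhaustive recomputation is exact; behavioural properties (expansion
  gain, placement bias, calibration) run on the generator's default
  30 × 30 / 150-species landscapes over 10–20 seeds, which keeps the whole
  suite within a coffee break on one CPU while leaving the assertions
  statistically meaningful.

## Known limitations

* The greedy removal recomputes all losses per iteration: O(cells² ×
  features). Fine to a few thousand cells; genuinely large grids would
  need the incremental-update and batched-removal machinery of production
  Zonation, which is out of scope.
* Connectivity, boundary-length penalties and cost layers beyond a
  constant are not implemented (an HMI-as-cost option exists at the API
  level via the `cost` argument but is not used in the headline runs).
* The stand-in scorer is one model, not an ensemble of algorithm
  families; model-structure uncertainty is therefore not propagated.
* Gap-analysis targets use the grid-cell approximation of range area;
  with equal-area cells this is exact up to cell granularity.
* The Brownian-niche generator cannot decouple deep-branch ranges from
  species richness: an internal branch's range is the union of its
  descendants' correlated ranges, so the cells richest in species are also
  the cells where most branches occur. One documented consequence is that
  on these landscapes a species-based ranking covers the *mean* branch
  range slightly better than the branch-weighted ranking (which instead
  maximises the total branch length represented, and does win on that
  statistic in every simulated landscape). Real floras contain relict,
  range-restricted deep lineages away from richness hotspots — exactly the
  situation where branch-weighted prioritization outperforms species-based
  prioritization on both statistics; reproducing that contrast requires
  range models richer than this generator. The corresponding simulation
  check in the test suite is expected to fail and is retained as a
  documented boundary of the synthetic study system.
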