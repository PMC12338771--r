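---
title: "Matching cells across serial tissue sections: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Matching cells across serial tissue sections: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coexist)
```

## The problem

Multiplexed tissue imaging (MTI) platforms measure tens of protein
markers per cell on a thin tissue section. Panel size limits and
incompatible assay protocols push studies to stain *consecutive*
sections of the same block with different panels. Registration can align
the images, but the sections contain different physical cells — except
for the nuclei that happen to span the cut between two sections. This
package estimates how many such shared nuclei to expect, matches them at
single-cell resolution, propagates combined-panel cell-type labels to
the cells that could not be matched, and summarizes the local
neighborhood structure around the matched cells.

## How many cells are shared? The overlap model

Model a nucleus as a sphere of diameter $d \sim \mathcal N(M, S)$
truncated to $d > 0$, with its center uniformly distributed along the
sectioning axis. Two consecutive sections occupy $(0, W)$ and $(W, 2W)$.
For one draw with radius $r = d/2$ and center $x$:

* **shared** if $x - r < W < x + r$ (the nucleus spans the cut);
* **unshared** if $0 < x + r < W$ (its top boundary lies inside
  section 1);
* otherwise it never touches section 1 and is skipped.

`simulate_overlap()` is the Monte Carlo version; `expected_shared_fraction()`
is the closed form. Conditional on $d$, the shared event has probability
proportional to $d$ and the unshared event probability proportional to
$W$ (it depends only on the top boundary), so the ratio converges to
$E[d]/(E[d] + W)$ with $E[d]$ the zero-truncated normal mean. At
$M = 7.8$, $S = 2.4$, $W = 5$ µm this gives $0.6095$; the simulation at
$10^6$ iterations lands within Monte Carlo error of it.

Numerical choices: non-positive diameter draws are *resampled*, not
clipped — clipping would create an atom at zero with no physical
meaning. Boundary comparisons use the strict inequalities above; tangent
configurations are measure-zero and are skipped, stated here for exact
reproducibility. The slab bounds for the uniform center default to
$(-(M+6S),\ W + M + 6S)$ and are checked at run time against the largest
sampled radius; the estimator is invariant to the bounds (a property the
tests assert), so the default only affects efficiency. The reported
standard error is the binomial $\sqrt{f(1-f)/n}$ on the classified
draws.

## Matching model

Both sections come as a registered integer label mask plus a per-cell
feature table (`section_data`). Three matchers share one candidate
notion and differ in the selection rule.

**Tracking** (`track_cells()`): for reference nucleus $a_i$, candidates
are the target labels present under its pixel footprint; the candidate
with the largest pixel overlap wins, ties broken by smaller centroid
distance, then lower label id. A reverse pass applies the same rule from
the chosen target over *its* full footprint; the pair is kept only if it
maps back. Kept pairs are exactly the mutual-best pairs, so the result
is bijective and identical when the sections are swapped (cycle
consistency by construction). The final label-id tiebreak is ours — the
overlap-then-distance chain alone does not guarantee determinism — and
makes the reverse-tie behavior well defined.

**Constrained assignment** (`build_cost_matrix()` +
`constrained_lsa()`): the cost of a pair is the Spearman correlation
distance $1 - \rho$ across the shared markers, with average ranks for
ties. Pairs whose centroid distance (in µm, via `pixel_size`) exceeds a
radius are *structurally infeasible*: they are excluded from the solver
input rather than given a large finite cost, which avoids overflow and
degeneracy, and a post-condition asserts that no solution uses one. The
solver is a rectangular Jonker–Volgenant-style successive
shortest-augmenting-path method with dual potentials. Each augmentation
runs Dijkstra from a virtual source joined to every still-unassigned
row, which yields a minimum-cost *maximum-cardinality* matching: rows
with no feasible augmenting path are reported unmatched instead of
failing the solve. The radius has no default — it is an empirical,
dataset-level choice — and `radius_um = Inf` gives the unconstrained
bulk-level baseline.

**Combined matcher** (`coexist_match()`): candidates are gathered
exactly as in tracking (the tests assert the candidate sets are equal),
but within the candidates the assignment minimizes the shared-marker
correlation distance, again with a reverse pass over the chosen target's
full footprint. Costs are computed lazily for candidate pairs only, so
total work is linear in the number of cells for bounded candidate
counts. Cost ties fall back to larger overlap, then smaller centroid
distance, then lower label. If either profile is constant the
correlation is undefined; such pairs carry the neutral sentinel cost 1.0
but lose to any defined cost, and among themselves the overlap rule
decides — this avoids both privileging and excluding feature-dead cells.
With no shared markers the matcher degrades to tracking. The reverse
pass reads the matcher's pseudocode literally (the chosen target's whole
footprint, symmetric with tracking); restricting it further is a
plausible alternative reading but breaks the symmetry that gives
swap-invariance.

### Two Spearman quantities

The package computes Spearman correlations in two orthogonal
directions, which must not be confused:

* `spearman_pair_cost()` — across *markers within one candidate pair*;
  this is the matching cost.
* `match_correlation()` — across *pairs within one marker*; its
  unweighted mean over markers is the **match quality** used to score a
  matching. Markers constant across pairs are excluded from the mean
  with a warning count. Whether the mean should weight markers is
  genuinely open; we use the unweighted mean.

### Standardization and ranks

`standardize_features()` z-scores each marker with the table's own mean
and population (divide-by-$n$) SD; the population convention is stated
because both conventions are common and the choice is otherwise
invisible. One subtlety discovered while testing: per-marker z-scoring
is *not* exactly neutral for the across-marker Spearman cost. Each
marker receives its own affine map, and maps with different scales can
reorder the values within one cell's profile differently for different
cells. The effect is negligible when marker scales are comparable, but
it is not identically zero, so the matchers take the feature table as
given and standardization remains an explicit, user-controlled step.

## Evaluation metrics

* `cycle_consistency_fraction()` — agreement between matching ref→target
  and target→ref, relative to the anchor count. Tracking attains 1 by
  construction. Constrained assignment does not: when anchors are taken
  on each side, the two directions optimize over different row sets, and
  the tests include a 2-vs-3 fixture where the directions provably
  disagree. `lsa_cycle_consistency_sweep()` traces the decay with
  radius, sharing radii between directions.
* `anchored_radius_sweep()` — match quality of the constrained
  assignment restricted to tracked anchors, random anchors (5 seeds by
  default, sampled without replacement), or all cells, across radii.
* `pairing_scores()` — precision/recall/F1 against a known
  correspondence, available on synthetic data.
* `pair_recovery()` and `misregistration_recovery()` — fraction of
  unperturbed pairs recovered after a rigid rotation/translation of the
  target section.

## The synthetic generator

`generate_tissue()` places spheres uniformly in a lateral slab with a
hard minimum center separation (rejection sampling), draws
zero-truncated normal diameters, assigns each nucleus one of
`n_cell_types` types, and builds a latent log-expression vector per
nucleus: a per-type archetype (i.i.d. $\mathcal N(0,
\text{type\_separation}^2)$ per marker) plus per-cell variation
($\mathcal N(0, \text{cell\_level\_sd}^2)$, log-normal on the intensity
scale). The z-extent is derived as
$[-(M+6S)/2,\ n_\text{sections} W + (M+6S)/2]$ so that every nucleus
that could touch a section is sampled uniformly; a separate z-size
parameter would only add a way to mis-specify the same condition.

`slice_sections()` renders section $k$ from the open interval
$((k-1)W, kW)$: a present nucleus becomes a disk at its $(x, y)$ center
with radius equal to the *maximal* circular cross-section of the sphere
inside the interval — that is how a 2D segmentation of a stained section
sees a nucleus, and it guarantees the presence rule of the overlap
model. Colliding disks are rasterized by nearest-center assignment
(parameter-free and deterministic; the hard-sphere separation keeps
collisions rare); disks below one pixel are dropped and counted. Odd
sections carry panel A, even sections panel B, with
`n_shared_markers = 8` present in both (two panels sharing eight markers
mirrors the tumor/immune panel design this kind of study uses). Observed
intensities are $\exp(\text{latent} + \varepsilon)$ with independent
per-section noise $\varepsilon \sim \mathcal N(0, \sigma^2)$,
$\sigma = \text{type\_separation}/\text{signal\_to\_noise}$.

Defaults and why: `diameter_mean = 7.8`, `diameter_sd = 2.4`,
`section_thickness = 5` (µm) are the nuclear statistics and thickness of
the breast-cancer TMA setting the methods target; `pixel_size = 0.65`
µm/px is a standard 10× MTI resolution; `min_center_separation = 4` µm
keeps nuclei from interpenetrating without imposing crystal order;
`type_separation = 2`, `cell_level_sd = 1`, `signal_to_noise = 2` give
matched true pairs a shared-marker correlation around 0.7–0.8 —
the "moderate" regime reported for real serial sections — while keeping
types separable.

**What the generator does not emulate.** Sections are perfectly
registered and the two disks of one nucleus are exactly concentric;
there is no segmentation error, no tissue loss, no staining artifacts,
and no batch effect between panels. This makes pure overlap voting
nearly an oracle — stronger than on real data, where segmentation and
registration differences are precisely what breaks it. Passing tests on
this generator therefore validate correctness and calibration of the
machinery, not end-to-end superiority on real tissue. In this clean
regime the combined matcher raises match quality over tracking by about
2–4 points (consistently across seeds), while its ground-truth pairing
F1 is statistically indistinguishable from tracking's (mean difference
about −0.007 across ten seeds at 1,000 nuclei): with concentric
footprints the 8-marker rank correlation occasionally lets a neighboring
cell steal a true pair in the reverse pass, a cost the molecular
information can only repay where geometry is ambiguous. The tests state
this comparison exactly as measured.

## Label propagation and its validation

`propagate_labels()` assigns each unlabeled cell the majority label of
its $k = 10$ nearest labeled cells under Euclidean distance on the
panel-specific markers; votes are unweighted ("majority" read
literally), and a vote tie goes to the nearest neighbor carrying one of
the tied labels — deterministic and distance-respecting. The k-NN vote
is computed directly on chunked vectorized distances so the tie rule is
exact. An optional `log1p` + z-score transform (fitted on the pooled
rows) matches common preprocessing.

`validate_propagation()` is the single-slide harness: cells with known
labels are split into "tracked" and "untracked" at proportions 0.1–1.0,
and for each of `n_panels` random marker panels (default 1000 panels of
half the markers) a classifier fitted on the tracked cells predicts a
subsample of the untracked ones (default `min(5000, n_untracked)`),
scored by class-weighted F1. At proportion 1.0 a random sample of the
tracked cells themselves is predicted, defining the self-consistency
ceiling. Ground-truth labels come from the synthetic generator's known
types; any label vector may be supplied, so labels from an external
clustering drop in unchanged. A panel/proportion whose tracked split
misses a class is flagged, not fatal. Everything is deterministic given
the seed.

## Recurrent cellular neighborhoods

`neighborhood_counts()` counts cell types within a closed ball of 30 µm
(default) around each anchor, excluding the anchor itself ("neighboring"
read literally; `include_anchor = TRUE` shifts every row by one count of
the anchor's own type). `rcn_cluster()` row-normalizes each panel's
count matrix to proportions, concatenates the two blocks, and runs
seeded k-means with 10 restarts at `n_clusters = 15` by default, with an
inertia curve over 5–50 clusters for elbow selection. Anchors with an
empty neighborhood in either panel are flagged and excluded — their
proportion rows are undefined. k-means uses the exact Hartigan–Wong
iteration (capped at 100 iterations); when the requested cluster count
reaches the number of distinct composition rows, the partition into
distinct rows is returned directly with a warning.

## Problem sizes and budgets in the test-suite

The tests run entirely on generated data: toy masks with hand-enumerated
expectations, 70–200-nucleus tissues for property checks (cycle
consistency across 20 seeds, swap invariance, candidate-set equality),
2,200–2,500-nucleus tissues for the geometric calibration checks
(tracked fraction and sliced shared fraction versus the analytic
overlap), ten 1,000-nucleus tissues for the matcher comparison, and
1,500 cells × 20 panels for the propagation harness. These sizes put
every Monte Carlo assertion at least a few standard errors away from its
threshold while keeping the whole suite around a quarter of a minute.
The assignment solver is validated against exhaustive enumeration on
hundreds of random instances up to 7×7 including infeasibility patterns.

## Known limitations

* Matching assumes pre-registered masks on a common grid; only rigid
  perturbation is provided, for robustness testing, not registration
  itself.
* Intensity normalization across platforms or batches is out of scope;
  costs are rank-based per pair, which absorbs monotone distortions of a
  single profile but not cross-marker batch structure.
* The matchers operate on one section pair per call; longer chains are
  composed by the caller, e.g. anchored on a middle reference section.
* Label masks are limited to 65,535 labels per image by the 16-bit TIFF
  writer.
* Spearman costs on small shared panels are noisy (rank-correlation SD
  is roughly $1/\sqrt{p-1}$ at $p$ markers); with very few shared
  markers the combined matcher approaches tracking and the sentinel
  fallback handles the degenerate cases.
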