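# coexist

Single-cell integration of serial multiplexed tissue images (MTI).

Multiplexed tissue imaging measures tens of protein markers per cell, but
panel size is limited, so studies routinely stain *consecutive* sections
of the same tissue block with different panels. Because a nucleus of
diameter *d* sliced into sections of thickness *W* often spans the cut
between two sections, a substantial fraction of cells is physically
present in both — under uniformly placed spherical nuclei the expected
shared fraction is *E[d] / (E[d] + W)*, about 61% for breast-cancer TMA
nuclei (*d* ~ N(7.8, 2.4) µm) at *W* = 5 µm. Matching those shared cells
across sections lets both panels be combined on the same physical cells.

The package is aimed at computational biologists working with registered
nuclear segmentation masks and per-cell mean-intensity tables (CyCIF,
mIHC, and similar platforms). It provides:

- **`simulate_overlap()` / `expected_shared_fraction()`** — Monte Carlo
  simulation of nuclei sharing between consecutive sections, and its
  closed-form limit.
- **`track_cells()`** — purely spatial matching: for each reference
  nucleus, the target label with the largest pixel overlap under its
  footprint wins, and a reverse pass enforces cycle consistency, so the
  pair set is bijective and identical when the sections are swapped.
- **`build_cost_matrix()` + `constrained_lsa()`** — spatially
  constrained rectangular linear sum assignment on the Spearman
  correlation distance (1 − ρ) of shared markers; pairs farther apart
  than a radius are structurally infeasible (never a large finite cost).
- **`coexist_match()`** — the combined matcher: candidates come from
  mask overlap exactly as in tracking, but the assignment minimizes the
  shared-marker correlation distance, with a cycle-consistency reverse
  pass. Costs are computed only for overlap candidates, so the work is
  linear in the number of cells.
- **`propagate_labels()` / `validate_propagation()`** — k-NN propagation
  of combined-panel cell-type labels to unmatched cells, plus the
  random-panel × tracked-proportion validation harness (class-weighted
  F1).
- **`neighborhood_counts()` / `rcn_cluster()`** — recurrent cellular
  neighborhood (RCN) analysis: per-anchor cell-type composition within a
  radius, row-normalized, concatenated across the two panels, and
  clustered with seeded k-means.
- **`generate_tissue()` / `slice_sections()`** — a synthetic
  serial-section generator (spherical nuclei, zero-truncated normal
  diameters, two panels with a shared subset, per-section noise) with
  exact ground-truth cross-section pairings, plus
  `apply_misregistration()` for rigid-perturbation robustness tests.
- **Metrics** — `match_correlation()` (match quality: mean Spearman
  correlation of shared markers across matched pairs),
  `cycle_consistency_fraction()`, `pairing_scores()`, `pair_recovery()`,
  `anchored_radius_sweep()`.

A command-line wrapper (`inst/cli/coexist`) exposes the stages as
subcommands (`simulate-overlap`, `synth`, `track`, `match`, `evaluate`,
`propagate`, `validate-propagation`, `rcn`).

## Worked example

```r
library(coexist)

# how many cells should two consecutive 5 um sections share?
simulate_overlap(1e6, diameter_mean = 7.8, diameter_sd = 2.4,
                 section_thickness = 5, seed = 1)
#> Monte Carlo nuclear overlap simulation
#>   diameter ~ N(7.8, 2.4) um (zero-truncated), thickness 5 um
#>   1000000 iterations: 158208 shared, 101311 unshared, 740481 skipped
#>   f_shared = 0.6096 (SE 0.00096); analytic limit 0.6095

# synthetic serial sections with known ground truth
cfg <- synthetic_tissue_config(n_nuclei = 500, slab_size = c(250, 250), seed = 7)
st  <- slice_sections(generate_tissue(cfg))
s1 <- st$sections[[1]]; s2 <- st$sections[[2]]
truth <- ground_truth_pairs(st)

cx <- coexist_match(s1, s2)        # overlap candidates + marker costs
tr <- track_cells(s1, s2)          # overlap majority vote only

pairing_scores(cx, truth)
#> # A tibble: 1 × 5
#>   precision recall    f1 n_matched n_truth
#> 1     0.880  0.972 0.924       117     106

match_correlation(cx, s1, s2)      # match quality, combined matcher
#> match quality (mean Spearman over 8 markers): 0.6943
match_correlation(tr, s1, s2)      # match quality, spatial baseline
#> match quality (mean Spearman over 8 markers): 0.6377
```

The simulator says ~61% of nuclei that touch the first section should
also appear in the second; the matchers recover the ground-truth pairs
with F1 ≈ 0.92 on this small tissue, and enriching the tracker with
shared-marker correlations raises the match quality from 0.64 to 0.69.
`autoplot()` methods are available for the simulator result, radius
sweeps, recovery sweeps, panel-validation tables and RCN results;
fitted-object summaries follow the `tidy()` / `glance()` convention.

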