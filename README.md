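# chromarch

Tools for dissecting bacterial chromosome architecture from two
complementary data streams, built around the *Corynebacterium glutamicum*
case: a circular ~3.2 Mb chromosome whose two replichores are zipped
together at a parS-site cluster near *oriC* by a ParB/SMC loading pathway,
visible in Hi-C contact maps as a secondary diagonal perpendicular to the
main one, and whose ParB partition complexes resolve under PALM into
macroclusters containing discrete nucleation subclusters.

The package is written for people who analyze bacterial 3C/Hi-C libraries
or single-molecule localization (SMLM/PALM) tables and want the full
chain — from raw read pairs or localization events to domain calls and
cluster statistics — as small composable functions with a ground-truthed
simulator behind every stage.

## What it computes

**Hi-C side**

- Read-pair event classification: the four strand-orientation classes
  (`++`, `+-`, `-+`, `--`) are profiled against restriction-fragment
  separation; uncut fragments appear as an inward (`+-`) excess and
  self-circles as an outward (`-+`) excess at short separations. Pairs in
  those excess zones, and all same-fragment pairs, are discarded as
  non-informative religation artifacts.
- Binning into 5 kb contact matrices and **sequential component
  normalization** (SCN): alternating L1 row/column scaling of the valid
  submatrix to a doubly stochastic limit, equalizing per-bin visibility.
- Map comparison: element-wise log2 ratio maps (masked, never infinite),
  and a stratum-adjusted correlation coefficient (SCC): both maps are
  mean-filter smoothed (half-width *h* = 3), cells are stratified by
  circular diagonal distance, and per-stratum Pearson correlations are
  combined with weights `N_k * sd(A_k) * sd(B_k)`. Strains are grouped by
  average-linkage clustering on `1 - SCC`.
- **Directional index** domain detection: for each 5 kb bin, the
  correlation-matrix vectors toward the left and right flanks (250 kb each
  way, circular wrap) are compared with a paired t-test; boundaries of
  chromatin interaction domains (CIDs) sit where t crosses from negative to
  positive with a significant, materially sized flank.
- **Secondary-diagonal score**: mean log2 enrichment of the anti-diagonal
  band through the parS-like anchor over distance-matched off-band
  controls — the dose readout for replichore cohesion.

**SMLM side**

- Event filtering (photons 70–350, PSF width at 1/e 70–170 nm, inclusive),
  blink grouping (3 on-frames, 0 off-frames, 30 nm radius, photon-weighted
  centroids), and point-in-polygon cell assignment.
- **OPTICS** reachability ordering (MinPts = 32, ε = 3000 nm) per cell,
  with nested cluster extraction by horizontal reachability cuts: 50 nm
  for macroclusters, 35 nm for subclusters; clusters under 32 events are
  noise.
- Per-cell statistics on the two biggest macroclusters (events per
  macrocluster, subclusters per macrocluster) and two-tailed
  Kruskal–Wallis rank-sum comparison between conditions.

**Synthetic data with ground truth**

`generate_genome()`, `folding_truth()`, `expected_contact_matrix()` and
`sample_pairs()` build a parametric folded chromosome — power-law distance
decay `P(s) ∝ (1+s)^-α`, CID blocks, the anchored anti-diagonal band, the
ori cross, planted self-circles/uncuts with their strand signatures — and
sample fragment-level read pairs from it. `smlm_scene()` and
`simulate_localizations()` build per-cell localization tables with nested
macro/sub cluster structure, blinking, photon/PSF laws and background.
Every record carries its true label, so each pipeline stage is scored
against truth in the tests.

## Worked example

The `analysis/` scripts chain the exported functions into the two
workflows; run them in order from the repository root:

```sh
Rscript analysis/01_simulate_hic.R     # 2M read pairs, two conditions
Rscript analysis/02_contact_maps.R     # classify -> bin -> SCN -> DI -> compare
Rscript analysis/03_arm_cohesion.R     # arm-score dose response
Rscript analysis/04_simulate_smlm.R    # PALM scenes, two conditions
Rscript analysis/05_smlm_clusters.R    # filter -> group -> OPTICS -> stats
```

`02_contact_maps.R` prints, for a wild-type-like library versus a
cohesion-null library (band and cross absent):

```
wt: thresholds (uncut 3, circle 0); SCN 11 iterations; 12 boundaries; arm score 0.926
cohesion_null: thresholds (uncut 3, circle 0); SCN 8 iterations; 12 boundaries; arm score 0.031
SCC(wt, cohesion_null) = 0.6638
```

Read: the classifier recovered the planted uncut separation (3 fragments);
SCN converged in ~10 passes; about a dozen CID boundaries are called on a
map with 9 planted domain edges; and the arm-cohesion score collapses from
0.93 to 0.03 when the planted band is removed — the contrast the log2
ratio map localizes to the anti-diagonal. `05_smlm_clusters.R` ends with

```
   metric    chisq df            p nA nB
 n_events 14.38304  1 1.491393e-04 10 10
    n_sub 19.00000  1 1.307185e-05 10 10
```

the Kruskal–Wallis comparison of the two biggest macroclusters per cell
between a three-subcluster and a one-subcluster condition: both cluster
size and subcluster count separate the conditions decisively.

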