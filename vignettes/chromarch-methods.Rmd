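---
title: "Models and methods behind chromarch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind chromarch}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

chromarch implements two analysis chains for bacterial chromosome
architecture — Hi-C contact maps and PALM/SMLM cluster analysis — together
with a ground-truthed simulator for both. This vignette explains the models,
the parameters that matter, the numerical choices, and what the synthetic
data do and do not establish about real data.

## The folded-chromosome model

The simulator describes a circular chromosome of length $L$ (default
3.21 Mb, the *C. glutamicum* size) binned at $b$ = 5 kb. The expected
contact intensity between bins $i$ and $j$ is

$$E_{ij} = P(d_c)\; c_{ij}\; \bigl(1 + A e^{-d_a^2/2w^2}\bigr)
           \bigl(1 + C (g_i + g_j)\bigr) + \eta \bar{E}$$

with

* $P(s) = (1+s)^{-\alpha}$, the power-law contact decay in circular bin
  distance $d_c(i,j) = \min(|i-j|,\,n-|i-j|)$. The $+1$ keeps the diagonal
  finite; $\alpha$ defaults to 0.7, a typical short-range decay for
  bacterial 3C data at 5 kb resolution.
* $c_{ij}$, the chromatin-interaction-domain (CID) factor: `cid_contrast`
  (default 1.5) when $i$ and $j$ fall in the same planted domain, 1
  otherwise. Default boundaries cut the circle into nine domains of a few
  hundred kb, the scale of published bacterial CIDs.
* the anti-diagonal band: loci equidistant from an anchor on opposite arms
  (positions $a+s$ and $a-s$) contact each other. $d_a$ is the distance of
  $(i,j)$ from that anti-diagonal, $w$ = 50 kb its width, and $A$ the
  amplitude (default 1; 0 removes the band). The anchor default, 3.16 Mb,
  is the parS-cluster position, ~73 kb upstream of *oriC* at the origin of
  coordinates. This emulates replichore cohesion zipped from a
  ParB-*parS*/SMC loading site.
* the cross: $g_i$ is a Gaussian (width 50 kb) in the circular distance of
  bin $i$ from the anchor, so the anchor's row and column are enriched
  against the whole chromosome ($C$ = 0.3) — the faint cross shape around
  an anchored locus.
* $\eta \bar E$, a uniform floor at fraction $\eta$ = 0.05 of the mean
  structured signal.

The model is phenomenological: it reproduces the *map-level* features the
analyses quantify (decay, domains, band, cross) without polymer physics.
Pairs are sampled per matrix cell, placed uniformly within bins, snapped to
restriction fragments (i.i.d. exponential lengths, mean 256 bp — the
expectation for a 4-cutter such as MluCI), and given uniform strand
orientations. Non-informative classes are planted with their geometric
signatures: self-circles as same-fragment outward (`-+`) pairs, uncuts as
inward (`+-`) pairs within `uncut_max_fragments` (default 3).

What passing tests on this generator show: the classifier, normalizer,
comparison statistics and boundary caller recover *planted* structure of
the stated kind at realistic depth. What they do not show: robustness to
mapping artifacts, copy-number gradients from replication, restriction-site
density bias, or duplicate reads — none of which the generator emulates.

## Pair classification

The classifier follows the religation-geometry logic: genuine trans-fragment
ligations carry all four strand configurations equally often, so each
non-informative class betrays itself as an excess of one configuration at
short fragment separations. `estimate_event_thresholds()` scans the
orientation profile and takes, per class, the largest separation whose
own-orientation frequency exceeds 1/4 by more than `tolerance` (default
0.05) *and* more than 3 binomial standard errors. Two details are
deliberate:

* **one-sided**: an uncut excess at separation $k$ necessarily depresses
  the other three frequencies at $k$; treating that deficit as evidence of
  a self-circle excess would discard a quarter of the genuine contacts at
  those separations. Only an excess of the class's own orientation counts.
* **the 3-SE gate**: at sparsely populated separations the frequencies
  fluctuate by far more than 0.05 from shot noise alone; without the gate
  the scan returns spuriously large thresholds.

Same-fragment pairs are always discarded, whatever their orientation — a
religated same-fragment pair cannot be informative, and the outward
subclass is exactly the self-circle geometry.

## SCN normalization

`scn_normalize()` alternates L1 row and column division over the valid
submatrix until every valid row sum is within `tol` = 1e-6 of 1 (at most
`max_iter` = 200 passes, ~10 in practice on these maps), then symmetrizes
as $(M + M^T)/2$ to remove the residual half-step asymmetry. Bins with zero
or bottom-quantile coverage (default quantile 0.01) are masked first; a
mask that leaves zero-coverage rows is an error rather than a silent
division by zero. Non-convergence warns and flags the result instead of
erroring: a pathological input should surface downstream, not vanish.
The fixed point is the doubly stochastic scaling, so the procedure is
invariant to global scale; the tests verify entry-wise agreement with an
independently coded scaling-vector Sinkhorn reference.

Display saturation is interpreted as clipping at the 99.5th *percentile* of
positive entries. The literal reading — 99.5% of the maximum value — is
implemented as `method = "fraction_of_max"` but not the default, because on
heavy-tailed contact maps it clips almost nothing.

## Map comparison

Log2 ratio maps mask any cell with a zero or masked operand rather than
clamping: infinities would otherwise dominate color scales and downstream
means. The SCC follows the stratum-adjusted recipe: smooth both maps with a
$(2h+1)\times(2h+1)$ circular mean filter ($h$ = 3), stratify by circular
diagonal distance up to 500 kb (resolution and smoothing are fixed by the
analysis protocol; the distance cap is this package's choice — half an arm
keeps every stratum populated on a 3.2 Mb circle), correlate per stratum,
and combine with weights $N_k \,\mathrm{sd}(A_k)\,\mathrm{sd}(B_k)$.
Zero-variance strata are skipped. One property worth knowing: smoothing
leaves the null SCC centered at zero but widens its spread, because window
means are spatially autocorrelated within each map; the package's null test
therefore checks independence at $h = 0$, where stratum cells are i.i.d.
Strain grouping uses average linkage on $1 - \mathrm{SCC}$ — the least
structure-imposing of the common linkages, since no linkage is prescribed
by the protocol being reproduced.

The secondary-diagonal score collects band cells (anti-diagonal distance
$\le$ `band_halfwidth_bins` = 2, i.e. ±10 kb) and compares them, per
circular-distance stratum, against off-band cells at the same distance
(anti-diagonal distance > 3× the half-width). The summary is the mean over
strata of $\log_2(\text{band mean} / \text{control mean})$. Stratum means
are compared — not individual cells — because per-cell log ratios on sparse
sampled maps require dropping zeros, which biases the score upward, while
Jensen's inequality biases it downward; stratum means sidestep both.
Strata within `min_dist_bins` = 10 of the main diagonal are excluded so
decay and domain structure near the diagonal cannot leak into the score.
The dose–response experiment in the tests and acceptance script varies the
band amplitude with the CID contrast at 1 and the cross at 0: it
calibrates the band detector in isolation, so that a zero amplitude
corresponds to a truly exchangeable band/off-band null.

## Directional index and boundary calls

The DI operates on the Pearson correlation matrix of the normalized map
(masked bins propagate as NA; correlations use pairwise-complete rows).
For each bin the left and right correlation vectors — 50 bins each way at
the 250 kb default window, circular wrap — are paired by distance and
compared with a paired t-test; positive $t$ means rightward preference.
Degenerate cases are pinned down explicitly: differences below $10^{-10}$
give $t = 0, p = 1$ (a circulant map has *exactly* zero preference, and
float dust must not manufacture one); constant nonzero differences give an
infinite $t$.

A boundary is a negative-to-positive $t$ transition between consecutive
informative bins where (i) at least one flank has $p < \alpha$ (default
0.05) and (ii) the flanking mean paired correlation difference reaches
`min_effect` = 0.01. The effect-size gate exists because significance alone
is not a preference: on noise-free maps, positions of exact local symmetry
(the midpoint of a domain, say) carry mean correlation differences of
order $10^{-5}$ that are perfectly consistent and hence wildly
"significant", yet are numerical residue on a scale where correlations
span [-1, 1]. One percent of that scale is the smallest difference we are
prepared to call a directional preference. The published analyses report
domain counts at a "resolution"; here that maps onto the window length
parameter, the one scale knob the procedure has.

The t-test's type-I behavior is verified by simulation: under i.i.d. null
differences the rejection rate at $\alpha = 0.05$ sits at 0.05 (2000
replicates in the acceptance suite).

## SMLM chain

Filtering keeps events with photons in [70, 350] and PSF width in
[70, 170] nm, all bounds inclusive ("between" read inclusively; the choice
is visible in the tests). Grouping merges events in consecutive frames
(0 off-frames allowed) within 30 nm of the running photon-weighted
centroid, splitting runs greedily after 3 on-frames, one event per frame
per molecule. Cell assignment is ray-casting point-in-polygon with
boundary points inside; an event claimed by two polygons is an error, not
an arbitrary choice.

OPTICS is implemented from its definition: core distance of a point is the
distance to its MinPts-th closest point (the point itself counted, so
exactly MinPts points fit in the ball), undefined beyond ε; reachability of
$q$ from $p$ is $\max(\mathrm{core}(p), d(p,q))$; the next point is always
the pending one with smallest reachability. All ties — and the choice of a
new component's start — resolve to the lowest point index, making the
ordering fully deterministic and testable against a brute-force reference
that recomputes every pending reachability from scratch at every step.
MinPts = 32 and ε = 3000 nm are the analysis defaults (ε spans a whole
cell, so no in-cell structure is truncated). Cluster extraction is the
horizontal cut: reachability above the threshold closes a cluster, the
closing point starts a new one iff its own core distance is within the
threshold, and clusters under MinPts events are demoted to noise — the
reading of "thresholds chosen to separate subclusters" consistent with a
fixed 50/35 nm pair. Nesting (every 35 nm cluster inside a 50 nm cluster)
is a theorem of the horizontal cut and is asserted, not repaired. Whether
the 32-event minimum applies before or after blink grouping is not pinned
by the protocol; the pipeline clusters grouped molecules, and MinPts
counts those.

Per cell, only the two biggest macroclusters (by event count, ties to the
smaller mean reachability — the tighter cluster) enter condition
comparisons, which use `stats::kruskal.test` (tie-corrected rank sums) on
events per macrocluster and subclusters per macrocluster. Fully tied
samples short-circuit to $\chi^2 = 0, p = 1$.

## The SMLM scene and its calibration

`smlm_scene()` builds rod-shaped cells with two polar macroclusters, each a
diffuse Gaussian envelope (SD 80 nm, 180 emitters) carrying three tight
subclusters (SD 12 nm, 118 emitters each, so ~200 events per subcluster
after blinking at run-length probabilities 0.5/0.3/0.2), plus uniform
background at 0.5 events/µm² and 4 nm localization jitter. Photons are
log-normal around 150 and PSF widths log-normal around 110 nm, placing
nearly all events inside the filter window.

The envelope is the load-bearing design choice. A horizontal reachability
cut separates two clusters only where the reachability valley between them
rises above the cut; for bare Gaussian subclusters at practical densities,
overlapping tails keep bridge-point core distances far below 35 nm and the
subclusters merge at any separation small enough to keep them inside one
50 nm macrocluster — there is no geometry of isolated Gaussians that the
50/35 pair resolves reliably. Real partition complexes are not isolated
Gaussians: nucleation peaks sit on a diffuse protein envelope. With the
envelope, the saddle density between subclusters is set by the envelope
(placing valleys between 35 and 50 nm) while macrocluster gaps stay far
above 50 nm, which is exactly the structure the published thresholds were
chosen to resolve. The defaults (subcluster separation 150 nm, envelope
180 emitters) were fixed by this calibration before the recovery
experiment was frozen; the experiment (100 seeded scenes in the acceptance
suite) then measures recovery of the planted (2 macro, 3 sub) structure
end to end through filter → group → assign → OPTICS → nested cuts.

What the scene does not emulate: drift, z-structure, dipole PSF effects,
fluorophore re-activation after dark gaps (blink runs are strictly
contiguous frames, matching the 0-off-frame grouping rule they exercise),
and cell-to-cell variability in expression level.

## Problem sizes and runtime

The test suite and acceptance script are sized for a desk machine: Hi-C
fixtures use an 800 kb / 160-bin genome at 1e5 pairs where the full size is
not the point, and the full 3.2 Mb / 640-bin chromosome for classification
accuracy and boundary recovery; OPTICS oracle checks run 50 instances at
n ≤ 300 plus 100 full scenes (~1400 molecules each). The whole suite runs
in ~3 minutes, the acceptance script in ~2.

## Known limitations

* The folding model is multiplicative and stationary; it cannot express
  position-dependent decay exponents or loop anchors, so boundary callers
  tuned here may behave differently on maps with point loops.
* SCN convergence is checked on row sums only (columns follow by
  symmetry); wildly asymmetric inputs are rejected rather than balanced.
* The DI's `min_effect` is an absolute correlation-scale constant; on maps
  whose correlation contrasts are globally tiny it would need lowering.
* OPTICS is O(n²) in memory and time per cell; cells beyond ~10⁴ grouped
  molecules would need an indexed implementation.
* WKT polygon I/O covers single-ring `POLYGON` geometries only.
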