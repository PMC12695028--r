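---
title: "Quantifying heterodonty and tooth complexity from crown outlines"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying heterodonty and tooth complexity from crown outlines}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(heterodont)
```

## The problem and the model

Heterodont dentitions vary in tooth shape along the jaw and between jaws,
often abruptly, which defeats landmark-based morphometrics that assume
point-to-point homology. This package instead works from the raw 2D crown
outline — an open, ordered point sequence from the mesial to the distal
baseline terminus — and layers three kinds of summaries on top of it:
pairwise outline distances, per-tooth complexity indices, and jaw- or
dentition-level heterodonty statistics. No homology beyond "same relative
position along the outline" is ever assumed, so morphologically
heterogeneous taxa stay comparable.

All shape computations run on a standardized representation: outlines are
resampled to equal arc-length spacing (default 1000 points), centered on
the arithmetic mean of the resampled points, and size-normalized either by
total outline length or by the area of the crown polygon closed with the
straight baseline segment. The point centroid (rather than the area
centroid) matches the point-based distance formulas. Tooth size is
deliberately not part of any measure; it is treated as an independent
phenotypic dimension.

## Pairwise distances and the superimposition search

Six measures capture complementary aspects of shape difference. Three
compare point sets directly and receive a bounded partial Procrustes
search; three are computed on normalized outlines without any search
because their representations already discard placement:

* EMD (nearest-point mean distance, both directions summed) is robust to
  unequal feature placement but blind to ordering;
* HED (twice the mean positionwise distance; nearest-relative-position
  matching when point counts differ) is a pseudo-homologous counterpart;
* SAO (rasterized area overlap of the baseline-closed crowns) responds to
  bulk rather than boundary detail. It is a similarity in [0, 1]; the
  pipeline stores 1 − SAO so that all six measures are distances and can
  be averaged coherently;
* DFD: Euclidean distance between orthonormal type-II discrete cosine
  coefficients of the coordinate series x(t) and y(t), 24 harmonics per
  stream, DC terms excluded (translation is already removed by centering).
  A cosine basis suits open curves; elliptic Fourier analysis would assume
  closure;
* OAD: the cumulative surface-angle functions of both outlines (interior
  angle in [0, π] at each of 100 equidistant points, accumulated from a
  common anchor of 0) are overlaid and the area between them summed;
* ADD: Euclidean distance between cosine coefficients of those angle
  functions (24 harmonics, DC excluded — the common anchor makes the mean
  level uninformative).

The superimposition search explores rotation ±π/8, per-axis shifts of up
to 10% of the normalized outline's bounding-box diagonal, and scale
0.75–1.25 on a regular grid (default 17 × 9 × 9 × 11), under both size
normalization modes, keeping the lower distance. Two design points were
genuinely open and are resolved as follows:

* *Refinement.* After the coarse grid, two coordinate-descent sweeps run
  per-dimension line searches at 1/4 and then 1/16 of the coarse step
  around the incumbent. A full joint 4-D refinement grid would cost 6561
  evaluations per mode, which the rasterized SAO measure cannot afford;
  coordinate descent costs ~70 evaluations and, because the incumbent is
  only replaced by strictly smaller values, refinement can never worsen
  the reported minimum.
* *Directionality.* Transforming only one outline of a pair makes the
  result order-dependent (the scale window [0.75, 1.25] is not symmetric
  under inversion; shifts are relative to the transformed outline's
  bounding box). The search therefore runs in both directions and keeps
  the smallest distance, which restores exact symmetry in the pair.

The SAO raster grid (each axis of the joint bounding box divided into 100
cells) is fixed *before* the search, so pixel size never changes under the
transform; pixels count as inside when their center is inside the closed
polygon under the even-odd rule. Distance kernels and the grid search are
compiled (Rcpp) because each tensor involves 10⁴–10⁵ kernel evaluations.

## Heterodonty statistics

With d(i, j) a tooth distance under one measure, per jaw row of n teeth:
HMS = Σᵢ (d(i, i−1) + d(i, i+1)) / 2n (missing neighbor terms at the row
ends are skipped while the denominator 2n is kept as printed, so HMS
equals the mean sequential distance × (n−1)/n; a `boundary = "mean"`
variant divides by the number of existing terms); HMT = Σᵢⱼ d(i, j) / n²
with the zero diagonal included; HMX = max d(i, j). HDG matches each
tooth to the opposing-jaw tooth at the nearest relative position
(argmin |i/nᵢ − j/nⱼ|, so teeth may be matched repeatedly when counts
differ) and sums the two directed mean distances; the same matching
applied within matching jaws of two species, averaged over the two jaws,
gives the interspecific phenotypic distance DP.

Because the six distance measures live on incommensurable scales, each
statistic is min–max normalized per measure across the species set first
and the six normalized values averaged afterwards. Derived ratios
(graduality HMX/HMS; HDG/HMT) are computed on the unnormalized
per-measure values and averaged over measures, since ratios within one
measure are scale-free. The outline-vs-angle contrast compares mean
normalized heterodonty under EMD/HED/SAO against OAD/ADD.

## Single-tooth complexity

Ten per-tooth measures are computed on the length-normalized outline:

* CUSP1/CUSP2: apex candidates are local maxima of the distance to the
  baseline; a cusp's prominence is its height minus the higher of its two
  flanking cols, and cusps below 2% of outline length are minor
  (cusplets). The largest cusp is always major. The purely geometric 2%
  rule also stands in for visually identified serrations, which are not
  computable from outlines.
* OAR = outline length / crown area; OCR = outline length / √(Σ distances
  to centroid). OCR's denominator grows with point count, so it is only
  comparable at the standard resampling (1000 points).
* OIR: area ratio of the smallest enclosing circle to the largest
  inscribed circle, capped at 25. (The ratio is implemented as
  escribed/inscribed: the opposite order would be ≤ 1 and could never
  reach the cap.) The enclosing circle comes from a randomized-incremental
  search over the convex hull (deterministically seeded); the inscribed
  circle from a compiled grid search (256² cells, three local refinement
  passes).
* DFS: sum of |cosine coefficients| over 24 harmonics of both coordinate
  streams. Note that under any size normalization this sum is dominated by
  overall extent: adding cusps at fixed normalization moves coefficient
  mass from low to high harmonics while the total stays nearly constant.
  DFS therefore discriminates eccentricity and bulk shape rather than
  cusp count on synthetic crowns — a property worth keeping in mind when
  interpreting it, and the reason the test suite checks the spectral
  shift rather than a monotone response of the plain sum.
* ANS/ASC/AND: at six resolutions n_R = n/(5·2^(R−1)) (200, 100, 50, 25,
  13, 6 at n = 1000; rounded half-up; resolutions below 3 points are
  dropped with a warning), the interior angles α are computed. ANS is the
  mean over resolutions of Σ|α − π|; ASC the mean signed difference of
  that sum between successive resolutions (a flag switches to absolute
  differences); AND the mean over resolutions of the mean |αᵢ − αⱼ| over
  interior-point pairs (as printed without absolute values the double sum
  cancels identically, so the absolute-value reading is the only
  meaningful one).
* OPC: each inter-point vector is binned into a circular sector; a patch
  is a maximal run of constant sector. Counts are averaged over
  partitions (2, 4, 8), rotations (none and half a sector each, plus a
  quarter sector for the coarsest partition) and the resolution ladder. A
  straight line scores exactly 1.

Species-level values are pooled means over all teeth of both jaws (a
per-jaw-then-species average would weight jaws equally regardless of
tooth counts; pooling keeps every tooth equal). Cx_combined sums the ten
globally min–max-normalized measures; the pooled groups are Cx_exc
(OCR + OAR + OIR), Cx_ang (ANS + ASC + AND + OPC) and Cx_four (DFS), all
on normalized values; the cusp ratio CUSP2/CUSP1 uses raw counts with the
convention 0 when CUSP1 = 0.

## Genetic distances and the divergence scan

K2P distances are counted from pairwise-complete sites (gap or ambiguity
in either sequence excludes the site for that pair) and the closed form
d = −½ ln((1 − 2P − Q)√(1 − 2Q)) applied; saturated pairs raise an error
by default or can be flagged as missing. Neighbor joining runs through
the standard Saitou–Nei implementation; negative branch lengths are
clamped to zero with the deficit moved to the sister branch. dG is the
min–max normalization of patristic distances over all species pairs — the
only reading of "normalized genetic distance" that is comparable across
datasets. An externally estimated Newick tree can substitute for the
built-in K2P + NJ path.

The divergence scan orders all species pairs by dG (ties broken by pair
name for determinism), slides two half-open 100-pair windows separated by
a configurable rank offset (0 or 200), and tests whether trait
differences in the higher-dG window are stochastically greater with a
one-sided two-sample Wilcoxon rank-sum (Mann–Whitney) test, normal
approximation with tie correction. No multiple-testing correction is
applied across windows, matching the descriptive intent of the scan. Both
window anchors (dG at the window start and at the top of the lower
window) are emitted.

## The synthetic generator

`make_tooth` models a crown as a unit-width baseline carrying raised-
cosine bumps: evenly spread major cusps (centers shifted by the asymmetry
parameter), Gaussian corner rounding of the major profile, and narrow
minor cusplets superimposed afterwards so that serration-scale structure
survives the rounding. `make_dentition` derives each tooth from a base
template plus a positional gradient (monognathic shape change), a
lower-jaw offset (dignathic change), and seeded Gaussian noise applied to
the shape *parameters* — not to individual points — so resampling
invariants hold exactly. All randomness flows from one integer seed per
call and the caller's RNG state is restored afterwards.

What the generator emulates: open cusped crowns, mesial→distal rows,
gradual within-jaw change, jaw offsets, fine serrations. What it does not
emulate: digitization noise on individual points, partially overlapping or
damaged teeth, material transitions at the crown base, and the strongly
asymmetric, recurved shapes of real shark teeth. Passing tests therefore
demonstrate correctness of the measures and the recovery machinery on
idealized crowns, not field robustness to segmentation artifacts.

Sequence simulation evolves sites down a tree under the K2P model using
closed-form transition probabilities; `kappa` is the expected
transition/transversion *count* ratio (the empirical ts/tv ratio between
closely related sequences converges to it), so the rates are
α = 2κβ.

## Numerical choices and degenerate inputs

* Resampling preserves endpoints exactly; it is exactly idempotent on
  equal-chord polylines and second-order accurate (~10⁻⁷ relative) on
  curved ones.
* Crown segmentation applies three rules in order: annotated termini;
  otherwise the lowest concave point per lateral side of the window-5
  smoothed outline (curvature sign from cross products, computed
  cyclically so junctions at the traversal start are seen); otherwise the
  most distant pair among lower-half points. The crown is the arc
  containing the global y-maximum, following the declared y = basal→apical
  file convention.
* Area normalization rejects outlines whose baseline closure crosses the
  outline interior.
* The homodonty null is exact: identical teeth give identically zero
  distances under all six measures because the identity transform lies on
  every search grid (odd step counts).
* Degenerate inputs (zero-length outlines, zero-area crowns, single-tooth
  rows, saturated sequence pairs, equidistant leaf sets) raise errors
  naming the offending record rather than propagating NaN.

## Problem sizes in tests

The test and acceptance suites run the identical code paths at reduced
problem sizes chosen once: 64–100 outline points, 5 × 3 × 3 search grids,
jaw rows of 4–6 teeth, 50-species trees and 10⁵-site alignments. These
sizes keep full-suite runs to a few minutes while leaving every algorithmic
branch exercised; the package defaults (1000 points, 17 × 9 × 9 × 11 grid,
24 harmonics) match the standard analysis parameters.

## Known limitations

* The alignment search is a bounded grid, not an analytic optimum; the
  reported minimum depends (monotonically) on grid density.
* OCR is resolution-bound by construction; comparisons are only valid at
  a fixed point count.
* DFS is scale-dominated (see above).
* The cusplet/serration distinction relies entirely on the 2% prominence
  rule; serrations on near-vertical cutting edges do not create
  baseline-distance maxima and are invisible to outline-based counting.
* dG is a relative quantity; values are comparable within a dataset, not
  across datasets with different spans of divergence.
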