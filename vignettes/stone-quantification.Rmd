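---
title: "Quantifying urinary stones on single-energy CT: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying urinary stones on single-energy CT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stonequant)
```

## The problem

Roughly one person in ten forms a urinary stone. Most are calcium-based
and need mechanical treatment when they do not pass, but pure uric-acid
(UA) stones can be dissolved by alkalinizing the urine — so knowing the
composition at the time of diagnosis changes management. Composition is
classically obtained from dual-energy CT or post-retrieval infrared
spectroscopy; `stonequant` instead quantifies the unenhanced thin-slice
single-energy scan that diagnosed the stone, using two point estimates —
the peak attenuation `maxHU` and the peak point Laplacian `ppLapl` — and
a simple box-shaped decision rule.

This vignette explains the model and its assumptions, the tunable
parameters, the numerical choices, and what the package's synthetic
phantoms can and cannot establish.

## Segmentation: half-of-peak thresholding

A stone sits on a background of urine/soft tissue whose attenuation is
near water, approximated as exactly 0 HU. Given a user-supplied ROI that
contains one stone, the pipeline:

1. finds the ROI maximum `maxHU` and its voxel, the *peak point* (ties
   broken by raster order: slice, then row, then column);
2. thresholds the **whole volume** at `maxHU / 2` (half way between peak
   and background; comparison inclusive, so the peak always belongs);
3. keeps the 26-connected component containing the peak point;
4. fills interior holes — background voxels not reachable from the grid
   exterior by 6-connected background steps — and counts them as stone.

Foreground 26- / background 6-connectivity is the standard complementary
pairing in 3D; hole filling runs in full 3D, not slice-wise. The
component may grow beyond the ROI box (the ROI merely selects the stone);
`clip_to_roi = TRUE` confines it when neighboring structures interfere.
Segmentation is *deliberately not shift-invariant*: adding a constant to
the volume changes the mask, because the threshold is anchored to the
0 HU background by definition. A component touching the volume boundary
triggers a truncation warning. A non-positive ROI maximum is an error —
there is no stone to segment.

## The scaled 3D Laplacian and ppLapl

The texture filter maps each voxel to

    L(v) = I(v) - sum_i w_i I(n_i),   i over the 26 neighbors,

with weights summing to exactly 1, so constant regions map to 0 and the
output remains in HU. The exact weighting of the original formulation is
not recoverable, so the package defines a documented family and treats
the choice as a parameter:

* `"inverse-square"` (default): `w_i` proportional to the reciprocal
  squared center-to-neighbor distance in voxel index units — face 1,
  edge 1/2, corner 1/3 before normalization, i.e. `w_face = 3/44`,
  `w_edge = 3/88`, `w_corner = 1/44`.
* `"uniform"`: all 26 weights equal to 1/26, for sensitivity analysis.

Distances are measured in index units by default — the target protocol
(0.8 × 0.8 × 1.0 mm) is nearly isotropic and a single scalar filter is
reported — with a `metric = "mm"` variant that down-weights the coarser
slice direction. Borders use replicate padding; stones of interest are
interior, and the choice is isolated behind `scaled_laplacian()`.

`ppLapl` is the filtered value at the peak point: large for a sharp
narrow peak, near 0 for a broad plateau. Because different kernels give
systematically different ppLapl magnitudes for the same stone, published
cutoffs and kernel choice belong together; the package's default rule
values (1000/195, 800/190) are the published ones, and on the package's
own phantom cohort the default kernel keeps UA stones comfortably below
the 195 HU cutoff (the consequence of a milder kernel is slack, not
inversion, of the decision boundary).

## Histogram and shape statistics

Histogram statistics over the mask (hole-filled voxels included — they
are part of the stone) use the conventions of the numeric environment
the cutoffs were developed in: sdHU with the sample (n−1) denominator;
skewness `m3 / m2^1.5` and **non-excess** kurtosis `m4 / m2^2`
(normal → 3) from population moments. A constant mask has sd 0 and
missing skewness/kurtosis; a single-voxel mask is defined to have sd 0.

Volume and surface area come from a 3D **alpha shape** over all voxel
centers of the mask, in mm; sphericity is `pi^(1/3) (6V)^(2/3) / A`,
1 for a perfect ball. Degenerate masks — fewer than 4 points, collinear,
or confined to a single image plane — have no 3D shape and report
volume 0 with missing sphericity (this situation occurs in practice for
thin stones only 1 slice thick).

### Numerical design of the alpha shape

No computational-geometry library is available in the target
environment, so the package implements incremental (Bowyer–Watson) 3D
Delaunay tetrahedralization in C++ and derives the alpha complex from
tetrahedra circumradii, with two numerical choices worth recording:

* **Symbolic jitter.** Voxel centers on a regular grid are maximally
  degenerate for Delaunay (many cospherical 5-point configurations). A
  deterministic, index-keyed perturbation of at most ±0.001 mm is applied
  before tetrahedralization. Measured effect on volume/area is orders of
  magnitude below reported digits; amplitudes much below this leave the
  degeneracy inside floating-point noise and were observed to corrupt
  the triangulation.
* **Alpha radius.** The canonical parameter-free radius is the critical
  alpha: the smallest radius whose complex contains every point and
  forms one region. Measured on voxelized balls, however, the critical
  complex hugs every voxel step and is partly porous: a 6 mm-radius ball
  reads sphericity ≈ 0.47 and volume ≈ −21% — physically wrong for a
  sphere, and inconsistent with sphericities up to 0.9 reported for real
  stones of ~100 voxels. The default is therefore `alpha_scale = 2`
  (radius = 2 × critical): sub-voxel staircase concavities are bridged
  while genuine supra-voxel concavities are preserved, and the same ball
  measures sphericity 0.96 with volume −13%. `alpha_scale = 1` restores
  the strict critical shape. Residual negative volume bias (~half a
  voxel of erosion all around) is inherent to shapes built on voxel
  *centers* and grows for small stones.

The axial diameter adds one in-plane voxel diagonal to the largest
center-to-center in-slice distance, approximating edge-to-edge caliper
placement; it stands in for a manual PACS measurement and is
informational only.

## Classification and evaluation

The dual rule calls a stone UA iff `maxHU <= 1000` *and* `ppLapl <= 195`
(both inclusive — the boundary belongs to UA); the alternative 800/190
rule targets the main UA cluster, and the single-parameter rule is
`maxHU <= 745`. Decisions are monotone (lowering either feature never
flips UA to non-UA) and the 800/190 decision region nests inside
1000/195.

Diagnostic metrics (sensitivity, specificity, accuracy, PPV, NPV, with
UA positive) are reported as percentages with two-sided **exact
Clopper–Pearson** intervals, computed in beta-quantile form with the
conventional boundary cases (lower = 0 at 0 successes, upper = 1 at n).
The exact method is inferred from numeric agreement of all published
brackets at printed rounding; a Wilson option exists should a different
convention ever be documented. Display rounds half away from zero, one
decimal for accuracy and whole percents otherwise; full precision is
retained in JSON output. Zero-denominator metrics are reported missing.

## The phantom generator: a stated world

Phantoms replace patient data. A stone is a smooth attenuation peak on a
0 HU background: gaussian by default (`peak * exp(-r²/2)` in
Mahalanobis units of per-axis `sigma_mm`), with truncated-gaussian and
uniform-ellipsoid (flat-topped) variants, plus optional additive white
Gaussian noise. Defaults encode the targeted acquisition: 0.8 × 0.8 mm
in-plane pixels, 1 mm contiguous slices; noise sd defaults to 15 HU, a
plausible figure for a 120 kVp, 70 mAs abdominal protocol (no published
noise figure exists for the reference data, so it is configurable). The
validity guard `peak > 2 (background + 5 sd)` keeps the half-of-peak rule
meaningful. Identical specs (including seed) render bit-identical
volumes.

`make_cohort()` draws labelled single-stone phantoms whose peak
attenuations follow the published group moments — UA ~ N(559, 139) HU
truncated to the observed 365–966 range; Ca ~ N(1275, 306) truncated to
301–1938 — and whose widths encode the size–attenuation relation that
motivates ppLapl:

* UA: in-plane sigma `0.9 + 1.8 (peak − 365)/601 + U(0, 0.5)` mm —
  broad, broader at higher attenuation;
* Ca: `0.55 + 4.0 ((peak − 301)/1637)² + U(0, 0.3)` mm — small and
  sharply peaked when faint, broad when dense.

The two laws were calibrated once, against a closed-form ppLapl
predictor, to reproduce the published qualitative structure — UA below
both cutoffs, faint calcium stones above the ppLapl cutoff, and a pooled
maxHU–ppLapl correlation near zero (published: 0.05) — and then frozen.
The slice-direction sigma varies ±15% around the in-plane value, and
stone centers are dithered by up to half a voxel so that peaks do not
always coincide with voxel centers.

**What a green phantom test establishes** is that the pipeline's
machinery is correct: exact peak recovery, mask = analytic half-max
voxelization, filter contracts, rule arithmetic, interval coverage.
**What it does not establish** is clinical performance: real stones are
heterogeneous, non-ellipsoidal, sit on textured backgrounds, and are
blurred by scanner-specific reconstruction; the phantom cohort contains
none of that, so cohort accuracies near 100% are a property of the
generator plus pipeline, not a claim about patients. Mixed UA/calcium
stones are representable as overlapping peaks but have no ground-truth
label semantics, mirroring the fact that mixed stones resist
classification even with dual-energy methods.

## Known limitations

* The Laplacian kernel family reproduces the documented *contract*
  (difference from a weighted 26-neighbor mean), not the original
  weights, which are unrecoverable; ppLapl magnitudes are therefore
  kernel-relative.
* Alpha-shape volumes of small stones are biased low (voxel-center
  erosion); sphericity is validated by properties (sphere limit, cube
  closed form, coplanar degeneracy), not by value matching.
* The DICOM reader supports the uncompressed explicit-VR little-endian
  subset sufficient for exported axial CT series — not compressed
  transfer syntaxes, multi-frame objects, or gantry-tilted geometry.
* The automated axial diameter approximates, but does not replicate, a
  manual bone-window caliper measurement.
* Stone *detection* is out of scope: the caller supplies one ROI per
  stone.
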