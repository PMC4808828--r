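---
title: "Methods: lung-nodule CAD on chest CT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lung-nodule CAD on chest CT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The detection problem

Pulmonary nodules larger than 4 mm are the clinically actionable targets of
CT screening; smaller opacities carry negligible malignancy risk and sit at
the resolution limit of thick-slice scans. A computer-aided detection (CAD)
system proposes candidate locations for radiologist review, so it must hold
high sensitivity while keeping false positives (FPs) per scan low enough to
be worth the reader's time. The dominant FP source is the vascular tree:
vessel bifurcations look locally blob-like and bright, exactly like small
nodules.

`nodulecad` implements a four-stage pipeline:

1. **Lung extraction** — minimum-error histogram thresholding, border
   cleanup, pleural reconstruction.
2. **Candidate segmentation** — per-slice structure filtering by area and
   intensity, 3D component formation under 26-connectivity, blob-shape
   discrimination.
3. **Feature extraction** — eight shape/histogram descriptors per candidate,
   with pairwise-correlation feature selection.
4. **Classification** — an RBF-kernel epsilon-SVR on ±1 targets, thresholded
   at 0, trained on a balanced matrix with joint min–max normalization.

All stages run on a `ct_volume`: a `(z, y, x)` grid with per-axis spacing in
mm, voxel-center coordinate convention, normalized to the 8-bit range before
thresholding.

# Stage models and assumptions

## Lung extraction

The chest histogram is assumed bimodal: an air/parenchyma mode and a
soft-tissue/bone mode. `minimum_error_threshold()` minimizes the
Kittler–Illingworth criterion

$$J(t) = 1 + 2\,[P_1 \ln \sigma_1 + P_2 \ln \sigma_2]
           - 2\,[P_1 \ln P_1 + P_2 \ln P_2]$$

exhaustively over all interior 8-bit thresholds, modeling each class as a
Gaussian. Numerical choices: class variances are floored at $1/12$ (the
quantization variance of a single bin) so single-spike classes keep a finite
log-likelihood; ties break toward the smaller threshold; the returned cut is
$t^\*+0.5$, i.e. halfway between bins, so that "below the cut" is unambiguous
for integer-valued histograms.

Binarizing at the cut keeps the dark side (the class holding the
lower-intensity mode). Per slice, dark components touching the in-plane
border (outside air, scanner table) are removed; border removal is 2D because
the top and bottom slices legitimately cut through the lungs. Of the
remaining 3D components the largest one or two are kept — the second only if
it reaches 10% of the largest, since near the carina the two lungs can fuse
into one component.

**Pleural reconstruction.** Thresholding excises pleura-attached (juxtapleural)
nodules from the lung mask: they are as bright as the chest wall and merge
with it. Slice-wise hole filling (`fill_holes()`: every background region not
4-connected to the slice border becomes foreground) recovers *enclosed*
bright structures — vessels and isolated nodules — but cannot recover a
pleural bite whose mouth stays open to the wall on its widest slices.
`extract_lungs()` therefore first applies a per-slice morphological closing
with a small disc (default radius 3.5 mm, the rolling-ball idea) to seal bite
mouths, then fills holes. The closing radius trades off: it must exceed half
the bite-mouth width of the nodules to be recovered, and must stay well below
half the inter-lung (mediastinal) gap or the two lungs merge and drag
mediastinal tissue into the mask.

## Candidate segmentation

Inside the lung mask, bright structures are separated from parenchyma by a
per-scan Otsu threshold on the lung-interior intensities (the choice of a
histogram-derived threshold is logged on the report). Each slice's structures
(8-connected in-plane) are kept only when **both** indicators agree: pixel
area at least `area_floor_from_spacing()` — the equatorial cross-section of
the smallest nodule of interest,
$\lceil \pi (d_{\min}/2)^2 / (d_y d_x) \rceil$ with $d_{\min} = 4$ mm — and
mean intensity at least the structure threshold.

Surviving pixels are assembled into 3D candidates under 26-connectivity
(face, edge, and corner adjacency), with component ids fixed in lexicographic
order of each component's first voxel so runs are reproducible.
`blob_scores()` summarizes shape: *sphericity* is the candidate volume over
the volume of the sphere with radius equal to the maximal centroid-to-voxel
distance (a bounding-sphere ratio — chosen over surface-area sphericity,
which is noisy on small digitized blobs); *width* is the shortest
bounding-box edge. Candidates are kept when sphericity ≥ 0.3, width ≥ 2 mm,
and bounding-box elongation ≤ 4. The width floor must stay below the slice
thickness: with 2.5 mm slices a legitimate 4–6 mm nodule often survives the
per-slice area floor in a single slice, so its z-edge is exactly one slice
thick and a 3 mm floor would reject it categorically. There is deliberately
no upper size filter — large masses must reach classification.

## Features

Eight descriptors per candidate (`feature_matrix()`), mixing 2D and
volumetric measurements. d1 (pixel area) and d2 (circularity) are measured on
the candidate's largest-area axial slice, matching the per-slice character of
the 2D stage; d3–d8 are volumetric:

| feature | definition | units / default behavior |
|---|---|---|
| d1 | pixels of the largest axial cross-section | px |
| d2 | $d_1 / (4\pi (D/2)^2)$, $D$ = max pairwise pixel distance + 1 px | dimensionless; digital disk → 1/4 |
| d3 | mean intensity over candidate voxels | 8-bit units |
| d4 | population variance of intensity | squared units |
| d5 | skewness $m_3/m_2^{3/2}$, population moments | dimensionless |
| d6 | kurtosis $m_4/m_2^2$, raw (normal → 3, uniform → 9/5) | dimensionless |
| d7 | bounding-box volume, edges $(\text{extent}+1)\times$spacing | mm³ |
| d8 | sum of intensity | 8-bit units |

The +1-pixel diameter convention makes d2 total (a single pixel has $D = 1$,
$d_2 = 1/\pi$); the moments are the population (1/n) forms, not
sample-corrected, and kurtosis is *not* excess kurtosis. Zero-variance
candidates have undefined moment ratios and raise an error rather than
returning 0 — with realistic noise this does not arise.

`select_features_by_correlation()` greedily drops the more-redundant member
of the most-correlated feature pair while any pair exceeds `r_max`
(default 0.95); constant columns are dropped first with a warning. The full
eight-descriptor set is already lowly correlated on phantom candidates, so
selection is a guard, not a routine reduction.

## Classification

The classifier is an epsilon-SVR (RBF kernel) used for classification:
regression on targets +1 (nodule) / −1 (non-nodule), called a nodule when the
regression output reaches the decision threshold (default 0). The
epsilon-insensitive loss width defaults to `epsilon_p = 0.4`, the selected
operating point of the protocol this package reproduces; `roc_over_epsilon()`
exposes the sensitivity/specificity trade-off as epsilon varies.

Training uses a **balanced matrix** (`build_balanced_matrix()`, default 20
rows per class, sampled without replacement under a seed) because nodules are
always the minority among candidates. Features are min–max normalized to
[0, 1]. Two normalization protocols are provided: *transductive* — training
and new data normalized jointly, then split, reproducing the reference
protocol exactly — and the leakage-free default, where statistics come from
the training matrix alone and are stored on the classifier
(`norm_stats`) for deployment. `C` and `gamma` are chosen by grid search
($C \in 2^{-5}..2^{15}$, $\gamma \in 2^{-15}..2^{3}$, multiplicative steps of
4) maximizing 5-fold cross-validated accuracy of the thresholded prediction,
with ties preferring the smaller `C`, then the smaller `gamma`.

## Evaluation

`match_candidates_to_truth()` scores predictions against planted ground
truth: a predicted nodule whose centroid lies within the truth radius of an
unmatched truth center is a TP (nearest pair first, each truth matched at
most once); unmatched predicted nodules are FPs; unmatched truths are FNs —
including truths whose only candidate was classified non-nodule, and truths
that never produced a candidate; predicted non-nodules overlapping no truth
are TNs. The centroid-within-radius hit criterion is this package's
definition: the study it reproduces deferred to expert cross-reference
without a numeric rule. Sensitivity, specificity, and accuracy are the
standard ratios, reported as percentages rounded half-up to two decimals;
zero-denominator metrics are undefined (`NA`), never 0.

`leave_two_out_cv()` enumerates all $\binom{n}{2}$ two-row test sets when
there are at most `max_folds` (default 500, keeping CV desk-scale);
otherwise it samples `max_folds` distinct pairs built from a random disjoint
cover of all rows plus random extras, so every candidate is tested at least
once and per-candidate final predictions (majority over folds) are well
defined. Within each fold a balanced matrix is drawn from the training rows
(capped at the scarcer class), normalized per protocol, and a classifier is
fit. `C` and `gamma` are tuned **once** on an initial balanced matrix and
reused across folds: re-running the 110-point grid inside every fold would
multiply compute by two orders of magnitude without changing what the
cross-validation measures.

# The synthetic phantom

`phantom_spec()` / `generate_phantom()` render a desk-scale thorax: an
elliptical body cylinder (intensity 190) on an air background (60), enclosing
two lung ellipsoids (60) — giving the two-peak histogram lung extraction
assumes — plus vessel trees and nodules (210) on a 0–255 scale, with additive
Gaussian noise (default sigma 5) clipped to range. Defaults: 128 × 128
in-plane at 0.7 mm, 40–80 slices at 2.5 mm — inside the slice-thickness range
of the clinical scans the pipeline targets, but small enough that a 20-scan
suite runs in about a minute.

Design choices, fixed once:

* **Vessels** are capsule unions (segment + radius) with optional
  Y-bifurcations. The junction carries an ellipsoidal bulge aligned with the
  parent axis (semi-axes 2.2/1.8/1.8 × parent radius) so that ramification
  points — the chief FP source — genuinely survive the area floor and reach
  classification as deliberate non-nodule candidates. Straight vessels
  without bifurcations stay below the area floor and vanish in the 2D stage.
* **Partial volume**: vessels and bulges are rendered with a soft edge
  (linear ramp over ~0.7 mm). Thin structures on real CT are dimmer and more
  heterogeneous than solid nodules for exactly this reason, and this is what
  gives the intensity features (d3–d6) their discriminative value. Nodules
  are rendered as hard spheres: voxel membership is exactly "center within
  radius", which keeps the generator's ground-truth contract brute-force
  checkable.
* **Nodule kinds**: isolated (uniform in the lung interior), vascular
  (seated on the vessel trunk), juxtapleural (seated on the lateral/medial
  pleural surface — the gently curved part of the ellipsoid, as with the
  costal pleura — with the center 0.88–0.97 radii inside the boundary and the
  cap clipped to the body). Irregular nodules perturb the radius with a
  low-order directional polynomial scaled by `irregularity`.
* **Suite randomization** (`phantom_suite()`): 0–2 nodules per scan, radii
  uniform 2.5–6 mm (diameters 5–12 mm, the actionable screening range, all
  above the 4 mm floor), kind mix 2:1:1 isolated:juxtapleural:vascular, one
  bifurcating tree per lung, slice counts 40–80 — all reproducible from one
  seed, with per-scan sub-seeds kept below 2³¹.

**What the phantom does not emulate** — and hence what passing tests do not
show about clinical data: no reconstruction physics (beam hardening, streak,
sinogram noise), no textured parenchyma or airways, no HU calibration, convex
analytic lungs rather than anatomical shapes, and nodule/vessel intensities
drawn from one material value instead of tissue distributions. The
end-to-end bars (sensitivity ≥ 0.85, ≤ 1 FP/scan on a 20-phantom suite) are
internal regression bars for this synthetic population, not claims about
real scans.

# Degenerate inputs and edge rules

* Constant volume: `normalize_volume()` maps to all zeros;
  `extract_lungs()` then reports "no lungs detected".
* Single-voxel candidate: bounding-sphere radius would be 0, so it is set to
  half the largest spacing and sphericity to 1.
* Empty candidate set: `feature_matrix()` returns a 0-row tibble with all
  eight named columns; `classify()` returns empty scores.
* `joint_normalize()` with an empty new matrix falls back to the training
  min–max; constant features map to 0.
* `minimum_error_threshold()` requires at least two nonzero bins.

# Known limitations

* Trachea/main-bronchi removal is not implemented; on real scans the airway
  column survives lung extraction and is left to the downstream shape
  filters.
* Vessel ramification points are handled only implicitly by
  sphericity/width/elongation and the classifier; there is no explicit
  junction detector, so a bulge the size and shape of a small nodule is a
  genuine, intended failure mode.
* DICOM support covers single-frame, uncompressed little-endian CT series
  only (enough to stack a conventional axial series into a volume).
* d1/d2 are slice-based by design; strongly oblique lesions are summarized
  by their largest axial footprint.
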