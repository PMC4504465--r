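---
title: "Methods: automated muscle MRI fat quantification with musclefat"
author: "musclefat authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: automated muscle MRI fat quantification with musclefat}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Fatty replacement of skeletal muscle is the imaging hallmark of many
muscular dystrophies. On axial T1-weighted MR images of the thigh,
adipose tissue (both the subcutaneous ring, SAT, and the infiltration
inside the fascia, IMAT) is bright, muscle is mid-grey, and cortical
bone and background are dark. The quantity of interest is the
intramuscular fat fraction

$$\mathrm{FF} \;=\; \frac{|\mathrm{IMAT}|}{|\mathrm{IMAT}| + |\mathrm{muscle}|},$$

a pixel-count ratio taken inside the deep fascia, excluding the femur.
The difficulty is that SAT and IMAT have identical signal; they can only
be separated *geometrically*, by finding the fascia. `musclefat`
automates that separation and quantifies FF per slice and per volume.
This vignette documents the model, the tunable parameters, the numerical
choices, and what the synthetic validation does and does not show.

# The segmentation model

## Intensity clustering

Each slice is clustered independently into three intensity classes with
k-means (Lloyd's iteration). The clusters map onto tissues by T1
contrast: the darkest centroid is background/bone/vessels, the middle
one muscle, the brightest adipose tissue. Design choices:

* **k-means++ seeding, 8 restarts, explicit seed.** Lloyd's iteration
  only finds local optima; restarts with careful seeding make the
  1-D clustering reproducible and in practice optimal (the package
  asserts equality with an exhaustive contiguous-partition oracle on
  small inputs — the 1-D optimum is contiguous in sorted order).
* **Ties** (a pixel equidistant to two centroids) go to the lower-index,
  darker centroid, for determinism.
* Clustering uses intensities only; no spatial features. Per-slice
  clustering (rather than per-volume) is the default so that a slowly
  varying coil profile across slices cannot skew shared centroids.

## Cleanup

Two signals must not reach the boundary stage: bright vessel lumina
inside muscle (they belong to the fat class) and the thin mid-grey skin
rim (it belongs to the muscle class). Vessels are absorbed into the
muscle class by a morphological closing with a disc of radius 3 px;
the skin rim is identified as a thin muscle-class component adjacent to
the exterior that vanishes under erosion with the same disc, and is
reassigned to background. The closing also absorbs fat speckle smaller
than the disc — intentionally so, because the *cleaned* map only feeds
the boundary fitting; the final IMAT/muscle separation always uses the
*initial* clustering, which the cleanup never touches. The exterior mask
computed before skin removal is kept so that the limb contour is fitted
to the true skin surface.

## Boundary fitting: binary targets

The two snakes need binary target images whose edges are the boundaries
to find:

* **Limb target** — everything not connected to the image border as
  background (largest component, holes filled). Its edge is the skin
  surface.
* **Muscle-region target** — "muscle plus interior fat, filled". This
  is the delicate one. At moderate-to-severe infiltration the muscle
  class is a sparse speckle and naive constructions (fill-holes,
  closing, convex hull of the muscle class) all systematically carve
  fat-rich bites out of the compartment near the fascia, biasing FF
  downward by selection. The package instead exploits an asymmetry: SAT
  contains essentially *no* muscle-class pixels, so the fascia is the
  **outer envelope of the muscle class**. The envelope is taken
  star-convex around the centroid of the muscle-density support: the
  outermost muscle pixel per 1° angular bin, then a circular running
  maximum over ±15°, which bridges fat blobs that sit directly on the
  fascia. A smoothed muscle-density field (Gaussian, σ = 4 px),
  thresholded at half its interior level (estimated robustly as the
  median over the filled and eroded support), provides the centroid and
  a fallback region.

  The assumptions this makes about the anatomy are explicit: the
  fascia-enclosed compartment is star-convex about its centroid and its
  radius profile varies slowly over ~30° arcs. Both hold for thigh
  cross-sections; strongly bilobed or crescent-shaped compartments
  would need a different support construction.

## The snake

The boundary itself is delineated by a closed polygonal active contour
of N = 50 control points minimizing

$$\varepsilon = \sum_i \alpha\,\|p_i - p_{i-1}\|^2
  + \beta\,\|p_{i-1} - 2p_i + p_{i+1}\|^2 + \gamma\,E_{image}(p_i),$$

with weights (α, β, γ) = (0.1, 0.6, 0.3) controlling tension, rigidity
and data attachment. $E_{image}$ is the negative, normalized,
Gaussian-smoothed gradient magnitude of the binary target (σ = 3 px),
so region edges are energy minima with an attraction range of a few σ.

Minimization is greedy, in the Williams–Shah style, with two deliberate
choices:

* **Per-window min–max normalization.** Within each point's square
  search window (7 × 7 px) every energy term is rescaled to [0, 1]
  before weighting. This is what makes the fixed weights meaningful
  across heterogeneous term scales — and it is functionally necessary:
  with raw squared terms and integer candidate moves, the curvature
  penalty of a one-pixel move dwarfs any distant image gradient and the
  contour cannot travel at all (a failure mode we confirmed
  numerically before adopting the normalization).
* **Frozen-neighbour (Jacobi) sweeps.** All points choose their best
  candidate against the *sweep-start* positions of their neighbours,
  and the moves are applied simultaneously. Because each point's
  current position competes in its own window under the same
  normalization, the summed frozen-neighbour local energy can only
  decrease within a sweep — the per-sweep trace is recorded and
  asserted non-increasing in the tests — and the result is exactly
  invariant to a cyclic rotation of the initial point ordering (the
  contour is also canonicalized to counterclockwise order starting at
  the lexicographically smallest vertex).

After each sweep the points are redistributed to equal arc length,
which prevents bunching; convergence is declared when at most
`move_tol` = 2 % of points moved (≤ 1 of 50), with a cap of 500 sweeps
and a warning flag (never an exception) on non-convergence.
Self-intersection of the converged polygon raises a failure flag.
Initialization is the dilated convex hull of the respective support
(about 5 px outside), so the snake approaches each boundary from
outside.

## Compartments and aggregation

With both contours fitted (even–odd rasterization at pixel centres,
boundary pixels interior): SAT = fat-class pixels between limb and
muscle contours; inside the muscle contour, fat is IMAT and mid-grey is
muscle, both minus the bone mask. The femur is found as a dark
component inside the muscle contour whose filled hull contains a bright
marrow core, and is used filled, so marrow is never counted as IMAT.
Non-tissue pixels (skin, unclassified) fall into `outside`, keeping the
five compartments an exact partition of every slice.

The volume summary averages the per-slice FF over the **20 middle
slices** (a mean of ratios, not pooled counts), centred on the stack
midpoint, ties resolved toward the proximal end; volumes with fewer
valid slices use all of them and carry a warning flag.

## Failure detection and manual fallback

Severe confluent infiltration makes the SAT/IMAT boundary intrinsically
ambiguous; on real cohorts automated methods fail on the most affected
patients and underestimate IMAT. A slice is flagged for manual
correction when (a) the muscle class is near-empty, (b) the muscle
contour encloses less than 20 % of the limb-contour area, (c) the two
contours touch (non-annular SAT), or (d) the 3-px band just inside the
fascia is ≥ 75 % fat — the operational signature of SAT and IMAT
merging. Manually drawn polygon contours (CSV) can then be substituted
for the mid-portion slice; the result is recomputed with the same
partition rules and marked `manual_corrected`.

# The synthetic phantom

`make_thigh_phantom()` renders what the pipeline needs to be tested
against, with pixel-exact ground truth:

* concentric geometry — skin rim (2 px), SAT ring (8 px), muscle
  compartment, femur (cortical ring, radius 10 px, with bright marrow,
  6 px) inside a 56-px limb on a 128-px slice;
* T1 contrast by prescribed means (fat 240 > marrow 220 > muscle 110 >
  skin 90 > cortical bone 25 ≈ background 20) — contrast is prescribed,
  not physically simulated;
* "moth-eaten" IMAT speckle: a Gaussian random field smoothed at the
  speckle grain (3 px) is thresholded *exactly* at the top-k quantile
  inside the muscle compartment, so the realized fraction equals the
  target up to one-pixel quantization and is strictly monotone in it;
* an optional linear proximal→distal infiltration gradient (default
  endpoints 11.6 % → 27.2 %, typical of dystrophic thighs);
* a smooth multiplicative bias field (single broad Gaussian bump,
  ±5 % by default, ≤ 20 % allowed) and Rician noise (magnitude of a
  complex Gaussian perturbation, σ = 7.3, i.e. muscle SNR ≈ 15).

Identical spec and seed reproduce the volume bit for bit; the caller's
RNG state is saved and restored.

What the phantom does **not** emulate: partial-volume mixing at tissue
boundaries, chemical-shift artefacts, anatomical muscle septa, multiple
bones (the lower leg), non-circular fascia, or realistic SAT/IMAT
texture statistics beyond the thresholded-field speckle. Passing the
phantom validation therefore demonstrates the geometric and statistical
correctness of the machinery under controlled contrast, not clinical
performance on patient images.

The cohort generator mirrors the visual-scoring side: grades for 10
thigh and 6 leg muscles, bilaterally, drawn around three archetype
patterns (near-normal 1.7; posterior-dominant 3.7/2.5; diffuse 3.4 for
the thigh — with leg analogues 1.2 / selective medial gastrocnemius
3.0 / diffuse 2.8 sparing the tibialis posterior), Gaussian noise
(sd 0.4) rounded and clipped to the 1–4 scale, independent sides, and
Bernoulli STIR flags (3.1 % default). Cluster sizes default to the
16/10/9 split of a 35-patient cohort.

# Cohort statistics

* **Imaging-pattern clustering**: Lloyd's k-means (20 restarts) on the
  side-averaged per-muscle grades, thigh and leg separately; cluster
  labels are re-ordered by ascending mean severity. Whether clustering
  should use side-averaged (10-feature) or raw (20-feature) vectors is
  genuinely open; side-averaged is the default, raw is available via
  `side_average = FALSE`.
* **ICC**: the two-way random-effects, absolute-agreement,
  single-measure form ICC(2,1), from the mean squares of the
  subject × rater decomposition; absolute agreement is the conservative
  choice for method reproducibility, and the consistency form ICC(3,1)
  is available. The CV is per-subject sd/mean × 100, summarized as
  mean ± sd over subjects.
* **Spearman/Bonferroni**: mid-rank correlation; the two-sided p is an
  exact full permutation enumeration for n ≤ 10 (n! ≤ 3.6 M, one
  matrix product) and the t approximation above; Bonferroni is
  `min(1, m·p)`.
* **Linear vs log R²**: simple-regression R² of FF and log FF on the
  mean visual score. Zero fractions are offset by half the smallest
  positive value, with a warning. The validation experiment draws
  `log FF = −3.5 + 0.8·score + N(0, 0.35²)` for n = 35 patients, chosen
  so that the true log-scale R² is ≈ 0.80 — the regime where a visual
  score saturates while the quantitative measure keeps resolving — and
  verifies that the log fit wins in ≥ 95 % of replicates.

# Numerical choices and problem sizes

Tolerances and degenerate inputs are handled explicitly: fewer distinct
values than k, constant correlation inputs, zero pooled variance,
all-empty fraction denominators and non-nested manual contours are
errors; empty muscle classes, non-convergent snakes and short volumes
are flags or warnings, because on real data they demand a human
decision rather than a crash.

The validation suite runs on deliberately small problems so that the
whole cycle stays interactive: 128-px single- or few-slice phantoms,
a 40-slice gradient volume for the aggregation check, 24-value
clustering oracles, 150-patient cohorts, 10,000-replicate t-test
calibration and 500-replicate R² experiments. The acceptance script
(`scripts/acceptance.R`) recomputes all of it from one seed in under a
minute.

# Known limitations

* The muscle-region envelope assumes a star-convex compartment with a
  slowly varying radius profile; it was calibrated and validated on
  circular-fascia phantoms.
* One limb per image: fields of view containing both thighs must be
  cropped upstream.
* Bone handling is per-slice; no 3-D continuity is enforced.
* The fat fraction is a pixel-count ratio without partial-volume
  modelling, consistent with its definition on hard-labelled classes.
* Thigh (single-femur) geometry only in the phantom; leg (two-bone)
  geometry is not yet generated.
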