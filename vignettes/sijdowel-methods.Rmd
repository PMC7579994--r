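---
title: "Methods: virtual dowel analysis of sacroiliac bone quality"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: virtual dowel analysis of sacroiliac bone quality}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sijdowel)
```

## The procedure

`sijdowel` compares candidate sacroiliac implant trajectories by the bone
they would actually engage. Each trajectory is a fiducial pair in world
millimetres: the projected distal tip of the implant and a second point on
the proximal (entry) side of the ilium. The analysed region of interest is
the *virtual dowel*: the closed finite cylinder between the two fiducials,
12 mm in diameter by default, matching the implant envelope. The cylinder
is not extended beyond either landmark, because the landmarks are defined
as the trajectory's endpoints.

Voxels are counted whole: a voxel belongs to the dowel if and only if its
center lies within the cylinder (perpendicular distance ≤ radius, axial
projection within [0, length]). There is no partial-volume weighting, so
every count is an integer and the dowel volume converges to
pi r^2 L as spacing shrinks (the test suite checks < 2% relative error at
0.3 mm spacing). Boundary ties — a center exactly at the radius, or
projecting exactly onto an end plane — are *included* (closed-set
convention), which keeps membership deterministic.

Within the dowel, voxels are split by the segmentation label mask into
bodies (ilium, sacrum) plus an extra-osseous remainder. Metrics are
computed per body:

* `a_t`: mean HU over all dowel voxels inside the body;
* `a_c`, `a_ca`: mean HU over its cortical and cancellous voxels;
* voxel counts `n_cortical`, `n_cancellous`, `n_total`;
* `bone_fraction = (n_cortical + n_cancellous) / n_total`.

Two choices here were genuinely open. First, the ROI total is the dowel
intersected with the body mask, not the whole cylinder: sub-threshold
voxels *inside* a body (marrow, fat) count toward the total, while
extra-osseous cylinder voxels are tallied separately and excluded from the
bone fraction. This is what makes cohort totals far exceed
cortical + cancellous counts, as observed in real trajectory data. Second,
the bone fraction combines cortical and cancellous counts in one
numerator; recombining published per-trajectory mean counts this way
reproduces the published mean fractions in most cells (e.g.
(109 + 2436)/10778 = 0.24 for the inferior posterolateral dowel in the
ilium), which pinned the definition. Means over empty classes are
reported as `NA`, never 0, so downstream averaging cannot silently absorb
an undefined value.

## Density classification

Classification uses two Hounsfield-unit cut points applied to raw HU:
cortical bone at HU ≥ 867 and cancellous bone on the half-open interval
[219, 867). The defaults are calibration-phantom means (scans of inserts
of known density); `derive_thresholds()` reproduces that calibration from
per-scan (cancellous, cortical) ROI mean pairs, averaging across scans and
rounding to integer HU, and records per-scan means and SDs as provenance.
No per-specimen rescaling is applied: fixed thresholds are appropriate
when every scan shares one scanner and protocol, and the package makes no
attempt to convert HU to mass density. The three classes partition every
finite HU value (non-finite values are an error, not a class).

## Joint gap

The joint gap along a trajectory is the closest distance between the
opposing bone surfaces *within the dowel*. Surfaces are voxel-based: a
body voxel is a surface voxel if at least one face-adjacent
(6-connectivity) neighbour lies outside the body, with the grid border
counting as outside. Surface points are the world coordinates of those
voxel centers; no sub-voxel interpolation is attempted, which buys an
honest error bar — the computed gap is within sqrt(3) × spacing of the
true surface separation — instead of false precision. Two consequences
follow from the center convention and are deliberate:

* Bodies in face contact report a gap of one voxel spacing (adjacent
  centers); `joint_gap_distance()` logs a contact caveat when the gap
  does not exceed the spacing, since the true separation may be zero.
* The phrase "closest distance which intersects the trajectory" is read
  as the closest pair over surface points *restricted to the dowel*, not
  a distance measured along the dowel axis. The two readings differ for
  oblique crossings: a dowel at 60 degrees to the gap normal traverses
  2 g of empty space along its axis, but the joint separation is still g,
  and the closest-pair reading returns g. A regression test pins this.

Nearest-neighbour queries are computed exactly (chunked all-pairs
distances); ties are broken by the lexicographically smallest pair of
world coordinates so results are deterministic. `gap_map()` returns the
full per-point distance field; its minimum equals the scalar gap by
construction. If the dowel contains no surface points of one body, the
trajectory does not span the joint and the gap is an error, not a number.

## The phantom generator

No CT data ships with the package, so the generator builds scenes whose
ground truth is known *exactly*, trading anatomical realism for test
power. `make_two_body_phantom()` produces two slab-like bodies ("ilium",
"sacrum") on a regular grid:

* each body has a cortical-HU shell (default 1.8 mm for the ilium,
  0.6 mm for the sacrum — the ilium really is the cortex-rich body) and
  a cancellous core (defaults 450 HU ilium, 330 HU sacrum, again ordered
  as in real pelvic bone);
* a configurable fraction of core voxels (default 50%) is replaced by
  sub-threshold "marrow" at 100 HU, so ROI totals exceed bone counts as
  in real data;
* the joint gap is filled with soft tissue (30 HU) against a background
  of −800 HU, and i.i.d. Gaussian noise (default SD 5 HU, the scale of
  calibration-phantom variability) is added last.

Gaps are snapped to the voxel grid so that opposing boundary-voxel
*centers* are exactly `round(gap/spacing)` spacings apart; the achieved
value is recorded in the `ground_truth` attribute along with per-body
shell/core/marrow counts. The joint has two regions: an anterior gap
(default 1.2 mm) crossed near-perpendicularly by the three lateral
trajectories, and a wider posterior, "ligamentous" gap (default 4.8 mm)
crossed by the two posterolateral trajectories — the geometric feature
that produces the lateral-versus-posterolateral gap ordering. A tilt
parameter instead makes the sacral face a wedge, so the gap grows
linearly along the anteroposterior axis; this is what the `gap_map` field
tests exercise.

`make_trajectory_landmarks()` derives the five fiducial pairs from the
same specification: lateral dowels run parallel to the gap normal at
three vertical stations; posterolateral dowels cross at the configured
oblique angle (default 40 degrees from the normal), descending vertically
so they remain inside the posterior gap region for their whole width.
Every pair starts outside the ilium on its entry side and ends inside the
sacrum, and each dowel is verified to intersect both bodies.

Bodies are rectangular slabs, not anatomical meshes: every downstream
computation consumes only masks and HU values, so geometric realism adds
nothing a test could check, while slabs make gap widths, counts and
fractions exact by construction. What the phantoms deliberately do *not*
emulate: CT physics (partial-volume blur, beam hardening, reconstruction
kernels), curved joint surfaces, cartilage, and anatomical landmark
variability. Passing the phantom battery therefore validates the
geometry, counting and statistics of the pipeline — not segmentation
quality or HU calibration on clinical scans.

Synthetic cohorts (`simulate_cohort()`) jitter the cancellous HU means
(SD 25 HU) and the two gap widths (SD 0.4 mm) across specimens and give
each specimen its own sub-seed; identical spec + seed is guaranteed to
reproduce a phantom voxel for voxel.

## Statistics

The cohort battery mirrors standard practice for this design:

* a repeated-measures one-way ANOVA of joint gap by trajectory, computed
  by absorbing the specimen effect as a block (F on
  (k − 1, (k − 1)(n − 1)) degrees of freedom). No sphericity correction
  is applied — a documented limitation;
* Bonferroni-corrected pairwise paired t tests
  (`p_adj = min(1, p × n_pairs)`); zero-variance differences yield p = 1
  with a warning rather than an error;
* per-outcome univariate two-way fixed-effects ANOVAs over
  body × trajectory on balanced designs. A multivariate test across the
  five outcomes is deliberately out of scope: per-outcome comparisons are
  what the downstream questions need, and inventing unreported
  multivariate statistics would add nothing checkable.

Degenerate fits are normalised: an effect sum of squares at
rounding-noise scale reports F = 0, p = 1; a perfect fit with a genuine
effect reports F = Inf, p = 0. Oracle tests recompute every F statistic
from raw sums-of-squares formulas, and a 1000-replicate null simulation
checks the repeated-measures test holds its nominal 5% type-I error.

Demographics summaries use sample SDs (n − 1). WHO T-score bands are the
standard ones — normal at T ≥ −1.0, osteoporosis at T ≤ −2.5, osteopenia
between — which also exactly reproduce the reference cohort's 2/4/3
split, confirming the band convention.

## Numerical choices and problem sizes

* Voxel indices are 0-based; a voxel's world coordinate is its center.
  Coordinate transforms are exact inverses (tested to 1e-9).
* Cylinder membership uses an absolute tolerance of 1e-7 mm^2 on the
  squared perpendicular distance so exact-boundary centers are included
  despite floating-point rounding.
* NIfTI I/O goes through RNifti; NIfTI stores spacing as 32-bit floats,
  so geometry round-trips to ~1e-6 mm while voxel data round-trip
  bit-exactly (float64). The MetaImage reader/writer is a minimal
  built-in implementation of the uncompressed format.
* Default unit-test phantoms are 64 × 48 × 48 voxels at 0.5 mm; the
  standard scene is 96 × 72 × 72 at 0.6 mm (the slice thickness of the
  motivating protocol, assumed isotropic since no in-plane spacing is
  specified). These sizes keep the full suite and the acceptance script
  in the tens of seconds while leaving every geometric property
  measurable at its stated tolerance.

## Limitations

* Whole-voxel counting and center-to-center distances limit gap accuracy
  to sqrt(3) × spacing; sub-voxel surface models are out of scope.
* Fixed HU thresholds assume a single scanner/protocol; cross-scanner
  cohorts would need per-scan calibration.
* The phantom's slab geometry cannot detect errors that only curved or
  thin-walled anatomy would expose.
* Left/right sides are analysed as supplied; the synthetic scenes model a
  single side. When averaging sides per specimen is desired, do so before
  the ANOVA stage.
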