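---
title: "Measuring tree heights from fisheye images: model, calibration and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring tree heights from fisheye images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fisheyetree)
```

## The measurement problem

A fisheye lens can capture an entire standing tree from a few meters away,
which makes single-image photogrammetry attractive for forest inventory:
photograph the tree, detect it, and convert the detection box into a
metric height. The price of the wide field of view is strong radial
distortion, so the conversion requires an explicit camera model and a
calibration procedure. This vignette documents the model implemented here,
the choices made where the design was genuinely open, and what the
validation machinery does and does not demonstrate.

## The equidistant projection model

The model assumes the measured object lies in a vertical plane
perpendicular to the optical axis (fronto-parallel) at horizontal distance
`L` from the lens. A world point $P(x_w, y_w)$ in that plane is seen under
the incident angle

$$ w = \arctan\!\left(\sqrt{x_w^2 + y_w^2}\,/\,L\right), $$

and under equidistant projection its radial image displacement is
proportional to $w$, not to $\tan w$ as in a pinhole camera. Splitting the
radial displacement into axes by the azimuth of $P$ gives the forward
model implemented in `project_to_pixel()`:

$$ u = u_0 + k_x\,\frac{x_w}{r}\,\arctan\frac{r}{L}, \qquad
   v = v_0 + k_y\,\frac{y_w}{r}\,\arctan\frac{r}{L}, \qquad
   r = \sqrt{x_w^2+y_w^2}. $$

The composite coefficients $k_x, k_y$ (pixels per radian) absorb the focal
length, the per-axis distortion factors and the sensor magnification.
Those individual factors are not separately identifiable from image data,
so the package stores only the composites; nothing downstream ever needs
them individually. A depth coordinate for $P$ is likewise redundant: under
the fronto-parallel assumption the scalar distance `L` carries all of it.

Pixel convention: origin at the image top-left, `u` along columns
(rightward), `v` along rows (downward), continuous sub-pixel values. World
`y_w` increases in the same sense as `v`, so a treetop has the smaller
`v` and the smaller `y_w`. The library is unit-agnostic: pixels are always
pixels, and all lengths (world coordinates, `L`, `h`, `l`, heights) are in
whatever single unit the caller chooses.

The distance actually entered into the model is $L = h + l$, where $h$ is
the measured horizontal distance and $l$ a lens-specific virtual imaging
distance. `l` is a calibration input with default 0; since omitting a
genuinely nonzero `l` biases every measurement, `measure_tree_height()`
emits an advisory message (once per call, suppressible with
`quiet = TRUE`) whenever it measures with `l = 0`.

### The closed-form inverse

`backproject_to_world()` inverts the forward model exactly. Writing
$a = (u-u_0)/k_x$ and $b = (v-v_0)/k_y$, the pair $(a, b)$ is the incident
angle decomposed along the azimuth, so $\theta = \sqrt{a^2+b^2}$ recovers
the incident angle and

$$ x_w = \frac{a}{\theta}\, L \tan\theta, \qquad
   y_w = \frac{b}{\theta}\, L \tan\theta. $$

This polar form is algebraically identical to the per-axis closed form one
gets by eliminating variables between the two forward equations, but it
needs no branch analysis: the azimuth is preserved exactly (including all
sign cases), and the principal point maps to the optical axis as the
continuous limit $\theta \to 0$, handled by evaluating
$L\tan\theta/\theta \to L$. A pixel implying $\theta \ge \pi/2$ has no
fronto-parallel pre-image and raises a classed out-of-field error.

Numerical behavior worth knowing: the round trip
world → pixel → world is exact to better than $10^{-9}$ relative error for
incident angles up to 85° across coefficient scales of 100–5000 px/rad
(property-tested); accuracy degrades only in the last degrees before 90°
where $\tan$ explodes, which is outside any realistic shooting geometry.

## Checkerboard calibration

`calibrate()` estimates $k_x, k_y$ from corner correspondences — pixel
position, board-plane world position, board distance — by inverting the
forward model per corner:

$$ \hat k_x = \frac{u-u_0}{(x_w/r)\arctan(r/L)}, $$

and symmetrically for $\hat k_y$, then averaging arithmetically over all
corners, pooling every board position equally. Choices behind this:

* **The principal point is an input, not an estimate.** Principal-point
  estimation belongs to general omnidirectional calibration tools; this
  package consumes their output (or the image center as a default
  approximation).
* **Both axes are estimated from every corner where conditioned.** A
  corner nearly on one axis carries almost no information about the other
  coefficient: the denominator $(x_w/r)\arctan(r/L)$ goes to zero with
  $x_w/r$, amplifying pixel noise unboundedly. Corners with
  $|x_w|/r < 0.05$ (about 3° of azimuth from the vertical axis) return
  `NA` for $\hat k_x$ rather than an unstable number; the threshold is a
  conservative conditioning cut, configurable via `min_axis_ratio`.
  A corner exactly on the optical axis constrains nothing and is an error.
* **Plain pooled averaging.** Nothing in the procedure's definition
  weights boards by distance or corner count, and the estimator is already
  unbiased under zero-mean pixel noise, so the simplest average is used.
  Permutation invariance of the corner list is tested.

`verify_distances()` closes the loop the way the physical experiment does:
distances between back-projected corner pairs are compared against
tape-measured separations, reporting per-pair relative error and its mean.
The package bundles such a verification dataset
(`checkerboard_corner_pairs()`: 5 board distances × 3 corner pairs, mm
units); recomputing it yields a mean relative error of 0.766%, i.e. the
calibrated model preserves metric geometry to well under a percent across
a 320–2041 mm working range. The test suite freezes the dataset's
originally reported derived values as references; three of those reported
cells are mutually inconsistent with their own coordinates (transcription
defects in the source report), and the corresponding expectations document
the discrepancy rather than hiding it.

Report files round to 4 decimals for distances and percentages, matching
the print precision of the source data.

## From detection box to tree height

The detector contributes one axis-aligned box per tree. The image points
of the tree's highest and lowest world points — the *extreme points* — are
taken as the midpoints of the box's top and bottom edges
(`box_extremes()`). `measure_tree_height()` back-projects both at
$L = h + l$ and returns their planar distance. Which end is the treetop is
irrelevant to the distance; the package labels the smaller-`v` point "top"
for reporting.

The midpoint rule is exact when the tree's extreme points share an image
column, which holds when the trunk stands on the principal-point column
and the crown is laterally symmetric — the natural shooting geometry for a
single centered tree, and the default geometry of the synthetic generator.
Off-column trees incur a small model error that grows with azimuthal
offset; quantifying it requires the generator's off-axis mode
(`trunk_base` with nonzero first coordinate), where the ground-truth box
is still correct but the midpoint rule is only approximate.

`batch_measure()` applies the measurement per annotated box with one
distance `h` per image (several boxes in an image share its `h`), filters
boxes by detector confidence first (default threshold 0.5, configurable —
detectors rarely document their deployment cutoff), and summarizes
relative errors `100·|pred − ref|/ref` against reference heights where
available.

## Detection metrics

Single-class precision, recall, F1 and AP are standard but their matching
step is often left vague, so it is pinned down here: greedy one-to-one
matching in descending confidence order, a prediction counting as a true
positive iff its best IoU against a still-unmatched ground truth reaches
the threshold (default 0.5, the long-standing benchmark convention), ties
broken deterministically by input order. F1 is the harmonic mean
$2PR/(P+R)$ reported as a ratio rounded to two decimals, the form in which
detection benchmarks print it. AP uses all-point interpolation — the exact
area under the monotone precision envelope versus recall — rather than the
older 11-point approximation, because it equals the continuous integral
$\int_0^1 P(R)\,dR$ that defines the metric. The implementation is checked
against a brute-force oracle (per-true-positive max-precision summation)
on random small instances; the two formulations agree to machine
precision.

Metrics with zero denominators (no predictions, no ground truths) raise a
classed `undefined-metric` error instead of silently returning 0, since a
silent 0 poisons averages.

## Mosaic augmentation

`mosaic()` implements the four-image mosaic recipe used to train
single-stage detectors: per image an optional horizontal mirror
(probability 0.5), a uniform rescale (longer side drawn from 0.4–1.0 of
the output size), HSV color jitter (multiplicative, half-ranges
0.02/0.3/0.3 for hue/saturation/value; hue wraps), placement into the four
quadrants around a center point drawn from the central half of the canvas,
and the same affine map applied to the boxes with clipping to the
quadrant. A clipped box is dropped when it loses more than 75% of its area
or a side falls under 2 px — tiny slivers teach a detector nothing and
destabilize loss normalization. All parameters are configurable; none of
them is canonical in the literature, so the defaults follow the common
recipe with a 640 px canvas (the usual training input size). Every draw
comes from one seeded stream, making outputs bit-reproducible; resizing is
nearest-neighbor so that the fixed-parameter case (scale exactly 0.5,
jitter off, center at the canvas midpoint) tiles input pixels exactly,
which the tests exploit.

## The synthetic scene generator

Real validation of this method needs a calibrated lens, surveyed trees and
a trained detector. The generator replaces all three for testing purposes
with scenes whose ground truth is exact by construction:

* `generate_board()` projects a regular corner grid through a chosen
  intrinsics object, optionally adding isotropic Gaussian pixel noise
  (seeded) to emulate corner-detector error. Corners beyond an 85°
  incident angle — the usable half field of view of a realistic fisheye in
  this fronto-parallel setup — refuse to generate.
* `generate_tree_scene()` models a tree as a vertical trunk rectangle
  (lower 40% of the height) under an elliptical crown (upper 60%,
  configurable width), fronto-parallel at distance `h`, by default
  standing on the principal-point column with the camera at mid-height.
  The ground-truth box's top and bottom edges pass through the exact
  projections of the tree's extreme points; its sides bound the projected
  silhouette boundary. Optional seeded Gaussian jitter on the four edges
  emulates detector localization noise. Rendering (a dark silhouette on a
  light background, produced by back-projecting each pixel center and
  testing membership) is optional and only needed when an actual image
  file is wanted.

What the generator deliberately does **not** emulate: photographic
texture, illumination and weather variation, occlusion between trees,
trunk lean, and wind deformation of the crown. Consequently, passing
end-to-end tests demonstrates the *geometric* correctness of the
projection, calibration and measurement chain — it says nothing about how
well any particular detector finds trees in real fisheye photographs, nor
about field error sources (distance measurement error, extreme-point
misdetection under wind). Those require a field campaign by design.

## Validation setup and problem sizes

The test suite and `scripts/acceptance.R` exercise, with fixed seeds:

* projection round trips at 200 random camera/point configurations
  (tolerance $10^{-9}$ relative);
* end-to-end height recovery on 100 random noiseless scenes (heights
  2–40 length units, distances 0.7–4× the height, coefficients
  400–4000 px/rad; tolerance $10^{-6}$ relative);
* calibration recovery from a 32×32 corner grid at 0.5 px noise
  (recovered coefficients within 1% — in practice within ~0.03%);
* AP versus the brute-force oracle on 50 random instances of up to 8
  boxes;
* a 30-tree batch with 1 px box jitter (mean relative error under 2%).

These sizes keep the full suite under a minute on one CPU while leaving
each property's sampling broad enough to catch sign, branch and
conditioning mistakes; they are not tuned to any particular hardware.

## Known limitations

* The fronto-parallel assumption ignores camera tilt; photographing
  uphill/downhill or tilting the phone biases heights systematically.
* The midpoint extreme-point rule is exact only for trees centered on the
  principal-point column (see above).
* `l = 0` is a biased default when the lens has a substantial virtual
  imaging distance; calibrating `l` requires measurements at multiple
  known distances and is not implemented.
* Only single-class evaluation is provided; multi-class mAP is out of
  scope.
* The checkerboard pipeline consumes corner correspondences; corner
  *detection* from images is delegated to external tools.
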