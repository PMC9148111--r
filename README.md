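# fisheyetree

Monocular photogrammetric measurement of standing-tree heights from single
fisheye photographs.

Tree height is a central variable in forest inventory, biomass estimation
and carbon accounting, but it is awkward to measure directly: theodolite
surveys are slow, ultrasonic rangefinders are operator- and wind-sensitive,
and laser scanning is expensive. A practical alternative is to photograph
the whole tree with a fisheye lens — whose wide field of view captures a
tall tree from a short distance — detect the tree in the image, and convert
the detection box into a metric height through a calibrated camera model.
`fisheyetree` implements everything in that chain except the detector
itself: the fisheye projection model, its checkerboard calibration, the
box-to-height pipeline, single-class detection metrics, mosaic
augmentation for detector training data, and a synthetic scene generator
used to validate the whole chain end to end.

## The measurement model

The lens is modeled as an equidistant projection: a world point `P(xw, yw)`
in a fronto-parallel plane at horizontal distance `L` from the lens is seen
under the incident angle

    w = arctan( sqrt(xw² + yw²) / L )

and images at pixel coordinates

    u = u0 + kx · (xw / r) · arctan(r / L),   r = sqrt(xw² + yw²)
    v = v0 + ky · (yw / r) · arctan(r / L)

where `(u0, v0)` is the principal point and `kx`, `ky` (pixels per radian)
are composite per-axis distortion coefficients absorbing the focal length,
distortion factors and sensor magnification. The model distance is
`L = h + l`, with `h` the measured camera-to-target distance and `l` the
lens's virtual imaging distance.

The coefficients are calibrated from checkerboard corners with known
board-plane coordinates: each corner yields closed-form per-axis estimates
by inverting the projection, and the estimates are averaged over all
corners and board positions.

To measure a tree at distance `h`, the midpoints of the top and bottom
edges of its detection box — the image points `A′`, `B′` of the tree's
highest and lowest world points — are back-projected through the inverse
model to world coordinates `A(xA, yA)`, `B(xB, yB)`, and the height is

    H = sqrt( (xA − xB)² + (yA − yB)² ).

## Worked example

Calibrate from a synthetic checkerboard (known ground truth, 0.3 px corner
noise), then measure a synthetic 12.4 m tree photographed from 16 m whose
box edges carry 1 px of localization jitter:

```r
library(fisheyetree)

cam_true <- fisheye_intrinsics(kx = 1320, ky = 1280, u0 = 960, v0 = 540,
                               units = "m")
board <- generate_board(
  board_spec(rows = 8, cols = 8, square_size = 0.05,
             board_center = c(0.02, 0.015), L = 1.2,
             pixel_noise_sd = 0.3, seed = 11), cam_true)
fit <- calibrate(board, principal = c(960, 540), units = "m")
fit
#> Fisheye calibration from 60/64 corner estimates (x/y axis)
#> Fisheye intrinsics (equidistant projection)
#>   kx = 1321.99 px/rad, ky = 1281.4 px/rad
#>   principal point (u0, v0) = (960, 540) px
#>   virtual imaging distance l = 0 m
#>   reprojection residual: mean 0.417 px, max 0.907 px

scene <- generate_tree_scene(
  tree_scene_spec(tree_height = 12.4, h = 16, cam = fit$intrinsics,
                  crown_width = 3.5, box_jitter_sd = 1, seed = 3),
  render = FALSE)
round(scene$boxes[, 1:4], 2)
#>    x_min y_min   x_max   y_max
#> 1 816.11 65.99 1103.19 1012.56

measure_tree_height(scene$boxes, h = 16, cam = fit$intrinsics)
#> virtual imaging distance l = 0: using L = h for measurement
#> [1] 12.38798
```

The calibrated coefficients land within 0.15% of the generating values and
the measured height within 0.1% of the true 12.4 m — the residual error
coming entirely from the injected corner noise and box jitter.

The package also bundles a physical verification dataset: checkerboard
corner pairs photographed at five board distances with surveyed world
coordinates and tape-measured separations.

```r
verify_distances(checkerboard_corner_pairs())
#>  label board_distance ... calculated relative_error_pct
#>     AB            320 ...   656.3162             0.9717
#>     AB           1502 ...   652.1023             0.3234
#>     AD            612 ...   921.6589             0.2634
#>  ...   (15 corner pairs)
#> mean relative error: 0.766%
```

Each `calculated` value is the planar distance between the two
back-projected corners; the sub-percent relative errors against the taped
separations confirm that the calibrated model preserves metric geometry
across the board's working range.

Detector-side utilities follow the usual single-class conventions —
`evaluate_detections()` returns precision, recall, F1 (harmonic mean,
`f1_score(92.27, 97.95)` → `0.95`) and all-point interpolated average
precision, and `mosaic()` builds seeded four-image mosaic augmentations
with remapped boxes. A thin command-line wrapper with subcommands
`calibrate`, `verify`, `measure`, `evaluate`, `simulate` and `augment`
ships in `inst/cli/fisheyetree.R`.

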