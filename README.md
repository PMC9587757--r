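# fiberwo

Pixel-wise orientation mapping of fiber-like structures (blood vessels,
collagen, neurites) in 2D images and 3D stacks, with the analysis window
chosen **adaptively from the local fiber thickness**.

## The problem and the method

Windowed orientation estimators need a window matched to the fiber
calibre: a window smaller than a thick fiber sees a featureless patch
(undersampling), a window larger than a thin fiber mixes in its
neighbours (contamination). Vascular images contain trunk vessels and
capillaries side by side — calibres spanning 1–60 px — so no fixed window
works everywhere.

fiberwo implements the window-optimizing approach:

1. **Pixel-wise thickness** `d` by distance transfer: an exact Euclidean
   distance transform of the binary mask, reduced to distance-ridge
   seeds, whose inscribed discs propagate their diameter to every pixel
   they cover — i.e. `d(p)` is the diameter of the largest inscribed
   disc/sphere containing `p`.
2. **Per-pixel window** `W(p) = 2 d(p) + 1`.
3. **Weighted orientation vector summation** inside that window: each
   neighbouring foreground pixel contributes its direction from the
   centre with weight `I / r` (intensity over distance). Orientations
   are axial (period 180°), so 2D contributions enter as doubled-angle
   vectors, `theta = 1/2 atan2(sum)`; 3D contributions accumulate a
   direction-dyad tensor whose dominant eigenvector gives the axis
   `(theta, phi)`.
4. **Alignment statistics**: directional variance `V ∈ [0, 1]`
   (0 = parallel, 1 = isotropic) per neighbourhood, per depth slice, and
   stratified by physical vessel calibre.

A synthetic phantom generator (straight / sinusoidal 2D fibers, 3D
cylinders, exact per-pixel ground truth) and an evaluation harness
(`run_comparison()`) reproduce the accuracy studies: the adaptive window
beats every fixed window from 21 to 201 px on images whose fiber
diameters span 1–60 px.

## Worked example

```r
library(fiberwo)

spec  <- phantom_spec(c(300, 300), diameters = c(3, 10, 30), seed = 7)
ph    <- generate_straight_fibers_2d(spec)
ph
#> <phantom> 300 x 300, 3 fiber diameter(s): 3, 10, 30
#>   foreground: 7403 px (8.2%), model: straight, seed: 7

thick <- local_thickness(ph$truth$mask)
round(range(thick[ph$truth$mask]), 2)
#> [1]  2.83 30.07        # recovered diameters track 3, 10, 30 px

field <- orient2d(ph$image, ph$truth$mask, thick)
err   <- error_map(field, ph$truth, "theta")
mean(err[ph$truth$mask & field$valid])
#> [1] 5.72               # mean angular error, degrees

rep <- run_comparison(spec, window_sizes = c(21L, 161L), n_images = 2L,
                      seed = 7)
glance(rep)
#> # A tibble: 1 × 6
#>   kind  wo_error fixed_min fixed_median fixed_max wo_dominates
#> 1 theta     4.59      9.46         10.3      11.1 TRUE
```

The `glance()` line is the package's headline readout: the
thickness-adaptive estimator (4.6°) against the best and worst fixed
window (9.5°–11.1°) on the same images, each diameter class weighted
equally. `tidy(rep)` gives the per-method table (both the
diameter-balanced and the pixel-pooled averages), `plot_comparison(rep)`
the error-vs-window curve, and `autoplot(field)` the hue-coded
orientation map. For 3D stacks use `generate_fibers_3d()` /
`orient3d()`, then `local_variance_map()`, `depth_profile()` and
`stratify_by_thickness()` for alignment summaries.

A command-line front end (`inst/scripts/fiberwo-cli`) wraps the same
functions for TIFF-in/TIFF-out batch use
(`thickness`, `orient`, `variance`, `profile`, `stratify`, `compare`).

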