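# oodetect

Vision pipeline for locating a metaphase-II **oocyte** and its **polar
body** in a single inverted-microscope image, for automated
intracytoplasmic sperm injection (ICSI) micromanipulation. The injection
site must be kept as far as possible from the polar body (it marks the
chromosome region), so the micromanipulation controller needs the centers
and sizes of both objects and the polar-body bearing before every
injection.

## Method

Given an 8-bit micrograph and user-supplied radius ranges for the two
objects (in µm with a µm/px calibration, or directly in px):

1. grayscale conversion `(R+G+B)/3`, linear contrast stretch with
   `E_f = (2^n − 1)/(gray_max − gray_min)`, and weighted-average smoothing
   with a normalized binomial mask (5×5 default, 3×3 selectable);
2. Sobel gradients; edge points are the pixels whose gradient magnitude
   `‖∇f‖ = √(Gx² + Gy²)` exceeds an automatic threshold (top 10% kept);
3. **gradient-weighted circular Hough transform**: each edge point votes at
   `(x ± r cosθ, y ± r sinθ)` for every radius step, weighted by its
   gradient magnitude, so sharp boundaries outvote blurred ones and the
   result is invariant to bright-on-dark vs dark-on-bright imaging; the
   smoothed accumulator's peak is the center estimate, gated by a
   confidence measured in ideal-circle vote masses;
4. **elliptical sizing**: with the center fixed, every axis-aligned
   semi-axis pair `(a, b)` in the range grid is scored by the mean gradient
   magnitude along `x = x0 + a cosθ, y = y0 + b sinθ`; the reported
   diameter is the equal-area value `2√(ab)`;
5. the polar-body search repeats 3–4 inside the perivitelline annulus
   around the detected oocyte (its rim's edge points withheld from the
   vote), and reports "polar body not located" when no coherent circle
   passes the confidence gate.

A seeded synthetic-scene generator renders ground-truthed look-alikes
(140 µm oocyte, 20 µm polar body, varying backgrounds, bearings,
magnifications, blur, noise, optional cumulus clutter), and a benchmark
harness scores the detector against the truth. See the methods vignette
(`vignettes/oocyte-detection-methods.Rmd`) for the model, parameters and
design choices.

## Worked example

```r
library(oodetect)

spec <- scene_spec(seed = 7)            # synthetic scene, 0.5 um/px
sc   <- render_scene(spec)
rep  <- oodetect(sc$image, oocyte_radius = c(55, 85), pb_radius = c(5, 15),
                 um_per_px = spec$um_per_px)
rep
```

```
Oocyte / polar-body detection report
  oocyte    : center (row 218, col 221) px, a = 135 px, b = 140 px, diameter 274.95 px (137.48 um, rel. center x = 2, y = -0.5 um), confidence 5.926
  polar body: center (row 112, col 343) px, a = 20 px, b = 20 px, diameter 40 px (20 um, rel. center x = 63, y = 52.5 um), confidence 13.011
  polar-body bearing: 40.99 deg from +x axis (CCW)
```

The scene's ground truth is a 140-µm oocyte centered on the vision field
and a 20-µm polar body at bearing 40°; the report recovers the polar-body
diameter exactly and the oocyte diameter within 1.8%.

The oocyte is reported at its center (rows/columns, 1-based), with fitted
semi-axes `a` (along x/columns) and `b` (along y/rows), the equal-area
diameter in px and µm, and the position relative to the image center (the
microscope's vision-field center) in µm with y pointing up. The bearing is
the counter-clockwise angle of the oocyte→polar-body line from the +x axis;
the true bearing of this scene is 40°. `coef(rep)` returns the same numbers
as a matrix, `plot(rep, sc$image)` displays the overlay, and
`report_json(rep)` serializes the report.

Command-line use (`inst/cli/oodetect.R`):

```sh
Rscript inst/cli/oodetect.R detect --image scene.png \
    --oocyte-radius-um 55:85 --pb-radius-um 5:15 --scale-um-per-px 0.5 \
    --out report.json --overlay overlay.png
Rscript inst/cli/oodetect.R simulate --suite suite.json --out scenes/
Rscript inst/cli/oodetect.R bench --suite suite.json --out bench/
```

Exit status: 0 both objects found, 2 no oocyte, 3 oocyte only ("polar body
not located"), 1 bad input.

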