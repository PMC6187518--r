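---
title: "Methods: gradient-weighted Hough localization and elliptical sizing of oocytes"
author: "oodetect"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gradient-weighted Hough localization and elliptical sizing of oocytes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

In intracytoplasmic sperm injection (ICSI) a single sperm is injected into a
metaphase-II oocyte. The injection must stay as far as possible from the
polar body, the small extruded cell that marks the chromosome region and sits
in the perivitelline space between the oocyte membrane and the zona
pellucida. Automating the manipulation therefore requires, from a single
inverted-microscope image, the positions and sizes of the oocyte and its
polar body, plus the bearing of the polar body relative to the vision-field
center. `oodetect` implements that vision stage and ships a synthetic scene
generator so detection accuracy can be quantified against exact ground truth
without microscope data.

## The detection chain

```{r, eval = FALSE}
library(oodetect)
rep <- oodetect("micrograph.png", oocyte_radius = c(55, 85),
                pb_radius = c(5, 15), um_per_px = 0.5)
```

1. **Grayscale conversion.** Channel mean `(R + G + B)/3`, rounded to the
   nearest integer. Rounding rule (here: ties to even, R's `round()`) is not
   dictated by the method; it is fixed and documented so results are
   reproducible to the bit.
2. **Linear contrast enhancement.** The observed range `[graymin, graymax]`
   is stretched to `[0, 2^n - 1]` with the factor
   `E_f = (2^n - 1)/(graymax - graymin)`. A constant image is returned
   unchanged with a warning — the only non-destructive choice for a
   degenerate input. Enhancement precedes filtering, so noise is stretched
   too and then suppressed by the smoothing step.
3. **Weighted-average smoothing.** Spatial correlation with a normalized
   binomial mask; the default is the 5×5 mask (outer product of
   `[1 4 6 4 1]`, normalized by 256), the natural extension of the classic
   3×3 mask `[1 2 1; 2 4 2; 1 2 1]/16`, which remains selectable
   (`mask_size = 3`). The 5×5 default suppresses the granular texture of the
   ooplasm, which otherwise floods the edge set. Borders are handled by edge
   replication everywhere (smoothing and gradients): zero padding would
   manufacture a strong frame edge that pollutes the Hough vote. Arithmetic
   stays in floating point; intensities are quantized only when an image is
   written out.
4. **Gradients.** 3×3 Sobel operator (the method needs a gradient operator
   but does not name one; Sobel is the standard separable choice). Magnitude
   `sqrt(Gx^2 + Gy^2)`; orientation `atan2(Gy, Gx)`, so
   `cos(theta) = Gx/|grad|` and `sin(theta) = Gy/|grad|`. Throughout, `x` is
   the column index (rightward) and `y` the row index (downward), 1-based.
5. **Edge thresholding.** Pixels with magnitude at or above a threshold. The
   default threshold is automatic: the quantile keeping at most 10% of
   nonzero-magnitude pixels (`keep_fraction = 0.10`), plus a hard cap of
   20 000 points (strongest kept) that bounds the voting cost on large
   images. Both limits are exposed in the configuration.
6. **Gradient-weighted circular Hough vote.** Every edge point casts, for
   each radius step in the user-supplied range, two votes at
   `(x ± r cos(theta), y ± r sin(theta))`, weighted by its gradient
   magnitude. Both polarities are used because an object may be brighter or
   darker than its background (background colors vary across microscopes),
   which flips the gradient sign. The accumulator is 2-D over centers with
   the radius marginalized — sizing is a separate, later stage. Radius steps
   default to 1 px.
7. **Peak extraction.** The accumulator is smoothed with the 3×3 binomial
   mask (discretization splits the maximum region across neighboring cells),
   and the argmax cell is returned; ties break toward the smallest row, then
   the smallest column.
8. **Elliptical sizing.** With the center held fixed, every semi-axis pair
   `(a, b)` on the range grid is scored by the mean gradient magnitude,
   sampled bilinearly, at `K = max(64, ceiling(2*pi*r_max))` equally spaced
   points of the axis-aligned ellipse `x = x0 + a cos(t)`,
   `y = y0 + b sin(t)` — at least one sample per boundary pixel. Gradients
   are taken in the square window of side `2*r_max` around the center. No
   rotation term is searched: the boundary parameterization carries none,
   and metaphase-II oocytes are near-circular, so axis-aligned ellipses
   capture the morphological variance the sizing stage is meant to absorb.
   The reported diameter is the equal-area value `2*sqrt(a*b)`.

The polar-body search repeats stages 6–8 with the small radius range and two
restrictions derived from the detected oocyte (below). The final report
gives centers in pixels and, when calibrated, relative to the image center
in micrometers with the y-axis pointing up; the polar-body bearing is the
counter-clockwise angle from the +x axis, so a polar body directly above the
oocyte is at 90°.

## Confidence, and how "polar body not located" is decided

A center estimate's `peak_vote` is the raw vote mass around the peak. An
edge point whose orientation is off by a small angle `e` misses the center
by about `r*e`, so a coherent circle's vote cluster widens in proportion to
its radius: the neighborhood half-width scales as `max(1, r_min/32)` pixels
(3×3 at polar-body radii, wider for the oocyte at low magnification).
Confidence divides that mass by the theoretical maximum vote of a full
circle at `r_min`: `ceiling(2*pi*r_min)` boundary pixels all voting with the
strongest edge magnitude observed in the image into a single cell. This
makes confidence invariant to rescaling the gradient magnitudes and
comparable across radius ranges.

Measured on the synthetic scenes, two well-separated populations emerge. A
genuine circular boundary whose radius lies in the searched range scores
4.5–13 (oocyte, across magnifications and clutter) or 10–20 (polar body).
When nothing of the searched size exists, the peak is *echo* mass: every
point of a boundary at some other radius casts votes that land in filled
annular bands on both sides of that boundary, and those bands score about
0.3–1.1. The detection gate `min_confidence = 2` — at least two
ideal-circle masses — sits a factor of two or more from both populations.
Falling below it produces the "polar body not located" report, the behavior
expected when the polar body is out of the focal plane; it also rejects a
radius range that brackets no real structure.

One additional measure keeps the polar-body stage clean: edge points lying
in a shell of half-width `rim_shell_px = 12` around the fitted oocyte
boundary are withheld from the polar-body vote. That boundary is already
explained by the oocyte detection, and its echo bands at polar-body radii
would otherwise reach confidence ≈ 2 (the shell covers the smoothed rim's
gradient ridge plus the center localization uncertainty; confidence still
references the strongest edge of the *full* image, so evidence filtering
cannot inflate it).

The center search itself is restricted to the perivitelline annulus
`[0.8 * min(a, b), max(a, b) + 3 * r_max_pb]` around the oocyte center — the
region where a polar body can physically sit, with margin for elliptical
oocytes and boundary-adjacent polar bodies.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `oocyte_radius` | 55–85 | µm | literature radius range of denudated MII oocytes (~140 µm diameter) |
| `pb_radius` | 5–15 | µm | polar bodies ~20 µm diameter |
| `um_per_px` | user | µm/px | converts µm ranges to pixels; report stays in px without it |
| `mask_size` | 5 | px | see stage 3 |
| `keep_fraction` | 0.10 | — | edge budget; the vote needs boundary points, not texture |
| `max_edge_points` | 20 000 | — | hard cost bound for large images |
| `min_confidence` | 2 | — | detection gate: two ideal-circle vote masses |
| `rim_shell_px` | 12 | px | rim evidence withheld from the polar-body vote |

## The synthetic scenes

`scene_spec()`/`render_scene()` draw a denudated MII oocyte: ooplasm disc
(default 140 µm equal-area diameter) with band-limited multiplicative
granularity (smoothed white noise, fractional amplitude 0.08 — this is what
the 5×5 filter exists to suppress), a rim 60 intensity units below the
background, the perivitelline gap at background level, a mild zona ring
(+25), an optional polar body (20 µm, same rim contrast) wholly inside the
gap, and optional dark cumulus-like blobs (contrast −70, radius 4–10 µm)
near the zona. The whole scene is Gaussian-blurred (σ = 1.5 px) and
corrupted with additive Gaussian noise (σ = 3) per channel. The default
scale is 0.5 µm/px. All randomness derives from the spec's seed; identical
`(spec, seed)` render identical images.

Two deliberate departures from real micrographs:

* the perivitelline gap is 24 µm wide — wider than in real oocytes — so that
  the 20-µm polar body lies *wholly* inside the gap, which is what the
  annulus-restricted search assumes;
* cumulus clutter is modeled as compact dark blobs. Real cumulus morphology
  is irregular, so the disturbance suite demonstrates the qualitative
  behavior (polar-body detection degrades, oocyte detection does not) rather
  than reproducing a particular failure rate.

Passing the synthetic benchmarks therefore shows the geometry, weighting and
gating logic are correct at realistic contrasts, blur and noise; it does not
certify performance on Hoffman/DIC optics, debris-laden preparations, or
out-of-focus polar bodies.

`generate_suite()` builds the four seeded benchmark categories (distinct
background colors; polar-body bearings evenly spanning the circle with small
center offsets; magnifications varying `um_per_px` geometrically over
0.5×–2× of the default with constant µm geometry; 5–20 clutter blobs), and
`run_benchmark()` scores the detector against truth. A detection is
*correct* when the center error is at most 25% of the object's true
diameter — a threshold that separates hits from gross failures at both
object scales; diameter and position errors are aggregated over detected
scenes only. These definitions are the single source of truth used by the
package's accuracy tests and by `scripts/acceptance.R`.

## Numerical choices and degenerate inputs

* Votes are cast to the nearest accumulator cell; off-image votes are
  discarded. Peak ties break to the smallest row, then column.
* Ellipse-fit score ties break toward the smaller `a + b`, then smaller `a`
  (the most compact consistent size).
* Bilinear sampling returns 0 outside the image.
* Constant image: contrast enhancement warns and returns it unchanged;
  the all-zero gradient field yields an empty accumulator and a
  "no detection" result rather than an error.
* The automatic threshold raises past a tied magnitude so at most the
  requested fraction survives (unless the tie is the maximum itself).
* Benchmark problem sizes: the suite in `tests/` uses a 30-scene mixed
  clean benchmark and 20-scene category suites; `scripts/acceptance.R` runs
  the full 80-scene mixed benchmark plus two 20-scene category suites.

## Known limitations

* Axis-aligned ellipses only; a rotated elliptical oocyte is sized by its
  bounding axis-aligned approximation.
* Single oocyte per image; no video tracking; no z-stack reasoning — an
  out-of-plane polar body is reported as not located.
* The confidence gates were characterized on the synthetic contrast regime;
  images with radically different rim/texture contrast ratios may need the
  gates adjusted through `oodetect_config()`.
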