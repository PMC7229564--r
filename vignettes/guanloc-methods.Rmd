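---
title: "Locating the GUAN pulse site in thermal wrist images: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Locating the GUAN pulse site in thermal wrist images: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(guanloc)
```

## The problem

GUAN is the segment of the radial artery lying directly above the radial
styloid process — the central of the three pulse-palpation positions in
traditional Chinese medicine. Steering a pressure sensor onto GUAN by touch
is imprecise relative to the sensitive area of a single sensor; a thermal
camera, by contrast, sees the wrist outline (skin against cool background),
the styloid process (a convex bump on that outline) and the radial artery
(a warm superficial stripe) in a single noncontact acquisition. `guanloc`
turns such an image into a pixel coordinate pair $(x_0, y_0)$ and, given
the imaging platform's geometry, into millimetres on the wrist bracket.

The package assumes the platform's acquisition convention throughout: the
forearm enters the frame from the left, the hand lies at the right, the
radial (styloid) side of the wrist is the upper contour, and the wrist
crease sits near the right image edge. A `hand_side = "left"` configuration
mirrors the image internally for the opposite orientation, and
`contour.side = "lower"` handles a flipped radial side.

## Pipeline

### Edge detection at arbitrary angles

The front end is a first-derivative-of-Gaussian filter at scale
`edge.sigma` (default 2 px — about the half-width of the thermal blur of a
skin/background boundary in a 320-px-wide wrist frame). Its gradient
magnitude feeds a per-line non-maximum suppression: the grid is partitioned
into digital straight lines at `edge.n_angles` (default 8) angles equally
spaced in $[0^\circ, 45^\circ]$, and a pixel survives on its line only if
its response strictly exceeds both line neighbours and a global threshold.
The $[0^\circ,45^\circ]$ machinery is extended to all directions by the
four symmetries of the square grid (identity, transpose, column flip and
their composition give scan directions $a$, $90-a$, $180-a$, $90+a$), and
the per-direction maps are OR-ed together.

Two numerical choices matter here:

* **Threshold.** The floor is the `edge.threshold_quantile` (default 0.90)
  quantile of the full gradient-response field, computed per image, so the
  detector is invariant to affine intensity rescaling — thermal cameras
  disagree about units, and nothing downstream should depend on them. The
  quantile is taken over *all* pixels (with a rounding-level floor) rather
  than only strictly positive responses so that its meaning does not change
  discontinuously when sensor noise vanishes. The default sits above the
  response level of sensor noise whenever true edges occupy less than 10%
  of the frame; at lower quantiles the edge bands thicken with noise
  speckle and the extracted outline jitters by several pixels between
  acquisitions of the same scene.
* **Gradient gating.** A scan family only marks pixels whose local gradient
  direction lies within `edge.grad_tol_deg` (default 45°) of the scan-line
  direction. A digital line running nearly parallel to an edge rasterizes
  into horizontal runs with occasional one-pixel jogs; sampled on the
  smooth response skirt of the edge, those jogs create sawtooth maxima that
  deposit spurious mark chains several pixels away from the true edge crest
  (on noiseless phantoms they alone degrade the outline RMS error from
  0.3 px to 3.7 px). With the default tolerance every gradient orientation
  is still covered by several scan families, so no true edge direction is
  lost. Setting the tolerance to 90° disables the gating and restores the
  plain superposition.

Both digital-line constructions are available (`edge.connection`):
`"compact"` rounds the ideal line offset symmetrically (Bresenham-style),
`"sparse"` floors it. They generate slightly different pixel partitions;
either satisfies the partition and 8-connectivity invariants, and the
choice has no measurable effect on the phantom pipeline.

### Wrist contour extraction

The wrist edge is taken to be the largest 8-connected component of the edge
image. When it already touches both lateral borders it is accepted as the
complete wrist edge; otherwise breakpoints are connected iteratively: from
the component's leftmost pixel, other edge fragments are searched within a
Chebyshev range of 2 px over the left half of a 5×5 neighbourhood (up,
left-up, left, left-down, down), the nearest hit is bridged by straight-line
pixel interpolation and its whole component merged, until the left border is
reached; the right side proceeds with mirrored directions. If the largest
component cannot be completed — it may be an interior structure such as the
artery ridge, with genuinely nothing to bridge to — the next-largest
components are tried in turn (the rank used is recorded in the
diagnostics). This fallback generalizes the maximum-domain assumption
rather than replacing it: on clean wrist images the first candidate wins.

Side branches shorter than `contour.max_spur_len` (default 15 px; the
operator footprint is given but no length criterion, so the default is
roughly twice the edge-skirt width, small enough never to threaten the
contour itself) are pruned by walking inward from every loose end; the
branching pixel itself is removed when its remaining neighbourhood stays
locally connected without it. End segments containing a border-column pixel
are never treated as spurs — the wrist edge terminates at the borders by
construction, and amputating its terminations would disconnect it.

The surviving path is reduced to a single-valued outline: the minimum row
per column for the upper (radial) side, with column gaps of at most 2
filled by linear interpolation and larger gaps raising an error.

### The GUAN column

The raw outline carries one-pixel quantization steps that dominate any
finite-difference curvature, so it is smoothed first. The smoothing filter
is specified in the signal-processing vocabulary of the acquisition
platform: a minimum-order Butterworth low-pass with sample rate 70 Hz,
passband corner 2 Hz, stopband corner 3 Hz, 3 dB passband ripple and 30 dB
stopband attenuation, with one outline column treated as one sample — i.e.
a spatial cutoff near 2/70 cycles per pixel, passing anatomy wider than
about 35 px and rejecting pixel steps. `signal::buttord`/`butter` perform
the design (order 9 for the defaults); the numerator is renormalized to
exactly unit DC gain, and the filter is applied in zero phase — a causal
pass would delay the outline and bias the landmark columns. The
zero-phase application pads by odd reflection, starts each pass from
matched initial conditions, filters about the signal mean (so constants
pass through exactly), and averages the forward–backward with the
backward–forward result so that filtering commutes with column reversal by
construction.

The curvature $cc(x) = sw''/(1+sw'^2)^{3/2}$ is computed by central finite
differences (one-sided at the ends). Working directly on row values, a
protrusion of the upper outline — a bump toward smaller rows — is a local
minimum and therefore has *positive* curvature; for the lower side the rows
are negated first so the same convention holds. The **salient** is the
column of the global positive-curvature maximum (ties to the smallest
column); a profile with no positive curvature has no styloid and raises an
error.

$x_0$ is then the first strict local maximum of $cc$ scanning leftward from
the salient within the finger-width window `landmark.window_px`
(default 100 px), subject to a rising-outline gate. Two readings of "first"
are possible; both are implemented (`landmark.scan_order`), and the default
`"nearest"` scans from the salient outward because the recess adjoins the
styloid — the `"leftmost"` order is kept for comparison. The window is open
at both ends: the salient column and the column exactly `window_px` away
are excluded. The slope gate is evaluated as the mean outward slope over
the (at most six) columns approaching the candidate from the left rather
than the pointwise central difference at the candidate: when the recess
edge is a genuine small bump, the curvature maximum sits at its apex, where
the central difference vanishes by symmetry, while the approach from the
recess side — which is what the rule describes geometrically — is clearly
rising.

### The GUAN row

A `artery.region_size` × `artery.region_size` region (default 10×10,
anchored to span rows $[r-5, r+4]$ and columns $[c-5, c+4]$ — an explicit
convention because an even window has no center pixel) is placed at every
interior edge point, and its intensity mean and population standard
deviation are computed via integral images. Regions passing a mean window
and a std window select artery pixels; the union of their pixels composes
the partial artery image, per-column mean rows are fitted by ordinary least
squares, and $y_0$ is the fitted row at $x_0$, rounded half-away-from-zero
(the unrounded value is kept in the diagnostics and is available for the
millimetre mapping).

The gates themselves are the design point. Deriving them from a histogram
of "the artery region" is circular — the artery region is what is being
sought — and fixed percentile windows over the region statistics turn out
to be composition-dependent: whichever structures happen to dominate the
edge map shift every percentile, and with realistic edge-point mixtures the
wrist-outline regions pass both windows and drag the least-squares line
tens of rows off the artery. The default `artery.method = "adaptive"`
therefore derives the gates from the image's gray histogram, which does not
depend on where edge points happened to fall:

* foreground pixels are split off by an Otsu threshold; the **skin level**
  is their median (the forearm dominates the foreground) and the **artery
  level** their 99.9th percentile;
* `mean_min` is placed between the two, at skin + 0.4 × (artery − skin):
  regions straddling the artery boundary have means near the midpoint of
  the two levels, so a floor slightly below the midpoint keeps them while
  rejecting both plain skin and skin/background mixtures;
* `std_min` is three times a robust image-noise estimate (median absolute
  one-pixel difference, scaled), rejecting flat regions — background
  speckle and saturated stripe interiors — whatever their temperature;
* the upper bounds are left open.

When the histogram shows no distinct hot structure the mean floor falls
back to an Otsu split of the warm half of the region means. The fixed
percentile windows remain available as `artery.method = "percentile"` with
`artery.mean_pct`/`artery.std_pct`. All gates shift with a constant
intensity offset, so artery selection is invariant under intensity shifts.
An optional `artery.band_px` restricts the fit to columns near $x_0$; the
default fits all selected columns, which is more stable when the stripe is
long and clean.

### Pixel-to-millimetre mapping

The platform views the wrist bracket from height $h$ (camera axis
perpendicular to the ground) with the bracket tilted by $\alpha$, producing
trapezoid distortion. With the step angle proportional to the pixel offset,
$\Delta\theta = X/(\text{height}/2)\cdot\theta$ (the only reading of the
proportionality under which the frame edge maps to the full half field
angle $\theta$), the sine theorem in the side-view triangle gives

$$HP = \frac{\sin\Delta\theta \cdot h}{\sin(90 - \Delta\theta \mp \alpha)}\sin(90-\alpha'),
\qquad AP = \frac{\sin(90\pm\alpha')\,h}{\sin(90-\Delta\theta\mp\alpha)},$$

with the sign pair selected by the side of the origin: $x_P = -HP$ on one
side (denominator $\cos(\Delta\theta+\alpha)$) and $x_P = +HP$ on the other
(denominator $\cos(\Delta\theta-\alpha)$). The transverse coordinate is
$y_P = AP\tan\Delta\beta \cdot \mathrm{sign}(Y)$ with
$\Delta\beta = |Y|/(\text{width}/2)\cdot\beta$. All $\sin(90-u)$ terms are
implemented as $\cos u$; angles are taken in degrees as specified and
converted internally. The case/sign assignment was fixed by requiring
agreement with an independent 3-D ray–plane-intersection construction
(camera at the origin looking straight down, bracket plane
$z = -h + x\tan\alpha$); the test suite pins this agreement to
$10^{-6}$ mm over a 17×17 pixel grid at four tilt angles, and at
$\alpha = 0$ the formulas reduce exactly to $x_P = h\tan\Delta\theta$,
$y_P = (h/\cos\Delta\theta)\tan\Delta\beta$.

One axis-assignment subtlety: the equations are written with the tilt along
the image *height*, but in the pipeline's images the arm — and hence the
bracket's tilt direction — runs along the *columns*. `map_guan()` therefore
takes a `tilt_axis` argument (default `"columns"`): the along-arm pixel
offset feeds the $\Delta\theta$ equations and the cross-arm offset the
$\Delta\beta$ equation, with `height_px` read as the tilt-axis extent.
Offsets are measured from the pixel-center of the frame, $(\text{extent}+1)/2$.

## The phantom generator

`phantom_spec()` defines the study conditions used throughout the tests: a
240×320 frame with a warm forearm band (intensity 170 on an
8-bit-like scale) on a cool background (90), an upper contour with a gentle
taper, a Gaussian styloid bump (amplitude 12 px, σ 8 px, apex at column
250), a concave recess (depth 7 px, σ 7 px) 70 px to the bump's left, a
warmer artery stripe (196, width 8 px, soft edges) along a configurable
line visible over columns 130–290 (the radial artery is superficial — and
hence thermally visible — only near the wrist), a cold 8×8 crease marker
(60) at column 296 standing in for the platform's insulated reference
sheet, and Gaussian sensor noise (σ 2). Rendering uses sub-pixel coverage
blending, so edges fall at continuously varying sub-pixel positions, and a
rigid transform (translation, rotation about the frame center) models
acquisition-to-acquisition posture change. Output is deterministic for a
fixed spec, including its seed.

The anatomy defaults were chosen by hand analysis of the curvature
superposition before the pipeline was run: the recess-edge curvature
maximum survives the 2 Hz/70 Hz smoothing only if the recess sits well
clear of the bump's negative-curvature tail (about $\sqrt 3$ effective
widths), which the 70 px offset with 7–8 px feature widths guarantees. At
recess offsets near 40 px the smoothing merges the features and the
landmark genuinely ceases to exist — the rule applied to the analytic
noise-free contour finds nothing, and the pipeline correctly reports
failure on the same cases rather than inventing a coordinate; the
parameter-recovery sweep asserts exactly this consistency.

**Ground truth.** The truth landmark is defined as the landmark *rule*
applied to the noise-free analytic contour (sampled per column, same
smoothing), with the truth row taken from the analytic artery line at that
column. Recovery tests therefore measure the imaging chain — rendering,
noise, edge detection, contour extraction, artery segmentation — against an
exactly known target, not a second, competing landmark definition.

**Jitter defaults.** Repeated acquisitions draw along-arm translation
±3 px, cross-arm translation ±1 px, rotation ±1°, and a ±10% styloid-bump
amplitude scaling. The cross-arm range is deliberately tighter than the
along-arm range: the physical wrist support constrains side-to-side
placement to roughly a millimetre (≈1 px at the phantom's transverse scale
of ≈1.1 mm/px), whereas the arm can slide along the support — and the
crease-referenced x distance is insensitive to that slide, which is exactly
why the physical platform carries a crease marker. These ranges were fixed
from this error budget before any repeatability run and not revisited.

**What the phantom does not emulate.** Perfusion physiology, vasomotion,
breathing drift, non-rigid skin deformation, radiometric calibration,
camera fixed-pattern noise, and anatomical variation beyond the parameter
ranges above. Passing the synthetic repeatability bounds therefore shows
the *algorithm* is stable under pose jitter and sensor noise at realistic
contrasts; it does not certify performance on human subjects.

## The repeatability experiment

`repeatability_experiment()` mirrors the platform validation protocol:
8 synthetic subjects (anatomy drawn per subject: salient column 235–265,
bump amplitude 9–15 px, recess offset 50–80 px, recess depth 5–8 px, artery
row 150–175, artery slope ±0.1, crease column 290–300), 10 jittered
acquisitions each, full pipeline per image, millimetre mapping through the
phantom geometry (θ=20°, β=25°, h=300 mm, α=10°, tilt axis = 320-px column
axis), and per-subject mean, SD and RSD of the crease-to-GUAN x distance
and of the GUAN y coordinate. Failed repeats are excluded from that
subject's statistics and counted. The test suite and `scripts/acceptance.R`
run this at full size (80 images, about a minute on one CPU); the
parameter-recovery sweep uses 50 noiseless phantoms across bump amplitudes
5–20 px and recess offsets 40–90 px.

## Degenerate inputs and error handling

Every failure mode raises a classed condition (`guan_no_edge_error`,
`guan_connection_error`, `guan_no_salient_error`, `guan_no_guan_x_error`,
`guan_artery_error`, ...), and `locate_guan()` re-raises them as a
`guan_stage_error` carrying the stage name and the diagnostics accumulated
so far. Constant images produce an empty edge map and fail at the
maximum-domain stage; outlines without positive curvature fail at the
salient stage; threshold derivation refuses degenerate (all-equal) region
statistics; the artery stage requires at least two distinct selected
columns; predicted rows outside the image are rejected. Pixel coordinates
are 1-based `(column, row)` everywhere, matching R's indexing.

## Known limitations

* The salient/recess rule needs the recess at least about one smoothing
  wavelength from the styloid apex; closer recesses are reported as
  not-found rather than guessed.
* The artery gate assumes the artery is the warmest extended structure in
  the frame; strong warm artifacts (e.g. another vessel) would be selected
  together with it, moving the fitted line.
* The millimetre mapping models an ideal angle-proportional camera on a
  singly-tilted plane; lens distortion and transverse tilt are out of
  scope, as is full checkerboard calibration.
* The crease reference in synthetic runs comes from the phantom truth
  (mirroring the physical marker); `detect_cold_spot()` is a best-effort
  detector for real images and is deliberately not part of the validated
  path.
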