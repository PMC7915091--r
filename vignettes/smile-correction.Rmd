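---
title: "Correcting spectral smile and slit tilt without an optical laboratory"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Correcting spectral smile and slit tilt without an optical laboratory}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

A push-broom hyperspectral imager records, per camera frame, the spectra of
one spatial line: frame rows *y* run along the entrance slit, frame columns
*x* along the spectral axis. Stacking frames over a scan yields an image
cube with dims `(scan_index, y, x)`. Two geometric aberrations corrupt the
spectral axis of affordable, hand-assembled instruments:

* **Spectral smile**: dispersion bends each monochromatic emission line
  into a shallow circular arc. Typical curvatures are a few times
  10⁻⁵ 1/px, i.e. arc radii of tens of thousands of pixels — maximum
  deflections of only 2–3 px over an 800-row frame, but enough to smear
  narrow spectral features.
* **Tilt**: a hand-mounted slit cannot be aligned perfectly with the
  grating and sensor, rotating all lines by roughly 1–2° from vertical.

Both are usually characterized with laboratory equipment (monochromators,
calibration lamps). desmile instead estimates and removes them from a
single frame of any sharp-lined light source, such as a fluorescent lamp.

## The correction model

For each emission line we collect per-row peak positions
`(y, x_p)` and fit a circle with center `(a, b)` and radius `r`. Assuming
the photon that should have landed at column `x_p` of row `y_p` landed on
the arc instead, the displacement is the horizontal distance from the arc
to the vertical tangent line through the arc's apex row:

    d(y_p) = r * (1 - cos(asin((y_p - b) / r)))

`d` is zero at the apex row `b` and grows symmetrically with `|y_p - b|`;
for `r >> |y_p - b|` it approaches the sagitta `(y_p - b)^2 / (2 r)`. The
`asin` is defined because `r` is always far larger than the row offsets —
were it not, the frame would be unusably distorted. If the circle center
lies at larger columns than the line (the line's ends curve toward larger
`x`), the correct value for a pixel comes from `x + d`, otherwise from
`x - d`. These signed displacements form a per-pixel **shift matrix**
`s(x, y)`; applying it by row-wise linear interpolation straightens every
line in one pass.

Tilt needs no separate treatment: a tilted line is fitted by a huge-radius
arc whose center row `b` lies far off the frame's vertical center, so the
`d` profile is asymmetric — approximately linear in `y` with slope
`tan(theta)` — and the interpolation removes the tilt as a side product of
the same machinery.

Two consequences follow from the model:

* Emission lines land on new columns (each is straightened onto one column
  of its fitted arc), so **wavelength calibration is only valid after
  correction**.
* The shift matrix depends only on instrument geometry, so it can be
  computed once per imaging session from a light-reference frame and
  reused for every frame and cube of that session (`correct_frame`
  returns it; `apply_shift` reapplies it).

## Synthetic frames: what the generator emulates

`generate_ideal_frame` builds a noise-free instrument model and corrupts
it exactly the way the correction works, in reverse:

* a base spectrum (`make_base_spectrum`) of Gaussian emission peaks on a
  constant background, standing in for the mean-row spectrogram of a
  fluorescent lamp;
* each illuminated row is the base times a Gaussian gain
  `N(1, gain_sigma^2)` — row-to-row sensitivity differences — plus
  zero-mean uniform pixel noise; non-illuminated rows carry only uniform
  noise on `[0, 2 * noise_amplitude]`;
* `make_distortion_shift_matrix` builds the distortion field
  `s(y) = tan(theta) * (y - y_ref) + sign(kappa) * d_arc(y)` with
  `r = 1 / |kappa|`, constant across columns, and `distort_frame` applies
  it by the same row-wise interpolation used for correction.

Defaults are the study conditions: 2000 spectral × 800 spatial px (the
illuminated crop of the sensor), four correction bands at columns 629,
762, 980 and 1517 plus two bystander lines, tilt 1°, curvature
3×10⁻⁵ 1/px, and — where no value is stated anywhere — one-time choices a
practitioner would call realistic: `gain_sigma = 0.02` and
`noise_amplitude` = 1% of the maximum peak height (a clean but not
noiseless CCD at moderate exposure), both exposed as parameters. The
reference row and arc center default to the frame's vertical center,
making pure smile symmetric top/bottom.

What the generator does **not** emulate: keystone (spatial
stretch/shortening across the spectral axis), defocus point-spread
functions, scan-speed jitter, sensor saturation and hot pixels, or a real
lamp's line blends. Passing tests therefore demonstrate the geometric
correction under the stated noise model, not robustness to every real
detector artifact.

Closed-form expectations under this generator anchor the batch tests: the
tilt metric reads back the generated `tan(theta)` exactly (the symmetric
smile term is orthogonal to a linear fit over symmetric row support), the
curvature metric reads `1/r`, and the apex-anchored correction shift
averages `(var(y) + (r tan(theta))^2) / (2 r)` — about 5.9 px for the
default distortion.

## Detection parameters

All are fields of `detection_params()` / keys of the CLI control file:

| parameter | default | units | why |
|---|---|---|---|
| `window_halfwidth` | 20 | px | must cover a line's wander: 2° of tilt moves a line ±14 px over 800 rows, smile adds ~2.4 px. Estimates must be separated by more than twice this. |
| `min_prominence` | 50 | counts | rejects uniform-noise maxima (prominence ≲ 2 × noise amplitude) while keeping weak lines hundreds of counts high. |
| `smoothing_halfwidth` | 0 (off) | px | moving-average pre-smoothing; unnecessary at the default noise level. |
| `min_coverage` | 0.8 | fraction | a line must yield a peak on 80% of illuminated rows; guards against grouping noise into a "line". |
| `subpixel` | on | — | three-point parabolic refinement. Integer peaks would quantize the 2–3 px arc deflection too coarsely for reliable curvature estimates. |

Within each window, at most one peak per row is kept: the local maximum
with the highest window-limited prominence, ties resolved toward the
window center. With lines separated by more than the window width this
coincides with nearest-peak grouping but is order-free and vectorizable.

## Metrics

Lines are nearly vertical, so both metrics fit `x` as a function of `y`
(the transposed fit would have near-infinite slope):

* **tilt**: ordinary least squares `x = slope * y + c`;
  `angle = atan(slope)` in degrees. Under the package's sign conventions a
  line whose top leans toward larger `x` reads a negative angle.
* **curvature**: least-squares parabola `x = alpha y^2 + beta y + gamma`
  (row-centered for conditioning); `kappa = 2 alpha / (1 + beta^2)^(3/2)`,
  signed. For these near-vertical lines the `beta` correction is below
  0.1%.

The curvature metric fluctuates at the 10⁻⁶ 1/px level on straight noisy
lines — corrected values below that floor mean "straight to within the
metric", not literally zero, and tests assert thresholds (0.05°,
2×10⁻⁶ 1/px) rather than exact zeros.

## Numerical design choices

**Two-route circle fit.** The algebraic (Kåsa) least-squares circle — on
coordinates centered at the point centroid and scaled to the row span — is
essentially exact on genuine arcs across the whole radius range of
interest (10³–10⁶ px and beyond). But on nearly collinear noisy points
(vertical lines, pure tilt, already-corrected frames) it is
noise-amplified and collapses onto small spurious circles that no radius
or condition-number gate catches. `fit_circle` therefore also computes a
shallow-arc candidate — the circle osculating the least-squares parabola
of `x(y)` at the data center, radius `(1 + beta^2)^(3/2) / (2 |alpha|)` —
which is stable in exactly that regime, and keeps whichever candidate has
the smaller RMS radial residual. Osculating at the data center rather
than at the parabola's vertex matters: for a tilted line the vertex lies
`~r tan(theta)` rows away and a vertex-osculating circle drifts off the
data. Input is treated as degenerate (straight) when fewer than 3 points
are given, the fitted radius exceeds 10⁹ px, or both routes fail
(collinear input).

**Anchoring.** Each line is straightened onto the column its fitted arc
occupies at the apex row `b` — no global re-anchoring, so line spacings
change, as the model predicts. For nearly straight lines, however, the
apex row lies far outside the frame (`|b|` grows like `r tan(theta)`) and
the apex column would be off the sensor entirely; when `b` falls more
than one frame height outside the frame, the line is instead anchored at
the frame's center row. Genuine smile always takes the apex branch.

**Shift interpolation across columns.** Shifts are defined by the model
only at the emission-line anchor columns; between anchors they are
interpolated linearly in `x`, and held constant beyond the outermost
anchors. This is the simplest field consistent with the observation that
smile varies slowly across the sensor; with four well-spread bands the
choice is uncritical for the line metrics, which are evaluated at the
anchors.

**Resampling.** Rows are resampled by linear interpolation (a compiled
kernel; exactly linear in the frame, so corrections distribute over frame
sums). Samples falling outside the frame take a fill value defaulting to
the frame median, i.e. the background level. Degenerate lines contribute
zero local shift rather than aborting the whole correction; a failed
re-detection after correction yields `NA` post-metrics rather than an
error.

**Determinism.** Every generator takes a seed and restores the caller's
RNG state; batch runs derive per-frame seeds as `master_seed + i`. Rerunning
any experiment with the same master seed reproduces outputs byte for byte.

## Cube operations

Reflectance is `(S - dark) / (white - dark)` per pixel against per-pixel
reference frames (a white target imaged in-scene, dark with the lens
capped), clipped to `[0, 2]` — specular highlights can exceed 1 — with
non-positive denominators mapped to `NA`. The cube and references must
agree on whether the smile correction has been applied; mixing corrected
and uncorrected data is refused. False color extracts three spectral
columns and normalizes each channel between its 1st and 99th percentiles.
Spectral angle mapping uses the usual
`acos(<s1, s2> / (||s1|| ||s2||))`, scale-invariant in both arguments.
`simulate_scan` exercises all of this end to end on a tiled reflectance
scene (spectrally flat or colored tiles) under smooth broadband
illumination with a known tile-to-frame map.

Cubes, frames and shift matrices persist in a single-file self-describing
container (JSON header with named dims and metadata, little-endian
float64 payload; bit-exact round trip). Frames can additionally be
exported as 16-bit TIFF for inspection and false-color images as PNG.

## Problem sizes

The validation suite runs the full-size study — 200 frames of 2000×800 px
for the batch statistics, a 4×3 grid of tilt/curvature combinations for
the round-trip property, 1000 random geometries for the shift-distance
oracle — sizes chosen so the whole suite completes in a few minutes on a
single core while keeping the batch standard errors an order of magnitude
below the asserted tolerances. `scripts/acceptance.R` re-runs the
200-frame batch from scratch and reports its statistics as JSON.

## Limitations

* Keystone is not corrected; like smile it could be framed as arc
  straightening along the other axis, but that is future work.
* There is no wavelength calibration; the corrected axis is still in
  pixels.
* The method needs a light source with isolated sharp lines and
  reasonable estimates of their columns; blended or drifting lines
  degrade the arc fits (the weakest band in the default spectrum is
  deliberately the hardest to track).
* Shift interpolation between anchor columns is linear; instruments whose
  smile varies strongly and non-linearly across the sensor would need
  more bands.
* The least-squares fits at the core of both metrics set the accuracy
  floor; corrected values below the fluctuation floor are
  indistinguishable from zero.
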