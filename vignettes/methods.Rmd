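---
title: "Depth-camera respirometry: model, pipeline and validation phantom"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Depth-camera respirometry: model, pipeline and validation phantom}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(depthresp)
```

## The measurement principle

An overhead depth camera looking down at a patient measures, for every
pixel, the distance to the first surface along that pixel's ray. As the
lungs fill, the chest wall rises and the camera-to-thorax distance
shrinks; the volume of air moved is mirrored, with opposite sign, by the
volume of the space between camera and chest. `depthresp` turns a depth
video into that volume signal and derives from it the parameter set a
ventilator would display: respiratory rate (RR), tidal volume (Vt),
minute ventilation, inspiratory and expiratory times (Ti, Te), the I:E
ratio, and peak inspiratory/expiratory flows (PIF, PEF).

The volume estimator is pixel-wise. With pinhole intrinsics
(`fx`, `fy`, `cx`, `cy`), a pixel `(u, v)` with depth `d` unprojects to

    x = (u - cx) d / fx,   y = (v - cy) d / fy,   z = d.

Each pixel's 3D surface area is estimated from its immediate
neighbours: the four neighbours are unprojected at their own measured
depths, central-difference tangent vectors along the two pixel axes are
formed, and the area is the magnitude of their cross product (one-sided
differences at borders or next to invalid pixels). Unlike the flat
approximation `d^2/(fx fy)`, the cross product is exact for tilted
surfaces. The per-frame volume is then

    V(k) = sum over ROI pixels of depth(p, k) * area(p) / 1000   [mL],

with the area map computed **once** and frozen for the whole
acquisition, so the signal reflects depth change rather than area
jitter. The series is inverted and zeroed to its first sample
(`v'(k) = -(v(k) - v(1))`), low-pass filtered, segmented into cycles,
and differentiated into flow. A simpler baseline estimator (mean ROI
depth change times total ROI area) is provided for comparison; it
coincides with the pixel-wise method when pixel areas are uniform and
degrades when they are not, e.g. under oblique viewing.

## Choices the user can make, and their defaults

* **ROI.** The region of interest is an oriented (rotatable) bounding
  box. In a production deployment it would come from a learned
  thorax detector on infrared images; this package defines the detector
  *contract* (sequence in, box plus confidence out) and ships two
  implementations: a fixed, user-configured box, and a motion-variance
  heuristic — per-pixel temporal standard deviation of depth,
  thresholded at its 0.98 quantile, minimum-area rotated rectangle
  around the largest connected candidate component. The detector fails
  over to the fixed box when the largest coherent component has fewer
  than 50 pixels (a static scene: the quantile threshold always admits
  ~2% of pixels, but on noise they are scattered single pixels, so
  coherence — not count — is the meaningful test). Including some
  motionless bed inside the box is harmless: static pixels contribute
  no volume *variation*.
* **Reference surface.** Pixel areas are geometric quantities of the
  chest surface, but each tangent vector is a difference of noisy
  depths: independent noise of sd `sigma` inflates the cross-product
  area by roughly `sigma^2 (1/dx^2 + 1/dy^2)/2`, where `dx, dy` are the
  3D pixel spacings — nearly +10% at 640 x 576 from 1.1 m. The area map
  is therefore computed on a denoised reference surface: the per-pixel
  temporal mean of the first ~2 s of frames (`reference_surface()`).
  Breathing moves the surface by millimetres against a metre of depth,
  so averaging over a fraction of a cycle leaves the geometry
  essentially unchanged while suppressing the noise bias by the frame
  count. Per-frame volume summation still uses raw depths.
* **Filter.** A linear-phase FIR low-pass, order 10 (11 taps), cutoff
  2 Hz at 30 frames/s — 2 Hz corresponding to 120 breaths/min, the
  physiological ceiling, so everything faster is treated as noise. The
  design is a Hamming-windowed sinc normalised to exact unit DC gain.
  Offline, the group delay (5 samples) is compensated so output and
  input share timestamps; the first and last 5 samples use a truncated,
  renormalised kernel and are flagged as the edge region. A causal mode
  (no compensation, constant 5-sample lag) suits streaming display.
* **Cycle detection.** Local extrema with (i) a minimum inter-peak
  distance of `round(fps * 60 / 120)` frames — 15 at 30 FPS — and (ii)
  a minimum prominence of 0.2 of the observed signal range. The
  prominence fraction is a judgement call (no canonical value exists):
  0.2 rejects residual ripple while keeping breaths down to a fifth of
  the deepest one. Flat extrema resolve to their leftmost sample for
  determinism. Peaks and troughs are merged into a strictly alternating
  sequence and paired into complete trough–peak–trough cycles; Ti runs
  trough-to-peak and Te peak-to-trough. Note that this pairing costs up
  to two boundary cycles relative to naive peak counting (an N-peak
  recording yields as few as N - 2 complete cycles); RR is unaffected
  because it divides by the span of the complete cycles only.
* **Conventions.** Vt defaults to the expiratory reading (peak volume
  minus the following trough: air exhaled); the inspiratory variant is
  available and equals it for symmetric breathing. PIF/PEF are reported
  under two conventions: flow-extremum *differences* (expiratory drop,
  and its opposite-direction counterpart — about twice a ventilator's
  reading) and the *standard* per-phase flow extrema directly
  comparable to ventilator displays. Minute ventilation divides the
  summed Vt by the complete-cycle span, making `MV = mean(Vt) x RR` an
  exact identity rather than an approximation.

## The breathing phantom

Real validation of such a system needs a spirometer or ventilator;
desk-scale validation here uses a synthetic scene with analytically
known truth. The phantom renders a bed plane at `bed_distance` carrying
an elliptical cosine-squared dome,

    h(x, y, t) = (baseline_height + A(t)) * cos^2(pi r / 2),  r <= 1,

whose amplitude `A(t)` follows a raised-cosine breathing waveform
(separate inspiratory and expiratory half-cosines, inspiratory fraction
configurable) scaled so the peak-to-trough added volume equals the
requested Vt exactly. Per-pixel depth solves the ray–surface
intersection by fixed-point iteration (3 steps; the dome height is
three orders of magnitude below the camera distance, so convergence is
immediate), Gaussian noise is added (default sd 1.1 mm, the sensor's
stated accuracy at 1 m), and depths are quantised to 0.1 mm. Ground
truth — `true_volume(t) = Vt * w(t)` and its analytic derivative — is
computed from the waveform and the cached dome volume integral, never
through the camera path, so recovery errors measure the pipeline alone.

Presets: *adult* (bed 1.10 m, Vt 400 mL, RR 15, dome semi-axes
180 x 130 mm — a chest-sized breathing region) and *child* (bed
0.80 m, Vt 50 mL, RR 40, semi-axes 110 x 85 mm), at the sensor's
640 x 576 narrow-field mode and 30 FPS; a 320 x 288 reduced mode keeps
routine test runs fast. The static dome height defaults to 5 mm in both
presets: the method's accuracy contract assumes a near-perpendicular,
gently curved surface (see below), and the static offset contributes
nothing to the measured signal except surface tilt, which is exactly
what the parameter exists to control in robustness experiments.

What the phantom does *not* emulate: occlusions (sheets, cables),
gross patient motion, several people in the frame, lateral chest
expansion, lens distortion, and spatially correlated sensor noise.
Passing recovery tests here therefore demonstrates the correctness of
the geometry, signal processing and parameter derivations — not
robustness to ward conditions.

## Known systematics, quantified on the phantom

Three effects bound the accuracy and are worth knowing about:

* **Filter passband droop.** The order-10 / 2 Hz filter is short, so
  its passband is not flat: |H| is 0.995 at 0.25 Hz (RR 15) but 0.966
  at 0.67 Hz (RR 40) (`fir_response()`; these values are pinned in the
  test suite). Tidal volume read off the filtered signal is attenuated
  accordingly — negligible at adult rates, about 1 − 0.966 ≈ 3.4% at
  RR 40. This is a property of the specified filter, not of the volume
  estimator; the child-scale recovery error is dominated by it.
* **Parallax on sloped surfaces.** The camera records z-depth along
  diverging rays. Where the surface is tilted, the z-change of the
  ray–surface intersection exceeds the vertical surface motion by a
  factor ~`1/(1 - h' * X/d)`, coherent across an inflating dome. The
  resulting overestimate grows with (dome height / semi-axis) x
  (lateral extent / distance); the noise-free recovery test bounds it
  below 1% for the gentle default geometry. This is inherent to
  single-camera depth respirometry of curved surfaces.
* **Variance-ROI rim loss.** The motion-variance detector cannot see
  pixels whose breathing excursion is below the noise floor (or the
  candidate quantile), so its box slightly clips the dome rim where
  the height profile tends to zero, losing of order 1% of the volume
  excursion. A detector trained on intensity images (the production
  path) does not share this limit.

Numerical details: depth quantisation is 0.1 mm, round half to even,
applied after noise; the dome volume integral uses 2D midpoint
quadrature at `min(a, b)/400` step (relative error ~1e-5, verified
against the closed form `a b (pi/2 - 2/pi)`); the waveform's sampled
maximum sits within 0.1% of 1 at adult rates (sampling at 30 FPS);
invalid pixels (depth 0) hold their last valid value so the frozen area
assumption survives dropouts, with the held fraction reported and a
quality warning above 20%; ties in flat extrema break to the left.

## Scale of the shipped experiments

The recovery experiments run by `scripts/acceptance.R` (and mirrored in
the test suite) use ten 30-s adult-scale runs at full 640 x 576
resolution for the tidal-volume and RR-sweep figures, one default adult
run for the waveform correlation, and one 60-s child-scale run — sizes
chosen so the whole set completes in minutes on a single CPU while
leaving per-run Monte-Carlo scatter well below the tolerances being
checked. Unit and property tests use the 320 x 288 or 160 x 144 modes.
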