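---
title: "Quantifying cortical fluorescence asymmetry in embryo movies"
author: "cortexQuant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying cortical fluorescence asymmetry in embryo movies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## What is being measured

In early embryos, contractility regulators such as the RhoGEF ECT-2 bind
the cell cortex — the thin actomyosin layer under the membrane that
appears as a bright ring around the cell in fluorescence images — and are
locally displaced near centrosomes. The quantity of interest is how much
protein sits on the cortex, relative to the cytoplasmic pool, at every
position around the embryo perimeter and at every time point. The
package's central statistic is the cytoplasm-normalized **accumulation**

$$a(s) \;=\; \frac{I_{\max}(s) - I_{\mathrm{bg}}}{I_{\mathrm{cyto}} -
I_{\mathrm{bg}}},$$

where $I_{\max}(s)$ is the maximum intensity along a short line drawn
perpendicular to the cortex at position $s$, and $I_{\mathrm{bg}}$,
$I_{\mathrm{cyto}}$ are per-frame background and cytoplasm means. $a = 1$
means the cortical signal equals the cytoplasm; values of 2–3 are typical
anterior enrichments in this system. The position coordinate $s \in
[0,1)$ is the arc-length fraction of the perimeter, anchored at the
anterior pole ($s = 0$) and increasing clockwise in image coordinates, so
the posterior pole sits at $s = 0.5$.

## The measurement chain and its assumptions

1. **Segmentation** (`segmentEmbryo`). Gaussian blur (default
   $\sigma = 2$ px) on a copy of the frame, automatic threshold, largest
   connected component, hole filling. Assumes one dominant bright object
   over a darker background. Two numerical refinements matter for
   accuracy: the Otsu threshold is polished by ISODATA iteration so the
   mask edge sits at the half-intensity point of the blurred boundary
   step, and a second pass re-thresholds with intensities clipped at the
   estimated cytoplasm level. Without the second pass the bright cortical
   rim pulls the detected boundary outward in proportion to local rim
   brightness, which distorts the arc-length coordinate downstream.
   Because thresholds are computed on the min–max-normalized image, the
   mask is exactly invariant under positive affine rescalings of the
   intensities.

2. **Contour extraction** (`extractContour`). The mask is lightly blurred
   ($\sigma = 1$ px; larger values round genuine corners, smaller values
   leave pixel staircase) and its 0.5 iso-contour is taken with
   `grDevices::contourLines`, giving a sub-pixel closed polyline,
   resampled to ~1 px spacing. On analytic discs, ellipses and squares
   this recovers perimeters to well under 1%.

3. **Anchoring** (`anchorContour`). The long axis comes from the
   principal components of the contour points; the anterior end is the
   one nearer a user-supplied hint (from metadata, or the generator's
   ground truth in synthetic runs). The anchor is placed at the exact,
   interpolated intersection of the axis with the contour — not at the
   nearest vertex. This sub-pixel choice is deliberate: a vertex-snapped
   anchor wobbles by a few pixels tangentially (the contour is nearly
   flat at the poles), which shifts the whole $s$ coordinate by ~0.002
   and produces spurious differences wherever the profile is steep.
   Traversal is flipped if necessary so $s$ increases clockwise
   (positive shoelace area in (col, row) coordinates with row pointing
   down). Re-anchoring an anchored contour with a consistent hint is a
   no-op, so the operation is idempotent; a hint equidistant from both
   poles is an error.

4. **Straightening** (`extractBand`, `maxDepthProfile`). At each contour
   point the image is sampled by bilinear interpolation along the outward
   normal: 50 samples at 1 px steps, centred on the contour (25 inward,
   25 outward). Centring tolerates segmentation bias of up to ~12 px
   either way. Normals come from tangents smoothed over ±2 points to
   suppress staircase jitter. Samples falling outside the frame are
   clamped to the edge and flagged. The per-position raw value is the
   maximum over the full 50 px depth of the band after averaging depth
   profiles over 3 neighbouring positions (periodic wrap) — the package's
   reading of "the maximum of a 3 px-wide perpendicular line". The
   lateral-average-then-maximum order is isolated in one function so the
   alternative (max then average) can be swapped in if needed. Taking
   the maximum over the full depth (rather than a sub-range) is a
   documented choice; it assumes the cortex is the brightest structure
   along the normal, which holds whenever $a > 1$.

5. **Regions and time series** (`regionSpec`, `buildTimeSeries`).
   "Anterior/posterior 20% of the embryo" is interpreted in perimeter
   coordinates: 20% of the perimeter centred on each pole
   ($[0.9, 1) \cup [0, 0.1)$ and $[0.4, 0.6)$), with the anterior 60%
   ($[0.7, 1) \cup [0, 0.3)$) used for the boundary threshold. All
   regions are half-open to avoid double-counting the wrap point. The
   alternative reading (axial projection bands) was considered and
   rejected because every downstream profile statistic is defined in
   perimeter coordinates. The A:P ratio is computed per embryo and then
   averaged across embryos, not from averaged regions. A non-positive
   posterior mean flags the ratio as undefined for that frame rather
   than failing.

6. **Boundary length** (`smoothProfile`, `boundaryLength`). The profile
   is smoothed with a cyclic cubic regression spline (`mgcv::gam`,
   basis `"cc"`, knots pinned at $s = 0, 1$), smoothing parameter by GCV
   unless fixed. Basis dimension defaults to 20, which resolves depleted
   domains down to ~5% of the perimeter without chasing noise; it is a
   config parameter. Thresholding uses the smoothed values (85% of the
   anterior-60% mean), and the boundary length is the fraction of *all*
   grid positions below threshold — no contiguity requirement, matching
   a plain count of below-threshold positions. If the spline fit fails
   the function falls back to a periodic moving average (window 5% of
   the perimeter) and flags the result.

7. **FRAP** (`normalizeTrace`, `fitRecovery`). Traces are full-scale
   normalized — pre-bleach mean to 1, first post-bleach frame to 0 —
   which makes the fitted amplitude $a$ directly the mobile fraction.
   Time zero is the first post-bleach frame (not the minimum-intensity
   frame, should they differ). The fit is bounded Levenberg–Marquardt
   ($a \in [0, 1.5]$, $b > 0$) initialized from the tail plateau and the
   observed half-rise time. Flat traces are rejected with an informative
   error instead of returning an unidentifiable rate. No correction for
   acquisition bleaching is applied. Condition averages are means of
   per-embryo coefficients; note that the curve of mean coefficients is
   not the mean of curves when rates are heterogeneous.

8. **Furrow kinetics** (`furrowSeries`, `initiationTime`,
   `completionCall`). Widths are normalized to the maximum embryo width;
   the rolling average is *centred* (period 3) — the trailing
   alternative is not used — and endpoints without a full window are
   omitted. Initiation (90% width) is linearly interpolated between the
   bracketing frames, removing the 10 s sampling quantization; an embryo
   that never crosses is reported as not-initiated, not as an error.
   Completion tolerates a residual normalized width of 0.02 (exposed as
   `completionTol`), since "reached 0%" is a visual call on real data.
   Furrow-tip and centrosome positions are annotation inputs, mirroring
   manual measurement; there is no automatic tip detection.

## The synthetic generator

`syntheticEmbryoSpec` + `accumulationGroundTruth` render an elliptical
embryo — by default 125 × 75 px semi-axes at 0.2 µm/px, i.e. a 50 × 30 µm
zygote — as uniform cytoplasm (100) over background (10) with a cortical
ring of width 4 px (ring thickness in real images is not well
constrained; 4 px is a default, not a measurement, and is a parameter).
Ring pixels are those within half the ring width of the ellipse, by true
point-to-ellipse projection; each takes the intensity
$I_{\mathrm{bg}} + (I_{\mathrm{cyto}} - I_{\mathrm{bg}})\,a_{\mathrm{true}}(s,t)$
at its nearest boundary position, so the rendered ring is an exact affine
image of the true field. The true field is

$$a_{\mathrm{true}}(s,t) = r_t\left(\beta + \gamma\,
\tfrac{1 + \cos 2\pi s}{2} - \delta\, D(s)\right)_+,$$

a baseline $\beta$ plus a smooth anterior bump of amplitude $\gamma$,
minus a posterior depletion domain $D(s)$ built as the product of two
periodic logistic edges (centre, half-width, edge steepness all
controllable), scaled by a per-frame ramp $r_t$. Defaults
($\beta = 1.6$, $\gamma = 1.4$, $\delta = 0.45$, half-width 0.15,
steepness 40) give anterior accumulation near 3 and posterior near 1.2,
the regime reported for control embryos. Noise (gaussian or Poisson) is
applied last, clipped at zero, and fully seeded: identical seeds give
bit-identical frames. FRAP traces default to 25 pre-bleach + 175
post-bleach frames at 100 ms with amplitude 0.8 and rate 0.23 1/s
(half-time ≈ 3 s); furrow trajectories are a plateau followed by linear
ingression with closed-form initiation time.

What the generator does **not** emulate — and hence what passing recovery
tests cannot certify on real data: out-of-focus light and the point
spread function, acquisition photobleaching, embryo shape change and
cortical flow between frames, myosin puncta texture, neighbouring
embryos in the field, and 3-D effects of a curved cortex imaged in a
single plane. Tests on this generator certify the measurement chain, not
the microscope.

## Numerical choices and degenerate inputs

- Point-to-ellipse projection uses the first-order foot-point estimate
  polished by five damped Newton steps; rendering is restricted to a
  band of candidate pixels around the boundary for speed.
- Bilinear sampling clamps out-of-frame coordinates to the edge and
  flags the band. Segmentation failure (no component above `minArea`)
  raises a typed `NoEmbryoFound` condition.
- `cytoplasm <= background` makes the accumulation undefined and is an
  error; an empty eroded mask (embryo too small for the margin) is an
  error; ties in the maximal-asymmetry frame go to the earliest frame.
- The cytoplasm erosion margin defaults to 8 px (twice a 4 px ring) — a
  band-width-derived margin would erode a typical embryo away.
- Determinism: all randomness flows through seeds carried by the spec
  objects; pipeline CSVs embed their parameter set and reruns are
  byte-identical.

## Problem sizes used by the test-suite

The suites run on single frames of the default 212 × 312 px embryo
(about 1000 cortical positions per contour), 5% gaussian camera noise
where noise is called for, three seeds per A:P ratio target, 100–200
Monte-Carlo replicates for FRAP estimator checks, 1000 null replicates
for the Welch type-I rate and 500 for CI coverage. These sizes were
chosen so each suite probes estimator behaviour (bias well below the
tolerances being asserted) while the whole suite stays fast enough to
run on every change.

## Known limitations

- The accumulation statistic reads the *maximum* along the normal; in
  regions where true accumulation drops below 1 the maximum reports the
  cytoplasm instead, so values below 1 are compressed toward 1. The
  depleted-domain statistics operate in the $a > 1$ regime where this
  does not bite.
- Perimeter-fraction regions assume roughly elliptical embryos; for
  strongly bent embryos perimeter fractions and axial fractions diverge.
- The single-exponential FRAP model has no immobile-pool kinetics or
  diffusion component; the mobile fraction is a plateau parameter, not a
  mechanistic constant.
- One embryo per field of view; no 3-D segmentation; no bleach-trend
  detrending of time series; no multiple-testing correction across
  timepoints (the per-timepoint tests mirror common practice in this
  literature and should be read accordingly).
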