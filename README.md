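# cortexQuant

Quantification of cortical fluorescence asymmetry in single-cell embryo
time-lapse movies.

## The problem

During polarization and cytokinesis of early embryos — the *C. elegans*
zygote being the canonical system — regulators of cortical contractility
such as the RhoGEF ECT-2 are displaced from the cortex near spindle poles
and centrosomes ("polar relaxation"), producing an anterior–posterior
asymmetry in cortical fluorescence. Measuring that asymmetry from
spinning-disk movies requires a reproducible chain of image measurements:
find the embryo, trace its cortex, read the cortical signal at every
position around the perimeter, and normalize it so embryos and conditions
can be compared. cortexQuant implements that chain as tested, scriptable R
functions, for cell biologists analysing single-channel 2-D time-lapse
TIFFs.

## The statistic

For each frame the embryo is segmented (Gaussian blur, automatic
threshold, largest component, hole fill), its boundary is extracted as a
sub-pixel contour anchored at the anterior pole with arc-length
coordinate *s* ∈ [0, 1) running clockwise (anterior at *s* = 0, posterior
at *s* = 0.5), and the image is straightened into a 50 px band around the
contour. At every cortical position the maximum of a 3 px-wide
perpendicular intensity profile is recorded and converted to
**accumulation**

    a(s) = (max intensity − background) / (cytoplasm − background)

so that *a* = 1 means the cortex is indistinguishable from cytoplasm.
Downstream statistics follow the conventions of the field:

- **A:P ratio** — mean *a* over the anterior 20% of the perimeter divided
  by the mean over the posterior 20%, per frame; the asymmetry readout.
- **Boundary length** — the accumulation profile is smoothed with a
  cyclic penalized spline (mgcv GAM); a threshold is set at 85% of the
  anterior-60% mean and the boundary length is the fraction of cortical
  positions below it: the size of the depleted posterior domain.
- **Furrow kinetics** — tip-to-tip furrow width normalized to the maximum
  embryo width, period-3 rolling average, interpolated time of crossing
  90% width, and completion/failure calls.
- **FRAP** — full-scale-normalized recovery traces fitted to
  *y = a*(1 − e^(−*b t*)), with *t*½ = ln 2 / *b* and mobile fraction
  *a*; per-embryo coefficients averaged per condition.
- **Centrosome–cortex distance** — nearest-cortex distance of annotated
  centrosome positions, paired with the local accumulation at that
  cortical position.

Every stage is verifiable against a built-in synthetic embryo generator
(elliptical embryo, thin cortical ring with a controllable anterior
enrichment and posterior depletion domain, camera noise) whose ground
truth — contour, accumulation field, FRAP and furrow parameters — is
known exactly.

## Worked example

```r
library(cortexQuant)

## a synthetic embryo in the control regime, 5% camera noise
spec  <- syntheticEmbryoSpec(noiseModel = list(type = "gaussian", sd = 5),
                             rngSeed = 11)
truth <- accumulationGroundTruth()     # anterior ~3, posterior ~1.2
frame <- renderFrame(spec, truth, 1)

res <- quantifyEmbryo(list(frame), anteriorHint = anteriorPole(spec))
seriesData(res$timeSeries)
#>   time anteriorMean posteriorMean  apRatio cortexMean perimeterNorm
#> 1    0      2.97442      1.228841 2.420509   2.183872             1

boundaryLength(smoothProfile(res$profiles[[1]]), timepoint = 0)
#> BoundaryResult at t = 0 s: anterior-60% mean 2.669, threshold 2.269,
#> boundary length 0.476

fitRecovery(simulateFrapTrace(frapGroundTruth(noiseSd = 0.02, rngSeed = 11)))
#> FrapFit: a = 0.8029, b = 0.2266 1/s, t1/2 = 3.058 s, mobile fraction 0.803
```

The measured anterior mean (2.97) and posterior mean (1.23) recover the
generator's true regional means (2.96 and 1.21); the boundary length
0.476 matches the true below-threshold fraction of this accumulation
field (0.483); and the FRAP fit recovers the generating amplitude 0.8 and
rate 0.23 1/s (half-time ≈ 3 s) from a noisy trace.

Movies on disk are handled the same way: `simulateMovie()` writes a
multi-page TIFF plus a JSON ground-truth sidecar, and `quantifyMovie()`
reads a TIFF, quantifies every frame and writes deterministic CSV tables
(time series and per-position profiles) with the parameter set embedded
in the header.

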