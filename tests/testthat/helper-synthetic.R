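# Shared fixtures: everything is generated in code at test time.

# Test-side bilinear lookup of an image at (row, col) points.
bilinearSampleAt <- function(img, pts) {
  r <- pts[, 1]; c <- pts[, 2]
  r0 <- floor(r); c0 <- floor(c)
  fr <- r - r0; fc <- c - c0
  img[cbind(r0, c0)] * (1 - fr) * (1 - fc) +
    img[cbind(r0 + 1, c0)] * fr * (1 - fc) +
    img[cbind(r0, c0 + 1)] * (1 - fr) * fc +
    img[cbind(r0 + 1, c0 + 1)] * fr * fc
}

ramanujanPerimeter <- function(a, b) {
  h <- ((a - b) / (a + b))^2
  pi * (a + b) * (1 + 3 * h / (10 + sqrt(4 - 3 * h)))
}

# Default study-condition embryo, optionally noisy (sd in camera units).
studySpec <- function(noiseSd = 0, seed = 1L, ...) {
  nm <- if (noiseSd > 0) list(type = "gaussian", sd = noiseSd)
        else list(type = "none")
  syntheticEmbryoSpec(noiseModel = nm, rngSeed = as.integer(seed), ...)
}

quantifyOneFrame <- function(spec, truth, frameIndex = 1L,
                             config = runConfig()) {
  quantifyEmbryo(list(renderFrame(spec, truth, frameIndex)),
                 anteriorHint = anteriorPole(spec), config = config)
}

# Build an AccumulationProfile directly from values (already normalized).
makeProfile <- function(s, a, time = 0) {
  new("AccumulationProfile", s = s, a = a, time = time,
      background = 0, cytoplasm = 1)
}

# Minimal EmbryoTimeSeries around given A:P ratios.
makeSeries <- function(apRatio, times = seq_along(apRatio) - 1) {
  new("EmbryoTimeSeries",
      data = data.frame(time = times, anteriorMean = apRatio,
                        posteriorMean = 1, apRatio = apRatio,
                        cortexMean = apRatio, perimeterNorm = 1),
      event = "anaphase")
}

# Minimal valid contour (octagon) with a prescribed perimeter slot.
octagonContour <- function(per = 100) {
  phi <- (0:7) / 8 * 2 * pi
  new("CortexContour", points = cbind(10 + 5 * sin(phi), 10 + 5 * cos(phi)),
      s = (0:7) / 8, anchorIndex = 1L, pixelSize = 1, perimeter = per)
}

# Anterior gain giving a target true A:P ratio (no depletion domain).
gainForRatio <- function(target, baseline = 1.5) {
  if (target <= 1) return(0)
  trueRatio <- function(g) {
    s <- seq(0, 1, length.out = 20001)[-20001]
    a <- trueProfile(accumulationGroundTruth(
      baseline = baseline, anteriorGain = g, depletionDepth = 0), s, 1)
    mean(a[s >= 0.9 | s < 0.1]) / mean(a[s >= 0.4 & s < 0.6])
  }
  stats::uniroot(function(g) trueRatio(g) - target, c(1e-6, 20))$root
}

# Low-anterior-gain truth used for boundary-length experiments, where the
# below-threshold domain is set by the depletion dip alone.
boundaryTruth <- function(halfWidth, depth = 0.45) {
  accumulationGroundTruth(baseline = 1.6, anteriorGain = 0.2,
                          depletionHalfWidth = halfWidth,
                          depletionDepth = depth, edgeSteepness = 80)
}
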