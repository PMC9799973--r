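#' @include AllClasses.R utils-geometry.R
NULL

## Ellipse machinery ---------------------------------------------------------
## The synthetic embryo is an ellipse with semi-axes (a, b), long-axis angle
## `orientation` (from +col toward +row), and the anterior pole at one end of
## the long axis. The cortical position s is the arc-length fraction measured
## clockwise (in image coordinates, row down) from the anterior pole.

ellipseAxes <- function(spec) {
  th <- spec@orientation
  list(u = c(cos(th), sin(th)),        # (x, y-down) unit vector, long axis
       v = c(-sin(th), cos(th)))
}

# phi0: world parameter angle of the anterior pole.
anteriorPhi0 <- function(spec) if (spec@anteriorEnd > 0) 0 else pi

# Arc-length lookup table: phi measured from the anterior pole, cumulative
# arc length and total perimeter (pixels). The ellipse speed is symmetric
# under phi -> phi + pi, so the table is independent of which end is
# anterior.
ellipseArcTable <- function(spec, n = 4096L) {
  a <- spec@semiAxes[1]; b <- spec@semiAxes[2]
  phi <- seq(0, 2 * pi, length.out = n + 1L)
  w <- phi + anteriorPhi0(spec)
  speed <- sqrt(a^2 * sin(w)^2 + b^2 * cos(w)^2)
  # trapezoidal cumulative arc length
  cum <- c(0, cumsum((speed[-1] + speed[-(n + 1L)]) / 2 * diff(phi)))
  list(phi = phi, cum = cum, total = cum[n + 1L])
}

# Map world parameter angles w to arc-length fraction s from the anterior.
sFromParam <- function(spec, w, table = ellipseArcTable(spec)) {
  phi <- (w - anteriorPhi0(spec)) %% (2 * pi)
  stats::approx(table$phi, table$cum, xout = phi)$y / table$total
}

# Point(s) on the ellipse at world parameter angles w, as (row, col).
ellipsePoint <- function(spec, w) {
  ax <- ellipseAxes(spec)
  a <- spec@semiAxes[1]; b <- spec@semiAxes[2]
  x <- spec@center[2] + a * cos(w) * ax$u[1] + b * sin(w) * ax$v[1]
  y <- spec@center[1] + a * cos(w) * ax$u[2] + b * sin(w) * ax$v[2]
  cbind(row = y, col = x)
}

# Project pixel coordinates onto the ellipse: returns the world parameter
# angle of the foot point and the signed distance (negative inside).
# Starts from the first-order foot-point estimate and polishes with a few
# Newton steps on the distance objective.
projectToEllipse <- function(spec, rows, cols) {
  ax <- ellipseAxes(spec)
  a <- spec@semiAxes[1]; b <- spec@semiAxes[2]
  dx <- cols - spec@center[2]; dy <- rows - spec@center[1]
  uu <- dx * ax$u[1] + dy * ax$u[2]
  vv <- dx * ax$v[1] + dy * ax$v[2]
  w <- atan2(a * vv, b * uu)
  for (i in 1:5) {
    g <- (b^2 - a^2) * sin(w) * cos(w) + a * uu * sin(w) - b * vv * cos(w)
    gp <- (b^2 - a^2) * cos(2 * w) + a * uu * cos(w) + b * vv * sin(w)
    step <- ifelse(gp > 1e-9, g / gp, 0)
    w <- w - pmin(pmax(step, -0.5), 0.5)
  }
  dist <- sqrt((a * cos(w) - uu)^2 + (b * sin(w) - vv)^2)
  inside <- (uu / a)^2 + (vv / b)^2 < 1
  list(w = w, signedDist = ifelse(inside, -dist, dist))
}

## Constructors --------------------------------------------------------------

#' Describe a synthetic embryo movie
#'
#' Builds a [SyntheticEmbryoSpec-class]. Defaults mimic a one-cell
#' C. elegans embryo: a 50 x 30 um ellipse imaged at 0.2 um/px (125 x 75 px
#' semi-axes) with a 4 px cortical ring, anterior pole to the left.
#'
#' @param imageShape c(rows, cols) of the frame in pixels.
#' @param center ellipse centre c(row, col); default image centre.
#' @param semiAxes c(major, minor) semi-axes in pixels.
#' @param orientation long-axis angle in radians.
#' @param anteriorEnd +1 or -1: which end of the long axis is anterior.
#' @param cortexWidth ring thickness in pixels.
#' @param backgroundLevel,cytoplasmLevel intensities in camera units.
#' @param noiseModel list(type = "none"|"gaussian"|"poisson", sd, gain).
#' @param pixelSize micrometres per pixel.
#' @param frameInterval seconds between frames.
#' @param nFrames number of frames.
#' @param rngSeed integer seed for the noise stream.
#' @return a \code{SyntheticEmbryoSpec}.
#' @export
syntheticEmbryoSpec <- function(imageShape = c(212L, 312L),
                                center = (imageShape + 1) / 2,
                                semiAxes = c(125, 75),
                                orientation = 0,
                                anteriorEnd = -1,
                                cortexWidth = 4,
                                backgroundLevel = 10,
                                cytoplasmLevel = 100,
                                noiseModel = list(type = "none"),
                                pixelSize = 0.2,
                                frameInterval = 10,
                                nFrames = 1L,
                                rngSeed = 1L) {
  noiseModel <- utils::modifyList(list(type = "none", sd = 0, gain = 1),
                                  noiseModel)
  new("SyntheticEmbryoSpec",
      imageShape = as.integer(imageShape), center = as.numeric(center),
      semiAxes = as.numeric(semiAxes), orientation = orientation,
      anteriorEnd = anteriorEnd, cortexWidth = cortexWidth,
      backgroundLevel = backgroundLevel, cytoplasmLevel = cytoplasmLevel,
      noiseModel = noiseModel, pixelSize = pixelSize,
      frameInterval = frameInterval, nFrames = as.integer(nFrames),
      rngSeed = as.integer(rngSeed))
}

#' Describe the true cortical accumulation field
#'
#' Ground truth a_true(s, t) = ramp(t) * (baseline
#' + anteriorGain * (1 + cos(2 pi s)) / 2
#' - depletionDepth * D(s)), truncated at zero, where D is a smooth
#' top-hat built from two periodic logistic edges centred on
#' \code{depletionCenter}. Defaults give a paper-regime control embryo:
#' anterior accumulation near 3, posterior near 1.2.
#'
#' @param baseline uniform accumulation level.
#' @param anteriorGain anterior enrichment amplitude.
#' @param depletionCenter centre of the depleted domain (0.5 = posterior).
#' @param depletionHalfWidth half-width as a perimeter fraction, in (0, 0.5).
#' @param depletionDepth depth of the depletion.
#' @param edgeSteepness logistic steepness of the domain edges.
#' @param temporalRamp per-frame multiplier, recycled over frames.
#' @return an \code{AccumulationGroundTruth}.
#' @export
accumulationGroundTruth <- function(baseline = 1.6, anteriorGain = 1.4,
                                    depletionCenter = 0.5,
                                    depletionHalfWidth = 0.15,
                                    depletionDepth = 0.45,
                                    edgeSteepness = 40,
                                    temporalRamp = 1) {
  new("AccumulationGroundTruth",
      baseline = baseline, anteriorGain = anteriorGain,
      depletionCenter = depletionCenter,
      depletionHalfWidth = depletionHalfWidth,
      depletionDepth = depletionDepth, edgeSteepness = edgeSteepness,
      temporalRamp = as.numeric(temporalRamp))
}

#' Describe a simulated FRAP experiment
#'
#' Defaults follow the cortical FRAP acquisition design of 25 pre-bleach
#' and 175 post-bleach frames at 100 ms intervals, with a recovery rate
#' giving a half-time near 3 s.
#'
#' @param aTrue true amplitude (mobile fraction).
#' @param bTrue true recovery rate (1/s).
#' @param prebleachLevel normalized pre-bleach plateau.
#' @param bleachFloor normalized residual at t = 0.
#' @param nPre,nPost pre-/post-bleach frame counts.
#' @param dt frame interval (s).
#' @param noiseSd gaussian noise sd (normalized units).
#' @param rngSeed integer seed.
#' @return a \code{FrapGroundTruth}.
#' @export
frapGroundTruth <- function(aTrue = 0.8, bTrue = 0.23, prebleachLevel = 1,
                            bleachFloor = 0, nPre = 25L, nPost = 175L,
                            dt = 0.1, noiseSd = 0, rngSeed = 1L) {
  new("FrapGroundTruth", aTrue = aTrue, bTrue = bTrue,
      prebleachLevel = prebleachLevel, bleachFloor = bleachFloor,
      nPre = as.integer(nPre), nPost = as.integer(nPost), dt = dt,
      noiseSd = noiseSd, rngSeed = as.integer(rngSeed))
}

#' Describe a simulated furrow trajectory
#'
#' Width stays at the maximum until \code{plateauEnd}, then decreases
#' linearly at \code{rate} (width fraction per second) down to
#' \code{finalFraction}.
#'
#' @param maxWidth maximum embryo width (um).
#' @param plateauEnd time ingression starts (s).
#' @param rate ingression rate (fraction of width per s).
#' @param finalFraction normalized width reached at the end.
#' @param frameInterval seconds between measurements.
#' @param nFrames number of measurements.
#' @return a \code{FurrowGroundTruth}.
#' @export
furrowGroundTruth <- function(maxWidth = 30, plateauEnd = 60, rate = 0.01,
                              finalFraction = 0, frameInterval = 10,
                              nFrames = 30L) {
  new("FurrowGroundTruth", maxWidth = maxWidth, plateauEnd = plateauEnd,
      rate = rate, finalFraction = finalFraction,
      frameInterval = frameInterval, nFrames = as.integer(nFrames))
}

## Ground-truth evaluation ---------------------------------------------------

#' Evaluate the true accumulation field
#'
#' Exact evaluation of a_true(s, t); the parameter-recovery oracle for the
#' whole quantification pipeline.
#'
#' @param truth an [AccumulationGroundTruth-class].
#' @param positions cortical positions s in [0, 1).
#' @param frameIndex 1-based frame index selecting the temporal ramp value.
#' @return numeric vector of accumulation values, one per position.
#' @export
trueProfile <- function(truth, positions, frameIndex = 1L) {
  stopifnot(all(positions >= 0 & positions < 1))
  ramp <- truth@temporalRamp[(as.integer(frameIndex) - 1L) %%
                               length(truth@temporalRamp) + 1L]
  bump <- (1 + cos(2 * pi * positions)) / 2
  delta <- ((positions - truth@depletionCenter + 0.5) %% 1) - 0.5
  k <- truth@edgeSteepness
  hw <- truth@depletionHalfWidth
  dip <- stats::plogis(k * (delta + hw)) * stats::plogis(k * (hw - delta))
  pmax(0, ramp * (truth@baseline + truth@anteriorGain * bump -
                    truth@depletionDepth * dip))
}

#' Ground-truth cortex contour of a synthetic embryo
#'
#' @param spec a [SyntheticEmbryoSpec-class].
#' @param n number of points, uniformly spaced in arc length.
#' @return a [CortexContour-class] anchored at the anterior pole (s = 0),
#'   clockwise.
#' @export
trueContour <- function(spec, n = 1024L) {
  table <- ellipseArcTable(spec)
  sTarget <- seq(0, 1, length.out = n + 1L)[-(n + 1L)]
  phi <- stats::approx(table$cum / table$total, table$phi, xout = sTarget)$y
  pts <- ellipsePoint(spec, phi + anteriorPhi0(spec))
  new("CortexContour", points = pts, s = sTarget, anchorIndex = 1L,
      pixelSize = spec@pixelSize,
      perimeter = table$total * spec@pixelSize)
}

#' Anterior pole pixel position of a synthetic embryo
#'
#' @param spec a [SyntheticEmbryoSpec-class].
#' @return c(row, col) of the anterior pole; usable as the anterior hint.
#' @export
anteriorPole <- function(spec) {
  p <- ellipsePoint(spec, anteriorPhi0(spec))
  c(row = p[1, 1], col = p[1, 2])
}

#' True below-threshold fraction of the accumulation field
#'
#' Applies the boundary-length definition (threshold at
#' \code{thresholdFactor} times the anterior-60% mean, fraction of grid
#' positions below it) directly to a_true on a fine grid; the ground truth
#' against which the measured boundary length is compared.
#'
#' @param truth an [AccumulationGroundTruth-class].
#' @param frameIndex 1-based frame index.
#' @param nGrid grid resolution.
#' @param thresholdFactor threshold as a fraction of the anterior-60% mean.
#' @return the true below-threshold fraction in [0, 1].
#' @export
trueBoundaryFraction <- function(truth, frameIndex = 1L, nGrid = 1000L,
                                 thresholdFactor = 0.85) {
  s <- seq(0, 1, length.out = nGrid + 1L)[-(nGrid + 1L)]
  a <- trueProfile(truth, s, frameIndex)
  ant60 <- s >= 0.7 | s < 0.3
  thr <- thresholdFactor * mean(a[ant60])
  mean(a < thr)
}

## Rendering -----------------------------------------------------------------

#' Render one synthetic embryo frame
#'
#' Pixels outside the ellipse take the background level, interior pixels
#' the cytoplasm level, and pixels within half the cortex width of the
#' ellipse boundary take background + (cytoplasm - background) *
#' a_true(s, t) evaluated at the nearest boundary position. Noise is
#' applied last and clipped at zero; with a seed the frame is
#' bit-reproducible.
#'
#' @param spec a [SyntheticEmbryoSpec-class].
#' @param truth an [AccumulationGroundTruth-class].
#' @param frameIndex 1-based frame index (must not exceed \code{nFrames}).
#' @return an [ImageFrame-class].
#' @export
renderFrame <- function(spec, truth, frameIndex = 1L) {
  frameIndex <- as.integer(frameIndex)
  stopifnot(frameIndex >= 1L, frameIndex <= spec@nFrames)
  a <- spec@semiAxes[1]; b <- spec@semiAxes[2]
  th <- spec@orientation
  halfW <- spec@cortexWidth / 2
  hx <- sqrt((a * cos(th))^2 + (b * sin(th))^2) + halfW
  hy <- sqrt((a * sin(th))^2 + (b * cos(th))^2) + halfW
  overLo <- c(spec@center[1] - hy - 1, spec@center[2] - hx - 1)
  overHi <- c(spec@center[1] + hy + 1, spec@center[2] + hx + 1) -
    spec@imageShape
  if (any(overLo < 0) || any(overHi > 0))
    stop(sprintf(
      "embryo exceeds the image by up to %.1f px; enlarge imageShape",
      max(c(-overLo, overHi))))

  nr <- spec@imageShape[1]; nc <- spec@imageShape[2]
  rows <- rep(seq_len(nr), times = nc)
  cols <- rep(seq_len(nc), each = nr)
  ax <- ellipseAxes(spec)
  dx <- cols - spec@center[2]; dy <- rows - spec@center[1]
  uu <- dx * ax$u[1] + dy * ax$u[2]
  vv <- dx * ax$v[1] + dy * ax$v[2]
  q <- (uu / a)^2 + (vv / b)^2

  img <- matrix(spec@backgroundLevel, nr, nc)
  img[q < 1] <- spec@cytoplasmLevel

  cand <- which(abs(sqrt(q) - 1) * b <= halfW + 3)
  if (length(cand)) {
    pr <- projectToEllipse(spec, rows[cand], cols[cand])
    ring <- abs(pr$signedDist) <= halfW
    if (any(ring)) {
      table <- ellipseArcTable(spec)
      sRing <- sFromParam(spec, pr$w[ring], table)
      aRing <- trueProfile(truth, sRing %% 1, frameIndex)
      img[cand[ring]] <- spec@backgroundLevel +
        (spec@cytoplasmLevel - spec@backgroundLevel) * aRing
    }
  }

  nm <- spec@noiseModel
  if (nm$type != "none") {
    img <- withLocalSeed(spec@rngSeed + 7919 * frameIndex, {
      if (nm$type == "gaussian") img + stats::rnorm(length(img), 0, nm$sd)
      else matrix(stats::rpois(length(img), img / nm$gain) * nm$gain, nr, nc)
    })
    img <- pmax(img, 0)
  }
  new("ImageFrame", intensity = img, pixelSize = spec@pixelSize,
      time = (frameIndex - 1) * spec@frameInterval, frameIndex = frameIndex)
}

## Trace / trajectory simulators --------------------------------------------

#' Simulate a FRAP recovery trace
#'
#' Post-bleach values follow y(t) = bleachFloor + aTrue (1 - e^{-bTrue t})
#' plus gaussian noise, with t = 0 at the first post-bleach frame.
#'
#' @param truth a [FrapGroundTruth-class].
#' @return a [FrapTrace-class].
#' @export
simulateFrapTrace <- function(truth) {
  t <- (seq_len(truth@nPost) - 1L) * truth@dt
  y <- truth@bleachFloor + truth@aTrue * (1 - exp(-truth@bTrue * t))
  if (truth@noiseSd > 0)
    y <- withLocalSeed(truth@rngSeed,
                       y + stats::rnorm(length(y), 0, truth@noiseSd))
  new("FrapTrace", times = t, values = y, nPre = truth@nPre,
      prebleachMean = truth@prebleachLevel, bleachValue = truth@bleachFloor)
}

#' Simulate a furrow-width trajectory
#'
#' @param truth a [FurrowGroundTruth-class].
#' @return a [FurrowSeries-class]; the closed-form initiation time is
#'   available via [trueInitiationTime()].
#' @export
simulateFurrowSeries <- function(truth) {
  t <- (seq_len(truth@nFrames) - 1L) * truth@frameInterval
  wn <- pmax(truth@finalFraction,
             pmin(1, 1 - truth@rate * pmax(0, t - truth@plateauEnd)))
  furrowSeries(t, wn * truth@maxWidth, maxWidth = truth@maxWidth)
}

#' Closed-form initiation time of a simulated furrow
#'
#' @param truth a [FurrowGroundTruth-class].
#' @param threshold normalized width defining initiation.
#' @return time (s) the trajectory first crosses the threshold, or NA if it
#'   never does.
#' @export
trueInitiationTime <- function(truth, threshold = 0.9) {
  if (truth@rate <= 0 || truth@finalFraction > threshold) return(NA_real_)
  truth@plateauEnd + (1 - threshold) / truth@rate
}
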