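#' @import methods
NULL

#' ImageFrame: a single fluorescence image with physical calibration
#'
#' Container for one 2-D intensity grid of a time-lapse movie, together
#' with the pixel size and the acquisition time relative to a named
#' cell-cycle event (NEBD or anaphase onset).
#'
#' @slot intensity numeric matrix (row, col), camera units, non-negative.
#' @slot pixelSize physical pixel size in micrometres per pixel.
#' @slot time acquisition time in seconds relative to the event clock.
#' @slot frameIndex 1-based index of the frame within its movie.
#' @export
setClass("ImageFrame",
  representation(intensity = "matrix", pixelSize = "numeric",
                 time = "numeric", frameIndex = "integer"),
  prototype(pixelSize = 0.2, time = 0, frameIndex = 1L))

setValidity("ImageFrame", function(object) {
  if (!is.numeric(object@intensity)) return("intensity must be numeric")
  if (any(object@intensity < 0)) return("intensity values must be >= 0")
  if (length(object@pixelSize) != 1L || object@pixelSize <= 0)
    return("pixelSize must be a single positive number")
  TRUE
})

#' CortexContour: ordered closed outline of the embryo cortex
#'
#' An ordered, closed polyline around the embryo boundary. Once anchored,
#' point 1 is the anterior-pole midpoint (s = 0), traversal is clockwise in
#' image coordinates (row down), and \code{s} is the arc-length fraction of
#' the perimeter in [0, 1).
#'
#' @slot points n x 2 matrix of (row, col) pixel coordinates, closed
#'   implicitly (last point connects to first).
#' @slot s arc-length fraction per point, in [0, 1).
#' @slot anchorIndex index of the anterior anchor (NA until anchored).
#' @slot pixelSize micrometres per pixel.
#' @slot perimeter polyline length in micrometres.
#' @export
setClass("CortexContour",
  representation(points = "matrix", s = "numeric", anchorIndex = "integer",
                 pixelSize = "numeric", perimeter = "numeric"))

setValidity("CortexContour", function(object) {
  if (ncol(object@points) != 2L) return("points must be an n x 2 matrix")
  if (nrow(object@points) < 8L) return("contour needs at least 8 points")
  if (length(object@s) != nrow(object@points))
    return("s must have one value per point")
  if (any(object@s < 0 | object@s >= 1)) return("s must lie in [0, 1)")
  if (object@perimeter <= 0) return("perimeter must be positive")
  TRUE
})

#' CortexBand: straightened cortical intensity band
#'
#' The image resampled perpendicular to the cortex contour: one column per
#' contour position, one row per depth sample along the outward normal
#' (negative offsets inward, positive outward, centred on the contour).
#'
#' @slot values depth x position intensity matrix.
#' @slot s arc-length fraction of each column.
#' @slot offsets signed depth offsets in pixels for each row.
#' @slot clamped TRUE if any sample fell outside the frame and was clamped.
#' @export
setClass("CortexBand",
  representation(values = "matrix", s = "numeric", offsets = "numeric",
                 clamped = "logical"))

#' AccumulationProfile: normalized cortical accumulation versus position
#'
#' Cytoplasm-normalized cortical signal
#' \eqn{a(s) = (\mathrm{max\ intensity} - \mathrm{background}) /
#' (\mathrm{cytoplasm} - \mathrm{background})} per cortical position
#' \eqn{s \in [0,1)}; a value of 1 means the cortex equals the cytoplasm.
#'
#' @slot s cortical positions in [0, 1), anterior at 0, posterior at 0.5.
#' @slot a dimensionless accumulation values.
#' @slot time frame time in seconds on the event clock.
#' @slot background background intensity used for normalization.
#' @slot cytoplasm cytoplasm intensity used for normalization.
#' @export
setClass("AccumulationProfile",
  representation(s = "numeric", a = "numeric", time = "numeric",
                 background = "numeric", cytoplasm = "numeric"))

setValidity("AccumulationProfile", function(object) {
  if (length(object@s) != length(object@a)) return("s and a lengths differ")
  if (any(!is.finite(object@a))) return("accumulation must be finite")
  if (object@cytoplasm <= object@background)
    return("cytoplasm must exceed background")
  TRUE
})

#' EmbryoTimeSeries: per-frame regional accumulation summaries
#'
#' Per-frame anterior/posterior 20% mean accumulation, their ratio
#' (the A:P asymmetry readout), the whole-cortex mean, and the normalized
#' perimeter, on a common event clock.
#'
#' @slot data data.frame with columns time, anteriorMean, posteriorMean,
#'   apRatio, cortexMean, perimeterNorm.
#' @slot event name of the time-zero event ("anaphase" or "NEBD").
#' @export
setClass("EmbryoTimeSeries",
  representation(data = "data.frame", event = "character"))

setValidity("EmbryoTimeSeries", function(object) {
  need <- c("time", "anteriorMean", "posteriorMean", "apRatio",
            "cortexMean", "perimeterNorm")
  if (!all(need %in% names(object@data)))
    return(paste("data must contain columns:", paste(need, collapse = ", ")))
  TRUE
})

#' BoundaryResult: size of the cortical domain below threshold
#'
#' The boundary-length statistic: the smoothed accumulation profile at the
#' frame of maximal A:P asymmetry is thresholded at 85% of its
#' anterior-60% mean, and the boundary length is the fraction of cortical
#' positions falling below that threshold.
#'
#' @slot timepoint time (s) of the maximal-asymmetry frame.
#' @slot anterior60Mean mean smoothed accumulation over the anterior 60%.
#' @slot threshold 0.85 x anterior60Mean (or the configured factor).
#' @slot boundaryLength fraction of positions below threshold, in [0, 1].
#' @slot smoothed the smoothed profile used for counting.
#' @slot s grid positions of the smoothed profile.
#' @export
setClass("BoundaryResult",
  representation(timepoint = "numeric", anterior60Mean = "numeric",
                 threshold = "numeric", boundaryLength = "numeric",
                 smoothed = "numeric", s = "numeric"))

#' FrapTrace: normalized fluorescence recovery trace
#'
#' Full-scale-normalized FRAP recovery: pre-bleach mean maps to 1, the
#' first post-bleach frame to 0; time zero is the first post-bleach frame.
#'
#' @slot times seconds since the first post-bleach frame.
#' @slot values normalized intensities.
#' @slot nPre number of pre-bleach frames averaged for normalization.
#' @slot prebleachMean raw pre-bleach mean intensity.
#' @slot bleachValue raw intensity of the first post-bleach frame.
#' @export
setClass("FrapTrace",
  representation(times = "numeric", values = "numeric", nPre = "integer",
                 prebleachMean = "numeric", bleachValue = "numeric"))

setValidity("FrapTrace", function(object) {
  if (length(object@times) != length(object@values))
    return("times and values lengths differ")
  if (is.unsorted(object@times, strictly = TRUE))
    return("times must be strictly increasing")
  if (object@nPre < 1L) return("nPre must be >= 1")
  TRUE
})

#' FrapFit: single-exponential recovery fit
#'
#' Least-squares fit of \eqn{y = a (1 - e^{-b t})} to a normalized FRAP
#' trace. Under full-scale normalization the amplitude \code{a} is the
#' mobile fraction and \eqn{t_{1/2} = \ln 2 / b}.
#'
#' @slot a dimensionless amplitude (mobile fraction).
#' @slot b recovery rate in 1/s.
#' @slot tHalf half-time ln(2)/b in seconds.
#' @slot mobileFraction equal to a for full-scale-normalized traces.
#' @slot residualRms root-mean-square residual of the fit.
#' @export
setClass("FrapFit",
  representation(a = "numeric", b = "numeric", tHalf = "numeric",
                 mobileFraction = "numeric", residualRms = "numeric"))

setValidity("FrapFit", function(object) {
  if (object@b <= 0) return("rate b must be positive")
  if (abs(object@tHalf * object@b - log(2)) > 1e-9)
    return("tHalf * b must equal ln 2")
  if (object@mobileFraction < 0 || object@mobileFraction > 1.1)
    return("mobile fraction out of [0, 1.1]")
  TRUE
})

#' FurrowSeries: cleavage-furrow ingression kinetics
#'
#' Furrow tip-to-tip width over time, normalized to the maximum embryo
#' width, with its period-3 rolling average, the interpolated time of
#' ingression initiation (first crossing below 90% width) and the
#' completion call.
#'
#' @slot times seconds relative to NEBD or anaphase onset.
#' @slot width tip-to-tip width in micrometres.
#' @slot widthNorm width / maximum embryo width, in [0, 1].
#' @slot smoothed centred rolling average (period 3) of widthNorm; NA where
#'   no full window exists.
#' @slot initiationTime interpolated first crossing below the initiation
#'   threshold; NA if the furrow never initiated.
#' @slot completed TRUE if the furrow reached (near) zero width.
#' @export
setClass("FurrowSeries",
  representation(times = "numeric", width = "numeric", widthNorm = "numeric",
                 smoothed = "numeric", initiationTime = "numeric",
                 completed = "logical"))

setValidity("FurrowSeries", function(object) {
  n <- length(object@times)
  if (length(object@width) != n || length(object@widthNorm) != n)
    return("times, width and widthNorm lengths differ")
  if (any(object@widthNorm < -1e-9 | object@widthNorm > 1 + 1e-9))
    return("widthNorm must lie in [0, 1]")
  TRUE
})

## ---- synthetic ground-truth containers ----

#' SyntheticEmbryoSpec: geometry and imaging model of a synthetic embryo
#'
#' Describes an elliptical one-cell embryo rendered as uniform cytoplasm
#' over background with a thin bright cortical ring, plus the camera noise
#' model and acquisition timing. Defaults mimic a C. elegans zygote:
#' ~50 um long axis imaged at 0.2 um/px.
#'
#' @slot imageShape c(rows, cols) of the rendered frame.
#' @slot center c(row, col) of the ellipse centre, pixels.
#' @slot semiAxes c(major, minor) semi-axes in pixels.
#' @slot orientation long-axis angle in radians (from +col toward +row).
#' @slot anteriorEnd +1 if the anterior pole lies along +orientation, -1
#'   for the opposite end.
#' @slot cortexWidth cortical ring thickness in pixels.
#' @slot backgroundLevel background intensity (camera units).
#' @slot cytoplasmLevel cytoplasm intensity (camera units).
#' @slot noiseModel list(type = "none" | "gaussian" | "poisson", sd, gain).
#' @slot pixelSize micrometres per pixel.
#' @slot frameInterval seconds between frames.
#' @slot nFrames number of frames.
#' @slot rngSeed integer seed for the noise stream.
#' @export
setClass("SyntheticEmbryoSpec",
  representation(imageShape = "integer", center = "numeric",
                 semiAxes = "numeric", orientation = "numeric",
                 anteriorEnd = "numeric", cortexWidth = "numeric",
                 backgroundLevel = "numeric", cytoplasmLevel = "numeric",
                 noiseModel = "list", pixelSize = "numeric",
                 frameInterval = "numeric", nFrames = "integer",
                 rngSeed = "integer"))

setValidity("SyntheticEmbryoSpec", function(object) {
  if (any(object@semiAxes <= object@cortexWidth))
    return("semiAxes must exceed cortexWidth")
  if (object@cortexWidth <= 0) return("cortexWidth must be positive")
  if (object@cytoplasmLevel <= object@backgroundLevel)
    return("cytoplasmLevel must exceed backgroundLevel")
  if (object@backgroundLevel < 0) return("backgroundLevel must be >= 0")
  if (!object@noiseModel$type %in% c("none", "gaussian", "poisson"))
    return("noiseModel$type must be none, gaussian or poisson")
  if (!object@anteriorEnd %in% c(-1, 1)) return("anteriorEnd must be +1 or -1")
  TRUE
})

#' AccumulationGroundTruth: true cortical accumulation field
#'
#' The ground-truth accumulation a_true(s, t): a uniform baseline plus a
#' smooth anterior enrichment bump, minus a posterior depletion domain
#' shaped as the product of two periodic logistic edges, all scaled by a
#' per-frame temporal ramp.
#'
#' @slot baseline uniform accumulation level (dimensionless).
#' @slot anteriorGain amplitude of the anterior enrichment bump.
#' @slot depletionCenter centre of the depleted domain in s (0.5 = posterior).
#' @slot depletionHalfWidth half-width of the domain as perimeter fraction.
#' @slot depletionDepth depth of the depletion (dimensionless).
#' @slot edgeSteepness logistic steepness of the domain edges.
#' @slot temporalRamp per-frame multiplier (recycled to nFrames).
#' @export
setClass("AccumulationGroundTruth",
  representation(baseline = "numeric", anteriorGain = "numeric",
                 depletionCenter = "numeric", depletionHalfWidth = "numeric",
                 depletionDepth = "numeric", edgeSteepness = "numeric",
                 temporalRamp = "numeric"))

setValidity("AccumulationGroundTruth", function(object) {
  if (object@depletionHalfWidth <= 0 || object@depletionHalfWidth >= 0.5)
    return("depletionHalfWidth must lie in (0, 0.5)")
  if (object@depletionDepth < 0) return("depletionDepth must be >= 0")
  if (any(object@temporalRamp < 0)) return("temporalRamp must be >= 0")
  TRUE
})

#' FrapGroundTruth: parameters of a simulated FRAP experiment
#'
#' Generates a recovery trace y(t) = bleachFloor + aTrue (1 - e^{-bTrue t})
#' with gaussian noise, preceded by nPre pre-bleach frames at
#' prebleachLevel. Defaults follow a typical cortical FRAP design: 25
#' pre-bleach and 175 post-bleach frames at 100 ms intervals.
#'
#' @slot aTrue true amplitude (mobile fraction), dimensionless.
#' @slot bTrue true rate, 1/s.
#' @slot prebleachLevel normalized pre-bleach plateau (1.0).
#' @slot bleachFloor normalized residual right after the bleach.
#' @slot nPre pre-bleach frame count.
#' @slot nPost post-bleach frame count.
#' @slot dt frame interval in seconds.
#' @slot noiseSd gaussian noise sd in normalized units.
#' @slot rngSeed integer seed.
#' @export
setClass("FrapGroundTruth",
  representation(aTrue = "numeric", bTrue = "numeric",
                 prebleachLevel = "numeric", bleachFloor = "numeric",
                 nPre = "integer", nPost = "integer", dt = "numeric",
                 noiseSd = "numeric", rngSeed = "integer"))

setValidity("FrapGroundTruth", function(object) {
  if (object@aTrue < 0 || object@aTrue > 1.05)
    return("aTrue must lie in [0, 1.05]")
  if (object@bTrue <= 0) return("bTrue must be positive")
  if (object@nPre < 1L || object@nPost < 1L)
    return("nPre and nPost must be >= 1")
  TRUE
})

#' FurrowGroundTruth: parameters of a simulated furrow trajectory
#'
#' A plateau at full width followed by linear ingression at a constant
#' rate down to a final fraction. The closed-form initiation time (first
#' crossing of 90% width) and completion status are retrievable.
#'
#' @slot maxWidth maximum embryo width in micrometres.
#' @slot plateauEnd time (s) at which ingression starts.
#' @slot rate ingression rate in width-fraction per second.
#' @slot finalFraction normalized width reached at the end.
#' @slot frameInterval seconds between width measurements.
#' @slot nFrames number of measurements.
#' @export
setClass("FurrowGroundTruth",
  representation(maxWidth = "numeric", plateauEnd = "numeric",
                 rate = "numeric", finalFraction = "numeric",
                 frameInterval = "numeric", nFrames = "integer"))

setValidity("FurrowGroundTruth", function(object) {
  if (object@maxWidth <= 0) return("maxWidth must be positive")
  if (object@rate < 0) return("rate must be >= 0")
  if (object@finalFraction < 0 || object@finalFraction > 1)
    return("finalFraction must lie in [0, 1]")
  TRUE
})
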