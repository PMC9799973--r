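#' @include AllClasses.R
NULL

#' Accessors for cortexQuant objects
#'
#' Small accessor layer over the S4 containers so user code never touches
#' slots directly.
#'
#' @param object a cortexQuant S4 object.
#' @return the requested component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("intensity", function(object) standardGeneric("intensity"))
#' @rdname accessors
#' @export
setMethod("intensity", "ImageFrame", function(object) object@intensity)

#' @rdname accessors
#' @export
setGeneric("pixelSize", function(object) standardGeneric("pixelSize"))
#' @rdname accessors
#' @export
setMethod("pixelSize", "ImageFrame", function(object) object@pixelSize)
#' @rdname accessors
#' @export
setMethod("pixelSize", "CortexContour", function(object) object@pixelSize)

#' @rdname accessors
#' @export
setGeneric("frameTime", function(object) standardGeneric("frameTime"))
#' @rdname accessors
#' @export
setMethod("frameTime", "ImageFrame", function(object) object@time)
#' @rdname accessors
#' @export
setMethod("frameTime", "AccumulationProfile", function(object) object@time)

#' @rdname accessors
#' @export
setGeneric("contourPoints", function(object) standardGeneric("contourPoints"))
#' @rdname accessors
#' @export
setMethod("contourPoints", "CortexContour", function(object) object@points)

#' @rdname accessors
#' @export
setGeneric("arcFraction", function(object) standardGeneric("arcFraction"))
#' @rdname accessors
#' @export
setMethod("arcFraction", "CortexContour", function(object) object@s)
#' @rdname accessors
#' @export
setMethod("arcFraction", "AccumulationProfile", function(object) object@s)
#' @rdname accessors
#' @export
setMethod("arcFraction", "CortexBand", function(object) object@s)
#' @rdname accessors
#' @export
setMethod("arcFraction", "BoundaryResult", function(object) object@s)

#' @rdname accessors
#' @export
setGeneric("perimeter", function(object) standardGeneric("perimeter"))
#' @rdname accessors
#' @export
setMethod("perimeter", "CortexContour", function(object) object@perimeter)

#' @rdname accessors
#' @export
setGeneric("anchorIndex", function(object) standardGeneric("anchorIndex"))
#' @rdname accessors
#' @export
setMethod("anchorIndex", "CortexContour", function(object) object@anchorIndex)

#' @rdname accessors
#' @export
setGeneric("bandValues", function(object) standardGeneric("bandValues"))
#' @rdname accessors
#' @export
setMethod("bandValues", "CortexBand", function(object) object@values)

#' @rdname accessors
#' @export
setGeneric("bandOffsets", function(object) standardGeneric("bandOffsets"))
#' @rdname accessors
#' @export
setMethod("bandOffsets", "CortexBand", function(object) object@offsets)

#' @rdname accessors
#' @export
setGeneric("accumulation", function(object) standardGeneric("accumulation"))
#' @rdname accessors
#' @export
setMethod("accumulation", "AccumulationProfile", function(object) object@a)

#' @rdname accessors
#' @export
setGeneric("seriesData", function(object) standardGeneric("seriesData"))
#' @rdname accessors
#' @export
setMethod("seriesData", "EmbryoTimeSeries", function(object) object@data)
#' @rdname accessors
#' @export
setMethod("seriesData", "FurrowSeries", function(object)
  data.frame(time = object@times, width = object@width,
             widthNorm = object@widthNorm, smoothed = object@smoothed))

#' @rdname accessors
#' @export
setGeneric("boundaryFraction", function(object) standardGeneric("boundaryFraction"))
#' @rdname accessors
#' @export
setMethod("boundaryFraction", "BoundaryResult", function(object) object@boundaryLength)

#' @rdname accessors
#' @export
setGeneric("boundaryThreshold", function(object) standardGeneric("boundaryThreshold"))
#' @rdname accessors
#' @export
setMethod("boundaryThreshold", "BoundaryResult", function(object) object@threshold)

#' @rdname accessors
#' @export
setGeneric("smoothedValues", function(object) standardGeneric("smoothedValues"))
#' @rdname accessors
#' @export
setMethod("smoothedValues", "BoundaryResult", function(object) object@smoothed)

#' @rdname accessors
#' @export
setGeneric("recoveryAmplitude", function(object) standardGeneric("recoveryAmplitude"))
#' @rdname accessors
#' @export
setMethod("recoveryAmplitude", "FrapFit", function(object) object@a)

#' @rdname accessors
#' @export
setGeneric("recoveryRate", function(object) standardGeneric("recoveryRate"))
#' @rdname accessors
#' @export
setMethod("recoveryRate", "FrapFit", function(object) object@b)

#' @rdname accessors
#' @export
setGeneric("traceTimes", function(object) standardGeneric("traceTimes"))
#' @rdname accessors
#' @export
setMethod("traceTimes", "FrapTrace", function(object) object@times)

#' @rdname accessors
#' @export
setGeneric("traceValues", function(object) standardGeneric("traceValues"))
#' @rdname accessors
#' @export
setMethod("traceValues", "FrapTrace", function(object) object@values)

#' @rdname accessors
#' @export
setGeneric("initiationTimeOf", function(object) standardGeneric("initiationTimeOf"))
#' @rdname accessors
#' @export
setMethod("initiationTimeOf", "FurrowSeries", function(object) object@initiationTime)

#' @rdname accessors
#' @export
setGeneric("isCompleted", function(object) standardGeneric("isCompleted"))
#' @rdname accessors
#' @export
setMethod("isCompleted", "FurrowSeries", function(object) object@completed)

## ---- show methods ----

setMethod("show", "ImageFrame", function(object) {
  d <- dim(object@intensity)
  cat(sprintf("ImageFrame %d x %d px (%.3g um/px), t = %g s, frame %d\n",
              d[1], d[2], object@pixelSize, object@time, object@frameIndex))
})

setMethod("show", "CortexContour", function(object) {
  cat(sprintf("CortexContour: %d points, perimeter %.2f um, %s\n",
              nrow(object@points), object@perimeter,
              if (is.na(object@anchorIndex)) "unanchored"
              else "anchored at anterior (s = 0)"))
})

setMethod("show", "AccumulationProfile", function(object) {
  cat(sprintf(
    "AccumulationProfile: %d positions, t = %g s, a in [%.3f, %.3f]\n",
    length(object@s), object@time, min(object@a), max(object@a)))
})

setMethod("show", "EmbryoTimeSeries", function(object) {
  cat(sprintf("EmbryoTimeSeries: %d frames, time zero = %s onset\n",
              nrow(object@data), object@event))
  print(utils::head(object@data, 4))
  if (nrow(object@data) > 4) cat("...\n")
})

setMethod("show", "BoundaryResult", function(object) {
  cat(sprintf(
    paste0("BoundaryResult at t = %g s: anterior-60%% mean %.3f, ",
           "threshold %.3f, boundary length %.3f\n"),
    object@timepoint, object@anterior60Mean, object@threshold,
    object@boundaryLength))
})

setMethod("show", "FrapFit", function(object) {
  cat(sprintf(
    "FrapFit: a = %.4f, b = %.4f 1/s, t1/2 = %.3f s, mobile fraction %.3f\n",
    object@a, object@b, object@tHalf, object@mobileFraction))
})

setMethod("show", "FurrowSeries", function(object) {
  cat(sprintf(
    "FurrowSeries: %d frames, initiation %s, %s\n",
    length(object@times),
    if (is.na(object@initiationTime)) "not reached"
    else sprintf("at %.1f s", object@initiationTime),
    if (object@completed) "completed" else "failed"))
})
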