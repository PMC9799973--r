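#' @include AllClasses.R utils-geometry.R
NULL

#' Centred rolling average
#'
#' Mean over each full centred window; endpoints without a full window are
#' omitted, so the result is \code{period - 1} elements shorter.
#'
#' @param x numeric series.
#' @param period odd window length (default 3).
#' @return numeric vector of window means.
#' @export
rollingAverage <- function(x, period = 3) {
  if (period %% 2 != 1) stop("period must be odd")
  if (length(x) < period) stop("series shorter than the window")
  vapply(seq_len(length(x) - period + 1L),
         function(i) mean(x[i:(i + period - 1L)]), numeric(1))
}

#' Build a furrow-width series
#'
#' Normalizes tip-to-tip widths to the maximum embryo width, attaches the
#' period-3 centred rolling average (NA-padded at the ends), the
#' interpolated initiation time, and the completion call.
#'
#' @param times seconds relative to NEBD or anaphase onset.
#' @param width tip-to-tip furrow width in micrometres.
#' @param maxWidth maximum embryo width (um); defaults to max(width).
#' @param initiationThreshold normalized width defining initiation.
#' @param completionTol normalized width below which ingression counts as
#'   complete.
#' @return a [FurrowSeries-class].
#' @export
furrowSeries <- function(times, width, maxWidth = max(width),
                         initiationThreshold = 0.9, completionTol = 0.02) {
  stopifnot(length(times) == length(width), maxWidth > 0)
  wn <- pmin(width / maxWidth, 1)
  sm <- rep(NA_real_, length(wn))
  if (length(wn) >= 3) sm[2:(length(wn) - 1)] <- rollingAverage(wn, 3)
  new("FurrowSeries", times = as.numeric(times), width = as.numeric(width),
      widthNorm = wn, smoothed = sm,
      initiationTime = initiationTime(times, wn, initiationThreshold),
      completed = min(wn) <= completionTol)
}

#' Interpolated furrow initiation time
#'
#' Earliest time the normalized width crosses below the threshold, with
#' linear interpolation between the bracketing frames to remove sampling
#' quantization. An embryo that never crosses is reported as not
#' initiated (NA), not as an error.
#'
#' @param times seconds relative to anaphase onset.
#' @param widthNorm normalized widths in [0, 1].
#' @param threshold crossing threshold (default 0.9, i.e. 90% width).
#' @return interpolated crossing time in seconds, or NA.
#' @export
initiationTime <- function(times, widthNorm, threshold = 0.9) {
  i <- which(widthNorm <= threshold)[1]
  if (is.na(i)) return(NA_real_)
  if (i == 1L) return(times[1])
  f <- (widthNorm[i - 1] - threshold) / (widthNorm[i - 1] - widthNorm[i])
  times[i - 1] + f * (times[i] - times[i - 1])
}

#' Completion call for a furrow series
#'
#' @param series a [FurrowSeries-class].
#' @return "completed" if the minimum normalized width reached (near)
#'   zero, otherwise "failed".
#' @export
completionCall <- function(series) {
  if (isCompleted(series)) "completed" else "failed"
}

#' Fraction of embryos whose furrow failed to complete
#'
#' @param seriesList list of [FurrowSeries-class].
#' @return fraction in [0, 1] of series that did not reach zero width.
#' @export
failureFraction <- function(seriesList) {
  mean(!vapply(seriesList, isCompleted, logical(1)))
}

#' Centrosome-to-cortex distance with local accumulation
#'
#' Minimum Euclidean distance from an interior point (a centrosome) to the
#' cortex contour, by segment-wise projection, in micrometres. If a
#' profile is supplied (conventionally the maximal-asymmetry-frame
#' profile), the accumulation at the nearest cortical position is
#' attached.
#'
#' @param point c(row, col) centrosome position in pixels.
#' @param contour an anchored [CortexContour-class].
#' @param profile optional [AccumulationProfile-class].
#' @return list with \code{distanceUm}, \code{s} (nearest cortical
#'   position), \code{foot} (row, col), and \code{localAccumulation} (NA
#'   without a profile).
#' @export
centrosomeCortexDistance <- function(point, contour, profile = NULL) {
  pts <- contourPoints(contour)
  if (!pointInPolygon(point, pts))
    stop("centrosome position lies outside the cortex contour")
  hit <- nearestOnContour(point, pts, arcFraction(contour))
  acc <- if (is.null(profile)) NA_real_
         else periodicInterp(profile@s, profile@a, hit$s)
  list(distanceUm = hit$distance * pixelSize(contour), s = hit$s,
       foot = hit$foot, localAccumulation = acc)
}

#' Condition-average accumulation profile
#'
#' Pointwise mean across embryos of their smoothed maximal-asymmetry
#' profiles, as a function of cortical position with 0 the anterior and
#' 0.5 the posterior. Profiles on different grids are resampled (with
#' periodic interpolation) to the grid of the first profile, with a
#' warning.
#'
#' @param profiles list of numeric profiles, each with attribute
#'   \code{"s"} (as returned by [smoothProfile()]).
#' @return data.frame with columns \code{s} and \code{mean}.
#' @export
conditionMeanProfile <- function(profiles) {
  stopifnot(length(profiles) >= 1)
  sRef <- attr(profiles[[1]], "s")
  vals <- vapply(profiles, function(p) {
    sp <- attr(p, "s")
    if (length(sp) == length(sRef) && all(abs(sp - sRef) < 1e-9))
      as.numeric(p)
    else {
      warning("profile grids differ; resampling to the common grid")
      periodicInterp(sp, as.numeric(p), sRef)
    }
  }, numeric(length(sRef)))
  data.frame(s = sRef, mean = rowMeans(vals))
}
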