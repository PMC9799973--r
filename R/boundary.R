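#' @include AllClasses.R accumulation.R
NULL

#' Smooth an accumulation profile with a periodic penalized spline
#'
#' Fits a cyclic cubic regression spline of a on s (periodic over the
#' cortex) by penalized regression, with the smoothing parameter chosen by
#' generalized cross-validation unless fixed. If the spline fit fails the
#' function falls back to a periodic moving average with a window of 5% of
#' the perimeter and flags the result.
#'
#' @param profile an [AccumulationProfile-class] with >= 50 positions.
#' @param basisDim cyclic spline basis dimension.
#' @param sp fixed smoothing parameter, or NULL for GCV.
#' @return numeric fitted values on the sampled grid, with attributes
#'   \code{"s"} and \code{"method"} ("gam" or "moving-average").
#' @export
smoothProfile <- function(profile, basisDim = 20, sp = NULL) {
  s <- profile@s; a <- profile@a
  if (length(s) < 50) stop("need at least 50 positions to smooth")
  df <- data.frame(s = s, a = a)
  fit <- tryCatch({
    g <- mgcv::gam(a ~ s(s, bs = "cc", k = basisDim),
                   knots = list(s = c(0, 1)), data = df,
                   sp = if (is.null(sp)) NULL else sp, method = "GCV.Cp")
    as.numeric(stats::predict(g, newdata = df))
  }, error = function(e) NULL)
  if (is.null(fit)) {
    warning("spline fit failed; falling back to periodic moving average")
    win <- max(3L, round(0.05 * length(a)))
    if (win %% 2 == 0) win <- win + 1L
    half <- (win - 1L) / 2L
    n <- length(a)
    fit <- vapply(seq_len(n), function(i)
      mean(a[((i - 1L + (-half:half)) %% n) + 1L]), numeric(1))
    method <- "moving-average"
  } else method <- "gam"
  attr(fit, "s") <- s
  attr(fit, "method") <- method
  fit
}

#' Frame of maximal anterior:posterior asymmetry
#'
#' @param series an [EmbryoTimeSeries-class].
#' @return 1-based frame index of the maximum A:P ratio; the earliest
#'   frame wins ties.
#' @export
maxAsymmetryTimepoint <- function(series) {
  ap <- seriesData(series)$apRatio
  ok <- is.finite(ap)
  if (!any(ok)) stop("no frame has a defined A:P ratio")
  which(ok & ap == max(ap[ok]))[1]
}

#' Boundary length: fraction of the cortex below threshold
#'
#' The mean of the smoothed accumulation over the anterior 60% of the
#' cortex defines the reference level; the threshold is
#' \code{thresholdFactor} (default 0.85) times that mean, and the boundary
#' length is the fraction of all grid positions whose smoothed value falls
#' below the threshold. All positions are counted, without a contiguity
#' requirement.
#'
#' @param smoothed smoothed accumulation values on a uniform s-grid (from
#'   [smoothProfile()]), with positions in attribute \code{"s"} or given
#'   via \code{s}.
#' @param s grid positions; defaults to \code{attr(smoothed, "s")}.
#' @param regions region definitions from [regionSpec()].
#' @param thresholdFactor fraction of the anterior-60% mean.
#' @param timepoint time (s) the profile belongs to, carried through.
#' @return a [BoundaryResult-class].
#' @export
boundaryLength <- function(smoothed, s = attr(smoothed, "s"),
                           regions = regionSpec(), thresholdFactor = 0.85,
                           timepoint = NA_real_) {
  if (is.null(s)) stop("grid positions s are required")
  hit <- inRegion(s, regions$anterior60)
  ant60 <- mean(smoothed[hit])
  thr <- thresholdFactor * ant60
  new("BoundaryResult", timepoint = timepoint, anterior60Mean = ant60,
      threshold = thr, boundaryLength = mean(smoothed < thr),
      smoothed = as.numeric(smoothed), s = as.numeric(s))
}
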