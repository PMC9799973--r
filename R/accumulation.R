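#' @include AllClasses.R utils-geometry.R
NULL

#' Cortical region definitions in perimeter coordinates
#'
#' Regions are perimeter fractions centred on the poles, half-open in s to
#' avoid double-counting the wrap point: the anterior 20% is
#' [0.9, 1) U [0, 0.1), the posterior 20% is [0.4, 0.6), and the anterior
#' 60% (used for the boundary threshold) is [0.7, 1) U [0, 0.3).
#'
#' @return a named list of regions, each a list of c(lo, hi) s-intervals.
#' @export
regionSpec <- function() {
  list(anterior20 = list(c(0.9, 1), c(0, 0.1)),
       posterior20 = list(c(0.4, 0.6)),
       anterior60 = list(c(0.7, 1), c(0, 0.3)))
}

#' Which positions fall in a region
#'
#' @param s positions in [0, 1).
#' @param region a list of c(lo, hi) half-open s-intervals.
#' @return logical vector.
#' @export
inRegion <- function(s, region) {
  hit <- rep(FALSE, length(s))
  for (iv in region) hit <- hit | (s >= iv[1] & s < iv[2])
  hit
}

#' Normalize a raw cortical profile to accumulation units
#'
#' a(s) = (raw(s) - background) / (cytoplasm - background). A value of 1
#' means the cortical signal equals the cytoplasm; the statistic is
#' invariant under positive affine transforms applied jointly to raw,
#' background and cytoplasm.
#'
#' @param raw raw per-position cortical intensities (from
#'   [maxDepthProfile()]), with positions in attribute \code{"s"} or
#'   supplied via \code{s}.
#' @param background background intensity.
#' @param cytoplasm cytoplasm intensity; must exceed the background.
#' @param s positions in [0, 1); defaults to \code{attr(raw, "s")}.
#' @param time frame time in seconds.
#' @return an [AccumulationProfile-class].
#' @export
normalizeProfile <- function(raw, background, cytoplasm,
                             s = attr(raw, "s"), time = 0) {
  if (cytoplasm <= background)
    stop("cytoplasm must exceed background; normalization is degenerate")
  if (is.null(s)) stop("positions s are required")
  new("AccumulationProfile", s = as.numeric(s),
      a = (as.numeric(raw) - background) / (cytoplasm - background),
      time = time, background = background, cytoplasm = cytoplasm)
}

#' Mean accumulation over a cortical region
#'
#' @param profile an [AccumulationProfile-class].
#' @param region a list of s-intervals (see [regionSpec()]).
#' @return unweighted mean of a(s) over sampled positions in the region.
#' @export
regionalMean <- function(profile, region) {
  hit <- inRegion(profile@s, region)
  if (!any(hit)) stop("region contains no sampled positions")
  mean(profile@a[hit])
}

#' Build the per-embryo accumulation time series
#'
#' Per frame: anterior and posterior 20% mean accumulation, their ratio
#' (A:P ratio; NA when the posterior mean is not positive), the
#' whole-cortex mean, and the perimeter normalized to the embryo maximum.
#'
#' @param profiles list of [AccumulationProfile-class], one per frame.
#' @param contours list of matching [CortexContour-class] objects.
#' @param regions region definitions from [regionSpec()].
#' @param event name of the time-zero event.
#' @return an [EmbryoTimeSeries-class].
#' @export
buildTimeSeries <- function(profiles, contours, regions = regionSpec(),
                            event = "anaphase") {
  stopifnot(length(profiles) >= 1, length(profiles) == length(contours))
  perNorm <- normalizedPerimeter(contours)
  rows <- lapply(seq_along(profiles), function(i) {
    p <- profiles[[i]]
    ant <- regionalMean(p, regions$anterior20)
    post <- regionalMean(p, regions$posterior20)
    data.frame(time = p@time, anteriorMean = ant, posteriorMean = post,
               apRatio = if (post > 0) ant / post else NA_real_,
               cortexMean = mean(p@a), perimeterNorm = perNorm[i])
  })
  new("EmbryoTimeSeries", data = do.call(rbind, rows), event = event)
}

#' Background-subtracted mean embryo intensity
#'
#' Mean pixel intensity over the embryo mask minus the background;
#' measured at NEBD it serves as the per-embryo expression level for
#' depletion normalization against a control-group mean.
#'
#' @param frame an [ImageFrame-class] (the NEBD frame).
#' @param mask logical embryo mask.
#' @param background background intensity.
#' @return background-subtracted mean intensity in camera units.
#' @export
totalEmbryoIntensity <- function(frame, mask, background) {
  if (!any(mask)) stop("embryo mask is empty")
  mean(intensity(frame)[mask]) - background
}

#' Per-timepoint condition mean with 95% confidence interval
#'
#' Aligns embryo series on the shared event clock and returns, per
#' timepoint, the across-embryo mean and the t-based 95% CI
#' (mean +/- t(0.975, n-1) sd / sqrt(n)); the CI is NA where fewer than
#' two embryos contribute.
#'
#' @param seriesList list of [EmbryoTimeSeries-class].
#' @param variable column to aggregate (default \code{"apRatio"}).
#' @return data.frame with columns time, mean, lo, hi, n.
#' @export
aggregateCondition <- function(seriesList, variable = "apRatio") {
  frames <- lapply(seriesList, function(x) seriesData(x)[, c("time", variable)])
  all <- do.call(rbind, frames)
  names(all) <- c("time", "value")
  all <- all[is.finite(all$value), ]
  out <- lapply(sort(unique(all$time)), function(tt) {
    v <- all$value[all$time == tt]
    n <- length(v)
    half <- if (n >= 2) stats::qt(0.975, n - 1) * stats::sd(v) / sqrt(n)
            else NA_real_
    data.frame(time = tt, mean = mean(v), lo = mean(v) - half,
               hi = mean(v) + half, n = n)
  })
  do.call(rbind, out)
}

#' Welch test between two conditions at one timepoint
#'
#' Two-sample Welch t-test with the conventional significance key:
#' ns (p > 0.05), * (p < 0.05), ** (p < 0.01), *** (p < 0.001),
#' **** (p < 0.0001). When both groups have zero variance and equal means
#' the test is undefined and reported as such.
#'
#' @param groupA,groupB per-embryo values at one timepoint (each n >= 2).
#' @return list with elements \code{p} (NA if undefined) and \code{label}.
#' @export
perTimepointTest <- function(groupA, groupB) {
  stopifnot(length(groupA) >= 2, length(groupB) >= 2)
  if (stats::sd(groupA) == 0 && stats::sd(groupB) == 0) {
    if (mean(groupA) == mean(groupB))
      return(list(p = NA_real_, label = "undefined"))
    return(list(p = 0, label = starLabel(0)))
  }
  p <- stats::t.test(groupA, groupB, var.equal = FALSE)$p.value
  list(p = p, label = starLabel(p))
}

#' Significance star label for a p-value
#'
#' @param p a p-value.
#' @return one of "ns", "*", "**", "***", "****".
#' @export
starLabel <- function(p) {
  if (is.na(p)) return("undefined")
  if (p < 1e-4) "****" else if (p < 1e-3) "***" else if (p < 0.01) "**"
  else if (p < 0.05) "*" else "ns"
}
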