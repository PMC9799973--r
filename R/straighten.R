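#' @include AllClasses.R utils-geometry.R
NULL

#' Straighten the cortex into an intensity band
#'
#' At each contour point the image is sampled by bilinear interpolation
#' along the outward unit normal, \code{bandWidth} samples at 1 px steps
#' centred on the contour (half inward, half outward). Normals come from
#' tangents smoothed by central differences over +/-2 points, which
#' suppresses pixel-staircase jitter. Samples falling outside the frame
#' are clamped to the edge and the band is flagged.
#'
#' @param frame an [ImageFrame-class].
#' @param contour an anchored [CortexContour-class].
#' @param bandWidth total band width in pixels (50 by convention).
#' @return a [CortexBand-class] (rows = depth, columns = position).
#' @export
extractBand <- function(frame, contour, bandWidth = 50) {
  pts <- contour@points
  n <- nrow(pts)
  img <- intensity(frame)
  i2 <- function(k) ((seq_len(n) - 1L + k) %% n) + 1L
  tang <- pts[i2(2L), ] - pts[i2(-2L), ]
  tang <- tang / sqrt(rowSums(tang^2))
  # rotate tangent 90 degrees, then point each normal away from the centroid
  norm <- cbind(tang[, 2], -tang[, 1])
  centroid <- colMeans(pts)
  outward <- (pts[, 1] - centroid[1]) * norm[, 1] +
    (pts[, 2] - centroid[2]) * norm[, 2]
  norm <- norm * sign(ifelse(outward == 0, 1, outward))

  offsets <- seq(-(bandWidth - 1) / 2, (bandWidth - 1) / 2, by = 1)
  rows <- outer(offsets, norm[, 1]) + matrix(pts[, 1], bandWidth, n,
                                             byrow = TRUE)
  cols <- outer(offsets, norm[, 2]) + matrix(pts[, 2], bandWidth, n,
                                             byrow = TRUE)
  vals <- bilinearSample(img, as.vector(rows), as.vector(cols))
  clamped <- attr(vals, "clamped")
  if (clamped)
    warning("band extends outside the frame; samples clamped to the edge")
  new("CortexBand", values = matrix(vals, bandWidth, n), s = contour@s,
      offsets = offsets, clamped = clamped)
}

#' Perpendicular-maximum cortical intensity profile
#'
#' Emulates recording the maximum of a 3 px-wide line drawn perpendicular
#' to the cortex: depth profiles are averaged over \code{lateralWidth}
#' neighbouring positions (periodic wrap along the cortex), then the
#' maximum over the full band depth is taken at each position.
#'
#' @param band a [CortexBand-class].
#' @param lateralWidth odd number of neighbouring positions to average.
#' @return numeric raw cortical intensity per position, with the positions
#'   attached as attribute \code{"s"}.
#' @export
maxDepthProfile <- function(band, lateralWidth = 3) {
  if (lateralWidth %% 2 != 1) stop("lateralWidth must be odd")
  v <- band@values
  n <- ncol(v)
  half <- (lateralWidth - 1L) / 2L
  sm <- matrix(0, nrow(v), n)
  for (k in -half:half)
    sm <- sm + v[, ((seq_len(n) - 1L + k) %% n) + 1L, drop = FALSE]
  sm <- sm / lateralWidth
  out <- apply(sm, 2, max)
  attr(out, "s") <- band@s
  out
}
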