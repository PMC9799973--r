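#' @include AllClasses.R utils-geometry.R
NULL

#' Segment the embryo in a frame
#'
#' Gaussian blur on a copy of the frame, automatic intensity threshold on
#' the blurred copy, retention of the largest connected component, and
#' hole filling. Two refinements keep the boundary placement accurate and
#' uniform: the Otsu threshold is polished by ISODATA iteration (midpoint
#' between class means, so the mask edge lands at the half-intensity point
#' of the boundary step), and a second pass re-thresholds with the bright
#' cortical rim clipped at the estimated cytoplasm level, so the boundary
#' offset does not vary with local rim brightness. The threshold is
#' computed on the min-max-normalized image, making the mask invariant
#' under positive affine rescaling of the intensities.
#'
#' @param frame an [ImageFrame-class].
#' @param blurSigma Gaussian blur sigma in pixels.
#' @param minArea smallest acceptable embryo area in px^2.
#' @return a logical matrix, TRUE inside the embryo.
#' @export
segmentEmbryo <- function(frame, blurSigma = 2, minArea = 500) {
  img <- intensity(frame)
  rng <- range(img)
  if (diff(rng) <= 0)
    stop(noEmbryoError("frame has no intensity contrast"))
  norm <- (img - rng[1]) / diff(rng)
  mask <- thresholdMask(norm, blurSigma, minArea)
  # second pass: clip at the cytoplasm level so the rim does not pull the
  # boundary outward where the cortex is bright
  interior <- tryCatch(
    EBImage::erode(mask + 0, EBImage::makeBrush(17L, "disc")) > 0,
    error = function(e) NULL)
  if (!is.null(interior) && sum(interior) >= minArea) {
    cytoLevel <- mean(norm[interior])
    mask <- thresholdMask(pmin(norm, cytoLevel), blurSigma, minArea)
  }
  mask
}

thresholdMask <- function(norm, blurSigma, minArea) {
  blurred <- EBImage::gblur(norm, sigma = blurSigma)
  thr <- EBImage::otsu(blurred, range = c(0, 1))
  for (i in 1:8) {
    lo <- blurred[blurred <= thr]; hi <- blurred[blurred > thr]
    if (!length(lo) || !length(hi)) break
    thr <- (mean(lo) + mean(hi)) / 2
  }
  lab <- EBImage::bwlabel(blurred > thr)
  sizes <- tabulate(lab[lab > 0])
  if (!length(sizes) || max(sizes) < minArea)
    stop(noEmbryoError(sprintf(
      "no connected component of at least %d px^2 found", minArea)))
  filled <- EBImage::fillHull(lab == which.max(sizes))
  matrix(as.logical(filled), nrow(norm), ncol(norm))
}

noEmbryoError <- function(msg) {
  structure(class = c("NoEmbryoFound", "error", "condition"),
            list(message = msg, call = sys.call(-1)))
}

#' Estimate the background intensity
#'
#' Mean intensity over pixels outside the embryo mask dilated by a safety
#' margin, keeping cortex bleed-through out of the estimate.
#'
#' @param frame an [ImageFrame-class].
#' @param mask logical embryo mask.
#' @param margin dilation margin in pixels.
#' @return background intensity in camera units.
#' @export
estimateBackground <- function(frame, mask, margin = 10) {
  brush <- EBImage::makeBrush(2L * as.integer(margin) + 1L, shape = "disc")
  dil <- EBImage::dilate(mask + 0, brush) > 0
  ext <- !dil
  if (!any(ext)) stop("no exterior pixels left after dilating the mask")
  mean(intensity(frame)[ext])
}

#' Estimate the cytoplasm intensity
#'
#' Mean intensity over the embryo mask eroded by \code{cortexMargin},
#' excluding the bright cortical rim. The default margin is twice a
#' typical 4 px cortical ring width.
#'
#' @param frame an [ImageFrame-class].
#' @param mask logical embryo mask.
#' @param cortexMargin erosion margin in pixels.
#' @return cytoplasm intensity in camera units.
#' @export
estimateCytoplasm <- function(frame, mask, cortexMargin = 8) {
  brush <- EBImage::makeBrush(2L * as.integer(cortexMargin) + 1L,
                              shape = "disc")
  er <- EBImage::erode(mask + 0, brush) > 0
  if (!any(er))
    stop("eroded mask is empty; cortexMargin too large for this embryo")
  mean(intensity(frame)[er])
}

#' Extract the sub-pixel cortex contour from a mask
#'
#' The mask is lightly blurred and its 0.5 iso-contour is taken as the
#' boundary, giving a sub-pixel polyline free of pixel staircase; the
#' polyline is resampled to ~1 px arc-length spacing. The contour is
#' returned unanchored (s measured from an arbitrary start point).
#'
#' @param mask logical embryo mask with a single filled component.
#' @param pixelSize micrometres per pixel.
#' @return an unanchored [CortexContour-class].
#' @export
extractContour <- function(mask, pixelSize = 1) {
  lab <- EBImage::bwlabel(mask + 0)
  if (max(lab) != 1L)
    stop(sprintf("mask must contain exactly one component, found %d",
                 max(lab)))
  sm <- EBImage::gblur(mask + 0, sigma = 1)
  cl <- grDevices::contourLines(x = seq_len(nrow(mask)),
                                y = seq_len(ncol(mask)),
                                z = sm, levels = 0.5)
  if (!length(cl)) stop("no iso-contour found at level 0.5")
  lens <- vapply(cl, function(ct)
    polylineLength(cbind(ct$x, ct$y), closed = TRUE), numeric(1))
  ct <- cl[[which.max(lens)]]
  pts <- cbind(row = ct$x, col = ct$y)
  if (nrow(pts) > 2 && all(abs(pts[1, ] - pts[nrow(pts), ]) < 1e-9))
    pts <- pts[-nrow(pts), , drop = FALSE]
  pts <- resampleClosed(pts, spacing = 1)
  per <- polylineLength(pts, closed = TRUE)
  cum <- cumsum(c(0, sqrt(rowSums(diff(pts)^2))))
  new("CortexContour", points = pts, s = cum / per, anchorIndex = NA_integer_,
      pixelSize = pixelSize, perimeter = per * pixelSize)
}

#' Anchor a contour at the anterior pole and orient it clockwise
#'
#' Fits the long axis by principal components of the contour points, picks
#' the axis end nearer the anterior hint, anchors s = 0 at the contour
#' point there, and flips the traversal if needed so that s increases
#' clockwise in image coordinates. For an ellipse the posterior pole then
#' maps to s = 0.5. Idempotent.
#'
#' @param contour a [CortexContour-class].
#' @param anteriorHint c(row, col) near the anterior pole.
#' @return an anchored, clockwise [CortexContour-class].
#' @export
anchorContour <- function(contour, anteriorHint) {
  pts <- contour@points
  centroid <- colMeans(pts)
  if (!is.na(contour@anchorIndex)) {
    # already anchored: a hint on the same side makes this a no-op; a hint
    # at the opposite pole triggers re-anchoring
    a0 <- pts[contour@anchorIndex, ]
    if (sum((anteriorHint - centroid) * (a0 - centroid)) > 0)
      return(contour)
  }
  ev <- eigen(stats::cov(pts), symmetric = TRUE)
  axis <- ev$vectors[, 1]                      # long-axis direction (row, col)
  proj <- sum((anteriorHint - centroid) * axis)
  scale <- sqrt(ev$values[1])
  if (abs(proj) < 1e-3 * scale)
    stop(paste("anterior hint is equidistant from both poles;",
               "provide a hint closer to one end of the long axis"))
  axis <- axis * sign(proj)

  # clockwise in image coordinates (row down) <=> positive signed area
  if (signedArea(pts) < 0) pts <- pts[rev(seq_len(nrow(pts))), , drop = FALSE]

  # sub-pixel anchor: exact intersection of the long axis with the contour
  # on the anterior side, interpolated on the crossing segment
  perp <- c(-axis[2], axis[1])
  u <- (pts[, 1] - centroid[1]) * axis[1] + (pts[, 2] - centroid[2]) * axis[2]
  v <- (pts[, 1] - centroid[1]) * perp[1] + (pts[, 2] - centroid[2]) * perp[2]
  n <- nrow(pts)
  nxt <- c(2:n, 1L)
  onAxis <- which(abs(v) < 1e-9 & u > 0)
  if (length(onAxis)) {                     # already anchored here: reuse
    anchor <- onAxis[which.max(u[onAxis])]
    pts <- pts[c(anchor:n, seq_len(anchor - 1L)), , drop = FALSE]
  } else {
    cross <- which(v * v[nxt] < 0 & (u + u[nxt]) > 0)
    if (!length(cross)) cross <- which(v * v[nxt] < 0)
    f <- v[cross] / (v[cross] - v[nxt][cross])
    uCross <- u[cross] + f * (u[nxt][cross] - u[cross])
    k <- cross[which.max(uCross)]
    fk <- v[k] / (v[k] - v[nxt[k]])
    pStar <- pts[k, ] + fk * (pts[nxt[k], ] - pts[k, ])
    idx <- if (k == n) seq_len(n) else c((k + 1L):n, seq_len(k))
    pts <- rbind(pStar, pts[idx, , drop = FALSE])
    # drop the old vertex if the inserted anchor duplicates it
    if (sqrt(sum((pts[1, ] - pts[2, ])^2)) < 1e-9)
      pts <- pts[-2, , drop = FALSE]
  }
  per <- polylineLength(pts, closed = TRUE)
  cum <- cumsum(c(0, sqrt(rowSums(diff(pts)^2))))
  new("CortexContour", points = pts, s = cum / per, anchorIndex = 1L,
      pixelSize = contour@pixelSize, perimeter = per * contour@pixelSize)
}

#' Perimeter normalized to the per-embryo maximum
#'
#' @param contours list of [CortexContour-class], one per frame.
#' @return numeric vector perimeter(t) / max(perimeter), maximum exactly 1.
#' @export
normalizedPerimeter <- function(contours) {
  per <- vapply(contours, perimeter, numeric(1))
  per / max(per)
}
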