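# Low-level geometry helpers shared by the generator, segmentation and
# straightening code. All coordinates are (row, col) with origin top-left;
# in (col, row) = (x, y-down) coordinates an increasing ellipse parameter
# runs visually clockwise.

# Bilinear interpolation of `img` at fractional (rows, cols); coordinates
# outside the grid are clamped to the frame edge. Returns the values plus
# an attribute saying whether any clamping happened.
bilinearSample <- function(img, rows, cols) {
  nr <- nrow(img); nc <- ncol(img)
  clamped <- any(rows < 1 | rows > nr | cols < 1 | cols > nc)
  r <- pmin(pmax(rows, 1), nr)
  c <- pmin(pmax(cols, 1), nc)
  r0 <- pmin(floor(r), nr - 1L); c0 <- pmin(floor(c), nc - 1L)
  fr <- r - r0; fc <- c - c0
  v00 <- img[cbind(r0, c0)]
  v10 <- img[cbind(r0 + 1, c0)]
  v01 <- img[cbind(r0, c0 + 1)]
  v11 <- img[cbind(r0 + 1, c0 + 1)]
  out <- v00 * (1 - fr) * (1 - fc) + v10 * fr * (1 - fc) +
    v01 * (1 - fr) * fc + v11 * fr * fc
  attr(out, "clamped") <- clamped
  out
}

# Length of a polyline (n x 2 matrix); closed connects last to first.
polylineLength <- function(points, closed = TRUE) {
  p <- points
  if (closed) p <- rbind(p, p[1, , drop = FALSE])
  sum(sqrt(rowSums(diff(p)^2)))
}

# Signed polygon area with x = col, y = row. Positive values correspond to
# visually clockwise traversal when the image is displayed row-down.
signedArea <- function(points) {
  x <- points[, 2]; y <- points[, 1]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

# Resample a closed polyline to (approximately) uniform spacing; returns a
# matrix whose points cover [0, L) half-open, so the first input point is
# kept and the closing point is not duplicated.
resampleClosed <- function(points, spacing = 1) {
  p <- rbind(points, points[1, , drop = FALSE])
  seg <- sqrt(rowSums(diff(p)^2))
  keep <- c(TRUE, seg > 1e-12)        # drop exact duplicates
  p <- p[keep, , drop = FALSE]
  if (nrow(p) < 4) stop("degenerate polyline")
  seg <- sqrt(rowSums(diff(p)^2))
  cum <- c(0, cumsum(seg))
  L <- cum[length(cum)]
  n <- max(8L, round(L / spacing))
  target <- seq(0, L, length.out = n + 1L)[-(n + 1L)]
  cbind(stats::approx(cum, p[, 1], xout = target)$y,
        stats::approx(cum, p[, 2], xout = target)$y)
}

# Ray-casting point-in-polygon test for a closed polygon (n x 2, row/col).
pointInPolygon <- function(point, points) {
  x <- points[, 2]; y <- points[, 1]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  px <- point[2]; py <- point[1]
  crosses <- ((y > py) != (yn > py)) &
    (px < (xn - x) * (py - y) / (yn - y) + x)
  sum(crosses) %% 2L == 1L
}

# Minimum distance from a point to a closed polyline by segment-wise
# projection; returns the distance (px), the foot point, and the arc-length
# fraction s of the foot point given the per-vertex s values.
nearestOnContour <- function(point, points, s) {
  p1 <- points
  p2 <- points[c(2:nrow(points), 1), , drop = FALSE]
  seg <- p2 - p1
  len2 <- rowSums(seg^2)
  d <- cbind(point[1] - p1[, 1], point[2] - p1[, 2])
  t <- (d[, 1] * seg[, 1] + d[, 2] * seg[, 2]) / pmax(len2, 1e-12)
  t <- pmin(pmax(t, 0), 1)
  foot <- p1 + seg * t
  dist <- sqrt((point[1] - foot[, 1])^2 + (point[2] - foot[, 2])^2)
  i <- which.min(dist)
  s2 <- c(s[-1], 1)                   # wrap: closing segment ends at s = 1
  sFoot <- (s[i] + t[i] * (s2[i] - s[i])) %% 1
  list(distance = dist[i], foot = foot[i, ], s = sFoot)
}

# Evaluate a periodic profile (values on grid sGrid in [0,1)) at sOut by
# linear interpolation with wrap-around.
periodicInterp <- function(sGrid, values, sOut) {
  ord <- order(sGrid)
  sg <- sGrid[ord]; v <- values[ord]
  sgExt <- c(sg[length(sg)] - 1, sg, sg[1] + 1)
  vExt <- c(v[length(v)], v, v[1])
  stats::approx(sgExt, vExt, xout = sOut %% 1)$y
}

# Run code with a locally seeded RNG, restoring the caller's RNG state.
withLocalSeed <- function(seed, code) {
  hadSeed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (hadSeed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (hadSeed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(code)
}
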