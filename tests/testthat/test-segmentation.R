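test_that("background and cytoplasm estimates recover constructed levels", {
  img <- matrix(10, 120, 120)
  img[40:80, 40:80] <- 110
  fr <- new("ImageFrame", intensity = img, pixelSize = 1, time = 0,
            frameIndex = 1L)
  mask <- matrix(FALSE, 120, 120); mask[40:80, 40:80] <- TRUE
  expect_equal(estimateBackground(fr, mask), 10)
  expect_equal(estimateCytoplasm(fr, mask, cortexMargin = 5), 110)

  img2 <- img
  ext <- which(!mask)
  img2[ext[seq(1, length(ext), 2)]] <- 8
  img2[ext[seq(2, length(ext), 2)]] <- 12
  fr2 <- new("ImageFrame", intensity = img2, pixelSize = 1, time = 0,
             frameIndex = 1L)
  # mean over a half-8 half-12 exterior (up to the one-pixel parity split)
  expect_equal(estimateBackground(fr2, mask), 10, tolerance = 1e-3)

  expect_error(estimateCytoplasm(fr, mask, cortexMargin = 40), "empty")
})

test_that("estimates hold on noisy synthetic embryos despite the rim", {
  spec <- syntheticEmbryoSpec(backgroundLevel = 100, cytoplasmLevel = 200,
                              noiseModel = list(type = "gaussian", sd = 5),
                              rngSeed = 5L)
  truth <- accumulationGroundTruth(baseline = 2, anteriorGain = 0,
                                   depletionDepth = 0)
  fr <- renderFrame(spec, truth, 1)
  mask <- segmentEmbryo(fr)
  expect_gt(sum(!mask), 1e4)
  expect_lt(abs(estimateBackground(fr, mask) - 100), 0.5)
  expect_lt(abs(estimateCytoplasm(fr, mask) - 200), 1)
})

test_that("segmentation finds the embryo and only the embryo", {
  spec <- studySpec(cortexWidth = 0.5)
  flat <- accumulationGroundTruth(baseline = 1, anteriorGain = 0,
                                  depletionDepth = 0)
  fr <- renderFrame(spec, flat, 1)
  mask <- segmentEmbryo(fr)
  expect_lt(abs(sum(mask) - pi * 125 * 75) / (pi * 125 * 75), 0.01)

  # affine intensity rescaling leaves the mask unchanged
  fr2 <- new("ImageFrame", intensity = 3 * intensity(fr) + 50,
             pixelSize = 0.2, time = 0, frameIndex = 1L)
  expect_identical(segmentEmbryo(fr2), mask)

  # a small bright distractor blob is discarded by the largest-component rule
  img3 <- intensity(fr); img3[5:12, 5:12] <- 200
  fr3 <- new("ImageFrame", intensity = img3, pixelSize = 0.2, time = 0,
             frameIndex = 1L)
  mask3 <- segmentEmbryo(fr3)
  expect_false(any(mask3[5:12, 5:12]))
  expect_lt(abs(sum(mask3) - sum(mask)) / sum(mask), 0.01)

  # featureless frame
  flat0 <- new("ImageFrame", intensity = matrix(7, 60, 60), pixelSize = 1,
               time = 0, frameIndex = 1L)
  expect_error(segmentEmbryo(flat0), class = "NoEmbryoFound")
})

test_that("contour extraction matches analytic perimeters within 1%", {
  grid <- expand.grid(r = 1:200, c = 1:200)
  circ <- matrix((grid$r - 100)^2 + (grid$c - 100)^2 <= 80^2, 200, 200)
  expect_lt(abs(perimeter(extractContour(circ, 1)) - 2 * pi * 80) /
              (2 * pi * 80), 0.01)

  ell <- matrix(((grid$r - 100) / 60)^2 + ((grid$c - 100) / 95)^2 <= 1,
                200, 200)
  expect_lt(abs(perimeter(extractContour(ell, 1)) -
                  ramanujanPerimeter(95, 60)) / ramanujanPerimeter(95, 60),
            0.01)

  sq <- matrix(FALSE, 160, 160); sq[31:130, 31:130] <- TRUE
  expect_lt(abs(perimeter(extractContour(sq, 1)) - 400) / 400, 0.01)

  two <- circ; two[5:10, 5:10] <- TRUE
  expect_error(extractContour(two, 1), "one component")

  # physical units scale with pixel size
  expect_equal(perimeter(extractContour(circ, 0.1)),
               perimeter(extractContour(circ, 1)) * 0.1)
})

test_that("anchoring places s = 0 at the anterior pole, clockwise", {
  spec <- studySpec(cortexWidth = 0.5)
  flat <- accumulationGroundTruth(baseline = 1, anteriorGain = 0,
                                  depletionDepth = 0)
  fr <- renderFrame(spec, flat, 1)
  mask <- segmentEmbryo(fr)
  raw <- extractContour(mask, 0.2)
  hint <- anteriorPole(spec)            # leftmost point (anteriorEnd = -1)
  ct <- anchorContour(raw, hint)
  expect_identical(anchorIndex(ct), 1L)
  p0 <- contourPoints(ct)[1, ]
  expect_lt(sqrt(sum((p0 - hint)^2)), 2)
  # clockwise in image coordinates: positive shoelace with x = col, y = row
  pts <- contourPoints(ct)
  x <- pts[, 2]; y <- pts[, 1]
  area2 <- sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)
  expect_gt(area2, 0)
  # posterior pole maps to s ~ 0.5
  post <- contourPoints(ct)[which.min(abs(arcFraction(ct) - 0.5)), ]
  expect_lt(abs(post[2] - (spec@center[2] + 125)), 2)

  # idempotence
  ct2 <- anchorContour(ct, hint)
  expect_equal(contourPoints(ct2), contourPoints(ct))
  expect_equal(arcFraction(ct2), arcFraction(ct))

  # ambiguous hint: the centroid is equidistant from both poles
  expect_error(anchorContour(raw, colMeans(contourPoints(raw))),
               "equidistant")
})

test_that("flipping the hint shifts the profile by half a perimeter", {
  spec <- studySpec()
  truth <- accumulationGroundTruth()
  fr <- renderFrame(spec, truth, 1)
  resA <- quantifyEmbryo(list(fr), anteriorHint = anteriorPole(spec))
  postHint <- 2 * spec@center - anteriorPole(spec)
  resP <- quantifyEmbryo(list(fr), anteriorHint = postHint)
  pA <- resA$profiles[[1]]; pP <- resP$profiles[[1]]
  shifted <- cortexQuant:::periodicInterp(arcFraction(pA), accumulation(pA),
                                          (arcFraction(pP) + 0.5) %% 1)
  expect_lt(sqrt(mean((accumulation(pP) - shifted)^2)), 0.03)
})

test_that("mirroring the image reverses the profile", {
  spec <- studySpec()
  truth <- accumulationGroundTruth()
  fr <- renderFrame(spec, truth, 1)
  res <- quantifyEmbryo(list(fr), anteriorHint = anteriorPole(spec))
  img <- intensity(fr)
  mir <- img[, rev(seq_len(ncol(img)))]
  frM <- new("ImageFrame", intensity = mir, pixelSize = 0.2, time = 0,
             frameIndex = 1L)
  hintM <- anteriorPole(spec)
  hintM[2] <- ncol(img) + 1 - hintM[2]
  resM <- quantifyEmbryo(list(frM), anteriorHint = hintM)
  p <- res$profiles[[1]]; pM <- resM$profiles[[1]]
  reversed <- cortexQuant:::periodicInterp(arcFraction(p), accumulation(p),
                                           (1 - arcFraction(pM)) %% 1)
  expect_lt(sqrt(mean((accumulation(pM) - reversed)^2)), 0.03)
})

test_that("perimeters are normalized to the per-embryo maximum", {
  mk <- octagonContour
  expect_equal(normalizedPerimeter(list(mk(100), mk(110), mk(99))),
               c(100, 110, 99) / 110)
  expect_equal(normalizedPerimeter(list(mk(42))), 1)
})
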