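test_that("ring intensity is an affine image of the true accumulation", {
  spec <- studySpec()
  flat <- accumulationGroundTruth(baseline = 1, anteriorGain = 0,
                                  depletionDepth = 0)
  fr <- renderFrame(spec, flat, 1)
  ctr <- trueContour(spec, 256)
  onRing <- bilinearSampleAt(intensity(fr), contourPoints(ctr))
  # uniform accumulation 1 makes the ring equal the cytoplasm
  expect_true(all(abs(onRing - 100) < 1e-6))

  dbl <- accumulationGroundTruth(baseline = 2, anteriorGain = 0,
                                 depletionDepth = 0)
  fr2 <- renderFrame(spec, dbl, 1)
  onRing2 <- bilinearSampleAt(intensity(fr2), contourPoints(ctr))
  expect_true(all(abs(onRing2 - 190) < 1e-6))   # 10 + 90 * 2

  # general field: ring centreline equals bg + (cyto - bg) * a_true(s)
  truth <- accumulationGroundTruth()
  fr3 <- renderFrame(spec, truth, 1)
  onRing3 <- bilinearSampleAt(intensity(fr3), contourPoints(ctr))
  expected <- 10 + 90 * trueProfile(truth, arcFraction(ctr), 1)
  expect_lt(max(abs(onRing3 - expected)), 0.02 * diff(range(expected)))
})

test_that("seeded noise renders are bit-reproducible", {
  for (nm in list(list(type = "gaussian", sd = 5),
                  list(type = "poisson", gain = 2))) {
    spec <- syntheticEmbryoSpec(noiseModel = nm, rngSeed = 99L)
    a <- intensity(renderFrame(spec, accumulationGroundTruth(), 1))
    b <- intensity(renderFrame(spec, accumulationGroundTruth(), 1))
    expect_identical(a, b)
    expect_true(all(a >= 0))
  }
})

test_that("rotating the spec rotates the ground-truth contour", {
  th <- pi / 6
  spec0 <- syntheticEmbryoSpec(imageShape = c(320L, 320L))
  spec1 <- syntheticEmbryoSpec(imageShape = c(320L, 320L), orientation = th)
  p0 <- contourPoints(trueContour(spec0, 512))
  p1 <- contourPoints(trueContour(spec1, 512))
  ctr <- spec0@center
  # rotate p0 about the centre by th in (col, row-down) coordinates
  dx <- p0[, 2] - ctr[2]; dy <- p0[, 1] - ctr[1]
  rot <- cbind(ctr[1] + dx * sin(th) + dy * cos(th),
               ctr[2] + dx * cos(th) - dy * sin(th))
  expect_lt(max(sqrt(rowSums((p1 - rot)^2))), 0.5)
})

test_that("embryos that do not fit in the image are rejected", {
  spec <- syntheticEmbryoSpec(imageShape = c(100L, 100L))
  expect_error(renderFrame(spec, accumulationGroundTruth(), 1),
               "exceeds the image")
  expect_error(renderFrame(studySpec(), accumulationGroundTruth(), 2),
               "frameIndex")
})

test_that("true accumulation field behaves as specified", {
  flat <- accumulationGroundTruth(anteriorGain = 0, depletionDepth = 0,
                                  baseline = 1.3)
  s <- seq(0, 1, length.out = 1000 + 1)[-1001]
  expect_equal(trueProfile(flat, s, 1), rep(1.3, 1000))

  steep <- accumulationGroundTruth(baseline = 1.6, anteriorGain = 0,
                                   depletionDepth = 0.5,
                                   edgeSteepness = 500)
  expect_equal(trueProfile(steep, 0.5, 1), 1.6 - 0.5, tolerance = 1e-6)

  # periodicity in s
  truth <- accumulationGroundTruth()
  expect_equal(trueProfile(truth, 1e-9, 1),
               trueProfile(truth, 1 - 1e-9, 1), tolerance = 1e-5)

  # below-cut fraction on a 1000-point grid vs a fine-grid counting oracle
  cut <- 1.55
  frac1000 <- mean(trueProfile(truth, s, 1) < cut)
  sFine <- seq(0, 1, length.out = 100001)[-100001]
  fracFine <- mean(trueProfile(truth, sFine, 1) < cut)
  expect_lt(abs(frac1000 - fracFine), 0.002)
})

test_that("temporal ramp scales the field frame by frame", {
  truth <- accumulationGroundTruth(temporalRamp = c(1, 1.5))
  s <- seq(0, 0.9, by = 0.1)
  expect_equal(trueProfile(truth, s, 2), 1.5 * trueProfile(truth, s, 1))
})

test_that("simulated FRAP traces follow the single-exponential model", {
  tr <- simulateFrapTrace(frapGroundTruth(aTrue = 0.8, bTrue = 0.23,
                                          bleachFloor = 0.1))
  expect_equal(traceValues(tr)[1], 0.1)              # floor at t = 0
  longT <- frapGroundTruth(aTrue = 0.8, bTrue = 2, nPost = 300L,
                           bleachFloor = 0.1)        # b t > 20 at the end
  v <- traceValues(simulateFrapTrace(longT))
  expect_lt(abs(v[length(v)] - 0.9), 1e-8)

  # mean of 200 seeded noisy replicates stays within 3 sd / sqrt(200)
  noiseless <- traceValues(simulateFrapTrace(frapGroundTruth()))
  acc <- rowMeans(vapply(1:200, function(sd) traceValues(simulateFrapTrace(
    frapGroundTruth(noiseSd = 0.02, rngSeed = sd))),
    numeric(length(noiseless))))
  expect_lt(max(abs(acc - noiseless)), 3 * 0.02 / sqrt(200))
})

test_that("simulated furrow trajectories carry their ground truth", {
  flat <- furrowGroundTruth(rate = 0, nFrames = 10L)
  fs <- simulateFurrowSeries(flat)
  expect_true(all(seriesData(fs)$widthNorm == 1))
  expect_false(isCompleted(fs))

  ingress <- furrowGroundTruth(plateauEnd = 0, rate = 1 / 100,
                               frameInterval = 10, nFrames = 15L)
  fs2 <- simulateFurrowSeries(ingress)
  expect_true(isCompleted(fs2))
  expect_equal(trueInitiationTime(ingress), 10)
  expect_equal(initiationTimeOf(fs2), 10, tolerance = 1e-9)

  plateau <- furrowGroundTruth(plateauEnd = 10, rate = 0.01, nFrames = 25L)
  expect_equal(trueInitiationTime(plateau), 10 + 0.1 / 0.01)
})
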