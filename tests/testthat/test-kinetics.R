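test_that("rolling averages equal brute-force window means", {
  expect_equal(rollingAverage(c(1, 2, 3, 4, 5)), c(2, 3, 4))
  expect_equal(rollingAverage(rep(7, 10)), rep(7, 8))
  expect_error(rollingAverage(1:10, period = 4), "odd")
  expect_error(rollingAverage(1:2, period = 3), "shorter")

  set.seed(17)
  x <- rnorm(50)
  for (period in c(3, 5, 7)) {
    brute <- vapply(seq_len(50 - period + 1), function(i)
      mean(x[i:(i + period - 1)]), numeric(1))
    expect_identical(rollingAverage(x, period), brute)
  }
})

test_that("initiation time interpolates the 90%-width crossing", {
  expect_equal(initiationTime(c(0, 10, 20), c(1.0, 0.95, 0.89)),
               10 + (0.05 / 0.06) * 10, tolerance = 1e-9)
  # w(t) = 1 - t/100 crosses 0.9 at exactly t = 10
  t <- seq(0, 60, by = 10)
  expect_lt(abs(initiationTime(t, 1 - t / 100) - 10), 0.1)
  expect_true(is.na(initiationTime(t, rep(0.95, 7))))
  # already below threshold at the first frame
  expect_equal(initiationTime(c(5, 10), c(0.8, 0.7)), 5)
})

test_that("completion calls count failed furrows", {
  done <- furrowSeries(0:10 * 10, c(seq(30, 0, length.out = 11)))
  expect_equal(completionCall(done), "completed")
  stuck <- furrowSeries(0:10 * 10, c(seq(30, 9, length.out = 11)),
                        maxWidth = 30)
  expect_equal(completionCall(stuck), "failed")

  cohort <- c(lapply(1:10, function(i) simulateFurrowSeries(
    furrowGroundTruth(plateauEnd = 0, rate = 0.01, nFrames = 15L))),
    lapply(1:10, function(i) simulateFurrowSeries(
      furrowGroundTruth(plateauEnd = 0, rate = 0.01, finalFraction = 0.3,
                        nFrames = 15L))))
  expect_equal(failureFraction(cohort), 0.5)
})

test_that("simulated trajectories match their closed-form initiation", {
  for (plateau in c(0, 30, 60)) for (rate in c(0.005, 0.01, 0.02)) {
    truth <- furrowGroundTruth(plateauEnd = plateau, rate = rate,
                               nFrames = 60L)
    fs <- simulateFurrowSeries(truth)
    expect_lt(abs(initiationTimeOf(fs) - trueInitiationTime(truth)), 0.1)
  }
})

test_that("centrosome-cortex distances match a brute-force search", {
  spec <- studySpec()
  ct <- trueContour(spec, 1024)
  centre <- spec@center

  circleSpec <- syntheticEmbryoSpec(imageShape = c(312L, 312L),
                                    semiAxes = c(100, 99.999),
                                    pixelSize = 0.1)
  circ <- trueContour(circleSpec, 1024)
  atCentre <- centrosomeCortexDistance(circleSpec@center, circ)
  expect_equal(atCentre$distanceUm, 10, tolerance = 1e-3)

  nearCortex <- 0.9999 * contourPoints(ct)[200, ] + 0.0001 * centre
  onCortex <- centrosomeCortexDistance(nearCortex, ct)
  expect_lt(onCortex$distanceUm, 0.01)

  dense <- contourPoints(trueContour(spec, 16384))
  set.seed(23)
  for (i in 1:8) {
    pt <- centre + c(runif(1, -40, 40), runif(1, -80, 80))
    got <- centrosomeCortexDistance(pt, ct)
    brute <- min(sqrt((pt[1] - dense[, 1])^2 + (pt[2] - dense[, 2])^2))
    expect_lt(abs(got$distanceUm - brute * spec@pixelSize),
              0.5 * spec@pixelSize)
  }

  outside <- centre + c(0, 200)
  expect_error(centrosomeCortexDistance(outside, ct), "outside")
})

test_that("distances are invariant under rotation and translation", {
  spec <- studySpec()
  ct <- trueContour(spec, 512)
  pt <- spec@center + c(20, 55)
  d0 <- centrosomeCortexDistance(pt, ct)$distanceUm

  th <- 0.7; shift <- c(12, -8)
  R <- function(p) {
    dr <- p[, 1] - 150; dc <- p[, 2] - 150
    cbind(150 + cos(th) * dr - sin(th) * dc + shift[1],
          150 + sin(th) * dr + cos(th) * dc + shift[2])
  }
  ct2 <- new("CortexContour", points = R(contourPoints(ct)),
             s = arcFraction(ct), anchorIndex = 1L,
             pixelSize = spec@pixelSize, perimeter = perimeter(ct))
  pt2 <- as.numeric(R(matrix(pt, 1)))
  expect_lt(abs(centrosomeCortexDistance(pt2, ct2)$distanceUm - d0), 1e-6)
})

test_that("local accumulation is read at the nearest cortical position", {
  spec <- studySpec()
  truth <- accumulationGroundTruth()
  ct <- trueContour(spec, 512)
  s <- seq(0, 1, length.out = 512 + 1)[-513]
  prof <- makeProfile(s, trueProfile(truth, s, 1))
  # a point pushed toward the posterior pole lands near s = 0.5
  pt <- spec@center + c(0, 0.9 * spec@semiAxes[1])
  got <- centrosomeCortexDistance(pt, ct, prof)
  expect_lt(abs(got$s - 0.5), 0.01)
  expect_equal(got$localAccumulation, trueProfile(truth, got$s, 1),
               tolerance = 1e-3)
})

test_that("condition mean profiles average pointwise and shrink noise", {
  s <- seq(0, 1, length.out = 500 + 1)[-501]
  mk <- function(vals) { attr(vals, "s") <- s; vals }
  same <- conditionMeanProfile(list(mk(sin(2 * pi * s)),
                                    mk(sin(2 * pi * s))))
  expect_equal(same$mean, sin(2 * pi * s))
  expect_equal(conditionMeanProfile(list(mk(rep(1, 500)),
                                         mk(rep(3, 500))))$mean,
               rep(2, 500))

  truth <- accumulationGroundTruth()
  aTrue <- trueProfile(truth, s, 1)
  sigma <- 0.1
  set.seed(29)
  for (n in c(2, 8, 32)) {
    profs <- lapply(seq_len(n), function(i)
      mk(aTrue + rnorm(length(s), 0, sigma)))
    rmse <- sqrt(mean((conditionMeanProfile(profs)$mean - aTrue)^2))
    expect_lt(abs(rmse - sigma / sqrt(n)), 0.3 * sigma / sqrt(n))
  }
})
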