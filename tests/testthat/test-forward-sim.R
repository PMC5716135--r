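test_that("anchor calibration pins the gain and reports residuals", {
  m <- calibrateOpticalModel()
  ## the single-leaf own-ROI response defines the gain exactly
  own <- predictRoiLight(m, 32L)[["32"]]
  expect_equal(own, 29.1, tolerance = 0.5 / 29.1)
  expect_true(all(abs(m@fitResiduals) <= 8))
  ## single-leaf light relative to the 10 cm (16-leaf) field: the 0.48
  ## output factor is reproduced within the recorded fit residual
  ref <- mean(predictRoiLight(m, 25:40)[c("32", "33")])
  expect_equal(29.1 / ref, 0.48,
               tolerance = (max(abs(m@fitResiduals)) + 0.01) / ref)
  expect_error(calibrateOpticalModel(anchors = list(singleLeafCenter = 29.1)),
               "anchor set")
  expect_error(calibrateOpticalModel(tolerance = 0.5), "residuals")
})

test_that("scatter kernel is non-negative with a central maximum", {
  m <- calibrateOpticalModel()
  w <- scatterWeights(m, 30)
  expect_true(all(w >= 0))
  expect_equal(w[1], 1)
  expect_true(all(w[-1] <= w[1]))
  expect_true(all(diff(w[-1]) <= 0))
  expect_error(opticalModel(scatterAmp = 3, scatterLambda = 100), "central")
})

test_that("zero-scatter model puts no light on closed-leaf ROIs", {
  m <- noiseFreeModel()
  lt <- predictRoiLight(m, 25:40)
  expect_true(all(lt[as.character(25:40)] > 0))
  expect_equal(unname(lt[!names(lt) %in% as.character(25:40)]),
               rep(0, sum(!names(lt) %in% as.character(25:40))))
})

test_that("expected ROI light is monotone in the number of open leaves", {
  m <- calibrateOpticalModel()
  centre <- vapply(1:28, function(n) {
    lo <- ceiling(32.5 - n / 2)
    mean(predictRoiLight(m, lo:(lo + n - 1))[c("32", "33")])
  }, numeric(1))
  expect_true(all(diff(centre) >= 0))
})

test_that("light superposes over disjoint open-leaf sets before quantization", {
  g <- smallGeometry()
  m <- calibrateOpticalModel(pixelNoiseSd = 0, transientProb = 0)
  fA <- numeric(64); fA[c(27, 28, 31)] <- c(1, 0.4, 0.7)
  fB <- numeric(64); fB[c(33, 36)] <- c(0.9, 0.2)
  pA <- lightPattern(fA, m, g, angle = 25)
  pB <- lightPattern(fB, m, g, angle = 25)
  pAB <- lightPattern(fA + fB, m, g, angle = 25)
  expect_equal(pA + pB, pAB, tolerance = 1e-12)
})

test_that("simulated stacks are deterministic in the seed", {
  g <- smallGeometry()
  m <- calibrateOpticalModel()
  s <- simplePattern(g, 2)
  a <- simulateDelivery(s, m, g, seed = 5)
  b <- simulateDelivery(s, m, g, seed = 5)
  expect_identical(a@frames, b@frames)
  d <- simulateDelivery(s, m, g, seed = 6)
  expect_false(identical(a@frames, d@frames))
})

test_that("an all-zero sinogram yields background-only frames", {
  g <- smallGeometry()
  m <- noiseFreeModel()
  s <- sinogram(matrix(0, 3, 64), g)
  stk <- simulateDelivery(s, m, g, seed = 1)
  ## background 0.36 pv quantizes to 0 in the 8-bit frames
  expect_true(all(stk@frames == as.raw(0)))
  ## and the un-quantized model value is exactly zero light
  expect_equal(max(lightPattern(numeric(64), m, g)), 0)
})

test_that("static exposures have floor(duration x fps) frames", {
  g <- tomoGeometry()
  m <- noiseFreeModel()
  stk <- simulateStaticExposure(32L, 2, m, smallGeometry(), seed = 1)
  expect_equal(nFrames(stk), floor(2 * 29.97))
  ## the 294.12 ms single-leaf exposure of the profile measurement
  stk2 <- simulateStaticExposure(32L, 0.29412, m, smallGeometry(), seed = 1)
  expect_equal(nFrames(stk2), 8L)  # floor(294.12 / 33.37)
  expect_warning(simulateStaticExposure(32L, 0.01, m, smallGeometry(),
                                        seed = 1),
                 "empty")
  ## frame count arithmetic of the 300 s preclinical recording
  expect_equal(floor(300 * g@frameRate), 8991L)
})

test_that("timestamps advance at the nominal frame period", {
  g <- smallGeometry()
  stk <- simulateStaticExposure(32L, 1, noiseFreeModel(), g, seed = 1)
  expect_equal(diff(timestamps(stk)), rep(framePeriod(g), nFrames(stk) - 1))
  expect_true(all(diff(timestamps(stk)) > 0))
})

test_that("sinogram and geometry must agree on the leaf count", {
  g <- smallGeometry()
  s <- sinogram(matrix(0.5, 2, 64), g)
  g2 <- tomoGeometry(nLeaves = 32L, leafWidthIso = 1.25,
                     observedLeaves = c(10L, 20L))
  expect_error(simulateDelivery(s, noiseFreeModel(), g2, seed = 1),
               "disagree")
})

test_that("ROI light survives rotation and back-rotation within 2%", {
  g <- smallGeometry()
  m <- calibrateOpticalModel(pixelNoiseSd = 0, transientProb = 0)
  f <- numeric(64); f[27:38] <- 1
  fo <- matrix(f, ncol = 1)
  amp <- scintQA:::leafAmplitudes(fo, 0, m, g)
  ref <- NULL
  for (th in c(0, 1, 37, 90, 133.5, 201, 270, 359)) {
    fr <- scintQA:::renderStack(amp, th, m, g)
    stk <- scintQA:::frameStack(fr, 0, th, g)
    rec <- extractLight(stk, bg = m@backgroundMean, backRotate = TRUE)
    if (th == 0) ref <- rec@q[, 1] else
      expect_equal(rec@q[, 1], ref, tolerance = 0.02)
  }
})

test_that("transient artifacts are saturated discs that detection finds", {
  g <- tinyGeometry()
  m <- opticalModel(transientProb = 0.5)  # high rate for a cheap smoke test
  stk <- simulateStaticExposure(integer(0), 2, m, g, seed = 4)
  n <- countTransientFrames(stk)
  expect_gt(n, 0)
  ## a transient-free render of the same scene has none
  m0 <- opticalModel(transientProb = 0)
  stk0 <- simulateStaticExposure(integer(0), 2, m0, g, seed = 4)
  expect_equal(countTransientFrames(stk0), 0L)
})
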