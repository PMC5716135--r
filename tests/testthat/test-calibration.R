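test_that("the open-time line is recovered exactly on noiseless points", {
  t <- c(29.41, 50, 100, 200, 294.12)
  fit <- fitTimeCalibration(t, 0.2 * t)
  expect_equal(fit$slope, 0.2)
  expect_equal(fit$intercept, 0, tolerance = 1e-12)
  ## inverse round trip on the fitted points
  expect_equal(predictOpenTime(fit, 0.2 * t), t, tolerance = 1e-9)
  ## negative predictions clip to zero
  expect_equal(predictOpenTime(fit, -1), 0)
  expect_error(fitTimeCalibration(100, 20), "two distinct")
  expect_error(fitTimeCalibration(c(100, 100), c(20, 21)), "two distinct")
  expect_error(fitTimeCalibration(c(50, 100), c(30, 20)), "slope")
})

test_that("a simulated open-time sweep recovers the truth within 3%", {
  g <- smallGeometry()
  m <- calibrateOpticalModel()  # noise on
  times <- seq(29.41, 294.12, length.out = 10)
  Q <- vapply(seq_along(times), function(k) {
    stk <- simulateStaticExposure(25:40, times[k] / 1000 + 0.1, m, g,
                                  seed = 50 + k,
                                  openTime = times[k] / 1000)
    qCenter(extractLight(stk, bg = m@backgroundMean))
  }, numeric(1))
  fit <- fitTimeCalibration(times, Q)
  expect_equal(predictOpenTime(fit, Q), times, tolerance = 0.03)
})

test_that("lateral corrections invert the single-leaf profile", {
  flat <- setNames(rep(2.5, 5), 30:34)
  expect_equal(unname(measureLateralProfile(flat)), rep(1, 5))
  prof <- setNames(c(0.90, 1), c("18", "32"))
  k1 <- measureLateralProfile(prof)
  expect_equal(k1[["18"]], 1 / 0.90)
  expect_equal(k1[["32"]], 1)
  expect_error(measureLateralProfile(setNames(c(0, 1), c("18", "32"))),
               "non-positive")
  expect_error(measureLateralProfile(setNames(1, "18")), "32")
})

test_that("simulated profile exposures recover the configured profile", {
  g <- smallGeometry()
  cal <- smallNoiseFreeCal()
  truth <- lateralProfileAt(noiseFreeModel(), observedLeaves(g), g)
  ## k1 x profile = 1 up to the 8-bit quantization of the frames
  expect_equal(unname(cal@k1 * truth / truth[observedLeaves(g) == 32]),
               rep(1, length(truth)), tolerance = 0.02)
})

test_that("drift correction is the inverse windowed output, 1 at 100 s", {
  g <- tomoGeometry()
  nF <- floor(150 * g@frameRate)
  ts <- (seq_len(nF) - 1) / g@frameRate
  ## constant output -> k2 identically 1
  q <- matrix(5, 2, nF)
  rec <- lightRecord(q, g, leaves = c(32L, 33L))
  k2c <- measureDriftCorrection(rec)
  expect_equal(k2c$k2, rep(1, nrow(k2c)))
  ## 2% linear drift over 300 s -> k2 recovers the inverse within 0.5%
  drift <- 1.01 - 0.02 / 300 * (ts + 1 / (2 * g@frameRate))
  rec2 <- lightRecord(rbind(5 * drift, 5 * drift), g, leaves = c(32L, 33L))
  bins <- measureDriftCorrection(rec2)
  ref <- 1.01 - 0.02 / 300 * (bins$tStart + 5)
  refNorm <- ref / ref[bins$tStart == 100]
  expect_equal(bins$k2, 1 / refNorm, tolerance = 0.005)
  ## the 100 s bin is exactly 1 by normalization
  expect_equal(bins$k2[bins$tStart == 100], 1)
  expect_equal(k2At(calibrationSet(list(slope = 1, intercept = 0),
                                   k2Bins = bins), 105), 1)
  ## exposures shorter than the normalization point are refused
  expect_error(measureDriftCorrection(lightRecord(q[, 1:100, drop = FALSE],
                                                  g, leaves = c(32L, 33L))),
               "100 s")
})

test_that("field factors use centre leaves and flanking-ROI edges", {
  g <- smallGeometry()
  m <- noiseFreeModel(backgroundMean = 0)  # zero-scatter, clean zeros
  mkExposure <- function(leaves) {
    stk <- simulateStaticExposure(leaves, 0.4, m, g, seed = 3,
                                  openTime = 0.29412)
    list(record = extractLight(stk, bg = 0), leaves = leaves,
         openTimeMs = 294.12)
  }
  ff <- measureFieldFactors(list(mkExposure(32L), mkExposure(32:33),
                                 mkExposure(30:35)), g)
  expect_equal(ff$nOpen, c(1L, 2L, 6L))
  ## zero-scatter: no light beyond the aperture
  expect_equal(ff$edge, rep(0, 3))
  ## centre light equals the gain within quantization
  expect_equal(ff$center, rep(m@gain, 3), tolerance = 0.03)
  ## centre factor is monotone in n for a scattering model
  mS <- calibrateOpticalModel(pixelNoiseSd = 0, transientProb = 0)
  ffS <- measureFieldFactors(lapply(list(32L, 31:34, 30:35, 28:37),
                                    function(lv) {
    stk <- simulateStaticExposure(lv, 0.4, mS, g, seed = 3,
                                  openTime = 0.29412)
    list(record = extractLight(stk, bg = mS@backgroundMean), leaves = lv,
         openTimeMs = 294.12)
  }), g)
  expect_true(all(diff(ffS$center) > 0))
  expect_true(all(diff(ffS$edge) > 0))
  ## an aperture touching the observed range loses that flank with warning
  expect_warning(measureFieldFactors(list(mkExposure(26:30)), g), "flank")
})

test_that("corrections are scale-free in the gain", {
  g <- smallGeometry()
  m1 <- noiseFreeModel()
  m2 <- noiseFreeModel(gain = 2 * m1@gain)
  k1 <- lapply(list(m1, m2), function(m) {
    ol <- observedLeaves(g)
    Q <- vapply(ol, function(l) {
      stk <- simulateStaticExposure(l, 0.35, m, g, seed = 7,
                                    openTime = 0.29412)
      accumulatedLight(extractLight(stk,
                                    bg = m@backgroundMean))[[as.character(l)]]
    }, numeric(1))
    measureLateralProfile(setNames(Q, ol))
  })
  expect_equal(k1[[1]], k1[[2]], tolerance = 0.02)
})

test_that("calibration JSON round trips", {
  cal <- smallNoiseFreeCal()
  path <- withr::local_tempfile(fileext = ".json")
  writeCalibration(cal, path)
  cal2 <- readCalibration(path)
  expect_equal(cal2@timeSlope, cal@timeSlope)
  expect_equal(cal2@timeIntercept, cal@timeIntercept)
  expect_equal(cal2@k1, cal@k1)
  expect_equal(cal2@k2Bins, cal@k2Bins)
})
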