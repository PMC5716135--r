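test_that("corrections multiply q by k1 and k2 elementwise", {
  g <- smallGeometry()
  q <- matrix(2, 14, 4)
  rec <- lightRecord(q, g)
  ol <- observedLeaves(g)
  k1 <- setNames(rep(1.1, 14), ol); k1[["32"]] <- 1
  k2Bins <- data.frame(tStart = 0, tEnd = 1000, relOutput = 1 / 0.9,
                       k2 = 0.9)
  cal <- calibrationSet(list(slope = 1, intercept = 0), k1 = k1,
                        k2Bins = k2Bins)
  corr <- applyCorrections(rec, cal, nProjections = 1)
  expect_equal(unname(corr@qc[ol != 32, ]), matrix(2 * 1.1 * 0.9, 13, 4))
  expect_equal(unname(corr@qc["32", ]), rep(2 * 0.9, 4))
  ## identity corrections leave q untouched
  calI <- calibrationSet(list(slope = 1, intercept = 0))
  expect_equal(applyCorrections(rec, calI, nProjections = 1)@qc,
               rec@q)
  ## missing k1 entries are an error
  calBad <- calibrationSet(list(slope = 1, intercept = 0),
                           k1 = k1[1:3])
  expect_error(applyCorrections(rec, calBad, nProjections = 1), "missing")
})

test_that("with identity corrections qc equals q exactly", {
  g <- smallGeometry()
  set.seed(8)
  q <- matrix(rnorm(14 * 9, 10, 2), 14, 9)
  rec <- lightRecord(q, g)
  corr <- applyCorrections(rec, calibrationSet(list(slope = 1,
                                                    intercept = 0)),
                           nProjections = 2)
  expect_equal(corr@qc, rec@q)
})

test_that("classification is strictly-greater with equality closed", {
  expect_true(classifyOpen(matrix(29.1), 28)[1, 1])
  expect_false(classifyOpen(matrix(28), 28)[1, 1])
  expect_false(classifyOpen(matrix(29.1), 44)[1, 1])
  expect_error(classifyOpen(matrix(1), -1), ">= 0")
})

test_that("the Youden index combines the printed rates", {
  expect_equal(youdenIndex(0.998, 0.989), 0.987, tolerance = 1e-12)
  expect_equal(youdenIndex(1, 1), 1)
  expect_equal(youdenIndex(0.5, 0.5), 0)
})

test_that("ROC sweep matches a brute-force enumeration on a toy table", {
  ## 4 bins: scores and truth chosen so every threshold case occurs
  score <- matrix(c(50, 30, 10, 5), 2, 2)
  truth <- matrix(c(1, 0.4, 0, 0), 2, 2)
  grid <- c(0, 4, 9, 10, 20, 29, 30, 49, 50, 60)
  roc <- rocAnalysis(score, truth, thGrid = grid,
                     geometry = smallGeometry())
  brute <- t(vapply(grid, function(th) {
    calls <- score > th
    open <- truth > 0
    c(sum(calls & open) / sum(open), sum(!calls & !open) / sum(!open))
  }, numeric(2)))
  expect_equal(roc$sensitivity, brute[, 1])
  expect_equal(roc$specificity, brute[, 2])
  expect_equal(roc$youden, brute[, 1] + brute[, 2] - 1)
})

test_that("sensitivity falls and specificity rises along the grid", {
  g <- smallGeometry()
  m <- calibrateOpticalModel()
  sc <- clinicalPattern(g, nProjections = 12, seed = 31)
  stk <- simulateDelivery(sc, m, g, seed = 32)
  rec <- extractLight(stk, bg = m@backgroundMean, backRotate = TRUE)
  corr <- applyCorrections(rec, smallNoiseFreeCal(), nProjections = 12)
  roc <- rocAnalysis(corr, sc)
  expect_true(all(diff(roc$sensitivity) <= 1e-12))
  expect_true(all(diff(roc$specificity) >= -1e-12))
  expect_true(all(roc$youden >= -1 - 1e-12 & roc$youden <= 1 + 1e-12))
  th <- youdenThreshold(roc)
  expect_gte(max(roc$youden), 0)
  ## ties break toward the smallest threshold
  toy <- data.frame(th = c(1, 2, 3), youden = c(0.5, 0.9, 0.9))
  expect_equal(youdenThreshold(toy), 2)
})

test_that("everything below threshold reconstructs as closed", {
  g <- smallGeometry()
  rec <- lightRecord(matrix(0.2, 14, 18), g)
  cal <- calibrationSet(list(slope = 0.9, intercept = 0))
  corr <- applyCorrections(rec, cal, nProjections = 2)
  recon <- reconstructSinogram(corr, cal, th = 10, g)
  expect_true(all(sinogramValues(recon) == 0))
})

test_that("a noise-free simple pattern reconstructs to full openings", {
  g <- smallGeometry()
  m <- noiseFreeModel()
  cal <- smallNoiseFreeCal()
  s <- simplePattern(g, 6)
  stk <- simulateDelivery(s, m, g, seed = 41)
  rec <- extractLight(stk, bg = m@backgroundMean, backRotate = TRUE)
  corr <- applyCorrections(rec, cal, nProjections = 6)
  recon <- reconstructSinogram(corr, cal, th = 5, g)
  ol <- observedLeaves(g)
  expect_equal(unname(sinogramValues(recon)[, ol]),
               matrix(1, 6, length(ol)), tolerance = 0.02)
  expect_true(all(sinogramValues(recon)[, -ol] == 0))
})

test_that("an isolated half-open leaf reconstructs near 0.5", {
  g <- smallGeometry()
  m <- noiseFreeModel()
  cal <- smallNoiseFreeCal()
  v <- matrix(0, 6, 64); v[, 30] <- 0.5
  s <- sinogram(v, g)
  stk <- simulateDelivery(s, m, g, seed = 42)
  rec <- extractLight(stk, bg = m@backgroundMean, backRotate = TRUE)
  corr <- applyCorrections(rec, cal, nProjections = 6)
  recon <- reconstructSinogram(corr, cal, th = 2, g)
  expect_equal(unname(sinogramValues(recon)[, 30]), rep(0.5, 6),
               tolerance = 0.05 / 0.5)
  expect_true(all(sinogramValues(recon)[, -30] == 0))
})

test_that("noise-free round trips recover arbitrary sinograms within 2%", {
  g <- smallGeometry()
  m <- noiseFreeModel()
  cal <- smallNoiseFreeCal()
  for (seed in c(11, 12)) {
    sc <- clinicalPattern(g, nProjections = 15, seed = seed)
    stk <- simulateDelivery(sc, m, g, seed = 200 + seed)
    rec <- extractLight(stk, bg = m@backgroundMean, backRotate = TRUE)
    corr <- applyCorrections(rec, cal, nProjections = 15)
    th <- youdenThreshold(rocAnalysis(corr, sc))
    recon <- reconstructSinogram(corr, cal, th, g)
    cm <- confusionMetrics(sc, recon)
    expect_equal(cm$sensitivity, 1.0)
    expect_equal(cm$specificity, 1.0)
    expect_lt(max(abs(sinogramValues(recon) - sinogramValues(sc))), 0.02)
  }
})

test_that("gated and midpoint accumulation agree on totals", {
  g <- smallGeometry()
  m <- noiseFreeModel()
  sc <- clinicalPattern(g, nProjections = 10, seed = 13)
  stk <- simulateDelivery(sc, m, g, seed = 14, rotateGantry = FALSE)
  rec <- extractLight(stk, bg = m@backgroundMean)
  cal <- smallNoiseFreeCal()
  a <- applyCorrections(rec, cal, nProjections = 10, method = "gated")
  b <- applyCorrections(rec, cal, nProjections = 10, method = "midpoint")
  o <- applyCorrections(rec, cal, nProjections = 10, method = "overlap")
  ## light is conserved by every accumulation scheme (up to the small
  ## model-implied reattribution of the delivery-edge frames)
  expect_equal(sum(a@S), sum(b@S), tolerance = 0.01)
  expect_equal(sum(a@S), sum(o@S), tolerance = 0.01)
})
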