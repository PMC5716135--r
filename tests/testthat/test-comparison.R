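test_that("confusion metrics count open/closed detections", {
  g <- smallGeometry()
  sc <- clinicalPattern(g, nProjections = 8, seed = 5)
  cm <- confusionMetrics(sc, sc)
  expect_equal(cm$sensitivity, 1.0)
  expect_equal(cm$specificity, 1.0)
  ## counting oracle: 10 open all detected, 100 closed with 8 false opens
  ol <- observedLeaves(g)
  truth <- matrix(0, 11, length(ol)); truth[1, 1:10] <- 1
  recon <- truth
  false_open <- which(truth == 0)[sample.int(100, 8)]
  recon[false_open] <- 0.5
  cm2 <- confusionMetrics(truth, recon, g)
  expect_equal(cm2$sensitivity, 1.0)
  expect_equal(cm2$specificity, (sum(truth == 0) - 8) / sum(truth == 0))
  ## 3 x 3 case against an exhaustive hand count
  t3 <- matrix(c(1, 0, 0.5, 0, 0, 1, 0.2, 0, 0), 3)
  r3 <- matrix(c(1, 0.1, 0, 0, 0, 1, 0.2, 0, 0), 3)
  cm3 <- confusionMetrics(t3, r3, g)
  expect_equal(cm3$sensitivity, 3 / 4)  # bins (1,1),(3,1),(2,3),(1,3): 3 hit
  expect_equal(cm3$specificity, 4 / 5)  # 5 closed, 1 false open
  expect_equal(cm3$counts, list(tp = 3L, fn = 1L, tn = 4L, fp = 1L))
})

test_that("confusion metrics are permutation-invariant over bins", {
  g <- smallGeometry()
  set.seed(6)
  truth <- matrix(rbinom(60, 1, 0.5) * runif(60), 5)
  recon <- matrix(rbinom(60, 1, 0.6) * runif(60), 5)
  cm <- confusionMetrics(truth, recon, g)
  p <- sample(60)
  cmP <- confusionMetrics(matrix(truth[p], 5), matrix(recon[p], 5), g)
  expect_equal(cm$sensitivity, cmP$sensitivity)
  expect_equal(cm$specificity, cmP$specificity)
})

test_that("degenerate truths yield NaN rates with a warning", {
  g <- smallGeometry()
  allOpen <- matrix(1, 2, 14)
  expect_warning(cm <- confusionMetrics(allOpen, allOpen, g), "specificity")
  expect_true(is.nan(cm$specificity))
  allClosed <- matrix(0, 2, 14)
  expect_warning(cm2 <- confusionMetrics(allClosed, allClosed, g),
                 "sensitivity")
  expect_true(is.nan(cm2$sensitivity))
})

test_that("relative errors are normalized by each projection's maximum", {
  g <- smallGeometry()
  sc <- clinicalPattern(g, nProjections = 6, seed = 9)
  expect_equal(relativeErrorMap(sc, sc),
               matrix(0, 6, 14))
  ## one bin off by -0.05 with row max 1 is -5%
  truth <- matrix(0, 2, 14); truth[1, 3] <- 1; truth[1, 5] <- 0.4
  truth[2, 2] <- 0.5
  recon <- truth; recon[1, 5] <- 0.35
  err <- relativeErrorMap(truth, recon, g)
  expect_equal(err[1, 5], -5)
  ## row 2 max is 0.5: same absolute offset doubles in percent
  recon2 <- truth; recon2[2, 2] <- 0.45
  expect_equal(relativeErrorMap(truth, recon2, g)[2, 2], -10)
  ## brute-force oracle on a random pair
  set.seed(10)
  t5 <- matrix(runif(25), 5); r5 <- matrix(runif(25), 5)
  err5 <- relativeErrorMap(t5, r5, g)
  for (p in 1:5) for (j in 1:5)
    expect_equal(err5[p, j], (r5[p, j] - t5[p, j]) / max(t5[p, ]) * 100)
  ## all-zero truth rows report zeros with a warning
  t0 <- matrix(0, 2, 14); t0[1, 1] <- 1
  expect_warning(e0 <- relativeErrorMap(t0, t0 + 0.001, g), "all-zero")
  expect_equal(unname(e0[2, ]), rep(0, 14))
})

test_that("swapping truth and reconstruction flips the error sign", {
  g <- smallGeometry()
  set.seed(11)
  a <- matrix(runif(42, 0.5, 1), 3); b <- matrix(runif(42, 0.5, 1), 3)
  ## when the per-projection normalizers coincide the map is antisymmetric
  a[, 1] <- 1; b[, 1] <- 1
  expect_equal(relativeErrorMap(a, b, g), -relativeErrorMap(b, a, g))
})

test_that("leaf-open-error statistics follow the definition", {
  stats <- leafOpenError(matrix(c(-3, 0, 3, 6), 2))
  expect_equal(stats$mean, 1.5)
  expect_equal(stats$fractionWithin, 0.75)
  ## population SD (divide by n)
  expect_equal(stats$sd, sqrt(mean((c(-3, 0, 3, 6) - 1.5)^2)))
  z <- leafOpenError(matrix(0, 4, 4))
  expect_equal(c(z$mean, z$sd, z$fractionWithin), c(0, 0, 1))
  expect_error(leafOpenError(matrix(numeric(0), 0, 0)), "empty")
  ## sampling oracle at the scale of the reported leaf-open errors
  set.seed(12)
  x <- matrix(rnorm(4000, -1.3, 7.5), 40)
  st <- leafOpenError(x)
  expect_equal(st$mean, -1.3, tolerance = 3 * 7.5 / sqrt(4000) / 1.3)
  expect_equal(st$sd, 7.5, tolerance = 3 / sqrt(2 * 4000))
  expect_equal(st$fractionWithin,
               pnorm(3, -1.3, 7.5) - pnorm(-3, -1.3, 7.5),
               tolerance = 0.05)
})

test_that("the within-tolerance fraction grows with the tolerance", {
  set.seed(13)
  x <- matrix(rnorm(500, 0, 5), 25)
  fr <- vapply(c(1, 2, 3, 5, 8), function(tol)
    leafOpenError(x, tolerancePct = tol)$fractionWithin, numeric(1))
  expect_true(all(diff(fr) >= 0))
})

test_that("the verification report assembles all scores", {
  g <- smallGeometry()
  sc <- clinicalPattern(g, nProjections = 8, seed = 14)
  v <- sinogramValues(sc)
  v[v > 0] <- pmin(1, v[v > 0] * 1.02)
  recon <- sinogram(v, g)
  rep <- verificationReport(sc, recon, threshold = 28)
  expect_equal(rep@sensitivity, 1.0)
  expect_equal(rep@specificity, 1.0)
  expect_equal(rep@youden, 1.0)
  expect_equal(rep@threshold, 28)
  expect_equal(dim(rep@relativeError), c(8L, 14L))
  expect_gte(rep@leafOpenErrorMean, 0)
  expect_true(rep@fractionWithin3pct > 0.5)
  expect_equal(sum(rep@histogram$count), 8L * 14L)
  ## histogram uses 1 percent bins
  expect_equal(unique(round(diff(rep@histogram$mid), 10)), 1)
  path <- withr::local_tempfile(fileext = ".json")
  writeReport(rep, path)
  z <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(z$sensitivity, 1.0)
  expect_equal(z$leaf_open_error_mean_pct, rep@leafOpenErrorMean)
})
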