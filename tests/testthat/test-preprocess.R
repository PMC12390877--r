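singlePixelSeries <- function(values, ...) {
  seriesFromCurves(matrix(values, ncol = 1), ...)
}

test_that("background subtraction handles polarity and clips negatives", {
  s <- singlePixelSeries(c(5, 7, 9))
  s@backgroundSubtracted <- FALSE
  cfg <- preprocessConfig("projection")
  out <- subtractBackground(s, cfg)
  expect_equal(as.vector(intensities(out)), c(0, 2, 4))
  expect_true(out@backgroundSubtracted)
  expect_error(subtractBackground(out, cfg), "already background-subtracted")

  sNeg <- singlePixelSeries(c(9, 7, 5))
  sNeg@backgroundSubtracted <- FALSE
  cfgNeg <- preprocessConfig("projection", polarity = "negative_contrast")
  expect_equal(as.vector(intensities(subtractBackground(sNeg, cfgNeg))),
               c(0, 2, 4))

  sConst <- singlePixelSeries(c(3, 3, 3))
  sConst@backgroundSubtracted <- FALSE
  expect_equal(as.vector(intensities(subtractBackground(sConst, cfg))),
               c(0, 0, 0))
})

test_that("cropping slices space and preserves dt and spacing", {
  set.seed(21)
  s <- DynamicSeries(array(runif(3 * 2 * 16 * 16), dim = c(3, 2, 16, 16)),
                     dt = 0.5, spacing = c(2, 1, 1))
  out <- cropSeries(s, list(z = c(0, 1), y = c(4, 11), x = c(4, 11)))
  expect_equal(dim(intensities(out)), c(3L, 2L, 8L, 8L))
  expect_equal(intensities(out), intensities(s)[, , 5:12, 5:12, drop = FALSE])
  expect_equal(frameInterval(out), 0.5)
  expect_equal(voxelSpacing(out), c(2, 1, 1))
  full <- cropSeries(s, list(z = c(0, 1), y = c(0, 15), x = c(0, 15)))
  expect_identical(intensities(full), intensities(s))
  expect_error(cropSeries(s, list(z = c(0, 1), y = c(5, 4), x = c(0, 15))),
               "out of bounds or empty")
})

test_that("temporal median removes isolated spikes, keeps constants", {
  s <- singlePixelSeries(c(0, 0, 9, 0, 0))
  expect_equal(as.vector(intensities(temporalMedianFilter(s, 3))),
               rep(0, 5))
  sc <- singlePixelSeries(rep(4, 7))
  expect_equal(as.vector(intensities(temporalMedianFilter(sc, 5))),
               rep(4, 7))
  expect_error(temporalMedianFilter(s, 4), "must be odd")
  expect_error(temporalMedianFilter(s, 7), "exceeds")
})

test_that("temporal median matches a sliding-window sort oracle", {
  set.seed(22)
  for (win in c(3, 5)) {
    arr <- array(rnorm(7 * 2 * 3 * 3), dim = c(7, 2, 3, 3))
    s <- DynamicSeries(arr, dt = 1)
    got <- intensities(temporalMedianFilter(s, win))
    expect_equal(got, oracleTemporalMedian(arr, win), tolerance = 1e-15)
  }
})

test_that("spatial median rejects impulses and matches the gather oracle", {
  imp <- array(0, dim = c(1, 1, 5, 5)); imp[1, 1, 3, 3] <- 1
  s <- DynamicSeries(array(rep(imp, 2), dim = c(2, 1, 5, 5)), dt = 1)
  out <- spatialMedianFilter(s, c(3, 3))
  expect_true(all(intensities(out) == 0))
  sc <- DynamicSeries(array(2.5, dim = c(2, 1, 4, 4)), dt = 1)
  expect_equal(intensities(spatialMedianFilter(sc, c(2, 2))),
               intensities(sc))
  set.seed(23)
  for (k in list(c(2, 2), c(3, 3), c(2, 3))) {
    mat <- matrix(rnorm(64), 8, 8)
    arr <- array(0, dim = c(2, 1, 8, 8))
    arr[1, 1, , ] <- mat; arr[2, 1, , ] <- mat * 2
    s <- DynamicSeries(arr, dt = 1)
    got <- intensities(spatialMedianFilter(s, k))[1, 1, , ]
    expect_equal(got, oracleSpatialMedian(mat, k[1], k[2]),
                 tolerance = 1e-15)
  }
  expect_error(spatialMedianFilter(sc, c(9, 2)), "larger than")
})

test_that("odd median filters commute with strictly increasing maps", {
  set.seed(24)
  arr <- array(rnorm(6 * 1 * 5 * 5), dim = c(6, 1, 5, 5))
  s <- DynamicSeries(arr, dt = 1)
  f <- function(x) x^3 + 2 * x   # strictly increasing
  sf <- DynamicSeries(f(arr), dt = 1)
  expect_equal(f(intensities(temporalMedianFilter(s, 3))),
               intensities(temporalMedianFilter(sf, 3)), tolerance = 1e-12)
  expect_equal(f(intensities(spatialMedianFilter(s, c(3, 3)))),
               intensities(spatialMedianFilter(sf, c(3, 3))),
               tolerance = 1e-12)
})

test_that("global normalization maps to [0,1] and ignores affine rescaling", {
  arr <- array(2, dim = c(3, 1, 2, 2))
  arr[1, 1, 1, 1] <- 2; arr[2, 1, 1, 1] <- 4; arr[3, 1, 1, 1] <- 6
  s <- DynamicSeries(arr, dt = 1)
  out <- intensities(normalizeGlobal(s))
  expect_equal(out[, 1, 1, 1], c(0, 0.5, 1))
  expect_equal(range(out), c(0, 1))
  expect_identical(intensities(normalizeGlobal(normalizeGlobal(s))), out)
  set.seed(25)
  r <- DynamicSeries(array(runif(40), dim = c(10, 1, 2, 2)), dt = 1)
  r2 <- DynamicSeries(3.7 * intensities(r) + 11, dt = 1)
  expect_equal(intensities(normalizeGlobal(r)),
               intensities(normalizeGlobal(r2)), tolerance = 1e-12)
  expect_error(normalizeGlobal(DynamicSeries(array(1, dim = c(2, 1, 2, 2)),
                                             dt = 1)),
               "constant series")
})

test_that("noise threshold zeroes sub-threshold values against the oracle", {
  s <- seriesFromCurves(matrix(c(0, 0.05, 0.5, 1.0), ncol = 1))
  expect_equal(as.vector(intensities(applyNoiseThreshold(s, 0.08))),
               c(0, 0, 0.5, 1.0))
  expect_identical(intensities(applyNoiseThreshold(s, 0)), intensities(s))
  set.seed(26)
  arr <- array(runif(200), dim = c(8, 1, 5, 5))
  r <- DynamicSeries(arr, dt = 1)
  out <- intensities(applyNoiseThreshold(r, 0.1))
  expect_equal(sum(out == 0), sum(arr < 0.1 * max(arr)))
  expect_error(applyNoiseThreshold(s, 1.5), "noiseFraction")
})

test_that("the chain preserves shape and records its configuration", {
  ph <- simulatePhantom(defaultPhantomSpec(nFrames = 24, noiseSd = 0.02))
  pre <- preprocessSeries(ph$series)
  expect_equal(dim(intensities(pre)), dim(intensities(ph$series)))
  log <- attr(pre, "preprocessLog")
  expect_equal(log$temporalWindow, 5L)
  expect_equal(log$spatialKernel, c(2L, 2L))
  expect_equal(log$noiseFraction, 0.08)
})
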