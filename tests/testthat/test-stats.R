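mapFromValues <- function(v, kind = "toa_norm", dt = 1) {
  new("MarkerMap", values = array(v, dim = c(1, 1, length(v))), kind = kind,
      dt = dt, spacing = c(1, 1, 1))
}

test_that("binning follows the kind defaults and the top-edge rule", {
  h <- buildHistogram(mapFromValues(c(0.04, 0.04, 0.96, 0.96, 0, 1),
                                    "toa_norm"))
  expect_equal(length(frequencies(h)), 20)
  # 0 and 0.04 land in bin 1; 0.96 and the top edge 1 land in bin 20
  expect_equal(frequencies(h)[1], 0.5)
  expect_equal(frequencies(h)[20], 0.5)
  expect_equal(sum(frequencies(h)), 1)

  ht <- buildHistogram(mapFromValues(c(0.4, 1.7, 3.2), "toa", dt = 0.5))
  expect_equal(binEdges(ht), seq(0, 3.5, by = 0.5))
  expect_equal(nValues(ht), 3L)
  expect_error(buildHistogram(mapFromValues(NA_real_, "toa")), "empty")
  expect_error(buildHistogram(mapFromValues(c(0.1, 0.2)), binWidth = -1),
               "binWidth")
})

test_that("bin counts match an exhaustive comparison-loop oracle", {
  set.seed(51)
  v <- runif(1000)
  h <- buildHistogram(mapFromValues(v, "toa_norm"))
  want <- oracleHistCounts(v, binEdges(h)) / 1000
  expect_equal(frequencies(h), want, tolerance = 1e-15)
})

test_that("moment conventions: population moments, non-excess kurtosis", {
  m <- histogramMetrics(c(1, 2, 3))
  expect_identical(m@mean, 2)
  expect_identical(m@median, 2)
  expect_identical(m@skewness, 0)
  expect_identical(m@kurtosis, 1.5)
  expect_true(m@kurtosis >= m@skewness^2 + 1)
  expect_error(histogramMetrics(c(2, 2, 2)), "zero variance")
})

test_that("moments agree with an independent implementation", {
  skip_if_not_installed("e1071")
  set.seed(52)
  v <- rgamma(500, shape = 2)
  m <- histogramMetrics(v)
  expect_equal(m@skewness, e1071::skewness(v, type = 1), tolerance = 1e-12)
  expect_equal(m@kurtosis, e1071::kurtosis(v, type = 1) + 3,
               tolerance = 1e-12)
})

test_that("metrics ignore voxel order and histogram binning", {
  set.seed(53)
  v <- rnorm(200, 5, 2)
  m1 <- histogramMetrics(mapFromValues(v, "toa"))
  m2 <- histogramMetrics(mapFromValues(sample(v), "toa"))
  expect_equal(m1@skewness, m2@skewness, tolerance = 1e-12)
  expect_equal(m1@kurtosis, m2@kurtosis, tolerance = 1e-12)
})

test_that("chi-square comparison matches hand computation and is symmetric", {
  mkHist <- function(f) new("MarkerHistogram", binEdges = c(0, 0.5, 1),
                            frequencies = f, nValues = 10L,
                            kind = "toa_norm")
  a <- mkHist(c(0.6, 0.4)); b <- mkHist(c(0.4, 0.6))
  cmp <- compareHistograms(a, b)
  expect_equal(cmp@chi2, 0.04 / 1.0 + 0.04 / 1.0, tolerance = 1e-12)
  expect_equal(cmp@df, 1L)
  expect_equal(cmp@pValue, pchisq(0.08, 1, lower.tail = FALSE),
               tolerance = 1e-12)
  swap <- compareHistograms(b, a)
  expect_equal(swap@chi2, cmp@chi2)
  expect_equal(swap@pValue, cmp@pValue)

  self <- compareHistograms(a, a)
  expect_identical(self@chi2, 0)
  expect_identical(self@pValue, 1)

  expect_error(compareHistograms(a, new("MarkerHistogram",
    binEdges = c(0, 1), frequencies = 1, nValues = 1L, kind = "slope_norm")),
    "incompatible kinds")
})

test_that("disjoint-support histograms give chi2 = 2 (all mass unmatched)", {
  a <- new("MarkerHistogram", binEdges = c(0, 0.25), frequencies = 1,
           nValues = 5L, kind = "toa_norm")
  b <- new("MarkerHistogram", binEdges = c(0.75, 1), frequencies = 1,
           nValues = 5L, kind = "toa_norm")
  cmp <- compareHistograms(a, b, bins = 4)
  expect_equal(cmp@chi2, 2, tolerance = 1e-12)
})

test_that("padding empty bins changes nothing", {
  a <- new("MarkerHistogram", binEdges = seq(0, 1, 0.25),
           frequencies = c(0.25, 0.25, 0.25, 0.25), nValues = 8L,
           kind = "toa_norm")
  b <- new("MarkerHistogram", binEdges = seq(0, 1, 0.25),
           frequencies = c(0.4, 0.3, 0.2, 0.1), nValues = 8L,
           kind = "toa_norm")
  aPad <- new("MarkerHistogram", binEdges = seq(-0.5, 1.5, 0.25),
              frequencies = c(0, 0, 0.25, 0.25, 0.25, 0.25, 0, 0),
              nValues = 8L, kind = "toa_norm")
  bPad <- new("MarkerHistogram", binEdges = seq(-0.5, 1.5, 0.25),
              frequencies = c(0, 0, 0.4, 0.3, 0.2, 0.1, 0, 0),
              nValues = 8L, kind = "toa_norm")
  c1 <- compareHistograms(a, b, bins = 8)
  c2 <- compareHistograms(aPad, bPad, bins = 8)
  expect_equal(c1@chi2, c2@chi2, tolerance = 1e-12)
})

test_that("the goodness-of-fit mode weights by the reference histogram", {
  a <- new("MarkerHistogram", binEdges = c(0, 0.5, 1),
           frequencies = c(0.6, 0.4), nValues = 10L, kind = "toa_norm")
  b <- new("MarkerHistogram", binEdges = c(0, 0.5, 1),
           frequencies = c(0.5, 0.5), nValues = 10L, kind = "toa_norm")
  cmp <- compareHistograms(a, b, method = "expected")
  expect_equal(cmp@chi2, 0.01 / 0.5 + 0.01 / 0.5, tolerance = 1e-12)
})
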