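test_that("arrival time is the first crossing of 10% of the local peak", {
  s <- seriesFromCurves(cbind(c(0, 0, 1, 1), c(0, 0.05, 0.2, 1.0)))
  toa <- computeToa(s, maskAll(s))
  expect_equal(as.vector(presentValues(toa)), c(2, 2))
  expect_error(computeToa(s, maskAll(s), fraction = 1.2), "fraction")
})

test_that("discrete arrival lies within dt of the continuous crossing", {
  dtS <- 0.5
  t <- seq(0, 9.5, by = dtS)
  curve <- gammaVariate(t, t0 = 3, alpha = 2, tau = 1)
  s <- seriesFromCurves(matrix(curve, ncol = 1), dt = dtS)
  toa <- computeToa(s, maskAll(s))
  # bisection on the closed form against the sampled peak level
  thr <- 0.1 * max(curve)
  root <- uniroot(function(tt) gammaVariate(tt, 3, 2, 1) - thr,
                  c(3 + 1e-9, 5), tol = 1e-10)$root
  expect_lt(abs(presentValues(toa) - root), dtS)
  # sub-frame interpolation tightens the estimate
  toaI <- computeToa(s, maskAll(s), interpolate = TRUE)
  expect_lt(abs(presentValues(toaI) - root), abs(presentValues(toa) - root))
})

test_that("arrival normalization reverses and rescales by tEff", {
  vals <- array(c(2, 5, 10), dim = c(1, 1, 3))
  toa <- new("MarkerMap", values = vals, kind = "toa", dt = 1,
             spacing = c(1, 1, 1), context = list(tEff = 10))
  tn <- normalizeToa(toa)
  expect_equal(as.vector(markerValues(tn)), c(0.8, 0.5, 0.0))
  expect_equal(markerContext(tn)$toaMax, 10)
  expect_equal(markerContext(tn)$tEff, 10)

  single <- new("MarkerMap", values = array(4, dim = c(1, 1, 1)),
                kind = "toa", dt = 1, spacing = c(1, 1, 1),
                context = list(tEff = 7))
  expect_equal(as.vector(markerValues(normalizeToa(single))), 0)
})

test_that("wash-in slope is peak-scaled and matches a dense-grid oracle", {
  s <- seriesFromCurves(matrix(c(0, 0, 1, 1), ncol = 1))
  sl <- computeSlope(s, maskAll(s))
  expect_equal(as.vector(presentValues(sl)), 1)
  s5 <- seriesFromCurves(matrix(5 * c(0, 0, 1, 1), ncol = 1))
  expect_equal(presentValues(computeSlope(s5, maskAll(s5))),
               presentValues(sl))

  dtS <- 0.1
  t <- seq(0, 8, by = dtS)
  curve <- gammaVariate(t, t0 = 1, alpha = 2, tau = 1)
  sg <- seriesFromCurves(matrix(curve, ncol = 1), dt = dtS)
  si <- presentValues(computeSlope(sg, maskAll(sg)))
  h <- 1e-4
  td <- seq(0, 8, by = h)
  dense <- gammaVariate(td, 1, 2, 1)
  oracle <- max(diff(dense / max(dense))) / h
  expect_lt(abs(si - oracle) / oracle, 0.05)
})

test_that("slope normalization divides by the map maximum", {
  vals <- array(c(0.5, 1.0, 2.0), dim = c(1, 1, 3))
  sl <- new("MarkerMap", values = vals, kind = "slope", dt = 1,
            spacing = c(1, 1, 1))
  sn <- normalizeSlope(sl)
  expect_equal(as.vector(markerValues(sn)), c(0.25, 0.5, 1.0))
  expect_equal(markerContext(sn)$siMax, 2.0)
  # scalar-loop oracle on a random map
  set.seed(41)
  rv <- array(runif(24, 0.01, 3), dim = c(2, 3, 4))
  rm <- new("MarkerMap", values = rv, kind = "slope", dt = 1,
            spacing = c(1, 1, 1))
  got <- markerValues(normalizeSlope(rm))
  want <- rv
  for (i in seq_along(rv)) want[i] <- rv[i] / max(rv)
  expect_equal(got, want, tolerance = 1e-15)
  single <- new("MarkerMap", values = array(0.4, dim = c(1, 1, 1)),
                kind = "slope", dt = 1, spacing = c(1, 1, 1))
  expect_equal(as.vector(markerValues(normalizeSlope(single))), 1.0)
})

test_that("prepending zero frames shifts arrivals and not slopes", {
  set.seed(42)
  t <- seq(0, 11, by = 1)
  m <- sapply(c(2, 3.5, 5), function(t0) gammaVariate(t, t0, 2, 1))
  s <- seriesFromCurves(m, dt = 1)
  k <- 3
  mShift <- rbind(matrix(0, k, ncol(m)), m)
  sShift <- seriesFromCurves(mShift, dt = 1)
  toa <- presentValues(computeToa(s, maskAll(s)))
  toaShift <- presentValues(computeToa(sShift, maskAll(sShift)))
  expect_equal(toaShift, toa + k * 1, tolerance = 1e-12)
  expect_equal(presentValues(computeSlope(sShift, maskAll(sShift))),
               presentValues(computeSlope(s, maskAll(s))),
               tolerance = 1e-12)
})

test_that("markers are invariant to global and per-voxel positive scaling", {
  set.seed(43)
  t <- seq(0, 14, by = 0.5)
  m <- sapply(runif(6, 1, 4), function(t0) gammaVariate(t, t0, 2, 1))
  s <- seriesFromCurves(m, dt = 0.5)
  factors <- runif(6, 0.2, 5)
  sv <- seriesFromCurves(sweep(m, 2, factors, `*`), dt = 0.5)
  sg <- seriesFromCurves(m * 4.2, dt = 0.5)
  for (other in list(sv, sg)) {
    expect_equal(presentValues(computeToa(other, maskAll(other))),
                 presentValues(computeToa(s, maskAll(s))),
                 tolerance = 1e-12)
    expect_equal(presentValues(computeSlope(other, maskAll(other))),
                 presentValues(computeSlope(s, maskAll(s))),
                 tolerance = 1e-12)
  }
})

test_that("arrival is nondecreasing in the crossing fraction", {
  set.seed(44)
  t <- seq(0, 14, by = 0.5)
  m <- sapply(runif(8, 1, 4), function(t0) gammaVariate(t, t0, 2, 1))
  s <- seriesFromCurves(m, dt = 0.5)
  t10 <- presentValues(computeToa(s, maskAll(s), fraction = 0.1))
  t20 <- presentValues(computeToa(s, maskAll(s), fraction = 0.2))
  expect_true(all(t20 >= t10))
})

test_that("all-zero masked curves become missing, not instant arrivals", {
  m <- cbind(c(0, 0, 0, 0), c(0, 0, 1, 1))
  s <- seriesFromCurves(m)
  toa <- computeToa(s, maskAll(s))
  expect_true(is.na(markerValues(toa)[1, 1, 1]))
  expect_equal(markerValues(toa)[1, 1, 2], 2)
  sl <- computeSlope(s, maskAll(s))
  expect_true(is.na(markerValues(sl)[1, 1, 1]))
})

test_that("marker tables list present voxels with 0-based indices", {
  vals <- array(NA_real_, dim = c(1, 2, 2)); vals[1, 2, 1] <- 3.5
  m <- new("MarkerMap", values = vals, kind = "toa", dt = 1,
           spacing = c(1, 1, 1))
  tab <- markerTable(m)
  expect_equal(nrow(tab), 1)
  expect_equal(unlist(tab), c(z = 0, y = 1, x = 0, value = 3.5))
})
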