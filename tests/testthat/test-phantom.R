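test_that("gamma variate is zero at onset and peaks at A at t0 + alpha*tau", {
  expect_equal(gammaVariate(3, t0 = 3, alpha = 2, tau = 1.5), 0)
  expect_equal(gammaVariate(3 + 2 * 1.5, t0 = 3, alpha = 2, tau = 1.5,
                            A = 2.4), 2.4, tolerance = 1e-12)
  expect_error(gammaVariate(1, 0, alpha = -1, tau = 1), "alpha and tau")
})

test_that("the 10%-of-peak crossing matches a bisection oracle", {
  f <- function(t) gammaVariate(t, t0 = 0, alpha = 2, tau = 1) - 0.1
  root <- uniroot(f, c(1e-9, 2), tol = 1e-10)$root
  expect_equal(gammaVariate(root, 0, 2, 1), 0.1, tolerance = 1e-8)
  # generator truth uses the same crossing (via a noiseless simulation)
  spec <- defaultPhantomSpec(dt = 0.25, nFrames = 120)
  ph <- simulatePhantom(spec)
  arteryToa <- ph$truth@trueToa[ph$truth@labels == "artery" &
                                !is.na(ph$truth@labels)][1]
  expect_equal(arteryToa, 1 + root, tolerance = 1e-8)  # bolus t0 = 1 s
})

test_that("phantom rasterization is disjoint and passes delays through", {
  spec <- defaultPhantomSpec()
  bp <- buildPhantom(spec)
  counts <- vapply(bp$kinetics, function(k) length(k$idx), integer(1))
  expect_equal(sum(counts), sum(!is.na(bp$labels)))
  arteryT0 <- bp$kinetics[[1]]$t0
  veinT0 <- bp$kinetics[[3]]$t0
  expect_equal(veinT0 - arteryT0, 4)
  # brute-force membership recount of the nidus box
  nid <- spec@segments[[2]]$box
  g <- spec@gridShape
  n <- 0
  for (z in seq_len(g[1])) for (y in seq_len(g[2])) for (x in seq_len(g[3]))
    if (z - 1 >= nid$z[1] && z - 1 <= nid$z[2] &&
        y - 1 >= nid$y[1] && y - 1 <= nid$y[2] &&
        x - 1 >= nid$x[1] && x - 1 <= nid$x[2]) n <- n + 1
  expect_equal(sum(bp$labels == "nidus", na.rm = TRUE), n)
  expect_equal(length(bp$kinetics[[2]]$idx), n)
})

test_that("overlapping segments are rejected", {
  spec <- defaultPhantomSpec()
  bad <- spec@segments
  bad[[2]]$box <- bad[[1]]$box
  expect_error(phantomSpec(spec@gridShape, spec@spacing, spec@dt,
                           spec@nFrames, bad), "disjoint")
})

test_that("a noiseless unblurred simulation equals the closed form", {
  spec <- defaultPhantomSpec(dt = 0.5, nFrames = 48)
  ph <- simulatePhantom(spec)
  bp <- buildPhantom(spec)
  times <- (seq_len(spec@nFrames) - 1) * spec@dt
  arr <- intensities(ph$series)
  m <- matrix(arr, nrow = spec@nFrames)
  for (k in bp$kinetics) {
    want <- gammaVariate(times, k$t0, k$alpha, k$tau, k$A)
    for (i in k$idx)
      expect_equal(m[, i], want, tolerance = 1e-12)
  }
  expect_true(all(m[, setdiff(seq_len(prod(spec@gridShape)),
                              unlist(lapply(bp$kinetics, `[[`, "idx")))] == 0))
})

test_that("simulation is seed-deterministic and noise has the stated sd", {
  spec <- defaultPhantomSpec(noiseSd = 0.05, seed = 99L)
  a <- simulatePhantom(spec); b <- simulatePhantom(spec)
  expect_identical(intensities(a$series), intensities(b$series))

  # pre-onset frames contain pure noise clipped at zero; the surviving
  # positive half must match the upper tail of N(0, noiseSd)
  specPre <- defaultPhantomSpec(dt = 0.2, nFrames = 120, noiseSd = 0.05,
                                seed = 99L)
  noisy <- simulatePhantom(specPre)
  pre <- intensities(noisy$series)[1:5, , , ]  # all earlier than t0 = 1 s
  q90 <- qnorm(0.9, 0, 0.05)
  expect_lt(abs(mean(pre > q90) - 0.1), 0.02)
  posSd <- sd(c(pre[pre > 0], -pre[pre > 0]))  # unfold the clipped half
  expect_lt(abs(posSd - 0.05) / 0.05, 0.2)
})

test_that("ground truth is recovered from the noiseless series", {
  spec <- defaultPhantomSpec(dt = 0.5, nFrames = 120)
  ph <- simulatePhantom(spec)
  pre <- normalizeGlobal(ph$series)
  mask <- detectVessels(temporalStdMap(pre), 3.0)
  toa <- computeToa(pre, mask)
  sel <- which(maskArray(mask) & !is.na(markerValues(toa)))
  expect_true(all(abs(markerValues(toa)[sel] - ph$truth@trueToa[sel])
                  <= spec@dt + 1e-9))
  expect_gt(length(sel), 100)
})

test_that("median arrival respects artery < nidus < vein ordering", {
  for (seed in c(1, 2, 3)) {
    ph <- simulatePhantom(defaultPhantomSpec(noiseSd = 0.05, seed = seed))
    pre <- preprocessSeries(ph$series)
    mask <- detectVessels(temporalStdMap(pre), 3.0)
    toa <- computeToa(pre, mask)
    med <- vapply(c("artery", "nidus", "vein"), function(lb) {
      sel <- which(ph$truth@labels == lb & maskArray(mask))
      median(markerValues(toa)[sel], na.rm = TRUE)
    }, numeric(1))
    expect_true(med["artery"] < med["nidus"])
    expect_true(med["nidus"] < med["vein"])
  }
})

test_that("the projection twin is the z-sum of the volume", {
  ph <- simulatePhantom(defaultPhantomSpec(nFrames = 24))
  arr <- intensities(ph$series)
  proj <- intensities(ph$projection)
  expect_equal(dim(proj)[2], 1L)
  expect_equal(proj[5, 1, , ], apply(arr[5, , , ], c(2, 3), sum),
               tolerance = 1e-12)
  expect_equal(modalityTag(ph$projection), "projection")
})

test_that("the late venous compartment arrives far after the artery", {
  spec <- defaultPhantomSpec(lateVenous = TRUE)
  ph <- simulatePhantom(spec)
  arterialPeak <- 1 + 2 * 1  # t0 + alpha * tau
  lateToa <- ph$truth@trueToa[!is.na(ph$truth@trueToa)]
  expect_gt(max(lateToa), 3 * arterialPeak)
})
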