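#' Gamma-variate bolus concentration
#'
#' Standard first-pass bolus model in the normalized parameterization
#' `c(t) = A * ((t - t0) / (alpha * tau))^alpha * exp(alpha - (t - t0) / tau)`
#' for `t > t0` and 0 otherwise, which peaks at exactly `A` at
#' `t = t0 + alpha * tau`.
#'
#' @param t time(s) in seconds (vectorized).
#' @param t0 bolus onset in seconds.
#' @param alpha shape parameter (> 0).
#' @param tau time constant in seconds (> 0).
#' @param A peak amplitude (> 0).
#' @return Concentration value(s), same length as `t`.
#' @examples
#' gammaVariate(c(0, 2), t0 = 0, alpha = 2, tau = 1)  # peak 1 at t = 2
#' @export
gammaVariate <- function(t, t0, alpha, tau, A = 1) {
  .stopIf(alpha <= 0 || tau <= 0, "alpha and tau must be > 0")
  x <- (t - t0) / tau
  out <- numeric(length(t))
  pos <- x > 0
  out[pos] <- A * (x[pos] / alpha)^alpha * exp(alpha - x[pos])
  out
}

# Unit-peak shape in x = (t - t0)/tau and its derivative scale:
# h(x) = (x/alpha)^alpha exp(alpha - x), peak 1 at x = alpha.
.gvCrossX <- function(alpha, fraction = 0.1) {
  h <- function(x) (x / alpha)^alpha * exp(alpha - x) - fraction
  stats::uniroot(h, c(1e-12, alpha), tol = 1e-12)$root
}

.gvMaxSlopeX <- function(alpha) {
  # maximize h'(x) = h(x) (alpha/x - 1) on (0, alpha)
  hp <- function(x) (x / alpha)^alpha * exp(alpha - x) * (alpha / x - 1)
  stats::optimize(hp, c(1e-9, alpha), maximum = TRUE, tol = 1e-12)$objective
}

.fracBox <- function(zf, yf, xf, g) {
  r <- function(f, n) {
    lo <- min(n - 1L, floor(f[1] * n))
    hi <- max(lo, ceiling(f[2] * n) - 1L)
    c(lo, min(hi, n - 1L))
  }
  list(z = r(zf, g[1]), y = r(yf, g[2]), x = r(xf, g[3]))
}

#' Construct a PhantomSpec
#'
#' Low-level constructor; most users want [defaultPhantomSpec()].
#'
#' @param gridShape spatial grid `(z, y, x)`.
#' @param spacing voxel spacing `(mm_z, mm_y, mm_x)`.
#' @param dt frame interval in seconds.
#' @param nFrames number of frames; the acquisition window must cover
#'   the slowest bolus (`t0 + max onset + 5 * (tau + max dispersion)`).
#' @param segments list of segment definitions (see
#'   [PhantomSpec-class]).
#' @param bolus list `t0`, `alpha`, `tau`, `A`.
#' @param noiseSd,psfFwhm,seed,secondPass see [PhantomSpec-class].
#' @return A validated [PhantomSpec-class].
#' @export
phantomSpec <- function(gridShape, spacing, dt, nFrames, segments,
                        bolus = list(t0 = 1, alpha = 2, tau = 1, A = 1),
                        noiseSd = 0, psfFwhm = 0, seed = 42L,
                        secondPass = list()) {
  segments <- lapply(segments, function(s) {
    if (is.null(s$amplitude)) s$amplitude <- 1
    s
  })
  new("PhantomSpec", gridShape = as.integer(gridShape),
      spacing = as.numeric(spacing), dt = as.numeric(dt),
      nFrames = as.integer(nFrames), segments = segments, bolus = bolus,
      noiseSd = as.numeric(noiseSd), psfFwhm = as.numeric(psfFwhm),
      seed = as.integer(seed), secondPass = secondPass)
}

#' Default artery -> nidus -> veins phantom
#'
#' Builds the standard three-compartment vessel tree used throughout the
#' package's validation: a feeding artery (onset 0 s, no extra
#' dispersion), a nidus-like core (onset 1.5 s, +0.5 s dispersion) and
#' two draining veins (onset 4 s, +1 s dispersion), traversed by a
#' gamma-variate bolus (`t0` 1 s, shape 2, `tau` 1 s, unit peak).
#' Regions are boxes placed by fractional grid coordinates, so any grid
#' shape carries the same topology. With `lateVenous = TRUE` an extra
#' draining-venule compartment is appended whose contrast is a second,
#' delayed, low-amplitude gamma-variate (onset 15 s, +2 s dispersion,
#' amplitude 0.5), emulating the late venous drainage tail seen in
#' capillary-venulous malformations.
#'
#' @param modality `"volumetric"` (MRA-like: 8 x 24 x 24 grid, dt 1.1 s)
#'   or `"projection"` (DSA-like: fine-grid volume intended for z-sum
#'   projection, dt 0.125 s).
#' @param gridShape,dt,nFrames,noiseSd,psfFwhm,seed overrides;
#'   `nFrames = NULL` picks the shortest window covering the slowest
#'   bolus with 20% margin.
#' @param lateVenous append the late venule compartment (default
#'   `FALSE`).
#' @param secondPass optional recirculation, `list(delay =, fraction =)`.
#' @return A [PhantomSpec-class].
#' @examples
#' defaultPhantomSpec(dt = 0.5, nFrames = 120)
#' @export
defaultPhantomSpec <- function(modality = c("volumetric", "projection"),
                               gridShape = NULL, dt = NULL, nFrames = NULL,
                               noiseSd = 0, psfFwhm = 0, seed = 42L,
                               lateVenous = FALSE, secondPass = list()) {
  modality <- match.arg(modality)
  if (is.null(gridShape))
    gridShape <- if (modality == "volumetric") c(10L, 32L, 32L)
                 else c(10L, 64L, 64L)
  if (is.null(dt)) dt <- if (modality == "volumetric") 1.1 else 0.125
  spacing <- if (modality == "volumetric") c(1.4, 1.35, 1.35)
             else c(1.4, 0.675, 0.675)
  g <- as.integer(gridShape)
  # region sizes approximate the physical tree at MRA resolution:
  # nidus ~16 x 12 x 9 mm (~12 x 9 x 6 voxels at 1.35/1.4 mm), feeding
  # artery ~3 voxels across, draining veins ~2-3 voxels across
  segments <- list(
    list(label = "artery", box = .fracBox(c(0.40, 0.60), c(0.48, 0.58),
                                          c(0.00, 0.33), g),
         onsetDelay = 0, dispersionTau = 0, amplitude = 1),
    list(label = "nidus", box = .fracBox(c(0.20, 0.80), c(0.30, 0.70),
                                         c(0.36, 0.66), g),
         onsetDelay = 1.5, dispersionTau = 0.5, amplitude = 0.9),
    list(label = "vein", box = .fracBox(c(0.40, 0.60), c(0.18, 0.26),
                                        c(0.70, 1.00), g),
         onsetDelay = 4, dispersionTau = 1, amplitude = 0.7),
    list(label = "vein", box = .fracBox(c(0.40, 0.60), c(0.74, 0.82),
                                        c(0.70, 1.00), g),
         onsetDelay = 4, dispersionTau = 1, amplitude = 0.7))
  if (lateVenous)
    segments <- c(segments, list(
      list(label = "vein", box = .fracBox(c(0.40, 0.60), c(0.46, 0.54),
                                          c(0.70, 1.00), g),
           onsetDelay = 15, dispersionTau = 2, amplitude = 0.5)))
  bolus <- list(t0 = 1, alpha = 2, tau = 1, A = 1)
  if (is.null(nFrames)) {
    delays <- vapply(segments, `[[`, numeric(1), "onsetDelay")
    disp <- vapply(segments, `[[`, numeric(1), "dispersionTau")
    need <- bolus$t0 + max(delays) + 5 * (bolus$tau + max(disp))
    nFrames <- ceiling(1.2 * need / dt) + 1L
  }
  phantomSpec(g, spacing, dt, nFrames, segments, bolus,
              noiseSd = noiseSd, psfFwhm = psfFwhm, seed = seed,
              secondPass = secondPass)
}

# Per-segment effective kinetic parameters.
.segmentKinetics <- function(spec) {
  b <- spec@bolus
  lapply(spec@segments, function(s) list(
    label = s$label,
    idx = .boxIndices(s$box, spec@gridShape),
    t0 = b$t0 + s$onsetDelay,
    tau = b$tau + s$dispersionTau,
    alpha = b$alpha,
    A = b$A * s$amplitude))
}

# Segment curve at arbitrary times, including the optional second pass.
.segmentCurve <- function(k, t, secondPass) {
  cur <- gammaVariate(t, k$t0, k$alpha, k$tau, k$A)
  if (length(secondPass))
    cur <- cur + secondPass$fraction *
      gammaVariate(t, k$t0 + secondPass$delay, k$alpha, k$tau, k$A)
  cur
}

#' Rasterize a phantom's vessel tree
#'
#' @param spec a [PhantomSpec-class].
#' @return A list with `labels` (character `(z, y, x)` array, `NA`
#'   outside the tree) and `kinetics`, one entry per segment with the
#'   voxel indices and the effective per-voxel bolus parameters
#'   (`t0 = bolus t0 + onset delay`, `tau = bolus tau + dispersion`).
#' @export
buildPhantom <- function(spec) {
  validObject(spec)
  labels <- array(NA_character_, dim = spec@gridShape)
  kin <- .segmentKinetics(spec)
  for (k in kin) labels[k$idx] <- k$label
  list(labels = labels, kinetics = kin)
}

#' Simulate a dynamic phantom acquisition
#'
#' Evaluates every vessel voxel's gamma-variate curve at the frame times
#' `0, dt, ..., (nFrames - 1) * dt`, applies an optional Gaussian blur
#' of FWHM `psfFwhm` mm (partial-volume emulation), adds seeded
#' zero-mean Gaussian noise of sd `noiseSd` and clips negatives to 0.
#' Ground truth (continuous 10%-of-peak crossing and maximum unit-peak
#' derivative) is computed on the noiseless, unblurred curves - in
#' closed form via root finding, or on a dense time grid when a second
#' pass is present.
#'
#' @param spec a [PhantomSpec-class].
#' @return A list with `series` (a [DynamicSeries-class]), `truth`
#'   (a [PhantomTruth-class]) and `projection` (the z-sum
#'   [DynamicSeries-class] twin emulating a DSA projection of the same
#'   object).
#' @examples
#' ph <- simulatePhantom(defaultPhantomSpec(noiseSd = 0.05, seed = 7))
#' ph$series
#' @export
simulatePhantom <- function(spec) {
  validObject(spec)
  g <- spec@gridShape
  T <- spec@nFrames
  times <- (seq_len(T) - 1L) * spec@dt
  m <- matrix(0, nrow = T, ncol = prod(g))
  kin <- .segmentKinetics(spec)
  labels <- array(NA_character_, dim = g)
  trueToa <- array(NA_real_, dim = g)
  trueSi <- array(NA_real_, dim = g)
  for (k in kin) {
    m[, k$idx] <- .segmentCurve(k, times, spec@secondPass)
    labels[k$idx] <- k$label
    if (length(spec@secondPass)) {
      tDense <- seq(0, (T - 1L) * spec@dt, by = spec@dt / 200)
      cur <- .segmentCurve(k, tDense, spec@secondPass)
      pk <- max(cur)
      cross <- which(cur >= 0.1 * pk)[1]
      trueToa[k$idx] <- tDense[cross]
      trueSi[k$idx] <- max(diff(cur / pk)) / (spec@dt / 200)
    } else {
      trueToa[k$idx] <- k$t0 + k$tau * .gvCrossX(k$alpha)
      trueSi[k$idx] <- .gvMaxSlopeX(k$alpha) / k$tau
    }
  }
  arr <- array(m, dim = c(T, g))
  if (spec@psfFwhm > 0) {
    sigma <- spec@psfFwhm / (2 * sqrt(2 * log(2))) / spec@spacing
    for (t in seq_len(T))
      arr[t, , , ] <- .gaussianBlur3d(array(arr[t, , , ], dim = g), sigma)
  }
  if (spec@noiseSd > 0) {
    seedState <- if (exists(".Random.seed", .GlobalEnv))
      get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(seedState))
      assign(".Random.seed", seedState, .GlobalEnv))
    set.seed(spec@seed)
    arr <- arr + stats::rnorm(length(arr), 0, spec@noiseSd)
    arr[arr < 0] <- 0
  }
  series <- DynamicSeries(arr, dt = spec@dt, spacing = spec@spacing,
                          modalityTag = if (g[1] == 1L) "projection"
                                        else "volumetric",
                          backgroundSubtracted = TRUE)
  truth <- new("PhantomTruth", trueToa = trueToa, trueSi = trueSi,
               labels = labels)
  list(series = series, truth = truth, projection = projectSeries(series))
}

#' Project a volumetric series to a planar (DSA-like) series
#'
#' Sums the intensity along z, a deliberate idealization of cone-beam
#' projection imaging: every frame becomes a single 2D projection of the
#' contrast column.
#'
#' @param series a [DynamicSeries-class].
#' @return A planar [DynamicSeries-class] with `modalityTag`
#'   `"projection"` and z-extent 1.
#' @export
projectSeries <- function(series) {
  arr <- intensities(series)
  d <- dim(arr)
  proj <- array(0, dim = c(d[1], 1L, d[3], d[4]))
  proj[, 1L, , ] <- colSums(aperm(arr, c(2, 1, 3, 4)))
  DynamicSeries(proj, dt = frameInterval(series),
                spacing = voxelSpacing(series),
                injectionTime = injectionTime(series),
                modalityTag = "projection",
                backgroundSubtracted = series@backgroundSubtracted)
}

#' Twin-acquisition phantom pair
#'
#' Simulates the same vessel-tree geometry under the two acquisition
#' regimes used for in vitro validation: a fine-grid, fast-frame
#' (dt 0.125 s) acquisition summed along z into a DSA-like projection
#' series, and a coarse-grid, slow-frame (dt 1.1 s) blurred MRA-like
#' volumetric series. Both share the bolus kinetics; only sampling,
#' blur and noise realizations differ.
#'
#' @param seed RNG seed; the two acquisitions use `seed` and
#'   `seed + 1`.
#' @param noiseSd additive noise sd for both acquisitions (default
#'   0.02).
#' @param lateVenous passed to [defaultPhantomSpec()].
#' @return A list with `projection` and `volumetric`
#'   [DynamicSeries-class] objects and the volumetric `truth`.
#' @export
twinPhantomPair <- function(seed = 42L, noiseSd = 0.02, lateVenous = FALSE) {
  fine <- simulatePhantom(defaultPhantomSpec(
    "projection", noiseSd = noiseSd, seed = seed, lateVenous = lateVenous))
  coarse <- simulatePhantom(defaultPhantomSpec(
    "volumetric", noiseSd = noiseSd, psfFwhm = 2.0, seed = seed + 1L,
    lateVenous = lateVenous))
  list(projection = fine$projection, volumetric = coarse$series,
       truth = coarse$truth)
}
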