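#' @useDynLib pavmark, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @import methods
#' @importFrom stats median sd rnorm runif optimize uniroot pchisq quantile
#' @importFrom utils write.csv read.csv packageVersion modifyList
NULL

.MARKER_KINDS <- c("toa", "toa_norm", "slope", "slope_norm")

#' DynamicSeries: a time-resolved intensity grid
#'
#' Container for a dynamic angiographic acquisition: a 4D intensity array
#' indexed `(t, z, y, x)` (planar series carry a z-extent of 1), the frame
#' interval in seconds, voxel spacing in mm, and acquisition metadata.
#' Frame `k` (0-based) is acquired at `k * frameInterval(x)` seconds from
#' the start of the acquisition.
#'
#' @slot intensities 4D numeric array, `(t, z, y, x)`, finite values.
#' @slot dt frame interval in seconds (> 0).
#' @slot spacing voxel spacing `(mm_z, mm_y, mm_x)`, all > 0.
#' @slot injectionTime contrast injection time in seconds relative to
#'   frame 0 (default 0).
#' @slot modalityTag `"projection"` (DSA-like 2D+t) or `"volumetric"`
#'   (MRA-like 3D+t).
#' @slot backgroundSubtracted whether the pre-contrast background frame
#'   has already been removed.
#' @exportClass DynamicSeries
setClass("DynamicSeries",
  representation(
    intensities = "array",
    dt = "numeric",
    spacing = "numeric",
    injectionTime = "numeric",
    modalityTag = "character",
    backgroundSubtracted = "logical"
  )
)

setValidity("DynamicSeries", function(object) {
  msg <- character()
  d <- dim(object@intensities)
  if (length(d) != 4L)
    msg <- c(msg, "intensities must be a 4D (t, z, y, x) array")
  else {
    if (d[1] < 2L) msg <- c(msg, "temporal extent < 2")
    if (any(d < 1L)) msg <- c(msg, "all dimensions must be >= 1")
  }
  if (!all(is.finite(object@intensities)))
    msg <- c(msg, "intensities must be finite")
  if (length(object@dt) != 1L || !is.finite(object@dt) || object@dt <= 0)
    msg <- c(msg, "dt must be a single positive number (seconds)")
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    msg <- c(msg, "spacing must be three positive numbers (mm_z, mm_y, mm_x)")
  if (!object@modalityTag %in% c("projection", "volumetric"))
    msg <- c(msg, "modalityTag must be 'projection' or 'volumetric'")
  if (length(msg)) msg else TRUE
})

#' Construct a DynamicSeries
#'
#' @param intensities 4D `(t, z, y, x)` array, or a 3D `(t, y, x)` array
#'   which is promoted to z-extent 1.
#' @param dt frame interval in seconds.
#' @param spacing voxel spacing `(mm_z, mm_y, mm_x)`.
#' @param injectionTime injection time in seconds relative to frame 0.
#' @param modalityTag `"projection"` or `"volumetric"`; defaults to
#'   `"projection"` for z-extent 1 and `"volumetric"` otherwise.
#' @param backgroundSubtracted logical.
#' @return A [DynamicSeries-class] object.
#' @examples
#' s <- DynamicSeries(array(runif(5 * 4 * 4), dim = c(5, 1, 4, 4)), dt = 1.1)
#' nFrames(s)
#' @export
DynamicSeries <- function(intensities, dt, spacing = c(1, 1, 1),
                          injectionTime = 0, modalityTag = NULL,
                          backgroundSubtracted = FALSE) {
  if (length(dim(intensities)) == 3L)
    dim(intensities) <- c(dim(intensities)[1], 1L, dim(intensities)[2:3])
  storage.mode(intensities) <- "double"
  if (is.null(modalityTag))
    modalityTag <- if (dim(intensities)[2] == 1L) "projection" else "volumetric"
  new("DynamicSeries",
      intensities = intensities, dt = as.numeric(dt),
      spacing = as.numeric(spacing), injectionTime = as.numeric(injectionTime),
      modalityTag = modalityTag,
      backgroundSubtracted = backgroundSubtracted)
}

#' VesselMask: contrast-carrying voxels
#'
#' Boolean spatial grid `(z, y, x)` of voxels judged to carry contrast
#' agent, produced by [detectVessels()].
#'
#' @slot mask logical 3D array `(z, y, x)`.
#' @slot thresholdUsed the detection threshold, in units of the robust
#'   noise scale of the temporal standard deviation map.
#' @slot sourceStat the statistic the mask was derived from
#'   (`"temporal_std"`).
#' @exportClass VesselMask
setClass("VesselMask",
  representation(mask = "array", thresholdUsed = "numeric",
                 sourceStat = "character")
)

setValidity("VesselMask", function(object) {
  msg <- character()
  if (length(dim(object@mask)) != 3L)
    msg <- c(msg, "mask must be a 3D (z, y, x) array")
  if (!is.logical(object@mask)) msg <- c(msg, "mask must be logical")
  if (any(is.na(object@mask))) msg <- c(msg, "mask must not contain NA")
  if (!object@sourceStat %in% "temporal_std")
    msg <- c(msg, "sourceStat must be 'temporal_std'")
  if (length(msg)) msg else TRUE
})

#' StdMap: per-voxel temporal standard deviation
#'
#' @slot values nonnegative 3D `(z, y, x)` array of per-voxel sample
#'   standard deviations over time.
#' @slot noiseScale robust background level of the std population (the
#'   median per-voxel std); 0 only for series with no temporal variation
#'   anywhere.
#' @exportClass StdMap
setClass("StdMap",
  representation(values = "array", noiseScale = "numeric")
)

setValidity("StdMap", function(object) {
  msg <- character()
  if (length(dim(object@values)) != 3L)
    msg <- c(msg, "values must be a 3D (z, y, x) array")
  if (any(!is.finite(object@values)) || any(object@values < 0))
    msg <- c(msg, "values must be finite and >= 0")
  if (length(object@noiseScale) != 1L || !is.finite(object@noiseScale) ||
      object@noiseScale < 0)
    msg <- c(msg, "noiseScale must be a single number >= 0")
  if (length(msg)) msg else TRUE
})

#' MarkerMap: a per-voxel hemodynamic marker field
#'
#' Scalar `(z, y, x)` field for one marker kind, with `NA` as the missing
#' value sentinel outside the vessel mask (and for masked voxels whose
#' time-intensity curve never rises above zero, for which no arrival is
#' defined). Kinds:
#'
#' * `toa` — contrast time-of-arrival in seconds (time from injection to
#'   the first frame at or above 10% of the voxel's own peak intensity);
#' * `toa_norm` — reversed, normalized arrival
#'   `(max ToA - ToA) / tEff` in `[0, 1]`;
#' * `slope` — maximum forward-difference wash-in slope of the unit-peak
#'   (dilution-corrected) curve, in 1/s;
#' * `slope_norm` — slope divided by the map-wide maximum slope, in
#'   `[0, 1]` with maximum exactly 1.
#'
#' @slot values numeric 3D `(z, y, x)` array with `NA` outside the mask.
#' @slot kind one of `"toa"`, `"toa_norm"`, `"slope"`, `"slope_norm"`.
#' @slot dt frame interval of the parent series in seconds.
#' @slot spacing voxel spacing `(mm_z, mm_y, mm_x)` of the parent series.
#' @slot context named list of normalization context: `toaMax`, `tEff`
#'   (seconds) and/or `siMax` (1/s) where applicable.
#' @exportClass MarkerMap
setClass("MarkerMap",
  representation(values = "array", kind = "character", dt = "numeric",
                 spacing = "numeric", context = "list")
)

setValidity("MarkerMap", function(object) {
  msg <- character()
  if (length(dim(object@values)) != 3L)
    msg <- c(msg, "values must be a 3D (z, y, x) array")
  if (!object@kind %in% .MARKER_KINDS)
    msg <- c(msg, sprintf("kind must be one of %s",
                          paste(.MARKER_KINDS, collapse = ", ")))
  v <- object@values[!is.na(object@values)]
  if (length(v)) {
    if (any(!is.finite(v))) msg <- c(msg, "present values must be finite")
    tol <- 1e-8
    if (object@kind == "toa" && any(v < -tol))
      msg <- c(msg, "toa values must be >= 0")
    if (object@kind %in% c("toa_norm", "slope_norm")) {
      # the attained endpoints (toa_norm touches 0, slope_norm touches 1)
      # are postconditions of normalizeToa()/normalizeSlope(), not class
      # invariants: subsets of a valid map remain valid objects
      if (any(v < -tol) || any(v > 1 + tol))
        msg <- c(msg, sprintf("%s values must lie in [0, 1]", object@kind))
    }
  }
  if (length(object@dt) != 1L || object@dt <= 0)
    msg <- c(msg, "dt must be a single positive number")
  if (length(object@spacing) != 3L || any(object@spacing <= 0))
    msg <- c(msg, "spacing must be three positive numbers")
  if (length(msg)) msg else TRUE
})

.MarkerMap <- function(values, kind, dt, spacing, context = list()) {
  storage.mode(values) <- "double"
  new("MarkerMap", values = values, kind = kind, dt = as.numeric(dt),
      spacing = as.numeric(spacing), context = context)
}

#' MarkerHistogram: normalized frequency distribution of a marker
#'
#' @slot binEdges strictly increasing numeric vector of length `m + 1`.
#' @slot frequencies nonnegative numeric vector of length `m` summing
#'   to 1 over the contributing voxels.
#' @slot nValues number of contributing voxels.
#' @slot kind marker kind the histogram was built from.
#' @exportClass MarkerHistogram
setClass("MarkerHistogram",
  representation(binEdges = "numeric", frequencies = "numeric",
                 nValues = "integer", kind = "character")
)

setValidity("MarkerHistogram", function(object) {
  msg <- character()
  if (length(object@binEdges) != length(object@frequencies) + 1L)
    msg <- c(msg, "binEdges must have one more element than frequencies")
  if (any(diff(object@binEdges) <= 0))
    msg <- c(msg, "binEdges must be strictly increasing")
  if (any(object@frequencies < 0))
    msg <- c(msg, "frequencies must be nonnegative")
  if (abs(sum(object@frequencies) - 1) > 1e-9)
    msg <- c(msg, "frequencies must sum to 1")
  if (object@nValues < 1L) msg <- c(msg, "nValues must be >= 1")
  if (!object@kind %in% .MARKER_KINDS)
    msg <- c(msg, "kind must be a marker kind")
  if (length(msg)) msg else TRUE
})

#' HistogramMetrics: moment summary of a marker distribution
#'
#' Moments are computed on the raw per-voxel values with the population
#' (divisor n) convention: skewness is the Fisher-Pearson
#' `m3 / m2^(3/2)` and kurtosis is the non-excess `m4 / m2^2`, so a
#' normal sample prints a kurtosis near 3.
#'
#' @slot mean,median,skewness,kurtosis the four summary statistics.
#' @slot n number of values summarized.
#' @exportClass HistogramMetrics
setClass("HistogramMetrics",
  representation(mean = "numeric", median = "numeric", skewness = "numeric",
                 kurtosis = "numeric", n = "integer")
)

#' HistogramComparison: chi-square comparison of two marker histograms
#'
#' @slot chi2 the symmetric chi-square statistic on normalized
#'   frequencies, `sum((fa - fb)^2 / (fa + fb))` over bins with mass.
#' @slot pValue upper-tail chi-square probability at `df`.
#' @slot df degrees of freedom: occupied bins minus 1, forced >= 1.
#' @slot binsCompared number of bins on the common grid.
#' @slot method `"symmetric"` or `"expected"` (goodness-of-fit against
#'   the second histogram).
#' @exportClass HistogramComparison
setClass("HistogramComparison",
  representation(chi2 = "numeric", pValue = "numeric", df = "integer",
                 binsCompared = "integer", method = "character")
)

#' PhantomSpec: synthetic bolus-transport phantom definition
#'
#' Describes an artery -> nidus -> draining-vein tree on a voxel grid,
#' traversed by a dispersed gamma-variate contrast bolus. Each segment is
#' a spatially disjoint box region carrying the bolus with a
#' segment-specific onset delay and extra dispersion (effective time
#' constant `tau + dispersionTau`), modelling increasing bolus dispersion
#' from the feeding artery towards the draining veins.
#'
#' @slot gridShape spatial grid `(z, y, x)`.
#' @slot spacing voxel spacing `(mm_z, mm_y, mm_x)`.
#' @slot dt frame interval in seconds.
#' @slot nFrames number of frames.
#' @slot segments list of segments, each a list with elements `label`
#'   (`"artery"`, `"nidus"` or `"vein"`), `box` (list of 0-based
#'   inclusive index ranges `z`, `y`, `x`), `onsetDelay` (s),
#'   `dispersionTau` (s) and `amplitude`.
#' @slot bolus list with `t0` (s), `alpha` (shape), `tau` (s) and
#'   `A` (peak amplitude) of the injected gamma-variate bolus.
#' @slot noiseSd additive Gaussian noise standard deviation (>= 0).
#' @slot psfFwhm Gaussian blur FWHM in mm (>= 0), emulating
#'   partial-volume averaging.
#' @slot seed integer RNG seed for the noise.
#' @slot secondPass optional recirculation: a list with `delay` (s) and
#'   `fraction`; when non-empty every vessel voxel receives an additional
#'   delayed gamma-variate of that relative amplitude.
#' @exportClass PhantomSpec
setClass("PhantomSpec",
  representation(gridShape = "integer", spacing = "numeric", dt = "numeric",
                 nFrames = "integer", segments = "list", bolus = "list",
                 noiseSd = "numeric", psfFwhm = "numeric", seed = "integer",
                 secondPass = "list")
)

setValidity("PhantomSpec", function(object) {
  msg <- character()
  if (length(object@gridShape) != 3L || any(object@gridShape < 1L))
    msg <- c(msg, "gridShape must be three positive integers (z, y, x)")
  if (object@dt <= 0) msg <- c(msg, "dt must be > 0")
  if (object@nFrames < 2L) msg <- c(msg, "nFrames must be >= 2")
  b <- object@bolus
  if (!all(c("t0", "alpha", "tau", "A") %in% names(b)))
    msg <- c(msg, "bolus must have t0, alpha, tau, A")
  else if (b$alpha <= 0 || b$tau <= 0 || b$A <= 0)
    msg <- c(msg, "bolus alpha, tau, A must be > 0")
  if (!length(object@segments)) msg <- c(msg, "at least one segment required")
  occupied <- NULL
  for (s in object@segments) {
    if (!all(c("label", "box", "onsetDelay", "dispersionTau") %in% names(s))) {
      msg <- c(msg, "each segment needs label, box, onsetDelay, dispersionTau")
      next
    }
    if (!s$label %in% c("artery", "nidus", "vein"))
      msg <- c(msg, "segment label must be artery, nidus or vein")
    idx <- .boxIndices(s$box, object@gridShape)
    if (!length(idx)) msg <- c(msg, "segment box is empty or out of bounds")
    if (any(idx %in% occupied)) msg <- c(msg, "segments must be disjoint")
    occupied <- c(occupied, idx)
  }
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
  if (object@psfFwhm < 0) msg <- c(msg, "psfFwhm must be >= 0")
  if (length(msg) == 0 && all(c("t0", "alpha", "tau", "A") %in% names(b))) {
    delays <- vapply(object@segments, function(s) s$onsetDelay, numeric(1))
    disp <- vapply(object@segments, function(s) s$dispersionTau, numeric(1))
    need <- b$t0 + max(delays) + 5 * (b$tau + max(disp))
    if (object@nFrames * object@dt <= need)
      msg <- c(msg, sprintf(
        "acquisition window %.1f s too short: bolus needs > %.1f s",
        object@nFrames * object@dt, need))
  }
  if (length(msg)) msg else TRUE
})

#' PhantomTruth: ground truth for a simulated phantom
#'
#' Ground truth is defined on the noiseless, unblurred voxel curves:
#' `trueToa` is the continuous 10%-of-peak crossing time and `trueSi`
#' the maximum derivative of the unit-peak curve. Voxels outside every
#' segment are `NA`.
#'
#' @slot trueToa seconds, `(z, y, x)` array.
#' @slot trueSi 1/s, `(z, y, x)` array.
#' @slot labels character `(z, y, x)` array of segment labels
#'   (`NA` outside the tree).
#' @exportClass PhantomTruth
setClass("PhantomTruth",
  representation(trueToa = "array", trueSi = "array", labels = "array")
)

#' PreprocessConfig: parameters of the preprocessing chain
#'
#' Defaults follow the two acquisition regimes: volumetric (MRA-like)
#' series use a 5-frame temporal median and a 2x2 in-plane median;
#' projection (DSA-like) series use a 3-frame temporal median and a 6x6
#' in-plane median (finer grids carry more salt-and-pepper noise). The
#' noise threshold default 0.08 is the midpoint of the intended
#' 0.07-0.10 range.
#'
#' @slot temporalWindow odd integer temporal median window (frames).
#' @slot spatialKernel integer pair `(ky, kx)` in-plane median kernel.
#' @slot noiseFraction fraction of the global maximum below which
#'   intensities are zeroed, in `[0, 1)`.
#' @slot cropBox optional list of 0-based inclusive index ranges
#'   `z`, `y`, `x` (empty list = no crop).
#' @slot backgroundFrame 0-based index of the pre-contrast frame.
#' @slot polarity `"positive_contrast"` or `"negative_contrast"`.
#' @exportClass PreprocessConfig
setClass("PreprocessConfig",
  representation(temporalWindow = "integer", spatialKernel = "integer",
                 noiseFraction = "numeric", cropBox = "list",
                 backgroundFrame = "integer", polarity = "character")
)

setValidity("PreprocessConfig", function(object) {
  msg <- character()
  if (object@temporalWindow < 1L || object@temporalWindow %% 2L == 0L)
    msg <- c(msg, "temporalWindow must be odd and >= 1")
  if (length(object@spatialKernel) != 2L || any(object@spatialKernel < 1L))
    msg <- c(msg, "spatialKernel must be two integers >= 1")
  if (object@noiseFraction < 0 || object@noiseFraction >= 1)
    msg <- c(msg, "noiseFraction must lie in [0, 1)")
  if (object@backgroundFrame < 0L)
    msg <- c(msg, "backgroundFrame must be >= 0")
  if (!object@polarity %in% c("positive_contrast", "negative_contrast"))
    msg <- c(msg, "polarity must be positive_contrast or negative_contrast")
  if (length(msg)) msg else TRUE
})

#' RenderSpec: colour rendering parameters
#'
#' Marker renderings use a perceptual red-to-blue map: low arrival times
#' (early, arterial) render red, late (venous) blue; slopes use the same
#' scale with low values red.
#'
#' @slot colormapName a `grDevices::hcl.colors` palette name.
#' @slot valueRange explicit `(lo, hi)` or `NULL` for the map's range.
#' @slot background `"transparent"` or `"black"` for missing voxels.
#' @slot projectionMode `"slice"` or `"maximum_intensity"`.
#' @exportClass RenderSpec
setClass("RenderSpec",
  representation(colormapName = "character", valueRange = "ANY",
                 background = "character", projectionMode = "character")
)

setValidity("RenderSpec", function(object) {
  msg <- character()
  if (!is.null(object@valueRange)) {
    if (length(object@valueRange) != 2L ||
        object@valueRange[1] >= object@valueRange[2])
      msg <- c(msg, "valueRange must be (lo, hi) with lo < hi")
  }
  if (!object@background %in% c("transparent", "black"))
    msg <- c(msg, "background must be 'transparent' or 'black'")
  if (!object@projectionMode %in% c("slice", "maximum_intensity"))
    msg <- c(msg, "projectionMode must be 'slice' or 'maximum_intensity'")
  if (length(msg)) msg else TRUE
})

#' @describeIn RenderSpec-class Constructor.
#' @param colormapName,valueRange,background,projectionMode see slots.
#' @export
RenderSpec <- function(colormapName = "RdYlBu", valueRange = NULL,
                       background = "black",
                       projectionMode = "slice") {
  new("RenderSpec", colormapName = colormapName, valueRange = valueRange,
      background = background, projectionMode = projectionMode)
}
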