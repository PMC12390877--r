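#' Per-voxel temporal standard deviation
#'
#' Computes the sample standard deviation (divisor `T - 1`) of every
#' voxel's time course. Voxels traversed by contrast fluctuate strongly
#' over time; static background voxels fluctuate only with noise, so the
#' std population is background-dominated and its median serves as a
#' robust noise scale against which vessel detection thresholds are
#' expressed.
#'
#' @param series a [DynamicSeries-class] with at least 2 frames.
#' @return A [StdMap-class].
#' @export
temporalStdMap <- function(series) {
  arr <- intensities(series)
  T <- dim(arr)[1]
  .stopIf(T < 2L, "temporal std needs at least 2 frames")
  m <- .asTimeByVoxel(arr)
  mu <- colMeans(m)
  v <- colSums(m * m) - T * mu * mu
  v[v < 0] <- 0  # guard rounding on constant courses
  s <- sqrt(v / (T - 1))
  vals <- array(s, dim = dim(arr)[-1])
  new("StdMap", values = vals, noiseScale = stats::median(s))
}

#' Detect contrast-carrying voxels
#'
#' Thresholds the temporal std map at `threshold` times its robust noise
#' scale (the median per-voxel std). The default 3.0 sits mid-way in the
#' useful tuning range 2.7-3.4; lower values admit fainter vessels at
#' the cost of noise. Because the threshold is expressed in noise-scale
#' units it is invariant to global intensity rescaling. Voxels with zero
#' temporal variation are never included.
#'
#' @param stdMap a [StdMap-class], or a [DynamicSeries-class] (the std
#'   map is then computed first).
#' @param threshold positive multiplier of the noise scale (default 3.0,
#'   tuning range 2.7-3.4).
#' @return A [VesselMask-class].
#' @examples
#' ph <- simulatePhantom(defaultPhantomSpec(nFrames = 24))
#' detectVessels(temporalStdMap(ph$series))
#' @export
detectVessels <- function(stdMap, threshold = 3.0) {
  if (is(stdMap, "DynamicSeries")) stdMap <- temporalStdMap(stdMap)
  .stopIf(threshold <= 0, "threshold must be > 0")
  v <- stdValues(stdMap)
  m <- v >= threshold * noiseScale(stdMap) & v > 0
  .stopIf(!any(m),
    "empty vessel mask: no voxel reaches %g x noise scale; try a lower threshold (range 2.7-3.4)",
    threshold)
  new("VesselMask", mask = m, thresholdUsed = threshold,
      sourceStat = "temporal_std")
}
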