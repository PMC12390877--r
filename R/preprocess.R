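#' Preprocessing configuration
#'
#' Build a [PreprocessConfig-class] with modality-appropriate defaults:
#' volumetric (MRA-like) series default to a 5-frame temporal median and
#' a 2x2 in-plane median; projection (DSA-like) series to a 3-frame
#' temporal median and a 6x6 in-plane median. The noise threshold
#' defaults to 0.08 (intended range 0.07-0.10).
#'
#' @param modality `"volumetric"` or `"projection"`.
#' @param temporalWindow odd integer; overrides the modality default.
#' @param spatialKernel integer pair `(ky, kx)`; overrides the default.
#' @param noiseFraction fraction of the global maximum in `[0, 1)`.
#' @param cropBox optional list of 0-based inclusive ranges `z`, `y`, `x`.
#' @param backgroundFrame 0-based pre-contrast frame index.
#' @param polarity `"positive_contrast"` (vessels brighten) or
#'   `"negative_contrast"` (vessels darken, as in raw DSA).
#' @return A [PreprocessConfig-class].
#' @examples
#' preprocessConfig("projection")
#' @export
preprocessConfig <- function(modality = c("volumetric", "projection"),
                             temporalWindow = NULL, spatialKernel = NULL,
                             noiseFraction = 0.08, cropBox = list(),
                             backgroundFrame = 0L,
                             polarity = "positive_contrast") {
  modality <- match.arg(modality)
  if (is.null(temporalWindow))
    temporalWindow <- if (modality == "volumetric") 5L else 3L
  if (is.null(spatialKernel))
    spatialKernel <- if (modality == "volumetric") c(2L, 2L) else c(6L, 6L)
  new("PreprocessConfig",
      temporalWindow = as.integer(temporalWindow),
      spatialKernel = as.integer(spatialKernel),
      noiseFraction = as.numeric(noiseFraction),
      cropBox = cropBox,
      backgroundFrame = as.integer(backgroundFrame),
      polarity = polarity)
}

.replaceIntensities <- function(series, arr, backgroundSubtracted = NULL) {
  series@intensities <- arr
  if (!is.null(backgroundSubtracted))
    series@backgroundSubtracted <- backgroundSubtracted
  validObject(series)
  series
}

#' Subtract the pre-contrast background frame
#'
#' Removes the background frame (taken before contrast injection) from
#' every frame. For `negative_contrast` series (vessels darker than
#' background, as in unsubtracted DSA) the difference is sign-flipped
#' first so that contrast always increases intensity. Negative residuals
#' are clipped to 0, since the markers are defined on nonnegative
#' wash-in curves.
#'
#' @param series a [DynamicSeries-class] not yet background-subtracted.
#' @param cfg a [PreprocessConfig-class] (uses `backgroundFrame` and
#'   `polarity`).
#' @return A background-subtracted [DynamicSeries-class] of the same
#'   shape (the background frame becomes all-zero).
#' @export
subtractBackground <- function(series, cfg = preprocessConfig(modalityTag(series))) {
  .stopIf(series@backgroundSubtracted,
          "series is already background-subtracted")
  arr <- intensities(series)
  bg <- cfg@backgroundFrame
  .stopIf(bg < 0L || bg >= dim(arr)[1],
          "background frame index %d outside [0, %d]", bg, dim(arr)[1] - 1L)
  bgFrame <- arr[bg + 1L, , , , drop = FALSE]
  diffArr <- sweep(arr, 2:4, array(bgFrame, dim = dim(arr)[-1]), `-`)
  if (cfg@polarity == "negative_contrast") diffArr <- -diffArr
  diffArr[diffArr < 0] <- 0
  .replaceIntensities(series, diffArr, backgroundSubtracted = TRUE)
}

#' Crop a series to a spatial box
#'
#' @param series a [DynamicSeries-class].
#' @param box list of 0-based inclusive index ranges `z`, `y`, `x`
#'   (e.g. `list(z = c(0, 0), y = c(4, 11), x = c(4, 11))`).
#' @return The cropped [DynamicSeries-class]; `dt` and spacing unchanged.
#' @export
cropSeries <- function(series, box) {
  arr <- intensities(series)
  d <- dim(arr)[-1]
  .stopIf(!all(c("z", "y", "x") %in% names(box)),
          "crop box must have z, y, x ranges")
  rng <- lapply(c(z = "z", y = "y", x = "x"), function(ax) box[[ax]])
  for (ax in 1:3) {
    r <- rng[[ax]]
    .stopIf(length(r) != 2L || r[1] > r[2] || r[1] < 0 || r[2] >= d[ax],
            "crop box %s-range out of bounds or empty", names(rng)[ax])
  }
  out <- arr[, seq.int(rng$z[1] + 1L, rng$z[2] + 1L),
             seq.int(rng$y[1] + 1L, rng$y[2] + 1L),
             seq.int(rng$x[1] + 1L, rng$x[2] + 1L), drop = FALSE]
  .replaceIntensities(series, out)
}

#' Temporal median filter
#'
#' Replaces each voxel's time course by its running median with mirror
#' (reflect) boundary padding, suppressing isolated temporal intensity
#' spikes.
#'
#' @param series a [DynamicSeries-class].
#' @param window odd integer window length, `<=` the temporal extent.
#' @return The filtered [DynamicSeries-class], same shape.
#' @export
temporalMedianFilter <- function(series, window) {
  arr <- intensities(series)
  T <- dim(arr)[1]
  window <- as.integer(window)
  .stopIf(window %% 2L == 0L, "temporal median window must be odd")
  .stopIf(window > T, "temporal median window %d exceeds %d frames", window, T)
  if (window == 1L) return(series)
  m <- .temporalMedianCpp(.asTimeByVoxel(arr), window)
  .replaceIntensities(series, .fromTimeByVoxel(m, dim(arr)))
}

#' In-plane spatial median filter
#'
#' Filters every frame and every z-slice independently with a
#' `ky` x `kx` neighbourhood median (mirror padding), reducing
#' salt-and-pepper noise. For even window lengths the window origin sits
#' at offset `floor((k - 1) / 2)` and the median of an even count is the
#' mean of the two middle order statistics. Filtering is always 2D
#' in-plane, never across z.
#'
#' @param series a [DynamicSeries-class].
#' @param kernel integer pair `(ky, kx)`, each `>= 1` and `<=` the
#'   in-plane extents.
#' @return The filtered [DynamicSeries-class], same shape.
#' @export
spatialMedianFilter <- function(series, kernel) {
  arr <- intensities(series)
  d <- dim(arr)
  kernel <- as.integer(kernel)
  .stopIf(length(kernel) != 2L || any(kernel < 1L),
          "kernel must be two integers >= 1")
  .stopIf(kernel[1] > d[3] || kernel[2] > d[4],
          "kernel %dx%d larger than the %dx%d image plane",
          kernel[1], kernel[2], d[3], d[4])
  if (all(kernel == 1L)) return(series)
  out <- arr
  for (t in seq_len(d[1]))
    for (z in seq_len(d[2]))
      out[t, z, , ] <- .spatialMedianCpp(arr[t, z, , ], kernel[1], kernel[2])
  .replaceIntensities(series, out)
}

#' Global min-max normalization
#'
#' Affinely rescales the whole 4D volume to `[0, 1]` using one global
#' minimum and maximum across all frames, so relative intensities between
#' frames are preserved.
#'
#' @param series a [DynamicSeries-class] with non-constant intensities.
#' @return The normalized [DynamicSeries-class].
#' @export
normalizeGlobal <- function(series) {
  arr <- intensities(series)
  lo <- min(arr); hi <- max(arr)
  .stopIf(hi == lo, "cannot normalize a constant series (max == min)")
  .replaceIntensities(series, (arr - lo) / (hi - lo))
}

#' Noise thresholding
#'
#' Zeroes intensities strictly below `noiseFraction` times the global
#' maximum. Intended for normalized series; the 0.07-0.10 range balances
#' noise suppression against the visibility of faint vessels.
#'
#' @param series a [DynamicSeries-class] (normalized to `[0, 1]`).
#' @param noiseFraction fraction in `[0, 1)`.
#' @return The thresholded [DynamicSeries-class].
#' @export
applyNoiseThreshold <- function(series, noiseFraction = 0.08) {
  .stopIf(noiseFraction < 0 || noiseFraction >= 1,
          "noiseFraction must lie in [0, 1)")
  if (noiseFraction == 0) return(series)
  arr <- intensities(series)
  cut <- noiseFraction * max(arr)
  arr[arr < cut] <- 0
  .replaceIntensities(series, arr)
}

#' Run the full preprocessing chain
#'
#' Fixed order: background subtraction (projection series only) -> crop
#' (if configured) -> temporal median -> in-plane spatial median ->
#' global normalization -> noise threshold. The configuration actually
#' applied is attached to the result as attribute
#' `"preprocessLog"`.
#'
#' @param series a [DynamicSeries-class].
#' @param cfg a [PreprocessConfig-class]; defaults to the modality's
#'   standard configuration.
#' @param subtract whether to background-subtract; defaults to `TRUE`
#'   for projection series that are not yet subtracted, `FALSE`
#'   otherwise.
#' @return The preprocessed [DynamicSeries-class].
#' @examples
#' ph <- simulatePhantom(defaultPhantomSpec(nFrames = 24))
#' pre <- preprocessSeries(ph$series)
#' @export
preprocessSeries <- function(series, cfg = preprocessConfig(modalityTag(series)),
                             subtract = NULL) {
  validObject(cfg)
  if (is.null(subtract))
    subtract <- modalityTag(series) == "projection" &&
      !series@backgroundSubtracted
  if (subtract) series <- subtractBackground(series, cfg)
  if (length(cfg@cropBox)) series <- cropSeries(series, cfg@cropBox)
  series <- temporalMedianFilter(series, cfg@temporalWindow)
  series <- spatialMedianFilter(series, cfg@spatialKernel)
  series <- normalizeGlobal(series)
  series <- applyNoiseThreshold(series, cfg@noiseFraction)
  attr(series, "preprocessLog") <- list(
    temporalWindow = cfg@temporalWindow,
    spatialKernel = cfg@spatialKernel,
    noiseFraction = cfg@noiseFraction,
    cropBox = cfg@cropBox,
    backgroundFrame = cfg@backgroundFrame,
    polarity = cfg@polarity,
    subtracted = subtract)
  series
}
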