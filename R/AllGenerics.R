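#' @name pavmark-accessors
#' @title Accessors for pavmark classes
#' @description Accessor generics for the container classes. Slots are
#'   never accessed with `@` in user code.
#' @param x a pavmark object.
#' @return The requested component.
NULL

#' @rdname pavmark-accessors
#' @export
setGeneric("intensities", function(x) standardGeneric("intensities"))
#' @rdname pavmark-accessors
#' @export
setGeneric("frameInterval", function(x) standardGeneric("frameInterval"))
#' @rdname pavmark-accessors
#' @export
setGeneric("voxelSpacing", function(x) standardGeneric("voxelSpacing"))
#' @rdname pavmark-accessors
#' @export
setGeneric("injectionTime", function(x) standardGeneric("injectionTime"))
#' @rdname pavmark-accessors
#' @export
setGeneric("modalityTag", function(x) standardGeneric("modalityTag"))
#' @rdname pavmark-accessors
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))
#' @rdname pavmark-accessors
#' @export
setGeneric("spatialShape", function(x) standardGeneric("spatialShape"))
#' @rdname pavmark-accessors
#' @export
setGeneric("maskArray", function(x) standardGeneric("maskArray"))
#' @rdname pavmark-accessors
#' @export
setGeneric("thresholdUsed", function(x) standardGeneric("thresholdUsed"))
#' @rdname pavmark-accessors
#' @export
setGeneric("stdValues", function(x) standardGeneric("stdValues"))
#' @rdname pavmark-accessors
#' @export
setGeneric("noiseScale", function(x) standardGeneric("noiseScale"))
#' @rdname pavmark-accessors
#' @export
setGeneric("markerValues", function(x) standardGeneric("markerValues"))
#' @rdname pavmark-accessors
#' @export
setGeneric("markerKind", function(x) standardGeneric("markerKind"))
#' @rdname pavmark-accessors
#' @export
setGeneric("markerContext", function(x) standardGeneric("markerContext"))
#' @rdname pavmark-accessors
#' @export
setGeneric("binEdges", function(x) standardGeneric("binEdges"))
#' @rdname pavmark-accessors
#' @export
setGeneric("frequencies", function(x) standardGeneric("frequencies"))

setMethod("intensities", "DynamicSeries", function(x) x@intensities)
setMethod("frameInterval", "DynamicSeries", function(x) x@dt)
setMethod("frameInterval", "MarkerMap", function(x) x@dt)
setMethod("voxelSpacing", "DynamicSeries", function(x) x@spacing)
setMethod("voxelSpacing", "MarkerMap", function(x) x@spacing)
setMethod("injectionTime", "DynamicSeries", function(x) x@injectionTime)
setMethod("modalityTag", "DynamicSeries", function(x) x@modalityTag)
setMethod("nFrames", "DynamicSeries", function(x) dim(x@intensities)[1])
setMethod("spatialShape", "DynamicSeries", function(x) dim(x@intensities)[-1])
setMethod("spatialShape", "VesselMask", function(x) dim(x@mask))
setMethod("spatialShape", "MarkerMap", function(x) dim(x@values))
setMethod("maskArray", "VesselMask", function(x) x@mask)
setMethod("thresholdUsed", "VesselMask", function(x) x@thresholdUsed)
setMethod("stdValues", "StdMap", function(x) x@values)
setMethod("noiseScale", "StdMap", function(x) x@noiseScale)
setMethod("markerValues", "MarkerMap", function(x) x@values)
setMethod("markerKind", "MarkerMap", function(x) x@kind)
setMethod("markerKind", "MarkerHistogram", function(x) x@kind)
setMethod("markerContext", "MarkerMap", function(x) x@context)
setMethod("binEdges", "MarkerHistogram", function(x) x@binEdges)
setMethod("frequencies", "MarkerHistogram", function(x) x@frequencies)

#' @rdname pavmark-accessors
#' @export
setGeneric("nValues", function(x) standardGeneric("nValues"))
setMethod("nValues", "MarkerHistogram", function(x) x@nValues)

setMethod("show", "DynamicSeries", function(object) {
  d <- dim(object@intensities)
  cat(sprintf(
    "DynamicSeries: %d frames x (%d, %d, %d) [%s], dt = %g s, spacing = (%g, %g, %g) mm\n",
    d[1], d[2], d[3], d[4], object@modalityTag, object@dt,
    object@spacing[1], object@spacing[2], object@spacing[3]))
  cat(sprintf("  intensity range [%g, %g]; background subtracted: %s\n",
              min(object@intensities), max(object@intensities),
              object@backgroundSubtracted))
})

setMethod("show", "VesselMask", function(object) {
  cat(sprintf("VesselMask: %d / %d voxels (threshold %g x noise scale, %s)\n",
              sum(object@mask), length(object@mask), object@thresholdUsed,
              object@sourceStat))
})

setMethod("show", "StdMap", function(object) {
  cat(sprintf("StdMap: (%s) temporal std in [%g, %g], noise scale %g\n",
              paste(dim(object@values), collapse = ", "),
              min(object@values), max(object@values), object@noiseScale))
})

setMethod("show", "MarkerMap", function(object) {
  v <- object@values[!is.na(object@values)]
  unit <- switch(object@kind, toa = "s", slope = "1/s", "unitless")
  cat(sprintf("MarkerMap '%s': %d present voxels of %d, range [%g, %g] %s\n",
              object@kind, length(v), length(object@values),
              if (length(v)) min(v) else NA, if (length(v)) max(v) else NA,
              unit))
  if (length(object@context))
    cat("  context:", paste(names(object@context), "=",
        vapply(object@context, function(z) sprintf("%g", z), character(1)),
        collapse = ", "), "\n")
})

setMethod("show", "MarkerHistogram", function(object) {
  cat(sprintf(
    "MarkerHistogram '%s': %d bins on [%g, %g], n = %d\n",
    object@kind, length(object@frequencies), min(object@binEdges),
    max(object@binEdges), object@nValues))
})

setMethod("show", "HistogramMetrics", function(object) {
  cat(sprintf(
    "HistogramMetrics (n = %d): mean %.4g, median %.4g, skewness %.4g, kurtosis %.4g\n",
    object@n, object@mean, object@median, object@skewness, object@kurtosis))
})

setMethod("show", "HistogramComparison", function(object) {
  cat(sprintf("HistogramComparison (%s): chi2 = %.4g, df = %d, p = %.4g\n",
              object@method, object@chi2, object@df, object@pValue))
})

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf(
    "PhantomSpec: grid (%s), %d frames @ dt %g s, %d segments, noise sd %g, psf %g mm\n",
    paste(object@gridShape, collapse = ", "), object@nFrames, object@dt,
    length(object@segments), object@noiseSd, object@psfFwhm))
})

setMethod("show", "PreprocessConfig", function(object) {
  cat(sprintf(
    "PreprocessConfig: temporal window %d, spatial kernel %dx%d, noise fraction %g, background frame %d, %s\n",
    object@temporalWindow, object@spatialKernel[1], object@spatialKernel[2],
    object@noiseFraction, object@backgroundFrame, object@polarity))
})
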