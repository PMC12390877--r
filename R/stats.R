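#' Build a normalized marker histogram
#'
#' Default binning by kind: `toa` uses bins of width `dt` from 0 to the
#' maximum arrival; `toa_norm` and `slope_norm` use 20 equal bins on
#' `[0, 1]`; `slope` uses 20 equal bins on `[0, max]`. Counts are
#' divided by the number of contributing voxels, and values equal to the
#' top edge fall in the last bin.
#'
#' @param map a [MarkerMap-class] with at least one present value.
#' @param binWidth optional positive bin width overriding the default.
#' @param range optional `(lo, hi)` overriding the default; present
#'   values outside the range are excluded from the histogram.
#' @return A [MarkerHistogram-class].
#' @examples
#' ph <- simulatePhantom(defaultPhantomSpec(nFrames = 24))
#' mask <- detectVessels(temporalStdMap(ph$series))
#' buildHistogram(normalizeToa(computeToa(ph$series, mask)))
#' @export
buildHistogram <- function(map, binWidth = NULL, range = NULL) {
  v <- markerValues(map)[!is.na(markerValues(map))]
  .stopIf(!length(v), "empty marker map")
  .stopIf(!is.null(binWidth) && binWidth <= 0, "binWidth must be positive")
  kind <- markerKind(map)
  if (is.null(range)) {
    range <- switch(kind,
      toa = c(0, max(v)),
      toa_norm = c(0, 1),
      slope_norm = c(0, 1),
      slope = c(0, max(v)))
  }
  lo <- range[1]; hi <- range[2]
  .stopIf(hi <= lo, "histogram range must have hi > lo")
  if (is.null(binWidth)) {
    binWidth <- if (kind == "toa") frameInterval(map) else (hi - lo) / 20
  }
  nb <- max(1L, ceiling((hi - lo) / binWidth - 1e-9))
  edges <- lo + seq.int(0L, nb) * binWidth
  if (edges[nb + 1L] < hi) {
    nb <- nb + 1L
    edges <- c(edges, lo + nb * binWidth)
  }
  idx <- findInterval(v, edges, rightmost.closed = TRUE)
  keep <- idx >= 1L & idx <= nb
  .stopIf(!any(keep), "no values inside the histogram range")
  counts <- tabulate(idx[keep], nbins = nb)
  new("MarkerHistogram", binEdges = edges,
      frequencies = counts / sum(counts),
      nValues = as.integer(sum(keep)), kind = kind)
}

#' Moment summary of a marker distribution
#'
#' Mean, median, skewness and kurtosis computed on the raw per-voxel
#' values (never on binned frequencies), with population (divisor n)
#' moments: skewness is `m3 / m2^(3/2)` and kurtosis the non-excess
#' `m4 / m2^2`, so near-normal samples report a kurtosis near 3.
#'
#' @param map a [MarkerMap-class] (or a numeric vector) with at least
#'   two present values and nonzero variance.
#' @return A [HistogramMetrics-class].
#' @export
histogramMetrics <- function(map) {
  v <- if (is.numeric(map)) map[!is.na(map)] else {
    mv <- markerValues(map); mv[!is.na(mv)]
  }
  n <- length(v)
  .stopIf(n < 2L, "need at least 2 values")
  mu <- mean(v)
  m2 <- mean((v - mu)^2)
  .stopIf(m2 == 0, "zero variance: moments undefined")
  m3 <- mean((v - mu)^3)
  m4 <- mean((v - mu)^4)
  new("HistogramMetrics", mean = mu, median = stats::median(v),
      skewness = m3 / m2^1.5, kurtosis = m4 / m2^2, n = as.integer(n))
}

# Redistribute a histogram's mass onto new edges assuming uniform density
# within each source bin.
.rebinHistogram <- function(h, edges) {
  srcLo <- h@binEdges[-length(h@binEdges)]
  srcHi <- h@binEdges[-1]
  out <- numeric(length(edges) - 1L)
  for (i in seq_along(out)) {
    ov <- pmax(0, pmin(srcHi, edges[i + 1L]) - pmax(srcLo, edges[i]))
    out[i] <- sum(h@frequencies * ov / (srcHi - srcLo))
  }
  out
}

#' Chi-square comparison of two marker histograms
#'
#' Rebins both histograms onto a common grid spanning the union of their
#' ranges, then computes the symmetric chi-square statistic on the
#' normalized frequencies,
#' `chi2 = sum over occupied bins of (fa - fb)^2 / (fa + fb)`,
#' with `df` = occupied bins - 1 (forced to at least 1) and the upper
#' tail chi-square probability as p-value. Identical histograms give
#' `chi2 = 0`, `p = 1`. The `"expected"` method instead computes the
#' goodness-of-fit statistic `sum((fa - fb)^2 / fb)` over bins where the
#' second histogram has mass.
#'
#' @param a,b two [MarkerHistogram-class] objects of the same kind.
#' @param bins number of bins on the common grid; defaults to the larger
#'   of the two inputs' bin counts.
#' @param method `"symmetric"` (default) or `"expected"`.
#' @return A [HistogramComparison-class].
#' @export
compareHistograms <- function(a, b, bins = NULL,
                              method = c("symmetric", "expected")) {
  method <- match.arg(method)
  .stopIf(markerKind(a) != markerKind(b),
          "incompatible kinds: %s vs %s", markerKind(a), markerKind(b))
  if (is.null(bins)) bins <- max(length(a@frequencies), length(b@frequencies))
  lo <- min(a@binEdges, b@binEdges)
  hi <- max(a@binEdges, b@binEdges)
  edges <- seq(lo, hi, length.out = bins + 1L)
  fa <- .rebinHistogram(a, edges)
  fb <- .rebinHistogram(b, edges)
  if (method == "symmetric") {
    occ <- fa + fb > 0
    chi2 <- sum((fa[occ] - fb[occ])^2 / (fa[occ] + fb[occ]))
  } else {
    occ <- fb > 0
    chi2 <- sum((fa[occ] - fb[occ])^2 / fb[occ])
  }
  df <- max(1L, sum(occ) - 1L)
  new("HistogramComparison", chi2 = chi2,
      pValue = stats::pchisq(chi2, df, lower.tail = FALSE),
      df = as.integer(df), binsCompared = as.integer(bins), method = method)
}
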