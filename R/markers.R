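# Marker computations operate on the preprocessed series restricted to
# the vessel mask. All per-voxel work is vectorized over the masked
# columns of the T x nvox time-course matrix.

.checkMask <- function(series, mask) {
  .stopIf(!is(mask, "VesselMask"), "mask must be a VesselMask")
  .stopIf(!identical(spatialShape(series), spatialShape(mask)),
          "mask shape does not match the series' spatial shape")
  .stopIf(!any(maskArray(mask)), "empty vessel mask")
}

.colMax <- function(m) {
  out <- m[1, ]
  for (t in seq_len(nrow(m))[-1]) out <- pmax(out, m[t, ])
  out
}

# First (and last) 1-based row index at or above thr per column; columns
# with no crossing return NA.
.firstAtOrAbove <- function(m, thr) {
  cross <- m >= rep(thr, each = nrow(m))
  any <- colSums(cross) > 0L
  first <- rep(NA_integer_, ncol(m))
  first[any] <- apply(cross[, any, drop = FALSE], 2, which.max)
  first
}

#' Contrast time-of-arrival (CA_ToA)
#'
#' For every masked voxel, the arrival time is the time from injection
#' until the voxel's signal first reaches `fraction` (default 10%) of
#' its maximum. The threshold is relative to the voxel's own peak, so
#' faint, diluted veins are datable just like the bright feeding artery;
#' set `reference = "global"` to threshold against the series-wide
#' maximum instead. Masked voxels whose curve never rises above zero
#' (possible after noise thresholding) are recorded as missing, never as
#' zero: zero would mean instant arrival.
#'
#' @param series a preprocessed [DynamicSeries-class].
#' @param mask a [VesselMask-class] matching the series.
#' @param fraction crossing fraction in `(0, 1)`, default 0.1.
#' @param interpolate if `TRUE`, the crossing time is linearly
#'   interpolated between the frames bracketing the threshold (default
#'   `FALSE`: the first frame at or above the threshold).
#' @param reference `"voxel"` (per-voxel peak, default) or `"global"`.
#' @return A [MarkerMap-class] of kind `"toa"` (seconds). The context
#'   records `tEff`, the span from the earliest to the latest time any
#'   masked voxel sits at or above its own threshold level, used by
#'   [normalizeToa()].
#' @examples
#' ph <- simulatePhantom(defaultPhantomSpec(nFrames = 24))
#' mask <- detectVessels(temporalStdMap(ph$series))
#' computeToa(ph$series, mask)
#' @export
computeToa <- function(series, mask, fraction = 0.1, interpolate = FALSE,
                       reference = c("voxel", "global")) {
  reference <- match.arg(reference)
  .stopIf(fraction <= 0 || fraction >= 1, "fraction must lie in (0, 1)")
  .checkMask(series, mask)
  arr <- intensities(series)
  dt <- frameInterval(series)
  T <- dim(arr)[1]
  sel <- which(maskArray(mask))
  m <- .asTimeByVoxel(arr)[, sel, drop = FALSE]
  peaks <- .colMax(m)
  thr <- if (reference == "voxel") fraction * peaks
         else rep(fraction * max(arr), length(peaks))
  ok <- peaks > 0
  first <- rep(NA_integer_, length(sel))
  first[ok] <- .firstAtOrAbove(m[, ok, drop = FALSE], thr[ok])
  toa <- rep(NA_real_, length(sel))
  hit <- !is.na(first)
  if (interpolate) {
    for (j in which(hit)) {
      k <- first[j]
      if (k > 1L && m[k, j] > m[k - 1L, j] && m[k - 1L, j] < thr[j]) {
        f <- (thr[j] - m[k - 1L, j]) / (m[k, j] - m[k - 1L, j])
        toa[j] <- ((k - 2L) + f) * dt
      } else toa[j] <- (k - 1L) * dt
    }
  } else {
    toa[hit] <- (first[hit] - 1L) * dt
  }
  toa <- pmax(0, toa - injectionTime(series))
  # effective presence span: earliest first-crossing to latest
  # last-at-or-above time over the mask
  last <- rep(NA_integer_, length(sel))
  if (any(hit)) {
    rev_first <- .firstAtOrAbove(m[T:1, hit, drop = FALSE], thr[hit])
    last[hit] <- T + 1L - rev_first
  }
  tEff <- if (any(hit))
    (max(last, na.rm = TRUE) - min(first, na.rm = TRUE)) * dt else 0
  vals <- array(NA_real_, dim = spatialShape(series))
  vals[sel] <- toa
  .MarkerMap(vals, "toa", dt, voxelSpacing(series),
             context = list(tEff = tEff, fraction = fraction))
}

#' Normalized, reversed time-of-arrival (CA_ToA_norm)
#'
#' Subtracts each voxel's arrival time from the latest arrival on the
#' map and scales by the total effective time `tEff` in which contrast
#' was present, yielding values in `[0, 1]`: the latest-arriving voxel
#' maps to 0 and early (arterial) voxels approach 1. This removes
#' injection-timing and acquisition-length differences so that
#' projection (DSA) and volumetric (MRA) histograms of the same lesion
#' are directly comparable.
#'
#' @param toa a [MarkerMap-class] of kind `"toa"`.
#' @param tEff effective contrast-presence time in seconds; by default
#'   the above-threshold span recorded by [computeToa()]. Supply the
#'   acquisition-derived value to override.
#' @return A [MarkerMap-class] of kind `"toa_norm"` with `toaMax` and
#'   `tEff` in its context.
#' @export
normalizeToa <- function(toa, tEff = NULL) {
  .stopIf(markerKind(toa) != "toa", "input must be a 'toa' marker map")
  v <- markerValues(toa)
  present <- !is.na(v)
  .stopIf(!any(present), "all-missing time-of-arrival map")
  if (is.null(tEff)) tEff <- markerContext(toa)$tEff
  .stopIf(is.null(tEff), "tEff unavailable: supply it explicitly")
  toaMax <- max(v[present])
  if (tEff <= 0) tEff <- frameInterval(toa)  # degenerate single-frame span
  out <- (toaMax - v) / tEff
  .MarkerMap(out, "toa_norm", frameInterval(toa), voxelSpacing(toa),
             context = list(toaMax = toaMax, tEff = tEff))
}

#' Maximum dispersive wash-in slope (CA_si)
#'
#' Each masked voxel's time-intensity curve is first divided by its own
#' peak intensity (dilution correction: vessels fed by contrast-poor
#' blood are rescaled to unit peak), then the marker is the maximum
#' forward finite difference
#' `(c(t + dt) - c(t)) / dt` over the curve, in 1/s. The final frame
#' contributes no difference. Voxels with zero peak are missing.
#'
#' @param series a preprocessed [DynamicSeries-class] with >= 2 frames.
#' @param mask a [VesselMask-class] matching the series.
#' @return A [MarkerMap-class] of kind `"slope"` (1/s).
#' @export
computeSlope <- function(series, mask) {
  .checkMask(series, mask)
  arr <- intensities(series)
  T <- dim(arr)[1]
  .stopIf(T < 2L, "slope needs at least 2 frames")
  dt <- frameInterval(series)
  sel <- which(maskArray(mask))
  m <- .asTimeByVoxel(arr)[, sel, drop = FALSE]
  peaks <- .colMax(m)
  si <- rep(NA_real_, length(sel))
  ok <- peaks > 0
  if (any(ok)) {
    mh <- m[, ok, drop = FALSE] / rep(peaks[ok], each = T)
    d <- (mh[2:T, , drop = FALSE] - mh[1:(T - 1), , drop = FALSE]) / dt
    si[ok] <- if (T == 2L) d[1, ] else .colMax(d)
  }
  vals <- array(NA_real_, dim = spatialShape(series))
  vals[sel] <- si
  .MarkerMap(vals, "slope", dt, voxelSpacing(series))
}

#' Normalized wash-in slope (CA_si_norm)
#'
#' Divides every slope by the map-wide maximum slope, yielding values in
#' `[0, 1]` with the maximum exactly 1, so lesions imaged under
#' different acquisition settings can be compared.
#'
#' @param slope a [MarkerMap-class] of kind `"slope"` with a positive
#'   maximum.
#' @return A [MarkerMap-class] of kind `"slope_norm"` with `siMax`
#'   (1/s) in its context.
#' @export
normalizeSlope <- function(slope) {
  .stopIf(markerKind(slope) != "slope", "input must be a 'slope' marker map")
  v <- markerValues(slope)
  present <- !is.na(v)
  .stopIf(!any(present), "all-missing slope map")
  siMax <- max(v[present])
  .stopIf(siMax <= 0, "nonpositive maximum slope: cannot normalize")
  .MarkerMap(v / siMax, "slope_norm", frameInterval(slope),
             voxelSpacing(slope), context = list(siMax = siMax))
}

#' Long-format table of a marker map
#'
#' @param map a [MarkerMap-class].
#' @return A data.frame with 0-based `z`, `y`, `x` indices and `value`
#'   for every present voxel, suitable for external statistics.
#' @export
markerTable <- function(map) {
  v <- markerValues(map)
  idx <- which(!is.na(v), arr.ind = TRUE)
  data.frame(z = idx[, 1] - 1L, y = idx[, 2] - 1L, x = idx[, 3] - 1L,
             value = v[idx])
}
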