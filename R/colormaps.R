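# Colour renderings of marker maps. Low arrival times render red
# (early, arterial side), late times blue, following the usual reading
# of colour-coded parametric angiography; slope maps use the same scale.
# Renders are pure functions of (map, spec): the PNG bytes are built
# directly from the value array, never through a graphics device.

.renderSlice <- function(slice, spec, lo, hi, pal) {
  h <- nrow(slice); w <- ncol(slice)
  n <- nrow(pal)
  rgba <- array(0, dim = c(h, w, 4))
  present <- !is.na(slice)
  idx <- pmin(n, pmax(1L, 1L + floor((slice[present] - lo) / (hi - lo) *
                                       (n - 1L) + 0.5)))
  for (ch in 1:3) {
    plane <- matrix(0, h, w)
    plane[present] <- pal[idx, ch]
    rgba[, , ch] <- plane
  }
  rgba[, , 4] <- if (spec@background == "transparent") present * 1 else 1
  rgba
}

# Vertical colour-bar strip (hi at top), same height as the image.
.colorBar <- function(h, pal, width) {
  n <- nrow(pal)
  idx <- pmin(n, pmax(1L, round(seq(n, 1, length.out = h))))
  bar <- array(1, dim = c(h, width, 4))
  for (ch in 1:3) bar[, , ch] <- matrix(pal[idx, ch], h, width)
  bar
}

#' Render a marker map slice as a colour PNG
#'
#' Writes a PNG of one z-slice (or an extremal projection along z) with
#' missing voxels as background and a colour-bar strip on the right
#' edge; the value range and physical units of the bar are recorded in
#' a JSON sidecar. In `maximum_intensity` projection mode the extremal
#' value along z is shown: the minimum for arrival times (earliest
#' arrival dominates, as in projection angiography) and the maximum for
#' slopes.
#'
#' @param map a [MarkerMap-class] with at least one present value.
#' @param path output `.png` path.
#' @param spec a [RenderSpec-class].
#' @param zIndex 0-based slice index (ignored in projection mode);
#'   defaults to the middle slice.
#' @return Invisibly, a list with `range` (the colour-bar limits),
#'   `units`, and `path`.
#' @export
renderMap2D <- function(map, path, spec = RenderSpec(), zIndex = NULL) {
  validObject(spec)
  v <- markerValues(map)
  .stopIf(all(is.na(v)), "empty marker map")
  if (spec@projectionMode == "maximum_intensity") {
    # plain toa: earliest arrival dominates the ray; toa_norm is
    # reversed (1 = earliest), so there and for slopes the maximum does
    f <- if (markerKind(map) == "toa") min else max
    slice <- apply(v, c(2, 3), function(col)
      if (all(is.na(col))) NA_real_ else f(col, na.rm = TRUE))
  } else {
    nz <- dim(v)[1]
    if (is.null(zIndex)) zIndex <- (nz - 1L) %/% 2L
    .stopIf(zIndex < 0L || zIndex >= nz,
            "zIndex %d outside [0, %d]", zIndex, nz - 1L)
    slice <- v[zIndex + 1L, , ]
  }
  rng <- spec@valueRange %||% range(v, na.rm = TRUE)
  if (rng[1] == rng[2]) rng <- rng + c(-0.5, 0.5)
  pal <- .paletteRgb(spec@colormapName)
  if (all(is.na(slice)))
    warning("all-missing slice: rendering background only")
  img <- .renderSlice(slice, spec, rng[1], rng[2], pal)
  barw <- max(4L, ncol(slice) %/% 10L)
  gap <- array(if (spec@background == "transparent") 0 else c(0, 0, 0, 1),
               dim = c(nrow(slice), 2L, 4L))
  if (spec@background == "transparent") gap[, , 4] <- 0
  out <- array(0, dim = c(nrow(img), ncol(img) + 2L + barw, 4))
  out[, seq_len(ncol(img)), ] <- img
  out[, ncol(img) + 1:2, ] <- gap
  out[, ncol(img) + 2L + seq_len(barw), ] <- .colorBar(nrow(img), pal, barw)
  png::writePNG(out, path)
  units <- switch(markerKind(map), toa = "s", slope = "1/s", "unitless")
  .writeSidecar(path, list(kind = markerKind(map), range = rng,
                           units = units, colormap = spec@colormapName,
                           projectionMode = spec@projectionMode))
  invisible(list(range = rng, units = units, path = path))
}

#' Export a volumetric marker map for 3D inspection
#'
#' Writes the masked scalar volume as NIfTI (for external viewers) plus
#' a rotating extremal-intensity-projection PNG sequence: the volume is
#' rotated about the z-axis in `angleStep`-degree increments and each
#' view projected along x (minimum for arrival times, maximum for
#' slopes).
#'
#' @param map a volumetric [MarkerMap-class] (z-extent > 1).
#' @param dir output directory (created if needed).
#' @param spec a [RenderSpec-class].
#' @param angleStep rotation step in degrees (default 10, i.e. 36
#'   frames).
#' @return Invisibly, the vector of frame paths.
#' @export
exportMap3D <- function(map, dir, spec = RenderSpec(), angleStep = 10) {
  v <- markerValues(map)
  .stopIf(dim(v)[1] <= 1L, "exportMap3D requires volumetric data")
  .stopIf(all(is.na(v)), "empty marker map")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeMarkerMap(map, file.path(dir, "volume.nii.gz"))
  angles <- seq(0, 360 - angleStep, by = angleStep)
  rng <- spec@valueRange %||% range(v, na.rm = TRUE)
  if (rng[1] == rng[2]) rng <- rng + c(-0.5, 0.5)
  pal <- .paletteRgb(spec@colormapName)
  extremal <- if (markerKind(map) == "toa") min else max
  d <- dim(v)
  cy <- (d[2] + 1) / 2; cx <- (d[3] + 1) / 2
  grid <- expand.grid(y = seq_len(d[2]), x = seq_len(d[3]))
  paths <- character(length(angles))
  for (i in seq_along(angles)) {
    th <- angles[i] * pi / 180
    # nearest-neighbour rotation of each z-slice about the plane centre
    ys <- round(cy + cos(th) * (grid$y - cy) - sin(th) * (grid$x - cx))
    xs <- round(cx + sin(th) * (grid$y - cy) + cos(th) * (grid$x - cx))
    ok <- ys >= 1 & ys <= d[2] & xs >= 1 & xs <= d[3]
    rot <- array(NA_real_, dim = d)
    for (z in seq_len(d[1])) {
      slice <- v[z, , ]
      plane <- matrix(NA_real_, d[2], d[3])
      plane[cbind(grid$y[ok], grid$x[ok])] <- slice[cbind(ys[ok], xs[ok])]
      rot[z, , ] <- plane
    }
    proj <- apply(rot, c(1, 2), function(ray)
      if (all(is.na(ray))) NA_real_ else extremal(ray, na.rm = TRUE))
    img <- .renderSlice(proj, spec, rng[1], rng[2], pal)
    paths[i] <- file.path(dir, sprintf("frame_%03d.png", i - 1L))
    png::writePNG(img, paths[i])
  }
  invisible(paths)
}
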