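# On-disk conventions: NIfTI stores (x, y, z, t) as usual; in memory the
# package is (t, z, y, x), so arrays are aperm()ed on the way through.
# Full-precision metadata (dt, spacing, context) lives in a JSON sidecar
# next to each NIfTI/CSV, because the NIfTI-1 header holds pixdim only in
# 32-bit floats; the sidecar is preferred on read, making the round trip
# bit-exact.

.sidecarPath <- function(path) {
  sub("\\.(nii(\\.gz)?|csv|png)$", ".json", path, ignore.case = TRUE)
}

.writeSidecar <- function(path, meta) {
  jsonlite::write_json(meta, .sidecarPath(path), auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
}

.readSidecar <- function(path) {
  sp <- .sidecarPath(path)
  if (file.exists(sp)) jsonlite::read_json(sp, simplifyVector = TRUE)
  else NULL
}

.isNiftiPath <- function(path) grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)

.readFrameFile <- function(f) {
  img <- if (grepl("\\.png$", f, ignore.case = TRUE)) png::readPNG(f)
         else if (grepl("\\.tiff?$", f, ignore.case = TRUE)) tiff::readTIFF(f)
         else stop("unsupported frame format: ", f, call. = FALSE)
  if (length(dim(img)) == 3L) img <- apply(img, c(1, 2), mean)  # to grayscale
  img
}

#' Load a dynamic image series
#'
#' Reads either a 4D NIfTI file or a directory (or explicit vector) of
#' equally shaped 2D TIFF/PNG frames in lexicographic temporal order.
#' The frame interval comes from the JSON sidecar (if present), the
#' NIfTI header, or `meta$dt`; frame stacks always need `meta$dt`.
#'
#' @param path a `.nii`/`.nii.gz` file, a directory of frames, or a
#'   character vector of frame files.
#' @param meta optional overrides: `dt`, `spacing` (mm, `(z, y, x)`),
#'   `injectionTime`, `modalityTag`.
#' @return A [DynamicSeries-class].
#' @export
loadDynamicSeries <- function(path, meta = list()) {
  side <- NULL
  if (length(path) == 1L && .isNiftiPath(path)) {
    .stopIf(!file.exists(path), "file not found: %s", path)
    img <- RNifti::readNifti(path)
    arr <- as.array(img)
    .stopIf(length(dim(arr)) != 4L,
            "expected a 4D (x, y, z, t) NIfTI; got %d dimensions",
            length(dim(arr)))
    side <- .readSidecar(path)
    pd <- RNifti::pixdim(img)
    units <- RNifti::pixunits(img)
    dt <- meta$dt %||% side$dt %||%
      (if (length(pd) >= 4L && pd[4] > 0) {
        scl <- if ("ms" %in% units) 1e-3 else if ("us" %in% units) 1e-6 else 1
        pd[4] * scl
      } else NULL)
    spacing <- meta$spacing %||% side$spacing %||% rev(pd[1:3])
    arr <- aperm(arr, c(4, 3, 2, 1))
  } else {
    files <- if (length(path) == 1L && dir.exists(path)) {
      sort(list.files(path, pattern = "\\.(png|tiff?)$", full.names = TRUE,
                      ignore.case = TRUE))
    } else as.character(path)
    .stopIf(length(files) < 2L, "temporal extent < 2 (%d frame file(s))",
            length(files))
    frames <- lapply(files, .readFrameFile)
    d1 <- dim(frames[[1]])
    .stopIf(!all(vapply(frames, function(f) identical(dim(f), d1),
                        logical(1))),
            "inconsistent frame shapes across files")
    arr <- array(0, dim = c(length(frames), 1L, d1))
    for (i in seq_along(frames)) arr[i, 1L, , ] <- frames[[i]]
    dt <- meta$dt
    spacing <- meta$spacing %||% c(1, 1, 1)
  }
  .stopIf(is.null(dt), "missing dt: not in header/sidecar and no meta$dt")
  .stopIf(any(!is.finite(arr)), "non-finite intensities in %s",
          paste(path[1], collapse = ""))
  DynamicSeries(arr, dt = dt, spacing = spacing,
                injectionTime = meta$injectionTime %||%
                  side$injectionTime %||% 0,
                modalityTag = meta$modalityTag %||% side$modalityTag %||%
                  NULL,
                backgroundSubtracted = isTRUE(side$backgroundSubtracted))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a dynamic series as 4D NIfTI
#'
#' @param series a [DynamicSeries-class].
#' @param path output `.nii` or `.nii.gz` path; a JSON sidecar with
#'   full-precision metadata is written next to it.
#' @return `path`, invisibly.
#' @export
writeDynamicSeries <- function(series, path) {
  arr <- aperm(intensities(series), c(4, 3, 2, 1))
  attr(arr, "pixdim") <- c(rev(voxelSpacing(series)), frameInterval(series))
  attr(arr, "pixunits") <- c("mm", "s")
  RNifti::writeNifti(RNifti::asNifti(arr, datatype = "double"), path,
                     datatype = "double")
  .writeSidecar(path, list(
    dt = frameInterval(series), spacing = voxelSpacing(series),
    injectionTime = injectionTime(series),
    modalityTag = modalityTag(series),
    backgroundSubtracted = series@backgroundSubtracted))
  invisible(path)
}

#' Write a marker map as 3D NIfTI plus JSON sidecar
#'
#' Missing voxels are written as NaN; the marker kind, frame interval
#' and normalization context go to the sidecar, so a reload reproduces
#' the map bit-exactly.
#'
#' @param map a [MarkerMap-class] with at least one present value.
#' @param path output `.nii`/`.nii.gz` path.
#' @return `path`, invisibly.
#' @export
writeMarkerMap <- function(map, path) {
  v <- markerValues(map)
  .stopIf(all(is.na(v)), "empty marker map")
  arr <- aperm(v, c(3, 2, 1))
  attr(arr, "pixdim") <- rev(voxelSpacing(map))
  attr(arr, "pixunits") <- "mm"
  RNifti::writeNifti(RNifti::asNifti(arr, datatype = "double"), path,
                     datatype = "double")
  .writeSidecar(path, list(
    kind = markerKind(map), dt = frameInterval(map),
    spacing = voxelSpacing(map), context = markerContext(map)))
  invisible(path)
}

#' Read a marker map written by [writeMarkerMap()]
#'
#' @param path the `.nii`/`.nii.gz` path.
#' @return A [MarkerMap-class].
#' @export
readMarkerMap <- function(path) {
  side <- .readSidecar(path)
  .stopIf(is.null(side), "missing sidecar for %s", path)
  arr <- as.array(RNifti::readNifti(path))
  # NIfTI readers drop trailing singleton dimensions (planar maps)
  if (length(dim(arr)) == 2L) dim(arr) <- c(dim(arr), 1L)
  .stopIf(length(dim(arr)) != 3L, "expected a 3D NIfTI marker map")
  .MarkerMap(aperm(arr, c(3, 2, 1)), side$kind, side$dt, side$spacing,
             context = as.list(side$context))
}

#' Write / read a vessel mask as 3D NIfTI (0/1)
#'
#' @param mask a [VesselMask-class].
#' @param path output `.nii`/`.nii.gz` path.
#' @param spacing voxel spacing recorded in the header.
#' @return `path` (write) or a [VesselMask-class] (read).
#' @export
writeVesselMask <- function(mask, path, spacing = c(1, 1, 1)) {
  arr <- aperm(array(as.integer(maskArray(mask)), dim = dim(maskArray(mask))),
               c(3, 2, 1))
  attr(arr, "pixdim") <- rev(spacing)
  RNifti::writeNifti(RNifti::asNifti(arr, datatype = "uint8"), path,
                     datatype = "uint8")
  .writeSidecar(path, list(thresholdUsed = thresholdUsed(mask),
                           sourceStat = mask@sourceStat))
  invisible(path)
}

#' @rdname writeVesselMask
#' @export
readVesselMask <- function(path) {
  side <- .readSidecar(path)
  .stopIf(is.null(side), "missing sidecar for %s", path)
  arr <- as.array(RNifti::readNifti(path))
  if (length(dim(arr)) == 2L) dim(arr) <- c(dim(arr), 1L)
  new("VesselMask", mask = aperm(arr, c(3, 2, 1)) > 0,
      thresholdUsed = as.numeric(side$thresholdUsed),
      sourceStat = side$sourceStat)
}

#' Write / read a marker histogram as CSV
#'
#' Columns `bin_lo`, `bin_hi`, `frequency`; kind and voxel count go to
#' a JSON sidecar.
#'
#' @param h a [MarkerHistogram-class].
#' @param path output `.csv` path.
#' @return `path` (write) or a [MarkerHistogram-class] (read).
#' @export
writeHistogram <- function(h, path) {
  e <- binEdges(h)
  df <- data.frame(bin_lo = e[-length(e)], bin_hi = e[-1],
                   frequency = frequencies(h))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  .writeSidecar(path, list(kind = markerKind(h), n_values = nValues(h)))
  invisible(path)
}

#' @rdname writeHistogram
#' @export
readHistogram <- function(path) {
  side <- .readSidecar(path)
  .stopIf(is.null(side), "missing sidecar for %s", path)
  df <- utils::read.csv(path)
  new("MarkerHistogram", binEdges = c(df$bin_lo, df$bin_hi[nrow(df)]),
      frequencies = df$frequency, nValues = as.integer(side$n_values),
      kind = side$kind)
}
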