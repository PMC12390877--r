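# Internal helpers shared across modules.

# Linear indices (into a (z, y, x) array) of a box given as 0-based
# inclusive index ranges list(z =, y =, x =). Out-of-bounds or empty
# boxes yield integer(0).
.boxIndices <- function(box, gridShape) {
  if (!all(c("z", "y", "x") %in% names(box))) return(integer(0))
  rng <- lapply(c(z = "z", y = "y", x = "x"), function(ax) {
    r <- box[[ax]]
    if (length(r) != 2L || any(!is.finite(r)) || r[1] > r[2]) return(NULL)
    seq.int(r[1] + 1L, r[2] + 1L)
  })
  if (any(vapply(rng, is.null, logical(1)))) return(integer(0))
  if (rng$z[1] < 1L || rng$y[1] < 1L || rng$x[1] < 1L ||
      max(rng$z) > gridShape[1] || max(rng$y) > gridShape[2] ||
      max(rng$x) > gridShape[3]) return(integer(0))
  idx <- expand.grid(z = rng$z, y = rng$y, x = rng$x)
  as.integer(idx$z + gridShape[1] * (idx$y - 1L) +
             gridShape[1] * gridShape[2] * (idx$x - 1L))
}

# Reshape a (t, z, y, x) array into a T x nvox matrix (voxels in (z, y, x)
# column-major order) and back.
.asTimeByVoxel <- function(arr) {
  d <- dim(arr)
  matrix(arr, nrow = d[1], ncol = prod(d[-1]))
}

.fromTimeByVoxel <- function(m, d) array(m, dim = d)

# Mirror-padded 1D convolution along a vector, kernel normalized.
.reflectIdx <- function(i, n) {
  while (any(bad <- (i < 1L | i > n))) {
    i[bad & i < 1L] <- 1L - i[bad & i < 1L]
    i[bad & i > n] <- 2L * n + 1L - i[bad & i > n]
  }
  i
}

# Separable Gaussian blur of a (z, y, x) volume; sigma per axis in voxel
# units (0 disables that axis). Mirror boundary handling.
.gaussianBlur3d <- function(vol, sigma) {
  d <- dim(vol)
  for (ax in 1:3) {
    s <- sigma[ax]
    if (s <= 0 || d[ax] == 1L) next
    half <- max(1L, ceiling(3 * s))
    k <- exp(-0.5 * ((-half:half) / s)^2)
    k <- k / sum(k)
    n <- d[ax]
    perm <- c(ax, setdiff(1:3, ax))
    m <- matrix(aperm(vol, perm), nrow = n)
    out <- matrix(0, nrow = n, ncol = ncol(m))
    for (j in seq_along(k)) {
      idx <- .reflectIdx(seq_len(n) + (j - half - 1L), n)
      out <- out + k[j] * m[idx, , drop = FALSE]
    }
    vol <- aperm(array(out, dim = d[perm]), order(perm))
  }
  vol
}

# Palette lookup: map values in [lo, hi] onto n colours of an hcl palette
# (RdYlBu runs red -> blue, so low values render red).
.paletteRgb <- function(name, n = 256L) {
  cols <- grDevices::hcl.colors(n, palette = name)
  t(grDevices::col2rgb(cols)) / 255
}

.stopIf <- function(cond, msg, ...) if (cond) stop(sprintf(msg, ...), call. = FALSE)
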