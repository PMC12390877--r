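# Independent brute-force oracles. These deliberately share no code with
# the package internals: plain loops, stats::median, two-pass variance.

reflectIdxOracle <- function(i, n) {
  while (i < 1 || i > n) {
    if (i < 1) i <- 1 - i
    if (i > n) i <- 2 * n + 1 - i
  }
  i
}

# Running median over time of a (t, z, y, x) array, mirror padding.
oracleTemporalMedian <- function(arr, window) {
  d <- dim(arr)
  off <- (window - 1) / 2
  out <- arr
  for (z in seq_len(d[2])) for (y in seq_len(d[3])) for (x in seq_len(d[4])) {
    tc <- arr[, z, y, x]
    for (t in seq_len(d[1])) {
      idx <- vapply(t - off + seq_len(window) - 1,
                    reflectIdxOracle, numeric(1), n = d[1])
      out[t, z, y, x] <- median(tc[idx])
    }
  }
  out
}

# ky x kx in-plane median of a matrix, window origin floor((k-1)/2).
oracleSpatialMedian <- function(mat, ky, kx) {
  d <- dim(mat)
  offy <- floor((ky - 1) / 2); offx <- floor((kx - 1) / 2)
  out <- mat
  for (y in seq_len(d[1])) for (x in seq_len(d[2])) {
    vals <- c()
    for (j in seq_len(ky)) for (i in seq_len(kx)) {
      yy <- reflectIdxOracle(y - offy + j - 1, d[1])
      xx <- reflectIdxOracle(x - offx + i - 1, d[2])
      vals <- c(vals, mat[yy, xx])
    }
    out[y, x] <- median(vals)
  }
  out
}

# Two-pass per-voxel sample std of a (t, z, y, x) array.
oracleTemporalStd <- function(arr) {
  d <- dim(arr)
  out <- array(0, dim = d[-1])
  for (z in seq_len(d[2])) for (y in seq_len(d[3])) for (x in seq_len(d[4])) {
    tc <- arr[, z, y, x]
    mu <- sum(tc) / d[1]
    out[z, y, x] <- sqrt(sum((tc - mu)^2) / (d[1] - 1))
  }
  out
}

# Exhaustive comparison-loop binning: [e_i, e_{i+1}), last bin closed.
oracleHistCounts <- function(values, edges) {
  m <- length(edges) - 1
  counts <- integer(m)
  for (v in values) {
    for (i in seq_len(m)) {
      inBin <- v >= edges[i] &&
        (v < edges[i + 1] || (i == m && v <= edges[i + 1]))
      if (inBin) { counts[i] <- counts[i] + 1; break }
    }
  }
  counts
}

# Build a (T, 1, 1, n) series from a T x n matrix of time courses.
seriesFromCurves <- function(m, dt = 1, injectionTime = 0) {
  arr <- array(0, dim = c(nrow(m), 1, 1, ncol(m)))
  arr[, 1, 1, ] <- m
  DynamicSeries(arr, dt = dt, injectionTime = injectionTime,
                backgroundSubtracted = TRUE)
}

maskAll <- function(series) {
  new("VesselMask", mask = array(TRUE, dim = spatialShape(series)),
      thresholdUsed = 0.1, sourceStat = "temporal_std")
}

presentValues <- function(map) {
  v <- markerValues(map)
  v[!is.na(v)]
}
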