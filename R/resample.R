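# Raster resampling primitives.
#
# Nearest-neighbour follows the half-pixel center rule: output index i
# (0-based) samples input index floor((i + 0.5) * n_in / n_out). Bilinear
# interpolation aligns pixel centers the same way and is separable.

nearestIndex <- function(nOut, nIn) {
  pmin(floor((seq_len(nOut) - 0.5) * nIn / nOut) + 1L, nIn)
}

resampleNearest <- function(m, size) {
  m[nearestIndex(size[1], nrow(m)), nearestIndex(size[2], ncol(m)),
    drop = FALSE]
}

# linear interpolation weights for one axis (pixel-center aligned)
linWeights <- function(nOut, nIn) {
  pos <- (seq_len(nOut) - 0.5) * nIn / nOut - 0.5
  lo <- floor(pos)
  frac <- pos - lo
  lo <- pmin(pmax(lo, 0), nIn - 1)
  hi <- pmin(lo + 1, nIn - 1)
  list(lo = as.integer(lo) + 1L, hi = as.integer(hi) + 1L, w = frac)
}

resampleBilinear <- function(m, size) {
  ry <- linWeights(size[1], nrow(m))
  rx <- linWeights(size[2], ncol(m))
  rows <- m[ry$lo, , drop = FALSE] * (1 - ry$w) + m[ry$hi, , drop = FALSE] * ry$w
  t(t(rows[, rx$lo, drop = FALSE]) * (1 - rx$w) +
      t(rows[, rx$hi, drop = FALSE]) * rx$w)
}

# geometric transforms shared by augmentation; masks and patches go through
# the same index permutations so they stay aligned
rot90cw <- function(m) t(m[nrow(m):1, , drop = FALSE])
flipH <- function(m) m[, ncol(m):1, drop = FALSE]
flipV <- function(m) m[nrow(m):1, , drop = FALSE]

applyToChannels <- function(a, f) {
  ch <- lapply(seq_len(dim(a)[3]), function(k) f(a[, , k]))
  array(unlist(ch), dim = c(dim(ch[[1]]), length(ch)))
}
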