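#' Sample training patches per class
#'
#' Draws `k` patches from every class (without replacement where a class
#' has at least `k`, with replacement otherwise), deterministically for a
#' given seed. The published analysis uses `k = 3` random samples per
#' category.
#'
#' @param train list of [PatchMaskPair-class] training pairs.
#' @param k patches per class. Default 3.
#' @param seed sampling seed.
#' @return named list: class id -> list of `k` pairs.
#' @export
sampleClassPatches <- function(train, k = 3L, seed = 1L) {
  byClass <- pairsByClass(train)
  if (!length(byClass)) stop("no training pairs supplied")
  withSeed(deriveSeed(seed, "classSample"), {
    lapply(byClass, function(ps) {
      n <- length(ps)
      if (n == 0L) stop("a class has no training patch")
      idx <- if (n >= k) sample.int(n, k) else sample.int(n, k, replace = TRUE)
      ps[idx]
    })
  })
}

#' Per-channel spatial mean of a feature volume
#'
#' Collapses an `H' x W' x D` activation volume to a length-`D` prototype
#' vector by global average pooling: element `d` is the mean of channel
#' `d`. This yields exactly `D` (e.g. 1024) variables per class.
#'
#' @param volume numeric 3-D array.
#' @return numeric vector of length `dim(volume)[3]`.
#' @export
summarizeVolumeMean <- function(volume) {
  d <- dim(volume)
  if (is.null(d) || length(d) != 3L || any(d == 0L))
    stop("volume must be a non-empty H' x W' x D array")
  colMeans(matrix(volume, nrow = d[1] * d[2], ncol = d[3]))
}

#' Raw depth-wise serialization of a feature volume
#'
#' Flattens an `H' x W' x D` volume to a vector in row-major spatial order
#' (position `(i, j)` before `(i, j + 1)`), channels fastest within each
#' position's block kept contiguous per spatial site. Exposed for
#' comparison with the pooled prototype route.
#'
#' @param volume numeric 3-D array.
#' @return numeric vector of length `H' * W' * D`.
#' @export
serializeVolume <- function(volume) {
  d <- dim(volume)
  if (is.null(d) || length(d) != 3L) stop("volume must be a 3-D array")
  # rows of the (H'W' x D) depth-wise rearrangement, concatenated
  as.vector(t(volumeToMatrix(volume)))
}

# (H' x W' x D) -> (H'W' x D), spatial positions in row-major order
volumeToMatrix <- function(volume) {
  d <- dim(volume)
  m <- aperm(volume, c(2, 1, 3))
  dim(m) <- c(d[1] * d[2], d[3])
  m
}

#' Reduce a deep backbone feature volume to a prototype vector
#'
#' Backbone-agnostic reduction path for wide feature volumes (the
#' reference case is a `32 x 32 x 4096` volume, whose full serialization
#' would hold about 4.19 million elements): the volume is depth-wise
#' rearranged into an `(H'W') x D` matrix with row-major spatial order,
#' its columns are projected onto the top `nComponents` principal axes
#' fitted on that same matrix, and the resulting `(H'W') x nComponents`
#' score matrix is serialized row-major — length `H'W' * nComponents`
#' (51,200 for the reference case at 50 components).
#'
#' @param volume numeric `H' x W' x D` array.
#' @param nComponents principal components kept (<= D). Default 50.
#' @return numeric vector of length `H' * W' * nComponents`.
#' @export
reduceDeepVolume <- function(volume, nComponents = 50L) {
  d <- dim(volume)
  if (is.null(d) || length(d) != 3L) stop("volume must be a 3-D array")
  nComponents <- as.integer(nComponents)
  if (nComponents > d[3])
    stop(sprintf("nComponents (%d) exceeds feature depth (%d)",
                 nComponents, d[3]))
  m <- volumeToMatrix(volume)
  pc <- stats::prcomp(m, center = TRUE, scale. = FALSE, rank. = nComponents)
  as.vector(t(pc$x[, seq_len(nComponents), drop = FALSE]))
}

#' Simple color-statistic features of a patch
#'
#' Mean and standard deviation of each color channel over the patch's
#' foreground (target-class) pixels — a training-free prototype route used
#' by the synthetic recovery experiments.
#'
#' @param pair a [PatchMaskPair-class].
#' @return numeric vector `(mean R, mean G, mean B, sd R, sd G, sd B)`.
#' @export
summarizeColorStats <- function(pair) {
  fg <- patchMask(pair) == targetClass(pair)
  if (!any(fg)) stop("patch has no foreground pixel")
  p <- patchImage(pair)
  ch <- lapply(1:3, function(k) p[, , k][fg])
  c(vapply(ch, mean, numeric(1)), vapply(ch, stats::sd, numeric(1)))
}

#' Assemble the class-prototype observation matrix
#'
#' One row per class: the arithmetic mean of that class's `k` feature
#' vectors. Rows are ordered by ascending class id.
#'
#' @param perClassVectors named list: class id -> list (or matrix rows) of
#'   equal-length numeric vectors.
#' @param featureOrigin provenance tag. Default `"unet_mean"`.
#' @return An [ObservationMatrix-class] with one row per class.
#' @export
buildObservationMatrix <- function(perClassVectors,
                                   featureOrigin = "unet_mean") {
  if (!length(perClassVectors)) stop("no classes supplied")
  ids <- sort(as.integer(names(perClassVectors)))
  lens <- unique(unlist(lapply(perClassVectors, function(v)
    vapply(v, length, integer(1)))))
  if (length(lens) != 1L)
    stop("feature vectors have inconsistent lengths: ",
         paste(lens, collapse = ", "))
  rows <- do.call(rbind, lapply(as.character(ids), function(id)
    colMeans(do.call(rbind, perClassVectors[[id]]))))
  ObservationMatrix(rows, ids, featureOrigin)
}

#' Class-prototype rows in principal-component space
#'
#' Centers the observation rows and projects them onto principal axes.
#' Components are retained either up to a cumulative explained-variance
#' target or as a fixed count; the axes are orthonormal, so projecting and
#' back-projecting with all components reproduces the centered data.
#'
#' @param obs an [ObservationMatrix-class] with at least 2 rows.
#' @param varianceTarget cumulative variance proportion to reach (used
#'   when `nComponents` is `NULL`). Default 0.95.
#' @param nComponents fixed component count, overrides `varianceTarget`.
#' @return An [ObservationMatrix-class] of PC scores, `featureOrigin`
#'   suffixed with `"+pca"`.
#' @export
pcaScores <- function(obs, varianceTarget = 0.95, nComponents = NULL) {
  x <- obs@values
  if (nrow(x) < 2L) stop("PCA needs at least 2 observations")
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  if (is.null(nComponents)) {
    ev <- pc$sdev^2
    frac <- cumsum(ev) / sum(ev)
    nComponents <- which(frac >= varianceTarget)[1]
    if (is.na(nComponents)) nComponents <- length(ev)
  }
  nComponents <- min(as.integer(nComponents), ncol(pc$x))
  ObservationMatrix(pc$x[, seq_len(nComponents), drop = FALSE],
                    obs@classOrder,
                    paste0(obs@featureOrigin, "+pca"))
}

#' Build class prototypes from a trained model's bottleneck
#'
#' Convenience composition of the prototype pipeline: sample `k` patches
#' per class, extract each patch's bottleneck volume, pool it to a
#' per-channel mean vector, and average within classes into an
#' [ObservationMatrix-class].
#'
#' @param model a trained [SegmentationModel-class].
#' @param train list of training [PatchMaskPair-class].
#' @param k patches sampled per class. Default 3.
#' @param seed sampling seed.
#' @return An [ObservationMatrix-class] tagged `"unet_mean"`.
#' @export
bottleneckObservationMatrix <- function(model, train, k = 3L, seed = 1L) {
  sel <- sampleClassPatches(train, k, seed)
  vecs <- lapply(sel, function(ps)
    lapply(ps, function(p)
      summarizeVolumeMean(extractBottleneck(model, patchImage(p)))))
  buildObservationMatrix(vecs, "unet_mean")
}

#' Color-statistic observation matrix
#'
#' Training-free counterpart of [bottleneckObservationMatrix()]: class
#' prototypes from per-patch foreground color statistics.
#'
#' @inheritParams bottleneckObservationMatrix
#' @return An [ObservationMatrix-class] tagged `"color_stats"`.
#' @export
colorObservationMatrix <- function(train, k = 3L, seed = 1L) {
  sel <- sampleClassPatches(train, k, seed)
  vecs <- lapply(sel, function(ps) lapply(ps, summarizeColorStats))
  buildObservationMatrix(vecs, "color_stats")
}
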