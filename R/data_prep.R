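#' Crop annotated trays into single-class ROI patch-mask pairs
#'
#' Cuts one patch per bounding box out of each tray. Within a patch, every
#' mask pixel whose tray-mask value differs from the box's class — pixels
#' of other foods included — is relabeled 0 (background), so each pair
#' shows exactly one class. Image pixel values are copied unchanged.
#'
#' @param trays list of [TrayRecord-class] objects.
#' @return list of [PatchMaskPair-class], one per box, in tray-then-box
#'   order, each tagged `"<trayId>:b<i>|identity"`.
#' @examples
#' tr <- generateTray(syntheticConfig(imageSize = c(64, 64)), traySeed = 1)
#' pairs <- cropRoiPatches(list(tr))
#' @export
cropRoiPatches <- function(trays) {
  out <- list()
  for (tr in trays) {
    if (!is(tr, "TrayRecord")) stop("inputs must be TrayRecord objects")
    b <- trayBoxes(tr)
    d <- dim(trayImage(tr))
    for (i in seq_len(nrow(b))) {
      if (b$x0[i] < 0 || b$y0[i] < 0 || b$x1[i] > d[2] || b$y1[i] > d[1])
        stop(sprintf("tray '%s' box %d [%d,%d)x[%d,%d) lies outside its %dx%d image",
                     trayId(tr), i, b$x0[i], b$x1[i], b$y0[i], b$y1[i],
                     d[1], d[2]))
      rows <- (b$y0[i] + 1):b$y1[i]
      cols <- (b$x0[i] + 1):b$x1[i]
      m <- trayMask(tr)[rows, cols, drop = FALSE]
      m[m != b$classId[i]] <- 0L
      out[[length(out) + 1L]] <- PatchMaskPair(
        patch = trayImage(tr)[rows, cols, , drop = FALSE],
        mask = m, targetClass = b$classId[i],
        provenance = sprintf("%s:b%d|identity", trayId(tr), i))
    }
  }
  out
}

#' Resize a patch-mask pair
#'
#' The image patch is resampled bilinearly; the mask with nearest-neighbour
#' (output pixel `i` samples input pixel `floor((i + 0.5) * n_in / n_out)`,
#' 0-based), so mask values remain in `{0, targetClass}`.
#'
#' @param pair a [PatchMaskPair-class].
#' @param size integer `(height, width)`, both positive.
#' @return The resized [PatchMaskPair-class] (identical object if already
#'   at `size`).
#' @export
resizePair <- function(pair, size) {
  size <- as.integer(size)
  if (length(size) != 2L || any(size < 1L))
    stop("size must be two positive integers (height, width)")
  if (identical(dim(patchMask(pair)), size)) return(pair)
  PatchMaskPair(
    patch = applyToChannels(patchImage(pair),
                            function(m) resampleBilinear(m, size)),
    mask = resampleNearest(patchMask(pair), size),
    targetClass = targetClass(pair), provenance = provenance(pair))
}

applyTransform <- function(pair, tag) {
  ops <- switch(tag,
    identity = list(),
    hflip = list(flipH),
    vflip = list(flipV),
    hvflip = list(flipH, flipV),
    rot90 = list(rot90cw),
    rot180 = list(rot90cw, rot90cw),
    rot270 = list(rot90cw, rot90cw, rot90cw),
    "vflip+rot90" = list(flipV, rot90cw),
    "vflip+rot180" = list(flipV, rot90cw, rot90cw),
    "vflip+rot270" = list(flipV, rot90cw, rot90cw, rot90cw),
    stop("unknown transform tag: ", tag))
  p <- patchImage(pair); m <- patchMask(pair)
  for (f in ops) {
    p <- applyToChannels(p, f)
    m <- f(m)
  }
  base <- sub("\\|[^|]*$", "", provenance(pair))
  PatchMaskPair(p, m, targetClass(pair), sprintf("%s|%s", base, tag))
}

#' Four-fold flip augmentation
#'
#' Expands every pair into itself, its horizontal flip, its vertical flip,
#' and the combined flip — patch and mask transformed identically — giving
#' exactly `4 n` output pairs (e.g. 2255 raw training pairs become 9020).
#'
#' @param pairs list of [PatchMaskPair-class].
#' @return list of length `4 * length(pairs)`, transform tags
#'   `identity`, `hflip`, `vflip`, `hvflip` recorded in the provenance.
#' @export
augmentFlips <- function(pairs) {
  tags <- c("identity", "hflip", "vflip", "hvflip")
  out <- vector("list", 4L * length(pairs))
  k <- 0L
  for (pair in pairs)
    for (tag in tags) {
      k <- k + 1L
      out[[k]] <- applyTransform(pair, tag)
    }
  out
}

#' Shuffle pairs and hold out a validation fraction
#'
#' Pairs are shuffled with a dedicated seeded generator (the caller's RNG
#' stream is untouched) and `round(valFraction * n)` of them (half-up) are
#' set aside for validation; e.g. 9020 pairs at 0.2 give 7216 training and
#' 1804 validation pairs.
#'
#' @param pairs non-empty list of [PatchMaskPair-class].
#' @param valFraction validation proportion in (0, 1). Default 0.2.
#' @param seed integer shuffle seed.
#' @return A [DatasetSplits-class] (test slot empty).
#' @export
splitTrainVal <- function(pairs, valFraction = 0.2, seed = 1L) {
  n <- length(pairs)
  if (n == 0L) stop("cannot split an empty pair list")
  if (!(valFraction > 0 && valFraction < 1))
    stop("valFraction must lie strictly between 0 and 1")
  nVal <- as.integer(roundHalfUp(valFraction * n))
  ord <- withSeed(deriveSeed(seed, "split"), sample.int(n))
  new("DatasetSplits",
      train = pairs[ord[seq.int(nVal + 1L, n)]],
      validation = pairs[ord[seq_len(nVal)]],
      test = list(), splitSeed = as.integer(seed))
}

testTransformOrder <- c("rot90", "rot180", "rot270", "vflip+rot90",
                        "vflip+rot180", "vflip+rot270", "vflip")

#' Expand under-represented test classes by rotation augmentation
#'
#' Brings every class up to `minimum` patches. New patches are generated by
#' cycling round-robin through a class's original patches, drawing for each
#' visit that patch's next unused transform in the fixed order rot90,
#' rot180, rot270, vflip+rot90, vflip+rot180, vflip+rot270, vflip (three
#' clockwise quarter-turns, the same three after a vertical flip, then the
#' flip itself) — at most 7 new patches per original. Classes already at or
#' above the minimum are returned unchanged.
#'
#' @param pairsByClass named list: class id -> list of
#'   [PatchMaskPair-class].
#' @param minimum target patch count per class (>= 1). Default 15.
#' @return The expanded named list; originals first, then new patches in
#'   generation order.
#' @export
augmentTestToMin <- function(pairsByClass, minimum = 15L) {
  if (minimum < 1L) stop("minimum must be at least 1")
  lapply(pairsByClass, function(orig) {
    m <- length(orig)
    if (m == 0L) stop("a class with no test patches cannot be expanded")
    need <- minimum - m
    if (need <= 0L) return(orig)
    if (minimum > 8L * m)
      stop(sprintf(
        "class needs %d patches from %d originals; the 7-transform scheme is exhausted",
        minimum, m))
    nextTransform <- integer(m) # per-original count of transforms used
    out <- orig
    i <- 0L
    while (need > 0L) {
      i <- i %% m + 1L
      if (nextTransform[i] >= 7L) next
      nextTransform[i] <- nextTransform[i] + 1L
      out[[length(out) + 1L]] <-
        applyTransform(orig[[i]], testTransformOrder[nextTransform[i]])
      need <- need - 1L
    }
    out
  })
}

#' Training steps per epoch
#'
#' Ceiling of pairs over batch size; 7216 training patches in batches of 20
#' give 361 steps.
#'
#' @param nPairs positive pair count.
#' @param batchSize positive batch size.
#' @return integer step count.
#' @export
stepsPerEpoch <- function(nPairs, batchSize) {
  if (!isCount(nPairs) || nPairs < 1L) stop("nPairs must be a positive count")
  if (!isCount(batchSize) || batchSize < 1L)
    stop("batchSize must be a positive count")
  as.integer(ceiling(nPairs / batchSize))
}

#' Group pairs by target class
#'
#' @param pairs list of [PatchMaskPair-class].
#' @return named list (class id as name) of pair lists, ascending class id.
#' @export
pairsByClass <- function(pairs) {
  cls <- vapply(pairs, targetClass, integer(1))
  ids <- sort(unique(cls))
  out <- lapply(ids, function(k) pairs[cls == k])
  names(out) <- as.character(ids)
  out
}
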