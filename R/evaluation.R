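# Pixel-level prediction quality: hit ratios, definite/indefinite
# classification, split cases, and top-2-plus-Other reports.

#' Predict one patch and tabulate per-class pixel counts
#'
#' @param model a [SegmentationModel-class].
#' @param pair a [PatchMaskPair-class] (its mask must already carry labels
#'   at the model's granularity).
#' @return A `PatchPrediction`: list with `predictedMask`, `truthMask`,
#'   `targetClass`, `pixelCounts` (named predicted-label counts summing to
#'   the pixel total).
#' @export
predictPatch <- function(model, pair) {
  prob <- unetForward(model, patchImage(pair))$prob
  patchPrediction(argmaxLabels(prob), patchMask(pair), targetClass(pair))
}

#' Construct a PatchPrediction from label rasters
#'
#' @param predictedMask,truthMask integer label matrices of equal shape.
#' @param targetClass the patch's single food class id.
#' @return A `PatchPrediction` list (see [predictPatch()]).
#' @export
patchPrediction <- function(predictedMask, truthMask, targetClass) {
  if (!identical(dim(predictedMask), dim(truthMask)))
    stop("predicted and truth masks differ in shape")
  counts <- table(factor(as.vector(predictedMask)))
  structure(list(predictedMask = predictedMask, truthMask = truthMask,
                 targetClass = as.integer(targetClass),
                 pixelCounts = stats::setNames(as.integer(counts),
                                               names(counts))),
            class = "PatchPrediction")
}

#' Pixel-level hit ratio of the target class
#'
#' Fraction of ground-truth target-class pixels predicted as the target
#' class. Background agreement is deliberately excluded: the denominator
#' is the truth foreground only.
#'
#' @param pred a `PatchPrediction`.
#' @return proportion in `[0, 1]`.
#' @export
hitRatio <- function(pred) {
  fg <- pred$truthMask == pred$targetClass
  if (!any(fg))
    stop("truth mask holds no target-class pixel; hit ratio is undefined")
  sum(pred$predictedMask[fg] == pred$targetClass) / sum(fg)
}

#' Definite or indefinite?
#'
#' A prediction is *definite* when its hit ratio strictly exceeds the
#' threshold (`> 0.75` by default — a ratio of exactly 0.75 is
#' indefinite).
#'
#' @param ratio hit ratio in `[0, 1]`.
#' @param threshold strict definiteness threshold. Default 0.75.
#' @return `"definite"` or `"indefinite"`.
#' @export
classifyDefiniteness <- function(ratio, threshold = 0.75) {
  if (any(ratio < 0 | ratio > 1)) stop("hit ratios must lie in [0, 1]")
  ifelse(ratio > threshold, "definite", "indefinite")
}

#' Summarize definiteness over a patch set
#'
#' @param preds non-empty list of `PatchPrediction` objects.
#' @param threshold strict definiteness threshold. Default 0.75.
#' @return A `DefinitenessSummary`: list with `nDefinite`, `nIndefinite`,
#'   `meanQuality` (mean hit ratio), `ratios`, and `perClass` (data.frame:
#'   `class`, `nDefinite`, `nPatches`).
#' @export
summarizeDefiniteness <- function(preds, threshold = 0.75) {
  if (!length(preds)) stop("no predictions to summarize")
  ratios <- vapply(preds, hitRatio, numeric(1))
  cls <- vapply(preds, function(p) p$targetClass, integer(1))
  def <- classifyDefiniteness(ratios, threshold) == "definite"
  per <- do.call(rbind, lapply(sort(unique(cls)), function(k)
    data.frame(class = k, nDefinite = sum(def[cls == k]),
               nPatches = sum(cls == k))))
  structure(list(nDefinite = sum(def), nIndefinite = sum(!def),
                 meanQuality = mean(ratios), ratios = ratios,
                 perClass = per, threshold = threshold),
            class = "DefinitenessSummary")
}

#' Classes on which models stay indefinite (split cases)
#'
#' A class is a split case for a model when the fraction of its patches
#' classified indefinite exceeds `rule`. The three-way (Venn-style) set
#' comparison names classes problematic for only the first model, only
#' the second, or both.
#'
#' @param summaryA,summaryB `DefinitenessSummary` objects over the same
#'   class universe.
#' @param rule indefinite-fraction threshold. Default 0.5.
#' @return list of integer vectors `onlyA`, `onlyB`, `both`.
#' @export
splitCases <- function(summaryA, summaryB, rule = 0.5) {
  pa <- summaryA$perClass
  pb <- summaryB$perClass
  if (!identical(pa$class, pb$class))
    stop("summaries cover different class sets")
  splitOf <- function(p) p$class[(p$nPatches - p$nDefinite) / p$nPatches > rule]
  a <- splitOf(pa)
  b <- splitOf(pb)
  list(onlyA = setdiff(a, b), onlyB = setdiff(b, a), both = intersect(a, b))
}

#' Top-k predicted labels plus "Other"
#'
#' Ranks the labels present in a prediction by predicted pixel count
#' (ties at the cut broken by ascending label id), reports the top `k` by
#' name and aggregates the remainder as `Other`. Fractions are ratios of
#' integer pixel counts and sum to one.
#'
#' @param pred a `PatchPrediction`.
#' @param topK labels reported by name. Default 2.
#' @return data.frame with columns `label` (character; `"Other"` last when
#'   present), `pixels`, `fraction`.
#' @export
topResponseReport <- function(pred, topK = 2L) {
  counts <- pred$pixelCounts
  ids <- as.integer(names(counts))
  ord <- order(-counts, ids)
  counts <- counts[ord]
  ids <- ids[ord]
  total <- sum(counts)
  k <- min(topK, length(counts))
  out <- data.frame(label = as.character(ids[seq_len(k)]),
                    pixels = as.integer(counts[seq_len(k)]),
                    stringsAsFactors = FALSE)
  if (length(counts) > k)
    out <- rbind(out, data.frame(label = "Other",
                                 pixels = sum(counts[-seq_len(k)])))
  out$fraction <- out$pixels / total
  out
}

#' Evaluate a model on test pairs at a hierarchy's final labels
#'
#' Predicts every pair and reduces to a definiteness summary.
#'
#' @param model a [SegmentationModel-class].
#' @param pairs list of [PatchMaskPair-class] test pairs.
#' @param threshold strict definiteness threshold. Default 0.75.
#' @return list with `summary` (a `DefinitenessSummary`), `predictions`,
#'   and `accuracy` (mean pixel accuracy over pairs).
#' @export
evaluateModel <- function(model, pairs, threshold = 0.75) {
  preds <- lapply(pairs, function(p) predictPatch(model, p))
  acc <- mean(vapply(seq_along(pairs), function(i)
    categoricalAccuracy(preds[[i]]$predictedMask, patchMask(pairs[[i]])),
    numeric(1)))
  list(summary = summarizeDefiniteness(preds, threshold),
       predictions = preds, accuracy = acc)
}

#' Write a label mask as a color-mapped PNG
#'
#' Minimal diagnostic rendering: each label gets a fixed hue, background
#' stays dark gray.
#'
#' @param mask integer label matrix.
#' @param file output PNG path.
#' @param maxLabel palette size; labels are mapped modulo this. Default
#'   `max(mask)`.
#' @return `file`, invisibly.
#' @export
writeLabelPng <- function(mask, file, maxLabel = max(mask)) {
  maxLabel <- max(1L, maxLabel)
  pal <- grDevices::hsv(h = (seq_len(maxLabel) - 1) / maxLabel, s = 0.7,
                        v = 0.9)
  rgb <- grDevices::col2rgb(pal) / 255
  img <- array(0.2, dim = c(dim(mask), 3))
  nz <- mask != 0L
  for (ch in 1:3) {
    plane <- img[, , ch]
    plane[nz] <- rgb[ch, (mask[nz] - 1L) %% maxLabel + 1L]
    img[, , ch] <- plane
  }
  png::writePNG(img, file)
  invisible(file)
}
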