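#' @rdname accessors
#' @export
setMethod("trayImage", "TrayRecord", function(x) x@image)
#' @rdname accessors
#' @export
setMethod("trayMask", "TrayRecord", function(x) x@mask)
#' @rdname accessors
#' @export
setMethod("trayBoxes", "TrayRecord", function(x) x@boxes)
#' @rdname accessors
#' @export
setMethod("trayId", "TrayRecord", function(x) x@trayId)

#' @rdname accessors
#' @export
setMethod("patchImage", "PatchMaskPair", function(x) x@patch)
#' @rdname accessors
#' @export
setMethod("patchMask", "PatchMaskPair", function(x) x@mask)
#' @rdname accessors
#' @export
setMethod("targetClass", "PatchMaskPair", function(x) x@targetClass)
#' @rdname accessors
#' @export
setMethod("provenance", "PatchMaskPair", function(x) x@provenance)

#' @rdname accessors
#' @export
setMethod("classOrder", "ObservationMatrix", function(x) x@classOrder)
#' @rdname accessors
#' @export
setMethod("featureOrigin", "ObservationMatrix", function(x) x@featureOrigin)

#' Matrix view of an ObservationMatrix
#'
#' @param x an [ObservationMatrix-class].
#' @param ... unused.
#' @return The underlying numeric matrix with class ids as row names.
#' @export
setMethod("as.matrix", "ObservationMatrix", function(x, ...) {
  m <- x@values
  rownames(m) <- as.character(x@classOrder)
  m
})

#' @rdname accessors
#' @export
setMethod("hierarchyStages", "LabelHierarchy", function(x) x@stages)
#' @rdname accessors
#' @export
setMethod("stageClassCounts", "LabelHierarchy",
          function(x) vapply(x@stages, function(s) s$C, integer(1)))

#' @rdname accessors
#' @export
setMethod("modelConfig", "SegmentationModel", function(x) x@config)
#' @rdname accessors
#' @export
setMethod("layerRegistry", "SegmentationModel", function(x) x@registry)

#' @rdname accessors
#' @export
setMethod("trainPairs", "DatasetSplits", function(x) x@train)
#' @rdname accessors
#' @export
setMethod("validationPairs", "DatasetSplits", function(x) x@validation)
#' @rdname accessors
#' @export
setMethod("testPairs", "DatasetSplits", function(x) x@test)

setMethod("show", "TrayRecord", function(object) {
  d <- dim(object@image)
  cat(sprintf("TrayRecord '%s': %d x %d image, %d boxes, %d classes in mask\n",
              object@trayId, d[1], d[2], nrow(object@boxes),
              length(setdiff(unique(as.vector(object@mask)), 0L))))
})

setMethod("show", "PatchMaskPair", function(object) {
  d <- dim(object@patch)
  cat(sprintf(
    "PatchMaskPair [%s]: %d x %d, target class %d (%.1f%% foreground)\n",
    object@provenance, d[1], d[2], object@targetClass,
    100 * mean(object@mask == object@targetClass)))
})

setMethod("show", "DatasetSplits", function(object) {
  cat(sprintf(
    "DatasetSplits: %d train / %d validation / %d test (seed %d)\n",
    length(object@train), length(object@validation), length(object@test),
    object@splitSeed))
})

setMethod("show", "ObservationMatrix", function(object) {
  cat(sprintf("ObservationMatrix: %d classes x %d features [%s]\n",
              nrow(object@values), ncol(object@values),
              object@featureOrigin))
})

setMethod("show", "LabelHierarchy", function(object) {
  cat(sprintf("LabelHierarchy: %d stages, C = %s (background fixed at 0)\n",
              length(object@stages),
              paste(stageClassCounts(object), collapse = ", ")))
})

setMethod("show", "NetworkConfig", function(object) {
  cat(sprintf(
    "NetworkConfig: input %dx%d, base %d, depth %d, bottleneck %d, C = %d\n",
    object@inputSize[1], object@inputSize[2], object@baseFilters,
    object@depth, object@bottleneckChannels, object@headClasses))
})

setMethod("show", "SegmentationModel", function(object) {
  r <- object@registry
  cat(sprintf(
    "SegmentationModel: %d convolutional layers, %s parameters, C = %d\n",
    sum(r$role != "pool" & r$role != "upsample"),
    format(sum(vapply(object@params,
                      function(p) length(p$W) + length(p$b), numeric(1))),
           big.mark = ","),
    object@config@headClasses))
})

setMethod("show", "SyntheticConfig", function(object) {
  cat(sprintf(
    "SyntheticConfig: %d families x %d classes, %dx%d trays, %d blobs/tray\n",
    object@nFamilies, object@classesPerFamily, object@imageSize[1],
    object@imageSize[2], object@blobsPerTray))
})
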