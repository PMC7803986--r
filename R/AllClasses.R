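#' @import methods
NULL

#' Annotated tray image
#'
#' One tray-style photograph together with its pixel-level ground truth: an
#' RGB raster, an integer label mask (0 = background / tray), and the
#' bounding boxes of the annotated food regions. Boxes are half-open,
#' 0-based pixel rectangles `[x0, x1) x [y0, y1)` with `x` running along
#' image columns and `y` along rows, so a box covers columns `x0+1 .. x1`
#' and rows `y0+1 .. y1` in 1-based R indexing.
#'
#' @slot image numeric array `H x W x 3`, intensities in `[0, 1]`.
#' @slot mask integer matrix `H x W`; 0 is background, positive values are
#'   class ids.
#' @slot boxes `data.frame` with columns `classId`, `x0`, `y0`, `x1`, `y1`.
#' @slot trayId character scalar identifying the tray.
#' @seealso [cropRoiPatches()], [generateTray()]
#' @export
setClass("TrayRecord",
  representation(image = "array", mask = "matrix", boxes = "data.frame",
                 trayId = "character"))

setValidity("TrayRecord", function(object) {
  msg <- character()
  d <- dim(object@image)
  if (length(d) != 3L || d[3] != 3L)
    msg <- c(msg, "image must be an H x W x 3 array")
  if (!identical(dim(object@mask), d[1:2]))
    msg <- c(msg, "mask and image dimensions differ")
  need <- c("classId", "x0", "y0", "x1", "y1")
  if (!all(need %in% names(object@boxes)))
    msg <- c(msg, "boxes needs columns classId, x0, y0, x1, y1")
  else if (nrow(object@boxes) > 0) {
    b <- object@boxes
    if (any(b$classId <= 0)) msg <- c(msg, "0 is never a box classId")
    if (any(b$x0 < 0 | b$y0 < 0 | b$x1 > d[2] | b$y1 > d[1] |
            b$x0 >= b$x1 | b$y0 >= b$y1))
      msg <- c(msg, "boxes must be non-empty rectangles inside the image")
    else {
      for (i in seq_len(nrow(b))) {
        sub <- object@mask[(b$y0[i] + 1):b$y1[i], (b$x0[i] + 1):b$x1[i]]
        if (!any(sub == b$classId[i])) {
          msg <- c(msg, sprintf(
            "box %d: class %d has no pixel inside its box", i, b$classId[i]))
          break
        }
      }
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct a TrayRecord
#'
#' @param image numeric `H x W x 3` array in `[0, 1]`.
#' @param mask integer `H x W` matrix of class labels (0 = background).
#' @param boxes data.frame of half-open 0-based boxes
#'   (`classId`, `x0`, `y0`, `x1`, `y1`).
#' @param trayId identifier string.
#' @return A [TrayRecord-class] object.
#' @export
TrayRecord <- function(image, mask, boxes, trayId = "tray") {
  storage.mode(mask) <- "integer"
  boxes <- as.data.frame(boxes)
  new("TrayRecord", image = image, mask = mask, boxes = boxes,
      trayId = as.character(trayId))
}

#' Single-class ROI patch
#'
#' An image crop taken from one annotated bounding box, paired with a mask
#' in which every pixel is either 0 (background) or the patch's single
#' target class. The provenance string records the source tray, the box,
#' and the geometric transform applied (e.g. `"t01:b2|hflip"`).
#'
#' @slot patch numeric array `h x w x 3`.
#' @slot mask integer matrix `h x w` with values in `{0, targetClass}`.
#' @slot targetClass positive integer class id.
#' @slot provenance character scalar.
#' @seealso [cropRoiPatches()], [augmentFlips()], [resizePair()]
#' @export
setClass("PatchMaskPair",
  representation(patch = "array", mask = "matrix", targetClass = "integer",
                 provenance = "character"))

setValidity("PatchMaskPair", function(object) {
  msg <- character()
  d <- dim(object@patch)
  if (length(d) != 3L || d[3] != 3L)
    msg <- c(msg, "patch must be an h x w x 3 array")
  if (!identical(dim(object@mask), d[1:2]))
    msg <- c(msg, "mask and patch dimensions differ")
  if (length(object@targetClass) != 1L || object@targetClass < 1L)
    msg <- c(msg, "targetClass must be a single positive integer")
  bad <- setdiff(unique(as.vector(object@mask)), c(0L, object@targetClass))
  if (length(bad))
    msg <- c(msg, sprintf("mask holds labels other than {0, target}: %s",
                          paste(bad, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' Construct a PatchMaskPair
#'
#' @param patch numeric `h x w x 3` array.
#' @param mask integer `h x w` matrix with values in `{0, targetClass}`.
#' @param targetClass positive integer class id.
#' @param provenance provenance tag string.
#' @return A [PatchMaskPair-class] object.
#' @export
PatchMaskPair <- function(patch, mask, targetClass, provenance = "patch") {
  storage.mode(mask) <- "integer"
  new("PatchMaskPair", patch = patch, mask = mask,
      targetClass = as.integer(targetClass),
      provenance = as.character(provenance))
}

#' Train / validation / test partition of patch-mask pairs
#'
#' @slot train,validation,test lists of [PatchMaskPair-class].
#' @slot splitSeed integer seed that produced the shuffle.
#' @seealso [splitTrainVal()]
#' @export
setClass("DatasetSplits",
  representation(train = "list", validation = "list", test = "list",
                 splitSeed = "integer"))

setValidity("DatasetSplits", function(object) {
  tv <- intersect(vapply(object@train, provenance, character(1)),
                  vapply(object@validation, provenance, character(1)))
  if (length(tv)) "train and validation overlap" else TRUE
})

#' Class-prototype observation matrix
#'
#' One feature observation (row) per food class, the input to hierarchical
#' clustering. `featureOrigin` records how the rows were produced
#' (`"unet_mean"`, `"deep_reduced"`, `"raw_serialized"`, `"color_stats"`,
#' optionally suffixed `"+pca"`).
#'
#' @slot values numeric matrix, `n_classes x F`, no missing values.
#' @slot classOrder integer vector of class ids, one per row, no duplicates.
#' @slot featureOrigin character tag.
#' @seealso [buildObservationMatrix()], [pcaScores()], [buildDendrogram()]
#' @export
setClass("ObservationMatrix",
  representation(values = "matrix", classOrder = "integer",
                 featureOrigin = "character"))

setValidity("ObservationMatrix", function(object) {
  msg <- character()
  if (nrow(object@values) != length(object@classOrder))
    msg <- c(msg, "one row per class id required")
  if (anyDuplicated(object@classOrder))
    msg <- c(msg, "classOrder has duplicates")
  if (anyNA(object@values) || any(!is.finite(object@values)))
    msg <- c(msg, "values must be finite with no missing entries")
  if (length(msg)) msg else TRUE
})

#' Construct an ObservationMatrix
#'
#' @param values numeric matrix with one row per class.
#' @param classOrder integer class ids in row order.
#' @param featureOrigin provenance tag for the features.
#' @return An [ObservationMatrix-class] object.
#' @export
ObservationMatrix <- function(values, classOrder,
                              featureOrigin = "unet_mean") {
  new("ObservationMatrix", values = as.matrix(values),
      classOrder = as.integer(classOrder),
      featureOrigin = as.character(featureOrigin))
}

#' Nested label hierarchy for curriculum training
#'
#' An ordered list of training stages. Stage `s` maps every original food
#' class id to a dense stage label in `1 .. C_s - 1`; label 0 is reserved
#' for background at every stage, so a stage with `k` food clusters has
#' `C = k + 1` head classes. Stages are strictly coarse-to-fine and nested:
#' classes sharing a label at stage `s + 1` also share one at stage `s`.
#' The final stage is the identity on the original labels.
#'
#' @slot stages list of `list(C = <int>, remap = <named integer vector>)`.
#' @slot backgroundLabel integer, always 0.
#' @seealso [buildLabelHierarchy()], [remapMask()], [runStl()]
#' @export
setClass("LabelHierarchy",
  representation(stages = "list", backgroundLabel = "integer"))

setValidity("LabelHierarchy", function(object) {
  msg <- character()
  if (!identical(object@backgroundLabel, 0L))
    msg <- c(msg, "background label must be 0")
  cs <- vapply(object@stages, function(s) s$C, numeric(1))
  if (length(cs) && any(diff(cs) <= 0))
    msg <- c(msg, "stage class counts C must be strictly increasing")
  for (s in object@stages) {
    if (!is.null(s$remap) && length(s$remap)) {
      if (any(s$remap == 0L))
        msg <- c(msg, "a food class may never map to background (0)")
      if (max(s$remap) != s$C - 1L)
        msg <- c(msg, "stage labels must be dense 1..C-1")
    }
  }
  ns <- length(object@stages)
  if (ns) {
    fin <- object@stages[[ns]]$remap
    if (!identical(unname(fin), as.integer(names(fin))))
      msg <- c(msg, "final stage must be the identity remap")
  }
  if (ns > 1) {
    for (s in seq_len(ns - 1L)) {
      co <- object@stages[[s]]$remap
      fi <- object@stages[[s + 1L]]$remap
      fi <- fi[names(co)]
      # classes sharing a fine label must share the coarse one
      if (length(unique(paste(fi, co))) != length(unique(fi)))
        msg <- c(msg, sprintf("stages %d and %d are not nested", s, s + 1L))
    }
  }
  if (length(msg)) unique(msg) else TRUE
})

#' Network hyper-parameter container
#'
#' Describes a U-Net-style encoder-decoder: `depth` encoder blocks whose
#' filter counts double per level starting from `baseFilters`, a bottleneck
#' of `baseFilters * 2^depth` channels, a mirrored decoder, and a 1x1
#' convolution head with `headClasses` output channels. The published
#' configuration is input 256x256, base 32, depth 5 (28 convolutional
#' layers, bottleneck depth 1024).
#'
#' @slot inputSize integer length-2 `(height, width)`, divisible by
#'   `2^depth`.
#' @slot baseFilters integer, filters of the first encoder block.
#' @slot depth integer number of encoder blocks.
#' @slot bottleneckChannels integer, always `baseFilters * 2^depth`.
#' @slot headClasses integer `C`, output channels of the classifier head.
#' @slot seed integer initialization seed.
#' @seealso [networkConfig()], [buildUnet()]
#' @export
setClass("NetworkConfig",
  representation(inputSize = "integer", baseFilters = "integer",
                 depth = "integer", bottleneckChannels = "integer",
                 headClasses = "integer", seed = "integer"))

setValidity("NetworkConfig", function(object) {
  msg <- character()
  if (length(object@inputSize) != 2L || any(object@inputSize < 1L))
    msg <- c(msg, "inputSize must be two positive integers")
  div <- 2L^object@depth
  if (any(object@inputSize %% div != 0L))
    msg <- c(msg, sprintf("input size must be divisible by 2^depth = %d", div))
  if (object@bottleneckChannels != object@baseFilters * 2L^object@depth)
    msg <- c(msg, "bottleneckChannels must equal baseFilters * 2^depth")
  if (object@headClasses < 2L)
    msg <- c(msg, "headClasses must be at least 2")
  if (length(msg)) msg else TRUE
})

#' Segmentation network with replaceable head
#'
#' Opaque parameter store for the in-package U-Net plus its configuration
#' and a layer registry naming every convolutional layer, the classifier
#' head, and the bottleneck tap. Parameters are plain numeric arrays so
#' exact equality checks (head-swap conservation) are meaningful.
#'
#' @slot config a [NetworkConfig-class].
#' @slot params named list of layer parameter sets.
#' @slot registry data.frame describing the layers (name, kernel, channels,
#'   role).
#' @seealso [buildUnet()], [replaceHead()], [extractBottleneck()]
#' @export
setClass("SegmentationModel",
  representation(config = "NetworkConfig", params = "list",
                 registry = "data.frame"))

setValidity("SegmentationModel", function(object) {
  head <- object@params[["head"]]
  if (is.null(head)) return("model must contain a 'head' layer")
  if (ncol(head$W) != object@config@headClasses)
    return("head output channels differ from config headClasses")
  TRUE
})

#' Parameters of the synthetic tray generator
#'
#' The generator draws tray images containing elliptical food-like blobs.
#' Classes are organized into visually correlated families: each family
#' owns a base color placed on a circle in RGB space at radius
#' `familyColorSpread` around the tray gray, and each class within a family
#' perturbs that base color with a Gaussian offset of standard deviation
#' `classColorSpread`. A recoverable hierarchy requires
#' `familyColorSpread > classColorSpread`.
#'
#' @slot nFamilies integer number of class families.
#' @slot classesPerFamily integer classes per family; total classes =
#'   `nFamilies * classesPerFamily` with ids `1..n` grouped by family.
#' @slot imageSize integer `(H, W)` of generated trays.
#' @slot blobsPerTray integer blobs per tray.
#' @slot familyColorSpread numeric, between-family color radius (RGB units).
#' @slot classColorSpread numeric, within-family color s.d. (RGB units).
#' @slot textureScales numeric vector of texture wavelengths in pixels.
#' @slot pixelNoise numeric s.d. of per-pixel Gaussian noise.
#' @slot seed integer seed fixing the class palette.
#' @seealso [syntheticConfig()], [generateTray()], [generateDataset()]
#' @export
setClass("SyntheticConfig",
  representation(nFamilies = "integer", classesPerFamily = "integer",
                 imageSize = "integer", blobsPerTray = "integer",
                 familyColorSpread = "numeric", classColorSpread = "numeric",
                 textureScales = "numeric", pixelNoise = "numeric",
                 seed = "integer"))

setValidity("SyntheticConfig", function(object) {
  msg <- character()
  if (object@nFamilies < 1L || object@classesPerFamily < 1L)
    msg <- c(msg, "need at least one family and one class per family")
  if (length(object@imageSize) != 2L || any(object@imageSize < 16L))
    msg <- c(msg, "imageSize must be two integers >= 16")
  if (object@blobsPerTray < 0L)
    msg <- c(msg, "blobsPerTray must be non-negative")
  if (object@familyColorSpread < 0 || object@classColorSpread < 0 ||
      object@pixelNoise < 0)
    msg <- c(msg, "spreads and noise must be non-negative")
  if (length(msg)) msg else TRUE
})
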