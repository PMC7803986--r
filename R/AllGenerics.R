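#' Accessor generics
#'
#' Small accessor family for the package's S4 containers: images, masks,
#' boxes, provenance tags, class orders and stage tables are read through
#' these rather than by slot access.
#'
#' @param x an object of the documented class.
#' @return The slot value named by the accessor.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("trayImage", function(x) standardGeneric("trayImage"))
#' @rdname accessors
#' @export
setGeneric("trayMask", function(x) standardGeneric("trayMask"))
#' @rdname accessors
#' @export
setGeneric("trayBoxes", function(x) standardGeneric("trayBoxes"))
#' @rdname accessors
#' @export
setGeneric("trayId", function(x) standardGeneric("trayId"))
#' @rdname accessors
#' @export
setGeneric("patchImage", function(x) standardGeneric("patchImage"))
#' @rdname accessors
#' @export
setGeneric("patchMask", function(x) standardGeneric("patchMask"))
#' @rdname accessors
#' @export
setGeneric("targetClass", function(x) standardGeneric("targetClass"))
#' @rdname accessors
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))
#' @rdname accessors
#' @export
setGeneric("classOrder", function(x) standardGeneric("classOrder"))
#' @rdname accessors
#' @export
setGeneric("featureOrigin", function(x) standardGeneric("featureOrigin"))
#' @rdname accessors
#' @export
setGeneric("hierarchyStages", function(x) standardGeneric("hierarchyStages"))
#' @rdname accessors
#' @export
setGeneric("stageClassCounts", function(x) standardGeneric("stageClassCounts"))
#' @rdname accessors
#' @export
setGeneric("modelConfig", function(x) standardGeneric("modelConfig"))
#' @rdname accessors
#' @export
setGeneric("layerRegistry", function(x) standardGeneric("layerRegistry"))
#' @rdname accessors
#' @export
setGeneric("trainPairs", function(x) standardGeneric("trainPairs"))
#' @rdname accessors
#' @export
setGeneric("validationPairs", function(x) standardGeneric("validationPairs"))
#' @rdname accessors
#' @export
setGeneric("testPairs", function(x) standardGeneric("testPairs"))
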