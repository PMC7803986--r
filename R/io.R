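# File interchange: JSON-lines tray manifests with PNG rasters, patch
# caches (paired PNGs + CSV index), observation-matrix CSVs, linkage CSVs
# and label-hierarchy JSON.
#
# Masks are stored as 8-bit single-channel PNGs holding the class index
# directly (value = id / 255), which caps class ids at 255 — ample for
# tray datasets of tens of classes.

#' Write trays as a JSON-lines manifest with PNG rasters
#'
#' One manifest line per tray: `{"trayId", "image", "mask", "boxes":
#' [[classId, x0, y0, x1, y1], ...]}` with paths relative to the manifest
#' and boxes in the package's half-open 0-based pixel convention.
#'
#' @param trays list of [TrayRecord-class].
#' @param dir output directory (created if missing).
#' @param name manifest file name. Default `"manifest.jsonl"`.
#' @return path of the manifest file, invisibly.
#' @export
writeTrayManifest <- function(trays, dir, name = "manifest.jsonl") {
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "masks"), recursive = TRUE, showWarnings = FALSE)
  lines <- vapply(trays, function(tr) {
    img <- file.path("images", paste0(trayId(tr), ".png"))
    msk <- file.path("masks", paste0(trayId(tr), ".png"))
    png::writePNG(trayImage(tr), file.path(dir, img))
    if (max(trayMask(tr)) > 255L) stop("mask class ids above 255 cannot be stored")
    png::writePNG(trayMask(tr) / 255, file.path(dir, msk))
    b <- trayBoxes(tr)
    jsonlite::toJSON(list(
      trayId = tr@trayId, image = img, mask = msk,
      boxes = unname(as.matrix(b[, c("classId", "x0", "y0", "x1", "y1")]))),
      auto_unbox = TRUE)
  }, character(1))
  path <- file.path(dir, name)
  writeLines(lines, path)
  invisible(path)
}

#' Read a JSON-lines tray manifest
#'
#' @param path manifest file written by [writeTrayManifest()] (or any
#'   manifest following the same schema).
#' @return list of [TrayRecord-class].
#' @export
readTrayManifest <- function(path) {
  dir <- dirname(path)
  lapply(readLines(path), function(line) {
    rec <- jsonlite::fromJSON(line)
    img <- png::readPNG(file.path(dir, rec$image))
    msk <- round(png::readPNG(file.path(dir, rec$mask)) * 255)
    storage.mode(msk) <- "integer"
    boxes <- as.data.frame(rec$boxes)
    if (nrow(boxes))
      names(boxes) <- c("classId", "x0", "y0", "x1", "y1")
    else boxes <- data.frame(classId = integer(), x0 = integer(),
                             y0 = integer(), x1 = integer(), y1 = integer())
    TrayRecord(img, msk, boxes, rec$trayId)
  })
}

#' Write a patch cache
#'
#' Pairs become numbered PNG pairs under `patches/` and `masks/` plus an
#' `index.csv` recording provenance, target class and split membership.
#'
#' @param pairs list of [PatchMaskPair-class].
#' @param dir cache directory.
#' @param split character split tag per pair (recycled). Default
#'   `"train"`.
#' @return path of the index CSV, invisibly.
#' @export
writePatchCache <- function(pairs, dir, split = "train") {
  dir.create(file.path(dir, "patches"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "masks"), recursive = TRUE, showWarnings = FALSE)
  split <- rep_len(split, length(pairs))
  idx <- do.call(rbind, lapply(seq_along(pairs), function(i) {
    p <- pairs[[i]]
    pf <- file.path("patches", sprintf("p%05d.png", i))
    mf <- file.path("masks", sprintf("p%05d.png", i))
    png::writePNG(patchImage(p), file.path(dir, pf))
    png::writePNG(patchMask(p) / 255, file.path(dir, mf))
    data.frame(patch = pf, mask = mf, targetClass = targetClass(p),
               provenance = provenance(p), split = split[i],
               stringsAsFactors = FALSE)
  }))
  path <- file.path(dir, "index.csv")
  utils::write.csv(idx, path, row.names = FALSE)
  invisible(path)
}

#' Read a patch cache
#'
#' @param dir cache directory written by [writePatchCache()].
#' @param split optional split tag filter.
#' @return list of [PatchMaskPair-class].
#' @export
readPatchCache <- function(dir, split = NULL) {
  idx <- utils::read.csv(file.path(dir, "index.csv"),
                         stringsAsFactors = FALSE)
  if (!is.null(split)) idx <- idx[idx$split %in% split, , drop = FALSE]
  lapply(seq_len(nrow(idx)), function(i) {
    img <- png::readPNG(file.path(dir, idx$patch[i]))
    msk <- round(png::readPNG(file.path(dir, idx$mask[i])) * 255)
    storage.mode(msk) <- "integer"
    PatchMaskPair(img, msk, idx$targetClass[i], idx$provenance[i])
  })
}

#' Write / read an observation matrix as CSV with a YAML sidecar
#'
#' The CSV holds one row per class (`classId` column first); the sidecar
#' `<file>.yml` records the feature origin.
#'
#' @param obs an [ObservationMatrix-class].
#' @param file CSV path.
#' @return `file` invisibly; `readObservationMatrix` the restored object.
#' @export
writeObservationMatrix <- function(obs, file) {
  df <- data.frame(classId = obs@classOrder, obs@values)
  names(df) <- c("classId", sprintf("f%d", seq_len(ncol(obs@values))))
  utils::write.csv(df, file, row.names = FALSE)
  yaml::write_yaml(list(featureOrigin = obs@featureOrigin,
                        nClasses = nrow(obs@values),
                        nFeatures = ncol(obs@values)),
                   paste0(file, ".yml"))
  invisible(file)
}

#' @rdname writeObservationMatrix
#' @export
readObservationMatrix <- function(file) {
  df <- utils::read.csv(file)
  side <- paste0(file, ".yml")
  origin <- if (file.exists(side)) yaml::read_yaml(side)$featureOrigin
            else "unknown"
  ObservationMatrix(as.matrix(df[, -1, drop = FALSE]), df$classId, origin)
}

#' Serialize a dendrogram's linkage table
#'
#' Four columns per merge — `left`, `right` (negative values are leaves,
#' positive earlier merges, as in [stats::hclust]), `height`, and the new
#' cluster's `size` — plus the leaf labels as a header comment-free
#' companion column file would be overkill: labels ride in the hierarchy
#' JSON instead.
#'
#' @param dendrogram a [stats::hclust] object.
#' @param file CSV path.
#' @return `file`, invisibly.
#' @export
writeLinkageCsv <- function(dendrogram, file) {
  sizes <- integer(nrow(dendrogram$merge))
  for (k in seq_len(nrow(dendrogram$merge))) {
    ab <- dendrogram$merge[k, ]
    sz <- function(v) if (v < 0) 1L else sizes[v]
    sizes[k] <- sz(ab[1]) + sz(ab[2])
  }
  utils::write.csv(data.frame(left = dendrogram$merge[, 1],
                              right = dendrogram$merge[, 2],
                              height = dendrogram$height, size = sizes),
                   file, row.names = FALSE)
  invisible(file)
}

#' Write / read a label hierarchy as JSON
#'
#' Schema: `{"stages": [{"C": <int>, "remap": {"<orig>": <label>}}, ...],
#' "backgroundLabel": 0}`.
#'
#' @param hierarchy a [LabelHierarchy-class].
#' @param file JSON path.
#' @return `file` invisibly; `readLabelHierarchy` the restored object.
#' @export
writeLabelHierarchy <- function(hierarchy, file) {
  stages <- lapply(hierarchy@stages, function(s)
    list(C = s$C, remap = as.list(s$remap)))
  jsonlite::write_json(list(stages = stages, backgroundLabel = 0L), file,
                       auto_unbox = TRUE)
  invisible(file)
}

#' @rdname writeLabelHierarchy
#' @export
readLabelHierarchy <- function(file) {
  j <- jsonlite::fromJSON(file, simplifyVector = FALSE)
  stages <- lapply(j$stages, function(s) {
    remap <- as.integer(unlist(s$remap))
    names(remap) <- names(s$remap)
    list(C = as.integer(s$C), remap = remap)
  })
  new("LabelHierarchy", stages = stages, backgroundLabel = 0L)
}
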