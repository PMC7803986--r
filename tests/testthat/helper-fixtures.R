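# Programmatic fixtures: tiny patch-mask pairs, hand-built trays, random
# observation matrices and dendrograms.

tinyPair <- function(h = 4L, w = 4L, cls = 1L, fill = 0.5,
                     provenance = "fix:b1|identity", fgRows = NULL) {
  patch <- array(fill, dim = c(h, w, 3))
  mask <- matrix(cls, h, w)
  if (!is.null(fgRows)) {
    mask[] <- 0L
    mask[fgRows, ] <- cls
  }
  PatchMaskPair(patch, mask, cls, provenance)
}

# A 12x12 tray: class 5 blob in a box that also overlaps a class 7 blob.
overlapTray <- function() {
  img <- array(0.4, dim = c(12, 12, 3))
  mask <- matrix(0L, 12, 12)
  mask[3:6, 3:8] <- 5L      # class 5 region
  mask[3:6, 7:10] <- 7L     # class 7 region overwrites columns 7:8
  img[, , 1][mask == 5L] <- 0.9
  img[, , 2][mask == 7L] <- 0.9
  boxes <- data.frame(classId = c(5L, 7L),
                      x0 = c(2L, 6L), y0 = c(2L, 2L),
                      x1 = c(8L, 10L), y1 = c(6L, 6L))
  TrayRecord(img, mask, boxes, "ovl")
}

randomObs <- function(n, f = 3L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ObservationMatrix(matrix(rnorm(n * f), n, f), seq_len(n), "color_stats")
}

randomDendrogram <- function(n, seed) {
  set.seed(seed)
  hc <- hclust(dist(matrix(rnorm(n * 3), n)), method = "ward.D2")
  hc$labels <- as.character(seq_len(n))
  hc
}

tinyNetConfig <- function(C = 3L, seed = 1L, size = c(16L, 16L),
                          base = 2L, depth = 2L) {
  networkConfig(size, base, depth, headClasses = C, seed = seed)
}

# Strongly separable two-class segmentation task: dark background with a
# bright square blob.
blobTask <- function(nTrain = 16L, nVal = 4L, size = 16L, seed = 1L) {
  set.seed(seed)
  mk <- function(i) {
    patch <- array(runif(size * size * 3, 0, 0.15), dim = c(size, size, 3))
    mask <- matrix(0L, size, size)
    side <- size %/% 2L + 2L
    r <- sample.int(size - side, 1L)
    c <- sample.int(size - side, 1L)
    mask[r:(r + side - 1L), c:(c + side - 1L)] <- 1L
    for (k in 1:3)
      patch[, , k][mask == 1L] <- runif(side * side, 0.8, 1.0)
    PatchMaskPair(patch, mask, 1L, sprintf("blob%02d|identity", i))
  }
  list(train = lapply(seq_len(nTrain), mk),
       val = lapply(nTrain + seq_len(nVal), mk))
}

sumAbsParamDiff <- function(a, b, layers) {
  sum(vapply(layers, function(nm)
    sum(abs(a[[nm]]$W - b[[nm]]$W)) + sum(abs(a[[nm]]$b - b[[nm]]$b)),
    numeric(1)))
}

nonHeadLayers <- function(model) setdiff(names(model@params), "head")
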