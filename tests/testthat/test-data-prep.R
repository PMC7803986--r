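test_that("cropRoiPatches yields one single-class pair per box", {
  tr <- overlapTray()
  pairs <- cropRoiPatches(list(tr))
  expect_length(pairs, 2L)
  expect_equal(vapply(pairs, targetClass, integer(1)), c(5L, 7L))
  for (p in pairs)
    expect_true(all(unique(as.vector(patchMask(p))) %in%
                      c(0L, targetClass(p))))
  # the class-5 box encloses class-7 pixels (columns 7:8); they become bg
  m5 <- patchMask(pairs[[1]])
  full <- trayMask(tr)[3:6, 3:8]
  expect_true(any(full == 7L))
  expect_true(all(m5[full == 7L] == 0L))
  # pixel values are preserved verbatim
  expect_identical(patchImage(pairs[[1]]), trayImage(tr)[3:6, 3:8, ])
})

test_that("cropRoiPatches matches a direct per-box crop oracle and tags provenance", {
  img <- array(runif(10 * 10 * 3), dim = c(10, 10, 3))
  mask <- matrix(0L, 10, 10)
  mask[2:5, 2:5] <- 3L; mask[7:9, 2:4] <- 3L; mask[2:4, 7:9] <- 3L
  boxes <- data.frame(classId = 3L, x0 = c(1L, 1L, 6L), y0 = c(1L, 6L, 1L),
                      x1 = c(5L, 4L, 9L), y1 = c(5L, 9L, 4L))
  tr <- TrayRecord(img, mask, boxes, "t3")
  pairs <- cropRoiPatches(list(tr))
  expect_length(pairs, 3L)
  expect_length(unique(vapply(pairs, provenance, character(1))), 3L)
  for (i in 1:3) {
    rows <- (boxes$y0[i] + 1):boxes$y1[i]
    cols <- (boxes$x0[i] + 1):boxes$x1[i]
    expect_identical(patchImage(pairs[[i]]), img[rows, cols, ])
    oracle <- mask[rows, cols]; oracle[oracle != 3L] <- 0L
    expect_identical(patchMask(pairs[[i]]), oracle)
  }
})

test_that("cropRoiPatches rejects out-of-bounds boxes and passes empty trays", {
  img <- array(0.5, dim = c(8, 8, 3))
  mask <- matrix(0L, 8, 8); mask[2:3, 2:3] <- 1L
  bad <- TrayRecord(img, mask, data.frame(classId = 1L, x0 = 1L, y0 = 1L,
                                          x1 = 4L, y1 = 4L), "bad")
  bad@boxes$x1 <- 12L   # corrupt past validity, as a broken manifest would
  expect_error(cropRoiPatches(list(bad)), "outside")
  empty <- TrayRecord(img, matrix(0L, 8, 8),
                      data.frame(classId = integer(), x0 = integer(),
                                 y0 = integer(), x1 = integer(),
                                 y1 = integer()), "empty")
  expect_length(cropRoiPatches(list(empty)), 0L)
})

test_that("resizePair keeps masks in {0, target} and is identity at size", {
  p <- tinyPair(4, 4, cls = 2L, fgRows = 1:2)
  expect_identical(resizePair(p, c(4, 4)), p)
  up <- resizePair(tinyPair(2, 2, cls = 6L), c(4, 4))
  expect_true(all(patchMask(up) == 6L))
  down <- resizePair(p, c(2, 2))
  expect_true(all(unique(as.vector(patchMask(down))) %in% c(0L, 2L)))
  # nearest-neighbour index-mapping oracle: out i samples in floor((i+.5)*n/m)
  m <- patchMask(p)
  idx <- function(nOut, nIn) floor(((seq_len(nOut) - 1) + 0.5) * nIn / nOut) + 1
  expect_identical(patchMask(down), m[idx(2, 4), idx(2, 4)])
  expect_error(resizePair(p, c(0, 4)), "positive")
})

test_that("augmentFlips quadruples pairs with involutive transforms", {
  p <- tinyPair(3, 5, cls = 1L, fgRows = 1L)
  out <- augmentFlips(list(p))
  expect_length(out, 4L)
  tags <- sub(".*\\|", "", vapply(out, provenance, character(1)))
  expect_setequal(tags, c("identity", "hflip", "vflip", "hvflip"))
  # patch and mask transformed identically; double flip is the original
  h <- out[[which(tags == "hflip")]]
  h2 <- stlseg:::applyTransform(h, "hflip")
  expect_equal(patchImage(h2), patchImage(p))
  expect_identical(patchMask(h2), patchMask(p))
  v <- out[[which(tags == "vflip")]]
  expect_identical(patchMask(v), patchMask(p)[3:1, ])
  expect_equal(patchImage(v), patchImage(p)[3:1, , ])
})

test_that("flip augmentation and validation split reproduce the published bookkeeping", {
  raw <- lapply(seq_len(2255), function(i)
    tinyPair(2, 2, cls = (i %% 5L) + 1L, provenance = sprintf("t%04d:b1|identity", i)))
  aug <- augmentFlips(raw)
  expect_length(aug, 9020L)
  splits <- splitTrainVal(aug, 0.2, seed = 3L)
  expect_length(trainPairs(splits), 7216L)
  expect_length(validationPairs(splits), 1804L)
})

test_that("splitTrainVal is deterministic, disjoint, and guards bad input", {
  pairs <- lapply(1:10, function(i)
    tinyPair(2, 2, cls = 1L, provenance = sprintf("p%02d|identity", i)))
  s1 <- splitTrainVal(pairs, 0.2, seed = 9L)
  s2 <- splitTrainVal(pairs, 0.2, seed = 9L)
  expect_length(trainPairs(s1), 8L)
  expect_length(validationPairs(s1), 2L)
  expect_identical(vapply(trainPairs(s1), provenance, character(1)),
                   vapply(trainPairs(s2), provenance, character(1)))
  expect_length(intersect(vapply(trainPairs(s1), provenance, character(1)),
                          vapply(validationPairs(s1), provenance,
                                 character(1))), 0L)
  expect_error(splitTrainVal(list(), 0.2), "empty")
  expect_error(splitTrainVal(pairs, 1.2), "between")
})

test_that("augmentTestToMin expands deficient classes round-robin", {
  mk <- function(cls, i) tinyPair(4, 4, cls = cls,
                                  provenance = sprintf("c%d_%d|identity", cls, i))
  by <- list("1" = lapply(1:15, mk, cls = 1L),
             "2" = lapply(1:2, mk, cls = 2L))
  out <- augmentTestToMin(by, 15L)
  expect_length(out[["1"]], 15L)
  expect_identical(out[["1"]], by[["1"]])     # already at minimum
  expect_length(out[["2"]], 15L)
  prov <- vapply(out[["2"]], provenance, character(1))
  expect_length(unique(prov), 15L)            # no duplicate (source, transform)
  # 13 new patches: 7 from the first original, 6 from the second
  src <- sub("\\|.*", "", prov[-(1:2)])
  expect_equal(as.vector(table(src)), c(7L, 6L))
  # fixed transform order, drawn alternately
  expect_match(prov[3], "c2_1\\|rot90")
  expect_match(prov[4], "c2_2\\|rot90")
  expect_match(prov[5], "c2_1\\|rot180")
  expect_match(prov[15], "c2_1\\|vflip$")
  expect_error(augmentTestToMin(list("9" = list(mk(9L, 1))), 9L), "exhausted")
})

test_that("65 classes brought to 15 patches give 975 in total", {
  by <- lapply(1:65, function(cls)
    lapply(1:2, function(i)
      tinyPair(2, 2, cls = cls, provenance = sprintf("c%d_%d|identity", cls, i))))
  names(by) <- as.character(1:65)
  out <- augmentTestToMin(by, 15L)
  expect_equal(sum(lengths(out)), 975L)
})

test_that("stepsPerEpoch is the ceiling of pairs over batch", {
  expect_identical(stepsPerEpoch(7216L, 20L), 361L)
  expect_identical(stepsPerEpoch(20L, 20L), 1L)
  expect_identical(stepsPerEpoch(21L, 20L), 2L)
  expect_error(stepsPerEpoch(10L, 0L), "positive")
})

test_that("rotation transforms preserve patch-mask alignment", {
  p <- tinyPair(4, 6, cls = 2L, fgRows = 1L)
  r <- stlseg:::applyTransform(p, "rot90")
  expect_identical(dim(patchMask(r)), c(6L, 4L))
  # four quarter turns restore the original
  r4 <- Reduce(function(q, .) stlseg:::applyTransform(q, "rot90"), 1:4,
               accumulate = FALSE, init = p)
  expect_identical(patchMask(r4), patchMask(p))
  expect_equal(patchImage(r4), patchImage(p))
})
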