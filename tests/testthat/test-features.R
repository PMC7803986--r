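test_that("class sampling is per-class, seeded, and replacement-aware", {
  pairs <- unlist(lapply(1:65, function(cls)
    lapply(seq_len(3 + cls %% 3), function(i)
      tinyPair(2, 2, cls = cls, provenance = sprintf("c%d_%d|identity", cls, i)))),
    recursive = FALSE)
  sel <- sampleClassPatches(pairs, k = 3L, seed = 2L)
  expect_length(sel, 65L)
  expect_identical(sum(lengths(sel)), 195L)
  sel2 <- sampleClassPatches(pairs, k = 3L, seed = 2L)
  expect_identical(lapply(sel, function(ps) vapply(ps, provenance, character(1))),
                   lapply(sel2, function(ps) vapply(ps, provenance, character(1))))
  # a class with exactly k patches contributes all of them
  three <- sel[["3"]]   # class 3 has 3 + (3 %% 3) = 3 patches
  expect_setequal(vapply(three, provenance, character(1)),
                  sprintf("c3_%d|identity", 1:3))
  # classes smaller than k are sampled with replacement
  one <- list(tinyPair(2, 2, cls = 9L))
  selR <- sampleClassPatches(one, k = 3L, seed = 1L)
  expect_length(selR[["9"]], 3L)
})

test_that("summarizeVolumeMean is the per-channel spatial mean", {
  v <- array(1:5, dim = c(1, 1, 5))
  expect_equal(summarizeVolumeMean(v), as.numeric(1:5))
  expect_equal(summarizeVolumeMean(array(3.5, c(4, 4, 2))), c(3.5, 3.5))
  set.seed(8)
  v2 <- array(rnorm(12), dim = c(2, 2, 3))
  brute <- vapply(1:3, function(d) mean(v2[, , d]), numeric(1))
  expect_equal(summarizeVolumeMean(v2), brute)
  expect_error(summarizeVolumeMean(array(0, c(0, 2, 2))), "empty")
})

test_that("deep-volume reduction serializes H'W' x nComponents scores", {
  set.seed(4)
  v <- array(rnorm(2 * 2 * 3), dim = c(2, 2, 3))
  out <- reduceDeepVolume(v, 3L)
  expect_length(out, 12L)
  # full-rank projection is lossless: reconstruct the centered matrix
  m <- stlseg:::volumeToMatrix(v)
  pc <- prcomp(m, center = TRUE, scale. = FALSE)
  rec <- pc$x %*% t(pc$rotation)
  expect_lt(max(abs(rec - scale(m, scale = FALSE))), 1e-10)
  scores <- matrix(out, nrow = 4, byrow = TRUE)
  expect_equal(abs(scores), abs(unname(pc$x)), tolerance = 1e-10)
  expect_error(reduceDeepVolume(v, 4L), "exceeds")
  # length contract holds for a non-square spatial grid
  v3 <- array(rnorm(2 * 4 * 5), dim = c(2, 4, 5))
  expect_length(reduceDeepVolume(v3, 2L), 16L)
})

test_that("the reference deep volume reduces from 4.19e6 to 51200 elements", {
  set.seed(1)
  v <- array(rnorm(32 * 32 * 4096), dim = c(32, 32, 4096))
  expect_equal(signif(length(serializeVolume(v)), 3), 4.19e6)
  expect_length(reduceDeepVolume(v, 50L), 51200L)
})

test_that("observation rows are class-wise vector means in ascending id order", {
  vecs <- list("7" = list(c(0, 0), c(2, 2)), "2" = list(c(1, 3)))
  obs <- buildObservationMatrix(vecs)
  expect_identical(classOrder(obs), c(2L, 7L))
  expect_equal(unname(as.matrix(obs)), rbind(c(1, 3), c(1, 1)))
  # k = 1 rows equal the single vectors; 65 classes give 65 rows
  many <- lapply(1:65, function(i) list(rnorm(4)))
  names(many) <- as.character(1:65)
  obs65 <- buildObservationMatrix(many)
  expect_identical(nrow(as.matrix(obs65)), 65L)
  expect_equal(unname(as.matrix(obs65)[3, ]), many[["3"]][[1]])
  # mean commutativity: sampling order of the vectors is irrelevant
  sw <- buildObservationMatrix(list("7" = rev(vecs[["7"]]), "2" = vecs[["2"]]))
  expect_equal(as.matrix(obs), as.matrix(sw))
  expect_error(buildObservationMatrix(list("1" = list(1:2), "2" = list(1:3))),
               "inconsistent")
})

test_that("pcaScores projects onto orthonormal axes and honors targets", {
  # collinear 3-D data: one component carries all variance
  t <- seq(-2, 2, length.out = 6)
  line <- ObservationMatrix(cbind(t, 2 * t, -t), 1:6, "color_stats")
  p1 <- pcaScores(line, varianceTarget = 0.99)
  expect_identical(ncol(as.matrix(p1)), 1L)
  expect_match(featureOrigin(p1), "\\+pca$")
  # two observations leave at most one nontrivial component
  two <- ObservationMatrix(rbind(c(0, 0, 0), c(1, 1, 1)), 1:2, "x")
  expect_lte(ncol(as.matrix(pcaScores(two, 0.999))), 1L)
  # full projection then inverse projection recovers the centered data
  obs <- randomObs(8, 5, seed = 3)
  pc <- prcomp(obs@values, center = TRUE)
  full <- pcaScores(obs, nComponents = 5L)
  rec <- as.matrix(full) %*% t(pc$rotation)
  expect_lt(max(abs(unname(rec) - unname(scale(obs@values, scale = FALSE)))),
            1e-8)
  expect_error(pcaScores(ObservationMatrix(matrix(1, 1, 3), 1L, "x")),
               "at least 2")
})

test_that("pca scores are row-order invariant up to sign", {
  obs <- randomObs(7, 4, seed = 5)
  perm <- c(4, 1, 7, 3, 6, 2, 5)
  shuffled <- ObservationMatrix(obs@values[perm, ], obs@classOrder[perm], "x")
  a <- as.matrix(pcaScores(obs, nComponents = 3L))
  b <- as.matrix(pcaScores(shuffled, nComponents = 3L))
  expect_equal(abs(a[as.character(perm), ]), abs(b), tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("color statistics summarize the foreground only", {
  p <- tinyPair(4, 4, cls = 2L, fgRows = 1:2, fill = 0.25)
  v <- summarizeColorStats(p)
  expect_length(v, 6L)
  expect_equal(v[1:3], rep(0.25, 3))
  expect_equal(v[4:6], rep(0, 3))
  bg <- tinyPair(2, 2, cls = 1L)
  bg@mask[] <- 0L
  expect_error(summarizeColorStats(bg), "foreground")
})
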