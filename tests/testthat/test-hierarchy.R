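lineObs <- function() ObservationMatrix(matrix(c(0, 1, 2, 10, 11), 5, 1),
                                        1:5, "x")

test_that("two observations give one link at their distance", {
  obs <- ObservationMatrix(rbind(c(0, 0), c(3, 4)), 1:2, "x")
  hc <- buildDendrogram(obs, "single")
  expect_identical(nLeaves(hc), 2L)
  expect_equal(hc$height, 5)
})

test_that("the line fixture merges and cuts as enumerated by hand", {
  hc <- buildDendrogram(lineObs(), "single")
  expect_length(hc$height, 4L)           # n - 1 links
  expect_equal(max(hc$height), 8)        # single-linkage gap 10 - 2
  p <- cutAtHeight(hc, 1.5)
  expect_identical(p$nClusters, 2L)
  expect_identical(unname(p$assignment[as.character(1:5)]),
                   c(1L, 1L, 1L, 2L, 2L))
  expect_identical(cutAtHeight(hc, 0)$nClusters, 5L)   # below all links
  expect_identical(cutAtHeight(hc, 99)$nClusters, 1L)  # above all links
})

test_that("65 observations produce 64 links", {
  expect_length(buildDendrogram(randomObs(65, 4, seed = 1))$height, 64L)
})

test_that("cutAtHeight matches brute-force connected components and the link-count identity", {
  for (seed in 1:10) {
    hc <- randomDendrogram(sample(4:12, 1), seed)
    for (h in c(0, sample(hc$height, 2), max(hc$height) * 1.1)) {
      p <- cutAtHeight(hc, h)
      expect_identical(p$nClusters, 1L + sum(hc$height > h))
      expect_true(samePartition(p$assignment, naiveCutComponents(hc, h)))
      expect_true(samePartition(p$assignment, cutree(hc, h = h)))
    }
  }
})

test_that("greatest-link cuts sever distinct heights coarse to fine, ties together", {
  hc <- buildDendrogram(lineObs(), "single")
  p1 <- cutsByGreatestLinks(hc, 1)
  expect_length(p1, 1L)
  expect_identical(p1[[1]]$nClusters, 2L)   # below the root link
  # the three height-1 links are tied: the second cut severs them together
  p2 <- cutsByGreatestLinks(hc, 2)
  expect_identical(vapply(p2, function(p) p$nClusters, integer(1)),
                   c(2L, 5L))
  # constructed tied-height fixture: pairs {0,1} and {100,101}
  tied <- ObservationMatrix(matrix(c(0, 1, 100, 101), 4, 1), 1:4, "x")
  hct <- buildDendrogram(tied, "complete")
  pt <- cutsByGreatestLinks(hct, 2)
  expect_identical(pt[[1]]$nClusters, 2L)
  expect_identical(pt[[2]]$nClusters, 4L)   # both tied links severed
  expect_error(cutsByGreatestLinks(hct, 4), "must lie in")
})

test_that("cut refinement: lower cuts refine higher ones", {
  for (seed in 1:8) {
    hc <- randomDendrogram(sample(5:12, 1), seed + 50)
    hs <- sort(c(0, sample(hc$height, 3), max(hc$height) + 1))
    parts <- lapply(hs, function(h) cutAtHeight(hc, h)$assignment)
    for (i in seq_len(length(hs) - 1)) {
      fine <- parts[[i]]; coarse <- parts[[i + 1]]
      # each fine cluster maps into exactly one coarse cluster
      expect_identical(length(unique(paste(fine, coarse))),
                       length(unique(fine)))
    }
  }
})

test_that("cutsByClusterCounts reaches at least the requested sizes", {
  hc <- buildDendrogram(lineObs(), "single")
  ps <- cutsByClusterCounts(hc, c(2L, 3L))
  # 3 clusters are unreachable between the tied height-1 links: overshoot
  expect_identical(vapply(ps, function(p) p$nClusters, integer(1)),
                   c(2L, 5L))
  hc2 <- randomDendrogram(9, 77)
  ps2 <- cutsByClusterCounts(hc2, c(2L, 4L))
  expect_identical(vapply(ps2, function(p) p$nClusters, integer(1)),
                   c(2L, 4L))
  expect_error(cutsByClusterCounts(hc2, c(4L, 2L)), "increasing")
})

test_that("label hierarchies are nested, background-fixed, identity-final", {
  obs <- randomObs(4, 3, seed = 21)
  hc <- buildDendrogram(obs)
  parts <- cutsByGreatestLinks(hc, 1)
  h <- buildLabelHierarchy(parts, 1:4)
  expect_identical(stageClassCounts(h), c(3L, 5L))  # 2 clusters + bg, then identity
  st <- hierarchyStages(h)
  expect_identical(unname(st[[2]]$remap), 1:4)
  # remap composition: the coarse label is a function of the fine label
  fine <- st[[2]]$remap; coarse <- st[[1]]$remap
  expect_identical(length(unique(paste(fine, coarse))), length(unique(fine)))
  # foreign, non-nested partitions are rejected
  bad <- list(
    list(assignment = c("1" = 1L, "2" = 1L, "3" = 2L, "4" = 2L),
         nClusters = 2L, cutHeight = 1),
    list(assignment = c("1" = 1L, "2" = 2L, "3" = 1L, "4" = 3L),
         nClusters = 3L, cutHeight = 0.5))
  expect_error(buildLabelHierarchy(bad, 1:4), "not nested")
  expect_error(buildLabelHierarchy(parts, c(2L, 3L, 4L, 5L)), "contiguous")
})

test_that("remapMask relabels element-wise and preserves background", {
  obs <- randomObs(9, 3, seed = 33)
  hc <- buildDendrogram(obs)
  h <- buildLabelHierarchy(cutsByGreatestLinks(hc, 2), 1:9)
  st <- hierarchyStages(h)[[1]]
  mask <- matrix(c(0L, 5L, 9L, 0L), 2, 2)
  out <- remapMask(mask, st)
  expect_identical(out[mask == 0L], c(0L, 0L))
  expect_identical(out[2, 1], unname(st$remap[["5"]]))
  # direct lookup oracle over every cell
  expect_identical(as.vector(out)[as.vector(mask) != 0],
                   unname(st$remap[as.character(mask[mask != 0])]))
  # classes sharing a cluster collapse to one stage label
  same <- which(st$remap == st$remap[["5"]])
  if (length(same) > 1) {
    m2 <- matrix(as.integer(same[1:2]), 1, 2)
    o2 <- remapMask(m2, st)
    expect_identical(o2[1], o2[2])
  }
  # identity stage leaves masks unchanged
  idSt <- hierarchyStages(h)[[length(hierarchyStages(h))]]
  expect_identical(remapMask(mask, idSt), mask)
  allBg <- matrix(0L, 3, 3)
  expect_identical(remapMask(allBg, st), allBg)
  expect_error(remapMask(matrix(77L, 1, 1), st), "77")
})

test_that("linkage and hierarchy serializations round-trip", {
  obs <- randomObs(8, 3, seed = 13)
  hc <- buildDendrogram(obs)
  f <- tempfile(fileext = ".csv")
  writeLinkageCsv(hc, f)
  lk <- read.csv(f)
  expect_identical(nrow(lk), 7L)
  expect_equal(lk$height, hc$height)
  expect_identical(lk$size[7], 8L)
  h <- buildLabelHierarchy(cutsByGreatestLinks(hc, 2), 1:8)
  fj <- tempfile(fileext = ".json")
  writeLabelHierarchy(h, fj)
  h2 <- readLabelHierarchy(fj)
  expect_identical(hierarchyStages(h), hierarchyStages(h2))
  unlink(c(f, fj))
})
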