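# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: the agglomeration oracle computes cluster
# dissimilarities directly from member points (centroid form for Ward),
# the cut oracle expands leaf sets from the merge table, and the adjusted
# Rand oracle evaluates the contingency-table formula.

# O(n^3) naive bottom-up agglomeration. Returns merge heights in order and
# the leaf set created by each merge.
naiveAgglom <- function(x, linkage = c("single", "complete", "average",
                                       "ward")) {
  linkage <- match.arg(linkage)
  n <- nrow(x)
  pd <- as.matrix(dist(x))
  cdist <- function(A, B) {
    switch(linkage,
      single = min(pd[A, B]),
      complete = max(pd[A, B]),
      average = mean(pd[A, B]),
      ward = {
        ca <- colMeans(x[A, , drop = FALSE])
        cb <- colMeans(x[B, , drop = FALSE])
        sqrt(2 * length(A) * length(B) / (length(A) + length(B)) *
               sum((ca - cb)^2))
      })
  }
  clusters <- lapply(seq_len(n), identity)
  ids <- seq_len(n)
  heights <- numeric(n - 1)
  merges <- vector("list", n - 1)
  for (k in seq_len(n - 1)) {
    best <- Inf; bi <- bj <- 0L
    for (i in seq_along(ids)) for (j in seq_along(ids)) if (i < j) {
      d <- cdist(clusters[[ids[i]]], clusters[[ids[j]]])
      if (d < best - 1e-12) { best <- d; bi <- i; bj <- j }
    }
    heights[k] <- best
    clusters[[length(clusters) + 1L]] <-
      c(clusters[[ids[bi]]], clusters[[ids[bj]]])
    merges[[k]] <- sort(clusters[[length(clusters)]])
    ids <- c(ids[-c(bi, bj)], length(clusters))
  }
  list(heights = heights, merges = merges, n = n)
}

# Partition (integer labels per leaf) after applying the oracle's first m
# merges.
oraclePartition <- function(oracle, m) {
  cl <- seq_len(oracle$n)
  for (i in seq_len(m)) {
    s <- oracle$merges[[i]]
    cl[cl %in% cl[s]] <- min(cl[s])
  }
  match(cl, unique(cl))
}

# Leaf sets of every internal node of an hclust merge table.
hclustLeafSets <- function(hc) {
  sets <- vector("list", nrow(hc$merge))
  for (k in seq_len(nrow(hc$merge))) {
    grab <- function(v) if (v < 0) -v else sets[[v]]
    sets[[k]] <- sort(c(grab(hc$merge[k, 1]), grab(hc$merge[k, 2])))
  }
  sets
}

# Brute-force connected components keeping links with height <= h.
naiveCutComponents <- function(hc, h) {
  n <- nrow(hc$merge) + 1L
  sets <- hclustLeafSets(hc)
  cl <- seq_len(n)
  for (k in which(hc$height <= h)) {
    s <- sets[[k]]
    cl[cl %in% cl[s]] <- min(cl[s])
  }
  match(cl, unique(cl))
}

samePartition <- function(a, b) {
  length(unique(a)) == length(unique(b)) &&
    length(unique(paste(a, b))) == length(unique(a))
}

# Adjusted Rand index straight from the contingency-table formula.
ariFormula <- function(a, b) {
  tab <- table(a, b)
  ch2 <- function(v) sum(v * (v - 1) / 2)
  sumIJ <- ch2(as.vector(tab))
  sumA <- ch2(rowSums(tab))
  sumB <- ch2(colSums(tab))
  nC2 <- ch2(sum(tab))
  expected <- sumA * sumB / nC2
  (sumIJ - expected) / ((sumA + sumB) / 2 - expected)
}
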