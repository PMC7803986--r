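# Dendrogram construction, cuts at the greatest link heights, and the
# nested label hierarchies driving the curriculum.
#
# The dendrogram container is the base R `stats::hclust` object (merge /
# height / labels), the field-standard linkage representation. A partition
# is a plain list: assignment (named integer, class id -> cluster id,
# cluster ids contiguous from 1 in order of first appearance), nClusters,
# cutHeight.

linkageMethods <- c(single = "single", complete = "complete",
                    average = "average", ward = "ward.D2")

#' Agglomerative clustering of class prototypes
#'
#' Builds the binary merge tree (dendrogram) over the observation rows
#' bottom-up under the chosen linkage and metric. Leaf labels are the
#' class ids. Default linkage is Ward (on Euclidean distances), which
#' yields stable, balanced groups for curriculum use; single, complete and
#' average linkage are available. Merges between tied dissimilarities are
#' resolved lowest-index-pair first, so results are deterministic.
#'
#' @param obs an [ObservationMatrix-class] with at least 2 rows.
#' @param linkage one of `"ward"`, `"single"`, `"complete"`, `"average"`.
#' @param metric distance metric passed to [stats::dist()]. Default
#'   `"euclidean"`.
#' @return A [stats::hclust] object with `n - 1` merges; `$labels` holds
#'   the class ids.
#' @export
buildDendrogram <- function(obs, linkage = "ward", metric = "euclidean") {
  x <- obs@values
  if (nrow(x) < 2L) stop("clustering needs at least 2 observations")
  linkage <- match.arg(linkage, names(linkageMethods))
  d <- stats::dist(x, method = metric)
  hc <- stats::hclust(d, method = linkageMethods[[linkage]])
  hc$labels <- as.character(obs@classOrder)
  hc
}

#' Number of dendrogram leaves
#'
#' @param dendrogram a [stats::hclust] object.
#' @return integer leaf count (`n merges + 1`).
#' @export
nLeaves <- function(dendrogram) nrow(dendrogram$merge) + 1L

# Partition the leaves into connected components of the merges selected by
# `keep` (logical over merge rows). Cluster ids are renumbered contiguously
# from 1 in order of the first member's appearance in leaf order.
componentsOfLinks <- function(dendrogram, keep) {
  n <- nLeaves(dendrogram)
  comp <- seq_len(n)                     # leaf -> component representative
  members <- as.list(seq_len(n))         # representative -> leaves
  nodeRep <- integer(nrow(dendrogram$merge)) # merge row -> representative
  for (k in seq_len(nrow(dendrogram$merge))) {
    ab <- dendrogram$merge[k, ]
    repOf <- function(v) if (v < 0) comp[-v] else nodeRep[v]
    ra <- repOf(ab[1]); rb <- repOf(ab[2])
    if (keep[k] && ra != rb) {
      members[[ra]] <- c(members[[ra]], members[[rb]])
      comp[members[[rb]]] <- ra
      members[rb] <- list(NULL)
      nodeRep[k] <- ra
    } else {
      # unmerged: the node is represented by its left child's component
      nodeRep[k] <- ra
    }
  }
  reps <- unique(comp[order(seq_len(n))])
  cl <- match(comp, reps)
  names(cl) <- dendrogram$labels
  cl
}

makePartition <- function(assignment, cutHeight) {
  list(assignment = assignment,
       nClusters = length(unique(assignment)),
       cutHeight = cutHeight)
}

#' Cut a dendrogram at a height
#'
#' Clusters are the connected groups formed by all links of height `<= h`;
#' consequently `nClusters = 1 + #(links with height > h)`.
#'
#' @param dendrogram a [stats::hclust] object.
#' @param h cut height (>= 0).
#' @return A partition: `list(assignment, nClusters, cutHeight)` with
#'   `assignment` a named integer vector (class id -> cluster id,
#'   contiguous from 1).
#' @export
cutAtHeight <- function(dendrogram, h) {
  if (h < 0) stop("cut height must be non-negative")
  makePartition(componentsOfLinks(dendrogram, dendrogram$height <= h), h)
}

#' Cuts below the k greatest link heights
#'
#' For each of the `k` greatest distinct link heights `h(1) > ... > h(k)`
#' the tree is cut infinitesimally below `h(i)`: links of height `>= h(i)`
#' are severed, ties at a height are severed together. Partitions are
#' returned coarse-to-fine; duplicates (possible with tied heights) are
#' collapsed.
#'
#' @param dendrogram a [stats::hclust] object.
#' @param k number of cuts, `1 <= k <= nLeaves - 1`.
#' @param tol relative tolerance grouping equal heights. Default 1e-8.
#' @return list of partitions (see [cutAtHeight()]) in coarse-to-fine
#'   order.
#' @export
cutsByGreatestLinks <- function(dendrogram, k, tol = 1e-8) {
  n <- nLeaves(dendrogram)
  if (k < 1L || k > n - 1L)
    stop(sprintf("k must lie in 1..%d", n - 1L))
  hts <- sort(dendrogram$height, decreasing = TRUE)
  scale <- max(abs(hts), 1)
  uh <- hts[c(TRUE, diff(hts) < -tol * scale)]   # distinct, descending
  k <- min(k, length(uh))
  parts <- lapply(uh[seq_len(k)], function(h)
    makePartition(
      componentsOfLinks(dendrogram, dendrogram$height < h - tol * scale),
      h))
  # collapse duplicates while preserving coarse-to-fine order
  keyOf <- function(p) paste(p$assignment, collapse = ",")
  parts[!duplicated(vapply(parts, keyOf, character(1)))]
}

#' Cuts targeting explicit cluster counts
#'
#' For each requested count the dendrogram is cut at the greatest height
#' whose partition reaches at least that many clusters (with tied link
#' heights a cut can overshoot the requested count, as in the published
#' 16/17-group fourth cuts). Counts must be increasing; duplicates
#' collapse.
#'
#' @param dendrogram a [stats::hclust] object.
#' @param counts increasing integer vector of target food-cluster counts.
#' @param tol relative tie tolerance. Default 1e-8.
#' @return list of partitions, coarse-to-fine.
#' @export
cutsByClusterCounts <- function(dendrogram, counts, tol = 1e-8) {
  counts <- as.integer(counts)
  if (any(diff(counts) <= 0)) stop("counts must be strictly increasing")
  all <- cutsByGreatestLinks(dendrogram, nLeaves(dendrogram) - 1L, tol)
  sizes <- vapply(all, function(p) p$nClusters, integer(1))
  parts <- lapply(counts, function(k) {
    i <- which(sizes >= k)[1]
    if (is.na(i))
      stop(sprintf("no cut yields %d clusters (max %d)", k, max(sizes)))
    all[[i]]
  })
  keyOf <- function(p) paste(p$assignment, collapse = ",")
  parts[!duplicated(vapply(parts, keyOf, character(1)))]
}

#' Assemble the nested label hierarchy
#'
#' Turns an ordered coarse-to-fine list of partitions into training
#' stages. Stage labels are the partition's cluster ids (1-based, dense);
#' background is appended as label 0 at every stage, so stage `C` equals
#' the partition's cluster count plus one. A final identity stage over the
#' original labels is always appended (its `C` is `n_classes + 1`). Input
#' partitions must be nested — guaranteed when they come from one
#' dendrogram, verified here to guard foreign input.
#'
#' @param partitions list of partitions ordered by increasing
#'   `nClusters`, all over the same class universe.
#' @param originalLabels integer vector of all original class ids
#'   (contiguous `1..n` for trainable hierarchies).
#' @return A [LabelHierarchy-class].
#' @export
buildLabelHierarchy <- function(partitions, originalLabels) {
  originalLabels <- sort(as.integer(originalLabels))
  if (!identical(originalLabels, seq_along(originalLabels)))
    stop("original class labels must be contiguous 1..n ",
         "(dense labels are required for a C-way head)")
  stages <- list()
  for (p in partitions) {
    a <- p$assignment[as.character(originalLabels)]
    if (anyNA(a))
      stop("partitions do not cover all original labels")
    remap <- as.integer(a)
    names(remap) <- as.character(originalLabels)
    stages[[length(stages) + 1L]] <-
      list(C = length(unique(remap)) + 1L, remap = remap)
  }
  idr <- originalLabels
  names(idr) <- as.character(originalLabels)
  stages[[length(stages) + 1L]] <-
    list(C = length(originalLabels) + 1L, remap = idr)
  # drop leading stages made redundant by equal C (all-singleton partition)
  cs <- vapply(stages, function(s) s$C, integer(1))
  stages <- stages[!duplicated(cs)]
  new("LabelHierarchy", stages = stages, backgroundLabel = 0L)
}

#' Relabel a mask through one hierarchy stage
#'
#' Element-wise lookup of every non-zero label in the stage's remap table;
#' background zeros are preserved. Unknown labels are an error naming the
#' offending value.
#'
#' @param mask integer label matrix.
#' @param stage one element of `hierarchyStages(h)` —
#'   `list(C, remap)`.
#' @return integer matrix of stage labels.
#' @export
remapMask <- function(mask, stage) {
  vals <- unique(as.vector(mask))
  unknown <- setdiff(vals, c(0L, as.integer(names(stage$remap))))
  if (length(unknown))
    stop("mask holds labels absent from the stage remap: ",
         paste(unknown, collapse = ", "))
  out <- mask
  nz <- mask != 0L
  out[nz] <- stage$remap[as.character(mask[nz])]
  storage.mode(out) <- "integer"
  out
}
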