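#' Create a synthetic tray generator configuration
#'
#' Defaults describe the fixture used throughout the package's tests: 3
#' families of 3 classes whose between-family color radius is ten times
#' the within-family spread, so the designed hierarchy is recoverable
#' from visual features alone.
#'
#' @param nFamilies families of visually correlated classes. Default 3.
#' @param classesPerFamily classes per family. Default 3.
#' @param imageSize tray raster size `(H, W)`. Default `c(96, 96)`.
#' @param blobsPerTray food blobs per tray. Default 3.
#' @param familyColorSpread between-family color radius in RGB units.
#'   Default 0.30.
#' @param classColorSpread within-family color standard deviation.
#'   Default 0.03.
#' @param textureScales texture wavelengths in pixels. Default
#'   `c(8, 16)`.
#' @param pixelNoise amplitude of per-blob texture and per-pixel noise
#'   (0 disables both, making all blobs of a class identical in fill).
#'   Default 0.02.
#' @param seed integer seed fixing the class color palette.
#' @return A [SyntheticConfig-class].
#' @export
syntheticConfig <- function(nFamilies = 3L, classesPerFamily = 3L,
                            imageSize = c(96L, 96L), blobsPerTray = 3L,
                            familyColorSpread = 0.30,
                            classColorSpread = 0.03,
                            textureScales = c(8, 16), pixelNoise = 0.02,
                            seed = 1L) {
  new("SyntheticConfig", nFamilies = as.integer(nFamilies),
      classesPerFamily = as.integer(classesPerFamily),
      imageSize = as.integer(imageSize),
      blobsPerTray = as.integer(blobsPerTray),
      familyColorSpread = familyColorSpread,
      classColorSpread = classColorSpread,
      textureScales = as.numeric(textureScales), pixelNoise = pixelNoise,
      seed = as.integer(seed))
}

#' Designed family membership of the synthetic classes
#'
#' Ground truth for hierarchy-recovery tests: class ids `1..n` are grouped
#' into contiguous families of `classesPerFamily`.
#'
#' @param cfg a [SyntheticConfig-class].
#' @return list with `familyOf`, a named integer vector (class id ->
#'   family id).
#' @export
designedHierarchy <- function(cfg) {
  n <- cfg@nFamilies * cfg@classesPerFamily
  fam <- rep(seq_len(cfg@nFamilies), each = cfg@classesPerFamily)
  names(fam) <- as.character(seq_len(n))
  structure(list(familyOf = fam), class = "DesignedHierarchy")
}

# Deterministic class palette: family base colors sit on a circle of
# radius familyColorSpread in the isoluminant plane around mid gray;
# class offsets are Gaussian with sd classColorSpread.
classPalette <- function(cfg) {
  nF <- cfg@nFamilies
  nC <- cfg@classesPerFamily
  u <- c(1, -1, 0) / sqrt(2)
  v <- c(1, 1, -2) / sqrt(6)
  withSeed(deriveSeed(cfg@seed, "palette"), {
    pal <- matrix(0, nrow = nF * nC, ncol = 3)
    for (f in seq_len(nF)) {
      th <- 2 * pi * (f - 1) / nF
      base <- 0.5 + cfg@familyColorSpread * (cos(th) * u + sin(th) * v)
      for (k in seq_len(nC)) {
        cls <- (f - 1L) * nC + k
        pal[cls, ] <- base + stats::rnorm(3, sd = cfg@classColorSpread)
      }
    }
    pmin(pmax(pal, 0.02), 0.98)
  })
}

trayGray <- 0.45
plateWhite <- 0.92

#' Generate one synthetic tray
#'
#' Draws a gray tray holding `blobsPerTray` elliptical food-like blobs,
#' each on a white plate disc. A blob's fill is its class color plus
#' band-limited texture (wavelengths `textureScales`, amplitude
#' `pixelNoise`) plus white pixel noise of the same amplitude. Blobs are
#' placed on a jittered grid so they never overlap; the tray errors if the
#' grid cells are too small to hold a blob. The mask labels exactly the
#' blob support; boxes are tight around each blob.
#'
#' @param cfg a [SyntheticConfig-class].
#' @param traySeed integer; together with `cfg@seed` determines the tray
#'   bit-exactly.
#' @param classIds optional integer vector of length `blobsPerTray`
#'   choosing each blob's class (defaults to a seeded draw).
#' @return A [TrayRecord-class].
#' @export
generateTray <- function(cfg, traySeed = 1L, classIds = NULL) {
  H <- cfg@imageSize[1]; W <- cfg@imageSize[2]
  nB <- cfg@blobsPerTray
  nClasses <- cfg@nFamilies * cfg@classesPerFamily
  pal <- classPalette(cfg)
  withSeed(deriveSeed(cfg@seed, paste0("tray", traySeed)), {
    if (is.null(classIds)) classIds <- sample.int(nClasses, nB, replace = TRUE)
    if (length(classIds) != nB)
      stop("classIds must supply one class per blob")
    img <- array(trayGray, dim = c(H, W, 3))
    mask <- matrix(0L, H, W)
    boxes <- NULL
    if (nB > 0L) {
      gr <- ceiling(sqrt(nB))
      gc <- ceiling(nB / gr)
      ch <- H %/% gr; cw <- W %/% gc
      if (min(ch, cw) < 16L)
        stop(sprintf(
          "cannot pack %d blobs into a %dx%d tray (grid cells %dx%d < 16px)",
          nB, H, W, ch, cw))
      ys <- matrix(rep(seq_len(H), W), H, W)
      xs <- matrix(rep(seq_len(W), each = H), H, W)
      cells <- sample.int(gr * gc, nB)
      for (b in seq_len(nB)) {
        cell <- cells[b]
        ci <- (cell - 1L) %/% gc; cj <- (cell - 1L) %% gc
        cy <- ci * ch + ch / 2 + stats::runif(1, -0.08, 0.08) * ch
        cx <- cj * cw + cw / 2 + stats::runif(1, -0.08, 0.08) * cw
        a <- stats::runif(1, 0.24, 0.34) * cw   # semi-axes
        bb <- stats::runif(1, 0.24, 0.34) * ch
        d2 <- ((xs - cx) / a)^2 + ((ys - cy) / bb)^2
        plate <- ((xs - cx)^2 + (ys - cy)^2) <= (1.35 * max(a, bb))^2
        blob <- d2 <= 1
        cls <- classIds[b]
        fill <- pal[cls, ]
        tex <- matrix(0, H, W)
        if (cfg@pixelNoise > 0 && length(cfg@textureScales)) {
          for (s in cfg@textureScales) {
            phi <- stats::runif(1, 0, pi)
            psi <- stats::runif(1, 0, 2 * pi)
            tex <- tex + sin(2 * pi * (xs * cos(phi) + ys * sin(phi)) / s + psi)
          }
          tex <- cfg@pixelNoise * tex / length(cfg@textureScales)
        }
        for (k in 1:3) {
          plane <- img[, , k]
          plane[plate] <- plateWhite
          val <- fill[k] + tex[blob]
          if (cfg@pixelNoise > 0)
            val <- val + stats::rnorm(sum(blob), sd = cfg@pixelNoise)
          plane[blob] <- clamp01(val)
          img[, , k] <- plane
        }
        mask[blob] <- cls
        rows <- range(which(rowSums(blob) > 0))
        colsr <- range(which(colSums(blob) > 0))
        boxes <- rbind(boxes, data.frame(
          classId = cls, x0 = colsr[1] - 1L, y0 = rows[1] - 1L,
          x1 = colsr[2], y1 = rows[2]))
      }
    }
    if (is.null(boxes))
      boxes <- data.frame(classId = integer(), x0 = integer(),
                          y0 = integer(), x1 = integer(), y1 = integer())
    TrayRecord(img, mask, boxes, sprintf("synth%04d", traySeed))
  })
}

#' Generate a synthetic dataset with its designed hierarchy
#'
#' Classes are dealt to the `nTrays * blobsPerTray` blob slots
#' round-robin (so frequencies are uniform up to one) in a seeded shuffled
#' order; every class is guaranteed at least one blob, and the call errors
#' if the slot count cannot cover all classes.
#'
#' @param cfg a [SyntheticConfig-class].
#' @param nTrays number of trays (>= 1).
#' @param seed dataset seed.
#' @return list with `trays` (list of [TrayRecord-class]) and `hierarchy`
#'   (a [designedHierarchy()]).
#' @export
generateDataset <- function(cfg, nTrays, seed = 1L) {
  if (nTrays < 1L) stop("nTrays must be at least 1")
  nClasses <- cfg@nFamilies * cfg@classesPerFamily
  slots <- nTrays * cfg@blobsPerTray
  if (slots < nClasses)
    stop(sprintf(
      "%d trays x %d blobs cannot cover %d classes", nTrays,
      cfg@blobsPerTray, nClasses))
  assign <- rep_len(seq_len(nClasses), slots)
  assign <- withSeed(deriveSeed(seed, "deal"), sample(assign))
  trays <- lapply(seq_len(nTrays), function(t)
    generateTray(cfg, traySeed = deriveSeed(seed, paste0("t", t)),
                 classIds = assign[seq.int((t - 1L) * cfg@blobsPerTray + 1L,
                                           t * cfg@blobsPerTray)]))
  list(trays = trays, hierarchy = designedHierarchy(cfg))
}

#' Agreement between designed and recovered partitions
#'
#' Adjusted Rand index between the designed family membership and a
#' recovered partition over the same classes; 1 means exact recovery, 0
#' chance-level agreement.
#'
#' @param designed a [designedHierarchy()].
#' @param partition a partition from [cutAtHeight()] /
#'   [cutsByGreatestLinks()].
#' @return adjusted Rand index in `[-1, 1]`.
#' @export
recoveryScore <- function(designed, partition) {
  ids <- names(designed$familyOf)
  if (!setequal(ids, names(partition$assignment)))
    stop("designed hierarchy and partition cover different classes")
  mclust::adjustedRandIndex(designed$familyOf[ids],
                            partition$assignment[ids])
}
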