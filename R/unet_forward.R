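# Forward and backward passes of the in-package U-Net.
#
# A sample is an H x W x C numeric array. Convolutions are stride-1,
# same-padded (pad top/left = floor((k-1)/2)), executed by the compiled
# im2col kernels; ReLU, nearest upsampling and channel concatenation are
# plain array operations. The backward pass mirrors the forward graph and
# returns exact gradients for every parameter tensor.

convPad <- function(k) as.integer((k - 1) %/% 2)

convLayer <- function(p, x) {
  .conv2dForward(x, p$W, p$b, p$kh, p$kw, convPad(p$kh), convPad(p$kw))
}

convLayerBwd <- function(p, x, dy) {
  .conv2dBackward(x, dy, p$W, p$kh, p$kw, convPad(p$kh), convPad(p$kw))
}

relu <- function(x) {
  x[x < 0] <- 0
  x
}

upsample2 <- function(x) {
  d <- dim(x)
  x[rep(seq_len(d[1]), each = 2L), rep(seq_len(d[2]), each = 2L), ,
    drop = FALSE]
}

upsample2Bwd <- function(dy) {
  h <- dim(dy)[1] %/% 2L
  w <- dim(dy)[2] %/% 2L
  o1 <- seq(1L, 2L * h, by = 2L); e1 <- o1 + 1L
  o2 <- seq(1L, 2L * w, by = 2L); e2 <- o2 + 1L
  dy[o1, o2, , drop = FALSE] + dy[e1, o2, , drop = FALSE] +
    dy[o1, e2, , drop = FALSE] + dy[e1, e2, , drop = FALSE]
}

concatChannels <- function(a, b) {
  array(c(a, b), dim = c(dim(a)[1:2], dim(a)[3] + dim(b)[3]))
}

softmaxChannels <- function(z) {
  d <- dim(z)
  m <- matrix(z, nrow = d[1] * d[2], ncol = d[3])
  m <- exp(m - apply(m, 1, max))
  array(m / rowSums(m), dim = d)
}

# Forward pass for one sample. Returns the per-pixel class probabilities,
# the bottleneck volume, and (when cache = TRUE) every intermediate needed
# by unetBackward.
unetForward <- function(model, x, cache = FALSE) {
  cfg <- model@config
  d <- dim(x)
  if (!identical(as.integer(d[1:2]), cfg@inputSize))
    stop(sprintf("input is %dx%d but the model expects %dx%d",
                 d[1], d[2], cfg@inputSize[1], cfg@inputSize[2]))
  p <- model@params
  cc <- list(convIn = list(), reluOut = list(), poolIdx = list(),
             poolDim = list())
  runConv <- function(name, x, act = TRUE) {
    if (cache) cc$convIn[[name]] <<- x
    y <- convLayer(p[[name]], x)
    if (act) {
      y <- relu(y)
      if (cache) cc$reluOut[[name]] <<- y
    }
    y
  }
  skips <- list()
  cur <- x
  for (i in seq_len(cfg@depth)) {
    cur <- runConv(sprintf("enc%d_conv1", i), cur)
    cur <- runConv(sprintf("enc%d_conv2", i), cur)
    skips[[i]] <- cur
    mp <- .maxpool2Forward(cur)
    if (cache) {
      cc$poolIdx[[i]] <- mp$idx
      cc$poolDim[[i]] <- dim(cur)[1:2]
    }
    cur <- mp$y
  }
  cur <- runConv("bott_conv1", cur)
  cur <- runConv("bott_conv2", cur)
  bottleneck <- cur
  for (i in rev(seq_len(cfg@depth))) {
    cur <- upsample2(cur)
    cur <- runConv(sprintf("dec%d_up", i), cur)
    cur <- concatChannels(cur, skips[[i]])
    cur <- runConv(sprintf("dec%d_conv1", i), cur)
    cur <- runConv(sprintf("dec%d_conv2", i), cur)
  }
  logits <- runConv("head", cur, act = FALSE)
  list(prob = softmaxChannels(logits), bottleneck = bottleneck,
       logits = logits, cache = if (cache) cc else NULL)
}

# Backward pass for one sample given d(loss)/d(logits). Returns a named
# list of list(dW, db) aligned with model@params.
unetBackward <- function(model, cc, dlogits) {
  cfg <- model@config
  p <- model@params
  grads <- list()
  backConv <- function(name, dy, act = TRUE) {
    if (act) dy <- dy * (cc$reluOut[[name]] > 0)
    g <- convLayerBwd(p[[name]], cc$convIn[[name]], dy)
    grads[[name]] <<- list(dW = g$dW, db = as.numeric(g$db))
    g$dx
  }
  cur <- backConv("head", dlogits, act = FALSE)
  dskips <- vector("list", cfg@depth)
  for (i in seq_len(cfg@depth)) {       # decoder fine -> coarse
    cur <- backConv(sprintf("dec%d_conv2", i), cur)
    cur <- backConv(sprintf("dec%d_conv1", i), cur)
    nUp <- p[[sprintf("dec%d_up", i)]]$cout
    dskips[[i]] <- cur[, , seq.int(nUp + 1L, dim(cur)[3]), drop = FALSE]
    cur <- cur[, , seq_len(nUp), drop = FALSE]
    cur <- backConv(sprintf("dec%d_up", i), cur)
    cur <- upsample2Bwd(cur)
  }
  cur <- backConv("bott_conv2", cur)
  cur <- backConv("bott_conv1", cur)
  for (i in rev(seq_len(cfg@depth))) {  # encoder deep -> shallow
    cur <- .maxpool2Backward(cur, cc$poolIdx[[i]],
                             cc$poolDim[[i]][1], cc$poolDim[[i]][2])
    cur <- cur + dskips[[i]]
    cur <- backConv(sprintf("enc%d_conv2", i), cur)
    cur <- backConv(sprintf("enc%d_conv1", i), cur)
  }
  grads
}

#' Per-pixel class probabilities for one patch
#'
#' Runs the network in inference mode and returns the softmax-normalized
#' `H x W x C` score volume (channels sum to 1 at every pixel).
#'
#' @param model a [SegmentationModel-class].
#' @param patch numeric `H x W x 3` array matching the model's input size.
#' @return numeric `H x W x C` probability array.
#' @export
predictProbabilities <- function(model, patch) {
  unetForward(model, patch)$prob
}

#' Extract the bottleneck feature volume
#'
#' Returns the deepest encoder activation — the output of the bottleneck
#' block — for one input patch: an `H/2^depth x W/2^depth x
#' bottleneckChannels` volume (8 x 8 x 1024 for the published model).
#' Inference is deterministic: the same patch always yields the same
#' volume.
#'
#' @param model a [SegmentationModel-class].
#' @param patch numeric `H x W x 3` array matching the model input size.
#' @return numeric 3-D array of bottleneck activations.
#' @export
extractBottleneck <- function(model, patch) {
  unetForward(model, patch)$bottleneck
}

#' Persist / restore a segmentation model
#'
#' The parameter store is serialized to a single binary file and the
#' configuration written alongside as a YAML sidecar (`<file>.yml`) for
#' inspection.
#'
#' @param model a [SegmentationModel-class].
#' @param file path of the weights file.
#' @return `saveModel` returns `file` invisibly; `loadModel` the restored
#'   model.
#' @export
saveModel <- function(model, file) {
  saveRDS(list(params = model@params,
               config = list(inputSize = model@config@inputSize,
                             baseFilters = model@config@baseFilters,
                             depth = model@config@depth,
                             headClasses = model@config@headClasses,
                             seed = model@config@seed)),
          file)
  yaml::write_yaml(list(inputSize = as.integer(model@config@inputSize),
                        baseFilters = model@config@baseFilters,
                        depth = model@config@depth,
                        bottleneckChannels = model@config@bottleneckChannels,
                        headClasses = model@config@headClasses,
                        seed = model@config@seed),
                   paste0(file, ".yml"))
  invisible(file)
}

#' @rdname saveModel
#' @export
loadModel <- function(file) {
  s <- readRDS(file)
  cfg <- networkConfig(s$config$inputSize, s$config$baseFilters,
                       s$config$depth, s$config$headClasses, s$config$seed)
  new("SegmentationModel", config = cfg, params = s$params,
      registry = unetRegistry(cfg))
}
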