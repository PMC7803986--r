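#' Create a network configuration
#'
#' @param inputSize `(height, width)` of training patches; must be
#'   divisible by `2^depth`. Default `c(256, 256)`.
#' @param baseFilters filters in the first encoder block. Default 32.
#' @param depth number of encoder blocks. Default 5 (the published
#'   configuration: 28 convolutional layers, 1024 bottleneck channels).
#' @param headClasses `C`, output channels of the classifier head.
#' @param seed initialization seed.
#' @return A [NetworkConfig-class].
#' @examples
#' networkConfig(c(64, 64), baseFilters = 8, depth = 3, headClasses = 4)
#' @export
networkConfig <- function(inputSize = c(256L, 256L), baseFilters = 32L,
                          depth = 5L, headClasses = 2L, seed = 1L) {
  new("NetworkConfig", inputSize = as.integer(inputSize),
      baseFilters = as.integer(baseFilters), depth = as.integer(depth),
      bottleneckChannels = as.integer(baseFilters * 2^depth),
      headClasses = as.integer(headClasses), seed = as.integer(seed))
}

#' Layer registry of a U-Net configuration
#'
#' Enumerates the network's layers without allocating parameters: two 3x3
#' convolutions then a 2x2 max-pool per encoder block, a two-convolution
#' bottleneck block (whose second activation is the bottleneck feature
#' tap), and per decoder block a nearest-neighbour upsample, a 2x2
#' "up-convolution" halving the channels, skip concatenation, and two 3x3
#' convolutions; a 1x1 `C`-way convolution head closes the network. Filter
#' counts double per encoder level and halve per decoder level, giving
#' `5 * depth + 3` convolutional layers (28 for the published depth-5
#' model).
#'
#' @param config a [NetworkConfig-class].
#' @return data.frame with columns `name`, `role` (`encoder`, `pool`,
#'   `bottleneck`, `upsample`, `upconv`, `decoder`, `head`), `kernel`,
#'   `inChannels`, `outChannels`, `convolutional`, `tap`.
#' @export
unetRegistry <- function(config) {
  f <- config@baseFilters * 2L^(seq_len(config@depth) - 1L)
  fb <- config@bottleneckChannels
  rows <- list()
  add <- function(name, role, k, cin, cout, tap = "") {
    rows[[length(rows) + 1L]] <<- data.frame(
      name = name, role = role, kernel = if (k > 0) sprintf("%dx%d", k, k) else "",
      inChannels = as.integer(cin), outChannels = as.integer(cout),
      convolutional = k > 0, tap = tap, stringsAsFactors = FALSE)
  }
  cin <- 3L
  for (i in seq_len(config@depth)) {
    add(sprintf("enc%d_conv1", i), "encoder", 3L, cin, f[i])
    add(sprintf("enc%d_conv2", i), "encoder", 3L, f[i], f[i])
    add(sprintf("pool%d", i), "pool", 0L, f[i], f[i])
    cin <- f[i]
  }
  add("bott_conv1", "bottleneck", 3L, f[config@depth], fb)
  add("bott_conv2", "bottleneck", 3L, fb, fb, tap = "bottleneck")
  above <- fb
  for (i in rev(seq_len(config@depth))) {
    add(sprintf("up%d", i), "upsample", 0L, above, above)
    add(sprintf("dec%d_up", i), "upconv", 2L, above, f[i])
    add(sprintf("dec%d_conv1", i), "decoder", 3L, 2L * f[i], f[i])
    add(sprintf("dec%d_conv2", i), "decoder", 3L, f[i], f[i])
    above <- f[i]
  }
  add("head", "head", 1L, f[1L], config@headClasses)
  do.call(rbind, rows)
}

#' Spatial shape of the bottleneck feature volume
#'
#' @param config a [NetworkConfig-class].
#' @return integer `(H', W', D)` with `H' = H / 2^depth` and `D` the
#'   bottleneck channel count (8 x 8 x 1024 for the published model).
#' @export
bottleneckShape <- function(config) {
  as.integer(c(config@inputSize %/% 2L^config@depth,
               config@bottleneckChannels))
}

kernelSize <- function(kernel) as.integer(sub("x.*", "", kernel))

# He-normal for hidden (ReLU) convolutions; the 1x1 classifier head gets a
# small-variance init so its initial logits are near zero (predictions near
# uniform) and a freshly swapped head cannot flood pretrained features with
# large gradients.
initConvParams <- function(k, cin, cout) {
  fanIn <- k * k * cin
  sd <- if (k == 1L) 0.01 else sqrt(2 / fanIn)
  list(W = matrix(stats::rnorm(fanIn * cout, sd = sd),
                  nrow = fanIn, ncol = cout),
       b = numeric(cout), kh = k, kw = k, cin = cin, cout = cout)
}

#' Build a seeded U-Net segmentation model
#'
#' Allocates all convolution weights with seeded He-normal initialization
#' (standard deviation `sqrt(2 / fan_in)`) drawn layer by layer in registry
#' order, so two builds from the same configuration are bit-identical. All
#' convolutions are same-padded, the output therefore keeps the input's
#' spatial size, and the per-pixel class scores are softmax-normalized.
#'
#' @param config a [NetworkConfig-class] whose input size is divisible by
#'   `2^depth` (anything else errors, naming the constraint).
#' @return A [SegmentationModel-class].
#' @examples
#' m <- buildUnet(networkConfig(c(32, 32), 4, 2, headClasses = 3))
#' @export
buildUnet <- function(config) {
  validObject(config)
  reg <- unetRegistry(config)
  params <- withSeed(config@seed, {
    p <- list()
    for (i in which(reg$convolutional))
      p[[reg$name[i]]] <- initConvParams(kernelSize(reg$kernel[i]),
                                         reg$inChannels[i],
                                         reg$outChannels[i])
    p
  })
  new("SegmentationModel", config = config, params = params, registry = reg)
}

#' Replace the classifier head
#'
#' Swaps the final 1x1 convolution for a freshly seeded `C`-way one. Every
#' parameter outside the head is carried over by reference and is
#' numerically identical before and after — the conservation the sequential
#' transfer rounds rely on.
#'
#' @param model a [SegmentationModel-class].
#' @param C new number of head classes (>= 2).
#' @param seed initialization seed for the new head.
#' @return The model with a new head and updated configuration.
#' @export
replaceHead <- function(model, C, seed = 1L) {
  C <- as.integer(C)
  if (C < 2L) stop("a classifier head needs at least 2 classes")
  cfg <- model@config
  cfg@headClasses <- C
  reg <- unetRegistry(cfg)
  params <- model@params
  params[["head"]] <- withSeed(deriveSeed(seed, "head"),
                               initConvParams(1L, cfg@baseFilters, C))
  new("SegmentationModel", config = cfg, params = params, registry = reg)
}
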