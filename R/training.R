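#' Training configuration
#'
#' Optimization settings shared by conventional and sequential training.
#' The optimizer is adaptive moment estimation (Adam) at its cited
#' defaults (learning rate 1e-3, beta1 0.9, beta2 0.999, epsilon 1e-8);
#' the published runs use batches of 20 patches of size 256 x 256.
#' `globalSeed` controls data order; model and head initialization seeds
#' are separate (see [networkConfig()], [replaceHead()]).
#'
#' @param batchSize patches per optimizer step. Default 20.
#' @param patchSize integer `(height, width)` patches are resized to
#'   before training. Default `c(256, 256)`.
#' @param learningRate,beta1,beta2,epsilon Adam hyper-parameters.
#' @param globalSeed integer seed for shuffling order.
#' @return A list of class `"TrainingConfig"`.
#' @export
trainingConfig <- function(batchSize = 20L, patchSize = c(256L, 256L),
                           learningRate = 1e-3, beta1 = 0.9, beta2 = 0.999,
                           epsilon = 1e-8, globalSeed = 1L) {
  if (batchSize < 1L) stop("batchSize must be at least 1")
  structure(list(batchSize = as.integer(batchSize),
                 patchSize = as.integer(patchSize),
                 learningRate = learningRate, beta1 = beta1, beta2 = beta2,
                 epsilon = epsilon, globalSeed = as.integer(globalSeed)),
            class = "TrainingConfig")
}

#' Stage specification for one training round
#'
#' @param C head classes of the stage (>= 2).
#' @param maxEpochs epoch budget (>= 1).
#' @param valAccuracyTarget validation accuracy at which the stage
#'   advances early. Default 0.90.
#' @param stage optional hierarchy stage `list(C, remap)` used to remap
#'   masks (`NULL` = labels already at stage granularity).
#' @param headSeed seed for head re-initialization.
#' @return A list of class `"StageSpec"`.
#' @export
stageSpec <- function(C, maxEpochs, valAccuracyTarget = 0.90,
                      stage = NULL, headSeed = 1L) {
  if (maxEpochs < 1L) stop("the epoch budget must be positive")
  if (C < 2L) stop("C must be at least 2")
  if (valAccuracyTarget < 0 || valAccuracyTarget > 1)
    stop("valAccuracyTarget must lie in [0, 1]")
  structure(list(C = as.integer(C), maxEpochs = as.integer(maxEpochs),
                 valAccuracyTarget = valAccuracyTarget, stage = stage,
                 headSeed = as.integer(headSeed)),
            class = "StageSpec")
}

oneHot <- function(mask, C) {
  hw <- length(mask)
  out <- numeric(hw * C)
  out[seq_len(hw) + as.vector(mask) * hw] <- 1
  array(out, dim = c(dim(mask), C))
}

#' Pixel-wise categorical cross-entropy
#'
#' Truth-weighted negative log predicted probability, reduced to the
#' per-pixel mean so values are comparable across patch sizes: a perfect
#' one-hot prediction scores 0, a uniform prediction over `c` channels
#' scores `log(c)` for any truth.
#'
#' @param prediction `H x W x C` per-pixel softmax probabilities.
#' @param truth either an `H x W` integer label matrix (labels `0..C-1`,
#'   channel `k` holding label `k - 1`) or an `H x W x C` one-hot array.
#' @return non-negative scalar loss.
#' @export
cceLoss <- function(prediction, truth) {
  d <- dim(prediction)
  if (is.matrix(truth)) {
    if (!identical(dim(truth), d[1:2]))
      stop("prediction and truth shapes disagree")
    if (any(truth < 0L | truth >= d[3]))
      stop("truth labels must lie in 0..C-1")
    idx <- cbind(as.vector(row(truth)), as.vector(col(truth)),
                 as.vector(truth) + 1L)
    pTrue <- prediction[idx]
  } else {
    if (!identical(dim(truth), d))
      stop("prediction and truth shapes disagree")
    pTrue <- apply(prediction * truth, c(1, 2), sum)
  }
  -mean(log(pmax(pTrue, 1e-12)))
}

#' Pixel-wise categorical accuracy
#'
#' Fraction of pixels whose highest-scoring channel matches the true
#' label.
#'
#' @param prediction `H x W x C` probability array (or an integer label
#'   matrix of predicted labels).
#' @param truth `H x W` integer label matrix, labels `0..C-1`.
#' @return proportion in `[0, 1]`.
#' @export
categoricalAccuracy <- function(prediction, truth) {
  pred <- if (is.matrix(prediction)) prediction else argmaxLabels(prediction)
  if (!identical(dim(pred), dim(truth)))
    stop("prediction and truth shapes disagree")
  mean(pred == truth)
}

# H x W x C probabilities -> integer label matrix (0-based labels)
argmaxLabels <- function(prob) {
  d <- dim(prob)
  m <- matrix(prob, nrow = d[1] * d[2], ncol = d[3])
  matrix(max.col(m, ties.method = "first") - 1L, nrow = d[1], ncol = d[2])
}

adamInit <- function(params) {
  lapply(params, function(p)
    list(mW = p$W * 0, vW = p$W * 0,
         mb = p$b * 0, vb = p$b * 0))
}

adamStep <- function(params, grads, state, cfg, t) {
  b1 <- cfg$beta1; b2 <- cfg$beta2
  c1 <- 1 - b1^t; c2 <- 1 - b2^t
  for (nm in names(grads)) {
    g <- grads[[nm]]; s <- state[[nm]]; p <- params[[nm]]
    s$mW <- b1 * s$mW + (1 - b1) * g$dW
    s$vW <- b2 * s$vW + (1 - b2) * g$dW^2
    s$mb <- b1 * s$mb + (1 - b1) * g$db
    s$vb <- b2 * s$vb + (1 - b2) * g$db^2
    p$W <- p$W - cfg$learningRate * (s$mW / c1) / (sqrt(s$vW / c2) + cfg$epsilon)
    p$b <- p$b - cfg$learningRate * (s$mb / c1) / (sqrt(s$vb / c2) + cfg$epsilon)
    state[[nm]] <- s
    params[[nm]] <- p
  }
  list(params = params, state = state)
}

stageData <- function(pairs, stage) {
  lapply(pairs, function(pr) {
    m <- patchMask(pr)
    if (!is.null(stage)) m <- remapMask(m, stage)
    list(x = patchImage(pr), y = m)
  })
}

evaluatePairs <- function(model, data) {
  loss <- acc <- 0
  for (s in data) {
    prob <- unetForward(model, s$x)$prob
    loss <- loss + cceLoss(prob, s$y)
    acc <- acc + categoricalAccuracy(prob, s$y)
  }
  c(loss = loss / length(data), accuracy = acc / length(data))
}

#' Run one training stage
#'
#' Trains the model on patch-mask pairs with the categorical
#' cross-entropy loss and Adam, evaluating the validation set at the end
#' of each epoch. The stage stops early once validation accuracy reaches
#' the target, otherwise when the epoch budget is exhausted. If the
#' model's head does not match `spec$C` it is replaced first (seeded from
#' `spec$headSeed`); masks are remapped through `spec$stage` when given.
#'
#' @param model a [SegmentationModel-class].
#' @param spec a [stageSpec()].
#' @param train,val lists of [PatchMaskPair-class].
#' @param cfg a [trainingConfig()].
#' @param stageIndex integer tag used to derive the per-epoch shuffle
#'   stream. Default 1.
#' @param verbose print per-epoch metrics. Default `FALSE`.
#' @return list with `model`, `history` (data.frame: epoch, trainLoss,
#'   trainAccuracy, valLoss, valAccuracy), `epochsRun`, `stopReason`
#'   (`"target_reached"` or `"budget_exhausted"`).
#' @export
runStage <- function(model, spec, train, val, cfg, stageIndex = 1L,
                     verbose = FALSE) {
  if (!length(train)) stop("training data is empty")
  if (model@config@headClasses != spec$C)
    model <- replaceHead(model, spec$C, spec$headSeed)
  trainD <- stageData(train, spec$stage)
  valD <- stageData(val, spec$stage)
  npix <- prod(model@config@inputSize)
  state <- adamInit(model@params)
  t <- 0L
  hist <- list()
  epochsRun <- 0L
  stopReason <- "budget_exhausted"
  for (epoch in seq_len(spec$maxEpochs)) {
    ord <- withSeed(deriveSeed(cfg$globalSeed,
                               sprintf("order.s%d.e%d", stageIndex, epoch)),
                    sample.int(length(trainD)))
    batches <- split(ord, ceiling(seq_along(ord) / cfg$batchSize))
    eLoss <- eAcc <- 0
    for (batch in batches) {
      grads <- NULL
      bLoss <- bAcc <- 0
      for (i in batch) {
        s <- trainD[[i]]
        fw <- unetForward(model, s$x, cache = TRUE)
        bLoss <- bLoss + cceLoss(fw$prob, s$y)
        bAcc <- bAcc + categoricalAccuracy(fw$prob, s$y)
        dlogits <- (fw$prob - oneHot(s$y, spec$C)) / (npix * length(batch))
        g <- unetBackward(model, fw$cache, dlogits)
        grads <- if (is.null(grads)) g else
          mapply(function(a, b) list(dW = a$dW + b$dW, db = a$db + b$db),
                 grads, g, SIMPLIFY = FALSE)
      }
      t <- t + 1L
      up <- adamStep(model@params, grads, state, cfg, t)
      model@params <- up$params
      state <- up$state
      eLoss <- eLoss + bLoss
      eAcc <- eAcc + bAcc
    }
    ev <- if (length(valD)) evaluatePairs(model, valD)
          else c(loss = NA_real_, accuracy = NA_real_)
    hist[[epoch]] <- data.frame(
      epoch = epoch, trainLoss = eLoss / length(trainD),
      trainAccuracy = eAcc / length(trainD),
      valLoss = ev[["loss"]], valAccuracy = ev[["accuracy"]])
    epochsRun <- epoch
    if (verbose)
      message(sprintf(
        "stage %d epoch %d: loss %.4f acc %.4f | val loss %.4f acc %.4f",
        stageIndex, epoch, eLoss / length(trainD), eAcc / length(trainD),
        ev[["loss"]], ev[["accuracy"]]))
    if (!is.na(ev[["accuracy"]]) &&
        ev[["accuracy"]] >= spec$valAccuracyTarget) {
      stopReason <- "target_reached"
      break
    }
  }
  list(model = model, history = do.call(rbind, hist),
       epochsRun = epochsRun, stopReason = stopReason)
}

#' Sequential transfer training over a label hierarchy
#'
#' Runs one training round per hierarchy stage, coarse to fine. Between
#' stages the classifier head is replaced by a freshly seeded `C`-way 1x1
#' convolution while every other weight is carried over unchanged; masks
#' are remapped through the stage's label table. The published schedule
#' cuts the 66-label problem into stages C = 3, 4, 5, 17, 66 with budgets
#' 10, 10, 10, 10, 20 (60 epochs in total).
#'
#' @param config a [NetworkConfig-class] (its `headClasses` is overridden
#'   stage by stage).
#' @param hierarchy a [LabelHierarchy-class].
#' @param splits a [DatasetSplits-class].
#' @param cfg a [trainingConfig()].
#' @param stageBudgets integer epoch budgets, one per stage.
#' @param valAccuracyTarget early-advance validation accuracy. Default
#'   0.90.
#' @param verbose print per-epoch metrics. Default `FALSE`.
#' @return list with `model` (final), `stages` (list of [runStage()]
#'   results), `history` (concatenated data.frame with a `stage` column).
#' @export
runStl <- function(config, hierarchy, splits, cfg, stageBudgets,
                   valAccuracyTarget = 0.90, verbose = FALSE) {
  stages <- hierarchyStages(hierarchy)
  if (length(stageBudgets) != length(stages))
    stop(sprintf("%d stage budgets supplied for %d stages",
                 length(stageBudgets), length(stages)))
  results <- list()
  model <- NULL
  for (s in seq_along(stages)) {
    st <- stages[[s]]
    spec <- stageSpec(st$C, stageBudgets[s], valAccuracyTarget, stage = st,
                      headSeed = deriveSeed(config@seed, paste0("head", s)))
    if (is.null(model)) {
      cfgS <- config
      cfgS@headClasses <- st$C
      model <- buildUnet(cfgS)
    }
    res <- runStage(model, spec, trainPairs(splits), validationPairs(splits),
                    cfg, stageIndex = s, verbose = verbose)
    model <- res$model
    results[[s]] <- res
  }
  hist <- do.call(rbind, lapply(seq_along(results), function(s)
    cbind(stage = s, results[[s]]$history)))
  list(model = model, stages = results, history = hist)
}

#' Conventional single-stage training
#'
#' Trains on the full label set from scratch — the baseline the
#' sequential curriculum is compared against (50 epochs at full scale).
#'
#' @param config a [NetworkConfig-class]; `headClasses` must equal the
#'   full label count plus background.
#' @param splits a [DatasetSplits-class] whose masks already carry final
#'   labels.
#' @param cfg a [trainingConfig()].
#' @param epochs epoch budget (>= 1).
#' @param valAccuracyTarget early-stop validation accuracy. Default 1.0
#'   (never binding) so the baseline consumes its whole budget.
#' @param verbose print per-epoch metrics. Default `FALSE`.
#' @return list with `model` and `result` (a [runStage()] result).
#' @export
runConventional <- function(config, splits, cfg, epochs,
                            valAccuracyTarget = 1.0, verbose = FALSE) {
  model <- buildUnet(config)
  spec <- stageSpec(config@headClasses, epochs, valAccuracyTarget)
  res <- runStage(model, spec, trainPairs(splits), validationPairs(splits),
                  cfg, stageIndex = 1L, verbose = verbose)
  list(model = res$model, result = res)
}
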