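test_that("cross-entropy obeys its closed forms", {
  truth <- matrix(c(0L, 1L, 1L, 0L), 2, 2)
  perfect <- stlseg:::oneHot(truth, 2L)
  expect_equal(cceLoss(perfect, truth), 0)
  for (c in c(2L, 5L, 10L)) {
    unif <- array(1 / c, dim = c(3, 3, c))
    anyTruth <- matrix(sample(0:(c - 1L), 9, TRUE), 3, 3)
    expect_lt(abs(cceLoss(unif, anyTruth) - log(c)), 1e-9)
  }
  onePix <- array(c(0.8, 0.2), dim = c(1, 1, 2))
  expect_equal(cceLoss(onePix, matrix(0L, 1, 1)), -log(0.8))
  expect_equal(cceLoss(onePix, matrix(1L, 1, 1)), -log(0.2))
  expect_error(cceLoss(onePix, matrix(0L, 2, 2)), "disagree")
  # one-hot truth arrays are accepted too
  expect_equal(cceLoss(onePix, array(c(1, 0), dim = c(1, 1, 2))), -log(0.8))
})

test_that("categorical accuracy counts argmax agreement", {
  truth <- matrix(c(0L, 1L, 1L, 0L), 2, 2)
  perfect <- stlseg:::oneHot(truth, 2L)
  expect_equal(categoricalAccuracy(perfect, truth), 1)
  expect_equal(categoricalAccuracy(perfect, 1L - truth), 0)
  threeOfFour <- perfect
  threeOfFour[1, 1, ] <- c(0.1, 0.9)    # truth 0 there -> wrong
  expect_equal(categoricalAccuracy(threeOfFour, truth), 0.75)
})

test_that("stage guards reject degenerate budgets and empty data", {
  expect_error(stageSpec(C = 3L, maxEpochs = 0L), "positive")
  expect_error(stageSpec(C = 1L, maxEpochs = 1L), "at least 2")
  m <- buildUnet(tinyNetConfig())
  expect_error(runStage(m, stageSpec(3L, 1L), list(), list(),
                        trainingConfig(batchSize = 2L)), "empty")
})

test_that("a zero validation target advances after the first epoch", {
  task <- blobTask(nTrain = 4L, nVal = 2L)
  m <- buildUnet(tinyNetConfig(C = 2L))
  res <- runStage(m, stageSpec(2L, maxEpochs = 5L, valAccuracyTarget = 0),
                  task$train, task$val, trainingConfig(batchSize = 2L))
  expect_identical(res$epochsRun, 1L)
  expect_identical(res$stopReason, "target_reached")
  expect_identical(nrow(res$history), 1L)
})

test_that("a tiny model learns the separable blob task to 90% validation accuracy", {
  task <- blobTask(nTrain = 16L, nVal = 4L, seed = 3L)
  m <- buildUnet(networkConfig(c(16L, 16L), 4L, 2L, headClasses = 2L,
                               seed = 1L))
  res <- runStage(m, stageSpec(2L, maxEpochs = 10L, valAccuracyTarget = 0.9),
                  task$train, task$val,
                  trainingConfig(batchSize = 2L, learningRate = 5e-3,
                                 globalSeed = 1L))
  expect_identical(res$stopReason, "target_reached")
  expect_gte(res$history$valAccuracy[res$epochsRun], 0.9)
  expect_lte(res$epochsRun, 10L)
  # bookkeeping: history length equals epochs run
  expect_identical(nrow(res$history), res$epochsRun)
})

test_that("training is deterministic for a fixed seed", {
  task <- blobTask(nTrain = 6L, nVal = 2L)
  cfg <- networkConfig(c(16L, 16L), 2L, 2L, headClasses = 2L, seed = 4L)
  splits <- new("DatasetSplits", train = task$train, validation = task$val,
                test = list(), splitSeed = 1L)
  r1 <- runConventional(cfg, splits, trainingConfig(batchSize = 3L,
                                                    globalSeed = 7L),
                        epochs = 2L)
  r2 <- runConventional(cfg, splits, trainingConfig(batchSize = 3L,
                                                    globalSeed = 7L),
                        epochs = 2L)
  expect_identical(r1$result$history, r2$result$history)
  expect_identical(r1$model@params, r2$model@params)
})

test_that("a single identity stage reduces STL to conventional training", {
  task <- blobTask(nTrain = 6L, nVal = 2L)
  splits <- new("DatasetSplits", train = task$train, validation = task$val,
                test = list(), splitSeed = 1L)
  idStage <- list(C = 2L, remap = c("1" = 1L))
  hier <- new("LabelHierarchy", stages = list(idStage),
              backgroundLabel = 0L)
  cfg <- networkConfig(c(16L, 16L), 2L, 2L, headClasses = 2L, seed = 4L)
  tc <- trainingConfig(batchSize = 3L, globalSeed = 7L)
  stl <- runStl(cfg, hier, splits, tc, stageBudgets = 2L,
                valAccuracyTarget = 1.0)
  conv <- runConventional(cfg, splits, tc, epochs = 2L)
  expect_equal(stl$stages[[1]]$history[, -1],
               conv$result$history[, -1], tolerance = 1e-12)
  expect_error(runStl(cfg, hier, splits, tc, stageBudgets = c(1L, 1L)),
               "budgets")
})

test_that("STL stages hand weights over exactly and replay deterministically", {
  set.seed(5)
  # two-stage toy hierarchy over 2 classes: {both} then {each}
  mkPair <- function(cls, i) {
    patch <- array(runif(16 * 16 * 3, 0, 0.2), dim = c(16, 16, 3))
    mask <- matrix(0L, 16, 16)
    mask[4:12, 4:12] <- cls
    patch[, , cls][mask == cls] <- 0.9
    PatchMaskPair(patch, mask, cls, sprintf("c%d_%d|identity", cls, i))
  }
  train <- c(lapply(1:4, mkPair, cls = 1L), lapply(1:4, mkPair, cls = 2L))
  val <- list(mkPair(1L, 9L), mkPair(2L, 9L))
  splits <- new("DatasetSplits", train = train, validation = val,
                test = list(), splitSeed = 1L)
  hier <- new("LabelHierarchy", stages = list(
    list(C = 2L, remap = c("1" = 1L, "2" = 1L)),
    list(C = 3L, remap = c("1" = 1L, "2" = 2L))), backgroundLabel = 0L)
  cfg <- networkConfig(c(16L, 16L), 2L, 2L, headClasses = 2L, seed = 2L)
  tc <- trainingConfig(batchSize = 4L, globalSeed = 3L)
  stl <- runStl(cfg, hier, splits, tc, stageBudgets = c(1L, 1L),
                valAccuracyTarget = 1.0)
  expect_length(stl$stages, 2L)
  # replay stage 2 by hand from the stage-1 model: identical outcome
  spec2 <- stageSpec(3L, 1L, 1.0, stage = hierarchyStages(hier)[[2]],
                     headSeed = stlseg:::deriveSeed(cfg@seed, "head2"))
  manual <- runStage(stl$stages[[1]]$model, spec2, train, val, tc,
                     stageIndex = 2L)
  expect_identical(manual$model@params, stl$model@params)
  expect_equal(manual$history, stl$stages[[2]]$history)
  # the hand-off conserved every non-head parameter before training:
  m1 <- stl$stages[[1]]$model
  swapped <- replaceHead(m1, 3L, spec2$headSeed)
  expect_identical(sumAbsParamDiff(m1@params, swapped@params,
                                   nonHeadLayers(m1)), 0)
})
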