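# End-to-end pipeline driver. State passes between stages through files
# under config$outputDir so every stage is independently runnable and
# testable; each stage records its configuration and seeds in a
# run-manifest YAML next to its outputs.

#' Default pipeline configuration
#'
#' A complete, desk-scale configuration for the synthetic end-to-end
#' pipeline; override any entry via [runPipeline()]'s `config` argument or
#' a YAML file with the same structure.
#'
#' @param outputDir root directory for all pipeline artifacts.
#' @return nested configuration list.
#' @export
defaultRunConfig <- function(outputDir = "stlseg-run") {
  list(
    outputDir = outputDir,
    synthetic = list(nFamilies = 3L, classesPerFamily = 3L,
                     imageSize = c(96L, 96L), blobsPerTray = 3L,
                     familyColorSpread = 0.30, classColorSpread = 0.03,
                     textureScales = c(8, 16), pixelNoise = 0.02,
                     seed = 1L, nTrainTrays = 24L, nTestTrays = 12L),
    network = list(patchSize = c(64L, 64L), baseFilters = 8L, depth = 3L,
                   seed = 1L),
    training = list(batchSize = 8L, learningRate = 1e-3, globalSeed = 1L,
                    valFraction = 0.2, useFlips = FALSE,
                    pretrainEpochs = 2L, stlBudgets = c(3L, 5L),
                    baselineEpochs = 8L, valAccuracyTarget = 0.90),
    features = list(type = "unet_mean", k = 3L, pca = TRUE,
                    varianceTarget = 0.95, seed = 1L),
    clustering = list(linkage = "ward", metric = "euclidean", k = 2L,
                      stageCounts = NULL),
    evaluation = list(threshold = 0.75, minPatches = NULL))
}

mergeConfig <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]))
      base[[nm]] <- mergeConfig(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

writeRunManifest <- function(dir, step, config) {
  yaml::write_yaml(list(step = step, written = format(Sys.time()),
                        config = config),
                   file.path(dir, paste0(step, "-manifest.yml")))
}

pipelinePaths <- function(cfg) {
  root <- cfg$outputDir
  list(root = root,
       trainData = file.path(root, "data", "train"),
       testData = file.path(root, "data", "test"),
       cache = file.path(root, "cache"),
       models = file.path(root, "models"),
       features = file.path(root, "features"),
       hierarchy = file.path(root, "hierarchy"),
       eval = file.path(root, "eval"))
}

needArtifact <- function(path, producer) {
  if (!file.exists(path))
    stop(sprintf("missing artifact '%s'; run the '%s' stage first",
                 path, producer))
  path
}

synthConfigOf <- function(cfg) {
  s <- cfg$synthetic
  syntheticConfig(s$nFamilies, s$classesPerFamily, s$imageSize,
                  s$blobsPerTray, s$familyColorSpread, s$classColorSpread,
                  s$textureScales, s$pixelNoise, s$seed)
}

networkConfigOf <- function(cfg, C) {
  n <- cfg$network
  networkConfig(n$patchSize, n$baseFilters, n$depth, headClasses = C,
                seed = n$seed)
}

trainingConfigOf <- function(cfg) {
  t <- cfg$training
  trainingConfig(batchSize = t$batchSize, patchSize = cfg$network$patchSize,
                 learningRate = t$learningRate, globalSeed = t$globalSeed)
}

nSyntheticClasses <- function(cfg)
  cfg$synthetic$nFamilies * cfg$synthetic$classesPerFamily

#' Run one pipeline stage
#'
#' Stages (`synth`, `prepare`, `pretrain`, `features`, `cluster`,
#' `train-stl`, `train-baseline`, `evaluate`, `compare`) communicate only
#' through files under `config$outputDir`, so each can be re-run in
#' isolation; a missing upstream artifact raises an error naming the
#' stage that produces it.
#'
#' \describe{
#'   \item{synth}{generate train/test trays and the designed hierarchy}
#'   \item{prepare}{crop ROI patches, resize, optionally flip-augment,
#'     split train/validation, cache}
#'   \item{pretrain}{conventional training on all classes — the feature
#'     extractor must be trained conventionally before prototypes can be
#'     read from its bottleneck}
#'   \item{features}{class-prototype observation matrix (bottleneck means
#'     or color statistics)}
#'   \item{cluster}{dendrogram, greatest-link cuts, label hierarchy}
#'   \item{train-stl}{sequential transfer training over the hierarchy}
#'   \item{train-baseline}{conventional training at matched budget}
#'   \item{evaluate}{definiteness metrics on the test patches (pass
#'     `model = "stl"` or `"baseline"`)}
#'   \item{compare}{split-case algebra between the two evaluations}
#' }
#'
#' @param step stage name.
#' @param config configuration list (see [defaultRunConfig()]); partial
#'   lists are merged over the defaults.
#' @param configFile optional YAML file merged over the defaults before
#'   `config`.
#' @param model which trained model `evaluate` scores (`"stl"` or
#'   `"baseline"`).
#' @param verbose print progress. Default `TRUE`.
#' @return The stage's primary result, invisibly (also written to disk).
#' @export
runPipeline <- function(step, config = list(), configFile = NULL,
                        model = c("stl", "baseline"), verbose = TRUE) {
  cfg <- defaultRunConfig()
  if (!is.null(configFile))
    cfg <- mergeConfig(cfg, yaml::read_yaml(configFile))
  cfg <- mergeConfig(cfg, config)
  p <- pipelinePaths(cfg)
  say <- function(...) if (verbose) message(sprintf(...))
  step <- match.arg(step, c("synth", "prepare", "pretrain", "features",
                            "cluster", "train-stl", "train-baseline",
                            "evaluate", "compare"))
  switch(step,
    synth = {
      sc <- synthConfigOf(cfg)
      train <- generateDataset(sc, cfg$synthetic$nTrainTrays,
                               seed = cfg$synthetic$seed)
      test <- generateDataset(sc, cfg$synthetic$nTestTrays,
                              seed = deriveSeed(cfg$synthetic$seed, "test"))
      writeTrayManifest(train$trays, p$trainData)
      writeTrayManifest(test$trays, p$testData)
      jsonlite::write_json(as.list(train$hierarchy$familyOf),
                           file.path(p$root, "designed-hierarchy.json"),
                           auto_unbox = TRUE)
      writeRunManifest(p$root, "synth", cfg$synthetic)
      say("synth: %d train and %d test trays under %s",
          length(train$trays), length(test$trays), p$root)
      invisible(train)
    },
    prepare = {
      man <- needArtifact(file.path(p$trainData, "manifest.jsonl"), "synth")
      size <- cfg$network$patchSize
      pairs <- lapply(cropRoiPatches(readTrayManifest(man)),
                      resizePair, size = size)
      if (isTRUE(cfg$training$useFlips)) pairs <- augmentFlips(pairs)
      splits <- splitTrainVal(pairs, cfg$training$valFraction,
                              seed = cfg$training$globalSeed)
      testPairs <- lapply(
        cropRoiPatches(readTrayManifest(
          needArtifact(file.path(p$testData, "manifest.jsonl"), "synth"))),
        resizePair, size = size)
      writePatchCache(c(trainPairs(splits), validationPairs(splits),
                        testPairs),
                      p$cache,
                      split = c(rep("train", length(trainPairs(splits))),
                                rep("val", length(validationPairs(splits))),
                                rep("test", length(testPairs))))
      writeRunManifest(p$cache, "prepare",
                       cfg[c("network", "training")])
      say("prepare: %d train / %d val / %d test patches cached",
          length(trainPairs(splits)), length(validationPairs(splits)),
          length(testPairs))
      invisible(splits)
    },
    pretrain = {
      needArtifact(file.path(p$cache, "index.csv"), "prepare")
      dir.create(p$models, recursive = TRUE, showWarnings = FALSE)
      splits <- cacheSplits(p$cache)
      nc <- networkConfigOf(cfg, nSyntheticClasses(cfg) + 1L)
      res <- runConventional(nc, splits, trainingConfigOf(cfg),
                             epochs = cfg$training$pretrainEpochs,
                             verbose = verbose)
      saveModel(res$model, file.path(p$models, "pretrained.rds"))
      utils::write.csv(res$result$history,
                       file.path(p$models, "pretrain-history.csv"),
                       row.names = FALSE)
      writeRunManifest(p$models, "pretrain", cfg$training)
      invisible(res)
    },
    features = {
      needArtifact(file.path(p$cache, "index.csv"), "prepare")
      dir.create(p$features, recursive = TRUE, showWarnings = FALSE)
      train <- readPatchCache(p$cache, "train")
      obs <- if (cfg$features$type == "color_stats") {
        colorObservationMatrix(train, cfg$features$k, cfg$features$seed)
      } else {
        mdl <- loadModel(needArtifact(file.path(p$models, "pretrained.rds"),
                                      "pretrain"))
        bottleneckObservationMatrix(mdl, train, cfg$features$k,
                                    cfg$features$seed)
      }
      writeObservationMatrix(obs, file.path(p$features, "observations.csv"))
      writeRunManifest(p$features, "features", cfg$features)
      say("features: %d x %d observation matrix [%s]", nrow(obs@values),
          ncol(obs@values), obs@featureOrigin)
      invisible(obs)
    },
    cluster = {
      obs <- readObservationMatrix(
        needArtifact(file.path(p$features, "observations.csv"), "features"))
      dir.create(p$hierarchy, recursive = TRUE, showWarnings = FALSE)
      if (isTRUE(cfg$features$pca) && ncol(obs@values) > nrow(obs@values))
        obs <- pcaScores(obs, cfg$features$varianceTarget)
      dend <- buildDendrogram(obs, cfg$clustering$linkage,
                              cfg$clustering$metric)
      parts <- if (!is.null(cfg$clustering$stageCounts))
        cutsByClusterCounts(dend, cfg$clustering$stageCounts)
      else cutsByGreatestLinks(dend, cfg$clustering$k)
      hier <- buildLabelHierarchy(parts, seq_len(nSyntheticClasses(cfg)))
      writeLinkageCsv(dend, file.path(p$hierarchy, "linkage.csv"))
      writeLabelHierarchy(hier, file.path(p$hierarchy, "hierarchy.json"))
      writeRunManifest(p$hierarchy, "cluster", cfg$clustering)
      say("cluster: stages C = %s",
          paste(stageClassCounts(hier), collapse = ", "))
      invisible(hier)
    },
    "train-stl" = {
      hier <- readLabelHierarchy(
        needArtifact(file.path(p$hierarchy, "hierarchy.json"), "cluster"))
      splits <- cacheSplits(p$cache)
      dir.create(p$models, recursive = TRUE, showWarnings = FALSE)
      budgets <- cfg$training$stlBudgets
      nc <- networkConfigOf(cfg, stageClassCounts(hier)[1])
      res <- runStl(nc, hier, splits, trainingConfigOf(cfg), budgets,
                    cfg$training$valAccuracyTarget, verbose = verbose)
      saveModel(res$model, file.path(p$models, "stl.rds"))
      utils::write.csv(res$history, file.path(p$models, "stl-history.csv"),
                       row.names = FALSE)
      writeRunManifest(p$models, "train-stl", cfg$training)
      invisible(res)
    },
    "train-baseline" = {
      splits <- cacheSplits(p$cache)
      dir.create(p$models, recursive = TRUE, showWarnings = FALSE)
      nc <- networkConfigOf(cfg, nSyntheticClasses(cfg) + 1L)
      res <- runConventional(nc, splits, trainingConfigOf(cfg),
                             epochs = cfg$training$baselineEpochs,
                             verbose = verbose)
      saveModel(res$model, file.path(p$models, "baseline.rds"))
      utils::write.csv(res$result$history,
                       file.path(p$models, "baseline-history.csv"),
                       row.names = FALSE)
      writeRunManifest(p$models, "train-baseline", cfg$training)
      invisible(res)
    },
    evaluate = {
      model <- match.arg(model)
      mdl <- loadModel(needArtifact(
        file.path(p$models, paste0(model, ".rds")),
        if (model == "stl") "train-stl" else "train-baseline"))
      test <- readPatchCache(p$cache, "test")
      if (!is.null(cfg$evaluation$minPatches)) {
        byClass <- augmentTestToMin(pairsByClass(test),
                                    cfg$evaluation$minPatches)
        test <- unlist(byClass, recursive = FALSE, use.names = FALSE)
      }
      ev <- evaluateModel(mdl, test, cfg$evaluation$threshold)
      dir.create(p$eval, recursive = TRUE, showWarnings = FALSE)
      jsonlite::write_json(
        list(model = model, accuracy = ev$accuracy,
             nDefinite = ev$summary$nDefinite,
             nIndefinite = ev$summary$nIndefinite,
             meanQuality = ev$summary$meanQuality,
             ratios = ev$summary$ratios,
             perClass = ev$summary$perClass),
        file.path(p$eval, paste0(model, ".json")),
        auto_unbox = TRUE, digits = NA)
      utils::write.csv(ev$summary$perClass,
                       file.path(p$eval, paste0(model, "-per-class.csv")),
                       row.names = FALSE)
      writeRunManifest(p$eval, paste0("evaluate-", model), cfg$evaluation)
      say("evaluate[%s]: accuracy %.3f, %d definite / %d indefinite",
          model, ev$accuracy, ev$summary$nDefinite, ev$summary$nIndefinite)
      invisible(ev)
    },
    compare = {
      readEval <- function(name) {
        j <- jsonlite::fromJSON(needArtifact(
          file.path(p$eval, paste0(name, ".json")), "evaluate"))
        structure(list(nDefinite = j$nDefinite,
                       nIndefinite = j$nIndefinite,
                       meanQuality = j$meanQuality, ratios = j$ratios,
                       perClass = j$perClass, accuracy = j$accuracy),
                  class = "DefinitenessSummary")
      }
      a <- readEval("stl")
      b <- readEval("baseline")
      sc <- splitCases(a, b, rule = 0.5)
      out <- list(stlAccuracy = a$accuracy, baselineAccuracy = b$accuracy,
                  stlDefinite = a$nDefinite, baselineDefinite = b$nDefinite,
                  splitOnlyStl = sc$onlyA, splitOnlyBaseline = sc$onlyB,
                  splitBoth = sc$both)
      jsonlite::write_json(out, file.path(p$eval, "comparison.json"),
                           auto_unbox = TRUE, digits = NA)
      say("compare: STL acc %.3f vs baseline %.3f", a$accuracy, b$accuracy)
      invisible(out)
    })
}

cacheSplits <- function(cacheDir) {
  new("DatasetSplits",
      train = readPatchCache(cacheDir, "train"),
      validation = readPatchCache(cacheDir, "val"),
      test = readPatchCache(cacheDir, "test"),
      splitSeed = 0L)
}
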