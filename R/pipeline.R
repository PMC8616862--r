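#' @include evaluate.R io.R
NULL

#' Pipeline run configuration
#'
#' Everything needed to reproduce a full run: scene parameters, grid
#' geometry, per-network schedules, dataset size and split, evaluation
#' settings and the output directory. A run is fully reproducible from the
#' configuration plus the code version; per-stage seeds are derived from the
#' global seed by fixed offsets (simulate +0, uncover +1000, weight +2000,
#' classifier +3000, evaluation +4000).
#'
#' @slot scene a [SceneParams]
#' @slot grid a [GridSpec]
#' @slot unetConfig,weightConfig,classifierConfig [TrainConfig-class]s
#' @slot nSamples number of subjects to simulate
#' @slot trainFraction fraction of subjects used for training
#' @slot repetitions evaluation repetitions
#' @slot modes regression regimes to evaluate
#' @slot unetLevels,unetBaseChannels,cnnChannels,headWidth,dropout
#'   architecture settings
#' @slot outDir artifact directory
#' @slot seed global seed
#' @export
setClass("RunConfig", representation(
  scene = "SceneParams", grid = "GridSpec",
  unetConfig = "TrainConfig", weightConfig = "TrainConfig",
  classifierConfig = "TrainConfig",
  nSamples = "integer", trainFraction = "numeric", repetitions = "integer",
  modes = "character", unetLevels = "integer", unetBaseChannels = "integer",
  cnnChannels = "integer", headWidth = "integer", dropout = "numeric",
  outDir = "character", seed = "integer"
))

#' @param scene,grid,unetConfig,weightConfig,classifierConfig,nSamples,trainFraction,repetitions,modes,unetLevels,unetBaseChannels,cnnChannels,headWidth,dropout,outDir,seed
#'   see slot descriptions
#' @rdname RunConfig-class
#' @export
RunConfig <- function(scene = SceneParams(), grid = GridSpec(),
                      unetConfig = unetTrainConfig(),
                      weightConfig = weightTrainConfig(),
                      classifierConfig = classifierTrainConfig(),
                      nSamples = 100L, trainFraction = 0.8,
                      repetitions = 5L,
                      modes = c("two-stage", "plain-covered",
                                "plain-uncovered"),
                      unetLevels = 4L, unetBaseChannels = 32L,
                      cnnChannels = c(16L, 24L, 32L, 48L, 64L),
                      headWidth = 128L, dropout = 0.8,
                      outDir = "uncoverweight-run", seed = 1L) {
  scene@seed <- as.integer(seed)
  new("RunConfig", scene = scene, grid = grid, unetConfig = unetConfig,
      weightConfig = weightConfig, classifierConfig = classifierConfig,
      nSamples = as.integer(nSamples), trainFraction = trainFraction,
      repetitions = as.integer(repetitions), modes = modes,
      unetLevels = as.integer(unetLevels),
      unetBaseChannels = as.integer(unetBaseChannels),
      cnnChannels = as.integer(cnnChannels),
      headWidth = as.integer(headWidth), dropout = dropout,
      outDir = outDir, seed = as.integer(seed))
}

#' Reduced desk-scale preset
#'
#' Small configuration for CPU-only runs: 24 x 48 x 16 grid over the same
#' cuboid, base-8 U-Net, weight-CNN channels 8-16-24-32 (four convolutions:
#' a 24-voxel axis cannot survive five halvings), 10 / 30 epoch schedules,
#' moderate dropout, and `n` subjects.
#'
#' @param n number of subjects (capped at 300)
#' @param seed global seed
#' @param outDir artifact directory
#' @param repetitions evaluation repetitions
#' @param ... overrides forwarded to [RunConfig()]
#' @return a [RunConfig-class]
#' @export
reducedRunConfig <- function(n = 120L, seed = 1L,
                             outDir = "uncoverweight-run",
                             repetitions = 3L, ...) {
  RunConfig(
    grid = GridSpec(dims = c(24L, 48L, 16L)),
    unetConfig = unetTrainConfig(epochs = 10L, milestones = 7L,
                                 batchSize = 4L),
    weightConfig = weightTrainConfig(epochs = 30L, milestones = c(15L, 25L)),
    classifierConfig = classifierTrainConfig(),
    nSamples = min(as.integer(n), 300L),
    unetLevels = 4L, unetBaseChannels = 8L,
    cnnChannels = c(8L, 16L, 24L, 32L), headWidth = 64L,
    dropout = 0.5, repetitions = repetitions, outDir = outDir,
    seed = seed, ...)
}

#' Write / read a run configuration as YAML
#'
#' @param config a [RunConfig-class]
#' @param path YAML path
#' @return `writeRunConfig`: invisibly the path; `readRunConfig`: a
#'   [RunConfig-class]
#' @export
writeRunConfig <- function(config, path) {
  tcList <- function(tc) list(lr = tc@lr, batchSize = tc@batchSize,
                              epochs = tc@epochs,
                              milestones = as.integer(tc@milestones),
                              seed = tc@seed)
  yaml::write_yaml(list(
    scene = sceneParamsToList(config@scene),
    grid = list(extent = as.numeric(config@grid@extent),
                dims = as.integer(config@grid@dims),
                origin = as.numeric(config@grid@origin)),
    unetConfig = tcList(config@unetConfig),
    weightConfig = tcList(config@weightConfig),
    classifierConfig = tcList(config@classifierConfig),
    nSamples = config@nSamples, trainFraction = config@trainFraction,
    repetitions = config@repetitions, modes = config@modes,
    unetLevels = config@unetLevels,
    unetBaseChannels = config@unetBaseChannels,
    cnnChannels = as.integer(config@cnnChannels),
    headWidth = config@headWidth, dropout = config@dropout,
    outDir = config@outDir, seed = config@seed), path)
  invisible(path)
}

#' @rdname writeRunConfig
#' @export
readRunConfig <- function(path) {
  y <- yaml::read_yaml(path)
  tc <- function(l) TrainConfig(epochs = l$epochs,
                                milestones = as.integer(l$milestones),
                                lr = l$lr, batchSize = l$batchSize,
                                seed = l$seed)
  RunConfig(scene = do.call(SceneParams, y$scene),
            grid = GridSpec(extent = y$grid$extent, dims = y$grid$dims,
                            origin = y$grid$origin),
            unetConfig = tc(y$unetConfig), weightConfig = tc(y$weightConfig),
            classifierConfig = tc(y$classifierConfig),
            nSamples = y$nSamples, trainFraction = y$trainFraction,
            repetitions = y$repetitions, modes = unlist(y$modes),
            unetLevels = y$unetLevels,
            unetBaseChannels = y$unetBaseChannels,
            cnnChannels = as.integer(unlist(y$cnnChannels)),
            headWidth = y$headWidth, dropout = y$dropout,
            outDir = y$outDir, seed = y$seed)
}

requireArtifact <- function(path, producer) {
  if (!file.exists(path))
    uwStop(sprintf("missing artifact '%s'; run the '%s' stage first",
                   path, producer), "dependencyError")
  path
}

writeStageManifest <- function(outDir, stage, inputs, outputs, seed) {
  man <- list(stage = stage, seed = seed,
              inputs = lapply(inputs, function(f)
                list(path = f, md5 = unname(tools::md5sum(f)))),
              outputs = lapply(outputs, function(f)
                list(path = f, md5 = unname(tools::md5sum(f)))))
  jsonlite::write_json(man, file.path(outDir,
                                      paste0(stage, ".manifest.json")),
                       digits = NA, auto_unbox = TRUE)
}

#' Run a pipeline stage
#'
#' Orchestrates the full study on disk artifacts under `config@outDir`:
#' \describe{
#'   \item{simulate}{generate the paired synthetic dataset (PNG/PLY/JSON).}
#'   \item{preprocess}{back-project, isolate the bed, segment the patient,
#'     voxelize; writes `volumes.rds` and the train/test split.}
#'   \item{train-uncover}{train the U-Net; writes `unet.rds` + loss CSV.}
#'   \item{train-weight}{train the configured regression regimes; writes
#'     one checkpoint per regime.}
#'   \item{train-classifier}{train the cover classifier.}
#'   \item{evaluate}{run [evaluatePipeline()] over the configured
#'     repetitions; writes `report.csv` / `report.json`.}
#'   \item{predict}{two-stage weight predictions for the test volumes;
#'     writes `predictions.csv`.}
#' }
#' Every stage writes a manifest (inputs, outputs, MD5 checksums, seed).
#' Missing dependencies raise an error naming the absent artifact.
#'
#' @param config a [RunConfig-class]
#' @param command one of the stages above, or "all"
#' @param verbose print progress?
#' @return invisibly, a list of produced artifact paths
#' @export
runPipeline <- function(config,
                        command = c("all", "simulate", "preprocess",
                                    "train-uncover", "train-weight",
                                    "train-classifier", "evaluate",
                                    "predict"),
                        verbose = FALSE) {
  command <- match.arg(command)
  if (command == "all") {
    stages <- c("simulate", "preprocess", "train-uncover", "train-weight",
                "train-classifier", "evaluate", "predict")
    res <- lapply(stages, function(s) runPipeline(config, s,
                                                  verbose = verbose))
    return(invisible(setNames(res, stages)))
  }
  out <- config@outDir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  dsDir <- file.path(out, "dataset")
  volPath <- file.path(out, "volumes.rds")
  unetPath <- file.path(out, "unet.rds")
  produced <- character(0)

  if (command == "simulate") {
    samples <- generateDataset(config@nSamples, config@scene)
    writeDataset(samples, dsDir, config@scene)
    produced <- file.path(dsDir, "manifest.json")
    writeStageManifest(out, "simulate", character(0), produced, config@seed)
  } else if (command == "preprocess") {
    requireArtifact(file.path(dsDir, "manifest.json"), "simulate")
    samples <- readDataset(dsDir)
    vols <- prepareVolumes(samples, config@grid, params = config@scene)
    n <- length(vols)
    nTrain <- max(1L, round(config@trainFraction * n))
    split <- list(train = seq_len(nTrain),
                  test = if (nTrain < n) (nTrain + 1L):n else integer(0))
    saveRDS(list(volumes = vols, split = split, grid = config@grid), volPath)
    produced <- volPath
    writeStageManifest(out, "preprocess",
                       file.path(dsDir, "manifest.json"), produced,
                       config@seed)
  } else if (command == "train-uncover") {
    requireArtifact(volPath, "preprocess")
    v <- readRDS(volPath)
    cfg <- config@unetConfig; cfg@seed <- config@seed + 1000L
    pairs <- lapply(v$volumes[v$split$train],
                    function(x) list(x = x$xcov, y = x$target))
    un <- trainUncover(pairs, cfg, levels = config@unetLevels,
                       baseChannels = config@unetBaseChannels,
                       verbose = verbose)
    saveCheckpoint(un, unetPath)
    lossCsv <- file.path(out, "unet_loss.csv")
    utils::write.csv(data.frame(epoch = seq_along(un@lossTrace),
                                loss = un@lossTrace,
                                lr = vapply(seq_along(un@lossTrace),
                                            function(e) lrAt(cfg, e),
                                            numeric(1))),
                     lossCsv, row.names = FALSE)
    produced <- c(unetPath, lossCsv)
    writeStageManifest(out, "train-uncover", volPath, produced,
                       config@seed + 1000L)
  } else if (command == "train-weight") {
    requireArtifact(volPath, "preprocess")
    v <- readRDS(volPath)
    train <- v$volumes[v$split$train]
    w <- vapply(train, `[[`, numeric(1), "weight")
    cfg <- config@weightConfig; cfg@seed <- config@seed + 2000L
    for (md in config@modes) {
      un <- NULL
      if (md == "two-stage") {
        requireArtifact(unetPath, "train-uncover")
        un <- loadCheckpoint(unetPath)
      }
      grids <- lapply(train, `[[`,
                      if (md == "plain-uncovered") "xunc" else "xcov")
      m <- trainWeight(grids, w,
                       mode = if (md == "two-stage") "two-stage" else "plain",
                       uncover = un, config = cfg,
                       channels = config@cnnChannels,
                       headWidth = config@headWidth,
                       dropout = config@dropout, verbose = verbose)
      p <- file.path(out, paste0("weight_", md, ".rds"))
      saveCheckpoint(m, p)
      produced <- c(produced, p)
    }
    writeStageManifest(out, "train-weight", volPath, produced,
                       config@seed + 2000L)
  } else if (command == "train-classifier") {
    requireArtifact(volPath, "preprocess")
    v <- readRDS(volPath)
    train <- v$volumes[v$split$train]
    grids <- c(lapply(train, `[[`, "xcov"), lapply(train, `[[`, "xunc"))
    lab <- rep(c(TRUE, FALSE), each = length(train))
    cfg <- config@classifierConfig; cfg@seed <- config@seed + 3000L
    cl <- trainCoverClassifier(grids, lab, cfg,
                               channels = config@cnnChannels,
                               headWidth = config@headWidth,
                               dropout = config@dropout, verbose = verbose)
    p <- file.path(out, "classifier.rds")
    saveCheckpoint(cl, p)
    produced <- p
    writeStageManifest(out, "train-classifier", volPath, produced,
                       config@seed + 3000L)
  } else if (command == "evaluate") {
    requireArtifact(volPath, "preprocess")
    v <- readRDS(volPath)
    if (length(v$split$test) == 0)
      uwStop("no test samples in the split", "contractError")
    rep_ <- evaluatePipeline(
      v$volumes, v$split$train, v$split$test, spec = v$grid,
      repetitions = config@repetitions, baseSeed = config@seed + 4000L,
      unetConfig = config@unetConfig, weightConfig = config@weightConfig,
      unetLevels = config@unetLevels,
      unetBaseChannels = config@unetBaseChannels,
      cnnChannels = config@cnnChannels, headWidth = config@headWidth,
      dropout = config@dropout, modes = config@modes, verbose = verbose)
    writeEvalReport(rep_, file.path(out, "report.csv"),
                    file.path(out, "report.json"))
    produced <- file.path(out, c("report.csv", "report.json"))
    writeStageManifest(out, "evaluate", volPath, produced,
                       config@seed + 4000L)
  } else if (command == "predict") {
    requireArtifact(volPath, "preprocess")
    requireArtifact(unetPath, "train-uncover")
    wPath <- requireArtifact(file.path(out, "weight_two-stage.rds"),
                             "train-weight")
    v <- readRDS(volPath)
    un <- loadCheckpoint(unetPath)
    wm <- loadCheckpoint(wPath)
    idx <- if (length(v$split$test)) v$split$test else v$split$train
    preds <- vapply(v$volumes[idx], function(x)
      predictWeight(x$xcov, un, wm)$weight, numeric(1))
    truth <- vapply(v$volumes[idx], `[[`, numeric(1), "weight")
    p <- file.path(out, "predictions.csv")
    utils::write.csv(data.frame(id = vapply(v$volumes[idx], `[[`,
                                            integer(1), "id"),
                                predicted = preds, truth = truth),
                     p, row.names = FALSE)
    produced <- p
    writeStageManifest(out, "predict", c(volPath, unetPath, wPath),
                       produced, config@seed)
  }
  invisible(produced)
}
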