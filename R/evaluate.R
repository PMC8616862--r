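#' @include training.R metrics.R voxel.R depth.R
NULL

#' Preprocess paired samples into network-ready volumes
#'
#' The full preprocessing chain per sample: back-project each depth frame,
#' isolate the bed region (depth thresholding + clustering), mean-center and
#' voxelize. Inputs for the uncovering network are the covered bed-region
#' volumes; the supervision target is the patient-segmented uncovered cloud
#' (bed plane removed), translated by the *covered* cloud's centroid so that
#' input and target grids stay voxel-aligned. The uncovered bed-region volume
#' (self-centered) is also produced for the plain upper-bound regressor.
#'
#' @param samples list of [PairedSample-class] objects
#' @param spec a [GridSpec]
#' @param params the generating [SceneParams] (for the depth interval);
#'   alternatively pass `interval` explicitly
#' @param interval depth interval in m for [extractBedRegion()]; default
#'   keeps everything above halfway down the bed side
#' @param tol bed-plane inlier tolerance in m for [segmentPatientFromBed()]
#' @return list, one element per sample: `xcov`, `xunc`, `target` (3D
#'   arrays), `weight`, `position` (supine/lateral-left/lateral-right),
#'   `cover`, `id`
#' @export
prepareVolumes <- function(samples, spec = GridSpec(), params = NULL,
                           interval = NULL, tol = 0.02) {
  if (is.null(interval)) {
    if (is.null(params))
      uwStop("provide either params or an explicit depth interval",
             "configError")
    interval <- c(0.3, params@camHeight + params@bedHeight / 2)
  }
  lapply(samples, function(s) {
    cCov <- extractBedRegion(depthToCloud(s@frameCovered), interval)
    cCovC <- meanCenter(cCov)
    ctr <- cCovC@meta$centroid
    cUnc <- extractBedRegion(depthToCloud(s@frameUncovered), interval)
    patient <- segmentPatientFromBed(cUnc, tol = tol)
    list(xcov = occupancy(voxelize(cCovC, spec)),
         xunc = occupancy(voxelize(meanCenter(cUnc), spec)),
         target = occupancy(voxelize(translateCloud(patient, ctr), spec)),
         weight = s@weight, position = s@position, cover = s@cover,
         id = s@id)
  })
}

positionStratum <- function(position) {
  ifelse(position == "supine", "supine", "lateral")
}

# mean/sd/n rows over repetitions for one (method, metric, stratum)
statRow <- function(method, metric, cover, position, values, n) {
  data.frame(method = method, metric = metric, cover = cover,
             position = position, mean = mean(values),
             sd = if (length(values) >= 2) sd(values) else NA_real_,
             n = n, stringsAsFactors = FALSE)
}

#' Train and evaluate the pipeline with repetitions
#'
#' The complete experiment harness: per repetition (with a distinct seed) it
#' trains the uncovering U-Net on the training pairs, evaluates Dice and
#' directed average surface distance of the binarized predictions on the test
#' set (plus the no-model "initial" covered-vs-target reference), trains the
#' requested weight-regression regimes, and reports stratified MAE / MRE
#' (cover x position, lateral-left/right merged) with mean and sd over
#' repetitions, together with cumulative-error curves.
#'
#' @param volumes output of [prepareVolumes()]
#' @param trainIdx,testIdx index vectors into `volumes`
#' @param spec the [GridSpec] (for voxel sizes in the surface distance)
#' @param repetitions number of training repetitions
#' @param baseSeed repetition r uses seed `baseSeed + r`
#' @param unetConfig,weightConfig [TrainConfig-class]s (seeds overridden per
#'   repetition)
#' @param unetLevels,unetBaseChannels,cnnChannels,headWidth,dropout
#'   architecture settings (see [buildUnet()], [buildWeightCnn()])
#' @param modes regimes to evaluate: subset of "two-stage", "plain-covered",
#'   "plain-uncovered"
#' @param uncover optionally a fixed pre-trained [UncoverModel-class]; when
#'   supplied the U-Net is not retrained per repetition
#' @param verbose print progress?
#' @return an [EvalReport-class]
#' @export
evaluatePipeline <- function(volumes, trainIdx, testIdx, spec = GridSpec(),
                             repetitions = 5L, baseSeed = 0L,
                             unetConfig = unetTrainConfig(),
                             weightConfig = weightTrainConfig(),
                             unetLevels = 4L, unetBaseChannels = 32L,
                             cnnChannels = c(16L, 24L, 32L, 48L, 64L),
                             headWidth = 128L, dropout = 0.8,
                             modes = c("two-stage", "plain-covered",
                                       "plain-uncovered"),
                             uncover = NULL, verbose = FALSE) {
  if (!all(c(trainIdx, testIdx) %in% seq_along(volumes)))
    uwStop("train/test indices out of range", "contractError")
  vs <- voxelSizes(spec)
  test <- volumes[testIdx]
  train <- volumes[trainIdx]
  wTrain <- vapply(train, `[[`, numeric(1), "weight")
  wTest <- vapply(test, `[[`, numeric(1), "weight")
  covT <- vapply(test, `[[`, character(1), "cover")
  posT <- positionStratum(vapply(test, `[[`, character(1), "position"))

  perRep <- list()
  errPool <- list()
  for (r in seq_len(repetitions)) {
    seed <- baseSeed + r
    if (verbose) message(sprintf("repetition %d/%d (seed %d)", r,
                                 repetitions, seed))
    un <- uncover
    if (is.null(un)) {
      cfgU <- unetConfig; cfgU@seed <- as.integer(seed)
      pairs <- lapply(train, function(v) list(x = v$xcov, y = v$target))
      un <- trainUncover(pairs, cfgU, levels = unetLevels,
                         baseChannels = unetBaseChannels, verbose = verbose)
    }
    probs <- unetApply(un, lapply(test, `[[`, "xcov"))
    rows <- list()
    asdSafe <- function(tgt, pred) {
      # an empty predicted volume has no surface; record NA for the stratum
      tryCatch(avgSurfaceDistance(tgt, pred, vs),
               distanceUndefinedError = function(e) NA_real_)
    }
    for (i in seq_along(test)) {
      pred <- (probs[[i]] > 0.5) * 1
      tgt <- test[[i]]$target
      ini <- test[[i]]$xcov
      rows[[i]] <- data.frame(
        cover = covT[i], position = posT[i],
        dice = dice(tgt, pred), diceInitial = dice(tgt, ini),
        asd = asdSafe(tgt, pred),
        asdInitial = asdSafe(tgt, ini))
    }
    seg <- do.call(rbind, rows)

    cfgW <- weightConfig; cfgW@seed <- as.integer(seed)
    preds <- list()
    if ("two-stage" %in% modes) {
      m <- trainWeight(lapply(train, `[[`, "xcov"), wTrain, "two-stage",
                       uncover = un, config = cfgW, channels = cnnChannels,
                       headWidth = headWidth, dropout = dropout,
                       verbose = verbose)
      preds[["two-stage"]] <- weightCnnApply(m, probs)
    }
    if ("plain-covered" %in% modes) {
      m <- trainWeight(lapply(train, `[[`, "xcov"), wTrain, "plain",
                       config = cfgW, channels = cnnChannels,
                       headWidth = headWidth, dropout = dropout,
                       verbose = verbose)
      preds[["plain-covered"]] <- weightCnnApply(m, lapply(test, `[[`, "xcov"))
    }
    if ("plain-uncovered" %in% modes) {
      m <- trainWeight(lapply(train, `[[`, "xunc"), wTrain, "plain",
                       config = cfgW, channels = cnnChannels,
                       headWidth = headWidth, dropout = dropout,
                       verbose = verbose)
      preds[["plain-uncovered"]] <- weightCnnApply(m,
                                                   lapply(test, `[[`, "xunc"))
    }
    perRep[[r]] <- list(seg = seg, preds = preds)
    for (md in names(preds))
      errPool[[md]] <- c(errPool[[md]], abs(preds[[md]] - wTest))
  }

  # aggregate over repetitions, stratified
  tab <- list()
  addStrat <- function(method, metric, valueFun, strata) {
    for (s in seq_len(nrow(strata))) {
      sel <- covT == strata$cover[s] & posT == strata$position[s]
      if (strata$cover[s] == "none") sel <- posT == strata$position[s]
      if (!any(sel)) next
      vals <- vapply(perRep, function(pr) valueFun(pr, sel), numeric(1))
      tab[[length(tab) + 1]] <<- statRow(method, metric, strata$cover[s],
                                         strata$position[s], vals, sum(sel))
    }
  }
  covStrata <- expand.grid(cover = c("thin", "thick"),
                           position = c("supine", "lateral"),
                           stringsAsFactors = FALSE)
  uncStrata <- expand.grid(cover = "none",
                           position = c("supine", "lateral"),
                           stringsAsFactors = FALSE)
  addStrat("unet", "dice",
           function(pr, sel) mean(pr$seg$dice[sel]), covStrata)
  addStrat("initial", "dice",
           function(pr, sel) mean(pr$seg$diceInitial[sel]), covStrata)
  addStrat("unet", "asd",
           function(pr, sel) mean(pr$seg$asd[sel], na.rm = TRUE), covStrata)
  addStrat("initial", "asd",
           function(pr, sel) mean(pr$seg$asdInitial[sel], na.rm = TRUE),
           covStrata)
  for (md in intersect(c("two-stage", "plain-covered"), modes)) {
    addStrat(md, "mae",
             function(pr, sel) mae(pr$preds[[md]][sel], wTest[sel]),
             covStrata)
    addStrat(md, "mre",
             function(pr, sel) mre(pr$preds[[md]][sel], wTest[sel]),
             covStrata)
  }
  if ("plain-uncovered" %in% modes) {
    addStrat("plain-uncovered", "mae",
             function(pr, sel) mae(pr$preds[["plain-uncovered"]][sel],
                                   wTest[sel]), uncStrata)
    addStrat("plain-uncovered", "mre",
             function(pr, sel) mre(pr$preds[["plain-uncovered"]][sel],
                                   wTest[sel]), uncStrata)
  }
  new("EvalReport", table = do.call(rbind, tab),
      curves = lapply(errPool, cumulativeErrorCurve),
      repetitions = as.integer(repetitions))
}

#' Serialize an evaluation report
#'
#' Writes the stratified table as CSV (one row per method x metric x
#' stratum) and the full report, including cumulative-error curve samples,
#' as JSON.
#'
#' @param report an [EvalReport-class]
#' @param csvPath,jsonPath output paths (either may be `NULL`)
#' @return invisibly, the report
#' @export
writeEvalReport <- function(report, csvPath = NULL, jsonPath = NULL) {
  if (!is.null(csvPath))
    utils::write.csv(report@table, csvPath, row.names = FALSE)
  if (!is.null(jsonPath))
    jsonlite::write_json(list(repetitions = report@repetitions,
                              table = report@table,
                              curves = report@curves),
                         jsonPath, dataframe = "columns", digits = NA,
                         auto_unbox = TRUE)
  invisible(report)
}
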