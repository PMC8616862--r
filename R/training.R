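#' @include unet.R weightcnn.R losses.R
NULL

asGridArray <- function(g) if (is(g, "VoxelGrid")) g@data else g

#' Train the uncovering U-Net
#'
#' Minimizes element-wise binary cross-entropy between the network's output
#' for the covered input volume and the binary target volume of the
#' patient-segmented uncovered cloud, with ADAM under the milestone schedule
#' of `config`. Deterministic given `config@seed` (initialization, shuffling)
#' on a fixed platform.
#'
#' @param pairs list of `list(x = , y = )` pairs: covered input volume and
#'   uncovered-patient target volume ([VoxelGrid] or 3D array), all of one
#'   shape
#' @param config a [TrainConfig-class]; default [unetTrainConfig()] (50
#'   epochs, lr 0.001 divided by 10 after epoch 30, batch 16)
#' @param levels,baseChannels architecture, see [buildUnet()]
#' @param model optionally a pre-built [UncoverModel-class] to continue from
#' @param verbose print per-epoch loss?
#' @return a trained [UncoverModel-class] with its per-epoch loss trace
#' @export
trainUncover <- function(pairs, config = unetTrainConfig(),
                         levels = 4L, baseChannels = 32L, model = NULL,
                         verbose = FALSE) {
  if (length(pairs) == 0) uwStop("empty training set", "contractError")
  xs <- lapply(pairs, function(p) asGridArray(p$x))
  ys <- lapply(pairs, function(p) asGridArray(p$y))
  set.seed(config@seed)
  if (is.null(model)) {
    model <- buildUnet(inDim = dim(xs[[1]]), levels = levels,
                       baseChannels = baseChannels)
    # initialize the output bias at the logit of the target occupancy rate:
    # sparse voxel targets otherwise dominate the first training epochs
    rate <- min(max(mean(vapply(ys, mean, numeric(1))), 1e-4), 1 - 1e-4)
    model@params[["out.b"]] <- log(rate / (1 - rate))
  }
  if (config@epochs == 0L) return(model)
  state <- adamInit(model@params)
  n <- length(xs)
  trace <- numeric(config@epochs)
  for (epoch in seq_len(config@epochs)) {
    lr <- lrAt(config, epoch)
    ord <- sample.int(n)
    losses <- c()
    for (b0 in seq(1L, n, by = config@batchSize)) {
      ii <- ord[b0:min(b0 + config@batchSize - 1L, n)]
      x <- stackGrids(xs[ii])
      t <- stackGrids(ys[ii])
      fw <- unetForwardBatch(model, x, training = TRUE)
      model@buffers <- fw$buffers
      l <- bceWithLogits(fw$z, t)
      losses <- c(losses, l$loss)
      grads <- unetBackwardBatch(model, fw$caches, l$grad)
      upd <- adamStep(model@params, grads, state, lr)
      model@params <- upd$params
      state <- upd$state
    }
    trace[epoch] <- mean(losses)
    if (verbose)
      message(sprintf("uncover epoch %d/%d: loss %.5f (lr %g)",
                      epoch, config@epochs, trace[epoch], lr))
  }
  model@lossTrace <- trace
  model
}

#' Train the weight regressor
#'
#' Three regimes:
#' \describe{
#'   \item{`"plain"`}{the 3D CNN trained directly on the input volumes
#'     (covered or uncovered, as supplied) with mean-squared-error loss.}
#'   \item{`"two-stage"`}{the CNN trained on the *soft* (non-binarized)
#'     output volumes of a trained, frozen uncovering network; the U-Net
#'     parameters are read once and never updated (bitwise freeze).}
#'   \item{`"e2e"`}{the composition U-Net + CNN trained end-to-end on the
#'     weight loss only, without the intermediate uncovering loss; both
#'     parameter sets are updated.}
#' }
#'
#' @param grids list of input volumes ([VoxelGrid] or 3D array)
#' @param weights numeric vector of ground-truth weights (kg)
#' @param mode "plain", "two-stage" or "e2e"
#' @param uncover a trained [UncoverModel-class]; required for "two-stage",
#'   optional initialization for "e2e" (fresh one built when `NULL`)
#' @param config a [TrainConfig-class]; default [weightTrainConfig()] (120
#'   epochs, lr 0.001 divided by 10 at epochs 60 and 100, batch 16)
#' @param channels,headWidth,dropout architecture, see [buildWeightCnn()]
#' @param unetLevels,unetBaseChannels U-Net architecture for a fresh "e2e"
#'   composition
#' @param verbose print per-epoch loss?
#' @return for "plain" and "two-stage", a trained [WeightModel-class]; for
#'   "e2e", `list(weight = , uncover = )` with both updated models
#' @export
trainWeight <- function(grids, weights,
                        mode = c("plain", "two-stage", "e2e"),
                        uncover = NULL, config = weightTrainConfig(),
                        channels = c(16L, 24L, 32L, 48L, 64L),
                        headWidth = 128L, dropout = 0.8,
                        unetLevels = 4L, unetBaseChannels = 32L,
                        verbose = FALSE) {
  mode <- match.arg(mode)
  if (length(grids) == 0 || length(grids) != length(weights))
    uwStop("grids and weights must be nonempty and of equal length",
           "contractError")
  xs <- lapply(grids, asGridArray)
  if (mode == "two-stage") {
    if (is.null(uncover))
      uwStop("two-stage training requires a trained uncovering model",
             "contractError")
    xs <- unetApply(uncover, xs)  # soft probability volumes, theta_f frozen
  }
  set.seed(config@seed)
  cnn <- buildWeightCnn(inDim = dim(xs[[1]]), channels = channels,
                        headWidth = headWidth, dropout = dropout,
                        mode = "regression", outputBias = mean(weights))
  if (mode == "e2e" && is.null(uncover))
    uncover <- buildUnet(inDim = dim(xs[[1]]), levels = unetLevels,
                         baseChannels = unetBaseChannels)
  if (config@epochs == 0L) {
    if (mode == "e2e") return(list(weight = cnn, uncover = uncover))
    return(cnn)
  }
  state <- adamInit(cnn@params)
  if (mode == "e2e") stateU <- adamInit(uncover@params)
  n <- length(xs)
  trace <- numeric(config@epochs)
  for (epoch in seq_len(config@epochs)) {
    lr <- lrAt(config, epoch)
    ord <- sample.int(n)
    losses <- c()
    for (b0 in seq(1L, n, by = config@batchSize)) {
      ii <- ord[b0:min(b0 + config@batchSize - 1L, n)]
      x <- stackGrids(xs[ii])
      y <- weights[ii]
      if (mode == "e2e") {
        fu <- unetForwardBatch(uncover, x, training = TRUE)
        uncover@buffers <- fu$buffers
        p <- sigmoid(fu$z)
        fw <- cnnForwardBatch(cnn, p, training = TRUE)
      } else {
        fw <- cnnForwardBatch(cnn, x, training = TRUE)
      }
      cnn@buffers <- fw$buffers
      resid <- fw$out - y
      losses <- c(losses, mean(resid^2))
      dout <- 2 * resid / length(y)
      bw <- cnnBackwardBatch(cnn, fw$caches, dout, needDx = (mode == "e2e"))
      upd <- adamStep(cnn@params, bw$grads, state, lr)
      cnn@params <- upd$params
      state <- upd$state
      if (mode == "e2e") {
        dz <- bw$dx * p * (1 - p)  # back through the logistic
        gu <- unetBackwardBatch(uncover, fu$caches, dz)
        updU <- adamStep(uncover@params, gu, stateU, lr)
        uncover@params <- updU$params
        stateU <- updU$state
      }
    }
    trace[epoch] <- mean(losses)
    if (verbose)
      message(sprintf("weight[%s] epoch %d/%d: mse %.3f (lr %g)",
                      mode, epoch, config@epochs, trace[epoch], lr))
  }
  cnn@lossTrace <- trace
  if (mode == "e2e") return(list(weight = cnn, uncover = uncover))
  cnn
}

#' Predict the weight of a covered patient
#'
#' The full two-stage pipeline: the uncovering network maps the covered
#' occupancy volume to the uncovered-patient probability volume, and the
#' weight CNN regresses weight from that volume. The intermediate volume is
#' returned for inspection.
#'
#' @param grid covered-patient [VoxelGrid] or 3D array
#' @param uncover a trained [UncoverModel-class]
#' @param weightModel a trained regression [WeightModel-class]
#' @return `list(weight = kg, uncovered = probability volume)`
#' @export
predictWeight <- function(grid, uncover, weightModel) {
  arr <- asGridArray(grid)
  if (!identical(as.integer(dim(arr)), as.integer(uncover@arch$inDim)) ||
      !identical(as.integer(dim(arr)), as.integer(weightModel@arch$inDim)))
    uwStop("grid spec does not match the models", "contractError")
  p <- unetApply(uncover, arr)
  list(weight = weightCnnApply(weightModel, p), uncovered = p)
}

#' Train the cover-presence classifier
#'
#' The baseline 3D CNN trained as a binary classifier (logistic output,
#' binary cross-entropy): covered (thin and thick pooled as one positive
#' class) vs uncovered volumes. Default schedule: 10 epochs, lr 0.001
#' divided by 10 after epochs 5 and 8.
#'
#' @param grids list of input volumes
#' @param covered logical vector (or "covered"/"uncovered" strings)
#' @param config a [TrainConfig-class]; default [classifierTrainConfig()]
#' @param channels,headWidth,dropout architecture, see [buildWeightCnn()]
#' @param verbose print per-epoch loss?
#' @return a trained classifier [WeightModel-class]
#' @export
trainCoverClassifier <- function(grids, covered,
                                 config = classifierTrainConfig(),
                                 channels = c(16L, 24L, 32L, 48L, 64L),
                                 headWidth = 128L, dropout = 0.8,
                                 verbose = FALSE) {
  if (is.character(covered)) covered <- covered == "covered"
  t <- as.numeric(covered)
  if (length(grids) == 0 || length(grids) != length(t))
    uwStop("grids and labels must be nonempty and of equal length",
           "contractError")
  if (length(unique(t)) < 2)
    uwStop("both classes must be present in the training data",
           "contractError")
  xs <- lapply(grids, asGridArray)
  set.seed(config@seed)
  cnn <- buildWeightCnn(inDim = dim(xs[[1]]), channels = channels,
                        headWidth = headWidth, dropout = dropout,
                        mode = "classifier")
  if (config@epochs == 0L) return(cnn)
  state <- adamInit(cnn@params)
  n <- length(xs)
  trace <- numeric(config@epochs)
  for (epoch in seq_len(config@epochs)) {
    lr <- lrAt(config, epoch)
    ord <- sample.int(n)
    losses <- c()
    for (b0 in seq(1L, n, by = config@batchSize)) {
      ii <- ord[b0:min(b0 + config@batchSize - 1L, n)]
      x <- stackGrids(xs[ii])
      fw <- cnnForwardBatch(cnn, x, training = TRUE)
      cnn@buffers <- fw$buffers
      l <- bceWithLogits(fw$out, t[ii])
      losses <- c(losses, l$loss)
      bw <- cnnBackwardBatch(cnn, fw$caches, as.numeric(l$grad))
      upd <- adamStep(cnn@params, bw$grads, state, lr)
      cnn@params <- upd$params
      state <- upd$state
    }
    trace[epoch] <- mean(losses)
    if (verbose)
      message(sprintf("classifier epoch %d/%d: bce %.4f", epoch,
                      config@epochs, trace[epoch]))
  }
  cnn@lossTrace <- trace
  cnn
}

#' Classify the cover condition of a volume
#'
#' Logistic probability thresholded at 0.5; the tie (probability exactly 0.5)
#' deterministically resolves to "uncovered". In the fully automatic
#' pipeline, "covered" volumes are routed through the two-stage uncovering
#' pipeline and "uncovered" volumes to the plain regressor.
#'
#' @param model a classifier [WeightModel-class]
#' @param grid input volume ([VoxelGrid] or 3D array), or list of them
#' @return character vector of "covered" / "uncovered"
#' @export
classifyCover <- function(model, grid) {
  if (model@arch$mode != "classifier")
    uwStop("model is not a classifier", "contractError")
  p <- weightCnnApply(model, grid)
  ifelse(p > 0.5, "covered", "uncovered")
}

#' Route a volume through the automatic pipeline
#'
#' Cover detection followed by the appropriate estimator: covered volumes go
#' through the two-stage uncovering pipeline, uncovered ones to the plain
#' regressor.
#'
#' @param grid input volume
#' @param classifier a classifier [WeightModel-class]
#' @param uncover a trained [UncoverModel-class]
#' @param twoStageModel regression model trained on uncovered volumes
#'   (two-stage regime)
#' @param plainModel regression model trained on uncovered inputs
#' @return `list(label = , weight = )`
#' @export
autoPredictWeight <- function(grid, classifier, uncover, twoStageModel,
                              plainModel) {
  label <- classifyCover(classifier, grid)
  w <- if (label == "covered")
    predictWeight(grid, uncover, twoStageModel)$weight
  else weightCnnApply(plainModel, grid)
  list(label = label, weight = w)
}
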