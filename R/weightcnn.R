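#' @include nn-layers.R
NULL

# analytic spatial-shape trace of the conv stack (conv k5 s2 p2, then
# [pool 2 -> conv k3 s1 p1] per remaining channel entry; pools use floor)
cnnShapeTrace <- function(inDim, nConv) {
  d <- inDim
  shapes <- list()
  d <- (d + 2L * 2L - 5L) %/% 2L + 1L  # conv1: k5, s2, p2
  shapes[["conv1"]] <- d
  for (i in seq_len(nConv - 1L)) {
    d <- d %/% 2L  # pool
    if (any(d < 1L)) return(NULL)
    shapes[[paste0("pool", i)]] <- d
    shapes[[paste0("conv", i + 1L)]] <- d  # k3 s1 p1 preserves shape
  }
  shapes
}

#' Build the 3D CNN for weight regression or cover classification
#'
#' The network downsamples the input volume to very low resolution before the
#' fully connected heads: a 5x5x5 convolution with stride 2, then alternating
#' 2x2x2 max pooling and 3x3x3 stride-1 convolutions — one conv per entry of
#' `channels`, with the channel count gradually increased to the last entry
#' (default 16-24-32-48-64, ending at 64). With the default five convolutions
#' the cumulative spatial downsampling is 2^5 = 32 per axis. Every
#' convolution is followed by batch normalization and a ReLU. The heads are a
#' fully connected layer (`headWidth` neurons, ReLU), dropout, and a single
#' output neuron: linear activation in `"regression"` mode (kg), logistic in
#' `"classifier"` mode. Shape-preserving padding (5 -> 2, 3 -> 1) and floor
#' pooling are used throughout. Initialization draws from the current RNG.
#'
#' @param inDim integer(3) input volume shape
#' @param channels conv channel schedule; length = number of convolutions
#' @param headWidth fully connected layer width
#' @param dropout dropout probability in the head
#' @param mode "regression" or "classifier"
#' @param outputBias initial output-neuron bias (e.g. the mean training
#'   weight in kg; speeds up regression convergence)
#' @return an untrained [WeightModel-class]
#' @export
buildWeightCnn <- function(inDim = c(48L, 96L, 32L),
                           channels = c(16L, 24L, 32L, 48L, 64L),
                           headWidth = 128L, dropout = 0.8,
                           mode = c("regression", "classifier"),
                           outputBias = 0) {
  mode <- match.arg(mode)
  inDim <- as.integer(inDim)
  nConv <- length(channels)
  shapes <- cnnShapeTrace(inDim, nConv)
  if (is.null(shapes))
    uwStop(sprintf("input %s too small to survive %d halvings",
                   paste(inDim, collapse = "x"), nConv),
           "constructionError")
  params <- list(); buffers <- list()
  init <- initConvBN(1L, channels[1], 5L)
  params <- c(params, prefixNames(init, "conv1"))
  buffers <- c(buffers, prefixNames(initBNBuffers(channels[1]), "conv1"))
  for (i in seq_len(nConv - 1L)) {
    nm <- paste0("conv", i + 1L)
    init <- initConvBN(channels[i], channels[i + 1L], 3L)
    params <- c(params, prefixNames(init, nm))
    buffers <- c(buffers, prefixNames(initBNBuffers(channels[i + 1L]), nm))
  }
  finalDim <- shapes[[length(shapes)]]
  flat <- channels[nConv] * prod(finalDim)
  params[["fc1.W"]] <- heInit(headWidth, flat)
  params[["fc1.b"]] <- numeric(headWidth)
  params[["fc2.W"]] <- matrix(rnorm(headWidth, sd = sqrt(1 / headWidth)), 1L)
  params[["fc2.b"]] <- outputBias
  new("WeightModel",
      arch = list(inDim = inDim, channels = as.integer(channels),
                  headWidth = as.integer(headWidth), dropout = dropout,
                  mode = mode, finalDim = finalDim, flat = flat),
      params = params, buffers = buffers, lossTrace = numeric(0))
}

#' Analytic shape trace of the weight CNN
#'
#' Spatial shape after every conv/pool stage, the cumulative downsampling
#' factor per axis, the final conv channel count and the flattened feature
#' length — all computed from the architecture alone.
#'
#' @param model a [WeightModel-class]
#' @return list with `stages`, `downsampleFactor`, `finalChannels`,
#'   `finalSpatial`, `flatFeatures`
#' @export
weightCnnShapes <- function(model) {
  nConv <- length(model@arch$channels)
  stages <- cnnShapeTrace(model@arch$inDim, nConv)
  list(stages = stages,
       downsampleFactor = 2L^nConv,
       finalChannels = model@arch$channels[nConv],
       finalSpatial = model@arch$finalDim,
       flatFeatures = model@arch$flat)
}

# forward on a (1, X, Y, Z, N) batch; returns raw output (length-N vector of
# kg or logits), caches, updated buffers
cnnForwardBatch <- function(model, x, training) {
  params <- model@params
  buffers <- model@buffers
  nConv <- length(model@arch$channels)
  caches <- list()
  r <- convBlockF(x, pget(params, "conv1"), bget(buffers, "conv1"),
                  5L, 2L, 2L, training)
  cur <- r$y
  caches[["conv1"]] <- r$cache
  buffers <- bset(buffers, "conv1", r$buf)
  for (i in seq_len(nConv - 1L)) {
    mp <- cpp_maxpool3d_fwd(cur)
    caches[[paste0("pool", i)]] <- list(idx = mp$idx, xdim = dim(cur))
    cur <- mp$y
    nm <- paste0("conv", i + 1L)
    r <- convBlockF(cur, pget(params, nm), bget(buffers, nm), 3L, 1L, 1L,
                    training)
    cur <- r$y
    caches[[nm]] <- r$cache
    buffers <- bset(buffers, nm, r$buf)
  }
  N <- dim(cur)[5]
  caches$convOutDim <- dim(cur)
  flat <- matrix(cur, model@arch$flat, N)
  d1 <- denseF(flat, params[["fc1.W"]], params[["fc1.b"]])
  h <- d1$y
  mask <- h > 0
  h[!mask] <- 0
  caches$fc1 <- list(x = d1$cache, mask = mask)
  dr <- dropoutF(h, model@arch$dropout, training)
  caches$drop <- dr$mask
  d2 <- denseF(dr$y, params[["fc2.W"]], params[["fc2.b"]])
  caches$fc2 <- d2$cache
  list(out = as.numeric(d2$y), caches = caches, buffers = buffers)
}

# backward; dout: gradient on the raw output (vector length N)
cnnBackwardBatch <- function(model, caches, dout, needDx = FALSE) {
  params <- model@params
  nConv <- length(model@arch$channels)
  grads <- list()
  d2 <- denseB(caches$fc2, params[["fc2.W"]], matrix(dout, 1L))
  grads[["fc2.W"]] <- d2$dW
  grads[["fc2.b"]] <- d2$db
  dh <- d2$dx
  if (!is.null(caches$drop)) dh <- dh * caches$drop
  dh[!caches$fc1$mask] <- 0
  d1 <- denseB(caches$fc1$x, params[["fc1.W"]], dh)
  grads[["fc1.W"]] <- d1$dW
  grads[["fc1.b"]] <- d1$db
  dcur <- array(d1$dx, caches$convOutDim)
  for (i in seq(nConv, 2L)) {
    nm <- paste0("conv", i)
    bb <- convBlockB(caches[[nm]], pget(params, nm), dcur, TRUE)
    grads <- c(grads, prefixNames(bb$grads, nm))
    pc <- caches[[paste0("pool", i - 1L)]]
    dcur <- cpp_maxpool3d_bwd(pc$idx, bb$dx, pc$xdim)
  }
  bb <- convBlockB(caches[["conv1"]], pget(params, "conv1"), dcur, needDx)
  grads <- c(grads, prefixNames(bb$grads, "conv1"))
  list(grads = grads, dx = bb$dx)
}

#' Apply the weight CNN
#'
#' Evaluation-mode forward pass. In regression mode returns predicted weights
#' in kg; in classifier mode returns the logistic cover probability.
#'
#' @param model a trained [WeightModel-class]
#' @param grids a [VoxelGrid], 3D array, or list of either
#' @return numeric vector, one value per input volume
#' @export
weightCnnApply <- function(model, grids) {
  if (!is.list(grids) || is(grids, "VoxelGrid")) grids <- list(grids)
  arrs <- lapply(grids, function(g) if (is(g, "VoxelGrid")) g@data else g)
  for (a in arrs)
    if (!identical(dim(a), as.integer(model@arch$inDim)))
      uwStop("grid shape does not match the model's input shape",
             "contractError")
  out <- numeric(length(arrs))
  bs <- 16L
  for (i0 in seq(1L, length(arrs), by = bs)) {
    ii <- i0:min(i0 + bs - 1L, length(arrs))
    x <- stackGrids(arrs[ii])
    o <- cnnForwardBatch(model, x, training = FALSE)$out
    out[ii] <- o
  }
  if (model@arch$mode == "classifier") sigmoid(out) else out
}
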