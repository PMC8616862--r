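#' @include nn-layers.R
NULL

pget <- function(params, nm) {
  list(W = params[[paste0(nm, ".W")]], b = params[[paste0(nm, ".b")]],
       gamma = params[[paste0(nm, ".gamma")]],
       beta = params[[paste0(nm, ".beta")]])
}

bget <- function(buffers, nm) {
  list(rm = buffers[[paste0(nm, ".rm")]], rv = buffers[[paste0(nm, ".rv")]])
}

bset <- function(buffers, nm, buf) {
  buffers[[paste0(nm, ".rm")]] <- buf$rm
  buffers[[paste0(nm, ".rv")]] <- buf$rv
  buffers
}

#' Build the 3D U-Net uncovering network
#'
#' Encoder/decoder with `levels` resolution levels: two 3x3x3 conv +
#' batch-norm + ReLU blocks per level, 2x2x2 max-pool downsampling in the
#' encoder, 2x2x2 transposed-convolution upsampling in the decoder, and skip
#' connections concatenating equal-resolution encoder features before the
#' decoder convolutions. Channels double per level from `baseChannels`
#' (default 32/64/128/256). A final 1x1x1 convolution produces per-voxel
#' logits; [unetApply()] returns logistic probabilities. Parameter
#' initialization draws from the current RNG.
#'
#' @param inDim integer(3) input volume shape; every axis must be divisible
#'   by `2^(levels - 1)`
#' @param levels number of resolution levels
#' @param baseChannels channels at the finest level
#' @return an untrained [UncoverModel-class]
#' @export
buildUnet <- function(inDim = c(48L, 96L, 32L), levels = 4L,
                      baseChannels = 32L) {
  inDim <- as.integer(inDim)
  if (any(inDim %% 2L^(levels - 1L) != 0L))
    uwStop(sprintf("input resolution (%s) must be divisible by %d per axis",
                   paste(inDim, collapse = ","), 2L^(levels - 1L)),
           "constructionError")
  ch <- as.integer(baseChannels * 2L^(0:(levels - 1L)))
  params <- list(); buffers <- list()
  for (l in seq_len(levels)) {
    cin <- if (l == 1L) 1L else ch[l - 1L]
    for (blk in c("c1", "c2")) {
      nm <- paste0("e", l, blk)
      init <- initConvBN(if (blk == "c1") cin else ch[l], ch[l], 3L)
      params <- c(params, prefixNames(init, nm))
      buffers <- c(buffers, prefixNames(initBNBuffers(ch[l]), nm))
    }
  }
  for (l in seq(levels - 1L, 1L)) {
    params[[paste0("d", l, "up.W")]] <- heInit(ch[l] * 8L, ch[l + 1L])
    params[[paste0("d", l, "up.b")]] <- numeric(ch[l])
    for (blk in c("c1", "c2")) {
      nm <- paste0("d", l, blk)
      init <- initConvBN(if (blk == "c1") 2L * ch[l] else ch[l], ch[l], 3L)
      params <- c(params, prefixNames(init, nm))
      buffers <- c(buffers, prefixNames(initBNBuffers(ch[l]), nm))
    }
  }
  params[["out.W"]] <- heInit(1L, ch[1])
  params[["out.b"]] <- numeric(1)
  new("UncoverModel",
      arch = list(inDim = inDim, levels = as.integer(levels),
                  baseChannels = as.integer(baseChannels), channels = ch),
      params = params, buffers = buffers, lossTrace = numeric(0))
}

#' Analytic U-Net shape trace
#'
#' Spatial sizes at every level for a given architecture, without running the
#' network: the bottleneck shape is the input halved `levels - 1` times and
#' the output shape equals the input shape.
#'
#' @param model an [UncoverModel-class]
#' @return list with `levelDims` (matrix, one row per level), `bottleneck`
#'   and `outDim`
#' @export
unetShapes <- function(model) {
  L <- model@arch$levels
  dims <- t(vapply(seq_len(L),
                   function(l) model@arch$inDim %/% as.integer(2^(l - 1)),
                   integer(3)))
  list(levelDims = dims, bottleneck = dims[L, ], outDim = model@arch$inDim)
}

# forward pass on a (1, X, Y, Z, N) batch; returns logits, caches, buffers
unetForwardBatch <- function(model, x, training) {
  L <- model@arch$levels
  params <- model@params
  buffers <- model@buffers
  caches <- list()
  acts <- vector("list", L - 1L)
  cur <- x
  for (l in seq_len(L)) {
    for (blk in c("c1", "c2")) {
      nm <- paste0("e", l, blk)
      r <- convBlockF(cur, pget(params, nm), bget(buffers, nm), 3L, 1L, 1L,
                      training)
      cur <- r$y
      caches[[nm]] <- r$cache
      buffers <- bset(buffers, nm, r$buf)
    }
    if (l < L) {
      acts[[l]] <- cur
      mp <- cpp_maxpool3d_fwd(cur)
      caches[[paste0("pool", l)]] <- list(idx = mp$idx, xdim = dim(cur))
      cur <- mp$y
    }
  }
  for (l in seq(L - 1L, 1L)) {
    nm <- paste0("d", l, "up")
    caches[[nm]] <- cur
    cur <- cpp_convt3d_fwd(cur, params[[paste0(nm, ".W")]],
                           params[[paste0(nm, ".b")]])
    skip <- acts[[l]]
    cc <- dim(cur)[1]; sc <- dim(skip)[1]
    comb <- array(0, c(cc + sc, dim(cur)[-1]))
    comb[seq_len(cc), , , , ] <- cur
    comb[cc + seq_len(sc), , , , ] <- skip
    caches[[paste0("cat", l)]] <- c(cc, sc)
    cur <- comb
    for (blk in c("c1", "c2")) {
      nm <- paste0("d", l, blk)
      r <- convBlockF(cur, pget(params, nm), bget(buffers, nm), 3L, 1L, 1L,
                      training)
      cur <- r$y
      caches[[nm]] <- r$cache
      buffers <- bset(buffers, nm, r$buf)
    }
  }
  caches$outx <- cur
  z <- cpp_conv3d_fwd(cur, params[["out.W"]], params[["out.b"]], 1L, 1L, 0L)
  list(z = z, caches = caches, buffers = buffers)
}

# backward pass; dz: gradient at the logits. Returns flat grads (and dx when
# requested, for the end-to-end regime this is not needed — dz already chains).
unetBackwardBatch <- function(model, caches, dz) {
  L <- model@arch$levels
  params <- model@params
  grads <- list()
  ob <- cpp_conv3d_bwd(caches$outx, params[["out.W"]], dz, 1L, 1L, 0L, TRUE)
  grads[["out.W"]] <- ob$dW
  grads[["out.b"]] <- ob$db
  dcur <- ob$dx
  dskips <- vector("list", L - 1L)
  for (l in seq_len(L - 1L)) {
    for (blk in c("c2", "c1")) {
      nm <- paste0("d", l, blk)
      bb <- convBlockB(caches[[nm]], pget(params, nm), dcur, TRUE)
      grads <- c(grads, prefixNames(bb$grads, nm))
      dcur <- bb$dx
    }
    cs <- caches[[paste0("cat", l)]]
    dup <- dcur[seq_len(cs[1]), , , , , drop = FALSE]
    dskips[[l]] <- dcur[cs[1] + seq_len(cs[2]), , , , , drop = FALSE]
    nm <- paste0("d", l, "up")
    ub <- cpp_convt3d_bwd(caches[[nm]], params[[paste0(nm, ".W")]], dup, TRUE)
    grads[[paste0(nm, ".W")]] <- ub$dW
    grads[[paste0(nm, ".b")]] <- ub$db
    dcur <- ub$dx
  }
  for (l in seq(L, 1L)) {
    if (l < L) {
      pc <- caches[[paste0("pool", l)]]
      dcur <- cpp_maxpool3d_bwd(pc$idx, dcur, pc$xdim) + dskips[[l]]
    }
    for (blk in c("c2", "c1")) {
      nm <- paste0("e", l, blk)
      bb <- convBlockB(caches[[nm]], pget(params, nm), dcur,
                       !(l == 1L && blk == "c1"))
      grads <- c(grads, prefixNames(bb$grads, nm))
      if (!is.null(bb$dx)) dcur <- bb$dx
    }
  }
  grads
}

#' Apply the uncovering network
#'
#' Evaluation-mode forward pass (batch-norm running statistics, no dropout):
#' maps a binary occupancy volume of a covered patient to the per-voxel
#' probability volume of the uncovered patient.
#'
#' @param model a trained [UncoverModel-class]
#' @param grid a [VoxelGrid], a 3D array, or a list of either
#' @return probability volume(s) in \[0,1\]: a [VoxelGrid] for [VoxelGrid]
#'   input, 3D array for array input, list for list input
#' @export
unetApply <- function(model, grid) {
  if (is.list(grid) && !is(grid, "VoxelGrid")) {
    arrs <- lapply(grid, function(g) if (is(g, "VoxelGrid")) g@data else g)
    out <- vector("list", length(arrs))
    bs <- 8L
    for (i0 in seq(1L, length(arrs), by = bs)) {
      ii <- i0:min(i0 + bs - 1L, length(arrs))
      x <- stackGrids(arrs[ii])
      z <- unetForwardBatch(model, x, training = FALSE)$z
      for (j in seq_along(ii)) out[[ii[j]]] <- sigmoid(z[1, , , , j])
    }
    return(out)
  }
  isVG <- is(grid, "VoxelGrid")
  arr <- if (isVG) grid@data else grid
  if (!identical(dim(arr), as.integer(model@arch$inDim)))
    uwStop("grid shape does not match the model's input shape",
           "contractError")
  x <- stackGrids(list(arr))
  z <- unetForwardBatch(model, x, training = FALSE)$z
  p <- sigmoid(z[1, , , , 1])
  if (isVG) VoxelGrid(p, grid@spec, meta = list(kind = "probability")) else p
}
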