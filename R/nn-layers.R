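#' @include AllClasses.R
NULL

# Minimal volumetric NN engine. Tensors are R arrays with dim
# (C, X, Y, Z, N), channels fastest; conv/pool kernels live in src/.
# Parameters are flat named lists of arrays; each layer contributes entries
# under a unique prefix. All stochastic choices go through the R RNG.

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.1

heInit <- function(nout, fanin) {
  matrix(rnorm(nout * fanin, sd = sqrt(2 / fanin)), nout, fanin)
}

# ---- conv + batchnorm + ReLU blocks -----------------------------------------

# parameter initialization for one conv-bn block
initConvBN <- function(cin, cout, k) {
  list(W = heInit(cout, cin * k^3), b = numeric(cout),
       gamma = rep(1, cout), beta = numeric(cout))
}

initBNBuffers <- function(cout) list(rm = numeric(cout), rv = rep(1, cout))

bnForward <- function(x, gamma, beta, buf, training) {
  C <- dim(x)[1]
  xm <- matrix(x, C)
  if (training) {
    mu <- rowMeans(xm)
    v <- rowMeans(xm * xm) - mu * mu
    v[v < 0] <- 0
    buf$rm <- (1 - BN_MOMENTUM) * buf$rm + BN_MOMENTUM * mu
    buf$rv <- (1 - BN_MOMENTUM) * buf$rv + BN_MOMENTUM * v
  } else {
    mu <- buf$rm
    v <- buf$rv
  }
  istd <- 1 / sqrt(v + BN_EPS)
  xhat <- (xm - mu) * istd
  y <- gamma * xhat + beta
  dim(y) <- dim(x)
  list(y = y, cache = list(xhat = xhat, istd = istd, gamma = gamma,
                           dims = dim(x), training = training),
       buf = buf)
}

bnBackward <- function(cache, dy) {
  C <- cache$dims[1]
  dym <- matrix(dy, C)
  dgamma <- rowSums(dym * cache$xhat)
  dbeta <- rowSums(dym)
  dxh <- dym * cache$gamma
  if (cache$training) {
    m1 <- rowMeans(dxh)
    m2 <- rowMeans(dxh * cache$xhat)
    dx <- cache$istd * (dxh - m1 - cache$xhat * m2)
  } else {
    dx <- cache$istd * dxh
  }
  dim(dx) <- cache$dims
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

# forward through conv(k, s, p) -> BN -> ReLU; P: params sublist, buf: buffers
convBlockF <- function(x, P, buf, k, s, p, training) {
  z <- cpp_conv3d_fwd(x, P$W, P$b, k, s, p)
  bn <- bnForward(z, P$gamma, P$beta, buf, training)
  y <- bn$y
  mask <- y > 0
  y[!mask] <- 0
  list(y = y, buf = bn$buf,
       cache = list(x = x, bn = bn$cache, mask = mask, k = k, s = s, p = p))
}

convBlockB <- function(cache, P, dy, needDx) {
  dy[!cache$mask] <- 0
  bb <- bnBackward(cache$bn, dy)
  cb <- cpp_conv3d_bwd(cache$x, P$W, bb$dx, cache$k, cache$s, cache$p, needDx)
  list(grads = list(W = cb$dW, b = cb$db, gamma = bb$dgamma, beta = bb$dbeta),
       dx = if (needDx) cb$dx else NULL)
}

# ---- dense / dropout ---------------------------------------------------------

denseF <- function(x, W, b) {            # x: features x batch
  list(y = W %*% x + b, cache = x)
}

denseB <- function(cache, W, dy) {
  list(dW = dy %*% t(cache), db = rowSums(dy), dx = t(W) %*% dy)
}

dropoutF <- function(x, rate, training) {
  if (!training || rate <= 0) return(list(y = x, mask = NULL))
  keep <- 1 - rate
  mask <- matrix(rbinom(length(x), 1, keep), nrow(x)) / keep
  list(y = x * mask, mask = mask)
}

sigmoid <- function(z) 1 / (1 + exp(-z))

# numerically fused binary cross-entropy on logits; grad wrt logits
bceWithLogits <- function(z, t) {
  n <- length(z)
  loss <- sum(pmax(z, 0) - z * t + log1p(exp(-abs(z)))) / n
  grad <- (sigmoid(z) - t) / n
  dim(grad) <- dim(z)
  list(loss = loss, grad = grad)
}

# ---- optimizer ---------------------------------------------------------------

adamInit <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0)
}

adamStep <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                     eps = 1e-8) {
  state$t <- state$t + 1
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

# learning rate at a given epoch under the /10 milestone schedule
lrAt <- function(config, epoch) {
  config@lr * 0.1^sum(epoch > config@milestones)
}

# stack a list of 3D arrays into a (1, X, Y, Z, N) batch tensor
stackGrids <- function(grids) {
  d <- dim(grids[[1]])
  x <- array(0, c(1, d, length(grids)))
  for (i in seq_along(grids)) x[1, , , , i] <- grids[[i]]
  x
}

# flatten nested grad name mapping: prefix param names of a block
prefixNames <- function(lst, prefix) {
  names(lst) <- paste0(prefix, ".", names(lst))
  lst
}

#' Checksum of a model's parameters
#'
#' Byte-level MD5 of the serialized parameter list; used to verify the freeze
#' contract (two-stage weight training must leave the uncovering network's
#' parameters bitwise unchanged).
#'
#' @param model an [UncoverModel-class] or [WeightModel-class]
#' @return MD5 string
#' @export
paramChecksum <- function(model) {
  con <- rawConnection(raw(0), "wb")
  on.exit(close(con))
  serialize(model@params, con)
  # md5 of the serialized bytes via a temp file (tools::md5sum is file-based)
  f <- tempfile()
  writeBin(rawConnectionValue(con), f)
  on.exit(unlink(f), add = TRUE)
  unname(tools::md5sum(f))
}
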