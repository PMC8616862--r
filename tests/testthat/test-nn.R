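# Analytic gradients of the full networks are validated against central
# finite differences on miniature architectures.

numGradParam <- function(lossFn, params, nm, idx, eps = 1e-5) {
  vapply(idx, function(i) {
    p1 <- params; p2 <- params
    p1[[nm]][i] <- p1[[nm]][i] + eps
    p2[[nm]][i] <- p2[[nm]][i] - eps
    (lossFn(p1) - lossFn(p2)) / (2 * eps)
  }, numeric(1))
}

test_that("U-Net parameter gradients match finite differences", {
  set.seed(20)
  un <- buildUnet(inDim = c(8, 8, 8), levels = 3, baseChannels = 2)
  x <- array(rbinom(8^3 * 2, 1, 0.2), c(1, 8, 8, 8, 2))
  t <- array(rbinom(8^3 * 2, 1, 0.2), c(1, 8, 8, 8, 2))
  fwdLoss <- function(params) {
    m <- un; m@params <- params
    z <- uncoverweight:::unetForwardBatch(m, x, training = TRUE)$z
    uncoverweight:::bceWithLogits(z, t)$loss
  }
  fw <- uncoverweight:::unetForwardBatch(un, x, training = TRUE)
  l <- uncoverweight:::bceWithLogits(fw$z, t)
  grads <- uncoverweight:::unetBackwardBatch(un, fw$caches, l$grad)
  expect_setequal(names(grads), names(un@params))
  set.seed(21)
  for (nm in c("e1c1.W", "e2c2.gamma", "e3c1.b", "d2up.W", "d1c2.W",
               "d2c1.beta", "out.W", "out.b")) {
    idx <- sample(seq_along(un@params[[nm]]),
                  min(4, length(un@params[[nm]])))
    expect_equal(as.numeric(grads[[nm]][idx]),
                 numGradParam(fwdLoss, un@params, nm, idx),
                 tolerance = 1e-5, label = nm)
  }
})

test_that("weight-CNN parameter and input gradients match finite differences", {
  set.seed(22)
  cnn <- buildWeightCnn(inDim = c(16, 16, 16), channels = c(3L, 4L),
                        headWidth = 5L, dropout = 0, mode = "regression")
  x <- array(runif(16^3 * 2), c(1, 16, 16, 16, 2))
  y <- c(2.5, -1)
  fwdLoss <- function(params) {
    m <- cnn; m@params <- params
    out <- uncoverweight:::cnnForwardBatch(m, x, training = TRUE)$out
    mean((out - y)^2)
  }
  fw <- uncoverweight:::cnnForwardBatch(cnn, x, training = TRUE)
  dout <- 2 * (fw$out - y) / length(y)
  bw <- uncoverweight:::cnnBackwardBatch(cnn, fw$caches, dout, needDx = TRUE)
  set.seed(23)
  for (nm in c("conv1.W", "conv2.gamma", "conv2.W", "fc1.W", "fc2.W",
               "fc2.b")) {
    idx <- sample(seq_along(cnn@params[[nm]]),
                  min(4, length(cnn@params[[nm]])))
    expect_equal(as.numeric(bw$grads[[nm]][idx]),
                 numGradParam(fwdLoss, cnn@params, nm, idx),
                 tolerance = 1e-5, label = nm)
  }
  # input gradient (needed by the end-to-end regime)
  lossX <- function(xx) {
    out <- uncoverweight:::cnnForwardBatch(cnn, xx, training = TRUE)$out
    mean((out - y)^2)
  }
  set.seed(24)
  ii <- sample(length(x), 6)
  num <- vapply(ii, function(i) {
    x1 <- x; x2 <- x
    x1[i] <- x1[i] + 1e-5; x2[i] <- x2[i] - 1e-5
    (lossX(x1) - lossX(x2)) / 2e-5
  }, numeric(1))
  expect_equal(as.numeric(bw$dx[ii]), num, tolerance = 1e-5)
})

test_that("batch normalization normalizes in training and uses buffers in eval", {
  set.seed(25)
  x <- array(rnorm(3 * 4 * 4 * 2 * 5, mean = 3, sd = 2), c(3, 4, 4, 2, 5))
  buf <- list(rm = numeric(3), rv = rep(1, 3))
  r <- uncoverweight:::bnForward(x, rep(1, 3), numeric(3), buf,
                                 training = TRUE)
  ym <- matrix(r$y, 3)
  expect_equal(rowMeans(ym), numeric(3), tolerance = 1e-9)
  expect_equal(apply(ym, 1, function(v) mean(v^2)), rep(1, 3),
               tolerance = 1e-3)
  # eval mode reproduces the affine transform of the running statistics
  r2 <- uncoverweight:::bnForward(x, rep(1, 3), numeric(3), r$buf,
                                  training = FALSE)
  manual <- (matrix(x, 3) - r$buf$rm) / sqrt(r$buf$rv + 1e-5)
  expect_equal(matrix(r2$y, 3), manual, tolerance = 1e-12)
})

test_that("the fused logit loss equals probability-space cross-entropy", {
  set.seed(26)
  z <- array(rnorm(64, sd = 3), c(1, 4, 4, 4, 1))
  t <- array(rbinom(64, 1, 0.4), c(1, 4, 4, 4, 1))
  fused <- uncoverweight:::bceWithLogits(z, t)$loss
  expect_equal(fused, ceLoss(1 / (1 + exp(-z)), t), tolerance = 1e-9)
})

test_that("training is exactly repeatable under a fixed seed", {
  set.seed(27)
  pairs <- lapply(1:6, function(i) list(
    x = array(rbinom(8^3, 1, 0.2), c(8, 8, 8)),
    y = array(rbinom(8^3, 1, 0.2), c(8, 8, 8))))
  cfg <- unetTrainConfig(epochs = 2L, milestones = integer(0),
                         batchSize = 2L, seed = 99L)
  m1 <- trainUncover(pairs, cfg, levels = 3L, baseChannels = 2L)
  m2 <- trainUncover(pairs, cfg, levels = 3L, baseChannels = 2L)
  expect_identical(m1@lossTrace, m2@lossTrace)
  expect_identical(m1@params, m2@params)
})

test_that("the milestone schedule divides the learning rate by ten", {
  cfg <- TrainConfig(epochs = 120L, milestones = c(60L, 100L))
  expect_equal(uncoverweight:::lrAt(cfg, 1), 0.001)
  expect_equal(uncoverweight:::lrAt(cfg, 60), 0.001)
  expect_equal(uncoverweight:::lrAt(cfg, 61), 1e-4)
  expect_equal(uncoverweight:::lrAt(cfg, 101), 1e-5)
})
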