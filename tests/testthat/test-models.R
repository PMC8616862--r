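test_that("the U-Net preserves shape and produces probabilities", {
  set.seed(30)
  un <- buildUnet(inDim = c(48, 96, 32), levels = 4, baseChannels = 4)
  sh <- unetShapes(un)
  expect_equal(sh$bottleneck, c(6L, 12L, 4L))
  expect_equal(sh$outDim, c(48L, 96L, 32L))
  x <- randomBinaryGrid(c(48, 96, 32), 0.05)
  p <- unetApply(un, x)
  expect_equal(dim(p), c(48L, 96L, 32L))
  expect_true(all(p >= 0 & p <= 1))
  # input resolution not divisible by 2^(levels-1) is rejected
  expect_error(buildUnet(inDim = c(44, 96, 32), levels = 4),
               class = "constructionError")
})

test_that("the weight CNN downsamples by 2^5 to 64 channels on the full grid", {
  set.seed(31)
  cnn <- buildWeightCnn(inDim = c(48, 96, 32))
  sh <- weightCnnShapes(cnn)
  expect_equal(sh$downsampleFactor, 32L)
  expect_equal(sh$finalChannels, 64L)
  expect_equal(sh$finalSpatial, c(1L, 3L, 1L))
  expect_equal(sh$flatFeatures, 192L)
  # too-small input cannot survive the halvings
  expect_error(buildWeightCnn(inDim = c(24, 48, 16)),
               class = "constructionError")
})

test_that("loss functions reproduce closed forms and hand computations", {
  t <- randomBinaryGrid(c(3, 3, 3), 0.5)
  # prediction equal to the clipped target
  eps <- 1e-7
  p <- t * (1 - eps) + (1 - t) * eps
  expect_lt(ceLoss(p, t), 1e-6)
  # uniform 0.5 prediction: ln 2 per voxel for any binary target
  expect_equal(ceLoss(array(0.5, dim(t)), t), log(2), tolerance = 1e-12)
  # two-voxel hand computation
  expect_equal(ceLoss(array(c(0.8, 0.4), c(2, 1, 1)),
                      array(c(1, 0), c(2, 1, 1))),
               -(log(0.8) + log(0.6)) / 2, tolerance = 1e-12)
  expect_error(ceLoss(array(0.5, c(2, 2, 2)), array(0, c(2, 2, 1))),
               class = "contractError")

  expect_equal(mseLoss(c(72, 59), c(70, 60)), 2.5)
  expect_equal(mseLoss(70, 70), 0)
  expect_equal(mseLoss(c(71, 61, 51), c(70, 60, 50)), 1)  # constant offset
  expect_error(mseLoss(1:3, 1:2), class = "contractError")

  # random tensors against the independent scalar-loop oracles
  set.seed(32)
  for (rep in 1:5) {
    pr <- array(runif(64), c(4, 4, 4))
    tg <- randomBinaryGrid(c(4, 4, 4), 0.5)
    expect_equal(ceLoss(pr, tg), oracleCE(pr, tg), tolerance = 1e-9)
    a <- rnorm(10); b <- rnorm(10)
    expect_equal(mseLoss(a, b), oracleMSE(a, b), tolerance = 1e-12)
  }
})

test_that("zero-epoch training returns the initialized model unchanged", {
  set.seed(33)
  pairs <- lapply(1:4, function(i) list(
    x = randomBinaryGrid(c(8, 8, 8), 0.2),
    y = randomBinaryGrid(c(8, 8, 8), 0.2)))
  cfg <- TrainConfig(epochs = 0L, seed = 50L)
  m <- trainUncover(pairs, cfg, levels = 3L, baseChannels = 2L)
  set.seed(50L)
  ref <- buildUnet(inDim = c(8, 8, 8), levels = 3L, baseChannels = 2L)
  ref@params[["out.b"]] <-
    m@params[["out.b"]]  # data-dependent bias init
  expect_identical(m@params[names(ref@params) != "out.b"],
                   ref@params[names(ref@params) != "out.b"])
  expect_length(m@lossTrace, 0)
  expect_error(trainUncover(list(), cfg), class = "contractError")
})

test_that("the U-Net learns the identity uncovering task", {
  set.seed(34)
  grids <- lapply(1:24, function(i) {
    g <- array(0, c(16, 32, 16))
    cx <- sample(4:12, 1); cy <- sample(8:24, 1)
    g[cx + (-3:3), cy + (-5:5), 2:6] <- 1
    g
  })
  pairs <- lapply(grids[1:20], function(g) list(x = g, y = g))
  un <- trainUncover(pairs,
                     unetTrainConfig(epochs = 15L, milestones = 12L,
                                     batchSize = 4L, seed = 60L),
                     levels = 3L, baseChannels = 8L)
  d <- vapply(grids[21:24], function(g) {
    dice(g, (unetApply(un, g) > 0.5) * 1)
  }, numeric(1))
  expect_gt(mean(d), 0.95)
})

test_that("two-stage training freezes the uncovering parameters bitwise", {
  set.seed(35)
  grids <- lapply(1:8, function(i) randomBinaryGrid(c(8, 8, 8), 0.2))
  w <- runif(8, 50, 90)
  un <- buildUnet(inDim = c(8, 8, 8), levels = 3L, baseChannels = 2L)
  ck <- paramChecksum(un)
  m <- trainWeight(grids, w, "two-stage", uncover = un,
                   config = TrainConfig(epochs = 2L, batchSize = 4L,
                                        seed = 61L),
                   channels = c(2L, 3L), headWidth = 4L, dropout = 0)
  expect_identical(paramChecksum(un), ck)
  expect_s4_class(m, "WeightModel")
  # two-stage without an uncovering model is a contract violation
  expect_error(trainWeight(grids, w, "two-stage", uncover = NULL,
                           config = TrainConfig(epochs = 1L, seed = 1L),
                           channels = c(2L, 3L), headWidth = 4L),
               class = "contractError")
})

test_that("the plain regressor learns a volume-proportional weight", {
  set.seed(36)
  n <- 80
  grids <- lapply(1:n, function(i) {
    # solid boxes of widely varying size: weight proportional to volume
    g <- array(0, c(16, 32, 16))
    hx <- sample(2:7, 1); hy <- sample(3:14, 1); hz <- sample(2:7, 1)
    g[(8 - hx):(8 + hx), (16 - hy):(16 + hy), (8 - hz):(8 + hz)] <- 1
    g
  })
  w <- vapply(grids, function(g) 0.01 * sum(g), numeric(1))
  tr <- 1:64; te <- 65:80
  m <- trainWeight(grids[tr], w[tr], "plain",
                   config = weightTrainConfig(epochs = 60L,
                                              milestones = c(45L, 55L),
                                              batchSize = 16L, seed = 62L),
                   channels = c(8L, 16L, 32L), headWidth = 16L, dropout = 0)
  pred <- weightCnnApply(m, grids[te])
  expect_lt(mae(pred, w[te]), 2)
  expect_gt(sd(w[te]), 6)   # the task is far from trivial
})

test_that("prediction exposes the intermediate uncovered volume", {
  set.seed(37)
  un <- buildUnet(inDim = c(8, 8, 8), levels = 3L, baseChannels = 2L)
  cnn <- buildWeightCnn(inDim = c(8, 8, 8), channels = c(2L, 3L),
                        headWidth = 4L, dropout = 0)
  g <- randomBinaryGrid(c(8, 8, 8), 0.2)
  r1 <- predictWeight(g, un, cnn)
  expect_length(r1$weight, 1)
  expect_true(is.finite(r1$weight))
  expect_equal(dim(r1$uncovered), c(8L, 8L, 8L))
  expect_true(all(r1$uncovered >= 0 & r1$uncovered <= 1))
  # inference determinism
  r2 <- predictWeight(g, un, cnn)
  expect_identical(r1$weight, r2$weight)
  expect_identical(r1$uncovered, r2$uncovered)
  # grid-spec mismatch
  expect_error(predictWeight(randomBinaryGrid(c(16, 16, 16), 0.2), un, cnn),
               class = "contractError")
})

test_that("end-to-end training updates both parameter sets", {
  set.seed(38)
  grids <- lapply(1:8, function(i) randomBinaryGrid(c(8, 8, 8), 0.2))
  w <- runif(8, 50, 90)
  r <- trainWeight(grids, w, "e2e",
                   config = TrainConfig(epochs = 2L, batchSize = 4L,
                                        seed = 63L),
                   channels = c(2L, 3L), headWidth = 4L, dropout = 0,
                   unetLevels = 3L, unetBaseChannels = 2L)
  expect_s4_class(r$weight, "WeightModel")
  expect_s4_class(r$uncover, "UncoverModel")
  set.seed(63L)
  # a freshly built U-Net with the same seed differs after e2e training
  fresh <- buildUnet(inDim = c(8, 8, 8), levels = 3L, baseChannels = 2L)
  expect_false(identical(r$uncover@params[["e1c1.W"]],
                         fresh@params[["e1c1.W"]]))
  expect_true(all(is.finite(r$weight@lossTrace)))
})

test_that("the cover classifier separates and routes deterministically", {
  set.seed(39)
  covered <- lapply(1:10, function(i) randomBinaryGrid(c(8, 8, 8), 0.45))
  uncov <- lapply(1:10, function(i) randomBinaryGrid(c(8, 8, 8), 0.05))
  grids <- c(covered, uncov)
  lab <- rep(c(TRUE, FALSE), each = 10)
  cl <- trainCoverClassifier(grids, lab,
                             config = classifierTrainConfig(batchSize = 4L,
                                                            seed = 64L),
                             channels = c(2L, 3L), headWidth = 4L,
                             dropout = 0)
  pred <- classifyCover(cl, grids)
  expect_equal(pred, ifelse(lab, "covered", "uncovered"))
  # probability exactly 0.5 resolves to "uncovered"
  tie <- cl
  tie@params[["fc2.W"]][] <- 0
  tie@params[["fc2.b"]] <- 0
  expect_equal(unname(classifyCover(tie, grids[[1]])), "uncovered")
  # a single-class training set is rejected
  expect_error(trainCoverClassifier(covered, rep(TRUE, 10),
                                    config = classifierTrainConfig(seed = 1L),
                                    channels = c(2L, 3L), headWidth = 4L),
               class = "contractError")
})
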