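test_that("body weight is the exact analytic ellipsoid volume", {
  prim <- data.frame(part = "torso", cx = 0, cy = 1, cz = 0.12,
                     ax = 0.2, ay = 0.6, az = 0.12)
  b <- BodySpec(prim, density = 1000)
  expect_equal(b@weight, 4 / 3 * pi * 0.2 * 0.6 * 0.12 * 1000,
               tolerance = 1e-12)

  # cubic scaling: doubling all semi-axes multiplies weight by 8
  prim2 <- prim
  prim2[, c("ax", "ay", "az")] <- 2 * prim2[, c("ax", "ay", "az")]
  prim2$cz <- prim2$az
  b2 <- BodySpec(prim2, density = 1000)
  expect_equal(b2@weight, 8 * b@weight, tolerance = 1e-12)
})

test_that("sampled bodies satisfy the weight and geometry invariants", {
  p <- SceneParams(seed = 1L)
  set.seed(7)
  for (i in 1:25) {
    b <- sampleBody(p)
    pr <- b@primitives
    # weight conservation: density x analytic union volume, 1e-9 relative
    vol <- sum(4 / 3 * pi * pr$ax * pr$ay * pr$az)
    expect_equal(b@weight, p@density * vol, tolerance = 1e-9)
    # all primitives above the bed plane
    expect_true(all(pr$cz - pr$az >= -1e-9))
    # pairwise disjoint (sufficient separating-axis certificate)
    expect_lte(uncoverweight:::worstPairDeficit(pr, margin = 0)$deficit, 0)
    # weight within the configured range
    expect_gte(b@weight, p@weightRange[1])
    expect_lte(b@weight, p@weightRange[2])
  }
})

test_that("the sampled weight population matches the configured range", {
  p <- SceneParams(seed = 1L)
  set.seed(11)
  ws <- vapply(seq_len(1000), function(i) sampleBody(p)@weight, numeric(1))
  expect_gte(min(ws), 43.7)
  expect_lte(max(ws), 105.1)
  expect_gt(sd(ws), 10)           # spread is wide by construction
  expect_equal(mean(ws), 68, tolerance = 0.05)
})

test_that("rendering puts the bed plane at the camera height", {
  p <- tinySceneParams(noise = 0)
  set.seed(2)
  b <- sampleBody(p, position = "supine")
  f <- renderDepth(b, p, covered = FALSE)
  D <- depthValues(f)
  # pixels over the bed but far from the body see exactly the deck
  k <- intrinsics(f)
  # foot-end bed corner region (body is centered, deck is clear there)
  v <- round(k[["fy"]] * (0.03 - p@bedExtent[2] / 2) / p@camHeight + k[["cy"]])
  u <- round(k[["fx"]] * 0 / p@camHeight + k[["cx"]])
  expect_equal(D[v + 1, u + 1], p@camHeight, tolerance = 1e-12)
})

test_that("the body apex depth matches the ray-intersection prediction", {
  p <- tinySceneParams(noise = 0)
  prim <- data.frame(part = "blob", cx = 0, cy = p@bedExtent[2] / 2,
                     cz = 0.15, ax = 0.25, ay = 0.3, az = 0.15)
  b <- BodySpec(prim, position = "supine", density = 1000)
  f <- renderDepth(b, p, covered = FALSE)
  k <- intrinsics(f)
  # apex projects to the principal point (body centered under the camera)
  d <- depthValues(f)[round(k[["cy"]]) + 1, round(k[["cx"]]) + 1]
  expect_equal(d, p@camHeight - (prim$cz + prim$az), tolerance = 2e-3)
})

test_that("covered and uncovered renders differ only under the blanket", {
  p <- tinySceneParams(noise = 0)
  set.seed(5)
  b <- sampleBody(p, position = "supine")
  fu <- renderDepth(b, p, covered = FALSE)
  fc <- renderDepth(b, p, covered = TRUE)
  Du <- depthValues(fu); Dc <- depthValues(fc)
  # coverage region ends at coverageFraction x bed length from the foot end
  k <- intrinsics(fu)
  yEnd <- p@coverageFraction * p@bedExtent[2] - p@bedExtent[2] / 2
  # conservative pixel bound for the region boundary (nearest surface)
  vEnd <- round(k[["fy"]] * yEnd / (p@camHeight - 0.6) + k[["cy"]])
  outside <- (vEnd + 3):nrow(Du)
  expect_identical(Du[outside, ], Dc[outside, ])
  # inside the region the cover lies at or above the body, so per-pixel
  # depth never grows — up to z-buffer discretization at silhouettes, where
  # perspective shifts which surface sample lands in a pixel
  inside <- 1:(vEnd - 3)
  valid <- Du[inside, ] > 0 & Dc[inside, ] > 0
  violating <- Dc[inside, ][valid] > Du[inside, ][valid] + 1e-9
  expect_lt(mean(violating), 0.01)
  expect_gt(sum(Dc[inside, ][valid] < Du[inside, ][valid] - 1e-6), 0)
})

test_that("the blanket drape lifts, bridges and preserves as specified", {
  p <- SceneParams(hfRes = 0.01)
  # constant-height body: covered = body + thickness over the region
  hf <- matrix(0.2, 60, 100)
  cov <- matrix(TRUE, 60, 100)
  d <- drapeBlanket(hf, p, thickness = 0.003, coverage = cov)
  core <- d[20:40, 30:70]
  expect_equal(core, matrix(0.203, nrow(core), ncol(core)),
               tolerance = 1e-9)

  # two parallel ridges with a narrow gap: the drape bridges the hollow
  hf2 <- matrix(0, 80, 80)
  hf2[, 30:34] <- 0.25
  hf2[, 40:44] <- 0.25   # 5 cm gap < 16 cm closing diameter
  d2 <- drapeBlanket(hf2, p, thickness = 0.003,
                     coverage = matrix(TRUE, 80, 80))
  expect_true(all(d2[20:60, 35:39] >= 0.25))
  # oracle: the drape dominates the grayscale closing everywhere
  r <- round(p@closingRadius / p@hfRes)
  closed <- as.matrix(EBImage::closing(hf2,
                                       EBImage::makeBrush(2 * r + 1, "disc")))
  expect_true(all(d2 >= closed - 1e-9))

  # cover monotonicity: covered height >= body height + thickness
  expect_true(all(d2 >= hf2 + 0.003 - 1e-12))

  # zero coverage: height field unchanged
  expect_identical(drapeBlanket(hf2, p, coverage = matrix(FALSE, 80, 80)),
                   hf2)
})

test_that("dataset generation is deterministic and correctly paired", {
  p <- tinySceneParams(seed = 9L)
  d1 <- generateDataset(2, p)
  d2 <- generateDataset(2, p)
  expect_identical(datasetManifest(d1), datasetManifest(d2))
  expect_identical(depthValues(d1[[1]]@frameCovered),
                   depthValues(d2[[1]]@frameCovered))
  expect_identical(depthValues(d1[[2]]@frameUncovered),
                   depthValues(d2[[2]]@frameUncovered))

  ds <- generateDataset(5, p)
  man <- datasetManifest(ds)
  expect_equal(man$id, 1:5)
  expect_equal(length(unique(man$weight)), 5)
  expect_true(all(man$cover %in% c("thin", "thick")))

  # pairing: the uncovered frame equals the covered frame away from the
  # blanket (shared rendering and shared noise realization)
  s <- ds[[1]]
  Du <- depthValues(s@frameUncovered); Dc <- depthValues(s@frameCovered)
  expect_gt(mean(Du == Dc), 0.4)
  expect_true(any(Du != Dc))
})
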