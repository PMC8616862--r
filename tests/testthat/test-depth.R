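test_that("pinhole back-projection follows the camera model", {
  D <- matrix(0, 3, 5)
  D[2, 2] <- 2       # pixel (u=1, v=1) = principal point
  D[2, 4] <- 1       # pixel (u=3, v=1) = one focal length right of center
  D[1, 1] <- 0       # invalid pixel emits no point
  f <- DepthFrame(D, c(fx = 2, fy = 2, cx = 1, cy = 1))
  cl <- depthToCloud(f)
  P <- cloudCoords(cl)
  expect_equal(nrow(P), 2)
  expect_equal(P[P[, 3] == 2, ], c(x = 0, y = 0, z = 2))   # principal ray
  expect_equal(P[P[, 3] == 1, ], c(x = 1, y = 0, z = 1))   # (u-cx) z / fx
})

test_that("an all-invalid frame yields an empty cloud with a warning", {
  f <- DepthFrame(matrix(0, 4, 4), c(fx = 1, fy = 1, cx = 1.5, cy = 1.5))
  expect_warning(cl <- depthToCloud(f), "no valid pixels")
  expect_equal(nPoints(cl), 0)
})

test_that("back-projection and re-projection round-trip the depth frame", {
  p <- tinySceneParams(noise = 0)
  set.seed(4)
  f <- renderDepth(sampleBody(p), p)
  cl <- depthToCloud(f)
  f2 <- projectCloud(cl, intrinsics(f), dim(depthValues(f)))
  expect_lt(max(abs(depthValues(f2) - depthValues(f))), 1e-6)
})

test_that("bed extraction thresholds depth and keeps the largest cluster", {
  p <- tinySceneParams(noise = 0)
  set.seed(4)
  f <- renderDepth(sampleBody(p), p)
  cl <- depthToCloud(f)
  interval <- c(0.3, p@camHeight + p@bedHeight / 2)
  bed <- extractBedRegion(cl, interval)
  # floor points (around the bed, one bed height deeper) are gone
  expect_lt(max(cloudCoords(bed)[, 3]), p@camHeight + p@bedHeight / 2)
  expect_lt(nPoints(bed), nPoints(cl))
  # subset preservation and idempotence
  key <- function(x) paste(round(cloudCoords(x), 9)[, 1],
                           round(cloudCoords(x), 9)[, 2],
                           round(cloudCoords(x), 9)[, 3])
  expect_true(all(key(bed) %in% key(cl)))
  expect_equal(cloudCoords(extractBedRegion(bed, interval)),
               cloudCoords(bed))
  # empty scene
  empty <- PointCloud(matrix(numeric(0), 0, 3))
  expect_error(extractBedRegion(empty, interval),
               class = "emptySceneError")
})

test_that("bed extraction clusters lattice-free clouds on 3D grid cells", {
  set.seed(8)
  main <- cbind(runif(400, -0.3, 0.3), runif(400, -0.5, 0.5),
                runif(400, 1.9, 2.0))
  outlier <- cbind(runif(20, 2, 2.1), runif(20, 2, 2.1), runif(20, 1.9, 2.0))
  cl <- PointCloud(rbind(main, outlier))
  bed <- extractBedRegion(cl, c(1.5, 2.5), minCluster = 100L)
  expect_equal(nPoints(bed), 400)
  expect_true(all(cloudCoords(bed)[, 1] < 1))
})

test_that("patient segmentation removes the bed plane and everything below", {
  set.seed(6)
  g <- expand.grid(x = seq(-0.4, 0.4, by = 0.02),
                   y = seq(-0.8, 0.8, by = 0.02))
  plane <- cbind(g$x, g$y, 2.0)
  box <- cbind(runif(150, -0.1, 0.1), runif(150, -0.3, 0.3),
               runif(150, 1.88, 1.90))   # 10 cm above the plane
  below <- cbind(runif(30, -0.2, 0.2), runif(30, -0.2, 0.2),
                 runif(30, 2.05, 2.10))  # behind the plane
  cl <- PointCloud(rbind(plane, box, below))
  pat <- segmentPatientFromBed(cl, tol = 0.02)
  expect_equal(nPoints(pat), 150)
  expect_true(all(cloudCoords(pat)[, 3] < 1.95))

  # a cloud entirely on the plane leaves nothing
  expect_equal(nPoints(segmentPatientFromBed(PointCloud(plane))), 0)

  # a structureless blob has no dominant plane
  blob <- matrix(rnorm(900, sd = 0.3), ncol = 3)
  expect_error(segmentPatientFromBed(PointCloud(blob)),
               class = "segmentationError")
})

test_that("mean centering is an exact isometry onto the origin", {
  cl <- PointCloud(matrix(c(0, 0, 0, 2, 0, 0), 2, 3, byrow = TRUE))
  cc <- meanCenter(cl)
  expect_equal(unname(cloudCoords(cc)),
               matrix(c(-1, 0, 0, 1, 0, 0), 2, 3, byrow = TRUE))

  set.seed(3)
  P <- matrix(rnorm(60, sd = 2), ncol = 3)
  cc <- meanCenter(PointCloud(P))
  expect_lt(sqrt(sum(colMeans(cloudCoords(cc))^2)), 1e-9)
  expect_lt(max(abs(dist(cloudCoords(cc)) - dist(P))), 1e-9)
  # idempotence
  cc2 <- meanCenter(cc)
  expect_equal(cloudCoords(cc2), cloudCoords(cc), tolerance = 1e-12)

  expect_error(meanCenter(PointCloud(matrix(numeric(0), 0, 3))),
               class = "contractError")
})
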