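test_that("mae and mre follow their definitions", {
  expect_equal(mae(c(70, 60), c(70, 60)), 0)
  expect_equal(mre(c(70, 60), c(70, 60)), 0)
  expect_equal(mae(c(71, 63), c(70, 60)), 2)        # errors {1, 3}
  expect_equal(mre(74.8, 68.0), 10)                 # 6.8 / 68 = 10%
  expect_error(mae(numeric(0), numeric(0)), class = "contractError")
  expect_error(mre(c(1, 2), c(1, -2)), class = "contractError")
})

test_that("dice matches its set formula and rejects empty references", {
  d <- c(4L, 4L, 4L)
  A <- array(0, d); A[1:4, 1, 1] <- 1                   # |A| = 4
  B <- array(0, d); B[2:4, 1, 1] <- 1; B[1, 2:4, 2] <- 1  # |B| = 6, n = 3
  expect_equal(dice(A, B), 0.6)
  expect_equal(dice(A, A), 1)
  expect_equal(dice(A, B), dice(B, A))
  disj <- array(0, d); disj[4, 4, 4] <- 1
  expect_equal(dice(A, disj), 0)
  expect_error(dice(array(0, d), A), class = "contractError")
  expect_error(dice(A, array(0.5, d)), class = "contractError")
})

test_that("surface distance uses anisotropic voxel sizes", {
  vox <- voxelSizes(GridSpec())   # y edge is exactly 2.5 cm
  d <- c(5L, 5L, 5L)
  A <- array(0, d); A[3, 2, 3] <- 1
  B <- array(0, d); B[3, 3, 3] <- 1   # one voxel apart along y
  expect_equal(avgSurfaceDistance(A, B, vox), 25)
  expect_equal(avgSurfaceDistance(A, A, vox), 0)
  expect_error(avgSurfaceDistance(A, array(0, d), vox),
               class = "distanceUndefinedError")
  # symmetric variant averages the two directions
  C2 <- array(0, d); C2[3, 3, 3] <- 1; C2[3, 4, 3] <- 1
  expect_equal(avgSurfaceDistance(A, C2, vox, symmetric = TRUE),
               (avgSurfaceDistance(A, C2, vox) +
                  avgSurfaceDistance(C2, A, vox)) / 2)
})

test_that("surface distance agrees with the brute-force oracle", {
  set.seed(13)
  vox <- c(0.035, 0.025, 0.022)
  for (rep in 1:10) {
    A <- randomBinaryGrid(c(5, 5, 5), 0.3)
    B <- randomBinaryGrid(c(5, 5, 5), 0.3)
    if (sum(A) == 0 || sum(B) == 0) next
    expect_equal(avgSurfaceDistance(A, B, vox), oracleASD(A, B, vox),
                 tolerance = 1e-9)
  }
})

test_that("the cumulative error curve is a valid empirical CDF", {
  c1 <- cumulativeErrorCurve(2)
  expect_equal(c1$fraction[c1$threshold == 2], 1)
  c2 <- cumulativeErrorCurve(c(1, 2, 3))
  expect_equal(c2$fraction[c2$threshold == 2], 2 / 3)
  set.seed(14)
  c3 <- cumulativeErrorCurve(rexp(50))
  expect_true(all(diff(c3$fraction) >= 0))
  expect_true(all(diff(c3$threshold) >= 0))
  expect_equal(tail(c3$fraction, 1), 1)
})

test_that("per-subject averaging is the arithmetic mean per subject", {
  expect_equal(unname(averageOverFrames(70, "a")), 70)
  expect_equal(unname(averageOverFrames(c(70, 72, 68), rep("a", 3))), 70)
  avg <- averageOverFrames(c(60, 62, 80), c("a", "a", "b"))
  expect_equal(avg[["a"]], 61)
  expect_equal(avg[["b"]], 80)
})

test_that("averaging several unbiased frames reduces the subject MAE", {
  set.seed(15)
  nSubj <- 200; nFrames <- 6
  noise <- matrix(rnorm(nSubj * nFrames, sd = 5), nSubj)
  perFrameMAE <- rowMeans(abs(noise))
  avgMAE <- abs(rowMeans(noise))
  tt <- t.test(avgMAE, perFrameMAE, paired = TRUE, alternative = "less")
  expect_lt(tt$p.value, 0.01)
})
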