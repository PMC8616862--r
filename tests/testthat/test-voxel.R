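test_that("the default grid matches the published cuboid geometry", {
  spec <- GridSpec()
  expect_equal(spec@extent, c(1.7, 2.4, 0.7))
  expect_equal(spec@dims, c(48L, 96L, 32L))
  expect_equal(round(100 * voxelSizes(spec), 1), c(3.5, 2.5, 2.2))
})

test_that("voxelization marks exactly the voxels containing points", {
  spec <- GridSpec(extent = c(1, 1, 1), dims = c(4L, 4L, 4L))
  # empty cloud: all-zero grid
  g <- voxelize(PointCloud(matrix(numeric(0), 0, 3)), spec)
  expect_equal(sum(occupancy(g)), 0)
  # a single point at the cuboid center occupies exactly one voxel
  g <- voxelize(PointCloud(matrix(0, 1, 3)), spec)
  expect_equal(sum(occupancy(g)), 1)
  expect_equal(occupancy(g)[3, 3, 3], 1)   # half-open: 0 falls in bin 3

  # random clouds match the independent per-point binning oracle
  set.seed(10)
  for (rep in 1:5) {
    P <- matrix(runif(150, -0.7, 0.7), ncol = 3)
    g <- voxelize(PointCloud(P), spec)
    expect_identical(occupancy(g),
                     oracleVoxelize(P, spec@extent, spec@dims, spec@origin))
    # discarded points are tallied
    out <- sum(apply(P, 1, function(q) any(q < -0.5 | q >= 0.5)))
    expect_equal(g@meta$nOutside, out)
    # occupied count never exceeds the point count
    expect_lte(sum(occupancy(g)), nrow(P))
  }
})

test_that("half-open binning discards the cuboid's maximum face", {
  spec <- GridSpec(extent = c(1, 1, 1), dims = c(2L, 2L, 2L))
  onMax <- voxelize(PointCloud(matrix(c(0.5, 0, 0), 1, 3)), spec)
  expect_equal(sum(occupancy(onMax)), 0)
  expect_equal(onMax@meta$nOutside, 1L)
  onMin <- voxelize(PointCloud(matrix(c(-0.5, -0.5, -0.5), 1, 3)), spec)
  expect_equal(occupancy(onMin)[1, 1, 1], 1)
})

test_that("voxel centers invert voxelization exactly", {
  spec <- GridSpec(extent = c(1.2, 0.8, 0.6), dims = c(6L, 8L, 4L))
  # all-zero grid: empty cloud
  empty <- VoxelGrid(array(0, spec@dims), spec)
  expect_equal(nPoints(voxelCenters(empty)), 0)
  # single occupied voxel at its center coordinates
  occ <- array(0, spec@dims); occ[2, 5, 3] <- 1
  ctr <- cloudCoords(voxelCenters(VoxelGrid(occ, spec)))
  e <- voxelSizes(spec)
  expect_equal(unname(ctr[1, ]),
               spec@origin + (c(2, 5, 3) - 0.5) * e, tolerance = 1e-12)

  # fixed point: voxelize(voxelCenters(G)) == G for random binary grids
  set.seed(11)
  for (rep in 1:10) {
    G <- VoxelGrid(randomBinaryGrid(spec@dims, 0.25), spec)
    back <- voxelize(voxelCenters(G), spec)
    expect_identical(occupancy(back), occupancy(G))
  }
})

test_that("adding points never clears an occupied voxel", {
  spec <- GridSpec(extent = c(1, 1, 1), dims = c(5L, 5L, 5L))
  set.seed(12)
  P1 <- matrix(runif(90, -0.45, 0.45), ncol = 3)
  P2 <- rbind(P1, matrix(runif(60, -0.45, 0.45), ncol = 3))
  g1 <- occupancy(voxelize(PointCloud(P1), spec))
  g2 <- occupancy(voxelize(PointCloud(P2), spec))
  expect_true(all(g2 >= g1))
})
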