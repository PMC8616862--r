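#' @include AllClasses.R
NULL

#' Voxelize a point cloud
#'
#' Deterministic binary voxelization into the fixed cuboid of a [GridSpec]: a
#' voxel takes the value 1 iff it contains at least one point. Voxels are
#' half-open intervals \[lo, hi) per axis, so a point exactly on the cuboid's
#' maximum face is out of bounds. Points outside the cuboid are discarded and
#' tallied in the result's `meta$nOutside`. Intended for mean-centered clouds
#' with the cuboid centered on the origin (the default `GridSpec()`).
#'
#' @param cloud a [PointCloud] (an empty cloud yields an all-zero grid)
#' @param spec a [GridSpec]
#' @return a binary [VoxelGrid]
#' @export
voxelize <- function(cloud, spec = GridSpec()) {
  stopifnot(is(cloud, "PointCloud"), is(spec, "GridSpec"))
  dims <- spec@dims
  occ <- array(0, dims)
  P <- cloud@coords
  nOutside <- 0L
  if (nrow(P) > 0) {
    e <- voxelSizes(spec)
    ix <- floor((P[, 1] - spec@origin[1]) / e[1])
    iy <- floor((P[, 2] - spec@origin[2]) / e[2])
    iz <- floor((P[, 3] - spec@origin[3]) / e[3])
    inb <- ix >= 0 & ix < dims[1] & iy >= 0 & iy < dims[2] &
      iz >= 0 & iz < dims[3]
    nOutside <- sum(!inb)
    occ[cbind(ix[inb] + 1, iy[inb] + 1, iz[inb] + 1)] <- 1
  }
  VoxelGrid(occ, spec, meta = list(nOutside = nOutside))
}

#' Voxel centers of an occupied grid
#'
#' One point per occupied voxel, at the voxel center. Inverse of
#' [voxelize()] in the sense that `voxelize(voxelCenters(g), gridSpec(g))`
#' reproduces any binary grid exactly.
#'
#' @param grid a binary [VoxelGrid]
#' @return a [PointCloud] of voxel centers
#' @export
voxelCenters <- function(grid) {
  stopifnot(is(grid, "VoxelGrid"))
  if (!isBinaryGrid(grid))
    uwStop("voxelCenters requires a binary grid", "contractError")
  idx <- which(grid@data == 1, arr.ind = TRUE)
  e <- voxelSizes(grid@spec)
  pts <- sweep(sweep(idx - 0.5, 2, e, "*"), 2, grid@spec@origin, "+")
  PointCloud(pts)
}
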