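#' @include AllClasses.R
NULL

#' Back-project a depth frame to a point cloud
#'
#' Pinhole back-projection: each valid pixel (u, v) with depth z yields the
#' point (x, y, z) with x = (u - cx) z / fx and y = (v - cy) z / fy, in the
#' camera frame (x right, y down, z along the optical axis; depth is z, not
#' ray length). Invalid pixels (depth 0) are skipped; an all-invalid frame
#' yields an empty cloud with a warning.
#'
#' @param frame a [DepthFrame]
#' @return a [PointCloud]; its `meta` records the source pixel lattice
#'   (`pixelIndex`: matrix of 1-based (row, col); `imageDim`) for
#'   lattice-based clustering and re-projection
#' @export
depthToCloud <- function(frame) {
  stopifnot(is(frame, "DepthFrame"))
  D <- frame@depths
  ii <- which(D > 0, arr.ind = TRUE)
  if (nrow(ii) == 0) {
    warning("depth frame has no valid pixels; returning an empty cloud")
    return(PointCloud(matrix(numeric(0), 0, 3),
                      meta = c(frame@meta, list(imageDim = dim(D)))))
  }
  z <- D[ii]
  k <- frame@intrinsics
  u <- ii[, "col"] - 1  # 0-based pixel coordinates
  v <- ii[, "row"] - 1
  pts <- cbind(x = (u - k[["cx"]]) * z / k[["fx"]],
               y = (v - k[["cy"]]) * z / k[["fy"]],
               z = z)
  PointCloud(pts, meta = c(frame@meta,
                           list(pixelIndex = unname(ii), imageDim = dim(D))))
}

#' Re-project a point cloud to a depth frame
#'
#' Inverse of [depthToCloud()] for round-trip checks and visualization:
#' points are projected through the intrinsics, rounded to the nearest pixel
#' and z-buffered (nearest depth wins). Pixels receiving no point carry 0.
#'
#' @param cloud a [PointCloud]
#' @param intrinsics named numeric(4): fx, fy, cx, cy
#' @param imageDim integer(2): image rows, cols
#' @return a [DepthFrame]
#' @export
projectCloud <- function(cloud, intrinsics, imageDim) {
  P <- cloud@coords
  D <- matrix(0, imageDim[1], imageDim[2])
  if (nrow(P) == 0) return(DepthFrame(D, intrinsics))
  u <- round(intrinsics[["fx"]] * P[, 1] / P[, 3] + intrinsics[["cx"]])
  v <- round(intrinsics[["fy"]] * P[, 2] / P[, 3] + intrinsics[["cy"]])
  keep <- u >= 0 & u <= imageDim[2] - 1 & v >= 0 & v <= imageDim[1] - 1
  u <- u[keep]; v <- v[keep]; z <- P[keep, 3]
  ord <- order(z, decreasing = TRUE)
  D[cbind(v[ord] + 1, u[ord] + 1)] <- z[ord]
  DepthFrame(D, intrinsics)
}

#' Isolate the bed region of a scene cloud
#'
#' Depth thresholding followed by clustering: retains points whose depth (z)
#' lies inside `interval`, then keeps the largest spatial cluster. When the
#' cloud carries its source pixel lattice (clouds from [depthToCloud()]),
#' clusters are 8-connected components on the pixel lattice; otherwise
#' 26-connected components of occupied 5 cm grid cells. The result is always
#' a subset of the input.
#'
#' @param cloud a [PointCloud]
#' @param interval numeric(2) depth interval in m (e.g. camera distance to
#'   the floor minus a margin)
#' @param minCluster minimum size of an acceptable cluster
#' @return the bed-region [PointCloud]
#' @export
extractBedRegion <- function(cloud, interval, minCluster = 100L) {
  stopifnot(is(cloud, "PointCloud"))
  if (length(interval) != 2 || diff(interval) <= 0)
    uwStop("depth interval must be nonempty", "contractError")
  if (nPoints(cloud) == 0)
    uwStop("empty cloud: no bed region found", "emptySceneError")
  z <- cloud@coords[, 3]
  keep <- which(z >= interval[1] & z <= interval[2])
  if (length(keep) == 0)
    uwStop("no points inside the depth interval", "emptySceneError")
  if (!is.null(cloud@meta$pixelIndex)) {
    mask <- matrix(FALSE, cloud@meta$imageDim[1], cloud@meta$imageDim[2])
    px <- cloud@meta$pixelIndex[keep, , drop = FALSE]
    mask[px] <- TRUE
    lab <- cpp_label8(mask)
    labs <- lab[px]
  } else {
    cells <- matrix(as.integer(floor(cloud@coords[keep, , drop = FALSE] /
                                       0.05)), ncol = 3)
    labs <- cpp_label_cells(cells)
  }
  tab <- tabulate(labs)
  if (max(tab) < minCluster)
    uwStop("largest cluster below the minimum size", "emptySceneError")
  sel <- keep[labs == which.max(tab)]
  meta <- cloud@meta
  if (!is.null(meta$pixelIndex))
    meta$pixelIndex <- meta$pixelIndex[sel, , drop = FALSE]
  PointCloud(cloud@coords[sel, , drop = FALSE], meta = meta)
}

# least-squares plane through points: returns list(point, normal)
fitPlaneLS <- function(P) {
  ctr <- colMeans(P)
  sv <- svd(sweep(P, 2, ctr), nu = 0, nv = 3)
  list(point = ctr, normal = sv$v[, 3])
}

#' Segment the patient from the bed plane
#'
#' Robustly fits the dominant bed plane with RANSAC (refined by least squares
#' on the inliers) and removes both plane inliers and all points on the far
#' side of the plane (below the mattress surface, as seen from the camera).
#' What remains is the patient's volumetric surface, which is the supervision
#' target for the uncovering network.
#'
#' @param cloud a [PointCloud] containing a dominant planar support
#' @param tol plane-inlier tolerance in m
#' @param iterations number of RANSAC hypotheses
#' @param minInlierFrac minimum inlier fraction for an acceptable plane fit
#' @param seed RANSAC seed (local to this call; the global RNG state is
#'   restored on exit)
#' @return the patient [PointCloud]
#' @export
segmentPatientFromBed <- function(cloud, tol = 0.02, iterations = 1000L,
                                  minInlierFrac = 0.25, seed = 1L) {
  stopifnot(is(cloud, "PointCloud"))
  P <- cloud@coords
  n <- nrow(P)
  if (n < 10) uwStop("too few points for a plane fit", "segmentationError")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
         else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  best <- 0L; bestIdx <- NULL
  for (it in seq_len(iterations)) {
    s <- sample.int(n, 3L)
    v1 <- P[s[2], ] - P[s[1], ]; v2 <- P[s[3], ] - P[s[1], ]
    nrm <- c(v1[2] * v2[3] - v1[3] * v2[2],
             v1[3] * v2[1] - v1[1] * v2[3],
             v1[1] * v2[2] - v1[2] * v2[1])
    nn <- sqrt(sum(nrm^2))
    if (nn < 1e-12) next
    nrm <- nrm / nn
    d <- abs((P[, 1] - P[s[1], 1]) * nrm[1] + (P[, 2] - P[s[1], 2]) * nrm[2] +
               (P[, 3] - P[s[1], 3]) * nrm[3])
    cnt <- sum(d < tol)
    if (cnt > best) { best <- cnt; bestIdx <- which(d < tol) }
  }
  if (is.null(bestIdx) || best < max(3, minInlierFrac * n))
    uwStop("plane fit failed: too few inliers", "segmentationError")
  pl <- fitPlaneLS(P[bestIdx, , drop = FALSE])
  nrm <- pl$normal
  if (nrm[3] > 0) nrm <- -nrm  # orient toward the camera (-z)
  sd_ <- (P[, 1] - pl$point[1]) * nrm[1] + (P[, 2] - pl$point[2]) * nrm[2] +
    (P[, 3] - pl$point[3]) * nrm[3]
  keep <- which(sd_ > tol)  # strictly above the bed surface
  meta <- cloud@meta
  if (!is.null(meta$pixelIndex))
    meta$pixelIndex <- meta$pixelIndex[keep, , drop = FALSE]
  PointCloud(P[keep, , drop = FALSE], meta = meta)
}

#' Mean-center a point cloud
#'
#' Translates the cloud so its centroid is the origin (an isometry: pairwise
#' distances are preserved). The removed centroid is stored in
#' `meta$centroid`.
#'
#' @param cloud a nonempty [PointCloud]
#' @return the centered [PointCloud]
#' @export
meanCenter <- function(cloud) {
  stopifnot(is(cloud, "PointCloud"))
  if (nPoints(cloud) == 0)
    uwStop("cannot mean-center an empty cloud", "contractError")
  ctr <- colMeans(cloud@coords)
  meta <- cloud@meta
  meta$centroid <- unname(ctr)
  PointCloud(sweep(cloud@coords, 2, ctr), meta = meta)
}

#' Translate a point cloud
#'
#' Applies a fixed translation (used to center a pair's target cloud with the
#' input cloud's centroid so that input and supervision grids stay aligned).
#'
#' @param cloud a [PointCloud]
#' @param offset numeric(3) subtracted from every point
#' @return translated [PointCloud]
#' @export
translateCloud <- function(cloud, offset) {
  meta <- cloud@meta
  meta$centroid <- unname(offset)
  PointCloud(sweep(cloud@coords, 2, offset), meta = meta)
}
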