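#' @include AllClasses.R
NULL

asBinaryArray <- function(x, what) {
  a <- if (is(x, "VoxelGrid")) x@data else x
  if (!all(a %in% c(0, 1)))
    uwStop(paste(what, "must be a binary volume"), "contractError")
  a
}

#' Mean absolute error
#'
#' @param pred,truth equal-length nonempty numeric vectors (kg)
#' @return MAE in kg
#' @export
mae <- function(pred, truth) {
  if (length(pred) == 0 || length(pred) != length(truth))
    uwStop("pred and truth must be nonempty and of equal length",
           "contractError")
  mean(abs(pred - truth))
}

#' Mean relative error
#'
#' Mean of |error| / truth, as a percentage.
#'
#' @param pred,truth equal-length nonempty numeric vectors; truths > 0
#' @return MRE in percent
#' @export
mre <- function(pred, truth) {
  if (length(pred) == 0 || length(pred) != length(truth))
    uwStop("pred and truth must be nonempty and of equal length",
           "contractError")
  if (any(truth <= 0)) uwStop("truths must be positive", "contractError")
  100 * mean(abs(pred - truth) / truth)
}

#' Dice overlap between two binary volumes
#'
#' `2 |A n B| / (|A| + |B|)`. An empty reference volume is an error (it
#' indicates an upstream failure rather than a definable overlap).
#'
#' @param a reference binary volume ([VoxelGrid] or array), nonempty
#' @param b comparison binary volume of the same shape
#' @return Dice coefficient in \[0, 1\]
#' @export
dice <- function(a, b) {
  A <- asBinaryArray(a, "reference")
  B <- asBinaryArray(b, "comparison")
  if (!identical(dim(A), dim(B)))
    uwStop("volume shapes differ", "contractError")
  na <- sum(A)
  if (na == 0) uwStop("empty reference volume", "contractError")
  2 * sum(A * B) / (na + sum(B))
}

# occupied voxels with at least one unoccupied 6-neighbor (the grid boundary
# counts as unoccupied); returns the surface mask
surfaceMask <- function(occ) {
  d <- dim(occ)
  pad <- array(0, d + 2L)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- occ
  interior <-
    pad[1:d[1], 2:(d[2] + 1), 2:(d[3] + 1)] *
    pad[3:(d[1] + 2), 2:(d[2] + 1), 2:(d[3] + 1)] *
    pad[2:(d[1] + 1), 1:d[2], 2:(d[3] + 1)] *
    pad[2:(d[1] + 1), 3:(d[2] + 2), 2:(d[3] + 1)] *
    pad[2:(d[1] + 1), 2:(d[2] + 1), 1:d[3]] *
    pad[2:(d[1] + 1), 2:(d[2] + 1), 3:(d[3] + 2)]
  occ == 1 & interior == 0
}

surfacePoints <- function(occ, vox) {
  idx <- which(surfaceMask(occ), arr.ind = TRUE)
  sweep(idx - 0.5, 2, vox, "*")
}

#' Average surface distance between two binary volumes
#'
#' Directed by default: the mean, over the target volume's surface voxel
#' centers, of the Euclidean distance (using the anisotropic voxel edge
#' lengths) to the nearest surface voxel center of the prediction. Surfaces
#' are occupied voxels with at least one unoccupied 6-neighbor; the grid
#' border counts as unoccupied. `symmetric = TRUE` averages the two directed
#' distances.
#'
#' @param target,pred nonempty binary volumes of one shape ([VoxelGrid] or
#'   array)
#' @param voxelSizes numeric(3) voxel edge lengths in meters; taken from the
#'   grid spec when `target` is a [VoxelGrid]
#' @param symmetric average both directions?
#' @return distance in mm
#' @export
avgSurfaceDistance <- function(target, pred, voxelSizes = NULL,
                               symmetric = FALSE) {
  if (is.null(voxelSizes)) {
    if (is(target, "VoxelGrid")) voxelSizes <- voxelSizes(target)
    else uwStop("voxelSizes required for array input", "contractError")
  }
  A <- asBinaryArray(target, "target")
  B <- asBinaryArray(pred, "prediction")
  if (!identical(dim(A), dim(B)))
    uwStop("volume shapes differ", "contractError")
  if (sum(A) == 0 || sum(B) == 0)
    uwStop("surface distance undefined for an empty volume",
           "distanceUndefinedError")
  sa <- surfacePoints(A, voxelSizes)
  sb <- surfacePoints(B, voxelSizes)
  d <- cpp_mean_nn_dist(sa, sb)
  if (symmetric) d <- (d + cpp_mean_nn_dist(sb, sa)) / 2
  1000 * d
}

#' Cumulative distribution of absolute errors
#'
#' Empirical CDF samples of absolute errors: a nondecreasing step function
#' from 0 to 1 over the sorted errors.
#'
#' @param errors nonempty numeric vector of absolute errors (kg)
#' @return data.frame with columns `threshold` (kg) and `fraction`
#' @export
cumulativeErrorCurve <- function(errors) {
  if (length(errors) == 0) uwStop("no errors supplied", "contractError")
  e <- sort(abs(errors))
  data.frame(threshold = e, fraction = seq_along(e) / length(e))
}

#' Average per-frame estimates over subjects
#'
#' Statistical averaging of multiple weight estimates of the same subject
#' from different frames: the arithmetic mean per subject.
#'
#' @param estimates numeric vector of per-frame estimates (kg)
#' @param subjects subject id per estimate
#' @return named numeric vector, one mean estimate per subject
#' @export
averageOverFrames <- function(estimates, subjects) {
  if (length(estimates) == 0 || length(estimates) != length(subjects))
    uwStop("estimates and subjects must be nonempty and of equal length",
           "contractError")
  avg <- tapply(estimates, subjects, mean)
  setNames(as.numeric(avg), names(avg))
}
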