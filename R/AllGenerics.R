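#' @include uncoverweight-package.R
NULL

#' Accessor generics
#'
#' Small accessor generics for the core data classes: `occupancy()` returns
#' the voxel volume as a plain array, `gridSpec()` the grid geometry,
#' `cloudCoords()` the N x 3 coordinate matrix, `nPoints()` the number of
#' points, `depthValues()` the depth matrix in meters, `intrinsics()` the
#' pinhole parameters, `bodyWeight()` the ground-truth weight in kg and
#' `voxelSizes()` the per-axis voxel edge lengths in meters.
#'
#' @param x object
#' @return the slot value described above.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("occupancy", function(x) standardGeneric("occupancy"))

#' @rdname accessors
#' @export
setGeneric("gridSpec", function(x) standardGeneric("gridSpec"))

#' @rdname accessors
#' @export
setGeneric("cloudCoords", function(x) standardGeneric("cloudCoords"))

#' @rdname accessors
#' @export
setGeneric("nPoints", function(x) standardGeneric("nPoints"))

#' @rdname accessors
#' @export
setGeneric("depthValues", function(x) standardGeneric("depthValues"))

#' @rdname accessors
#' @export
setGeneric("intrinsics", function(x) standardGeneric("intrinsics"))

#' @rdname accessors
#' @export
setGeneric("bodyWeight", function(x) standardGeneric("bodyWeight"))

#' @rdname accessors
#' @export
setGeneric("voxelSizes", function(x) standardGeneric("voxelSizes"))
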