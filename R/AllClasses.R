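#' @include AllGenerics.R
NULL

# structured error helper: all package errors carry a condition class so
# callers/tests can distinguish configuration, data and contract failures
uwStop <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "uncoverweightError")))
}

## ---- GridSpec ---------------------------------------------------------------

#' Voxel grid geometry
#'
#' `GridSpec` describes the fixed cuboid that point clouds are voxelized into:
#' its metric extent, the number of voxels per axis, and the position of its
#' minimum corner. The default is a 1.7 m x 2.4 m x 0.7 m cuboid discretized
#' into 48 x 96 x 32 voxels (edge lengths ~3.5 cm x 2.5 cm x 2.2 cm), centered
#' on the origin so that it covers mean-centered in-bed clouds: x across the
#' bed, y along the bed (the 2.4 m axis), z vertical.
#'
#' @slot extent numeric(3), cuboid side lengths in meters
#' @slot dims integer(3), voxel counts per axis
#' @slot origin numeric(3), minimum corner in meters
#' @export
setClass("GridSpec", representation(
  extent = "numeric", dims = "integer", origin = "numeric"
))

setValidity("GridSpec", function(object) {
  if (length(object@extent) != 3 || any(!is.finite(object@extent)) ||
      any(object@extent <= 0))
    return("extent must be 3 positive finite numbers")
  if (length(object@dims) != 3 || any(object@dims < 1L))
    return("dims must be 3 positive integers")
  if (length(object@origin) != 3 || any(!is.finite(object@origin)))
    return("origin must be 3 finite numbers")
  TRUE
})

#' @param extent,dims,origin see slot descriptions
#' @rdname GridSpec-class
#' @export
GridSpec <- function(extent = c(1.7, 2.4, 0.7), dims = c(48L, 96L, 32L),
                     origin = -extent / 2) {
  new("GridSpec", extent = as.numeric(extent), dims = as.integer(dims),
      origin = as.numeric(origin))
}

#' @rdname accessors
#' @export
setMethod("voxelSizes", "GridSpec", function(x) x@extent / x@dims)

setMethod("show", "GridSpec", function(object) {
  cat(sprintf("GridSpec: %s m cuboid, %s voxels (edges %s cm)\n",
              paste(object@extent, collapse = " x "),
              paste(object@dims, collapse = " x "),
              paste(round(100 * voxelSizes(object), 2), collapse = " x ")))
})

## ---- VoxelGrid --------------------------------------------------------------

#' Voxel occupancy volume
#'
#' A volume over a [GridSpec]: binary \{0,1\} occupancy for voxelized point
#' clouds, or real values in \[0,1\] for network outputs (per-voxel
#' probabilities). `meta` carries bookkeeping such as the number of points
#' that fell outside the cuboid during voxelization.
#'
#' @slot data 3D numeric array matching `dims(spec)`
#' @slot spec a [GridSpec]
#' @slot meta list of optional metadata
#' @export
setClass("VoxelGrid", representation(
  data = "array", spec = "GridSpec", meta = "list"
))

setValidity("VoxelGrid", function(object) {
  if (!identical(dim(object@data), as.integer(object@spec@dims)))
    return("data dimensions must match the grid spec")
  rng <- range(object@data)
  if (!all(is.finite(rng)) || rng[1] < 0 || rng[2] > 1)
    return("voxel values must lie in [0, 1]")
  TRUE
})

#' @param data,spec,meta see slot descriptions
#' @rdname VoxelGrid-class
#' @export
VoxelGrid <- function(data, spec, meta = list()) {
  new("VoxelGrid", data = data, spec = spec, meta = meta)
}

#' @rdname accessors
#' @export
setMethod("occupancy", "VoxelGrid", function(x) x@data)

#' @rdname accessors
#' @export
setMethod("gridSpec", "VoxelGrid", function(x) x@spec)

#' @rdname accessors
#' @export
setMethod("voxelSizes", "VoxelGrid", function(x) voxelSizes(x@spec))

#' Is a voxel grid strictly binary?
#' @param x a [VoxelGrid] or numeric array
#' @return logical
#' @export
isBinaryGrid <- function(x) {
  v <- if (is(x, "VoxelGrid")) x@data else x
  all(v %in% c(0, 1))
}

setMethod("show", "VoxelGrid", function(object) {
  kind <- if (isBinaryGrid(object)) "binary" else "probability"
  cat(sprintf("VoxelGrid (%s): %s voxels, %d occupied (>0.5)\n", kind,
              paste(dim(object@data), collapse = " x "),
              sum(object@data > 0.5)))
})

## ---- DepthFrame -------------------------------------------------------------

#' Metric depth frame
#'
#' A rectangular grid of depths in meters along the optical axis, with pinhole
#' intrinsics. Matrix rows index the image row v (y, pointing down), columns
#' the image column u (x, pointing right); pixel coordinates are 0-based.
#' Invalid pixels carry depth 0 and are never back-projected.
#'
#' @slot depths numeric matrix (rows = image rows), meters; 0 = invalid
#' @slot intrinsics named numeric(4): fx, fy, cx, cy in pixels
#' @slot meta list (subject / pose / position / cover labels etc.)
#' @export
setClass("DepthFrame", representation(
  depths = "matrix", intrinsics = "numeric", meta = "list"
))

setValidity("DepthFrame", function(object) {
  if (any(object@depths < 0, na.rm = TRUE) || any(!is.finite(object@depths)))
    return("depths must be finite and nonnegative (0 marks invalid pixels)")
  ks <- c("fx", "fy", "cx", "cy")
  if (!all(ks %in% names(object@intrinsics)))
    return("intrinsics must be named fx, fy, cx, cy")
  if (object@intrinsics[["fx"]] <= 0 || object@intrinsics[["fy"]] <= 0)
    return("focal lengths must be positive")
  TRUE
})

#' @param depths,intrinsics,meta see slot descriptions
#' @rdname DepthFrame-class
#' @export
DepthFrame <- function(depths, intrinsics, meta = list()) {
  new("DepthFrame", depths = depths,
      intrinsics = setNames(as.numeric(intrinsics[c("fx", "fy", "cx", "cy")]),
                            c("fx", "fy", "cx", "cy")),
      meta = meta)
}

#' @rdname accessors
#' @export
setMethod("depthValues", "DepthFrame", function(x) x@depths)

#' @rdname accessors
#' @export
setMethod("intrinsics", "DepthFrame", function(x) x@intrinsics)

setMethod("show", "DepthFrame", function(object) {
  v <- object@depths > 0
  cat(sprintf("DepthFrame %d x %d px, %.0f%% valid, depth range [%.3f, %.3f] m\n",
              nrow(object@depths), ncol(object@depths), 100 * mean(v),
              if (any(v)) min(object@depths[v]) else NA,
              if (any(v)) max(object@depths[v]) else NA))
})

## ---- PointCloud -------------------------------------------------------------

#' Metric 3D point cloud
#'
#' N points in the camera frame (x right, y down, z along the optical axis),
#' in meters. `meta` may carry subject / pose / position / cover labels, the
#' source pixel lattice (`pixelIndex`, `imageDim`) when the cloud came from a
#' depth frame, and the removed centroid after [meanCenter()].
#'
#' @slot coords N x 3 numeric matrix
#' @slot meta list
#' @export
setClass("PointCloud", representation(coords = "matrix", meta = "list"))

setValidity("PointCloud", function(object) {
  if (ncol(object@coords) != 3) return("coords must have 3 columns")
  if (nrow(object@coords) > 0 && any(!is.finite(object@coords)))
    return("coordinates must be finite")
  TRUE
})

#' @param coords,meta see slot descriptions
#' @rdname PointCloud-class
#' @export
PointCloud <- function(coords, meta = list()) {
  coords <- as.matrix(coords)
  if (length(coords) == 0) coords <- matrix(numeric(0), 0, 3)
  colnames(coords) <- c("x", "y", "z")
  new("PointCloud", coords = coords, meta = meta)
}

#' @rdname accessors
#' @export
setMethod("cloudCoords", "PointCloud", function(x) x@coords)

#' @rdname accessors
#' @export
setMethod("nPoints", "PointCloud", function(x) nrow(x@coords))

setMethod("show", "PointCloud", function(object) {
  cat(sprintf("PointCloud: %d points", nrow(object@coords)))
  if (!is.null(object@meta$cover)) cat(sprintf(", cover=%s", object@meta$cover))
  if (!is.null(object@meta$position))
    cat(sprintf(", position=%s", object@meta$position))
  cat("\n")
})

## ---- BodySpec ---------------------------------------------------------------

#' Primitive-based synthetic body
#'
#' A union of pairwise-disjoint axis-aligned ellipsoids (head, torso, pelvis
#' and four limb segments per side) lying above the bed plane (z = 0, z up).
#' Because the primitives are disjoint by construction, the body volume is the
#' exact sum of ellipsoid volumes and the ground-truth weight is analytic:
#' weight = density x total volume.
#'
#' @slot primitives data.frame with columns part, cx, cy, cz (centers, m),
#'   ax, ay, az (semi-axes, m)
#' @slot position "supine", "lateral-left" or "lateral-right"
#' @slot density kg/m^3
#' @slot weight kg (equals density x analytic volume)
#' @export
setClass("BodySpec", representation(
  primitives = "data.frame", position = "character",
  density = "numeric", weight = "numeric"
))

# exact union volume of disjoint ellipsoids
bodyVolume <- function(primitives) {
  sum(4 / 3 * pi * primitives$ax * primitives$ay * primitives$az)
}

setValidity("BodySpec", function(object) {
  p <- object@primitives
  need <- c("part", "cx", "cy", "cz", "ax", "ay", "az")
  if (!all(need %in% names(p))) return("primitives lack required columns")
  if (any(p$cz - p$az < -1e-9)) return("primitives must lie above the bed plane")
  w <- object@density * bodyVolume(p)
  if (abs(w - object@weight) > 1e-9 * max(1, abs(w)))
    return("weight must equal density x analytic union volume")
  TRUE
})

#' @param primitives,position,density,weight see slot descriptions
#' @rdname BodySpec-class
#' @export
BodySpec <- function(primitives, position = "supine", density = 1000,
                     weight = density * bodyVolume(primitives)) {
  new("BodySpec", primitives = primitives, position = position,
      density = density, weight = weight)
}

#' @rdname accessors
#' @export
setMethod("bodyWeight", "BodySpec", function(x) x@weight)

setMethod("show", "BodySpec", function(object) {
  cat(sprintf("BodySpec: %d primitives, %s, %.1f kg\n",
              nrow(object@primitives), object@position, object@weight))
})

## ---- SceneParams ------------------------------------------------------------

#' Synthetic in-bed scene parameters
#'
#' Geometry, sensor and population parameters of the scene simulator. The
#' defaults emulate a top-view consumer depth camera 2 m above a 1.0 m x 2.1 m
#' bed, a body-weight population with mean 68.0 kg and sd 12.7 kg truncated to
#' \[44.5, 104.5\] kg, cover material thicknesses of 1 mm (thin) and 3 mm
#' (thick), and additive Gaussian depth noise with sd 5 mm. `seed` fully
#' determines a generated dataset.
#'
#' @slot bedExtent numeric(2): bed width (x) and length (y), m
#' @slot bedHeight bed deck height above the floor, m
#' @slot camHeight camera height above the bed deck, m
#' @slot imageSize integer(2): image width, height in px
#' @slot focal numeric(2): fx, fy in px
#' @slot principal numeric(2): cx, cy in px (0-based pixel coordinates)
#' @slot thicknessThin,thicknessThick cover material thickness, m
#' @slot coverageFraction fraction of the bed length (from the foot end)
#'   covered by the blanket when rendered directly
#' @slot coverageRange range the per-sample coverage fraction is drawn from
#'   by [generateDataset()] (human-placed blankets vary in extent)
#' @slot closingRadius structuring-disk radius of the drape's morphological
#'   closing, m
#' @slot smoothSigma Gaussian smoothing sigma of the drape, m
#' @slot foldAmplitude amplitude (sd before rectification) of the drape's
#'   low-frequency fold field, m
#' @slot foldScale correlation length of the fold field, m
#' @slot hfRes height-field sampling resolution, m
#' @slot depthNoiseSd depth noise sd, m
#' @slot meanWeight,sdWeight,weightRange body-weight population, kg
#' @slot density body density, kg/m^3
#' @slot seed integer seed determining the dataset
#' @export
setClass("SceneParams", representation(
  bedExtent = "numeric", bedHeight = "numeric", camHeight = "numeric",
  imageSize = "integer", focal = "numeric", principal = "numeric",
  thicknessThin = "numeric", thicknessThick = "numeric",
  coverageFraction = "numeric", coverageRange = "numeric",
  closingRadius = "numeric", smoothSigma = "numeric",
  foldAmplitude = "numeric", foldScale = "numeric",
  hfRes = "numeric", depthNoiseSd = "numeric",
  meanWeight = "numeric", sdWeight = "numeric", weightRange = "numeric",
  density = "numeric", seed = "integer"
))

setValidity("SceneParams", function(object) {
  if (any(object@bedExtent <= 0) || object@bedHeight <= 0 ||
      object@camHeight <= 0)
    return("bed and camera geometry must be positive")
  if (any(object@focal <= 0)) return("focal lengths must be positive")
  if (object@thicknessThin <= 0 || object@thicknessThick <= 0)
    return("cover thicknesses must be positive")
  if (object@coverageFraction < 0 || object@coverageFraction > 1)
    return("coverageFraction must be in [0, 1]")
  if (length(object@coverageRange) != 2 ||
      any(object@coverageRange < 0 | object@coverageRange > 1) ||
      diff(object@coverageRange) < 0)
    return("coverageRange must be an increasing pair in [0, 1]")
  if (object@foldAmplitude < 0 || object@foldScale <= 0)
    return("fold field parameters must be nonnegative (scale positive)")
  if (object@hfRes <= 0) return("hfRes must be positive")
  if (object@depthNoiseSd < 0) return("depthNoiseSd must be nonnegative")
  if (object@sdWeight <= 0 || object@meanWeight <= 0)
    return("weight distribution parameters must be positive")
  if (diff(object@weightRange) <= 0) return("weightRange must be increasing")
  TRUE
})

#' @param ... slot overrides, see slot descriptions
#' @rdname SceneParams-class
#' @export
SceneParams <- function(...) {
  args <- list(...)
  defaults <- list(
    bedExtent = c(1.0, 2.1), bedHeight = 0.6, camHeight = 2.0,
    imageSize = c(112L, 224L), focal = c(160, 160), principal = NULL,
    thicknessThin = 0.001, thicknessThick = 0.003,
    coverageFraction = 0.72, coverageRange = c(0.55, 0.85),
    closingRadius = 0.08, smoothSigma = 0.03,
    foldAmplitude = 0.015, foldScale = 0.08,
    hfRes = 0.01, depthNoiseSd = 0.005,
    meanWeight = 68.0, sdWeight = 12.7, weightRange = c(44.5, 104.5),
    density = 1000, seed = 1L
  )
  bad <- setdiff(names(args), names(defaults))
  if (length(bad))
    uwStop(paste("unknown SceneParams fields:", paste(bad, collapse = ", ")),
           "configError")
  vals <- modifyList(defaults, args)
  if (is.null(vals$principal))
    vals$principal <- (as.numeric(vals$imageSize) - 1) / 2
  vals$imageSize <- as.integer(vals$imageSize)
  vals$seed <- as.integer(vals$seed)
  do.call(new, c(list(Class = "SceneParams"), vals))
}

setMethod("show", "SceneParams", function(object) {
  cat(sprintf(
    "SceneParams: bed %.1f x %.1f m, cam %.1f m, image %d x %d px, seed %d\n",
    object@bedExtent[1], object@bedExtent[2], object@camHeight,
    object@imageSize[1], object@imageSize[2], object@seed))
})

## ---- PairedSample -----------------------------------------------------------

#' Paired covered/uncovered training sample
#'
#' Two depth frames of the same body in an unchanged pose that differ only in
#' the cover condition, together with the ground-truth weight. Element of the
#' training set consumed by the uncovering network and the weight regressor.
#'
#' @slot id integer subject id
#' @slot body the generating [BodySpec]
#' @slot frameCovered,frameUncovered [DepthFrame]s
#' @slot weight kg
#' @slot position "supine", "lateral-left" or "lateral-right"
#' @slot cover "thin" or "thick"
#' @export
setClass("PairedSample", representation(
  id = "integer", body = "BodySpec",
  frameCovered = "DepthFrame", frameUncovered = "DepthFrame",
  weight = "numeric", position = "character", cover = "character"
))

#' @rdname accessors
#' @export
setMethod("bodyWeight", "PairedSample", function(x) x@weight)

setMethod("show", "PairedSample", function(object) {
  cat(sprintf("PairedSample #%d: %.1f kg, %s, %s cover\n", object@id,
              object@weight, object@position, object@cover))
})

## ---- TrainConfig ------------------------------------------------------------

#' Optimization schedule
#'
#' Learning-rate schedule and batching for the networks: ADAM with initial
#' learning rate `lr`, divided by 10 at each epoch in `milestones`. Default
#' schedules per network: the uncovering U-Net trains for 50 epochs with the
#' drop after epoch 30; the weight regressor for 120 epochs with drops at 60
#' and 100; the cover classifier for 10 epochs with drops at 5 and 8 — all at
#' lr 0.001 and batch size 16.
#'
#' @slot lr initial learning rate
#' @slot batchSize minibatch size
#' @slot epochs number of epochs
#' @slot milestones integer epochs after which lr is divided by 10
#' @slot seed RNG seed for init, shuffling and dropout
#' @export
setClass("TrainConfig", representation(
  lr = "numeric", batchSize = "integer", epochs = "integer",
  milestones = "integer", seed = "integer"
))

setValidity("TrainConfig", function(object) {
  if (object@lr <= 0) return("lr must be positive")
  if (object@batchSize < 1) return("batchSize must be >= 1")
  if (object@epochs < 0) return("epochs must be >= 0")
  if (length(object@milestones) && any(object@milestones >= object@epochs) &&
      object@epochs > 0)
    return("milestones must be smaller than the epoch count")
  TRUE
})

#' @param lr,batchSize,epochs,milestones,seed see slot descriptions
#' @rdname TrainConfig-class
#' @export
TrainConfig <- function(epochs, milestones = integer(0), lr = 0.001,
                        batchSize = 16L, seed = 1L) {
  new("TrainConfig", lr = lr, batchSize = as.integer(batchSize),
      epochs = as.integer(epochs), milestones = as.integer(milestones),
      seed = as.integer(seed))
}

#' @rdname TrainConfig-class
#' @export
unetTrainConfig <- function(epochs = 50L, milestones = 30L, ...)
  TrainConfig(epochs = epochs, milestones = milestones, ...)

#' @rdname TrainConfig-class
#' @export
weightTrainConfig <- function(epochs = 120L, milestones = c(60L, 100L), ...)
  TrainConfig(epochs = epochs, milestones = milestones, ...)

#' @rdname TrainConfig-class
#' @export
classifierTrainConfig <- function(epochs = 10L, milestones = c(5L, 8L), ...)
  TrainConfig(epochs = epochs, milestones = milestones, ...)

setMethod("show", "TrainConfig", function(object) {
  cat(sprintf(
    "TrainConfig: %d epochs, lr %g (/10 at %s), batch %d, seed %d\n",
    object@epochs, object@lr,
    if (length(object@milestones)) paste(object@milestones, collapse = ",")
    else "-", object@batchSize, object@seed))
})

## ---- models -----------------------------------------------------------------

#' Uncovering network (3D U-Net)
#'
#' Encoder/decoder volumetric network mapping a binary (h, w, d) occupancy
#' volume of a covered patient to a per-voxel probability volume of the
#' uncovered patient. `params` holds the learned tensors, `buffers` the
#' batch-norm running statistics, `lossTrace` the per-epoch training loss.
#'
#' @slot arch list: inDim, levels, baseChannels
#' @slot params named list of parameter arrays
#' @slot buffers named list of batch-norm running statistics
#' @slot lossTrace numeric per-epoch mean training loss
#' @export
setClass("UncoverModel", representation(
  arch = "list", params = "list", buffers = "list", lossTrace = "numeric"
))

setMethod("show", "UncoverModel", function(object) {
  cat(sprintf(
    "UncoverModel: 3D U-Net, input %s, %d levels, base %d channels, %s\n",
    paste(object@arch$inDim, collapse = "x"), object@arch$levels,
    object@arch$baseChannels,
    if (length(object@lossTrace)) sprintf("trained %d epochs",
                                          length(object@lossTrace))
    else "untrained"))
})

#' Weight regression / cover classification network (3D CNN)
#'
#' Compact 3D CNN that downsamples the input volume to a very low resolution
#' (stride-2 5x5x5 conv, then alternating 3x3x3 convs and 2x2x2 max pools)
#' before fully connected heads. In regression mode the single output neuron
#' has linear activation (kg); in classifier mode it is a logistic
#' cover-presence probability.
#'
#' @slot arch list: inDim, channels, headWidth, dropout, mode
#' @slot params,buffers,lossTrace as in [UncoverModel-class]
#' @export
setClass("WeightModel", representation(
  arch = "list", params = "list", buffers = "list", lossTrace = "numeric"
))

setMethod("show", "WeightModel", function(object) {
  cat(sprintf(
    "WeightModel (%s): input %s, channels %s, head %d, dropout %.2f, %s\n",
    object@arch$mode, paste(object@arch$inDim, collapse = "x"),
    paste(object@arch$channels, collapse = "-"), object@arch$headWidth,
    object@arch$dropout,
    if (length(object@lossTrace)) sprintf("trained %d epochs",
                                          length(object@lossTrace))
    else "untrained"))
})

## ---- EvalReport -------------------------------------------------------------

#' Stratified evaluation report
#'
#' Evaluation results stratified by cover condition (none / thin / thick) and
#' position (supine / lateral): MAE (kg) and MRE (%) per regression regime,
#' Dice and directed average surface distance (mm) for the uncovering network
#' with the no-model covered-vs-target reference ("initial" rows), with mean
#' and sd over training repetitions, plus cumulative-error curves.
#'
#' @slot table data.frame: method, metric, cover, position, mean, sd, n
#' @slot curves named list of cumulative-error data.frames
#' @slot repetitions integer
#' @export
setClass("EvalReport", representation(
  table = "data.frame", curves = "list", repetitions = "integer"
))

setMethod("show", "EvalReport", function(object) {
  cat(sprintf("EvalReport: %d repetitions\n", object@repetitions))
  print(object@table, row.names = FALSE, digits = 3)
})
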