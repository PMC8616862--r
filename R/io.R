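#' @include AllClasses.R depth.R
NULL

# ---- 16-bit grayscale PNG ----------------------------------------------------
# Depth maps are stored as 16-bit grayscale PNG with depth in millimeters
# (0 = invalid). Reading uses png::readPNG (which supports 16 bit); writing
# is implemented here (chunk layout + CRC32/Adler-32, deflate via
# memCompress) because png::writePNG only produces 8-bit output.

pngChunk <- function(type, data) {
  len <- length(data)
  lenBytes <- as.raw(c(bitwAnd(bitwShiftR(len, 24), 255),
                       bitwAnd(bitwShiftR(len, 16), 255),
                       bitwAnd(bitwShiftR(len, 8), 255),
                       bitwAnd(len, 255)))
  body <- c(charToRaw(type), data)
  crc <- cpp_crc32(body, 0)
  crcBytes <- as.raw(c(crc %/% 16777216, (crc %/% 65536) %% 256,
                       (crc %/% 256) %% 256, crc %% 256))
  c(lenBytes, body, crcBytes)
}

uint32be <- function(x) {
  as.raw(c(x %/% 16777216, (x %/% 65536) %% 256, (x %/% 256) %% 256,
           x %% 256))
}

#' Write a depth frame as 16-bit grayscale PNG
#'
#' Depth in millimeters (rounded; clamped to \[0, 65535\]); invalid pixels
#' (depth 0) stay 0.
#'
#' @param frame a [DepthFrame] or a depth matrix in meters
#' @param path output path
#' @return invisibly, the path
#' @export
writeDepthPNG <- function(frame, path) {
  D <- if (is(frame, "DepthFrame")) frame@depths else frame
  mm <- round(D * 1000)
  mm[mm < 0] <- 0; mm[mm > 65535] <- 65535
  H <- nrow(mm); W <- ncol(mm)
  # scanlines: filter byte 0 + big-endian uint16 per pixel
  sl <- matrix(as.raw(0), 1 + 2 * W, H)
  for (r in seq_len(H)) {
    v <- mm[r, ]
    px <- rbind(as.raw(v %/% 256), as.raw(v %% 256))
    sl[-1, r] <- as.raw(px)
  }
  rawData <- as.raw(sl)
  # memCompress(type = "gzip") emits a zlib stream (0x78 header + deflate +
  # Adler-32), which is exactly what IDAT requires
  idat <- memCompress(rawData, type = "gzip")
  stopifnot(idat[1] == as.raw(0x78))
  ihdr <- c(uint32be(W), uint32be(H),
            as.raw(c(16, 0, 0, 0, 0)))  # 16 bit, grayscale, no interlace
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x89, 0x50, 0x4e, 0x47, 0x0d, 0x0a, 0x1a, 0x0a)), con)
  writeBin(pngChunk("IHDR", ihdr), con)
  writeBin(pngChunk("IDAT", idat), con)
  writeBin(pngChunk("IEND", raw(0)), con)
  invisible(path)
}

#' Read a 16-bit grayscale depth PNG
#'
#' @param path PNG path (depth in mm)
#' @param intrinsics named numeric(4) fx, fy, cx, cy to attach
#' @param meta metadata list to attach
#' @return a [DepthFrame] with depths in meters
#' @export
readDepthPNG <- function(path, intrinsics = c(fx = 1, fy = 1, cx = 0,
                                              cy = 0),
                         meta = list()) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  DepthFrame(round(img * 65535) / 1000, intrinsics, meta = meta)
}

# ---- binary PLY --------------------------------------------------------------

#' Write a point cloud as binary little-endian PLY
#'
#' Vertex-only PLY with float32 x, y, z properties.
#'
#' @param cloud a [PointCloud]
#' @param path output path
#' @return invisibly, the path
#' @export
writePLY <- function(cloud, path) {
  n <- nPoints(cloud)
  con <- file(path, "wb")
  on.exit(close(con))
  header <- paste0(
    "ply\nformat binary_little_endian 1.0\n",
    "element vertex ", n, "\n",
    "property float x\nproperty float y\nproperty float z\n",
    "end_header\n")
  writeBin(charToRaw(header), con)
  if (n > 0)
    writeBin(as.numeric(t(cloud@coords)), con, size = 4, endian = "little")
  invisible(path)
}

#' Read a binary little-endian PLY point cloud
#'
#' Supports the vertex-only float32 x/y/z layout written by [writePLY()].
#'
#' @param path PLY path
#' @return a [PointCloud]
#' @export
readPLY <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  lines <- character(0)
  repeat {
    ch <- character(0)
    repeat {
      b <- readBin(con, "raw", 1)
      if (length(b) == 0) uwStop("truncated PLY header", "ioError")
      if (b == as.raw(10)) break
      ch <- c(ch, rawToChar(b))
    }
    line <- paste(ch, collapse = "")
    lines <- c(lines, line)
    if (line == "end_header") break
  }
  if (!any(grepl("^format binary_little_endian", lines)))
    uwStop("unsupported PLY format", "ioError")
  vline <- grep("^element vertex ", lines, value = TRUE)
  n <- as.integer(sub("^element vertex ", "", vline[1]))
  vals <- readBin(con, "numeric", n * 3, size = 4, endian = "little")
  PointCloud(matrix(vals, ncol = 3, byrow = TRUE))
}

# ---- NIfTI volumes -----------------------------------------------------------

#' Write a voxel volume as NIfTI
#'
#' Voxel edge lengths are stored in the header in millimeters.
#'
#' @param grid a [VoxelGrid]
#' @param path output path (.nii or .nii.gz)
#' @return invisibly, the path
#' @export
writeVolumeNifti <- function(grid, path) {
  img <- RNifti::asNifti(grid@data)
  RNifti::pixdim(img) <- 1000 * voxelSizes(grid)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI voxel volume
#'
#' @param path NIfTI path
#' @param spec optional [GridSpec]; reconstructed from the header voxel
#'   sizes (mm) when omitted, with the cuboid centered on the origin
#' @return a [VoxelGrid]
#' @export
readVolumeNifti <- function(path, spec = NULL) {
  img <- RNifti::readNifti(path)
  arr <- array(as.numeric(img), dim(img))
  if (is.null(spec)) {
    vox <- RNifti::pixdim(img)[seq_len(3)] / 1000
    extent <- vox * dim(arr)
    spec <- GridSpec(extent = extent, dims = dim(arr))
  }
  VoxelGrid(arr, spec)
}

# ---- datasets ----------------------------------------------------------------

sceneParamsToList <- function(params) {
  sn <- slotNames("SceneParams")
  setNames(lapply(sn, function(s) {
    v <- slot(params, s)
    if (is.integer(v)) as.integer(v) else as.numeric(v)
  }), sn)
}

#' Write / read scene parameters as YAML
#'
#' @param params a [SceneParams]
#' @param path YAML path
#' @return `writeSceneParams`: invisibly the path; `readSceneParams`: a
#'   [SceneParams]
#' @export
writeSceneParams <- function(params, path) {
  yaml::write_yaml(sceneParamsToList(params), path)
  invisible(path)
}

#' @rdname writeSceneParams
#' @export
readSceneParams <- function(path) {
  do.call(SceneParams, yaml::read_yaml(path))
}

#' Write a generated dataset to disk
#'
#' Per sample: covered and uncovered 16-bit depth PNGs (mm) and binary PLY
#' point clouds; one JSON manifest with subject id, pose position, cover
#' condition, weight, intrinsics and the body primitives; the scene
#' parameters as YAML.
#'
#' @param samples list of [PairedSample-class]
#' @param dir output directory (created)
#' @param params the generating [SceneParams]
#' @return invisibly, the manifest path
#' @export
writeDataset <- function(samples, dir, params) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  entries <- lapply(samples, function(s) {
    base <- sprintf("s%03d", s@id)
    writeDepthPNG(s@frameCovered, file.path(dir, paste0(base, "_cov.png")))
    writeDepthPNG(s@frameUncovered, file.path(dir, paste0(base, "_unc.png")))
    writePLY(depthToCloud(s@frameCovered),
             file.path(dir, paste0(base, "_cov.ply")))
    writePLY(depthToCloud(s@frameUncovered),
             file.path(dir, paste0(base, "_unc.ply")))
    list(id = s@id, weight = s@weight, position = s@position,
         cover = s@cover,
         intrinsics = as.list(s@frameCovered@intrinsics),
         density = s@body@density,
         primitives = s@body@primitives)
  })
  manifest <- file.path(dir, "manifest.json")
  jsonlite::write_json(entries, manifest, dataframe = "columns",
                       digits = NA, auto_unbox = TRUE)
  writeSceneParams(params, file.path(dir, "scene.yaml"))
  invisible(manifest)
}

#' Read a dataset written by [writeDataset()]
#'
#' Depths are restored at millimeter quantization.
#'
#' @param dir dataset directory
#' @return list of [PairedSample-class]
#' @export
readDataset <- function(dir) {
  entries <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                 simplifyVector = TRUE,
                                 simplifyDataFrame = FALSE)
  lapply(entries, function(e) {
    base <- sprintf("s%03d", e$id)
    intr <- unlist(e$intrinsics)
    body <- BodySpec(as.data.frame(e$primitives,
                                   stringsAsFactors = FALSE),
                     position = e$position, density = e$density,
                     weight = e$weight)
    meta <- list(subject = e$id, position = e$position)
    fc <- readDepthPNG(file.path(dir, paste0(base, "_cov.png")), intr,
                       meta = c(meta, list(cover = e$cover)))
    fu <- readDepthPNG(file.path(dir, paste0(base, "_unc.png")), intr,
                       meta = c(meta, list(cover = "none")))
    new("PairedSample", id = as.integer(e$id), body = body,
        frameCovered = fc, frameUncovered = fu, weight = e$weight,
        position = e$position, cover = e$cover)
  })
}

# ---- checkpoints -------------------------------------------------------------

#' Save / load a model checkpoint
#'
#' Checkpoints store the architecture descriptor, parameters, batch-norm
#' buffers and loss trace.
#'
#' @param model an [UncoverModel-class] or [WeightModel-class]
#' @param path checkpoint path (.rds)
#' @return `saveCheckpoint`: invisibly the path; `loadCheckpoint`: the model
#' @export
saveCheckpoint <- function(model, path) {
  saveRDS(list(class = class(model), arch = model@arch,
               params = model@params, buffers = model@buffers,
               lossTrace = model@lossTrace), path)
  invisible(path)
}

#' @rdname saveCheckpoint
#' @export
loadCheckpoint <- function(path) {
  ck <- readRDS(path)
  new(ck$class, arch = ck$arch, params = ck$params, buffers = ck$buffers,
      lossTrace = ck$lossTrace)
}
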