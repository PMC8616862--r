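#' @include AllClasses.R
NULL

# ---- primitive geometry ------------------------------------------------------

# support radius of an axis-aligned ellipsoid in direction u (unit vector)
ellipsoidSupport <- function(semi, u) sqrt(sum((semi * u)^2))

# separation deficit for the worst primitive pair: positive value means the
# sufficient separating-axis test (along the center line) failed by that much
worstPairDeficit <- function(p, margin = 1e-3) {
  n <- nrow(p)
  worst <- list(deficit = -Inf, i = NA, j = NA, u = NULL)
  cen <- as.matrix(p[, c("cx", "cy", "cz")])
  ax <- as.matrix(p[, c("ax", "ay", "az")])
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d <- cen[j, ] - cen[i, ]
      dn <- sqrt(sum(d^2))
      u <- if (dn > 0) d / dn else c(0, 0, 1)
      deficit <- ellipsoidSupport(ax[i, ], u) + ellipsoidSupport(ax[j, ], u) +
        margin - dn
      if (deficit > worst$deficit)
        worst <- list(deficit = deficit, i = i, j = j, u = u)
    }
  }
  worst
}

# deterministically push primitives apart along their center lines until the
# pairwise separating-axis test passes; semi-axes (hence volume/weight) are
# never touched
repairOverlaps <- function(p, maxIter = 200L) {
  for (it in seq_len(maxIter)) {
    w <- worstPairDeficit(p)
    if (w$deficit <= 0) return(p)
    shift <- w$u * (w$deficit / 2 + 1e-4)
    p[w$i, c("cx", "cy", "cz")] <- p[w$i, c("cx", "cy", "cz")] - shift
    p[w$j, c("cx", "cy", "cz")] <- p[w$j, c("cx", "cy", "cz")] + shift
  }
  uwStop("could not resolve primitive overlaps", "generationError")
}

# ---- body sampling -----------------------------------------------------------

#' Sample a synthetic body
#'
#' Draws a primitive-based body from the configured population: per-part
#' semi-axes are jittered around a template, parts are chained along the bed
#' axis with explicit gaps (so the ellipsoids are pairwise disjoint and the
#' union volume is the exact sum of ellipsoid volumes), limbs get random
#' splay, lateral positions roll the primitive centers about the body's long
#' axis, and the whole body is rescaled (anisotropically: girth varies more
#' than stature) so that weight = density x analytic volume exactly matches
#' a truncated-normal weight draw. Uses the current RNG state; seed with [set.seed()] (or let
#' [generateDataset()] do it) for reproducible bodies.
#'
#' @param params a [SceneParams] object
#' @param position body position; default samples supine / lateral-left /
#'   lateral-right with equal probability
#' @return a [BodySpec] lying above the bed plane, centered on the bed
#' @export
sampleBody <- function(params, position = NULL) {
  stopifnot(is(params, "SceneParams"))
  if (params@sdWeight <= 0)
    uwStop("invalid body-size distribution", "configError")
  if (is.null(position))
    position <- sample(c("supine", "lateral-left", "lateral-right"), 1L)

  # truncated-normal target weight (kg)
  lo <- params@weightRange[1]; hi <- params@weightRange[2]
  w <- params@meanWeight + params@sdWeight * rnorm(1)
  for (k in seq_len(200)) {
    if (w >= lo && w <= hi) break
    w <- params@meanWeight + params@sdWeight * rnorm(1)
  }
  w <- min(max(w, lo), hi)

  # template sized to ~68 kg at density 1000 (the population mean), so the
  # anisotropic rescale below stays close to 1
  template <- data.frame(
    part = c("head", "torso", "pelvis",
             "upperArmL", "upperArmR", "foreArmL", "foreArmR",
             "thighL", "thighR", "shankL", "shankR"),
    ax = 1.13 * c(.090, .170, .160, .050, .050, .045, .045, .075, .075,
                  .055, .055),
    ay = c(.110, .260, .120, .160, .160, .170, .170, .220, .220, .190, .190),
    az = 1.13 * c(.090, .110, .100, .050, .050, .045, .045, .075, .075,
                  .055, .055),
    stringsAsFactors = FALSE
  )
  jit <- matrix(runif(nrow(template) * 3, 0.9, 1.1), ncol = 3)
  p <- template
  p$ax <- p$ax * jit[, 1]; p$ay <- p$ay * jit[, 2]; p$az <- p$az * jit[, 3]

  g <- 0.025  # inter-part gap, m
  a <- function(part, col) p[p$part == part, col]
  # chain along y from the foot end (y = 0), resting on the deck (z = 0)
  p$cy <- 0; p$cx <- 0
  shankY <- a("shankL", "ay")
  thighY <- 2 * max(p$ay[p$part %in% c("shankL", "shankR")]) + g +
    a("thighL", "ay")
  pelvisY <- thighY + a("thighL", "ay") +
    max(a("thighL", "ay"), a("thighR", "ay")) - a("thighL", "ay") + g +
    a("pelvis", "ay")
  torsoY <- pelvisY + a("pelvis", "ay") + g + a("torso", "ay")
  headY <- torsoY + a("torso", "ay") + g + a("head", "ay")
  p$cy[p$part %in% c("shankL", "shankR")] <- shankY
  p$cy[p$part %in% c("thighL", "thighR")] <- thighY
  p$cy[p$part == "pelvis"] <- pelvisY
  p$cy[p$part == "torso"] <- torsoY
  p$cy[p$part == "head"] <- headY
  p$cy[p$part %in% c("upperArmL", "upperArmR")] <- torsoY + 0.3 * a("torso", "ay")
  p$cy[p$part %in% c("foreArmL", "foreArmR")] <- pelvisY

  # limb splay varies the pose in supine position; lateral bodies keep the
  # limbs tucked so the rolled silhouette stays at a realistic height
  supine <- position == "supine"
  legX <- a("thighL", "ax") + g / 2
  p$cx[p$part == "thighL"] <- -legX; p$cx[p$part == "thighR"] <- legX
  shX <- a("shankL", "ax") + g / 2 + if (supine) runif(1, 0, 0.03) else 0
  p$cx[p$part == "shankL"] <- -shX; p$cx[p$part == "shankR"] <- shX
  armX <- a("torso", "ax") + g + a("upperArmL", "ax") +
    if (supine) runif(1, 0, 0.05) else 0
  p$cx[p$part == "upperArmL"] <- -armX; p$cx[p$part == "upperArmR"] <- armX
  faX <- max(a("pelvis", "ax"), a("torso", "ax")) + g + a("foreArmL", "ax") +
    if (supine) runif(1, 0, 0.05) else 0
  p$cx[p$part == "foreArmL"] <- -faX; p$cx[p$part == "foreArmR"] <- faX
  p$cx[p$part == "head"] <- runif(1, -0.02, 0.02)
  p$cz <- p$az  # rest on the deck

  if (position != "supine") {
    dir <- if (position == "lateral-left") 1 else -1
    # arms move to the anterior side (which rotates upward under the roll)
    # and stack with a gap, ending up in front of the chest
    for (pairNm in list(c("upperArmL", "upperArmR"),
                        c("foreArmL", "foreArmR"))) {
      axFront <- a("torso", "ax") + g + a(pairNm[1], "ax")
      p$cx[p$part %in% pairNm] <- dir * axFront
      p$cz[p$part == pairNm[1]] <- a(pairNm[1], "az")
      p$cz[p$part == pairNm[2]] <- 2 * a(pairNm[1], "az") + g +
        a(pairNm[2], "az")
    }
    theta <- dir * runif(1, 70, 90) * pi / 180
    z0 <- a("torso", "az")
    x <- p$cx; z <- p$cz - z0
    p$cx <- cos(theta) * x - sin(theta) * z
    p$cz <- sin(theta) * x + cos(theta) * z + z0
  }

  p <- repairOverlaps(p)
  p$cz <- p$cz - min(p$cz - p$az) + 0.005  # settle above the deck

  # anisotropic rescale to hit the weight draw exactly: heavier bodies grow
  # mostly in cross-section (exponent 0.4 per lateral axis) and only mildly
  # in length (exponent 0.2), as stature varies far less than girth.
  # q^(0.4 + 0.4 + 0.2) = q, so weight = density x volume stays analytic,
  # and the diagonal linear map preserves disjointness and the above-plane
  # invariant.
  v0 <- bodyVolume(p)
  q <- w / (params@density * v0)
  sy <- q^0.2
  sxz <- q^0.4
  p[, c("cx", "cz", "ax", "az")] <- p[, c("cx", "cz", "ax", "az")] * sxz
  p[, c("cy", "ay")] <- p[, c("cy", "ay")] * sy

  # center the body along the bed
  bodyLen <- max(p$cy + p$ay)
  p$cy <- p$cy + (params@bedExtent[2] - bodyLen) / 2

  BodySpec(p, position = position, density = params@density)
}

# ---- height fields -----------------------------------------------------------

# top-surface height of the body over grid positions xs x ys (m above deck)
bodyHeightField <- function(body, xs, ys) {
  hf <- matrix(0, length(xs), length(ys))
  p <- body@primitives
  for (i in seq_len(nrow(p))) {
    tx <- ((xs - p$cx[i]) / p$ax[i])^2
    ty <- ((ys - p$cy[i]) / p$ay[i])^2
    m <- outer(tx, ty, "+")
    inside <- m <= 1
    if (!any(inside)) next
    h <- matrix(0, length(xs), length(ys))
    h[inside] <- p$cz[i] + p$az[i] * sqrt(1 - m[inside])
    hf <- pmax(hf, h)
  }
  hf
}

#' Drape a blanket over a body height field
#'
#' Height-field blanket model: within the coverage region the covered surface
#' is the pointwise maximum of the body surface, its grayscale morphological
#' closing (disk structuring element) and a Gaussian smoothing of the closing,
#' plus the cover material thickness. The closing bridges concavities narrower
#' than the structuring disk, reproducing the hollow space under a real
#' blanket; the maximum guarantees covered height >= body height + thickness
#' everywhere under the blanket. An optional nonnegative fold field models
#' the irregular fall of a human-placed blanket. Outside the coverage
#' region the surface is unchanged.
#'
#' @param hf body height-field matrix (m above the deck), x along rows,
#'   y (bed length, foot end first) along columns, sampled at `params@hfRes`
#' @param params a [SceneParams]
#' @param thickness cover material thickness in m (default: thick cover)
#' @param coverage optional logical matrix selecting the covered region;
#'   default: from the foot end up to `coverageFraction` of the bed length
#' @param folds optional nonnegative matrix (same shape) added to the drape
#'   inside the coverage region; see [sampleFoldField()]
#' @return covered height-field matrix of the same shape
#' @export
drapeBlanket <- function(hf, params, thickness = params@thicknessThick,
                         coverage = NULL, folds = NULL) {
  stopifnot(is.matrix(hf))
  if (any(hf < 0)) uwStop("height field must be nonnegative", "contractError")
  if (thickness <= 0)
    uwStop("cover thickness must be positive", "configError")
  if (is.null(coverage)) {
    ys <- seq(0, by = params@hfRes, length.out = ncol(hf))
    coverage <- matrix(rep(ys <= params@coverageFraction * params@bedExtent[2],
                           each = nrow(hf)), nrow(hf))
  }
  if (!any(coverage)) return(hf)
  r <- max(1L, round(params@closingRadius / params@hfRes))
  brush <- EBImage::makeBrush(2L * r + 1L, shape = "disc")
  closed <- as.matrix(EBImage::closing(hf, brush))
  sm <- as.matrix(EBImage::gblur(closed,
                                 sigma = params@smoothSigma / params@hfRes))
  drape <- pmax(hf, closed, sm) + thickness
  if (!is.null(folds)) {
    if (any(folds < 0))
      uwStop("fold field must be nonnegative", "contractError")
    drape <- drape + folds
  }
  out <- hf
  out[coverage] <- drape[coverage]
  out
}

#' Sample a blanket fold field
#'
#' Low-frequency nonnegative random field modeling the irregular fall and
#' folds of a human-placed blanket: white Gaussian noise smoothed to the
#' configured correlation length, scaled to `foldAmplitude`, and shifted to
#' its minimum, so adding it never lowers the drape below
#' body + thickness. Draws from the current RNG.
#'
#' @param nrow,ncol field dimensions (height-field grid)
#' @param params a [SceneParams]
#' @return nonnegative matrix
#' @export
sampleFoldField <- function(nrow, ncol, params) {
  if (params@foldAmplitude <= 0) return(matrix(0, nrow, ncol))
  raw <- matrix(rnorm(nrow * ncol), nrow, ncol)
  sm <- as.matrix(EBImage::gblur(raw,
                                 sigma = params@foldScale / params@hfRes))
  sm <- sm / max(sd(sm), 1e-12) * params@foldAmplitude
  sm - min(sm)
}

# bilinear 2x upsampling of a matrix (grid refinement for splatting)
upsample2 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  r <- matrix(0, 2 * nr - 1, nc)
  r[seq(1, 2 * nr - 1, 2), ] <- m
  if (nr > 1)
    r[seq(2, 2 * nr - 2, 2), ] <- (m[-nr, , drop = FALSE] +
                                     m[-1, , drop = FALSE]) / 2
  out <- matrix(0, 2 * nr - 1, 2 * nc - 1)
  out[, seq(1, 2 * nc - 1, 2)] <- r
  if (nc > 1)
    out[, seq(2, 2 * nc - 2, 2)] <- (r[, -nc, drop = FALSE] +
                                       r[, -1, drop = FALSE]) / 2
  out
}

# ---- depth rendering ---------------------------------------------------------

# conservative check that the body's bounding points project inside the image
bodyInFrustum <- function(body, params) {
  p <- body@primitives
  W <- params@imageSize[1]; H <- params@imageSize[2]
  bz <- params@camHeight - (p$cz + p$az)
  bu <- range(params@focal[1] * c(p$cx - p$ax, p$cx + p$ax) / rep(bz, 2) +
                params@principal[1])
  bv <- range(params@focal[2] *
                (c(p$cy - p$ay, p$cy + p$ay) - params@bedExtent[2] / 2) /
                rep(bz, 2) + params@principal[2])
  bu[1] >= 0 && bu[2] <= W - 1 && bv[1] >= 0 && bv[2] <= H - 1
}

#' Render a top-view depth frame of an in-bed scene
#'
#' Z-buffer rendering of bed (and surrounding floor), body, and optionally a
#' draped blanket, seen by a pinhole depth camera mounted above the bed
#' center and looking straight down. The scene top surface is sampled as a
#' height field, supersampled bilinearly, projected through the intrinsics
#' and z-buffered per pixel (nearest depth wins). Covered and uncovered
#' renders of the same body use identical sampling, so they differ only where
#' the blanket lies. Gaussian depth noise (if configured) is applied last;
#' pass a pre-drawn `noise` matrix to share one realization across the two
#' renders of a pair. Pixels hit by no surface sample carry the invalid
#' sentinel 0.
#'
#' @param body a [BodySpec]
#' @param params a [SceneParams]
#' @param covered render with the draped blanket?
#' @param thickness cover thickness in m (default thick); ignored when
#'   `covered = FALSE`
#' @param noise optional depth-noise matrix (image height x width, meters);
#'   `NULL` draws from the RNG when `depthNoiseSd > 0`
#' @param coverageFraction blanket extent for this render (fraction of the
#'   bed length from the foot end)
#' @param folds optional fold field on the height-field grid (see
#'   [sampleFoldField()]); `NULL` renders a fold-free drape
#' @return a [DepthFrame] (depths in m along the optical axis)
#' @export
renderDepth <- function(body, params, covered = FALSE,
                        thickness = params@thicknessThick, noise = NULL,
                        coverageFraction = params@coverageFraction,
                        folds = NULL) {
  bx <- params@bedExtent[1]; by <- params@bedExtent[2]
  res <- params@hfRes
  margin <- 0.25
  xs <- seq(-bx / 2 - margin, bx / 2 + margin, by = res)
  ys <- seq(-margin, by + margin, by = res)

  hfBody <- bodyHeightField(body, xs, ys)
  hf <- hfBody
  if (covered) {
    ycov <- ys >= 0 & ys <= coverageFraction * by
    xcov <- abs(xs) <= bx / 2
    coverage <- outer(xcov, ycov, "&")
    hf <- drapeBlanket(hfBody, params, thickness = thickness,
                       coverage = coverage, folds = folds)
  }
  insideBed <- outer(abs(xs) <= bx / 2, ys >= 0 & ys <= by, "&")
  hf[!insideBed] <- -params@bedHeight  # floor around the bed

  # supersample and project (x2 bilinear; the floor/bed step edge is
  # interpolated, which is harmless for the downstream thresholding)
  hf2 <- upsample2(hf)
  xs2 <- seq(xs[1], xs[length(xs)], length.out = nrow(hf2))
  ys2 <- seq(ys[1], ys[length(ys)], length.out = ncol(hf2))
  X <- rep(xs2, times = length(ys2))
  Y <- rep(ys2, each = length(xs2))
  Zc <- params@camHeight - as.vector(hf2)
  Xc <- X
  Yc <- Y - by / 2

  W <- params@imageSize[1]; H <- params@imageSize[2]
  fx <- params@focal[1]; fy <- params@focal[2]
  cx <- params@principal[1]; cy <- params@principal[2]
  u <- round(fx * Xc / Zc + cx)
  v <- round(fy * Yc / Zc + cy)

  if (!bodyInFrustum(body, params))
    uwStop("body outside the camera frustum", "generationError")

  keep <- u >= 0 & u <= W - 1 & v >= 0 & v <= H - 1
  u <- u[keep]; v <- v[keep]; z <- Zc[keep]
  D <- matrix(0, H, W)
  ord <- order(z, decreasing = TRUE)      # nearest surface written last
  D[cbind(v[ord] + 1, u[ord] + 1)] <- z[ord]

  if (is.null(noise) && params@depthNoiseSd > 0)
    noise <- matrix(rnorm(H * W, sd = params@depthNoiseSd), H, W)
  if (!is.null(noise)) {
    valid <- D > 0
    D[valid] <- pmax(D[valid] + noise[valid], 1e-6)
  }

  DepthFrame(D, c(fx = fx, fy = fy, cx = cx, cy = cy),
             meta = list(position = body@position,
                         cover = if (covered) "covered" else "none",
                         camHeight = params@camHeight))
}

# ---- dataset generation ------------------------------------------------------

#' Generate a paired synthetic dataset
#'
#' Generates `n` subjects; for each, a covered (thin or thick blanket) and an
#' uncovered depth frame of the identical body and pose, sharing one depth-
#' noise realization so the two frames differ only where the blanket lies.
#' Fully deterministic given `params@seed`.
#'
#' @param n number of subjects (>= 1)
#' @param params a [SceneParams]
#' @return list of [PairedSample-class] objects; see [datasetManifest()]
#' @export
generateDataset <- function(n, params) {
  if (n < 1) uwStop("n must be >= 1", "contractError")
  set.seed(params@seed)
  lapply(seq_len(n), function(i) {
    # rare extreme bodies can clip the frustum; resample them (bounded,
    # deterministic: retries consume the same RNG stream)
    for (attempt in 1:20) {
      body <- sampleBody(params)
      if (bodyInFrustum(body, params)) break
    }
    cover <- sample(c("thin", "thick"), 1L)
    thickness <- if (cover == "thin") params@thicknessThin
                 else params@thicknessThick
    H <- params@imageSize[2]; W <- params@imageSize[1]
    noise <- if (params@depthNoiseSd > 0)
      matrix(rnorm(H * W, sd = params@depthNoiseSd), H, W) else NULL
    # human-placed blankets vary in extent and fall between subjects
    coverageFraction <- runif(1, params@coverageRange[1],
                              params@coverageRange[2])
    margin <- 0.25
    nhx <- length(seq(-params@bedExtent[1] / 2 - margin,
                      params@bedExtent[1] / 2 + margin, by = params@hfRes))
    nhy <- length(seq(-margin, params@bedExtent[2] + margin,
                      by = params@hfRes))
    folds <- sampleFoldField(nhx, nhy, params)
    fCov <- renderDepth(body, params, covered = TRUE, thickness = thickness,
                        noise = noise, coverageFraction = coverageFraction,
                        folds = folds)
    fUnc <- renderDepth(body, params, covered = FALSE, noise = noise)
    fCov@meta$cover <- cover
    fCov@meta$subject <- i; fUnc@meta$subject <- i
    new("PairedSample", id = i, body = body, frameCovered = fCov,
        frameUncovered = fUnc, weight = body@weight,
        position = body@position, cover = cover)
  })
}

#' Dataset manifest
#'
#' One row per generated subject: id, ground-truth weight, position and cover
#' condition. Serializing this table is byte-stable for a fixed seed.
#'
#' @param samples list of [PairedSample-class] objects
#' @return data.frame
#' @export
datasetManifest <- function(samples) {
  data.frame(
    id = vapply(samples, function(s) s@id, integer(1)),
    weight = vapply(samples, function(s) s@weight, numeric(1)),
    position = vapply(samples, function(s) s@position, character(1)),
    cover = vapply(samples, function(s) s@cover, character(1)),
    stringsAsFactors = FALSE
  )
}
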