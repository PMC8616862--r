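# Independent brute-force oracles used to validate the package
# implementations. These deliberately share no code with the package.

# Dice by explicit voxel loops
oracleDice <- function(A, B) {
  inter <- 0; na <- 0; nb <- 0
  for (i in seq_along(A)) {
    if (A[i] == 1) na <- na + 1
    if (B[i] == 1) nb <- nb + 1
    if (A[i] == 1 && B[i] == 1) inter <- inter + 1
  }
  2 * inter / (na + nb)
}

# surface voxels by explicit 6-neighbor loops (border = unoccupied)
oracleSurface <- function(occ) {
  d <- dim(occ)
  out <- NULL
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (occ[i, j, k] != 1) next
    nb <- c(
      if (i > 1) occ[i - 1, j, k] else 0,
      if (i < d[1]) occ[i + 1, j, k] else 0,
      if (j > 1) occ[i, j - 1, k] else 0,
      if (j < d[2]) occ[i, j + 1, k] else 0,
      if (k > 1) occ[i, j, k - 1] else 0,
      if (k < d[3]) occ[i, j, k + 1] else 0)
    if (any(nb == 0)) out <- rbind(out, c(i, j, k))
  }
  out
}

# directed average surface distance (mm) by all-pairs nearest distance
oracleASD <- function(target, pred, vox) {
  st <- oracleSurface(target)
  sp <- oracleSurface(pred)
  if (is.null(st) || is.null(sp)) return(NA_real_)
  total <- 0
  for (i in seq_len(nrow(st))) {
    best <- Inf
    for (j in seq_len(nrow(sp))) {
      d2 <- sum(((st[i, ] - sp[j, ]) * vox)^2)
      if (d2 < best) best <- d2
    }
    total <- total + sqrt(best)
  }
  1000 * total / nrow(st)
}

# voxelization by per-point nested binning
oracleVoxelize <- function(points, extent, dims, origin) {
  occ <- array(0, dims)
  edge <- extent / dims
  for (i in seq_len(nrow(points))) {
    idx <- integer(3)
    ok <- TRUE
    for (a in 1:3) {
      v <- floor((points[i, a] - origin[a]) / edge[a])
      if (v < 0 || v >= dims[a]) { ok <- FALSE; break }
      idx[a] <- v + 1
    }
    if (ok) occ[idx[1], idx[2], idx[3]] <- 1
  }
  occ
}

# element-wise binary cross entropy by scalar loop
oracleCE <- function(p, t, eps = 1e-7) {
  total <- 0
  for (i in seq_along(p)) {
    pi_ <- min(max(p[i], eps), 1 - eps)
    total <- total - (t[i] * log(pi_) + (1 - t[i]) * log(1 - pi_))
  }
  total / length(p)
}

oracleMSE <- function(a, b) {
  total <- 0
  for (i in seq_along(a)) total <- total + (a[i] - b[i])^2
  total / length(a)
}

randomBinaryGrid <- function(dims, p = 0.3) {
  array(as.numeric(rbinom(prod(dims), 1, p)), dims)
}
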