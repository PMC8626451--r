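# Internal numeric helpers: grid/world conversions, interpolation,
# separable Gaussian filtering and finite-difference gradients.
# Everything operates on plain double arrays; the S4 layer wraps them.

.asVolumeArray <- function(data) {
  if (is.null(dim(data)) || length(dim(data)) != 3L)
    stop("expected a 3D array")
  storage.mode(data) <- "double"
  data
}

# Voxel-to-world affine with diag(spacing) and the grid centre at the world
# origin (0-based voxel indices).
.centeredAffine <- function(shape, spacing) {
  a <- diag(4)
  a[1, 1] <- spacing[1]; a[2, 2] <- spacing[2]; a[3, 3] <- spacing[3]
  a[1:3, 4] <- -(shape - 1) / 2 * spacing
  a
}

.sameGrid <- function(a, b, tol = 1e-6) {
  all(dim(volData(a))[1:3] == dim(volData(b))[1:3]) &&
    max(abs(volAffine(a) - volAffine(b))) <= tol
}

.stopUnlessSameGrid <- function(a, b, what = "images") {
  if (!.sameGrid(a, b))
    stop(what, " must share the same grid (shape and affine)", call. = FALSE)
  invisible(TRUE)
}

# 0-based voxel index triples of the full grid, column-major order matching
# R's array storage.
.gridIndices <- function(shape) {
  cbind(
    rep.int(seq_len(shape[1]) - 1L, times = shape[2] * shape[3]),
    rep.int(rep(seq_len(shape[2]) - 1L, each = shape[1]), times = shape[3]),
    rep(seq_len(shape[3]) - 1L, each = shape[1] * shape[2]))
}

# World coordinates (N x 3, mm) of all voxels of a grid.
.gridWorld <- function(shape, affine) {
  idx <- .gridIndices(shape)
  .voxelToWorld(idx, affine)
}

.voxelToWorld <- function(idx, affine) {
  sweep(idx %*% t(affine[1:3, 1:3, drop = FALSE]), 2L, affine[1:3, 4], "+")
}

.worldToVoxel <- function(world, affine) {
  inv <- solve(affine)
  sweep(world, 2L, affine[1:3, 4], "-") %*% t(inv[1:3, 1:3, drop = FALSE])
}

# Trilinear interpolation of `arr` at continuous 0-based voxel coordinates
# (N x 3). Sample points outside the grid blend with 0 (out-of-field value),
# consistent with skull-stripped zero backgrounds.
.interpTrilinear <- function(arr, idx) {
  d <- dim(arr)
  x0 <- floor(idx)
  fx <- idx - x0
  out <- numeric(nrow(idx))
  for (dx in 0:1) {
    wx <- if (dx == 1L) fx[, 1] else 1 - fx[, 1]
    ix <- x0[, 1] + dx
    for (dy in 0:1) {
      wy <- if (dy == 1L) fx[, 2] else 1 - fx[, 2]
      iy <- x0[, 2] + dy
      for (dz in 0:1) {
        wz <- if (dz == 1L) fx[, 3] else 1 - fx[, 3]
        iz <- x0[, 3] + dz
        w <- wx * wy * wz
        inside <- ix >= 0 & ix <= d[1] - 1 & iy >= 0 & iy <= d[2] - 1 &
          iz >= 0 & iz <= d[3] - 1 & w > 0
        if (any(inside)) {
          lin <- ix[inside] + d[1] * (iy[inside] + d[2] * iz[inside]) + 1
          out[inside] <- out[inside] + w[inside] * arr[lin]
        }
      }
    }
  }
  out
}

.interpNearest <- function(arr, idx) {
  d <- dim(arr)
  r <- round(idx)
  out <- numeric(nrow(idx))
  inside <- r[, 1] >= 0 & r[, 1] <= d[1] - 1 &
    r[, 2] >= 0 & r[, 2] <= d[2] - 1 &
    r[, 3] >= 0 & r[, 3] <= d[3] - 1
  if (any(inside)) {
    lin <- r[inside, 1] + d[1] * (r[inside, 2] + d[2] * r[inside, 3]) + 1
    out[inside] <- arr[lin]
  }
  out
}

.interpolate <- function(arr, idx, interpolation) {
  switch(interpolation,
    trilinear = .interpTrilinear(arr, idx),
    nearest = .interpNearest(arr, idx),
    stop("unknown interpolation '", interpolation,
         "' (use 'nearest' or 'trilinear')", call. = FALSE))
}

# Apply an n x n linear operator along one axis of a 3D array.
.axisApply <- function(arr, axis, S) {
  d <- dim(arr)
  perm <- c(axis, setdiff(1:3, axis))
  m <- matrix(aperm(arr, perm), nrow = d[axis])
  m <- S %*% m
  aperm(array(as.numeric(m), dim = d[perm]), order(perm))
}

# Row-normalized truncated Gaussian smoothing matrix: constants are exactly
# preserved and boundary rows renormalize (replicate-like behaviour).
.gaussMatrix <- function(n, sigma) {
  r <- max(1L, ceiling(4 * sigma))
  offs <- (-r):r
  k <- exp(-offs^2 / (2 * sigma^2))
  S <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- i + offs
    ok <- j >= 1L & j <= n
    S[i, j[ok]] <- k[ok] / sum(k[ok])
  }
  S
}

# Separable Gaussian filtering; sigma in voxels, per axis. sigma 0 on an
# axis is the identity.
.smoothArray <- function(arr, sigmaVox) {
  for (ax in 1:3) {
    if (sigmaVox[ax] > 0)
      arr <- .axisApply(arr, ax, .gaussMatrix(dim(arr)[ax], sigmaVox[ax]))
  }
  arr
}

# Central-difference derivative along one voxel axis, one-sided at the two
# boundary slices. Returns d(arr)/d(index), not yet scaled to world units.
.axisDiff <- function(arr, axis) {
  d <- dim(arr)
  perm <- c(axis, setdiff(1:3, axis))
  a <- aperm(arr, perm)
  n <- d[axis]
  g <- array(0, dim = dim(a))
  if (n >= 2L) {
    g[1, , ] <- a[2, , ] - a[1, , ]
    g[n, , ] <- a[n, , ] - a[n - 1, , ]
    if (n >= 3L)
      g[2:(n - 1), , ] <- (a[3:n, , ] - a[1:(n - 2), , ]) / 2
  }
  aperm(g, order(perm))
}

# Gradient with respect to world mm: d/dworld_j = sum_a d/dvox_a * invA[a, j].
# Returns a list of three arrays.
.gradientWorld <- function(arr, affine) {
  invA <- solve(affine[1:3, 1:3, drop = FALSE])
  gv <- lapply(1:3, function(ax) .axisDiff(arr, ax))
  lapply(1:3, function(j) {
    g <- gv[[1]] * invA[1, j]
    g <- g + gv[[2]] * invA[2, j]
    g + gv[[3]] * invA[3, j]
  })
}

# Run expr with a local, restored RNG state seeded by `seed`.
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Deterministic per-subject substream seed derived from (seed, index),
# kept inside 32-bit integer range.
.subjectSeed <- function(seed, index) {
  as.integer((as.numeric(seed) %% 2147483629 * 48271 +
                as.numeric(index) * 1664525) %% 2147483629)
}
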