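# Spatial normalization: a self-contained affine mutual-information
# registration for desk-scale use and a demons-style diffeomorphic backend
# honouring the reference configuration (gradient step 0.2, update-field
# Gaussian smoothing of 3 x voxel spacing). Both are deterministic: fixed
# pyramid schedules, no stochastic sampling.

#' Registration configuration
#'
#' @param similarity similarity metric; only `"mutual_information"`.
#' @param bins joint-histogram bins (>= 8).
#' @param pyramidLevels multiresolution levels (>= 1); level L works on the
#'   grid downsampled by `2^(L-1)`.
#' @param optimizerIterations Nelder-Mead iteration budget per level.
#' @param diffeoGradientStep demons step scaling (default 0.2).
#' @param diffeoSmoothingFactor update-field Gaussian sigma as a multiple of
#'   the voxel spacing (default 3, i.e. sigma = 3 x spacing mm).
#' @param diffeoTotalFieldSigma total-field Gaussian sigma in voxels applied
#'   after each demons iteration (default 1; 0 disables). A light elastic
#'   regularisation that keeps the accumulated field from drifting in
#'   gradient-free regions.
#' @param diffeoIterations demons iterations per pyramid level.
#' @param backend `"builtin_affine"`, `"builtin_demons"` or `"external"`
#'   (a user-supplied function, see [registerDiffeomorphic()]).
#' @return A named list of validated settings.
#' @export
registrationConfig <- function(similarity = "mutual_information", bins = 32L,
                               pyramidLevels = 2L, optimizerIterations = 400L,
                               diffeoGradientStep = 0.2,
                               diffeoSmoothingFactor = 3,
                               diffeoTotalFieldSigma = 1,
                               diffeoIterations = 100L,
                               backend = "builtin_affine") {
  stopifnot(similarity == "mutual_information", bins >= 8L,
            pyramidLevels >= 1L, diffeoGradientStep > 0)
  list(similarity = similarity, bins = as.integer(bins),
       pyramidLevels = as.integer(pyramidLevels),
       optimizerIterations = as.integer(optimizerIterations),
       diffeoGradientStep = diffeoGradientStep,
       diffeoSmoothingFactor = diffeoSmoothingFactor,
       diffeoTotalFieldSigma = diffeoTotalFieldSigma,
       diffeoIterations = as.integer(diffeoIterations),
       backend = backend)
}

#' Mutual information of two volumes
#'
#' Shannon mutual information (nats) of the joint intensity histogram of two
#' volumes over the mask voxels, with `bins` equal-width bins spanning each
#' image's own intensity range (which makes the value invariant under
#' separate positive affine rescalings of either image).
#'
#' @param a,b [VolumeImage-class] objects on the same grid.
#' @param mask a [BrainMask-class]; defaults to all voxels.
#' @param bins histogram bins per axis.
#' @return MI in nats (>= 0 up to floating-point rounding).
#' @export
mutualInformation <- function(a, b, mask = NULL, bins = 32L) {
  .stopUnlessSameGrid(a, b)
  sel <- if (is.null(mask)) rep(TRUE, length(a@data)) else {
    .stopUnlessSameGrid(a, mask, "image and mask")
    as.logical(mask@data)
  }
  if (!any(sel)) stop("empty mask")
  x <- a@data[sel]; y <- b@data[sel]
  if (length(x) < bins)
    warning("fewer mask voxels than histogram bins")
  .miFromSamples(x, y, bins)
}

.binIndex <- function(x, bins) {
  lo <- min(x); hi <- max(x)
  if (hi <= lo) return(rep(1L, length(x)))
  pmin(bins, as.integer(floor((x - lo) / (hi - lo) * bins)) + 1L)
}

.miFromSamples <- function(x, y, bins) {
  bx <- .binIndex(x, bins); by <- .binIndex(y, bins)
  joint <- tabulate(bx + bins * (by - 1L), nbins = bins * bins) / length(x)
  jm <- matrix(joint, bins, bins)
  px <- rowSums(jm); py <- colSums(jm)
  nz <- jm > 0
  sum(jm[nz] * log(jm[nz] / (px[row(jm)[nz]] * py[col(jm)[nz]])))
}

# Partial-volume (linearly weighted) joint histogram MI: each sample
# distributes its mass between the two nearest bin centres on each axis,
# making the estimate continuous in the intensities and hence a smooth
# optimization objective (the plain hard-binned estimate is piecewise
# constant in the transform parameters).
.miSoftSamples <- function(x, y, bins) {
  soft <- function(v) {
    lo <- min(v); hi <- max(v)
    t <- if (hi > lo) (v - lo) / (hi - lo) * (bins - 1) else rep(0, length(v))
    i0 <- pmin(as.integer(floor(t)), bins - 2L)
    list(i0 = i0 + 1L, w = t - i0)
  }
  sx <- soft(x); sy <- soft(y)
  idx <- c(sx$i0     + bins * (sy$i0 - 1L),
           sx$i0 + 1L + bins * (sy$i0 - 1L),
           sx$i0     + bins * sy$i0,
           sx$i0 + 1L + bins * sy$i0)
  wts <- c((1 - sx$w) * (1 - sy$w), sx$w * (1 - sy$w),
           (1 - sx$w) * sy$w, sx$w * sy$w)
  acc <- rowsum(wts, idx)
  jm <- matrix(0, bins, bins)
  jm[as.integer(rownames(acc))] <- acc
  jm <- jm / length(x)
  px <- rowSums(jm); py <- colSums(jm)
  nz <- jm > 1e-300
  sum(jm[nz] * log(jm[nz] / (px[row(jm)[nz]] * py[col(jm)[nz]])))
}

# Downsample by an integer factor: Gaussian presmoothing (sigma = factor/2
# voxels) then strided sampling; the affine absorbs the stride.
.downsample <- function(image, factor = 2L) {
  if (factor == 1L) return(image)
  d <- dim(image@data)
  sm <- .smoothArray(image@data, rep(factor / 2, 3))
  ix <- lapply(d, function(n) seq(1L, n, by = factor))
  out <- sm[ix[[1]], ix[[2]], ix[[3]], drop = FALSE]
  M <- diag(c(factor, factor, factor, 1))
  new("VolumeImage", data = array(out, dim = vapply(ix, length, 1L)),
      affine = image@affine %*% M)
}

.downsampleMask <- function(mask, factor = 2L) {
  if (factor == 1L) return(mask)
  d <- dim(mask@data)
  ix <- lapply(d, function(n) seq(1L, n, by = factor))
  out <- mask@data[ix[[1]], ix[[2]], ix[[3]], drop = FALSE]
  M <- diag(c(factor, factor, factor, 1))
  new("BrainMask", data = array(out, dim = vapply(ix, length, 1L)),
      affine = mask@affine %*% M)
}

.centerOfMass <- function(image) {
  w <- pmax(as.numeric(image@data), 0)
  tw <- sum(w)
  if (tw <= 0) return(.voxelToWorld(matrix((dim(image@data) - 1) / 2, 1), image@affine)[1, ])
  world <- .gridWorld(dim(image@data), image@affine)
  colSums(world * w) / tw
}

# Parameters: c(t1 t2 t3, log s1 s2 s3, rx ry rz). Transform maps fixed
# world p to moving world: R * S * (p - c) + c + t, with c the fixed-image
# centre of mass.
.paramsToMatrix <- function(par, center) {
  t <- par[1:3]; s <- exp(par[4:6]); r <- par[7:9]
  Rx <- matrix(c(1, 0, 0, 0, cos(r[1]), sin(r[1]), 0, -sin(r[1]), cos(r[1])), 3)
  Ry <- matrix(c(cos(r[2]), 0, -sin(r[2]), 0, 1, 0, sin(r[2]), 0, cos(r[2])), 3)
  Rz <- matrix(c(cos(r[3]), sin(r[3]), 0, -sin(r[3]), cos(r[3]), 0, 0, 0, 1), 3)
  A3 <- Rz %*% Ry %*% Rx %*% diag(s)
  m <- diag(4)
  m[1:3, 1:3] <- A3
  m[1:3, 4] <- center + t - A3 %*% center
  m
}

#' Affine registration by mutual-information maximization
#'
#' Registers `moving` to `fixed` with a 9-parameter transform (translation,
#' per-axis log scale, rotation), maximizing the mutual information of the
#' joint histogram over a coarse-to-fine pyramid. Initialization is
#' centre-of-mass alignment; optimization is Nelder-Mead with a fixed,
#' deterministic schedule.
#'
#' @param moving,fixed [VolumeImage-class] objects (any grids).
#' @param config a [registrationConfig()] list.
#' @param mask optional [BrainMask-class] on the fixed grid restricting the
#'   similarity domain; defaults to nonzero fixed voxels.
#' @return An [AffineTransform-class] mapping fixed-world to moving-world
#'   points (pull-back convention). Attribute `converged` reports optimizer
#'   convergence; the best transform found is returned either way.
#' @export
registerAffine <- function(moving, fixed, config = registrationConfig(),
                           mask = NULL) {
  if (is.null(mask))
    mask <- new("BrainMask", data = array(fixed@data != 0, dim(fixed@data)),
                affine = fixed@affine)
  center <- .centerOfMass(fixed)
  par <- c(.centerOfMass(moving) - center, rep(0, 6))
  converged <- TRUE
  levels <- rev(seq_len(config$pyramidLevels))
  for (lev in levels) {
    f <- 2L^(lev - 1L)
    fx <- .downsample(fixed, f)
    mk <- .downsampleMask(mask, f)
    if (sum(mk@data) < 8L * config$bins) mk@data[] <- TRUE
    world <- .gridWorld(dim(fx@data), fx@affine)[as.logical(mk@data), , drop = FALSE]
    fvals <- fx@data[mk@data]
    mv <- .downsample(moving, f)
    negmi <- function(p, soft) {
      T4 <- .paramsToMatrix(p, center)
      q <- sweep(world %*% t(T4[1:3, 1:3]), 2L, T4[1:3, 4], "+")
      w <- .interpTrilinear(mv@data, .worldToVoxel(q, mv@affine))
      if (soft) -.miSoftSamples(fvals, w, config$bins)
      else -.miFromSamples(fvals, w, config$bins)
    }
    # Optimize in a shifted/scaled space so the Nelder-Mead initial simplex
    # has a fixed, resolution-appropriate size (optim's default step is
    # proportional to the parameter magnitude, degenerate near zero).
    # The smooth partial-volume MI drives the global passes; a final pass on
    # the plain histogram MI (sharply peaked, but locally jagged) removes
    # the small bias the soft estimate carries near the optimum.
    scales <- c(rep(5 * max(voxelSpacing(fixed)) * f, 3), rep(0.25, 3),
                rep(0.25, 3))
    for (pass in 1:4) {
      # shrink the simplex on refinement passes; the hard-MI pass keeps a
      # simplex wide enough to cross the soft estimate's residual bias
      sc <- scales / c(1, 4, 16, 8)[pass]
      base <- par
      soft <- pass < 4L
      g <- function(q) negmi(base + (q - 1) * sc, soft)
      opt <- stats::optim(rep(1, 9L), g, method = "Nelder-Mead",
                          control = list(maxit = config$optimizerIterations,
                                         reltol = 1e-10))
      par <- base + (opt$par - 1) * sc
      if (opt$convergence != 0) converged <- FALSE
    }
  }
  out <- AffineTransform(.paramsToMatrix(par, center))
  attr(out, "converged") <- converged
  out
}

# Pull-back sampling of `arr` (grid `affine`) displaced by field d (mm).
.sampleDisplaced <- function(arr, affine, world, d) {
  moved <- world + cbind(as.numeric(d[, , , 1]), as.numeric(d[, , , 2]),
                         as.numeric(d[, , , 3]))
  array(.interpTrilinear(arr, .worldToVoxel(moved, affine)), dim = dim(arr)[1:3])
}

.smoothField <- function(d, sigmaVox) {
  for (c. in 1:3) d[, , , c.] <- .smoothArray(d[, , , c.], sigmaVox)
  d
}

# Trilinearly upsample a displacement field from a coarse grid onto a fine
# grid (same world space).
.upsampleField <- function(d, coarseAffine, fineShape, fineAffine) {
  world <- .gridWorld(fineShape, fineAffine)
  idx <- .worldToVoxel(world, coarseAffine)
  out <- array(0, dim = c(fineShape, 3L))
  for (c. in 1:3)
    out[, , , c.] <- array(.interpTrilinear(d[, , , c.], idx), dim = fineShape)
  out
}

#' Diffeomorphic registration (demons backend)
#'
#' Estimates a dense displacement field warping `fixed`-grid points into
#' `moving` space (pull-back) by a symmetric-force demons iteration over a
#' coarse-to-fine pyramid. Each iteration's update field is smoothed with a
#' Gaussian of sigma = `diffeoSmoothingFactor` x voxel spacing (mm) and
#' scaled by `diffeoGradientStep`. The result is checked for Jacobian
#' positivity; a non-positive minimum is reported as a warning and flagged
#' in the `jacobianPositive` attribute, with the field still returned.
#'
#' Affine pre-alignment is assumed: `moving` and `fixed` must share a grid.
#' With `config$backend = "external"`, `external` must be a function
#' `(moving, fixed, config) -> DeformationField` and is delegated to.
#'
#' @param moving,fixed [VolumeImage-class] objects on the same grid.
#' @param config a [registrationConfig()] list.
#' @param external optional external backend function.
#' @return A [DeformationField-class] on the fixed grid.
#' @export
registerDiffeomorphic <- function(moving, fixed,
                                  config = registrationConfig(backend = "builtin_demons"),
                                  external = NULL) {
  if (identical(config$backend, "external")) {
    if (!is.function(external)) stop("external backend not available")
    field <- external(moving, fixed, config)
    if (!is(field, "DeformationField"))
      stop("external backend must return a DeformationField")
    return(.checkFieldJacobian(field))
  }
  .stopUnlessSameGrid(moving, fixed, "moving and fixed")
  shape <- dim(fixed@data)
  spacing <- voxelSpacing(fixed)
  nLevels <- config$pyramidLevels
  d <- NULL
  for (lev in rev(seq_len(nLevels))) {
    f <- 2L^(lev - 1L)
    fx <- .downsample(fixed, f)
    mv <- .downsample(moving, f)
    shp <- dim(fx@data)
    sp <- voxelSpacing(fx)
    world <- .gridWorld(shp, fx@affine)
    d <- if (is.null(d)) array(0, dim = c(shp, 3L))
         else .upsampleField(d, prevAffine, shp, fx@affine)
    sigmaVox <- rep(config$diffeoSmoothingFactor, 3)  # sigma = factor x spacing
    L2 <- mean(sp)^2
    maxStep <- 2 * mean(sp) * config$diffeoGradientStep
    gF <- .gradientWorld(fx@data, fx@affine)
    for (it in seq_len(config$diffeoIterations)) {
      warped <- .sampleDisplaced(mv@data, mv@affine, world, d)
      diffim <- warped - fx@data
      gW <- .gradientWorld(warped, fx@affine)
      g1 <- (gF[[1]] + gW[[1]]) / 2
      g2 <- (gF[[2]] + gW[[2]]) / 2
      g3 <- (gF[[3]] + gW[[3]]) / 2
      denom <- g1^2 + g2^2 + g3^2 + diffim^2 / L2
      scale <- -diffim / denom
      scale[denom < 1e-12] <- 0
      u <- array(0, dim = c(shp, 3L))
      u[, , , 1] <- scale * g1
      u[, , , 2] <- scale * g2
      u[, , , 3] <- scale * g3
      u <- .smoothField(u, sigmaVox)
      mag <- sqrt(u[, , , 1]^2 + u[, , , 2]^2 + u[, , , 3]^2)
      top <- max(mag)
      if (top > maxStep) u <- u * (maxStep / top)
      d <- d + u
      if (config$diffeoTotalFieldSigma > 0)
        d <- .smoothField(d, rep(config$diffeoTotalFieldSigma, 3))
    }
    prevAffine <- fx@affine
  }
  field <- new("DeformationField", displacements = d, affine = fixed@affine)
  .checkFieldJacobian(field)
}

.checkFieldJacobian <- function(field) {
  jd <- jacobianDeterminant(field)
  ok <- min(jd@data) > 0
  if (!ok)
    warning("deformation field has non-positive Jacobian determinant (min ",
            signif(min(jd@data), 4), ")")
  attr(field, "jacobianPositive") <- ok
  field
}

#' Apply a spatial transform to a volume
#'
#' Pull-back resampling of `image` onto the `reference` grid through either
#' an [AffineTransform-class] (fixed world -> moving world) or a
#' [DeformationField-class] defined on the reference grid. Out-of-field
#' voxels are 0.
#'
#' @param image the moving [VolumeImage-class].
#' @param transform an [AffineTransform-class] or [DeformationField-class].
#' @param reference the [VolumeImage-class] (or [BrainMask-class]) whose
#'   grid defines the output.
#' @param interpolation `"trilinear"` (default) or `"nearest"`.
#' @return A [VolumeImage-class] on the reference grid.
#' @export
applyTransform <- function(image, transform, reference,
                           interpolation = "trilinear") {
  refShape <- dim(volData(reference))[1:3]
  refAffine <- volAffine(reference)
  world <- .gridWorld(refShape, refAffine)
  if (is(transform, "AffineTransform")) {
    q <- sweep(world %*% t(transform@matrix[1:3, 1:3]), 2L,
               transform@matrix[1:3, 4], "+")
  } else if (is(transform, "DeformationField")) {
    if (any(dim(transform@displacements)[1:3] != refShape) ||
        max(abs(transform@affine - refAffine)) > 1e-6)
      stop("deformation field grid does not match the reference grid")
    u <- transform@displacements
    q <- world + cbind(as.numeric(u[, , , 1]), as.numeric(u[, , , 2]),
                       as.numeric(u[, , , 3]))
  } else stop("transform must be an AffineTransform or DeformationField")
  vals <- .interpolate(image@data, .worldToVoxel(q, image@affine),
                       interpolation)
  new("VolumeImage", data = array(vals, dim = refShape), affine = refAffine)
}
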