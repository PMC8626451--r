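# Synthetic skull-stripped FDG-PET-like phantoms and cohorts. The phantom is
# a piecewise-constant ellipsoid "brain"; cohorts add smooth random warps,
# per-subject global gain, additive noise, and optional metabolic outliers.

#' Construct a PhantomSpec
#'
#' @param shape integer grid dimensions (voxels).
#' @param spacing numeric voxel size per axis (mm).
#' @param compartments list of compartments, each a list with `name`,
#'   `center` (world mm), `radii` (mm) and `uptake`. The first compartment
#'   is the outer brain ellipsoid; later compartments are painted on top.
#' @return A [PhantomSpec-class].
#' @export
phantomSpec <- function(shape, spacing, compartments) {
  new("PhantomSpec", shape = as.integer(shape), spacing = as.numeric(spacing),
      compartments = compartments)
}

#' Default brain-like phantom geometry
#'
#' An ellipsoidal brain whose radii scale with the field of view: a
#' high-uptake cortical shell, a lower-uptake white-matter core, a
#' high-uptake deep grey nucleus and a low-uptake ventricle. Uptake levels
#' (white matter 1.0, cortex 2.5, deep grey 2.2, ventricle 0.3) mirror the
#' roughly 2.5:1 grey/white FDG contrast of clinical images.
#'
#' @param shape integer grid dimensions; default 24^3.
#' @param spacing voxel size in mm; default 2 mm isotropic.
#' @return A [PhantomSpec-class].
#' @export
defaultPhantomSpec <- function(shape = c(24L, 24L, 24L), spacing = c(2, 2, 2)) {
  fov <- shape * spacing
  rb <- 0.42 * fov                    # brain ellipsoid radii, mm
  phantomSpec(shape, spacing, list(
    list(name = "cortex", center = c(0, 0, 0), radii = rb, uptake = 2.5),
    list(name = "white", center = c(0, 0, 0), radii = 0.72 * rb, uptake = 1.0),
    list(name = "deepgray", center = -0.22 * rb, radii = 0.28 * rb,
         uptake = 2.2),
    list(name = "ventricle", center = 0.25 * rb, radii = 0.18 * rb,
         uptake = 0.3)))
}

#' PET-like phantom: resolution-matched cohort source
#'
#' Blurs the piecewise-constant phantom with an isotropic Gaussian emulating
#' the intrinsic resolution of reconstructed brain FDG-PET (about 4-6 mm
#' FWHM on clinical scanners) and re-zeroes extracerebral voxels. Cohort
#' simulations should sample subjects from this volume rather than from the
#' crisp phantom: real PET images have no step edges, and step edges are
#' the worst case for any analysis of residual spatial misalignment.
#'
#' @param phantom output of [makePhantom()] (list with `image` and `mask`).
#' @param psfFWHM point-spread FWHM in mm (default 4).
#' @return A [VolumeImage-class].
#' @export
petLikePhantom <- function(phantom, psfFWHM = 4) {
  applyBrainMask(gaussianSmooth(phantom$image, psfFWHM), phantom$mask)
}

#' Construct a CohortSpec
#'
#' @param nSubjects cohort size.
#' @param deformationMagnitude maximum displacement of the per-subject
#'   smooth random warp, in mm (0 disables warping).
#' @param gainRange multiplicative interval for the per-subject global
#'   intensity gain.
#' @param noiseSigma standard deviation of additive Gaussian noise
#'   (intensity units, applied inside the brain).
#' @param nOutliers number of metabolic-outlier subjects.
#' @param outlierMultiplier factor applied to the outlier compartment.
#' @param outlierCompartment compartment name affected in outliers.
#' @param seed integer RNG seed for the cohort.
#' @return A [CohortSpec-class].
#' @export
cohortSpec <- function(nSubjects = 20L, deformationMagnitude = 2,
                       gainRange = c(0.9, 1.1), noiseSigma = 0.125,
                       nOutliers = 0L, outlierMultiplier = 0.4,
                       outlierCompartment = "cortex", seed = 1L) {
  new("CohortSpec", nSubjects = as.integer(nSubjects),
      deformationMagnitude = as.numeric(deformationMagnitude),
      gainRange = as.numeric(gainRange), noiseSigma = as.numeric(noiseSigma),
      nOutliers = as.integer(nOutliers),
      outlierMultiplier = as.numeric(outlierMultiplier),
      outlierCompartment = outlierCompartment, seed = as.integer(seed))
}

#' Render a phantom volume
#'
#' Paints the spec's ellipsoid compartments (in order, later compartments
#' overwriting earlier ones) onto the grid. Deterministic: no randomness is
#' involved.
#'
#' @param spec a [PhantomSpec-class].
#' @return A list with elements `image` ([VolumeImage-class]), `mask`
#'   ([BrainMask-class], the outer brain ellipsoid) and `labels`
#'   (integer 3D array; 0 = background, i = index of the compartment that
#'   owns the voxel).
#' @export
makePhantom <- function(spec) {
  affine <- .centeredAffine(spec@shape, spec@spacing)
  world <- .gridWorld(spec@shape, affine)
  img <- numeric(nrow(world))
  lab <- integer(nrow(world))
  corners <- .voxelToWorld(rbind(c(0, 0, 0), spec@shape - 1), affine)
  lo <- pmin(corners[1, ], corners[2, ]); hi <- pmax(corners[1, ], corners[2, ])
  for (i in seq_along(spec@compartments)) {
    cp <- spec@compartments[[i]]
    if (any(cp$center - cp$radii < lo - spec@spacing) ||
        any(cp$center + cp$radii > hi + spec@spacing))
      stop("compartment '", cp$name, "' extends outside the grid")
    q <- ((world[, 1] - cp$center[1]) / cp$radii[1])^2 +
         ((world[, 2] - cp$center[2]) / cp$radii[2])^2 +
         ((world[, 3] - cp$center[3]) / cp$radii[3])^2
    inside <- q <= 1
    img[inside] <- cp$uptake
    lab[inside] <- i
  }
  maskArr <- array(lab > 0L, dim = spec@shape)
  list(image = new("VolumeImage", data = array(img, dim = spec@shape),
                   affine = affine),
       mask = new("BrainMask", data = maskArr, affine = affine),
       labels = array(lab, dim = spec@shape))
}

# Smooth random displacement field with |u| capped at `magnitude` mm:
# white noise per component, Gaussian-smoothed (sigma 2 voxels), scaled so
# the maximum vector magnitude equals `magnitude`. At the magnitudes used
# here (< ~half a voxel of gradient) the warp stays invertible.
.randomWarp <- function(shape, spacing, magnitude) {
  comps <- lapply(1:3, function(c.)
    .smoothArray(array(stats::rnorm(prod(shape)), dim = shape), c(2, 2, 2)))
  mag <- sqrt(comps[[1]]^2 + comps[[2]]^2 + comps[[3]]^2)
  top <- max(mag)
  if (top <= 0) top <- 1
  u <- array(0, dim = c(shape, 3L))
  for (c. in 1:3) u[, , , c.] <- comps[[c.]] * (magnitude / top)
  u
}

#' Draw one synthetic subject
#'
#' Applies, in order: a smooth random warp (pull-back, trilinear), a global
#' multiplicative gain drawn uniformly from the gain range, additive
#' Gaussian noise, and re-zeroing of extracerebral voxels. Fully
#' reproducible from `(seed, index)`: the subject's RNG substream does not
#' depend on the other subjects.
#'
#' @param phantom the shared [VolumeImage-class] phantom.
#' @param mask the phantom's [BrainMask-class].
#' @param cohort a [CohortSpec-class].
#' @param index subject ordinal in `1:nSubjects`.
#' @return A [VolumeImage-class].
#' @export
sampleSubject <- function(phantom, mask, cohort, index) {
  if (index < 1L || index > cohort@nSubjects)
    stop("index must be in 1:nSubjects")
  .withSeed(.subjectSeed(cohort@seed, index), {
    shape <- dim(phantom@data)
    out <- phantom@data
    if (cohort@deformationMagnitude > 0) {
      u <- .randomWarp(shape, voxelSpacing(phantom),
                       cohort@deformationMagnitude)
      world <- .gridWorld(shape, phantom@affine)
      moved <- world + cbind(as.numeric(u[, , , 1]), as.numeric(u[, , , 2]),
                             as.numeric(u[, , , 3]))
      out <- array(.interpTrilinear(phantom@data,
                                    .worldToVoxel(moved, phantom@affine)),
                   dim = shape)
    }
    gain <- stats::runif(1, cohort@gainRange[1], cohort@gainRange[2])
    out <- out * gain
    if (cohort@noiseSigma > 0)
      out <- out + array(stats::rnorm(prod(shape), sd = cohort@noiseSigma),
                         dim = shape)
    out[!mask@data] <- 0
    new("VolumeImage", data = out, affine = phantom@affine)
  })
}

#' Inject a focal spherical lesion
#'
#' Scales all voxels inside a world-space sphere by `1 + relativeChange`
#' (e.g. -0.3 for a 30% hypometabolic lesion); voxels outside the sphere
#' are untouched.
#'
#' @param image a [VolumeImage-class].
#' @param center sphere centre in world mm (length 3).
#' @param radius sphere radius in mm.
#' @param relativeChange signed fractional change, > -1.
#' @return A [VolumeImage-class].
#' @export
injectLesion <- function(image, center, radius, relativeChange) {
  if (relativeChange <= -1) stop("relativeChange must exceed -1")
  shape <- dim(image@data)
  world <- .gridWorld(shape, image@affine)
  d2 <- (world[, 1] - center[1])^2 + (world[, 2] - center[2])^2 +
    (world[, 3] - center[3])^2
  inside <- d2 <= radius^2
  if (!any(inside)) stop("lesion sphere does not intersect the grid")
  out <- as.numeric(image@data)
  out[inside] <- out[inside] * (1 + relativeChange)
  new("VolumeImage", data = array(out, dim = shape), affine = image@affine)
}

#' Generate a full synthetic cohort with ground truth
#'
#' Draws `nSubjects` volumes via [sampleSubject()]; for `nOutliers` randomly
#' chosen indices the designated compartment is additionally multiplied by
#' the outlier multiplier (emulating a focal metabolic abnormality). The
#' outlier index set is part of the returned ground-truth manifest.
#'
#' @param phantom,mask,labels output of [makePhantom()] (labels may be NULL
#'   when `nOutliers` is 0).
#' @param cohort a [CohortSpec-class].
#' @param spec the [PhantomSpec-class] used (needed to resolve the outlier
#'   compartment name; may be NULL when `nOutliers` is 0).
#' @return A list: `images` (list of [VolumeImage-class]), `outliers`
#'   (sorted integer indices), `spec` (the CohortSpec).
#' @export
sampleCohort <- function(phantom, mask, cohort, labels = NULL, spec = NULL) {
  outlierIdx <- integer(0)
  if (cohort@nOutliers > 0L) {
    if (is.null(labels) || is.null(spec))
      stop("labels and spec are required when nOutliers > 0")
    compIdx <- match(cohort@outlierCompartment,
                     vapply(spec@compartments, `[[`, "", "name"))
    if (is.na(compIdx))
      stop("unknown outlier compartment '", cohort@outlierCompartment, "'")
    outlierIdx <- .withSeed(cohort@seed,
                            sort(sample.int(cohort@nSubjects,
                                            cohort@nOutliers)))
    compMask <- labels == compIdx
  }
  images <- vector("list", cohort@nSubjects)
  for (i in seq_len(cohort@nSubjects)) {
    img <- sampleSubject(phantom, mask, cohort, i)
    if (i %in% outlierIdx) {
      dat <- img@data
      dat[compMask] <- dat[compMask] * cohort@outlierMultiplier
      img <- new("VolumeImage", data = dat, affine = img@affine)
    }
    images[[i]] <- img
  }
  names(images) <- sprintf("subject%03d", seq_len(cohort@nSubjects))
  list(images = images, outliers = outlierIdx, spec = cohort)
}
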