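# S4 containers for the template-construction pipeline. All arithmetic is
# done in double precision; files are written as float32 (see volume-io.R).

.AFFINE_TOL <- 1e-6

.checkAffine <- function(affine) {
  if (!is.matrix(affine) || any(dim(affine) != c(4L, 4L)))
    return("affine must be a 4x4 matrix")
  if (any(!is.finite(affine)))
    return("affine must be finite")
  if (max(abs(affine[4L, ] - c(0, 0, 0, 1))) > .AFFINE_TOL)
    return("affine last row must be (0, 0, 0, 1)")
  d <- det(affine[1:3, 1:3, drop = FALSE])
  if (!is.finite(d) || abs(d) < 1e-12)
    return("affine is not invertible")
  NULL
}

#' VolumeImage: a 3D scalar volume with world geometry
#'
#' The unit of all pipeline data: a 3D array of tracer-uptake intensities
#' (arbitrary units) together with a 4x4 voxel-to-world affine in mm using
#' the RAS+ world convention. Voxel indices are 0-based in the affine
#' mapping, i.e. the affine maps \eqn{(i, j, k, 1)^T} (0-based) to world mm.
#'
#' @slot data numeric 3D array of voxel intensities.
#' @slot affine numeric 4x4 voxel-to-world matrix (mm).
#'
#' @section Validity:
#' `data` must have exactly three dimensions, each of extent at least 1;
#' the affine must be invertible with last row (0,0,0,1) and strictly
#' positive column-norm spacing.
#'
#' @seealso [readVolume()], [writeVolume()], [resampleToGrid()]
#' @export
setClass("VolumeImage",
  representation(data = "array", affine = "matrix"),
  validity = function(object) {
    if (length(dim(object@data)) != 3L)
      return("data must have exactly 3 dimensions")
    if (any(dim(object@data) < 1L))
      return("every dimension must have extent >= 1")
    msg <- .checkAffine(object@affine)
    if (!is.null(msg)) return(msg)
    sp <- sqrt(colSums(object@affine[1:3, 1:3, drop = FALSE]^2))
    if (any(sp <= 0)) return("voxel spacing must be strictly positive")
    TRUE
  })

#' @param data numeric 3D array.
#' @param affine numeric 4x4 voxel-to-world matrix; defaults to identity
#'   spacing of 1 mm with the volume centre at the world origin.
#' @rdname VolumeImage-class
#' @export
VolumeImage <- function(data, affine = NULL) {
  data <- .asVolumeArray(data)
  if (is.null(affine)) affine <- .centeredAffine(dim(data), c(1, 1, 1))
  new("VolumeImage", data = data, affine = affine)
}

#' BrainMask: a boolean voxel domain
#'
#' A logical 3D array on the same grid convention as [VolumeImage-class].
#' Used both to zero extracerebral voxels (facial-feature removal keeps only
#' brain tissue) and as the statistics domain for normalization, template
#' averaging and voxel-wise testing.
#'
#' @slot data logical 3D array.
#' @slot affine numeric 4x4 voxel-to-world matrix (mm).
#' @export
setClass("BrainMask",
  representation(data = "array", affine = "matrix"),
  validity = function(object) {
    if (length(dim(object@data)) != 3L)
      return("mask data must have exactly 3 dimensions")
    if (!is.logical(object@data))
      return("mask data must be logical")
    msg <- .checkAffine(object@affine)
    if (!is.null(msg)) return(msg)
    TRUE
  })

#' @param data logical (or 0/1 numeric) 3D array.
#' @param affine numeric 4x4 voxel-to-world matrix.
#' @rdname BrainMask-class
#' @export
BrainMask <- function(data, affine = NULL) {
  if (!is.logical(data)) {
    storage <- array(data != 0, dim = dim(data))
    data <- storage
  }
  if (is.null(affine)) affine <- .centeredAffine(dim(data), c(1, 1, 1))
  new("BrainMask", data = data, affine = affine)
}

#' AffineTransform: a world-to-world homogeneous transform
#'
#' Maps reference-space world points (mm) to moving-space world points
#' (pull-back convention): resampling a moving image onto a reference grid
#' samples the moving image at `matrix %*% c(p, 1)` for each reference
#' world point `p`.
#'
#' @slot matrix numeric 4x4 homogeneous matrix, last row (0,0,0,1).
#' @export
setClass("AffineTransform",
  representation(matrix = "matrix"),
  validity = function(object) {
    msg <- .checkAffine(object@matrix)
    if (!is.null(msg)) return(msg)
    TRUE
  })

#' @param matrix numeric 4x4 homogeneous matrix.
#' @rdname AffineTransform-class
#' @export
AffineTransform <- function(matrix = diag(4)) new("AffineTransform", matrix = matrix)

#' DeformationField: per-voxel displacement vectors
#'
#' Displacements in world mm defined on a reference grid, pull-back
#' convention: the field maps the world point of each reference voxel to the
#' corresponding moving-space world point `x + u(x)`. Serialized as 4D NIfTI
#' with dimension order (x, y, z, component).
#'
#' @slot displacements numeric 4D array, last dimension of extent 3.
#' @slot affine numeric 4x4 voxel-to-world matrix of the reference grid.
#' @export
setClass("DeformationField",
  representation(displacements = "array", affine = "matrix"),
  validity = function(object) {
    d <- dim(object@displacements)
    if (length(d) != 4L || d[4L] != 3L)
      return("displacements must be a 4D array with 3 components")
    if (any(!is.finite(object@displacements)))
      return("displacements must be finite everywhere")
    msg <- .checkAffine(object@affine)
    if (!is.null(msg)) return(msg)
    TRUE
  })

#' @param displacements numeric 4D array (nx, ny, nz, 3) in mm.
#' @param affine numeric 4x4 voxel-to-world matrix of the reference grid.
#' @rdname DeformationField-class
#' @export
DeformationField <- function(displacements, affine = NULL) {
  if (is.null(affine))
    affine <- .centeredAffine(dim(displacements)[1:3], c(1, 1, 1))
  new("DeformationField", displacements = displacements, affine = affine)
}

#' TemplatePair: mean and standard-deviation templates
#'
#' The product of cohort template construction: the voxel-wise mean image and
#' the voxel-wise standard-deviation image (both smoothed with the configured
#' Gaussian kernel), plus construction provenance.
#'
#' @slot mean [VolumeImage-class], the mean template.
#' @slot std [VolumeImage-class], the standard-deviation template (>= 0).
#' @slot fwhm numeric, smoothing kernel FWHM in mm.
#' @slot nSubjects integer, number of subjects retained after re-filtering.
#' @slot provenance character, identifiers of the retained subjects.
#' @export
setClass("TemplatePair",
  representation(mean = "VolumeImage", std = "VolumeImage",
                 fwhm = "numeric", nSubjects = "integer",
                 provenance = "character"),
  validity = function(object) {
    if (any(dim(object@mean@data) != dim(object@std@data)))
      return("mean and std templates must share a grid")
    if (max(abs(object@mean@affine - object@std@affine)) > .AFFINE_TOL)
      return("mean and std templates must share an affine")
    if (any(object@std@data < 0))
      return("std template must be non-negative everywhere")
    if (length(object@fwhm) != 1L || object@fwhm < 0)
      return("fwhm must be a single non-negative number")
    TRUE
  })

#' SSDReport: cohort re-filtering outcome
#'
#' Per-subject sums of squared differences to the initial mean template, the
#' cohort SSD mean and standard deviation, and the subjects excluded by the
#' three-sigma rule `|SSD_k - SSD_mean| > multiplier * SSD_std`.
#'
#' @slot ssd numeric vector of per-subject SSD values (>= 0).
#' @slot ssdMean numeric, cohort mean SSD.
#' @slot ssdStd numeric, cohort standard deviation of SSD.
#' @slot excluded integer indices of excluded subjects.
#' @slot multiplier numeric threshold multiplier (3 by default).
#' @slot ddof integer, 0 (population) or 1 (sample) degrees-of-freedom
#'   correction used for `ssdStd`.
#' @export
setClass("SSDReport",
  representation(ssd = "numeric", ssdMean = "numeric", ssdStd = "numeric",
                 excluded = "integer", multiplier = "numeric",
                 ddof = "integer"),
  validity = function(object) {
    if (any(object@ssd < 0)) return("SSD values must be non-negative")
    if (length(object@multiplier) != 1L || object@multiplier <= 0)
      return("multiplier must be a single positive number")
    if (!object@ddof %in% c(0L, 1L)) return("ddof must be 0 or 1")
    bad <- setdiff(object@excluded, seq_along(object@ssd))
    if (length(bad)) return("excluded indices out of range")
    TRUE
  })

#' TMapResult: permutation t-test outcome
#'
#' Voxel-wise t statistic map together with the permutation null of the
#' image-wide maximum statistic, the derived family-wise error threshold and
#' the significance mask. The observed labelling is always a member of the
#' null, so corrected p-values are bounded below by `1/(nPermutations + 1)`.
#'
#' @slot tmap [VolumeImage-class], voxel-wise t statistic (0 outside mask).
#' @slot alpha numeric significance level.
#' @slot nPermutations integer, relabelings in the null beyond the observed.
#' @slot maxNull numeric, permutation distribution of the image-wide maximum
#'   statistic (observed labelling included; length `nPermutations + 1`).
#' @slot threshold numeric, FWE threshold on the statistic.
#' @slot significant [BrainMask-class] of voxels with statistic > threshold.
#' @slot correctedP [VolumeImage-class] of FWE-corrected p-values (1 outside
#'   mask).
#' @slot tail character, one of "two", "left", "right".
#' @slot design character, "two_sample" or "single_case".
#' @export
setClass("TMapResult",
  representation(tmap = "VolumeImage", alpha = "numeric",
                 nPermutations = "integer", maxNull = "numeric",
                 threshold = "numeric", significant = "BrainMask",
                 correctedP = "VolumeImage", tail = "character",
                 design = "character"),
  validity = function(object) {
    if (length(object@alpha) != 1L || object@alpha <= 0 || object@alpha >= 1)
      return("alpha must be in (0, 1)")
    if (length(object@maxNull) != object@nPermutations + 1L)
      return("maxNull must have nPermutations + 1 entries")
    if (!object@tail %in% c("two", "left", "right"))
      return("tail must be 'two', 'left' or 'right'")
    TRUE
  })

#' PhantomSpec: geometry of the synthetic brain phantom
#'
#' A piecewise-constant ellipsoid phantom emulating a skull-stripped FDG-PET
#' volume: an outer "brain" ellipsoid enclosing named compartments (cortex
#' shell, white-matter core, deep grey nuclei, ...), each with a constant
#' uptake level. Background (extracerebral) voxels are 0.
#'
#' @slot shape integer grid dimensions (voxels).
#' @slot spacing numeric voxel size per axis (mm).
#' @slot compartments list of lists with elements `name`, `center` (mm,
#'   world), `radii` (mm) and `uptake`; painted in order, later compartments
#'   overwrite earlier ones. The first compartment is the outer brain
#'   ellipsoid and must enclose all others.
#' @seealso [defaultPhantomSpec()], [makePhantom()]
#' @export
setClass("PhantomSpec",
  representation(shape = "integer", spacing = "numeric",
                 compartments = "list"),
  validity = function(object) {
    if (length(object@shape) != 3L || any(object@shape < 1L))
      return("shape must be 3 positive integers")
    if (length(object@spacing) != 3L || any(object@spacing <= 0))
      return("spacing must be 3 positive numbers")
    if (length(object@compartments) < 1L)
      return("at least one compartment (the brain) is required")
    for (cp in object@compartments) {
      if (!all(c("name", "center", "radii", "uptake") %in% names(cp)))
        return("each compartment needs name, center, radii, uptake")
      if (cp$uptake < 0) return("uptake levels must be >= 0")
      if (any(cp$radii <= 0)) return("radii must be positive")
    }
    brain <- object@compartments[[1L]]
    for (cp in object@compartments[-1L]) {
      if (any(abs(cp$center - brain$center) + cp$radii > brain$radii + 1e-9))
        return(sprintf("compartment '%s' not enclosed by the brain ellipsoid",
                       cp$name))
    }
    TRUE
  })

#' CohortSpec: synthetic cohort generation parameters
#'
#' Describes how subject volumes are drawn from the shared phantom:
#' a smooth random warp (band-limited, magnitude-capped), a per-subject
#' global multiplicative gain, additive Gaussian noise inside the brain, and
#' optional metabolic-outlier subjects whose designated compartment is
#' rescaled.
#'
#' @slot nSubjects integer cohort size.
#' @slot deformationMagnitude numeric, maximum displacement of the random
#'   warp in mm (0 disables warping).
#' @slot gainRange numeric length-2, multiplicative interval for the
#'   per-subject global intensity gain (strictly positive).
#' @slot noiseSigma numeric, standard deviation of additive Gaussian noise
#'   (intensity units; applied inside the brain mask).
#' @slot nOutliers integer, number of metabolic-outlier subjects.
#' @slot outlierMultiplier numeric, factor applied to the outlier
#'   compartment's voxels.
#' @slot outlierCompartment character, name of the affected compartment.
#' @slot seed integer RNG seed; subject `i` uses a substream derived from
#'   `(seed, i)` so each subject is reproducible in isolation.
#' @export
setClass("CohortSpec",
  representation(nSubjects = "integer", deformationMagnitude = "numeric",
                 gainRange = "numeric", noiseSigma = "numeric",
                 nOutliers = "integer", outlierMultiplier = "numeric",
                 outlierCompartment = "character", seed = "integer"),
  validity = function(object) {
    if (object@nSubjects < 1L) return("nSubjects must be >= 1")
    if (object@nOutliers < 0L || object@nOutliers > object@nSubjects)
      return("nOutliers must be between 0 and nSubjects")
    if (length(object@gainRange) != 2L || any(object@gainRange <= 0) ||
        object@gainRange[2L] < object@gainRange[1L])
      return("gainRange must be a strictly positive increasing interval")
    if (object@deformationMagnitude < 0)
      return("deformationMagnitude must be >= 0")
    if (object@noiseSigma < 0) return("noiseSigma must be >= 0")
    if (object@outlierMultiplier <= -1)
      return("outlierMultiplier must exceed -1")
    TRUE
  })

#' NormalizationResult: outcome of intensity normalization
#'
#' @slot image [VolumeImage-class], the normalized volume.
#' @slot referenceMean numeric, the divisor (mean intensity of the
#'   normalization region; > 0).
#' @slot regionSize integer, number of voxels in the normalization region.
#' @slot bounds numeric length-2, the (lower, upper) fractions of the brain
#'   maximum that define the region.
#' @export
setClass("NormalizationResult",
  representation(image = "VolumeImage", referenceMean = "numeric",
                 regionSize = "integer", bounds = "numeric"),
  validity = function(object) {
    if (object@referenceMean <= 0) return("referenceMean must be positive")
    if (object@regionSize < 1L) return("regionSize must be >= 1")
    if (length(object@bounds) != 2L || object@bounds[1L] <= 0 ||
        object@bounds[1L] >= object@bounds[2L] || object@bounds[2L] > 1)
      return("bounds must satisfy 0 < lower < upper <= 1")
    TRUE
  })

#' DistortionSummary: pooled Jacobian-determinant distribution
#'
#' Histogram and summary statistics of the voxel-wise Jacobian determinant
#' |J| pooled over one or more deformation fields, restricted to a brain
#' mask. |J| = 1 is an isometric (volume-preserving) transform; values below
#' or above 1 indicate local shrinkage or expansion.
#'
#' @slot breaks numeric histogram bin edges.
#' @slot probs numeric bin probabilities (sum to 1).
#' @slot fracNear1 numeric, fraction of voxels with |J| in [0.9, 1.1].
#' @slot minJ,maxJ,meanJ numeric summary statistics of |J|.
#' @slot meanAbsLogJ numeric, mean |log J| (centrality-to-1 metric).
#' @slot perField data.frame with one row per field (min, max, mean,
#'   fracNear1, meanAbsLogJ).
#' @export
setClass("DistortionSummary",
  representation(breaks = "numeric", probs = "numeric", fracNear1 = "numeric",
                 minJ = "numeric", maxJ = "numeric", meanJ = "numeric",
                 meanAbsLogJ = "numeric", perField = "data.frame"),
  validity = function(object) {
    if (abs(sum(object@probs) - 1) > 1e-9)
      return("histogram probabilities must sum to 1")
    if (length(object@breaks) != length(object@probs) + 1L)
      return("breaks must have one more entry than probs")
    if (!(object@minJ <= object@meanJ && object@meanJ <= object@maxJ))
      return("min <= mean <= max violated")
    TRUE
  })

# ---- accessors ----

#' @rdname volData
#' @export
setMethod("volData", "VolumeImage", function(x) x@data)
#' @rdname volData
#' @export
setMethod("volData", "BrainMask", function(x) x@data)
#' @rdname volData
#' @export
setMethod("volData", "DeformationField", function(x) x@displacements)

#' @rdname volData
#' @export
setMethod("volAffine", "VolumeImage", function(x) x@affine)
#' @rdname volData
#' @export
setMethod("volAffine", "BrainMask", function(x) x@affine)
#' @rdname volData
#' @export
setMethod("volAffine", "DeformationField", function(x) x@affine)

#' @rdname volData
#' @export
setMethod("voxelSpacing", "VolumeImage",
          function(x) sqrt(colSums(x@affine[1:3, 1:3, drop = FALSE]^2)))
#' @rdname volData
#' @export
setMethod("voxelSpacing", "BrainMask",
          function(x) sqrt(colSums(x@affine[1:3, 1:3, drop = FALSE]^2)))
#' @rdname volData
#' @export
setMethod("voxelSpacing", "DeformationField",
          function(x) sqrt(colSums(x@affine[1:3, 1:3, drop = FALSE]^2)))

#' @rdname meanVolume
#' @export
setMethod("meanVolume", "TemplatePair", function(x) x@mean)
#' @rdname meanVolume
#' @export
setMethod("stdVolume", "TemplatePair", function(x) x@std)
#' @rdname meanVolume
#' @export
setMethod("templateFWHM", "TemplatePair", function(x) x@fwhm)

#' @rdname ssdValues
#' @export
setMethod("ssdValues", "SSDReport", function(x) x@ssd)
#' @rdname ssdValues
#' @export
setMethod("excludedSubjects", "SSDReport", function(x) x@excluded)

#' @rdname tStatistic
#' @export
setMethod("tStatistic", "TMapResult", function(x) x@tmap)
#' @rdname tStatistic
#' @export
setMethod("fweThreshold", "TMapResult", function(x) x@threshold)
#' @rdname tStatistic
#' @export
setMethod("significanceMask", "TMapResult", function(x) x@significant)
#' @rdname tStatistic
#' @export
setMethod("maxStatNull", "TMapResult", function(x) x@maxNull)

# ---- show methods ----

setMethod("show", "VolumeImage", function(object) {
  d <- dim(object@data)
  sp <- voxelSpacing(object)
  cat(sprintf("VolumeImage %dx%dx%d voxels, spacing %.3g x %.3g x %.3g mm\n",
              d[1], d[2], d[3], sp[1], sp[2], sp[3]))
  cat(sprintf("  intensity range [%.4g, %.4g]\n",
              min(object@data), max(object@data)))
})

setMethod("show", "BrainMask", function(object) {
  d <- dim(object@data)
  cat(sprintf("BrainMask %dx%dx%d voxels, %d in-mask (%.1f%%)\n",
              d[1], d[2], d[3], sum(object@data),
              100 * mean(object@data)))
})

setMethod("show", "DeformationField", function(object) {
  d <- dim(object@displacements)
  mag <- sqrt(object@displacements[, , , 1]^2 +
              object@displacements[, , , 2]^2 +
              object@displacements[, , , 3]^2)
  cat(sprintf("DeformationField on %dx%dx%d grid, |u| max %.3g mm, mean %.3g mm\n",
              d[1], d[2], d[3], max(mag), mean(mag)))
})

setMethod("show", "TemplatePair", function(object) {
  d <- dim(object@mean@data)
  cat(sprintf("TemplatePair %dx%dx%d voxels, %d subjects, %.3g mm FWHM smoothing\n",
              d[1], d[2], d[3], object@nSubjects, object@fwhm))
})

setMethod("show", "SSDReport", function(object) {
  cat(sprintf("SSDReport: %d subjects, SSD mean %.4g, std %.4g\n",
              length(object@ssd), object@ssdMean, object@ssdStd))
  if (length(object@excluded))
    cat("  excluded by the", object@multiplier, "sigma rule:",
        paste(object@excluded, collapse = ", "), "\n")
  else
    cat("  no subjects excluded\n")
})

setMethod("show", "TMapResult", function(object) {
  cat(sprintf(
    "TMapResult (%s, %s-tailed): %d permutations, alpha %.3g\n",
    object@design, object@tail, object@nPermutations, object@alpha))
  cat(sprintf("  FWE threshold %.4g, %d significant voxels\n",
              object@threshold, sum(object@significant@data)))
})

setMethod("show", "DistortionSummary", function(object) {
  cat(sprintf(
    "DistortionSummary: |J| in [%.3g, %.3g], mean %.4g, %.1f%% within [0.9, 1.1]\n",
    object@minJ, object@maxJ, object@meanJ, 100 * object@fracNear1))
})
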