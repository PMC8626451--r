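#' Voxel data of a volumetric object
#'
#' Accessors for the raw array payload, the voxel-to-world affine and the
#' voxel spacing (mm) of the volumetric S4 classes.
#'
#' @param x A [VolumeImage-class], [BrainMask-class] or
#'   [DeformationField-class] object.
#' @return `volData` returns the data array (3D, or 4D for deformation
#'   fields); `volAffine` the 4x4 voxel-to-world matrix; `voxelSpacing` the
#'   per-axis voxel size in mm derived from the affine column norms.
#' @aliases volAffine voxelSpacing
#' @export
setGeneric("volData", function(x) standardGeneric("volData"))

#' @rdname volData
#' @export
setGeneric("volAffine", function(x) standardGeneric("volAffine"))

#' @rdname volData
#' @export
setGeneric("voxelSpacing", function(x) standardGeneric("voxelSpacing"))

#' Template accessors
#'
#' @param x A [TemplatePair-class] object.
#' @return `meanVolume` and `stdVolume` return the mean and
#'   standard-deviation template as [VolumeImage-class]; `templateFWHM` the
#'   smoothing kernel FWHM in mm.
#' @aliases stdVolume templateFWHM
#' @export
setGeneric("meanVolume", function(x) standardGeneric("meanVolume"))

#' @rdname meanVolume
#' @export
setGeneric("stdVolume", function(x) standardGeneric("stdVolume"))

#' @rdname meanVolume
#' @export
setGeneric("templateFWHM", function(x) standardGeneric("templateFWHM"))

#' SSD re-filtering report accessors
#'
#' @param x An [SSDReport-class] object.
#' @return `ssdValues` returns the per-subject sums of squared differences;
#'   `excludedSubjects` the integer indices flagged by the three-sigma rule.
#' @aliases excludedSubjects
#' @export
setGeneric("ssdValues", function(x) standardGeneric("ssdValues"))

#' @rdname ssdValues
#' @export
setGeneric("excludedSubjects", function(x) standardGeneric("excludedSubjects"))

#' Permutation t-map accessors
#'
#' @param x A [TMapResult-class] object.
#' @return `tStatistic` returns the voxel-wise t map as a
#'   [VolumeImage-class]; `fweThreshold` the max-statistic family-wise error
#'   threshold at the configured alpha; `significanceMask` the
#'   [BrainMask-class] of suprathreshold voxels; `maxStatNull` the
#'   permutation null distribution of the image-wide maximum statistic.
#' @aliases fweThreshold significanceMask maxStatNull
#' @export
setGeneric("tStatistic", function(x) standardGeneric("tStatistic"))

#' @rdname tStatistic
#' @export
setGeneric("fweThreshold", function(x) standardGeneric("fweThreshold"))

#' @rdname tStatistic
#' @export
setGeneric("significanceMask", function(x) standardGeneric("significanceMask"))

#' @rdname tStatistic
#' @export
setGeneric("maxStatNull", function(x) standardGeneric("maxStatNull"))
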