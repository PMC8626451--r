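# Intensity normalization: divide each image by the mean intensity of the
# voxels lying within 40-90% of the maximum brain voxel intensity. Because
# the region is defined by fractions of the maximum, the operation is
# invariant to global positive rescaling and therefore idempotent.

#' Normalization reference region
#'
#' Returns the sub-mask of brain voxels whose intensity lies within
#' `[lower * M, upper * M]` (bounds inclusive), where `M` is the maximum
#' intensity over the brain mask. When no mask is supplied, nonzero voxels
#' are used, matching skull-stripped inputs whose extracerebral voxels are
#' exactly 0.
#'
#' @param image a [VolumeImage-class].
#' @param mask optional [BrainMask-class] defining "brain voxels".
#' @param lower,upper fractions of the brain maximum, 0 < lower < upper <= 1
#'   (defaults 0.40 and 0.90).
#' @return A [BrainMask-class] of the reference region.
#' @details An empty region (e.g. a constant image, whose maximum falls
#'   outside its own 40-90% window) raises an error of class
#'   `petSPM_empty_region`.
#' @export
normalizationRegion <- function(image, mask = NULL, lower = 0.40,
                                upper = 0.90) {
  stopifnot(lower > 0, lower < upper, upper <= 1)
  brain <- if (is.null(mask)) image@data != 0 else {
    .stopUnlessSameGrid(image, mask, "image and mask")
    mask@data
  }
  if (!any(brain)) stop("empty brain mask")
  M <- max(image@data[brain])
  inWindow <- brain & image@data >= lower * M & image@data <= upper * M
  if (!any(inWindow))
    stop(errorCondition(
      "empty normalization region (degenerate image, e.g. constant)",
      class = c("petSPM_empty_region", "error")))
  new("BrainMask", data = array(inWindow, dim = dim(image@data)),
      affine = image@affine)
}

#' Intensity-normalize a volume
#'
#' Divides every voxel by the mean intensity of the [normalizationRegion()]
#' so that the normalized image has mean exactly 1 over the reference
#' region. Scale-invariant (`normalize(a * I) == normalize(I)` for `a > 0`)
#' and hence idempotent; voxel ordering is preserved.
#'
#' @inheritParams normalizationRegion
#' @return A [NormalizationResult-class] with the normalized image, the
#'   divisor, the region size and the bounds used.
#' @examples
#' v <- VolumeImage(array(c(10, 5, 4, 1, 0, 0, 0, 0), c(2, 2, 2)))
#' r <- normalizeIntensity(v)
#' r@referenceMean  # 4.5: mean of {5, 4}, the voxels within [4, 9]
#' @export
normalizeIntensity <- function(image, mask = NULL, lower = 0.40,
                               upper = 0.90) {
  region <- normalizationRegion(image, mask, lower, upper)
  divisor <- mean(image@data[region@data])
  new("NormalizationResult",
      image = new("VolumeImage", data = image@data / divisor,
                  affine = image@affine),
      referenceMean = divisor, regionSize = sum(region@data),
      bounds = c(lower, upper))
}
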