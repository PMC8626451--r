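#' Resample a volume onto a reference grid
#'
#' Pull-back resampling: every voxel of the reference grid is mapped to
#' world mm through the reference affine, then into the input image's voxel
#' space through the inverse of its affine, and the input is interpolated
#' there. Sample points outside the input field of view give 0, consistent
#' with skull-stripped zero backgrounds.
#'
#' @param image a [VolumeImage-class] to resample.
#' @param reference a [VolumeImage-class] or [BrainMask-class] whose grid
#'   (shape + affine) defines the output.
#' @param interpolation `"trilinear"` (default) or `"nearest"`.
#' @return A [VolumeImage-class] on the reference grid.
#' @examples
#' v <- VolumeImage(array(stats::runif(27), c(3, 3, 3)))
#' identical(dim(volData(resampleToGrid(v, v))), c(3L, 3L, 3L))
#' @export
resampleToGrid <- function(image, reference, interpolation = "trilinear") {
  refShape <- dim(volData(reference))[1:3]
  refAffine <- volAffine(reference)
  world <- .gridWorld(refShape, refAffine)
  idx <- .worldToVoxel(world, image@affine)
  vals <- .interpolate(image@data, idx, interpolation)
  new("VolumeImage", data = array(vals, dim = refShape), affine = refAffine)
}
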