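# NIfTI reading and writing via RNifti. Files are written as float32 with
# the affine in both sform and qform; reads apply scl_slope/scl_inter and
# cast to double.

#' Read a 3D NIfTI volume
#'
#' Reads a NIfTI-1/NIfTI-2 file into a [VolumeImage-class]. The file's
#' sform (or qform when no sform is set) becomes the voxel-to-world affine;
#' intensity scaling (`scl_slope`, `scl_inter`) is applied, and the payload
#' is cast to double.
#'
#' @param path path to an existing NIfTI file (`.nii` or `.nii.gz`).
#' @return A [VolumeImage-class].
#' @details Distinct error conditions are signalled for a missing file
#'   (`petSPM_missing_file`), a payload that is not a 3D scalar volume
#'   (`petSPM_not_3d`), and a non-invertible affine
#'   (`petSPM_bad_affine`).
#' @seealso [writeVolume()], [readBrainMask()]
#' @export
readVolume <- function(path) {
  if (!file.exists(path))
    stop(errorCondition(paste0("file not found: ", path),
                        class = c("petSPM_missing_file", "error")))
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) == 4L && d[4L] == 1L) {
    img2 <- array(as.numeric(img), dim = d[1:3])
  } else if (length(d) == 3L) {
    img2 <- array(as.numeric(img), dim = d)
  } else {
    stop(errorCondition(paste0(path, ": not a 3D scalar volume (dims ",
                               paste(d, collapse = "x"), ")"),
                        class = c("petSPM_not_3d", "error")))
  }
  aff <- .niftiAffine(img)
  if (abs(det(aff[1:3, 1:3])) < 1e-12)
    stop(errorCondition(paste0(path, ": non-invertible affine"),
                        class = c("petSPM_bad_affine", "error")))
  new("VolumeImage", data = img2, affine = aff)
}

.niftiAffine <- function(img) {
  aff <- structure(RNifti::xform(img), imagedim = NULL, code = NULL)
  aff <- matrix(as.numeric(aff), 4L, 4L)
  aff
}

#' Write a volume as NIfTI-1
#'
#' Writes a [VolumeImage-class] (or [BrainMask-class]) as a float32 (uint8
#' for masks) NIfTI-1 file; the affine is stored in both sform and qform.
#'
#' @param image a [VolumeImage-class] or [BrainMask-class].
#' @param path output path ending in `.nii` or `.nii.gz`; the parent
#'   directory must exist.
#' @return `path`, invisibly.
#' @export
writeVolume <- function(image, path) {
  if (!dir.exists(dirname(path)))
    stop("parent directory does not exist: ", dirname(path))
  isMask <- is(image, "BrainMask")
  dat <- volData(image)
  arr <- if (isMask) array(as.integer(dat), dim = dim(dat))
         else array(as.numeric(dat), dim = dim(dat))
  nim <- RNifti::asNifti(arr)
  aff <- volAffine(image)
  RNifti::pixdim(nim) <- sqrt(colSums(aff[1:3, 1:3, drop = FALSE]^2))
  RNifti::sform(nim) <- structure(aff, code = 2L)
  RNifti::qform(nim) <- structure(aff, code = 1L)
  dtype <- if (isMask) "uint8" else "float"
  RNifti::writeNifti(nim, path, datatype = dtype)
  invisible(path)
}

#' Read a brain mask volume
#'
#' Reads a NIfTI file containing values in \{0, 1\} and returns a
#' [BrainMask-class]; any nonzero voxel is in-mask.
#'
#' @inheritParams readVolume
#' @return A [BrainMask-class].
#' @export
readBrainMask <- function(path) {
  v <- readVolume(path)
  BrainMask(v@data != 0, v@affine)
}

#' Read and write deformation fields
#'
#' Deformation fields are serialized as 4D NIfTI volumes with three vector
#' components per voxel (dimension order x, y, z, component), displacements
#' in world mm on the reference grid, pull-back convention.
#'
#' @param field a [DeformationField-class].
#' @param path NIfTI file path.
#' @return `readDeformationField` returns a [DeformationField-class];
#'   `writeDeformationField` returns `path` invisibly.
#' @export
writeDeformationField <- function(field, path) {
  nim <- RNifti::asNifti(field@displacements)
  aff <- field@affine
  RNifti::pixdim(nim) <- c(sqrt(colSums(aff[1:3, 1:3, drop = FALSE]^2)), 1)
  RNifti::sform(nim) <- structure(aff, code = 2L)
  RNifti::qform(nim) <- structure(aff, code = 1L)
  RNifti::writeNifti(nim, path, datatype = "float")
  invisible(path)
}

#' @rdname writeDeformationField
#' @export
readDeformationField <- function(path) {
  if (!file.exists(path))
    stop(errorCondition(paste0("file not found: ", path),
                        class = c("petSPM_missing_file", "error")))
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 4L || d[4L] != 3L)
    stop("not a 3-component 4D displacement volume: ", path)
  DeformationField(array(as.numeric(img), dim = d), .niftiAffine(img))
}

#' Zero extracerebral voxels
#'
#' Applies a brain mask: voxels outside the mask become exactly 0, in-mask
#' voxels are unchanged. This is the masking operation used to remove facial
#' features / extracerebral signal from skull-stripped volumes, and it is
#' idempotent.
#'
#' @param image a [VolumeImage-class].
#' @param mask a [BrainMask-class] on the same grid.
#' @return A masked [VolumeImage-class].
#' @export
applyBrainMask <- function(image, mask) {
  .stopUnlessSameGrid(image, mask, "image and mask")
  out <- image@data
  out[!mask@data] <- 0
  new("VolumeImage", data = out, affine = image@affine)
}
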