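# Template construction: voxel-wise mean and standard-deviation images from
# a spatially aligned, intensity-normalized cohort, with an SSD three-sigma
# re-filtering pass and isotropic Gaussian smoothing of the final templates.

.stackImages <- function(images) {
  shape <- dim(images[[1]]@data)
  for (im in images[-1]) .stopUnlessSameGrid(images[[1]], im)
  matrix(vapply(images, function(im) as.numeric(im@data),
                numeric(prod(shape))), nrow = prod(shape))
}

#' Voxel-wise mean of a cohort
#'
#' Arithmetic mean per voxel over the image list; voxels outside the mask
#' are set to 0.
#'
#' @param images non-empty list of [VolumeImage-class] on a shared grid.
#' @param mask optional [BrainMask-class]; defaults to all voxels.
#' @return A [VolumeImage-class].
#' @export
voxelwiseMean <- function(images, mask = NULL) {
  if (length(images) < 1L) stop("at least one image is required")
  X <- .stackImages(images)
  m <- rowMeans(X)
  shape <- dim(images[[1]]@data)
  if (!is.null(mask)) {
    .stopUnlessSameGrid(images[[1]], mask, "images and mask")
    m[!as.logical(mask@data)] <- 0
  }
  new("VolumeImage", data = array(m, dim = shape),
      affine = images[[1]]@affine)
}

#' Voxel-wise standard deviation of a cohort
#'
#' Per-voxel standard deviation with the configured degrees-of-freedom
#' correction (`ddof = 1`, the sample standard deviation, by default);
#' voxels outside the mask are set to 0.
#'
#' @inheritParams voxelwiseMean
#' @param ddof 0 (population) or 1 (sample) denominator correction.
#' @return A [VolumeImage-class] with non-negative voxel values.
#' @export
voxelwiseStd <- function(images, mask = NULL, ddof = 1L) {
  if (length(images) < 2L) stop("at least two images are required")
  stopifnot(ddof %in% c(0L, 1L))
  X <- .stackImages(images)
  n <- ncol(X)
  m <- rowMeans(X)
  ss <- rowSums((X - m)^2)
  s <- sqrt(pmax(ss / (n - ddof), 0))
  shape <- dim(images[[1]]@data)
  if (!is.null(mask)) {
    .stopUnlessSameGrid(images[[1]], mask, "images and mask")
    s[!as.logical(mask@data)] <- 0
  }
  new("VolumeImage", data = array(s, dim = shape),
      affine = images[[1]]@affine)
}

#' Isotropic Gaussian smoothing by FWHM
#'
#' Separable Gaussian filtering with an isotropic kernel specified by its
#' full width at half maximum in mm; the per-axis sigma in voxels is
#' `fwhm / (2 sqrt(2 ln 2)) / spacing_axis`, so anisotropic spacing is
#' handled correctly. `fwhm = 0` is the identity. Boundary handling
#' renormalizes the truncated kernel, so constant images are exactly
#' preserved.
#'
#' @param image a [VolumeImage-class].
#' @param fwhm kernel FWHM in mm (>= 0; default 8, the conventional
#'   template resolution for SPM-style analysis).
#' @return A smoothed [VolumeImage-class].
#' @export
gaussianSmooth <- function(image, fwhm = 8) {
  if (fwhm < 0) stop("fwhm must be >= 0")
  if (fwhm == 0) return(image)
  sigmaVox <- fwhm / (2 * sqrt(2 * log(2))) / voxelSpacing(image)
  new("VolumeImage", data = .smoothArray(image@data, sigmaVox),
      affine = image@affine)
}

#' Sum of squared differences between two volumes
#'
#' `SSD = sum_i (I_k(i) - I_mean(i))^2` over the mask voxels; the
#' subject-to-template discrepancy used for cohort re-filtering. Symmetric
#' in its two image arguments and >= 0. When both images have zero
#' extracerebral voxels, restricting the sum to the brain mask equals the
#' full-grid sum.
#'
#' @param subject,reference [VolumeImage-class] objects on a shared grid.
#' @param mask optional [BrainMask-class]; defaults to all voxels.
#' @return A non-negative scalar.
#' @export
ssd <- function(subject, reference, mask = NULL) {
  .stopUnlessSameGrid(subject, reference)
  d2 <- (subject@data - reference@data)^2
  if (!is.null(mask)) {
    .stopUnlessSameGrid(subject, mask, "images and mask")
    if (!any(mask@data)) stop("empty mask")
    return(sum(d2[mask@data]))
  }
  sum(d2)
}

#' Three-sigma SSD re-filtering
#'
#' Flags subject `k` for exclusion when
#' `|SSD_k - SSD_mean| > multiplier * SSD_std` (strict inequality), where
#' `SSD_mean` and `SSD_std` are the mean and standard deviation of the
#' cohort's SSD values. By default this is a single pass: the mean and
#' standard deviation are not recomputed after exclusions. With
#' `iterate = TRUE` the rule is re-applied to the survivors until no new
#' subject is flagged.
#'
#' With `SSD_std = 0` (all values equal) the strict inequality is never
#' satisfied and nothing is excluded. Note that the rule is insensitive at
#' small n: a cluster of k equal outliers among n subjects has standardized
#' deviation at most `sqrt((n-k)(n-1)/(kn))`, which for k = 2, n = 20 is
#' 2.92 — below the default multiplier of 3.
#'
#' @param ssds numeric vector of per-subject SSD values (length >= 2).
#' @param multiplier threshold multiplier (default 3).
#' @param ddof 0 or 1, denominator correction for `SSD_std` (default 1).
#' @param iterate re-apply the rule to survivors until stable.
#' @return An [SSDReport-class].
#' @export
threeSigmaFilter <- function(ssds, multiplier = 3, ddof = 1L,
                             iterate = FALSE) {
  if (length(ssds) < 2L) stop("at least two SSD values are required")
  stopifnot(ddof %in% c(0L, 1L))
  sdv <- function(x) {
    n <- length(x)
    sqrt(sum((x - mean(x))^2) / (n - ddof))
  }
  m <- mean(ssds); s <- sdv(ssds)
  excluded <- which(abs(ssds - m) > multiplier * s)
  if (iterate) {
    repeat {
      keep <- setdiff(seq_along(ssds), excluded)
      if (length(keep) < 2L) break
      m2 <- mean(ssds[keep]); s2 <- sdv(ssds[keep])
      newly <- keep[abs(ssds[keep] - m2) > multiplier * s2]
      if (!length(newly)) break
      excluded <- sort(c(excluded, newly))
    }
  }
  new("SSDReport", ssd = as.numeric(ssds), ssdMean = m, ssdStd = s,
      excluded = as.integer(excluded), multiplier = multiplier,
      ddof = as.integer(ddof))
}

#' Build mean and standard-deviation templates from a cohort
#'
#' The two-step construction workflow: intensity-normalize all spatially
#' aligned images, average them into an initial mean template, compute each
#' subject's SSD to that initial mean, exclude subjects by the three-sigma
#' rule, re-run intensity normalization on the survivors, compute the final
#' voxel-wise mean and standard-deviation templates, and smooth both with an
#' isotropic Gaussian kernel of the configured FWHM.
#'
#' @param images list (>= 3) of spatially aligned [VolumeImage-class].
#' @param mask [BrainMask-class] brain domain.
#' @param fwhm smoothing kernel FWHM in mm applied to the final mean and
#'   std templates (default 8; 0 disables smoothing).
#' @param sigmaMult three-sigma-rule multiplier (default 3).
#' @param ddof degrees-of-freedom correction for both the std template and
#'   `SSD_std` (default 1).
#' @param lower,upper intensity-normalization bounds (defaults 0.40, 0.90).
#' @param iterate passed to [threeSigmaFilter()].
#' @return A list with elements `template` ([TemplatePair-class]) and
#'   `report` ([SSDReport-class]).
#' @export
buildTemplate <- function(images, mask, fwhm = 8, sigmaMult = 3, ddof = 1L,
                          lower = 0.40, upper = 0.90, iterate = FALSE) {
  if (length(images) < 3L) stop("at least three images are required")
  ids <- names(images)
  if (is.null(ids)) ids <- sprintf("subject%03d", seq_along(images))
  norm1 <- lapply(images, function(im)
    normalizeIntensity(im, mask, lower, upper)@image)
  initMean <- voxelwiseMean(norm1, mask)
  ssds <- vapply(norm1, function(im) ssd(im, initMean, mask), 0)
  report <- threeSigmaFilter(ssds, multiplier = sigmaMult, ddof = ddof,
                             iterate = iterate)
  keep <- setdiff(seq_along(images), report@excluded)
  if (!length(keep)) stop("all subjects excluded: pathological cohort")
  norm2 <- lapply(images[keep], function(im)
    normalizeIntensity(im, mask, lower, upper)@image)
  finalMean <- voxelwiseMean(norm2, mask)
  finalStd <- voxelwiseStd(norm2, mask, ddof = ddof)
  tpl <- new("TemplatePair",
             mean = gaussianSmooth(finalMean, fwhm),
             std = gaussianSmooth(finalStd, fwhm),
             fwhm = as.numeric(fwhm), nSubjects = length(keep),
             provenance = ids[keep])
  list(template = tpl, report = report)
}
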