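# Jacobian-determinant auditing of deformation fields: |J(x)| is the local
# volume-change ratio of the transform x -> x + u(x); 1 is isometric, 0.9 a
# 10% shrinkage, 1.1 a 10% expansion.

#' Voxel-wise Jacobian determinant of a deformation field
#'
#' Computes `det(I + du/dx)` per voxel, with derivatives taken in world mm
#' (central differences in the interior, one-sided at boundary slices), so
#' anisotropic spacing does not bias the result. Central differences are
#' exact on affine displacement fields, for which the determinant is
#' `det(I + A)` at every interior voxel.
#'
#' @param field a [DeformationField-class] with at least 2 voxels per axis.
#' @return A [VolumeImage-class] of determinant values.
#' @export
jacobianDeterminant <- function(field) {
  shape <- dim(field@displacements)[1:3]
  if (any(shape < 2L)) stop("degenerate grid: need >= 2 voxels per axis")
  invA <- solve(field@affine[1:3, 1:3, drop = FALSE])
  # J[c, a] = d u_c / d world_a  (plus identity)
  J <- vector("list", 9L)
  for (c. in 1:3) {
    gv <- lapply(1:3, function(ax) .axisDiff(field@displacements[, , , c.], ax))
    for (a in 1:3) {
      J[[(c. - 1L) * 3L + a]] <- gv[[1]] * invA[1, a] + gv[[2]] * invA[2, a] +
        gv[[3]] * invA[3, a] + as.numeric(c. == a)
    }
  }
  m <- function(r, cc) J[[(r - 1L) * 3L + cc]]
  det. <- m(1, 1) * (m(2, 2) * m(3, 3) - m(2, 3) * m(3, 2)) -
    m(1, 2) * (m(2, 1) * m(3, 3) - m(2, 3) * m(3, 1)) +
    m(1, 3) * (m(2, 1) * m(3, 2) - m(2, 2) * m(3, 1))
  new("VolumeImage", data = det., affine = field@affine)
}

.interiorMask <- function(shape) {
  m <- array(FALSE, dim = shape)
  m[2:(shape[1] - 1), 2:(shape[2] - 1), 2:(shape[3] - 1)] <- TRUE
  m
}

#' Pooled distortion summary over deformation fields
#'
#' Histogram and summary statistics of |J| pooled over the mask voxels of
#' all fields. Boundary voxels (one-sided stencils, exact only to first
#' order) are excluded by default. Values outside the histogram range are
#' clamped into the end bins so probabilities always sum to 1.
#'
#' @param fields list of [DeformationField-class] on a shared grid.
#' @param mask optional [BrainMask-class]; defaults to all voxels.
#' @param bins histogram bin count (default 72).
#' @param range histogram range (default `c(0.4, 1.8)`, the span reported
#'   for Caucasian-template registrations of Chinese subjects).
#' @param excludeBoundary drop boundary voxels (default TRUE).
#' @return A [DistortionSummary-class].
#' @export
distortionSummary <- function(fields, mask = NULL, bins = 72L,
                              range = c(0.4, 1.8), excludeBoundary = TRUE) {
  if (!length(fields)) stop("at least one field is required")
  shape <- dim(fields[[1]]@displacements)[1:3]
  sel <- if (is.null(mask)) array(TRUE, dim = shape) else {
    .stopUnlessSameGrid(fields[[1]], mask, "fields and mask")
    mask@data
  }
  if (excludeBoundary) sel <- sel & .interiorMask(shape)
  if (!any(sel)) stop("empty mask after boundary exclusion")
  breaks <- seq(range[1], range[2], length.out = bins + 1L)
  per <- lapply(fields, function(f) {
    .stopUnlessSameGrid(fields[[1]], f, "fields")
    j <- jacobianDeterminant(f)@data[sel]
    list(j = j,
         row = data.frame(minJ = min(j), maxJ = max(j), meanJ = mean(j),
                          fracNear1 = mean(j >= 0.9 & j <= 1.1),
                          meanAbsLogJ = mean(abs(log(pmax(j, 1e-12))))))
  })
  all. <- unlist(lapply(per, `[[`, "j"))
  clamped <- pmin(pmax(all., range[1]), range[2])
  counts <- tabulate(pmin(bins, findInterval(clamped, breaks,
                                             rightmost.closed = TRUE)),
                     nbins = bins)
  new("DistortionSummary", breaks = breaks, probs = counts / length(all.),
      fracNear1 = mean(all. >= 0.9 & all. <= 1.1),
      minJ = min(all.), maxJ = max(all.), meanJ = mean(all.),
      meanAbsLogJ = mean(abs(log(pmax(all., 1e-12)))),
      perField = do.call(rbind, lapply(per, `[[`, "row")))
}

#' Compare two distortion distributions
#'
#' Quantifies which of two pooled |J| distributions is more centralized
#' around 1 (an isometric registration): reports, per summary, the mass
#' within [0.9, 1.1] and the mean |log J| centrality metric, their
#' differences (A minus B), and an overlay-ready histogram table.
#'
#' @param summaryA,summaryB [DistortionSummary-class] objects with
#'   identical binning.
#' @return A list: `massNear1` (length-2), `meanAbsLogJ` (length-2),
#'   `diffMass`, `diffCentrality`, and `histogram` (data.frame with bin
#'   midpoints and both probability columns).
#' @export
compareDistortion <- function(summaryA, summaryB) {
  if (length(summaryA@breaks) != length(summaryB@breaks) ||
      max(abs(summaryA@breaks - summaryB@breaks)) > 1e-9)
    stop("summaries use different binnings")
  mids <- (summaryA@breaks[-1] + summaryA@breaks[-length(summaryA@breaks)]) / 2
  list(massNear1 = c(A = summaryA@fracNear1, B = summaryB@fracNear1),
       meanAbsLogJ = c(A = summaryA@meanAbsLogJ, B = summaryB@meanAbsLogJ),
       diffMass = summaryA@fracNear1 - summaryB@fracNear1,
       diffCentrality = summaryA@meanAbsLogJ - summaryB@meanAbsLogJ,
       histogram = data.frame(mid = mids, probA = summaryA@probs,
                              probB = summaryB@probs))
}
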