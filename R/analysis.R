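# SPM-style analysis: z-score maps, voxel-wise t statistics and
# max-statistic permutation family-wise error control.

#' Voxel-wise z-score map of a patient against a template pair
#'
#' `z(i) = (patient(i) - mean(i)) / max(std(i), floor)` inside the mask,
#' 0 outside. The patient image must already be spatially and intensity
#' normalized to the template grid.
#'
#' @param patient a [VolumeImage-class] on the template grid.
#' @param template a [TemplatePair-class].
#' @param mask optional [BrainMask-class]; defaults to all voxels.
#' @param floor lower bound on the std denominator (default 1e-6) guarding
#'   near-zero-variance voxels.
#' @return A [VolumeImage-class] z map.
#' @export
zscoreMap <- function(patient, template, mask = NULL, floor = 1e-6) {
  mu <- meanVolume(template); sd. <- stdVolume(template)
  .stopUnlessSameGrid(patient, mu, "patient and template")
  z <- (patient@data - mu@data) / pmax(sd.@data, floor)
  if (!is.null(mask)) {
    .stopUnlessSameGrid(patient, mask, "patient and mask")
    z[!mask@data] <- 0
  }
  new("VolumeImage", data = array(z, dim = dim(patient@data)),
      affine = patient@affine)
}

# Voxel-wise single-case t for column j treated as the singleton "patient"
# against the remaining columns: t = (x_j - mean_ctrl)/(sd_ctrl sqrt(1+1/n)),
# df = n - 1. Algebraically identical to the pooled two-sample t with group
# sizes (1, n): the singleton contributes nothing to the pooled variance.
.singleCaseT <- function(X, j) {
  n <- ncol(X) - 1L
  S <- rowSums(X); S2 <- rowSums(X^2)
  xj <- X[, j]
  m <- (S - xj) / n
  v <- pmax((S2 - xj^2 - n * m^2) / (n - 1), 0)
  sdv <- sqrt(v)
  t <- (xj - m) / (sdv * sqrt(1 + 1 / n))
  t[sdv == 0] <- 0
  t
}

# Pooled two-sample t for columns `ia` (group A) vs the rest; df = n - 2.
.twoGroupT <- function(X, ia) {
  n <- ncol(X); nA <- length(ia); nB <- n - nA
  A <- X[, ia, drop = FALSE]; B <- X[, -ia, drop = FALSE]
  mA <- rowMeans(A); mB <- rowMeans(B)
  ssA <- rowSums((A - mA)^2); ssB <- rowSums((B - mB)^2)
  pv <- (ssA + ssB) / (nA + nB - 2)
  se <- sqrt(pv * (1 / nA + 1 / nB))
  t <- (mA - mB) / se
  t[se == 0] <- 0
  t
}

#' Single-case t map: one patient against a control group
#'
#' The pooled-variance two-sample t specialized to group sizes (1, n): the
#' pooled variance is estimable only from the controls, giving
#' `t(i) = (patient(i) - mean_ctrl(i)) / (sd_ctrl(i) * sqrt(1 + 1/n))` with
#' `n - 1` degrees of freedom. Zero-variance voxels get t = 0.
#'
#' @param patient a [VolumeImage-class].
#' @param controls list (>= 3) of control [VolumeImage-class] on the same
#'   grid.
#' @param mask optional [BrainMask-class]; t is 0 outside.
#' @return A [VolumeImage-class] t map.
#' @export
singleCaseTMap <- function(patient, controls, mask = NULL) {
  if (length(controls) < 3L) stop("at least three controls are required")
  X <- .stackImages(c(list(patient), controls))
  t <- .singleCaseT(X, 1L)
  shape <- dim(patient@data)
  if (!is.null(mask)) t[!as.logical(mask@data)] <- 0
  new("VolumeImage", data = array(t, dim = shape), affine = patient@affine)
}

#' Two-group pooled-variance t map
#'
#' Voxel-wise two-sample t with pooled variance, `df = nA + nB - 2`; voxels
#' with zero pooled variance get t = 0 by convention.
#'
#' @param groupA,groupB lists of [VolumeImage-class] (each >= 2) on a shared
#'   grid.
#' @param mask optional [BrainMask-class]; t is 0 outside.
#' @return A [VolumeImage-class] t map.
#' @export
twoGroupTMap <- function(groupA, groupB, mask = NULL) {
  if (length(groupA) < 2L || length(groupB) < 2L)
    stop("each group needs at least two images")
  X <- .stackImages(c(groupA, groupB))
  t <- .twoGroupT(X, seq_along(groupA))
  shape <- dim(groupA[[1]]@data)
  if (!is.null(mask)) t[!as.logical(mask@data)] <- 0
  new("VolumeImage", data = array(t, dim = shape),
      affine = groupA[[1]]@affine)
}

#' Nonparametric permutation t-test with max-statistic FWE control
#'
#' Voxel-wise nonparametric two-sample t-test: the null distribution of the
#' image-wide maximum statistic (|t|, -t or t depending on `tail`) is built
#' by relabeling exchangeable subjects, always including the observed
#' labelling. The family-wise error threshold at level `alpha` is the
#' `ceil((1 - alpha) * B)`-th order statistic of the B null values, and a
#' voxel is significant when its observed statistic strictly exceeds it.
#' Corrected p-values are `mean(null >= statistic)` and are bounded below by
#' `1/B`.
#'
#' For two-group designs all `choose(n, nA)` relabelings are enumerated when
#' their count is at most `nPermutations`; otherwise `nPermutations` random
#' relabelings are drawn (deterministically from `seed`). For single-case
#' designs (one group of size 1) the permutation set is the `n + 1`
#' assignments of the singleton label, fully enumerated when that count is
#' at most `nPermutations`.
#'
#' @param groupA,groupB lists of [VolumeImage-class] on a shared grid;
#'   `groupA` of length 1 selects the single-case design.
#' @param mask optional [BrainMask-class] statistics domain; defaults to
#'   all voxels.
#' @param alpha family-wise significance level (default 0.05).
#' @param nPermutations relabelings beyond the observed one (default 999).
#' @param seed RNG seed for sampled relabelings.
#' @param tail `"two"` (|t|, default), `"left"` (-t) or `"right"` (t).
#' @return A [TMapResult-class].
#' @details An error of class `petSPM_too_few_permutations` is raised when
#'   the minimum achievable corrected p-value `1/B` exceeds `alpha`.
#' @export
permutationFWE <- function(groupA, groupB, mask = NULL, alpha = 0.05,
                           nPermutations = 999L, seed = 1L, tail = "two") {
  stopifnot(tail %in% c("two", "left", "right"))
  if (is(groupA, "VolumeImage")) groupA <- list(groupA)
  nA <- length(groupA); nB <- length(groupB); n <- nA + nB
  X <- .stackImages(c(groupA, groupB))
  sel <- if (is.null(mask)) rep(TRUE, nrow(X)) else as.logical(mask@data)
  Xm <- X[sel, , drop = FALSE]
  singleCase <- nA == 1L
  if (!singleCase && (nA < 2L || nB < 2L))
    stop("each group needs >= 2 images (or use a single-case design)")
  if (singleCase && nB < 3L) stop("at least three controls are required")

  stat <- switch(tail, two = abs, left = function(t) -t, right = identity)

  if (singleCase) {
    total <- n  # n-1 controls + patient: assignments of the singleton label
    if (total <= nPermutations + 1L) {
      assigns <- seq_len(n)
    } else {
      assigns <- c(1L, .withSeed(seed, sample(2:n, nPermutations)))
    }
    tObs <- .singleCaseT(Xm, 1L)
    maxNull <- vapply(assigns, function(j) max(stat(.singleCaseT(Xm, j))), 0)
  } else {
    nComb <- choose(n, nA)
    if (nComb <= nPermutations + 1L) {
      combs <- utils::combn(n, nA)
      # move the observed labelling first
      obsCol <- which(apply(combs, 2L, function(cc) all(cc == seq_len(nA))))
      ord <- c(obsCol, setdiff(seq_len(ncol(combs)), obsCol))
      combs <- combs[, ord, drop = FALSE]
    } else {
      combs <- cbind(seq_len(nA),
                     .withSeed(seed, replicate(nPermutations,
                                               sort(sample.int(n, nA)))))
    }
    tObs <- .twoGroupT(Xm, seq_len(nA))
    maxNull <- apply(combs, 2L, function(ia) max(stat(.twoGroupT(Xm, ia))))
  }

  B <- length(maxNull)
  if (1 / B > alpha)
    stop(errorCondition(sprintf(
      "too few permutations: minimum achievable corrected p = 1/%d = %.4g > alpha = %g",
      B, 1 / B, alpha), class = c("petSPM_too_few_permutations", "error")))
  threshold <- sort(maxNull)[ceiling((1 - alpha) * B)]
  sObs <- stat(tObs)
  sig <- sObs > threshold
  pCorr <- vapply(sObs, function(s) mean(maxNull >= s), 0)

  shape <- dim(groupB[[1]]@data)
  aff <- groupB[[1]]@affine
  tFull <- numeric(prod(shape)); tFull[sel] <- tObs
  pFull <- rep(1, prod(shape)); pFull[sel] <- pCorr
  sigFull <- logical(prod(shape)); sigFull[sel] <- sig
  new("TMapResult",
      tmap = new("VolumeImage", data = array(tFull, shape), affine = aff),
      alpha = alpha, nPermutations = B - 1L, maxNull = maxNull,
      threshold = threshold,
      significant = new("BrainMask", data = array(sigFull, shape),
                        affine = aff),
      correctedP = new("VolumeImage", data = array(pFull, shape),
                       affine = aff),
      tail = tail, design = if (singleCase) "single_case" else "two_sample")
}

#' End-to-end single-patient SPM analysis
#'
#' Runs the full analysis a user would apply to a patient volume: optional
#' affine spatial normalization of the patient (and raw controls) onto the
#' template grid, intensity normalization by the 40-90% rule, optional
#' smoothing at the template FWHM, the single-case permutation t-test with
#' max-statistic FWE control, and a z-score map against the template pair.
#' With `outDir` set, writes the t map, z map and significance mask as
#' NIfTI plus a JSON report (threshold, null quantiles, suprathreshold peak
#' voxels); the report is byte-identical across runs with the same seed.
#'
#' @param patient a [VolumeImage-class].
#' @param controls list of control [VolumeImage-class].
#' @param template a [TemplatePair-class].
#' @param mask optional [BrainMask-class] statistics domain.
#' @param spatialNormalize register patient and controls to the mean
#'   template with the builtin affine MI registration (default FALSE:
#'   inputs are already aligned, the distributed-template use case).
#' @param smooth smooth patient and controls at the template FWHM before
#'   testing (default TRUE).
#' @param lower,upper intensity-normalization bounds.
#' @param alpha,nPermutations,seed,tail passed to [permutationFWE()].
#' @param outDir optional output directory for NIfTI and JSON outputs.
#' @return A list with elements `tmap` ([TMapResult-class]), `zmap`
#'   ([VolumeImage-class]) and `report` (the report list).
#' @export
spmAnalyze <- function(patient, controls, template, mask = NULL,
                       spatialNormalize = FALSE, smooth = TRUE,
                       lower = 0.40, upper = 0.90, alpha = 0.05,
                       nPermutations = 999L, seed = 1L, tail = "two",
                       outDir = NULL) {
  mu <- meanVolume(template)
  prep <- function(im, label) {
    if (spatialNormalize) {
      tr <- registerAffine(im, mu)
      im <- applyTransform(im, tr, mu)
    }
    im <- tryCatch(normalizeIntensity(im, mask, lower, upper)@image,
                   error = function(e)
                     stop("intensity normalization failed for ", label, ": ",
                          conditionMessage(e), call. = FALSE))
    if (smooth && templateFWHM(template) > 0)
      im <- gaussianSmooth(im, templateFWHM(template))
    im
  }
  patient <- prep(patient, "patient")
  controls <- lapply(seq_along(controls), function(i)
    prep(controls[[i]], paste0("control ", i)))
  res <- permutationFWE(patient, controls, mask = mask, alpha = alpha,
                        nPermutations = nPermutations, seed = seed,
                        tail = tail)
  z <- zscoreMap(patient, template, mask)
  tArr <- res@tmap@data
  sigIdx <- which(res@significant@data, arr.ind = TRUE)
  peaks <- if (nrow(sigIdx)) {
    o <- order(abs(tArr[res@significant@data]), decreasing = TRUE)
    head. <- utils::head(o, 10L)
    data.frame(i = sigIdx[head., 1], j = sigIdx[head., 2],
               k = sigIdx[head., 3],
               t = tArr[res@significant@data][head.])
  } else data.frame(i = integer(), j = integer(), k = integer(),
                    t = numeric())
  report <- list(
    alpha = alpha, nPermutations = res@nPermutations, seed = seed,
    tail = tail, fweThreshold = res@threshold,
    nSignificantVoxels = sum(res@significant@data),
    nullQuantiles = as.list(stats::quantile(res@maxNull,
                                            c(0.5, 0.9, 0.95, 0.99))),
    peakVoxels = peaks)
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    writeVolume(res@tmap, file.path(outDir, "tmap.nii.gz"))
    writeVolume(z, file.path(outDir, "zmap.nii.gz"))
    writeVolume(res@significant, file.path(outDir, "significance_mask.nii.gz"))
    jsonlite::write_json(report, file.path(outDir, "report.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  list(tmap = res, zmap = z, report = report)
}
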