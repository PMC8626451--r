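# z-score maps, single-case and two-group t statistics, permutation FWE.

# textbook pooled two-sample t at one voxel, written independently of the
# package's matrix implementation
pooledT <- function(xa, xb) {
  na <- length(xa); nb <- length(xb)
  ssq <- function(x) if (length(x) > 1) sum((x - mean(x))^2) else 0
  sp2 <- (ssq(xa) + ssq(xb)) / (na + nb - 2)
  (mean(xa) - mean(xb)) / sqrt(sp2 * (1 / na + 1 / nb))
}

test_that("z maps reproduce the defining identities", {
  ph <- stdPhantom()
  src <- petSource()
  cs <- cohortSpec(nSubjects = 8L, deformationMagnitude = 0,
                   gainRange = c(0.95, 1.05), noiseSigma = 0.08, seed = 9L)
  coh <- sampleCohort(src, ph$mask, cs)
  bt <- buildTemplate(coh$images, ph$mask, fwhm = 0)
  tpl <- bt$template
  z0 <- zscoreMap(meanVolume(tpl), tpl, ph$mask)
  expect_identical(max(abs(volData(z0))), 0)
  plus <- VolumeImage(volData(meanVolume(tpl)) + volData(stdVolume(tpl)),
                      volAffine(meanVolume(tpl)))
  z1 <- volData(zscoreMap(plus, tpl, ph$mask))
  ok <- volData(ph$mask) & volData(stdVolume(tpl)) > 1e-6
  expect_equal(unique(round(z1[ok], 9)), 1)
})

test_that("a hypometabolic lesion drives the z score below -3", {
  # uniform-uptake brain with 5% noise: a -30% lesion sits an expected six
  # standard deviations below the template mean
  spec <- phantomSpec(c(24, 24, 24), c(2, 2, 2), list(
    list(name = "brain", center = c(0, 0, 0), radii = c(16, 16, 16),
         uptake = 1)))
  ph <- makePhantom(spec)
  cs <- cohortSpec(nSubjects = 21L, deformationMagnitude = 0,
                   gainRange = c(0.95, 1.05), noiseSigma = 0.05, seed = 15L)
  coh <- sampleCohort(ph$image, ph$mask, cs)
  bt <- buildTemplate(coh$images[1:20], ph$mask, fwhm = 0)
  healthy <- normalizeIntensity(coh$images[[21]], ph$mask)@image
  patient <- injectLesion(healthy, c(0, 0, 0), 6, -0.3)
  z <- volData(zscoreMap(patient, bt$template, ph$mask))
  world <- petSPM:::.gridWorld(dim(z), volAffine(ph$image))
  lesion <- array(rowSums(world^2) <= 36, dim(z)) & volData(ph$mask)
  expect_lt(mean(z[lesion]), -3)
  # and the unlesioned remainder of the brain stays near zero on average
  expect_lt(abs(mean(z[volData(ph$mask) & !lesion])), 1)
})

test_that("single-case t matches its closed form and the pooled-t identity", {
  # patient 10, controls {1, 2, 3}: t = (10-2)/(1*sqrt(1+1/3))
  mk <- function(x) VolumeImage(array(x, c(1, 1, 1)))
  tm <- singleCaseTMap(mk(10), list(mk(1), mk(2), mk(3)))
  expect_equal(volData(tm)[1], 8 / sqrt(4 / 3), tolerance = 1e-12)
  expect_equal(volData(tm)[1], pooledT(10, c(1, 2, 3)), tolerance = 1e-12)
  # random voxels: singleton-group pooled t equals the single-case formula
  set.seed(20)
  p <- randomVolume(c(3L, 3L, 3L), seed = 21)
  ctr <- lapply(22:27, function(s) randomVolume(c(3L, 3L, 3L), seed = s))
  tmap <- volData(singleCaseTMap(p, ctr))
  for (i in c(1L, 9L, 27L)) {
    xa <- volData(p)[i]
    xb <- sapply(ctr, function(v) volData(v)[i])
    expect_equal(tmap[i], pooledT(xa, xb), tolerance = 1e-10)
  }
  # patient equal to the control mean gives t = 0
  cm <- voxelwiseMean(ctr)
  expect_lt(max(abs(volData(singleCaseTMap(cm, ctr)))), 1e-12)
})

test_that("two-group t matches the textbook oracle and its conventions", {
  A <- lapply(1:2, function(s) randomVolume(c(3L, 3L, 3L), seed = s))
  B <- lapply(3:7, function(s) randomVolume(c(3L, 3L, 3L), seed = s))
  tmap <- volData(twoGroupTMap(A, B))
  for (i in c(2L, 14L, 27L)) {
    xa <- sapply(A, function(v) volData(v)[i])
    xb <- sapply(B, function(v) volData(v)[i])
    expect_equal(tmap[i], pooledT(xa, xb), tolerance = 1e-10)
  }
  # same images in both groups: t = 0 everywhere
  expect_identical(max(abs(volData(twoGroupTMap(A, A)))), 0)
  # zero pooled variance: t = 0 by convention
  z0 <- VolumeImage(array(0, c(2, 2, 2))); o1 <- VolumeImage(array(1, c(2, 2, 2)))
  expect_identical(max(abs(volData(twoGroupTMap(list(z0, z0),
                                                list(o1, o1))))), 0)
  expect_error(twoGroupTMap(list(z0), list(o1, o1)), "at least two")
})

test_that("t maps are location- and scale-equivariant in the right way", {
  A <- lapply(1:3, function(s) randomVolume(c(3L, 3L, 3L), seed = 30 + s))
  B <- lapply(1:4, function(s) randomVolume(c(3L, 3L, 3L), seed = 40 + s))
  base <- volData(twoGroupTMap(A, B))
  shift <- randomVolume(c(3L, 3L, 3L), seed = 50)
  As <- lapply(A, function(v) VolumeImage(volData(v) + volData(shift)))
  Bs <- lapply(B, function(v) VolumeImage(volData(v) + volData(shift)))
  expect_equal(volData(twoGroupTMap(As, Bs)), base, tolerance = 1e-10)
  Am <- lapply(A, function(v) VolumeImage(3.7 * volData(v)))
  Bm <- lapply(B, function(v) VolumeImage(3.7 * volData(v)))
  expect_equal(volData(twoGroupTMap(Am, Bm)), base, tolerance = 1e-10)
})

test_that("identical inputs yield no significant voxels at any level", {
  v <- randomVolume(c(4L, 4L, 4L), seed = 60)
  same <- lapply(1:10, function(i) v)
  res <- permutationFWE(same[1:5], same[6:10], alpha = 0.05,
                        nPermutations = 200L, seed = 1L)
  expect_identical(sum(volData(significanceMask(res))), 0L)
})

test_that("too few permutations for the requested alpha is an error", {
  ctr <- lapply(1:9, function(s) randomVolume(c(3L, 3L, 3L), seed = s))
  p <- randomVolume(c(3L, 3L, 3L), seed = 99)
  # single-case with 9 controls enumerates 10 assignments: min p = 0.1
  expect_error(
    permutationFWE(p, ctr, alpha = 0.05, nPermutations = 999L),
    class = "petSPM_too_few_permutations")
  # and the same design is fine at alpha 0.2
  res <- permutationFWE(p, ctr, alpha = 0.2, nPermutations = 999L)
  expect_identical(res@nPermutations, 9L)
  expect_identical(res@design, "single_case")
})

test_that("permutation results are deterministic given the seed", {
  set.seed(3)
  imgs <- lapply(1:12, function(s) randomVolume(c(4L, 4L, 4L), seed = 70 + s))
  r1 <- permutationFWE(imgs[1:6], imgs[7:12], alpha = 0.05,
                       nPermutations = 99L, seed = 5L)
  r2 <- permutationFWE(imgs[1:6], imgs[7:12], alpha = 0.05,
                       nPermutations = 99L, seed = 5L)
  expect_identical(maxStatNull(r1), maxStatNull(r2))
  expect_identical(fweThreshold(r1), fweThreshold(r2))
  expect_identical(volData(significanceMask(r1)), volData(significanceMask(r2)))
})

test_that("full enumeration is used when the label space is small", {
  imgs <- lapply(1:6, function(s) randomVolume(c(3L, 3L, 3L), seed = 80 + s))
  res <- permutationFWE(imgs[1:3], imgs[4:6], alpha = 0.2,
                        nPermutations = 999L, seed = 1L)
  expect_identical(res@nPermutations, as.integer(choose(6, 3)) - 1L)
  # corrected p values respect the permutation floor
  pmin. <- 1 / (res@nPermutations + 1)
  expect_gte(min(volData(res@correctedP)), pmin.)
  expect_lte(max(volData(res@correctedP)), 1)
  # the significance mask is exactly the thresholded statistic
  expect_identical(volData(significanceMask(res)),
                   abs(volData(tStatistic(res))) > fweThreshold(res))
})

test_that("spmAnalyze is reproducible and writes a complete report", {
  ph <- stdPhantom()
  src <- petSource()
  cs <- cohortSpec(nSubjects = 13L, deformationMagnitude = 0,
                   gainRange = c(0.95, 1.05), noiseSigma = 0.1, seed = 8L)
  coh <- sampleCohort(src, ph$mask, cs)
  bt <- buildTemplate(coh$images[1:12], ph$mask, fwhm = 8)
  patient <- coh$images[[13]]
  d1 <- file.path(tempdir(), "spm1"); d2 <- file.path(tempdir(), "spm2")
  r1 <- spmAnalyze(patient, coh$images[1:12], bt$template, mask = ph$mask,
                   alpha = 0.1, nPermutations = 99L, seed = 7L, outDir = d1)
  r2 <- spmAnalyze(patient, coh$images[1:12], bt$template, mask = ph$mask,
                   alpha = 0.1, nPermutations = 99L, seed = 7L, outDir = d2)
  expect_identical(readLines(file.path(d1, "report.json")),
                   readLines(file.path(d2, "report.json")))
  for (f in c("tmap.nii.gz", "zmap.nii.gz", "significance_mask.nii.gz"))
    expect_true(file.exists(file.path(d1, f)))
  # a held-out healthy control is typically clean at a strict level
  expect_lte(sum(volData(significanceMask(r1$tmap))),
             0.001 * sum(volData(ph$mask)))
})
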