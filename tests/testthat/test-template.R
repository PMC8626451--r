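# Voxel-wise mean/std, Gaussian smoothing, SSD and the three-sigma
# re-filtering, plus the assembled template-construction pipeline.

naiveMean <- function(arrs) {
  out <- array(0, dim(arrs[[1]]))
  for (i in seq_along(out))
    out[i] <- mean(sapply(arrs, function(a) a[i]))
  out
}
naiveStd <- function(arrs, ddof) {
  out <- array(0, dim(arrs[[1]]))
  for (i in seq_along(out)) {
    x <- sapply(arrs, function(a) a[i])
    out[i] <- sqrt(sum((x - mean(x))^2) / (length(x) - ddof))
  }
  out
}

test_that("voxel-wise mean and std match brute-force loop oracles", {
  imgs <- lapply(1:5, function(s) randomVolume(c(4L, 4L, 4L), seed = s))
  arrs <- lapply(imgs, volData)
  expect_equal(volData(voxelwiseMean(imgs)), naiveMean(arrs),
               tolerance = 1e-12)
  for (ddof in c(0L, 1L))
    expect_equal(volData(voxelwiseStd(imgs, ddof = ddof)),
                 naiveStd(arrs, ddof), tolerance = 1e-12)
})

test_that("mean and std handle trivial stacks correctly", {
  v <- randomVolume(c(3L, 3L, 3L), seed = 2)
  expect_equal(volData(voxelwiseMean(list(v))), volData(v), tolerance = 1e-15)
  expect_equal(volData(voxelwiseMean(list(v, VolumeImage(3 * volData(v))))),
               2 * volData(v), tolerance = 1e-12)
  same <- list(v, v, v)
  expect_identical(max(volData(voxelwiseStd(same))), 0)
  # two images, voxel values 0 and 2
  a <- VolumeImage(array(0, c(2, 2, 2))); b <- VolumeImage(array(2, c(2, 2, 2)))
  expect_equal(volData(voxelwiseStd(list(a, b), ddof = 1L))[1], sqrt(2),
               tolerance = 1e-12)
  expect_equal(volData(voxelwiseStd(list(a, b), ddof = 0L))[1], 1,
               tolerance = 1e-12)
  expect_error(voxelwiseStd(list(v)), "two images")
})

test_that("mean respects the mask domain", {
  v <- randomVolume(c(4L, 4L, 4L), seed = 6)
  m <- array(FALSE, c(4, 4, 4)); m[1:2, , ] <- TRUE
  mk <- BrainMask(m, volAffine(v))
  out <- volData(voxelwiseMean(list(v, v), mk))
  expect_identical(unique(as.numeric(out[!m])), 0)
  expect_equal(out[m], volData(v)[m], tolerance = 1e-15)
})

test_that("Gaussian smoothing preserves constants and honours fwhm", {
  v <- VolumeImage(array(2.5, c(10, 10, 10)))
  expect_equal(volData(gaussianSmooth(v, 8)), volData(v), tolerance = 1e-12)
  r <- randomVolume(c(6L, 6L, 6L), seed = 4)
  expect_identical(volData(gaussianSmooth(r, 0)), volData(r))
  expect_error(gaussianSmooth(r, -1), ">= 0")
  # impulse response: measured FWHM within 5% of the nominal 8 mm
  arr <- array(0, c(25, 25, 25)); arr[13, 13, 13] <- 1
  vi <- VolumeImage(arr, petSPM:::.centeredAffine(c(25, 25, 25), c(2, 2, 2)))
  sm <- volData(gaussianSmooth(vi, 8))
  prof <- sm[, 13, 13]
  sigmaVox <- 8 / (2 * sqrt(2 * log(2))) / 2
  expect_equal(sigmaVox, 1.698643600, tolerance = 1e-8)
  # fit sigma from the profile's second moment
  x <- (1:25) - 13
  sigmaHat <- sqrt(sum(prof * x^2) / sum(prof))
  measuredFWHM <- 2 * sqrt(2 * log(2)) * sigmaHat * 2
  expect_lt(abs(measuredFWHM - 8) / 8, 0.05)
})

test_that("SSD matches hand-evaluated sums and is symmetric", {
  a <- VolumeImage(array(c(1, 2, 3, 0, 0, 0, 0, 0), c(2, 2, 2)))
  b <- VolumeImage(array(c(1, 1, 1, 0, 0, 0, 0, 0), c(2, 2, 2)))
  expect_identical(ssd(a, a), 0)
  expect_identical(ssd(a, b), 5)
  expect_identical(ssd(b, a), ssd(a, b))
  m <- array(TRUE, c(2, 2, 2)); m[3] <- FALSE
  expect_identical(ssd(a, b, BrainMask(m, volAffine(a))), 1)
  # loop oracle on random stacks
  x <- randomVolume(c(4L, 4L, 4L), seed = 11)
  y <- randomVolume(c(4L, 4L, 4L), seed = 12)
  expect_equal(ssd(x, y), sum((volData(x) - volData(y))^2), tolerance = 1e-12)
})

test_that("the three-sigma rule handles degenerate and textbook cases", {
  # all equal: std 0, strict inequality never fires
  r <- threeSigmaFilter(rep(2, 6))
  expect_length(excludedSubjects(r), 0)
  # small-n insensitivity: {1,1,1,1,100} excludes nothing under either ddof
  for (ddof in c(0L, 1L))
    expect_length(excludedSubjects(threeSigmaFilter(c(1, 1, 1, 1, 100),
                                                    ddof = ddof)), 0)
  # 99 values near 1 plus one at 100: exactly the large one flagged
  set.seed(42)
  vals <- c(stats::runif(99, 0.9, 1.1), 100)
  r2 <- threeSigmaFilter(vals)
  expect_identical(excludedSubjects(r2), 100L)
  # brute-force check of the rule for the same data
  m <- mean(vals); s <- stats::sd(vals)
  expect_identical(excludedSubjects(r2), which(abs(vals - m) > 3 * s))
})

test_that("exclusion is invariant under positive rescaling of all SSDs", {
  set.seed(7)
  vals <- c(stats::rgamma(18, 4), 60, 0.01)
  base <- excludedSubjects(threeSigmaFilter(vals))
  for (a in c(1e-3, 7, 1e5))
    expect_identical(excludedSubjects(threeSigmaFilter(a * vals)), base)
})

test_that("iterated re-filtering unmasks successive outliers", {
  # one extreme value hides a second; the single pass takes the first,
  # iteration takes both
  vals <- c(rep(1, 30), 8, 40)
  single <- threeSigmaFilter(vals)
  expect_identical(excludedSubjects(single), 32L)
  iter <- threeSigmaFilter(vals, iterate = TRUE)
  expect_identical(excludedSubjects(iter), c(31L, 32L))
})

test_that("a cohort of identical images yields the image itself and zero std", {
  ph <- stdPhantom()
  src <- petSource()
  res <- buildTemplate(list(src, src, src, src), ph$mask, fwhm = 0)
  gt <- normalizeIntensity(src, ph$mask)@image
  expect_equal(volData(meanVolume(res$template)), volData(gt),
               tolerance = 1e-12)
  expect_identical(max(volData(stdVolume(res$template))), 0)
  expect_length(excludedSubjects(res$report), 0)
})

test_that("no-deformation no-noise cohorts recover the normalized phantom", {
  ph <- stdPhantom()
  src <- petSource()
  cs <- cohortSpec(nSubjects = 6L, deformationMagnitude = 0,
                   gainRange = c(0.8, 1.2), noiseSigma = 0, seed = 3L)
  coh <- sampleCohort(src, ph$mask, cs)
  res <- buildTemplate(coh$images, ph$mask, fwhm = 8)
  gt <- gaussianSmooth(normalizeIntensity(src, ph$mask)@image, 8)
  expect_equal(volData(meanVolume(res$template)), volData(gt),
               tolerance = 1e-6)
})

test_that("injected outliers are excluded in detectable regimes", {
  ph <- stdPhantom()
  src <- petSource()
  # one outlier among 20 and two among 25 are both above the masking cap
  # sqrt((n-k)(n-1)/(kn)) of the single-pass rule
  for (cfg in list(c(n = 20L, k = 1L), c(n = 25L, k = 2L))) {
    cs <- cohortSpec(nSubjects = cfg[["n"]], deformationMagnitude = 0,
                     gainRange = c(1, 1), noiseSigma = 0.02,
                     nOutliers = cfg[["k"]], outlierMultiplier = 0.4,
                     seed = 400L + cfg[["n"]])
    coh <- sampleCohort(src, ph$mask, cs, labels = ph$labels,
                        spec = stdSpec())
    res <- buildTemplate(coh$images, ph$mask, fwhm = 0)
    expect_identical(sort(excludedSubjects(res$report)),
                     sort(as.integer(coh$outliers)))
    expect_identical(res$template@nSubjects,
                     as.integer(cfg[["n"]] - cfg[["k"]]))
  }
})

test_that("template provenance lists exactly the retained subjects", {
  ph <- stdPhantom()
  src <- petSource()
  imgs <- lapply(1:5, function(i) {
    set.seed(i)
    VolumeImage(volData(src) * (1 + 0.01 * stats::rnorm(1)), volAffine(src))
  })
  names(imgs) <- paste0("s", 1:5)
  res <- buildTemplate(imgs, ph$mask, fwhm = 0)
  expect_identical(res$template@provenance,
                   paste0("s", setdiff(1:5, excludedSubjects(res$report))))
})
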