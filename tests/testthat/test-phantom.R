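# Synthetic phantom and cohort generator: determinism, construction
# geometry, gain/noise/lesion semantics, ground-truth manifests.

test_that("single-ellipsoid phantom is binary and matches its mask", {
  spec <- phantomSpec(c(16, 16, 16), c(2, 2, 2), list(
    list(name = "brain", center = c(0, 0, 0), radii = c(12, 12, 12),
         uptake = 1)))
  ph <- makePhantom(spec)
  expect_setequal(unique(as.numeric(volData(ph$image))), c(0, 1))
  expect_identical(sum(volData(ph$mask)), sum(volData(ph$image) == 1))
})

test_that("nested compartments produce exactly the specified levels", {
  spec <- phantomSpec(c(16, 16, 16), c(2, 2, 2), list(
    list(name = "cortex", center = c(0, 0, 0), radii = c(12, 12, 12),
         uptake = 2),
    list(name = "core", center = c(0, 0, 0), radii = c(6, 6, 6),
         uptake = 0.5)))
  ph <- makePhantom(spec)
  expect_setequal(unique(as.numeric(volData(ph$image))), c(0, 0.5, 2))
})

test_that("ellipsoid voxel volume approximates the analytic volume", {
  spacing <- c(1, 1, 1)
  radii <- c(9, 10, 8)   # >= 8 voxels per radius
  spec <- phantomSpec(c(24, 24, 24), spacing, list(
    list(name = "brain", center = c(0, 0, 0), radii = radii, uptake = 1)))
  ph <- makePhantom(spec)
  analytic <- 4 / 3 * pi * prod(radii) / prod(spacing)
  expect_lt(abs(sum(volData(ph$mask)) - analytic) / analytic, 0.05)
})

test_that("a compartment leaking outside the grid is rejected", {
  spec <- phantomSpec(c(8, 8, 8), c(1, 1, 1), list(
    list(name = "brain", center = c(0, 0, 0), radii = c(20, 20, 20),
         uptake = 1)))
  expect_error(makePhantom(spec), "outside the grid")
})

test_that("degenerate cohort parameters reproduce the phantom exactly", {
  ph <- stdPhantom()
  cs <- cohortSpec(nSubjects = 3L, deformationMagnitude = 0,
                   gainRange = c(1, 1), noiseSigma = 0, seed = 4L)
  s <- sampleSubject(ph$image, ph$mask, cs, 2L)
  expect_identical(volData(s), volData(ph$image))
  # pure gain
  cs2 <- cohortSpec(nSubjects = 3L, deformationMagnitude = 0,
                    gainRange = c(2, 2), noiseSigma = 0, seed = 4L)
  s2 <- sampleSubject(ph$image, ph$mask, cs2, 1L)
  expect_equal(volData(s2), 2 * volData(ph$image), tolerance = 1e-12)
})

test_that("subjects are bitwise reproducible from (seed, index)", {
  ph <- stdPhantom()
  cs <- cohortSpec(nSubjects = 5L, deformationMagnitude = 2,
                   noiseSigma = 0.1, seed = 77L)
  a <- sampleSubject(ph$image, ph$mask, cs, 3L)
  b <- sampleSubject(ph$image, ph$mask, cs, 3L)
  expect_identical(volData(a), volData(b))
  # different index gives a different draw
  expect_false(identical(volData(a),
                         volData(sampleSubject(ph$image, ph$mask, cs, 4L))))
})

test_that("cohorts with identical specs are identical across runs", {
  ph <- stdPhantom()
  cs <- cohortSpec(nSubjects = 4L, deformationMagnitude = 1,
                   noiseSigma = 0.05, nOutliers = 1L, seed = 12L)
  a <- sampleCohort(ph$image, ph$mask, cs, labels = ph$labels,
                    spec = stdSpec())
  b <- sampleCohort(ph$image, ph$mask, cs, labels = ph$labels,
                    spec = stdSpec())
  expect_identical(a$outliers, b$outliers)
  for (i in seq_along(a$images))
    expect_identical(volData(a$images[[i]]), volData(b$images[[i]]))
})

test_that("warped subjects respect the displacement cap and zero background", {
  ph <- stdPhantom()
  cs <- cohortSpec(nSubjects = 2L, deformationMagnitude = 2,
                   gainRange = c(1, 1), noiseSigma = 0, seed = 5L)
  s <- sampleSubject(ph$image, ph$mask, cs, 1L)
  expect_identical(unique(as.numeric(volData(s)[!volData(ph$mask)])), 0)
  expect_lte(max(volData(s)), max(volData(ph$image)) + 1e-12)
})

test_that("lesion injection scales exactly the in-sphere voxels", {
  ph <- stdPhantom()
  img <- ph$image
  expect_identical(volData(injectLesion(img, c(0, 0, 0), 8, 0)), volData(img))
  les <- injectLesion(img, c(0, 0, 0), 8, -0.3)
  world <- petSPM:::.gridWorld(dim(volData(img)), volAffine(img))
  inside <- array(rowSums(world^2) <= 64, dim(volData(img)))
  expect_equal(volData(les)[inside], 0.7 * volData(img)[inside],
               tolerance = 1e-12)
  expect_identical(volData(les)[!inside], volData(img)[!inside])
  # sum deficit equals 0.3 x the pre-lesion in-sphere sum
  expect_equal(sum(volData(img)) - sum(volData(les)),
               0.3 * sum(volData(img)[inside]), tolerance = 1e-9)
  expect_error(injectLesion(img, c(500, 0, 0), 3, -0.3), "intersect")
  expect_error(injectLesion(img, c(0, 0, 0), 8, -1), "exceed")
})

test_that("outlier bookkeeping matches the requested counts", {
  ph <- stdPhantom()
  cs0 <- cohortSpec(nSubjects = 6L, deformationMagnitude = 0,
                    noiseSigma = 0, nOutliers = 0L, seed = 2L)
  expect_length(sampleCohort(ph$image, ph$mask, cs0)$outliers, 0)
  cs2 <- cohortSpec(nSubjects = 10L, deformationMagnitude = 0,
                    noiseSigma = 0, nOutliers = 2L, seed = 2L)
  coh <- sampleCohort(ph$image, ph$mask, cs2, labels = ph$labels,
                      spec = stdSpec())
  expect_length(coh$outliers, 2)
  expect_true(all(coh$outliers %in% 1:10))
})

test_that("outlier subjects carry the compartment multiplier", {
  ph <- stdPhantom()
  cs <- cohortSpec(nSubjects = 10L, deformationMagnitude = 0,
                   gainRange = c(1, 1), noiseSigma = 0, nOutliers = 2L,
                   outlierMultiplier = 0.4, outlierCompartment = "cortex",
                   seed = 31L)
  coh <- sampleCohort(ph$image, ph$mask, cs, labels = ph$labels,
                      spec = stdSpec())
  cortex <- ph$labels == 1L   # first compartment
  flaggedMean <- mean(sapply(coh$outliers, function(i)
    mean(volData(coh$images[[i]])[cortex])))
  normalMean <- mean(sapply(setdiff(1:10, coh$outliers), function(i)
    mean(volData(coh$images[[i]])[cortex])))
  expect_equal(flaggedMean / normalMean, 0.4, tolerance = 1e-9)
})

test_that("noise-free cohort mean equals gain-mean times the phantom", {
  ph <- stdPhantom()
  cs <- cohortSpec(nSubjects = 8L, deformationMagnitude = 0,
                   gainRange = c(0.8, 1.2), noiseSigma = 0, seed = 21L)
  coh <- sampleCohort(ph$image, ph$mask, cs)
  m <- voxelwiseMean(coh$images, ph$mask)
  gains <- sapply(1:8, function(i) {
    s <- volData(coh$images[[i]]); p <- volData(ph$image)
    s[p > 0][1] / p[p > 0][1]
  })
  expect_equal(volData(m), mean(gains) * volData(ph$image), tolerance = 1e-12)
})
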