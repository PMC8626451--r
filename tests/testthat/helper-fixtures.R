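# Shared fixtures, built once per test run. The standard phantom is the
# default 24^3 brain at 2 mm spacing; `petSource` is its PSF-blurred
# (PET-resolution) counterpart used as the cohort generating image.

.fixtures <- new.env(parent = emptyenv())

stdPhantom <- function() {
  if (is.null(.fixtures$phantom)) {
    .fixtures$spec <- defaultPhantomSpec()
    .fixtures$phantom <- makePhantom(.fixtures$spec)
  }
  .fixtures$phantom
}

stdSpec <- function() {
  stdPhantom()
  .fixtures$spec
}

petSource <- function() {
  if (is.null(.fixtures$src))
    .fixtures$src <- petLikePhantom(stdPhantom(), psfFWHM = 4)
  .fixtures$src
}

# Small random volume on a unit grid, reproducible.
randomVolume <- function(shape = c(6L, 6L, 6L), seed = 1L, affine = NULL) {
  set.seed(seed)
  VolumeImage(array(stats::runif(prod(shape)), dim = shape), affine)
}

fullMask <- function(image) {
  BrainMask(array(TRUE, dim(volData(image))), volAffine(image))
}
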