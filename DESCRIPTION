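Package: petSPM
Title: Brain PET Template Construction and Nonparametric Statistical
    Parametric Mapping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds population-specific [18F]-FDG PET brain templates from a
    cohort of spatially aligned, skull-stripped volumes and analyses single
    patient images against them. Provides cohort intensity normalization by
    the 40-90%-of-maximum rule, voxel-wise mean and standard-deviation
    template construction with sum-of-squared-differences (SSD) three-sigma
    re-filtering, isotropic Gaussian template smoothing, single-subject
    z-score maps, voxel-wise nonparametric permutation t-tests with
    max-statistic family-wise error control, mutual-information affine and
    demons-style diffeomorphic registration, Jacobian-determinant distortion
    auditing of deformation fields, and a synthetic brain-phantom cohort
    generator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    RNifti,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    oro.nifti
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'utils-internal.R'
    'volume-io.R'
    'resample.R'
    'phantom.R'
    'registration.R'
    'normalization.R'
    'template.R'
    'analysis.R'
    'jacobian.R'
    'demographics.R'
    'petSPM-package.R'
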