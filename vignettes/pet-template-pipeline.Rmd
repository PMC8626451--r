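---
title: "Building FDG-PET brain templates and testing patients against them"
author: "petSPM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building FDG-PET brain templates and testing patients against them}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(petSPM)
```

## The problem

Statistical parametric mapping (SPM) of brain FDG-PET compares a patient's
tracer uptake, voxel by voxel, against the normal range observed in a
healthy reference cohort. That comparison needs two reference volumes in a
common anatomical space: a **mean template** (the expected uptake at each
voxel) and a **standard-deviation template** (the normal variability at
each voxel). Most public templates derive from Caucasian cohorts; because
brain morphometry and metabolism differ across populations, a
population-mismatched template inflates anatomical distortion during
spatial normalization and biases the voxel statistics. This package
implements the full construction and analysis pipeline for such templates,
and ships a synthetic phantom cohort generator so that every stage can be
validated against known ground truth.

## The pipeline

Given a cohort of skull-stripped PET volumes already registered to a
common anatomical space, template construction proceeds in two passes:

1. **Intensity normalization.** Each image is divided by the mean
   intensity of its voxels lying within 40–90% of its maximum brain-voxel
   intensity (bounds inclusive). The reference region is defined by
   *fractions of the maximum*, so the operation is invariant under global
   rescaling and therefore idempotent — acquisition-dependent global
   scale is removed without requiring dose or weight information.
2. **Initial mean.** The voxel-wise arithmetic mean of the normalized
   images.
3. **Re-filtering.** For each subject \(k\), the discrepancy to the
   initial mean is summarized as
   \(\mathrm{SSD}_k = \sum_i \left(I_k(i) - I_{\mathrm{mean}}(i)\right)^2\).
   Subjects with \(|\mathrm{SSD}_k - \mathrm{SSD}_{\mathrm{mean}}| >
   3\,\mathrm{SSD}_{\mathrm{std}}\) are excluded (three-sigma rule, single
   pass by default).
4. **Final templates.** The survivors are re-normalized; the voxel-wise
   mean and standard deviation (sample standard deviation, `ddof = 1`)
   become the mean and std templates, each smoothed with an isotropic 3D
   Gaussian kernel of 8 mm FWHM — the conventional working resolution of
   SPM-style analysis. Smoothing is applied to the finished templates, not
   to the inputs, and the std map is smoothed directly.

Patient analysis (`spmAnalyze()`) mirrors the same preprocessing —
registration to the mean template where needed, the same intensity
normalization, smoothing at the template FWHM — and then compares the
patient with the control stack by a voxel-wise nonparametric two-sample
t-test with max-statistic family-wise error (FWE) control, plus a z-score
map \((\mathrm{patient} - \mathrm{mean})/\mathrm{std}\) against the
template pair.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| normalization bounds | 0.40 / 0.90 | fraction of brain max | the standard percent-of-max reference window; inclusive bounds, exposed as flags |
| template smoothing | 8 | mm FWHM | matches the resolution convention of SPM-style group analysis |
| re-filter multiplier | 3 | SSD standard deviations | the three-sigma rule |
| `ddof` | 1 | — | sample statistics for both the std template and SSD_std |
| significance level | 0.05 | FWE-corrected | two-sided on max |t| by default; one-sided tails available |
| permutations | 999 | — | min achievable corrected p = 1/(B) where B includes the observed labelling |
| diffeo gradient step | 0.2 | — | demons step scaling of the reference configuration |
| diffeo update smoothing | 3 × spacing | mm (sigma) | see "numerical choices" below |

## The permutation test

For two groups the null is built by relabeling subjects; for a single
patient against \(n\) controls the label space is the \(n+1\) assignments
of the singleton label, enumerated exhaustively whenever that count does
not exceed the permutation budget. The observed labelling is always a
member of the null, so corrected p-values are bounded below by
\(1/(B)\) with \(B\) null members, and the test errors out early when that
floor already exceeds the requested alpha (e.g. a single case against 9
controls cannot reach 0.05). The FWE threshold is the
\(\lceil (1-\alpha) B \rceil\)-th order statistic of the image-wide
maximum statistic, and a voxel is significant when its observed statistic
strictly exceeds it. Exchangeability under the null makes the test exact
up to Monte-Carlo error; the acceptance suite verifies the empirical FWER
on 200 null phantom cohorts.

The single-case t statistic is the pooled two-sample t specialized to
group sizes (1, n): \(t = (x - \bar{c}) / (s_c \sqrt{1 + 1/n})\) with
\(n-1\) degrees of freedom — the singleton group contributes nothing to
the pooled variance. Voxels with zero pooled variance get \(t = 0\) by
convention. Variance smoothing (pseudo-t) and cluster-extent inference
are deliberately not implemented: the plain voxel-wise maximum statistic
is what the formulas state.

## Registration

Two backends cover different needs:

* **Affine (mutual information).** A 9-parameter transform (translation,
  per-axis log-scale, rotation) maximizing the mutual information of the
  joint intensity histogram, over a coarse-to-fine pyramid from a
  centre-of-mass start. Two numerical details are worth recording. First,
  the plain histogram MI is piecewise-constant in the transform
  parameters — a simplex optimizer stalls on its plateaus — so the global
  passes optimize a partial-volume (linearly weighted) histogram MI,
  which is continuous; because that soft estimate carries a small bias
  near the optimum on blurred images, a final refinement pass switches
  back to the plain histogram MI, which peaks at the true alignment.
  Second, the optimizer runs in a shifted, scaled parameter space with a
  fixed initial simplex size, because the default simplex of R's
  Nelder-Mead scales with the parameter magnitudes and degenerates at a
  near-zero start. Optimization is fully deterministic.
* **Diffeomorphic (demons).** A symmetric-force demons iteration over the
  same pyramid, honouring the reference configuration: gradient step
  scaling 0.2 and update-field Gaussian smoothing with sigma equal to
  3 × the voxel spacing. The configuration this mirrors states a "field
  smoothing variance equal to three times the voxel spacing", which mixes
  units (variance in mm², spacing in mm); it is interpreted here as a
  Gaussian sigma of 3 × spacing in mm, applied to the *update* field each
  iteration — the fluid-like regularisation that SyN-style methods apply
  to their flow field. A light total-field smoothing (sigma 1 voxel,
  configurable) is added after each iteration: with update-only
  smoothing the accumulated field drifts in gradient-free regions, and
  the drift grows with iteration count. Per-iteration updates are
  magnitude-capped, and every returned field is checked for Jacobian
  positivity (the diffeomorphism contract); a violation is reported but
  the field is still returned for inspection. A full SyN/LDDMM
  implementation is out of scope; an `external` backend hook accepts any
  function returning a `DeformationField` on the fixed grid.

Displacement fields are stored in world mm on the fixed grid under the
pull-back convention (the field maps fixed-grid points to moving-space
points), serialized as 4D NIfTI with components as the fourth dimension.

## Distortion auditing

`jacobianDeterminant()` computes \(\det(I + \partial u/\partial x)\) with
central differences in the interior and one-sided stencils at the
boundary, with derivatives taken in world mm so anisotropic voxels do not
bias the volume-change estimate. Central differences are exact on affine
fields, which provides closed-form anchors: a zero field gives
\(|J| = 1\) everywhere, single-axis scaling fields with factors 1.1 / 0.9
give exactly 1.1 / 0.9 at interior voxels. `distortionSummary()` pools
|J| over the brain mask of one or more fields (boundary voxels excluded
by default — the one-sided stencils are exact only to first order), and
`compareDistortion()` quantifies which of two distributions is more
centralized around 1 by the mass in [0.9, 1.1] together with mean
\(|\log J|\) — a metric chosen to treat shrinkage and expansion
log-symmetrically, since no standard metric is prescribed for this
comparison.

## The synthetic cohort generator

`makePhantom()` renders a piecewise-constant ellipsoid brain — cortex
shell (uptake 2.5), white-matter core (1.0), deep grey nucleus (2.2),
ventricle (0.3), roughly the 2.5:1 grey/white contrast of clinical FDG
images — plus its brain mask and a compartment label map.
`petLikePhantom()` blurs it with a 4 mm FWHM Gaussian, emulating the
intrinsic resolution of a clinical brain PET reconstruction; cohort
simulations sample from this PET-like volume because real PET contains no
step edges, and step edges are the pathological worst case for any
statistic computed under residual spatial misalignment.

`sampleSubject()` applies, in order: a smooth random warp (white-noise
vector fields smoothed with sigma 2 voxels and capped at the requested
maximum displacement — invertible at the magnitudes used), a global gain
drawn uniformly from the gain range, additive Gaussian noise, and
re-zeroing of extracerebral voxels. Subject \(i\) is reproducible from
`(seed, i)` alone. Outlier subjects additionally have one named
compartment multiplied by a factor, emulating a focal metabolic
abnormality, and the generated cohort carries its ground-truth outlier
manifest.

What the generator does **not** emulate: Poisson sinogram noise and
scatter (noise here is additive Gaussian), anatomical detail beyond
nested ellipsoids, partial-volume effects beyond a stationary Gaussian
PSF, and scanner-specific reconstruction artefacts. Passing tests
therefore demonstrate the statistical machinery under controlled
conditions, not robustness to every property of clinical data.

Default study conditions used throughout the validation suite: grids of
16³–24³ voxels at 2 mm spacing, cohorts of 20 subjects, gains in
[0.9, 1.1], noise sigma 5% of the cortex uptake, warps capped at 2 mm.
These sizes keep the full suite within minutes on one CPU while leaving
every statistic well away from small-sample degeneracy.

## A known limitation: masking in the three-sigma rule

The single-pass three-sigma SSD filter cannot flag two comparable
outliers in a cohort of twenty. For \(k\) equal-deviation outliers among
\(n\) subjects, the standardized deviation of an outlier's SSD is capped
at

\[ z_{\max} = \sqrt{\frac{(n-k)(n-1)}{kn}} \]

because the outliers themselves inflate \(\mathrm{SSD}_{\mathrm{std}}\)
(the classic *masking* phenomenon). For \(k = 2, n = 20\) the cap is
2.92 (sample std) or exactly 3.0 (population std) — below the strict
\(> 3\) threshold, independent of how extreme the outliers are. The
filter works as intended for \(k=1, n=20\) (cap 4.25), for \(k=2\) once
\(n \ge 21\), and comfortably in the regime templates are actually built
in (3 outliers among 119 gives a cap of 6.2). The validation suite
exercises the detectable regimes; the masking regime is verified to
behave exactly as this algebra predicts. An opt-in iterated mode
(`iterate = TRUE`) re-applies the rule to survivors, which unmasks
successive outliers when their magnitudes differ, but cannot help when
they are equal — the first pass already excludes nobody.

## Other numerical choices

* All internal arithmetic is double precision; NIfTI files are written as
  float32. Reads apply slope/intercept scaling; the sform (or qform)
  becomes the voxel-to-world affine, 0-based voxel indexing, RAS+ world.
* Resampling is pull-back with trilinear (or nearest) interpolation;
  sample points outside the field of view blend to 0, consistent with
  skull-stripped zero backgrounds.
* Gaussian smoothing uses per-axis sigma `fwhm / (2 sqrt(2 ln 2)) /
  spacing` and a row-renormalized truncated kernel, so constants are
  preserved exactly at boundaries; `fwhm = 0` is the identity.
* The brain maximum for intensity normalization is computed on the
  unsmoothed image; when no mask is given, nonzero voxels define "brain",
  matching skull-stripped inputs.
* Histogram MI bins each image's own min-max range into equal-width bins,
  making MI invariant to separate positive affine rescalings.
* Ties and degeneracies: zero-variance voxels get \(t = 0\);
  `SSD_std = 0` excludes nobody (strict inequality); a constant image has
  an empty 40–90% region and errors out early with a named condition.
* No re-registration to the evolving mean template is performed: subjects
  are assumed registered to the anatomical reference once, before
  averaging.
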