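---
title: "The Centamine framework: models, phantom design and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The Centamine framework: models, phantom design and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(centamine)
```

## The harmonization problem

Dopaminergic imaging tracers — DAT SPECT with [123I]ioflupane, VMAT2 PET
with [18F]AV133, and others — measure the integrity of the same nigrostriatal
projection, but their raw regional outcome, the specific binding ratio

$$\mathrm{SBR} = \frac{\mathrm{SUV}_{\mathrm{target}}}{\mathrm{SUV}_{\mathrm{reference}}} - 1,$$

lives on a tracer-specific scale: affinity, non-specific binding and
modality resolution all differ.  The Centamine scale maps every tracer onto
a common percent axis on which **100% is the mean specific binding of
healthy controls measured with the reference tracer** and **0% is the
complete absence of specific binding**.  Unlike amyloid or tau scales that
anchor their upper end to a typical disease state, the healthy anchor makes
the scale definable from a control cohort alone; because dopaminergic loss
is regionally heterogeneous, Centamines are region-specific (one value per
target region per scan).

Three calibration tiers build the scale:

* **Level 1** — per region, the healthy-control mean SBR $\mu_{HC}$ of the
  reference tracer defines the anchors: $\mathrm{CM} = 100 \times
  \mathrm{SBR} / \mu_{HC}$.
* **Level 2** — a new tracer X is regressed on the reference tracer over
  head-to-head pairs, $\mathrm{SBR}^X = a\,\mathrm{SBR}^{ref} + b$, giving
  tracer-X anchors $\mathrm{SBR}^X_{CM0} = b$ and $\mathrm{SBR}^X_{CM100} =
  a\,\mu_{HC} + b$, and hence
  $\mathrm{CM}^X = 100 \times (\mathrm{SBR}^X - b) / (a\,\mu_{HC})$.
* **Level 3** — a further tracer Y with head-to-head data against an
  already-calibrated tracer X chains through X's anchors; algebraically the
  result equals the composed linear map onto the reference scale, an
  identity the test suite pins to 1e-10.

Centamine values are deliberately not clipped: values below 0% and above
100% are legal linear extrapolations and are reported as-is.  Ordinary least
squares with the new tracer as response is the default regression,
matching the orientation of the defining equation; repeated paired sessions
are treated as independent points (the published analysis choice), with
`one_pair_per_subject = TRUE` available as a clustering sensitivity
analysis.  Confidence intervals are the standard OLS 95% intervals.  Anchors
are stored at full precision; `round_half_up()` (2 decimals, half away from
zero) is applied only at presentation.

## The synthetic analysis space and atlas

All image-level machinery operates on a fixed "MNI152-like" grid — by
default 91 x 109 x 91 voxels at 2 mm isotropic, axis order
right-anterior-superior, physical origin at the grid centre.  Because no
real anatomical atlas can be redistributed here, `build_synthetic_atlas()`
paints a deterministic geometric stand-in: 18 ellipsoidal basal-ganglia
subregions (per hemisphere: pre/post caudate, pre-dorsal, pre-ventral,
post-dorsal and post-ventral putamen, accumbens, globus pallidus, ventral
pallidum) inside nested tissue shells (cerebral white matter — the reference
region — grey matter, CSF, skull, soft tissue), 23 base labels in all.
Regions are painted in a fixed order and later paint never overwrites
earlier labels, so base labels are disjoint by construction and every
composite (caudate, pre-/post-commissural putamen, putamen, striatum, per
side and bilateral) is an exact union of children.  The ellipsoid centres
and radii are configuration, not science: every downstream computation is
shape-agnostic, and the atlas can be built on any grid coarse enough to
resolve the smallest region (all radii are at least 4 mm, so a 4 mm grid is
the practical floor).

## The phantom forward model and template bank

The forward model is *paint then smooth*: each voxel receives the value of
its region, and the image is convolved with an isotropic Gaussian kernel,
$\sigma = \mathrm{FWHM} / (2\sqrt{2\ln 2})$, with the default
$\mathrm{FWHM} = 12$ mm emulating SPECT resolution.  The kernel is truncated
at $4\sigma$ and renormalized; zero padding is used at the grid boundary.
Plain zero-padded convolution is acceptable because all head content lies
far from the grid edge — the mass-conservation invariant (total image sum
preserved to 1e-6 relative) is tested, not assumed.  The kernel is taken as
isotropic; an anisotropic extension would be a configuration change, not a
model change.

Default healthy-control painted values put the white-matter reference at
1.0 and express target regions as $1 + \mathrm{SBR}$, with caudate 1.23,
pre-commissural putamen 1.86 and post-commissural putamen 1.33 — the
healthy-control anchor values of the reference tracer — and plausible fixed
values for non-quantified structures (accumbens 1.10, globus pallidus 0.70,
ventral pallidum 0.50, grey matter 0.25, CSF/skull/soft tissue below
reference).

`build_template_bank()` generates 17 disease-stage templates from a
17-row scaling table: template 1 is the healthy-control image; templates
2-7 reduce one putamen to 75/50/25%; templates 8-17 zero both putamina and
grade caudate loss down to 25%.  All other regions stay at 100%.

`fit_template_model()` inverts the forward model.  For a fixed kernel width
the model is linear in the 23 regional values, so they are profiled out by
nonnegative least squares on the smoothed-indicator basis (a small
active-set solver on the 23 x 23 normal equations); the width is then found
by a coarse grid search (8-16 mm, 2 mm steps) with parabolic refinement
iterated to a 0.005 mm lattice.  The fine lattice matters: regions are
smaller than the kernel, so deconvolved regional values respond at roughly
1% per 0.01 mm of kernel mismatch.  An all-zero or constant target leaves
the width unidentifiable; the fit then returns zero values (or the
grid midpoint width) with `converged = FALSE`.  On noise-free forward-model
targets the fit recovers regional values well within 1% relative and the
width within 0.2 mm (property-tested over 20 random parameter draws); with
1% voxel noise the residual RMSE sits at the noise floor.

## Spatial normalization

`register_to_bank()` aligns a scan to the canonical space by a 12-parameter
affine (translation, rotation, scale, shear; matrix composed in the fixed
order T·Rz·Ry·Rx·Shear·Scale, pull-back convention with trilinear
interpolation).  The registration target is a *nonnegative linear
combination of the 17 templates* — for any candidate affine the 17
combination weights (which also absorb the global intensity scale; no
sum-to-one constraint) have a closed-form nonnegative least-squares
solution, so they are profiled out of the cost.  The cost is a weighted sum
of squared differences with a weight image that is elevated (default 10:1)
over the smoothly dilated basal-ganglia union, baseline inside the head and
zero outside, prioritizing alignment of the structures that matter for
quantification.

The affine search is box-bounded L-BFGS-B with numerical gradients: first a
rigid 6-parameter pass on extra-smoothed (additional 8 mm) images to widen
the basin of attraction, then the full 12 parameters at native smoothness.
The parameter box (|translation| <= 25 mm, |rotation| <= 0.45 rad, scale in
[0.75, 1.35], |shear| <= 0.2) doubles as the plausibility QC: it excludes
the degenerate global minimum of a profiled-weights cost (mapping the scan
out of the field of view so that zero weights fit perfectly), and transforms
at the box edge flag `converged = FALSE`.  Baseline-weight voxels are
deterministically thinned (every third voxel) in the cost quadrature for
speed; elevated voxels are always kept.  Accepted iterations are
monotone in cost, and the visual QC of a human pipeline is replaced by
automatic flags (convergence, bounds, finite cost).

`quantify_scan()` is the full single-scan pipeline and adds an alternating
refinement: the forward model is fitted *in scan space* through the current
affine (the smoothed-indicator basis is carried through the affine and
regressed against raw scan voxels — the data are never interpolated and the
kernel stays exactly isotropic in aligned space), a subject-specific model
image is painted from the fitted values, and the affine is re-optimized
against that image.  Two alternations are the default.  This matters
because the 17-template span forces anterior = posterior putamen values
within a hemisphere, while realistic subjects (and the cohort simulator)
have an anterior-posterior gradient; registering to the subject's own
fitted model removes that mismatch.  On noise-free phantoms with
misalignments up to 8 mm / 8 degrees / 5% scale, the pipeline recovers
per-region cohort-mean SBR within 1% relative and cross-tracer calibration
slopes/intercepts within a few percent.

Two SBR estimators coexist deliberately.  `compute_sbr()` is the classical
mask-mean ratio (unweighted voxel means at native resolution, bilateral =
combined mask, no partial-volume correction) — simple, standard, but biased
by spill-over when the kernel is wide relative to the region.
`fit_regional_sbr()` forms SBR from the fitted regional values, inverting
the known point-spread; it is the estimator used for phantom-recovery
validation, where ground truth is defined pre-smoothing.  On painted,
unsmoothed images both agree exactly; on smoothed images the mask-mean
estimator's bias shrinks monotonically as the kernel narrows (tested at
three widths).

## Age/sex correction, classification, change

On healthy-control Centamines, `fit_agesex()` fits per region
$\mathrm{CM} = a\,\mathrm{age} + b\,\mathrm{sex} + c$ with sex coded 0 =
female, 1 = male.  The corrected value anchors to a 65-year-old sex-average
person:

$$\mathrm{CM}^* = \mathrm{CM} \times \frac{65a + 0.5b + c}{a\,\mathrm{age} + b\,\mathrm{sex} + c}.$$

The anchor sex value 0.5 is the definitional sex-average, not the cohort's
empirical sex mean.  A non-positive denominator means the linear model is
extrapolated beyond validity and is an error rather than a silent negative
correction.

`classify_deficit()` labels a scan by the lowest-sided putamen CM*: deficit
if and only if $\min(\mathrm{left}, \mathrm{right})$ is *strictly* below
the threshold (default 75%); the boundary itself is no-deficit.  The strict
rule is a documented, test-pinned choice — the published description does
not specify the boundary.  `concordance()` reports percent agreement and
Cohen's kappa with chance agreement from marginal label frequencies; the
degenerate case of two identical constant raters is defined as kappa = 1.

`annual_change()` fits a per-subject OLS line of CM against years from
baseline and averages the slopes; percent change per annum divides the mean
slope by the group mean baseline CM (dividing each subject's slope by their
own baseline is available behind `percent = "per_subject"`).

## The cohort simulator

`cohort_config()` pins the study conditions the package validates against:

* a scale-definition cohort of 227 healthy controls (137 M / 90 F, ages
  truncated-normal 62 +/- 11.8 in [30, 85]);
* a head-to-head cohort of 68 subjects (2 healthy, 66 with stage-graded
  deficits), 45 of them followed over 2 years so that 162 paired sessions
  accumulate (the first four longitudinal subjects contribute one extra
  visit);
* healthy-control mean SBRs for the primitive regions (caudate 1.23,
  pre-commissural putamen 1.86, post-commissural putamen 1.33); putamen and
  striatum are *voxel-weighted composites* of the primitives (default
  weights 0.5 within putamen and 0.5068 caudate-within-striatum, which
  reproduce the published putamen/striatum anchors to within ~2%, and can
  be set to the actual atlas voxel counts for image-level consistency);
* age and sex effects imposed on the CM scale — slope -0.24 CM/yr and
  male offset -14.8 CM, the published 2.4%-per-decade and 14.8% effects —
  anchored so that a 65-year-old sex-average person sits at CM 100; a 10%
  between-subject coefficient of variation on top;
* deficit subjects drawn across the 16 non-healthy template stages, with an
  anterior-posterior gradient (+/-0.1 on the putamen fraction) so that the
  post-commissural putamen is always reduced most and the caudate least;
* the cross-tracer truth: per-region slope/intercept links from the
  published level-2 column, applied to the *primitive* regions, with
  composites derived by weighting (so that tabular truth and painted images
  are a single consistent object);
* longitudinal decline of deficit subjects at the published absolute rates
  (caudate -3.7, pre-commissural -3.8, post-commissural -2.3 CM/yr; the
  weighted composites then decline at approximately the published putamen
  and striatum rates); healthy controls decline at the age slope;
* measurement noise: additive Gaussian per record, 0.10 SBR for the
  reference tracer and per-region second-tracer noise (0.40, 0.55, 0.25,
  0.45, 0.45 for striatum, putamen, caudate, pre-, post-commissural
  putamen) pinned once so that simulated head-to-head R-squared lands in
  the published moderate-strong 51-83% band.  That pinning is a soft
  calibration of realism, not an acceptance claim.

Everything is a pure function of (config, seed); determinism is asserted
bit-for-bit in the tests.  Tabular mode adds noise per region directly
(fast); image mode (`render_images()` plus `quantify_scan()`) paints
per-session primitive truths into the subregions, applies a per-tracer
global intensity scale, a random misalignment affine within stated bounds,
and optional voxel noise — the two fidelity tiers keep the routine test
suite fast while the image tier exercises the full pipeline.

What the simulator does *not* emulate: anatomical variability beyond an
affine, non-Gaussian SPECT noise and reconstruction artefacts, scanner and
protocol effects, and partial-volume behaviour beyond the single Gaussian
kernel.  Passing the end-to-end tests therefore demonstrates the internal
consistency and numerical correctness of the pipeline under its own forward
model, not clinical performance on real scans.

## Numerical choices and problem sizes

* NNLS: Lawson-Hanson active sets on the normal equations (17-23 unknowns);
  a ridge of 1e-10 x diag is added only if a passive-set solve is singular.
* Registration: L-BFGS-B, factr 1e7, maxit 60 (rigid) / 120 (full);
  cost-quadrature baseline stride 3.
* Kernel-width search: grid 8-16 mm step 2, parabolic refinement to a
  0.005 mm lattice, at most 8 refinement rounds.
* Smoothed-indicator bases and fitting masks are cached per (atlas, width);
  indicator smoothing is restricted to the region's padded bounding box
  (exact, since indicators vanish outside it).
* Validation problem sizes: the test suite and worked examples run on a
  46 x 55 x 46 grid at 4 mm — the same physical space at half resolution —
  with 10-subject, two-tracer image cohorts; tabular validation uses the
  full published cohort sizes (227 / 68 / 162).  The 2 mm canonical grid is
  the default for interactive use.

## Known limitations

* The geometric atlas is a stand-in; absolute SBR values depend on its
  region volumes, which is why the simulator's composite weights are
  configurable and why validation compares against the simulator's own
  truth rather than against cohort-dependent published statistics.
* Mask-mean SBR on 12 mm-smoothed images carries substantial spill-over
  bias by design; use the model-based estimator when ground-truth recovery
  matters.
* Level-2/3 regression is OLS in the published orientation; errors in the
  reference tracer attenuate slopes on noisy data.  A Deming-style
  errors-in-variables option would be the natural extension and is not
  implemented.
* The registration cost is unimodal only within moderate misalignments
  (roughly the rigid-pass smoothing scale); initialization from gross
  misplacement is out of scope.
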