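---
title: "Estimating intracranial volume with a reverse brain mask: models, phantom and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating intracranial volume with a reverse brain mask}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rbmicv)
```

## The problem

Intracranial volume (ICV) — everything inside the inner table of the
skull: brain, CSF and meninges — is the standard covariate for removing
head-size variation from regional brain volumetry. Manual tracing on
T1-weighted MRI is the reference but costs about half an hour per scan.
Automated alternatives based on tissue-class segmentation are sensitive to
scanner field strength: at 3T a centre-bright intensity non-uniformity of
the order of 30% (versus roughly 5% at 1.5T), and a systematic intensity
offset between ventricular and cisternal CSF, push peripheral CSF out of
the segmented intracranial compartment, so ICV estimates from 1.5T and 3T
scans of the same head disagree.

The reverse-brain-mask (RBM) method sidesteps intensity entirely: the sum
of the three standard-space tissue probability maps (GM + WM + CSF, the
"ICV prior") is carried into each subject's native space through the
*inverse* of the subject-to-standard transform with nearest-neighbour
interpolation, thresholded at 90% probability, and the surviving voxels
are counted. Because only the geometry of the registration enters, the
estimate is invariant to the intensity artifacts that break tissue-class
thresholding.

This package implements, on a fully ground-truthed synthetic head
phantom:

* the RBM estimator (`build_icv_prior()`, `rbm_icv()`);
* the tissue-class comparator: atlas-prior Gaussian-mixture EM
  segmentation (`fit_tissue_model()`) followed by thresholding the
  GM+WM+CSF posterior sum (`tissue_class_icv()`);
* a polynomial log-domain bias-field corrector (`estimate_bias()`,
  `apply_correction()`);
* CSF compartment analysis — ventricular versus cisternal separation,
  Monte-Carlo intensity sampling, compartment offset, normality testing
  (`split_compartments()`, `sample_csf_intensity()`,
  `intensity_rel_diff()`, `ks_normality()`);
* agreement metrics: signed and absolute relative volume difference,
  Dice overlap, absolute-agreement ICC, slice-wise error profiles and the
  every-tenth-slice (Cavalieri) estimator used by manual protocols.

## The phantom

`phantom_spec()` defines a nested-ellipsoid head: scalp > skull > inner
table (the ICV boundary) > dura > cisternal CSF > GM shell > WM core,
with two ventricular ellipsoids inside the WM. All structures are
analytic, so ground truth (labels, masks, volumes) is exact; a random
per-subject affine (per-axis scale 0.92–1.08, rotations ±8°, translations
±4 mm) maps native to standard space, and anatomy is evaluated directly
in native coordinates, so the truth carries no resampling error.

Acquisition artifacts are applied in native space:

* **Central brightening**: a multiplicative Gaussian gain
  `1 + a·exp(−4 ln2 r²/FWHM²)` centred on the head, with amplitude
  `a = 0.05` in "1.5T" mode and `a = 0.30` in "3T" mode (FWHM 150 mm).
* **Ventricular–cisternal CSF offset**: the rendered image exhibits a
  configured symmetric relative difference (16% at 1.5T, 32% at 3T)
  between ventricular and cisternal mean intensity. The offset is
  *calibrated against the bias field*: ventricular voxels are painted as
  `csf_mean · ratio · mean(field over cisterns) / field(x)`, so that after
  the multiplicative field is applied the compartment means differ by
  exactly the configured percentage. This makes the configured value an
  *observable* of the rendered image — the same quantity the sampling
  machinery measures on real scans — rather than a pre-artifact parameter
  that the bias field would then distort.
* **CSF intensity dispersion** (`csf_dispersion_pct`, default 25%):
  voxelwise multiplicative scatter in both CSF compartments, renormalized
  to exact unit mean per compartment. Reported CSF intensity spreads are
  far larger than thermal noise (pulsatile flow, partial volume with
  meninges), and a phantom without it would make CSF implausibly easy to
  model.
* **Additive Gaussian noise** (`noise_sd = 3` on tissue means of 30–90,
  i.e. SNR ≈ 30 for WM). Rician noise is deliberately not modelled: every
  analysis here concerns mean offsets and thresholds far from the noise
  floor, where the Gaussian approximation is exact enough.

Class mean intensities follow T1 contrast: air 5, cortical bone 15
(dark), cisternal CSF 30, dura 34 (deliberately close to CSF — the
similarity of dura and CSF signal is a real confound of peripheral
segmentation), GM 65, WM 85, scalp fat 90.

The same seed renders the *same subject* (same affine, same noise draws)
under both field modes, emulating paired acquisitions of one head on two
scanners.

## Tissue priors and the margin construction

The priors are Gaussian-blurred class indicators (default FWHM 2 mm),
renormalized so GM+WM+CSF ≤ 1. The CSF indicator includes the dura and
extends a margin of `qnorm(0.9)·σ_blur` (≈ 1.1 mm) beyond the inner
table. The margin emulates a real property of population-averaged tissue
probability maps: averaged over hundreds of affinely aligned subjects,
the CSF class (which includes meninges) spreads generously around any
individual's inner table. It also has a precise consequence: for a
blurred step edge, the 90% isocontour of the prior sits exactly
`qnorm(0.9)·σ` inside the indicator edge, so with this margin the
90%-probability surface of the ICV prior coincides with the inner-table
surface *by construction*. Without the margin, thresholding the warped
prior at the conventional 90% would bite `dura + 1.28·σ_blur` inside the
inner table and systematically underestimate ICV by several percent —
the blurred-indicator construction alone cannot reproduce the accuracy
that population priors achieve at that threshold.

The standard-space brain mask — used only to separate ventricular from
cisternal CSF — thresholds the blurred brain indicator (GM, WM,
ventricles) at 0.5, the majority-vote convention of population brain
masks.

## The segmentation model

`fit_tissue_model()` maximizes the spatially-weighted mixture likelihood

$$p(x_v) = \sum_c P_c(v) \sum_{k=1}^{K_c} w_{ck}\,
\mathcal N(x_v;\, \mu_{ck}, \sigma^2_{ck}),$$

where the warped priors \(P_c(v)\) (GM, WM, CSF, and background
\(= 1 - \sum\)) act as fixed per-voxel mixing proportions — the standard
atlas-prior EM formulation. Class posteriors are summed component
responsibilities; E and M steps are in closed form, and the
observed-data log-likelihood is non-decreasing (asserted to 1e-8 in the
tests).

Component counts default to 2 for GM, WM and CSF and **4 for the
background**. One or two background components cannot model a head
exterior that contains air (≈5), cortical bone (≈15) and a
bias-broadened fat/scalp band (90–105): with too few components the
orphaned bone intensities are captured by the CSF class (bone and CSF
are both dark in T1) and the entire skull enters the intracranial mask.
Four components — air, bone, and two for the fat/scalp band — are the
minimal faithful analogue of the several non-brain classes that
production segmenters carry. `K` remains a user parameter; `csf = 4`
reproduces the "more CSF Gaussians at 3T" configuration.

Initialization is deterministic and histogram-based: for each class, the
component means start at the strongest well-separated peaks of the
prior-weighted intensity histogram, restricted to high-confidence prior
support (prior ≥ 0.9) so that contested boundary voxels cannot anchor a
component. Starting SDs are set from the gap to the nearest neighbouring
component. The obvious alternatives fail on this data: weighted
quantiles or moments collapse onto the air mode (which outweighs bone
twentyfold), and loose starting SDs let the air mode capture the bone
component within one M-step. A component whose variance collapses below
`1e-12 ×` the data variance is restarted at the class mean with inflated
variance and the event is logged in the returned model.

EM frequently uses all 50 default iterations on the full phantom without
meeting the 1e-6 relative log-likelihood tolerance; per contract it then
returns `converged = FALSE` with valid parameters rather than raising.

## Bias-field estimation

`estimate_bias()` alternates (i) deterministic 1-D clustering of the
masked, currently-corrected intensities into `k` clusters (default 6 —
bone, CSF, dura, GM, WM, fat; merging two neighbouring tissue modes into
one cluster lets their spatial segregation masquerade as bias), (ii) a
least-squares fit of a degree-`order` (default 3) 3-D polynomial in
world coordinates to the log-residuals from the cluster means, and
(iii) a gain-normalized multiplicative update. The clusterer uses the
same histogram-peak seeding as the EM initializer. Estimation runs on
the full head without skull-stripping, and the field is normalized to
unit mean over the mask.

The corrector removes smooth gain — it recovers the generator's 30%
Gaussian brightening to within ~3% across the intracranial volume — but
*cannot* remove the ventricular–cisternal offset, because that offset is
attached to tissue compartments rather than to a smooth function of
position: dividing by any smooth field that is ≈1.29 at the ventricles
and ≈1.16 over the cisterns reduces the rendered 32% offset only to
≈ 22–26%. This is the mechanism behind the persistence of compartment
offsets under every smooth bias-correction scheme.

## CSF compartments and sampling

The brain CSF mask is `ICV AND NOT (GM+WM ≥ 0.9)`. The ventricular–
cisternal split uses exactly three ingredients: ball erosion (6 mm) of
the warped standard-space brain mask to form a core, a CSF-prior floor
(0.5), and 6-connected components of the candidate set whose centroids
lie inside a doubly-eroded core. The concrete morphological sequence is
this package's own parameterization (erosion radius and prior floor are
arguments and are logged in the result's provenance).

Intensity sampling draws 10 trials of 270 voxels without replacement
(fresh substream per trial). The 270 default reflects a stated design
rule — estimating a compartment intensity SD to 10% relative error at
90% confidence — which `sample_size_for_sd()` solves by chi-square
search: 140 per region, 280 for two regions (the normal approximation
gives 135, and 270 = 2 × 135 matches the two-region reading). The
compartment offset is reported in the symmetric two-mean form
`100·(V2−V1)/((V1+V2)/2)`; normality of sampled differences is tested
with a Lilliefors-corrected one-sample Kolmogorov–Smirnov test
(plug-in mean and SD; `nortest::lillie.test()`), optionally after a log
transform. The plug-in form is the defensible reading whenever the
tested samples are the same ones that furnish the moments.

## Numerical choices

* World coordinates are RAS+ mm; voxel indices are 0-based and map
  through the affine without half-voxel shifts; the sform is preferred
  over the qform on read. Affines are written as float32 in NIfTI-1
  headers, so file round-trips preserve the affine to ~1e-6 relative,
  not bit-exactly.
* Resampling is pull-back (iterate over target voxels, map into the
  source), which cannot produce holes; out-of-field voxels are 0 in
  every volume kind. Nearest-neighbour is used for the RBM warp
  (fidelity to the published protocol) and for masks; trilinear for
  probabilities, clipped to [0, 1].
* Gaussian blurring is FFT-based with circular wrap; the head sits well
  inside the grid, making wrap-around negligible.
* Ties in intensity clustering break toward the lower-mean cluster;
  all clustering, initialization and sampling are deterministic given
  the seed, and `synthesize_subject()` is bit-reproducible.
* The chi-square search in `sample_size_for_sd()` defines the interval
  half-width as half the distance between the two-sided confidence
  bounds for σ.

## Problem sizes

The default grid is 96³ voxels at 2 mm — the resolution of standard
tissue priors — for which template construction takes ~2 s, a subject
render ~1.5 s, an EM fit ~15 s and a bias estimation ~40 s on one core.
The acceptance analyses use this grid for the ICV, bias and sampling
studies (5 subjects per field mode) and a reduced 48³ grid at 4 mm
(same head geometry) for the ten-phantom EM correctness sweep; both
sizes are the package's own choice of desk-scale study.

## What passing tests do and do not show

The phantom reproduces the *mechanisms* the analyses need — nested
anatomy with exact truth, centre brightening, compartment-specific CSF
offsets, CSF/dura intensity similarity, dispersion, affine subject
variation — but not cortical folding, partial-volume voxels, Rician
noise, nonlinear anatomy differences, or the imperfections of population
priors relative to an individual (the priors here are built from the
same template that generates every subject, i.e. registration and
anatomy are ideal up to an affine). Results on the phantom therefore
validate the implementation and the geometric claims; they do not by
themselves establish performance on clinical data.

One known consequence of the idealized priors deserves emphasis. On real
3T images, tissue-class thresholding loses cisternal CSF — the CSF
model centres on brighter fluid and the peripheral band, where the
population CSF prior is weak and non-brain priors overlap, falls below
the cut-off. In this phantom the warped priors are exact up to blur, so
interior CSF (prior ≈ 1) is structurally protected no matter how its
intensity is distorted, and the comparator's error is instead a modest
*over*-inclusion of the inner-skull shell (~2–4%), where the margin
makes the CSF prior dominate and the CSF mixture accommodates the bone
intensity. The tissue-class method is still clearly inferior to RBM in
accuracy and cross-field consistency here, but the *direction* of its 3T
failure differs from the real-data phenomenon, and the acceptance check
asserting 3T underestimation stays red under these study conditions.
Reproducing the real direction would require population-imperfect priors
(weak peripheral CSF support and dedicated non-brain prior mass inside
the cisternal band), which is outside this phantom's design.

## Limitations

* Deformations are affine throughout; nonlinear warps are out of scope.
* The "iteratively determined" tissue-class threshold of published
  pipelines is exposed as a fixed configurable value (0.90, or 0.50
  after histogram-based correction); no stopping rule is guessed.
* The ICC is fixed to the two-way random-effects, single-measure,
  absolute-agreement form, the standard choice for method-versus-manual
  agreement; a consistency form is available by argument.
* The bias corrector is one generic polynomial log-domain scheme
  standing in for the family of smooth correctors; it reproduces their
  shared qualitative property (reduction but not elimination of
  compartment offsets), not any specific tool's output.
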