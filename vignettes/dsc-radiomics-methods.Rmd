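---
title: "Methods: multicenter DSC-MRI radiomics for IDH status prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multicenter DSC-MRI radiomics for IDH status prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the model assumptions, the tunable parameters and their defaults, what
the synthetic-data generator does and does not emulate, the numerical
choices, and the known limitations. It states no empirical result that
the test suite and `scripts/acceptance.R` do not themselves compute.

## The problem

Dynamic susceptibility contrast (DSC) MRI records a rapid T2*-weighted
signal drop while a gadolinium bolus transits tissue. In gliomas, the
depth and shape of that first-pass drop, and the spatial texture of the
tumor at characteristic moments of the transit, carry information about
the isocitrate dehydrogenase (IDH) genotype: wildtype tumors — the
worse-prognosis, here *positive* class — tend to show a steeper
downslope and larger signal drop than mutant tumors, consistent with
their stronger angiogenesis.

A multicenter radiomics analysis of such data faces a confound: MR
signal is recorded in arbitrary units, and both the intensity scale and
the *fractional* depth of the bolus drop depend on the scanner and the
echo time (TE). Features extracted from raw or conventionally
normalized images therefore mix biology with acquisition protocol. The
package implements and compares two standardizations:

* **np** — conventional: per-patient z-score over all tumor voxels
  across the full dynamic acquisition, times a scale factor of 100,
  shifted by the cohort-level histogram minimum so all tumor voxels are
  non-negative;
* **p** — dynamic: the transverse relaxation-rate transform
  $\Delta R_2(t) = \tfrac{1}{TE}\,\ln\!\big(\bar S_{\text{baseline}} / S(t)\big)$,
  which removes both the arbitrary intensity scale and the explicit TE
  dependence, mapping baseline voxels to about zero.

Everything downstream — time-point selection, resampling,
discretization, the 2499-feature extraction, the imbalance-aware
combinatorial model search ranked by Cohen's kappa, frozen external
validation on held-out centers, and model explainability — is applied
identically to both versions, so any performance difference is
attributable to the standardization itself.

## Perfusion time points

All decisions are taken once per patient on the tumor mean signal
curve. Contrast arrival is detected causally: at frame $t$, the running
mean and SD of frames $1..t-1$ define the threshold
$\bar S - k\,\sigma$ with $k = 3$ by default; because a first-pass
bolus drops by tens of percent while baseline noise on a mean curve
over thousands of voxels is well under one percent, the detector
additionally requires the signal to fall at least 3% below the running
mean (`min_drop_frac = 0.03`) and to stay below the threshold for two
consecutive frames. Without those two guards, the two- or three-point
running SD available at the very start of the acquisition occasionally
declares noise blips to be the bolus. Both constants are exposed as
arguments.

At least 5 baseline frames are required; `T0` is the detection frame,
`Tmax` the frame of the signal minimum (first index on ties), and `T2`
the first frame after `Tmax` recovering to within one baseline SD of
the baseline mean, with a last-frame fallback for non-recovering
curves, so `T2` is always defined.

## Standardization and discretization

The 3D volumes at `T0`, `Tmax` and `T2` are cropped to the lesion
bounding box plus an 8 mm margin and resampled to 1 mm isotropic voxels
with separable cubic B-spline interpolation (exact interpolating
prefilter with mirror boundaries; masks are resampled linearly and
re-binarized at 0.5, because a high-order spline on a binary mask
rings). Output grids have `ceil(extent / 1 mm)` samples per axis,
anchored at the input origin.

The relaxation-rate transform uses the patient-level scalar baseline
mean from the mean curve, not a per-voxel baseline: a per-voxel
baseline would cancel exactly the static spatial heterogeneity that the
texture features must measure. Non-positive voxels (possible after
interpolation) are clamped to a small fraction of the baseline mean and
counted, so the output is always finite.

Gray levels use fixed-bin-size discretization,
$FBS = \text{meanRange} / FBN$ with $FBN = 32$ by default (64 is a
config option), where meanRange is the arithmetic mean of per-patient
VOI intensity ranges over the *exploratory* cohort. One discretization
specification is built per image version and image type (original and
each wavelet sub-band) because the sub-bands live in different
intensity domains; bins are anchored at each image's own VOI minimum.
The z-scored version's histogram-minimum shift and every
discretization specification are frozen on the exploratory cohort and
reused verbatim on validation cohorts; both are persistable as JSON.

## The feature catalogue

Per 3D image: 16 first-order, 14 shape, 24 GLCM, 14 GLDM, 16 GLSZM, 16
GLRLM and 5 NGTDM features = 105; the eight sub-bands of a single-level
undecimated Coiflet-1 wavelet transform add 91 each (no shape) = 728,
i.e. 833 per time point and 2499 per patient. Conventions follow the
IBSI-style defaults widely used in 3D radiomics: co-occurrence and
run-length statistics are computed per direction over the 13 unique 3D
offsets at distance 1 and averaged; size zones and dependence counts
use 26-connectivity with dependence tolerance 0; entropies are in bits
with zero-probability terms omitted. First-order moments and
percentiles are computed on the continuous intensities, entropy and
uniformity on the discretized levels. The first-order set keeps the 16
of the 17 conventional histogram statistics obtained by dropping
root-mean-squared, which duplicates energy up to a factor $1/\sqrt n$.
Degenerate inputs take pinned convention values (constant VOI:
skewness, kurtosis and entropy 0, uniformity 1, GLCM correlation 1,
NGTDM coarseness capped at $10^6$), and any non-finite feature is
replaced by 0 and counted, never emitted as NaN.

The undecimated transform keeps every sub-band at the input shape so
the tumor mask applies unchanged; boundaries use half-sample symmetric
extension. Shape features mesh the 0.5 iso-surface of a lightly
Gaussian-smoothed indicator (sigma 0.8 voxel) by marching tetrahedra
with linear edge interpolation: meshing the raw binary staircase
overestimates a sphere's surface by roughly a quarter, while the
smoothed mesh brings the sphericity of a radius-20 digital ball within
2% of 1. The smoothing slightly erodes the mesh volume of small
lesions (a few percent at radius 8 voxels); voxel-count volume is
reported alongside. Maximum diameters use boundary voxel centres; axis
lengths come from the eigenvalues of the physical-coordinate
covariance.

## Model search, validation, explainability

The combinatorial search crosses a robust scaler (median /
interquartile range), nine feature reducers (Gini, F-ratio, information
gain, Spearman, mRMR, mutual-information maximization, a relief-based
statistic, lasso, elastic-net logistic; ranked reducers keep the top
$k \in \{5,10,\dots,50\}$), six imbalance strategies (SMOTE, ADASYN,
SMOTE+Tomek, random undersampling, NearMiss-1, none) and ten
classifiers. RUSBoost and balanced bagging handle imbalance internally,
so they force the no-resampling option. Classifier and reducer defaults
are pinned in `inst/config/pipeline-defaults.yaml`; changing one is a
configuration change. mRMR uses the greedy difference criterion on
quartile-binned features over a relevance-ranked candidate pool of 150,
which bounds its cost without changing the top of the ranking in
practice.

Every combination is scored on identical stratified 5-fold assignments
(repeated; 20 repeats by default, 200 as in large analyses is a config
value) built once from the labels and a seed and reused across all
combinations and both image versions. Scaler, reducer and resampler
are fit on training folds only; an automated leakage probe in the test
suite verifies that perturbing test rows changes no fitted parameter.
Combinations are ranked by mean validation-fold kappa (ties: ascending
SD, then canonical order); those at or below the chance baseline of 0
are flagged discarded; individual failures are caught and logged, never
aborting the search. The winner is refit once on the whole exploratory
cohort and applied untouched to the held-out centers, with IDH-wildtype
as the positive class.

Explainability reports (a) permutation importance — the mean ± SD drop
in kappa over 50 independent shuffles of each selected feature on the
validation set — and (b) Shapley values, computed in closed form
$\phi_i = w_i (x_i - \mu_i)$ on the margin scale for linear models
(exact additivity, verified against full coalition enumeration), with a
sampling permutation estimate as the fallback for non-linear models.

## The synthetic cohort generator

The generator exists because the real three-center cohort is private;
it defines the study conditions under which the pipeline is tested.
Three centers follow the published protocol mix: center A (3T, TE
40 ms, TR 1.8 s, 60 frames at 1.87 s, 1.718 mm in-plane), center B with
two scanner variants (TE 30 ms; 60 x 2.07 s and 40 x 1.53 s) and
center C (1.5T, TE 40 ms, 60 x 1.8 s), all with 5 mm slices; intensity
scales (1000 / 1450 / 650 a.u.) and additive offsets (0 / 60 / 30)
differ per center. The default cohort is 92 + 50 + 18 = 160 patients
with 26, 11 and 4 wildtype respectively (41 wildtype / 119 mutant,
mutant majority), and centers B + C form the external validation set.

Bolus kinetics are a gamma-variate relaxation-rate curve
$\Delta R_2(t) \propto ((t-t_a)/\alpha\beta)^{\alpha} e^{\alpha - (t-t_a)/\beta}$
mapped to signal through $S = \text{offset} + S_0 e^{-TE\,\Delta R_2}$,
which makes the dynamic standardization exactly invertible on
noise-free curves (a round-trip oracle in the tests). The arrival time
is drawn uniformly in 18-26 s (always at least 5 baseline frames) and
snapped so the continuous peak falls on a sampled frame. Phenotypes
pin the biology in scanner-independent units: the fractional drop is
defined at a reference TE of 40 ms, so the underlying relaxation-rate
peak is identical across centers while the *observed* drop varies with
the protocol TE — exactly the confound the dynamic standardization
removes. Wildtype-like lesions default to a deeper, steeper bolus
(45% drop at TE 40 ms, shape 2.2, time scale 2 s) and a slightly
shorter, stronger multiplicative texture field (correlation length
3 mm, SD 0.13) than mutant-like lesions (30%, 1.6, 3 s; 4 mm, 0.11);
per-patient lognormal jitter (CV 0.2) makes the classes overlap. The
kinetic contrast deliberately dominates the texture contrast: the
fractional-drop channel is exactly the one the echo time confounds, so
it is the channel on which the two standardizations can genuinely
differ, while a large scanner-independent texture contrast would let
any standardization separate the classes and the comparison would
saturate. Lesions are
spheres with radius drawn from 8-14 mm; texture is a Gaussian random
field smoothed at the correlation length (in millimetres, so it
survives anisotropic grids and resampling) and rescaled to an exact SD
over the lesion; per-voxel white measurement noise defaults to 1% of
baseline. Everything regenerates byte-identically from the cohort
seed.

What the generator does **not** emulate: brain anatomy, arterial input
functions, recirculation and leakage (a plateau offset parameter
exists but defaults to 0), partial-volume effects at the tumor rim,
non-spherical lesions, and spatially varying coil sensitivity. Passing
the recovery tests therefore shows that the pipeline detects
kinetic-plus-texture class structure under realistic multicenter
acquisition variation — not that it would reach any particular
performance on clinical data.

## Problem sizes used in tests and the acceptance script

Simulations are sized for a single desk CPU: the cohort keeps the full
160-patient three-center composition but a 40 x 40 x 12 acquisition
matrix (the lesion and its margin, not the surrounding air, carry all
information); the combinatorial search in the recovery experiments uses
a representative 36-combination subset (Gini / F-ratio / MIM x k in
{10, 20} x ADASYN / none x L2-logistic / elastic-net logistic / linear
SVM) at 20 CV repeats; the ordering experiment refits each version's
selected pipeline on ten independent 48-patient replicate cohorts; the
null experiment removes the phenotype difference at reduced cohort
size and reports the mean held-out kappa over several independent null
cohorts (four at half scale in the test suite, three at 0.4 scale in
the acceptance script), because one null draw at ~30 validation
patients has an SD of about 0.15.
Oracle-equivalence suites run on 8^3 volumes. The full grid and
200-repeat setting remain available through `enumerate_combos()` and
the config.

## Known limitations

* The additive intensity offset corrupts the relaxation-rate transform
  slightly (the log argument is no longer a pure exponential); offsets
  are small relative to the baseline signal in the defaults, as they
  are on real scanners after vendor reconstruction.
* The multiplicative texture model makes p-version texture amplitude
  scale as $1/TE$ across centers; the dominant class signal (the
  relaxation-rate peak) is fully TE-invariant, the texture term only
  approximately so.
* Mesh volume is biased a few percent low for small lesions (smoothed
  iso-surface); sphericity and surface area are accurate to ~1-2%.
* GLDM dependence counts are border-sensitive: even a constant VOI has
  nonzero dependence-count variance because edge voxels have fewer
  neighbours; this matches the 26-neighbourhood definition, not an
  idealized zero.
* No test-retest robustness study and no feature-level harmonization
  (e.g. ComBat); both are outside the package's scope.
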