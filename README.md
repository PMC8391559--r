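# dscradiomics

Multicenter DSC-perfusion-MRI radiomics for predicting the IDH
mutation status of gliomas, as a tested, reproducible R pipeline.

## The problem

Dynamic susceptibility contrast (DSC) MRI records the T2*-weighted
signal drop caused by a gadolinium bolus transiting tissue. IDH-wildtype
gliomas (the worse-prognosis genotype, treated throughout as the
positive class) tend to show a deeper, steeper first-pass drop and more
heterogeneous tumor texture than IDH-mutant gliomas. Exploiting that
non-invasively across *several* centers is hard because MR intensities
are arbitrary-unit and the observed fractional drop depends on the echo
time: features extracted from conventionally normalized images mix
biology with acquisition protocol.

The package implements the full comparison between two image
standardizations applied upstream of an identical radiomics + machine
learning pipeline:

* **np** — conventional: per-patient z-score of all tumor voxels across
  the dynamic series, scaled by 100 and shifted non-negative;
* **p** — dynamic: the relaxation-rate transform
  `dR2(t) = (1/TE) * log(S_baseline / S(t))`, which removes the
  intensity scale and the echo-time dependence.

The shared pipeline: tumor mean-curve time-point selection (T0 = first
frame after contrast detection, Tmax = maximum drop, T2 = return to
baseline); cropping and 1 mm isotropic cubic B-spline resampling;
cohort-level fixed-bin-size discretization (`FBS = meanRange / FBN`,
FBN = 32); an IBSI-aligned catalogue of 2499 features per patient (105
original-image features + 728 from eight undecimated Coiflet-1 wavelet
sub-bands, per time point: first-order, shape, GLCM, GLDM, GLSZM,
GLRLM, NGTDM); a combinatorial model search over scalers, feature
reducers, imbalance resamplers and classifiers scored by Cohen's kappa
under repeated stratified 5-fold cross-validation with strict
train-only fitting; frozen external validation on held-out centers; and
explainability via permutation importance and exact linear-model
Shapley values.

Because the clinical three-center cohort behind this design is private,
the package ships a first-class synthetic cohort generator
(gamma-variate bolus kinetics, center-specific TE/TR/temporal
resolution/intensity calibration, two texture phenotypes, configurable
imbalance) that makes every stage testable end to end.

## Worked example

Simulate a small three-center cohort, extract both feature versions,
search, and validate on the held-out centers B and C:

```r
library(dscradiomics)

spec <- cohort_spec(
  protocols = default_protocols(matrix_size = c(40L, 40L), n_slices = 12L),
  n_per_center = c(28L, 8L, 8L, 5L),
  wildtype_fraction_per_center = c(26/92, 5/25, 6/25, 4/18),
  seed = 22L)

cohort <- generate_cohort(spec)            # in-memory; pass dir= for NIfTI
is_val <- cohort$manifest$center %in% c("B", "C")

combos <- enumerate_combos(
  reducers = c("f_ratio", "mim"),
  resamplers = c("adasyn", "none"),
  classifiers = c("logreg_l2", "svm_linear"),
  k_grid = 10)

fits <- lapply(c(np = "np", p = "p"), function(version) {
  fe <- extract_cohort_features(subset_cohort(cohort, !is_val), version)
  fv <- extract_cohort_features(subset_cohort(cohort, is_val), version,
                                frozen = frozen_constants(fe))
  sr <- run_search(fe, combos = combos, n_repeats = 5, seed = 7)
  list(search = sr,
       model = external_validate(best_combo(sr), fe, val_features = fv,
                                 seed = 7))
})

glance(fits$p$search)
glance(fits$p$model)
glance(fits$np$model)
```

On this seed the run prints (abridged):

```
# glance(fits$p$search)
  n_combos n_discarded n_repeats best_combo                  best_mean_kappa
1        8           0         5 f_ratio|10|adasyn|logreg_l2           0.533

# glance(fits$p$model) — held-out centers B + C
  combo_id                    kappa    f1   auc accuracy sensitivity specificity
1 f_ratio|10|adasyn|logreg_l2 0.738   0.8 0.962    0.905         0.8       0.938

# glance(fits$np$model)
  combo_id                    kappa    f1   auc accuracy sensitivity specificity
1 mim|10|none|svm_linear      0.173 0.286 0.912    0.762         0.2       0.938
```

The dynamically standardized version generalizes to the held-out
centers far better than the conventional one (held-out kappa 0.74 vs
0.17): the z-score cannot remove the echo-time dependence of the bolus
drop, so the np model trained on center A (TE 40 ms) finds only one of
the five wildtype patients at the TE 30 ms center, while the
relaxation-rate features are center-consistent and recover four of
five. Explain the winning
model with

```r
er <- explain_model(fits$p$model,
                    extract_cohort_features(subset_cohort(cohort, is_val), "p",
                      frozen = frozen_constants(
                        extract_cohort_features(subset_cohort(cohort, !is_val), "p"))))
tidy(er)          # permutation importance, ranked
autoplot(er)      # importance bars
autoplot(er$shap) # per-patient SHAP beeswarm
```

or run everything in one call with `run_end_to_end(run_config(...))`,
which persists leaderboards, predictions, importance tables and a
summary stamped with the configuration hash.

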