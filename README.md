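# prostatlas

Statistical, voxelised biological atlas construction for prostate cancer.

Radiotherapy for prostate cancer is moving from uniform whole-gland dose
towards biologically optimised plans that boost the tumour-bearing
subvolumes. That requires knowing, voxel by voxel, how likely a tumour is
at each location and how cell density is distributed there — information
that only co-registered whole-mount histology can provide, and that no
single patient's data can supply reliably. `prostatlas` implements the full
pipeline for turning a cohort of co-registered, sparsely annotated
histology-derived volumes into a population-level statistical atlas:

1. **Slice interpolation** (`interpolate_contours`, `interpolate_density`,
   `interpolate_lesions`, `to_volumetric`): whole-mount sections sample
   every second axial MRI slice. Contours are filled by morphological
   interpolation, cell-density maps linearly (then converted from
   cells/mm² to cells/mm³ by a 3/2 power), and Gleason-graded lesions
   probabilistically — a filled-slice voxel gets weight 1 between
   same-grade lesions and 0.5 adjacent to a single annotated lesion.
2. **Reference geometry** (`principal_axis_align`, `consensus_volume`,
   `build_reference`, `urethra_tube`): cohort glands are centred and
   rotated onto their principal moments; the reference prostate is the
   region covered by half or more of the aligned glands, the reference
   peripheral zone (PZ) likewise after whole-gland registration, and the
   reference urethra a 1.5 mm spline tube.
3. **Distance-preserving registration** (`similarity_register`,
   `distance_preserving_register`, `register_patient`,
   `compose_and_apply`): an anisotropic similarity transform followed by a
   log-domain, symmetric-forces demons registration driven by *normalised
   distance maps*, so that a point at relative depth `d` in the patient
   gland lands at relative depth `d` in the reference — not just a
   boundary match. A second, PZ-driven stage runs with the gland border
   pinned to zero deformation.
4. **Voxel statistics** (`sampling_frequency`, `tumour_probability`,
   `fit_density_model`, `kde_estimate`, `kl_divergence`,
   `evaluate_models`, `build_atlas`): per voxel `x` the tumour frequency is
   modelled as `F(x) ~ B(n(x), p(x)) ≈ N(np, np(1-p))` with coefficient of
   variation `CV = sqrt((1-p)/(np))`; cell density is modelled both as
   `C(x) ~ N(mu, sigma^2)` and `log C(x) ~ N(mu, sigma^2)` (maximum-
   likelihood 1/n forms), and the two models are compared per voxel by the
   Kullback–Leibler divergence `D_KL(C_KDE || C_model)` in bits, where
   `C_KDE` is a Gaussian kernel density estimate with Scott's-rule
   bandwidth `h = sd · n^(-1/5)`.

A synthetic **phantom cohort generator** (`phantom_spec`,
`generate_cohort`, `cohort_truth`) reproduces the study's data structure —
ellipsoidal glands with anisotropic scale and rotation variation, a
posterior-crescent PZ, lesions seeded preferentially in the posterolateral
PZ, log-normal cell density, and annotation of every second 2.5 mm slice
away from apex and base — with exact ground truth, so the whole pipeline is
testable without any patient data.

## Worked example

```r
library(prostatlas)

## 1. a synthetic cohort with the study's sampling structure
spec   <- phantom_spec(n_patients = 60, rng_seed = 1)
filled <- lapply(generate_cohort(spec), fill_patient)

## 2. reference geometry + two-stage distance-preserving registration
cfg <- pipeline_config(iso_spacing = 1.6,
                       demons = list(iterations = c(20L, 15L, 10L)))
ref   <- build_reference(filled[1:12], cfg)
chain <- register_patient(filled[[1]], ref, cfg)
warped <- compose_and_apply(chain, filled[[1]]$prostate_mask, ref$prostate,
                            mode = "nearest", missing = 0)
dice(warped, ref$prostate)

## 3. voxelwise statistics on a common-frame cohort
spec0 <- phantom_spec(n_patients = 60, radii_jitter = 0, rotation_deg = 0,
                      rng_seed = 1)
recs  <- lapply(lapply(generate_cohort(spec0), fill_patient), patient_record)
atlas <- build_atlas(recs, compare_models = FALSE)
atlas$tumour
```

which prints

```
<reference_geometry> 41x41x41-voxel grid at 1.6 mm; prostate 8437, PZ 2860, urethra 23 voxels
gland Dice after the two-stage registration: 0.97
<tumour_probability_model> n max 60; p range [0, 0.133] over 26325 sampled voxels
```

The reference gland is the half-or-more consensus of the aligned cohort;
the Dice of 0.97 says the patient gland, pushed through the similarity and
deformable stages, almost exactly tiles the reference. The tumour model's
`p` map peaks at 0.133: at the most tumour-prone voxel, 13% of the cohort's
(probabilistically weighted) lesions cover that location, concentrated in
the posterolateral peripheral zone by construction of the phantom. Running
the density-model comparison on the same cohort without lesions
(`lesion_rate = 0`, `build_atlas(..., max_voxels = 2000)`) prints

```
<model_fit_report> normal:    D_KL 0.05046 +/- 0.02868 bits over 2000 voxels
<model_fit_report> lognormal: D_KL 0.04437 +/- 0.01714 bits over 2000 voxels
```

— the log-normal model loses less information against the per-voxel
empirical density distribution, and its advantage is what
`evaluate_models()` quantifies voxel by voxel.

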