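---
title: "Methods: building a voxelised statistical prostate atlas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: building a voxelised statistical prostate atlas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(prostatlas)
```

This vignette is the package's account of the science it implements: the
models, the choices that were genuinely open, the numerical conventions,
and what passing the test suite does and does not demonstrate.

## The problem

Whole-mount histology after prostatectomy gives the only gold-standard map
of where tumour actually was and how dense its cells were. But each
specimen is sectioned at 5 mm while the co-registered ex vivo MRI has
2.5 mm slices, so half the slices carry no histology; glands differ in
size, shape and orientation between patients; and any single patient is
one noisy draw. The pipeline turns a cohort of such datasets into a
reference-space atlas in which every voxel stores population-level
statistical parameters.

## Slice interpolation

Three payloads, three rules:

* **Contours** (peripheral zone, urethra): morphological interpolation.
  For the slice midway between two annotated slices, the two regions' 2D
  signed distance functions are aligned at their mid-centroid, averaged
  and thresholded at zero. This gives a smooth shape transition: identical
  neighbours reproduce themselves, nested discs give a disc of
  intermediate area. When one neighbour is empty the region shrinks
  towards its deepest point (a strict subset, possibly empty). The test
  surface constrains behaviour (intermediate area, idempotence on constant
  stacks), not the internal algorithm.
* **Cell density**: the arithmetic mean of the two neighbouring slices at
  the same in-plane position, so filled values always lie inside the range
  of the actual neighbouring values. Cross-sectional density (cells/mm²)
  is then converted to volumetric density by raising to the power 3/2
  (`density_exponent`, default 1.5; an exponent of 1 selects the linear
  scaling alternative).
* **Graded lesions**: one probabilistic 3D label image per Gleason grade.
  Annotated lesion voxels carry 1; each flanking annotated slice
  contributes 0.5 to the slice between, contributions of the same grade
  add and are capped at 1. So a voxel flanked by same-grade lesions
  carries 1, and a voxel flanked by two different grades carries 0.5 in
  each grade's image. The cap-at-1 reading (rather than summing beyond 1)
  is taken because a voxel flanked on both sides by the same grade is
  defined to be tumour with certainty. One annotated voxel may carry only
  one grade.

Slices beyond the first/last annotated slice receive no values and are
excluded from the validity mask: apex and base are genuinely unsampled.

## Reference geometry

Each gland mask is translated so its centroid sits at the origin and
rotated so its principal second moments lie along the axes. Eigenvector
sign and assignment are ambiguous; we resolve both by choosing, among all
24 signed axis permutations with determinant +1, the rotation nearest the
imaging axes (maximal trace). This implements "initialise from the imaging
axes, refine from the moments" and guarantees no axis flips; for
near-spherical glands the result is defined only up to that symmetry,
which is how it is tested. The reference prostate is the voxel set covered
by at least `consensus_fraction` (default 0.5, attained counts as inside)
of the aligned masks. The reference PZ is the consensus of the PZ masks
*after* the whole-gland registration stage, intersected with the reference
prostate; the reference urethra is an interpolating cubic spline through
the per-slice centroids of the mean warped urethra mask, expanded to a
tube of `urethra_radius` (default 1.5 mm).

## Distance-preserving registration

The registration's goal is anatomical correspondence, not intensity
matching. Stage 0 is an anisotropic similarity transform (per-axis scale
about the moving centroid along its principal axes, then rotation, then
translation) initialised by moment matching — centroids, principal axes,
and square-rooted second-moment ratios — with optional Nelder–Mead
refinement of all nine parameters on the mean squared difference of
normalised distance maps. If the moment-matched transform worsens the Dice
overlap it is replaced by the identity.

Stages 1 and 2 are demons registrations driven not by the binary masks but
by their **normalised distance maps**: signed distance to the boundary,
positive inside, divided by the maximal interior depth, exterior clipped
at −1. Equal values of this map define corresponding depth shells across
shapes of different size, so matching the maps as "intensity" images makes
the deformation preserve each point's relative distance to the boundary —
the property that plain boundary-only (binary mask) registration lacks,
and which the acceptance suite demonstrates by running exactly that
control. The demons updates use symmetric forces (mean of fixed and warped
moving gradients), per-iteration Gaussian smoothing of the update
(fluid-like, `sigma_update` = 1.5 voxels) and of the accumulated velocity
(diffusion-like, `sigma_total` = 0.5 voxels), a 3-level multiresolution
pyramid with 50/30/20 iterations, and a stationary velocity field
exponentiated by scaling-and-squaring (the log-domain construction), which
is why displacement fields keep positive Jacobian determinants. All of
these are exposed in `pipeline_config()$demons`; the algorithm family is
given by the method, the parameter values are engineering defaults.

Stage 2 registers the peripheral zones with the gland border **pinned**:
every velocity update is multiplied by a smooth weight that is 0 within
one voxel of the gland boundary and ramps to 1 over `pin_band` (default 3)
voxels, so the substructure stage cannot disturb the whole-gland match.
The spec of the constraint is "zero deformation at the border"; the ramp is
this package's mechanism for it.

Numerical conventions that matter:

* Distance maps subtract half a voxel from voxel-centre distances so the
  zero level sits on the mask *interface*. Without this the zero crossing
  sits half a voxel outside the voxelised mask and the boundary match
  carries a systematic half-voxel error.
* Deformable stages require an isotropic grid (resample first; the
  working default is the 0.8 mm atlas resolution). Displacements are kept
  in voxel units internally and returned in mm.
* Exterior clipping at −1 concentrates matching signal in a band around
  the boundary while interior shells carry the depth-preservation
  semantics; the method leaves the exterior open and this package defines
  it.
* Nearest-neighbour resampling of a warped binary mask has an inherent
  half-voxel boundary fuzz. For small shapes this caps the achievable
  Dice: for an 8→12-voxel sphere pair even the analytically ideal mapping
  scores only ≈0.93. Boundary-match claims are therefore tested on
  study-sized glands (radius ≈16–24 voxels), where the two-stage chain
  reaches Dice ≥ 0.97.

The chain is applied right-to-left to pull patient volumes onto the
reference grid: reference point → PZ-stage displacement → gland-stage
displacement → inverse similarity → sample the patient volume (nearest for
masks, trilinear for probabilistic and density data; positions outside the
patient volume become missing and leave the validity mask).

## Voxel statistics

With `n(x)` patients carrying valid data at voxel `x` (the sampling
frequency), the tumour model is binomial,
`F(x) ~ B(n, p)` ≈ `N(np, np(1−p))`, with `p` the mean per-patient
any-grade lesion weight (per-grade weights summed and capped at 1 — the
same rule as the interpolation, kept consistent for the per-grade maps).
Its coefficient of variation has the closed form `sqrt((1−p)/(np))`,
flagged undefined where `p = 0` or `n = 0`.

Cell density gets two voxelwise models, both in the maximum-likelihood 1/n
form (not 1/(n−1) — deliberately, matching the model definition):
normal in linear space and normal in log space. Zero densities have no
logarithm; they are excluded from the log-normal fit at that voxel with
the count adjusted (`lognormal_zero = "exclude"`), or floored at
`zero_floor` if configured. Voxels with fewer than `min_samples_fit`
(default 3) samples are unfit; model comparison additionally requires
`min_samples_kl` (default 5).

Model suitability is compared per voxel by the KL divergence from the
Gaussian KDE of the samples (bandwidth `sd · n^(−1/5)`, Scott's rule in
one dimension) to each fitted model density, integrated by the trapezoid
rule on a 512-point grid spanning the samples ±4 bandwidths, truncated to
strictly positive density values and with both densities renormalised on
that grid (the formal integral runs over (0, ∞); truncation plus
renormalisation controls the tail error). The model density is floored at
1e−30 inside the integrand; if it underflows where the KDE carries real
mass the capped contribution raises a warning rather than an error.

**A property worth knowing:** the linear-space Gaussian KDE uses a single
global bandwidth, so for strongly right-skewed samples it smears mass
toward zero where the log-normal left tail is thin. In that regime
(voxel-level log-sd ≳ 0.3) the *normal* model can win the KL comparison
even for log-normally generated data. The comparison is therefore
informative about model fit only in the mild-skew regime; the phantom's
default voxel-level density spread (volumetric log-sd ≈ 0.2, CV ≈ 20%) is
chosen to emulate that regime, which is also where the reported study-data
divergences (a few hundredths of a bit, log-normal smaller) live.

## The phantom generator

`generate_cohort()` emulates the *structure* of the study data: ellipsoid
glands (default semi-axes 22 × 18 × 20 mm, ±20% per-axis scale and ±15°
rotation per patient), a posterior outer-shell PZ, an anteriorly bowed
spline urethra, Poisson-count lesion blobs (thresholded radial field plus
smoothed noise) whose index lesion is seeded in the posterolateral PZ with
probability 0.4 — "posterolateral" operationalised as the posterior part
of the PZ further than a configurable offset from the midsagittal plane —
log-normal voxelwise cell density multiplied inside lesions, 2.5 mm
slices with every second slice annotated, and a 5 mm unannotated margin at
apex and base. Generation is a pure function of the spec including its
seed; each patient records its lesion provenance.

`cohort_truth()` returns the generator's latent fields on the canonical
(jitter-free) geometry. The lesion-probability field has no closed form
(lesions are correlated blobs), so it is evaluated by Monte Carlo over 800
independent lesion realisations with a *fixed internal seed* — identical
across spec seeds, as a latent parameter should be. Recovery tests
therefore compare two estimates and use the pooled two-sample binomial
standard error.

What the phantom does **not** emulate: MRI physics and intensity
characteristics, histology staining and its normalisation, the
histology-to-MRI co-registration errors of the upstream pipeline,
anatomically realistic lesion shapes, or spatial correlation of the
density noise. Passing tests demonstrate that the pipeline's machinery is
correct under the stated sampling structure, not that it is robust to
those real-data effects.

Two deliberate test-design consequences of the pipeline's own properties:

* Linearly interpolated filled-slice density values are means of two
  draws, with systematically reduced variance. Parameter-recovery tests
  therefore fit on raw annotated-slice samples
  (`patient_record(p, slices = "annotated")`); atlas builds for sampling
  frequency count interpolated slices as sampled, reproducing the
  near-100% mid-gland coverage with taper to apex and base.
* At lesion voxels the density samples are two-component mixtures
  (baseline vs multiplied); neither density model is correct there, so the
  model-selection experiments run on lesion-free cohorts.

## Problem sizes

The shipped tests run registrations on 48³–64³ isotropic grids (seconds
each), statistical recovery on 200-patient cohorts at the phantom's native
resolution (≈53×53×27 voxels at 1.2×1.2×2.5 mm), and model comparison on
60-patient cohorts with the KL evaluation subsampled to ≤2000 voxels
(seeded). These sizes were chosen so the whole suite completes in a few
minutes while keeping every statistical bound at its stated strength; all
of them scale up by configuration only.

## Known limitations

* Registration accuracy has no inter-patient ground truth; acceptance is
  property-based on phantoms (depth preservation, pinned borders, Jacobian
  positivity), not a clinical error figure.
* The KDE/KL comparison is only meaningful in the mild-skew regime (see
  above); with heavy voxel-level skew its verdict reflects the KDE's
  bandwidth limitations as much as the models.
* Morphological interpolation is defined for one-slice gaps (the study
  geometry); wider gaps are rejected rather than extrapolated.
* Consensus geometry and moment alignment assume roughly consistent
  patient orientation; pathological cohorts (empty consensus) raise
  errors rather than produce degenerate references.
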