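---
title: "Methods: PVS function markers and their statistical battery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: PVS function markers and their statistical battery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alpspvs)
```

This vignette documents the models and procedures the package implements,
the assumptions behind them, the tunable parameters, and the design
decisions taken where the methodology was genuinely open. It states no
empirical result that the test suite or `scripts/acceptance.R` does not
itself compute.

## 1. The diffusion signal model and tensor fit

Diffusion-weighted acquisitions are modelled with the single-tensor
Stejskal–Tanner relation

$$ S_i = S_0 \exp(-b_i\, g_i^\top D\, g_i), $$

with $b_i$ in s/mm², unit gradient directions $g_i$, and $D$ a symmetric
positive-definite tensor in mm²/s. `fit_tensor()` estimates the six tensor
components and $\ln S_0$ per voxel by **log-linear least squares** — the
default estimator of the widely used command-line tensor-fit tools — rather
than weighted or nonlinear least squares. The choice trades a little
statistical efficiency at low SNR for exact reproducibility and a
closed-form oracle: on noiseless phantoms the fit must return the planted
tensor to numerical precision, and the test suite asserts agreement to
1e-10 mm²/s.

Numerical choices:

- **Signal floor.** Log-domain fitting cannot accept $S \le 0$. Such values
  are raised to `floor_frac * S0` (default `1e-6`, per voxel) and the voxel
  is counted in `qc$n_floored`. Voxels with an all-zero signal vector are
  flagged invalid and never fitted.
- **Polarity handling.** The emulated acquisition measures each gradient
  direction in positive and negative polarity. Both polarities enter the
  fit as independent measurements (no pre-averaging): this uses all data
  and matches the acquisition description; for a pure tensor model the two
  conventions give identical noiseless results, so the choice is recorded
  rather than consequential.
- **No eigenvalue clamping.** Voxels with a negative smallest eigenvalue
  (possible under noise) are counted in `qc$n_negative_eig` but never
  silently clamped; clamping would hide noise problems from QC.
- **Axis convention.** Dxx/Dyy/Dzz are the tensor diagonal in
  right–anterior–superior axis order; `read_dwi()` reorients volumes to RAS
  on load so the ALPS ratio is anatomically unambiguous. In-memory phantoms
  are built in RAS by construction.

Derived maps follow the standard definitions: MD $=(\lambda_1+\lambda_2+
\lambda_3)/3$, FA from the eigenvalue formula, V1 the principal
eigenvector. Median white-matter MD is the median over a supplied WM mask.
PSMD is implemented in simplified form — the p95 − p5 spread of MD within a
*supplied* skeleton mask (linear-interpolation percentile convention,
`stats::quantile(type = 7)`); the TBSS-style skeletonization that produces
the mask is upstream of this package.

## 2. The DTI-ALPS index

Four 6-mm-diameter spheres at template coordinates (24, −12, 24),
(−28, −12, 24), (36, −12, 24), (−40, −12, 24) sample the projection-fiber
(medial) and association-fiber (lateral) white matter in each hemisphere.
Per side,

$$ \mathrm{ALPS} = \frac{\overline{Dxx}_{proj} + \overline{Dxx}_{assoc}}
{\overline{Dyy}_{proj} + \overline{Dzz}_{assoc}}, $$

and the mean index averages left and right. Design decisions:

- **Role assignment.** The four published center coordinates carry no
  explicit labels; roles are assigned by geometry — projection = medial
  (smaller |x|, corona radiata), association = lateral (superior
  longitudinal fasciculus) — matching the anatomy of the originating
  method. The assignment is a config default and overridable.
- **Sampling path.** The default resamples the diffusivity maps into
  template space (trilinear, 1-mm lattice restricted to each sphere),
  matching workflows that register individual maps to the template before
  ROI extraction. The inverse path (`method = "native"`: rasterize spheres
  onto the native grid through the affine, average voxel values) is
  available behind a flag. On phantoms built on a template-aligned grid
  the two agree exactly, which the tests assert.
- **Rasterization.** Voxel-center-in-sphere, no partial volumes:
  deterministic, and checkable against a brute-force enumeration oracle
  (123 lattice points at 1 mm for a 3-mm radius).
- **Invalid voxels** (failed fits) are excluded from ROI means and counted
  in QC, so one dead voxel cannot silently bias a sphere mean.
- **Orientation QC.** The published workflow includes a manual check of ROI
  placement against fiber-direction maps. The automated surrogate reports,
  per ROI, the fraction of voxels whose principal eigenvector is dominant
  along the expected axis (projection: z, association: y) and warns below a
  threshold (default 0.5). It flags but never moves ROIs, since nothing is
  known about how far manual corrections moved them.

## 3. PVS volumetry

PVS maps are constructed by set subtraction from an already-segmented CSF
class: `PVS = CSF \ (lacunes ∪ ventricles ∪ vessel/extra-cerebral CSF)`.
The "CSF surrounding large vessels and outside the brain" has no published
algorithmic definition (it was a manual step), so it is operationalized as
an explicit exclusion mask in `tissue_maps()`; an optional `review_mask`
stands in for manual inspection. No size or shape filtering of PVS
candidates is applied — the procedure is purely subtraction plus review.

Volumes are voxel count × voxel volume, for whole brain and for
intersections with basal-ganglia and white-matter region masks, normalized
by brain volume (GM + WM) and natural-log transformed. A zero whole-brain
PVS volume raises an error rather than receiving a pseudo-count: silent
offsets would distort downstream regression coefficients, so subjects with
zero volume must be handled explicitly. Rater agreement uses SEM
($\mathrm{SD}(\Delta)/\sqrt{2}$), mean percent variability, and ICC(2,1)
from the two-way random-effects ANOVA decomposition.

## 4. The synthetic generators

The generators define the study conditions under which the pipeline is
validated; they are first-class, tested code.

**DWI phantoms** (`phantom_spec()`/`generate_dwi_phantom()`): rectangular
grids with geometric regions carrying constant SPD tensors, the emulated
acquisition geometry (25 directions at b = 1000 s/mm² in two polarities, 8
b = 0 volumes, 2.5 mm isotropic default), and optional **Rician** noise —
the magnitude-MRI convention — at a stated SNR. Phantoms are built directly
in template space with an identity-scaled affine, so registration
estimation (an external-tool step in real pipelines) never enters the test
path. `generate_alps_phantom()` plants axis-aligned tensors at the four ROI
sites on a 1-mm template-aligned grid; sample lattice nodes then coincide
with voxel centers, trilinear resampling is exact, and the index has the
closed-form value $(d_{xx,proj}+d_{xx,assoc})/(d_{yy,proj}+d_{zz,assoc})$.
Planted spheres extend 2 mm beyond the ROI radius so every sample point
sees the planted constant.

**Tissue phantoms** (`generate_tissue_phantom()`): an ellipsoidal brain
with box ventricles, a basal-ganglia block, a cortical GM shell, an
extra-cerebral CSF rim, spherical lacunes and individually planted PVS
voxels, with exact planted counts returned as ground truth. The WM and BG
masks are regional (SynthSeg-style) masks that still cover planted PVS
voxels, so PVS-in-region volumes are well defined.

**Cohort simulator** (`cohort_spec()`/`generate_cohort()`): n subjects with
MRI visits at years 0–3 and cognition visits at years 0–5, in long format.
Structure and defaults:

- Demographics anchored to a single-center lacunar-stroke cohort: n = 120,
  age 70 (SD 8) years, 65% male; risk-factor prevalences (hypertension
  0.85, diabetes 0.20, hypercholesterolemia 0.60, smoking
  never/ex/current = 0.35/0.45/0.20) and NART-IQ 100 (SD 12) are the
  simulator's own field-realistic choices.
- ALPS follows a linear mixed trajectory: baseline 1.30 (SD 0.15),
  fixed annual slope −0.010, random-slope SD 0.006, residual SD 0.03.
  The slope default is the observed decline reported for such cohorts; the
  variance components are generator choices, since random-effect variances
  are essentially never published.
- A latent severity factor (correlation −0.5 with standardized baseline
  ALPS) drives the baseline imaging markers (WMH, lacune and microbleed
  counts, median MD, PSMD, PVS volumes), reproducing the observed pattern
  of negative cross-sectional associations with ALPS.
- Cognition scores are age-standardized z-scores (mean 0, SD 1 at
  baseline); each domain's annual slope is linear in standardized baseline
  ALPS (defaults 0.030/0.060/0.045/0.010 z/yr per SD for
  global/executive/memory/speed — chosen to mirror the reported ordering of
  effects, strongest for executive function, absent for speed).
- Dementia times follow a **Weibull-baseline proportional-hazards** model,
  $h(t) = h_0(t)\exp(\beta z)$ with $z$ the standardized baseline ALPS and
  $\beta = \log 0.328$; shape 1.2; the scale is calibrated at spec
  construction so the marginal five-year incidence (numerically integrated
  over $z \sim N(0,1)$) equals 18.2%. Administrative censoring at 5 years.
  The same integral (`implied_incidence()`) serves as the independent
  oracle for the simulator's incidence in tests.

What the phantoms do **not** emulate: brain anatomy, partial-volume
effects, eddy-current or motion artifacts, registration error, missing
visits, or informative dropout. Passing tests therefore demonstrate the
correctness of the computations under the stated models, not robustness to
real-data artifacts.

## 5. The statistical battery

- **Standardized β convention.** Cross-sectional linear models z-score the
  outcome and all continuous predictors (binary covariates and factors
  untouched), so coefficients are standardized βs; switchable via
  `standardize`.
- **Mixed models** are fitted by **maximum likelihood** (not REML), since
  fixed-effect p-values are the quantity of interest; p-values use the
  Satterthwaite degrees-of-freedom approximation (`lmerTest`). Random
  intercept and linear time slope are correlated; a singular random-effects
  covariance triggers a documented fallback to random-intercept-only with
  the note recorded in the result. Per-subject slopes are extracted as
  empirical-Bayes **BLUPs** by default (per-subject OLS behind
  `slope_method = "ols"` for sensitivity analyses); BLUP shrinkage is
  asserted in the tests.
- **Cox models** use **Efron** tie handling — yearly visit schedules make
  ties material, and Efron is the better-behaved common default. Hazard
  ratios are per SD of the predictor when standardization is on. The
  nested covariate sets are named (`base`, `base_nart`, `csvd`, `md`,
  `psmd`; see `covariate_set()`) so the adjustment ladder is reproducible.
  Vascular risk factors are fixed to hypertension, diabetes,
  hypercholesterolemia and 3-level smoking.
- **Logistic models** detect complete separation and report
  non-convergence with `NA` estimates instead of a silently diverging
  coefficient.
- **FDR families.** Benjamini–Hochberg is applied within one family per
  results table (baseline, progression, cognition, dementia). Family
  definitions for FDR are rarely stated explicitly in applied work; here
  the choice is explicit in `run_analysis()` and recorded in the manifest.
- **Optimal cutpoint**: exhaustive search over midpoints of consecutive
  distinct scores, maximizing Youden's J, the common default of the
  dedicated cutpoint packages; the risk direction comes from the sign of
  the score–event association, ties break toward balanced groups, then the
  smaller cutoff. Any published single-cohort cutoff (e.g. a value near
  1.2 for ALPS) is method- and sample-dependent; the implementation is
  validated against an enumeration oracle, not against a constant.
- **Variable importance** uses a seeded standard random forest with
  permutation importance (`ranger`). Conditional-inference forests are a
  known alternative (and were used in some published analyses); the
  difference is documented in the result metadata. Duplicated (perfectly
  collinear) predictors share importance — both copies are detected, each
  attenuated — which the tests demonstrate by controlled duplication.

## 6. Problem sizes and reproducibility

Validation uses problem sizes chosen so the full suite runs comfortably on
one CPU: ALPS phantoms on a ~97×23×23 1-mm grid with 58 volumes; tensor
oracles on ≤10³-voxel grids; mixed-model recovery at 200 subjects × 4
visits; Cox recovery at n = 1000 with ~20% events and CI coverage over 100
replicates at n = 400; cutpoint equivalence at n = 2000; importance
ranking over 100 seeds at n = 500. Every stochastic component takes an
explicit integer seed and is bit-reproducible given it; `end_to_end_demo()`
regenerates its entire report deterministically from one seed.

## 7. Known limitations

- The tensor fit is unweighted log-linear; at very low SNR its bias is
  larger than weighted or nonlinear alternatives.
- PSMD here requires a precomputed skeleton mask; results are not
  comparable to full-pipeline PSMD values unless the same skeleton is used.
- The PVS procedure inherits every imperfection of the upstream CSF
  segmentation; no intensity-based detection is attempted.
- The cohort simulator's cognition and marker cross-correlations are
  single-factor; real cohorts have richer dependence structure.
- The automated ROI orientation QC approximates, but cannot replace,
  expert review of fiber-direction maps.
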