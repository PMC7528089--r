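---
title: "Statistical shape modelling of the lungs and fissures with LungSSM"
author: "LungSSM authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical shape modelling of the lungs and fissures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(LungSSM)
```

## The problem and the model

Lung shape changes with age, body habitus and disease, but most quantitative
descriptions reduce it to a handful of linear dimensions. A statistical shape
model (SSM) instead describes the whole bi-lung geometry — including the
lobar fissures — as a mean shape plus orthogonal modes of variation learned
from a cohort of corresponded surfaces. Each subject is then a compact vector
of mode scores, which can be tested for associations with age, sex, BMI and
lung volume.

LungSSM implements the full pipeline:

1. **Surface representation.** Bicubic Hermite finite-element quadrilateral
   patches. Every node carries 12 degrees of freedom — position and the
   `d/dxi1`, `d/dxi2` and `d2/dxi1 dxi2` parametric derivative vectors
   (four scalars per spatial direction) — so a coarse node layout still
   encodes surface curvature. Five labelled surfaces are modelled: left and
   right lung, left and right oblique fissure, and the right horizontal
   fissure. A fixed template topology shared by all subjects provides the
   point-to-point correspondence that shape statistics require.
2. **Mesh fitting.** The template is deformed to each subject's segmented
   surface point cloud by minimising
   `T(u) = sum_p gamma_p ||z(xi_p) - z_p||^2 + integral g(u)`,
   a weighted point-to-surface misfit plus a Sobolev-type smoothness penalty
   on the first, second and mixed parametric derivatives.
3. **Alignment.** Generalised Procrustes alignment (GPA) removes
   translation and rotation; with the scaling toggle on it also removes
   size, yielding a *size-inclusive* and a *size-exclusive* dataset.
4. **Decomposition.** The aligned shape vectors are column-stacked, centred,
   and factorised by thin SVD. Left singular vectors are the shape modes;
   mode variances are `sigma_l^2 / (N - 1)`; subject scores are expressed in
   SD units of the training cohort.
5. **Statistics.** Per-mode Pearson/OLS associations with age, BMI and lung
   volume (whole-cohort and sex-stratified), Welch's t between sexes, and
   one-way ANOVA over user-supplied groupings, at alpha = 0.05 per test.

## Numerical and design choices

**Element conventions.** Local corners are ordered
(0,0), (1,0), (0,1), (1,1) in `(xi1, xi2)`; derivatives are stored per unit
local coordinate (no arc-length scaling), which is sufficient for statistics
because the topology — and hence the parameter scaling — is shared across
subjects. The coordinate frame is right-handed: +x toward the subject's
left, +y posterior to anterior, +z caudal to cranial, in millimetres.

**Fitting.** The misfit couples the data to the surface through
closest-point projections, which themselves depend on the geometry, so the
solver alternates projection (coarse per-element grid search refined by
damped Newton on the squared distance; exact grid ties go to the lowest
element id; a diverging Newton falls back to the grid optimum) with an exact
linear least-squares solve in all nodal DoFs at fixed projections. The three
coordinates share one normal matrix, factorised once per iteration. Points
are only ever matched to elements of their own anatomical label — lung
points never pull on fissure patches.

Two defaults deserve comment:

- *The penalty acts on the deformation.* The quadratic smoothness form is
  evaluated on the displacement of the surface away from the placed
  template, not on the surface itself. This keeps the template's own
  curvature penalty-free, leaves rigid offsets of whole surfaces (such as a
  fissure translating toward the lung base) uncharged — a constant
  displacement field has zero parametric derivatives — and specifically
  damps wrinkling and tangential node sliding, the error modes that corrupt
  cross-subject correspondence.
- *Smoothness weights* default to `1e-3` on the first-derivative term and
  `0.3` on the second and cross terms. The curvature terms carry the
  regularisation burden: at realistic sampling densities the
  mixed-derivative DoFs are weakly constrained by the data, and weak
  curvature penalties leave them dominated by noise, which then contaminates
  the PCA. The first-derivative weight is kept small because it resists
  tangential stretch, which real subjects legitimately have. The weights
  were calibrated once by minimising recovery error against known
  ground-truth meshes (with the residual RMSE required to stay inside the
  sampling-noise band) and then frozen.
- *Initial placement*: before iterating, the template is translated and
  isotropically scaled so its surface centroid and RMS size match the data
  cloud (skipped when the change would be under 2%). Closest-point fitting
  is a local method; without this step subjects far from the template size
  converge slowly and with scale-dependent bias, which leaks a spurious
  size-linked mode into the size-exclusive model.

With exact projections the fitting energy is non-increasing across outer
iterations; the default loop runs at most 10 iterations or until the RMSE
changes by under `1e-3` mm.

**GPA.** Only nodal positions drive the similarity estimation (derivative
DoFs would mix units); the estimated transform is then applied to all 12
DoFs, with translation acting on positions only. Scale is removed by
centroid size, the morphometrics standard. The first shape initialises the
reference; the consensus is re-centred at the origin every iteration and, in
the size-exclusive model, normalised to unit centroid size, so the output
frame is defined up to the first shape's orientation. Convergence is a
relative consensus change below `1e-6` (at most 100 iterations, error on
failure).

**PCA.** The training matrix is parameters x subjects. Eigenvalues of the
sample covariance are `sigma^2 / (N - 1)`; variance *fractions* are
unaffected by that scaling choice. Scores are reported in SD units (each
mode's training scores have sample SD 1), so perturbing the mean by
`w = +/- 2.5` SD reproduces the conventional mode-visualisation protocol,
and `reconstructShape()` inverts `projectShapes()` exactly on the training
set. Mode signs are fixed by making each mode's largest-magnitude loading
positive, which makes results reproducible across BLAS/LAPACK builds; the
orientation of a mode relative to a covariate therefore still needs to be
fixed by the analyst (or, on synthetic data, by the planted loading) before
interpreting the sign of a correlation. Degenerate cohorts of identical
shapes yield a valid all-zero-variance model, and leave-one-out stability is
then flagged as undefined rather than fabricated.

**Statistics.** No multiple-testing correction is applied by default
(alpha = 0.05 per test, matching common practice in cohort shape studies);
`associationTable(..., adjust = TRUE)` adds Benjamini-Hochberg adjusted
p-values for users who want them. Simple regressions report the signed R
convention. Subjects with missing covariates are dropped with a reported
count; duplicated subject ids are an error, never silently merged.

## What the synthetic cohort emulates — and what it does not

The generator stands in for the imaging arm of a cohort study: volumetric CT
at full inspiration, segmentation of lung and fissure surfaces, and
anthropometrics. It produces, per subject, a ground-truth mesh, a noisy
labelled point cloud, covariates, and the planted effect loadings that make
end-to-end parameter-recovery tests possible.

- **Geometry.** Idealised ellipsoid-like lungs with a basal diaphragm dome
  and three planar-ish fissure sheets, tabulated into Hermite patches with
  analytic derivatives. Default resolution is 96 nodes / 66 elements over
  the five surfaces, comparable to a clinical bi-lung template; the grids
  are configurable (a denser build with 225 nodes / 2700 shape parameters is
  used to exercise full-scale dimensions).
- **Covariates.** n = 83; age drawn from a two-centre recruitment mixture
  (47/83 weight on 71.2 +/- 10.9 years clipped to 50-93, 36/83 weight on
  32.0 +/- 12 years clipped to 20-49), giving cohort moments of about
  53 +/- 22 years; sex 49 F / 34 M in expectation; BMI 24.7 +/- 2.7 clipped
  below the 30 kg/m^2 exclusion threshold; imaged lung volume
  6.81 +/- 1.16 L (M) and 4.84 +/- 0.85 L (F).
- **Planted effects**, applied in a fixed order with exact transport of the
  derivative DoFs (Jacobian, plus the Hessian contraction for the mixed
  derivative): isotropic scale from the target volume; an age-linked apical
  antero-posterior taper (0.002 per effective age year — older lungs more
  pyramidal); age-linked basal translation of the horizontal fissure
  (0.3 mm/yr, a calibration knob rather than a measured value) and posterior
  rotation of the oblique fissures; a BMI-linked antero-posterior change;
  and a smooth random residual deformation (six low-frequency trigonometric
  fields, 1 mm amplitude SD). The latent age severity carries Gaussian
  noise whose SD is computed from the exact truncated-normal moments of the
  age mixture so that its population correlation with age is 0.75; the
  recovered age mode should therefore correlate with age at about -0.75,
  minus whatever attenuation fitting noise introduces.
- **Clouds.** 36 uniform-random surface samples per element (roughly 2400
  points per subject, a down-sampled segmentation density) with 1 mm
  isotropic Gaussian noise and labels inherited from the surface of origin.

It does **not** emulate real anatomical detail (lobar surface curvature
beyond the idealised forms, incomplete fissures), segmentation artefacts or
label noise, posture or gravity effects, breathing-state variation, or any
non-linear covariate interaction. Passing the recovery tests therefore shows
that the pipeline's machinery is sound — correspondence, alignment,
decomposition and statistics recover planted, covariate-linked effects at
realistic noise levels — not that the idealised geometry is an anatomical
model.

## Problem sizes used by the test-suite

Unit tests run on single patches and small cohorts (6-24 subjects of
ground-truth shapes). The end-to-end recovery suite runs the complete
pipeline — cloud simulation, mesh fitting, size-exclusive GPA, PCA,
projection, association — on 20 independent cohorts of n = 83 and requires
the age-planted mode to be the strongest age correlate in at least 18 of
them, with the sign-aligned sample correlation within 0.15 of the planted
population value. The fitting consistency checks use dense sampling
(25-49 points per element) at noise 0 and sigma = 1 mm.

## Known limitations

- Closest-point fitting is local; grossly misplaced templates (beyond what
  the initial placement corrects, e.g. large rotations) are out of scope.
- Node correspondence rests entirely on the shared topology and the fit's
  smoothness; nodes can slide tangentially within a surface, which inflates
  within-cohort variance slightly and attenuates covariate correlations.
- The size-exclusive model removes *similarity* size only; allometric shape
  change proportional to size is retained by design.
- Reflection (left/right mirroring) alignment and missing-landmark
  imputation are not implemented.
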