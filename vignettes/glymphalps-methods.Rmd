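---
title: "Methods: DTI-ALPS, voxel-based morphometry and bootstrap mediation on synthetic cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: DTI-ALPS, voxel-based morphometry and bootstrap mediation on synthetic cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glymphalps)
```

This vignette is the package's account of its own methods: the models it
fits, the assumptions they carry, the defaults it chose where choices were
genuinely open, and what its synthetic data can and cannot demonstrate.

## The ALPS model

Diffusion in white matter is modeled per voxel by a symmetric tensor $D$
(mm²/s). At the level of the lateral ventricle body, perivascular spaces
around the medullary veins run along the left–right x-axis, perpendicular
to both the projection fibers (corona radiata, axis z) and the association
fibers (superior longitudinal fasciculus, axis y). The ALPS index contrasts
x-axis diffusivity in these two fiber systems with the diffusivities
perpendicular to the fibers:

$$\mathrm{ALPS} = \frac{\tfrac12\,(\bar D_{xx}^{proj} + \bar D_{xx}^{assoc})}
                       {\tfrac12\,(\bar D_{yy}^{proj} + \bar D_{zz}^{assoc})}$$

where each $\bar D$ is the arithmetic mean of the named diagonal element
over a 5-mm-thick slab ROI, computed per hemisphere and then averaged
across sides. Descriptions of the index sometimes write the numerator as a mean of the
summed diffusivities; since numerator and denominator are treated alike,
the ratio is identical whether means or sums are used, and we implement
the mean-of-ROI-means form. $\bar D_{zz}^{proj}$ and
$\bar D_{yy}^{assoc}$ are recorded but by construction do not enter the
index. The index is dimensionless, scale-invariant, equals 1 for isotropic
tensors, and increases with perivascular-direction diffusivity.

Assumptions worth keeping in mind: the anatomy argument fixes the fiber
axes to the grid axes, so the index is only meaningful in a space aligned
with them (template space here); and the index is a *global* summary — it
carries no regional glymphatic information.

### Tensor estimation

`fit_tensor()` solves the log-linearized signal model
$\log S_i = \log S_0 - b_i\, g_i^\top D\, g_i$ per voxel. The default is
weighted least squares with weights $S_i^2$, the standard correction for
the log transform's noise distortion; ordinary least squares is available
(`method = "ols"`). The design requires at least one $b=0$ frame and six
non-collinear unit directions (rank check on the 7-column design). Voxels
with any non-positive signal are excluded and counted. No FA threshold is
applied to ROI voxels: thresholding would couple the ROI definition to
the data, and the index definition does not call for one.

`fractional_anisotropy()` uses the rotationally invariant form
$\mathrm{FA} = \sqrt{3/2}\,\lVert D - \bar\lambda I\rVert_F / \lVert D\rVert_F$,
which equals the eigenvalue formula without per-voxel eigendecompositions;
all-zero tensors give FA 0 by convention.

ROI masks defined on the template grid are transported to a subject grid by
nearest-neighbour resampling under an optional rigid affine (a mask
shrinking below 10 voxels warns; to zero, errors). Nearest neighbour keeps
masks binary; any interpolation rule here is a choice, as none is
prescribed for this step.

## Voxel-based morphometry

Modulated GM maps are smoothed with a separable Gaussian kernel,
$\sigma_\text{axis} = \mathrm{FWHM} / (2\sqrt{2\ln 2}\cdot\text{voxel size})$
(8 mm FWHM default; at 2-mm voxels $\sigma = 1.6986$ voxels). The kernel is
truncated at $4\sigma$ and renormalized, with zero padding at the volume
edge — total intensity is conserved for interior-supported input, and edge
attenuation only affects voxels within $4\sigma$ of the boundary, outside
the analysis mask in practice.

`voxelwise_glm()` fits one OLS model per voxel and reports the Student-t
statistic of a single contrast, $t = c^\top\hat\beta / \widehat{SE}$, with
$df = n - \mathrm{rank}(X)$. Residual sums of squares are computed from
explicit residuals rather than the $\sum y^2 - \sum (Q^\top y)^2$ shortcut,
which cancels catastrophically for near-perfect fits. Voxels with zero
residual variance and zero effect (constant GM) get $t = 0$ and are
counted. The default analysis mask keeps voxels whose cohort-mean GM
exceeds 10% of the grand mean — the usual implicit-mask heuristic, since no
explicit mask is prescribed.

Two thresholding regimes mirror the two questions:

- **Group atrophy**: voxel-level family-wise error $p < 0.05$, cluster
  extent > 100 voxels. FWE control uses the permutation distribution of the
  maximum |T| (`fwe_threshold_maxT()`) rather than random-field theory —
  a deliberate methodological replacement: max-statistic permutation is
  assumption-light (no smoothness estimation, no Gaussianity of the field)
  and exact at desk scale. Exchangeability under nuisance covariates uses
  Freedman–Lane residual permutation: the response is reduced against the
  zero-contrast columns, reduced-model residuals are permuted and refitted
  under the full model. For a group contrast with intercept-only nuisance
  this reduces to label permutation. Corrected p-values are
  $(1 + \#\{\max T_b \ge |T_v|\})/(1 + B)$, so they can never undercut
  $1/(1+B)$ and always dominate the uncorrected p.
- **ALPS coherence**: an "uncorrected p < 0.001 at the cluster level with
  cluster size > 100 voxels" criterion is implemented — as is conventional
  for this software family — as a voxel-forming threshold of $p < 0.001$
  combined with an extent threshold. The extent rule is strict
  (`size > 100`, i.e. ≥ 101), a literal reading of the inequality. The model is GM ~ ALPS + eTIV; eTIV adjustment
  removes head-size scaling of modulated GM.

Cluster labeling uses 18-connectivity (faces + edges), the convention of
the originating software family; 6 and 26 are available. Up to three local
maxima per cluster, separated by at least 8 mm, are reported with world
coordinates (0-based voxel indices through the RAS+ affine; a voxel's
position is its center). Voxel-forming tests are one-sided by default
(`alternative = "greater"`): both GLM questions are directional (atrophy:
controls > patients; coherence: positive ALPS association).

## Seeds and mediation

`sphere_mask()` includes every voxel whose center lies within the radius
(inclusive) of the seed center: 33 voxels for a 4-mm sphere on a 2-mm grid,
257 on a 1-mm grid (both verified against brute-force enumeration in the
tests). `extract_seed_volume()` returns the sum of GM over the seed times
the voxel volume — a volume-like quantity in modulated units. Seeds default
to the left hemisphere (config flag), following the symmetric-pathology
argument for typical Alzheimer pathology. Extraction defaults to the **smoothed**
modulated maps — the images that entered the GLM which defined the seed,
which is the standard practice of this software family. This matters
statistically, not just cosmetically: extracting from unsmoothed maps adds
independent voxel noise to the mediator, and classical measurement error in
M attenuates the b path while leaking part of the true indirect effect into
the direct path c′ — enough, at these noise levels, to turn a genuinely
full mediation into an apparent partial one. The unsmoothed alternative
remains a config option (`mediator_maps = "unsmoothed"`), as does covariate
adjustment inside the mediation model — off by default: the workflow
adjusts its regressions for confounders, not the mediation model itself.

`fit_paths()` implements Preacher–Hayes simple mediation as three OLS fits:
`M ~ X` (a), `Y ~ X + M` (c′ and b), `Y ~ X` (c). For OLS on a common
sample $c = c' + ab$ exactly — a test invariant. `bootstrap_indirect()`
case-resamples rows, recomputes $a^*b^*$, and builds the **bias-corrected**
(not BCa — no acceleration term, matching the stated method) interval:
$z_0 = \Phi^{-1}(\#\{a^*b^* < \hat a\hat b\}/B)$ with a strict less-than
count and $z_0 = 0$ when the bootstrap distribution is degenerate at the
estimate; endpoints are the empirical quantiles (Hazen/type-6) at
$\Phi(2z_0 \pm z_{1-\alpha/2})$. When $z_0 = 0$ this is the percentile
interval. Degenerate resamples (constant predictor/mediator) are redrawn
and counted; more than 10% redraws aborts. Classification: *none* when the
CI covers zero, otherwise *full* if c′ is non-significant at
$\alpha = 0.05$, else *partial*.

Cohort-level statistics follow common case-control reporting conventions:
Student's
(pooled) t for group comparisons with Shapiro–Wilk reported as QC only,
Spearman partial correlations via rank-transform-then-residualize with
midranks for ties, and OLS of each cognitive score on ALPS + education +
age. Such regressions are reported in both orientations in this
literature; score-as-outcome is the default and the reversed orientation
(ALPS as outcome) is available via `direction`. No multiple-testing
correction is applied across cognitive subdomains by default, matching the
usual uncorrected reporting of subdomain tables; Benjamini–Hochberg is
available via `adjust = "BH"`.

## The synthetic cohort generator

`simulate_subjects()` draws, per subject:

- latent ALPS $X \sim N(\mu_g, 0.10)$ with $\mu_{CTL} = 1.45$ and
  $\mu_{YOAD} = 1.30$. Healthy-adult ALPS values cluster around 1.4–1.5
  with between-subject SDs near 0.1; the −0.15 patient shift is a
  configurable choice of a clearly detectable disease effect — the
  direction (patients lower) is the modeled claim, not its magnitude.
- a **noiseless tensor field** realizing $X$ exactly: projection ROIs get
  $\mathrm{diag}(X d_\perp,\; d_\perp,\; X d_\perp)$ (fiber axis z),
  association ROIs $\mathrm{diag}(X d_\perp,\; X d_\perp,\; d_\perp)$
  (fiber axis y), $d_\perp = 0.6\times10^{-3}$ mm²/s, isotropic background
  $0.7\times10^{-3}$; so the analytic ALPS of the field equals $X$ and
  $X = 1$ yields isotropic ROI tensors. Diffusivities are clamped to the
  physiological range $[10^{-4}, 3.5\times10^{-3}]$ mm²/s — an unreachable
  target ALPS errors rather than silently clipping. Determinism here is a
  design decision: subject-level ALPS variability enters through $X$, and
  measurement noise is exercised separately through the DWI forward model
  (`simulate_dwi()`, Rician by default — the magnitude-MR model — with
  Gaussian and noise-free options for debugging).
- mediator $M = m_0 + a(X - \mu_{CTL}) + \varepsilon_m$, outcome
  $Y = c'(X - \mu_{CTL}) + b(M - m_0) + \varepsilon_y$, defaults
  $a = 250$ mm³ per ALPS unit, $b = 0.35$ score units per mm³, $c' = 0$
  (full-mediation truth), $\sigma_m = 12$, $\sigma_y = 8$, $m_0 = 700$ mm³.
  These were chosen once to give path signal-to-noise comparable to a
  strong neuroimaging mediation (correlations ~0.7–0.9 on the a path,
  ~0.5 on the b path at n = 130).
- printed cognitive scores as affine recalibrations of $Y$ to each test's
  control-group mean/SD (e.g. CASI total 92.41 ± 5.21) using the
  *theoretical* control moments (not the sample's), with a shared loading
  of 0.85 plus independent residual noise per test, clipped into each
  test's valid range. Clipping is logged; truth-recovery tests use the
  unclipped $Y$. Control scores sit near their ceilings, so ceiling
  clipping is an emulated feature, not an artifact.
- GM maps: a brain ellipsoid (85% of the half field of view per axis) at
  intensity 0.5, a left-hemisphere **seed region** (7-mm sphere) whose
  integrated volume equals $M$, a mirrored right-hemisphere region whose
  intensity follows $0.3\,(X - \mu_{CTL})$ (`gm_coupling`), and voxelwise
  white noise (SD 0.05) clipped at zero. Maps are generated unsmoothed —
  smoothing belongs to the VBM stage, as in the real processing chain.
- covariates matching the reference demographics (age ~58.5/60.2 y,
  education 12.5/9.6 y, eTIV 1450 ± 130 ml, female proportions per group).

Everything derives from one run seed; per-subject volume noise uses seeds
derived from it, so volumes can be regenerated lazily (`volume_fn`) and a
streamed pipeline run is bit-identical to a materialized one.

**What the generator does not emulate:** brain anatomy beyond an ellipsoid,
partial-volume effects, multi-shell acquisitions, head motion, scanner
artifacts, nonlinear spatial normalization (subject-to-template
registration is represented by an optional rigid affine only), and spatial
autocorrelation of GM noise beyond what smoothing induces. Passing tests
therefore demonstrate that the *statistical machinery* behaves as specified
under its own assumptions — calibrated nulls, recovered designed effects,
correct bootstrap coverage — not that the pipeline is robust to real-data
pathology.

## Numerical and reproducibility choices

- All randomized operations take explicit integer seeds; the pipeline
  derives stage seeds from the config seed. Two runs with one seed produce
  byte-identical tables.
- The pipeline is deterministic and desk-scale (a full default run takes
  well under a minute), so no stage caching is implemented; re-running is
  the cache.
- Missing data are handled by listwise deletion per analysis, with logged
  counts.
- NIfTI round trips are bit-preserving for values (double storage); affines
  are exact to the NIfTI-1 header's float32 precision.
- Default permutation count is 199 for the group FWE map (the corrected-p
  floor $1/(1+B) = 0.005$ sits comfortably under the 0.05 threshold);
  bootstrap default is B = 1000, the customary count for bias-corrected
  mediation intervals.

## Problem sizes in the test suite

The suite checks calibration and recovery at sizes chosen to balance power
against a few minutes of runtime: 20 null cohorts of n = 50 on the full
40×48×40 grid (~21,000 in-mask voxels) for GLM calibration; 10 full-size
cohorts (n = 267) for cluster recovery of the designed region; 100
replications at n = 130 with B = 1000 for bootstrap coverage and
classification rates; 10 end-to-end pipeline runs for the qualitative
headline (lower patient ALPS, full mediation). Unit tests run reduced grids
(e.g. 30×36×30, n = 80) where only correctness, not power, is at stake.

## Known limitations

- The max-T permutation FWE answers the same question as random-field
  theory corrections but is not numerically identical to them.
- The ALPS index is computed in template-aligned axes; oblique acquisitions
  would need resampling first.
- `fit_tensor()` loops voxels in R for the WLS path; it is intended for
  ROI-scale fitting, not whole-brain tractography preprocessing.
- Mediation here is the simple three-variable model: one mediator, no
  latent variables, no moderated paths.
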