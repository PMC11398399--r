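---
title: "Models and methods behind histatlas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind histatlas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`histatlas` implements the computational core of a histology-driven
probabilistic brain-atlas pipeline: rebuilding a coherent 3D volume from
stacks of distorted stained sections, turning a population of labelled
volumes into a voxelwise probabilistic atlas, segmenting new intensity
volumes against that atlas with a Bayesian mixture model, and analysing the
resulting regional volumes. This vignette describes the models, the
numerical choices, and what the synthetic phantoms do and do not exercise.

## Deformation model

All nonlinear deformations are stationary velocity fields (SVFs): a
time-constant vector field `v` whose time-1 flow `exp(v)` is a
diffeomorphism. `exp_svf()` computes the flow by scaling and squaring —
divide the field by `2^n`, then square (self-compose) `n` times; `n = 8` by
default, a standard accuracy/speed balance that we validate in the test
suite against a 256-step Runge–Kutta integrator of the same field (< 0.05
voxel discrepancy on smooth fields). Inverses are free (`exp(-v)`), which
the atlas builder uses to pull subjects into atlas space without a separate
inverse-consistency machinery.

Displacements are stored in voxel units of the fixed grid; world coordinates
enter only at I/O through the affine. Fields are parameterised by cubic
B-spline control grids (`bspline_field()`); the control lattice extends one
point beyond each edge of the volume so the basis is a partition of unity
everywhere inside.

A field sampled by `sample_svf()` is rescaled so its largest velocity equals
the requested amplitude. Amplitudes up to `0.4 x control_spacing` are
treated as *safe*: across seeds this conservative bound kept the Jacobian
determinant of the exponential strictly positive in every case we tested,
and the bound is asserted in the test suite rather than assumed.

## Histology-stack reconstruction

The reconstruction follows an overconstrained measure-then-reconcile
strategy. For a stack of `S` sections with three images each (the reference
slice `M_s` and two stains `A_s`, `B_s`):

* **Initial blockface alignment** (`register_blocks_joint()`): each tissue
  block gets a similarity pose (translation, rotation, isotropic log-scale)
  optimised against the global NCC with the reference volume, plus an
  overlap/gap regulariser. The regulariser soft-warps every block mask onto
  the reference grid and penalises the squared deviation of the voxelwise
  mask sum from 1 — overlaps (sum > 1) and gaps (sum < 1) are punished
  symmetrically and a perfect tiling scores exactly zero. The penalty is
  analytically differentiable in the poses (block masks are zero-padded by
  one voxel so their interpolants decay continuously at the support edge;
  without this the gradient is wrong exactly on the block boundary, which we
  discovered the hard way). The optimisation is hierarchical: early levels
  force groups of blocks to share pose parameters, reflecting how tissue is
  cut; each level initialises the next, and a level that fails to improve
  the objective is discarded, so the objective is non-increasing across
  levels.
* **Per-section nonlinear registration**
  (`register_section_nonlinear()`): a B-spline SVF maximising local NCC
  (Gaussian windows) minus a bending-energy penalty. Local (rather than
  global) NCC makes the similarity robust to uneven staining; cross-stain
  pairs are first passed through monotone histogram matching
  (`match_histogram()`), which stands in for learned style transfer while
  preserving the registration interface.
* **Measurement graph** (`build_registration_graph()`): within each section
  the three inter-modality registrations, and within each modality directed
  neighbour registrations at offsets ±1 and ±2, giving `15S - 18`
  measurements of a spanning tree with only `3S - 1` latent transforms
  (the reference chain `M_s -> M_(s+1)` plus the per-section stain edges).
  Neighbour measurements are computed in both directions while
  inter-modality ones are single-direction — the only convention consistent
  with the `15S - 18` count.
* **Robust L1 inference** (`refine_bayesian()`): each measured SVF is
  modelled as the signed sum of latent SVFs along its tree path (first-order
  composition — velocities add; this approximation is used only here, where
  it is what makes the problem linear). Laplace measurement noise leads to a
  weighted least-absolute-deviation problem that decouples per control point
  and per vector component into many small linear programs, each solved with
  the simplex method (`boot::simplex`) after introducing slack variables.
  The L1 norm is what buys robustness: a single grossly wrong registration
  (a fold or tear) perturbs the least-squares solution globally but leaves
  the LAD solution essentially untouched, which the test suite demonstrates
  by direct comparison.

Chaining each section only to its neighbours is smooth but straightens
curved structures (the "banana effect"); registering each section to the
reference independently is unbiased but jagged and fragile. The spanning
tree anchored at the reference slices with redundant neighbour constraints
gets both properties, and the evaluation utilities
(`evaluate_reconstruction()`) report landmark error alongside a smoothness
score so the trade-off is visible rather than implied.

## Atlas construction

`build_atlas()` alternates two steps until the atlas stops changing: (i)
register every subject's label volume to the current atlas
(`register_labels_to_atlas()`), maximising the log-probability of the
observed labels under the warped atlas with a weak Dirichlet pseudo-count
`alpha = 1e-5` so logs stay finite, minus a bending-energy penalty; (ii)
average the inverse-deformed one-hot segmentations (`update_atlas()`).
Convergence is declared when the maximum voxelwise probability change drops
below `tol = 1e-3` (the change log is returned so the decision is
inspectable). Subjects flagged for mirroring are flipped along the first
axis on entry, which is how left and right hemispheres pool into a single
one-sided atlas.

Numerical choices that mattered:

* Gradients of the data term come from interpolated central-difference
  images of the atlas channels, so they exist even for hard (one-hot)
  atlases; channel smoothing is available but off by default — smoothing
  blurs the data term enough that the optimum drifts away from an exact
  one-hot stationary point.
* The data-term curvature is dominated by voxels where the deformed atlas
  assigns the observed label probability near `alpha` — the log slope there
  is `1/alpha`. Plain gradient or quasi-Newton line searches stall on this
  landscape (the gradient is tiny in most coordinates and the curvature
  enormous in a few). The deformation update therefore uses a damped
  diagonally preconditioned Gauss–Newton scheme: the Fisher-style diagonal
  `sum_i B_ij^2 g_i^2` equalises the per-control-point scales, steps are
  sized in voxel units of control displacement, and backtracking halving
  guarantees the objective never increases. The same engine serves the
  segmentation deformation update.
* The bending penalty is evaluated on the control lattice (scaled by
  `spacing^(d-4)` and normalised per voxel), as B-spline registration
  packages conventionally do; it is orders of magnitude cheaper than dense
  finite differences and keeps `reg_weight` comparable across grid sizes.
* Image gradients are precomputed central differences, interpolated at the
  warped positions — differentiating the linear interpolant itself is
  one-sided at voxel centres and breaks line searches right at the usual
  integer-coordinate starting point.

## Bayesian segmentation

The generative model: each anatomical label belongs to a tissue class (the
`tissue_clustering` map; the shipped default has 15 classes, mirroring
common practice for in vivo MRI, though phantom tests use fewer); each class
emits log-intensities from its own Gaussian mixture; a smooth bias field —
multiplicative on intensities, hence additive in the log domain — corrupts
the signal; and the warped probabilistic atlas supplies per-voxel class
priors. `em_fit()` estimates mixture weights, means, variances and the
polynomial bias coefficients by EM: responsibilities in the E-step,
closed-form mixture updates and a responsibility-weighted least-squares
solve for the bias in the M-step. The observed-data log-likelihood is
asserted non-decreasing on every run. Working in the log domain is what
makes the bias M-step a linear solve; voxels with non-positive intensity are
excluded from the mask. Variances are floored at `1e-6` times the data
variance and floored components are flagged rather than silently accepted.
When the priors are uninformative the prior-weighted initial means collapse
to a single value; initial class means are then spread over the intensity
quantiles so EM can break the symmetry.

`segment_bayes()` interleaves EM with the deformation update
(`optimize_deformation()`, which holds the mixture fixed and moves the
class-aggregated atlas channels) for a default of five outer alternations or
until the joint objective changes by less than `1e-5` relative. Final label
posteriors multiply the warped per-label prior with the class likelihood;
the hard segmentation takes the per-voxel argmax with ties broken towards
the lowest label id; expected ROI volumes are posterior sums times the voxel
volume, which avoids the bias of counting argmax voxels.

`segment_by_registration()` provides the registration-based baseline:
B-spline registration of a single labelled template to the target with
control spacing 5 voxels (2.5 mm at 0.5 mm voxels), local NCC with 2.5 mm
windows and bending weight 0.001, then nearest-neighbour label propagation.

## Volumetric statistics

* `correct_volumes()` divides by ICV and regresses out the chosen
  covariates; the corrected feature is residual plus grand mean. Inside
  leave-one-out loops the correction is re-fit on each training fold and its
  coefficients applied to the held-out subject. The covariate set is a
  parameter (sex only, or sex and age) rather than a fixed choice, since
  analyses differ in whether age is a nuisance or the variable of interest.
* `loo_lda()` fits, for each held-out subject, unit-variance scaling, class
  means, the pooled covariance `S` and the ridge-regularised
  `Sigma = S + lambda I` (`lambda = 1` by default; unit-variance scaling is
  what makes a fixed unit ridge sensible), then evaluates
  `L(x) = (mu1 - mu0)' Sigma^-1 (x - 0.5 (mu1 + mu0))`. `roc()` computes
  AUROC by the rank formulation with ties counting one half, and reports
  accuracy at the ROC *elbow*, which we define as the Youden point
  (maximum sensitivity + specificity, ties towards higher sensitivity) —
  the operating point had to be pinned down somehow, and Youden's J is the
  standard choice. `delong_test()` compares two correlated AUROCs with the
  structural-component variance estimate.
* `spearman_age_map()` reports the rank correlation of each corrected
  volume with age: rank statistics fit monotone but non-linear ageing
  trajectories better than Pearson. Raw p values are always reported;
  a Benjamini–Hochberg column is provided because the per-ROI maps are a
  multiple-testing situation, but no thresholding is imposed.
* `fit_laplace_bspline()` models volume-versus-age with an age-dependent
  Laplace distribution whose location and scale are both B-splines over four
  control ages (30, 51.6, 73.3, 95 years by default; any ordered knot list
  is accepted for synthetic cohorts). The Laplace choice makes the fit
  robust to segmentation outliers. The log-likelihood is maximised by
  gradient ascent with backtracking halving; the scale curve passes through
  a softplus with floor `1e-6` to stay positive; the location is initialised
  from a least-absolute-deviations spline fit (IRLS) and the scale from the
  residual MAD. The central 95% interval of a Laplace extends
  `-log(0.05) = 2.996 ~ 3` scale units either side of the location, so the
  reported band is `mu(a) +/- 3 b(a)`.

## What the phantoms emulate — and what they do not

The phantom module generates every input class with retained ground truth:
ellipsoidal label geometry (rejection-sampled, optionally nested within
parent blobs), class-mixture intensities, exponential-polynomial bias
fields, safe random SVFs, distorted multi-modal section stacks with exact
landmark pairs (per-section distortions are themselves SVFs — a rigid
velocity plus a smooth B-spline field — so inverse mappings are exact),
jittered block sets, and cohorts whose ROI volumes follow exactly the
ICV-multiplicative, sex-additive, Laplace-noise trajectory model the
statistics module fits.

Passing recovery tests on these phantoms shows the estimators are correct
under their own assumptions and robust to the planted corruption types
(bias, distortion, outlier registrations). It does **not** show performance
on real histology: the phantoms have no cortical folding, no histological
texture, no staining artefacts beyond monotone remaps and noise, no scanner
noise model, and far fewer, far rounder regions than a real ontology. The
tissue-mask and hemisphere-splitting steps of a production pipeline are
replaced by a required mask input.

Problem sizes in the shipped tests are chosen to exercise every code path at
desk scale: stacks of 4–8 sections at 24–32 voxels in plane, atlases from
4–5 subjects at 28³, and one end-to-end build-and-segment exercise at 64³
with five subjects. These sizes make the full suite reproducible on a
laptop; all thresholds are stated in the tests themselves.

## Degenerate inputs and tie-breaks

Constant images make NCC undefined and are rejected with an error naming
the image. Labels missing from an atlas or a clustering map abort with the
offending ids listed. Empty masks, empty block sets, empty subject lists and
rank-deficient path matrices are all explicit errors rather than silent
degradation. Argmax ties in segmentation go to the lowest label id; ROC
elbow ties go to higher sensitivity; labels empty in both volumes yield an
undefined (NA) Dice rather than 0.
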