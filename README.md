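# histatlas

Building a probabilistic brain atlas from serial histology means solving
four coupled problems: putting distorted 2D sections back into a coherent
3D volume, averaging several labelled volumes into a voxelwise probability
map, segmenting new intensity volumes against that map, and analysing the
regional volumes that come out. `histatlas` implements that computational
chain for R users — image-analysis methodologists who want an inspectable,
desk-scale implementation of each stage, with seeded phantom generators so
every estimator can be tested against known ground truth.

## What is inside

**3D reconstruction of section stacks.** Tissue blocks get similarity poses
by hierarchical joint registration against a reference volume (global NCC
plus a differentiable overlap/gap regulariser that is exactly zero on a
perfect tiling). Individual sections are registered with B-spline
stationary velocity fields (SVFs) under local normalised cross-correlation
with a bending-energy penalty. For a stack of S sections in three
modalities (reference slice M, stains A and B), the pipeline computes an
overconstrained set of 15S − 18 pairwise registrations and reconciles them
with the 3S − 1 transforms of a spanning tree by minimising

```
sum_k w_k || y_k − A_k x ||_1
```

where each measurement `y_k` is the signed sum of latent tree SVFs along
its path (velocities add at first order). The L1 norm — Laplace measurement
noise — makes the reconstruction robust to catastrophically failed
registrations; the problem decouples per control point and component into
small linear programs solved by the simplex method.

**Probabilistic atlas construction.** `build_atlas()` alternates
diffeomorphic registration of each subject's labels to the current atlas
(data term `sum_v log[(p_v(l_v)+α)/(1+αL)]`, bending-energy regularised,
SVF deformation model) with voxelwise averaging of the inverse-deformed
one-hot segmentations, until the atlas stops changing.

**Bayesian segmentation.** `segment_bayes()` jointly estimates a Gaussian
mixture per tissue class (ROIs grouped by a clustering config), a smooth
bias field (multiplicative on intensities, additive in the log domain) and
the atlas deformation, interleaving EM with a monotone deformation update.
Outputs are label posteriors, an argmax segmentation, and expected ROI
volumes `sum_v p(l|y_v) · voxel volume`. A registration-based baseline
(`segment_by_registration()`) propagates a single labelled template with
the conventional settings (5-voxel control spacing, 2.5 mm local NCC
windows, bending weight 0.001).

**Volumetric statistics.** ICV/covariate correction, leave-one-out
regularised LDA with the criterion
`L(x) = (μ̄₁−μ̄₀)ᵀ Σ⁻¹ (x − ½(μ̄₁+μ̄₀))`, `Σ = S + λI`, λ = 1 after
unit-variance scaling; ROC with AUROC by the rank formulation and accuracy
at the Youden elbow; paired DeLong tests; Spearman age–volume maps; and
age-dependent Laplace trajectory fits where location μ(a) and scale b(a)
are B-splines over four control ages (30, 51.6, 73.3, 95 years by default)
with the 95% band μ(a) ± 3 b(a).

**Phantoms.** `make_label_phantom()`, `sample_intensity()`,
`sample_bias()`, `sample_svf()`, `make_section_stack()`, `make_blocks()`
and `make_cohort()` generate every input class with retained ground truth;
all are pure functions of their seed.

## Worked example: ageing trajectories with Laplace noise

```r
library(histatlas)

# a declining ROI with age-constant noise scale, hippocampus-like numbers
tr <- trajectory_spec(knot_ages = c(30, 51.6, 73.3, 95),
                      theta_mu = matrix(c(5000, 4800, 4400, 4000), 1),
                      theta_b  = matrix(rep(120, 4), 1),
                      roi_names = "hippocampus")
coh <- make_cohort(1000, c(30, 95), tr, seed = 6)

X <- correct_volumes(coh, "sex")                 # ICV division + sex regression
icv_ref <- attr(coh, "truth")$icv_ref
fit <- fit_laplace_bspline(coh$age_years, X[, 1] * icv_ref)

ages <- seq(30, 95, 1)
band <- fit$band(ages)                           # mu, b, mu +/- 3b
mu_true <- trajectory_basis(ages, tr$knot_ages) %*% tr$theta_mu[1, ]
cat(sprintf("mu RMSE: %.1f mm^3 (%.2f%% of the true range)\n",
            sqrt(mean((band$mu - mu_true)^2)),
            100 * sqrt(mean((band$mu - mu_true)^2)) / diff(range(mu_true))))

sm <- spearman_age_map(coh)
cat(sprintf("Spearman rho vs age: %.3f (p = %.2g)\n", sm$rho, sm$p))
```

```
mu RMSE: 3.7 mm^3 (0.42% of the true range)
Spearman rho vs age: -0.877 (p = 1.7e-320)
```

The fitted location curve tracks the generating B-spline to well under a
percent of its dynamic range at n = 1000, and the rank correlation with age
is strongly negative, as built into the generator. The band `mu ± 3b`
covers about 95% of fresh draws — the central 95% interval of a Laplace
distribution extends `−log(0.05) ≈ 3` scale units either side of its
location (`laplace_interval_halfwidth()`).

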