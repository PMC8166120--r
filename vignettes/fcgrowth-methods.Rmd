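---
title: "Latent growth models for longitudinal seed connectivity: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Latent growth models for longitudinal seed connectivity: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fcgrowth)
```

# The problem

Cohorts at risk for cognitive decline are often followed with resting-state
fMRI over a handful of widely spaced measurement occasions, with substantial
attrition. The scientific question is whether a baseline characteristic —
here, the degree of self-perceived memory decline measured by the Memory
Functioning Questionnaire Frequency-of-Forgetting score (MFQ-FoF, rescaled
to 0–6 with higher = more concern) — predicts the *rate of change* of
seed-based functional connectivity (FC), voxel by voxel, and whether FC
change in turn relates to change in cognitive performance.

`fcgrowth` implements that analysis end to end: Fisher-z seed-correlation
maps from preprocessed 4D BOLD images, per-voxel conditional latent growth
curve models estimated by full-information maximum likelihood (FIML),
fit-index masking, cluster-extent correction, peak-voxel reporting, and
parallel-process models coupling FC change to cognitive change. A
synthetic-cohort generator with known ground truth makes every stage
testable without access to participant data.

# The growth model

At one voxel, let $y_{it}$ be subject $i$'s Fisher-z connectivity at wave
$t = 1, \dots, T$. The linear latent growth model is

$$
y_{it} = \eta_{Ii} + \lambda_t\, \eta_{Si} + \varepsilon_{it},
\qquad \varepsilon_{it} \sim N(0, \theta_t),
$$

with latent intercept $\eta_I$ (centred at the first wave: $\lambda_1 = 0$)
and latent slope $\eta_S$. In the conditional model both factors are
regressed on the baseline covariates $m$ (MFQ-FoF) and $a$ (age centred at
70 years):

$$
\eta_{Ii} = \alpha_I + \gamma_{Im} m_i + \gamma_{Ia} a_i + \zeta_{Ii},
\qquad
\eta_{Si} = \alpha_S + \gamma_{Sm} m_i + \gamma_{Sa} a_i + \zeta_{Si},
$$

with $(\zeta_I, \zeta_S) \sim N(0, \Psi)$. The voxelwise statistic of
interest is $\gamma_{Sm}$, the effect of subjective decline on the rate of
FC change. The engine behind `fit_lgm()` is a small general SEM core
(latent regressions $B$, covariate paths $\Gamma$, loadings $\Lambda$,
disturbances $\Psi$, residuals $\Theta$), which also expresses the
parallel-process model below.

**Wave coding.** Loadings default to $0, 1, \dots, T-1$: time is measured
in units of one inter-wave interval (about 18 months in the emulated
design), so $\alpha_S$ is change per interval. This is a choice, not a
datum; `build_lgm_spec(loadings = ...)` accepts calendar-time codings, and
a rescaling of the loadings is a pure reparameterization (the test suite
asserts that the likelihood and all fit indices are invariant, with slope
quantities rescaling as $1/c$ and $1/c^2$).

# Estimation: FIML with missing outcomes

Each subject contributes the multivariate-normal log-density of whatever
subvector of $(y_1, \dots, y_T, m, a)$ they have observed. Covariates are
required complete and are modelled as an exogenous block with saturated
moments; the joint likelihood then factorizes into a conditional outcome
part and a closed-form covariate part, so the structural parameters are
estimated from the conditional likelihood while the reported log-likelihood
refers to the joint vector. This is the standard missing-at-random argument:
attrition related to observed baseline variables (age, MFQ-FoF) is absorbed
by conditioning.

Numerically, subjects are grouped by missingness pattern so the likelihood
and its analytic gradient cost the same regardless of $n$ within a pattern.
Optimization is quasi-Newton (BFGS with backtracking line search) from a
method-of-moments start (wave-wise OLS for the mean structure, least
squares on the pairwise-complete residual covariance for the variance
structure), with the initial inverse Hessian taken from the closed-form
expected information so that parameters on very different scales are
well-conditioned from the first step. Convergence requires a gradient
supremum norm below $10^{-6}$ or a step below $10^{-9}$. `fit_lgm()`
defaults to three deterministic starts (the moment start plus two seeded
jitters); the voxelwise driver uses the single moment start, which the
agreement tests show reaches the same optimum on these low-dimensional
models.

Standard errors come from the inverse observed information (a
central-difference Hessian of the negative log-likelihood at the optimum);
Wald $z$ statistics and two-sided $p$-values follow. Variance parameters
are deliberately **unconstrained** during optimization so that negative
estimates are observable — see the boundary rule below.

## Reference models and fit indices

- **Saturated model**: unstructured mean and covariance of the joint
  observed vector, maximized under the same missingness by
  expectation–maximization (with a direct quasi-Newton maximization over a
  Cholesky parameterization available as a cross-check; the two agree to
  $10^{-5}$ in the tests).
- **Baseline model**: all variables independent with free means and
  variances — closed form per variable under FIML.
- $\chi^2 = 2(\ell_\text{sat} - \ell_\text{model})$, with degrees of
  freedom from moment counting over the joint vector (a conditional 3-wave
  model with two covariates has $20 - 17 = 3$).
- CFI uses the baseline just defined; RMSEA is
  $\sqrt{\max(\chi^2 - df, 0) / (df \cdot N)}$ with $N$ the number of
  subjects (an $N-1$ convention is available), and its 95% interval comes
  from root-finding on the noncentral $\chi^2$. When $\chi^2 \le df$ —
  common at these sample sizes — RMSEA is exactly 0 by construction, and a
  saturated model reports CFI = 1, RMSEA = 0.
- SRMR is computed over covariance residuals only (means excluded, a
  documented convention choice among FIML variants), standardizing the
  difference between the saturated-estimate and model-implied covariances
  by the saturated standard deviations, over all $p(p+1)/2$ unique entries
  of the joint vector.

## The negative-variance boundary rule

At $n \approx 69$ with slope variances of order $10^{-3}$, residual and
disturbance variance estimates frequently fall below zero by sampling
error. `apply_heywood_rule()` implements the conventional handling: any
variance estimate below 0 whose 95% Wald interval contains 0 is fixed to 0
and the model refit, iterating until no new violation appears (bounded by
the number of variance parameters). A negative variance whose interval
*excludes* 0 signals genuine misfit and is flagged inadmissible instead of
being silently repaired. Constrained refits can only lower the maximized
likelihood; the tests assert this monotonicity. The rule applies to
residual variances and latent disturbance variances alike, which is what
fixes a cognitive slope disturbance to zero in `fit_cognitive_lgm()` when
the data demand it.

# The voxelwise pipeline

`fit_voxelwise()` runs the conditional model independently at every in-mask
voxel of a stacked map set, recording estimate, SE, $z$, $p$ (two-sided, of
the slope-on-MFQ path by default), $\chi^2$, CFI, RMSEA, SRMR, convergence
and constraint flags. Results are written by voxel position, so output is
independent of iteration order; with the default single moment start the
entire run is deterministic given the data. Then:

1. `fit_quality_mask()` keeps voxels with RMSEA $\le .10$, CFI $\ge .90$
   and SRMR $\le .10$ (closed thresholds) whose model converged. These are
   conventional "reasonable fit" cutoffs; note that at $n = 69$ a
   correctly specified model fails this tri-criterion at a nontrivial rate
   by sampling error alone (about a fifth of null voxels in our synthetic
   runs), which is a property of the indices, not a defect of the mask.
2. `cluster_correct()` thresholds $p < .001$ inside the mask, labels
   connected components (face connectivity by default; 18/26 available)
   and keeps components of at least 240 mm³ — 30 voxels at 2-mm isotropic
   resolution. The extent threshold is a user-supplied constant; no
   Monte-Carlo cluster-threshold estimation is performed.
3. `select_peak()` reports, per cluster, the member voxel with the largest
   absolute slope-on-MFQ estimate among voxels where no boundary
   constraint was applied, refitting the full conditional and the
   unconditional model there; `cluster_unconditional_range()` reports the
   range of unconditional slope variances across the cluster as context
   for individual differences in change.

Two-sided thresholding of the Wald $p$ is the default (signed one-sided
maps are a configuration away); the choice of neighbourhood and thresholds
are arguments, not constants.

# Parallel-process models

`build_parallel_spec()` couples two growth blocks over the same subjects —
connectivity ($I_{fc}, S_{fc}$) and cognition ($I_{cog}, S_{cog}$, with
WMS-IV-style proportion scores in $[0,1]$) — by directed paths
$S_{cog} \leftarrow I_{fc}$ and $S_{cog} \leftarrow S_{fc}$, with every
latent regressed on both covariates. Disturbances covary within a block
only, so fixing the cross paths to zero makes the joint likelihood equal
the sum of the two marginal growth-model likelihoods (asserted to machine
tolerance in the tests); reverse coupling (FC on cognition) is deliberately
not modelled. `indirect_effect()` provides the minimal standard mediation
estimator: the product of the two component paths with a first-order
delta-method standard error
$\sqrt{b^2 \mathrm{Var}(a) + a^2 \mathrm{Var}(b) + 2ab\,\mathrm{Cov}(a,b)}$.
A bootstrap would be preferable near zero products; it is out of scope by
design.

# Seed connectivity

`make_sphere_roi()` builds 12-mm-diameter spheres by voxel-centre distance
(no partial-volume weighting) around the packaged seed coordinates
(`seed_table()`: retrosplenial cortex 2, −48, 24; left/right posterior
hippocampus ∓26, −30, −10; left/right dorsal anterior insula −32, 20, 2 and
36, 20, −2; MNI mm), intersected with a cortical gray-matter mask. The
printed retrosplenial coordinate is used verbatim. `seed_map()` correlates
the ROI-mean series with every gray-matter voxel and applies the Fisher
z-transform; correlations of exactly ±1 are clamped to ±(1 − 10⁻⁷) and
flagged rather than mapped to ±∞, and zero-variance voxel series are
flagged undefined. `regress_global_signal()` residualizes every voxel on an
intercept plus the within-mask mean series. Inputs are assumed
preprocessed, co-registered and on a common grid; a grid mismatch is an
error, never a silent resample.

# The synthetic cohort generator

`simulation_config()` defaults emulate the target design: 69 subjects at
baseline of whom an expected 49 enrol longitudinally, thinning to expected
wave counts of about 34 and 28 (marginal retention 34/49 and 28/49 among
enrollees); three waves ≈ 18 months apart coded 0/1/2; MFQ-FoF truncated
normal on 0–6 with mean 2.99, SD 0.91; age truncated to 50–85 with mean
68.33, SD 7.95; 81% women and 78% African American as descriptive columns.
Attendance is non-monotone by default (intermittent returns allowed), with
a monotone mode that requires non-increasing retention targets; dropout can
depend on baseline covariates through configurable log-odds coefficients,
centred so that zero coefficients reproduce the marginal targets — which is
what makes `audit_missingness()` testable against a known truth.

The default outcome truth (`growth_truth()`) describes a plausible
Fisher-z FC trajectory: baseline mean 0.3, slight decline (−0.01 per
interval), intercept variance 0.04, slope variance 0.004 (the middle of the
plausible range for 18-month FC change), zero intercept–slope covariance,
and residual variances 0.02 per wave. The cognition default uses a
proportion-score scale (baseline 0.40, SD ≈ 0.12 total). The
pipeline-recovery scenario plants one 300 mm³ spherical cluster with a
strong slope-on-MFQ path of −0.15 against this default noise — "strong
effect, low noise" — sized as the 38 voxels nearest the centre.

What the generator deliberately does **not** emulate: spatial noise
correlation (voxels are independent draws around the planted structure),
hemodynamics, motion, or preprocessing failures in the time-series
fixtures. Passing pipeline tests therefore demonstrate correct inference
and bookkeeping under the modelled design, not robustness to spatially
smooth noise — on real data the cluster-extent null behaviour will differ,
which is one reason the extent threshold is a user constant here.

All generator randomness flows from the configured seed; two runs with the
same configuration are identical, and the growth-panel, voxel-field and
time-series generators take independent seeds so stages can be varied
separately.

# Problem sizes and numerical tolerances used in validation

The test suite validates the engine at the sizes the questions demand, each
chosen as the smallest scale at which the check is statistically sharp:
moment agreement at $n = 2 \times 10^5$ (within 4 Monte-Carlo SEs);
parameter recovery and pooled 95% CI coverage over 500 replicates at
$N = 2000$ (coverage asserted in [.93, .97] pooled across parameters, since
a per-parameter band of ±0.02 at 500 replicates is only a 2σ margin);
null calibration of the slope-on-MFQ Wald test over 2000 replicates at the
$N = 69$ attrition design; and the full pipeline on one planted 24³ grid
plus twenty matched null grids. Cross-implementation agreement against
`nlme::lme` / `nlme::gls` on the packaged 69-subject cohort is asserted at
$10^{-4}$ for log-likelihoods and $10^{-3}$ for estimates and fit indices;
that fixture was generated from a truth with comfortably interior variances
(slope variance 0.012, residuals 0.01) because the mixed-model oracle
constrains variances to be non-negative and a boundary optimum would make
the two estimators answer different questions.

# Known limitations

- **Small-sample Wald calibration.** At $N = 69$ with roughly 49 subjects
  informative about slopes, the two-sided Wald test of $\gamma_{Sm}$ is
  anti-conservative: the observed-information SE underestimates the
  sampling SD by a few percent and the test rejects at roughly 8% at
  nominal 5% in our null simulations — matching what `nlme::lme`'s ML
  standard errors produce on the same data (mixed-model software applies
  degrees-of-freedom corrections for exactly this reason). The suite
  measures and reports this rate rather than hiding it; inference at these
  sample sizes should lean on the voxelwise $p < .001$ threshold and
  cluster extent, where the empirical null behaves as designed, and treat
  per-parameter $p$-values near .05 with caution.
- Covariate missingness is unsupported by design (covariates enter the
  FIML joint vector as a complete, saturated block).
- No categorical outcomes, robust (sandwich) SEs, bootstrap intervals,
  multi-group models, or nonlinear growth shapes.
- No permutation or random-field cluster inference; the 240 mm³ extent is
  a constant, not an estimated threshold.
- The delta-method indirect-effect SE is a first-order approximation; its
  agreement with the Monte-Carlo SD is part of the test suite, but
  near-zero products have non-normal sampling distributions.
- **Detection of small clusters is marginal by design.** A 300 mm³ planted
  cluster is 38 voxels against a 30-voxel extent minimum, and the
  fit-quality mask removes roughly a sixth of correctly specified voxels at
  $n = 69$ (mostly through the RMSEA criterion, whose null exceedance
  probability at df = 3 is about 0.17). Single-run recovery of a cluster
  that close to the extent threshold is therefore a near-coin-flip across
  cohort draws, which is why the acceptance script reports a recovery
  *rate* over several seeded replicates; clusters comfortably above the
  extent minimum are recovered reliably, and null grids stay silent.

# A worked example

```{r example, eval = FALSE}
library(fcgrowth)

cfg <- simulation_config(
  effect_clusters = list(effect_cluster(c(12, 12, 12), gamma = -0.15,
                                        volume_mm3 = 300)),
  seed = 1001)
field <- generate_voxel_field(cfg)
maps <- fit_voxelwise(as_map_stack(field), seed = 1)
clusters <- cluster_correct(maps)
clusters
peak <- select_peak(clusters, maps, cluster_id = 1)
glance(peak$fit)
tidy(peak$fit)
```
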