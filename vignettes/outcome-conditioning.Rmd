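---
title: "Methods: simulating and analysing longitudinal exposure trajectories"
author: "trajsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analysing longitudinal exposure trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trajsim)
```

## What the package simulates

The study system is a birth cohort with weight (kg) measured at ages 0, 1
and 2 years and glycated haemoglobin (HbA1c, %) measured at age 40.
Diabetes is defined by the diagnostic rule HbA1c > 6.5% (strict
inequality; a value of exactly 6.5 is classified non-diabetic). Three
causal structures are studied, each placing a single direct standardised
path of strength `direct_effect` from one weight measure onto HbA1c:
birthweight in scenario A, weight at age 1 in scenario B, weight at age 2
in scenario C. Latent quantities that a structural account would include —
an underlying growth factor, and an unmeasured common cause of birthweight
and growth — are deliberately *not* simulated: all their consequences are
absorbed into the reduced-form joint Gaussian over the four observed
variables, which is all any of the analysis methods can see.

### Calibration

`scenario_spec()` fixes the marginal moments (weights: means 4/8/12 kg,
SDs 2 kg; HbA1c: mean 5.8%, SD 1%) and calibrates the 3×3 weight
correlation matrix from target cross-sectional weight–HbA1c correlations.
Under a single direct arrow, d-separation implies

corr(W_j, H) = direct_effect × corr(W_j, W_causal)

for every non-causal weight j. Reading this identity across the three
scenarios gives two independent equations for each pairwise weight
correlation — an over-determined system solved by least squares
(`derive_weight_correlations()`). The calibration fails loudly rather than
silently averaging away disagreement: any single residual of 0.01 or more
between a target and its fitted value raises an error, as does a
non-positive-definite solution. With the default targets the calibrated
pairwise correlations are approximately 0.040 (ages 0–1), −0.151 (ages
0–2) and 0.327 (ages 1–2), and they are *identical across scenarios*: only
the position of the causal arrow moves. `direct_effect` defaults to 0.70,
the value consistent with all three causal-weight target correlations.

`build_joint_gaussian()` then assembles the 4×4 covariance
(weights block `diag(sd) %*% R %*% diag(sd)`; outcome column
`direct_effect × corr(W_j, W_causal) × sd_j × sd_H`) and verifies positive
definiteness by eigendecomposition; `simulate_cohort()` draws i.i.d.
individuals from it via `MASS::mvrnorm`, deterministic given its seed.

### What the generator does and does not emulate

The generator reproduces the study conditions exactly as specified: joint
normality, linear mean growth, a single causal weight per scenario, no
missingness, no competing events, no loss to follow-up, and homogeneous
measurement error. Real growth data are non-linear, skewed,
heteroscedastic and incomplete; a method that passes here can still fail
on such data, and the package's conclusions are about the *logical*
behaviour of the estimators under a known causal truth, not about their
robustness to real-data pathologies.

## The mixed model and its estimation

All model-based analyses rest on `lmm_ar1()`: a linear mixed model with
random intercept and random time slope per subject and first-order
autoregressive within-subject errors,

$$V_j = Z_j G Z_j^\top + \sigma^2_e R(\rho), \qquad
  Z_j = [\,1, t_j\,], \quad R_{st} = \rho^{|s-t|},$$

with lags counted in measurement occasions (identical to calendar lags for
the equally spaced design used here). Age is centred at one year, so the
subject-level time variable takes the values −1, 0, 1 and the intercept is
interpreted at age 1.

Estimation maximises the marginal Gaussian likelihood directly rather than
delegating to an existing mixed-model fitter:

* **Profiling.** At each variance-parameter value the fixed effects are
  the generalised-least-squares solution, so the optimiser works only over
  the five variance parameters. Because the design is balanced, subjects
  are grouped by their (times, fixed-design) pattern and the likelihood is
  evaluated from per-pattern sufficient statistics (counts, response sums
  and cross-products), making one evaluation O(1) in the number of
  subjects.
* **Parameterisation.** Log standard deviations and Fisher-z (atanh)
  transforms of the intercept–slope correlation and of ρ. This keeps the
  optimiser off hard boundaries and mirrors standard practice.
* **Gradient.** The analytic gradient of the profiled (restricted)
  likelihood is supplied (envelope theorem for the profiled fixed
  effects), verified in the test suite against central differences.
* **Constraints and convergence.** With only three occasions per subject
  the five variance parameters are weakly identified, and the
  intercept–slope correlation routinely maximises the likelihood at ±1.
  The unconstrained coordinates are therefore boxed (log-SDs in ±8,
  Fisher-z terms in ±6, i.e. |corr| ≤ 0.99998) and convergence is judged
  on the **projected** gradient of the per-observation objective: a
  coordinate pinned at its bound with the gradient pushing outward
  contributes zero. The tolerance is a max-norm of 1e−5; fits that fail
  it after three jittered restarts (deterministic jitter, SD 0.5 on the
  unconstrained scale) are flagged `converged = FALSE` and discarded by
  the Monte-Carlo harness, never summarised.
* **Start values.** Moment estimates from per-subject ordinary
  least-squares lines, with variances floored at 0.05 to avoid log(0).
* **REML vs ML.** REML is the default (the convention of reference
  mixed-model software); ML is available via `estimation = "ML"` and the
  two are checked to agree closely at large n in the tests. The REML
  objective adds ½ log det(Σ Xᵀ V⁻¹ X) − ½ p log 2π to the profiled ML
  objective, matching the likelihood convention of `nlme::lme`, against
  which the implementation is cross-checked numerically.
* **Degenerate inputs.** Non-positive-definite covariance proposals are
  penalised rather than crashing the line search; singular fixed-effect
  designs and single-subject data are rejected with explicit errors.

Per-subject growth rates are empirical-Bayes (BLUP-style) conditional
means, `γ₁ + G Zᵀ V⁻¹ (y_j − X_j β̂)` in the slope coordinate — the
conventional "individual age coefficients" — and shrink toward the
population slope in proportion to noise.

## The three analysis methods

* **Z-score profiles** (`zscore_profiles()`): weight at each age is
  standardised by the age-specific within-cohort mean and SD (n−1
  denominator; the choice of estimator is irrelevant at n = 1000 but is
  fixed for bit-reproducibility), then averaged within
  outcome groups. A standardisation identity — the prevalence-weighted sum
  of the two group means is zero at every age — is asserted in the tests
  to 1e−10. For a bivariate normal pair with correlation ρ and threshold
  z = 0.7, the expected group means are ρ·φ(0.7)/(1−Φ(0.7)) and
  −ρ·φ(0.7)/Φ(0.7), so the group *separation* is ρ × 1.7025: the profile
  is a picture of cross-sectional correlations, nothing more. This closed
  form is the oracle the tests compare against.
* **Outcome as covariate** (`outcome_covariate_model()`): the mixed model
  with fixed terms intercept, age, diabetes, age×diabetes. The
  age×diabetes interaction is the quantity conventionally misread as a
  causal growth-rate effect.
* **Two-step** (`two_step()`): step 1 fits the exposure-only mixed model —
  by construction it receives a data frame containing only id, time and
  weight, so it *cannot* condition on the outcome — and extracts
  empirical-Bayes growth rates; step 2 is maximum-likelihood logistic
  regression of diabetes on growth rate and birthweight. The growth rate
  is divided by 0.1 before entering the model so its exponentiated
  coefficient is an odds ratio per 0.1 kg/year; birthweight enters in kg.
  An intercept is fitted. Logistic estimation is standard binomial IRLS
  with (quasi-)complete separation detected via fitted probabilities
  numerically at 0 or 1 and flagged as non-convergence. No correction is
  made for the estimated-regressor uncertainty of the step-1 slopes; the
  second-step standard errors are therefore understated, a known
  limitation of two-step approaches.

## The Monte-Carlo harness

`run_scenario()` simulates `n_replicates` cohorts of `n_per_cohort`
individuals (defaults 1000 × 1000, the study's reporting scale), records
per replicate the variable moments, outcome-group mean weights, z-score
profile, outcome-covariate fixed effects and variance components, and
two-step odds ratios, and summarises each quantity by mean, median and the
2.5th/97.5th centiles (linear interpolation between order statistics).
Both mean and median are reported because summaries of this design
conventionally mix the two. Discarding is per model: a replicate whose
outcome-covariate fit fails still contributes its z-score profile and
moments. The discard log records (replicate, model).

Seeding: one master seed deterministically spawns a distinct sub-seed for
every (scenario, replicate) pair, so any single replicate can be
regenerated in isolation and identical configurations are byte-identical
end to end — asserted in the tests by hashing the rendered CSVs.

### Problem sizes used in the checks

The packaged acceptance checks run 300 replicates of n = 1000 per
scenario. At that size the Monte-Carlo standard error of every reported
mean (about 0.006 for the interaction coefficients, about 0.002 for the
correlations) is several times smaller than the tolerances asserted, so
doubling the replicate count would change no conclusion; 1000 replicates
remain the default for `study_config()`. Property tests use cohorts up to
2×10⁵ individuals where a closed-form oracle (truncated-normal group
means, the normal-CDF prevalence 1−Φ(0.7) ≈ 0.242) is being matched, and
5–10-subject fixtures where the likelihood is compared to a dense
multivariate-normal evaluation (agreement to 1e−8).

## Known limitations

* Three occasions identify the variance components only weakly; the
  intercept–slope correlation frequently estimates at its boundary. Fixed
  effects — the quantities the study compares — are insensitive to this,
  but individual variance components should be read with care, and the
  reported "Constant–Age" association is given on both covariance and
  correlation scales.
* Linear growth only: the fixed-effect structure matches the generating
  mean model, so model misfit appears only through the outcome-group
  nonlinearity that conditioning induces (visible in
  `plot_fitted_trajectories()`), not through exposure-model
  misspecification.
* No time-varying confounding, missing data or competing events; methods
  for those settings (g-methods, latent growth-curve models) are out of
  scope.
* Discard counts depend on the optimiser and convergence rule and are not
  comparable across implementations; only the summarised estimates are.
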