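# trajsim

Simulation-based evaluation of common strategies for analysing a
longitudinal exposure in relation to a later-life outcome.

## The problem

Lifecourse studies often relate repeated measurements of an exposure —
here, weight at ages 0, 1 and 2 years — to an outcome measured much later —
glycated haemoglobin (HbA1c, %) at age 40, dichotomised into type-2
diabetes at the diagnostic threshold HbA1c > 6.5%. Popular analyses
*condition on the outcome* while describing the exposure process: z-score
trajectory plots stratified by outcome group, and mixed models of the
exposure that include the outcome as a covariate. Because the exposure
precedes the outcome, such conditioning turns apparent "growth patterns"
into mere reflections of the cross-sectional exposure–outcome correlation
at each age, with no causal meaning. A two-step alternative — model growth
agnostic to the outcome, then regress the outcome on the extracted growth
rate — avoids the problem.

`trajsim` makes this concrete with a fully specified simulation study.
Three causal scenarios are encoded as joint Gaussian laws over
(weight₀, weight₁, weight₂, HbA1c):

* **A** — birthweight directly causes HbA1c; growth rate has no effect;
* **B** — weight at age 1 directly causes HbA1c;
* **C** — weight at age 2 directly causes HbA1c.

Each scenario places a single standardised path of strength 0.70 from one
weight onto HbA1c; every other weight's outcome correlation factorises as
0.70 × corr(weight, causal weight), and the three pairwise weight
correlations are calibrated by least squares from the target outcome
correlations. Weights have means 4/8/12 kg (SD 2 kg); HbA1c has mean 5.8%
(SD 1%).

## The core model

The mixed models are fitted by a purpose-built estimator, `lmm_ar1()`:

  w_ij = x_ij'β + u_0j + u_1j t_ij + ε_ij,
  (u_0j, u_1j) ~ N(0, G),  corr(ε_sj, ε_tj) = ρ^|s−t|

a random-intercept + random-slope model with first-order autoregressive
within-subject errors. The marginal per-subject covariance
V = Z G Zᵀ + σ²R(ρ) is assembled directly; fixed effects are profiled out
by generalised least squares, and the five variance parameters are
maximised on an unconstrained scale (log SDs, Fisher-z correlations) by
box-constrained quasi-Newton iteration with an analytic gradient, under
either REML (default) or ML. Per-subject growth rates are extracted as the
fixed slope plus the empirical-Bayes (BLUP) slope deviation.

On top of this sit the three analysis methods (`zscore_profiles()`,
`outcome_covariate_model()`, `two_step()`) and a Monte-Carlo harness
(`study_config()`, `run_scenario()`, `run_study()`) reporting
across-replicate means, medians and empirical 95% intervals (2.5th/97.5th
centiles), with non-converged fits discarded per model.

## Worked example

```r
library(trajsim)

sp <- scenario_spec("A")                 # birthweight causes HbA1c
jg <- build_joint_gaussian(sp)
round(implied_outcome_correlations(jg), 3)
#> weight_0 weight_1 weight_2
#>    0.700    0.028   -0.106

cohort <- simulate_cohort(jg, n = 1000, seed = 1)
fit <- lmm_ar1(weight ~ time_centered * diabetes, to_long(cohort))
print(summary(fit), digits = 3)
#> Linear mixed model (REML), 1000 subjects, 3000 observations
#> logLik: -6256  converged: TRUE
#>
#> Fixed effects:
#>                        Estimate Std. Error z value Pr(>|z|)
#> (Intercept)              7.8151     0.0451  173.33  < 2e-16 ***
#> time_centered            4.3661     0.0534   81.76  < 2e-16 ***
#> diabetes                 0.7547     0.0936    8.06  7.5e-16 ***
#> time_centered:diabetes  -1.4934     0.1109  -13.47  < 2e-16 ***
#> ...

two_step(cohort)
#> Analysis method: two_step  converged: TRUE
#> Odds ratios (growth rate per 0.1 kg/yr):
#> growth_rate    weight_0    constant
#>      0.9834      2.2600      0.0131
```

The single-cohort fit already shows the pattern the full study averages
over: although growth rate has **no** causal effect on HbA1c in scenario A,
the outcome-as-covariate model reports a strongly negative age-by-diabetes
interaction (here −1.49 kg/yr) — an artefact of conditioning on the
outcome — while the two-step growth-rate odds ratio sits at the null
(0.98 per 0.1 kg/yr).

The full study is one call:

```r
study <- run_study(study_config(n_replicates = 1000, master_seed = 20191204,
                                output_dir = "study-output"))
```

which writes a tidy per-replicate CSV, per-table summary CSVs and a
discard log; `plot_zscore_summary()` and `plot_fitted_trajectories()` draw
the outcome-stratified profile and fitted-trajectory figures.

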