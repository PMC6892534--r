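test_that("z-score profiles satisfy the standardisation identity", {
  jg <- build_joint_gaussian(scenario_spec("A"))
  co <- simulate_cohort(jg, 2000, seed = 31)
  zp <- zscore_profiles(co)
  nd <- attr(zp, "n_diabetic"); nn <- attr(zp, "n_non_diabetic")
  for (a in 0:2) {
    rows <- zp[zp$age == a, ]
    wsum <- nd * rows$mean_z[rows$group == "diabetic"] +
      nn * rows$mean_z[rows$group == "non_diabetic"]
    expect_lt(abs(wsum / (nd + nn)), 1e-10)
  }
})

test_that("group z-score means follow the truncated-normal oracle", {
  n <- 2e5
  for (s in c("A", "B", "C")) {
    jg <- build_joint_gaussian(scenario_spec(s))
    co <- simulate_cohort(jg, n, seed = 32 + match(s, c("A", "B", "C")))
    zp <- zscore_profiles(co)
    rho <- implied_outcome_correlations(jg)
    for (a in 0:2) {
      expected <- truncnorm_group_means(rho[a + 1])
      got_d <- zp$mean_z[zp$age == a & zp$group == "diabetic"]
      got_n <- zp$mean_z[zp$age == a & zp$group == "non_diabetic"]
      expect_lt(abs(got_d - expected[["diabetic"]]), 0.03)
      expect_lt(abs(got_n - expected[["non_diabetic"]]), 0.03)
    }
  }
})

test_that("profiles are flat when weight is independent of the outcome", {
  jg <- build_joint_gaussian(scenario_spec("A"))
  co <- simulate_cohort(jg, 5000, seed = 33)
  set.seed(34)
  co$diabetes <- sample(co$diabetes)   # break the association
  zp <- zscore_profiles(co)
  expect_true(all(abs(zp$mean_z) < 0.1))
  one_group <- co; one_group$diabetes <- 0L
  expect_error(zscore_profiles(one_group), "non-empty")
})

test_that("the outcome-covariate model reports all Eq-style fixed effects", {
  jg <- build_joint_gaussian(scenario_spec("C"))
  long <- to_long(simulate_cohort(jg, 800, seed = 35))
  res <- outcome_covariate_model(long)
  expect_s3_class(res, "method_result")
  expect_named(res$fixed_effects,
               c("Intercept", "Age", "Diabetes", "Diabetes*Age"))
  expect_true(res$converged)
  # positive interaction when the late weight carries the causal arrow
  expect_gt(res$fixed_effects[["Diabetes*Age"]], 0)
})

test_that("interaction sign follows the outcome-correlation gradient", {
  for (s in c("A", "B", "C")) {
    jg <- build_joint_gaussian(scenario_spec(s))
    long <- to_long(simulate_cohort(jg, 1000, seed = 36 + match(s, LETTERS)))
    res <- outcome_covariate_model(long)
    rho <- implied_outcome_correlations(jg)
    expect_equal(sign(res$fixed_effects[["Diabetes*Age"]]),
                 unname(sign(rho[3] - rho[1])), label = paste("scenario", s))
  }
})

test_that("the two-step growth model never sees the outcome", {
  jg <- build_joint_gaussian(scenario_spec("B"))
  co <- simulate_cohort(jg, 400, seed = 37)
  co_scrambled <- co
  set.seed(38)
  co_scrambled$hba1c <- sample(co$hba1c)
  co_scrambled$diabetes <- dichotomize(co_scrambled$hba1c)
  r1 <- two_step(co)
  r2 <- two_step(co_scrambled)
  # identical weights -> identical step-1 growth model, whatever the outcome
  expect_identical(coef(r1$fit), coef(r2$fit))
  expect_identical(r1$fit$varcomp, r2$fit$varcomp)
})

test_that("permuting the outcome nulls both two-step odds ratios", {
  jg <- build_joint_gaussian(scenario_spec("C"))
  co <- simulate_cohort(jg, 2000, seed = 39)
  set.seed(40)
  perm <- sample(nrow(co))
  co$hba1c <- co$hba1c[perm]
  co$diabetes <- co$diabetes[perm]
  res <- two_step(co)
  expect_true(res$converged)
  se <- sqrt(diag(res$logistic$vcov))
  expect_lt(abs(res$log_odds[["growth_rate"]]), 3 * se["growth_rate"])
  expect_lt(abs(res$log_odds[["weight_0"]]), 3 * se["weight_0"])
})

test_that("logistic wrapper matches closed forms and recovers parameters", {
  # intercept-only: logit of the observed proportion
  y <- rep(c(0L, 1L), c(70, 30))
  f <- fit_logistic(y, cbind(`(Intercept)` = rep(1, 100)))
  expect_equal(unname(f$coefficients), qlogis(0.3), tolerance = 1e-8)

  set.seed(41)
  n <- 1e5
  x <- rnorm(n)
  y <- rbinom(n, 1, plogis(-1 + 0.5 * x))
  f <- fit_logistic(y, cbind(`(Intercept)` = 1, x = x))
  se <- sqrt(diag(f$vcov))
  expect_true(f$converged)
  expect_lt(abs(f$coefficients[["(Intercept)"]] + 1), 3 * se[1])
  expect_lt(abs(f$coefficients[["x"]] - 0.5), 3 * se[2])
  expect_equal(unname(coef(glm(y ~ x, family = binomial()))),
               unname(f$coefficients), tolerance = 1e-6)

  # independence: slope ~ 0
  y0 <- rbinom(2000, 1, 0.25)
  x0 <- rnorm(2000)
  f0 <- fit_logistic(y0, cbind(`(Intercept)` = 1, x = x0))
  expect_lt(abs(f0$coefficients[["x"]]), 3 * sqrt(diag(f0$vcov))[2])

  # separation and rank deficiency are flagged, not silently returned
  ysep <- rep(c(0L, 1L), each = 20)
  xsep <- c(rnorm(20, -5), rnorm(20, 5))
  fsep <- fit_logistic(ysep, cbind(`(Intercept)` = 1, x = xsep))
  expect_true(fsep$separation)
  expect_false(fsep$converged)
  frank <- fit_logistic(y0, cbind(a = rep(1, 2000), b = rep(2, 2000)))
  expect_false(frank$converged)
})

test_that("plot methods run on a small study without error", {
  cfg <- study_config(scenarios = "A", n_per_cohort = 300, n_replicates = 3,
                      master_seed = 5)
  st <- run_study(cfg)
  f <- withr::local_tempfile(fileext = ".png")
  grDevices::png(f)
  expect_no_error(plot_zscore_summary(st, "A"))
  expect_no_error(plot_fitted_trajectories(st, "A"))
  co <- simulate_cohort(st$results$A$jg, 500, seed = 1)
  expect_no_error(plot(zscore_profiles(co)))
  grDevices::dev.off()
  expect_true(file.exists(f))
})
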