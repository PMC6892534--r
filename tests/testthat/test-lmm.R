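test_that("subject covariance reduces to known closed forms", {
  vc0 <- list(sigma_u0_sq = 0, sigma_u1_sq = 0, sigma_u01 = 0,
              sigma_e_sq = 1, rho = 0)
  expect_equal(subject_covariance(vc0, c(-1, 0, 1)), diag(3))

  vc_int <- list(sigma_u0_sq = 1, sigma_u1_sq = 0, sigma_u01 = 0,
                 sigma_e_sq = 0, rho = 0)
  expect_equal(subject_covariance(vc_int, c(-1, 0, 1)),
               matrix(1, 3, 3))

  vc_ar <- list(sigma_u0_sq = 0, sigma_u1_sq = 0, sigma_u01 = 0,
                sigma_e_sq = 1, rho = 0.5)
  expect_equal(subject_covariance(vc_ar, c(-1, 0, 1))[1, ], c(1, 0.5, 0.25))

  expect_error(subject_covariance(list(sigma_u0_sq = 1, sigma_u1_sq = 1,
                                       sigma_u01 = 2, sigma_e_sq = 1,
                                       rho = 0), c(-1, 0, 1)))
})

test_that("profiled likelihood equals the dense multivariate-normal oracle", {
  long <- make_fixture_long(n_subj = 5, seed = 10, diabetes = TRUE)
  long$diabetes[1:3] <- 1L                 # ensure both groups present
  vcs <- list(
    list(sigma_u0_sq = 1, sigma_u1_sq = 0.25, sigma_u01 = 0.2,
         sigma_e_sq = 1, rho = 0.3),
    list(sigma_u0_sq = 0.5, sigma_u1_sq = 0.7, sigma_u01 = -0.3,
         sigma_e_sq = 2, rho = -0.4),
    list(sigma_u0_sq = 0, sigma_u1_sq = 0, sigma_u01 = 0,
         sigma_e_sq = 1.3, rho = 0))
  for (vc in vcs) for (est in c("ML", "REML")) {
    ours <- lmm_profile_nll(vc, weight ~ time_centered * diabetes, long,
                            estimation = est, details = TRUE)
    oracle <- dense_nll_oracle(vc, weight ~ time_centered * diabetes, long,
                               estimation = est)
    expect_lt(abs(as.numeric(ours) - as.numeric(oracle)), 1e-8)
    expect_equal(unname(attr(ours, "beta")), unname(attr(oracle, "beta")),
                 tolerance = 1e-10)
  }
})

test_that("iid variance components recover the ordinary least-squares likelihood", {
  long <- make_fixture_long(n_subj = 8, seed = 21)
  vc0 <- list(sigma_u0_sq = 0, sigma_u1_sq = 0, sigma_u01 = 0,
              sigma_e_sq = 1.7, rho = 0)
  nll <- lmm_profile_nll(vc0, weight ~ time_centered, long,
                         estimation = "ML", details = TRUE)
  ols <- lm(weight ~ time_centered, long)
  expect_equal(unname(attr(nll, "beta")), unname(coef(ols)),
               tolerance = 1e-10)
  rss <- sum(residuals(ols)^2)
  N <- nrow(long)
  expect_equal(as.numeric(nll),
               0.5 * (N * log(2 * pi) + N * log(1.7) + rss / 1.7),
               tolerance = 1e-10)
})

test_that("likelihood is invariant to subject ordering", {
  long <- make_fixture_long(n_subj = 6, seed = 30)
  vc <- list(sigma_u0_sq = 0.8, sigma_u1_sq = 0.3, sigma_u01 = 0.1,
             sigma_e_sq = 1.1, rho = 0.25)
  shuffled <- long[sample(nrow(long)), ]
  expect_equal(lmm_profile_nll(vc, weight ~ time_centered, long),
               lmm_profile_nll(vc, weight ~ time_centered, shuffled),
               tolerance = 1e-12)
})

test_that("fitting matches nlme on a simulated cohort", {
  jg <- build_joint_gaussian(scenario_spec("B"))
  long <- to_long(simulate_cohort(jg, 600, seed = 8))
  fit <- lmm_ar1(weight ~ time_centered * diabetes, long, estimation = "ML")
  expect_true(fit$converged)

  ref <- nlme::lme(weight ~ time_centered * diabetes,
                   random = ~ time_centered | id,
                   correlation = nlme::corAR1(form = ~ 1 | id),
                   data = long, method = "ML",
                   control = nlme::lmeControl(maxIter = 200, msMaxIter = 200,
                                              niterEM = 50, opt = "optim"))
  # same likelihood convention: our NLL at nlme's estimates equals its logLik
  vcr <- nlme::VarCorr(ref)
  vcn <- list(
    sigma_u0_sq = as.numeric(vcr["(Intercept)", "StdDev"])^2,
    sigma_u1_sq = as.numeric(vcr["time_centered", "StdDev"])^2,
    sigma_u01 = as.numeric(vcr["time_centered", "Corr"][1]) *
      as.numeric(vcr["(Intercept)", "StdDev"]) *
      as.numeric(vcr["time_centered", "StdDev"]),
    sigma_e_sq = as.numeric(vcr["Residual", "StdDev"])^2,
    rho = as.numeric(coef(ref$modelStruct$corStruct, unconstrained = FALSE)))
  expect_equal(
    -lmm_profile_nll(vcn, weight ~ time_centered * diabetes, long,
                     estimation = "ML"),
    as.numeric(logLik(ref)), tolerance = 1e-4)
  # our optimum is at least as good, and the fixed effects agree
  expect_gte(fit$logLik, as.numeric(logLik(ref)) - 1e-3)
  expect_equal(unname(coef(fit)), unname(nlme::fixef(ref)), tolerance = 1e-3)
})

test_that("variance components are recovered on data from a known model", {
  truth <- list(sigma_u0_sq = 1, sigma_u1_sq = 0.25, sigma_u01 = 0.2,
                sigma_e_sq = 1, rho = 0.3)
  long <- make_fixture_long(n_subj = 3000, vc = truth, seed = 42)
  fit <- lmm_ar1(weight ~ time_centered, long, estimation = "REML")
  expect_true(fit$converged)
  vc <- fit$varcomp
  # loose 3-SE-style bands for n = 3000 subjects, 3 occasions
  expect_equal(vc$sigma_u0_sq, truth$sigma_u0_sq, tolerance = 0.15)
  expect_equal(vc$sigma_u1_sq, truth$sigma_u1_sq, tolerance = 0.35)
  expect_equal(vc$sigma_e_sq, truth$sigma_e_sq, tolerance = 0.15)
  expect_equal(vc$rho, truth$rho, tolerance = 0.35)
  expect_equal(unname(coef(fit)), c(8, 4), tolerance = 0.1)

  # pure-noise generating model: random-effect variances collapse to ~0
  long0 <- make_fixture_long(n_subj = 5000,
                             vc = list(sigma_u0_sq = 0, sigma_u1_sq = 0,
                                       sigma_u01 = 0, sigma_e_sq = 1,
                                       rho = 0),
                             seed = 7)
  fit0 <- lmm_ar1(weight ~ time_centered, long0, estimation = "REML")
  expect_true(fit0$converged)
  expect_lt(fit0$varcomp$sigma_u0_sq, 0.05)
  expect_lt(fit0$varcomp$sigma_u1_sq, 0.05)
  expect_equal(fit0$varcomp$sigma_e_sq, 1, tolerance = 0.05)
  expect_lt(abs(fit0$varcomp$rho), 0.1)
})

test_that("REML and ML agree at large n", {
  truth <- list(sigma_u0_sq = 0.8, sigma_u1_sq = 0.4, sigma_u01 = 0.1,
                sigma_e_sq = 1.2, rho = 0.2)
  long <- make_fixture_long(n_subj = 5000, vc = truth, seed = 9)
  f_reml <- lmm_ar1(weight ~ time_centered, long, estimation = "REML")
  f_ml <- lmm_ar1(weight ~ time_centered, long, estimation = "ML")
  expect_true(f_reml$converged && f_ml$converged)
  rel <- abs(unlist(f_reml$varcomp) - unlist(f_ml$varcomp)) /
    pmax(abs(unlist(f_reml$varcomp)), 0.1)
  expect_true(all(rel < 0.01))
  expect_equal(unname(coef(f_reml)), unname(coef(f_ml)), tolerance = 1e-4)
})

test_that("empirical-Bayes effects match the dense conditional-mean oracle", {
  long <- make_fixture_long(n_subj = 5, seed = 11)
  fit <- lmm_ar1(weight ~ time_centered, long, n_restarts = 1)
  oracle <- dense_blup_oracle(fit$varcomp, fit$coefficients,
                              weight ~ time_centered, long)
  expect_equal(fit$ranef, oracle, tolerance = 1e-8)
  sl <- random_slopes(fit)
  expect_equal(unname(sl),
               unname(coef(fit)["time_centered"] + oracle[, "slope"]),
               tolerance = 1e-8)
  expect_equal(mean(sl), unname(coef(fit)["time_centered"]), tolerance = 0.25)
})

test_that("model methods behave coherently", {
  long <- make_fixture_long(n_subj = 50, seed = 12)
  fit <- lmm_ar1(weight ~ time_centered, long)
  expect_true(fit$converged)
  expect_equal(fitted(fit) + residuals(fit), long$weight, tolerance = 1e-12)
  expect_equal(predict(fit, newdata = long), fitted(fit), tolerance = 1e-12)
  cond <- residuals(fit, type = "conditional")
  expect_lt(mean(cond^2), mean(residuals(fit)^2))  # EB shrinks residuals
  expect_equal(dim(vcov(fit)), c(2L, 2L))
  expect_s3_class(summary(fit), "summary.lmm_ar1")
  expect_output(print(fit), "Linear mixed model")
  expect_equal(attr(logLik(fit), "nobs"), 150L)

  sims <- simulate(fit, nsim = 2, seed = 1)
  expect_equal(dim(sims), c(150L, 2L))
  expect_false(identical(sims$sim_1, sims$sim_2))
  # simulated responses re-fit near the generating parameters
  long2 <- long; long2$weight <- sims$sim_1
  fit2 <- lmm_ar1(weight ~ time_centered, long2)
  expect_equal(unname(coef(fit2)), unname(coef(fit)), tolerance = 0.5)

  f <- withr::local_tempfile(fileext = ".json")
  write_lmm_json(fit, f)
  js <- jsonlite::read_json(f)
  expect_equal(js$varcomp$rho, fit$varcomp$rho, tolerance = 1e-9)
  g <- withr::local_tempfile(fileext = ".csv")
  write_slopes_csv(fit, g)
  expect_equal(nrow(read.csv(g)), 50L)
})

test_that("degenerate inputs are rejected", {
  long <- make_fixture_long(n_subj = 4, seed = 13)
  expect_error(lmm_ar1(weight ~ 1, long), "main effect")
  expect_error(lmm_ar1(weight ~ time_centered, long[long$id == 1, ]),
               "2 subjects")
  fit <- lmm_ar1(weight ~ time_centered, long)
  fit$converged <- FALSE
  expect_error(random_slopes(fit), "converged")
})
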