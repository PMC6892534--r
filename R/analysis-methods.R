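# The three analysis strategies under comparison.  Two of them condition on
# the outcome (z-score profiles; the mixed model with diabetes as covariate),
# one does not (the two-step approach).

#' Outcome-stratified z-score profile of weight
#'
#' Standardises weight at each age into z-scores using the age-specific
#' within-cohort sample mean and SD (n-1 denominator), then averages the
#' z-scores within the diabetic and non-diabetic groups at each age.  By
#' construction the prevalence-weighted average of the two group means is
#' zero at every age, so the "profile" reflects nothing but the size of the
#' cross-sectional weight--outcome correlation at each age.
#'
#' @param cohort A `cohort_data` frame; both outcome groups must be
#'   non-empty.
#' @return An object of class `zscore_profile`: data frame with columns
#'   `age`, `group` (`"diabetic"`/`"non_diabetic"`), `mean_z`, plus the group
#'   sizes as attributes.
#' @examples
#' jg <- build_joint_gaussian(scenario_spec("A"))
#' zscore_profiles(simulate_cohort(jg, 500, seed = 1))
#' @export
zscore_profiles <- function(cohort) {
  stopifnot(is.data.frame(cohort), "diabetes" %in% names(cohort))
  d <- cohort$diabetes
  if (!any(d == 1) || !any(d == 0))
    stop("both outcome groups must be non-empty")
  ages <- c(0, 1, 2)
  cols <- paste0("weight_", ages)
  rows <- lapply(seq_along(ages), function(j) {
    w <- cohort[[cols[j]]]
    s <- stats::sd(w)
    if (s == 0) stop("zero weight SD at age ", ages[j])
    z <- (w - mean(w)) / s
    data.frame(age = ages[j],
               group = c("diabetic", "non_diabetic"),
               mean_z = c(mean(z[d == 1]), mean(z[d == 0])))
  })
  out <- do.call(rbind, rows)
  attr(out, "n_diabetic") <- sum(d == 1)
  attr(out, "n_non_diabetic") <- sum(d == 0)
  class(out) <- c("zscore_profile", "data.frame")
  out
}

#' Mixed model of weight with the outcome as a covariate
#'
#' Fits the random-intercept + random-slope AR(1) mixed model of weight on
#' age with diabetes status and an age-by-diabetes interaction as fixed
#' covariates.  The interaction coefficient is the quantity conventionally
#' read as "difference in growth rate between outcome groups".
#'
#' @param long Long-format data with columns `id`, `time_centered`, `weight`,
#'   `diabetes`.
#' @param estimation `"REML"` (default) or `"ML"`.
#' @param ... Passed to [lmm_ar1()].
#' @return A `method_result` list: `method = "outcome_covariate"`,
#'   `fixed_effects` (Intercept, Age, Diabetes, Diabetes*Age), `varcomp`,
#'   `converged`, and the underlying `fit`.
#' @export
outcome_covariate_model <- function(long, estimation = "REML", ...) {
  stopifnot(all(c("id", "time_centered", "weight", "diabetes") %in%
                  names(long)))
  if (length(unique(long$diabetes)) < 2L)
    stop("both outcome groups must be non-empty")
  fit <- lmm_ar1(weight ~ time_centered * diabetes, long,
                 estimation = estimation, ...)
  fe <- stats::setNames(
    fit$coefficients[c("(Intercept)", "time_centered", "diabetes",
                       "time_centered:diabetes")],
    c("Intercept", "Age", "Diabetes", "Diabetes*Age"))
  structure(list(method = "outcome_covariate",
                 fixed_effects = fe,
                 varcomp = fit$varcomp,
                 converged = fit$converged,
                 fit = fit),
            class = "method_result")
}

#' Maximum-likelihood logistic regression with separation detection
#'
#' Thin wrapper around binomial iteratively reweighted least squares
#' (`stats::glm.fit`) that reports coefficients together with a convergence
#' flag covering both IRLS convergence and (quasi-)complete separation,
#' detected as fitted probabilities numerically at 0 or 1.
#'
#' @param y Binary 0/1 response vector.
#' @param X Design matrix (include an intercept column explicitly).
#' @return List with `coefficients` (named), `vcov`, `converged`,
#'   `separation`.
#' @examples
#' X <- cbind(`(Intercept)` = 1, x = rnorm(200))
#' y <- rbinom(200, 1, plogis(-1 + 0.5 * X[, "x"]))
#' fit_logistic(y, X)$coefficients
#' @export
fit_logistic <- function(y, X) {
  stopifnot(all(y %in% c(0, 1)), nrow(X) == length(y))
  if (qr(X)$rank < ncol(X))
    return(list(coefficients = stats::setNames(rep(NA_real_, ncol(X)),
                                               colnames(X)),
                vcov = NULL, converged = FALSE, separation = FALSE))
  fit <- suppressWarnings(
    stats::glm.fit(X, y, family = stats::binomial()))
  mu <- fit$fitted.values
  separation <- any(mu < 1e-10 | mu > 1 - 1e-10)
  w <- fit$weights
  info <- crossprod(X * sqrt(w))
  vc <- tryCatch(solve(info), error = function(e) NULL)
  list(coefficients = stats::setNames(fit$coefficients, colnames(X)),
       vcov = vc,
       converged = isTRUE(fit$converged) && !separation && !is.null(vc),
       separation = separation)
}

#' Two-step analysis: outcome-agnostic growth model, then logistic regression
#'
#' Step 1 fits the exposure-only mixed model of weight on age (random
#' intercept + slope, AR(1) errors) *without ever seeing the outcome*: the
#' model receives only the id, time and weight columns.  Each subject's
#' growth rate is extracted as the fixed slope plus the empirical-Bayes slope
#' deviation.  Step 2 fits a logistic regression of diabetes on the growth
#' rate (rescaled to per 0.1 kg/year) with birthweight as a confounder
#' adjustment.
#'
#' @param cohort A `cohort_data` frame.
#' @param estimation `"REML"` (default) or `"ML"` for step 1.
#' @param ... Passed to [lmm_ar1()].
#' @return A `method_result` list: `method = "two_step"`, `odds_ratios`
#'   (`growth_rate` per 0.1 kg/yr, `weight_0` per kg, `constant`),
#'   `log_odds` (the raw coefficients), `converged`, plus the step-1 `fit`
#'   and the step-2 output.
#' @export
two_step <- function(cohort, estimation = "REML", ...) {
  stopifnot(is.data.frame(cohort),
            all(c("id", "weight_0", "hba1c", "diabetes") %in% names(cohort)))
  long_exposure <- to_long(cohort, keep_outcome = FALSE)   # id/time/weight only
  step1 <- lmm_ar1(weight ~ time_centered, long_exposure,
                   estimation = estimation, ...)
  if (!step1$converged)
    return(structure(list(method = "two_step", odds_ratios = NULL,
                          log_odds = NULL, converged = FALSE,
                          fit = step1, logistic = NULL),
                     class = "method_result"))
  slopes <- random_slopes(step1)
  slopes <- slopes[as.character(cohort$id)]
  X <- cbind(`(Intercept)` = 1,
             growth_rate = slopes / 0.1,   # per 0.1 kg/year
             weight_0 = cohort$weight_0)
  step2 <- fit_logistic(cohort$diabetes, X)
  lo <- step2$coefficients
  structure(list(method = "two_step",
                 odds_ratios = c(growth_rate = unname(exp(lo["growth_rate"])),
                                 weight_0 = unname(exp(lo["weight_0"])),
                                 constant = unname(exp(lo["(Intercept)"]))),
                 log_odds = lo,
                 converged = step2$converged,
                 fit = step1,
                 logistic = step2),
            class = "method_result")
}

#' @export
print.method_result <- function(x, digits = 4, ...) {
  cat("Analysis method:", x$method, " converged:", x$converged, "\n")
  if (x$method == "outcome_covariate") {
    print(round(x$fixed_effects, digits))
  } else if (x$method == "two_step" && !is.null(x$odds_ratios)) {
    cat("Odds ratios (growth rate per 0.1 kg/yr):\n")
    print(signif(x$odds_ratios, digits))
  }
  invisible(x)
}
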