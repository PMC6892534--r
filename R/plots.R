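# Base-graphics figures: outcome-stratified z-score profiles and fitted
# group trajectories from the outcome-as-covariate model.

#' @export
plot.zscore_profile <- function(x, main = "Weight z-score by outcome group",
                                ...) {
  ages <- sort(unique(x$age))
  zd <- x$mean_z[x$group == "diabetic"][order(x$age[x$group == "diabetic"])]
  zn <- x$mean_z[x$group == "non_diabetic"][
    order(x$age[x$group == "non_diabetic"])]
  ylim <- range(c(zd, zn, 0))
  graphics::plot(ages, zd, type = "b", lty = 3, pch = 16, ylim = ylim,
                 xlab = "Age (years)", ylab = "Mean weight z-score",
                 main = main, ...)
  graphics::lines(ages, zn, type = "b", lty = 2, pch = 17)
  graphics::abline(h = 0, col = "grey70")
  graphics::legend("topright", legend = c("diabetic", "non-diabetic"),
                   lty = c(3, 2), pch = c(16, 17), bty = "n")
  invisible(x)
}

.pull_summary <- function(study, scenario, method, parameters) {
  s <- study$results[[scenario]]$summary
  idx <- match(parameters, s$parameter[s$method == method])
  sm <- s[s$method == method, ][idx, ]
  if (anyNA(idx)) stop("missing summary parameters for plot")
  sm
}

#' Plot averaged z-score profiles with empirical confidence intervals
#'
#' Draws the across-replicate mean weight z-score in the diabetic and
#' non-diabetic groups at each age, with error bars at the empirical 2.5th
#' and 97.5th centiles.
#'
#' @param study An `mc_study` from [run_study()].
#' @param scenario Scenario id present in the study.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, the plotted summary frame.
#' @export
plot_zscore_summary <- function(study, scenario, ...) {
  stopifnot(inherits(study, "mc_study"))
  ages <- 0:2
  sd_ <- .pull_summary(study, scenario, "zscore",
                       paste0("z_diabetic_age_", ages))
  sn_ <- .pull_summary(study, scenario, "zscore",
                       paste0("z_non_diabetic_age_", ages))
  ylim <- range(c(sd_$centile_2_5, sd_$centile_97_5,
                  sn_$centile_2_5, sn_$centile_97_5, 0))
  graphics::plot(ages, sd_$mean, type = "b", lty = 3, pch = 16, ylim = ylim,
                 xlab = "Age (years)", ylab = "Mean weight z-score",
                 main = paste("Scenario", scenario), ...)
  graphics::arrows(ages, sd_$centile_2_5, ages, sd_$centile_97_5,
                   angle = 90, code = 3, length = 0.04)
  graphics::lines(ages, sn_$mean, type = "b", lty = 2, pch = 17)
  graphics::arrows(ages, sn_$centile_2_5, ages, sn_$centile_97_5,
                   angle = 90, code = 3, length = 0.04)
  graphics::abline(h = 0, col = "grey70")
  graphics::legend("topright", legend = c("diabetic", "non-diabetic"),
                   lty = c(3, 2), pch = c(16, 17), bty = "n")
  invisible(rbind(sd_, sn_))
}

#' Plot fitted group trajectories against observed group means
#'
#' Evaluates the averaged outcome-as-covariate fixed effects at ages 0, 1, 2
#' for each outcome group and overlays the across-replicate mean observed
#' group weights, exposing the misfit introduced by the linearity constraint.
#'
#' @inheritParams plot_zscore_summary
#' @return Invisibly, a list with the fitted lines and observed means.
#' @export
plot_fitted_trajectories <- function(study, scenario, ...) {
  stopifnot(inherits(study, "mc_study"))
  fe <- .pull_summary(study, scenario, "outcome_covariate",
                      c("Intercept", "Age", "Diabetes", "Diabetes*Age"))
  est <- stats::setNames(fe$mean, fe$parameter)
  tt <- (0:2) - 1
  fit_non <- est["Intercept"] + est["Age"] * tt
  fit_dia <- fit_non + est["Diabetes"] + est["Diabetes*Age"] * tt
  gm_d <- .pull_summary(study, scenario, "group_means",
                        paste0("gm_weight_", 0:2, "_diabetic"))$mean
  gm_n <- .pull_summary(study, scenario, "group_means",
                        paste0("gm_weight_", 0:2, "_non_diabetic"))$mean
  ylim <- range(c(fit_non, fit_dia, gm_d, gm_n))
  graphics::plot(0:2, fit_dia, type = "l", lty = 3, ylim = ylim,
                 xlab = "Age (years)", ylab = "Weight (kg)",
                 main = paste("Scenario", scenario), ...)
  graphics::lines(0:2, fit_non, lty = 2)
  graphics::points(0:2, gm_d, pch = 16)
  graphics::points(0:2, gm_n, pch = 17)
  graphics::legend("topleft",
                   legend = c("fitted, diabetic", "fitted, non-diabetic",
                              "observed mean, diabetic",
                              "observed mean, non-diabetic"),
                   lty = c(3, 2, NA, NA), pch = c(NA, NA, 16, 17), bty = "n")
  invisible(list(fitted_diabetic = fit_dia, fitted_non_diabetic = fit_non,
                 observed_diabetic = gm_d, observed_non_diabetic = gm_n))
}
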