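#' @export
print.lmm_ar1 <- function(x, digits = 4, ...) {
  cat("Linear mixed model: random intercept + slope",
      if (x$ar1) "with AR(1) errors" else "(independent errors)", "\n")
  cat("  estimation:", x$estimation,
      " logLik:", format(x$logLik, digits = digits),
      " converged:", x$converged, "\n")
  cat("  subjects:", x$n_subjects, " observations:", x$n_obs, "\n")
  cat("Fixed effects:\n")
  print(round(x$coefficients, digits))
  invisible(x)
}

#' @export
summary.lmm_ar1 <- function(object, ...) {
  se <- sqrt(diag(object$vcov))
  z <- object$coefficients / se
  coef_table <- cbind(Estimate = object$coefficients,
                      `Std. Error` = se,
                      `z value` = z,
                      `Pr(>|z|)` = 2 * stats::pnorm(-abs(z)))
  vc <- object$varcomp
  cor01 <- if (vc$sigma_u0_sq > 0 && vc$sigma_u1_sq > 0)
    vc$sigma_u01 / sqrt(vc$sigma_u0_sq * vc$sigma_u1_sq) else NA_real_
  out <- list(call = object$call, coefficients = coef_table,
              varcomp = vc, cor_intercept_slope = cor01,
              logLik = object$logLik, estimation = object$estimation,
              converged = object$converged, n_obs = object$n_obs,
              n_subjects = object$n_subjects, ar1 = object$ar1)
  class(out) <- "summary.lmm_ar1"
  out
}

#' @export
print.summary.lmm_ar1 <- function(x, digits = 4, ...) {
  cat("Linear mixed model (", x$estimation, "), ",
      x$n_subjects, " subjects, ", x$n_obs, " observations\n", sep = "")
  cat("logLik:", format(x$logLik, digits = digits),
      " converged:", x$converged, "\n\nFixed effects:\n")
  stats::printCoefmat(x$coefficients, digits = digits)
  cat("\nVariance components:\n")
  v <- x$varcomp
  cat(sprintf("  intercept variance   %s\n", format(v$sigma_u0_sq, digits = digits)))
  cat(sprintf("  slope variance       %s\n", format(v$sigma_u1_sq, digits = digits)))
  cat(sprintf("  intercept-slope cov  %s (corr %s)\n",
              format(v$sigma_u01, digits = digits),
              format(x$cor_intercept_slope, digits = digits)))
  cat(sprintf("  residual variance    %s\n", format(v$sigma_e_sq, digits = digits)))
  if (x$ar1)
    cat(sprintf("  AR(1) correlation    %s\n", format(v$rho, digits = digits)))
  invisible(x)
}

#' @export
coef.lmm_ar1 <- function(object, ...) object$coefficients

#' @export
vcov.lmm_ar1 <- function(object, ...) object$vcov

#' @export
logLik.lmm_ar1 <- function(object, ...) {
  structure(object$logLik,
            df = length(object$coefficients) + if (object$ar1) 5L else 4L,
            nobs = object$n_obs, class = "logLik")
}

#' Extract empirical-Bayes random effects
#'
#' @param object A fitted `lmm_ar1`.
#' @param ... Unused.
#' @return A matrix of per-subject intercept and slope deviations.
#' @export
ranef <- function(object, ...) UseMethod("ranef")

#' @rdname ranef
#' @export
ranef.lmm_ar1 <- function(object, ...) object$ranef

#' @export
fitted.lmm_ar1 <- function(object, ...) {
  # population-level fitted values, mapped back to the original row order
  p <- object$patterns
  mu_sorted <- drop(p$X %*% object$coefficients)
  out <- numeric(length(mu_sorted))
  out[p$order] <- mu_sorted
  out
}

#' @export
residuals.lmm_ar1 <- function(object, type = c("marginal", "conditional"),
                              ...) {
  type <- match.arg(type)
  p <- object$patterns
  res_sorted <- p$y - drop(p$X %*% object$coefficients)
  if (type == "conditional") {
    u <- object$ranef
    subj <- as.character(p$ids)
    res_sorted <- res_sorted - (u[subj, "intercept"] +
                                  u[subj, "slope"] * p$times)
  }
  out <- numeric(length(res_sorted))
  out[p$order] <- res_sorted
  out
}

#' @export
predict.lmm_ar1 <- function(object, newdata = NULL, level = 0, ...) {
  if (is.null(newdata)) {
    out <- fitted(object)
    if (level > 0) {
      p <- object$patterns
      u <- object$ranef
      subj <- as.character(p$ids)
      add <- u[subj, "intercept"] + u[subj, "slope"] * p$times
      tmp <- numeric(length(add)); tmp[p$order] <- add
      out <- out + tmp
    }
    return(out)
  }
  Terms <- stats::delete.response(object$terms)
  mf <- stats::model.frame(Terms, newdata, xlev = object$xlevels)
  X <- stats::model.matrix(Terms, mf)
  out <- as.vector(X %*% object$coefficients)
  if (level > 0) {
    subj <- as.character(newdata[[object$id_var]])
    known <- subj %in% rownames(object$ranef)
    if (!all(known)) stop("level > 0 prediction for unknown subject ids")
    out <- out + object$ranef[subj, "intercept"] +
      object$ranef[subj, "slope"] * newdata[[object$time_var]]
  }
  out
}

#' @export
simulate.lmm_ar1 <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  p <- object$patterns
  vc <- object$varcomp
  n_total <- length(p$y)
  sims <- matrix(NA_real_, nrow = n_total, ncol = nsim)
  mu_sorted <- drop(p$X %*% object$coefficients)
  for (s in seq_len(nsim)) {
    y_sorted <- numeric(n_total)
    row_of <- split(seq_len(n_total), p$ids)
    for (pat in p$patterns) {
      V <- subject_covariance(vc, pat$times)
      L <- chol(V)
      Zdraw <- matrix(stats::rnorm(pat$n * length(pat$times)), nrow = pat$n)
      E <- Zdraw %*% L
      for (i in seq_along(pat$ids)) {
        rows <- row_of[[pat$ids[i]]]
        y_sorted[rows] <- mu_sorted[rows] + E[i, ]
      }
    }
    sims[p$order, s] <- y_sorted
  }
  out <- as.data.frame(sims)
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}
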