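# Serialisation helpers for fitted models.

#' Serialise a fitted mixed model to JSON
#'
#' Writes the fixed effects, variance components, log-likelihood, estimation
#' method and convergence flag.
#'
#' @param fit An `lmm_ar1` fit.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_lmm_json <- function(fit, path) {
  stopifnot(inherits(fit, "lmm_ar1"))
  jsonlite::write_json(list(
    fixed_effects = as.list(fit$coefficients),
    varcomp = fit$varcomp,
    logLik = fit$logLik,
    estimation = fit$estimation,
    ar1 = fit$ar1,
    converged = fit$converged,
    n_subjects = fit$n_subjects,
    n_obs = fit$n_obs
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Export per-subject growth rates as CSV
#'
#' @param fit A converged `lmm_ar1` fit.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_slopes_csv <- function(fit, path) {
  sl <- random_slopes(fit)
  utils::write.csv(data.frame(id = names(sl), slope = unname(sl)),
                   path, row.names = FALSE)
  invisible(path)
}
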