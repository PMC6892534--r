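#' Default cross-sectional outcome-correlation targets
#'
#' The calibration targets used by [scenario_spec()]: for each causal scenario,
#' the cross-sectional Pearson correlation of weight at ages 0, 1 and 2 years
#' with continuous HbA1c.  Scenario A places the direct causal arrow on
#' birthweight, scenario B on weight at age 1 and scenario C on weight at age
#' 2; the remaining correlations are induced through the correlations between
#' the weight measures themselves.
#'
#' @return A 3x3 numeric matrix; rows are scenarios `A`, `B`, `C`, columns the
#'   weights at ages 0, 1, 2.
#' @export
default_outcome_targets <- function() {
  matrix(c(0.699,  0.029, -0.105,
           0.027,  0.699,  0.229,
          -0.106,  0.229,  0.700),
         nrow = 3, byrow = TRUE,
         dimnames = list(c("A", "B", "C"),
                         c("weight_0", "weight_1", "weight_2")))
}

#' Calibrate the weight correlation matrix from outcome-correlation targets
#'
#' Each causal scenario places a direct (standardised) path of strength
#' `direct_effect` from exactly one weight measure onto the outcome.  By
#' d-separation every *other* weight is correlated with the outcome only
#' through the causal weight, so its outcome correlation factorises as
#' `direct_effect * corr(weight_j, causal weight)`.  Reading this identity
#' across all scenarios gives an over-determined linear system for the three
#' pairwise weight correlations, which is solved by least squares.
#'
#' @param targets 3x3 matrix of target outcome correlations, rows = scenarios,
#'   columns = weights at ages 0, 1, 2 (see [default_outcome_targets()]).
#' @param direct_effect Standardised path coefficient of the causal weight on
#'   the outcome, in (0, 1].
#' @param causal_index Integer vector giving, per scenario (row of `targets`),
#'   the column index of the causal weight.  Default `c(1, 2, 3)`: scenario A
#'   acts through birthweight, B through weight at age 1, C through weight at
#'   age 2.
#' @param max_residual Largest tolerated absolute residual between a target
#'   and its fitted value `direct_effect * rho`; larger residuals signal
#'   mutually inconsistent targets and raise an error.
#'
#' @return A 3x3 correlation matrix across the weight ages (symmetric, unit
#'   diagonal, positive definite).
#' @examples
#' derive_weight_correlations(default_outcome_targets(), 0.70)
#' @export
derive_weight_correlations <- function(targets, direct_effect,
                                       causal_index = c(1L, 2L, 3L),
                                       max_residual = 0.01) {
  stopifnot(is.matrix(targets), dim(targets) == c(3L, 3L),
            length(causal_index) == 3L, all(causal_index %in% 1:3),
            anyDuplicated(causal_index) == 0L,
            direct_effect > 0, direct_effect <= 1)

  # each scenario's causal weight must carry (approximately) the full path
  causal_resid <- abs(targets[cbind(1:3, causal_index)] - direct_effect)
  if (any(causal_resid >= max_residual))
    stop("causal-weight targets inconsistent with direct_effect (residual ",
         signif(max(causal_resid), 3), ")")

  W <- diag(3)
  for (j in 1:2) for (k in (j + 1):3) {
    # equations from scenarios whose causal weight is one of the pair
    s_j <- which(causal_index == k)  # scenario where j is the non-causal one
    s_k <- which(causal_index == j)
    eqs <- c(targets[s_j, j], targets[s_k, k])
    rho <- sum(eqs) / (length(eqs) * direct_effect)  # least squares
    if (any(abs(eqs - direct_effect * rho) >= max_residual))
      stop("inconsistent outcome-correlation targets for weight pair (",
           j - 1, ",", k - 1, ")")
    W[j, k] <- W[k, j] <- rho
  }
  dimnames(W) <- list(colnames(targets), colnames(targets))
  ev <- eigen(W, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0)
    stop("calibrated weight correlation matrix is not positive definite")
  W
}

#' Declare a causal scenario for the growth--outcome simulation
#'
#' A scenario fixes which weight measure carries the direct causal arrow onto
#' HbA1c, the marginal moments of all four observed variables, the strength of
#' the direct standardised effect, and the correlation structure among the
#' weight measures.  The weight correlations are calibrated once from the
#' cross-sectional outcome-correlation targets and are identical across
#' scenarios: only the position of the causal arrow moves.
#'
#' @param scenario_id `"A"`, `"B"` or `"C"`.  A: birthweight causes HbA1c
#'   (growth rate has no effect); B: weight at age 1 causes HbA1c; C: weight
#'   at age 2 causes HbA1c.
#' @param direct_effect Standardised path coefficient of the causal weight on
#'   HbA1c; default 0.70.
#' @param weight_means,weight_sds Means and SDs (kg) of weight at ages 0, 1,
#'   2 years.
#' @param hba1c_mean,hba1c_sd Mean and SD of HbA1c (%).
#' @param targets Outcome-correlation targets passed to
#'   [derive_weight_correlations()].
#'
#' @return An object of class `scenario_spec`.
#' @examples
#' sp <- scenario_spec("A")
#' sp$causal_weight_index
#' @export
scenario_spec <- function(scenario_id = c("A", "B", "C"),
                          direct_effect = 0.70,
                          weight_means = c(4, 8, 12),
                          weight_sds = c(2, 2, 2),
                          hba1c_mean = 5.8,
                          hba1c_sd = 1,
                          targets = default_outcome_targets()) {
  scenario_id <- match.arg(scenario_id)
  stopifnot(length(weight_means) == 3L, length(weight_sds) == 3L,
            all(weight_sds > 0), hba1c_sd > 0,
            direct_effect > 0, direct_effect < 1 || direct_effect == 1)
  causal_index <- match(scenario_id, c("A", "B", "C"))
  W <- derive_weight_correlations(targets, direct_effect)
  out <- list(
    scenario_id = scenario_id,
    causal_weight_index = causal_index - 1L,  # age in years of causal weight
    direct_effect = direct_effect,
    weight_means = as.numeric(weight_means),
    weight_sds = as.numeric(weight_sds),
    hba1c_mean = hba1c_mean,
    hba1c_sd = hba1c_sd,
    weight_corr = W
  )
  class(out) <- "scenario_spec"
  out
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat("Causal scenario", x$scenario_id, "\n")
  cat("  direct arrow: weight_", x$causal_weight_index, " -> HbA1c (",
      "standardised effect ", x$direct_effect, ")\n", sep = "")
  cat("  weight means (kg):", x$weight_means,
      " SDs:", x$weight_sds, "\n")
  cat("  HbA1c mean (%):", x$hba1c_mean, " SD:", x$hba1c_sd, "\n")
  cat("  weight correlations:\n")
  print(round(x$weight_corr, 4))
  invisible(x)
}

#' Build the joint Gaussian law implied by a causal scenario
#'
#' Converts a [scenario_spec()] into the reduced-form multivariate normal
#' distribution over the observed variables (weight_0, weight_1, weight_2,
#' hba1c).  The weight block is `diag(sds) %*% weight_corr %*% diag(sds)`; the
#' outcome covariances follow from the single-direct-arrow structure:
#' `cov(W_j, H) = direct_effect * corr(W_j, W_causal) * sd_j * hba1c_sd`.
#'
#' @param spec A `scenario_spec`.
#' @return An object of class `joint_gaussian`: list with `labels`, `mean`
#'   (length 4) and `covariance` (4x4, positive definite).
#' @examples
#' jg <- build_joint_gaussian(scenario_spec("A"))
#' implied_outcome_correlations(jg)
#' @export
build_joint_gaussian <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  k <- spec$causal_weight_index + 1L
  rho_with_causal <- spec$weight_corr[, k]     # corr(W_j, W_causal), =1 at j=k
  outcome_corr <- spec$direct_effect * rho_with_causal
  Sw <- diag(spec$weight_sds) %*% spec$weight_corr %*% diag(spec$weight_sds)
  cov_wh <- outcome_corr * spec$weight_sds * spec$hba1c_sd
  covariance <- rbind(cbind(Sw, cov_wh), c(cov_wh, spec$hba1c_sd^2))
  labels <- c("weight_0", "weight_1", "weight_2", "hba1c")
  dimnames(covariance) <- list(labels, labels)
  ev <- eigen(covariance, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0)
    stop("implied 4x4 covariance is not positive definite: calibration failure")
  out <- list(labels = labels,
              mean = stats::setNames(c(spec$weight_means, spec$hba1c_mean),
                                     labels),
              covariance = covariance)
  class(out) <- "joint_gaussian"
  out
}

#' @export
print.joint_gaussian <- function(x, ...) {
  cat("Joint Gaussian over", paste(x$labels, collapse = ", "), "\n")
  cat("mean:\n"); print(round(x$mean, 4))
  cat("covariance:\n"); print(round(x$covariance, 4))
  invisible(x)
}

#' Outcome correlations implied by a joint Gaussian
#'
#' @param jg A `joint_gaussian`.
#' @return Named length-3 vector: `corr(weight_j, hba1c)` for ages 0, 1, 2.
#' @export
implied_outcome_correlations <- function(jg) {
  stopifnot(inherits(jg, "joint_gaussian"))
  R <- stats::cov2cor(jg$covariance)
  R[1:3, 4]
}

#' Read and write scenario definitions as YAML
#'
#' Serialises the declarative part of a scenario (id, direct effect, moments,
#' calibration targets); the weight correlation matrix is re-derived on read,
#' so a round trip reproduces the scenario exactly.
#'
#' @param spec A `scenario_spec`.
#' @param path File path.
#' @return `write_scenario_yaml` returns `path` invisibly;
#'   `read_scenario_yaml` returns a `scenario_spec`.
#' @export
write_scenario_yaml <- function(spec, path) {
  stopifnot(inherits(spec, "scenario_spec"))
  yaml::write_yaml(list(
    scenario_id = spec$scenario_id,
    direct_effect = spec$direct_effect,
    weight_means = spec$weight_means,
    weight_sds = spec$weight_sds,
    hba1c_mean = spec$hba1c_mean,
    hba1c_sd = spec$hba1c_sd,
    targets = lapply(seq_len(3), function(i) unname(default_outcome_targets()[i, ])),
    targets_note = "rows A,B,C x weights at ages 0,1,2"
  ), path)
  invisible(path)
}

#' @rdname write_scenario_yaml
#' @export
read_scenario_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  targets <- do.call(rbind, y$targets)
  dimnames(targets) <- dimnames(default_outcome_targets())
  scenario_spec(y$scenario_id,
                direct_effect = y$direct_effect,
                weight_means = y$weight_means,
                weight_sds = y$weight_sds,
                hba1c_mean = y$hba1c_mean,
                hba1c_sd = y$hba1c_sd,
                targets = targets)
}

#' Export a joint Gaussian as CSV for audit
#'
#' Writes a 5-row CSV: the mean vector followed by the 4x4 covariance matrix.
#'
#' @param jg A `joint_gaussian`.
#' @param path File path.
#' @export
export_joint_gaussian_csv <- function(jg, path) {
  stopifnot(inherits(jg, "joint_gaussian"))
  df <- rbind(data.frame(quantity = "mean", t(jg$mean)),
              data.frame(quantity = paste0("cov_", jg$labels),
                         jg$covariance, row.names = NULL))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
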