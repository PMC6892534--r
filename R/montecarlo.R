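# Replicate loop, discard policy, percentile summaries and table rendering.

#' Configure a simulation study
#'
#' @param scenarios Subset of `c("A", "B", "C")`.
#' @param n_per_cohort Individuals per simulated cohort (>= 10); default 1000.
#' @param n_replicates Simulated cohorts per scenario (>= 2); default 1000.
#' @param master_seed Integer master seed; per-replicate seeds are spawned
#'   from it so each replicate is individually reproducible.
#' @param estimation `"REML"` (default) or `"ML"` for all mixed models.
#' @param direct_effect Standardised direct effect passed to
#'   [scenario_spec()].
#' @param output_dir Optional directory for CSV output; `NULL` keeps results
#'   in memory only.
#' @param verbose Print progress messages.
#' @return A `study_config` list.
#' @export
study_config <- function(scenarios = c("A", "B", "C"),
                         n_per_cohort = 1000L,
                         n_replicates = 1000L,
                         master_seed = 20191204L,
                         estimation = c("REML", "ML"),
                         direct_effect = 0.70,
                         output_dir = NULL,
                         verbose = FALSE) {
  estimation <- match.arg(estimation)
  stopifnot(all(scenarios %in% c("A", "B", "C")), length(scenarios) >= 1L,
            n_per_cohort >= 10L, n_replicates >= 2L,
            is.numeric(master_seed), length(master_seed) == 1L,
            master_seed == round(master_seed), abs(master_seed) < 2^31)
  structure(list(scenarios = scenarios,
                 n_per_cohort = as.integer(n_per_cohort),
                 n_replicates = as.integer(n_replicates),
                 master_seed = as.integer(master_seed),
                 estimation = estimation,
                 direct_effect = direct_effect,
                 output_dir = output_dir,
                 verbose = isTRUE(verbose)),
            class = "study_config")
}

# Deterministic per-replicate seed table: one master seed spawns a distinct
# sub-seed for every (scenario, replicate) pair.
.replicate_seeds <- function(master_seed, n_replicates) {
  set.seed(master_seed)
  matrix(sample.int(2147483646L, 3L * n_replicates), ncol = 3L,
         dimnames = list(NULL, c("A", "B", "C")))
}

#' Mean, median and empirical 95% interval of a set of estimates
#'
#' Centiles are computed by linear interpolation between order statistics
#' (`stats::quantile` type 7), giving the empirical 2.5th and 97.5th
#' centiles used as Monte-Carlo confidence intervals.
#'
#' @param values Numeric vector with at least 2 finite values.
#' @return Named vector: `mean`, `median`, `centile_2_5`, `centile_97_5`.
#' @examples
#' summarize_values(1:100)
#' @export
summarize_values <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 2L) stop("need at least 2 finite values")
  qs <- stats::quantile(values, c(0.025, 0.975), names = FALSE, type = 7)
  c(mean = mean(values), median = stats::median(values),
    centile_2_5 = qs[1L], centile_97_5 = qs[2L])
}

# One replicate: simulate a cohort and run descriptive moments, group means,
# z-score profile, outcome-covariate model and two-step model.  Returns a
# tidy record frame (parameter long format).
.run_replicate <- function(jg, n, seed, estimation, replicate, scenario) {
  cohort <- simulate_cohort(jg, n, seed)
  rec <- function(method, parameter, estimate, converged = TRUE)
    data.frame(replicate = replicate, scenario = scenario, method = method,
               parameter = parameter, estimate = estimate,
               converged = converged)
  out <- list()

  vars <- c("weight_0", "weight_1", "weight_2", "hba1c")
  out$moments <- rec("moments",
                     c(paste0("mean_", vars), paste0("sd_", vars),
                       paste0("corr_", vars[1:3], "_hba1c"),
                       "prevalence"),
                     c(vapply(vars, function(v) mean(cohort[[v]]), 0),
                       vapply(vars, function(v) stats::sd(cohort[[v]]), 0),
                       vapply(vars[1:3], function(v)
                         stats::cor(cohort[[v]], cohort$hba1c), 0),
                       mean(cohort$diabetes)))

  d <- cohort$diabetes
  gm <- unlist(lapply(0:2, function(a) {
    w <- cohort[[paste0("weight_", a)]]
    c(mean(w[d == 1]), mean(w[d == 0]))
  }))
  out$group_means <- rec("group_means",
                         paste0("gm_weight_", rep(0:2, each = 2L), "_",
                                rep(c("diabetic", "non_diabetic"), 3L)),
                         gm)

  zp <- tryCatch(zscore_profiles(cohort), error = function(e) NULL)
  if (!is.null(zp)) {
    out$zscore <- rec("zscore", paste0("z_", zp$group, "_age_", zp$age),
                      zp$mean_z)
  } else {
    out$zscore <- rec("zscore", "z_profile_failed", NA_real_, FALSE)
  }

  oc <- tryCatch(outcome_covariate_model(to_long(cohort),
                                         estimation = estimation),
                 error = function(e) NULL)
  if (!is.null(oc)) {
    vc <- oc$varcomp
    cor01 <- if (vc$sigma_u0_sq > 0 && vc$sigma_u1_sq > 0)
      vc$sigma_u01 / sqrt(vc$sigma_u0_sq * vc$sigma_u1_sq) else NA_real_
    out$oc <- rec("outcome_covariate",
                  c(names(oc$fixed_effects), "Intercept variance",
                    "Age variance", "Residual variance",
                    "Constant-Age covariance", "Constant-Age correlation",
                    "Autocorrelation parameter"),
                  c(oc$fixed_effects, vc$sigma_u0_sq, vc$sigma_u1_sq,
                    vc$sigma_e_sq, vc$sigma_u01, cor01, vc$rho),
                  oc$converged)
  } else {
    out$oc <- rec("outcome_covariate", "fit_failed", NA_real_, FALSE)
  }

  ts <- tryCatch(two_step(cohort, estimation = estimation),
                 error = function(e) NULL)
  if (!is.null(ts) && ts$converged) {
    out$ts <- rec("two_step",
                  c("Growth rate", "Weight_0", "Constant"),
                  unname(ts$odds_ratios[c("growth_rate", "weight_0",
                                          "constant")]),
                  TRUE)
  } else {
    out$ts <- rec("two_step", "fit_failed", NA_real_, FALSE)
  }

  do.call(rbind, out)
}

#' Run all replicates of one causal scenario
#'
#' For every replicate: simulate a cohort, record its moments and the
#' outcome-group mean weights, and run the three analysis methods.  Replicates
#' where a model fails to converge are excluded from that model's summaries
#' (the discard policy is per model: a z-score profile has no convergence
#' concept) and logged.
#'
#' @param cfg A [study_config()].
#' @param scenario_id `"A"`, `"B"` or `"C"`.
#' @return List of class `scenario_result`: `scenario`, `replicates` (tidy
#'   per-replicate frame), `summary` (per-parameter mean/median/centiles with
#'   `n_used`, `n_discarded`), `discards` (per-model discard log), `jg`.
#' @export
run_scenario <- function(cfg, scenario_id) {
  stopifnot(inherits(cfg, "study_config"), scenario_id %in% c("A", "B", "C"))
  spec <- scenario_spec(scenario_id, direct_effect = cfg$direct_effect)
  jg <- build_joint_gaussian(spec)
  seeds <- .replicate_seeds(cfg$master_seed, cfg$n_replicates)[, scenario_id]
  reps <- vector("list", cfg$n_replicates)
  for (r in seq_len(cfg$n_replicates)) {
    reps[[r]] <- .run_replicate(jg, cfg$n_per_cohort, seeds[r],
                                cfg$estimation, r, scenario_id)
    if (cfg$verbose && r %% 50L == 0L)
      message("scenario ", scenario_id, ": replicate ", r, "/",
              cfg$n_replicates)
  }
  replicates <- do.call(rbind, reps)
  rownames(replicates) <- NULL

  used <- replicates[replicates$converged & is.finite(replicates$estimate), ]
  if (nrow(used) == 0L)
    stop("all replicates discarded in scenario ", scenario_id)
  key <- interaction(used$method, used$parameter, drop = TRUE)
  summ <- do.call(rbind, lapply(split(used, key), function(df) {
    s <- summarize_values(df$estimate)
    data.frame(scenario = scenario_id, method = df$method[1L],
               parameter = df$parameter[1L],
               mean = s[["mean"]], median = s[["median"]],
               centile_2_5 = s[["centile_2_5"]],
               centile_97_5 = s[["centile_97_5"]],
               n_used = nrow(df),
               n_discarded = cfg$n_replicates - nrow(df))
  }))
  rownames(summ) <- NULL

  disc <- replicates[!replicates$converged, c("replicate", "method")]
  discards <- unique(disc)
  structure(list(scenario = scenario_id, replicates = replicates,
                 summary = summ, discards = discards, jg = jg,
                 config = cfg),
            class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, ...) {
  cat("Scenario", x$scenario, "-", x$config$n_replicates, "replicates of n =",
      x$config$n_per_cohort, "\n")
  nd <- stats::aggregate(n_discarded ~ method, x$summary, max)
  cat("Discarded replicates per method:\n")
  print(nd, row.names = FALSE)
  invisible(x)
}

#' Run the full simulation study
#'
#' Runs [run_scenario()] for every configured scenario and, when
#' `cfg$output_dir` is set, writes the tidy per-replicate CSV, the rendered
#' summary tables and a discard log.
#'
#' @param cfg A [study_config()].
#' @return List of class `mc_study`: `config` plus one `scenario_result` per
#'   scenario.
#' @export
run_study <- function(cfg) {
  stopifnot(inherits(cfg, "study_config"))
  results <- lapply(cfg$scenarios, function(s) run_scenario(cfg, s))
  names(results) <- cfg$scenarios
  study <- structure(list(config = cfg, results = results),
                     class = "mc_study")
  if (!is.null(cfg$output_dir)) {
    dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
    all_reps <- do.call(rbind, lapply(results, `[[`, "replicates"))
    utils::write.csv(all_reps,
                     file.path(cfg$output_dir, "replicates.csv"),
                     row.names = FALSE)
    all_disc <- do.call(rbind, lapply(results, function(r)
      if (nrow(r$discards)) cbind(scenario = r$scenario, r$discards)))
    utils::write.csv(if (is.null(all_disc))
      data.frame(scenario = character(), replicate = integer(),
                 method = character()) else all_disc,
      file.path(cfg$output_dir, "discards.csv"), row.names = FALSE)
    render_tables(study, cfg$output_dir)
  }
  study
}

#' @export
print.mc_study <- function(x, ...) {
  cat("Monte-Carlo study:", x$config$n_replicates, "replicates x n =",
      x$config$n_per_cohort, "per cohort, estimation:",
      x$config$estimation, "\n")
  for (r in x$results) print(r)
  invisible(x)
}

.fmt3 <- function(x) ifelse(is.na(x), NA, formatC(x, format = "f", digits = 3))

.summary_row <- function(study, scenario, method, parameter) {
  s <- study$results[[scenario]]$summary
  row <- s[s$method == method & s$parameter == parameter, ]
  if (nrow(row) == 0L) {
    warning("missing summary cell: ", scenario, "/", method, "/", parameter)
    return(data.frame(parameter = parameter, scenario = scenario,
                      mean = NA_real_, ci_low = NA_real_,
                      ci_high = NA_real_))
  }
  data.frame(parameter = parameter, scenario = scenario, mean = row$mean,
             ci_low = row$centile_2_5, ci_high = row$centile_97_5)
}

#' Render the study's summary tables as CSV files
#'
#' Writes one CSV per reported table: per-scenario simulated-variable
#' summaries (means, SDs and outcome correlations), the outcome-as-covariate
#' mixed-model parameters, and the two-step odds ratios.  Columns are
#' `parameter, scenario, mean, ci_low, ci_high` with 3-decimal formatting.
#'
#' @param study An `mc_study` from [run_study()].
#' @param output_dir Directory to write into (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
render_tables <- function(study, output_dir) {
  stopifnot(inherits(study, "mc_study"))
  scen <- names(study$results)
  if (length(scen) == 0L) {
    warning("no scenarios to render")
    return(invisible(character()))
  }
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  vars <- c("weight_0", "weight_1", "weight_2", "hba1c")
  for (s in scen) {
    rows <- rbind(
      do.call(rbind, lapply(paste0("mean_", vars), function(p)
        .summary_row(study, s, "moments", p))),
      do.call(rbind, lapply(paste0("sd_", vars), function(p)
        .summary_row(study, s, "moments", p))),
      do.call(rbind, lapply(paste0("corr_", vars[1:3], "_hba1c"), function(p)
        .summary_row(study, s, "moments", p))))
    rows[, 3:5] <- lapply(rows[, 3:5], .fmt3)
    f <- file.path(output_dir, paste0("table_moments_", s, ".csv"))
    utils::write.csv(rows, f, row.names = FALSE)
    files <- c(files, f)
  }
  oc_pars <- c("Diabetes", "Age", "Diabetes*Age", "Intercept",
               "Intercept variance", "Age variance", "Residual variance",
               "Constant-Age covariance", "Constant-Age correlation",
               "Autocorrelation parameter")
  rows <- do.call(rbind, lapply(scen, function(s)
    do.call(rbind, lapply(oc_pars, function(p)
      .summary_row(study, s, "outcome_covariate", p)))))
  rows[, 3:5] <- lapply(rows[, 3:5], .fmt3)
  f <- file.path(output_dir, "table_outcome_covariate.csv")
  utils::write.csv(rows, f, row.names = FALSE)
  files <- c(files, f)

  ts_pars <- c("Growth rate", "Weight_0", "Constant")
  rows <- do.call(rbind, lapply(scen, function(s)
    do.call(rbind, lapply(ts_pars, function(p)
      .summary_row(study, s, "two_step", p)))))
  rows[, 3:5] <- lapply(rows[, 3:5], .fmt3)
  f <- file.path(output_dir, "table_two_step.csv")
  utils::write.csv(rows, f, row.names = FALSE)
  files <- c(files, f)
  invisible(files)
}
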