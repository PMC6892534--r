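# Random-intercept + random-slope linear mixed model with AR(1) within-subject
# errors, fitted by direct optimisation of the profiled marginal (restricted)
# likelihood.  The marginal covariance of one subject's T observations is
#     V = Z G Z' + sigma_e^2 * R(rho),   Z = [1, t],  R_st = rho^|s-t|
# with G the 2x2 random-effects covariance and the AR(1) lag counted in
# measurement occasions.  Fixed effects are profiled out by generalised least
# squares at every variance-parameter value, so the optimiser works in the
# 5-dimensional unconstrained space (log SDs, atanh correlations).

#' Marginal covariance of one subject's repeated measures
#'
#' @param vc Named list or vector of variance components: `sigma_u0_sq`
#'   (intercept variance), `sigma_u1_sq` (slope variance), `sigma_u01`
#'   (intercept--slope covariance), `sigma_e_sq` (residual variance), `rho`
#'   (AR(1) correlation, |rho| < 1).
#' @param times Vector of centred measurement times; AR(1) lags are counted
#'   in occasions (positions in `times`), which coincides with calendar lags
#'   for equally spaced occasions.
#' @return The T x T marginal covariance matrix `Z G Z' + sigma_e^2 R(rho)`.
#' @examples
#' subject_covariance(c(sigma_u0_sq = 0, sigma_u1_sq = 0, sigma_u01 = 0,
#'                      sigma_e_sq = 1, rho = 0.5), times = c(-1, 0, 1))
#' @export
subject_covariance <- function(vc, times) {
  vc <- as.list(vc)
  with(vc, {
    stopifnot(sigma_u0_sq >= 0, sigma_u1_sq >= 0, sigma_e_sq >= 0,
              abs(rho) < 1,
              sigma_u01^2 <= sigma_u0_sq * sigma_u1_sq + 1e-12)
    Tn <- length(times)
    Z <- cbind(1, times)
    G <- matrix(c(sigma_u0_sq, sigma_u01, sigma_u01, sigma_u1_sq), 2L)
    occ <- seq_len(Tn)
    Z %*% G %*% t(Z) + sigma_e_sq * rho^abs(outer(occ, occ, "-"))
  })
}

# unconstrained optimiser scale <-> variance components
.par_to_vc <- function(par, ar1) {
  su0 <- exp(par[1L]); su1 <- exp(par[2L])
  list(sigma_u0_sq = su0^2,
       sigma_u1_sq = su1^2,
       sigma_u01 = tanh(par[3L]) * su0 * su1,
       sigma_e_sq = exp(par[4L])^2,
       rho = if (ar1) tanh(par[5L]) else 0)
}

.vc_to_par <- function(vc, ar1) {
  vc <- as.list(vc)
  cor01 <- if (vc$sigma_u0_sq > 0 && vc$sigma_u1_sq > 0)
    vc$sigma_u01 / sqrt(vc$sigma_u0_sq * vc$sigma_u1_sq) else 0
  par <- c(0.5 * log(vc$sigma_u0_sq), 0.5 * log(vc$sigma_u1_sq),
           atanh(cor01), 0.5 * log(vc$sigma_e_sq))
  if (ar1) par <- c(par, atanh(vc$rho))
  par
}

# fast, non-validating covariance used in the optimisation hot path
.subject_cov_fast <- function(vc, Z, lagmat) {
  G <- matrix(c(vc$sigma_u0_sq, vc$sigma_u01, vc$sigma_u01, vc$sigma_u1_sq),
              2L)
  Z %*% G %*% t(Z) + vc$sigma_e_sq * vc$rho^lagmat
}

# Group subjects by identical (times, fixed-design) pattern and precompute the
# per-pattern sufficient statistics that make one likelihood evaluation O(1)
# in the number of subjects: n_g, sum of responses s_g, response cross-product
# S_g, plus the shared T x p design block X_g.
.build_patterns <- function(y, X, ids, times) {
  ord <- order(ids, times)
  y <- y[ord]; X <- X[ord, , drop = FALSE]
  ids <- ids[ord]; times <- times[ord]
  idx <- split(seq_along(y), ids)
  keys <- vapply(idx, function(i)
    paste(c(times[i], round(X[i, ], 12)), collapse = "\r"), character(1))
  patterns <- lapply(split(names(idx), keys), function(subj_ids) {
    rows <- idx[subj_ids]
    Tn <- length(rows[[1L]])
    first <- rows[[1L]]
    Y <- matrix(y[unlist(rows)], ncol = Tn, byrow = TRUE)
    occ <- seq_len(Tn)
    list(ids = subj_ids,
         times = times[first],
         X = X[first, , drop = FALSE],
         Z = cbind(1, times[first]),
         lagmat = abs(outer(occ, occ, "-")),
         n = length(rows),
         Y = Y,
         s = colSums(Y),
         S = crossprod(Y))
  })
  list(patterns = patterns, order = ord, y = y, X = X, ids = ids,
       times = times, idx = idx)
}

# Profiled negative log-likelihood at given variance components, with an
# optional analytic gradient on the unconstrained scale.  Returns the scalar
# NLL; GLS fixed effects / their covariance / the gradient are attached as
# attributes on request.  `patterns` comes from .build_patterns().
#
# Gradient: with beta profiled out by GLS, the envelope theorem gives
#   dNLL/dtheta = 1/2 [ sum_j tr(V^-1 dV) - sum_j r_j' V^-1 dV V^-1 r_j ]
# plus, under REML, -1/2 sum_j tr(P dV) with P = V^-1 X A^-1 X' V^-1.  The
# residual term uses the per-pattern residual cross-product, available from
# the sufficient statistics.
.nll_core <- function(vc, patterns, estimation, details = FALSE,
                      grad_par = NULL, penalty = 1e10) {
  pats <- patterns$patterns
  p <- ncol(pats[[1L]]$X)
  N <- length(patterns$y)
  if (!all(is.finite(unlist(vc))) || vc$sigma_u0_sq < 0 ||
      vc$sigma_u1_sq < 0 || vc$sigma_e_sq <= 0 || abs(vc$rho) >= 1 ||
      vc$sigma_u01^2 > vc$sigma_u0_sq * vc$sigma_u1_sq * (1 + 1e-12))
    return(penalty)
  A <- matrix(0, p, p); b <- numeric(p)
  logdet_sum <- 0
  pre <- vector("list", length(pats))
  for (k in seq_along(pats)) {
    pat <- pats[[k]]
    V <- .subject_cov_fast(vc, pat$Z, pat$lagmat)
    ch <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(ch)) return(penalty)
    Vinv <- chol2inv(ch)
    XtVi <- crossprod(pat$X, Vinv)           # p x T
    A <- A + pat$n * XtVi %*% pat$X
    b <- b + XtVi %*% pat$s
    logdet_sum <- logdet_sum + pat$n * 2 * sum(log(diag(ch)))
    pre[[k]] <- list(Vinv = Vinv, XtVi = XtVi)
  }
  Ach <- tryCatch(chol(A), error = function(e) NULL)
  if (is.null(Ach)) return(penalty)
  Ainv <- chol2inv(Ach)
  beta <- drop(Ainv %*% b)
  q <- 0
  for (k in seq_along(pats)) {
    pat <- pats[[k]]
    XtViX <- pre[[k]]$XtVi %*% pat$X
    q <- q + sum(pre[[k]]$Vinv * pat$S) -
      2 * drop(crossprod(beta, pre[[k]]$XtVi %*% pat$s)) +
      pat$n * drop(crossprod(beta, XtViX %*% beta))
  }
  nll <- 0.5 * (N * log(2 * pi) + logdet_sum + q)
  if (estimation == "REML")
    nll <- nll + 0.5 * (2 * sum(log(diag(Ach))) - p * log(2 * pi))
  if (!is.finite(nll)) return(penalty)

  if (!is.null(grad_par)) {
    ar1 <- length(grad_par) == 5L
    su0 <- sqrt(vc$sigma_u0_sq); su1 <- sqrt(vc$sigma_u1_sq)
    tc <- tanh(grad_par[3L])
    grad <- numeric(length(grad_par))
    for (k in seq_along(pats)) {
      pat <- pats[[k]]
      Vinv <- pre[[k]]$Vinv
      mu <- drop(pat$X %*% beta)
      # residual cross-product sum_j r_j r_j'
      Rss <- pat$S - outer(pat$s, mu) - outer(mu, pat$s) +
        pat$n * outer(mu, mu)
      W <- Vinv %*% Rss %*% Vinv
      M <- pat$n * Vinv - W
      if (estimation == "REML") {
        ViX <- t(pre[[k]]$XtVi)              # T x p
        M <- M - pat$n * ViX %*% Ainv %*% t(ViX)
      }
      Z <- pat$Z
      dG <- list(
        matrix(c(2 * su0^2, tc * su0 * su1, tc * su0 * su1, 0), 2L),
        matrix(c(0, tc * su0 * su1, tc * su0 * su1, 2 * su1^2), 2L),
        (1 - tc^2) * su0 * su1 * matrix(c(0, 1, 1, 0), 2L))
      for (m in 1:3)
        grad[m] <- grad[m] + 0.5 * sum(M * (Z %*% dG[[m]] %*% t(Z)))
      R <- vc$rho^pat$lagmat
      grad[4L] <- grad[4L] + 0.5 * sum(M * (2 * vc$sigma_e_sq * R))
      if (ar1) {
        dR <- pat$lagmat * vc$rho^pmax(pat$lagmat - 1L, 0L)
        grad[5L] <- grad[5L] +
          0.5 * sum(M * (vc$sigma_e_sq * (1 - vc$rho^2) * dR))
      }
    }
    attr(nll, "gradient") <- grad
  }
  if (details) {
    attr(nll, "beta") <- stats::setNames(beta, colnames(patterns$X))
    attr(nll, "vcov_beta") <- Ainv
  }
  nll
}

#' Profiled negative log-likelihood of the AR(1) mixed model
#'
#' Evaluates the marginal Gaussian negative log-likelihood of the
#' random-intercept + random-slope AR(1) model at fixed variance components,
#' with the fixed effects replaced by their generalised-least-squares profile
#' values.  Intended for audits and for checking the fitter against dense
#' multivariate-normal computations.
#'
#' @inheritParams lmm_ar1
#' @param vc Variance components as in [subject_covariance()].
#' @param details If `TRUE`, attach the profiled fixed effects (`beta`) and
#'   their covariance (`vcov_beta`) as attributes.
#' @return The scalar negative log-likelihood (REML includes the restricted
#'   adjustment `log det(sum X' V^-1 X) - p log 2 pi`, halved).
#' @export
lmm_profile_nll <- function(vc, formula, data, id = "id",
                            time = "time_centered",
                            estimation = c("REML", "ML"), details = FALSE) {
  estimation <- match.arg(estimation)
  mf <- stats::model.frame(formula, data)
  pats <- .build_patterns(stats::model.response(mf),
                          stats::model.matrix(attr(mf, "terms"), mf),
                          data[[id]], data[[time]])
  .nll_core(vc, pats, estimation, details = details)
}

.num_grad <- function(f, x, h = 1e-6) {
  vapply(seq_along(x), function(i) {
    hi <- h * (1 + abs(x[i]))
    e <- numeric(length(x)); e[i] <- hi
    (f(x + e) - f(x - e)) / (2 * hi)
  }, numeric(1))
}

# moment-based starting values from per-subject OLS lines
.start_values <- function(patterns, ar1) {
  ints <- c(); slps <- c(); rss <- 0; rdf <- 0; h11 <- c(); h22 <- c()
  for (pat in patterns$patterns) {
    Z <- cbind(1, pat$times)
    if (length(pat$times) < 2L) next
    H <- solve(crossprod(Z), t(Z))
    coefs <- pat$Y %*% t(H)
    ints <- c(ints, coefs[, 1L]); slps <- c(slps, coefs[, 2L])
    R <- pat$Y - coefs %*% t(Z)
    rss <- rss + sum(R^2)
    rdf <- rdf + pat$n * max(length(pat$times) - 2L, 0L)
    ZtZi <- solve(crossprod(Z))
    h11 <- c(h11, ZtZi[1L, 1L]); h22 <- c(h22, ZtZi[2L, 2L])
  }
  se2 <- if (rdf > 0) rss / rdf else 0.5
  su0_sq <- max(stats::var(ints) - se2 * mean(h11), 0.05)
  su1_sq <- max(stats::var(slps) - se2 * mean(h22), 0.05)
  par <- c(0.5 * log(su0_sq), 0.5 * log(su1_sq), 0, 0.5 * log(max(se2, 0.05)))
  if (ar1) par <- c(par, 0)
  par
}

#' Fit a random-intercept + random-slope mixed model with AR(1) errors
#'
#' Fits the linear mixed model
#' \deqn{y_{ij} = x_{ij}'\beta + u_{0j} + u_{1j} t_{ij} + \epsilon_{ij}}
#' where the subject-level intercept and slope deviations \eqn{(u_{0j},
#' u_{1j})} are bivariate normal with free covariance, and the within-subject
#' errors follow a first-order autoregressive process across measurement
#' occasions.  Estimation maximises the marginal likelihood directly: fixed
#' effects are profiled out by generalised least squares, and the five
#' variance parameters are optimised on an unconstrained scale (log standard
#' deviations; Fisher-z for the intercept--slope correlation and for the
#' AR(1) parameter) by quasi-Newton iteration with random restarts.
#'
#' The fixed-effect design is given by `formula`; the random part is always
#' intercept + `time` (the model this package studies has no other random
#' terms).  A fit is declared converged when the optimiser reports success
#' and the per-observation gradient max-norm falls below `gtol`; fits that
#' fail after all restarts are returned with `converged = FALSE` and should
#' be discarded by the caller.
#'
#' @param formula Fixed-effects formula, e.g. `weight ~ time_centered` or
#'   `weight ~ time_centered * diabetes`.  The `time` variable must appear as
#'   a main effect.
#' @param data Long-format data frame (one row per measurement occasion).
#' @param id Name of the subject identifier column.
#' @param time Name of the (centred) time column used for the random slope
#'   and the AR(1) ordering.
#' @param estimation `"REML"` (default) or `"ML"`.
#' @param ar1 Fit the AR(1) residual correlation (`TRUE`, default) or assume
#'   independent residuals.
#' @param n_restarts Number of jittered restarts tried when the first
#'   optimisation does not meet the convergence test.
#' @param gtol Convergence tolerance for the max-norm of the numerical
#'   gradient of the per-observation objective on the unconstrained scale.
#' @param start Optional variance-component starting values (named as in
#'   [subject_covariance()]); default: moment estimates from per-subject
#'   least-squares lines.
#' @param restart_seed Integer controlling the deterministic jitter sequence
#'   used for restarts.
#'
#' @return An object of class `lmm_ar1` with components `coefficients`
#'   (fixed effects), `varcomp`, `logLik`, `converged`, `ranef` (per-subject
#'   empirical-Bayes deviations), `vcov`, and bookkeeping fields; see the
#'   `print`, `summary`, `coef`, `vcov`, `ranef`, `fitted`, `residuals`,
#'   `predict` and `simulate` methods.
#' @examples
#' jg <- build_joint_gaussian(scenario_spec("A"))
#' long <- to_long(simulate_cohort(jg, 200, seed = 1))
#' fit <- lmm_ar1(weight ~ time_centered * diabetes, long)
#' summary(fit)
#' @export
lmm_ar1 <- function(formula, data, id = "id", time = "time_centered",
                    estimation = c("REML", "ML"), ar1 = TRUE,
                    n_restarts = 3L, gtol = 1e-5, start = NULL,
                    restart_seed = 1L) {
  estimation <- match.arg(estimation)
  stopifnot(id %in% names(data), time %in% names(data))
  mf <- stats::model.frame(formula, data)
  terms_obj <- attr(mf, "terms")
  y <- stats::model.response(mf)
  X <- stats::model.matrix(terms_obj, mf)
  if (!(time %in% colnames(X)))
    stop("`time` ('", time, "') must appear as a main effect in `formula`")
  if (length(unique(data[[id]])) < 2L)
    stop("need at least 2 subjects")
  pats <- .build_patterns(y, X, data[[id]], data[[time]])
  N <- length(pats$y)
  npar <- if (ar1) 5L else 4L

  # objective on the per-observation scale with analytic gradient; one cache
  # slot avoids recomputing when optim() asks for fn and gr at the same point
  cache <- new.env(parent = emptyenv())
  evaluate <- function(par) {
    if (!is.null(cache$par) && identical(par, cache$par)) return(cache$val)
    val <- .nll_core(.par_to_vc(par, ar1), pats, estimation, grad_par = par)
    cache$par <- par; cache$val <- val
    val
  }
  obj <- function(par) as.numeric(evaluate(par)) / N
  grad <- function(par) {
    v <- evaluate(par)
    g <- attr(v, "gradient")
    if (is.null(g)) g <- .num_grad(obj, par) * N   # at penalty values
    g / N
  }

  par0 <- if (is.null(start)) .start_values(pats, ar1)
          else .vc_to_par(start, ar1)

  # box constraints on the unconstrained scale: log-SDs in [-8, 8], Fisher-z
  # correlations in [-6, 6] (|corr| <= 0.99998).  The intercept--slope
  # correlation routinely maximises the likelihood at |corr| -> 1 with only
  # three occasions, so convergence is judged on the *projected* gradient:
  # a coordinate pinned at its bound with the gradient pushing outward
  # contributes zero.
  lower <- c(-8, -8, -6, -8, -6)[seq_len(npar)]
  upper <- -lower
  proj_grad <- function(par, g) {
    at_lo <- par <= lower + 1e-8
    at_hi <- par >= upper - 1e-8
    g[at_lo] <- pmin(g[at_lo], 0)
    g[at_hi] <- pmax(g[at_hi], 0)
    g
  }

  best <- NULL
  for (attempt in 0:n_restarts) {
    par_try <- par0
    if (attempt > 0L) {
      set.seed(restart_seed + attempt)
      par_try <- par0 + stats::rnorm(npar, sd = 0.5)
    }
    par_try <- pmin(pmax(par_try, lower + 1e-3), upper - 1e-3)
    opt <- tryCatch(
      stats::optim(par_try, obj, gr = grad, method = "L-BFGS-B",
                   lower = lower, upper = upper,
                   control = list(maxit = 500L, factr = 1e3, pgtol = 0)),
      error = function(e) NULL)
    if (is.null(opt)) next
    # second pass from the first solution: restarting resets the limited-
    # memory Hessian approximation and often tightens the gradient further
    opt <- tryCatch(
      stats::optim(opt$par, obj, gr = grad, method = "L-BFGS-B",
                   lower = lower, upper = upper,
                   control = list(maxit = 200L, factr = 1e3, pgtol = 0)),
      error = function(e) opt)
    g <- suppressWarnings(proj_grad(opt$par, grad(opt$par)))
    opt$max_grad <- max(abs(g))
    opt$ok <- is.finite(opt$value) && opt$value < 1e9 &&
      opt$convergence %in% c(0L, 52L) && is.finite(opt$max_grad) &&
      opt$max_grad < gtol
    if (is.null(best) || opt$value < best$value ||
        (opt$ok && !best$ok)) {
      if (is.null(best) || !best$ok || opt$ok) best <- opt
    }
    if (opt$ok) break
  }
  if (is.null(best)) stop("optimisation failed to produce any evaluation")

  vc <- .par_to_vc(best$par, ar1)
  nll <- .nll_core(vc, pats, estimation, details = TRUE)
  beta <- attr(nll, "beta")
  vcov_beta <- attr(nll, "vcov_beta")
  dimnames(vcov_beta) <- list(names(beta), names(beta))

  # empirical-Bayes (BLUP-style) random effects: u_j = G Z' V^-1 (y_j - X_j b)
  G <- matrix(c(vc$sigma_u0_sq, vc$sigma_u01, vc$sigma_u01, vc$sigma_u1_sq), 2L)
  re <- matrix(NA_real_, nrow = length(pats$idx), ncol = 2L,
               dimnames = list(names(pats$idx), c("intercept", "slope")))
  for (pat in pats$patterns) {
    V <- subject_covariance(vc, pat$times)
    Z <- cbind(1, pat$times)
    K <- G %*% t(Z) %*% chol2inv(chol(V))      # 2 x T
    R <- pat$Y - matrix(drop(pat$X %*% beta), nrow = pat$n,
                        ncol = length(pat$times), byrow = TRUE)
    re[pat$ids, ] <- R %*% t(K)
  }

  structure(list(
    call = match.call(),
    formula = formula,
    terms = terms_obj,
    xlevels = stats::.getXlevels(terms_obj, mf),
    coefficients = beta,
    varcomp = vc,
    logLik = -as.numeric(nll),
    converged = isTRUE(best$ok),
    max_grad = best$max_grad,
    estimation = estimation,
    ar1 = ar1,
    vcov = vcov_beta,
    ranef = re,
    id_var = id,
    time_var = time,
    n_obs = N,
    n_subjects = length(pats$idx),
    patterns = pats
  ), class = "lmm_ar1")
}

#' Per-subject growth rates from a fitted model
#'
#' Returns each subject's estimated time slope: the population fixed slope
#' plus the subject's empirical-Bayes (BLUP) slope deviation.  The average
#' over subjects is approximately the fixed slope.
#'
#' @param fit A converged `lmm_ar1` fit.
#' @return Named numeric vector, one slope per subject id.
#' @export
random_slopes <- function(fit) {
  stopifnot(inherits(fit, "lmm_ar1"))
  if (!fit$converged)
    stop("random_slopes() requires a converged fit")
  fit$coefficients[[fit$time_var]] + fit$ranef[, "slope"]
}
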