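# Independent oracles used across the test files.  These deliberately avoid
# the package's own computational paths: the dense likelihood builds the full
# stacked covariance matrix entry by entry and evaluates the generic
# multivariate-normal log-density with determinant() and solve().

# Dense negative log-likelihood of the random-intercept+slope AR(1) model.
# vc: list(sigma_u0_sq, sigma_u1_sq, sigma_u01, sigma_e_sq, rho)
# long: data.frame with columns id, the time column, and the response;
# X built from `formula`.
dense_nll_oracle <- function(vc, formula, long, time = "time_centered",
                             estimation = "ML") {
  long <- long[order(long$id, long[[time]]), ]
  mf <- model.frame(formula, long)
  y <- model.response(mf)
  X <- model.matrix(attr(mf, "terms"), mf)
  N <- length(y)
  Sigma <- matrix(0, N, N)
  pos <- 0L
  for (idv in unique(long$id)) {
    tt <- long[[time]][long$id == idv]
    Tn <- length(tt)
    V <- matrix(NA_real_, Tn, Tn)
    for (s in seq_len(Tn)) for (t in seq_len(Tn)) {
      V[s, t] <- vc$sigma_u0_sq + vc$sigma_u01 * (tt[s] + tt[t]) +
        vc$sigma_u1_sq * tt[s] * tt[t] +
        vc$sigma_e_sq * vc$rho^abs(s - t)
    }
    Sigma[pos + seq_len(Tn), pos + seq_len(Tn)] <- V
    pos <- pos + Tn
  }
  Si <- solve(Sigma)
  A <- t(X) %*% Si %*% X
  beta <- solve(A, t(X) %*% Si %*% y)
  r <- y - X %*% beta
  nll <- 0.5 * (N * log(2 * pi) +
                  as.numeric(determinant(Sigma, logarithm = TRUE)$modulus) +
                  drop(t(r) %*% Si %*% r))
  if (estimation == "REML")
    nll <- nll + 0.5 * (as.numeric(determinant(A, logarithm = TRUE)$modulus) -
                          ncol(X) * log(2 * pi))
  attr(nll, "beta") <- drop(beta)
  nll
}

# Dense empirical-Bayes random effects: u_j = G Z_j' V_j^-1 (y_j - X_j beta)
dense_blup_oracle <- function(vc, beta, formula, long,
                              time = "time_centered") {
  long <- long[order(long$id, long[[time]]), ]
  mf <- model.frame(formula, long)
  y <- model.response(mf)
  X <- model.matrix(attr(mf, "terms"), mf)
  G <- matrix(c(vc$sigma_u0_sq, vc$sigma_u01, vc$sigma_u01, vc$sigma_u1_sq),
              2)
  ids <- unique(long$id)
  out <- matrix(NA_real_, length(ids), 2,
                dimnames = list(as.character(ids), c("intercept", "slope")))
  for (idv in ids) {
    sel <- long$id == idv
    tt <- long[[time]][sel]
    Tn <- length(tt)
    V <- matrix(NA_real_, Tn, Tn)
    for (s in seq_len(Tn)) for (t in seq_len(Tn))
      V[s, t] <- vc$sigma_u0_sq + vc$sigma_u01 * (tt[s] + tt[t]) +
        vc$sigma_u1_sq * tt[s] * tt[t] + vc$sigma_e_sq * vc$rho^abs(s - t)
    Z <- cbind(1, tt)
    r <- y[sel] - drop(X[sel, , drop = FALSE] %*% beta)
    out[as.character(idv), ] <- drop(G %*% t(Z) %*% solve(V, r))
  }
  out
}

# Conditional means of a standard-normal covariate with correlation `rho` to
# the (standard-normal) latent outcome, above/below threshold c: the group
# z-score means of the outcome-stratified profile.
truncnorm_group_means <- function(rho, c = 0.7) {
  rho <- unname(rho)
  lambda_hi <- dnorm(c) / pnorm(c, lower.tail = FALSE)
  lambda_lo <- dnorm(c) / pnorm(c)
  c(diabetic = rho * lambda_hi, non_diabetic = -rho * lambda_lo)
}

# small balanced long-format fixture with known variance components
make_fixture_long <- function(n_subj = 5, vc = list(sigma_u0_sq = 1,
                                                    sigma_u1_sq = 0.25,
                                                    sigma_u01 = 0.2,
                                                    sigma_e_sq = 1,
                                                    rho = 0.3),
                              beta = c(8, 4), seed = 1,
                              diabetes = FALSE) {
  set.seed(seed)
  tt <- c(-1, 0, 1)
  rows <- list()
  G <- matrix(c(vc$sigma_u0_sq, vc$sigma_u01, vc$sigma_u01, vc$sigma_u1_sq), 2)
  L <- if (max(abs(G)) == 0) matrix(0, 2, 2) else chol(G + 1e-12 * diag(2))
  for (j in seq_len(n_subj)) {
    u <- drop(t(L) %*% rnorm(2))
    R <- vc$rho^abs(outer(1:3, 1:3, "-"))
    e <- drop(t(chol(vc$sigma_e_sq * R)) %*% rnorm(3))
    rows[[j]] <- data.frame(id = j, time_centered = tt,
                            weight = beta[1] + u[1] +
                              (beta[2] + u[2]) * tt + e)
  }
  out <- do.call(rbind, rows)
  if (diabetes) out$diabetes <- rep(rbinom(n_subj, 1, 0.3), each = 3)
  out
}
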