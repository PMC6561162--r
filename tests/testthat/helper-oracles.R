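# Independent oracles used across the suite.  These deliberately avoid the
# package's own code paths: densities are summed row by row, regressions go
# through lm()/lm.fit directly, and the sandwich is assembled from textbook
# formulas.

# joint multivariate-normal log-density, one row at a time via Cholesky
oracle_mvn_loglik <- function(Y, mu, sigma) {
  R <- chol(sigma)
  ld <- 2 * sum(log(diag(R)))
  k <- ncol(Y)
  tot <- 0
  for (i in seq_len(nrow(Y))) {
    z <- backsolve(R, Y[i, ] - mu, transpose = TRUE)
    tot <- tot - 0.5 * (k * log(2 * pi) + ld + sum(z^2))
  }
  tot
}

# FIML oracle: per-row marginal normal density over the observed subset
oracle_fiml_loglik <- function(Y, mu, sigma) {
  tot <- 0
  for (i in seq_len(nrow(Y))) {
    o <- which(!is.na(Y[i, ]))
    if (!length(o)) next
    tot <- tot + oracle_mvn_loglik(Y[i, o, drop = FALSE], mu[o],
                                   sigma[o, o, drop = FALSE])
  }
  tot
}

# per-equation least squares over a recursive spec (complete data)
oracle_ols_equations <- function(spec, data) {
  out <- list()
  for (y in spec$endogenous) {
    pa <- spec$edges$from[spec$edges$to == y]
    if (length(pa)) {
      fml <- stats::as.formula(paste(y, "~", paste(pa, collapse = "+")))
      cf <- coef(lm(fml, data = data))
      out[paste0(pa, "->", y)] <- cf[pa]
    }
  }
  unlist(out)
}

# textbook HC0 sandwich for one linear regression (coefficient block)
oracle_lm_sandwich <- function(X, y) {
  fit <- lm.fit(X, y)
  u <- fit$residuals
  bread <- solve(crossprod(X))
  meat <- crossprod(X * u)
  bread %*% meat %*% bread
}

# random recursive DAG spec over <= 6 variables, treatment exogenous
random_dag_spec <- function(n_endo, edge_prob = 0.5) {
  vars <- c("treatment", paste0("v", seq_len(n_endo)))
  edges <- list()
  for (j in 2:length(vars)) {
    for (i in 1:(j - 1)) {
      if (runif(1) < edge_prob) {
        edges[[length(edges) + 1]] <- c(vars[i], vars[j])
      }
    }
  }
  if (!length(edges)) edges <- list(c("treatment", vars[2]))
  path_model_spec(vars, edges)
}

# simulate a complete-data change table from a spec + params
simulate_from_params <- function(spec, params, n) {
  d <- data.frame(treatment = rbinom(n, 1, 0.5))
  for (v in setdiff(spec$order, spec$exogenous)) {
    pa <- spec$edges$from[spec$edges$to == v]
    mu <- rep(params$alpha[v], n)
    for (p in pa) mu <- mu + params$B[v, p] * d[[p]]
    d[[v]] <- mu + rnorm(n, 0, params$psi_sd[v])
  }
  d
}

# small noisy cohort used by several files
small_cohort <- function(n_per_arm = 40, seed = 42, regions = NULL, ...) {
  generate_cohort(generator_config(n_per_arm = n_per_arm, seed = seed,
                                   regions = regions, ...))
}

model_vars <- c("cholesterol", "PBVC", "EDSS", "block_design",
                "MSIS29_physical")
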