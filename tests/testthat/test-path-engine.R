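test_that("spec validation: topological order, cycles, unknown variables", {
  # the cholesterol-independent edge set is valid and starts at treatment
  spec <- model_b_spec()
  expect_equal(spec$order[1], "treatment")
  expect_equal(spec$order[length(spec$order)], "MSIS29_physical")
  expect_error(path_model_spec(c("a"), list(c("a", "a")), exogenous = NULL),
               "cycle|exogenous")
  expect_error(path_model_spec(c("treatment", "a"), list(c("a", "a"))),
               "cycle")
  expect_error(path_model_spec(c("treatment", "a"), list(c("a", "zz"))),
               "unknown")
  expect_error(path_model_spec(c("treatment", "a"),
                               list(c("treatment", "a"), c("treatment", "a"))),
               "duplicate")
  expect_error(path_model_spec(c("treatment", "a"), list(c("a", "treatment"))),
               "exogenous")
  # two-variable chain: order is exogenous then endogenous
  two <- path_model_spec(c("treatment", "y"), list(c("treatment", "y")))
  expect_equal(two$order, c("treatment", "y"))
})

test_that("spec JSON dialect round-trips and matches shipped fixtures", {
  fixture <- system.file("extdata", "model_B.json", package = "pathtrial")
  spec <- read_path_spec(fixture)
  expect_equal(spec$edges, model_b_spec()$edges)
  f <- tempfile(fileext = ".json")
  write_path_spec(model_a_spec(), f)
  expect_equal(read_path_spec(f)$edges, model_a_spec()$edges)
})

test_that("implied moments: no-path identity and hand-computed chain", {
  spec <- path_model_spec(c("x", "m", "y"), NULL, exogenous = "x")
  prm <- path_params(spec, intercepts = c(m = 2, y = -1),
                     residual_sd = c(m = 3, y = 0.5),
                     exo_mean = c(x = 1),
                     exo_cov = matrix(4, 1, 1, dimnames = list("x", "x")))
  mom <- implied_moments(spec, prm)
  expect_equal(unname(mom$mu), c(1, 2, -1))
  expect_equal(unname(diag(mom$sigma)), c(4, 9, 0.25))
  expect_equal(mom$sigma[lower.tri(mom$sigma)], rep(0, 3))

  # chain x -> m -> y, unit coefficients and unit residual variances,
  # Var(x) = 1: Var(y) = 3, Cov(x, y) = 1 (hand computation)
  chain <- path_model_spec(c("x", "m", "y"),
                           list(c("x", "m"), c("m", "y")), exogenous = "x")
  prm2 <- path_params(chain, coefficients = c("x->m" = 1, "m->y" = 1))
  mom2 <- implied_moments(chain, prm2)
  expect_equal(mom2$sigma["y", "y"], 3)
  expect_equal(mom2$sigma["x", "y"], 1)
  expect_equal(mom2$sigma["m", "m"], 2)
})

test_that("simulated moments match implied moments at n = 10000", {
  chain <- path_model_spec(c("treatment", "m", "y"),
                           list(c("treatment", "m"), c("m", "y")))
  prm <- path_params(chain, coefficients = c("treatment->m" = -0.7,
                                             "m->y" = 0.4),
                     intercepts = c(m = 0.2, y = -0.1),
                     residual_sd = c(m = 0.5, y = 0.8),
                     exo_mean = c(treatment = 0.5),
                     exo_cov = matrix(0.25, 1, 1,
                                      dimnames = list("treatment",
                                                      "treatment")))
  set.seed(99)
  n <- 10000
  d <- simulate_from_params(chain, prm, n)
  mom <- implied_moments(chain, prm)
  for (v in chain$variables) {
    mc_se <- sqrt(mom$sigma[v, v] / n)
    expect_lt(abs(mean(d[[v]]) - mom$mu[v]), 3 * mc_se, label = v)
  }
  expect_lt(abs(cov(d$treatment, d$y) - mom$sigma["treatment", "y"]), 0.02)
})

test_that("fiml_loglik equals the joint MVN log-likelihood on complete data", {
  set.seed(20)
  chain <- path_model_spec(c("treatment", "m", "y"),
                           list(c("treatment", "m"), c("m", "y")))
  prm <- path_params(chain, coefficients = c("treatment->m" = 0.5,
                                             "m->y" = -0.3),
                     residual_sd = c(m = 1.2, y = 0.7),
                     exo_mean = c(treatment = 0.4),
                     exo_cov = matrix(0.24, 1, 1,
                                      dimnames = list("treatment",
                                                      "treatment")))
  d <- simulate_from_params(chain, prm, 50)
  mom <- implied_moments(chain, prm)
  ll <- fiml_loglik(chain, prm, d)
  oracle <- oracle_mvn_loglik(as.matrix(d[, chain$variables]),
                              mom$mu, mom$sigma)
  expect_equal(ll, oracle, tolerance = 1e-10)
})

test_that("single observed standard-normal value contributes -log(2*pi)/2", {
  spec <- path_model_spec(c("treatment", "y"), NULL)
  prm <- path_params(spec, intercepts = c(y = 0), residual_sd = c(y = 1),
                     exo_mean = c(treatment = 0),
                     exo_cov = matrix(1, 1, 1,
                                      dimnames = list("treatment",
                                                      "treatment")))
  d <- data.frame(treatment = NA, y = 0)
  expect_equal(fiml_loglik(spec, prm, d), -0.5 * log(2 * pi))
})

test_that("fiml_loglik equals brute-force marginals under random missingness", {
  set.seed(21)
  spec <- model_b_spec()
  prm <- path_params(spec, coefficients = default_model_b_coefficients(),
                     residual_sd = c(cholesterol = 0.45, PBVC = 0.55,
                                     EDSS = 0.25, block_design = 2.6,
                                     MSIS29_physical = 4),
                     exo_mean = c(treatment = 0.5),
                     exo_cov = matrix(0.25, 1, 1,
                                      dimnames = list("treatment",
                                                      "treatment")))
  d <- simulate_from_params(spec, prm, 80)
  Y <- as.matrix(d[, spec$variables])
  Y[sample(length(Y), 100)] <- NA
  Y[rowSums(!is.na(Y)) == 0, 1] <- 0  # keep every row partly observed
  dd <- as.data.frame(Y)
  mom <- implied_moments(spec, prm)
  expect_equal(fiml_loglik(spec, prm, dd),
               oracle_fiml_loglik(Y, mom$mu, mom$sigma), tolerance = 1e-9)
})

test_that("complete-data FIML equals per-equation OLS over random DAGs", {
  set.seed(22)
  for (rep in 1:5) {
    spec <- random_dag_spec(n_endo = sample(2:4, 1))
    prm <- path_params(
      spec,
      coefficients = setNames(runif(nrow(spec$edges), -1, 1),
                              paste(spec$edges$from, spec$edges$to,
                                    sep = "->")),
      residual_sd = setNames(runif(length(spec$endogenous), 0.5, 1.5),
                             spec$endogenous))
    d <- simulate_from_params(spec, prm, 300)
    fit <- fit_path_model(spec, d, robust = FALSE)
    ols <- oracle_ols_equations(spec, d)
    est <- setNames(fit$coefficients$estimate, rownames(fit$coefficients))
    expect_equal(est[names(ols)], ols, tolerance = 1e-5)
  }
})

test_that("zero-residual-variance data are recovered exactly", {
  set.seed(23)
  chain <- path_model_spec(c("treatment", "m", "y"),
                           list(c("treatment", "m"), c("m", "y")))
  n <- 60
  tr <- rep(0:1, each = n / 2)
  d <- data.frame(treatment = tr, m = 1 + 0.8 * tr)
  d$y <- -0.5 + 2 * d$m
  fit <- fit_path_model(chain, d, robust = FALSE)
  expect_equal(fit$coefficients["treatment->m", "estimate"], 0.8,
               tolerance = 1e-4)
  expect_equal(fit$coefficients["m->y", "estimate"], 2, tolerance = 1e-4)
  expect_lt(fit$params$psi_sd["y"], 1e-3)
})

test_that("robust SEs match the textbook sandwich for a single equation", {
  set.seed(24)
  n <- 400
  tr <- rbinom(n, 1, 0.5)
  y <- 0.3 + 0.6 * tr + rnorm(n, 0, 1) * (1 + tr)  # heteroscedastic
  d <- data.frame(treatment = tr, y = y)
  spec <- path_model_spec(c("treatment", "y"), list(c("treatment", "y")))
  fit <- fit_path_model(spec, d)
  X <- cbind(1, tr)
  sw <- oracle_lm_sandwich(X, y)
  expect_equal(fit$coefficients["treatment->y", "robust_se"],
               sqrt(sw[2, 2]), tolerance = 0.02)
  # sandwich covariance is symmetric PSD
  V <- fit$vcov_robust
  expect_equal(V, t(V), tolerance = 1e-8)
  expect_true(all(eigen(V, symmetric = TRUE, only.values = TRUE)$values >
                    -1e-8))
})

test_that("robust and naive SEs agree under homoscedastic normality", {
  set.seed(25)
  n <- 20000
  tr <- rbinom(n, 1, 0.5)
  d <- data.frame(treatment = tr, y = 0.2 + 0.5 * tr + rnorm(n))
  spec <- path_model_spec(c("treatment", "y"), list(c("treatment", "y")))
  fit <- fit_path_model(spec, d)
  ratio <- fit$coefficients["treatment->y", "robust_se"] /
    fit$coefficients["treatment->y", "se"]
  expect_equal(ratio, 1, tolerance = 0.05)
})

test_that("standardization: unit variances, rescaling invariance, hand value", {
  set.seed(26)
  chain <- path_model_spec(c("treatment", "m", "y"),
                           list(c("treatment", "m"), c("m", "y")))
  prm <- path_params(chain, coefficients = c("treatment->m" = 0.6,
                                             "m->y" = 0.5),
                     residual_sd = c(m = 1, y = 1),
                     exo_mean = c(treatment = 0.5),
                     exo_cov = matrix(0.25, 1, 1,
                                      dimnames = list("treatment",
                                                      "treatment")))
  d <- simulate_from_params(chain, prm, 2000)
  fit <- fit_path_model(chain, d, robust = FALSE)
  std <- standardize(fit)
  # doubling a predictor's scale halves the raw coefficient, leaves std
  d2 <- d
  d2$m <- 2 * d$m
  fit2 <- fit_path_model(chain, d2, robust = FALSE)
  expect_equal(fit2$coefficients["m->y", "estimate"],
               fit$coefficients["m->y", "estimate"] / 2, tolerance = 1e-4)
  expect_equal(unname(standardize(fit2)["m->y"]), unname(std["m->y"]),
               tolerance = 1e-4)
  # hand value: std(m->y) = b * SD(m)/SD(y) at the estimates
  mom <- implied_moments(chain, fit$params)
  expect_equal(unname(std["m->y"]),
               fit$coefficients["m->y", "estimate"] *
                 sqrt(mom$sigma["m", "m"] / mom$sigma["y", "y"]))
})

test_that("likelihood ordering and edge monotonicity hold", {
  set.seed(27)
  sim <- small_cohort(n_per_arm = 60, seed = 28, regions = NULL)
  ct <- annualize(sim$cohort, model_vars)
  fitB <- fit_path_model(model_b_spec(), ct, robust = FALSE)
  sat <- fit_path_model(saturated_spec(model_b_spec()), ct, robust = FALSE)
  base <- fit_path_model(baseline_spec(model_b_spec()), ct, robust = FALSE)
  expect_gte(sat$loglik + 1e-6, fitB$loglik)
  expect_gte(fitB$loglik + 1e-6, base$loglik)
  # adding a free edge never decreases the likelihood
  spec_plus <- path_model_spec(
    model_b_spec()$variables,
    rbind(model_b_spec()$edges, c("cholesterol", "EDSS")))
  fit_plus <- fit_path_model(spec_plus, ct, robust = FALSE)
  expect_gte(fit_plus$loglik + 1e-6, fitB$loglik)
})

test_that("fit indices: saturated identity, df bookkeeping, hand CFI", {
  set.seed(29)
  sim <- small_cohort(n_per_arm = 50, seed = 30, regions = NULL)
  ct <- annualize(sim$cohort, model_vars)
  sat <- fit_path_model(saturated_spec(model_b_spec()), ct, robust = FALSE)
  fi <- fit_indices(sat, ct)
  expect_true(fi$saturated)
  expect_equal(fi$CFI, 1)
  expect_equal(fi$RMSEA, 0)
  expect_lt(fi$SRMR, 1e-4)
  # df = p(p+3)/2 - k
  fitB <- fit_path_model(model_b_spec(), ct, robust = FALSE)
  fiB <- fit_indices(fitB, ct)
  p <- 6
  expect_equal(fiB$df, p * (p + 3) / 2 - fitB$npar)
  expect_true(fiB$CFI >= 0 && fiB$CFI <= 1)
  expect_gte(fiB$RMSEA_ci[2], fiB$RMSEA_ci[1])
  # hand CFI arithmetic from the reported T and df
  Tm <- fiB$T; dfm <- fiB$df
  Tb <- 2 * (fiB$loglik_sat - fiB$loglik_baseline)
  dfb <- p * (p + 3) / 2 - 2 * p
  expect_equal(fiB$CFI,
               1 - max(Tm - dfm, 0) / max(Tb - dfb, Tm - dfm, 0))
  # AIC/BIC by definition
  expect_equal(fiB$AIC, -2 * fitB$loglik + 2 * fitB$npar)
  expect_equal(fiB$BIC, -2 * fitB$loglik + fitB$npar * log(fitB$n))
})

test_that("well-specified model at n = 5000 clears the published thresholds", {
  sim <- generate_cohort(generator_config(n_per_arm = 2500, regions = NULL,
                                          seed = 31))
  ct <- annualize(sim$cohort, model_vars)
  fit <- fit_path_model(model_b_spec(), ct, robust = FALSE)
  fi <- fit_indices(fit, ct)
  expect_gt(fi$CFI, 0.95)
  expect_lt(fi$SRMR, 0.08)
  expect_lt(fi$RMSEA, 0.06)
})
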