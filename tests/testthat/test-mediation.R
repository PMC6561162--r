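make_mediation_data <- function(n, a, b, cprime, seed,
                                sd_m = 0.45, sd_y = 0.55) {
  set.seed(seed)
  tr <- rep(0:1, each = n / 2)
  m <- a * tr + rnorm(n, 0, sd_m)
  y <- cprime * tr + b * m + rnorm(n, 0, sd_y)
  data.frame(treatment = tr, cholesterol = m, PBVC = y)
}

med_spec <- mediation_spec("treatment", "cholesterol", "PBVC")

test_that("spec and input validation", {
  expect_error(mediation_spec("t", "t", "y"), "distinct")
  d <- make_mediation_data(100, -0.7, 0.1, 0.3, seed = 1)
  expect_error(mcmc_sample(med_spec, d[1:5, ]), "complete cases")
  dc <- d
  dc$cholesterol <- 1
  expect_error(mcmc_sample(med_spec, dc, n_burn = 10, n_keep = 20,
                           chains = 2), "constant")
  expect_error(mcmc_sample(med_spec, d, n_burn = 10, n_keep = 21,
                           chains = 2), "divisible")
})

test_that("flat-prior posterior means match OLS and the analytic posterior", {
  d <- make_mediation_data(1500, -0.739, 0.108, 0.32, seed = 2)
  post <- mcmc_sample(med_spec, d, n_burn = 500, n_keep = 4000, chains = 4,
                      seed = 3)
  ols_a <- coef(lm(cholesterol ~ treatment, d))["treatment"]
  fy <- lm(PBVC ~ treatment + cholesterol, d)
  ols <- coef(fy)
  expect_equal(median(post$draws$a), unname(ols_a), tolerance = 0.01)
  expect_equal(median(post$draws$cprime), unname(ols["treatment"]),
               tolerance = 0.01)
  expect_equal(median(post$draws$b), unname(ols["cholesterol"]),
               tolerance = 0.01)
  # analytic marginal posterior of a coefficient under flat priors is a
  # location-scale t centered at OLS with scale ~ the classical SE
  se_c <- summary(fy)$coefficients["treatment", "Std. Error"]
  expect_equal(sd(post$draws$cprime), se_c, tolerance = 0.1 * se_c)
  expect_true(post$ok)
  expect_true(all(post$rhat < 1.01))
})

test_that("draws are deterministic given the seed and carry the identities", {
  d <- make_mediation_data(200, -0.7, 0.1, 0.3, seed = 4)
  p1 <- mcmc_sample(med_spec, d, n_burn = 100, n_keep = 400, chains = 2,
                    seed = 5)
  p2 <- mcmc_sample(med_spec, d, n_burn = 100, n_keep = 400, chains = 2,
                    seed = 5)
  expect_identical(p1$draws, p2$draws)
  expect_equal(nrow(p1$draws), 400)
  # indirect draws are the elementwise product; total = indirect + direct
  expect_equal(p1$draws$indirect, p1$draws$a * p1$draws$b)
  expect_equal(p1$draws$total, p1$draws$indirect + p1$draws$cprime)
  # CI ordering
  s <- p1$summary
  expect_true(all(s$lower <= s$median & s$median <= s$upper))
})

test_that("mediation_effects: significance rule and proportion summaries", {
  d <- make_mediation_data(2000, -0.739, 0.108, 0.24, seed = 6)
  post <- mcmc_sample(med_spec, d, n_burn = 200, n_keep = 2000, chains = 2,
                      seed = 7)
  eff <- mediation_effects(post)
  expect_true(eff$proportion_defined)
  # the CI-crosses-zero rule, checked directly against the intervals
  s <- eff$summary
  for (i in seq_len(nrow(s))) {
    expect_equal(s$significant[i], s$lower[i] > 0 || s$upper[i] < 0)
  }
  # ratio-of-medians equals its definition
  med_ind <- median(post$draws$indirect)
  med_tot <- median(post$draws$total)
  expect_equal(eff$proportion_mediated, med_ind / med_tot)
})

test_that("a-draws identically zero give indirect == 0 and proportion 0", {
  # degenerate-by-construction posterior: fabricate draws directly
  d <- make_mediation_data(400, 0, 0.5, 0.4, seed = 8)
  post <- mcmc_sample(med_spec, d, n_burn = 200, n_keep = 1000, chains = 2,
                      seed = 9)
  post$draws$a <- 0
  post$draws$indirect <- post$draws$a * post$draws$b
  post$draws$total <- post$draws$indirect + post$draws$cprime
  eff <- mediation_effects(post)
  expect_equal(eff$summary$median[eff$summary$effect == "indirect"], 0)
  expect_equal(eff$proportion_mediated, 0)
})

test_that("undefined proportion is flagged when the total effect is ~ 0", {
  d <- make_mediation_data(400, 0.5, 0.4, -0.2, seed = 10)
  post <- mcmc_sample(med_spec, d, n_burn = 100, n_keep = 500, chains = 2,
                      seed = 11)
  post$draws$total <- 0
  post$draws$cprime <- -post$draws$indirect
  eff <- mediation_effects(post)
  expect_false(eff$proportion_defined)
  expect_true(is.na(eff$proportion_mediated))
})

test_that("true b = 0 gives ~95% coverage of zero by the indirect CI", {
  hits <- 0L
  reps <- 80L
  for (r in seq_len(reps)) {
    d <- make_mediation_data(120, -0.7, 0, 0.3, seed = 6000 + r)
    post <- mcmc_sample(med_spec, d, n_burn = 100, n_keep = 800, chains = 1,
                        seed = r)
    s <- post$summary
    ind <- s[s$quantity == "indirect", ]
    if (ind$lower <= 0 && ind$upper >= 0) hits <- hits + 1L
  }
  # binomial 3-SE band around 0.95
  expect_gt(hits / reps, 0.95 - 3 * sqrt(0.95 * 0.05 / reps))
})

test_that("posterior export round-trips", {
  d <- make_mediation_data(150, -0.7, 0.1, 0.3, seed = 12)
  post <- mcmc_sample(med_spec, d, n_burn = 50, n_keep = 200, chains = 2,
                      seed = 13)
  csv <- tempfile(fileext = ".csv")
  js <- tempfile(fileext = ".json")
  write_mediation_draws(post, csv)
  write_mediation_json(post, js)
  back <- read.csv(csv)
  expect_equal(nrow(back), 200)
  j <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_equal(j$settings$chains, 2)
  expect_equal(j$model$mediator, "cholesterol")
})
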