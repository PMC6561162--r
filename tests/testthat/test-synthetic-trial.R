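test_that("generator config validates its invariants", {
  expect_error(generator_config(n_per_arm = 1), "n_per_arm")
  expect_error(generator_config(visit_times = c(1, 2)), "visit_times")
  expect_error(generator_config(visit_times = c(0, 2, 1)), "visit_times")
  expect_error(generator_config(missing_rate = 1), "missing_rate")
  expect_error(generator_config(
    residual_sds = c(cholesterol = -1, PBVC = 1, EDSS = 1,
                     block_design = 1, MSIS29_physical = 1)),
    "residual_sds")
  # cyclic structural model rejected at spec level
  expect_error(path_model_spec(c("treatment", "a", "b"),
                               list(c("a", "b"), c("b", "a"))),
               "cycle")
})

test_that("cohort structure honours the trial layout", {
  sim <- small_cohort(n_per_arm = 15, seed = 3,
                      regions = default_regional_rates()[1:4, ])
  co <- sim$cohort
  expect_s3_class(co, "trial_cohort")
  # every subject has a baseline row; arm constant within subject
  byid <- split(co, co$subject_id)
  expect_true(all(vapply(byid, function(d) any(d$visit_time == 0), TRUE)))
  expect_true(all(vapply(byid, function(d) length(unique(d$arm)) == 1, TRUE)))
  # PBVC at baseline is 0 by construction
  expect_equal(co$PBVC[co$visit_time == 0], rep(0, 30))
  # EDSS on the half-point grid within [0, 10]
  expect_true(all(co$EDSS * 2 == round(co$EDSS * 2)))
  expect_true(all(co$EDSS >= 0 & co$EDSS <= 10))
  expect_equal(sum(co$arm == 1), sum(co$arm == 0))
})

test_that("noise-free generation reproduces structural predictions exactly", {
  zero <- c(cholesterol = 0, PBVC = 0, EDSS = 0, block_design = 0,
            MSIS29_physical = 0)
  cfg <- generator_config(n_per_arm = 30, residual_sds = zero,
                          measurement_sds = 0, regions = NULL, seed = 9)
  sim <- generate_cohort(cfg)
  ct <- annualize(sim$cohort, model_vars)
  # treatment -> cholesterol path is the exact arm difference
  expect_equal(mean(ct$cholesterol[ct$treatment == 1]) -
                 mean(ct$cholesterol[ct$treatment == 0]),
               -0.739, tolerance = 1e-12)
  # every endogenous arm difference equals the reduced-form total effect
  truth <- sim$truth
  spec <- cfg$spec
  params <- path_params(spec, coefficients = cfg$coefficients,
                        intercepts = cfg$rate_intercepts,
                        residual_sd = zero)
  total <- total_treatment_effects(spec, params)
  for (v in c("cholesterol", "PBVC", "block_design", "MSIS29_physical")) {
    expect_equal(mean(ct[[v]][ct$treatment == 1]) -
                   mean(ct[[v]][ct$treatment == 0]),
                 unname(total[v]), tolerance = 1e-10, label = v)
  }
  expect_equal(truth$arm_difference, total)
})

test_that("same config and seed give identical cohorts", {
  cfg <- generator_config(n_per_arm = 10, seed = 77, missing_rate = 0.1)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$cohort, b$cohort)
  expect_identical(a$truth, b$truth)
  # and a different seed does not
  cfg2 <- generator_config(n_per_arm = 10, seed = 78, missing_rate = 0.1)
  expect_false(identical(generate_cohort(cfg2)$cohort, a$cohort))
})

test_that("large-n arm difference in PBVC approaches the generating path", {
  cfg <- generator_config(n_per_arm = 5000, regions = NULL, seed = 123)
  sim <- generate_cohort(cfg)
  ct <- annualize(sim$cohort, "PBVC")
  diff <- mean(ct$PBVC[ct$treatment == 1]) - mean(ct$PBVC[ct$treatment == 0])
  mc_se <- 0.55 * sqrt(4 / nrow(ct))
  expect_lt(abs(diff - 0.234), 3 * mc_se)
})

test_that("sample moments of changes converge to implied moments", {
  cfg <- generator_config(n_per_arm = 5000, regions = NULL, seed = 21,
                          measurement_sds = 0)
  sim <- generate_cohort(cfg)
  ct <- annualize(sim$cohort, model_vars)
  spec <- cfg$spec
  params <- path_params(spec, coefficients = cfg$coefficients,
                        intercepts = cfg$rate_intercepts,
                        residual_sd = cfg$residual_sds,
                        exo_mean = c(treatment = 0.5),
                        exo_cov = matrix(0.25, 1, 1,
                                         dimnames = list("treatment",
                                                         "treatment")))
  mom <- implied_moments(spec, params)
  n <- nrow(ct)
  for (v in setdiff(spec$variables, "EDSS")) {  # EDSS carries rounding noise
    mc_se <- sqrt(mom$sigma[v, v] / n)
    expect_lt(abs(mean(ct[[v]]) - mom$mu[v]), 3 * mc_se, label = v)
    sd_se <- sqrt(mom$sigma[v, v]) / sqrt(2 * (n - 1))  # SE of a normal SD
    expect_lt(abs(sd(ct[[v]]) - sqrt(mom$sigma[v, v])), 4 * sd_se, label = v)
  }
})

test_that("missingness: rate 0 is the identity; MCAR hits the target rate", {
  sim <- small_cohort(n_per_arm = 20, seed = 4)
  expect_identical(apply_missingness(sim$cohort, 0, "MCAR", seed = 1),
                   sim$cohort)
  big <- small_cohort(n_per_arm = 600, seed = 5, regions = NULL)
  out <- apply_missingness(big$cohort, 0.3, "MCAR", seed = 2)
  fu <- out[out$visit_time > 0, ]
  frac <- mean(is.na(fu$cholesterol))
  expect_lt(abs(frac - 0.3), 3 * sqrt(0.3 * 0.7 / nrow(fu)))
  # treatment assignment and baseline rows untouched
  expect_false(anyNA(out$arm))
  expect_false(anyNA(out[out$visit_time == 0, "cholesterol"]))
  expect_error(apply_missingness(big$cohort, 1.2, "MCAR"), "rate")
})

test_that("MAR dropout tracks baseline EDSS, not follow-up residuals", {
  big <- small_cohort(n_per_arm = 1500, seed = 6, regions = NULL)
  full <- big$cohort
  out <- apply_missingness(full, 0.3, "MAR", seed = 2)
  fu <- out[out$visit_time > 0, ]
  base_edss <- full$EDSS[full$visit_time == 0][
    match(fu$subject_id, full$subject_id[full$visit_time == 0])]
  miss <- is.na(fu$cholesterol)
  expect_gt(cor(miss, base_edss), 0.15)
  # overall rate calibrated to the requested fraction
  expect_lt(abs(mean(miss) - 0.3), 0.03)
  # missingness unrelated to the *unobserved* follow-up residual: compare
  # against the pre-deletion cholesterol change net of baseline EDSS
  resid_chol <- full$cholesterol[full$visit_time > 0] -
    full$cholesterol[full$visit_time == 0][
      match(fu$subject_id, full$subject_id[full$visit_time == 0])]
  r <- cor(miss, resid(lm(resid_chol ~ base_edss)))
  expect_lt(abs(r), 0.05)
})

test_that("cohort CSV round-trips", {
  sim <- small_cohort(n_per_arm = 5, seed = 8,
                      regions = default_regional_rates()[1:2, ])
  f <- tempfile(fileext = ".csv")
  write_cohort_csv(sim$cohort, f)
  back <- read_cohort_csv(f)
  expect_equal(as.data.frame(back), as.data.frame(sim$cohort),
               tolerance = 1e-12)
  g <- tempfile(fileext = ".json")
  write_ground_truth(sim$truth, g)
  j <- jsonlite::read_json(g, simplifyVector = TRUE)
  expect_equal(j$coefficients[["treatment->PBVC"]], 0.234)
})
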