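# Synthetic two-arm trial cohorts.  The restricted trial data cannot be
# shipped, so analyses are exercised on simulated cohorts whose annualized
# changes obey a user-chosen structural model.

#' Default generating coefficients for the cholesterol-independent model
#'
#' The three treatment paths reported in the reference analysis
#' (treatment to cholesterol -0.739, to PBVC 0.234, to EDSS -0.086) anchor
#' the generator; the remaining paths are synthetic stand-ins with
#' field-plausible signs (more atrophy, i.e. more negative PBVC change,
#' worsens EDSS, block design and MSIS).
#'
#' @return named numeric vector keyed \code{"from->to"}.
#' @export
default_model_b_coefficients <- function() {
  c("treatment->cholesterol" = -0.739,
    "treatment->PBVC" = 0.234,
    "treatment->EDSS" = -0.086,
    "treatment->block_design" = 0.9,
    "treatment->MSIS29_physical" = -1.2,
    "PBVC->EDSS" = -0.15,
    "PBVC->block_design" = 1.2,
    "PBVC->MSIS29_physical" = -1.5,
    "EDSS->MSIS29_physical" = 2.0,
    "block_design->MSIS29_physical" = -0.3)
}

# residual SDs of the annualized-change equations; cholesterol/PBVC/EDSS are
# back-computed from the reported coefficient SEs at the trial's n (~140):
# sd ~= SE * sqrt(n_total) / 2
default_residual_sds <- function() {
  c(cholesterol = 0.45, PBVC = 0.55, EDSS = 0.25,
    block_design = 2.6, MSIS29_physical = 4.0)
}

# placebo-arm mean annual rates of change (intercepts of the equations)
default_rate_intercepts <- function() {
  c(cholesterol = -0.05, PBVC = -0.65, EDSS = 0.15,
    block_design = -0.8, MSIS29_physical = 1.5)
}

# visit-level measurement noise SDs; small relative to each scale, enough
# to keep per-subject trajectories off an exact line (mixed models need a
# nonzero residual).  PBVC noise is kept small because measured-with-error
# mediators attenuate downstream paths.
default_measurement_sds <- function() {
  c(cholesterol = 0.2, EDSS = 0, block_design = 1.5, PASAT = 1.5,
    FAB = 0.7, MSIS29_physical = 2.0, PBVC = 0.1)
}

default_baselines <- function() {
  data.frame(
    variable = c("cholesterol", "EDSS", "block_design", "PASAT", "FAB",
                 "MSIS29_physical"),
    mean = c(5.5, 5.7, 45, 45, 15.5, 55),
    sd = c(1.0, 0.9, 8, 9, 1.8, 12),
    stringsAsFactors = FALSE)
}

#' Default regional atrophy-rate table
#'
#' Per-region baseline volumes (mL, hemispheres pre-summed) and true annual
#' percentage volume change.  The lateral ventricles (+1.95\%/y expansion),
#' transverse temporal gyrus (placebo -1.58\%/y with a +0.79\%/y treatment
#' effect), thalamus (-0.24\%/y) and medulla oblongata (0\%/y) follow the
#' rates reported for the reference trial; all other regions are synthetic
#' stand-ins with plausible slow cortical loss.
#'
#' @return data.frame with columns \code{region}, \code{baseline_ml},
#'   \code{placebo_rate} (\%/year) and \code{treatment_effect}
#'   (\%/year added to the treated arm's rate).
#' @export
default_regional_rates <- function() {
  tab <- rbind(
    c("lateral_ventricles",   25.0,  1.95, 0),
    c("transverse_temporal",   1.7, -1.58, 0.79),
    c("thalamus",             15.0, -0.24, 0),
    c("medulla_oblongata",     4.6,  0.00, 0),
    c("precentral",           13.0, -0.70, 0),
    c("postcentral",          12.0, -0.65, 0),
    c("precuneus",            11.0, -0.60, 0),
    c("anterior_cingulate",    5.0, -0.55, 0),
    c("middle_cingulate",      5.5, -0.50, 0),
    c("superior_frontal",     16.0, -0.60, 0),
    c("middle_frontal",       14.0, -0.55, 0),
    c("inferior_frontal",      8.0, -0.50, 0),
    c("hippocampus",           3.7, -0.40, 0),
    c("amygdala",              1.6, -0.30, 0),
    c("caudate",               3.5, -0.20, 0),
    c("putamen",               4.1, -0.35, 0),
    c("pallidum",              1.3, -0.20, 0),
    c("insula",                7.0, -0.45, 0),
    c("superior_temporal",     7.5, -0.50, 0),
    c("middle_temporal",      10.0, -0.45, 0),
    c("inferior_temporal",     9.8, -0.40, 0),
    c("fusiform",              7.4, -0.35, 0),
    c("parahippocampal",       3.1, -0.30, 0),
    c("lingual",               6.4, -0.30, 0),
    c("cuneus",                4.4, -0.35, 0),
    c("superior_parietal",    10.5, -0.50, 0),
    c("inferior_parietal",    12.0, -0.55, 0),
    c("supramarginal",         8.1, -0.50, 0),
    c("angular",               9.0, -0.45, 0),
    c("occipital",             8.0, -0.30, 0),
    c("cerebellum",          110.0, -0.25, 0),
    c("brainstem",            20.0, -0.10, 0))
  data.frame(region = tab[, 1],
             baseline_ml = as.numeric(tab[, 2]),
             placebo_rate = as.numeric(tab[, 3]),
             treatment_effect = as.numeric(tab[, 4]),
             stringsAsFactors = FALSE)
}

#' Configure the synthetic trial generator
#'
#' The generator emulates a two-arm randomized trial with three annual
#' visits.  Per subject, latent annual rates of change are drawn from the
#' structural model (treatment exogenous; endogenous rates
#' equation-by-equation in topological order with independent normal
#' residuals), and visit values are \code{baseline + rate * visit_time +
#' measurement noise}.  EDSS is rounded to \code{edss_step} within [0, 10]
#' (its stated non-normality); PBVC is a cumulative percentage change from
#' baseline, 0 at baseline by construction.  Regional volumes shrink or
#' expand at configured \%/year rates of their baseline volume, with a
#' shared subject-level atrophy factor.
#'
#' @param n_per_arm subjects per arm (>= 2; default 70, a configuration
#'   choice in the absence of a published analysis n).
#' @param visit_times visit schedule in years, strictly increasing from 0.
#' @param spec structural model (default [model_b_spec()]).
#' @param coefficients generating path coefficients, keyed
#'   \code{"from->to"}.
#' @param rate_intercepts placebo-arm mean annual rates per endogenous
#'   variable.
#' @param residual_sds residual SDs of the annual-rate equations (>= 0).
#' @param extra_outcomes named list of variables generated outside the
#'   structural model, each \code{list(intercept, sd, arm_effect)};
#'   defaults add PASAT and FAB with no treatment effect.
#' @param edss_step EDSS granularity (default 0.5).
#' @param measurement_sds named visit-level measurement noise SDs; the
#'   defaults ([default_measurement_sds()]) are small relative to each
#'   variable's scale so that the structural (annualized-change) signal
#'   dominates; a single unnamed value (e.g. 0) applies to every clinical
#'   variable, giving the exact noise-free limit.
#' @param regions regional rate table as in [default_regional_rates()];
#'   \code{NULL} to skip regional volumes.
#' @param regional_resid_sd between-subject SD of a region's \%/year rate.
#' @param regional_meas_frac measurement noise on a regional volume,
#'   as a fraction of its typical volume.
#' @param shared_atrophy_sd SD of the shared subject-level atrophy factor
#'   added to every region's rate (\%/year).
#' @param missing_rate fraction of follow-up values set missing, in [0, 1).
#' @param missing_mechanism \code{"MCAR"} or \code{"MAR"} (dropout driven
#'   by baseline EDSS).
#' @param seed integer seed.
#' @return validated list of class \code{"generator_config"}.
#' @export
generator_config <- function(n_per_arm = 70,
                             visit_times = c(0, 1, 2),
                             spec = model_b_spec(),
                             coefficients = default_model_b_coefficients(),
                             rate_intercepts = default_rate_intercepts(),
                             residual_sds = default_residual_sds(),
                             extra_outcomes = list(
                               PASAT = list(intercept = -0.5, sd = 2.0,
                                            arm_effect = 0),
                               FAB = list(intercept = -0.2, sd = 1.0,
                                          arm_effect = 0)),
                             edss_step = 0.5,
                             measurement_sds = NULL,
                             regions = default_regional_rates(),
                             regional_resid_sd = 0.4,
                             regional_meas_frac = 0.005,
                             shared_atrophy_sd = 0.25,
                             missing_rate = 0,
                             missing_mechanism = c("MCAR", "MAR"),
                             seed = 1) {
  if (n_per_arm < 2) stop("n_per_arm must be >= 2")
  if (visit_times[1] != 0 || any(diff(visit_times) <= 0))
    stop("visit_times must be strictly increasing and start at 0")
  if (missing_rate < 0 || missing_rate >= 1)
    stop("missing_rate must be in [0, 1)")
  if (any(residual_sds < 0)) stop("residual_sds must be >= 0")
  spec <- validate_spec(spec)
  missing <- setdiff(spec$endogenous, names(residual_sds))
  if (length(missing)) stop("residual_sds missing for: ",
                            paste(missing, collapse = ", "))
  structure(list(
    n_per_arm = as.integer(n_per_arm), visit_times = visit_times,
    spec = spec, coefficients = coefficients,
    rate_intercepts = rate_intercepts, residual_sds = residual_sds,
    extra_outcomes = extra_outcomes, edss_step = edss_step,
    measurement_sds = measurement_sds, regions = regions,
    regional_resid_sd = regional_resid_sd,
    regional_meas_frac = regional_meas_frac,
    shared_atrophy_sd = shared_atrophy_sd,
    missing_rate = missing_rate,
    missing_mechanism = match.arg(missing_mechanism),
    seed = as.integer(seed)), class = "generator_config")
}

#' Generate a synthetic trial cohort
#'
#' @param config a [generator_config()].
#' @return list with \code{cohort} (long-format visit-level data.frame of
#'   class \code{"trial_cohort"}) and \code{truth} (the
#'   \code{"ground_truth"} actually used: generating coefficient matrix,
#'   intercepts, residual SDs, regional rate table, and the per-variable
#'   total treatment effect on annualized change implied by the structural
#'   model).  Deterministic given \code{config$seed}.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  spec <- config$spec
  n <- 2L * config$n_per_arm
  arm <- rep(c(0L, 1L), each = config$n_per_arm)
  subject_id <- sprintf("S%04d", seq_len(n))

  age <- round(stats::rnorm(n, 51, 7), 1)
  sex <- ifelse(stats::runif(n) < 0.65, "F", "M")
  center <- sample(c("C1", "C2", "C3"), n, replace = TRUE,
                   prob = c(0.5, 0.3, 0.2))
  scanner <- ifelse(center == "C1", "3T", "1.5T")
  tiv <- stats::rnorm(n, 1450, 120)

  bl <- default_baselines()
  baseline <- list()
  for (i in seq_len(nrow(bl))) {
    baseline[[bl$variable[i]]] <- stats::rnorm(n, bl$mean[i], bl$sd[i])
  }
  baseline$EDSS <- pmin(pmax(round(baseline$EDSS / config$edss_step) *
                               config$edss_step, 0), 10)
  baseline$PBVC <- rep(0, n)

  # latent annual rates from the structural model, in topological order
  params <- path_params(spec,
                        coefficients = config$coefficients,
                        intercepts = config$rate_intercepts,
                        residual_sd = config$residual_sds)
  rates <- matrix(NA_real_, n, length(spec$variables),
                  dimnames = list(NULL, spec$variables))
  rates[, "treatment"] <- arm
  for (v in setdiff(spec$order, spec$exogenous)) {
    pa <- spec_parents(spec, v)
    mu <- params$alpha[v]
    for (p in pa) mu <- mu + params$B[v, p] * rates[, p]
    rates[, v] <- mu + stats::rnorm(n, 0, params$psi_sd[v])
  }
  for (v in names(config$extra_outcomes)) {
    eo <- config$extra_outcomes[[v]]
    rates <- cbind(rates, stats::setNames(
      data.frame(eo$intercept + eo$arm_effect * arm +
                   stats::rnorm(n, 0, eo$sd)), v))
    rates <- as.matrix(rates)
  }

  clinical_vars <- c(setdiff(spec$variables, "treatment"),
                     names(config$extra_outcomes))
  meas_sd <- stats::setNames(rep(0, length(clinical_vars)), clinical_vars)
  defaults <- default_measurement_sds()
  keep <- intersect(names(defaults), clinical_vars)
  meas_sd[keep] <- defaults[keep]
  ms <- config$measurement_sds
  if (!is.null(ms)) {
    if (is.null(names(ms))) {
      if (length(ms) != 1) stop("unnamed measurement_sds must be a scalar")
      meas_sd[] <- ms
    } else {
      meas_sd[intersect(names(ms), clinical_vars)] <-
        ms[intersect(names(ms), clinical_vars)]
    }
  }

  # regional volumes
  reg <- config$regions
  if (!is.null(reg)) {
    shared <- stats::rnorm(n, 0, config$shared_atrophy_sd)
    vol0 <- matrix(NA_real_, n, nrow(reg))
    reg_rate <- matrix(NA_real_, n, nrow(reg))
    for (j in seq_len(nrow(reg))) {
      vol0[, j] <- stats::rnorm(n, reg$baseline_ml[j],
                                0.08 * reg$baseline_ml[j]) * (tiv / 1450)
      reg_rate[, j] <- reg$placebo_rate[j] + reg$treatment_effect[j] * arm +
        shared + stats::rnorm(n, 0, config$regional_resid_sd)
    }
  }

  rows <- vector("list", length(config$visit_times))
  for (k in seq_along(config$visit_times)) {
    t <- config$visit_times[k]
    df <- data.frame(subject_id = subject_id, arm = arm, age = age,
                     sex = sex, center = center, scanner = scanner,
                     visit_time = t, TIV = tiv,
                     stringsAsFactors = FALSE)
    for (v in setdiff(clinical_vars, "PBVC")) {
      base_v <- if (!is.null(baseline[[v]])) baseline[[v]] else rep(0, n)
      val <- base_v + rates[, v] * t +
        if (meas_sd[v] > 0) stats::rnorm(n, 0, meas_sd[v]) else 0
      if (v == "EDSS") {
        val <- pmin(pmax(round(val / config$edss_step) * config$edss_step,
                         0), 10)
      }
      df[[v]] <- val
    }
    if ("PBVC" %in% clinical_vars) {
      # cumulative % change from baseline; exactly 0 at the baseline visit
      noise <- if (t > 0 && meas_sd["PBVC"] > 0)
        stats::rnorm(n, 0, meas_sd["PBVC"]) else 0
      df$PBVC <- rates[, "PBVC"] * t + noise
    }
    if (!is.null(reg)) {
      for (j in seq_len(nrow(reg))) {
        noise <- if (config$regional_meas_frac > 0)
          stats::rnorm(n, 0, config$regional_meas_frac * reg$baseline_ml[j])
        else 0
        df[[paste0("vol_", reg$region[j])]] <-
          vol0[, j] * (1 + reg_rate[, j] * t / 100) + noise
      }
    }
    rows[[k]] <- df
  }
  cohort <- do.call(rbind, rows)
  cohort <- cohort[order(cohort$subject_id, cohort$visit_time), ]
  rownames(cohort) <- NULL
  class(cohort) <- c("trial_cohort", "data.frame")

  if (config$missing_rate > 0) {
    cohort <- apply_missingness(cohort, config$missing_rate,
                                config$missing_mechanism,
                                seed = config$seed + 104729L)
  }

  total <- total_treatment_effects(spec, params)
  truth <- structure(list(
    coefficients = config$coefficients,
    B = params$B,
    intercepts = config$rate_intercepts,
    residual_sds = config$residual_sds,
    extra_outcomes = config$extra_outcomes,
    regions = reg,
    arm_difference = total,
    seed = config$seed), class = "ground_truth")
  list(cohort = cohort, truth = truth)
}

#' Total (reduced-form) treatment effect on every variable
#'
#' Column of \eqn{(I - B)^{-1}} belonging to the treatment indicator: the
#' model-implied arm difference in each variable's annualized change.
#'
#' @param spec a path-model spec.
#' @param params a \code{"path_params"}.
#' @return named numeric vector over the endogenous variables.
#' @export
total_treatment_effects <- function(spec, params) {
  v <- spec$variables
  IBinv <- solve(diag(length(v)) - params$B[v, v])
  dimnames(IBinv) <- list(v, v)
  IBinv[spec$endogenous, "treatment"]
}

#' Inject missingness into a cohort
#'
#' MCAR sets each follow-up measurement cell missing independently with
#' probability \code{rate}.  MAR is visit-level dropout whose probability
#' depends (logistically, slope 0.8 per EDSS point) on the subject's
#' baseline EDSS only, with the intercept calibrated so the expected
#' overall missing fraction equals \code{rate}.  Baseline rows and the
#' treatment assignment are never made missing.
#'
#' @param cohort a trial cohort.
#' @param rate fraction in [0, 1).
#' @param mechanism \code{"MCAR"} or \code{"MAR"}.
#' @param seed integer seed.
#' @return the cohort with \code{NA}s injected; a summary of counts is
#'   attached as attribute \code{"missingness"}.
#' @export
apply_missingness <- function(cohort, rate, mechanism = c("MCAR", "MAR"),
                              seed = 1) {
  mechanism <- match.arg(mechanism)
  if (rate < 0 || rate >= 1) stop("rate must be in [0, 1)")
  if (rate == 0) return(cohort)
  set.seed(seed)
  meas_cols <- setdiff(
    names(cohort)[vapply(cohort, is.numeric, TRUE)],
    c("arm", "age", "visit_time", "TIV"))
  follow <- which(cohort$visit_time > 0)
  n_set <- 0L
  if (mechanism == "MCAR") {
    for (cl in meas_cols) {
      hit <- follow[stats::runif(length(follow)) < rate]
      cohort[hit, cl] <- NA
      n_set <- n_set + length(hit)
    }
  } else {
    base <- cohort[cohort$visit_time == 0,
                   c("subject_id", "EDSS")]
    edss0 <- stats::setNames(base$EDSS, base$subject_id)
    z <- 0.8 * (edss0[cohort$subject_id[follow]] - mean(edss0, na.rm = TRUE))
    # calibrate the intercept so mean dropout probability equals rate
    a <- stats::uniroot(function(a) mean(stats::plogis(a + z)) - rate,
                        lower = -30, upper = 30)$root
    drop <- follow[stats::runif(length(follow)) < stats::plogis(a + z)]
    for (cl in meas_cols) cohort[drop, cl] <- NA
    n_set <- length(drop) * length(meas_cols)
  }
  attr(cohort, "missingness") <- list(
    mechanism = mechanism, rate = rate, cells_set = n_set,
    cells_eligible = length(follow) * length(meas_cols))
  cohort
}

#' Write a cohort as CSV / ground truth as JSON
#' @param cohort a trial cohort.
#' @param path output file.
#' @export
write_cohort_csv <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @param truth a \code{"ground_truth"}.
#' @export
write_ground_truth <- function(truth, path) {
  obj <- unclass(truth)
  obj$B <- NULL  # redundant with the coefficient list
  # named vectors as JSON objects (jsonlite drops atomic-vector names)
  for (f in c("coefficients", "intercepts", "residual_sds",
              "arm_difference")) {
    obj[[f]] <- as.list(obj[[f]])
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  invisible(path)
}

#' Read a cohort written by [write_cohort_csv()]
#' @param path CSV file.
#' @export
read_cohort_csv <- function(path) {
  cohort <- utils::read.csv(path, stringsAsFactors = FALSE)
  class(cohort) <- c("trial_cohort", "data.frame")
  cohort
}
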