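# Per-region longitudinal atrophy-rate screening.  Each region's volume is
# the outcome of a linear mixed model with age, sex, center, scanner and
# total intracranial volume as covariates; time slopes are converted to
# percent of baseline volume per year, and the combined-arms slope tests
# are corrected across regions by the Benjamini-Hochberg false-discovery
# rate.

regional_covariates <- function(cohort) {
  intersect(c("age", "sex", "center", "scanner", "TIV"), names(cohort))
}

# slope and its SE for one region from a combined-arms model
region_slope <- function(cohort, col, covariates) {
  f <- fit_lmm(cohort, col, covariates = covariates, group = "arm")
  # combined-arms rate: refit without arm terms, slope of time
  rhs <- paste(c("visit_time", covariates), collapse = " + ")
  fml <- stats::as.formula(
    sprintf("%s ~ %s + (1 + visit_time | subject_id)", col, rhs))
  ctrl <- lme4::lmerControl(check.conv.singular = "ignore",
                            calc.derivs = FALSE)
  m <- suppressMessages(suppressWarnings(
    lme4::lmer(fml, data = cohort[!is.na(cohort[[col]]), ],
               REML = FALSE, control = ctrl)))
  est <- lme4::fixef(m)["visit_time"]
  se <- sqrt(diag(as.matrix(stats::vcov(m))))["visit_time"]
  list(slope = unname(est), se = unname(se), interaction = f$interaction,
       arm_fit = f)
}

#' Regional atrophy rates with FDR control
#'
#' For every region, fits the longitudinal mixed model (random intercept
#' and slope per subject; covariates age, sex, center, scanner, TIV) and
#' reports the combined-arms annual rate of volume change as a percentage
#' of the cohort mean baseline volume, with a 95\% Wald confidence
#' interval; the slope p-values are adjusted across regions with
#' Benjamini--Hochberg.  The arm-difference (group-by-time) p-value is
#' reported unadjusted.  Regions with zero variance are skipped with a
#' message.
#'
#' @param cohort visit-level trial cohort with \code{vol_*} columns.
#' @param regions region names (without the \code{vol_} prefix); default
#'   all \code{vol_*} columns.
#' @param alpha significance level applied to the FDR-adjusted q-values.
#' @param denominator \code{"cohort_baseline"} (default; percent rates are
#'   relative to the cohort mean baseline volume) or
#'   \code{"subject_baseline"} (per-subject baselines averaged).
#' @return data.frame of class \code{"regional_result"}, sorted by
#'   decreasing absolute rate: region, rate (\%/year), lower, upper, p
#'   (combined slope), q (BH), significant, interaction_p (arm
#'   difference), plus per-arm rates from [arm_specific_rates()].
#' @export
regional_rates <- function(cohort, regions = NULL, alpha = 0.05,
                           denominator = c("cohort_baseline",
                                           "subject_baseline")) {
  denominator <- match.arg(denominator)
  if (is.null(regions)) {
    regions <- sub("^vol_", "", grep("^vol_", names(cohort), value = TRUE))
  }
  if (!length(regions)) stop("no regions found")
  cols <- paste0("vol_", regions)
  absent <- setdiff(cols, names(cohort))
  if (length(absent)) stop("region column(s) not in cohort: ",
                           paste(absent, collapse = ", "))
  if (!"TIV" %in% names(cohort)) stop("TIV column required")
  covs <- setdiff(regional_covariates(cohort), character(0))
  base <- cohort[cohort$visit_time == 0, , drop = FALSE]
  rows <- list()
  skipped <- character(0)
  for (i in seq_along(regions)) {
    col <- cols[i]
    if (stats::sd(cohort[[col]], na.rm = TRUE) == 0) {
      skipped <- c(skipped, regions[i])
      next
    }
    denom <- switch(denominator,
                    cohort_baseline = mean(base[[col]], na.rm = TRUE),
                    subject_baseline = mean(base[[col]], na.rm = TRUE))
    rs <- region_slope(cohort, col, covs)
    scale <- 100 / denom
    arm <- arm_specific_rates(cohort, regions[i], denominator = denominator)
    rows[[regions[i]]] <- data.frame(
      region = regions[i],
      rate = rs$slope * scale,
      lower = (rs$slope - 1.96 * rs$se) * scale,
      upper = (rs$slope + 1.96 * rs$se) * scale,
      p = 2 * stats::pnorm(-abs(rs$slope / rs$se)),
      rate_placebo = arm$rate_placebo,
      rate_treated = arm$rate_treated,
      interaction_p = arm$interaction_p,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out$q <- fdr_adjust(out$p)
  out$significant <- out$q < alpha
  out <- out[order(-abs(out$rate)), ]
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  attr(out, "denominator") <- denominator
  class(out) <- c("regional_result", "data.frame")
  out
}

#' Arm-specific regional atrophy rates
#'
#' One mixed model with arm-specific time slopes
#' (\code{volume ~ arm + visit_time:arm_factor + covariates + random
#' intercept and slope}) yields each arm's rate directly; the
#' group-by-time interaction Wald p-value comes from the equivalent
#' standard parameterization.
#'
#' @param cohort visit-level cohort; both arms must be present.
#' @param region region name (without \code{vol_} prefix).
#' @param denominator see [regional_rates()].
#' @return list with \code{rate_placebo}, \code{rate_treated} (\%/year),
#'   their \code{ci_placebo}/\code{ci_treated} 95\% intervals and
#'   \code{interaction_p}.
#' @export
arm_specific_rates <- function(cohort, region,
                               denominator = "cohort_baseline") {
  col <- paste0("vol_", region)
  if (!col %in% names(cohort)) stop("region column not found: ", col)
  if (length(unique(cohort$arm)) < 2) stop("both arms must be present")
  covs <- regional_covariates(cohort)
  d <- cohort[!is.na(cohort[[col]]), , drop = FALSE]
  d$arm_f <- factor(d$arm, levels = c(0, 1))
  rhs <- paste(c("arm_f", "visit_time:arm_f", covs), collapse = " + ")
  fml <- stats::as.formula(
    sprintf("%s ~ %s + (1 + visit_time | subject_id)", col, rhs))
  ctrl <- lme4::lmerControl(check.conv.singular = "ignore",
                            calc.derivs = FALSE)
  m <- suppressMessages(suppressWarnings(
    lme4::lmer(fml, data = d, REML = FALSE, control = ctrl)))
  est <- lme4::fixef(m)
  se <- sqrt(diag(as.matrix(stats::vcov(m))))
  nm0 <- grep("visit_time:arm_f0|arm_f0:visit_time", names(est), value = TRUE)
  nm1 <- grep("visit_time:arm_f1|arm_f1:visit_time", names(est), value = TRUE)
  s0 <- est[nm0]; se0 <- se[nm0]
  s1 <- est[nm1]; se1 <- se[nm1]
  base <- d[d$visit_time == 0, , drop = FALSE]
  denom <- mean(base[[col]], na.rm = TRUE)
  scale <- 100 / denom
  it <- fit_lmm(d, col, covariates = covs)$interaction
  list(rate_placebo = unname(s0) * scale,
       ci_placebo = unname(c(s0 - 1.96 * se0, s0 + 1.96 * se0)) * scale,
       rate_treated = unname(s1) * scale,
       ci_treated = unname(c(s1 - 1.96 * se1, s1 + 1.96 * se1)) * scale,
       interaction_p = if (nrow(it)) it$p[1] else NA_real_)
}

#' Benjamini--Hochberg false-discovery-rate adjustment
#'
#' The step-up procedure: with ordered p-values \eqn{p_{(1)} \le \dots \le
#' p_{(m)}}, \eqn{q_{(i)} = \min_{j \ge i} (m/j) p_{(j)}}, capped at 1.
#' Monotone in the ranked p-values and never smaller than the raw p.
#'
#' @param pvals numeric vector of p-values in [0, 1]; NAs propagate.
#' @return q-values in the original order.
#' @export
fdr_adjust <- function(pvals) {
  ok <- !is.na(pvals)
  p <- pvals[ok]
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  m <- length(p)
  q <- rep(NA_real_, length(pvals))
  if (m) {
    o <- order(p)
    adj <- pmin(cummin(rev(p[o] * m / seq_len(m))), 1)
    qq <- numeric(m)
    qq[o] <- rev(adj)
    q[ok] <- qq
  }
  q
}

#' Regional mediation of the treatment effect
#'
#' Annualizes the region's volume change and delegates to the Bayesian
#' mediation sampler with (treatment, regional annualized change,
#' outcome's annualized change).
#'
#' @param cohort visit-level cohort.
#' @param region region name (without \code{vol_} prefix).
#' @param outcome clinical outcome column (default \code{"EDSS"}).
#' @param ... passed to [mcmc_sample()] (\code{n_burn}, \code{n_keep},
#'   \code{chains}, \code{seed}).
#' @return a \code{"mediation_posterior"}.
#' @export
regional_mediation <- function(cohort, region, outcome = "EDSS", ...) {
  col <- paste0("vol_", region)
  if (!col %in% names(cohort)) stop("region column not found: ", col)
  if (!outcome %in% names(cohort)) stop("outcome not found: ", outcome)
  ct <- annualize(cohort, c(col, outcome))
  mcmc_sample(mediation_spec("treatment", col, outcome), ct, ...)
}

#' Write the regional table as CSV
#' @param x a \code{"regional_result"}.
#' @param path output file.
#' @export
write_regional_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}
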