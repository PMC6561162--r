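#' Annualized per-subject changes
#'
#' For each requested variable the annualized change is
#' \code{(year-2 value - baseline value) / 2}; if either visit value is
#' missing the change is missing and the subject is retained.  PBVC is 0 at
#' baseline by construction, so its annualized change is the year-2 value
#' halved, which the same formula delivers.  The result is the analysis
#' matrix of the multivariate (path-model) stage: one row per subject, a
#' \code{treatment} indicator, and one annualized-change column per
#' variable.
#'
#' @param cohort a long-format trial cohort with \code{visit_time} 0 and 2
#'   rows.
#' @param variables variables to annualize (must exist in the cohort).
#' @return data.frame of class \code{"change_table"} with columns
#'   \code{subject_id}, \code{treatment}, then one column per variable.
#' @export
annualize <- function(cohort, variables) {
  absent <- setdiff(variables, names(cohort))
  if (length(absent)) stop("variable(s) not in cohort: ",
                           paste(absent, collapse = ", "))
  if (!any(cohort$visit_time == 2))
    stop("cohort has no visit_time == 2 rows")
  b <- cohort[cohort$visit_time == 0, , drop = FALSE]
  y2 <- cohort[cohort$visit_time == 2, , drop = FALSE]
  ids <- b$subject_id
  m <- match(ids, y2$subject_id)
  out <- data.frame(subject_id = ids,
                    treatment = b$arm,
                    stringsAsFactors = FALSE)
  for (v in variables) {
    out[[v]] <- (y2[[v]][m] - b[[v]]) / 2
  }
  class(out) <- c("change_table", "data.frame")
  out
}

#' Write a change table as CSV
#' @param x a change table.
#' @param path output file.
#' @export
write_change_table <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' Longitudinal linear mixed model for one outcome
#'
#' Fits \code{outcome ~ time * group + covariates} with correlated random
#' intercept and slope per subject, by maximum likelihood (so that
#' likelihoods are comparable across fixed-effect structures), via
#' \pkg{lme4}.  The treatment contrast of interest is the Wald test of the
#' \code{group x time} interaction (difference in rates of change between
#' arms); p-values use the normal reference for the Wald statistic.  When
#' the random-effects covariance is singular the model is refitted with a
#' random intercept only, and flagged.
#'
#' @param data long-format visit-level data.
#' @param outcome outcome column name.
#' @param covariates optional character vector of additional fixed-effect
#'   columns.
#' @param group,time,subject column names (defaults \code{"arm"},
#'   \code{"visit_time"}, \code{"subject_id"}).
#' @return object of class \code{"lmm_fit"}: \code{$fixed} (data.frame of
#'   term, estimate, se, z, p), \code{$interaction} (the group-by-time
#'   row), \code{$varcomp} (random-effect SDs/correlation and residual
#'   SD), \code{$loglik}, \code{$converged}, \code{$singular_fallback},
#'   \code{$n_obs}, \code{$n_subjects} and the underlying \code{$model}.
#' @export
fit_lmm <- function(data, outcome, covariates = NULL,
                    group = "arm", time = "visit_time",
                    subject = "subject_id") {
  need <- c(outcome, covariates, group, time, subject)
  absent <- setdiff(need, names(data))
  if (length(absent)) stop("column(s) not in data: ",
                           paste(absent, collapse = ", "))
  if (!is.numeric(data[[outcome]])) stop("outcome must be numeric")
  data <- data[!is.na(data[[outcome]]), , drop = FALSE]
  rhs <- paste(c(sprintf("%s * %s", time, group), covariates),
               collapse = " + ")
  fml <- stats::as.formula(sprintf("%s ~ %s + (1 + %s | %s)",
                                   outcome, rhs, time, subject))
  ctrl <- lme4::lmerControl(check.conv.singular = "ignore",
                            calc.derivs = FALSE)
  fit <- tryCatch(suppressMessages(suppressWarnings(
    lme4::lmer(fml, data = data, REML = FALSE, control = ctrl))),
    error = function(e) NULL)
  singular_fallback <- FALSE
  # a singular (or numerically failed) random-slope fit falls back to a
  # random intercept only, flagged rather than silent
  if (is.null(fit) || lme4::isSingular(fit, tol = 1e-4)) {
    fml2 <- stats::as.formula(sprintf("%s ~ %s + (1 | %s)",
                                      outcome, rhs, subject))
    fit2 <- tryCatch(suppressMessages(suppressWarnings(
      lme4::lmer(fml2, data = data, REML = FALSE, control = ctrl))),
      error = function(e) NULL)
    if (!is.null(fit2)) {
      fit <- fit2
      singular_fallback <- TRUE
    } else if (is.null(fit)) {
      stop("mixed model failed for outcome '", outcome,
           "' (random slope and random intercept fits both failed)")
    }
  }
  conv_msgs <- fit@optinfo$conv$lme4$messages
  converged <- is.null(conv_msgs) || length(conv_msgs) == 0L

  est <- lme4::fixef(fit)
  vc <- as.matrix(stats::vcov(fit))
  se <- sqrt(diag(vc))
  z <- est / se
  fixed <- data.frame(term = names(est), estimate = unname(est),
                      se = unname(se), z = unname(z),
                      p = unname(2 * stats::pnorm(-abs(z))),
                      stringsAsFactors = FALSE)
  int_term <- grep(paste0("^", time, ":", group, "|^", group, ":", time),
                   fixed$term, value = TRUE)
  interaction <- fixed[fixed$term %in% int_term, , drop = FALSE]

  vcmat <- lme4::VarCorr(fit)
  rs <- as.data.frame(vcmat)
  structure(list(
    fixed = fixed,
    interaction = interaction,
    varcomp = rs,
    loglik = as.numeric(stats::logLik(fit)),
    converged = converged,
    conv_messages = conv_msgs,
    singular_fallback = singular_fallback,
    n_obs = nrow(data),
    n_subjects = length(unique(data[[subject]])),
    model = fit), class = "lmm_fit")
}

#' @export
print.lmm_fit <- function(x, digits = 4, ...) {
  cat("Linear mixed model (ML):", x$n_obs, "observations,",
      x$n_subjects, "subjects\n")
  if (!x$converged) cat("WARNING: optimizer reported non-convergence\n")
  if (x$singular_fallback)
    cat("NOTE: singular random slope; refitted with random intercept only\n")
  fx <- x$fixed
  fx[-1] <- lapply(fx[-1], signif, digits)
  print(fx, row.names = FALSE)
  invisible(x)
}

#' Univariate mixed-effects variable screening
#'
#' The variable-selection stage: each candidate outcome is fitted with
#' [fit_lmm()] on the visit-level cohort, and variables whose
#' group-by-time (arm difference in rate of change) Wald p-value is below
#' \code{alpha} are selected for the multivariate stage.
#'
#' @param cohort visit-level trial cohort.
#' @param candidates character vector of candidate outcome columns.
#' @param alpha selection threshold (default 0.05).
#' @param covariates optional nuisance covariates passed to [fit_lmm()].
#' @return object of class \code{"screen_result"}: data.frame with columns
#'   \code{variable}, \code{estimate} (interaction coefficient),
#'   \code{se}, \code{p}, \code{selected}, plus attribute
#'   \code{"selected"} with the selected names.
#' @export
screen_variables <- function(cohort, candidates, alpha = 0.05,
                             covariates = NULL) {
  if (!length(candidates)) stop("empty candidate list")
  rows <- lapply(candidates, function(v) {
    f <- fit_lmm(cohort, v, covariates = covariates)
    it <- f$interaction
    data.frame(variable = v,
               estimate = if (nrow(it)) it$estimate[1] else NA_real_,
               se = if (nrow(it)) it$se[1] else NA_real_,
               p = if (nrow(it)) it$p[1] else NA_real_,
               converged = f$converged,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$selected <- !is.na(out$p) & out$p < alpha
  attr(out, "selected") <- out$variable[out$selected]
  attr(out, "alpha") <- alpha
  class(out) <- c("screen_result", "data.frame")
  out
}

#' Write a screening report as JSON
#' @param x a \code{"screen_result"}.
#' @param path output file.
#' @export
write_screen_json <- function(x, path) {
  jsonlite::write_json(
    list(alpha = attr(x, "alpha"),
         selected = attr(x, "selected"),
         table = as.data.frame(x)),
    path, auto_unbox = TRUE, digits = NA, dataframe = "rows",
    pretty = TRUE)
  invisible(path)
}
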