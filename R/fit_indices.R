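#' Fit indices of a path model
#'
#' Computes the likelihood-ratio statistic against the saturated model and
#' the standard SEM fit measures:
#' \itemize{
#'   \item \eqn{T = 2(\ell_{sat} - \ell_M)} with
#'     \eqn{df = p(p+3)/2 - k} for \eqn{p} observed variables with mean
#'     structure and \eqn{k} free parameters;
#'   \item CFI, against the uncorrelated-variables baseline (free means and
#'     variances only): \eqn{1 - \max(T_M - df_M, 0) /
#'     \max(T_B - df_B, T_M - df_M, 0)} (acceptable fit > 0.95);
#'   \item RMSEA \eqn{= \sqrt{\max(T - df, 0)/(df \cdot N)}} with a 90\%
#'     confidence interval by noncentral-chi-square inversion (good fit
#'     < 0.06); N, not N-1, in the denominator;
#'   \item SRMR, the root-mean-square of correlation-scale covariance
#'     residuals between the saturated (ML sample) and model-implied
#'     covariances over unique elements (good fit < 0.08); mean residuals
#'     are not included;
#'   \item AIC \eqn{= -2\ell + 2k} and BIC \eqn{= -2\ell + k \ln N}.
#' }
#' The saturated and baseline models are themselves fitted by FIML (as a
#' complete recursive system and an edge-free system), so the indices are
#' well defined under missing data.
#'
#' @param fit a \code{"path_fit"}.
#' @param data the data the model was fitted to.
#' @return object of class \code{"fit_indices"}: list with \code{T},
#'   \code{df}, \code{CFI}, \code{SRMR}, \code{RMSEA},
#'   \code{RMSEA_ci} (90\% CI), \code{AIC}, \code{BIC}, \code{npar},
#'   \code{n}, \code{loglik_sat}, \code{loglik_baseline} and a
#'   \code{saturated} flag.
#' @export
fit_indices <- function(fit, data) {
  spec <- fit$spec
  N <- fit$n
  k <- fit$npar
  p <- length(spec$variables)
  df <- p * (p + 3) / 2 - k

  sat <- fit_path_model(saturated_spec(spec), data, robust = FALSE)
  base <- fit_path_model(baseline_spec(spec), data, robust = FALSE)
  ll_sat <- sat$loglik
  ll_base <- base$loglik

  T_M <- max(2 * (ll_sat - fit$loglik), 0)
  df_B <- p * (p + 3) / 2 - base$npar
  T_B <- max(2 * (ll_sat - ll_base), 0)

  saturated <- df <= 0
  if (saturated) {
    cfi <- 1
    rmsea <- 0
    rmsea_ci <- c(0, 0)
  } else {
    num <- max(T_M - df, 0)
    den <- max(T_B - df_B, T_M - df, 0)
    cfi <- if (den == 0) 1 else 1 - num / den
    rmsea <- sqrt(max(T_M - df, 0) / (df * N))
    rmsea_ci <- rmsea_ci90(T_M, df, N)
  }

  mom_sat <- implied_moments(sat$spec, sat$params)
  mom_fit <- implied_moments(spec, fit$params)
  v <- spec$variables
  S <- mom_sat$sigma[v, v]
  Sig <- mom_fit$sigma[v, v]
  d <- sqrt(diag(S))
  res <- (S - Sig) / tcrossprod(d)
  srmr <- sqrt(mean(res[upper.tri(res, diag = TRUE)]^2))

  structure(list(T = T_M, df = df, CFI = cfi, SRMR = srmr,
                 RMSEA = rmsea, RMSEA_ci = rmsea_ci,
                 AIC = -2 * fit$loglik + 2 * k,
                 BIC = -2 * fit$loglik + k * log(N),
                 npar = k, n = N,
                 loglik = fit$loglik, loglik_sat = ll_sat,
                 loglik_baseline = ll_base, saturated = saturated),
            class = "fit_indices")
}

# 90% CI for RMSEA by inverting the noncentral chi-square distribution
rmsea_ci90 <- function(T, df, N) {
  lo_ncp <- ncp_solve(T, df, 0.95)
  hi_ncp <- ncp_solve(T, df, 0.05)
  c(sqrt(max(lo_ncp, 0) / (df * N)), sqrt(max(hi_ncp, 0) / (df * N)))
}

# solve pchisq(T, df, ncp) = prob for ncp >= 0; 0 when no root exists
ncp_solve <- function(T, df, prob) {
  if (stats::pchisq(T, df, ncp = 0) < prob) return(0)
  upper <- max(T * 2, df * 2, 10)
  while (stats::pchisq(T, df, ncp = upper) > prob && upper < 1e8) {
    upper <- upper * 2
  }
  stats::uniroot(function(l) stats::pchisq(T, df, ncp = l) - prob,
                 lower = 0, upper = upper, tol = 1e-8)$root
}

#' @export
print.fit_indices <- function(x, digits = 3, ...) {
  cat(sprintf("chi-square T = %.3f on df = %d (n = %d, k = %d)\n",
              x$T, as.integer(x$df), x$n, x$npar))
  cat(sprintf("CFI = %.3f  SRMR = %.3f  RMSEA = %.3f (90%% CI %.3f, %.3f)\n",
              x$CFI, x$SRMR, x$RMSEA, x$RMSEA_ci[1], x$RMSEA_ci[2]))
  cat(sprintf("AIC = %.1f  BIC = %.1f\n", x$AIC, x$BIC))
  if (x$saturated) cat("NOTE: model is saturated (df <= 0)\n")
  invisible(x)
}
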