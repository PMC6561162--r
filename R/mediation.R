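# Three-variable Bayesian mediation: treatment -> mediator -> outcome plus
# a direct treatment -> outcome path.  The model is two linear regressions
#   mediator ~ 1 + treatment              (coefficient a)
#   outcome  ~ 1 + treatment + mediator   (coefficients c', b)
# sampled by a Gibbs sampler with conjugate full conditionals under flat
# priors on coefficients and a uniform prior on the log residual SDs.

#' Specify a three-variable mediation model
#'
#' @param treatment,mediator,outcome distinct column names; the treatment
#'   must be binary.
#' @return list of class \code{"mediation_spec"}.
#' @export
mediation_spec <- function(treatment = "treatment", mediator, outcome) {
  v <- c(treatment, mediator, outcome)
  if (anyDuplicated(v)) stop("treatment, mediator and outcome must be distinct")
  structure(list(treatment = treatment, mediator = mediator,
                 outcome = outcome, logsd_bounds = c(-10, 10)),
            class = "mediation_spec")
}

# one Gibbs chain for one linear regression; returns draws of beta and sigma.
# Flat prior on beta; p(sigma^2) proportional to 1/sigma^2 (uniform on log
# sigma), truncated to exp(bounds).
gibbs_lm_chain <- function(X, y, n_iter, beta_init, logsd_bounds) {
  XtX <- crossprod(X)
  U <- chol(XtX)
  bhat <- backsolve(U, backsolve(U, crossprod(X, y), transpose = TRUE))
  n <- length(y)
  k <- ncol(X)
  rss_hat <- sum((y - X %*% bhat)^2)
  lo <- exp(2 * logsd_bounds[1]); hi <- exp(2 * logsd_bounds[2])
  beta <- beta_init
  B <- matrix(NA_real_, n_iter, k)
  S <- numeric(n_iter)
  for (it in seq_len(n_iter)) {
    zq <- U %*% (beta - bhat)
    rss <- rss_hat + sum(zq^2)
    sigma2 <- (rss / 2) / stats::rgamma(1L, n / 2)
    sigma2 <- min(max(sigma2, lo), hi)
    beta <- bhat + backsolve(U, stats::rnorm(k)) * sqrt(sigma2)
    B[it, ] <- beta
    S[it] <- sqrt(sigma2)
  }
  list(beta = B, sigma = S)
}

# split-Rhat over a draws matrix (iterations x chains)
split_rhat <- function(draws) {
  n <- nrow(draws)
  half <- floor(n / 2)
  seqs <- cbind(draws[seq_len(half), , drop = FALSE],
                draws[(n - half + 1):n, , drop = FALSE])
  m <- ncol(seqs)
  nn <- nrow(seqs)
  means <- colMeans(seqs)
  vars <- apply(seqs, 2, stats::var)
  B <- nn * stats::var(means)
  W <- mean(vars)
  if (W <= 0) return(1)
  sqrt(((nn - 1) / nn * W + B / nn) / W)
}

# crude effective sample size: pooled draws, initial positive autocorrelations
ess_basic <- function(x) {
  n <- length(x)
  if (stats::sd(x) == 0) return(n)
  ac <- stats::acf(x, lag.max = min(100, n - 1), plot = FALSE)$acf[-1]
  pos <- which(ac < 0.05)
  cut <- if (length(pos)) pos[1] - 1 else length(ac)
  denom <- 1 + 2 * sum(ac[seq_len(cut)])
  n / max(denom, 1)
}

#' Gibbs sampler for a three-variable mediation model
#'
#' Samples the two regressions jointly (their posteriors factorize under
#' flat priors, and the Gibbs full conditionals are exact
#' normal--inverse-gamma steps), on the complete cases of the three
#' variables (listwise deletion, counted).  Four chains with jittered
#' starts are run by default; a split-Rhat above 1.01 on any coefficient
#' flags the result as unreliable rather than failing.
#'
#' @param spec a [mediation_spec()].
#' @param data a change table (or any data.frame) with the three columns.
#' @param n_burn discarded warm-up draws per chain (default 4000).
#' @param n_keep total retained draws pooled across chains (default
#'   10000; must be divisible by \code{chains}).
#' @param chains number of chains (default 4).
#' @param seed integer seed; all draws are deterministic given it.
#' @return object of class \code{"mediation_posterior"}: \code{$draws}
#'   (data.frame with chain, a, b, cprime, sigma_m, sigma_y, indirect,
#'   total, proportion), \code{$summary} (per-quantity posterior median,
#'   95\% credible interval, significance flag by the CI-excludes-zero
#'   rule), \code{$rhat}, \code{$ess}, \code{$ok}, \code{$n_used},
#'   \code{$n_dropped}, and the sampler settings.
#' @export
mcmc_sample <- function(spec, data, n_burn = 4000, n_keep = 10000,
                        chains = 4, seed = 1) {
  stopifnot(inherits(spec, "mediation_spec"))
  cols <- c(spec$treatment, spec$mediator, spec$outcome)
  absent <- setdiff(cols, names(data))
  if (length(absent)) stop("column(s) not in data: ",
                           paste(absent, collapse = ", "))
  if (n_keep %% chains != 0)
    stop("n_keep must be divisible by the number of chains")
  d <- data[stats::complete.cases(data[, cols]), cols, drop = FALSE]
  n_dropped <- nrow(data) - nrow(d)
  if (nrow(d) < 10) stop("fewer than 10 complete cases on the three variables")
  tr <- d[[spec$treatment]]
  if (length(unique(tr)) != 2)
    stop("treatment must take exactly two values in the complete cases")
  for (cl in cols) {
    if (stats::sd(d[[cl]]) == 0) stop("variable '", cl, "' is constant")
  }
  med <- d[[spec$mediator]]
  out <- d[[spec$outcome]]
  Xm <- cbind(1, tr)
  Xy <- cbind(1, tr, med)

  set.seed(seed)
  keep_per <- n_keep %/% chains
  n_iter <- n_burn + keep_per
  ols_m <- stats::lm.fit(Xm, med)$coefficients
  ols_y <- stats::lm.fit(Xy, out)$coefficients
  draws <- vector("list", chains)
  for (ch in seq_len(chains)) {
    jit <- if (ch == 1) 0 else stats::rnorm(1, 0, 0.5)
    cm <- gibbs_lm_chain(Xm, med, n_iter, ols_m + jit, spec$logsd_bounds)
    cy <- gibbs_lm_chain(Xy, out, n_iter, ols_y + jit, spec$logsd_bounds)
    keep <- (n_burn + 1):n_iter
    draws[[ch]] <- data.frame(
      chain = ch,
      a = cm$beta[keep, 2],
      cprime = cy$beta[keep, 2],
      b = cy$beta[keep, 3],
      sigma_m = cm$sigma[keep],
      sigma_y = cy$sigma[keep])
  }
  dd <- do.call(rbind, draws)
  dd$indirect <- dd$a * dd$b
  dd$total <- dd$indirect + dd$cprime
  dd$proportion <- ifelse(abs(dd$total) > 1e-12, dd$indirect / dd$total, NA)

  pars <- c("a", "b", "cprime", "indirect", "total")
  rhat <- vapply(pars, function(p)
    split_rhat(matrix(dd[[p]], ncol = chains)), 0)
  ess <- vapply(pars, function(p) ess_basic(dd[[p]]), 0)
  ok <- all(rhat < 1.01)

  summ <- do.call(rbind, lapply(c(pars, "sigma_m", "sigma_y"), function(p) {
    q <- stats::quantile(dd[[p]], c(0.025, 0.5, 0.975), names = FALSE)
    data.frame(quantity = p, median = q[2], lower = q[1], upper = q[3],
               significant = q[1] > 0 | q[3] < 0,
               stringsAsFactors = FALSE)
  }))
  structure(list(
    spec = spec, draws = dd, summary = summ,
    rhat = rhat, ess = ess, ok = ok,
    n_used = nrow(d), n_dropped = n_dropped,
    n_burn = n_burn, n_keep = n_keep, chains = chains, seed = seed,
    logsd_bounds = spec$logsd_bounds),
    class = "mediation_posterior")
}

#' Direct, indirect, total effects and proportion mediated
#'
#' Derives the mediation decomposition from a posterior: indirect draws
#' are \code{a * b}, total draws \code{a * b + c'}.  The headline
#' proportion mediated is the ratio of posterior medians
#' (median indirect / median total); the posterior of the per-draw ratio
#' is reported alongside, since the two summaries differ whenever the
#' total-effect posterior is wide.  Significance uses the 95\% credible
#' interval excludes-zero rule.  When the posterior median total effect is
#' within 1e-8 of zero the proportion is undefined and flagged.
#'
#' @param posterior a \code{"mediation_posterior"}.
#' @return list of class \code{"mediation_effects"} with \code{$summary}
#'   (direct, indirect, total rows with medians, CIs, significance),
#'   \code{$proportion_mediated} (ratio of medians),
#'   \code{$proportion_posterior} (median and CI of per-draw ratio),
#'   \code{$proportion_defined}.
#' @export
mediation_effects <- function(posterior) {
  dd <- posterior$draws
  qs <- function(x) stats::quantile(x, c(0.025, 0.5, 0.975), names = FALSE)
  rows <- list(direct = qs(dd$cprime), indirect = qs(dd$indirect),
               total = qs(dd$total))
  summ <- do.call(rbind, lapply(names(rows), function(nm) {
    q <- rows[[nm]]
    data.frame(effect = nm, median = q[2], lower = q[1], upper = q[3],
               significant = q[1] > 0 | q[3] < 0, stringsAsFactors = FALSE)
  }))
  med_tot <- rows$total[2]
  med_ind <- rows$indirect[2]
  defined <- abs(med_tot) >= 1e-8
  prop <- if (defined) med_ind / med_tot else NA_real_
  ratio <- dd$proportion[!is.na(dd$proportion)]
  prop_post <- if (length(ratio)) qs(ratio) else rep(NA_real_, 3)
  structure(list(
    summary = summ,
    proportion_mediated = prop,
    proportion_posterior = c(lower = prop_post[1], median = prop_post[2],
                             upper = prop_post[3]),
    proportion_defined = defined),
    class = "mediation_effects")
}

#' @export
print.mediation_posterior <- function(x, digits = 3, ...) {
  cat("Bayesian mediation:", x$spec$treatment, "->", x$spec$mediator,
      "->", x$spec$outcome, "\n")
  cat(sprintf("%d chains, %d burn-in + %d retained; n = %d (%d dropped)\n",
              x$chains, x$n_burn, x$n_keep, x$n_used, x$n_dropped))
  if (!x$ok) cat("WARNING: split-Rhat >= 1.01; treat results with caution\n")
  s <- x$summary
  s[2:4] <- lapply(s[2:4], signif, digits)
  print(s, row.names = FALSE)
  invisible(x)
}

#' @export
print.mediation_effects <- function(x, digits = 3, ...) {
  s <- x$summary
  s[2:4] <- lapply(s[2:4], signif, digits)
  print(s, row.names = FALSE)
  if (x$proportion_defined) {
    cat(sprintf("proportion mediated (ratio of medians): %.1f%%\n",
                100 * x$proportion_mediated))
    cat(sprintf("posterior of ratio: %.1f%% (95%% CI %.1f%%, %.1f%%)\n",
                100 * x$proportion_posterior["median"],
                100 * x$proportion_posterior["lower"],
                100 * x$proportion_posterior["upper"]))
  } else {
    cat("proportion mediated undefined (total effect ~ 0)\n")
  }
  invisible(x)
}

#' Export posterior draws to CSV / summaries to JSON
#' @param posterior a \code{"mediation_posterior"}.
#' @param path output file.
#' @export
write_mediation_draws <- function(posterior, path) {
  utils::write.csv(posterior$draws, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_mediation_draws
#' @export
write_mediation_json <- function(posterior, path) {
  eff <- mediation_effects(posterior)
  jsonlite::write_json(
    list(model = unclass(posterior$spec),
         settings = list(n_burn = posterior$n_burn,
                         n_keep = posterior$n_keep,
                         chains = posterior$chains, seed = posterior$seed,
                         logsd_bounds = posterior$logsd_bounds),
         n_used = posterior$n_used, n_dropped = posterior$n_dropped,
         rhat = as.list(posterior$rhat), ok = posterior$ok,
         summary = posterior$summary,
         effects = eff$summary,
         proportion_mediated = eff$proportion_mediated,
         proportion_posterior = as.list(eff$proportion_posterior)),
    path, auto_unbox = TRUE, digits = NA, dataframe = "rows", pretty = TRUE)
  invisible(path)
}
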