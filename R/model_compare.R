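#' Akaike / Schwarz weights from information criteria
#'
#' Normalized model probabilities \eqn{w_m = \exp(-\Delta_m/2) / \sum_j
#' \exp(-\Delta_j/2)} with \eqn{\Delta_m = IC_m - \min_j IC_j}.  Applied to
#' AIC values these are Akaike weights; applied to BIC values, Schwarz
#' weights.  Computed on the log scale, so differences of hundreds of IC
#' units remain numerically stable.
#'
#' @param ics numeric vector (length >= 2) of AIC or BIC values.
#' @return numeric vector of weights summing to 1, with names preserved.
#' @export
akaike_weights <- function(ics) {
  if (length(ics) < 2L) stop("need at least 2 information criteria")
  if (any(!is.finite(ics))) stop("non-finite information criterion")
  delta <- ics - min(ics)
  lw <- -delta / 2
  w <- exp(lw - max(lw))
  out <- w / sum(w)
  names(out) <- names(ics)
  out
}

#' Compare candidate path models on one data set
#'
#' Fits every candidate by FIML, computes AIC and BIC, the Akaike and
#' Schwarz weights, and all pairwise evidence ratios
#' \eqn{w_i / w_j} (the factor by which model \eqn{i} is more probable
#' than model \eqn{j} given the data).
#'
#' @param specs named list of path-model specs (all over the same data
#'   columns).
#' @param data a change table containing the model variables.
#' @param indices also compute CFI/SRMR/RMSEA per model (default TRUE).
#' @return object of class \code{"model_comparison"}: \code{$table}
#'   (model, loglik, npar, AIC, BIC, akaike_weight, schwarz_weight, CFI,
#'   SRMR, RMSEA), \code{$evidence_akaike} and \code{$evidence_schwarz}
#'   (ratio matrices), \code{$fits} (the path fits), \code{$winner}
#'   (highest Akaike weight).
#' @export
compare_models <- function(specs, data, indices = TRUE) {
  if (is.null(names(specs)) || any(names(specs) == ""))
    names(specs) <- paste0("model_", seq_along(specs))
  fits <- vector("list", length(specs))
  names(fits) <- names(specs)
  for (nm in names(specs)) {
    fits[[nm]] <- tryCatch(
      fit_path_model(specs[[nm]], data, robust = FALSE),
      error = function(e) stop("model '", nm, "' failed to fit: ",
                               conditionMessage(e)))
    if (!fits[[nm]]$converged)
      stop("model '", nm, "' did not converge; comparison aborted")
  }
  tab <- data.frame(
    model = names(specs),
    loglik = vapply(fits, function(f) f$loglik, 0),
    npar = vapply(fits, function(f) as.integer(f$npar), 0L),
    n = vapply(fits, function(f) as.integer(f$n), 0L),
    stringsAsFactors = FALSE)
  tab$AIC <- -2 * tab$loglik + 2 * tab$npar
  tab$BIC <- -2 * tab$loglik + tab$npar * log(tab$n)
  tab$akaike_weight <- akaike_weights(stats::setNames(tab$AIC, tab$model))
  tab$schwarz_weight <- akaike_weights(stats::setNames(tab$BIC, tab$model))
  if (indices) {
    fi <- lapply(fits, fit_indices, data = data)
    tab$CFI <- vapply(fi, function(x) x$CFI, 0)
    tab$SRMR <- vapply(fi, function(x) x$SRMR, 0)
    tab$RMSEA <- vapply(fi, function(x) x$RMSEA, 0)
  }
  structure(list(
    table = tab,
    evidence_akaike = outer(tab$akaike_weight, tab$akaike_weight, "/"),
    evidence_schwarz = outer(tab$schwarz_weight, tab$schwarz_weight, "/"),
    fits = fits,
    winner = tab$model[which.max(tab$akaike_weight)]),
    class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, digits = 3, ...) {
  cat("Model comparison (", nrow(x$table), " candidates)\n", sep = "")
  tab <- x$table
  num <- vapply(tab, is.numeric, TRUE)
  tab[num] <- lapply(tab[num], function(v) signif(v, digits + 2))
  print(tab, row.names = FALSE)
  cat("winner by Akaike weight:", x$winner, "\n")
  invisible(x)
}

#' Bootstrap distributions of fit measures
#'
#' Nonparametric case resampling: subjects (rows of the change table) are
#' resampled with replacement \code{n_boot} times; the model is refitted on
#' each replicate and CFI, SRMR, RMSEA, AIC and BIC recorded.  The median
#' and 2.5/97.5 percentiles summarize each measure.  Replicates whose refit
#' fails to converge are dropped and counted; more than
#' \code{max_fail_frac} failures is an error unless
#' \code{allow_high_failure = TRUE}.
#'
#' @param spec a path-model spec.
#' @param data a change table.
#' @param n_boot number of bootstrap replicates (the reference analysis
#'   uses 1000).
#' @param seed integer seed controlling the resample indices.
#' @param max_fail_frac maximum tolerated fraction of non-converged
#'   replicates (default 0.1).
#' @param allow_high_failure downgrade the failure-rate error to a warning.
#' @return object of class \code{"bootstrap_fit"}: \code{$summary}
#'   (measure, median, lower, upper), \code{$replicates} (matrix of
#'   per-replicate measures), \code{$n_boot}, \code{$n_failed},
#'   \code{$seed}.
#' @export
bootstrap_fit_measures <- function(spec, data, n_boot = 1000, seed = 1,
                                   max_fail_frac = 0.1,
                                   allow_high_failure = FALSE) {
  if (n_boot < 1) stop("n_boot must be >= 1")
  set.seed(seed)
  n <- nrow(data)
  measures <- c("CFI", "SRMR", "RMSEA", "AIC", "BIC")
  reps <- matrix(NA_real_, n_boot, length(measures),
                 dimnames = list(NULL, measures))
  n_failed <- 0L
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    res <- tryCatch({
      f <- fit_path_model(spec, data[idx, , drop = FALSE], robust = FALSE)
      fi <- fit_indices(f, data[idx, , drop = FALSE])
      c(fi$CFI, fi$SRMR, fi$RMSEA, fi$AIC, fi$BIC)
    }, error = function(e) NULL)
    if (is.null(res)) n_failed <- n_failed + 1L else reps[b, ] <- res
  }
  if (n_failed / n_boot > max_fail_frac) {
    msg <- sprintf("%d of %d bootstrap replicates failed to converge",
                   n_failed, n_boot)
    if (allow_high_failure) warning(msg) else stop(msg)
  }
  ok <- stats::complete.cases(reps)
  summ <- data.frame(
    measure = measures,
    median = apply(reps[ok, , drop = FALSE], 2, stats::median),
    lower = apply(reps[ok, , drop = FALSE], 2, stats::quantile, probs = 0.025),
    upper = apply(reps[ok, , drop = FALSE], 2, stats::quantile, probs = 0.975),
    row.names = NULL)
  structure(list(summary = summ, replicates = reps, n_boot = n_boot,
                 n_failed = n_failed, seed = seed),
            class = "bootstrap_fit")
}

#' @export
print.bootstrap_fit <- function(x, digits = 3, ...) {
  cat("Bootstrap fit measures:", x$n_boot, "replicates,",
      x$n_failed, "failed\n")
  s <- x$summary
  s[-1] <- lapply(s[-1], signif, digits + 2)
  print(s, row.names = FALSE)
  invisible(x)
}
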