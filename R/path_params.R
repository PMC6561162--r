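#' Parameters of a recursive path model
#'
#' Holds the free parameters of a \code{"path_model_spec"}: the coefficient
#' matrix B (entry \code{B[to, from]} per edge), intercepts and residual
#' variances of the endogenous variables, and free means and covariance of
#' the exogenous block.
#'
#' @param spec a path-model spec.
#' @param coefficients named numeric vector of edge coefficients, keyed
#'   \code{"from->to"}; missing edges default to 0.
#' @param intercepts named numeric over endogenous variables (default 0).
#' @param residual_sd named numeric of residual standard deviations over
#'   endogenous variables (default 1).
#' @param exo_mean named numeric over exogenous variables (default 0).
#' @param exo_cov covariance matrix of the exogenous block (default identity).
#' @return an object of class \code{"path_params"}.
#' @export
path_params <- function(spec, coefficients = NULL, intercepts = NULL,
                        residual_sd = NULL, exo_mean = NULL, exo_cov = NULL) {
  v <- spec$variables
  p <- length(v)
  endo <- spec$endogenous
  exo <- spec$exogenous
  B <- matrix(0, p, p, dimnames = list(v, v))
  if (!is.null(coefficients)) {
    keys <- edge_keys(spec)
    unknown <- setdiff(names(coefficients), keys)
    if (length(unknown)) stop("coefficients for edges not in spec: ",
                              paste(unknown, collapse = ", "))
    for (k in names(coefficients)) {
      ft <- strsplit(k, "->", fixed = TRUE)[[1]]
      B[ft[2], ft[1]] <- coefficients[[k]]
    }
  }
  alpha <- stats::setNames(rep(0, length(endo)), endo)
  if (!is.null(intercepts)) alpha[names(intercepts)] <- intercepts
  psi_sd <- stats::setNames(rep(1, length(endo)), endo)
  if (!is.null(residual_sd)) {
    if (any(residual_sd < 0)) stop("residual_sd must be >= 0")
    psi_sd[names(residual_sd)] <- residual_sd
  }
  mx <- stats::setNames(rep(0, length(exo)), exo)
  if (!is.null(exo_mean)) mx[names(exo_mean)] <- exo_mean
  if (is.null(exo_cov)) {
    exo_cov <- diag(length(exo))
    dimnames(exo_cov) <- list(exo, exo)
  }
  structure(list(spec = spec, B = B, alpha = alpha, psi_sd = psi_sd,
                 exo_mean = mx, exo_cov = exo_cov),
            class = "path_params")
}

#' Edge keys of a spec, in edge order
#' @keywords internal
edge_keys <- function(spec) {
  paste(spec$edges$from, spec$edges$to, sep = "->")
}

#' Model-implied moments of a path model
#'
#' With all variables stacked in spec order, the reduced form of the linear
#' system \eqn{y = \alpha^* + B y + \epsilon} gives
#' \deqn{\mu = (I - B)^{-1} \alpha^*, \quad
#'       \Sigma = (I - B)^{-1} \Psi^* (I - B)^{-T},}
#' where \eqn{\Psi^*} carries the exogenous covariance block and the
#' diagonal endogenous residual variances, and \eqn{\alpha^*} the exogenous
#' means and endogenous intercepts.  For an acyclic B, \eqn{I - B} is
#' always invertible.
#'
#' @param spec a path-model spec.
#' @param params a \code{"path_params"} object for that spec.
#' @return list with \code{mu} (named vector) and \code{sigma}
#'   (named covariance matrix), both over \code{spec$variables}.
#' @export
implied_moments <- function(spec, params) {
  v <- spec$variables
  p <- length(v)
  B <- params$B[v, v, drop = FALSE]
  astar <- stats::setNames(rep(0, p), v)
  astar[names(params$exo_mean)] <- params$exo_mean
  astar[names(params$alpha)] <- params$alpha
  psistar <- matrix(0, p, p, dimnames = list(v, v))
  exo <- spec$exogenous
  psistar[exo, exo] <- params$exo_cov[exo, exo]
  diag(psistar)[spec$endogenous] <- params$psi_sd[spec$endogenous]^2
  IB <- diag(p) - B
  inv <- solve(IB)
  mu <- drop(inv %*% astar)
  sigma <- inv %*% psistar %*% t(inv)
  sigma <- (sigma + t(sigma)) / 2
  names(mu) <- v
  dimnames(sigma) <- list(v, v)
  list(mu = mu, sigma = sigma)
}

# ---- internal parameter vector packing --------------------------------------
# theta layout: exo means | exo Cholesky (lower tri, log diagonal) |
#               endogenous intercepts | edge coefficients | log residual SDs

pack_index <- function(spec) {
  q <- length(spec$exogenous)
  e <- length(spec$endogenous)
  m <- nrow(spec$edges)
  nchol <- as.integer(q * (q + 1L) / 2L)
  i <- 0L
  idx <- list(
    exo_mean = i + seq_len(q)); i <- i + q
  idx$exo_chol <- i + seq_len(nchol); i <- i + nchol
  idx$alpha <- i + seq_len(e); i <- i + e
  idx$beta <- i + seq_len(m); i <- i + m
  idx$log_psi <- i + seq_len(e); i <- i + e
  idx$n <- i
  idx
}

pack_params <- function(params) {
  spec <- params$spec
  idx <- pack_index(spec)
  theta <- numeric(idx$n)
  theta[idx$exo_mean] <- params$exo_mean[spec$exogenous]
  L <- t(chol(params$exo_cov[spec$exogenous, spec$exogenous, drop = FALSE]))
  ltri <- which(lower.tri(L, diag = TRUE), arr.ind = TRUE)
  vals <- L[ltri]
  diag_pos <- ltri[, 1] == ltri[, 2]
  vals[diag_pos] <- log(vals[diag_pos])
  theta[idx$exo_chol] <- vals
  theta[idx$alpha] <- params$alpha[spec$endogenous]
  if (length(idx$beta)) {
    theta[idx$beta] <- mapply(function(f, t) params$B[t, f],
                              spec$edges$from, spec$edges$to)
  }
  theta[idx$log_psi] <- log(pmax(params$psi_sd[spec$endogenous], 1e-8))
  theta
}

unpack_params <- function(spec, theta) {
  idx <- pack_index(spec)
  q <- length(spec$exogenous)
  L <- matrix(0, q, q)
  ltri <- which(lower.tri(L, diag = TRUE), arr.ind = TRUE)
  vals <- theta[idx$exo_chol]
  diag_pos <- ltri[, 1] == ltri[, 2]
  vals[diag_pos] <- exp(vals[diag_pos])
  L[ltri] <- vals
  exo_cov <- L %*% t(L)
  dimnames(exo_cov) <- list(spec$exogenous, spec$exogenous)
  coefs <- NULL
  if (length(idx$beta)) {
    coefs <- stats::setNames(theta[idx$beta], edge_keys(spec))
  }
  path_params(
    spec,
    coefficients = coefs,
    intercepts = stats::setNames(theta[idx$alpha], spec$endogenous),
    residual_sd = stats::setNames(exp(theta[idx$log_psi]), spec$endogenous),
    exo_mean = stats::setNames(theta[idx$exo_mean], spec$exogenous),
    exo_cov = exo_cov)
}

#' Count of free parameters of a spec (means, variances/covariances, edges)
#' @keywords internal
n_free_params <- function(spec) {
  q <- length(spec$exogenous)
  e <- length(spec$endogenous)
  as.integer(q + q * (q + 1L) / 2L + 2L * e + nrow(spec$edges))
}
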