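#' Specify a recursive path model
#'
#' A path model is a system of linear regressions over observed variables,
#' encoded as a directed acyclic graph: each arrow \code{from -> to} is a
#' regression coefficient of \code{to} on \code{from}.  Exogenous variables
#' (at least the treatment indicator) have free means and covariances;
#' every other variable is endogenous with a free intercept and residual
#' variance, and residuals are mutually independent (diagonal Psi).
#'
#' @param variables character vector of variable names.
#' @param edges two-column character matrix, data.frame, or list of
#'   \code{c(from, to)} pairs.
#' @param exogenous character vector of exogenous variable names
#'   (default \code{"treatment"}).
#' @return An object of class \code{"path_model_spec"} with elements
#'   \code{variables}, \code{exogenous}, \code{endogenous}, \code{edges}
#'   (data.frame with columns \code{from}, \code{to}) and \code{order}
#'   (a topological evaluation order).
#' @seealso [validate_spec()], [model_a_spec()], [model_b_spec()]
#' @export
path_model_spec <- function(variables, edges, exogenous = "treatment") {
  variables <- as.character(variables)
  exogenous <- as.character(exogenous)
  if (is.list(edges) && !is.data.frame(edges)) {
    edges <- do.call(rbind, lapply(edges, function(e) as.character(e)))
  }
  if (is.matrix(edges)) {
    edges <- data.frame(from = edges[, 1], to = edges[, 2],
                        stringsAsFactors = FALSE)
  }
  if (is.null(edges) || nrow(edges) == 0) {
    edges <- data.frame(from = character(0), to = character(0))
  }
  names(edges) <- c("from", "to")
  spec <- structure(
    list(variables = variables,
         exogenous = exogenous,
         endogenous = setdiff(variables, exogenous),
         edges = edges,
         order = NULL),
    class = "path_model_spec")
  validate_spec(spec)
}

#' Validate a path-model specification
#'
#' Checks that all edge endpoints are declared variables, that no edge is
#' duplicated, that no edge points into an exogenous variable, and that the
#' graph is acyclic.  Acyclicity is established constructively by a Kahn
#' topological sort; the resulting evaluation order is stored on the spec.
#'
#' @param spec a \code{"path_model_spec"} (or a bare list with the same
#'   fields, e.g. freshly parsed from JSON).
#' @return the spec, with \code{$order} filled in.
#' @export
validate_spec <- function(spec) {
  v <- spec$variables
  if (anyDuplicated(v)) stop("duplicate variable names: ",
                             paste(unique(v[duplicated(v)]), collapse = ", "))
  if (!all(spec$exogenous %in% v))
    stop("exogenous variables not declared: ",
         paste(setdiff(spec$exogenous, v), collapse = ", "))
  e <- spec$edges
  bad <- setdiff(unique(c(e$from, e$to)), v)
  if (length(bad)) stop("unknown variable in edges: ",
                        paste(bad, collapse = ", "))
  key <- paste(e$from, e$to, sep = "->")
  if (anyDuplicated(key)) stop("duplicate edges: ",
                               paste(unique(key[duplicated(key)]), collapse = ", "))
  if (any(e$to %in% spec$exogenous))
    stop("edges point into exogenous variables: ",
         paste(unique(e$to[e$to %in% spec$exogenous]), collapse = ", "))
  # Kahn's algorithm; ties broken by declared variable order
  indeg <- stats::setNames(integer(length(v)), v)
  for (i in seq_len(nrow(e))) indeg[e$to[i]] <- indeg[e$to[i]] + 1L
  order <- character(0)
  remaining <- v
  while (length(remaining)) {
    ready <- remaining[indeg[remaining] == 0L]
    if (!length(ready)) {
      stop("cycle detected among: ", paste(remaining, collapse = " -> "))
    }
    nxt <- ready[1L]
    order <- c(order, nxt)
    remaining <- setdiff(remaining, nxt)
    out <- e$to[e$from == nxt]
    indeg[out] <- indeg[out] - 1L
  }
  spec$endogenous <- setdiff(v, spec$exogenous)
  spec$order <- order
  class(spec) <- "path_model_spec"
  spec
}

#' @export
print.path_model_spec <- function(x, ...) {
  cat("Path model:", length(x$variables), "variables,",
      nrow(x$edges), "edges\n")
  cat("  exogenous:", paste(x$exogenous, collapse = ", "), "\n")
  if (nrow(x$edges)) {
    cat("  edges:\n")
    for (i in seq_len(nrow(x$edges)))
      cat("    ", x$edges$from[i], "->", x$edges$to[i], "\n")
  }
  invisible(x)
}

#' Parents of an endogenous variable
#' @param spec a path-model spec.
#' @param var variable name.
#' @return character vector of predictors of \code{var}.
#' @keywords internal
spec_parents <- function(spec, var) {
  spec$edges$from[spec$edges$to == var]
}

#' Read / write path-model specs as JSON
#'
#' The on-disk dialect is
#' \code{{"variables": [...], "exogenous": [...], "edges": [["from","to"], ...]}}.
#'
#' @param path file path.
#' @return \code{read_path_spec}: a validated \code{"path_model_spec"}.
#' @export
read_path_spec <- function(path) {
  j <- jsonlite::fromJSON(paste(readLines(path, warn = FALSE),
                                collapse = "\n"),
                          simplifyVector = TRUE)
  edges <- j$edges
  if (is.null(edges) || length(edges) == 0) edges <- NULL
  path_model_spec(j$variables, edges, exogenous = j$exogenous)
}

#' @rdname read_path_spec
#' @param spec a path-model spec.
#' @export
write_path_spec <- function(spec, path) {
  edges <- unname(lapply(seq_len(nrow(spec$edges)), function(i)
    c(spec$edges$from[i], spec$edges$to[i])))
  jsonlite::write_json(
    list(variables = spec$variables,
         exogenous = spec$exogenous,
         edges = edges),
    path, auto_unbox = FALSE, pretty = TRUE)
  invisible(path)
}

# The two candidate causal structures for the simvastatin trial.  Variables
# are annualized changes; "treatment" is the randomization arm (1 = statin).

#' Candidate causal models of the simvastatin trial
#'
#' \code{model_a_spec()} is the cholesterol-mediated structure: the drug
#' acts on serum cholesterol, and cholesterol change drives brain atrophy
#' (PBVC), disability (EDSS), visuospatial cognition (block design) and the
#' patient-reported physical scale (MSIS-29v2 physical).
#' \code{model_b_spec()} is the cholesterol-independent (pleiotropic)
#' structure: the drug acts directly on every outcome, with cholesterol an
#' unconnected sink.  In both, atrophy drives EDSS, block design and MSIS,
#' and EDSS and block design drive MSIS, which closes the cascade.
#'
#' @return a \code{"path_model_spec"}.
#' @export
model_b_spec <- function() {
  path_model_spec(
    variables = c("treatment", "cholesterol", "PBVC", "EDSS",
                  "block_design", "MSIS29_physical"),
    edges = list(
      c("treatment", "cholesterol"),
      c("treatment", "PBVC"),
      c("treatment", "EDSS"),
      c("treatment", "block_design"),
      c("treatment", "MSIS29_physical"),
      c("PBVC", "EDSS"),
      c("PBVC", "block_design"),
      c("PBVC", "MSIS29_physical"),
      c("EDSS", "MSIS29_physical"),
      c("block_design", "MSIS29_physical")))
}

#' @rdname model_b_spec
#' @export
model_a_spec <- function() {
  path_model_spec(
    variables = c("treatment", "cholesterol", "PBVC", "EDSS",
                  "block_design", "MSIS29_physical"),
    edges = list(
      c("treatment", "cholesterol"),
      c("cholesterol", "PBVC"),
      c("cholesterol", "EDSS"),
      c("cholesterol", "block_design"),
      c("cholesterol", "MSIS29_physical"),
      c("PBVC", "EDSS"),
      c("PBVC", "block_design"),
      c("PBVC", "MSIS29_physical"),
      c("EDSS", "MSIS29_physical"),
      c("block_design", "MSIS29_physical")))
}

#' Saturated and baseline companion specs
#'
#' \code{saturated_spec} builds a complete recursive system over the same
#' variables (every earlier variable, in spec order with exogenous first,
#' predicts every later endogenous one); it reproduces any mean vector and
#' positive-definite covariance, so its FIML likelihood is the saturated
#' likelihood.  \code{baseline_spec} drops every edge: all variables are
#' mutually uncorrelated with free means and variances, the null model of
#' the comparative fit index.
#'
#' @param spec a path-model spec.
#' @return a \code{"path_model_spec"}.
#' @keywords internal
saturated_spec <- function(spec) {
  vars <- c(spec$exogenous, setdiff(spec$order, spec$exogenous))
  endo <- setdiff(vars, spec$exogenous)
  edges <- list()
  for (j in seq_along(vars)) {
    if (!(vars[j] %in% endo)) next
    for (i in seq_len(j - 1L)) edges[[length(edges) + 1L]] <- c(vars[i], vars[j])
  }
  path_model_spec(vars, edges, exogenous = spec$exogenous)
}

#' @rdname saturated_spec
#' @keywords internal
baseline_spec <- function(spec) {
  path_model_spec(spec$variables, NULL, exogenous = spec$exogenous)
}
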