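#' Configure an end-to-end pipeline run
#'
#' @param generator a [generator_config()] to simulate a cohort, or
#'   \code{NULL} if \code{cohort_csv} is given.
#' @param cohort_csv path to a long-format cohort CSV (ignored when a
#'   generator is given).
#' @param model_specs named list of candidate path-model specs (default
#'   the two cholesterol models, A mediated and B independent).
#' @param candidates variables entering the univariate screening stage.
#' @param screen_alpha screening threshold (default 0.05).
#' @param n_boot bootstrap replicates for the winning model's fit
#'   measures (0 to skip).
#' @param mediations list of \code{c(mediator, outcome)} pairs for the
#'   Bayesian stage; defaults cover the cholesterol/atrophy/EDSS/block
#'   design chains.
#' @param n_burn,n_keep,chains MCMC settings.
#' @param regional run the regional-atrophy stage (default TRUE when
#'   \code{vol_*} columns exist).
#' @param out_dir output directory for reports.
#' @param seed global seed; every stochastic stage derives its seed from
#'   it deterministically.
#' @return list of class \code{"pipeline_config"}.
#' @export
pipeline_config <- function(generator = generator_config(),
                            cohort_csv = NULL,
                            model_specs = list(model_A = model_a_spec(),
                                               model_B = model_b_spec()),
                            candidates = c("cholesterol", "PBVC", "EDSS",
                                           "block_design", "PASAT", "FAB",
                                           "MSIS29_physical"),
                            screen_alpha = 0.05,
                            n_boot = 1000,
                            mediations = list(
                              c("cholesterol", "PBVC"),
                              c("cholesterol", "EDSS"),
                              c("PBVC", "EDSS"),
                              c("PBVC", "block_design")),
                            n_burn = 4000, n_keep = 10000, chains = 4,
                            regional = TRUE,
                            out_dir = tempfile("pathtrial_run_"),
                            seed = 1) {
  if (is.null(generator) && is.null(cohort_csv))
    stop("either a generator config or a cohort CSV is required")
  if (!is.null(cohort_csv) && is.null(generator) && !file.exists(cohort_csv))
    stop("cohort CSV does not exist: ", cohort_csv)
  structure(list(generator = generator, cohort_csv = cohort_csv,
                 model_specs = model_specs, candidates = candidates,
                 screen_alpha = screen_alpha, n_boot = n_boot,
                 mediations = mediations, n_burn = n_burn,
                 n_keep = n_keep, chains = chains, regional = regional,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Stages: (optional) cohort simulation, annualization, univariate
#' mixed-effects screening, FIML fits of every candidate path model,
#' information-criterion comparison with bootstrap of the winner, the
#' Bayesian mediation set, and the regional-atrophy screen.  Reports
#' (\code{comparison.json}, \code{pathfit_<model>.json},
#' \code{screening.json}, \code{mediation.csv}, \code{mediation.json},
#' \code{regional.csv}, \code{run.log}) are written to
#' \code{config$out_dir}.  A stage failure halts the run with the stage
#' named; outputs of earlier stages are preserved.
#'
#' @param config a [pipeline_config()].
#' @return (invisibly) a list bundle with all stage results.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(config$out_dir, "run.log")
  log_line <- function(...) {
    msg <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
    cat(msg, "\n", file = logf, append = TRUE)
    message(msg)
  }
  stage <- function(name, expr) {
    log_line("stage: ", name)
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  cfg_hash <- digest_config(config)
  cat("pathtrial run, seed ", config$seed, ", config hash ", cfg_hash, "\n",
      file = logf)
  bundle <- list(config_hash = cfg_hash, seed = config$seed)

  cohort <- stage("cohort", {
    if (!is.null(config$generator)) {
      gen <- config$generator
      gen$seed <- config$seed
      sim <- generate_cohort(gen)
      write_cohort_csv(sim$cohort, file.path(config$out_dir, "cohort.csv"))
      write_ground_truth(sim$truth,
                         file.path(config$out_dir, "ground_truth.json"))
      bundle$truth <- sim$truth
      sim$cohort
    } else {
      read_cohort_csv(config$cohort_csv)
    }
  })

  screening <- stage("screen", {
    cand <- intersect(config$candidates, names(cohort))
    s <- screen_variables(cohort, cand, alpha = config$screen_alpha)
    write_screen_json(s, file.path(config$out_dir, "screening.json"))
    s
  })
  bundle$screening <- screening

  model_vars <- unique(unlist(lapply(config$model_specs, function(s)
    setdiff(s$variables, "treatment"))))
  changes <- stage("annualize", {
    ct <- annualize(cohort, intersect(model_vars, names(cohort)))
    write_change_table(ct, file.path(config$out_dir, "changes.csv"))
    ct
  })
  bundle$changes <- changes

  comparison <- stage("compare", {
    cmp <- compare_models(config$model_specs, changes)
    for (nm in names(cmp$fits)) {
      fit <- cmp$fits[[nm]]
      fit$vcov_robust <- robust_vcov(fit, changes)
      fit$coefficients <- coef_table(fit)
      write_path_fit(fit, file.path(config$out_dir,
                                    paste0("pathfit_", nm, ".json")),
                     indices = fit_indices(fit, changes))
      cmp$fits[[nm]] <- fit
    }
    jsonlite::write_json(
      list(table = cmp$table, winner = cmp$winner,
           evidence_akaike = cmp$evidence_akaike,
           evidence_schwarz = cmp$evidence_schwarz),
      file.path(config$out_dir, "comparison.json"),
      auto_unbox = TRUE, digits = NA, dataframe = "rows", pretty = TRUE)
    cmp
  })
  bundle$comparison <- comparison

  if (config$n_boot > 0) {
    bundle$bootstrap <- stage("bootstrap", {
      bs <- bootstrap_fit_measures(
        config$model_specs[[comparison$winner]], changes,
        n_boot = config$n_boot, seed = config$seed + 1L)
      jsonlite::write_json(
        list(summary = bs$summary, n_boot = bs$n_boot,
             n_failed = bs$n_failed, seed = bs$seed),
        file.path(config$out_dir, "bootstrap.json"),
        auto_unbox = TRUE, digits = NA, dataframe = "rows", pretty = TRUE)
      bs
    })
  }

  bundle$mediation <- stage("mediate", {
    res <- list()
    rows <- list()
    for (i in seq_along(config$mediations)) {
      mo <- config$mediations[[i]]
      if (!all(mo %in% names(changes))) next
      key <- paste(mo, collapse = "_")
      post <- mcmc_sample(mediation_spec("treatment", mo[1], mo[2]),
                          changes, n_burn = config$n_burn,
                          n_keep = config$n_keep, chains = config$chains,
                          seed = config$seed + 100L + i)
      eff <- mediation_effects(post)
      res[[key]] <- post
      s <- eff$summary
      s$mediator <- mo[1]
      s$outcome <- mo[2]
      s$proportion_mediated <- eff$proportion_mediated
      rows[[key]] <- s
    }
    tab <- do.call(rbind, rows)
    utils::write.csv(tab, file.path(config$out_dir, "mediation.csv"),
                     row.names = FALSE)
    jsonlite::write_json(tab, file.path(config$out_dir, "mediation.json"),
                         auto_unbox = TRUE, digits = NA,
                         dataframe = "rows", pretty = TRUE)
    list(posteriors = res, table = tab)
  })

  if (config$regional && any(grepl("^vol_", names(cohort)))) {
    bundle$regional <- stage("regional", {
      rr <- regional_rates(cohort)
      write_regional_csv(rr, file.path(config$out_dir, "regional.csv"))
      rr
    })
  }

  log_line("done; winner = ", comparison$winner)
  invisible(bundle)
}

# small deterministic config hash (no external digest dependency)
digest_config <- function(config) {
  s <- paste(utils::capture.output(utils::str(config, give.attr = FALSE)),
             collapse = "\n")
  raw <- utf8ToInt(s)
  h <- 5381
  for (x in raw) h <- (h * 33 + x) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Command-line entry point
#'
#' Subcommands: \code{simulate}, \code{screen}, \code{fit},
#' \code{compare}, \code{mediate}, \code{regional}, \code{all} (the
#' default, equivalent to [run_pipeline()]).  Flags: \code{--seed},
#' \code{--out}, \code{--cohort} (CSV input instead of simulation),
#' \code{--n-boot}, \code{--burn}, \code{--keep}, \code{--chains}.
#'
#' @param args character vector, default \code{commandArgs(TRUE)}.
#' @return invisibly, the result bundle of the executed stage.
#' @export
pathtrial_cli <- function(args = commandArgs(TRUE)) {
  getopt <- function(flag, default) {
    i <- which(args == flag)
    if (length(i) && i < length(args)) args[i + 1L] else default
  }
  cmd <- if (length(args) && !startsWith(args[1], "--")) args[1] else "all"
  seed <- as.integer(getopt("--seed", "1"))
  out <- getopt("--out", "pathtrial_out")
  cohort_csv <- getopt("--cohort", NA)
  n_boot <- as.integer(getopt("--n-boot", "200"))
  n_burn <- as.integer(getopt("--burn", "4000"))
  n_keep <- as.integer(getopt("--keep", "10000"))
  chains <- as.integer(getopt("--chains", "4"))

  gen <- if (is.na(cohort_csv)) generator_config(seed = seed) else NULL
  cohort <- if (!is.na(cohort_csv)) read_cohort_csv(cohort_csv) else
    generate_cohort(gen)$cohort

  res <- switch(
    cmd,
    simulate = {
      dir.create(out, showWarnings = FALSE, recursive = TRUE)
      sim <- generate_cohort(generator_config(seed = seed))
      write_cohort_csv(sim$cohort, file.path(out, "cohort.csv"))
      write_ground_truth(sim$truth, file.path(out, "ground_truth.json"))
      sim
    },
    screen = {
      dir.create(out, showWarnings = FALSE, recursive = TRUE)
      s <- screen_variables(cohort, c("cholesterol", "PBVC", "EDSS",
                                      "block_design", "PASAT", "FAB",
                                      "MSIS29_physical"))
      write_screen_json(s, file.path(out, "screening.json"))
      print(s)
      s
    },
    fit = {
      dir.create(out, showWarnings = FALSE, recursive = TRUE)
      ct <- annualize(cohort, c("cholesterol", "PBVC", "EDSS",
                                "block_design", "MSIS29_physical"))
      f <- fit_path_model(model_b_spec(), ct)
      write_path_fit(f, file.path(out, "pathfit_model_B.json"),
                     indices = fit_indices(f, ct))
      print(f)
      f
    },
    compare = ,
    mediate = ,
    regional = ,
    all = {
      cfg <- pipeline_config(generator = gen, cohort_csv = cohort_csv,
                             n_boot = n_boot, n_burn = n_burn,
                             n_keep = n_keep, chains = chains,
                             out_dir = out, seed = seed)
      run_pipeline(cfg)
    },
    stop("unknown subcommand: ", cmd))
  invisible(res)
}
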