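# End-to-end pipeline: eligibility -> model fitting -> g-formula ->
# bootstrap -> effects table, plus the natural-course diagnostic.

#' Natural-course diagnostic
#'
#' Compares observed end-of-follow-up outcome means (uncensored records)
#' with the simulated natural-course standardized means. Close agreement is
#' a necessary (not sufficient) check against gross model misspecification.
#' An outcome is flagged when the absolute difference exceeds `tol_frac` of
#' the observed outcome SD.
#'
#' @param models a full `pt_models` set.
#' @param cohort the eligible cohort the models were fitted on.
#' @param mc_size Monte Carlo size.
#' @param seed RNG seed.
#' @param tol_frac flag threshold as a fraction of the observed SD.
#' @return data.frame per outcome: observed and simulated means, difference,
#'   observed SD, flag.
#' @export
natural_course_diagnostic <- function(models, cohort, mc_size = 20000,
                                      seed = 1, tol_frac = 0.05) {
  est <- run_all_strategies(models, list(natural_course()), mc_size, seed,
                            mode = "parametric")
  simulated <- est[[1]]$standardized_mean
  d <- cohort$data[cohort$data$censor == "none", , drop = FALSE]
  outs <- names(simulated)
  observed <- vapply(outs, function(k) mean(d[[paste0(k, 2)]]), 0)
  obs_sd <- vapply(outs, function(k) stats::sd(d[[paste0(k, 2)]]), 0)
  data.frame(outcome = outs, observed_mean = unname(observed),
             simulated_mean = unname(simulated),
             difference = unname(simulated - observed),
             observed_sd = unname(obs_sd),
             flag = unname(abs(simulated - observed) > tol_frac * obs_sd),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Effects table
#'
#' One row per strategy and outcome with the standardized mean, its 95%
#' percentile CI, and the average treatment effect versus the natural
#' course with its CI. The natural-course rows have ATE 0 and no contrast
#' CI (it is the reference).
#'
#' @param boot a `pt_bootstrap`.
#' @return a `pt_effects` data.frame.
#' @export
effects_table <- function(boot) {
  stopifnot(inherits(boot, "pt_bootstrap"))
  tb <- boot$ci
  nc <- tb$strategy == "natural_course"
  tb$ate[nc] <- 0
  tb$ate_lower[nc] <- NA_real_
  tb$ate_upper[nc] <- NA_real_
  tb$pathological <- NULL
  class(tb) <- c("pt_effects", "data.frame")
  tb
}

#' Recompute the effects table from stored bootstrap replicates
#'
#' Uses `replicate_means` / `replicate_ates` without refitting anything;
#' must reproduce [effects_table()] exactly.
#' @param boot a `pt_bootstrap` with `keep_replicates = TRUE`.
#' @export
regenerate_effects <- function(boot) {
  stopifnot(!is.null(boot$replicate_means))
  means <- boot$replicate_means
  ates <- boot$replicate_ates
  ok <- !is.na(means[, 1, 1])
  q <- function(x) stats::quantile(x, c(0.025, 0.975), names = FALSE,
                                   na.rm = TRUE)
  labels <- dimnames(means)[[2]]
  outcomes <- dimnames(means)[[3]]
  tb <- do.call(rbind, lapply(seq_along(labels), function(j) {
    do.call(rbind, lapply(seq_along(outcomes), function(k) {
      qm <- q(means[ok, j, k]); qa <- q(ates[ok, j, k])
      data.frame(strategy = labels[j], outcome = outcomes[k],
                 mean = unname(boot$point[[j]]$standardized_mean[k]),
                 mean_lower = qm[1], mean_upper = qm[2],
                 ate = unname(boot$point[[j]]$ate_vs_natural[k]),
                 ate_lower = qa[1], ate_upper = qa[2],
                 stringsAsFactors = FALSE, row.names = NULL)
    }))
  }))
  nc <- tb$strategy == "natural_course"
  tb$ate[nc] <- 0
  tb$ate_lower[nc] <- NA_real_
  tb$ate_upper[nc] <- NA_real_
  class(tb) <- c("pt_effects", "data.frame")
  tb
}

#' @export
print.pt_effects <- function(x, ...) {
  y <- x
  num <- vapply(y, is.numeric, TRUE)
  y[num] <- lapply(y[num], round, digits = 1)
  NextMethod(object = y)
  invisible(x)
}

#' Run the full pipeline
#'
#' Stages: load (or generate) the cohort, eligibility filtering, model
#' fitting, Monte Carlo g-formula for every strategy, bootstrap CIs, effects
#' table and natural-course diagnostic. Any stage error is rethrown with the
#' stage name. Fully deterministic given the configuration.
#'
#' @param config a list (or path to a YAML file) with entries:
#'   `cohort` (a `pt_cohort`) or `cohort_csv` (path) or `dgp` (a
#'   [dgp_config()] or list of its arguments; the default), `strategies`
#'   (string for [parse_strategies()] or list; default the study grid),
#'   `mc_size` (default 20000), `n_resamples` (default 500), `seed`
#'   (default 1), `mode` (`"parametric"`), `out_dir` (optional: write CSV /
#'   JSON artifacts).
#' @return list: `effects`, `bootstrap`, `models`, `diagnostic`,
#'   `exclusions`, `run_log`.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "': ", conditionMessage(e),
           call. = FALSE))
  }
  seed <- config$seed %||% 1L
  mc_size <- config$mc_size %||% 20000
  n_resamples <- config$n_resamples %||% 500
  mode <- config$mode %||% "parametric"
  strategies <- config$strategies %||% strategy_grid()
  if (is.character(strategies)) strategies <- parse_strategies(strategies)

  cohort <- stage("load", {
    if (!is.null(config$cohort)) config$cohort
    else if (!is.null(config$cohort_csv)) read_cohort(config$cohort_csv)
    else {
      dgp <- config$dgp %||% list()
      if (!inherits(dgp, "pt_dgp_config"))
        dgp <- do.call(dgp_config, c(dgp, list(seed = seed)))
      generate_cohort(dgp)
    }
  })
  elig <- stage("eligibility", apply_eligibility(cohort))
  specs <- stage("model_spec", default_model_specs(elig$cohort$schema))
  boot <- stage("bootstrap",
                gf_bootstrap(elig$cohort, specs, strategies,
                             n_resamples = n_resamples, mc_size = mc_size,
                             seed = seed, mode = mode))
  models <- boot$models
  diagnostic <- stage("diagnostic",
                      if (mode == "parametric")
                        natural_course_diagnostic(models, elig$cohort,
                                                  mc_size, seed))
  effects <- stage("table", effects_table(boot))
  run_log <- list(
    seed = seed, mc_size = mc_size, n_resamples = n_resamples, mode = mode,
    n_input = nrow(cohort$data), n_eligible = nrow(elig$cohort$data),
    exclusions = elig$exclusions,
    censoring = as.list(censoring_summary(elig$cohort)),
    n_bootstrap_failed = boot$n_failed,
    spec_hash = rlang::hash(specs),
    config_hash = rlang::hash(config[setdiff(names(config), "cohort")]),
    package_version = as.character(utils::packageVersion("proteintrial"))
  )
  out <- list(effects = effects, bootstrap = boot, models = models,
              diagnostic = diagnostic, exclusions = elig$exclusions,
              run_log = run_log)
  if (!is.null(config$out_dir)) write_pipeline_outputs(out, config$out_dir)
  out
}

#' Write pipeline artifacts
#'
#' `effects.csv` is rounded to one decimal (presentation precision for cm^2,
#' kg and percentage quantities); `effects.json` keeps full precision.
#' @param result output of [run_pipeline()].
#' @param dir output directory (created if needed).
#' @export
write_pipeline_outputs <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rounded <- result$effects
  num <- vapply(rounded, is.numeric, TRUE)
  rounded[num] <- lapply(rounded[num], round, digits = 1)
  utils::write.csv(rounded, file.path(dir, "effects.csv"), row.names = FALSE)
  jsonlite::write_json(result$effects, file.path(dir, "effects.json"),
                       dataframe = "rows", na = "null", digits = NA)
  utils::write.csv(result$exclusions, file.path(dir, "exclusions.csv"),
                   row.names = FALSE)
  if (!is.null(result$diagnostic))
    utils::write.csv(result$diagnostic, file.path(dir, "diagnostic.csv"),
                     row.names = FALSE)
  jsonlite::write_json(result$run_log, file.path(dir, "run_log.json"),
                       auto_unbox = TRUE, dataframe = "rows", digits = NA)
  invisible(dir)
}
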