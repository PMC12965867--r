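# Nonparametric bootstrap for standardized means and treatment effects.
#
# Resampling unit: the participant (rows of the eligible cohort), before
# model fitting, matching the emulation order (eligibility applied once,
# pre-bootstrap). Percentile 95% intervals. Replicate r uses a seed derived
# deterministically from (master seed, r), so results are reproducible and
# independent of execution order.

#' Bootstrap confidence intervals for g-formula estimates
#'
#' Each replicate resamples participants with replacement, refits all
#' required models and reruns every strategy. Confidence bounds are the
#' 2.5th/97.5th percentiles of the replicate estimates. Replicates whose
#' model fits fail (e.g. a factor level lost in resampling) are dropped and
#' counted; a failure rate above 10% is an error.
#'
#' @param cohort an eligible `pt_cohort`.
#' @param specs model specifications (default [default_model_specs()]).
#' @param strategies list of strategies incl. the natural course.
#' @param n_resamples bootstrap resamples (>= 2; the study default is 500).
#' @param mc_size Monte Carlo size per replicate (parametric mode).
#' @param seed master RNG seed.
#' @param mode covariate-simulation mode, see [simulate_covariates()].
#' @param keep_replicates store per-replicate estimates (needed to
#'   regenerate tables without recomputation).
#' @return a `pt_bootstrap`: `point` (full-data `pt_gestimates`), `ci`
#'   (data.frame), replicate arrays, failure count.
#' @export
gf_bootstrap <- function(cohort, specs = default_model_specs(cohort$schema),
                         strategies = strategy_grid(), n_resamples = 500,
                         mc_size = 20000, seed = 1,
                         mode = c("parametric", "empirical"),
                         keep_replicates = TRUE) {
  mode <- match.arg(mode)
  stopifnot(n_resamples >= 2)
  components <- if (mode == "empirical") "outcomes"
                else c("covariates", "y1", "exposure", "outcomes")
  point_models <- fit_all(cohort, specs, components = components)
  point <- run_all_strategies(point_models, strategies, mc_size,
                              seed = derive_seed(seed, 0), mode = mode)
  labels <- vapply(point, `[[`, "", "label")
  outcomes <- names(point[[1]]$standardized_mean)
  dims <- c(n_resamples, length(labels), length(outcomes))
  means <- array(NA_real_, dims, dimnames = list(NULL, labels, outcomes))
  ates <- means
  failures <- character(0)
  n <- nrow(cohort$data)
  for (r in seq_len(n_resamples)) {
    seed_r <- derive_seed(seed, r)
    idx <- with_seed(seed_r, sample.int(n, n, replace = TRUE))
    boot <- cohort
    boot$data <- cohort$data[idx, , drop = FALSE]
    rownames(boot$data) <- NULL
    res <- tryCatch({
      m <- fit_all(boot, specs, components = components)
      run_all_strategies(m, strategies, mc_size,
                         seed = derive_seed(seed_r, 1), mode = mode)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures, sprintf("replicate %d: %s", r,
                                      conditionMessage(res)))
      next
    }
    for (j in seq_along(res)) {
      means[r, j, ] <- res[[j]]$standardized_mean
      ates[r, j, ] <- res[[j]]$ate_vs_natural
    }
  }
  n_fail <- length(failures)
  if (n_fail > 0.10 * n_resamples)
    stop("bootstrap: ", n_fail, "/", n_resamples,
         " replicates failed:\n", paste(utils::head(failures, 5),
                                        collapse = "\n"), call. = FALSE)
  ok <- !is.na(means[, 1, 1])
  q <- function(x) stats::quantile(x, c(0.025, 0.975), names = FALSE,
                                   na.rm = TRUE)
  ci <- do.call(rbind, lapply(seq_along(labels), function(j) {
    do.call(rbind, lapply(seq_along(outcomes), function(k) {
      qm <- q(means[ok, j, k])
      qa <- q(ates[ok, j, k])
      pt_mean <- point[[j]]$standardized_mean[k]
      data.frame(strategy = labels[j], outcome = outcomes[k],
                 mean = unname(pt_mean),
                 mean_lower = qm[1], mean_upper = qm[2],
                 ate = unname(point[[j]]$ate_vs_natural[k]),
                 ate_lower = qa[1], ate_upper = qa[2],
                 pathological = pt_mean < qm[1] | pt_mean > qm[2],
                 stringsAsFactors = FALSE, row.names = NULL)
    }))
  }))
  structure(list(point = point, models = point_models, ci = ci,
                 n_resamples = n_resamples, n_failed = n_fail,
                 failure_log = failures, seed = seed, mode = mode,
                 mc_size = mc_size,
                 replicate_means = if (keep_replicates) means,
                 replicate_ates = if (keep_replicates) ates),
            class = "pt_bootstrap")
}

#' @export
print.pt_bootstrap <- function(x, ...) {
  cat("<pt_bootstrap> ", x$n_resamples, " resamples (", x$n_failed,
      " failed), mode = ", x$mode, "\n", sep = "")
  print(x$ci, row.names = FALSE, digits = 4)
  invisible(x)
}
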