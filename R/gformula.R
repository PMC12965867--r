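# Monte Carlo parametric g-formula.
#
# One pseudo-population of simulated histories is shared by every strategy
# (common random numbers), so treatment contrasts are paired differences and
# the natural-course ATE is identically zero. Censoring is abolished by
# construction: outcome means are predicted for every pseudo-individual from
# models fitted on uncensored records.

#' Simulate baseline covariates and the natural-course exposure
#'
#' In `"parametric"` mode, pre-baseline records are resampled with
#' replacement and each baseline covariate, baseline outcome value and the
#' exposure are drawn sequentially from their fitted conditional
#' distributions (declared order; continuous draws add resampled residuals
#' and are truncated to the observed range). In `"empirical"` mode the
#' observed baseline rows are used directly (regression standardization);
#' `mc_size` is ignored.
#'
#' @param models a `pt_models` set from [fit_all()].
#' @param mc_size number of pseudo-individuals (parametric mode).
#' @param seed RNG seed.
#' @param mode `"parametric"` or `"empirical"`.
#' @return data.frame of simulated histories with attribute `a_natural`.
#' @export
simulate_covariates <- function(models, mc_size = 20000, seed = 1,
                                mode = c("parametric", "empirical")) {
  stopifnot(inherits(models, "pt_models"))
  mode <- match.arg(mode)
  a1 <- paste0(models$schema$exposure, 1)
  if (mode == "empirical") {
    sim <- models$data
    attr(sim, "a_natural") <- sim[[a1]]
    return(sim)
  }
  with_seed(seed, {
    idx <- sample.int(nrow(models$data), mc_size, replace = TRUE)
    sim <- models$data[idx, , drop = FALSE]
    rownames(sim) <- NULL
    set_col <- function(sim, stem, value, transform) {
      sim[[stem]] <- value
      if (transform == "log") sim[[paste0("log_", stem)]] <- log(value)
      sim
    }
    for (f in models$covariate_fits)
      sim <- set_col(sim, f$spec$target, simulate_fit(f, sim),
                     f$spec$transform)
    for (f in models$y1_fits)
      sim <- set_col(sim, f$spec$target, simulate_fit(f, sim),
                     f$spec$transform)
    a_nat <- simulate_fit(models$exposure_fit, sim)
    sim <- set_col(sim, a1, a_nat, "log")
    attr(sim, "a_natural") <- a_nat
    sim
  })
}

.strategy_key <- function(s) {
  if (s$kind == "natural_course") "natural_course" else sprintf("t=%.6g", s$t)
}

#' Run the g-formula for a set of strategies
#'
#' Simulates one pseudo-population, applies each intervention rule to the
#' shared natural-course exposure draws, predicts end-of-follow-up outcomes,
#' and standardizes (averages). The natural course must be included and is
#' listed first as the reference.
#'
#' @param models a `pt_models` set.
#' @param strategies list of `pt_strategy` (default [strategy_grid()]).
#' @param mc_size pseudo-population size (parametric mode; >= 1e4
#'   recommended, < 100 warns).
#' @param seed RNG seed for the Monte Carlo draws.
#' @param mode covariate-simulation mode, see [simulate_covariates()].
#' @return a `pt_gestimates` list, one element per strategy with
#'   `standardized_mean`, `ate_vs_natural` and `mc_se` per outcome.
#' @export
run_all_strategies <- function(models, strategies = strategy_grid(),
                               mc_size = 20000, seed = 1,
                               mode = c("parametric", "empirical")) {
  mode <- match.arg(mode)
  stopifnot(length(strategies) >= 1,
            all(vapply(strategies, inherits, TRUE, "pt_strategy")))
  keys <- vapply(strategies, .strategy_key, "")
  if (anyDuplicated(keys)) stop("duplicate strategies", call. = FALSE)
  nc <- which(keys == "natural_course")
  if (length(nc) != 1)
    stop("reference strategy required: include natural_course()",
         call. = FALSE)
  if (mode == "parametric" && mc_size < 100)
    warning("mc_size < 100: Monte Carlo error will dominate")
  strategies <- c(strategies[nc], strategies[-nc])

  sim <- simulate_covariates(models, mc_size, seed, mode)
  a_nat <- attr(sim, "a_natural")
  n_mc <- nrow(sim)
  preds <- lapply(strategies, function(s)
    predict_outcome(models, apply_intervention(a_nat, s), sim))
  est <- lapply(seq_along(strategies), function(j) {
    pred <- preds[[j]]
    diff <- pred - preds[[1]]
    list(strategy = strategies[[j]], label = strategy_label(strategies[[j]]),
         standardized_mean = colMeans(pred),
         ate_vs_natural = colMeans(pred) - colMeans(preds[[1]]),
         mc_se = apply(pred, 2, stats::sd) / sqrt(n_mc),
         # paired MC error of the contrast (common random numbers)
         ate_mc_se = apply(diff, 2, stats::sd) / sqrt(n_mc),
         mc_size = n_mc, seed = seed, mode = mode)
  })
  structure(est, class = "pt_gestimates")
}

#' Single-strategy g-formula estimate
#'
#' Convenience wrapper around [run_all_strategies()] sharing draws with the
#' natural-course reference.
#' @inheritParams run_all_strategies
#' @param strategy a `pt_strategy`.
#' @export
gformula_estimate <- function(models, strategy, mc_size = 20000, seed = 1,
                              mode = c("parametric", "empirical")) {
  mode <- match.arg(mode)
  sts <- if (strategy$kind == "natural_course") list(natural_course())
         else list(natural_course(), strategy)
  out <- run_all_strategies(models, sts, mc_size, seed, mode)
  out[[length(out)]]
}

#' @export
print.pt_gestimates <- function(x, ...) {
  cat("<pt_gestimates> mode =", x[[1]]$mode, ", mc_size =", x[[1]]$mc_size,
      "\n")
  print(as.data.frame(x), row.names = FALSE, digits = 4)
  invisible(x)
}

#' Tidy g-formula estimates
#'
#' @param x a `pt_gestimates`.
#' @param ... unused.
#' @return data.frame with one row per strategy x outcome.
#' @export
as.data.frame.pt_gestimates <- function(x, ...) {
  do.call(rbind, lapply(x, function(e) {
    data.frame(strategy = e$label,
               outcome = names(e$standardized_mean),
               mean = unname(e$standardized_mean),
               ate = unname(e$ate_vs_natural),
               mc_se = unname(e$mc_se),
               stringsAsFactors = FALSE, row.names = NULL)
  }))
}

# -- discrete cohorts: exact oracle and saturated MC -------------------------

#' Exact plug-in standardization on a fully discrete cohort
#'
#' Enumerates confounder strata: the standardized mean under a strategy is
#' `sum_l P(l) sum_a P(a | l) E[Y | g(a), l]` with empirical cell means and
#' probabilities, where `g` is the intervention rule. No randomness. The
#' intervened exposure must itself be an observed exposure level (choose
#' thresholds from the support), unless a known conditional-mean function
#' `outcome_fn(a, stratum)` is supplied.
#'
#' @param data data.frame of one row per participant.
#' @param strategy a `pt_strategy`.
#' @param covariates names of discrete confounder columns.
#' @param exposure name of the discrete numeric exposure column (g/kg/day).
#' @param outcome name of the numeric outcome column.
#' @param outcome_fn optional function `(a, stratum_data_frame) -> mean`,
#'   replacing the empirical cell means.
#' @return the exact standardized mean (scalar).
#' @export
plugin_standardization_oracle <- function(data, strategy, covariates,
                                          exposure = "a", outcome = "y",
                                          outcome_fn = NULL) {
  stopifnot(inherits(strategy, "pt_strategy"))
  n <- nrow(data)
  stratum <- interaction(data[covariates], drop = TRUE, sep = "|")
  total <- 0
  for (lv in levels(stratum)) {
    rows <- which(stratum == lv)
    p_l <- length(rows) / n
    a_vals <- data[[exposure]][rows]
    tab <- table(a_vals)
    a_levels <- as.numeric(names(tab))
    p_a <- as.numeric(tab) / length(rows)
    for (j in seq_along(a_levels)) {
      a_int <- apply_intervention(a_levels[j], strategy)
      if (is.null(outcome_fn)) {
        cell <- rows[abs(data[[exposure]][rows] - a_int) < 1e-12]
        if (!length(cell))
          stop("empty stratum: no observations with ", exposure, " = ",
               a_int, " in stratum ", lv, call. = FALSE)
        ey <- mean(data[[outcome]][cell])
      } else {
        ey <- outcome_fn(a_int, data[rows[1], , drop = FALSE])
      }
      total <- total + p_l * p_a[j] * ey
    }
  }
  total
}

#' Monte Carlo standardization on a discrete cohort with saturated models
#'
#' The MC counterpart of [plugin_standardization_oracle()]: fits a saturated
#' multinomial exposure model and a saturated linear outcome model through
#' the package's model machinery, resamples confounders, draws the natural
#' exposure, applies the intervention rule and averages predicted means.
#' Converges to the exact plug-in value as `mc_size` grows.
#'
#' @inheritParams plugin_standardization_oracle
#' @param mc_size Monte Carlo sample size.
#' @param seed RNG seed.
#' @return list with `mean`, `mc_se`, `mc_size`.
#' @export
mc_standardization_discrete <- function(data, strategy, covariates,
                                        exposure = "a", outcome = "y",
                                        mc_size = 1e5, seed = 1) {
  stopifnot(inherits(strategy, "pt_strategy"))
  d <- data
  for (cv in covariates) d[[cv]] <- factor(d[[cv]])
  a_num <- d[[exposure]]
  d$.a_f <- factor(a_num)
  exp_fit <- fit_one(model_spec(".a_f", "multinomial",
                                predictors = covariates, saturated = TRUE),
                     d)
  out_fit <- fit_one(model_spec(outcome, "linear",
                                predictors = c(".a_f", covariates),
                                saturated = TRUE), d)
  a_levels <- as.numeric(levels(d$.a_f))
  with_seed(seed, {
    idx <- sample.int(nrow(d), mc_size, replace = TRUE)
    sim <- d[idx, covariates, drop = FALSE]
    a_nat_f <- simulate_fit(exp_fit, sim)
    a_int <- apply_intervention(as.numeric(as.character(a_nat_f)), strategy)
    bad <- !vapply(a_int, function(v) any(abs(v - a_levels) < 1e-12), TRUE)
    if (any(bad))
      stop("intervened exposure value ", a_int[which(bad)[1]],
           " is not an observed exposure level; choose thresholds from the ",
           "support", call. = FALSE)
    sim$.a_f <- factor(a_int, levels = levels(d$.a_f))
    pred <- predict_lp(out_fit, sim)
    list(mean = mean(pred), mc_se = stats::sd(pred) / sqrt(mc_size),
         mc_size = mc_size)
  })
}
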