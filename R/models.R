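# Parametric models for the g-formula: baseline covariates given pre-baseline
# history, baseline outcome values, the exposure (natural-course draw),
# end-of-follow-up outcomes, and censoring.
#
# Families: linear (lm; optional log transform of the target, residuals kept
# for residual-resampling simulation), logistic (glm), multinomial (nested
# sequence of binary logits -- an exact reparameterization of the multinomial
# when saturated). Continuous simulated values are truncated to the observed
# range of the training data, standard g-formula practice.

#' Model specification
#'
#' @param target column stem of the modelled variable (a prepared-data column).
#' @param family `"linear"`, `"logistic"` or `"multinomial"`.
#' @param predictors character vector of prepared-data columns, in temporal
#'   order (predictors must precede the target).
#' @param transform `"identity"` or `"log"` (continuous targets only).
#' @param saturated if `TRUE`, fit the fully saturated model (all predictor
#'   interactions); predictors must be categorical.
#' @param subset optional name of a logical column restricting the fit.
#' @export
model_spec <- function(target, family = c("linear", "logistic", "multinomial"),
                       predictors, transform = c("identity", "log"),
                       saturated = FALSE, subset = NULL) {
  family <- match.arg(family)
  transform <- match.arg(transform)
  structure(list(target = target, family = family,
                 predictors = predictors, transform = transform,
                 saturated = saturated, subset = subset),
            class = "pt_model_spec")
}

# Prepared model data: adds log columns for log-transformed covariates and
# the exposure, and collapsed-factor columns (<col>_m) for categoricals with
# a collapse map, so specs can reference e.g. log_energy1 / race_m.
prep_model_data <- function(cohort) {
  d <- cohort$data
  sc <- cohort$schema
  for (cv in sc$covariates) {
    visits <- if (cv$time_varying) 0:1 else ""
    if (cv$transform == "log") {
      for (v in visits) {
        cl <- paste0(cv$name, v)
        d[[paste0("log_", cl)]] <- log(d[[cl]])
      }
    }
    if (!is.null(cv$collapse)) {
      map <- setNames(cv$levels, cv$levels)
      for (new in names(cv$collapse)) map[cv$collapse[[new]]] <- new
      new_levels <- unique(unname(map))
      for (v in visits) {
        cl <- paste0(cv$name, v)
        d[[paste0(cl, "_m")]] <- factor(unname(map[as.character(d[[cl]])]),
                                        levels = new_levels)
      }
    }
  }
  for (v in 0:1) {
    cl <- paste0(sc$exposure, v)
    d[[paste0("log_", cl)]] <- log(d[[cl]])
  }
  d
}

# covariate columns at a visit with log / collapsed stand-ins substituted
.prepared_cols <- function(schema, visit) {
  vapply(schema$covariates, function(cv) {
    nm <- if (cv$time_varying) paste0(cv$name, visit) else cv$name
    if (cv$transform == "log") paste0("log_", nm)
    else if (!is.null(cv$collapse)) paste0(nm, "_m")
    else nm
  }, "")
}

#' Default model specifications
#'
#' Main-effects-only formulas (the convention absent stated functional
#' forms): each baseline (visit-1) time-varying covariate given full
#' pre-baseline history and previously listed baseline covariates; each
#' baseline outcome value given history and previously listed baseline
#' outcomes; the exposure (log scale) given everything at baseline; each
#' end-of-follow-up outcome given the exposure and the complete adjustment
#' set (pre-baseline and baseline confounders, pre-baseline intake, and both
#' earlier outcome measurements); and logistic models for death and loss to
#' follow-up given baseline history.
#'
#' @param schema a [cohort_schema()].
#' @return named list of [model_spec()] lists: `covariates`, `y1`,
#'   `exposure`, `outcomes`, `censoring`.
#' @export
default_model_specs <- function(schema) {
  l0 <- unname(.prepared_cols(schema, 0))
  l1_all <- .prepared_cols(schema, 1)
  y0 <- outcome_columns(schema, 0)
  y1 <- outcome_columns(schema, 1)
  a0_log <- paste0("log_", schema$exposure, 0)
  a0_raw <- paste0(schema$exposure, 0)
  a1_raw <- paste0(schema$exposure, 1)
  hist0 <- unique(c(l0, y0, a0_log))

  tv <- Filter(function(cv) cv$time_varying, schema$covariates)
  cov_specs <- list()
  done1 <- character(0)
  for (cv in tv) {
    tgt <- paste0(cv$name, 1)
    if (!is.null(cv$collapse)) tgt <- paste0(tgt, "_m")
    fam <- switch(cv$type, continuous = "linear", binary = "logistic",
                  categorical = "multinomial")
    cov_specs[[tgt]] <- model_spec(tgt, fam,
                                   predictors = c(hist0, done1),
                                   transform = cv$transform)
    done1 <- c(done1, if (cv$transform == "log") paste0("log_", tgt) else tgt)
  }
  y1_specs <- list()
  done_y1 <- character(0)
  for (k in schema$outcomes) {
    tgt <- paste0(k, 1)
    y1_specs[[tgt]] <- model_spec(tgt, "linear",
                                  predictors = c(hist0, done1, done_y1))
    done_y1 <- c(done_y1, tgt)
  }
  exposure_spec <- model_spec(a1_raw, "linear",
                              predictors = c(hist0, done1, y1),
                              transform = "log")
  out_specs <- lapply(schema$outcomes, function(k) {
    model_spec(paste0(k, 2), "linear",
               predictors = unique(c(a1_raw, l0, y0, a0_raw, done1, y1)))
  })
  names(out_specs) <- paste0(schema$outcomes, 2)
  cens_specs <- list(
    death = model_spec("cens_death", "logistic",
                       predictors = c(done1, y1, a1_raw)),
    ltfu = model_spec("cens_ltfu", "logistic",
                      predictors = c(done1, y1, a1_raw),
                      subset = "at_risk_ltfu")
  )
  list(covariates = cov_specs, y1 = y1_specs, exposure = exposure_spec,
       outcomes = out_specs, censoring = cens_specs)
}

# -- single-model fitting ----------------------------------------------------

.spec_formula <- function(spec, target) {
  if (spec$saturated)
    stats::as.formula(paste(target, "~", paste(spec$predictors,
                                               collapse = " * ")))
  else stats::reformulate(spec$predictors, response = target)
}

.check_rank <- function(fit, label) {
  cf <- stats::coef(fit)
  if (anyNA(cf))
    stop("model for '", label, "' is rank deficient; collinear terms: ",
         paste(names(cf)[is.na(cf)], collapse = ", "), call. = FALSE)
}

fit_one <- function(spec, data) {
  rows <- if (!is.null(spec$subset)) which(data[[spec$subset]])
          else seq_len(nrow(data))
  d <- data[rows, , drop = FALSE]
  target <- spec$target
  if (spec$family == "linear") {
    ycol <- if (spec$transform == "log") paste0("log_", target) else target
    if (spec$transform == "log" && is.null(d[[ycol]]))
      d[[ycol]] <- log(d[[target]])
    fit <- stats::lm(.spec_formula(spec, ycol), data = d)
    .check_rank(fit, target)
    out <- list(spec = spec, fit = fit,
                residuals = unname(stats::residuals(fit)),
                sigma = suppressWarnings(summary(fit)$sigma),
                range = range(d[[target]]), n = nrow(d), converged = TRUE)
  } else if (spec$family == "logistic") {
    fit <- suppressWarnings(
      stats::glm(.spec_formula(spec, target), data = d,
                 family = stats::binomial(),
                 control = stats::glm.control(maxit = 100)))
    .check_rank(fit, target)
    if (!fit$converged)
      stop("logistic model for '", target, "' did not converge",
           call. = FALSE)
    out <- list(spec = spec, fit = fit, n = nrow(d), converged = TRUE)
  } else {
    lv <- levels(d[[target]])
    lv <- lv[lv %in% unique(as.character(d[[target]]))]
    if (length(lv) < 2)
      stop("multinomial target '", target, "' has fewer than 2 observed ",
           "levels", call. = FALSE)
    fits <- list()
    for (j in seq_len(length(lv) - 1)) {
      dj <- d[as.character(d[[target]]) %in% lv[j:length(lv)], ,
              drop = FALSE]
      dj$.ind <- as.integer(as.character(dj[[target]]) == lv[j])
      fj <- suppressWarnings(
        stats::glm(.spec_formula(spec, ".ind"), data = dj,
                   family = stats::binomial(),
                   control = stats::glm.control(maxit = 100)))
      .check_rank(fj, paste0(target, " [", lv[j], "]"))
      if (!fj$converged)
        stop("multinomial model for '", target, "' (level ", lv[j],
             ") did not converge", call. = FALSE)
      fits[[lv[j]]] <- fj
    }
    out <- list(spec = spec, fits = fits, levels = lv,
                all_levels = levels(d[[target]]), n = nrow(d),
                converged = TRUE)
  }
  class(out) <- c(paste0("pt_fit_", spec$family), "pt_fit")
  out
}

# conditional-mean prediction (linear: on the target's natural scale unless
# transform = log, in which case the log-scale linear predictor is returned)
predict_lp <- function(object, newdata) {
  UseMethod("predict_lp")
}

#' @export
predict_lp.pt_fit_linear <- function(object, newdata) {
  stats::predict(object$fit, newdata = newdata)
}

#' @export
predict_lp.pt_fit_logistic <- function(object, newdata) {
  stats::predict(object$fit, newdata = newdata, type = "response")
}

#' @export
predict_lp.pt_fit_multinomial <- function(object, newdata) {
  # matrix of level probabilities
  n <- nrow(newdata)
  lv <- object$levels
  probs <- matrix(0, n, length(lv), dimnames = list(NULL, lv))
  remaining <- rep(1, n)
  for (j in seq_len(length(lv) - 1)) {
    pj <- stats::predict(object$fits[[lv[j]]], newdata = newdata,
                         type = "response")
    probs[, j] <- remaining * pj
    remaining <- remaining * (1 - pj)
  }
  probs[, length(lv)] <- remaining
  probs
}

# stochastic simulation of the target given newdata (RNG must be seeded by
# the caller)
simulate_fit <- function(object, newdata) {
  UseMethod("simulate_fit")
}

#' @export
simulate_fit.pt_fit_linear <- function(object, newdata) {
  mu <- unname(stats::predict(object$fit, newdata = newdata))
  res <- object$residuals
  y <- mu + sample(res, length(mu), replace = TRUE)
  if (object$spec$transform == "log") y <- exp(y)
  pmin(pmax(y, object$range[1]), object$range[2])
}

#' @export
simulate_fit.pt_fit_logistic <- function(object, newdata) {
  p <- stats::predict(object$fit, newdata = newdata, type = "response")
  stats::rbinom(length(p), 1, p)
}

#' @export
simulate_fit.pt_fit_multinomial <- function(object, newdata) {
  probs <- predict_lp(object, newdata)
  u <- stats::runif(nrow(probs))
  cum <- t(apply(probs, 1, cumsum))
  idx <- rowSums(u > cum) + 1L
  factor(object$levels[idx], levels = object$all_levels)
}

# -- fitting the full set ----------------------------------------------------

#' Fit all parametric models required by the g-formula
#'
#' Outcome models are fitted on uncensored records only (the implicit
#' "abolish censoring" intervention); covariate, exposure and censoring
#' models use all eligible records. Errors name the offending model on
#' non-convergence or rank deficiency.
#'
#' @param cohort an eligible `pt_cohort` (run [apply_eligibility()] first).
#' @param specs output of [default_model_specs()] (or a modified copy).
#' @param components which model blocks to fit; the empirical
#'   (regression-standardization) engine mode only needs `"outcomes"`, which
#'   makes bootstrap replicates much cheaper.
#' @return a `pt_models` set.
#' @export
fit_all <- function(cohort, specs = default_model_specs(cohort$schema),
                    components = c("covariates", "y1", "exposure",
                                   "outcomes", "censoring")) {
  stopifnot(inherits(cohort, "pt_cohort"))
  components <- match.arg(components, several.ok = TRUE)
  d <- prep_model_data(cohort)
  d$cens_death <- as.integer(d$censor == "death")
  d$at_risk_ltfu <- d$censor != "death"
  d$cens_ltfu <- as.integer(d$censor == "ltfu")
  uncens <- d[d$censor == "none", , drop = FALSE]

  wrap <- function(spec, data) {
    tryCatch(fit_one(spec, data),
             error = function(e) stop("fit_all: ", conditionMessage(e),
                                      call. = FALSE))
  }
  has <- function(x) x %in% components
  covariate_fits <- if (has("covariates"))
    lapply(specs$covariates, wrap, data = d) else list()
  y1_fits <- if (has("y1")) lapply(specs$y1, wrap, data = d) else list()
  exposure_fit <- if (has("exposure")) wrap(specs$exposure, d)
  outcome_fits <- if (has("outcomes"))
    lapply(specs$outcomes, wrap, data = uncens) else list()
  censoring_fits <- if (has("censoring"))
    lapply(specs$censoring, wrap, data = d) else list()

  diag <- data.frame(
    model = c(names(covariate_fits), names(y1_fits),
              if (!is.null(exposure_fit)) "exposure",
              names(outcome_fits), names(censoring_fits)),
    n = c(vapply(covariate_fits, `[[`, 0L, "n"),
          vapply(y1_fits, `[[`, 0L, "n"),
          if (!is.null(exposure_fit)) exposure_fit$n,
          vapply(outcome_fits, `[[`, 0L, "n"),
          vapply(censoring_fits, `[[`, 0L, "n")),
    converged = TRUE,
    stringsAsFactors = FALSE
  )
  structure(list(schema = cohort$schema, specs = specs,
                 covariate_fits = covariate_fits, y1_fits = y1_fits,
                 exposure_fit = exposure_fit, outcome_fits = outcome_fits,
                 censoring_fits = censoring_fits,
                 data = d, n = nrow(d), diagnostics = diag),
            class = "pt_models")
}

#' @export
print.pt_models <- function(x, ...) {
  cat("<pt_models> fitted on n =", x$n, "eligible records\n")
  print(x$diagnostics, row.names = FALSE)
  invisible(x)
}

#' Predict end-of-follow-up outcome means
#'
#' Evaluates the fitted outcome models at an intervened exposure value and a
#' complete simulated (or observed) history. Pure function of its inputs;
#' unseen categorical levels raise an error rather than extrapolating.
#'
#' @param models a `pt_models` set.
#' @param a exposure value(s), g/kg/day (recycled to `nrow(history)`).
#' @param history data.frame of prepared history columns.
#' @return matrix (rows of `history` x outcomes) of conditional means.
#' @export
predict_outcome <- function(models, a, history) {
  stopifnot(inherits(models, "pt_models"))
  nd <- history
  a1 <- paste0(models$schema$exposure, 1)
  nd[[a1]] <- rep_len(a, nrow(nd))
  nd[[paste0("log_", a1)]] <- log(nd[[a1]])
  out <- vapply(models$outcome_fits,
                function(f) as.numeric(predict_lp(f, nd)),
                numeric(nrow(nd)))
  if (is.null(dim(out))) out <- matrix(out, nrow = nrow(nd))
  colnames(out) <- sub("2$", "", names(models$outcome_fits))
  out
}
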