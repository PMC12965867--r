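# Synthetic WHI-like cohort generator with known counterfactual truth.
#
# Structural model (all covariate terms centred so stated means are marginal
# means; a_ref = 1 g/kg/day):
#
#   U ~ N(0,1)                      shared latent "adiposity" factor
#   x0 fixed covariates + AR(1) time-varying continuous covariates
#   z0 = mu_A + b'x0c + sA*eps0,    A0 = shift + exp(z0)
#   z1 = mu_A + b'x1c + sA*(rz*eps0 + sqrt(1-rz^2)*eps1),  A1 = shift+exp(z1)
#   Y0_k = m_k + lam_k U + g_k'x0c + e0_k
#   Y1_k = m_k + lam_k U + g_k'x1c + phi_k (A0 - 1) + e1_k
#   Y2_k = m_k + lam_k U + g_k'x1c + beta_k (Aset - 1) + e2_k
#   e_t  = r*e_{t-1} + sqrt(1-r^2)*s_k*eta_t   (stationary AR(1), var s_k^2)
#
# The exposure is a shifted (three-parameter) log-normal calibrated so the
# baseline category distribution approximates the published one (41% in
# 0.5-0.8, 11% above 1.5 g/kg/day). Censoring (death, loss to follow-up) is
# missing-at-random given (L1, A1): counterfactual means are defined under
# no censoring and are invariant to censoring parameters.

# marginal means / dispersions used for centring (shared by generator, truth)
.dgp_marginals <- function() {
  list(
    age = c(mean = 63.4, sd = 7.4), hei = c(mean = 65.8, sd = 10.6),
    alcohol = c(mean = 1.9, sd = 4.4), met = c(mean = 12, sd = 10),
    cesd = c(mean = 0.12, sd = 0.08),
    log_energy = c(mean = 7.293, sd = 0.42),
    rho = c(hei = 0.65, alcohol = 0.7, met = 0.6, cesd = 0.6,
            log_energy = 0.7)
  )
}

#' Synthetic data-generating-process configuration
#'
#' Defaults emulate the eligible postmenopausal DXA sub-cohort: n = 4681,
#' age 50-79 (mean 63.4), the published race/ethnicity/income/education/
#' marital/sleep/smoking margins, right-skewed protein intake with ~41% of
#' baseline intake in 0.5-0.8 g/kg/day and ~11% above 1.5, correlated
#' body-composition outcomes, and ~3.4% deaths / ~12.1% loss to follow-up.
#'
#' @param n cohort size.
#' @param seed default RNG seed used by [generate_cohort()].
#' @param effect_protein named per-outcome slope of the end-of-follow-up
#'   outcome on baseline protein intake (units per g/kg/day). The default
#'   fixes the visceral-adipose slope at -10 cm^2 per g/kg/day and scales the
#'   other outcomes to the published effect ratios.
#' @param confounding scale factor on the exposure model's covariate
#'   coefficients; 0 gives an unconfounded exposure.
#' @param clip_outcomes clip generated outcomes into physiologic ranges
#'   (VAT/SAT >= 1 cm^2, percentages in (0.5, 99.5), weight >= 30 kg).
#'   Must be `FALSE` for the closed-form truth method, which assumes a purely
#'   linear structural model.
#' @param missing_protein_rate fraction of records with pre-baseline protein
#'   set missing (exercises the eligibility filter).
#' @param censoring generate death / loss-to-follow-up censoring.
#' @param overrides named list merged over the built config (advanced use).
#' @return a `pt_dgp_config`.
#' @export
dgp_config <- function(n = 4681, seed = 1L,
                       effect_protein = c(vat = -10, sat = -19.3,
                                          fatpct = -0.76, leanpct = 0.69,
                                          weight = -1.91),
                       confounding = 1,
                       clip_outcomes = TRUE,
                       missing_protein_rate = 0.01,
                       censoring = TRUE,
                       overrides = NULL) {
  stopifnot(n > 0, confounding >= 0)
  mg <- .dgp_marginals()
  outcomes <- c("vat", "sat", "fatpct", "leanpct", "weight")
  eff <- c(vat = 0, sat = 0, fatpct = 0, leanpct = 0, weight = 0)
  eff[names(effect_protein)] <- effect_protein
  cfg <- list(
    n = as.integer(n), seed = as.integer(seed),
    schema = default_schema(),
    outcomes = outcomes,
    marginals = mg,
    categorical_probs = list(
      race = c(aian = 0.0105, asian = 0.0048, black = 0.1111,
               white = 0.8673, multi = 0.0063),
      income = c(lt35k = 0.523, `35to75k` = 0.347, ge75k = 0.130),
      educ = c(hs_or_less = 0.3007, some_college = 0.3558,
               college = 0.1822, graduate = 0.1613),
      marital = c(never = 0.039, divorced = 0.138, widowed = 0.194,
                  married = 0.618, marriage_like = 0.011),
      sleep = c(le5 = 0.090, h6 = 0.267, h7 = 0.380, h8 = 0.216,
                ge9 = 0.047),
      smoking = c(never = 0.500, former = 0.344, current = 0.156)
    ),
    binary_probs = c(hispanic = 0.074, diabetes = 0.062, cancer = 0.095),
    # visit-to-visit transition matrix (rows: from; cols: to). Mostly
    # persistent, with current -> former quitting and small off-diagonal
    # probabilities (reporting noise / relapse) so no cell is structurally
    # empty.
    smoking_transition = matrix(
      c(0.97, 0.02, 0.01,
        0.02, 0.93, 0.05,
        0.01, 0.14, 0.85),
      nrow = 3, byrow = TRUE,
      dimnames = list(c("never", "former", "current"),
                      c("never", "former", "current"))),
    exposure = list(
      shift = 0.45, mu = -0.878, sigma = 0.6213, rho_z = 0.5,
      coefs = confounding * c(hei = 0.015, met = 0.012, age = -0.004,
                              log_energy = 0.9),
      smoking_coefs = confounding * c(never = 0, former = -0.03,
                                      current = -0.10)
    ),
    outcome_params = list(
      mean = c(vat = 153.6, sat = 358.5, fatpct = 43.2, leanpct = 53.9,
               weight = 70.1),
      sd = c(vat = 81.7, sat = 135.2, fatpct = 7.2, leanpct = 7.5,
             weight = 15.0),
      loading = c(vat = 60, sat = 100, fatpct = 5.5, leanpct = -5.5,
                  weight = 10),
      gamma = list(
        vat = c(hei = -1.5, met = -1.5, age = 0.8, diabetes = 20, cesd = 30),
        sat = c(hei = -2.5, met = -2.5, age = 1.33, diabetes = 33, cesd = 50),
        fatpct = c(hei = -0.10, met = -0.12, age = 0.05, diabetes = 1.2,
                   cesd = 2),
        leanpct = c(hei = 0.10, met = 0.12, age = -0.05, diabetes = -1.2,
                    cesd = -2),
        weight = c(hei = -0.15, met = -0.20, age = -0.05, diabetes = 3,
                   cesd = 3)
      ),
      rho = 0.7,
      effect = eff,
      effect_a0 = 0.5 * eff,   # pre-baseline intake effect on baseline outcome
      a_ref = 1.0
    ),
    censoring_params = list(
      enabled = isTRUE(censoring),
      death = list(intercept = stats::qlogis(0.0335),
                   age = 0.06, diabetes = 0.6, cesd = 1.0, a1 = -0.15),
      ltfu = list(intercept = stats::qlogis(0.1251),
                  age = 0.02, cesd = 0.8, current_smoker = 0.3, a1 = -0.1)
    ),
    clip_outcomes = isTRUE(clip_outcomes),
    missing_protein_rate = missing_protein_rate
  )
  if (!is.null(overrides)) cfg <- utils::modifyList(cfg, overrides)
  cfg <- .finalize_dgp(cfg)
  structure(cfg, class = "pt_dgp_config")
}

# derive residual SDs from target marginal SDs and validate
.finalize_dgp <- function(cfg) {
  op <- cfg$outcome_params
  mg <- cfg$marginals
  sds <- c(hei = mg$hei[["sd"]], met = mg$met[["sd"]], age = mg$age[["sd"]],
           cesd = mg$cesd[["sd"]])
  pdiab <- cfg$binary_probs[["diabetes"]]
  resid_sd <- vapply(cfg$outcomes, function(k) {
    g <- op$gamma[[k]]
    vg <- sum((g[setdiff(names(g), "diabetes")] *
                 sds[setdiff(names(g), "diabetes")])^2)
    if ("diabetes" %in% names(g))
      vg <- vg + g[["diabetes"]]^2 * pdiab * (1 - pdiab)
    v <- op$sd[[k]]^2 - op$loading[[k]]^2 - vg
    if (v <= 0)
      stop("outcome '", k, "': loading + covariate effects exceed the ",
           "target marginal variance", call. = FALSE)
    sqrt(v)
  }, 0)
  cfg$outcome_params$resid_sd <- resid_sd
  for (p in cfg$categorical_probs)
    assert_that(abs(sum(p) - 1) < 1e-6, "categorical probs must sum to 1")
  assert_that(cfg$exposure$sigma > 0, "exposure residual SD must be > 0")
  cfg
}

# -- structural simulation ---------------------------------------------------

.draw_cat <- function(n, probs) {
  factor(sample(names(probs), n, replace = TRUE, prob = probs),
         levels = names(probs))
}

# centred covariate effect sum for one visit ("0" or "1")
.gamma_term <- function(g, st, visit, mg) {
  out <- 0
  for (nm in names(g)) {
    x <- switch(nm,
                age = st$age - mg$age[["mean"]],
                diabetes = st$diabetes - attr(st, "pdiab"),
                hei = st[[paste0("hei", visit)]] - mg$hei[["mean"]],
                met = st[[paste0("met", visit)]] - mg$met[["mean"]],
                cesd = st[[paste0("cesd", visit)]] - mg$cesd[["mean"]],
                stop("unknown gamma covariate ", nm))
    out <- out + g[[nm]] * x
  }
  out
}

# exposure linear predictor deviation b'xc at a visit
.exposure_lp <- function(cfg, st, visit) {
  b <- cfg$exposure$coefs
  mg <- cfg$marginals
  sm <- cfg$exposure$smoking_coefs
  smc <- sm - sum(sm * cfg$categorical_probs$smoking)
  lp <- b[["hei"]] * (st[[paste0("hei", visit)]] - mg$hei[["mean"]]) +
    b[["met"]] * (st[[paste0("met", visit)]] - mg$met[["mean"]]) +
    b[["age"]] * (st$age - mg$age[["mean"]]) +
    b[["log_energy"]] * (st[[paste0("log_energy", visit)]] -
                           mg$log_energy[["mean"]])
  lp + smc[as.character(st[[paste0("smoking", visit)]])]
}

# Simulate the full structural model for n individuals. `a_setter` maps the
# natural baseline intake to the intervened intake (identity for the
# observational world). RNG must already be seeded by the caller.
.simulate_structural <- function(cfg, n, a_setter = identity) {
  mg <- cfg$marginals
  op <- cfg$outcome_params
  ex <- cfg$exposure
  st <- list()
  st$age <- pmin(pmax(stats::rnorm(n, mg$age[["mean"]], mg$age[["sd"]]),
                      50), 79)
  for (nm in c("race", "income", "educ", "marital", "sleep"))
    st[[nm]] <- .draw_cat(n, cfg$categorical_probs[[nm]])
  for (nm in names(cfg$binary_probs))
    st[[nm]] <- stats::rbinom(n, 1, cfg$binary_probs[[nm]])
  st$smoking0 <- .draw_cat(n, cfg$categorical_probs$smoking)
  P <- cfg$smoking_transition
  lv <- colnames(P)
  s1 <- character(n)
  for (from in rownames(P)) {
    rows <- which(st$smoking0 == from)
    if (length(rows))
      s1[rows] <- sample(lv, length(rows), replace = TRUE, prob = P[from, ])
  }
  st$smoking1 <- factor(s1, levels = lv)
  for (nm in c("hei", "alcohol", "met", "cesd", "log_energy")) {
    m <- mg[[nm]][["mean"]]; s <- mg[[nm]][["sd"]]; r <- mg$rho[[nm]]
    x0 <- stats::rnorm(n, m, s)
    x1 <- m + r * (x0 - m) + stats::rnorm(n, 0, s * sqrt(1 - r^2))
    st[[paste0(nm, "0")]] <- x0
    st[[paste0(nm, "1")]] <- x1
  }
  attr(st, "pdiab") <- cfg$binary_probs[["diabetes"]]

  eps0 <- stats::rnorm(n)
  z0 <- ex$mu + .exposure_lp(cfg, st, "0") + ex$sigma * eps0
  st$a0 <- ex$shift + exp(z0)
  z1 <- ex$mu + .exposure_lp(cfg, st, "1") +
    ex$sigma * (ex$rho_z * eps0 + sqrt(1 - ex$rho_z^2) * stats::rnorm(n))
  st$a1_natural <- ex$shift + exp(z1)
  st$a1 <- a_setter(st$a1_natural)

  U <- stats::rnorm(n)
  r <- op$rho
  for (k in cfg$outcomes) {
    s_k <- op$resid_sd[[k]]
    e0 <- stats::rnorm(n, 0, s_k)
    e1 <- r * e0 + sqrt(1 - r^2) * stats::rnorm(n, 0, s_k)
    e2 <- r * e1 + sqrt(1 - r^2) * stats::rnorm(n, 0, s_k)
    base_k <- op$mean[[k]] + op$loading[[k]] * U
    g <- op$gamma[[k]]
    st[[paste0(k, "0")]] <- base_k + .gamma_term(g, st, "0", mg) + e0
    st[[paste0(k, "1")]] <- base_k + .gamma_term(g, st, "1", mg) +
      op$effect_a0[[k]] * (st$a0 - op$a_ref) + e1
    st[[paste0(k, "2")]] <- base_k + .gamma_term(g, st, "1", mg) +
      op$effect[[k]] * (st$a1 - op$a_ref) + e2
  }
  if (cfg$clip_outcomes) {
    for (v in 0:2) {
      for (k in intersect(c("vat", "sat"), cfg$outcomes))
        st[[paste0(k, v)]] <- pmax(st[[paste0(k, v)]], 1)
      for (k in intersect(c("fatpct", "leanpct"), cfg$outcomes))
        st[[paste0(k, v)]] <- pmin(pmax(st[[paste0(k, v)]], 0.5), 99.5)
      if ("weight" %in% cfg$outcomes)
        st[[paste0("weight", v)]] <- pmax(st[[paste0("weight", v)]], 30)
    }
  }
  st
}

#' Generate a synthetic cohort
#'
#' Deterministic given `(config, seed)`. The exposure depends on diet
#' quality, physical activity, age, energy intake and smoking, all of which
#' also enter the outcomes, so confounding is real: the crude
#' exposure-outcome contrast differs from the structural effect. Censored
#' records have their end-of-follow-up outcomes removed but retain complete
#' pre-baseline and baseline data.
#'
#' @param config a [dgp_config()].
#' @param seed RNG seed; defaults to `config$seed`.
#' @return a `pt_cohort`.
#' @export
generate_cohort <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "pt_dgp_config"))
  with_seed(seed, {
    n <- config$n
    st <- .simulate_structural(config, n)
    cp <- config$censoring_params
    censor <- rep("none", n)
    if (isTRUE(cp$enabled)) {
      mg <- config$marginals
      dl <- cp$death
      lp_d <- dl$intercept + dl$age * (st$age - mg$age[["mean"]]) +
        dl$diabetes * st$diabetes +
        dl$cesd * (st$cesd1 - mg$cesd[["mean"]]) + dl$a1 * (st$a1 - 1)
      death <- stats::rbinom(n, 1, stats::plogis(lp_d)) == 1
      ll <- cp$ltfu
      lp_l <- ll$intercept + ll$age * (st$age - mg$age[["mean"]]) +
        ll$cesd * (st$cesd1 - mg$cesd[["mean"]]) +
        ll$current_smoker * (st$smoking1 == "current") + ll$a1 * (st$a1 - 1)
      ltfu <- !death & stats::rbinom(n, 1, stats::plogis(lp_l)) == 1
      censor[death] <- "death"
      censor[ltfu] <- "ltfu"
    }
    d <- data.frame(id = sprintf("P%05d", seq_len(n)))
    fixed <- c("age", "race", "hispanic", "income", "educ", "marital",
               "sleep", "diabetes", "cancer")
    for (nm in fixed) d[[nm]] <- st[[nm]]
    for (nm in c("smoking", "hei", "alcohol", "met", "cesd"))
      for (v in 0:1) d[[paste0(nm, v)]] <- st[[paste0(nm, v)]]
    d$energy0 <- exp(st$log_energy0)
    d$energy1 <- exp(st$log_energy1)
    d$a0 <- st$a0
    d$a1 <- st$a1
    for (k in config$outcomes)
      for (v in 0:2) d[[paste0(k, v)]] <- st[[paste0(k, v)]]
    d$grams0 <- d$a0 * d$weight0
    d$grams1 <- d$a1 * d$weight1
    d$censor <- censor
    cens <- d$censor != "none"
    for (cl in paste0(config$outcomes, 2)) d[[cl]][cens] <- NA_real_
    if (config$missing_protein_rate > 0) {
      miss <- stats::runif(n) < config$missing_protein_rate
      d$a0[miss] <- NA_real_
      d$grams0[miss] <- NA_real_
    }
    as_cohort(d, config$schema)
  })
}

#' True counterfactual mean under an intervention strategy
#'
#' Computes E[Y2 under strategy] from the structural model with censoring
#' abolished, either by large-sample oracle simulation or, for purely linear
#' configurations (`clip_outcomes = FALSE`), in closed form: the truth is
#' `m_k + beta_k * (E[max(A1, t)] - a_ref)` with `E[max(A1, t)]` evaluated by
#' numerical integration over the exposure's shifted-log-normal mixture.
#'
#' @param config a [dgp_config()].
#' @param strategy a `pt_strategy`.
#' @param method `"oracle_simulation"` (default) or `"closed_form"`.
#' @param oracle_n simulation size (>= 1e6) for the oracle method.
#' @param seed oracle RNG seed.
#' @return a `pt_truth` list: `strategy`, `true_mean` (named per-outcome),
#'   `se` (0 for closed form), `method`, `oracle_n`.
#' @export
true_intervention_mean <- function(config, strategy,
                                   method = c("oracle_simulation",
                                              "closed_form"),
                                   oracle_n = 1e6, seed = 20260911L) {
  stopifnot(inherits(config, "pt_dgp_config"),
            inherits(strategy, "pt_strategy"))
  method <- match.arg(method)
  if (method == "closed_form") {
    if (config$clip_outcomes)
      stop("closed-form truth requires clip_outcomes = FALSE ",
           "(purely linear structural model)", call. = FALSE)
    ea <- .expected_intervened_intake(config, strategy)
    op <- config$outcome_params
    mu <- op$mean[config$outcomes] + op$effect[config$outcomes] *
      (ea - op$a_ref)
    return(structure(list(strategy = strategy, true_mean = mu,
                          se = setNames(rep(0, length(mu)), names(mu)),
                          method = "closed_form", oracle_n = NA_integer_),
                     class = "pt_truth"))
  }
  if (oracle_n < 1e6)
    stop("oracle_n must be >= 1e6 for a simulated truth record",
         call. = FALSE)
  chunk <- 1e6
  k <- length(config$outcomes)
  sums <- sq <- setNames(rep(0, k), config$outcomes)
  total <- 0
  with_seed(seed, {
    remaining <- oracle_n
    while (remaining > 0) {
      m <- as.integer(min(chunk, remaining))
      st <- .simulate_structural(config, m,
                                 a_setter = function(a)
                                   apply_intervention(a, strategy))
      for (nm in config$outcomes) {
        y <- st[[paste0(nm, 2)]]
        sums[nm] <- sums[nm] + sum(y)
        sq[nm] <- sq[nm] + sum(y^2)
      }
      total <- total + m
      remaining <- remaining - m
    }
  })
  mu <- sums / total
  se <- sqrt(pmax(sq / total - mu^2, 0) / total)
  structure(list(strategy = strategy, true_mean = mu, se = se,
                 method = "oracle_simulation", oracle_n = as.integer(total)),
            class = "pt_truth")
}

# E[intervened A1] by numerical integration over the marginal distribution of
# log(A1 - shift): a normal mixture over smoking level (the only categorical
# term in the exposure model), all other terms being Gaussian.
.expected_intervened_intake <- function(config, strategy) {
  ex <- config$exposure
  mg <- config$marginals
  b <- ex$coefs
  v_lin <- (b[["hei"]] * mg$hei[["sd"]])^2 +
    (b[["met"]] * mg$met[["sd"]])^2 +
    (b[["age"]] * mg$age[["sd"]])^2 +
    (b[["log_energy"]] * mg$log_energy[["sd"]])^2
  sdz <- sqrt(v_lin + ex$sigma^2)
  p0 <- config$categorical_probs$smoking
  # baseline smoking distribution after one transition step
  p1 <- drop(p0[rownames(config$smoking_transition)] %*%
               config$smoking_transition)
  smc <- ex$smoking_coefs - sum(ex$smoking_coefs * p0)
  tval <- if (strategy$kind == "threshold") strategy$t else -Inf
  total <- 0
  for (lv in names(p1)) {
    muz <- ex$mu + smc[[lv]]
    f <- function(z) pmax(ex$shift + exp(z), tval) * stats::dnorm(z, muz, sdz)
    total <- total + p1[[lv]] *
      stats::integrate(f, muz - 10 * sdz, muz + 10 * sdz,
                       rel.tol = 1e-10)$value
  }
  total
}

#' Write a DGP config to YAML / read it back
#' @param config a `pt_dgp_config`.
#' @param path YAML path.
#' @export
write_dgp_yaml <- function(config, path) {
  obj <- unclass(config)
  obj$schema <- NULL  # schema is reconstructed as the default on read
  P <- obj$smoking_transition
  obj$smoking_transition <- setNames(
    lapply(rownames(P), function(r) as.list(setNames(P[r, ], colnames(P)))),
    rownames(P))
  # yaml drops names on named atomic vectors; write them as mappings
  namify <- function(x) {
    if (is.list(x)) lapply(x, namify)
    else if (is.atomic(x) && !is.null(names(x))) as.list(x)
    else x
  }
  yaml::write_yaml(namify(obj), path)
  invisible(path)
}

#' @rdname write_dgp_yaml
#' @export
read_dgp_yaml <- function(path) {
  obj <- yaml::read_yaml(path)
  base <- unclass(dgp_config())
  # restore R structures that YAML flattens: named numeric vectors and the
  # smoking transition matrix (written row-wise as a mapping of mappings)
  restore <- function(cur, val) {
    if (is.matrix(cur)) {
      m <- do.call(rbind, lapply(val, unlist))
      rownames(m) <- names(val)
      return(m[rownames(cur), colnames(cur), drop = FALSE])
    }
    if (is.numeric(cur) && !is.null(names(cur))) {
      v <- unlist(val)
      return(v[names(cur)])
    }
    if (is.list(cur) && is.list(val)) {
      for (nm in intersect(names(val), names(cur)))
        cur[[nm]] <- restore(cur[[nm]], val[[nm]])
      extra <- setdiff(names(val), names(cur))
      for (nm in extra) cur[[nm]] <- val[[nm]]
      return(cur)
    }
    if (is.numeric(cur) || is.integer(cur)) return(unlist(val))
    val
  }
  for (nm in setdiff(names(obj), c("schema", "resid_sd")))
    base[[nm]] <- restore(base[[nm]], obj[[nm]])
  base$n <- as.integer(base$n)
  base$seed <- as.integer(base$seed)
  base$schema <- default_schema()
  structure(.finalize_dgp(base), class = "pt_dgp_config")
}
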