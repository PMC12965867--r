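# Cohort data model for the emulated trial.
#
# Time convention: index 0 = enrollment (pre-baseline), 1 = analytic baseline
# (the 3-year visit, "time zero" of the emulated trial), 2 = end of follow-up
# (the 6-year visit). Time-varying variable `x` is stored as columns x0/x1
# (and x2 for outcomes); time-fixed covariates use their bare name.

#' Declare a covariate
#'
#' @param name column stem.
#' @param type one of `"continuous"`, `"binary"`, `"categorical"`.
#' @param levels factor levels, required for categorical covariates. For
#'   ordered categoricals, give the levels in order; they are modelled as
#'   unordered multinomials regardless (strictly more flexible).
#' @param time_varying if `TRUE` the covariate has pre-baseline (`x0`) and
#'   baseline (`x1`) columns and receives its own covariate model in the
#'   g-formula; otherwise it is a single column carried forward.
#' @param transform `"identity"` or `"log"`; log-transformed covariates are
#'   modelled on the log scale (they must be strictly positive).
#' @param collapse optional named list merging sparse levels for modelling
#'   (e.g. `list(other = c("aian", "asian", "multi"))`): descriptive output
#'   keeps the full levels, models use the collapsed factor. Sparse cells
#'   otherwise break bootstrap refits (a resample can lose the level
#'   entirely, and prediction at an unseen level is an error by design).
#' @return a `pt_covariate` list.
#' @export
covariate <- function(name, type = c("continuous", "binary", "categorical"),
                      levels = NULL, time_varying = FALSE,
                      transform = c("identity", "log"), collapse = NULL) {
  type <- match.arg(type)
  transform <- match.arg(transform)
  if (type == "categorical" && is.null(levels))
    stop("categorical covariate '", name, "' needs levels", call. = FALSE)
  if (!is.null(collapse) && !all(unlist(collapse) %in% levels))
    stop("collapse refers to unknown levels of '", name, "'", call. = FALSE)
  structure(list(name = name, type = type, levels = levels,
                 time_varying = time_varying, transform = transform,
                 collapse = collapse),
            class = "pt_covariate")
}

#' Cohort schema
#'
#' Declares covariates, outcome stems and the exposure stem. The exposure is
#' protein intake in g per kg body weight per day (columns `a0`, `a1`);
#' outcomes are measured at all three visits (columns `y0`, `y1`, `y2`).
#'
#' @param covariates list of [covariate()] declarations.
#' @param outcomes character vector of outcome stems.
#' @param exposure exposure stem (default `"a"`).
#' @export
cohort_schema <- function(covariates, outcomes, exposure = "a") {
  stopifnot(length(outcomes) >= 1)
  names(covariates) <- vapply(covariates, `[[`, "", "name")
  structure(list(covariates = covariates, outcomes = outcomes,
                 exposure = exposure),
            class = "pt_schema")
}

#' Default WHI-like schema
#'
#' The covariate set mirrors a postmenopausal DXA sub-cohort: demographics and
#' socioeconomics (time-fixed), behavioural and diet-quality measures
#' (time-varying), and five body-composition outcomes (visceral and
#' subcutaneous abdominal adipose tissue in cm^2, body fat and lean soft
#' tissue percentages, and weight in kg).
#' @export
default_schema <- function() {
  cohort_schema(
    covariates = list(
      covariate("age", "continuous"),
      covariate("race", "categorical",
                levels = c("aian", "asian", "black", "white", "multi"),
                collapse = list(other = c("aian", "asian", "multi"))),
      covariate("hispanic", "binary"),
      covariate("income", "categorical",
                levels = c("lt35k", "35to75k", "ge75k")),
      covariate("educ", "categorical",
                levels = c("hs_or_less", "some_college", "college",
                           "graduate")),
      covariate("marital", "categorical",
                levels = c("never", "divorced", "widowed", "married",
                           "marriage_like"),
                collapse = list(married = c("married", "marriage_like"))),
      covariate("sleep", "categorical",
                levels = c("le5", "h6", "h7", "h8", "ge9")),
      covariate("smoking", "categorical",
                levels = c("never", "former", "current"), time_varying = TRUE),
      covariate("diabetes", "binary"),
      covariate("cancer", "binary"),
      covariate("hei", "continuous", time_varying = TRUE),
      covariate("alcohol", "continuous", time_varying = TRUE),
      covariate("met", "continuous", time_varying = TRUE),
      covariate("cesd", "continuous", time_varying = TRUE),
      covariate("energy", "continuous", time_varying = TRUE,
                transform = "log")
    ),
    outcomes = c("vat", "sat", "fatpct", "leanpct", "weight"),
    exposure = "a"
  )
}

# Column names of covariates at a visit (0 or 1).
covariate_columns <- function(schema, visit) {
  vapply(schema$covariates, function(cv) {
    if (cv$time_varying) paste0(cv$name, visit) else cv$name
  }, "")
}

outcome_columns <- function(schema, visit) paste0(schema$outcomes, visit)

#' Construct a cohort from a participant-level data frame
#'
#' One row per participant. Required columns: `id`, every covariate column
#' implied by the schema, `a0`/`a1` (exposure), outcome columns at visits
#' 0/1/2, and `censor` (one of `"none"`, `"death"`, `"ltfu"`). Outcome values
#' at visit 2 must be missing exactly for censored participants.
#'
#' @param data data.frame.
#' @param schema a [cohort_schema()]; defaults to [default_schema()].
#' @param validate check record invariants (default `TRUE`).
#' @return a `pt_cohort`.
#' @export
as_cohort <- function(data, schema = default_schema(), validate = TRUE) {
  stopifnot(is.data.frame(data))
  data <- as.data.frame(data)
  needed <- c("id",
              unique(c(covariate_columns(schema, 0),
                       covariate_columns(schema, 1))),
              paste0(schema$exposure, 0:1),
              outcome_columns(schema, 0), outcome_columns(schema, 1),
              outcome_columns(schema, 2), "censor")
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols))
    stop("cohort is missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  # coerce declared factor levels
  for (cv in schema$covariates) {
    cols <- if (cv$time_varying) paste0(cv$name, 0:1) else cv$name
    for (cl in cols) {
      if (cv$type == "categorical") {
        data[[cl]] <- factor(as.character(data[[cl]]), levels = cv$levels)
      } else if (cv$type == "binary") {
        data[[cl]] <- as.integer(data[[cl]])
      } else {
        data[[cl]] <- as.numeric(data[[cl]])
      }
    }
  }
  data$censor <- factor(as.character(data$censor),
                        levels = c("none", "death", "ltfu"))
  ch <- structure(list(data = data, schema = schema), class = "pt_cohort")
  if (validate) validate_cohort(ch)
  ch
}

#' Validate cohort record invariants
#'
#' Checks id uniqueness, censor coding, exposure positivity, weight
#' positivity, percentage outcomes within (0, 100), and that end-of-follow-up
#' outcomes are present exactly for uncensored participants.
#' @param cohort a `pt_cohort`.
#' @export
validate_cohort <- function(cohort) {
  d <- cohort$data
  sc <- cohort$schema
  assert_that(!anyDuplicated(d$id), "participant ids must be unique")
  assert_that(!any(is.na(d$censor)),
              "censor must be one of none/death/ltfu for every record")
  for (cl in paste0(sc$exposure, 0:1)) {
    v <- d[[cl]]
    assert_that(all(v[!is.na(v)] > 0),
                paste0(cl, " (protein g/kg/day) must be > 0 when present"))
  }
  pct <- intersect(c("fatpct", "leanpct"), sc$outcomes)
  for (p in pct) for (v in 0:2) {
    x <- d[[paste0(p, v)]]
    assert_that(all(x[!is.na(x)] > 0 & x[!is.na(x)] < 100),
                paste0(p, v, " must lie in (0, 100)"))
  }
  if ("weight" %in% sc$outcomes) for (v in 0:2) {
    x <- d[[paste0("weight", v)]]
    assert_that(all(x[!is.na(x)] > 0), paste0("weight", v, " must be > 0"))
  }
  uncens <- d$censor == "none"
  for (cl in outcome_columns(sc, 2)) {
    assert_that(all(is.na(d[[cl]][!uncens])),
                paste0(cl, " must be missing for censored records"))
    assert_that(all(!is.na(d[[cl]][uncens])),
                paste0(cl, " must be present for uncensored records"))
  }
  invisible(cohort)
}

#' @export
print.pt_cohort <- function(x, ...) {
  cat("<pt_cohort> ", nrow(x$data), " participants, ",
      length(x$schema$outcomes), " outcomes (",
      paste(x$schema$outcomes, collapse = ", "), ")\n", sep = "")
  print(censoring_summary(x))
  invisible(x)
}

#' Protein intake per kg body weight
#'
#' Daily protein in grams divided by body weight at the same visit.
#'
#' @param grams_per_day protein intake, g/day (>= 0).
#' @param weight_kg body weight at the same visit, kg (> 0).
#' @return g/kg/day.
#' @export
compute_protein_per_kg <- function(grams_per_day, weight_kg) {
  if (any(!is.na(grams_per_day) & grams_per_day < 0))
    stop("grams_per_day must be non-negative", call. = FALSE)
  if (any(!is.na(weight_kg) & weight_kg <= 0))
    stop("weight_kg must be positive", call. = FALSE)
  grams_per_day / weight_kg
}

#' Descriptive protein intake categories
#'
#' Intervals above 0.5 are left-open/right-closed, matching the usual
#' presentation (0.5-0.8, >0.8-1.0, >1.0-1.2, >1.2-1.5, >1.5); values at or
#' below 0.5 fall in `<0.5`. Descriptive use only.
#'
#' @param a protein intake, g/kg/day (> 0).
#' @return factor with the six category labels.
#' @export
categorize_protein <- function(a) {
  stopifnot(all(a[!is.na(a)] > 0))
  labs <- c("<0.5", "0.5-0.8", ">0.8-1.0", ">1.0-1.2", ">1.2-1.5", ">1.5")
  idx <- findInterval(a, c(0.5, 0.8, 1.0, 1.2, 1.5), left.open = TRUE) + 1L
  factor(labs[idx], levels = labs)
}

#' Eligibility filtering
#'
#' Removes records with implausible baseline energy intake (below 500 or
#' above 5000 kcal/day; exact boundary values are retained) and records
#' missing protein intake at either visit. Records missing any modelled
#' covariate or pre-baseline/baseline outcome value are also dropped
#' (complete-case analysis). Each record is counted once under the first
#' applicable reason.
#'
#' @param cohort a `pt_cohort`.
#' @return list with elements `cohort` (filtered) and `exclusions`
#'   (data.frame of reason/n, including `retained`).
#' @export
apply_eligibility <- function(cohort) {
  d <- cohort$data
  sc <- cohort$schema
  energy1 <- d[["energy1"]]
  bad_energy <- !is.na(energy1) & (energy1 < 500 | energy1 > 5000)
  a_cols <- paste0(sc$exposure, 0:1)
  bad_protein <- Reduce(`|`, lapply(a_cols, function(cl) is.na(d[[cl]])))
  model_cols <- unique(c(covariate_columns(sc, 0), covariate_columns(sc, 1),
                         outcome_columns(sc, 0), outcome_columns(sc, 1)))
  bad_covar <- Reduce(`|`, lapply(model_cols, function(cl) is.na(d[[cl]])))
  reason <- rep(NA_character_, nrow(d))
  reason[bad_covar] <- "incomplete_covariates"
  reason[bad_protein] <- "incomplete_protein"
  reason[bad_energy] <- "implausible_energy"
  keep <- is.na(reason)
  if (!any(keep)) stop("no records remain after eligibility filtering",
                       call. = FALSE)
  exclusions <- data.frame(
    reason = c("implausible_energy", "incomplete_protein",
               "incomplete_covariates", "retained"),
    n = c(sum(reason == "implausible_energy", na.rm = TRUE),
          sum(reason == "incomplete_protein", na.rm = TRUE),
          sum(reason == "incomplete_covariates", na.rm = TRUE),
          sum(keep)),
    stringsAsFactors = FALSE
  )
  out <- cohort
  out$data <- d[keep, , drop = FALSE]
  rownames(out$data) <- NULL
  list(cohort = out, exclusions = exclusions)
}

#' Censoring summary
#'
#' @param cohort a `pt_cohort`.
#' @return named integer vector with counts of `none`, `death`, `ltfu`.
#' @export
censoring_summary <- function(cohort) {
  tab <- table(factor(cohort$data$censor, levels = c("none", "death", "ltfu")))
  out <- as.integer(tab)
  names(out) <- names(tab)
  out
}

#' Read a cohort from CSV
#'
#' @param path CSV path, one row per participant.
#' @param schema a [cohort_schema()] or a path to a YAML schema file written
#'   by [write_schema_yaml()].
#' @export
read_cohort <- function(path, schema = default_schema()) {
  if (is.character(schema)) schema <- read_schema_yaml(schema)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  as_cohort(df, schema)
}

#' Write a cohort to CSV
#' @param cohort a `pt_cohort`.
#' @param path output path.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort$data, path, row.names = FALSE)
  invisible(path)
}

#' Write / read a schema as YAML
#' @param schema a `pt_schema`.
#' @param path YAML file path.
#' @export
write_schema_yaml <- function(schema, path) {
  obj <- list(
    exposure = schema$exposure,
    outcomes = as.list(schema$outcomes),
    covariates = lapply(unname(schema$covariates), function(cv) {
      out <- list(name = cv$name, type = cv$type,
                  time_varying = cv$time_varying, transform = cv$transform)
      if (!is.null(cv$levels)) out$levels <- as.list(cv$levels)
      if (!is.null(cv$collapse))
        out$collapse <- lapply(cv$collapse, as.list)
      out
    })
  )
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_schema_yaml
#' @export
read_schema_yaml <- function(path) {
  obj <- yaml::read_yaml(path)
  covs <- lapply(obj$covariates, function(cv) {
    covariate(cv$name, cv$type,
              levels = if (!is.null(cv$levels)) unlist(cv$levels),
              time_varying = isTRUE(cv$time_varying),
              transform = cv$transform %||% "identity",
              collapse = if (!is.null(cv$collapse))
                lapply(cv$collapse, unlist))
  })
  cohort_schema(covs, unlist(obj$outcomes), exposure = obj$exposure %||% "a")
}
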