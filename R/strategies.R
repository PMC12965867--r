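# Intervention strategies on baseline protein intake.
#
# A threshold strategy t enforces intake >= t g/kg/day at baseline and
# through follow-up; women already at or above t keep their natural intake
# (minimal-change lifting, a -> max(a, t)). The natural course leaves intake
# as it occurred and serves as the reference.

#' @export
natural_course <- function() {
  structure(list(kind = "natural_course", t = NA_real_),
            class = "pt_strategy")
}

#' Threshold intervention on protein intake
#' @param t threshold in g/kg/day (> 0). The study grid is 0.8, 1.0, 1.2, 1.5.
#' @export
threshold_intervention <- function(t) {
  stopifnot(is.numeric(t), length(t) == 1, is.finite(t), t > 0)
  structure(list(kind = "threshold", t = as.numeric(t)),
            class = "pt_strategy")
}

#' @export
print.pt_strategy <- function(x, ...) {
  cat("<strategy> ", strategy_label(x), "\n", sep = "")
  invisible(x)
}

#' Human-readable strategy label
#' @param strategy a `pt_strategy`.
#' @export
strategy_label <- function(strategy) {
  if (strategy$kind == "natural_course") "natural_course"
  else sprintf(">=%.1f g/kg/day", strategy$t)
}

#' Apply an intervention rule to natural exposure draws
#'
#' @param a_natural numeric vector of natural-course intakes (g/kg/day).
#' @param strategy a `pt_strategy`.
#' @return intervened intakes.
#' @export
apply_intervention <- function(a_natural, strategy) {
  stopifnot(inherits(strategy, "pt_strategy"))
  if (strategy$kind == "natural_course") a_natural
  else pmax(a_natural, strategy$t)
}

#' The study strategy grid
#'
#' Natural course plus thresholds 0.8, 1.0, 1.2 and 1.5 g/kg/day.
#' @export
strategy_grid <- function() {
  c(list(natural_course()),
    lapply(c(0.8, 1.0, 1.2, 1.5), threshold_intervention))
}

#' Parse a strategy string such as "nc,0.8,1.0,1.2,1.5"
#' @param x comma-separated tokens; `nc` (or `natural`) is the natural course,
#'   numbers are thresholds.
#' @export
parse_strategies <- function(x) {
  toks <- trimws(strsplit(x, ",")[[1]])
  lapply(toks, function(tk) {
    if (tolower(tk) %in% c("nc", "natural", "natural_course")) natural_course()
    else threshold_intervention(as.numeric(tk))
  })
}
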