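---
title: "Methods: threshold protein-intake interventions via the parametric g-formula"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: threshold protein-intake interventions via the parametric g-formula}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(proteintrial)
```

## The estimand and the emulated trial

The package estimates, for a cohort of postmenopausal women, the mean
end-of-follow-up body composition (visceral adipose tissue VAT in cm²,
abdominal subcutaneous adipose tissue SAT in cm², total body fat %, lean
soft tissue %, and weight in kg) that would be observed if every woman
adhered, from the analytic baseline through three years of follow-up, to a
*threshold intervention* on daily protein intake:

> set \(A \leftarrow \max(A, t)\), with \(A\) the usual intake in g per kg
> body weight per day and \(t \in \{0.8, 1.0, 1.2, 1.5\}\).

Women already at or above the threshold keep their natural intake: this
minimal-change reading is the standard pragmatic operationalization of
"adhere to at least \(t\)". The alternative — forcing everyone exactly to
\(t\) — would also lower the intake of already-adherent women and answers a
different question. This is the central interpretive decision of the
implementation; it preserves the natural course as the limiting case
\(t \to 0\).

The reference is the *natural course*: intake as it occurred. An average
treatment effect (ATE) is the difference between a strategy's standardized
mean and the natural-course standardized mean. The analysis is the
observational analogue of a per-protocol contrast in the target trial.

Time is indexed 0 (enrollment, "pre-baseline"), 1 (the 3-year visit, the
analytic baseline and the trial's time zero), and 2 (the 6-year visit, end
of follow-up). Covariates are measured at visits 0 and 1; outcomes at all
three (earlier outcome values act as covariates); the exposure is
intervened on at baseline only — dietary self-report is taken to reflect
usual intake over the surrounding years, so no within-follow-up exposure
updating is simulated.

## The estimator

The parametric g-formula (g-computation) with Monte Carlo standardization:

1. **Fit** parametric models on the eligible cohort: each baseline
   covariate given full pre-baseline history and previously listed baseline
   covariates (linear for continuous, logistic for binary, multinomial for
   categorical); each baseline outcome value given history; the exposure
   (log scale) given everything at baseline; each end-of-follow-up outcome
   given the exposure and the complete history; and logistic censoring
   models (diagnostics only, see below).
2. **Simulate** a pseudo-population: resample pre-baseline records with
   replacement, then draw baseline covariates, baseline outcome values and
   the natural-course exposure sequentially from the fitted conditionals.
3. **Intervene**: replace the natural draw \(a\) by \(\max(a, t)\).
4. **Standardize**: average the fitted outcome means evaluated at the
   intervened exposure and simulated history.

All strategies share one pseudo-population (common random numbers), so ATEs
are paired differences with small Monte Carlo error and the natural-course
ATE is identically zero. Default `mc_size` is 20,000 pseudo-individuals.

Two covariate-simulation modes are provided because the source description
does not say which was used: `"parametric"` (step 2 as above) and
`"empirical"` (use the observed baseline rows directly, which reduces the
estimator to regression standardization). Under a correctly specified
outcome model the two agree within Monte Carlo error, and that agreement is
enforced by a test. The heavy simulation experiments in the acceptance
suite use the empirical mode for runtime; the parametric mode is validated
against the same truth oracle at single-run scale.

**Censoring.** Deaths and losses to follow-up before the year-6 measurement
are censoring events. The primary estimator handles them by outcome-model
standardization: outcome models are fitted on uncensored records and
predictions are made for *all* pseudo-individuals — the g-formula's
implicit "abolish censoring" intervention, valid because the synthetic
censoring mechanism is missing-at-random given modelled baseline variables.
Censoring models are fitted for diagnostics, not used by the estimator.
Treating deaths as censoring (rather than as a competing event) mirrors the
emulated analysis; it is a known methodological ambiguity of that design.

**Inference.** Nonparametric bootstrap: resample participants with
replacement (after eligibility, matching the emulation order), refit all
models, rerun all strategies; 95% intervals are the 2.5th/97.5th
percentiles of 500 resamples by default. Percentile intervals were chosen
because nothing more specific than "bootstrap non-parametric sampling" is
stated; the choice is recorded in the output metadata. Replicates that fail
to fit (e.g. a rare factor level lost in resampling) are dropped and
counted; a failure rate above 10% is a hard error. Within-replicate Monte
Carlo seeds derive deterministically from (master seed, replicate index),
so results do not depend on execution order.

**Diagnostics.** The natural-course check compares simulated natural-course
means with observed uncensored means; an outcome is flagged when the gap
exceeds 5% of the observed SD (configurable). Passing is necessary, not
sufficient: a model that omits the exposure entirely still passes (the
natural course needs no exposure effect) while attenuating every ATE to
zero — this documented behaviour is itself tested.

## Eligibility and derived exposure

Records with baseline energy intake below 500 or above 5000 kcal/day are
excluded as implausible; exact boundary values are retained ("below … or
above" is read strictly). Records missing protein intake at either visit,
or any modelled covariate, are excluded with a logged reason (complete-case
analysis; no imputation procedure is specified for the emulated analysis).
Protein in g/kg/day is grams per day divided by measured body weight at the
same visit.

## The synthetic cohort and its truth

No public accession exists for the emulated cohort, so all validation runs
against a synthetic data-generating process (DGP) with known counterfactual
truth. The generator's defaults *are* the published cohort description:

* n = 4681 eligible women aged 50–79 (mean 63.4, SD 7.4); the published
  abstract's smaller n is a documented internal inconsistency of the source
  and the section-level figure is followed.
* Categorical margins (race, ethnicity, income, education, marital status,
  sleep, smoking, diabetes, cancer) match the published percentages.
* Exposure: a three-parameter (shifted) log-normal,
  \(A = 0.45 + \exp(z)\), \(z \sim N(\mu(L), \sigma^2)\), calibrated so the
  baseline category distribution reproduces the published table (≈41% in
  0.5–0.8, ≈11% above 1.5 g/kg/day). A two-parameter log-normal cannot
  satisfy those two percentages simultaneously (it puts ≈9% of mass below
  0.5 g/kg/day where the published table has essentially none), which is
  why the shift exists. \(\mu(L)\) depends on diet quality, physical
  activity, age, log energy intake and smoking — all of which also affect
  outcomes, so confounding is real: the crude exposure–outcome contrast is
  significantly different from the structural effect (tested).
* Outcomes: linear structural equations with a shared latent "adiposity"
  factor (loadings of opposite sign for fat and lean %) inducing the
  cross-outcome correlation, AR(1) person-level residuals across visits,
  and marginal means/SDs matching the published baseline table. The
  published baseline table prints body fat 54.2% / lean 42.8% while the
  results table prints 43.2% / 53.9% for the same quantities — an evident
  label swap; the generator follows the results-table orientation (also the
  one consistent with fat + lean + bone ≈ 100%).
* Protein effect: linear in \(A\) at baseline. The default VAT slope is
  −10 cm² per g/kg/day (the value the validation criteria fix); the other
  outcomes scale with the published effect ratios (SAT −19.3, fat −0.76,
  lean +0.69, weight −1.91 per g/kg/day). With the calibrated exposure
  distribution this yields a threshold(1.5) VAT effect of ≈ −5.6 cm² —
  the same order as, but smaller than, the published −13.1; the slope value
  was kept because the validation criteria pin it explicitly.
* Censoring: logistic in age, depression score, smoking, diabetes and
  intake, calibrated to ≈157 deaths and ≈566 losses to follow-up per 4681 —
  missing-at-random given modelled variables by construction, so the
  estimator's censoring handling is consistent.
* Outcomes are clipped to physiologic ranges (VAT/SAT ≥ 1 cm², percentages
  in (0.5, 99.5), weight ≥ 30 kg) by default. Clipping affects ~1–3% of
  draws and makes the structural model mildly non-linear; the closed-form
  truth is therefore only available with `clip_outcomes = FALSE`, and the
  clipped default is validated against the simulation oracle, which shares
  the generator's code path.

**Truth records.** `true_intervention_mean()` computes
\(E[Y_2(\max(A,t))]\) either by simulating ≥10⁶ individuals from the
structural model with censoring abolished (the oracle; default 10⁶–10⁷
draws with chunked accumulation), or, for the purely linear configuration,
in closed form: truth \(= m_k + \beta_k (E[\max(A,t)] - 1)\) with
\(E[\max(A,t)]\) evaluated by numerical integration over the exposure's
normal-mixture log scale. The two routes agree within oracle Monte Carlo
error (tested), and the truth is invariant to censoring parameters by
construction.

**What the generator does not emulate** — and hence what a green test does
not establish: the real joint covariate distribution (dependence is
stylized: demographics independent, continuous covariates AR(1) and
mutually independent given the latent factor), measurement error in the
food-frequency instrument, clinic-site clustering, sampling design, and any
non-linearity or effect modification in the true dose–response. Green
tests establish that the estimator recovers the truth *of this stated
world*; they cannot certify the published effect estimates.

## Numerical and design choices

* **Multinomial fits** use nested (sequential) binary logits via `glm` —
  an exact reparameterization of the saturated multinomial and a standard
  generative factorization otherwise (`nnet` is deliberately not a
  dependency). IRLS gets `maxit = 100`; non-convergence and rank deficiency
  are named errors, never warnings.
* **Residual resampling.** Simulated continuous covariates and the
  exposure add bootstrap-resampled fitted residuals rather than normal
  draws, then truncate to the observed range (standard g-formula practice
  against extrapolation). Residual resampling keeps simulated
  natural-course margins calibrated even when residuals are mildly
  non-normal — exactly what the natural-course diagnostic checks.
* **Sparse categorical levels** (race aian/asian/multi at ≤1.1%, marital
  "marriage-like" at 1.1%) are collapsed for modelling while full levels
  are kept descriptively. Without collapsing, a bootstrap resample at
  n = 2000 can lose a level among uncensored records; prediction for a
  censored carrier of that level is then an error by design (no silent
  extrapolation), and replicate failure rates can exceed the 10% bound.
* **Prediction at unseen categorical levels is an error**, not reference-
  level substitution. Dropped bootstrap replicates are the visible,
  counted consequence.
* **Eligibility boundaries** (exactly 500 / 5000 kcal) are retained.
* **Protein categories** above 0.5 g/kg/day are left-open/right-closed
  (0.8 belongs to 0.5–0.8); the bottom label `<0.5` absorbs values at or
  below 0.5. Descriptive use only.
* **Ties and ordering.** Strategies are keyed by threshold; duplicates are
  an error; the natural course is always reordered first as the reference.
* **Output precision**: CSV tables round to one decimal (presentation
  precision for cm², kg and %); JSON keeps full precision. Pipeline run
  logs record every seed, count and a hash of the model specification, and
  reruns are byte-identical.

## Known limitations

* One decision point: no time-varying strategies with treatment–confounder
  feedback, no dynamic regimes, no effect-modification analyses.
* Deaths are censoring, not a competing event; the estimand is the one the
  emulated design targets, with the interpretive caveats that carries.
* The bootstrap is percentile-only; no BCa, no simultaneous bands, and no
  multiplicity adjustment across the five outcomes (intervals are reported
  per outcome, as in the emulated analysis).
* The parametric mode simulates covariates from main-effects conditionals;
  interactions or splines must be added through the model-spec interface if
  the data call for them.
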