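# proteintrial

Target-trial emulation of hypothetical dietary protein interventions on
body composition in postmenopausal women, estimated with the **parametric
g-formula** (g-computation) and nonparametric bootstrap confidence
intervals.

## Who this is for

Epidemiologists and biostatisticians who want a tested, reusable pipeline
for *threshold interventions on a continuous exposure*: "what if every
woman consumed at least *t* g of protein per kg body weight per day?" The
package ships a synthetic cohort generator with fully known counterfactual
truth, so every stage of the estimator is validated without access to the
restricted source data it emulates.

## The estimator

For strategies *t* ∈ {0.8, 1.0, 1.2, 1.5} g/kg/day plus the natural course
(no intervention, the reference), the standardized mean outcome under
strategy *g* is

```
E[Y(g)] = E_L [ E( Y | A = g(A), L ) ],   g(a) = max(a, t)
```

estimated by (1) fitting parametric models for baseline covariates given
pre-baseline history, for the exposure, for each end-of-follow-up outcome
given exposure and history, and for censoring; (2) Monte Carlo simulation
of a pseudo-population from the fitted conditionals; (3) setting the
exposure by the intervention rule; (4) averaging predicted outcomes.
Already-adherent women keep their natural intake (minimal-change lifting).
Censoring (death, loss to follow-up) is abolished by predicting outcomes
for all pseudo-individuals from models fitted on uncensored records. All
strategies share one pseudo-population (common random numbers), so average
treatment effects versus the natural course are paired contrasts. 95% CIs
come from a percentile bootstrap over participants (500 resamples by
default). Details and design decisions: `vignettes/protein-gformula-methods.Rmd`.

## Worked example

```r
library(proteintrial)

cohort <- generate_cohort(dgp_config(n = 2000), seed = 1)  # synthetic, WHI-like
elig   <- apply_eligibility(cohort)   # 500-5000 kcal window, complete protein
models <- fit_all(elig$cohort)
est    <- run_all_strategies(models, strategy_grid(),
                             mc_size = 20000, seed = 1)
print(est)
```

```
<pt_gestimates> mode = parametric , mc_size = 20000
       strategy outcome   mean       ate   mc_se
 natural_course     vat 153.48   0.00000 0.48911
 ...
 >=1.2 g/kg/day     vat 151.29  -2.19335 0.48779
 >=1.5 g/kg/day     vat 149.39  -4.08940 0.48748
 >=1.5 g/kg/day     sat 341.62 -10.63162 0.85379
 >=1.5 g/kg/day  fatpct  42.41  -0.42688 0.04749
 >=1.5 g/kg/day leanpct  54.71   0.56719 0.04815
 >=1.5 g/kg/day  weight  68.62  -1.09873 0.09074
```

Reading: if everyone consumed ≥1.5 g/kg/day, mean visceral adipose tissue
after three years is estimated 4.1 cm² lower than under the natural course
(this cohort's true structural value is ≈ −5.4 cm²; n = 2000 sampling
noise accounts for the gap — the parameter-recovery tests quantify this).
Effects are monotone in the threshold and near-null at ≥0.8 and ≥1.0,
because most women already consume 0.5–0.8 g/kg/day and small thresholds
barely move the intake distribution.

The natural-course diagnostic (model-misspecification check) and bootstrap
CIs:

```r
natural_course_diagnostic(models, elig$cohort, seed = 1)
#   outcome observed_mean simulated_mean difference observed_sd  flag
#       vat        152.18         153.48       1.30       78.65 FALSE
#       ...                                      (all flags clear)

boot <- gf_bootstrap(elig$cohort, strategies = strategy_grid(),
                     n_resamples = 500, seed = 1)
effects_table(boot)   # strategy x outcome with 95% percentile CIs
```

Or end to end, writing CSV/JSON artifacts and a reproducibility log:

```r
res <- run_pipeline(list(dgp = list(n = 4681), seed = 1,
                         mc_size = 20000, n_resamples = 500,
                         out_dir = "report"))
```

A command-line launcher (`generate`, `estimate`, `bootstrap`, `report`)
ships in `inst/cli/proteintrial.R`; cohort CSVs are described by
`inst/extdata/data_dictionary.csv` and a YAML schema
(`inst/extdata/default_schema.yaml`).

## Validation against known truth

`true_intervention_mean()` computes each strategy's true counterfactual
mean from the synthetic structural model, by a ≥10⁶-draw oracle simulation
or in closed form for the purely linear configuration. The test suite
(`tests/testthat/test-acceptance.R`) checks: Monte Carlo standardization
against an exact plug-in oracle on discrete cohorts; recovery of the
threshold(1.5) effect at the emulated cohort size with <10% bias over 200
replicates; null protection under confounding (adjusted ATEs ≈ 0 while the
crude contrast is not); bootstrap coverage of the true effect; monotone
dose-response; and byte-identical reruns.

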