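test_that("generation is a pure function of (config, seed)", {
  cfg <- dgp_config(n = 500)
  a <- generate_cohort(cfg, seed = 7)
  b <- generate_cohort(cfg, seed = 7)
  expect_identical(a$data, b$data)
  c <- generate_cohort(cfg, seed = 8)
  expect_false(identical(a$data, c$data))
})

test_that("default cohort matches the published calibration targets", {
  ch <- generate_cohort(dgp_config(), seed = 1)
  d <- ch$data
  expect_equal(nrow(d), 4681)
  cat1 <- prop.table(table(categorize_protein(d$a1)))
  expect_gt(cat1[["0.5-0.8"]], 0.39)   # 41.0% +/- 2pp
  expect_lt(cat1[["0.5-0.8"]], 0.43)
  expect_gt(cat1[[">1.5"]], 0.09)      # 11.0% +/- 2pp
  expect_lt(cat1[[">1.5"]], 0.13)
  # baseline outcome marginals (generous 4-sigma-of-the-mean bands)
  expect_equal(mean(d$vat0), 153.6, tolerance = 0.05)
  expect_equal(mean(d$weight0), 70.1, tolerance = 0.02)
  expect_equal(sd(d$vat0), 81.7, tolerance = 0.05)
  # censoring counts near the emulated cohort's 157 deaths / 566 ltfu
  cs <- censoring_summary(ch)
  expect_true(cs[["death"]] > 110 && cs[["death"]] < 230)
  expect_true(cs[["ltfu"]] > 450 && cs[["ltfu"]] < 720)
  # censored records retain baseline data but no end-of-follow-up outcomes
  cens <- d$censor != "none"
  expect_true(all(is.na(d$vat2[cens])))
  expect_true(all(!is.na(d$vat1[cens])))
  # grams/day and g/kg/day are consistent with the per-visit weight
  expect_equal(compute_protein_per_kg(d$grams1, d$weight1), d$a1,
               tolerance = 1e-12)
})

test_that("exposure is genuinely confounded under defaults and not under
           confounding = 0", {
  ch <- generate_cohort(dgp_config(missing_protein_rate = 0), seed = 3)
  crude <- summary(lm(vat2 ~ a1, data = ch$data))$coefficients["a1", ]
  # crude slope differs from the structural -10 by more than 3 SE
  expect_gt(abs(crude[["Estimate"]] - (-10)) / crude[["Std. Error"]], 3)
  ch0 <- generate_cohort(dgp_config(confounding = 0, censoring = FALSE,
                                    missing_protein_rate = 0), seed = 3)
  crude0 <- summary(lm(vat2 ~ a1, data = ch0$data))$coefficients["a1", ]
  expect_lt(abs(crude0[["Estimate"]] - (-10)) / crude0[["Std. Error"]], 3)
})

test_that("truth: threshold at/below the intake floor reproduces the natural
           course; means are monotone in the threshold", {
  cfg <- dgp_config(clip_outcomes = FALSE)
  nc <- true_intervention_mean(cfg, natural_course(), method = "closed_form")
  floor_t <- true_intervention_mean(cfg, threshold_intervention(0.45),
                                    method = "closed_form")
  expect_equal(floor_t$true_mean, nc$true_mean, tolerance = 1e-10)
  means <- sapply(c(0.8, 1.0, 1.2, 1.5), function(t)
    true_intervention_mean(cfg, threshold_intervention(t),
                           method = "closed_form")$true_mean)
  expect_true(all(diff(means["vat", ]) < 0))      # negative slope: decreasing
  expect_true(all(diff(means["leanpct", ]) > 0))  # positive slope: increasing
  expect_true(all(means["vat", ] < nc$true_mean[["vat"]]))
})

test_that("truth is invariant to censoring parameters", {
  t1 <- true_intervention_mean(dgp_config(censoring = TRUE),
                               threshold_intervention(1.2), seed = 5)
  t2 <- true_intervention_mean(dgp_config(censoring = FALSE),
                               threshold_intervention(1.2), seed = 5)
  expect_identical(t1$true_mean, t2$true_mean)
})

test_that("oracle simulation agrees with closed-form truth for the linear
           DGP", {
  cfg <- dgp_config(clip_outcomes = FALSE)
  for (s in list(natural_course(), threshold_intervention(1.5))) {
    sim <- true_intervention_mean(cfg, s, oracle_n = 1e6, seed = 11)
    cf <- true_intervention_mean(cfg, s, method = "closed_form")
    z <- abs(sim$true_mean - cf$true_mean) / sim$se
    expect_true(all(z < 4), info = paste("max z:", max(z)))
  }
})

test_that("truth gap equals slope times expected intake lift", {
  # beta_vat = -10; gap(t) = -10 * (E[max(A,t)] - E[A])
  cfg <- dgp_config(clip_outcomes = FALSE)
  nc <- true_intervention_mean(cfg, natural_course(), method = "closed_form")
  t12 <- true_intervention_mean(cfg, threshold_intervention(1.2),
                                method = "closed_form")
  gap_vat <- t12$true_mean[["vat"]] - nc$true_mean[["vat"]]
  gap_wt <- t12$true_mean[["weight"]] - nc$true_mean[["weight"]]
  # same lift scales every outcome by its slope
  expect_equal(gap_vat / -10, gap_wt / -1.91, tolerance = 1e-8)
  expect_lt(gap_vat, 0)
})

test_that("invalid configurations are rejected", {
  expect_error(dgp_config(overrides = list(
    outcome_params = list(loading = c(vat = 1000)))), "variance")
  expect_error(true_intervention_mean(dgp_config(), natural_course(),
                                      oracle_n = 1e4), ">= 1e6")
  expect_error(true_intervention_mean(dgp_config(clip_outcomes = TRUE),
                                      natural_course(),
                                      method = "closed_form"),
               "clip_outcomes")
})

test_that("DGP YAML round-trips the numeric configuration", {
  cfg <- dgp_config(n = 321, effect_protein = c(vat = -4), confounding = 0.5)
  f <- tempfile(fileext = ".yaml")
  write_dgp_yaml(cfg, f)
  cfg2 <- read_dgp_yaml(f)
  expect_equal(cfg2$n, 321)
  expect_equal(cfg2$outcome_params$effect[["vat"]], -4)
  expect_equal(cfg2$exposure$coefs[["hei"]], 0.5 * 0.015)
  a <- generate_cohort(cfg, seed = 2)
  b <- generate_cohort(cfg2, seed = 2)
  expect_identical(a$data, b$data)
  unlink(f)
})
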