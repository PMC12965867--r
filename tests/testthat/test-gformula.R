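test_that("intervention rules: minimal-change lifting and nesting", {
  expect_equal(apply_intervention(0.9, threshold_intervention(1.2)), 1.2)
  expect_equal(apply_intervention(1.4, threshold_intervention(1.2)), 1.4)
  expect_equal(apply_intervention(0.9, natural_course()), 0.9)
  set.seed(2)
  a <- runif(200, 0.4, 2.5)
  for (i in 1:10) {
    t1 <- runif(1, 0.5, 1.2); t2 <- t1 + runif(1, 0.1, 0.8)
    expect_true(all(apply_intervention(a, threshold_intervention(t2)) >=
                      apply_intervention(a, threshold_intervention(t1))))
  }
  expect_error(threshold_intervention(0))
})

test_that("plug-in oracle: exposure-independent outcomes and known-function
           cells", {
  # E[Y|a,l] = l, P(L=1) = 0.5: standardized mean 0.5 for every strategy
  d <- data.frame(l = factor(rep(0:1, each = 20)),
                  a = rep(c(0.6, 1.4), 20),
                  y = rep(0:1, each = 20))
  for (s in list(natural_course(), threshold_intervention(1.4)))
    expect_equal(plugin_standardization_oracle(d, s, "l"), 0.5)
  # known mean function E[Y|a,l] = a with a in {0.6, 1.4}, threshold 1.2:
  # mean of max(a, 1.2) = (1.2 + 1.4) / 2
  expect_equal(
    plugin_standardization_oracle(d, threshold_intervention(1.2), "l",
                                  outcome_fn = function(a, s) a),
    1.3)
  # empirical cell means need the intervened level in the support
  expect_error(
    plugin_standardization_oracle(d, threshold_intervention(1.2), "l"),
    "empty stratum")
})

test_that("MC standardization converges to the plug-in oracle on random
           discrete cohorts", {
  set.seed(314)
  for (rep in 1:5) {
    d <- random_discrete_cohort(n = 1500, k = 2)
    for (s in strategy_set()) {
      mc <- mc_standardization_discrete(d, s, c("l1", "l2"),
                                        mc_size = 2e5, seed = rep)
      exact <- plugin_standardization_oracle(d, s, c("l1", "l2"))
      expect_lt(abs(mc$mean - exact), 4 * mc$mc_se + 1e-9)
    }
  }
})

test_that("threshold at or below the minimum intake reproduces the natural
           course exactly under shared seeds", {
  ch <- small_cohort()
  el <- apply_eligibility(ch)$cohort
  m <- fit_all(el)
  t_min <- min(el$data$a1)
  est <- run_all_strategies(m, list(natural_course(),
                                    threshold_intervention(t_min)),
                            mc_size = 3000, seed = 9)
  expect_identical(est[[1]]$standardized_mean, est[[2]]$standardized_mean)
  expect_true(all(est[[2]]$ate_vs_natural == 0))
})

test_that("strategy bookkeeping: duplicates and missing reference are
           errors; natural-course ATE is identically zero", {
  ch <- small_cohort()
  m <- fit_all(apply_eligibility(ch)$cohort, components = "outcomes")
  expect_error(run_all_strategies(m, list(natural_course(),
                                          threshold_intervention(1.2),
                                          threshold_intervention(1.2)),
                                  mode = "empirical"), "duplicate")
  expect_error(run_all_strategies(m, list(threshold_intervention(1.2)),
                                  mode = "empirical"),
               "reference strategy required")
  est <- run_all_strategies(m, list(threshold_intervention(1.2),
                                    natural_course()), mode = "empirical")
  expect_equal(est[[1]]$label, "natural_course")  # reordered first
  expect_true(all(est[[1]]$ate_vs_natural == 0))
  expect_equal(nrow(as.data.frame(est)), 2 * length(ch$schema$outcomes))
})

test_that("g-formula runs are deterministic given the seed", {
  ch <- small_cohort()
  el <- apply_eligibility(ch)$cohort
  m <- fit_all(el)
  e1 <- run_all_strategies(m, strategy_set(), mc_size = 2000, seed = 4)
  e2 <- run_all_strategies(m, strategy_set(), mc_size = 2000, seed = 4)
  expect_identical(as.data.frame(e1), as.data.frame(e2))
  e3 <- run_all_strategies(m, strategy_set(), mc_size = 2000, seed = 5)
  expect_false(identical(as.data.frame(e1), as.data.frame(e3)))
})

test_that("simulated covariate and exposure margins calibrate to the
           observed cohort (natural course)", {
  ch <- generate_cohort(dgp_config(missing_protein_rate = 0), seed = 55)
  el <- apply_eligibility(ch)$cohort
  m <- fit_all(el)
  sim <- simulate_covariates(m, mc_size = 50000, seed = 12)
  d <- el$data
  for (cl in c("hei1", "met1", "cesd1", "vat1", "weight1")) {
    obs_se <- sd(d[[cl]]) / sqrt(nrow(d))
    mc_se <- sd(sim[[cl]]) / sqrt(nrow(sim))
    expect_lt(abs(mean(sim[[cl]]) - mean(d[[cl]])),
              4 * sqrt(obs_se^2 + mc_se^2) + 0.02 * sd(d[[cl]]))
  }
  a_sim <- attr(sim, "a_natural")
  expect_lt(abs(mean(a_sim) - mean(d$a1)), 0.02)
  expect_lt(abs(sd(a_sim) - sd(d$a1)), 0.05)
})

test_that("empirical and parametric engine modes agree under correct
           specification", {
  ch <- generate_cohort(dgp_config(missing_protein_rate = 0), seed = 77)
  el <- apply_eligibility(ch)$cohort
  m <- fit_all(el)
  ep <- run_all_strategies(m, strategy_set(), mc_size = 30000, seed = 13)
  ee <- run_all_strategies(m, strategy_set(), mode = "empirical")
  for (j in 2:5) {
    tol <- 4 * sqrt(ep[[j]]$ate_mc_se^2 + ee[[j]]$ate_mc_se^2) +
      0.1 * abs(ee[[j]]$ate_vs_natural) + 0.05
    expect_true(all(abs(ep[[j]]$ate_vs_natural - ee[[j]]$ate_vs_natural) <
                      tol),
                info = paste("strategy", ep[[j]]$label))
  }
})
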