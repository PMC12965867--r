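fit_one <- proteintrial:::fit_one
predict_lp <- proteintrial:::predict_lp
simulate_fit <- proteintrial:::simulate_fit

test_that("saturated logistic fit reproduces empirical cell proportions", {
  d <- data.frame(
    a = factor(rep(c(1, 0), c(100, 100))),
    y = c(rep(1, 30), rep(0, 70), rep(1, 10), rep(0, 90))
  )
  f <- fit_one(model_spec("y", "logistic", "a", saturated = TRUE), d)
  p <- predict_lp(f, data.frame(a = factor(c(1, 0), levels = c("0", "1"))))
  expect_equal(unname(p), c(0.30, 0.10), tolerance = 1e-8)
})

test_that("linear fit interpolates noise-free data exactly", {
  set.seed(5)
  d <- data.frame(a1 = runif(100, 0.5, 2))
  d$y <- 100 - 10 * d$a1
  f <- fit_one(model_spec("y", "linear", "a1"), d)
  expect_equal(unname(coef(f$fit)), c(100, -10), tolerance = 1e-10)
  expect_equal(unname(predict_lp(f, data.frame(a1 = 1.5))), 85,
               tolerance = 1e-10)
})

test_that("nested-logit multinomial reproduces a saturated conditional
           distribution", {
  set.seed(6)
  n <- 3000
  l <- factor(rbinom(n, 1, 0.4))
  pr <- ifelse(l == "1", list(c(0.2, 0.3, 0.5)), list(c(0.6, 0.3, 0.1)))
  y <- factor(vapply(pr, function(p) sample(letters[1:3], 1, prob = p), ""),
              levels = letters[1:3])
  d <- data.frame(l = l, y = y)
  f <- fit_one(model_spec("y", "multinomial", "l", saturated = TRUE), d)
  probs <- predict_lp(f, data.frame(l = factor(c("0", "1"))))
  emp0 <- prop.table(table(y[l == "0"]))
  expect_equal(unname(probs[1, ]), as.numeric(emp0), tolerance = 1e-8)
  # simulated draws follow the fitted distribution
  set.seed(7)
  sims <- simulate_fit(f, d[d$l == "1", , drop = FALSE][1:2000, , drop = FALSE])
  emp1 <- prop.table(table(y[l == "1"]))
  expect_equal(as.numeric(prop.table(table(sims))), as.numeric(emp1),
               tolerance = 0.05)
})

test_that("rank deficiency and unseen levels raise named errors", {
  set.seed(8)
  d <- data.frame(x = rnorm(50))
  d$x2 <- 2 * d$x
  d$y <- d$x + rnorm(50)
  expect_error(fit_one(model_spec("y", "linear", c("x", "x2")), d),
               "rank deficient")
  d2 <- data.frame(g = factor(rep(c("u", "v"), 25)), y = rnorm(50))
  f <- fit_one(model_spec("y", "linear", "g"), d2)
  nd <- data.frame(g = factor("w"))
  expect_error(predict_lp(f, nd), "new level")
})

test_that("zero-residual fits simulate constant values equal to the fitted
           mean", {
  d <- data.frame(z = rnorm(40), y = 5)
  f <- fit_one(model_spec("y", "linear", "z"), d)
  set.seed(1)
  sims <- simulate_fit(f, d)
  expect_equal(sims, rep(5, 40), tolerance = 1e-10)
})

test_that("outcome-model coefficients recover DGP truth on synthetic data", {
  ch <- generate_cohort(dgp_config(missing_protein_rate = 0), seed = 21)
  el <- apply_eligibility(ch)$cohort
  m <- fit_all(el, components = "outcomes")
  sm <- summary(m$outcome_fits$vat2$fit)$coefficients
  est <- sm["a1", "Estimate"]; se <- sm["a1", "Std. Error"]
  expect_lt(abs(est - (-10)) / se, 3)
  # normal-equation identity: fitted means equal observed uncensored means
  unc <- el$data[el$data$censor == "none", ]
  expect_equal(mean(fitted(m$outcome_fits$vat2$fit)), mean(unc$vat2),
               tolerance = 1e-10)
})

test_that("coefficient error shrinks as n grows", {
  est_and_se <- function(n, seed) {
    ch <- generate_cohort(dgp_config(n = n, missing_protein_rate = 0),
                          seed = seed)
    el <- apply_eligibility(ch)$cohort
    m <- fit_all(el, components = "outcomes")
    summary(m$outcome_fits$vat2$fit)$coefficients["a1", 1:2]
  }
  small <- est_and_se(1000, 31)
  big <- est_and_se(10000, 32)
  expect_lt(big[[2]], small[[2]])                 # standard error shrinks
  expect_lt(abs(big[[1]] - (-10)) / big[[2]], 4)  # and stays near truth
})

test_that("predict_outcome is pure and rejects unseen categorical levels", {
  ch <- small_cohort()
  el <- apply_eligibility(ch)$cohort
  m <- fit_all(el, components = "outcomes")
  hist <- proteintrial:::prep_model_data(el)[1:5, ]
  p1 <- predict_outcome(m, 1.2, hist)
  p2 <- predict_outcome(m, 1.2, hist)
  expect_identical(p1, p2)
  expect_equal(colnames(p1), el$schema$outcomes)
  # shifting the exposure by +1 moves predictions by the a1 coefficient
  p3 <- predict_outcome(m, 2.2, hist)
  b <- coef(m$outcome_fits$vat2$fit)[["a1"]]
  expect_equal(p3[, "vat"] - p1[, "vat"], rep(b, 5), tolerance = 1e-10)
})

test_that("censoring models are fitted on the proper risk sets and track
           the generated rates", {
  ch <- small_cohort()
  el <- apply_eligibility(ch)$cohort
  m <- fit_all(el)
  cs <- censoring_summary(el)
  d <- proteintrial:::prep_model_data(el)
  p_death <- predict(m$censoring_fits$death$fit, type = "response")
  expect_equal(m$censoring_fits$death$n, nrow(el$data))
  expect_equal(sum(p_death), unname(cs[["death"]]), tolerance = 1e-6)
  # ltfu is modelled among survivors only
  expect_equal(m$censoring_fits$ltfu$n, sum(el$data$censor != "death"))
  p_ltfu <- predict(m$censoring_fits$ltfu$fit, type = "response")
  expect_equal(sum(p_ltfu), unname(cs[["ltfu"]]), tolerance = 1e-6)
})
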