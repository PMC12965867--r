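# Shared fixtures, all built in code.

# Small default-DGP cohort for structural tests (cached per session).
small_cohort <- local({
  cache <- NULL
  function(n = 800, seed = 42, ...) {
    if (is.null(cache)) {
      cfg <- dgp_config(n = n, seed = seed, missing_protein_rate = 0, ...)
      cache <<- generate_cohort(cfg)
    }
    cache
  }
})

# Random fully discrete cohort: `k` binary confounders, discrete exposure
# drawn from `levels` with confounder-dependent probabilities, outcome linear
# in exposure and confounders plus noise. Guarantees every (a, l) cell is
# populated by seeding one observation per cell.
random_discrete_cohort <- function(n = 2000, k = 1,
                                   levels = c(0.6, 0.8, 1.0, 1.2, 1.5)) {
  L <- matrix(rbinom(n * k, 1, 0.5), n, k)
  lp <- L %*% runif(k, -1, 1)
  w <- outer(drop(lp), seq_along(levels), function(x, j) exp(0.6 * x * j))
  a <- levels[apply(w, 1, function(p) sample(length(levels), 1, prob = p))]
  beta <- runif(1, -3, 3)
  y <- beta * a + L %*% runif(k, -2, 2) + rnorm(n)
  d <- data.frame(y = drop(y), a = a)
  for (j in seq_len(k)) d[[paste0("l", j)]] <- factor(L[, j])
  # populate every cell so saturated estimates are well-defined
  grid <- expand.grid(c(list(a = levels),
                        setNames(rep(list(0:1), k), paste0("l", k:1))))
  seedrows <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    r <- d[1, , drop = FALSE]
    r$a <- grid$a[i]
    for (j in seq_len(k)) r[[paste0("l", j)]] <- factor(grid[[paste0("l", j)]][i],
                                                        levels = 0:1)
    r$y <- beta * r$a + rnorm(1)
    r
  }))
  rbind(d, seedrows)
}

strategy_set <- function() {
  c(list(natural_course()),
    lapply(c(0.8, 1.0, 1.2, 1.5), threshold_intervention))
}
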