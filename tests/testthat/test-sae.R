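test_that("aggregate_expectation is a guarded convex combination", {
  expect_equal(aggregate_expectation(0.37, 5), 0.37)
  expect_equal(aggregate_expectation(c(0.2, 0.1), c(1000, 3000)), 0.125)
  set.seed(9)
  for (r in 1:20) {
    p <- runif(5)
    w <- runif(5, 0, 10)
    m <- aggregate_expectation(p, w)
    expect_true(m >= min(p) && m <= max(p))
  }
  expect_error(aggregate_expectation(c(0.1, 0.2), c(0, 0)), "invalid argument")
  expect_error(aggregate_expectation(c(0.1, 0.2), 1), "aligned")
})

test_that("zero-variance intercept-only fit pools to k/n", {
  w <- small_world()
  obs <- simulate_indicator_observations(w$truth, design = list(agg_frac = 0),
                                         seed = 21)
  st <- build_effect_structure(w$geog, w$truth$strata, list())
  st$X <- st$X[, "intercept", drop = FALSE]
  fit <- fit_indicator_model(obs, st, config = list(
    theta_init = list(county = 20, year = 20, age = 20, race = 20),
    theta_fixed = TRUE))
  pooled <- sum(obs$k) / sum(obs$n)
  expect_lt(max(abs(predict(fit) - pooled)), 1e-4)
})

test_that("an aggregated observation over duplicated strata equals its singleton", {
  w <- small_world()
  st <- build_effect_structure(w$geog, w$truth$strata,
                               list(covariates = w$truth$covariates))
  lat <- halesae:::build_latent_design(st)
  set.seed(4)
  x <- rnorm(sum(lat$sizes), 0, 0.1)
  obs1 <- data.table::data.table(stratum_set = list(7L), weights = list(1),
                                 n = 50L, k = 20L)
  obs2 <- data.table::data.table(stratum_set = list(c(7L, 7L, 7L)),
                                 weights = list(c(2, 2, 2)), n = 50L, k = 20L)
  ll1 <- halesae:::sae_loglik(x, halesae:::obs_weight_matrix(obs1, nrow(w$truth$strata)),
                              lat$M, 20, 50)
  ll2 <- halesae:::sae_loglik(x, halesae:::obs_weight_matrix(obs2, nrow(w$truth$strata)),
                              lat$M, 20, 50)
  expect_equal(ll1, ll2)
})

test_that("weight rescaling leaves the aggregated likelihood unchanged", {
  w <- small_world()
  st <- build_effect_structure(w$geog, w$truth$strata,
                               list(covariates = w$truth$covariates))
  lat <- halesae:::build_latent_design(st)
  set.seed(5)
  x <- rnorm(sum(lat$sizes), 0, 0.1)
  obs1 <- data.table::data.table(stratum_set = list(c(3L, 9L, 40L)),
                                 weights = list(c(1, 2, 5)), n = 80L, k = 11L)
  obs2 <- data.table::data.table(stratum_set = list(c(3L, 9L, 40L)),
                                 weights = list(10 * c(1, 2, 5)), n = 80L, k = 11L)
  ns <- nrow(w$truth$strata)
  expect_equal(
    halesae:::sae_loglik(x, halesae:::obs_weight_matrix(obs1, ns), lat$M, 11, 80),
    halesae:::sae_loglik(x, halesae:::obs_weight_matrix(obs2, ns), lat$M, 11, 80))
})

test_that("posterior draws have the right count, range, and centring", {
  w <- small_world()
  obs <- simulate_indicator_observations(w$truth, seed = 12)
  st <- build_effect_structure(w$geog, w$truth$strata,
                               list(covariates = w$truth$covariates))
  fit <- fit_indicator_model(obs, st)
  expect_true(fit$converged)
  cube <- draw_posterior(fit, n_draws = 500, seed = 8)
  expect_equal(ncol(cube$draws), 500)
  expect_equal(nrow(cube$draws), nrow(w$truth$strata))
  expect_true(all(cube$draws >= 0 & cube$draws <= 1))
  # draw means sit within 3 Monte-Carlo SEs of the mode prediction
  mode_p <- predict(fit)
  mc_se <- apply(cube$draws, 1, sd) / sqrt(500)
  frac_in <- mean(abs(rowMeans(cube$draws) - mode_p) <= 3 * mc_se + 1e-4)
  expect_gt(frac_in, 0.97)
  # determinism per seed
  cube2 <- draw_posterior(fit, n_draws = 500, seed = 8)
  expect_identical(cube$draws, cube2$draws)
})

test_that("separable data trigger the ridge fallback with a warning", {
  w <- small_world()
  obs <- simulate_indicator_observations(w$truth, seed = 12)
  obs[, k := 0L]
  st <- build_effect_structure(w$geog, w$truth$strata,
                               list(covariates = w$truth$covariates))
  expect_warning(
    fit_indicator_model(obs, st, config = list(theta_fixed = TRUE)),
    "separable")
})

test_that("education models marginalise to population-weighted prevalence", {
  w <- small_world()
  st0 <- w$truth$strata[year == 2011 & age_start == 0]
  edu <- data.table::data.table(education = c("low", "high"))
  strata_e <- data.table::data.table(
    st0[rep(seq_len(nrow(st0)), each = 2)], edu[rep(1:2, nrow(st0))])
  pop_e <- data.table::data.table(
    strata_e[, .(county, race, sex, year, education)],
    population = rep(c(600, 400), nrow(st0)))
  m <- matrix(runif(nrow(strata_e) * 4), ncol = 4)
  cube <- draw_cube(m, strata_e[, !"stratum_id"])
  out <- marginalize_education(cube, pop_e)
  expect_equal(nrow(out$draws), nrow(st0))
  expect_equal(out$draws[1, ], 0.6 * m[1, ] + 0.4 * m[2, ])
  expect_error(marginalize_education(out, pop_e), "no education axis")
})
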