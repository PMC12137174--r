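make_yld_inputs <- function() {
  w <- small_world()
  design <- yld_design(w$truth$strata, w$geog, w$truth$populations,
                       w$truth$covariates)
  list(w = w, design = design)
}

test_that("a saturated single-cell model reproduces the benchmark exactly", {
  w <- small_world()
  st1 <- w$truth$strata[county == "C001" & race == "Black" & sex == "female" &
                          year == 2011 & age_start == 0]
  des <- yld_design(st1, w$geog, w$truth$populations, w$truth$covariates)
  des$Xbase <- des$Xbase[, "intercept", drop = FALSE]
  bench <- data.table::data.table(
    state = w$geog$state_of["C001"], sex = "female", age_start = 0,
    year = 2011L, value = 0.042)
  fit <- fit_cause_model(bench, yll = 0.003, indicators = cbind(ind = 0.2),
                         design = des)
  # intercept + log-yll + indicator on one cell: fitted mean is the benchmark
  expect_equal(fit$fitted_cells, log(0.042), tolerance = 1e-8)
})

test_that("noise-free generation recovers the coefficients", {
  inp <- make_yld_inputs()
  des <- inp$design
  yll <- inp$w$truth$yll[, "cause_01"]
  ind <- cbind(indicator_1 = inp$w$truth$prevalence[, "indicator_1"])
  beta_true <- c(intercept = -2.1, covariate = 0.05, log_yll = 0.8,
                 indicator_1 = 1.0)
  X <- cbind(des$Xbase, log_yll = log(yll), ind)
  rate <- exp(as.vector(X %*% beta_true))
  bench_val <- as.vector(des$G %*% rate)
  bench <- data.table::data.table(des$cells[, .(state, sex, age_start, year)],
                                  value = bench_val)
  fit <- fit_cause_model(bench, yll, ind, des)
  expect_equal(unname(fit$beta), unname(beta_true), tolerance = 1e-3)
  expect_lt(fit$sigma2, 1e-10)
  # and predictions match the stratum-level truth within 0.1%
  expect_equal(predict(fit), rate, tolerance = 1e-3)
})

test_that("predictions are invariant to county relabeling", {
  inp <- make_yld_inputs()
  w <- inp$w
  yll <- w$truth$yll[, "cause_01"]
  ind <- cbind(indicator_1 = w$truth$prevalence[, "indicator_1"])
  bench <- simulate_benchmarks(w$truth, n_draws = 1, noise_sd = 0)
  bench1 <- bench[cause == "cause_01", .(state, sex, age_start, year, value)]
  fit1 <- fit_cause_model(bench1, yll, ind, inp$design)
  # permute the stratum rows (relabeling counties reorders design rows)
  perm <- rev(seq_len(nrow(w$truth$strata)))
  st_p <- w$truth$strata[perm]
  pop_p <- w$truth$populations[perm]
  des_p <- yld_design(st_p, w$geog, pop_p, w$truth$covariates)
  fit2 <- fit_cause_model(bench1, yll[perm], ind[perm, , drop = FALSE], des_p)
  expect_equal(predict(fit2), predict(fit1)[perm], tolerance = 1e-6)
})

test_that("draw splitting yields n_models x draws_per_model aligned draws", {
  inp <- make_yld_inputs()
  w <- inp$w
  bench <- simulate_benchmarks(w$truth, n_draws = 4, noise_sd = 0.01)
  prev_cube <- draw_cube(
    matrix(rep(w$truth$prevalence[, "indicator_1"], 4), ncol = 4),
    w$truth$strata)
  cube <- propagate_draws("cause_01", bench[cause == "cause_01"],
                          w$truth$yll[, "cause_01"],
                          list(indicator_1 = prev_cube), inp$design,
                          n_models = 4, draws_per_model = 5, seed = 2)
  expect_equal(ncol(cube$draws), 20)
  expect_equal(cube$lineage$model, rep(1:4, each = 5))
  expect_equal(cube$lineage$input_draw, cube$lineage$model)
  # law of total variance: total draw variance exceeds variance of the
  # per-model plug-in predictions
  fits <- attr(cube, "fits")
  plug <- vapply(fits, function(f) predict(f)[100], 0)
  expect_gte(var(cube$draws[100, ]), var(plug) * 0.5)
  expect_error(
    propagate_draws("cause_01", bench[cause == "cause_01" & draw <= 2],
                    w$truth$yll[, "cause_01"], list(indicator_1 = prev_cube),
                    inp$design, n_models = 4, draws_per_model = 5),
    "benchmark draws < n_models")
})

test_that("degenerate single-model single-draw equals the plug-in prediction", {
  inp <- make_yld_inputs()
  w <- inp$w
  des <- inp$design
  yll <- w$truth$yll[, "cause_01"]
  ind <- cbind(indicator_1 = w$truth$prevalence[, "indicator_1"])
  beta_true <- c(intercept = -2.1, covariate = 0.05, log_yll = 0.8,
                 indicator_1 = 1.0)
  rate <- exp(as.vector(cbind(des$Xbase, log_yll = log(yll), ind) %*% beta_true))
  bench <- data.table::data.table(
    des$cells[, .(state, sex, age_start, year)], draw = 1L,
    value = as.vector(des$G %*% rate))
  prev_cube <- draw_cube(cbind(ind[, 1]), w$truth$strata)
  cube <- propagate_draws("cause_01", bench, yll,
                          list(indicator_1 = prev_cube), des,
                          n_models = 1, draws_per_model = 1, seed = 3)
  # noise-free: residual variance vanishes, the single draw is the plug-in
  expect_equal(cube$draws[, 1], rate, tolerance = 1e-3)
})

test_that("summing causes adds cell-wise, clips, and commutes", {
  w <- small_world()
  st <- w$truth$strata[year == 2011 & age_start == 0]
  m1 <- matrix(0.02, nrow(st), 3)
  m2 <- matrix(0.05, nrow(st), 3)
  c1 <- draw_cube(m1, st, data.table::data.table(draw = 1:3))
  c2 <- draw_cube(m2, st, data.table::data.table(draw = 1:3))
  s <- sum_causes(list(c1, c2))
  expect_equal(s$draws, m1 + m2)
  s0 <- sum_causes(list(c1, draw_cube(matrix(0, nrow(st), 3), st,
                                      data.table::data.table(draw = 1:3))))
  expect_equal(s0$draws, m1)
  expect_equal(sum_causes(list(c2, c1))$draws, s$draws)
  big <- draw_cube(matrix(0.99, nrow(st), 3), st,
                   data.table::data.table(draw = 1:3))
  expect_message(sbig <- sum_causes(list(big, c2)), "clipped")
  expect_true(all(sbig$draws <= 1))
  c3 <- draw_cube(matrix(0.1, nrow(st), 2), st,
                  data.table::data.table(draw = 1:2))
  expect_error(sum_causes(list(c1, c3)), "mismatched draw counts")
})
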