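two_strata_cube <- function(values, draws = 4) {
  st <- data.table::data.table(county = c("C001", "C002"), race = "White",
                               year = 2019L)
  draw_cube(matrix(rep(values, draws), ncol = draws), st,
            data.table::data.table(draw = seq_len(draws)))
}

test_that("population-weighted aggregation averages draws within groups", {
  cube <- two_strata_cube(c(64, 68))
  agg <- aggregate_weighted(cube, c(1, 1), by = c("race", "year"))
  expect_equal(as.vector(agg$draws), rep(66, 4))
  # singleton group is the identity
  one <- aggregate_weighted(cube, c(1, 1), by = "county")
  expect_equal(one$draws, cube$draws)
  expect_error(aggregate_weighted(cube, c(0, 0), by = "race"), "all-zero")
})

test_that("intervals come from aggregated draws, not aggregated intervals", {
  set.seed(8)
  st <- data.table::data.table(county = c("C001", "C002"), race = "White",
                               year = 2019L)
  m <- rbind(rnorm(500, 60, 5), rnorm(500, 70, 5))
  cube <- draw_cube(m, st)
  agg <- aggregate_weighted(cube, c(1, 3), by = "race")
  ui_agg <- point_and_ui(agg)
  pooled <- colSums(m * c(1, 3)) / 4
  expect_equal(ui_agg$lower, quantile(pooled, 0.025, type = 7, names = FALSE))
  expect_equal(ui_agg$upper, quantile(pooled, 0.975, type = 7, names = FALSE))
  # aggregating the stratum-level intervals would give a wider band
  ui_each <- point_and_ui(cube)
  naive <- sum(ui_each$lower * c(1, 3)) / 4
  expect_false(isTRUE(all.equal(ui_agg$lower, naive)))
})

test_that("point_and_ui uses draw means and type-7 percentiles", {
  expect_equal(point_and_ui(rep(3.5, 10)),
               c(mean = 3.5, lower = 3.5, upper = 3.5))
  got <- point_and_ui(as.numeric(1:1000))
  expect_equal(got, c(mean = 500.5, lower = 25.975, upper = 975.025))
  set.seed(2)
  x <- rnorm(300)
  expect_equal(point_and_ui(x), point_and_ui(sample(x)))
  expect_error(point_and_ui(c(1, NA, 3)), "NaN/NA")
  expect_error(point_and_ui(1), "at least 2")
})

test_that("significance follows the 2.5% / 97.5% posterior-probability rule", {
  st <- data.table::data.table(county = "C001", race = "White", year = 2019L)
  mk <- function(v) draw_cube(matrix(v, 1), st)
  zero <- mk(rep(0, 1000))
  d980 <- mk(c(rep(1, 980), rep(-1, 20)))
  d970 <- mk(c(rep(1, 970), rep(-1, 30)))
  r980 <- compare_draws(d980, zero)
  expect_equal(r980$posterior_prob, 0.98)
  expect_true(r980$significant)
  r970 <- compare_draws(d970, zero)
  expect_equal(r970$posterior_prob, 0.97)
  expect_false(r970$significant)
  # draw-wise identical cubes: all ties, flagged not significant
  same <- mk(rnorm(1000))
  rsame <- compare_draws(same, same)
  expect_equal(rsame$posterior_prob, 0)
  expect_false(rsame$significant)
  expect_error(compare_draws(mk(1:4), mk(1:6)), "mismatched draw counts")
})

test_that("null comparisons are significant at roughly the nominal rate", {
  set.seed(77)
  n_rep <- 1000; D <- 400
  st <- data.table::data.table(rep_id = seq_len(n_rep))
  mA <- rnorm(n_rep); mB <- rnorm(n_rep)
  a <- draw_cube(mA + matrix(rnorm(n_rep * D), n_rep), st)
  b <- draw_cube(mB + matrix(rnorm(n_rep * D), n_rep), st)
  rate <- mean(compare_draws(a, b)$significant)
  expect_gte(rate, 0.03)
  expect_lte(rate, 0.07)
})

test_that("masking applies strictly below the threshold and leaves values alone", {
  res <- data.table::data.table(county = c("C001", "C002"), race = "White",
                                mean = c(64, 65))
  pop <- data.table::CJ(county = c("C001", "C002"), race = "White",
                        sex = c("female", "male"), year = 2011:2013)
  pop[, population := ifelse(county == "C001", 999 / 2, 1000 / 2)]
  m <- mask_small(res, pop, threshold = 1000)
  expect_equal(m$masked, c(TRUE, FALSE))
  expect_equal(m$mean_annual_pop, c(999, 1000))
  expect_equal(m$mean, res$mean)
  m0 <- mask_small(res, pop, threshold = 0)
  expect_false(any(m0$masked))
  expect_error(mask_small(res[, .(county, race, mean)],
                          pop[county == "C002"]), "missing population")
})

test_that("county disparity statistics reproduce ranges, medians, and shares", {
  vals <- c(50.1, 60.2, 62.8, 70.0, 74.6)
  pts <- data.table::data.table(county = sprintf("C%03d", 1:5), race = "AIAN",
                                mean = vals, masked = FALSE)
  s <- county_disparity_stats(pts)
  expect_equal(s$spread$range, 24.5)
  expect_equal(s$spread$min, 50.1)
  expect_equal(s$spread$median, median(vals))
  one <- county_disparity_stats(pts[1])
  expect_equal(one$spread$range, 0)
  expect_equal(one$spread$median, 50.1)
  expect_error(county_disparity_stats(pts[, .(county, race, mean,
                                              masked = TRUE)]), "unmasked")
  chg <- data.table::data.table(
    county = sprintf("C%03d", 1:10), race = "Total",
    diff_mean = c(rep(-1, 9), 1),
    significant = c(rep(TRUE, 6), rep(FALSE, 4)), masked = FALSE)
  s2 <- county_disparity_stats(pts, changes = chg)
  expect_equal(s2$trends$pct_declined, 90)
  expect_equal(s2$trends$n_sig_declined, 6)
  expect_equal(s2$trends$pct_sig_declined, 60)
})

test_that("percentages round half-up at one decimal", {
  expect_equal(pct_round(100 * 2812 / 3079), 91.3)
  expect_equal(pct_round(91.25), 91.3)  # round() would give 91.2
  expect_equal(pct_round(100 * 2019 / 3079), 65.6)
  expect_equal(pct_round(16.308), 16.3)
})
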