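make_rake_setup <- function(n_draws = 8, seed = 17) {
  w <- small_world()
  truth <- w$truth
  set.seed(seed)
  noise <- matrix(exp(rnorm(nrow(truth$strata) * n_draws, 0, 0.15)),
                  ncol = n_draws)
  cube <- draw_cube(rowSums(truth$yld) * noise, truth$strata,
                    data.table::data.table(draw = seq_len(n_draws)))
  bm <- simulate_benchmarks(truth, n_draws = n_draws, noise_sd = 0.02)
  bm_all <- bm[, .(value = sum(value)), by = .(state, sex, age_start, year, draw)]
  list(w = w, cube = cube, bm = bm_all)
}

test_that("raking_factor matches hand arithmetic and scales linearly", {
  expect_equal(raking_factor(c(0.2, 0.1), c(1000, 3000), 0.125), 1)
  f <- raking_factor(c(0.2, 0.1), c(1000, 3000), 0.15)
  expect_equal(f, 1.2)
  expect_equal(f * c(0.2, 0.1), c(0.24, 0.12))
  expect_equal(raking_factor(c(0.2, 0.1), c(1000, 3000), 0.30), 2.4)
  expect_error(raking_factor(c(0, 0), c(1, 1), 0.1), "cannot rake")
})

test_that("raked weighted means equal benchmarks to 1e-10 in every cell and draw", {
  s <- make_rake_setup()
  raked <- suppressMessages(
    apply_raking(s$cube, s$w$truth$populations, s$bm, geography = s$w$geog))
  # independent recomputation, straight from the definition
  st <- data.table::copy(raked$strata)
  st[, state := s$w$geog$state_of[county]]
  pop <- s$w$truth$populations$population
  for (d in c(1, 5, 8)) {
    chk <- data.table::data.table(st[, .(state, sex, age_start, year)],
                                  w = pop, v = raked$draws[, d])
    wm <- chk[, .(wm = sum(w * v) / sum(w)), by = .(state, sex, age_start, year)]
    m <- merge(wm, s$bm[draw == d], by = c("state", "sex", "age_start", "year"))
    expect_lt(max(abs(m$wm - m$value) / m$value), 1e-10)
  }
})

test_that("raking to the current weighted mean is the identity, and is idempotent", {
  s <- make_rake_setup(n_draws = 3)
  st <- data.table::copy(s$cube$strata)
  st[, state := s$w$geog$state_of[county]]
  pop <- s$w$truth$populations$population
  long <- data.table::rbindlist(lapply(1:3, function(d) {
    data.table::data.table(st[, .(state, sex, age_start, year)], w = pop,
                           v = s$cube$draws[, d], draw = d)
  }))
  bm_self <- long[, .(value = sum(w * v) / sum(w)),
                  by = .(state, sex, age_start, year, draw)]
  raked <- suppressMessages(
    apply_raking(s$cube, s$w$truth$populations, bm_self, geography = s$w$geog))
  expect_equal(raked$draws, s$cube$draws, tolerance = 1e-12)
  # idempotence: raking a raked cube to the same benchmarks changes nothing
  r1 <- suppressMessages(
    apply_raking(s$cube, s$w$truth$populations, s$bm, geography = s$w$geog))
  r2 <- suppressMessages(
    apply_raking(r1, s$w$truth$populations, s$bm, geography = s$w$geog))
  expect_equal(r2$draws, r1$draws, tolerance = 1e-12)
})

test_that("scaling benchmarks scales unclipped raked values linearly", {
  s <- make_rake_setup(n_draws = 2)
  bm2 <- data.table::copy(s$bm)[, value := value * 1.3]
  r1 <- suppressMessages(
    apply_raking(s$cube, s$w$truth$populations, s$bm, geography = s$w$geog))
  r2 <- suppressMessages(
    apply_raking(s$cube, s$w$truth$populations, bm2, geography = s$w$geog))
  # linearity holds within every cell in which no stratum hit the cap
  st <- data.table::copy(r2$strata)
  st[, state := s$w$geog$state_of[county]]
  st[, cell := .GRP, by = .(state, sex, age_start, year)]
  for (d in 1:2) {
    clipped_cells <- unique(st$cell[r2$draws[, d] >= 1])
    keep <- !(st$cell %in% clipped_cells)
    expect_gt(sum(keep), 0)
    expect_equal(r2$draws[keep, d], 1.3 * r1$draws[keep, d],
                 tolerance = 1e-10)
  }
})

test_that("raking preserves within-cell rank order when nothing clips", {
  s <- make_rake_setup(n_draws = 2)
  raked <- suppressMessages(
    apply_raking(s$cube, s$w$truth$populations, s$bm, geography = s$w$geog))
  expect_true(all(raked$draws < 1))
  st <- data.table::copy(raked$strata)
  st[, state := s$w$geog$state_of[county]]
  st[, cell := .GRP, by = .(state, sex, age_start, year)]
  set.seed(3)
  for (cc in sample(unique(st$cell), 10)) {
    ix <- which(st$cell == cc)
    expect_equal(order(raked$draws[ix, 1]), order(s$cube$draws[ix, 1]))
  }
})

test_that("clip-and-rerake keeps the benchmark exactly while capping at 1", {
  # two strata, one pushed over 1 by a high benchmark
  st <- data.table::data.table(
    county = c("C001", "C002"), race = "White", sex = "female",
    age_start = 0, year = 2011L, state = "S01", stratum_id = 1:2)
  pop <- data.table::data.table(st[, .(county, race, sex, age_start, year,
                                       stratum_id)], population = c(100, 300))
  cube <- draw_cube(cbind(c(0.9, 0.3)), st)
  bm <- data.table::data.table(state = "S01", sex = "female", age_start = 0,
                               year = 2011L, draw = 1L, value = 0.6)
  raked <- suppressMessages(apply_raking(cube, pop, bm))
  expect_equal(raked$draws[1, 1], 1)  # clipped
  # remaining stratum absorbs the rest: (100*1 + 300*x)/400 = 0.6
  expect_equal(raked$draws[2, 1], (0.6 * 400 - 100) / 300, tolerance = 1e-12)
  # infeasible benchmark errors
  bm_bad <- data.table::copy(bm)[, value := 1.5]
  expect_error(suppressMessages(apply_raking(cube, pop, bm_bad)))
})

test_that("benchmark coverage and population guards are enforced", {
  s <- make_rake_setup(n_draws = 2)
  expect_error(
    apply_raking(s$cube, s$w$truth$populations, s$bm[draw == 1],
                 geography = s$w$geog),
    "every cell and draw")
})
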