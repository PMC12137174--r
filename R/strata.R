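#' Default configuration for the synthetic study
#'
#' The configuration fixes the study conditions: the stratification
#' (counties, races, sexes, abridged age groups, years), the indicator and
#' cause lists, the fixed-effect coefficients and random-effect variances
#' (on the link scale) used to generate ground truth, and the draw
#' bookkeeping (`n_models` x `draws_per_model` = total draws). Defaults give
#' 48 counties in 4 states, 2 of the 5 supported racial and ethnic
#' populations, 2 sexes, abridged ages 0, 1, 5, 10, ..., 85+ and years
#' 2009-2019, so a full pipeline run completes in minutes on one CPU.
#'
#' Link functions are logit for prevalence surfaces and log for YLD and
#' mortality rates. Random-effect variances are: `county` (ICAR on the
#' county graph), `year` (first-order random walk), `age` (first-order
#' random walk over age-group index), `race` (exchangeable), and `resid`
#' (independent stratum-level noise).
#'
#' @param n_counties,n_states geography size
#' @param n_races number of racial and ethnic populations (1-5)
#' @param age_starts left endpoints of the abridged age groups; the last is
#'   open-ended
#' @param years calendar years covered
#' @param indicators character vector of indicator names
#' @param causes character vector of cause-group names (default 16)
#' @param n_models,draws_per_model YLD draw-splitting scheme (50 x 20 = 1000)
#' @param prev_var,yld_var,mx_var named variance lists for the three surface
#'   types (entries `county`, `year`, `age`, `race`, `resid`)
#' @param mask_threshold mean annual population below which county-race
#'   estimates are masked
#' @param seed master seed
#' @return a list of class `hale_config`
#' @export
sim_config <- function(n_counties = 48L, n_states = 4L, n_races = 2L,
                       age_starts = c(0, 1, seq(5, 85, by = 5)),
                       years = 2009:2019,
                       indicators = paste0("indicator_", 1:3),
                       causes = sprintf("cause_%02d", 1:16),
                       n_models = 50L, draws_per_model = 20L,
                       prev_var = list(county = 0.04, year = 0.005, age = 0.02,
                                       race = 0.04, resid = 0),
                       yld_var  = list(county = 0.01, year = 0.002, age = 0.005,
                                       race = 0.01, resid = 0.002),
                       mx_var   = list(county = 0.02, year = 0.002, age = 0.01,
                                       race = 0.02, resid = 0.002),
                       mask_threshold = 1000,
                       seed = 1L) {
  stopifnot(n_races >= 1L, n_races <= 5L)
  for (v in c(prev_var, yld_var, mx_var)) {
    if (v < 0) stop("invalid argument: negative variance")
  }
  races <- c("Black", "White", "AIAN", "Asian", "Latino")[seq_len(n_races)]
  cfg <- list(
    n_counties = as.integer(n_counties), n_states = as.integer(n_states),
    races = sort(races), sexes = c("female", "male"),
    age_starts = age_starts, years = as.integer(years),
    indicators = indicators, causes = causes,
    n_models = as.integer(n_models), draws_per_model = as.integer(draws_per_model),
    prev_var = prev_var, yld_var = yld_var, mx_var = mx_var,
    mask_threshold = mask_threshold, seed = as.integer(seed),
    # fixed effects on the link scale; covariate is the simulated
    # county-level deprivation score (standardised)
    # in the standardised design basis of build_effect_structure():
    # intercept, sex_male, age_std = (age_start - 40) / 25, covariate
    prev_beta = c(intercept = qlogis(0.15), sex_male = -0.1, age_std = 0.625,
                  covariate = 0.3),
    mx_beta = list(intercept = -8.6, age_slope = 0.082, infant = 3.0,
                   sex_male = 0.25, covariate = 0.15),
    # per-cause YLD truth: log yld = b0 + b_yll * log(yll) + b_ind * prev +
    #   b_cov * covariate + random effects
    yld_beta = list(b_yll = 0.30, b_ind = 1.0, b_cov = 0.05),
    yll_share = NULL  # filled per cause in simulate_truth
  )
  class(cfg) <- c("hale_config", "list")
  cfg
}

#' Enumerate the fine strata of a configuration
#'
#' One row per (county, race, sex, age group, year) cell, the resolution at
#' which all rates and estimates are keyed. Age groups are half-open
#' `[age_start, age_end)` with the terminal group open-ended
#' (`age_end = Inf`).
#'
#' @param geography a `hale_geography`
#' @param config a `hale_config`
#' @return a data.table keyed by stratum with an integer `stratum_id`
#' @export
make_strata <- function(geography, config) {
  ages <- age_table(config$age_starts)
  st <- CJ(county = geography$counties, race = config$races,
           sex = config$sexes, age_start = ages$age_start,
           year = config$years, sorted = TRUE)
  st <- merge(st, ages, by = "age_start", sort = FALSE)
  setcolorder(st, c("county", "race", "sex", "age_start", "age_end", "year"))
  setkey(st, county, race, sex, age_start, year)
  st[, stratum_id := seq_len(.N)]
  st[]
}

#' Abridged age-group table
#'
#' @param age_starts left endpoints; must be strictly increasing, starting
#'   at 0 so the groups cover `[0, Inf)`
#' @return data.table with `age_start`, `age_end`, `age_n` (width, `Inf` for
#'   the terminal group) and `age_index`
#' @export
age_table <- function(age_starts) {
  if (is.unsorted(age_starts, strictly = TRUE) || age_starts[1] != 0) {
    stop("invalid argument: age_starts must be strictly increasing from 0")
  }
  k <- length(age_starts)
  data.table(age_start = age_starts,
             age_end = c(age_starts[-1], Inf),
             age_n = c(diff(age_starts), Inf),
             age_index = seq_len(k))
}
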