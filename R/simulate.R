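#' Simulate stratum population counts
#'
#' County base populations are lognormal; race shares within county are
#' drawn on the logit scale so that minority shares span roughly 0.5-50%,
#' which puts a realistic subset of county-race populations below the
#' masking threshold; age structure decays smoothly with age; populations
#' grow ~1% per year. Totals over races equal county totals by
#' construction.
#'
#' @param geography a `hale_geography`
#' @param config a `hale_config`
#' @param seed integer seed (defaults to a child of `config$seed`)
#' @return data.table aligned with [make_strata()] rows: stratum keys +
#'   `population`
#' @export
simulate_populations <- function(geography, config, seed = NULL) {
  if (is.null(seed)) seed <- child_seed(config$seed, "populations")
  set.seed(seed)
  strata <- make_strata(geography, config)
  ncty <- length(geography$counties)
  base <- exp(rnorm(ncty, mean = log(3e4), sd = 0.9))
  names(base) <- geography$counties
  nr <- length(config$races)
  shr <- matrix(rnorm(ncty * nr, 0, 1.6), ncty, nr)
  shr[, 1] <- shr[, 1] - 1.5  # first race systematically smaller
  share <- exp(shr) / rowSums(exp(shr))
  dimnames(share) <- list(geography$counties, config$races)
  ages <- age_table(config$age_starts)
  aw <- exp(-0.022 * ifelse(is.finite(ages$age_end),
                            (ages$age_start + ages$age_end) / 2,
                            ages$age_start + 5)) *
        ifelse(is.finite(ages$age_n), ages$age_n, 10)
  aw <- aw / sum(aw)
  names(aw) <- as.character(ages$age_start)
  y0 <- min(config$years)
  pop <- base[strata$county] * share[cbind(strata$county, strata$race)] *
    0.5 * aw[as.character(strata$age_start)] * 1.01^(strata$year - y0)
  out <- copy(strata)[, population := as.numeric(pop)]
  out[]
}

#' Simulate county-level sociodemographic covariates
#'
#' A single standardised deprivation-style score per county, spatially
#' smoothed over the adjacency graph so it correlates with the ICAR county
#' effects the way real sociodemographic covariates do.
#'
#' @inheritParams simulate_populations
#' @return data.table `county`, `covariate`
#' @export
simulate_covariates <- function(geography, config, seed = NULL) {
  if (is.null(seed)) seed <- child_seed(config$seed, "covariates")
  set.seed(seed)
  n <- length(geography$counties)
  z <- rnorm(n)
  A <- geography$adjacency
  deg <- pmax(Matrix::rowSums(A), 1)
  sm <- 0.5 * z + 0.5 * as.vector(A %*% z) / deg
  data.table(county = geography$counties,
             covariate = as.numeric(scale(sm)))
}

#' Simulate ground truth surfaces
#'
#' Generates the true prevalence surface for each indicator (logit link),
#' true mortality rates (log link), true cause-specific YLL rates, and true
#' cause-specific YLD rates (log link), each as fixed effects plus
#' structured random effects: ICAR county field, first-order random walks
#' over year and age, exchangeable race effects, and independent residual
#' noise, with variances from the configuration. Setting every variance to
#' zero yields the inverse-link of the fixed-effect predictor alone.
#' Per-surface child seeds are derived from the master seed in a documented
#' order (covariates, populations, then `prev:<indicator>`, `mx`,
#' `yll:<cause>`, `yld:<cause>`), so each surface is reproducible in
#' isolation.
#'
#' @param geography a `hale_geography`
#' @param config a `hale_config`
#' @param seed master seed (defaults to `config$seed`)
#' @return an object of class `hale_truth`: strata, covariates,
#'   populations, matrices `prevalence` (strata x indicators), `mx`
#'   (strata), `yll` and `yld` (strata x causes), and the effect fields and
#'   coefficients used
#' @export
simulate_truth <- function(geography, config, seed = NULL) {
  if (is.null(seed)) seed <- config$seed
  for (v in c(config$prev_var, config$yld_var, config$mx_var)) {
    if (v < 0) stop("invalid argument: negative variance")
  }
  strata <- make_strata(geography, config)
  covariates <- simulate_covariates(geography, config, child_seed(seed, "covariates"))
  populations <- simulate_populations(geography, config, child_seed(seed, "populations"))
  struct <- build_effect_structure(geography, strata,
                                   list(covariates = covariates))
  n <- nrow(strata)
  covariate <- struct$X[, "covariate"]
  sex_male <- struct$X[, "sex_male"]
  age_mid <- ifelse(is.finite(strata$age_end),
                    (strata$age_start + strata$age_end) / 2,
                    strata$age_start + 5)
  effects <- list()

  sample_surface <- function(vars, sseed) {
    set.seed(sseed)
    bl <- struct$blocks
    u_c <- sample_intrinsic(bl$county$Q, vars$county, 1L)[, 1]
    u_y <- sample_intrinsic(bl$year$Q, vars$year, 1L)[, 1]
    u_a <- sample_intrinsic(bl$age$Q, vars$age, 1L)[, 1]
    u_r <- if (!is.null(bl$race)) rnorm(length(bl$race$levels), 0, sqrt(vars$race)) else 0
    if (length(u_r) > 1L) u_r <- u_r - mean(u_r)  # deviations around intercept
    eps <- rnorm(n, 0, sqrt(vars$resid))
    eta <- u_c[bl$county$map] + u_y[bl$year$map] + u_a[bl$age$map] + eps
    if (!is.null(bl$race)) eta <- eta + u_r[bl$race$map]
    list(eta = eta, county = u_c, year = u_y, age = u_a, race = u_r, resid = eps)
  }

  # indicator prevalence surfaces; fixed effects in the fitter's design
  # basis so the generating coefficients are the recovery target
  pb <- config$prev_beta
  lp_fixed <- as.vector(struct$X[, names(pb)] %*% pb)
  prev <- matrix(NA_real_, n, length(config$indicators),
                 dimnames = list(NULL, config$indicators))
  for (ind in config$indicators) {
    sf <- sample_surface(config$prev_var, child_seed(seed, "prev", ind))
    prev[, ind] <- plogis(lp_fixed + sf$eta)
    effects[[paste0("prev:", ind)]] <- sf
  }

  # mortality rates
  mb <- config$mx_beta
  sf <- sample_surface(config$mx_var, child_seed(seed, "mx"))
  log_mx <- mb$intercept + mb$age_slope * age_mid +
    mb$infant * (strata$age_start == 0) + mb$sex_male * sex_male +
    mb$covariate * covariate + sf$eta
  mx <- exp(log_mx)
  # keep rates where the abridged q = n m / (1 + (n - a) m) stays below 1
  # (a = n/2, a0 = 0.2), so every simulated schedule yields a valid table
  agn <- ifelse(is.finite(strata$age_end), strata$age_end - strata$age_start, Inf)
  ax <- ifelse(agn == 1 & strata$age_start == 0, 0.2, agn / 2)
  cap <- ifelse(is.finite(agn), 0.95 / (agn - ax), Inf)
  mx <- pmin(mx, cap)
  effects[["mx"]] <- sf

  # cause-specific YLL rates: shares of mortality burden, log-scale noise
  ncau <- length(config$causes)
  set.seed(child_seed(seed, "yll_shares"))
  shares <- exp(rnorm(ncau, 0, 0.5)); shares <- shares / sum(shares)
  names(shares) <- config$causes
  yll <- matrix(NA_real_, n, ncau, dimnames = list(NULL, config$causes))
  for (cs in config$causes) {
    set.seed(child_seed(seed, "yll", cs))
    yll[, cs] <- mx * shares[cs] * 30 * exp(rnorm(n, 0, 0.1))
  }

  # cause-specific YLD rates; per-cause intercept calibrated so the
  # population-weighted all-cause YLD rate is ~0.13 (roughly the share of
  # life lived in poor health in high-income settings)
  yb <- config$yld_beta
  w <- populations$population
  set.seed(child_seed(seed, "yld_targets"))
  target <- 0.13 / ncau * exp(rnorm(ncau, 0, 0.3))
  yld <- matrix(NA_real_, n, ncau, dimnames = list(NULL, config$causes))
  for (j in seq_len(ncau)) {
    cs <- config$causes[j]
    sf <- sample_surface(config$yld_var, child_seed(seed, "yld", cs))
    lp <- yb$b_yll * log(yll[, cs]) + yb$b_ind * prev[, 1] +
      yb$b_cov * covariate + sf$eta
    b0 <- log(target[j]) - log(sum(w * exp(lp)) / sum(w))
    yld[, j] <- pmin(exp(b0 + lp), 1)
    effects[[paste0("yld:", cs)]] <- c(sf, intercept = b0)
  }

  structure(list(geography = geography, config = config, strata = strata,
                 covariates = covariates, populations = populations,
                 prevalence = prev, mx = mx, yll = yll, yld = yld,
                 effects = effects, seed = seed),
            class = "hale_truth")
}

#' Simulate survey-style indicator observations
#'
#' Observations are binomial counts attached to a *set* of fine strata: the
#' expected proportion is the population-weighted mean of the true
#' prevalences over the set, matching the aggregation-consistent likelihood
#' used at fit time. The design controls which observations are reported at
#' the fine stratum level and which only at a coarser merge (counties
#' collapsed within state, or age groups collapsed).
#'
#' @param truth a `hale_truth`
#' @param populations stratum population table (defaults to
#'   `truth$populations`)
#' @param design list: `indicator` (name; default first), `n_fine` trials
#'   per fine observation, `fine_frac` fraction of fine strata observed,
#'   `n_agg` trials per aggregated observation, `agg_frac` fraction of
#'   coarse cells observed as aggregates, `collapse` ("county" or "age")
#' @param seed integer seed
#' @return data.table of class `hale_obs`: `obs_id`, `indicator`,
#'   `stratum_set` (list of stratum_ids), `weights` (list of population
#'   weights), `n`, `k`, `aggregated`
#' @export
simulate_indicator_observations <- function(truth, populations = NULL,
                                            design = list(), seed = NULL) {
  if (is.null(populations)) populations <- truth$populations
  d <- modifyList(list(indicator = truth$config$indicators[1], n_fine = 500L,
                       fine_frac = 1.0, n_agg = 2000L, agg_frac = 0.25,
                       collapse = "county"), design)
  if (is.null(seed)) seed <- child_seed(truth$seed, "obs", d$indicator)
  set.seed(seed)
  strata <- truth$strata
  p_true <- truth$prevalence[, d$indicator]
  pop <- populations$population
  ns <- nrow(strata)

  fine_ids <- sort(sample.int(ns, size = round(d$fine_frac * ns)))
  obs <- list()
  if (length(fine_ids) && d$n_fine > 0L) {
    obs[[1]] <- data.table(
      stratum_set = as.list(fine_ids),
      weights = lapply(fine_ids, function(i) pop[i]),
      n = rep(as.integer(d$n_fine), length(fine_ids)),
      p = p_true[fine_ids], aggregated = FALSE)
  }
  if (d$agg_frac > 0 && d$n_agg > 0L) {
    gdt <- copy(strata)
    gdt[, state := truth$geography$state_of[county]]
    key_cols <- if (d$collapse == "county") {
      c("state", "race", "sex", "age_start", "year")
    } else {
      c("county", "race", "sex", "year")
    }
    gdt[, cell_id := .GRP, by = key_cols]
    cells <- unique(gdt$cell_id)
    take <- sample(cells, size = round(d$agg_frac * length(cells)))
    sets <- split(gdt$stratum_id, gdt$cell_id)[as.character(take)]
    pbar <- vapply(sets, function(ix) {
      if (!length(ix)) stop("invalid argument: empty stratum set")
      sum(pop[ix] * p_true[ix]) / sum(pop[ix])
    }, 0)
    obs[[length(obs) + 1L]] <- data.table(
      stratum_set = unname(sets),
      weights = lapply(unname(sets), function(ix) pop[ix]),
      n = rep(as.integer(d$n_agg), length(sets)),
      p = unname(pbar), aggregated = TRUE)
  }
  out <- rbindlist(obs)
  out <- out[n > 0L]
  out[, k := rbinom(.N, n, p)]
  out[, p := NULL]
  out[, obs_id := seq_len(.N)]
  out[, indicator := d$indicator]
  setcolorder(out, c("obs_id", "indicator", "stratum_set", "weights", "n", "k",
                     "aggregated"))
  setattr(out, "class", c("hale_obs", class(out)))
  out[]
}

#' Simulate state-level YLD benchmarks
#'
#' The benchmark for each (cause, state, sex, age, year) cell is the
#' population-weighted mean of the true county-by-race YLD rates over the
#' state, the highest resolution at which such estimates are available.
#' Draws add independent lognormal noise; with `noise_sd = 0` all draws
#' equal the weighted mean.
#'
#' @param truth a `hale_truth`
#' @param populations stratum population table (default `truth$populations`)
#' @param n_draws number of benchmark draws
#' @param noise_sd lognormal (log-scale) noise sd per draw
#' @param seed integer seed
#' @return data.table `cause`, `state`, `sex`, `age_start`, `year`, and
#'   draw columns in a `benchmarks` attribute-free long table with `draw`,
#'   `value`
#' @export
simulate_benchmarks <- function(truth, populations = NULL, n_draws = 1000L,
                                noise_sd = 0.02, seed = NULL) {
  if (is.null(populations)) populations <- truth$populations
  if (is.null(seed)) seed <- child_seed(truth$seed, "benchmarks")
  set.seed(seed)
  strata <- copy(truth$strata)
  strata[, state := truth$geography$state_of[county]]
  pop <- populations$population
  cells <- strata[, .(ids = list(stratum_id), W = sum(pop[stratum_id])),
                  by = .(state, sex, age_start, year)]
  if (any(cells$W <= 0)) {
    stop("invalid argument: zero total population in a state-age-sex-year cell")
  }
  out <- vector("list", length(truth$config$causes))
  for (j in seq_along(truth$config$causes)) {
    cs <- truth$config$causes[j]
    wm <- vapply(seq_len(nrow(cells)), function(r) {
      ix <- cells$ids[[r]]
      sum(pop[ix] * truth$yld[ix, cs]) / cells$W[r]
    }, 0)
    noise <- if (noise_sd > 0) {
      matrix(exp(rnorm(nrow(cells) * n_draws, -noise_sd^2 / 2, noise_sd)),
             nrow(cells), n_draws)
    } else matrix(1, nrow(cells), n_draws)
    vals <- wm * noise
    out[[j]] <- data.table(cause = cs,
                           cells[, .(state, sex, age_start, year)],
                           draw = rep(seq_len(n_draws), each = nrow(cells)),
                           value = as.vector(vals))
  }
  rbindlist(out)
}

#' Build abridged life tables for every stratum from true mortality
#'
#' Deterministic given the truth: applies the standard abridged life-table
#' construction (see [lifetable_from_mx()]) to the true `m_x` schedule of
#' each (county, race, sex, year) unit.
#'
#' @param truth a `hale_truth`
#' @param a0 average years lived in \[0,1) by those dying in it
#' @return data.table: unit keys + age columns `age_start`, `mx`, `ax`,
#'   `qx`, `lx`, `nLx`, `Tx`, `ex`
#' @export
simulate_life_tables <- function(truth, a0 = 0.2) {
  st <- copy(truth$strata)
  setorder(st, county, race, sex, year, age_start)
  ages <- age_table(truth$config$age_starts)
  k <- nrow(ages)
  units <- unique(st[, .(county, race, sex, year)])
  mxm <- matrix(truth$mx[st$stratum_id], nrow = k)  # ages vary fastest
  out <- vector("list", nrow(units))
  for (r in seq_len(nrow(units))) {
    lt <- lifetable_from_mx(mxm[, r], ages$age_start, a0 = a0)
    out[[r]] <- cbind(units[r], lt)
  }
  rbindlist(out)
}
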