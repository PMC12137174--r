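#' Run the estimation pipeline
#'
#' Orchestrates the stages (`simulate`, `fit_indicators`, `fit_ylds`,
#' `rake`, `hale`, `summarize`, or `all`) against an output directory.
#' Every stage writes its artifacts plus a JSON manifest recording the
#' configuration hash, the stage seed, the MD5 of every input and output
#' file, and row counts; a stage refuses to run when an upstream manifest
#' is missing or an input hash no longer matches its file. Reruns with
#' identical inputs are byte-identical.
#'
#' @param config a `hale_config` (see [sim_config()]) or a YAML path
#'   accepted by [read_config()]
#' @param out_dir output directory (created if needed)
#' @param stages character vector of stage names, or `"all"`
#' @return invisibly, the list of manifests
#' @export
run_pipeline <- function(config, out_dir, stages = "all") {
  if (is.character(config)) config <- read_config(config)
  all_stages <- c("simulate", "fit_indicators", "fit_ylds", "rake", "hale",
                  "summarize")
  if (identical(stages, "all")) stages <- all_stages
  bad <- setdiff(stages, all_stages)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  res <- lapply(stages, function(s) run_stage(s, config, out_dir))
  invisible(setNames(res, stages))
}

#' @rdname run_pipeline
#' @param stage one stage name
#' @export
run_stage <- function(stage, config, out_dir) {
  if (is.character(config)) config <- read_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- proc.time()[["elapsed"]]
  deps <- switch(stage,
    simulate = character(0),
    fit_indicators = "simulate",
    fit_ylds = c("simulate", "fit_indicators"),
    rake = c("simulate", "fit_ylds"),
    hale = c("simulate", "rake"),
    summarize = c("simulate", "hale"),
    stop("unknown stage: ", stage))
  inputs <- character(0)
  for (d in deps) {
    mpath <- file.path(out_dir, paste0("manifest_", d, ".json"))
    if (!file.exists(mpath)) {
      stop("stage '", stage, "' needs outputs of stage '", d,
           "'; run that stage first")
    }
    man <- jsonlite::read_json(mpath, simplifyVector = TRUE)
    for (f in names(man$outputs)) {
      fp <- file.path(out_dir, f)
      if (!file.exists(fp) ||
          unname(tools::md5sum(fp)) != man$outputs[[f]]$md5) {
        stop("input '", f, "' changed since stage '", d,
             "' ran (hash mismatch); rerun '", d, "' first")
      }
      inputs[f] <- man$outputs[[f]]$md5
    }
  }
  outputs <- stage_impl(stage, config, out_dir)
  man <- list(stage = stage, config_hash = config_hash(config),
              seed = config$seed, inputs = as.list(inputs),
              outputs = lapply(outputs, function(o) o))
  jsonlite::write_json(man, file.path(out_dir, paste0("manifest_", stage, ".json")),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  message(sprintf("[%s] done in %.1fs (%d output file(s))", stage,
                  proc.time()[["elapsed"]] - t0, length(outputs)))
  invisible(man)
}

out_record <- function(out_dir, files, rows = NULL) {
  setNames(lapply(seq_along(files), function(i) {
    list(md5 = unname(tools::md5sum(file.path(out_dir, files[i]))),
         rows = if (!is.null(rows)) rows[i] else NA)
  }), files)
}

stage_impl <- function(stage, config, out_dir) {
  switch(stage,
    simulate = stage_simulate(config, out_dir),
    fit_indicators = stage_fit_indicators(config, out_dir),
    fit_ylds = stage_fit_ylds(config, out_dir),
    rake = stage_rake(config, out_dir),
    hale = stage_hale(config, out_dir),
    summarize = stage_summarize(config, out_dir))
}

stage_simulate <- function(config, out_dir) {
  geog <- make_geography(config$n_counties, config$n_states,
                         seed = child_seed(config$seed, "geography"))
  truth <- simulate_truth(geog, config)
  total_draws <- config$n_models * config$draws_per_model
  write_geography(geog, file.path(out_dir, "geography.csv"))
  write_population(truth$populations, file.path(out_dir, "population.csv"))
  fwrite(truth$covariates, file.path(out_dir, "covariates.csv"))
  files <- c("geography.csv", "population.csv", "covariates.csv")
  for (ind in config$indicators) {
    obs <- simulate_indicator_observations(truth, design = list(indicator = ind))
    f <- paste0("indicator_obs_", ind, ".csv")
    write_observations(obs, file.path(out_dir, f))
    files <- c(files, f)
  }
  bm <- simulate_benchmarks(truth, n_draws = total_draws)
  fwrite(bm, file.path(out_dir, "benchmarks.csv"))
  lt <- simulate_life_tables(truth)
  fwrite(lt, file.path(out_dir, "lifetables.csv"))
  dir.create(file.path(out_dir, "truth"), showWarnings = FALSE)
  fwrite(data.table(truth$strata[, .(county, race, sex, age_start, year)],
                    truth$prevalence), file.path(out_dir, "truth/prevalence.csv"))
  fwrite(data.table(truth$strata[, .(county, race, sex, age_start, year)],
                    mx = truth$mx, truth$yll),
         file.path(out_dir, "truth/yll_mx.csv"))
  fwrite(data.table(truth$strata[, .(county, race, sex, age_start, year)],
                    truth$yld), file.path(out_dir, "truth/yld.csv"))
  saveRDS(truth, file.path(out_dir, "truth.rds"))
  files <- c(files, "benchmarks.csv", "lifetables.csv", "truth/prevalence.csv",
             "truth/yll_mx.csv", "truth/yld.csv", "truth.rds")
  out_record(out_dir, files)
}

stage_fit_indicators <- function(config, out_dir) {
  truth <- readRDS(file.path(out_dir, "truth.rds"))
  total_draws <- config$n_models * config$draws_per_model
  struct <- build_effect_structure(truth$geography, truth$strata,
                                   list(covariates = truth$covariates))
  files <- character(0)
  for (ind in config$indicators) {
    obs <- read_observations(file.path(out_dir, paste0("indicator_obs_", ind, ".csv")))
    fit <- fit_indicator_model(obs, struct)
    cube <- draw_posterior(fit, n_draws = total_draws,
                           seed = child_seed(config$seed, "prevdraws", ind))
    f <- paste0("prev_cube_", ind, ".rds")
    saveRDS(cube, file.path(out_dir, f))
    saveRDS(fit[c("beta", "beta_se", "theta", "converged", "grad_norm", "logml")],
            file.path(out_dir, paste0("prev_fit_", ind, ".rds")))
    files <- c(files, f, paste0("prev_fit_", ind, ".rds"))
  }
  out_record(out_dir, files)
}

stage_fit_ylds <- function(config, out_dir) {
  truth <- readRDS(file.path(out_dir, "truth.rds"))
  bm <- fread(file.path(out_dir, "benchmarks.csv"))
  design <- yld_design(truth$strata, truth$geography, truth$populations,
                       truth$covariates)
  cubes <- lapply(config$indicators, function(ind) {
    readRDS(file.path(out_dir, paste0("prev_cube_", ind, ".rds")))
  })
  names(cubes) <- config$indicators
  total <- NULL
  lineage <- NULL
  n_clip <- 0L
  for (cs in config$causes) {
    cube <- propagate_draws(cs, bm[cause == cs], truth$yll[, cs], cubes, design,
                            n_models = config$n_models,
                            draws_per_model = config$draws_per_model,
                            seed = child_seed(config$seed, "yld", cs))
    attr(cube, "fits") <- NULL
    if (is.null(total)) {
      total <- cube
    } else {
      assert_aligned(total, cube)
      total$draws <- total$draws + cube$draws
    }
  }
  n_clip <- sum(total$draws > 1)
  if (n_clip > 0) {
    message("all-cause sum: clipped ", n_clip, " cell(s) to [0, 1]")
    total$draws <- pmin(total$draws, 1)
  }
  saveRDS(total, file.path(out_dir, "allcause_yld.rds"))
  out_record(out_dir, "allcause_yld.rds")
}

stage_rake <- function(config, out_dir) {
  truth <- readRDS(file.path(out_dir, "truth.rds"))
  cube <- readRDS(file.path(out_dir, "allcause_yld.rds"))
  bm <- fread(file.path(out_dir, "benchmarks.csv"))
  bm_all <- bm[, .(value = sum(value)), by = .(state, sex, age_start, year, draw)]
  raked <- apply_raking(cube, truth$populations, bm_all,
                        geography = truth$geography)
  saveRDS(raked, file.path(out_dir, "raked_yld.rds"))
  fwrite(attr(raked, "raking_report"), file.path(out_dir, "raking_report.csv"))
  out_record(out_dir, c("raked_yld.rds", "raking_report.csv"))
}

stage_hale <- function(config, out_dir) {
  lt <- fread(file.path(out_dir, "lifetables.csv"))
  raked <- readRDS(file.path(out_dir, "raked_yld.rds"))
  hale <- hale_from_lifetables(lt, raked)
  saveRDS(hale, file.path(out_dir, "hale_draws.rds"))
  out_record(out_dir, "hale_draws.rds")
}

stage_summarize <- function(config, out_dir) {
  pop <- read_population(file.path(out_dir, "population.csv"))
  hale <- readRDS(file.path(out_dir, "hale_draws.rds"))
  lt <- fread(file.path(out_dir, "lifetables.csv"))
  s <- summarize_hale(hale, lt, pop, mask_threshold = config$mask_threshold)
  fwrite(s$summary, file.path(out_dir, "hale_summary.csv"))
  fwrite(s$disparity$spread, file.path(out_dir, "county_spread.csv"))
  fwrite(s$disparity$trends, file.path(out_dir, "county_trends.csv"))
  fwrite(s$national, file.path(out_dir, "national_summary.csv"))
  out_record(out_dir, c("hale_summary.csv", "county_spread.csv",
                        "county_trends.csv", "national_summary.csv"))
}

#' Sullivan HALE draws for every life-table unit
#'
#' Applies Sullivan's method draw by draw: each (county, race, sex, year)
#' unit's person-years are discounted by that unit's all-cause YLD rate
#' draws, giving HALE at every age. HALE is computed per draw and only then
#' summarised -- never from draw means.
#'
#' @param lifetables long life-table table from [simulate_life_tables()]
#' @param yld_cube raked all-cause `draw_cube` over the same strata
#' @return a `draw_cube` of HALE with the same strata (all ages), plus an
#'   `ex` column in its strata table
#' @export
hale_from_lifetables <- function(lifetables, yld_cube) {
  st <- copy(yld_cube$strata)
  st[, row_id := seq_len(.N)]
  setorder(st, county, race, sex, year, age_start)
  lt <- copy(lifetables)
  lt[, age_start := as.numeric(age_start)]
  st[, age_start := as.numeric(age_start)]
  setorder(lt, county, race, sex, year, age_start)
  if (!isTRUE(all.equal(st[, .(county, race, sex, year, age_start)],
                        lt[, .(county, race, sex, year, age_start)],
                        check.attributes = FALSE))) {
    stop("invalid argument: life tables and YLD cube strata do not match")
  }
  k <- length(unique(st$age_start))
  n_units <- nrow(st) / k
  D <- ncol(yld_cube$draws)
  out <- matrix(NA_real_, nrow(st), D)
  for (u in seq_len(n_units)) {
    ix <- (u - 1L) * k + seq_len(k)
    nL <- lt$nLx[ix]
    lx <- lt$lx[ix]
    d <- yld_cube$draws[st$row_id[ix], , drop = FALSE]
    healthy <- nL * (1 - d)
    csum <- apply(healthy[k:1, , drop = FALSE], 2, cumsum)[k:1, , drop = FALSE]
    out[ix, ] <- csum / lx
  }
  strata_out <- st[, .(county, race, sex, year, age_start, ex = lt$ex)]
  draw_cube(out, strata_out, yld_cube$lineage)
}

#' Summarise HALE draws into the reported tables
#'
#' Combines sexes and aggregates counties to the national level with
#' population weights (per draw), computes point estimates and 95%
#' uncertainty intervals, years and proportion of life in poor health,
#' applies small-population masking, flags significant changes between the
#' first and last study year, and derives county disparity statistics for
#' the last year.
#'
#' @param hale_cube output of [hale_from_lifetables()]
#' @param lifetables the life-table table (for life expectancy)
#' @param populations population table with `stratum_id`-free keys
#' @param mask_threshold mean annual population threshold
#' @return list: `summary` (county-race-year table with mean/lower/upper,
#'   masked flag), `national` (race-year and total-year estimates of HALE,
#'   life expectancy, years and percent of life in poor health),
#'   `disparity` (see [county_disparity_stats()])
#' @export
summarize_hale <- function(hale_cube, lifetables, populations,
                           mask_threshold = 1000) {
  st <- hale_cube$strata
  at_birth <- which(st$age_start == 0)
  h0 <- draw_cube(hale_cube$draws[at_birth, , drop = FALSE],
                  st[at_birth, .(county, race, sex, year, ex)],
                  hale_cube$lineage)
  # population weights at age-summed county-race-sex-year level
  pw <- populations[, .(population = sum(population)),
                    by = .(county, race, sex, year)]
  w <- stratum_weights(h0$strata, pw)
  ex_cube <- draw_cube(matrix(h0$strata$ex, nrow(h0$draws), ncol(h0$draws)),
                       h0$strata, h0$lineage)
  # combine sexes, then counties -> national, per draw
  both_h <- aggregate_weighted(h0, w, by = c("county", "race", "year"))
  both_e <- aggregate_weighted(ex_cube, w, by = c("county", "race", "year"))
  w2 <- stratum_weights(both_h$strata,
                        pw[, .(population = sum(population)),
                           by = .(county, race, year)])
  nat_h <- aggregate_weighted(both_h, w2, by = c("race", "year"))
  nat_e <- aggregate_weighted(both_e, w2, by = c("race", "year"))
  w3 <- stratum_weights(nat_h$strata,
                        pw[, .(population = sum(population)), by = .(race, year)])
  tot_h <- aggregate_weighted(nat_h, w3, by = "year")
  tot_e <- aggregate_weighted(nat_e, w3, by = "year")

  summary <- point_and_ui(both_h)
  summary <- mask_small(summary, populations, mask_threshold)
  nat <- rbindlist(list(
    cbind(race = nat_h$strata$race, year = nat_h$strata$year,
          nat_summary(nat_h, nat_e)),
    cbind(race = "Total", year = tot_h$strata$year,
          nat_summary(tot_h, tot_e))))

  years <- sort(unique(st$year))
  y0 <- years[1]; y1 <- years[length(years)]
  sub_year <- function(cube, y) {
    ix <- which(cube$strata$year == y)
    draw_cube(cube$draws[ix, , drop = FALSE],
              cube$strata[ix, !"year"], cube$lineage)
  }
  chg <- compare_draws(sub_year(both_h, y1), sub_year(both_h, y0))
  chg <- mask_small(chg, populations, mask_threshold)
  pts <- summary[year == y1, .(county, race, mean, masked)]
  disparity <- county_disparity_stats(
    pts, changes = chg[, .(county, race, diff_mean, significant, masked)])
  list(summary = summary[], national = nat[], disparity = disparity,
       changes = chg[])
}

nat_summary <- function(h_cube, e_cube) {
  hp <- point_and_ui(h_cube)
  yp_draws <- e_cube$draws - h_cube$draws
  pp_draws <- 100 * yp_draws / e_cube$draws
  qs <- function(m) t(apply(m, 1, quantile, probs = c(0.025, 0.975), type = 7,
                            names = FALSE))
  qy <- qs(yp_draws); qp <- qs(pp_draws); qe <- qs(e_cube$draws)
  data.table(hale = hp$mean, hale_lower = hp$lower, hale_upper = hp$upper,
             ex = rowMeans(e_cube$draws), ex_lower = qe[, 1], ex_upper = qe[, 2],
             years_poor = rowMeans(yp_draws),
             years_poor_lower = qy[, 1], years_poor_upper = qy[, 2],
             prop_poor_pct = rowMeans(pp_draws),
             prop_poor_lower = qp[, 1], prop_poor_upper = qp[, 2])
}

#' Read / write a pipeline configuration as YAML
#'
#' Scalars override the defaults of [sim_config()]; list-valued entries
#' (variances, coefficient blocks) are merged element-wise.
#'
#' @param path YAML file
#' @return a `hale_config`
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  base <- sim_config()
  direct <- intersect(names(y), setdiff(names(formals(sim_config)), "..."))
  cfg <- do.call(sim_config, y[direct])
  rest <- setdiff(names(y), direct)
  for (nm in rest) {
    cfg[[nm]] <- if (is.list(cfg[[nm]])) utils::modifyList(cfg[[nm]], y[[nm]])
                 else y[[nm]]
  }
  cfg
}

#' @rdname read_config
#' @param config a `hale_config`
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

config_hash <- function(config) {
  f <- tempfile(fileext = ".yaml")
  on.exit(unlink(f))
  yaml::write_yaml(unclass(config), f)
  unname(tools::md5sum(f))
}
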