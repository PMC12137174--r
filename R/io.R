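#' Delimited-text readers and writers for pipeline inputs
#'
#' All synthetic inputs round-trip through plain CSV with fixed, documented
#' columns:
#' \describe{
#'   \item{population.csv}{`county, race, sex, age_start, year, population`}
#'   \item{covariates.csv}{`county` plus one numeric column per covariate}
#'   \item{benchmarks.csv}{`cause, state, sex, age_start, year, draw, value`}
#'   \item{lifetables.csv}{`county, race, sex, year` plus life-table columns}
#'   \item{indicator_obs.csv}{`obs_id, indicator, stratum_ids` and
#'     `weights` (semicolon-joined), `n, k, aggregated`}
#' }
#'
#' @param x table to write
#' @param path file path
#' @name io
NULL

#' @rdname io
#' @export
write_population <- function(x, path) {
  fwrite(x[, .(county, race, sex, age_start, year,
               population = signif(population, 15))], path)
  invisible(path)
}

#' @rdname io
#' @export
read_population <- function(path) {
  dt <- fread(path)
  setkey(dt, county, race, sex, age_start, year)
  dt[, stratum_id := seq_len(.N)]
  dt[]
}

#' @rdname io
#' @export
write_observations <- function(x, path) {
  flat <- data.table(
    obs_id = x$obs_id, indicator = x$indicator,
    stratum_ids = vapply(x$stratum_set, paste, "", collapse = ";"),
    weights = vapply(x$weights, function(w) paste(signif(w, 15), collapse = ";"), ""),
    n = x$n, k = x$k, aggregated = x$aggregated)
  fwrite(flat, path)
  invisible(path)
}

#' @rdname io
#' @export
read_observations <- function(path) {
  flat <- fread(path, colClasses = list(character = c("stratum_ids", "weights")))
  out <- data.table(
    obs_id = flat$obs_id, indicator = flat$indicator,
    stratum_set = lapply(strsplit(flat$stratum_ids, ";", fixed = TRUE), as.integer),
    weights = lapply(strsplit(flat$weights, ";", fixed = TRUE), as.numeric),
    n = flat$n, k = flat$k, aggregated = flat$aggregated)
  setattr(out, "class", c("hale_obs", class(out)))
  out[]
}
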