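#' Population-weighted aggregation of a draw cube
#'
#' Collapses strata to the groups defined by `by` (e.g. dropping `sex` to
#' combine sexes, or collapsing counties to a national estimate) by taking
#' the population-weighted mean within each group, draw by draw. Summaries
#' (means, intervals) are always taken *after* aggregation, never on
#' pre-aggregated summaries.
#'
#' @param cube a `draw_cube`
#' @param weights population weight per stratum (aligned with the cube
#'   rows), or a population table accepted by [stratum_weights()]
#' @param by character vector of stratum columns defining the groups
#' @return a `draw_cube` over the groups
#' @export
aggregate_weighted <- function(cube, weights, by) {
  if (!is.numeric(weights)) weights <- stratum_weights(cube$strata, weights)
  if (any(weights < 0)) stop("invalid argument: negative weights")
  st <- copy(cube$strata)
  st[, cell_id := .GRP, by = by]
  groups <- unique(st[, c(by, "cell_id"), with = FALSE])
  setorder(groups, cell_id)
  G <- Matrix::sparseMatrix(i = st$cell_id, j = seq_len(nrow(st)), x = weights,
                            dims = c(nrow(groups), nrow(st)))
  W <- Matrix::rowSums(G)
  if (any(W <= 0)) {
    bad <- groups[which(W <= 0)[1]]
    stop("all-zero weights in group ",
         paste(unlist(bad[, !"cell_id"]), collapse = "/"))
  }
  out <- as.matrix(G %*% cube$draws) / W
  groups[, cell_id := NULL]
  draw_cube(out, groups, cube$lineage)
}

#' Point estimate and 95% uncertainty interval from draws
#'
#' Point estimates are draw means; intervals are the empirical 2.5th and
#' 97.5th percentiles under the linear-interpolation quantile definition
#' (R's type 7), pinned for reproducibility.
#'
#' @param cube a `draw_cube` (at least 2 draws), or a numeric vector of
#'   draws
#' @return for a cube, the stratum table plus `mean`, `lower`, `upper`; for
#'   a vector, a named numeric of the three values
#' @export
point_and_ui <- function(cube) {
  if (is.numeric(cube)) {
    if (length(cube) < 2L) stop("invalid argument: need at least 2 draws")
    if (anyNA(cube)) stop("invalid argument: NaN/NA draws")
    q <- quantile(cube, c(0.025, 0.975), type = 7, names = FALSE)
    return(c(mean = mean(cube), lower = q[1], upper = q[2]))
  }
  if (ncol(cube$draws) < 2L) stop("invalid argument: need at least 2 draws")
  if (anyNA(cube$draws)) stop("invalid argument: NaN/NA draws")
  qs <- t(apply(cube$draws, 1, quantile, probs = c(0.025, 0.975), type = 7,
                names = FALSE))
  out <- copy(cube$strata)
  out[, `:=`(mean = rowMeans(cube$draws), lower = qs[, 1], upper = qs[, 2])]
  out[]
}

#' Compare two aligned draw cubes
#'
#' Differences are taken draw by draw (A minus B), preserving the
#' correlation carried by draw alignment. The posterior probability that
#' the difference is greater than zero is the fraction of difference draws
#' strictly above zero (ties count as not greater, a conservative choice);
#' a difference is statistically significant when that probability is below
#' 2.5% or above 97.5%, analogous to a two-tailed test at alpha 0.05.
#' Because draws are correlated, differences can be significant even when
#' the two marginal intervals overlap substantially.
#'
#' @param a,b aligned `draw_cube`s (same strata, same draw count)
#' @return stratum table plus `diff_mean`, `diff_lower`, `diff_upper`,
#'   `posterior_prob`, `significant`
#' @export
compare_draws <- function(a, b) {
  assert_aligned(a, b)
  d <- a$draws - b$draws
  qs <- t(apply(d, 1, quantile, probs = c(0.025, 0.975), type = 7,
                names = FALSE))
  pp <- rowMeans(d > 0)
  # a row of pure ties (identical draws) is never flagged: its posterior
  # probability is 0 only by the tie convention, not by evidence
  any_diff <- rowSums(d != 0) > 0
  out <- copy(a$strata)
  out[, `:=`(diff_mean = rowMeans(d), diff_lower = qs[, 1],
             diff_upper = qs[, 2], posterior_prob = pp,
             significant = (pp < 0.025 | pp > 0.975) & any_diff)]
  out[]
}

#' Mean annual population and small-population masking
#'
#' Estimates for county-race populations whose mean annual population over
#' the study years falls below the threshold are flagged as masked;
#' masking never alters values, only their inclusion in county summaries.
#'
#' @param results data.table with `county` and `race` columns (estimates at
#'   any stratification nested in county-race)
#' @param populations stratum population table (county, race, sex, age,
#'   year, population)
#' @param threshold mask below this mean annual population (default 1000)
#' @return `results` with `mean_annual_pop` and `masked` columns added
#' @export
mask_small <- function(results, populations, threshold = 1000) {
  if (!all(c("county", "race") %in% names(results))) {
    stop("invalid argument: results must carry county and race")
  }
  mp <- populations[, .(annual = sum(population)), by = .(county, race, year)]
  mp <- mp[, .(mean_annual_pop = mean(annual)), by = .(county, race)]
  out <- merge(results, mp, by = c("county", "race"), all.x = TRUE, sort = FALSE)
  if (anyNA(out$mean_annual_pop)) stop("missing population for some county-race cells")
  out[, masked := mean_annual_pop < threshold]
  out[]
}

#' Round a percentage half-up to one decimal
#'
#' Reported percentages are count ratios rounded half-up at one decimal
#' place (R's `round()` rounds half to even, which is not the reporting
#' convention here).
#'
#' @param x percentage values
#' @return rounded values
#' @export
pct_round <- function(x) floor(x * 10 + 0.5) / 10

#' County-level disparity statistics
#'
#' Summarises unmasked county estimates per population: minimum, maximum,
#' range, median and IQR; optionally counts (and half-up percentages) of
#' counties with statistically significant increases and declines between
#' two years, and pairwise cross-population significant-difference counts.
#'
#' @param points data.table with `county`, `race`, `mean`, `masked`
#' @param changes optional data.table with `county`, `race`,
#'   `diff_mean`, `significant`, `masked` (difference = later minus
#'   earlier year)
#' @param pairwise optional data.table with `county`, `race_a`, `race_b`,
#'   `diff_mean`, `significant`, `masked`
#' @return list with `spread` (per-race min/max/range/median/IQR over
#'   unmasked counties), and when supplied `trends` (counts and
#'   percentages of significant increases/declines) and `pairs` (counts of
#'   counties where race_a is significantly above/below race_b)
#' @export
county_disparity_stats <- function(points, changes = NULL, pairwise = NULL) {
  pu <- points[masked == FALSE]
  if (nrow(pu) == 0L) stop("no unmasked counties")
  spread <- pu[, .(
    n_counties = .N, min = min(mean), max = max(mean),
    range = max(mean) - min(mean), median = median(mean),
    q25 = quantile(mean, 0.25, type = 7, names = FALSE),
    q75 = quantile(mean, 0.75, type = 7, names = FALSE)), by = race]
  out <- list(spread = spread[])
  if (!is.null(changes)) {
    cu <- changes[masked == FALSE]
    out$trends <- cu[, .(
      n_counties = .N,
      n_declined = sum(diff_mean < 0),
      pct_declined = pct_round(100 * sum(diff_mean < 0) / .N),
      n_sig_declined = sum(significant & diff_mean < 0),
      pct_sig_declined = pct_round(100 * sum(significant & diff_mean < 0) / .N),
      n_sig_increased = sum(significant & diff_mean > 0),
      pct_sig_increased = pct_round(100 * sum(significant & diff_mean > 0) / .N)),
      by = race][]
  }
  if (!is.null(pairwise)) {
    pw <- pairwise[masked == FALSE]
    out$pairs <- pw[, .(
      n_counties = .N,
      n_sig_above = sum(significant & diff_mean > 0),
      pct_sig_above = pct_round(100 * sum(significant & diff_mean > 0) / .N),
      n_sig_below = sum(significant & diff_mean < 0),
      pct_sig_below = pct_round(100 * sum(significant & diff_mean < 0) / .N)),
      by = .(race_a, race_b)][]
  }
  out
}
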