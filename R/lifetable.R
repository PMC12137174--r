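#' Abridged life table from age-specific mortality rates
#'
#' Standard abridged construction: for a closed group of width `n` with
#' death rate `m` and average years lived by decedents `a`,
#' `q = n m / (1 + (n - a) m)`; survivors `l` start at the radix 100 000;
#' person-years `nL = n (l - d) + a d`; in the open-ended terminal group
#' `q = 1` and `nL = l / m`. `T` accumulates person-years from the oldest
#' group down and `e = T / l`.
#'
#' @param mx death rates per person-year, one per age group
#' @param age_starts left endpoints of the age groups (terminal open-ended)
#' @param ax average years lived in the group by those dying in it; default
#'   `a0` for the first group when it is \[0,1) (infant deaths cluster early
#'   in the year), `n/2` for other closed groups
#' @param a0 infant `a` convention (used only when the first group is
#'   \[0,1))
#' @param radix l at the youngest age
#' @return data.table with columns `age_start`, `age_n`, `mx`, `ax`, `qx`,
#'   `lx`, `ndx`, `nLx`, `Tx`, `ex`
#' @export
lifetable_from_mx <- function(mx, age_starts, ax = NULL, a0 = 0.2,
                              radix = 1e5) {
  k <- length(mx)
  if (length(age_starts) != k) {
    stop("invalid argument: mx and age_starts lengths differ")
  }
  ages <- age_table(age_starts)
  nn <- ages$age_n
  if (mx[k] <= 0) {
    stop("invalid argument: non-positive m in terminal group [",
         age_starts[k], ", Inf) - terminal e undefined")
  }
  if (is.null(ax)) {
    ax <- ifelse(is.finite(nn), nn / 2, 1 / mx[k])
    if (k > 1L && nn[1] == 1) ax[1] <- a0
  }
  if (any(is.finite(nn) & (ax < 0 | ax > nn))) {
    stop("invalid argument: ax outside [0, n]")
  }
  qx <- numeric(k)
  cl <- is.finite(nn)
  qx[cl] <- nn[cl] * mx[cl] / (1 + (nn[cl] - ax[cl]) * mx[cl])
  qx[!cl] <- 1
  bad <- which(qx < 0 | qx > 1)
  if (length(bad)) {
    stop("death probability outside [0,1] in age group starting at ",
         age_starts[bad[1]])
  }
  lx <- radix * cumprod(c(1, 1 - qx[-k]))
  ndx <- lx * qx
  nLx <- numeric(k)
  nLx[cl] <- nn[cl] * (lx[cl] - ndx[cl]) + ax[cl] * ndx[cl]
  nLx[k] <- lx[k] / mx[k]
  Tx <- rev(cumsum(rev(nLx)))
  ex <- ifelse(lx > 0, Tx / lx, 0)
  data.table(age_start = age_starts, age_n = nn, mx = mx, ax = ax, qx = qx,
             lx = lx, ndx = ndx, nLx = nLx, Tx = Tx, ex = ex)
}

#' Healthy life expectancy by Sullivan's method
#'
#' Discounts each age group's person-years by the fraction of the year
#' lived in full health: `HALE_x = sum_{y >= x} nL_y (1 - d_y) / l_x`,
#' where `d_y` is the all-cause YLD rate (per person-year, in \[0,1\]).
#' With `d = 0` everywhere this reduces to life expectancy; a constant `d`
#' scales life expectancy by `1 - d`.
#'
#' @param lifetable a data.table from [lifetable_from_mx()]
#' @param yld_rates all-cause YLD rate per age group, aligned with the life
#'   table rows
#' @return numeric vector of HALE at each age group start
#' @export
hale_sullivan <- function(lifetable, yld_rates) {
  if (length(yld_rates) != nrow(lifetable)) {
    stop("invalid argument: yld_rates length does not match life table")
  }
  if (any(yld_rates < 0 | yld_rates > 1)) {
    stop("invalid argument: yld_rates must lie in [0, 1]")
  }
  healthy <- lifetable$nLx * (1 - yld_rates)
  rev(cumsum(rev(healthy))) / lifetable$lx
}

#' Years and proportion of life in poor health
#'
#' @param ex life expectancy (years)
#' @param hale healthy life expectancy (years), `hale <= ex`
#' @return list `years_poor = ex - hale`, `prop_poor = years_poor / ex`
#' @export
poor_health_summaries <- function(ex, hale) {
  if (any(ex == 0)) stop("invalid argument: proportion undefined when e = 0")
  if (any(hale > ex + 1e-9)) stop("invalid argument: HALE exceeds life expectancy")
  years_poor <- ex - hale
  list(years_poor = years_poor, prop_poor = years_poor / ex)
}
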