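#' Structured random-effect precision matrices
#'
#' `icar_precision` returns the intrinsic conditional autoregressive (ICAR)
#' precision on the county graph, the degree matrix minus the adjacency
#' matrix. `rw1_precision` returns the first-order random-walk
#' second-difference penalty over an ordered index. Both are intrinsic
#' (singular) with zero row sums; identifiability comes from sum-to-zero
#' constraints, imposed per connected component for the ICAR.
#'
#' @param geography a `hale_geography`
#' @param k number of ordered levels (years or age groups)
#' @return a sparse symmetric Matrix
#' @export
icar_precision <- function(geography) {
  adj <- geography$adjacency
  deg <- Matrix::Diagonal(x = Matrix::rowSums(adj))
  Q <- deg - adj
  dimnames(Q) <- dimnames(adj)
  Q
}

#' @rdname icar_precision
#' @export
rw1_precision <- function(k) {
  if (k == 1L) return(Matrix::Matrix(0, 1, 1, sparse = TRUE))
  D <- Matrix::sparseMatrix(i = rep(seq_len(k - 1L), 2L),
                            j = c(seq_len(k - 1L), seq_len(k - 1L) + 1L),
                            x = rep(c(-1, 1), each = k - 1L),
                            dims = c(k - 1L, k))
  Matrix::crossprod(D)
}

#' Sample an intrinsic Gaussian field on its constrained subspace
#'
#' Draws from the Gaussian with precision `Q / sigma2` restricted to the
#' subspace orthogonal to the null space of `Q` (the sum-to-zero subspace,
#' per connected component for an ICAR), using the eigendecomposition
#' pseudo-inverse construction: eigenvectors with (numerically) zero
#' eigenvalue are dropped and the remainder scaled by `sqrt(sigma2 /
#' lambda)`.
#'
#' @param Q intrinsic precision matrix (unit scale)
#' @param sigma2 marginal variance scale (>= 0; 0 returns the zero field)
#' @param n number of samples
#' @return matrix `nrow(Q)` x `n`; each column sums to zero within each
#'   null-space component
#' @export
sample_intrinsic <- function(Q, sigma2, n = 1L) {
  if (sigma2 < 0) stop("invalid argument: negative variance")
  m <- nrow(Q)
  if (sigma2 == 0 || m == 1L) return(matrix(0, m, n))
  eg <- eigen(as.matrix(Q), symmetric = TRUE)
  tol <- max(eg$values) * 1e-9
  keep <- eg$values > tol
  if (!any(keep)) return(matrix(0, m, n))
  z <- matrix(rnorm(sum(keep) * n), sum(keep), n)
  eg$vectors[, keep, drop = FALSE] %*% (z * sqrt(sigma2 / eg$values[keep]))
}

#' Assemble the random-effect structure for a small-area model
#'
#' Builds the fixed-effect design and the structured random-effect blocks
#' used by both the truth simulator and the model fitter: county (ICAR over
#' the geography), year (RW1), age (RW1), race (exchangeable) and,
#' optionally, education (exchangeable). Each block carries its intrinsic
#' precision `Q` (zero row sums for ICAR/RW1), the stratum-to-level map,
#' and the sum-to-zero constraint blocks (one per connected component for
#' the ICAR, the whole index for RW1), imposed at fit time as soft
#' penalties.
#'
#' @param geography a `hale_geography`
#' @param strata the stratum table from [make_strata()] (optionally with an
#'   `education` column)
#' @param config list; `covariates` may give a data.table of county-level
#'   covariates (column `county` plus numeric columns) entering the fixed
#'   design; `use_education` adds an exchangeable education block when the
#'   strata carry an `education` column
#' @return list of class `hale_effects` with elements `X` (dense fixed
#'   design), `blocks` (named list; each with `Q`, `map`, `levels`, `type`,
#'   `constraints`), and `strata`
#' @export
build_effect_structure <- function(geography, strata, config = list()) {
  bad <- setdiff(unique(strata$county), geography$counties)
  if (length(bad)) {
    stop("invalid argument: strata contain counties absent from geography: ",
         paste(head(bad, 3), collapse = ", "))
  }
  n <- nrow(strata)
  X <- cbind(intercept = rep(1, n),
             sex_male = as.numeric(strata$sex == "male"),
             age_std = scale_age(strata$age_start))
  if (!is.null(config$covariates)) {
    cv <- config$covariates
    num_cols <- setdiff(names(cv), "county")
    rows <- match(strata$county, cv$county)
    if (anyNA(rows)) stop("invalid argument: covariates missing for some counties")
    X <- cbind(X, as.matrix(cv[rows, num_cols, with = FALSE]))
  }
  blocks <- list()
  cty_lev <- geography$counties
  Qc <- icar_precision(geography)
  comp <- geography$component[cty_lev]
  constr_c <- lapply(split(seq_along(cty_lev), comp), identity)
  blocks$county <- list(
    Q = Qc, type = "icar", levels = cty_lev,
    map = match(strata$county, cty_lev), constraints = constr_c)
  yr_lev <- sort(unique(strata$year))
  blocks$year <- list(
    Q = rw1_precision(length(yr_lev)), type = "rw1", levels = yr_lev,
    map = match(strata$year, yr_lev), constraints = list(seq_along(yr_lev)))
  age_lev <- sort(unique(strata$age_start))
  blocks$age <- list(
    Q = rw1_precision(length(age_lev)), type = "rw1", levels = age_lev,
    map = match(strata$age_start, age_lev), constraints = list(seq_along(age_lev)))
  # exchangeable blocks also carry a sum-to-zero constraint: their levels are
  # deviations around the shared intercept, which keeps the intercept
  # identified and the block variance estimable from the contrasts
  race_lev <- sort(unique(strata$race))
  if (length(race_lev) > 1L) {
    blocks$race <- list(
      Q = Matrix::Diagonal(length(race_lev)), type = "iid", levels = race_lev,
      map = match(strata$race, race_lev),
      constraints = list(seq_along(race_lev)))
  }
  if (isTRUE(config$use_education) && "education" %in% names(strata)) {
    edu_lev <- sort(unique(strata$education))
    blocks$education <- list(
      Q = Matrix::Diagonal(length(edu_lev)), type = "iid", levels = edu_lev,
      map = match(strata$education, edu_lev),
      constraints = list(seq_along(edu_lev)))
  }
  structure(list(X = X, blocks = blocks, strata = strata),
            class = "hale_effects")
}

# standardise age for the fixed design so coefficients are O(1)
scale_age <- function(age_start) (age_start - 40) / 25
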