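#' Design for the state-benchmark YLD regression
#'
#' Precomputes the fixed parts shared by every cause model: the stratum
#' table, the county covariate per stratum, and the sparse aggregation
#' matrix mapping county-race strata to their (state, sex, age, year)
#' benchmark cell with population-normalised weights. Cells with zero total
#' population are excluded with a warning.
#'
#' @param strata stratum table from [make_strata()]
#' @param geography a `hale_geography`
#' @param populations stratum population table
#' @param covariates county covariate table (column `county` + numerics)
#' @return list of class `yld_design`: `strata`, `cells`, `G` (cells x
#'   strata, rows sum to 1), `Xbase` (intercept + covariates)
#' @export
yld_design <- function(strata, geography, populations, covariates) {
  st <- copy(strata)
  st[, state := geography$state_of[county]]
  pop <- populations$population[match(st$stratum_id, populations$stratum_id)]
  st[, cell_id := .GRP, by = .(state, sex, age_start, year)]
  cells <- unique(st[, .(cell_id, state, sex, age_start, year)])
  setorder(cells, cell_id)
  G <- Matrix::sparseMatrix(i = st$cell_id, j = seq_len(nrow(st)), x = pop,
                            dims = c(nrow(cells), nrow(st)))
  W <- Matrix::rowSums(G)
  empty <- W <= 0
  if (any(empty)) {
    warning(sum(empty), " state cell(s) with zero population excluded")
    G <- G[!empty, , drop = FALSE]
    cells <- cells[!empty]
    W <- W[!empty]
  }
  G <- G / W
  rows <- match(st$county, covariates$county)
  if (anyNA(rows)) stop("invalid argument: covariates missing for some counties")
  num_cols <- setdiff(names(covariates), "county")
  Xbase <- cbind(intercept = rep(1, nrow(st)),
                 as.matrix(covariates[rows, num_cols, with = FALSE]))
  out <- list(strata = st, cells = cells, G = G, Xbase = Xbase)
  class(out) <- "yld_design"
  out
}

#' Fit one cause-specific YLD model to a single benchmark draw
#'
#' Gaussian likelihood on the log benchmark rate with mean equal to the log
#' of the population-weighted average of `exp(X beta)` over the state's
#' county-race strata (the aggregation-consistent mean on the rate scale).
#' Solved by Gauss-Newton with analytic Jacobian and step halving; the
#' returned fit carries the coefficient covariance (Gaussian at the
#' optimum) and the residual variance.
#'
#' @param benchmark data.table with `state`, `sex`, `age_start`, `year`,
#'   `value` for one cause and one input draw
#' @param yll YLL rate per stratum for this cause (positive)
#' @param indicators matrix (strata x indicators) of prevalence values for
#'   one input draw
#' @param design a [yld_design()]
#' @param input_draw index of the input draw consumed (bookkeeping)
#' @return object of class `yld_fit`: `beta`, `vcov`, `sigma2`,
#'   `input_draw`, `X`, and the fitted cell means
#' @export
fit_cause_model <- function(benchmark, yll, indicators, design,
                            input_draw = NA_integer_) {
  X <- cbind(design$Xbase, log_yll = log(yll), indicators)
  b <- merge(design$cells, benchmark,
             by = c("state", "sex", "age_start", "year"), sort = FALSE)
  setorder(b, cell_id)
  if (nrow(b) != nrow(design$cells)) {
    stop("invalid argument: benchmark does not cover every state cell")
  }
  y <- log(b$value)
  G <- design$G
  # linear initialisation: log benchmark ~ cell-aggregated design; tiny
  # ridge keeps degenerate (saturated or collinear) designs solvable
  Xc <- as.matrix(G %*% X)
  ridge_solve <- function(A, b) {
    AtA <- crossprod(A)
    solve(AtA + diag(1e-10 * max(diag(AtA), 1), ncol(A)), crossprod(A, b))
  }
  beta <- as.vector(ridge_solve(Xc, y))
  sse_at <- function(beta) {
    e <- exp(as.vector(X %*% beta))
    r <- y - log(as.vector(G %*% e))
    list(r = r, sse = sum(r^2), e = e)
  }
  cur <- sse_at(beta)
  J <- NULL
  for (it in 1:100) {
    pbar <- as.vector(G %*% cur$e)
    J <- as.matrix(G %*% (cur$e * X)) / pbar
    step <- as.vector(ridge_solve(J, cur$r))
    if (max(abs(step)) < 1e-12) break
    alpha <- 1
    repeat {
      cand <- sse_at(beta + alpha * step)
      if (is.finite(cand$sse) && cand$sse <= cur$sse + 1e-14) break
      alpha <- alpha / 2
      if (alpha < 1e-12) break
    }
    if (alpha < 1e-12) break
    beta <- beta + alpha * step
    prev_sse <- cur$sse
    cur <- cand
    if (prev_sse - cur$sse < 1e-14 * (1 + cur$sse)) break
  }
  p <- ncol(X)
  sigma2 <- cur$sse / max(length(y) - p, 1)
  JtJ <- crossprod(J)
  V <- tryCatch(sigma2 * solve(JtJ), error = function(e) {
    sigma2 * solve(JtJ + diag(1e-8, p))
  })
  out <- list(beta = setNames(as.vector(beta), colnames(X)), vcov = V,
              sigma2 = sigma2, input_draw = input_draw, X = X,
              fitted_cells = log(as.vector(G %*% cur$e)), sse = cur$sse)
  class(out) <- "yld_fit"
  out
}

#' Predict stratum YLD rates from a fitted cause model
#'
#' @param object a `yld_fit`
#' @param ... unused
#' @return rate per stratum, `exp(X beta)`
#' @export
predict.yld_fit <- function(object, ...) {
  exp(as.vector(object$X %*% object$beta))
}

#' Propagate uncertainty through a cause model by draw splitting
#'
#' Fits `n_models` models for the cause, model `m` consuming input draw `m`
#' of every stochastic input (benchmark and indicator prevalences), then
#' simulates `draws_per_model` prediction draws from each fit (coefficient
#' uncertainty via the Gaussian at the optimum, plus lognormal residual
#' noise), concatenated in (model, draw) order.
#'
#' @param cause cause name (for lineage metadata)
#' @param benchmarks long benchmark table for this cause (`state`, `sex`,
#'   `age_start`, `year`, `draw`, `value`)
#' @param yll YLL rate per stratum for this cause
#' @param indicator_cubes named list of `draw_cube`s of indicator
#'   prevalence over the same strata
#' @param design a [yld_design()]
#' @param n_models,draws_per_model draw-splitting scheme; the product is
#'   the total number of output draws
#' @param seed integer seed
#' @return a `draw_cube` (strata x `n_models * draws_per_model`) with
#'   lineage columns `draw`, `model`, `input_draw`
#' @export
propagate_draws <- function(cause, benchmarks, yll, indicator_cubes, design,
                            n_models = 50L, draws_per_model = 20L, seed = 1L) {
  n_bd <- max(benchmarks$draw)
  if (n_bd < n_models) {
    stop("invalid argument: ", n_bd, " benchmark draws < n_models = ", n_models)
  }
  for (cb in indicator_cubes) {
    if (n_draws(cb) < n_models) {
      stop("invalid argument: fewer indicator draws than n_models")
    }
  }
  set.seed(as.integer(seed))
  ns <- nrow(design$strata)
  total <- n_models * draws_per_model
  out <- matrix(NA_real_, ns, total)
  fits <- vector("list", n_models)
  for (m in seq_len(n_models)) {
    bm <- benchmarks[draw == m]
    ind <- do.call(cbind, lapply(names(indicator_cubes), function(nm) {
      indicator_cubes[[nm]]$draws[, m]
    }))
    colnames(ind) <- names(indicator_cubes)
    fit <- fit_cause_model(bm[, .(state, sex, age_start, year, value)],
                           yll, ind, design, input_draw = m)
    fits[[m]] <- fit
    p <- length(fit$beta)
    Rv <- tryCatch(chol(fit$vcov), error = function(e) matrix(0, p, p))
    for (j in seq_len(draws_per_model)) {
      bstar <- fit$beta + as.vector(t(Rv) %*% rnorm(p))
      pred <- exp(as.vector(fit$X %*% bstar) +
                    rnorm(ns, 0, sqrt(fit$sigma2)))
      out[, (m - 1L) * draws_per_model + j] <- pred
    }
  }
  lineage <- data.table(draw = seq_len(total),
                        model = rep(seq_len(n_models), each = draws_per_model),
                        input_draw = rep(seq_len(n_models), each = draws_per_model))
  cube <- draw_cube(out, design$strata[, !c("cell_id")], lineage)
  attr(cube, "cause") <- cause
  attr(cube, "fits") <- fits
  cube
}

#' Sum cause-specific cubes to an all-cause YLD cube
#'
#' Element-wise sum over aligned cubes (same strata, same draw count, same
#' lineage). All-cause rates are clipped to \[0, 1\] -- a YLD rate is
#' bounded by full-time disability -- and the number of clipped cells is
#' reported via `message()`.
#'
#' @param cause_cubes list of `draw_cube`s
#' @return an all-cause `draw_cube`
#' @export
sum_causes <- function(cause_cubes) {
  stopifnot(length(cause_cubes) >= 1L)
  ref <- cause_cubes[[1]]
  total <- ref$draws
  for (cb in cause_cubes[-1]) {
    assert_aligned(ref, cb)
    total <- total + cb$draws
  }
  n_clip <- sum(total > 1) + sum(total < 0)
  if (n_clip > 0) {
    message("sum_causes: clipped ", n_clip, " cell(s) to [0, 1]")
    total <- pmin(pmax(total, 0), 1)
  }
  draw_cube(total, ref$strata, ref$lineage)
}
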