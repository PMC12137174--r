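#' Population-weighted expectation over a stratum set
#'
#' The aggregation-consistent likelihood treats an outcome reported for a
#' merged stratum as the population-weighted average of its constituent
#' fine strata; this is that average.
#'
#' @param p rates per stratum
#' @param weights population weights, aligned with `p`
#' @return `sum(w * p) / sum(w)`
#' @export
aggregate_expectation <- function(p, weights) {
  if (length(p) != length(weights)) {
    stop("invalid argument: p and weights are not aligned")
  }
  if (any(!is.finite(weights)) || any(weights < 0) || sum(weights) <= 0) {
    stop("invalid argument: weights must be non-negative, finite, with positive sum")
  }
  sum(weights * p) / sum(weights)
}

# ---- internal machinery for the Laplace-approximate marginal likelihood ----

# sparse [X | Z_block1 | Z_block2 | ...] design over the latent vector
build_latent_design <- function(structure) {
  n <- nrow(structure$X)
  p <- ncol(structure$X)
  mats <- list(Matrix::Matrix(structure$X, sparse = TRUE))
  sizes <- c(beta = p)
  for (bn in names(structure$blocks)) {
    b <- structure$blocks[[bn]]
    nl <- length(b$levels)
    mats[[length(mats) + 1L]] <- Matrix::sparseMatrix(
      i = seq_len(n), j = b$map, x = 1, dims = c(n, nl))
    sizes[bn] <- nl
  }
  list(M = do.call(cbind, mats), sizes = sizes,
       offsets = setNames(cumsum(c(0, sizes))[seq_along(sizes)], names(sizes)))
}

# full latent prior precision: weak ridge on beta, tau_b * Q_b plus soft
# sum-to-zero penalties on intrinsic blocks
latent_precision <- function(structure, lat, theta, beta_prec = 1e-4,
                             constraint_prec = 1e4) {
  d <- sum(lat$sizes)
  P <- matrix(0, d, d)
  p <- lat$sizes[["beta"]]
  diag(P)[seq_len(p)] <- beta_prec
  for (j in seq_along(structure$blocks)) {
    bn <- names(structure$blocks)[j]
    b <- structure$blocks[[bn]]
    ix <- lat$offsets[[bn]] + seq_len(lat$sizes[[bn]])
    Pb <- exp(theta[[bn]]) * as.matrix(b$Q)
    for (cc in b$constraints) {
      v <- numeric(length(ix)); v[cc] <- 1
      Pb <- Pb + constraint_prec * tcrossprod(v)
    }
    P[ix, ix] <- P[ix, ix] + Pb
  }
  P
}

# sparse observation-weight matrix: obs x strata, entries w_ij / W_i
obs_weight_matrix <- function(obs, n_strata) {
  lens <- lengths(obs$stratum_set)
  if (any(lens == 0L)) stop("invalid argument: empty stratum set")
  j <- unlist(obs$stratum_set)
  w <- unlist(obs$weights)
  if (any(!is.finite(w)) || any(w <= 0)) {
    stop("invalid argument: observation weights must be positive and finite")
  }
  i <- rep(seq_len(nrow(obs)), lens)
  Wtot <- vapply(split(w, i), sum, 0)
  Matrix::sparseMatrix(i = i, j = j, x = w / Wtot[i],
                       dims = c(nrow(obs), n_strata))
}

# binomial log-likelihood of all observations at latent state x
sae_loglik <- function(x, Wmat, M, kk, nn) {
  eta <- as.vector(M %*% x)
  pbar <- as.vector(Wmat %*% plogis(eta))
  pbar <- pmin(pmax(pbar, 1e-12), 1 - 1e-12)
  sum(kk * log(pbar) + (nn - kk) * log1p(-pbar))
}

#' Fit a hierarchical small-area prevalence model
#'
#' Binomial likelihood on the population-weighted mean prevalence of each
#' observation's stratum set (so coarsely reported observations enter at
#' their native resolution), with fixed effects and structured random
#' effects on the logit scale. Inference is Laplace-approximate maximum
#' marginal likelihood: an inner Newton solve (Fisher-scoring curvature,
#' step-halving line search that never accepts an objective increase) finds
#' the joint mode of fixed plus random effects given the block
#' log-precisions, and an outer derivative-free optimisation maximises the
#' Laplace-approximate marginal likelihood over the log-precisions.
#'
#' @param obs a `hale_obs` observation table (stratum sets index rows of
#'   `structure$strata`)
#' @param structure a `hale_effects` from [build_effect_structure()]
#' @param config list: `theta_init` (named log-precisions per block, default
#'   0), `theta_fixed` (fit with precisions held at `theta_init`),
#'   `tol` (inner gradient sup-norm, default 1e-6), `max_inner` (default
#'   50), `max_outer` (outer iterations, default 200), `beta_prec` (ridge on
#'   fixed effects, default 1e-4), `constraint_prec` (soft sum-to-zero
#'   penalty, default 1e4)
#' @return an object of class `hale_fit`: latent mode, fixed-effect
#'   estimates and standard errors, log-precisions, curvature at the mode,
#'   convergence diagnostics, and the Laplace log marginal likelihood
#' @export
fit_indicator_model <- function(obs, structure, config = list()) {
  cfg <- modifyList(list(theta_init = NULL, theta_fixed = FALSE, tol = 1e-6,
                         max_inner = 50L, max_outer = 200L, beta_prec = 1e-4,
                         constraint_prec = 1e4), config)
  lat <- build_latent_design(structure)
  M <- lat$M
  n_strata <- nrow(structure$strata)
  Wmat <- obs_weight_matrix(obs, n_strata)
  kk <- as.numeric(obs$k); nn <- as.numeric(obs$n)
  if (any(kk < 0 | kk > nn)) stop("invalid argument: need 0 <= k <= n")
  beta_prec <- cfg$beta_prec
  if (all(kk == 0) || all(kk == nn)) {
    warning("separable data (all k = 0 or all k = n); using ridge fallback")
    beta_prec <- max(beta_prec, 1)
  }
  bnames <- names(structure$blocks)
  theta <- setNames(rep(0, length(bnames)), bnames)
  if (!is.null(cfg$theta_init)) theta[names(cfg$theta_init)] <- unlist(cfg$theta_init)
  d <- sum(lat$sizes)

  inner_env <- new.env()
  inner_env$x <- numeric(d)

  inner_solve <- function(theta) {
    P <- latent_precision(structure, lat, as.list(theta), beta_prec,
                          cfg$constraint_prec)
    x <- inner_env$x
    f <- function(x) -sae_loglik(x, Wmat, M, kk, nn) +
      0.5 * sum(x * (P %*% x))
    fx <- f(x)
    grad_inf <- Inf
    H <- NULL
    for (it in seq_len(cfg$max_inner)) {
      eta <- as.vector(M %*% x)
      pr <- plogis(eta)
      pbar <- pmin(pmax(as.vector(Wmat %*% pr), 1e-12), 1 - 1e-12)
      gobs <- kk / pbar - (nn - kk) / (1 - pbar)
      Vmat <- Wmat %*% Matrix::Diagonal(x = pr * (1 - pr))
      grad <- as.vector(Matrix::t(Vmat) %*% gobs)
      grad <- as.vector(Matrix::t(M) %*% grad) - as.vector(P %*% x)
      grad_inf <- max(abs(grad))
      if (grad_inf <= cfg$tol) break
      cfish <- nn / (pbar * (1 - pbar))
      Bm <- Vmat %*% M
      H <- as.matrix(Matrix::crossprod(Matrix::Diagonal(x = sqrt(cfish)) %*% Bm)) + P
      step <- tryCatch(solve(H, grad), error = function(e) grad / max(diag(H)))
      if (grad_inf < 1e-3) {
        # near the mode the objective decrease falls below floating-point
        # resolution of f; take the full Newton step unguarded
        x <- x + step
        fx <- f(x)
        next
      }
      alpha <- 1
      repeat {
        xn <- x + alpha * step
        fn <- f(xn)
        if (is.finite(fn) && fn <= fx) { x <- xn; fx <- fn; break }
        alpha <- alpha / 2
        if (alpha < 1e-10) break
      }
      if (alpha < 1e-10) {
        if (grad_inf < 0.1) {
          # improvement below floating-point resolution; polish unguarded
          x <- x + step
          fx <- f(x)
          next
        }
        break
      }
    }
    # curvature at (or nearest to) the mode
    eta <- as.vector(M %*% x)
    pr <- plogis(eta)
    pbar <- pmin(pmax(as.vector(Wmat %*% pr), 1e-12), 1 - 1e-12)
    cfish <- nn / (pbar * (1 - pbar))
    Vmat <- Wmat %*% Matrix::Diagonal(x = pr * (1 - pr))
    Bm <- Vmat %*% M
    H <- as.matrix(Matrix::crossprod(Matrix::Diagonal(x = sqrt(cfish)) %*% Bm)) + P
    inner_env$x <- x
    list(x = x, f = fx, H = H, P = P, grad_inf = grad_inf, iterations = it)
  }

  laplace_nll <- function(theta_vec) {
    sol <- inner_solve(setNames(theta_vec, bnames))
    cP <- tryCatch(chol(sol$P), error = function(e) NULL)
    cH <- tryCatch(chol(sol$H), error = function(e) NULL)
    if (is.null(cP) || is.null(cH)) return(1e10)
    # -log Laplace ML = f(xhat) - 0.5 log det P + 0.5 log det H  (+ const),
    # plus a weak N(0, sd 2.5) penalty on log-precisions that keeps variance
    # components with few effective replicates (e.g. race, with a handful of
    # levels) from diverging
    sol$f - sum(log(diag(cP))) + sum(log(diag(cH))) +
      0.5 * sum(theta_vec^2) / 2.5^2
  }

  outer_iterations <- 0L
  if (!cfg$theta_fixed && length(bnames)) {
    op <- optim(unname(theta[bnames]), laplace_nll, method = "Nelder-Mead",
                control = list(maxit = cfg$max_outer, reltol = 1e-7))
    theta <- setNames(op$par, bnames)
    outer_iterations <- op$counts[["function"]]
    logml <- -op$value
  } else {
    logml <- -laplace_nll(unname(theta[bnames]))
  }
  sol <- inner_solve(theta)
  p <- lat$sizes[["beta"]]
  beta_ix <- seq_len(p)
  Hinv_beta <- tryCatch(solve(sol$H)[beta_ix, beta_ix, drop = FALSE],
                        error = function(e) matrix(NA_real_, p, p))
  beta <- setNames(sol$x[beta_ix], colnames(structure$X))
  converged <- sol$grad_inf <= cfg$tol
  if (!converged) {
    warning(sprintf("inner Newton did not reach tolerance (grad sup-norm %.3g)",
                    sol$grad_inf))
  }
  out <- list(x_mode = sol$x, beta = beta,
              beta_se = sqrt(pmax(diag(Hinv_beta), 0)),
              theta = theta, H = sol$H, P = sol$P, lat = lat,
              structure = structure, converged = converged,
              grad_norm = sol$grad_inf, inner_iterations = sol$iterations,
              outer_iterations = outer_iterations, logml = logml,
              config = cfg)
  class(out) <- "hale_fit"
  out
}

#' @export
print.hale_fit <- function(x, ...) {
  cat(sprintf("<hale_fit> %d latent effects, log ML %.2f, %s (grad %.2g)\n",
              length(x$x_mode), x$logml,
              if (x$converged) "converged" else "NOT converged", x$grad_norm))
  print(round(rbind(estimate = x$beta, se = x$beta_se), 4))
  invisible(x)
}

#' Predicted prevalence at the mode
#'
#' @param object a `hale_fit`
#' @param ... unused
#' @return prevalence per stratum (natural scale) at the joint mode
#' @export
predict.hale_fit <- function(object, ...) {
  plogis(as.vector(object$lat$M %*% object$x_mode))
}

#' Draw from the approximate posterior of a fitted prevalence model
#'
#' Samples latent effects from the Gaussian approximation at the joint mode
#' (curvature as precision) and maps them through the design and inverse
#' logit to stratum prevalences.
#'
#' @param fitted a converged `hale_fit`
#' @param n_draws number of posterior draws
#' @param seed integer seed
#' @return a [draw_cube()] over the fitted strata, values in \[0,1\]
#' @export
draw_posterior <- function(fitted, n_draws = 1000L, seed = 1L) {
  if (!fitted$converged) stop("model did not converge; refusing to draw")
  R <- tryCatch(chol(fitted$H), error = function(e) NULL)
  if (is.null(R)) {
    # name the offending block for diagnosis
    for (bn in names(fitted$structure$blocks)) {
      ix <- fitted$lat$offsets[[bn]] + seq_len(fitted$lat$sizes[[bn]])
      ok <- tryCatch({ chol(fitted$H[ix, ix]); TRUE }, error = function(e) FALSE)
      if (!ok) stop("curvature not positive definite in block '", bn, "'")
    }
    stop("curvature not positive definite (cross-block)")
  }
  set.seed(as.integer(seed))
  d <- length(fitted$x_mode)
  z <- matrix(rnorm(d * n_draws), d, n_draws)
  xs <- fitted$x_mode + backsolve(R, z)
  eta <- as.matrix(fitted$lat$M %*% xs)
  draw_cube(plogis(eta), fitted$structure$strata,
            lineage = data.table(draw = seq_len(n_draws)))
}

#' Marginalise the education dimension out of a prevalence cube
#'
#' Indicator models may carry an education axis that downstream strata do
#' not; this collapses it by population-weighted averaging within each
#' (county, race, sex, age, year) cell, draw by draw.
#'
#' @param cube a `draw_cube` whose strata include an `education` column
#' @param populations data.table with the cube's stratum keys (including
#'   `education`) and `population`
#' @return a `draw_cube` without the education axis
#' @export
marginalize_education <- function(cube, populations) {
  if (!"education" %in% names(cube$strata)) {
    stop("invalid argument: cube has no education axis")
  }
  keys <- setdiff(names(cube$strata),
                  c("education", "stratum_id", "age_end"))
  st <- copy(cube$strata)
  key_cols <- intersect(names(st), setdiff(names(populations), "population"))
  idx <- match(do.call(paste, st[, key_cols, with = FALSE]),
               do.call(paste, populations[, key_cols, with = FALSE]))
  if (anyNA(idx)) stop("missing population for some strata")
  w <- populations$population[idx]
  st[, cell_id := .GRP, by = keys]
  G <- Matrix::sparseMatrix(i = st$cell_id, j = seq_len(nrow(st)), x = w)
  G <- G / Matrix::rowSums(G)
  out_strata <- unique(st[, c(keys, "cell_id"), with = FALSE])
  setorder(out_strata, cell_id)
  out_strata[, cell_id := NULL]
  draw_cube(as.matrix(G %*% cube$draws), out_strata, cube$lineage)
}
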