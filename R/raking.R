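#' Multiplicative raking factor for one benchmark cell
#'
#' @param estimates rates for the strata in the cell
#' @param weights population weights
#' @param benchmark the target rate for the cell
#' @return `benchmark / weighted.mean(estimates, weights)`
#' @export
raking_factor <- function(estimates, weights, benchmark) {
  wm <- aggregate_expectation(estimates, weights)
  if (wm <= 0) {
    if (benchmark != 0) stop("cannot rake: zero weighted mean with nonzero benchmark")
    return(1)
  }
  benchmark / wm
}

#' Rake a draw cube to state benchmarks
#'
#' Scales the values in every (state, sex, age, year, draw) cell by a
#' multiplicative factor so the population-weighted mean over the state's
#' county-race strata equals the benchmark for that cell and draw. Values
#' pushed above 1 are clipped to 1 and the remaining strata re-raked until
#' no new clipping occurs (at most `max_passes` passes), so the benchmark
#' constraint holds exactly while rates stay in \[0, 1\]. The achieved
#' means are asserted against the benchmarks to `tol` relative error.
#'
#' @param cube a `draw_cube` over county-race strata; strata must carry a
#'   `state` column (or supply `geography`)
#' @param populations stratum population table (matched on `stratum_id` if
#'   present, otherwise on the shared key columns)
#' @param benchmarks long table `state`, `sex`, `age_start`, `year`,
#'   `draw`, `value` covering every cell and draw of the cube
#' @param geography optional `hale_geography` to derive states
#' @param tol post-condition tolerance (relative), default 1e-10
#' @param max_passes clip-and-rerake pass limit
#' @return the raked `draw_cube`, with a `raking_report` attribute giving
#'   max |factor - 1| by state and year
#' @export
apply_raking <- function(cube, populations, benchmarks, geography = NULL,
                         tol = 1e-10, max_passes = 50L) {
  st <- copy(cube$strata)
  if (!"state" %in% names(st)) {
    if (is.null(geography)) stop("strata carry no state; supply geography")
    st[, state := geography$state_of[county]]
  }
  w <- stratum_weights(st, populations)
  st[, cell_id := .GRP, by = .(state, sex, age_start, year)]
  cells <- unique(st[, .(cell_id, state, sex, age_start, year)])
  setorder(cells, cell_id)
  G <- Matrix::sparseMatrix(i = st$cell_id, j = seq_len(nrow(st)), x = 1,
                            dims = c(nrow(cells), nrow(st)))
  W <- as.vector(G %*% w)
  if (any(W <= 0)) stop("cannot rake: zero total population in a cell")
  D <- ncol(cube$draws)
  bm <- merge(cells, benchmarks, by = c("state", "sex", "age_start", "year"),
              allow.cartesian = TRUE)
  if (nrow(bm) != nrow(cells) * D || max(bm$draw) != D) {
    stop("invalid argument: benchmarks must cover every cell and draw")
  }
  setorder(bm, draw, cell_id)
  B <- matrix(bm$value, nrow(cells), D)

  cw <- w  # stratum weights
  V <- matrix(NA_real_, nrow(cube$draws), D)
  dev_cell <- rep(0, nrow(cells))
  n_clipped <- 0L
  # draws are processed in blocks to bound peak memory
  chunks <- split(seq_len(D), ceiling(seq_len(D) / 200))
  for (idx in chunks) {
    X0 <- cube$draws[, idx, drop = FALSE]
    Bc <- B[, idx, drop = FALSE]
    cl <- matrix(FALSE, nrow(X0), length(idx))
    Vc <- NULL
    for (pass in seq_len(max_passes)) {
      un <- !cl
      sw_clip <- as.matrix(G %*% (cw * cl))
      sxw_un <- as.matrix(G %*% (cw * X0 * un))
      Fmat <- (Bc * W - sw_clip) / sxw_un
      has_un <- as.matrix(G %*% un) > 0
      bad <- which(has_un & (!is.finite(Fmat) | Fmat <= 0) & Bc > 0)
      if (length(bad)) {
        rc <- arrayInd(bad[1], dim(Fmat))
        stop("cannot rake cell ", cells$state[rc[1]], "/",
             cells$sex[rc[1]], "/", cells$age_start[rc[1]], "/",
             cells$year[rc[1]], " draw ", idx[rc[2]],
             ": zero or infeasible weighted mean")
      }
      if (pass == 1L) {
        dev_cell <- pmax(dev_cell, apply(abs(Fmat - 1), 1, max))
      }
      Vc <- X0 * Fmat[st$cell_id, , drop = FALSE]
      Vc[cl] <- 1
      newclip <- (Vc > 1) & un
      if (!any(newclip)) break
      if (pass == max_passes) {
        rc <- arrayInd(which(newclip)[1], dim(Vc))
        stop("raking did not converge after ", max_passes,
             " clip passes (stratum row ", rc[1], ", draw ", idx[rc[2]], ")")
      }
      cl <- cl | newclip
    }
    achieved <- as.matrix(G %*% (cw * Vc)) / W
    rel_err <- abs(achieved - Bc) / pmax(Bc, .Machine$double.xmin)
    if (max(rel_err[Bc > 0]) > tol) {
      stop("raking post-condition violated: max relative error ",
           format(max(rel_err[Bc > 0])))
    }
    n_clipped <- n_clipped + sum(cl)
    V[, idx] <- Vc
  }
  report <- data.table(cells[, .(state, year)], dev = dev_cell)[
    , .(max_abs_factor_dev = max(dev)), by = .(state, year)]
  message("raking: max |factor - 1| = ",
          format(max(report$max_abs_factor_dev), digits = 4),
          if (n_clipped > 0L) paste0("; ", n_clipped, " cell(s) clipped at 1") else "")
  out <- draw_cube(V, cube$strata, cube$lineage)
  attr(out, "raking_report") <- report
  out
}

#' Population weights aligned with a stratum table
#'
#' @param strata stratum table (rows define the order)
#' @param populations population table; matched by `stratum_id` when both
#'   carry it, else by the shared key columns
#' @return numeric weight vector
#' @export
stratum_weights <- function(strata, populations) {
  if ("stratum_id" %in% names(strata) && "stratum_id" %in% names(populations)) {
    w <- populations$population[match(strata$stratum_id, populations$stratum_id)]
  } else {
    keys <- intersect(setdiff(names(strata), c("age_end", "stratum_id")),
                      names(populations))
    m <- merge(strata[, c(keys), with = FALSE][, .I, by = keys],
               populations, by = keys, sort = FALSE)
    w <- m$population[order(m$I)]
  }
  if (anyNA(w)) stop("missing population for some strata")
  w
}
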