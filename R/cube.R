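#' Stratum-by-draw cubes
#'
#' A `draw_cube` is the universal currency of uncertainty propagation: a
#' numeric matrix of rates (or years) with one row per stratum and one
#' column per posterior draw, together with the stratum key table and
#' optional draw lineage metadata (which fitted model and which input draw
#' each column descends from). Draw alignment is by column index throughout
#' the pipeline, preserving cross-quantity correlation.
#'
#' @param draws numeric matrix, strata x draws
#' @param strata data.table keying the rows (same order)
#' @param lineage optional data.table with one row per draw (columns such as
#'   `draw`, `model`, `input_draw`)
#' @return an object of class `draw_cube`
#' @export
draw_cube <- function(draws, strata, lineage = NULL) {
  draws <- as.matrix(draws)
  stopifnot(nrow(draws) == nrow(strata))
  if (!is.null(lineage)) stopifnot(nrow(lineage) == ncol(draws))
  structure(list(draws = draws, strata = as.data.table(strata),
                 lineage = lineage),
            class = "draw_cube")
}

#' @export
print.draw_cube <- function(x, ...) {
  cat(sprintf("<draw_cube> %d strata x %d draws", nrow(x$draws), ncol(x$draws)))
  if (!is.null(x$lineage)) cat(" (with lineage)")
  cat("\n")
  invisible(x)
}

#' @export
dim.draw_cube <- function(x) dim(x$draws)

#' Number of draws in a cube
#' @param cube a `draw_cube`
#' @export
n_draws <- function(cube) ncol(cube$draws)

#' Check that two cubes share strata and draw alignment
#'
#' Strata keys must match row-for-row; if both cubes carry lineage, the
#' lineage tables must be identical (same model/input-draw ancestry per
#' column).
#'
#' @param a,b `draw_cube` objects
#' @return TRUE invisibly, or an error
#' @export
assert_aligned <- function(a, b) {
  if (ncol(a$draws) != ncol(b$draws)) {
    stop("invalid argument: mismatched draw counts (", ncol(a$draws), " vs ",
         ncol(b$draws), ")")
  }
  if (nrow(a$draws) != nrow(b$draws) || !identical(
        unname(as.list(a$strata[, names(b$strata), with = FALSE])),
        unname(as.list(b$strata)))) {
    stop("invalid argument: cubes are not keyed by the same strata")
  }
  if (!is.null(a$lineage) && !is.null(b$lineage) &&
      !isTRUE(all.equal(a$lineage, b$lineage, check.attributes = FALSE))) {
    stop("invalid argument: draw lineage differs between cubes")
  }
  invisible(TRUE)
}

#' Write / read a draw cube
#'
#' Long-format CSV (stratum key columns + `draw` + `value`) for small cubes;
#' RDS for large pipeline artifacts. `write_cube` picks by file extension.
#'
#' @param cube a `draw_cube`
#' @param path destination (`.csv` or `.rds`)
#' @export
write_cube <- function(cube, path) {
  if (grepl("\\.rds$", path)) {
    saveRDS(cube, path)
  } else {
    long <- cbind(cube$strata[rep(seq_len(nrow(cube$strata)), ncol(cube$draws))],
                  draw = rep(seq_len(ncol(cube$draws)), each = nrow(cube$draws)),
                  value = as.vector(cube$draws))
    fwrite(long, path)
  }
  invisible(path)
}

#' @rdname write_cube
#' @export
read_cube <- function(path) {
  if (grepl("\\.rds$", path)) return(readRDS(path))
  long <- fread(path)
  keys <- setdiff(names(long), c("draw", "value"))
  d <- max(long$draw)
  strat <- unique(long[, ..keys])
  m <- matrix(long$value, nrow = nrow(strat), ncol = d)
  draw_cube(m, strat)
}
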