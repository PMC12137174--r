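#' Synthetic merged-county geography
#'
#' Builds a lattice-style county adjacency graph partitioned into states.
#' Counties are laid out on a near-square grid with rook adjacency; an
#' optional rewiring step replaces a fraction of edges with random ones
#' (kept symmetric and irreflexive) so that spatial structure can be
#' degraded in experiments. States are contiguous column bands of the grid,
#' so every state is non-empty and spatially coherent.
#'
#' @param n_counties number of county units (>= 1)
#' @param n_states number of states partitioning the counties (>= 1,
#'   <= `n_counties`)
#' @param seed integer seed controlling rewiring (the lattice itself is
#'   deterministic)
#' @param rewire fraction of lattice edges to replace with random edges
#' @return an object of class `hale_geography`: list with `counties`
#'   (character ids), `adjacency` (sparse symmetric 0/1 Matrix with empty
#'   diagonal), `state_of` (named character vector county -> state), and
#'   `component` (named integer vector of connected-component membership)
#' @export
make_geography <- function(n_counties, n_states, seed = 1L, rewire = 0) {
  if (n_states < 1L || n_counties < 1L || n_states > n_counties) {
    stop("invalid argument: need n_counties >= n_states >= 1")
  }
  counties <- sprintf("C%03d", seq_len(n_counties))
  nr <- floor(sqrt(n_counties))
  nc <- ceiling(n_counties / nr)
  # grid coordinates, row-major; last row may be partial
  idx <- seq_len(n_counties)
  row <- (idx - 1L) %/% nc + 1L
  col <- (idx - 1L) %% nc + 1L
  from <- integer(0); to <- integer(0)
  pos <- matrix(0L, nr, nc)
  pos[cbind(row, col)] <- idx
  for (i in idx) {
    r <- row[i]; cl <- col[i]
    if (cl < nc && pos[r, cl + 1L] > 0L) { from <- c(from, i); to <- c(to, pos[r, cl + 1L]) }
    if (r < nr && pos[r + 1L, cl] > 0L)  { from <- c(from, i); to <- c(to, pos[r + 1L, cl]) }
  }
  if (rewire > 0 && length(from) > 0L && n_counties > 2L) {
    set.seed(as.integer(seed))
    n_rw <- floor(rewire * length(from))
    if (n_rw > 0L) {
      pick <- sample.int(length(from), n_rw)
      for (e in pick) {
        a <- from[e]
        b <- sample(setdiff(idx, a), 1L)
        from[e] <- min(a, b); to[e] <- max(a, b)
      }
      keep <- !duplicated(cbind(from, to)) & from != to
      from <- from[keep]; to <- to[keep]
    }
  }
  if (length(from) > 0L) {
    adj <- Matrix::sparseMatrix(i = c(from, to), j = c(to, from), x = 1,
                                dims = c(n_counties, n_counties))
    adj@x[] <- 1  # collapse any duplicated entries
  } else {
    adj <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                                dims = c(n_counties, n_counties))
  }
  dimnames(adj) <- list(counties, counties)
  # states are contiguous near-equal chunks in column-major grid order, so
  # each is non-empty and spatially coherent
  ord <- order(col, row)
  band <- integer(n_counties)
  band[ord] <- ((seq_len(n_counties) - 1L) * n_states) %/% n_counties + 1L
  state_of <- setNames(sprintf("S%02d", band), counties)
  g <- igraph::graph_from_adjacency_matrix(adj > 0, mode = "undirected")
  comp <- igraph::components(g)$membership
  structure(list(counties = counties, adjacency = adj,
                 state_of = state_of,
                 component = setNames(as.integer(comp), counties)),
            class = "hale_geography")
}

#' @export
print.hale_geography <- function(x, ...) {
  cat(sprintf("<hale_geography> %d counties, %d states, %d edges, %d component(s)\n",
              length(x$counties), length(unique(x$state_of)),
              sum(x$adjacency > 0) / 2, max(x$component)))
  invisible(x)
}

#' Write / read a geography as delimited text
#'
#' `geography.csv` has one row per county with columns `county`, `state`,
#' `neighbors` (semicolon-joined county ids). The adjacency round-trips
#' exactly.
#'
#' @param geography a `hale_geography`
#' @param path file path
#' @return `read_geography` returns a `hale_geography`
#' @export
write_geography <- function(geography, path) {
  adj <- geography$adjacency
  nb <- vapply(seq_along(geography$counties), function(i) {
    paste(geography$counties[adj[i, ] > 0], collapse = ";")
  }, "")
  dt <- data.table(county = geography$counties,
                   state = unname(geography$state_of[geography$counties]),
                   neighbors = nb)
  fwrite(dt, path)
  invisible(path)
}

#' @rdname write_geography
#' @export
read_geography <- function(path) {
  dt <- fread(path, colClasses = list(character = c("county", "state", "neighbors")))
  counties <- dt$county
  n <- length(counties)
  pos <- setNames(seq_len(n), counties)
  ii <- integer(0); jj <- integer(0)
  for (i in seq_len(n)) {
    if (nzchar(dt$neighbors[i])) {
      js <- pos[strsplit(dt$neighbors[i], ";", fixed = TRUE)[[1]]]
      ii <- c(ii, rep.int(i, length(js))); jj <- c(jj, js)
    }
  }
  adj <- Matrix::sparseMatrix(i = ii, j = jj, x = rep(1, length(ii)), dims = c(n, n),
                              dimnames = list(counties, counties))
  g <- igraph::graph_from_adjacency_matrix(adj > 0, mode = "undirected")
  comp <- igraph::components(g)$membership
  structure(list(counties = counties, adjacency = adj,
                 state_of = setNames(dt$state, counties),
                 component = setNames(as.integer(comp), counties)),
            class = "hale_geography")
}
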