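# Independent spreadsheet-style demography oracles: explicit loops over age
# groups, no shared code with the package internals.

oracle_lifetable <- function(mx, starts, ax = NULL, a0 = 0.2) {
  k <- length(mx)
  n <- c(diff(starts), Inf)
  if (is.null(ax)) {
    ax <- ifelse(is.finite(n), n / 2, NA)
    if (k > 1 && n[1] == 1) ax[1] <- a0
  }
  q <- l <- d <- L <- numeric(k)
  l[1] <- 1e5
  for (i in 1:k) {
    q[i] <- if (is.finite(n[i])) n[i] * mx[i] / (1 + (n[i] - ax[i]) * mx[i]) else 1
    d[i] <- l[i] * q[i]
    if (i < k) l[i + 1] <- l[i] - d[i]
    L[i] <- if (is.finite(n[i])) n[i] * (l[i] - d[i]) + ax[i] * d[i] else l[i] / mx[i]
  }
  Tx <- numeric(k)
  for (i in k:1) Tx[i] <- L[i] + if (i < k) Tx[i + 1] else 0
  list(q = q, l = l, L = L, T = Tx, e = Tx / l)
}

oracle_sullivan <- function(o, d) {
  k <- length(d)
  H <- numeric(k)
  acc <- 0
  for (i in k:1) {
    acc <- acc + o$L[i] * (1 - d[i])
    H[i] <- acc / o$l[i]
  }
  H
}

# a small shared synthetic world, built once per test run
small_world <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(n_counties = 12, n_states = 2, years = 2011:2013,
                        age_starts = c(0, 1, seq(5, 75, 10)),
                        indicators = c("indicator_1", "indicator_2"),
                        causes = c("cause_01", "cause_02"),
                        n_models = 4, draws_per_model = 5, seed = 11)
      geog <- make_geography(cfg$n_counties, cfg$n_states, seed = 3)
      truth <- simulate_truth(geog, cfg)
      cache <<- list(cfg = cfg, geog = geog, truth = truth)
    }
    cache
  }
})
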