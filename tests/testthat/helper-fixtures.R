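# Shared fixtures and independent oracles.  Worlds are cached per test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# A small multi-market world: big enough for the FE estimator, small enough
# to generate in well under a second.
small_world <- function() cached("small_world", {
  generate_world(world_config(
    n_markets = 4L, hydro_plants_per_market = 2L,
    combustion_plants_per_market = 2L, noncombustion_plants_per_market = 1L,
    months = month_seq("2000-01", "2005-12"),
    reference_years = c(2000L, 2005L),
    fine_step_deg = 0.06, drought_episode_rate = 0.10, seed = 11L))
})

small_panel <- function() cached("small_panel", world_panel(small_world()))

tiny_fixture <- function() cached("tiny_fixture", generate_tiny_fixture())

# Brute-force CR1 clustered sandwich, written independently of the package
# implementation (explicit per-cluster loop).
oracle_cr1 <- function(X, e, cluster, K = ncol(X)) {
  X <- as.matrix(X)
  XtXi <- solve(t(X) %*% X)
  meat <- matrix(0, ncol(X), ncol(X))
  for (g in unique(cluster)) {
    idx <- which(cluster == g)
    sg <- t(X[idx, , drop = FALSE]) %*% e[idx]
    meat <- meat + sg %*% t(sg)
  }
  G <- length(unique(cluster)); N <- nrow(X)
  (G / (G - 1)) * ((N - 1) / (N - K)) * XtXi %*% meat %*% XtXi
}

# Reachability oracle for watershed delineation: transitive closure by
# repeated boolean matrix products.
oracle_upstream <- function(basins, outlet) {
  ids <- basins$basin_id
  n <- length(ids)
  A <- matrix(FALSE, n, n, dimnames = list(ids, ids))
  ok <- !is.na(basins$downstream_id)
  A[cbind(basins$basin_id[ok], basins$downstream_id[ok])] <- TRUE
  reach <- A | diag(TRUE, n)
  repeat {
    nxt <- (reach %*% reach) > 0
    if (identical(nxt, reach)) break
    reach <- nxt
  }
  sort(ids[reach[, outlet]])
}

# A random basin forest with n basins (for property tests).
random_forest <- function(n, seed) {
  set.seed(seed)
  ids <- sprintf("b%03d", seq_len(n))
  # each basin points to a strictly later basin or nowhere: guaranteed acyclic
  down <- vapply(seq_len(n), function(i) {
    if (i == n || stats::runif(1) < 0.2) NA_character_
    else ids[i + sample.int(n - i, 1L)]
  }, character(1))
  tibble::tibble(basin_id = ids, downstream_id = down)
}

# Uniform single-cell-per-basin membership + uniform runoff grid helper.
grid_of <- function(cells, months, value, name = "g") {
  vals <- matrix(value, nrow(cells), length(months))
  field_grid(cells, months, vals, name = name)
}

simple_cells <- function(lons, lats, ids = sprintf("c%02d", seq_along(lons))) {
  tibble::tibble(cell_id = ids, lon = lons, lat = lats)
}
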