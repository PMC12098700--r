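test_that("watershed delineation traces exactly the upstream basins", {
  # isolated basin
  g1 <- basin_graph(tibble::tibble(basin_id = "A", downstream_id = NA),
                    tibble::tibble(basin_id = "A", cell_id = "c1"))
  expect_equal(delineate_watershed(g1, "A"), "A")
  # chain A -> B -> C
  ch <- basin_graph(
    tibble::tibble(basin_id = c("A", "B", "C"),
                   downstream_id = c("B", "C", NA)),
    tibble::tibble(basin_id = c("A", "B", "C"), cell_id = c("c1", "c2", "c3")))
  expect_setequal(delineate_watershed(ch, "C"), c("A", "B", "C"))
  expect_setequal(delineate_watershed(ch, "B"), c("A", "B"))
  # tree {A->C, B->C, C->D}: D excluded from watershed of C
  tr <- basin_graph(
    tibble::tibble(basin_id = c("A", "B", "C", "D"),
                   downstream_id = c("C", "C", "D", NA)),
    tibble::tibble(basin_id = c("A", "B", "C", "D"),
                   cell_id = paste0("c", 1:4)))
  expect_setequal(delineate_watershed(tr, "C"), c("A", "B", "C"))
  expect_error(delineate_watershed(tr, "Z"), "unknown outlet")
  # cyclic graph rejected at construction
  expect_error(basin_graph(
    tibble::tibble(basin_id = c("A", "B"), downstream_id = c("B", "A")),
    tibble::tibble(basin_id = c("A", "B"), cell_id = c("c1", "c2"))),
    "cycle")
})

test_that("watershed tracing matches a transitive-closure oracle on random forests", {
  for (s in 1:3) {
    n <- c(40L, 120L, 200L)[s]
    basins <- random_forest(n, seed = 100 + s)
    g <- basin_graph(basins, tibble::tibble(basin_id = basins$basin_id,
                                            cell_id = paste0("c", seq_len(n))))
    for (outlet in sample(basins$basin_id, 8L)) {
      expect_identical(delineate_watershed(g, outlet),
                       oracle_upstream(basins, outlet))
    }
  }
})

test_that("watershed runoff is the unweighted mean over member cells", {
  months <- month_seq("2000-01", "2000-03")
  cells <- simple_cells(c(0, 0.25), c(0, 0))
  g <- basin_graph(tibble::tibble(basin_id = c("A", "B"),
                                  downstream_id = c("B", NA)),
                   tibble::tibble(basin_id = c("A", "B"),
                                  cell_id = cells$cell_id))
  uni <- grid_of(cells, months, 0.7)
  expect_equal(unname(watershed_runoff(uni, g, c("A", "B"))), rep(0.7, 3))
  two <- field_grid(cells, months, rbind(rep(1, 3), rep(3, 3)))
  expect_equal(unname(watershed_runoff(two, g, c("A", "B"))), rep(2, 3))
  # adding a basin whose cells equal the current mean leaves the mean unchanged
  cells3 <- simple_cells(c(0, 0.25, 0.5), c(0, 0, 0))
  g3 <- basin_graph(tibble::tibble(basin_id = c("A", "B", "C"),
                                   downstream_id = c("B", NA, NA)),
                    tibble::tibble(basin_id = c("A", "B", "C"),
                                   cell_id = cells3$cell_id))
  v <- field_grid(cells3, months, rbind(rep(1, 3), rep(3, 3), rep(2, 3)))
  expect_equal(watershed_runoff(v, g3, c("A", "B", "C")),
               watershed_runoff(v, g3, c("A", "B")))
  expect_error(watershed_runoff(uni, g, character(0)), "empty")
})

test_that("anomalies subtract the calendar-month reference climatology", {
  months <- month_seq("2000-01", "2019-12")
  # constant series -> all zero
  const <- stats::setNames(rep(2, length(months)), months)
  expect_true(all(compute_anomalies(const, c(2000, 2019))$anomaly == 0))
  # pure seasonal cycle repeated every year -> all zero
  seas <- stats::setNames(rep(sin(2 * pi * (1:12) / 12) + 2, 20), months)
  expect_true(all(abs(compute_anomalies(seas, c(2000, 2019))$anomaly) < 1e-12))
  # +0.2 bump in one reference month of one year, 20 reference years
  bump <- seas
  bump["2007-05"] <- bump["2007-05"] + 0.2
  ws <- compute_anomalies(bump, c(2000, 2019))
  expect_equal(unname(ws$anomaly["2007-05"]), 0.2 * 19 / 20)
  expect_equal(unname(ws$anomaly["2013-05"]), -0.2 / 20)
  # reference years must be present
  expect_error(compute_anomalies(const, c(1990, 1999)), "reference")
})

test_that("anomaly climatology is zero-mean over the reference period", {
  w <- small_world()
  hydro <- w$plants[w$plants$type == "hydro", ]
  ref <- w$config$reference_years
  for (i in seq_len(nrow(hydro))) {
    shed <- delineate_watershed(w$basins, hydro$outlet_basin[i])
    ws <- compute_anomalies(watershed_runoff(w$runoff, w$basins, shed), ref)
    yrs <- month_year(ws$months)
    in_ref <- yrs >= ref[1] & yrs <= ref[2]
    cm_means <- tapply(ws$anomaly[in_ref], month_cal(ws$months)[in_ref], mean)
    scale <- max(abs(ws$runoff), 1)
    expect_lt(max(abs(cm_means)) / scale, 1e-9)
  }
})

test_that("rolling anomaly is a trailing window with missing ramp-up", {
  a <- stats::setNames(c(0, 0, 3), month_seq("2000-01", "2000-03"))
  expect_equal(rolling_anomaly(a, 1), a)
  r <- rolling_anomaly(a, 3)
  expect_true(all(is.na(r[1:2])))
  expect_equal(unname(r[3]), 1)
  const <- stats::setNames(rep(0.4, 12), month_seq("2000-01", "2000-12"))
  expect_equal(unname(rolling_anomaly(const, 3)[3:12]), rep(0.4, 10))
  expect_warning(rolling_anomaly(const, 4), "non-standard")
  expect_error(rolling_anomaly(const, 0), "positive")
})

test_that("drought indicator uses strict negativity and one-sd severity", {
  r <- c(a = 0.5, b = -0.1, c = 0, d = -0.5, e = NA)
  neg <- drought_indicator(r, "negative")
  expect_equal(unname(neg[1:4]), c(0L, 1L, 0L, 1L))
  expect_true(is.na(neg[5]))
  sev <- drought_indicator(r, "severe", sd = 1)
  expect_equal(unname(sev[1:4]), c(0L, 0L, 0L, 0L))  # -0.5 sd is not severe
  expect_equal(unname(drought_indicator(c(x = -1.5), "severe", sd = 1)), 1L)
  expect_error(drought_indicator(r, "severe", sd = 0), "positive")
  # severe indicator never exceeds the negative indicator
  set.seed(5)
  z <- stats::rnorm(500)
  expect_true(all(drought_indicator(z, "severe", sd = 0.8) <=
                    drought_indicator(z, "negative")))
})

test_that("market aggregation weights indicators by capacity", {
  months <- c("2000-01", "2000-02")
  ind <- matrix(c(1, 1, 0, 1), 2, 2,
                dimnames = list(c("p1", "p2"), months))
  plants <- tibble::tibble(plant_id = c("p1", "p2"), market = "M1",
                           capacity_mw = c(100, 300))
  # month 1: both in drought -> 1; month 2: only the 300 MW plant
  cap <- aggregate_market(ind, plants, "capacity")
  expect_equal(cap$value, c(1, 0.75))
  ari <- aggregate_market(ind, plants, "arithmetic")
  expect_equal(ari$value, c(1, 0.5))
  expect_error(aggregate_market(ind, dplyr::mutate(plants, capacity_mw = -1)),
               "positive")
  # market merge mapping
  plants2 <- tibble::tibble(plant_id = c("p1", "p2"), market = c("M1", "M2"),
                            capacity_mw = c(100, 300))
  merged <- aggregate_market(ind, plants2, "capacity",
                             market_map = c(M1 = "R1", M2 = "R1"))
  expect_equal(unique(merged$market), "R1")
  expect_equal(merged$value, c(1, 0.75))
})

test_that("FHD lies in [0,1] and is monotone in the drought set", {
  w <- small_world()
  fhd <- w$market_exposure$fhd
  expect_true(all(fhd >= 0 & fhd <= 1, na.rm = TRUE))
  expect_true(all(w$market_exposure$fhd_severe <= w$market_exposure$fhd,
                  na.rm = TRUE))
  # flipping one plant into drought can only raise the FHD
  months <- "2000-01"
  set.seed(9)
  for (rep in 1:20) {
    np <- sample(2:6, 1)
    ind <- matrix(sample(0:1, np, replace = TRUE), np, 1,
                  dimnames = list(paste0("p", 1:np), months))
    plants <- tibble::tibble(plant_id = paste0("p", 1:np), market = "M1",
                             capacity_mw = stats::runif(np, 10, 500))
    f0 <- aggregate_market(ind, plants, "capacity")$value
    off <- which(ind[, 1] == 0)
    if (!length(off)) next
    ind2 <- ind; ind2[sample(off, 1), 1] <- 1
    f1 <- aggregate_market(ind2, plants, "capacity")$value
    expect_gte(f1, f0)
  }
})

test_that("markets without hydropower are missing, not zero", {
  w <- small_world()
  hydro <- w$plants[w$plants$type == "hydro", ]
  exp_tbl <- compute_market_exposure(w$runoff, w$basins, hydro,
                                     w$config$reference_years,
                                     markets = c(w$markets, "M99"))
  m99 <- exp_tbl[exp_tbl$market == "M99", ]
  expect_true(all(is.na(m99$fhd)))
  expect_true(all(is.na(m99$mean_anomaly)))
})

test_that("market mean anomaly preserves sign and capacity weights", {
  months <- "2000-01"
  an <- matrix(c(1, -1), 2, 1, dimnames = list(c("p1", "p2"), months))
  plants <- tibble::tibble(plant_id = c("p1", "p2"), market = "M1",
                           capacity_mw = c(50, 50))
  expect_equal(market_mean_anomaly(an, plants, "capacity")$value, 0)
  one <- market_mean_anomaly(an[1, , drop = FALSE], plants[1, ], "capacity")
  expect_equal(one$value, 1)
  an2 <- matrix(c(0, -2), 2, 1, dimnames = list(c("p1", "p2"), months))
  plants2 <- tibble::tibble(plant_id = c("p1", "p2"), market = "M1",
                            capacity_mw = c(1, 3))
  expect_equal(market_mean_anomaly(an2, plants2, "capacity")$value, -1.5)
})
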