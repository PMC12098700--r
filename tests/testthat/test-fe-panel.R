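test_that("within-transformed estimator matches the dummy-variable oracle", {
  p <- small_panel()
  fit_dm <- fit_fe_ols(p, dummy_threshold = 0L)       # force demeaning route
  fit_dv <- fit_fe_ols(p, dummy_threshold = 1e7)      # force exact dummy solve
  expect_equal(fit_dm$route, "demean")
  expect_equal(fit_dv$route, "dummy")
  expect_equal(fit_dm$coefficients, fit_dv$coefficients, tolerance = 1e-8)
  # independent oracle: plain lm() on the full dummy design
  d <- p[p$analysis_sample, ]
  d <- d[stats::complete.cases(d[, c("pm25", "fhd", "local_drought")]), ]
  ol <- stats::lm(pm25 ~ fhd + temp_c + precip_mm_h + rh_pct + pressure_pa +
                    wind10_ms + wind100_ms + local_drought + hdd + cdd +
                    factor(plant_id) + factor(month) + factor(market_cm),
                  data = d)
  expect_equal(unname(fit_dv$coefficients["fhd"]),
               unname(stats::coef(ol)["fhd"]), tolerance = 1e-8)
})

test_that("CR1 covariance matches the brute-force sandwich", {
  set.seed(42)
  n <- 380; G <- 19
  cl <- sample(sprintf("g%02d", 1:G), n, replace = TRUE)
  X <- cbind(1, stats::rnorm(n), stats::rnorm(n))
  colnames(X) <- c("(Intercept)", "x1", "x2")
  y <- X %*% c(1, 0.5, -0.2) + stats::rnorm(n)[match(cl, unique(cl))] +
    stats::rnorm(n)
  b <- solve(crossprod(X), crossprod(X, y))
  e <- as.vector(y - X %*% b)
  expect_equal(cluster_vcov(X, e, cl), oracle_cr1(X, e, cl),
               tolerance = 1e-10)
  expect_error(cluster_vcov(X, e, rep("g1", n)), "one cluster")
})

test_that("point estimates are invariant to duplicating observations", {
  p <- small_panel()
  fit1 <- fit_fe_ols(p)
  p2 <- dplyr::bind_rows(p, p)
  fit2 <- fit_fe_ols(p2)
  expect_equal(fit1$coefficients["fhd"], fit2$coefficients["fhd"],
               tolerance = 1e-6)
})

test_that("CR1 agrees with classical OLS errors under homoskedastic independence", {
  # many clusters, iid errors: clustering should not change the SE much
  ratios <- sapply(1:5, function(s) {
    set.seed(300 + s)
    n <- 2000; G <- 50
    cl <- rep(sprintf("g%02d", 1:G), each = n / G)
    x <- stats::rnorm(n)
    y <- 0.5 * x + stats::rnorm(n)
    X <- cbind(1, x)
    b <- solve(crossprod(X), crossprod(X, y))
    e <- as.vector(y - X %*% b)
    se_cl <- sqrt(cluster_vcov(X, e, cl)[2, 2])
    se_ols <- sqrt((sum(e^2) / (n - 2)) * solve(crossprod(X))[2, 2])
    se_cl / se_ols
  })
  expect_lt(abs(mean(ratios) - 1), 0.2)
})

test_that("a noise-free null world yields a numerically zero coefficient", {
  w0 <- generate_world(world_config(
    n_markets = 3L, hydro_plants_per_market = 2L,
    combustion_plants_per_market = 2L, noncombustion_plants_per_market = 0L,
    months = month_seq("2000-01", "2004-12"), reference_years = c(2000L, 2004L),
    fine_step_deg = 0.1, true_beta = 0, noise_sd = 0, seed = 8L))
  p0 <- world_panel(w0)
  fit0 <- fit_fe_ols(p0)   # 360 rows: exact dummy route
  expect_equal(fit0$route, "dummy")
  expect_lt(abs(fit0$coefficients["fhd"]), 1e-8)
})

test_that("the Frisch-Waugh property holds for the absorbed fixed effects", {
  p <- small_panel()
  spec <- fhd_model_spec()
  d <- p[p$analysis_sample, ]
  d <- d[stats::complete.cases(d[, c(spec$outcome, spec$exposure,
                                     spec$controls)]), ]
  dm <- droughtpm:::.demean_fe(
    as.matrix(d[, c("pm25", "fhd", spec$controls)]),
    list(d$plant_id, d$month, d$market_cm))
  dd <- as.data.frame(dm$values)
  fw <- stats::lm(pm25 ~ 0 + ., data = dd)
  fit <- fit_fe_ols(p)
  expect_equal(unname(stats::coef(fw)["fhd"]),
               unname(fit$coefficients["fhd"]), tolerance = 1e-6)
})

test_that("adding a constant to one plant's outcome leaves beta unchanged", {
  p <- small_panel()
  fit1 <- fit_fe_ols(p)
  p2 <- p
  shift <- p2$plant_id == p2$plant_id[1]
  p2$pm25[shift] <- p2$pm25[shift] + 5
  fit2 <- fit_fe_ols(p2)
  expect_equal(fit1$coefficients["fhd"], fit2$coefficients["fhd"],
               tolerance = 1e-6)
})

test_that("collinear exposure is reported with a diagnostic error", {
  p <- small_panel()
  p$always1 <- 1
  spec <- fhd_model_spec(exposure = "always1", controls = "temp_c")
  expect_error(fit_fe_ols(p, spec), "collinear|absorbed")
})

test_that("dose-response bins recover the linear effect pattern", {
  # a hand-built linear-in-FHD panel: bin coefficients should approximate
  # slope * (bin mean exposure - reference mean exposure)
  set.seed(66)
  G <- 20; months <- month_seq("2000-01", "2004-12")
  grid <- tidyr::expand_grid(market = sprintf("M%02d", 1:G), pidx = 1:2,
                             month = months)
  grid$plant_id <- paste(grid$market, grid$pidx)
  fhd_tbl <- tidyr::expand_grid(market = sprintf("M%02d", 1:G),
                                month = months)
  fhd_tbl$fhd <- stats::runif(nrow(fhd_tbl))
  grid <- dplyr::left_join(grid, fhd_tbl, by = c("market", "month"))
  grid$year <- month_year(grid$month)
  grid$market_cm <- paste(grid$market, month_cal(grid$month))
  grid$x1 <- stats::rnorm(nrow(grid))
  slope <- 1.55
  grid$pm25 <- 15 + slope * grid$fhd + 0.3 * grid$x1 +
    stats::rnorm(nrow(grid), 0, 0.4)
  spec <- fhd_model_spec(controls = "x1", sample_flag = NULL)
  fit <- dose_response(grid, spec)
  bins <- attr(fit, "bins")
  expect_equal(nrow(bins), 4L)
  expect_equal(sum(bins$n), nrow(grid))
  b <- fit$coefficients[paste0("fhd_bin", 2:4)]
  expected <- slope * (bins$mean_exposure[2:4] - bins$mean_exposure[1])
  expect_equal(unname(b), unname(expected), tolerance = 0.12)
  # the dose response of a positive linear effect rises across bins
  expect_true(all(diff(b) > 0))
  # an empty reference bin is an error listing occupancy
  grid2 <- dplyr::mutate(grid, fhd = 0.3 + 0.7 * fhd)
  expect_error(dose_response(grid2, spec), "bin")
})

test_that("heterogeneous effects recover subgroup ordering and bookkeeping", {
  # hand-built panel with known fuel-specific drought effects
  set.seed(77)
  G <- 12; Tm <- 48
  months <- month_seq("2000-01", "2003-12")
  grid <- tidyr::expand_grid(market = sprintf("M%02d", 1:G),
                             pidx = 1:3, month = months)
  grid$plant_id <- paste(grid$market, grid$pidx)
  grid$fuel <- c("coal", "gas", "oil")[grid$pidx]
  grid$capacity_mw <- c(200, 40, 10)[grid$pidx]
  fhd_tbl <- tidyr::expand_grid(market = sprintf("M%02d", 1:G), month = months)
  fhd_tbl$fhd <- stats::runif(nrow(fhd_tbl))
  grid <- dplyr::left_join(grid, fhd_tbl, by = c("market", "month"))
  beta_fuel <- c(coal = 0.5, gas = 1.0, oil = 2.0)
  grid$year <- month_year(grid$month)
  grid$calmonth <- month_cal(grid$month)
  grid$market_cm <- paste(grid$market, grid$calmonth)
  grid$x1 <- stats::rnorm(nrow(grid))
  grid$pm25 <- 15 + beta_fuel[grid$fuel] * grid$fhd + 0.3 * grid$x1 +
    stats::rnorm(nrow(grid), 0, 0.5)
  spec <- fhd_model_spec(controls = "x1", sample_flag = NULL)
  het <- heterogeneous_effects(grid, spec, group = "fuel")
  eff <- het$effects
  expect_equal(sum(eff$n), nrow(grid))
  est <- stats::setNames(eff$estimate, eff$level)
  expect_lt(est["coal"], est["gas"])
  expect_lt(est["gas"], est["oil"])
  expect_equal(unname(est[c("coal", "gas", "oil")]),
               unname(beta_fuel), tolerance = 0.25)
  # size split on the same panel: 30 MW cut defines two groups
  het2 <- heterogeneous_effects(grid, spec, group = "size30")
  expect_setequal(het2$effects$level, c("lt30MW", "ge30MW"))
  expect_equal(sum(het2$effects$n), nrow(grid))
})

test_that("truly homogeneous effects show no spurious subgroup differences", {
  hits <- sapply(1:10, function(s) {
    set.seed(400 + s)
    G <- 15; months <- month_seq("2000-01", "2002-12")
    grid <- tidyr::expand_grid(market = sprintf("M%02d", 1:G),
                               pidx = 1:2, month = months)
    grid$plant_id <- paste(grid$market, grid$pidx)
    grid$fuel <- c("coal", "oil")[grid$pidx]
    grid$capacity_mw <- 100
    fhd_tbl <- tidyr::expand_grid(market = sprintf("M%02d", 1:G),
                                  month = months)
    fhd_tbl$fhd <- stats::runif(nrow(fhd_tbl))
    grid <- dplyr::left_join(grid, fhd_tbl, by = c("market", "month"))
    grid$year <- month_year(grid$month)
    grid$market_cm <- paste(grid$market, month_cal(grid$month))
    grid$x1 <- stats::rnorm(nrow(grid))
    grid$pm25 <- 15 + 1.5 * grid$fhd + 0.3 * grid$x1 +
      stats::rnorm(nrow(grid), 0, 1)
    het <- heterogeneous_effects(grid,
                                 fhd_model_spec(controls = "x1",
                                                sample_flag = NULL),
                                 group = "fuel")
    all(abs(het$difference_tests$t) < 2)
  })
  expect_gte(mean(hits), 0.7)
})

test_that("implied totals add the marginal effect to the no-drought baseline", {
  fit <- structure(list(coefficients = c(fhd = 1.55),
                        baseline_prediction = 15.76, exposure = "fhd"),
                   class = "fhd_fit")
  expect_equal(implied_total(fit, 1), 17.31)
  expect_equal(implied_total(fit, 0), 15.76)
  mean_fhd <- 0.83 / 1.55
  expect_equal(implied_total(fit, mean_fhd), 16.59)
  expect_equal(implied_total(fit, mean_fhd) - implied_total(fit, 0), 0.83)
  expect_error(implied_total(fit, 1.2))
})

test_that("placebo samples follow their selection rules and show no effect", {
  # a world where every combustion plant commissions mid-panel, so the
  # pre-operational months form a sizeable placebo sample
  w <- generate_world(world_config(
    n_markets = 4L, hydro_plants_per_market = 2L,
    combustion_plants_per_market = 3L, noncombustion_plants_per_market = 1L,
    months = month_seq("2000-01", "2005-12"), reference_years = c(2000L, 2005L),
    fine_step_deg = 0.1, commission_midpanel_share = 1, seed = 23L))
  p <- world_panel(w)
  comb <- w$plants[w$plants$type == "combustion", ]
  pre <- placebo_run(p, "pre_operational")
  sample_rows <- dplyr::inner_join(
    pre$sample_index, p[, c("plant_id", "month", "year",
                            "commissioning_year")],
    by = c("plant_id", "month"))
  expect_true(all(sample_rows$year < sample_rows$commissioning_year))
  # the DGP carries no drought response before commissioning
  expect_lt(abs(pre$t[["fhd"]]), 4)
  # non-combustion placebo: the drought effect is absent by construction
  pp <- world_panel(w, "noncombustion")
  plc <- placebo_run(pp, "non_combustion", combustion_plants = comb)
  expect_lt(abs(plc$t[["fhd"]]), 4)
  # a non-combustion plant sitting on top of a combustion plant is screened out
  coords <- attr(pp, "plant_coords")
  comb2 <- dplyr::bind_rows(
    comb[, c("plant_id", "lon", "lat")],
    tibble::tibble(plant_id = "near", lon = coords$lon[1], lat = coords$lat[1]))
  plc2 <- placebo_run(pp, "non_combustion", combustion_plants = comb2)
  expect_false(coords$plant_id[1] %in% plc2$sample_index$plant_id)
  expect_lt(plc2$n_obs, nrow(pp))
})
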