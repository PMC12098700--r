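# Shared projection inputs on the small world.
proj_setup <- function() cached("proj_setup", {
  w <- small_world()
  hydro <- w$plants[w$plants$type == "hydro", ]
  list(world = w, hydro = hydro,
       years = 2020:2029,
       months = month_seq("2020-01", "2029-12"))
})

# A projected grid equal to a multiple of the historical climatology.
clim_grid <- function(world, months, factor = 1) {
  hist <- world$runoff
  ref <- world$config$reference_years
  hy <- month_year(hist$months); hc <- month_cal(hist$months)
  in_ref <- hy >= ref[1] & hy <= ref[2]
  clim <- vapply(1:12, function(m)
    rowMeans(hist$values[, in_ref & hc == m, drop = FALSE]),
    numeric(nrow(hist$cells)))
  field_grid(hist$cells, months, factor * clim[, month_cal(months)],
             unit = "mm/h")
}

test_that("projected FHD is zero at climatology and one under uniform drying", {
  s <- proj_setup()
  ref <- s$world$config$reference_years
  at_clim <- projected_fhd(clim_grid(s$world, s$months, 1), s$world$runoff,
                           s$world$basins, s$hydro, ref)
  expect_true(all(at_clim$fhd[!is.na(at_clim$fhd)] == 0))
  halved <- projected_fhd(clim_grid(s$world, s$months, 0.5), s$world$runoff,
                          s$world$basins, s$hydro, ref)
  expect_true(all(halved$fhd[!is.na(halved$fhd)] == 1))
  expect_true(all(is.na(halved$fhd[halved$month %in% c("2020-01", "2020-02")])))
  # misaligned grid is rejected
  bad <- clim_grid(s$world, s$months, 1)
  bad$cells <- bad$cells[-1, ]; bad$values <- bad$values[-1, ]
  expect_error(projected_fhd(bad, s$world$runoff, s$world$basins, s$hydro,
                             ref), "misaligned")
})

test_that("stronger imposed drying yields higher projected FHD", {
  s <- proj_setup()
  ref <- s$world$config$reference_years
  mild <- projected_fhd(clim_grid(s$world, s$months, 0.95), s$world$runoff,
                        s$world$basins, s$hydro, ref)
  strong <- projected_fhd(clim_grid(s$world, s$months, 0.70), s$world$runoff,
                          s$world$basins, s$hydro, ref)
  expect_gte(mean(strong$fhd, na.rm = TRUE), mean(mild$fhd, na.rm = TRUE))
  expect_true(all(strong$fhd >= 0 & strong$fhd <= 1, na.rm = TRUE))
})

test_that("ensemble generation produces one grid per model-scenario", {
  s <- proj_setup()
  ens <- generate_runoff_ensemble(s$world, n_models = 4L, years = 2020:2024,
                                  seed = 31L)
  expect_equal(nrow(ens$manifest), 12L)
  expect_equal(length(ens$grids), 12L)
  expect_setequal(names(ens$grids),
                  paste(ens$manifest$model_id, ens$manifest$ssp_rcp,
                        sep = "|"))
  # determinism
  ens2 <- generate_runoff_ensemble(s$world, n_models = 4L, years = 2020:2024,
                                   seed = 31L)
  expect_identical(ens$grids[[1]]$values, ens2$grids[[1]]$values)
})

test_that("FHD percent change follows its definition", {
  months <- c(month_seq("2000-01", "2019-12"), month_seq("2020-01", "2059-12"))
  yr <- month_year(months)
  f <- tibble::tibble(month = months,
                      fhd = ifelse(yr <= 2019, 0.5, 0.6))
  out <- fhd_pct_change(f)
  expect_equal(out$pct_change, 20)
  eq <- tibble::tibble(month = months, fhd = 0.4)
  expect_equal(fhd_pct_change(eq)$pct_change, 0)
  # negative changes are allowed (drying reversal)
  dec <- tibble::tibble(month = months, fhd = ifelse(yr <= 2019, 0.4, 0.3))
  expect_equal(fhd_pct_change(dec)$pct_change, -25)
  z <- tibble::tibble(month = months, fhd = ifelse(yr <= 2019, 0, 0.3))
  expect_warning(zz <- fhd_pct_change(z), "zero base")
  expect_true(is.na(zz$pct_change))
})

test_that("retirement schedules retire the largest exposed population first", {
  pops <- tibble::tibble(plant_id = c("A", "B", "C"),
                         pop65 = c(100, 900, 500))
  expect_equal(nrow(build_retirement_schedule(pops, "RES")), 0L)
  qp <- tibble::tibble(year = c(2030L, 2031L), n_retire = c(1L, 1L))
  sch <- build_retirement_schedule(pops, "APS", qp)
  expect_equal(sch$plant_id, c("B", "C"))
  expect_equal(sch$retirement_year, c(2030L, 2031L))
  # over-long path truncates with a warning
  qp2 <- tibble::tibble(year = 2030L, n_retire = 5L)
  expect_warning(sch2 <- build_retirement_schedule(pops, "STEPS", qp2),
                 "truncated")
  expect_equal(nrow(sch2), 3L)
  # ties break by plant id
  tie <- tibble::tibble(plant_id = c("Z", "A"), pop65 = c(10, 10))
  s3 <- build_retirement_schedule(tie, "APS",
                                  tibble::tibble(year = 2030L, n_retire = 1L))
  expect_equal(s3$plant_id, "A")
})

test_that("scenario paths multiply out models, scenarios and policies", {
  s <- proj_setup()
  w <- s$world
  ens <- generate_runoff_ensemble(w, n_models = 3L, years = 2020:2024,
                                  seed = 17L)
  fhd_paths <- list()
  for (key in names(ens$grids)) {
    parts <- strsplit(key, "|", fixed = TRUE)[[1]]
    pf <- projected_fhd(ens$grids[[key]], w$runoff, w$basins, s$hydro,
                        w$config$reference_years)
    pf$model_id <- parts[1]; pf$ssp_rcp <- parts[2]
    fhd_paths[[key]] <- pf
  }
  fhd_paths <- dplyr::bind_rows(fhd_paths)
  comb <- w$plants[w$plants$type == "combustion", ]
  pop65_base <- tibble::tibble(plant_id = comb$plant_id,
                               market = comb$market,
                               pop65 = seq(1e4, by = 1e4,
                                           length.out = nrow(comb)))
  scal <- generate_scenario_scalings(w, years = 2020:2024, seed = 4L)
  vslb <- tibble::tibble(country = w$markets, vsl_usd2019 = 2e6)
  rets <- list(APS = build_retirement_schedule(
    pop65_base, "APS", tibble::tibble(year = 2022L, n_retire = 2L)),
    STEPS = build_retirement_schedule(pop65_base, "STEPS"),
    RES = build_retirement_schedule(pop65_base, "RES"))
  paths <- project_paths(fhd_paths, pop65_base, scal$demographic,
                         scal$economic, vslb, rets, beta = 1.55)
  expect_equal(attr(paths, "n_paths"), 9L)   # 3 models x 3 scenarios
  expect_true(all(paths$deaths >= 0))
  expect_true(all(paths$fhd_mean >= 0 & paths$fhd_mean <= 1, na.rm = TRUE))

  # full retirement zeroes deaths from the retirement year onward
  all_ret <- list(APS = tibble::tibble(plant_id = comb$plant_id,
                                       retirement_year = 2022L),
                  STEPS = rets$STEPS, RES = rets$RES)
  p2 <- project_paths(fhd_paths, pop65_base, scal$demographic,
                      scal$economic, vslb, all_ret, beta = 1.55)
  aps <- p2[p2$policy == "APS", ]
  expect_true(all(aps$deaths[aps$year >= 2022] == 0))
  expect_true(any(aps$deaths[aps$year < 2022] > 0))

  # at identical FHD paths, retiring plants can only lower deaths
  p_res <- project_paths(fhd_paths, pop65_base, scal$demographic,
                         scal$economic, vslb, rets,
                         pairing = c("SSP1-2.6" = "RES", "SSP2-4.5" = "RES",
                                     "SSP3-7.0" = "RES"), beta = 1.55)
  p_aps <- project_paths(fhd_paths, pop65_base, scal$demographic,
                         scal$economic, vslb, rets,
                         pairing = c("SSP1-2.6" = "APS", "SSP2-4.5" = "APS",
                                     "SSP3-7.0" = "APS"), beta = 1.55)
  expect_true(all(p_aps$deaths <= p_res$deaths + 1e-9))

  # raising the 65+ multiplier monotonically raises deaths
  dem2 <- scal$demographic
  dem2$pop65_multiplier <- dem2$pop65_multiplier * 2
  p3 <- project_paths(fhd_paths, pop65_base, dem2, scal$economic, vslb,
                      rets, beta = 1.55)
  expect_equal(p3$deaths, 2 * paths$deaths, tolerance = 1e-12)
  expect_error(project_paths(fhd_paths, pop65_base,
                             scal$demographic[1:10, ], scal$economic, vslb,
                             rets, beta = 1.55),
               "demographic scaling")
})

test_that("pointwise-higher FHD yields pointwise-higher deaths", {
  months <- month_seq("2020-01", "2021-12")
  base <- tidyr::expand_grid(model_id = "GCM01", ssp_rcp = "SSP2-4.5",
                             market = "M01", month = months)
  base$fhd <- 0.3
  hi <- base; hi$fhd <- 0.6
  pop <- tibble::tibble(plant_id = "P", market = "M01", pop65 = 1e5)
  dem <- tidyr::expand_grid(ssp_rcp = "SSP2-4.5", country = "M01",
                            year = 2020:2021)
  dem$pop65_multiplier <- 1
  eco <- dem; eco$pop65_multiplier <- NULL; eco$vsl_multiplier <- 1
  vslb <- tibble::tibble(country = "M01", vsl_usd2019 = 1e6)
  rets <- list(STEPS = build_retirement_schedule(pop, "RES"))
  pl <- project_paths(base, pop, dem, eco, vslb, rets,
                      pairing = c("SSP2-4.5" = "STEPS"), beta = 1.55)
  ph <- project_paths(hi, pop, dem, eco, vslb, rets,
                      pairing = c("SSP2-4.5" = "STEPS"), beta = 1.55)
  expect_true(all(ph$deaths > pl$deaths))
  expect_equal(ph$deaths, 2 * pl$deaths, tolerance = 1e-12)
})
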