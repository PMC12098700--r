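#' Radial mean of a gridded field around a point
#'
#' Unweighted mean over all grid cells whose centers lie within the given
#' great-circle distance of the point.  The 50 km default matches the
#' dispersion area used for plant-level PM2.5 and meteorology.
#'
#' @param grid A `field_grid`.
#' @param lon,lat Center coordinates (decimal degrees).
#' @param radius_km Radius in kilometres.
#' @param label Optional name used in error messages (e.g. a plant id).
#' @return Named numeric vector of per-month means.
#' @export
radial_mean <- function(grid, lon, lat, radius_km = 50, label = NULL) {
  d <- cell_distances_km(grid, lon, lat)
  idx <- which(d <= radius_km)
  if (!length(idx)) {
    stop("no grid cells within ", radius_km, " km",
         if (!is.null(label)) paste0(" of ", label), call. = FALSE)
  }
  if (length(idx) == 1L) grid$values[idx, ] else colMeans(grid$values[idx, , drop = FALSE])
}

#' Heating and cooling degree-days
#'
#' Degree-days follow the IEA convention with an 18 degC reference and
#' activation thresholds: HDD accrues as `days * (18 - T)` when the monthly
#' mean temperature is at or below 15 degC, CDD as `days * (T - 18)` when it
#' is at or above 21 degC; between the thresholds both are zero.
#'
#' @param temp_c Monthly mean temperature (degC); vectorized.
#' @param days Days in the month (same length or scalar).
#' @return A list with numeric vectors `hdd` and `cdd` (degC-days).
#' @export
degree_days <- function(temp_c, days) {
  stopifnot(all(is.finite(temp_c)))
  hdd <- ifelse(temp_c <= 15, days * (18 - temp_c), 0)
  cdd <- ifelse(temp_c >= 21, days * (temp_c - 18), 0)
  list(hdd = hdd, cdd = cdd)
}

# Plant-months with any positive fire emission (or active dust source)
# within radius_km. Returns a logical plant x month matrix.
.contamination_flags <- function(plants, fire_grid, radius_km,
                                 dust_cells = NULL, dust_season_months = NULL) {
  months <- fire_grid$months
  flags <- matrix(FALSE, nrow(plants), length(months),
                  dimnames = list(plants$plant_id, months))
  dust_active <- NULL
  if (!is.null(dust_cells)) {
    if (is.null(dust_season_months)) {
      stop("a season -> calendar-months mapping is required with a dust map",
           call. = FALSE)
    }
    cal <- month_cal(months)
    dust_active <- matrix(FALSE, length(fire_grid$cells$cell_id), length(months))
    rownames(dust_active) <- fire_grid$cells$cell_id
    for (s in names(dust_season_months)) {
      cells_s <- dust_cells$cell_id[dust_cells$season == s]
      dust_active[rownames(dust_active) %in% cells_s,
                  cal %in% dust_season_months[[s]]] <- TRUE
    }
  }
  for (i in seq_len(nrow(plants))) {
    d <- cell_distances_km(fire_grid, plants$lon[i], plants$lat[i])
    near <- d <= radius_km
    if (!any(near)) next
    hit <- colSums(fire_grid$values[near, , drop = FALSE] > 0) > 0
    if (!is.null(dust_active)) {
      hit <- hit | colSums(dust_active[near, , drop = FALSE]) > 0
    }
    flags[i, ] <- hit
  }
  flags
}

#' Exclude plant-months contaminated by fire (and optionally dust) emissions
#'
#' Drops exactly the plant-month rows with any positive fire-emission cell
#' (and, if a dust-source map is supplied, any dust cell active in that
#' month's season) within `radius_km` of the plant.
#'
#' @param panel Panel data frame with columns `plant_id`, `month`.
#' @param fire_grid A `field_grid` of fire emissions covering the panel
#'   months.
#' @param plants Data frame with `plant_id`, `lon`, `lat` for every plant in
#'   the panel.
#' @param radius_km Exclusion radius (50, 75 or 100 in the robustness
#'   ladder; any positive value is accepted).
#' @param dust_cells Optional data frame (`cell_id`, `season`) of seasonal
#'   dust-source cells on the fire grid.
#' @param dust_season_months Named list mapping season names to calendar
#'   months (1-12); required with `dust_cells`.
#' @return A list with `panel` (the retained rows) and `dropped` (a tibble
#'   `plant_id`, `month`, `reason`).
#' @export
exclusion_filter <- function(panel, fire_grid, plants, radius_km = 50,
                             dust_cells = NULL, dust_season_months = NULL) {
  if (!is.numeric(radius_km) || radius_km <= 0) {
    stop("radius_km must be positive", call. = FALSE)
  }
  if (length(setdiff(unique(panel$month), fire_grid$months))) {
    stop("fire grid does not cover all panel months", call. = FALSE)
  }
  plants <- tibble::as_tibble(plants)
  plants <- plants[plants$plant_id %in% unique(panel$plant_id), ]
  flags <- .contamination_flags(plants, fire_grid, radius_km,
                                dust_cells, dust_season_months)
  hit <- flags[cbind(match(panel$plant_id, rownames(flags)),
                     match(panel$month, colnames(flags)))]
  dropped <- tibble::tibble(plant_id = panel$plant_id[hit],
                            month = panel$month[hit],
                            reason = sprintf("emissions within %g km", radius_km))
  list(panel = panel[!hit, , drop = FALSE], dropped = dropped)
}

#' Population within 50 km of plants, Thiessen-partitioned
#'
#' Every populated cell within `radius_km` of at least one plant is assigned
#' to its nearest plant (great-circle distance), so overlapping radii never
#' double count: the per-plant totals sum exactly to the population of the
#' union of the radii.
#'
#' @param plants Data frame with `plant_id`, `lon`, `lat` (distinct
#'   coordinates; exact ties are broken by plant id order with a warning).
#' @param pop_cells Data frame of raster cells: `cell_id`, `lon`, `lat`.
#' @param counts Numeric matrix of population counts, one row per cell
#'   (rownames = `cell_id`), one column per time step (colnames = years).
#' @param radius_km Radius in kilometres.
#' @return Tibble with `plant_id`, `year`, `population`.
#' @export
thiessen_population <- function(plants, pop_cells, counts, radius_km = 50) {
  plants <- tibble::as_tibble(plants)
  if (anyDuplicated(plants[, c("lon", "lat")])) {
    warning("coincident plant coordinates; ties broken by plant id order",
            call. = FALSE)
  }
  dmat <- vapply(seq_len(nrow(plants)), function(i) {
    cell_distances_km(list(cells = pop_cells), plants$lon[i], plants$lat[i])
  }, numeric(nrow(pop_cells)))
  dmat <- matrix(dmat, nrow = nrow(pop_cells))
  in_union <- apply(dmat, 1L, min) <= radius_km
  nearest <- plants$plant_id[apply(dmat, 1L, which.min)]  # which.min = first on ties
  counts <- counts[match(pop_cells$cell_id, rownames(counts)), , drop = FALSE]
  years <- colnames(counts)
  assigned <- factor(nearest[in_union], levels = plants$plant_id)
  sums <- rowsum(counts[in_union, , drop = FALSE], assigned)
  out <- tidyr::expand_grid(plant_id = plants$plant_id, year = as.integer(years))
  out$population <- as.vector(t(sums[match(plants$plant_id, rownames(sums)), ,
                                     drop = FALSE]))
  out$population[is.na(out$population)] <- 0
  out
}

#' Interpolate stepwise population counts to an annual series
#'
#' Linear interpolation between 5-year census steps; the step years are
#' preserved exactly and no extrapolation occurs beyond the step range.
#'
#' @param pop Tibble from [thiessen_population()] (`plant_id`, `year`,
#'   `population`) at the step years.
#' @return Tibble with one row per plant and calendar year between the first
#'   and last step.
#' @export
interpolate_population <- function(pop) {
  pop <- tibble::as_tibble(pop)
  dplyr::group_modify(dplyr::group_by(pop, .data$plant_id), function(d, key) {
    if (nrow(d) == 1L) {
      warning("single population step for ", key$plant_id,
              "; returning a constant series", call. = FALSE)
      return(tibble::tibble(year = d$year, population = d$population))
    }
    yrs <- seq(min(d$year), max(d$year))
    tibble::tibble(year = yrs,
                   population = stats::approx(d$year, d$population, xout = yrs)$y)
  }) |> dplyr::ungroup()
}

#' Population 65 and older around each plant
#'
#' Multiplies the all-age annual exposed population by the plant's country
#' fraction of population aged 65+, assuming a uniform age distribution
#' within each country.
#'
#' @param pop_annual Tibble (`plant_id`, `year`, `population`).
#' @param plants Data frame with `plant_id`, `market` (country code).
#' @param frac65 Tibble (`country`, `year`, `frac_65plus`).
#' @return Tibble with `plant_id`, `year`, `pop65`.
#' @export
elderly_population <- function(pop_annual, plants, frac65) {
  x <- dplyr::left_join(tibble::as_tibble(pop_annual),
                        tibble::as_tibble(plants)[, c("plant_id", "market")],
                        by = "plant_id")
  x <- dplyr::left_join(x, tibble::as_tibble(frac65),
                        by = c(market = "country", year = "year"))
  if (anyNA(x$frac_65plus)) {
    bad <- unique(paste(x$market[is.na(x$frac_65plus)],
                        x$year[is.na(x$frac_65plus)]))
    stop("missing 65+ fraction for: ", paste(utils::head(bad, 5), collapse = ", "),
         call. = FALSE)
  }
  tibble::tibble(plant_id = x$plant_id, year = x$year,
                 pop65 = x$population * x$frac_65plus)
}

# Plant-level control series measured from the gridded inputs: radial means
# of the meteorological fields, the local hydrological drought indicator at
# the plant's own runoff cell, and market-level HDD/CDD.  Shared between the
# synthetic-world generator (which uses these measured controls in its DGP)
# and panel assembly, so the two are consistent by construction.
.plant_controls <- function(plants, met_grids, runoff_grid, reference_years,
                            radius_km = 50, local_window = 3L) {
  months <- met_grids[[1L]]$months
  np <- nrow(plants)
  ctrl <- list()
  for (v in names(met_grids)) {
    m <- matrix(NA_real_, np, length(months),
                dimnames = list(plants$plant_id, months))
    for (i in seq_len(np)) {
      m[i, ] <- radial_mean(met_grids[[v]], plants$lon[i], plants$lat[i],
                            radius_km, label = plants$plant_id[i])
    }
    ctrl[[v]] <- m
  }
  # local drought: 3-month rolled anomaly at the plant's own (nearest) cell
  local <- matrix(NA_real_, np, length(months),
                  dimnames = list(plants$plant_id, months))
  for (i in seq_len(np)) {
    d <- cell_distances_km(runoff_grid, plants$lon[i], plants$lat[i])
    cell_series <- runoff_grid$values[which.min(d), ]
    ws <- compute_anomalies(cell_series, reference_years)
    local[i, ] <- drought_indicator(rolling_anomaly(ws$anomaly, local_window),
                                    "negative")
  }
  ctrl$local_drought <- local
  # market HDD/CDD from the market mean temperature over its met cells
  ctrl
}

# Market-level HDD/CDD series from a temperature grid: market mean
# temperature over all of the market's cells, then degree-days.
.market_degree_days <- function(temp_grid, cell_market) {
  months <- temp_grid$months
  mk <- factor(cell_market)
  tm <- rowsum(temp_grid$values, mk) / as.vector(table(mk))
  dd <- degree_days(tm, rep(month_days(months), each = nrow(tm)))
  list(hdd = matrix(dd$hdd, nrow(tm), dimnames = list(levels(mk), months)),
       cdd = matrix(dd$cdd, nrow(tm), dimnames = list(levels(mk), months)))
}

#' Assemble the plant-month panel
#'
#' Builds one record per plant-month: the radial PM2.5 mean, the
#' meteorological controls, market degree-days, the local drought indicator,
#' the market drought exposure (FHD and variants) joined by market-month,
#' the fire-contamination flag, the operational flag (year at or after the
#' commissioning year) and the analysis-sample flag (operational, not
#' fire-contaminated, and in a market with hydropower capacity).
#'
#' @param plants Plant registry rows to assemble (combustion plants for the
#'   main panel; non-combustion plants for the placebo panel): `plant_id`,
#'   `market`, `lon`, `lat`, `capacity_mw`, `fuel`, `commissioning_year`.
#' @param pm25_grid `field_grid` of PM2.5 (ug/m3).
#' @param met_grids Named list of meteorological `field_grid`s
#'   (`temp_c`, `precip_mm_h`, `rh_pct`, `pressure_pa`, `wind10_ms`,
#'   `wind100_ms`).
#' @param runoff_grid `field_grid` of runoff (for the local drought
#'   control).
#' @param market_exposure Exposure table from [compute_market_exposure()].
#' @param fire_grid `field_grid` of fire emissions.
#' @param reference_years Reference year range for the local drought
#'   climatology.
#' @param radius_km Dispersion radius for PM2.5 and meteorology (km).
#' @param fire_radius_km Fire-exclusion radius (km).
#' @return Tibble with one row per plant-month and columns documented above.
#' @export
assemble_panel <- function(plants, pm25_grid, met_grids, runoff_grid,
                           market_exposure, fire_grid, reference_years,
                           radius_km = 50, fire_radius_km = 50) {
  plants <- tibble::as_tibble(plants)
  months <- pm25_grid$months
  np <- nrow(plants)

  pm <- matrix(NA_real_, np, length(months),
               dimnames = list(plants$plant_id, months))
  for (i in seq_len(np)) {
    pm[i, ] <- radial_mean(pm25_grid, plants$lon[i], plants$lat[i],
                           radius_km, label = plants$plant_id[i])
  }
  ctrl <- .plant_controls(plants, met_grids, runoff_grid, reference_years,
                          radius_km)
  cell_market <- .nearest_market(met_grids$temp_c$cells, plants)
  dd <- .market_degree_days(met_grids$temp_c, cell_market)
  fire <- .contamination_flags(plants, fire_grid, fire_radius_km)

  panel <- tibble::tibble(
    plant_id = rep(plants$plant_id, times = length(months)),
    market = rep(plants$market, times = length(months)),
    month = rep(months, each = np),
    year = month_year(rep(months, each = np)),
    calmonth = month_cal(rep(months, each = np)),
    capacity_mw = rep(plants$capacity_mw, times = length(months)),
    fuel = rep(plants$fuel, times = length(months)),
    commissioning_year = rep(plants$commissioning_year, times = length(months)),
    pm25 = as.vector(pm),
    temp_c = as.vector(ctrl$temp_c),
    precip_mm_h = as.vector(ctrl$precip_mm_h),
    rh_pct = as.vector(ctrl$rh_pct),
    pressure_pa = as.vector(ctrl$pressure_pa),
    wind10_ms = as.vector(ctrl$wind10_ms),
    wind100_ms = as.vector(ctrl$wind100_ms),
    local_drought = as.vector(ctrl$local_drought),
    fire_within = as.vector(fire)
  )
  mk_idx <- match(panel$market, rownames(dd$hdd))
  mo_idx <- match(panel$month, colnames(dd$hdd))
  panel$hdd <- dd$hdd[cbind(mk_idx, mo_idx)]
  panel$cdd <- dd$cdd[cbind(mk_idx, mo_idx)]

  exp_tbl <- tibble::as_tibble(market_exposure)
  panel <- dplyr::left_join(panel, exp_tbl[, c("market", "month", "fhd",
                                               "fhd_arith", "fhd_severe",
                                               "mean_anomaly")],
                            by = c("market", "month"))
  orphan <- setdiff(unique(panel$market), unique(exp_tbl$market))
  if (length(orphan)) {
    stop("markets missing from the exposure table: ",
         paste(orphan, collapse = ", "), call. = FALSE)
  }
  has_hydro <- tapply(!is.na(exp_tbl$fhd), exp_tbl$market, any)
  panel$market_has_hydro <- as.vector(has_hydro[panel$market])
  panel$operational <- panel$year >= panel$commissioning_year
  panel$analysis_sample <- panel$operational & !panel$fire_within &
    panel$market_has_hydro & !is.na(panel$fhd)
  panel$market_cm <- paste(panel$market, sprintf("%02d", panel$calmonth), sep = ":")
  attr(panel, "plant_coords") <- plants[, c("plant_id", "lon", "lat")]
  panel
}

# Market of the nearest plant, used to key grid cells to markets.
.nearest_market <- function(cells, plants) {
  dmat <- vapply(seq_len(nrow(plants)), function(i) {
    cell_distances_km(list(cells = cells), plants$lon[i], plants$lat[i])
  }, numeric(nrow(cells)))
  plants$market[apply(matrix(dmat, nrow = nrow(cells)), 1L, which.min)]
}
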