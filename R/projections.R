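#' Generate an ensemble of projected runoff grids
#'
#' Emulates a multi-model climate ensemble: each model draws a long-run
#' drying (or wetting) trend applied as a smooth ramp to the historical
#' calendar-month climatology, scaled by scenario severity, with
#' multiplicative month-to-month weather noise.  Higher-forcing scenarios
#' amplify each model's trend, so the imposed cross-scenario ordering of
#' drought exposure is known by construction.
#'
#' @param world An `fhd_world` (source of the historical climatology).
#' @param n_models Number of climate models (default 22).
#' @param scenarios Scenario labels (default the three SSP-RCPs).
#' @param years Projection years (default 2020-2059).
#' @param severity Named scenario multipliers on the model trend.
#' @param trend_mean,trend_sd Distribution of the per-model end-of-horizon
#'   runoff reduction (fraction; negative draws are wetting models).
#' @param noise_sd Log-scale sd of cell-month weather noise.
#' @param seed Seed; defaults to the world's seed.
#' @return A list with `manifest` (tibble `model_id`, `ssp_rcp`) and
#'   `grids`, a named list (`"<model>|<scenario>"`) of runoff `field_grid`s
#'   over the projection months.
#' @export
generate_runoff_ensemble <- function(world, n_models = 22L,
                                     scenarios = c("SSP1-2.6", "SSP2-4.5",
                                                   "SSP3-7.0"),
                                     years = 2020:2059,
                                     severity = c("SSP1-2.6" = 0.75,
                                                  "SSP2-4.5" = 1,
                                                  "SSP3-7.0" = 1.25),
                                     trend_mean = 0.25, trend_sd = 0.35,
                                     noise_sd = 0.2, seed = NULL) {
  if (is.null(seed)) seed <- world$config$seed
  stopifnot(all(scenarios %in% names(severity)))
  months <- month_seq(sprintf("%d-01", min(years)), sprintf("%d-12", max(years)))
  cal <- month_cal(months)
  # climatology of the historical runoff over the reference period, per cell
  hist <- world$runoff
  ref <- world$config$reference_years
  hy <- month_year(hist$months); hc <- month_cal(hist$months)
  in_ref <- hy >= ref[1L] & hy <= ref[2L]
  clim <- vapply(1:12, function(m) {
    rowMeans(hist$values[, in_ref & hc == m, drop = FALSE])
  }, numeric(nrow(hist$cells)))
  ramp <- (month_year(months) - (min(years) - 1L)) / (max(years) - (min(years) - 1L))

  model_ids <- sprintf("GCM%02d", seq_len(n_models))
  trends <- with_seed(stream_seed(seed, "ensemble"),
                      stats::rnorm(n_models, trend_mean, trend_sd))
  names(trends) <- model_ids
  grids <- list()
  manifest <- tidyr::expand_grid(model_id = model_ids, ssp_rcp = scenarios)
  for (r in seq_len(nrow(manifest))) {
    mdl <- manifest$model_id[r]; scn <- manifest$ssp_rcp[r]
    gseed <- stream_seed(seed + 131 * match(mdl, model_ids) +
                           17 * match(scn, scenarios), "ensemble")
    reduction <- trends[[mdl]] * severity[[scn]] * ramp
    base <- clim[, cal, drop = FALSE] *
      matrix(pmax(0.05, 1 - reduction), nrow(clim), length(months), byrow = TRUE)
    noise <- with_seed(gseed, matrix(
      exp(stats::rnorm(nrow(clim) * length(months), 0, noise_sd)),
      nrow(clim), length(months)))
    grids[[paste(mdl, scn, sep = "|")]] <-
      field_grid(hist$cells, months, base * noise, unit = "mm/h",
                 name = paste0("runoff_", mdl, "_", scn))
  }
  list(manifest = manifest, grids = grids, trends = trends)
}

#' Projected market drought exposure from a projected runoff grid
#'
#' Anomalies are the projected runoff minus the historical calendar-month
#' climatology of each watershed (the same climatology used in the
#' historical analysis); the drought indicator and capacity-weighted market
#' aggregation are then applied unchanged.
#'
#' @param proj_grid Projected runoff `field_grid`.
#' @param hist_runoff Historical runoff `field_grid`.
#' @param graph A [basin_graph()].
#' @param hydro_plants Hydro plant registry (`plant_id`, `market`,
#'   `capacity_mw`, `outlet_basin`).
#' @param reference_years Historical reference year range for the
#'   climatology.
#' @param window Trailing drought window (months).
#' @param market_map Optional market merge mapping.
#' @return Tibble (`market`, `month`, `fhd`).
#' @export
projected_fhd <- function(proj_grid, hist_runoff, graph, hydro_plants,
                          reference_years, window = 3L, market_map = NULL) {
  hydro_plants <- tibble::as_tibble(hydro_plants)
  months <- proj_grid$months
  cal <- month_cal(months)
  np <- nrow(hydro_plants)
  ind <- matrix(NA_real_, np, length(months),
                dimnames = list(hydro_plants$plant_id, months))
  for (i in seq_len(np)) {
    shed <- delineate_watershed(graph, hydro_plants$outlet_basin[i])
    cells <- unique(graph$membership$cell_id[graph$membership$basin_id %in% shed])
    if (length(setdiff(cells, proj_grid$cells$cell_id))) {
      stop("projected runoff grid is misaligned with the historical grid: ",
           "missing cells for watershed of ", hydro_plants$plant_id[i],
           call. = FALSE)
    }
    hist_series <- watershed_runoff(hist_runoff, graph, shed)
    clim <- compute_anomalies(hist_series, reference_years)$climatology
    proj_series <- watershed_runoff(proj_grid, graph, shed)
    anom <- proj_series - clim[cal]
    names(anom) <- months
    ind[i, ] <- drought_indicator(rolling_anomaly(anom, window), "negative")
  }
  out <- aggregate_market(ind, hydro_plants, "capacity", market_map)
  names(out)[names(out) == "value"] <- "fhd"
  out
}

#' Percent change in mean drought exposure between two periods
#'
#' @param fhd Tibble with columns `month` and `fhd` (optionally `market`,
#'   in which case the change is computed per market).  Historical and
#'   projected rows may simply be bound together.
#' @param base_period,future_period Year ranges `c(first, last)`.
#' @return Tibble (`market` if present) with `base_mean`, `future_mean` and
#'   `pct_change` = 100 * (future - base) / base; a zero base mean yields
#'   `NA` with a warning.
#' @export
fhd_pct_change <- function(fhd, base_period = c(2000, 2019),
                           future_period = c(2020, 2059)) {
  fhd <- tibble::as_tibble(fhd)
  yr <- month_year(fhd$month)
  in_base <- yr >= base_period[1L] & yr <= base_period[2L]
  in_fut <- yr >= future_period[1L] & yr <= future_period[2L]
  if (!any(in_base) || !any(in_fut)) {
    stop("both periods must be non-empty in the FHD series", call. = FALSE)
  }
  keys <- intersect("market", names(fhd))
  f <- fhd
  f$.period <- dplyr::case_when(in_base ~ "base", in_fut ~ "future",
                                TRUE ~ NA_character_)
  f <- f[!is.na(f$.period), ]
  agg <- dplyr::summarise(
    dplyr::group_by(f, dplyr::across(dplyr::all_of(c(keys, ".period")))),
    m = mean(.data$fhd, na.rm = TRUE), .groups = "drop")
  wide <- tidyr::pivot_wider(agg, names_from = ".period", values_from = "m")
  if (any(wide$base == 0, na.rm = TRUE)) {
    warning("zero base-period mean FHD: percent change undefined (NA)",
            call. = FALSE)
  }
  out <- wide
  names(out)[names(out) == "base"] <- "base_mean"
  names(out)[names(out) == "future"] <- "future_mean"
  out$pct_change <- ifelse(out$base_mean == 0, NA_real_,
                           100 * (out$future_mean - out$base_mean) / out$base_mean)
  out
}

#' Build a combustion-plant retirement schedule
#'
#' Under the announced-pledges (APS) and stated-policies (STEPS) scenarios,
#' plants retire according to a yearly quantity path, largest exposed
#' population first (ties broken by plant id); the reference scenario (RES)
#' retires nothing.  No new plants are ever added.
#'
#' @param exposed_pop Tibble (`plant_id`, `pop65`) of baseline exposed
#'   population used for the retirement ordering.
#' @param policy `"APS"`, `"STEPS"` or `"RES"`.
#' @param quantity_path Tibble (`year`, `n_retire`): number of plants to
#'   retire in each year (ignored for RES).
#' @return Tibble (`plant_id`, `retirement_year`); zero rows for RES.
#' @export
build_retirement_schedule <- function(exposed_pop,
                                      policy = c("APS", "STEPS", "RES"),
                                      quantity_path = NULL) {
  policy <- match.arg(policy)
  empty <- tibble::tibble(plant_id = character(), retirement_year = integer())
  if (policy == "RES") return(empty)
  if (is.null(quantity_path) || !nrow(quantity_path)) return(empty)
  ord <- exposed_pop[order(-exposed_pop$pop65, exposed_pop$plant_id), ]
  qp <- quantity_path[order(quantity_path$year), ]
  total <- sum(qp$n_retire)
  if (total > nrow(ord)) {
    warning("retirement path exceeds fleet size; truncated", call. = FALSE)
  }
  n_assign <- pmin(cumsum(qp$n_retire), nrow(ord))
  start <- c(0L, utils::head(n_assign, -1L))
  out <- list()
  for (j in seq_len(nrow(qp))) {
    if (n_assign[j] > start[j]) {
      out[[j]] <- tibble::tibble(
        plant_id = ord$plant_id[(start[j] + 1L):n_assign[j]],
        retirement_year = as.integer(qp$year[j]))
    }
  }
  if (!length(out)) empty else dplyr::bind_rows(out)
}

#' Project deaths and losses along the scenario ensemble
#'
#' For each (climate model, SSP-RCP) pair the projected FHD path is
#' combined with the constant concentration-response function and drought
#' coefficient, scenario demographic scalings of the exposed 65+
#' population, the paired energy-policy retirement schedule, and scenario
#' economic scalings of the value of statistical life.
#'
#' @param fhd_paths Tibble (`model_id`, `ssp_rcp`, `market`, `month`,
#'   `fhd`), e.g. from [projected_fhd()] over an ensemble.
#' @param pop65_base Tibble (`plant_id`, `market`, `pop65`): baseline
#'   exposed population 65+ per plant.
#' @param demographic_scaling Tibble (`ssp_rcp`, `country`, `year`,
#'   `pop65_multiplier`) relative to the baseline year.
#' @param economic_scaling Tibble (`ssp_rcp`, `country`, `year`,
#'   `vsl_multiplier`) applied to the baseline country VSL.
#' @param vsl_base Tibble (`country`, `vsl_usd2019`): baseline country VSL.
#' @param retirements Named list of retirement schedules per policy (see
#'   [build_retirement_schedule()]).
#' @param pairing Named character vector mapping each SSP-RCP to an energy
#'   policy; the default pairs increasing climate forcing with decreasing
#'   retirement ambition.
#' @param crf A [crf_spec()] (held constant: no adaptation).
#' @param beta Drought coefficient (held constant).
#' @return Tibble of class `scenario_paths` (`model_id`, `ssp_rcp`,
#'   `policy`, `year`, `market`, `fhd_mean`, `deaths`, `losses_usd2019`).
#' @export
project_paths <- function(fhd_paths, pop65_base, demographic_scaling,
                          economic_scaling, vsl_base, retirements,
                          pairing = c("SSP1-2.6" = "APS",
                                      "SSP2-4.5" = "STEPS",
                                      "SSP3-7.0" = "RES"),
                          crf = crf_spec(), beta = 1.55) {
  fhd_paths <- tibble::as_tibble(fhd_paths)
  scen <- unique(fhd_paths$ssp_rcp)
  if (length(setdiff(scen, names(pairing)))) {
    stop("pairing missing for scenarios: ",
         paste(setdiff(scen, names(pairing)), collapse = ", "), call. = FALSE)
  }
  fhd_paths$year <- month_year(fhd_paths$month)
  # monthly FHD sums and means per path-market-year
  ag <- dplyr::summarise(
    dplyr::group_by(fhd_paths, .data$model_id, .data$ssp_rcp, .data$market,
                    .data$year),
    fhd_sum = sum(.data$fhd, na.rm = TRUE),
    fhd_mean = mean(.data$fhd, na.rm = TRUE), .groups = "drop")
  ag$policy <- unname(pairing[ag$ssp_rcp])

  years <- sort(unique(ag$year))
  need_dem <- tidyr::expand_grid(ssp_rcp = scen,
                                 country = unique(pop65_base$market),
                                 year = years)
  dem <- dplyr::left_join(need_dem, demographic_scaling,
                          by = c("ssp_rcp", "country", "year"))
  if (anyNA(dem$pop65_multiplier)) {
    stop("demographic scaling missing for some scenario-country-years",
         call. = FALSE)
  }
  eco <- dplyr::left_join(need_dem, economic_scaling,
                          by = c("ssp_rcp", "country", "year"))
  if (anyNA(eco$vsl_multiplier)) {
    stop("economic scaling missing for some scenario-country-years",
         call. = FALSE)
  }

  # active exposed population per (policy, market, year)
  pol_pop <- list()
  for (pol in unique(ag$policy)) {
    sched <- retirements[[pol]]
    if (is.null(sched)) sched <- tibble::tibble(plant_id = character(),
                                                retirement_year = integer())
    ret_year <- sched$retirement_year[match(pop65_base$plant_id,
                                            sched$plant_id)]
    active_pop <- lapply(years, function(y) {
      act <- is.na(ret_year) | y < ret_year
      tapply(pop65_base$pop65 * act, pop65_base$market, sum)
    })
    pol_pop[[pol]] <- do.call(cbind, active_pop)
    colnames(pol_pop[[pol]]) <- years
  }

  key <- paste(dem$ssp_rcp, dem$country, dem$year)
  ag$pop_mult <- dem$pop65_multiplier[match(paste(ag$ssp_rcp, ag$market,
                                                  ag$year), key)]
  ag$vsl_mult <- eco$vsl_multiplier[match(paste(ag$ssp_rcp, ag$market,
                                                ag$year), key)]
  ag$base_pop <- mapply(function(pol, mk, y) {
    pp <- pol_pop[[pol]]
    if (mk %in% rownames(pp)) pp[mk, as.character(y)] else 0
  }, ag$policy, ag$market, ag$year)
  ag$deaths <- crf$rate * crf$days * beta * ag$fhd_sum *
    ag$base_pop * ag$pop_mult / 1e6
  vsl0 <- vsl_base$vsl_usd2019[match(ag$market, vsl_base$country)]
  ag$losses_usd2019 <- ag$deaths * vsl0 * ag$vsl_mult
  out <- ag[, c("model_id", "ssp_rcp", "policy", "year", "market",
                "fhd_mean", "deaths", "losses_usd2019")]
  attr(out, "n_paths") <- nrow(unique(ag[, c("model_id", "ssp_rcp")]))
  class(out) <- c("scenario_paths", class(out))
  out
}

#' Default scenario demographic and economic scalings
#'
#' Synthetic multipliers relative to the baseline year: the exposed 65+
#' population grows fastest under SSP1 (rapid ageing) and slowest under
#' SSP3, while income (and hence VSL) growth follows the same ordering.
#'
#' @param world An `fhd_world`.
#' @param scenarios Scenario labels.
#' @param years Projection years.
#' @param seed Seed; defaults to the world's.
#' @return List with `demographic` and `economic` scaling tibbles as
#'   consumed by [project_paths()].
#' @export
generate_scenario_scalings <- function(world,
                                       scenarios = c("SSP1-2.6", "SSP2-4.5",
                                                     "SSP3-7.0"),
                                       years = 2020:2059, seed = NULL) {
  if (is.null(seed)) seed <- world$config$seed
  markets <- world$markets
  g65 <- list("SSP1-2.6" = c(0.025, 0.035), "SSP2-4.5" = c(0.015, 0.025),
              "SSP3-7.0" = c(0.008, 0.018))
  ggni <- list("SSP1-2.6" = c(0.020, 0.030), "SSP2-4.5" = c(0.015, 0.025),
               "SSP3-7.0" = c(0.005, 0.015))
  base_year <- min(years) - 1L
  with_seed(stream_seed(seed, "scalings"), {
    dem <- list(); eco <- list()
    for (s in scenarios) {
      r65 <- stats::runif(length(markets), g65[[s]][1L], g65[[s]][2L])
      rg <- stats::runif(length(markets), ggni[[s]][1L], ggni[[s]][2L])
      dem[[s]] <- tidyr::expand_grid(ssp_rcp = s, country = markets,
                                     year = years)
      dem[[s]]$pop65_multiplier <-
        (1 + r65[match(dem[[s]]$country, markets)])^(dem[[s]]$year - base_year)
      eco[[s]] <- tidyr::expand_grid(ssp_rcp = s, country = markets,
                                     year = years)
      eco[[s]]$vsl_multiplier <-
        (1 + rg[match(eco[[s]]$country, markets)])^(eco[[s]]$year - base_year)
    }
    list(demographic = dplyr::bind_rows(dem), economic = dplyr::bind_rows(eco))
  })
}
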