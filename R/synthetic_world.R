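#' Synthetic-world configuration
#'
#' Defines the data-generating process of the synthetic study region: a set
#' of electricity markets (one market = one synthetic country), each with
#' hydropower plants fed by small basin networks on a coarse runoff grid,
#' combustion plants surrounded by a fine PM2.5/population raster, and a
#' separate, distant cluster of non-combustion plants used for placebo
#' analyses.  PM2.5 near each combustion plant follows the linear
#' fixed-effects model `plant + month-year + market-calendar-month effects +
#' controls + beta * FHD + noise`, with the FHD computed from the generated
#' runoff by the same drought machinery used in estimation.
#'
#' @param n_markets Number of markets (countries).
#' @param hydro_plants_per_market,combustion_plants_per_market,noncombustion_plants_per_market
#'   Plant counts per market.
#' @param months Month labels covered by the panel.
#' @param reference_years Reference period (year range) for climatologies.
#' @param coarse_step_deg Grid step of the runoff/fire/meteorology rasters
#'   (degrees).
#' @param fine_step_deg Grid step of the PM2.5/population rasters (degrees).
#' @param window_deg Side length of each fine raster window (degrees); each
#'   market has one window around its generation cluster and one around its
#'   non-combustion cluster.
#' @param tile_spacing_deg Longitudinal spacing between market tiles;
#'   `NULL` (default) auto-sizes it so that plant dispersion radii never
#'   overlap each other or neighbouring markets.
#' @param true_beta Drought effect on PM2.5 (ug/m3 at FHD = 1).
#' @param true_gamma Named control coefficients (see
#'   [fhd_model_spec()] controls).
#' @param fe_scales Standard deviations of the plant, month-year and
#'   market-calendar-month effects (ug/m3).
#' @param plant_effect_mean Mean plant effect, anchoring baseline PM2.5
#'   (ug/m3).
#' @param noise_sd Standard deviation of the plant-month disturbance and of
#'   the cell-level measurement noise (ug/m3).
#' @param drought_episode_rate Probability per watershed-month of a drought
#'   episode starting.
#' @param episode_mean_extra_months Episodes last `1 + Poisson(this)`
#'   months.
#' @param episode_depth_range Episode runoff reduction (fraction, drawn
#'   uniformly).
#' @param fire_event_rate Probability per coarse cell-month of a fire
#'   emission event.
#' @param commission_midpanel_share Share of combustion plants whose
#'   commissioning year falls inside the panel (enabling the
#'   pre-operational placebo).
#' @param drought_window Trailing window (months) of the drought
#'   indicators.
#' @param seed Integer seed; all components draw from seeds derived from
#'   it via independent streams.
#' @return A list of class `world_config`.
#' @export
world_config <- function(n_markets = 19L,
                         hydro_plants_per_market = 3L,
                         combustion_plants_per_market = 4L,
                         noncombustion_plants_per_market = 2L,
                         months = month_seq("2000-01", "2020-12"),
                         reference_years = c(2000L, 2019L),
                         coarse_step_deg = 0.25,
                         fine_step_deg = 0.01,
                         window_deg = 0.3,
                         tile_spacing_deg = NULL,
                         true_beta = 1.55,
                         true_gamma = c(temp_c = -0.04, precip_mm_h = -0.5,
                                        rh_pct = 0.02, pressure_pa = 2e-5,
                                        wind10_ms = -0.15, wind100_ms = -0.05,
                                        local_drought = 0.3,
                                        hdd = 0.002, cdd = 0.003),
                         fe_scales = c(plant = 2, month_year = 0.8,
                                       market_calmonth = 0.8),
                         plant_effect_mean = 15.5,
                         noise_sd = 1,
                         drought_episode_rate = 0.08,
                         episode_mean_extra_months = 2,
                         episode_depth_range = c(0.2, 0.6),
                         fire_event_rate = 0.01,
                         commission_midpanel_share = 0.25,
                         drought_window = 3L,
                         seed = 1L) {
  cfg <- list(n_markets = as.integer(n_markets),
              hydro_plants_per_market = as.integer(hydro_plants_per_market),
              combustion_plants_per_market = as.integer(combustion_plants_per_market),
              noncombustion_plants_per_market = as.integer(noncombustion_plants_per_market),
              months = months, reference_years = as.integer(reference_years),
              coarse_step_deg = coarse_step_deg, fine_step_deg = fine_step_deg,
              window_deg = window_deg,
              tile_spacing_deg = tile_spacing_deg %||%
                ((combustion_plants_per_market +
                    noncombustion_plants_per_market) * 1.0 + 2.5),
              true_beta = true_beta, true_gamma = true_gamma,
              fe_scales = fe_scales, plant_effect_mean = plant_effect_mean,
              noise_sd = noise_sd,
              drought_episode_rate = drought_episode_rate,
              episode_mean_extra_months = episode_mean_extra_months,
              episode_depth_range = episode_depth_range,
              fire_event_rate = fire_event_rate,
              commission_midpanel_share = commission_midpanel_share,
              drought_window = as.integer(drought_window),
              seed = as.integer(seed))
  validate_world_config(cfg)
  structure(cfg, class = "world_config")
}

#' @rdname world_config
#' @param config A configuration list.
#' @export
validate_world_config <- function(config) {
  with(config, {
    if (n_markets < 1L || hydro_plants_per_market < 1L ||
        combustion_plants_per_market < 1L) {
      stop("all plant/market counts must be >= 1", call. = FALSE)
    }
    if (coarse_step_deg <= 0 || fine_step_deg <= 0) {
      stop("grid steps must be positive", call. = FALSE)
    }
    if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
    yrs <- month_year(months)
    if (reference_years[1L] < min(yrs) || reference_years[2L] > max(yrs) ||
        reference_years[1L] > reference_years[2L]) {
      stop("reference_years must be a subrange of the panel years", call. = FALSE)
    }
    if (floor(window_deg / fine_step_deg) < 1L) {
      stop("impossible geometry: fine grid step exceeds the plant window",
           call. = FALSE)
    }
    if (n_markets * tile_spacing_deg > 300) {
      stop("impossible geometry: market tiles would wrap around the globe",
           call. = FALSE)
    }
    if (drought_episode_rate < 0 || drought_episode_rate > 1 ||
        fire_event_rate < 0 || fire_event_rate > 1) {
      stop("event rates must lie in [0, 1]", call. = FALSE)
    }
  })
  invisible(config)
}

# Cell centers of a square window [x0, x0+side] x [y0, y0+side].
.window_cells <- function(x0, y0, side, step, prefix) {
  off <- seq(step / 2, side - step / 2, by = step)
  grid <- expand.grid(dx = off, dy = off)
  tibble::tibble(cell_id = sprintf("%s%03d", prefix, seq_len(nrow(grid))),
                 lon = x0 + grid$dx, lat = y0 + grid$dy)
}

#' Generate a synthetic world
#'
#' Draws every pipeline input (plant registries, basin graph, runoff, fire,
#' meteorology, PM2.5 and population rasters, country tables) from the
#' configured data-generating process, and returns them together with the
#' ground truth (`truth`): the effect sizes, fixed effects, drought episode
#' calendar and the market exposure series implied by the generated runoff.
#'
#' @param config A [world_config()].
#' @return A list of class `fhd_world`; see Details in the package
#'   vignette.
#' @export
generate_world <- function(config = world_config()) {
  validate_world_config(config)
  months <- config$months
  nm <- length(months)
  cal <- month_cal(months)
  yrs <- month_year(months)
  M <- config$n_markets
  markets <- sprintf("M%02d", seq_len(M))
  lon0 <- (seq_len(M) - 1) * config$tile_spacing_deg

  ## ---- layout stream: geometry, registries, basins, population base ----
  ## Each market occupies one tile: a hydro/basin window on the left, then
  ## one slot per combustion and non-combustion plant, spaced 1 degree apart
  ## so that 50 km dispersion radii never overlap across plants or markets.
  layout <- with_seed(stream_seed(config$seed, "layout"), {
    coarse <- list(); fine <- list(); basins_list <- list()
    membership <- list(); plants <- list(); pop_base <- list()
    wdeg <- config$window_deg
    for (k in seq_len(M)) {
      mk <- markets[k]
      # hydro window: coarse runoff cells hosting the basin network
      cg <- .window_cells(lon0[k], 0, 0.5, config$coarse_step_deg,
                          paste0(mk, "_cg"))
      cg$market <- mk; cg$window <- "hydro"
      nb <- nrow(cg)
      bid <- sprintf("%s_b%d", mk, seq_len(nb))
      basins_list[[k]] <- tibble::tibble(
        basin_id = bid,
        downstream_id = c(bid[-1L], NA_character_))
      membership[[k]] <- tibble::tibble(basin_id = bid, cell_id = cg$cell_id)
      # hydropower plants: no point location, an outlet basin each
      nh <- config$hydro_plants_per_market
      hyd <- tibble::tibble(
        plant_id = sprintf("%s_h%d", mk, seq_len(nh)),
        market = mk, type = "hydro",
        lon = NA_real_, lat = NA_real_,
        capacity_mw = pmin(2000, pmax(5, stats::rlnorm(nh, log(200), 0.7))),
        fuel = "hydro",
        commissioning_year = sample(1960:1999, nh, replace = TRUE),
        outlet_basin = sample(bid, nh, replace = TRUE))
      # plant slots: combustion first, then non-combustion
      nc <- config$combustion_plants_per_market
      nn <- config$noncombustion_plants_per_market
      mid <- stats::runif(nc) < config$commission_midpanel_share
      com <- tibble::tibble(
        plant_id = sprintf("%s_c%d", mk, seq_len(nc)),
        market = mk, type = "combustion",
        capacity_mw = pmin(1500, pmax(2, stats::rlnorm(nc, log(80), 1.1))),
        fuel = sample(c("coal", "gas", "oil", "biomass"), nc, replace = TRUE,
                      prob = c(0.15, 0.3, 0.35, 0.2)),
        commissioning_year = ifelse(mid, sample(2003:2015, nc, replace = TRUE),
                                    sample(1960:1999, nc, replace = TRUE)),
        outlet_basin = NA_character_)
      non <- if (nn > 0) tibble::tibble(
        plant_id = sprintf("%s_n%d", mk, seq_len(nn)),
        market = mk, type = "noncombustion",
        capacity_mw = pmin(1500, pmax(2, stats::rlnorm(nn, log(60), 1))),
        fuel = sample(c("wind", "solar", "geothermal", "nuclear"), nn,
                      replace = TRUE),
        commissioning_year = sample(1960:1999, nn, replace = TRUE),
        outlet_basin = NA_character_) else NULL
      slotted <- dplyr::bind_rows(com, non)
      centers <- lon0[k] + 1.25 + (seq_len(nrow(slotted)) - 1)
      slotted$lon <- stats::runif(nrow(slotted), centers - 0.05, centers + 0.05)
      slotted$lat <- stats::runif(nrow(slotted), 0.20, 0.30)
      plants[[k]] <- dplyr::bind_rows(hyd, slotted)
      # per-slot coarse meteorology/fire/runoff window and fine PM window
      cs <- list(); fs <- list()
      for (s_i in seq_len(nrow(slotted))) {
        cw <- .window_cells(centers[s_i] - 0.25, 0, 0.5,
                            config$coarse_step_deg,
                            sprintf("%s_cs%d_", mk, s_i))
        cw$market <- mk; cw$window <- "plant"
        cs[[s_i]] <- cw
        fw <- .window_cells(centers[s_i] - wdeg / 2, 0.25 - wdeg / 2, wdeg,
                            config$fine_step_deg,
                            sprintf("%s_f%d_", mk, s_i))
        fw$market <- mk; fw$paint_plant <- slotted$plant_id[s_i]
        fs[[s_i]] <- fw
      }
      coarse[[k]] <- dplyr::bind_rows(c(list(cg), cs))
      fine[[k]] <- dplyr::bind_rows(fs)
      pop_base[[k]] <- stats::rlnorm(nrow(fine[[k]]), log(150), 1.2)
    }
    list(coarse = dplyr::bind_rows(coarse), fine = dplyr::bind_rows(fine),
         basins = dplyr::bind_rows(basins_list),
         membership = dplyr::bind_rows(membership),
         plants = dplyr::bind_rows(plants),
         pop_base = unlist(pop_base),
         pop_growth = matrix(1 + stats::runif(M * 4, 0.02, 0.10), M, 4,
                             dimnames = list(markets, NULL)))
  })
  coarse <- layout$coarse
  fine <- layout$fine
  plants <- layout$plants
  graph <- basin_graph(layout$basins, layout$membership)
  hydro <- plants[plants$type == "hydro", ]
  comb <- plants[plants$type == "combustion", ]
  noncomb <- plants[plants$type == "noncombustion", ]

  ## ---- runoff stream: seasonal baseline + scheduled drought episodes ----
  runoff_parts <- with_seed(stream_seed(config$seed, "runoff"), {
    base_cell <- stats::rlnorm(nrow(coarse), log(0.4), 0.5)
    phase <- stats::runif(M, 0, 12); names(phase) <- markets
    season <- 1 + 0.45 * sin(2 * pi * outer(rep(1, nrow(coarse)), cal) / 12 -
                             2 * pi * phase[coarse$market] / 12)
    values <- base_cell * season
    mult <- matrix(1, nrow(coarse), nm)
    episodes <- list()
    dur_extra <- config$episode_mean_extra_months
    for (i in seq_len(nrow(hydro))) {
      shed <- delineate_watershed(graph, hydro$outlet_basin[i])
      cells <- unique(graph$membership$cell_id[graph$membership$basin_id %in% shed])
      rows <- match(cells, coarse$cell_id)
      starts <- which(stats::runif(nm) < config$drought_episode_rate)
      if (!length(starts)) next
      durs <- 1L + stats::rpois(length(starts), dur_extra)
      depths <- stats::runif(length(starts), config$episode_depth_range[1L],
                             config$episode_depth_range[2L])
      for (j in seq_along(starts)) {
        span <- starts[j]:min(nm, starts[j] + durs[j] - 1L)
        mult[rows, span] <- mult[rows, span] * (1 - depths[j])
      }
      episodes[[length(episodes) + 1L]] <- tibble::tibble(
        plant_id = hydro$plant_id[i], start_month = months[starts],
        duration = durs, depth = depths)
    }
    # independent dry spells on plant-window cells: local hydrological
    # conditions at plant sites vary but are unrelated to the hydropower
    # watershed episodes that drive the FHD
    plc_rows <- which(coarse$window == "plant")
    for (r in plc_rows) {
      starts <- which(stats::runif(nm) < config$drought_episode_rate)
      if (!length(starts)) next
      durs <- 1L + stats::rpois(length(starts), dur_extra)
      depths <- stats::runif(length(starts), config$episode_depth_range[1L],
                             config$episode_depth_range[2L])
      for (j in seq_along(starts)) {
        span <- starts[j]:min(nm, starts[j] + durs[j] - 1L)
        mult[r, span] <- mult[r, span] * (1 - depths[j])
      }
    }
    list(values = values * mult,
         episodes = if (length(episodes)) dplyr::bind_rows(episodes) else
           tibble::tibble(plant_id = character(), start_month = character(),
                          duration = integer(), depth = numeric()),
         season_phase = phase)
  })
  runoff <- field_grid(coarse[, c("cell_id", "lon", "lat")], months,
                       runoff_parts$values, unit = "mm/h", name = "runoff")

  ## ---- market drought exposure implied by the generated runoff ----
  exposure <- compute_market_exposure(runoff, graph, hydro,
                                      config$reference_years,
                                      window = config$drought_window,
                                      markets = markets)

  ## ---- met stream: coarse meteorology fields ----
  met <- with_seed(stream_seed(config$seed, "met"), {
    ncc <- nrow(coarse)
    phase <- runoff_parts$season_phase
    seas <- sin(2 * pi * outer(rep(1, ncc), cal) / 12 -
                2 * pi * phase[coarse$market] / 12)
    cellsC <- coarse[, c("cell_id", "lon", "lat")]
    # market mean climates span cool highlands to hot lowlands, so both
    # heating and cooling degree-days vary somewhere in every world
    mk_base <- stats::runif(M, 12, 26)
    names(mk_base) <- markets
    temp <- (mk_base[coarse$market] + stats::rnorm(ncc, 0, 1)) + 8 * seas +
      matrix(stats::rnorm(ncc * nm, 0, 1.5), ncc, nm)
    precip <- matrix(stats::rgamma(ncc * nm, shape = 2,
                                   scale = 0.08), ncc, nm) * (1 + 0.5 * pmax(seas, 0))
    rh <- 65 + 12 * seas + matrix(stats::rnorm(ncc * nm, 0, 6), ncc, nm)
    rh <- pmin(pmax(rh, 5), 100)
    pres <- stats::rnorm(ncc, 96000, 400) +
      matrix(stats::rnorm(ncc * nm, 0, 150), ncc, nm)
    w10 <- pmax(3 + matrix(stats::rnorm(ncc * nm, 0, 1), ncc, nm), 0.2)
    w100 <- w10 * 1.4 + pmax(matrix(stats::rnorm(ncc * nm, 0.3, 0.2), ncc, nm), 0)
    list(temp_c = field_grid(cellsC, months, temp, "degC", "temp_c"),
         precip_mm_h = field_grid(cellsC, months, precip, "mm/h", "precip_mm_h"),
         rh_pct = field_grid(cellsC, months, rh, "%", "rh_pct"),
         pressure_pa = field_grid(cellsC, months, pres, "Pa", "pressure_pa"),
         wind10_ms = field_grid(cellsC, months, w10, "m/s", "wind10_ms"),
         wind100_ms = field_grid(cellsC, months, w100, "m/s", "wind100_ms"))
  })

  ## ---- effects stream: fixed effects of the panel DGP ----
  painted <- dplyr::bind_rows(comb, noncomb)
  effects <- with_seed(stream_seed(config$seed, "effects"), {
    pe <- stats::rnorm(nrow(painted), config$plant_effect_mean,
                       config$fe_scales[["plant"]])
    names(pe) <- painted$plant_id
    my <- stats::rnorm(nm, 0, config$fe_scales[["month_year"]])
    names(my) <- months
    cm <- matrix(stats::rnorm(M * 12, 0, config$fe_scales[["market_calmonth"]]),
                 M, 12, dimnames = list(markets, NULL))
    list(plant = pe, month_year = my, market_cm = cm)
  })

  ## ---- deterministic linear predictor from measured controls ----
  ctrl <- .plant_controls(painted, met, runoff, config$reference_years,
                          radius_km = 50, local_window = config$drought_window)
  dd <- .market_degree_days(met$temp_c, coarse$market)
  gam <- config$true_gamma
  pred <- matrix(0, nrow(painted), nm,
                 dimnames = list(painted$plant_id, months))
  for (v in c("temp_c", "precip_mm_h", "rh_pct", "pressure_pa",
              "wind10_ms", "wind100_ms", "local_drought")) {
    x <- ctrl[[v]]
    if (v == "local_drought") x[is.na(x)] <- 0  # incomplete rolling window
    pred <- pred + gam[[v]] * x
  }
  mk_idx <- match(painted$market, rownames(dd$hdd))
  pred <- pred + gam[["hdd"]] * dd$hdd[mk_idx, , drop = FALSE] +
    gam[["cdd"]] * dd$cdd[mk_idx, , drop = FALSE]
  pred <- pred + effects$plant[painted$plant_id] +
    matrix(effects$month_year, nrow(painted), nm, byrow = TRUE) +
    effects$market_cm[cbind(rep(mk_idx, times = nm), rep(cal, each = nrow(painted)))]
  # drought effect: combustion plants only
  fhd_wide <- tidyr::pivot_wider(exposure[, c("market", "month", "fhd")],
                                 names_from = "month", values_from = "fhd")
  fhd_mat <- as.matrix(fhd_wide[, months])
  rownames(fhd_mat) <- fhd_wide$market
  fhd_term <- fhd_mat[painted$market, , drop = FALSE]
  fhd_term[is.na(fhd_term)] <- 0
  # the generation-shift effect exists only while a plant is operational:
  # pre-commissioning months carry no drought response (placebo ground truth)
  operational <- outer(painted$commissioning_year, yrs, "<=")
  is_comb <- painted$type == "combustion"
  pred[is_comb, ] <- pred[is_comb, ] +
    config$true_beta * (fhd_term * operational)[is_comb, ]

  ## ---- noise stream: plant-month disturbance + cell measurement noise ----
  nf <- nrow(fine)
  noise <- with_seed(stream_seed(config$seed, "noise"), {
    eps <- matrix(stats::rnorm(nrow(painted) * nm, 0, config$noise_sd),
                  nrow(painted), nm, dimnames = list(painted$plant_id, months))
    cell <- matrix(stats::rnorm(nf * nm, 0, config$noise_sd), nf, nm)
    list(eps = eps, cell = cell)
  })
  nearest <- match(fine$paint_plant, painted$plant_id)
  pm_values <- pred[nearest, , drop = FALSE] + noise$eps[nearest, , drop = FALSE] +
    noise$cell
  pm25 <- field_grid(fine[, c("cell_id", "lon", "lat")], months, pm_values,
                     unit = "ug/m3", name = "pm25")

  ## ---- fire stream ----
  fire_values <- with_seed(stream_seed(config$seed, "fire"), {
    hit <- matrix(stats::runif(nrow(coarse) * nm) < config$fire_event_rate,
                  nrow(coarse), nm)
    emis <- matrix(stats::rlnorm(nrow(coarse) * nm, log(5), 1),
                   nrow(coarse), nm)
    emis * hit
  })
  fire <- field_grid(coarse[, c("cell_id", "lon", "lat")], months,
                     fire_values, unit = "gC/m2", name = "fire")

  ## ---- population stream: stepwise rasters every five years ----
  step_years <- seq(min(yrs) - min(yrs) %% 5, max(yrs), by = 5)
  if (step_years[1L] < min(yrs)) step_years[1L] <- min(yrs)
  if (max(step_years) < max(yrs)) step_years <- c(step_years, max(yrs))
  pop <- with_seed(stream_seed(config$seed, "population"), {
    counts <- matrix(NA_real_, nf, length(step_years),
                     dimnames = list(fine$cell_id, step_years))
    counts[, 1L] <- layout$pop_base
    for (s in seq_along(step_years)[-1L]) {
      gidx <- min(s - 1L, ncol(layout$pop_growth))
      counts[, s] <- counts[, s - 1L] *
        layout$pop_growth[fine$market, gidx]
    }
    counts
  })

  ## ---- country stream: GNI per capita and 65+ fractions ----
  years <- sort(unique(yrs))
  country_tables <- with_seed(stream_seed(config$seed, "country"), {
    gni0 <- stats::rlnorm(M, log(8000), 0.5)
    growth <- matrix(1.02 + stats::rnorm(M * (length(years) - 1L), 0, 0.01),
                     M, length(years) - 1L)
    gni <- t(apply(cbind(gni0, growth), 1L, cumprod))
    dimnames(gni) <- list(markets, years)
    f0 <- stats::runif(M, 0.05, 0.08)
    slope <- stats::runif(M, 0.001, 0.002)
    f65 <- pmin(outer(f0, rep(1, length(years))) +
                  outer(slope, years - years[1L]), 1)
    dimnames(f65) <- list(markets, years)
    us <- 55000 * 1.018^(years - 2019)
    list(
      gni = tibble::tibble(country = rep(markets, times = length(years)),
                           year = rep(years, each = M),
                           gni_pc = as.vector(gni)),
      us_gni = tibble::tibble(year = years, gni_pc = us),
      frac65 = tibble::tibble(country = rep(markets, times = length(years)),
                              year = rep(years, each = M),
                              frac_65plus = as.vector(f65)))
  })

  truth <- list(true_beta = config$true_beta, true_gamma = config$true_gamma,
                plant_effects = effects$plant,
                month_effects = effects$month_year,
                market_cm_effects = effects$market_cm,
                episodes = runoff_parts$episodes,
                eps = noise$eps,
                market_exposure = exposure)

  structure(list(config = config, markets = markets, plants = plants,
                 basins = graph, runoff = runoff, fire = fire, met = met,
                 pm25 = pm25,
                 population = list(cells = fine[, c("cell_id", "lon", "lat")],
                                   counts = pop, years = step_years),
                 country_tables = country_tables,
                 market_exposure = exposure, truth = truth),
            class = "fhd_world")
}

#' @export
print.fhd_world <- function(x, ...) {
  cat(sprintf("<fhd_world> %d markets, %d plants (%d hydro, %d combustion, %d non-combustion)\n",
              length(x$markets), nrow(x$plants),
              sum(x$plants$type == "hydro"), sum(x$plants$type == "combustion"),
              sum(x$plants$type == "noncombustion")))
  cat(sprintf("  months %s .. %s; true beta = %.3g ug/m3 per unit FHD\n",
              x$config$months[1L], x$config$months[length(x$config$months)],
              x$config$true_beta))
  invisible(x)
}

#' Assemble the combustion (or placebo) panel from a synthetic world
#'
#' Convenience wrapper around [assemble_panel()] wiring up the world's
#' grids, registry and exposure table.
#'
#' @param world An `fhd_world`.
#' @param type `"combustion"` or `"noncombustion"`.
#' @return A panel tibble (see [assemble_panel()]).
#' @export
world_panel <- function(world, type = c("combustion", "noncombustion")) {
  type <- match.arg(type)
  plants <- world$plants[world$plants$type == type, ]
  assemble_panel(plants, world$pm25, world$met, world$runoff,
                 world$market_exposure, world$fire,
                 world$config$reference_years)
}

#' Exposed population aged 65+ per plant-year
#'
#' Thiessen-partitions the population raster among the world's combustion
#' plants at each census step, interpolates to an annual series, and applies
#' the country 65+ fractions.
#'
#' @param world An `fhd_world`.
#' @param radius_km Dispersion radius (km).
#' @return Tibble (`plant_id`, `year`, `pop65`).
#' @export
world_pop65 <- function(world, radius_km = 50) {
  comb <- world$plants[world$plants$type == "combustion", ]
  steps <- thiessen_population(comb, world$population$cells,
                               world$population$counts, radius_km)
  annual <- interpolate_population(steps)
  elderly_population(annual, comb, world$country_tables$frac65)
}

#' Hand-sized deterministic fixture world
#'
#' A tiny world (2 markets, 2 hydro + 2 combustion + 1 non-combustion
#' plants each, 24 months, coarse PM grid) generated with a fixed internal
#' seed, together with its derived intermediates, for exact regression
#' tests.  Regeneration is idempotent.
#'
#' @return A list with `world`, `market_exposure`, `panel`,
#'   `placebo_panel` and `pop65`.
#' @export
generate_tiny_fixture <- function() {
  cfg <- world_config(
    n_markets = 2L, hydro_plants_per_market = 2L,
    combustion_plants_per_market = 2L, noncombustion_plants_per_market = 1L,
    months = month_seq("2000-01", "2001-12"),
    reference_years = c(2000L, 2001L),
    fine_step_deg = 0.05,
    drought_episode_rate = 0.15, fire_event_rate = 0.02,
    noise_sd = 0.5, seed = 42L)
  world <- generate_world(cfg)
  list(world = world,
       market_exposure = world$market_exposure,
       panel = world_panel(world, "combustion"),
       placebo_panel = world_panel(world, "noncombustion"),
       pop65 = world_pop65(world))
}
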