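#' Basin graphs
#'
#' A basin graph holds the drainage topology used to delineate hydropower
#' watersheds: each basin optionally points to the basin immediately
#' downstream of it, and owns at least one runoff grid cell.
#'
#' @param basins Data frame with columns `basin_id` and `downstream_id`
#'   (`NA` for terminal basins).
#' @param membership Data frame with columns `basin_id`, `cell_id` mapping
#'   basins to runoff grid cells.
#' @return An object of class `basin_graph`.
#' @export
basin_graph <- function(basins, membership) {
  basins <- tibble::as_tibble(basins)
  membership <- tibble::as_tibble(membership)
  stopifnot(all(c("basin_id", "downstream_id") %in% names(basins)),
            all(c("basin_id", "cell_id") %in% names(membership)))
  if (anyDuplicated(basins$basin_id)) stop("duplicate basin ids", call. = FALSE)
  down <- basins$downstream_id
  known <- is.na(down) | down %in% basins$basin_id
  if (!all(known)) stop("downstream pointer to unknown basin", call. = FALSE)
  missing_cells <- setdiff(basins$basin_id, membership$basin_id)
  if (length(missing_cells)) {
    stop("basins without grid cells: ", paste(missing_cells, collapse = ", "),
         call. = FALSE)
  }
  g <- structure(list(basins = basins, membership = membership),
                 class = "basin_graph")
  .assert_forest(g)
  g
}

# Downstream pointers must form a forest (no cycles).
.assert_forest <- function(graph) {
  ids <- graph$basins$basin_id
  nxt <- match(graph$basins$downstream_id, ids)  # NA for terminal
  for (s in seq_along(ids)) {
    slow <- s; fast <- s
    repeat {
      fast <- nxt[fast]
      if (is.na(fast)) break
      fast <- nxt[fast]
      if (is.na(fast)) break
      slow <- nxt[slow]
      if (slow == fast) stop("basin graph contains a cycle", call. = FALSE)
    }
  }
  invisible(graph)
}

#' Delineate the watershed upstream of an outlet basin
#'
#' Traces all basins from which water flows, along downstream pointers,
#' into the outlet basin.  The result is the contributing area of a
#' hydropower plant sited at the outlet.
#'
#' @param graph A [basin_graph()].
#' @param outlet Basin id of the plant's outlet.
#' @return Character vector of basin ids: the outlet plus every upstream
#'   basin whose downstream path reaches it.
#' @export
delineate_watershed <- function(graph, outlet) {
  ids <- graph$basins$basin_id
  if (!outlet %in% ids) stop("unknown outlet basin: ", outlet, call. = FALSE)
  # children-of map: which basins point at each basin
  upstream_of <- split(graph$basins$basin_id,
                       factor(graph$basins$downstream_id, levels = ids))
  shed <- character(0)
  frontier <- outlet
  while (length(frontier)) {
    shed <- c(shed, frontier)
    frontier <- unlist(upstream_of[frontier], use.names = FALSE)
  }
  sort(unique(shed))
}

#' Mean runoff over a watershed
#'
#' Per-month unweighted mean of the runoff grid over all cells belonging to
#' the union of the given basins.
#'
#' @param grid A `field_grid` of runoff (mm/h).
#' @param graph A [basin_graph()].
#' @param basins Character vector of basin ids (e.g. a watershed from
#'   [delineate_watershed()]).
#' @return Named numeric vector of monthly mean runoff (names = months).
#' @export
watershed_runoff <- function(grid, graph, basins) {
  if (!length(basins)) stop("empty basin set", call. = FALSE)
  cells <- unique(graph$membership$cell_id[graph$membership$basin_id %in% basins])
  idx <- match(cells, grid$cells$cell_id)
  if (!length(idx) || anyNA(idx)) {
    stop("watershed has no cells on the runoff grid", call. = FALSE)
  }
  if (length(idx) == 1L) grid$values[idx, ] else colMeans(grid$values[idx, , drop = FALSE])
}

#' Runoff anomalies relative to a reference-period climatology
#'
#' The anomaly in a month is the runoff minus the mean runoff of the same
#' calendar month over the reference years.  By construction the anomalies of
#' each calendar month average to zero across reference years.
#'
#' @param series Named numeric vector of monthly runoff (names =
#'   `"YYYY-MM"`, consecutive).
#' @param reference_years Length-2 integer vector `c(first, last)` reference
#'   year range (inclusive).
#' @return A list of class `watershed_series` with elements `months`,
#'   `runoff`, `anomaly`, `climatology` (length-12, indexed by calendar
#'   month) and `anomaly_sd` (standard deviation of the anomalies over the
#'   reference period).
#' @export
compute_anomalies <- function(series, reference_years) {
  months <- names(series)
  if (is.null(months)) stop("`series` must be named by month label", call. = FALSE)
  assert_month_run(months)
  yrs <- month_year(months)
  cal <- month_cal(months)
  in_ref <- yrs >= reference_years[1L] & yrs <= reference_years[2L]
  if (!any(in_ref)) stop("reference years absent from series", call. = FALSE)
  if (length(setdiff(1:12, unique(cal[in_ref])))) {
    stop("some calendar months are absent from the reference period", call. = FALSE)
  }
  clim <- vapply(1:12, function(m) mean(series[in_ref & cal == m]), numeric(1))
  anomaly <- unname(series) - clim[cal]
  names(anomaly) <- months
  structure(list(months = months, runoff = series, anomaly = anomaly,
                 climatology = clim,
                 anomaly_sd = stats::sd(anomaly[in_ref])),
            class = "watershed_series")
}

#' Trailing moving average of an anomaly series
#'
#' The value at month `t` is the mean of the anomalies over months
#' `t-k+1 .. t` (a trailing window including the current month); the first
#' `k-1` months are missing.
#'
#' @param anomaly Named numeric vector of monthly anomalies.
#' @param window Window length `k` in months.  The drought definitions used
#'   in the package are built on windows of 1, 3, 6, 9 or 12 months; other
#'   positive values are accepted with a warning.
#' @return Named numeric vector, `NA` for the first `k-1` months.
#' @export
rolling_anomaly <- function(anomaly, window = 3L) {
  window <- as.integer(window)
  if (is.na(window) || window < 1L) stop("window must be a positive integer", call. = FALSE)
  if (!window %in% c(1L, 3L, 6L, 9L, 12L)) {
    warning("non-standard drought window: ", window, " months", call. = FALSE)
  }
  n <- length(anomaly)
  if (window == 1L) return(anomaly)
  cs <- cumsum(c(0, anomaly))
  out <- rep(NA_real_, n)
  if (n >= window) {
    idx <- window:n
    out[idx] <- (cs[idx + 1L] - cs[idx + 1L - window]) / window
  }
  names(out) <- names(anomaly)
  out
}

#' Binary hydrological drought indicator
#'
#' In `negative` mode a watershed is in drought in months whose rolled
#' anomaly is strictly below zero (less water available than normal); in
#' `severe` mode only when the rolled anomaly is more than one reference
#' standard deviation below normal.
#'
#' @param rolled Named numeric vector of rolled anomalies (may contain `NA`
#'   for incomplete windows; missingness propagates).
#' @param mode `"negative"` or `"severe"`.
#' @param sd Reference-period anomaly standard deviation (required and
#'   strictly positive for `mode = "severe"`).
#' @param tol Numerical guard below zero: anomalies within `tol` of the
#'   threshold count as "normal", so floating-point dust around an exactly
#'   average month never registers as drought.
#' @return Integer vector of 0/1 (with `NA` where `rolled` is missing).
#' @export
drought_indicator <- function(rolled, mode = c("negative", "severe"),
                              sd = NULL, tol = 1e-10) {
  mode <- match.arg(mode)
  if (mode == "severe") {
    if (is.null(sd) || !is.finite(sd) || sd <= 0) {
      stop("`sd` must be a positive number for severe mode", call. = FALSE)
    }
    thr <- -sd
  } else {
    thr <- 0
  }
  out <- ifelse(is.na(rolled), NA_integer_, as.integer(rolled < thr - tol))
  names(out) <- names(rolled)
  out
}

#' Aggregate plant drought indicators to market exposure (FHD)
#'
#' The fraction of hydropower generation capacity affected by drought (FHD)
#' in a market-month is the capacity-weighted mean of the plant-level
#' drought indicators; the arithmetic variant weights all plants equally.
#' Markets without hydropower capacity are missing, not zero.
#'
#' @param indicators Numeric matrix of 0/1 drought indicators, one row per
#'   hydro plant (rownames = plant ids), one column per month.
#' @param plants Data frame of hydro plants with columns `plant_id`,
#'   `market`, `capacity_mw`.
#' @param weighting `"capacity"` or `"arithmetic"`.
#' @param market_map Optional named character vector mapping registry market
#'   codes to (possibly merged) analysis markets; identity by default.
#' @return Tibble with columns `market`, `month`, `value` in `[0, 1]`
#'   (`NA` where any plant's indicator is missing).
#' @export
aggregate_market <- function(indicators, plants,
                             weighting = c("capacity", "arithmetic"),
                             market_map = NULL) {
  weighting <- match.arg(weighting)
  plants <- tibble::as_tibble(plants)
  if (any(plants$capacity_mw <= 0)) stop("plant capacities must be positive", call. = FALSE)
  idx <- match(plants$plant_id, rownames(indicators))
  if (anyNA(idx)) stop("indicator rows missing for some plants", call. = FALSE)
  mk <- .map_market(plants$market, market_map)
  w <- if (weighting == "capacity") plants$capacity_mw else rep(1, nrow(plants))
  .weighted_market_mean(indicators[idx, , drop = FALSE], mk, w)
}

#' Capacity-weighted mean runoff anomaly per market
#'
#' A sign-preserving drought-intensity measure: unlike FHD, negative
#' anomalies at some plants can be offset by positive anomalies at others.
#'
#' @param anomalies Numeric matrix of (rolled) anomalies, one row per hydro
#'   plant (rownames = plant ids), one column per month.
#' @inheritParams aggregate_market
#' @return Tibble with columns `market`, `month`, `value` (mm/h).
#' @export
market_mean_anomaly <- function(anomalies, plants,
                                weighting = c("capacity", "arithmetic"),
                                market_map = NULL) {
  weighting <- match.arg(weighting)
  plants <- tibble::as_tibble(plants)
  if (any(plants$capacity_mw <= 0)) stop("plant capacities must be positive", call. = FALSE)
  idx <- match(plants$plant_id, rownames(anomalies))
  if (anyNA(idx)) stop("anomaly rows missing for some plants", call. = FALSE)
  mk <- .map_market(plants$market, market_map)
  w <- if (weighting == "capacity") plants$capacity_mw else rep(1, nrow(plants))
  .weighted_market_mean(anomalies[idx, , drop = FALSE], mk, w)
}

.map_market <- function(market, market_map) {
  if (is.null(market_map)) return(market)
  out <- unname(market_map[market])
  if (anyNA(out)) {
    stop("market_map missing entries for: ",
         paste(unique(market[is.na(out)]), collapse = ", "), call. = FALSE)
  }
  out
}

# Weighted column means by market; NA if any contributing value is NA.
# The ratio form keeps degenerate cases exact: all-ones gives exactly 1.
.weighted_market_mean <- function(mat, market, w) {
  months <- colnames(mat)
  out <- lapply(split(seq_along(market), market), function(rows) {
    colSums(mat[rows, , drop = FALSE] * w[rows]) / sum(w[rows])
  })
  tibble::tibble(
    market = rep(names(out), each = length(months)),
    month = rep(months, times = length(out)),
    value = unlist(out, use.names = FALSE)
  )
}

#' Market-level drought exposure table
#'
#' Drives the full hydro-drought chain: watershed delineation, watershed
#' runoff, anomalies against the reference climatology, trailing-window
#' rolling, the negative and severe drought indicators, and the market
#' aggregations (capacity-weighted FHD, arithmetic FHD, severe FHD, mean
#' anomaly).
#'
#' @param runoff A `field_grid` of runoff (mm/h).
#' @param graph A [basin_graph()].
#' @param hydro_plants Data frame of hydro plants with `plant_id`, `market`,
#'   `capacity_mw`, `outlet_basin`.
#' @param reference_years Length-2 integer reference year range.
#' @param window Trailing window length (months), default 3.
#' @param market_map Optional market merge mapping (see
#'   [aggregate_market()]).
#' @param markets Optional character vector of all analysis markets; markets
#'   without hydropower capacity are returned with missing exposure values.
#' @return Tibble with columns `market`, `month`, `window`, `fhd`,
#'   `fhd_arith`, `fhd_severe`, `mean_anomaly`.
#' @export
compute_market_exposure <- function(runoff, graph, hydro_plants,
                                    reference_years, window = 3L,
                                    market_map = NULL, markets = NULL) {
  hydro_plants <- tibble::as_tibble(hydro_plants)
  months <- runoff$months
  np <- nrow(hydro_plants)
  rolled <- matrix(NA_real_, np, length(months),
                   dimnames = list(hydro_plants$plant_id, months))
  ind_neg <- ind_sev <- rolled
  for (i in seq_len(np)) {
    shed <- delineate_watershed(graph, hydro_plants$outlet_basin[i])
    wr <- watershed_runoff(runoff, graph, shed)
    ws <- compute_anomalies(wr, reference_years)
    r <- rolling_anomaly(ws$anomaly, window)
    rolled[i, ] <- r
    ind_neg[i, ] <- drought_indicator(r, "negative")
    # a degenerate reference sd (constant anomalies) makes the severe
    # threshold coincide with the strict-negativity threshold
    ind_sev[i, ] <- if (ws$anomaly_sd > 0) {
      drought_indicator(r, "severe", sd = ws$anomaly_sd)
    } else {
      drought_indicator(r, "negative")
    }
  }
  fhd <- aggregate_market(ind_neg, hydro_plants, "capacity", market_map)
  fhd_a <- aggregate_market(ind_neg, hydro_plants, "arithmetic", market_map)
  fhd_s <- aggregate_market(ind_sev, hydro_plants, "capacity", market_map)
  anom <- market_mean_anomaly(rolled, hydro_plants, "capacity", market_map)
  out <- fhd
  names(out)[names(out) == "value"] <- "fhd"
  out$fhd_arith <- fhd_a$value
  out$fhd_severe <- fhd_s$value
  out$mean_anomaly <- anom$value
  out$window <- as.integer(window)
  if (!is.null(markets)) {
    no_hydro <- setdiff(markets, unique(out$market))
    if (length(no_hydro)) {
      pad <- tidyr::expand_grid(market = no_hydro, month = months)
      pad$fhd <- pad$fhd_arith <- pad$fhd_severe <- pad$mean_anomaly <- NA_real_
      pad$window <- as.integer(window)
      out <- dplyr::bind_rows(out, pad)
    }
  }
  dplyr::arrange(out[, c("market", "month", "window", "fhd", "fhd_arith",
                         "fhd_severe", "mean_anomaly")],
                 .data$market, .data$month)
}
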