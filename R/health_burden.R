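#' Concentration-response function specification
#'
#' A constant-rate CRF: excess deaths per day per microgram per cubic meter
#' per million adults aged 65+.  The default 0.69 daily rate with a 30-day
#' month is the causal Medicare-based CRF used for the headline mortality
#' counterfactual; alternative CRFs plug in by swapping this object only.
#'
#' @param daily_deaths_per_million_elderly_per_ug Daily excess death rate.
#' @param days_per_month Days used to convert the daily rate to monthly
#'   frequency (fixed at 30 by default; must lie in 28..31).
#' @param label Human-readable CRF name.
#' @return A list of class `crf_spec`.
#' @export
crf_spec <- function(daily_deaths_per_million_elderly_per_ug = 0.69,
                     days_per_month = 30, label = "medicare-causal") {
  rate <- daily_deaths_per_million_elderly_per_ug
  if (!is.numeric(rate) || rate < 0) stop("CRF rate must be >= 0", call. = FALSE)
  if (days_per_month < 28 || days_per_month > 31) {
    stop("days_per_month must lie in [28, 31]", call. = FALSE)
  }
  structure(list(rate = rate, days = days_per_month, label = label),
            class = "crf_spec")
}

#' Coefficient sampling specification for uncertainty propagation
#'
#' The drought coefficient is drawn from a normal distribution centered on
#' the estimate with the cluster-robust standard error as its standard
#' deviation (defaults 1.55 and 0.31 ug/m3), 1000 draws.
#'
#' @param mean,sd Normal mean and standard deviation (ug/m3).
#' @param n_draws Number of Monte-Carlo draws.
#' @param seed Integer seed for the draws.
#' @return A list of class `beta_draw_spec`.
#' @export
beta_draw_spec <- function(mean = 1.55, sd = 0.31, n_draws = 1000L, seed = 1L) {
  if (sd < 0) stop("sd must be >= 0", call. = FALSE)
  if (n_draws < 1) stop("n_draws must be >= 1", call. = FALSE)
  structure(list(mean = mean, sd = sd, n_draws = as.integer(n_draws),
                 seed = as.integer(seed)),
            class = "beta_draw_spec")
}

#' Drought-induced excess PM2.5
#'
#' @param beta Drought coefficient (ug/m3 per unit FHD).
#' @param fhd Fraction of hydropower capacity affected by drought, in
#'   `[0, 1]`.
#' @return Excess concentration `beta * fhd` (ug/m3).
#' @export
excess_pm <- function(beta, fhd) {
  stopifnot(all(fhd >= 0 & fhd <= 1, na.rm = TRUE))
  beta * fhd
}

#' Premature deaths from excess PM2.5 in one month
#'
#' `rate x days x excess x pop65 / 1e6`: the CRF daily rate scaled to
#' monthly frequency, times the exposed population 65+ in millions.
#'
#' @param excess Excess PM2.5 (ug/m3).
#' @param pop65 Exposed population aged 65+ (persons).
#' @param crf A [crf_spec()].
#' @return Premature deaths per month (persons; fractional).
#' @export
pm_deaths <- function(excess, pop65, crf = crf_spec()) {
  stopifnot(all(pop65 >= 0, na.rm = TRUE))
  crf$rate * crf$days * excess * pop65 / 1e6
}

#' Monte-Carlo mortality counterfactual
#'
#' Draws the drought coefficient `n_draws` times and converts each draw into
#' premature deaths for every plant-month (or directly at an aggregate
#' level, exactly equivalent by linearity of the death formula in the
#' coefficient).
#'
#' @param burden Tibble with one row per plant-month: `plant_id`, `market`
#'   (country), `year`, `month`, `fhd` (in `[0, 1]`), `pop65`.
#' @param crf A [crf_spec()].
#' @param draws A [beta_draw_spec()].
#' @param level Output resolution: `"plant-month"`, `"plant"`,
#'   `"country-year"` or `"region-year"` (region = whole study area).
#' @return Tibble of class `health_draws` with one row per draw x unit:
#'   `draw`, the level keys, `excess_pm` (the drawn coefficient times the
#'   mean FHD of the unit) and `deaths`.
#' @export
monte_carlo_deaths <- function(burden, crf = crf_spec(),
                               draws = beta_draw_spec(),
                               level = c("plant-month", "plant",
                                         "country-year", "region-year")) {
  level <- match.arg(level)
  burden <- tibble::as_tibble(burden)
  need <- c("plant_id", "market", "year", "month", "fhd", "pop65")
  miss <- setdiff(need, names(burden))
  if (length(miss)) stop("burden table missing columns: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (anyNA(burden$fhd) || anyNA(burden$pop65)) {
    stop("burden table has missing FHD or population; filter first", call. = FALSE)
  }
  beta_d <- with_seed(draws$seed, stats::rnorm(draws$n_draws, draws$mean, draws$sd))

  # deaths are linear in the drawn coefficient: deaths = draw * base
  burden$base <- crf$rate * crf$days * burden$fhd * burden$pop65 / 1e6
  keyed <- switch(level,
    "plant-month" = burden[, c("plant_id", "market", "year", "month", "fhd", "base")],
    "plant" = dplyr::summarise(dplyr::group_by(burden, .data$plant_id, .data$market),
                               fhd = mean(.data$fhd), base = sum(.data$base),
                               .groups = "drop"),
    "country-year" = dplyr::summarise(dplyr::group_by(burden, .data$market, .data$year),
                                      fhd = mean(.data$fhd), base = sum(.data$base),
                                      .groups = "drop"),
    "region-year" = dplyr::summarise(dplyr::group_by(burden, .data$year),
                                     fhd = mean(.data$fhd), base = sum(.data$base),
                                     .groups = "drop")
  )
  n_u <- nrow(keyed)
  out <- keyed[rep(seq_len(n_u), times = draws$n_draws), , drop = FALSE]
  out$draw <- rep(seq_len(draws$n_draws), each = n_u)
  out$beta <- rep(beta_d, each = n_u)
  out$excess_pm <- out$beta * out$fhd
  out$deaths <- out$beta * out$base
  out$base <- NULL
  out <- dplyr::relocate(out, "draw")
  attr(out, "beta_draws") <- beta_d
  attr(out, "level") <- level
  class(out) <- c("health_draws", class(out))
  out
}

#' Summarise Monte-Carlo draws
#'
#' @param draw_tbl A `health_draws` table.
#' @param level Aggregation keys: `"plant"`, `"country-year"`,
#'   `"region-year"`, or any character vector of key columns present in the
#'   table (summaries are over draws within key after summing deaths across
#'   finer units within each draw).
#' @param statistic One or more of `"mean"`, `"median"`, `"quantiles"`.
#' @param probs Quantile probabilities when `"quantiles"` is requested.
#' @return Tibble of per-key summaries of deaths across draws.
#' @export
aggregate_draws <- function(draw_tbl, level = "region-year",
                            statistic = c("mean", "median"),
                            probs = c(0.25, 0.75)) {
  keys <- switch(level,
                 "plant" = c("plant_id", "market"),
                 "country-year" = c("market", "year"),
                 "region-year" = "year",
                 level)
  miss <- setdiff(keys, names(draw_tbl))
  if (length(miss)) stop("unknown aggregation keys: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  per_draw <- dplyr::summarise(
    dplyr::group_by(draw_tbl, dplyr::across(dplyr::all_of(c("draw", keys)))),
    deaths = sum(.data$deaths), .groups = "drop")
  g <- dplyr::group_by(per_draw, dplyr::across(dplyr::all_of(keys)))
  out <- dplyr::summarise(g, n_draws = dplyr::n(), .groups = "drop")
  if ("mean" %in% statistic) {
    out$mean_deaths <- dplyr::summarise(g, v = mean(.data$deaths),
                                        .groups = "drop")$v
  }
  if ("median" %in% statistic) {
    out$median_deaths <- dplyr::summarise(g, v = stats::median(.data$deaths),
                                          .groups = "drop")$v
  }
  if ("quantiles" %in% statistic) {
    for (p in probs) {
      out[[sprintf("q%02d_deaths", round(100 * p))]] <-
        dplyr::summarise(g, v = unname(stats::quantile(.data$deaths, p)),
                         .groups = "drop")$v
    }
  }
  out
}
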