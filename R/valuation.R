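#' Value-of-statistical-life specification
#'
#' Country-year VSLs are extrapolated from a US base value using income
#' ratios: `VSL_cy = base * (GNI_cy / GNI_US,y) ^ elasticity`, with unit
#' income elasticity by default.  All values are constant 2019 USD; inputs
#' must be pre-deflated.
#'
#' @param base_vsl_usd2019 US base VSL in 2019 USD.  The default of 7.0e6 is
#'   a placeholder of the right order of magnitude and is NOT an
#'   authoritative estimate; supply the meta-analytic base value you intend
#'   to use.
#' @param income_elasticity Income elasticity of the VSL (>= 0).
#' @param gni Tibble (`country`, `year`, `gni_pc`) of GNI per capita.
#' @param us_gni Tibble (`year`, `gni_pc`) for the US.
#' @return A list of class `vsl_spec`.
#' @export
vsl_spec <- function(base_vsl_usd2019 = 7.0e6, income_elasticity = 1,
                     gni, us_gni) {
  if (base_vsl_usd2019 <= 0) stop("base VSL must be positive", call. = FALSE)
  if (income_elasticity < 0) stop("income elasticity must be >= 0", call. = FALSE)
  gni <- tibble::as_tibble(gni)
  us_gni <- tibble::as_tibble(us_gni)
  if (any(gni$gni_pc <= 0) || any(us_gni$gni_pc <= 0)) {
    stop("GNI per capita values must be positive", call. = FALSE)
  }
  structure(list(base_vsl = base_vsl_usd2019,
                 elasticity = income_elasticity,
                 gni = gni, us_gni = us_gni),
            class = "vsl_spec")
}

#' Country-year value of a statistical life
#'
#' @param spec A [vsl_spec()].
#' @param country,year Vectors (recycled together) identifying the
#'   country-years.
#' @return VSL in 2019 USD.
#' @export
country_vsl <- function(spec, country, year) {
  key <- paste(spec$gni$country, spec$gni$year)
  idx <- match(paste(country, year), key)
  us_idx <- match(year, spec$us_gni$year)
  if (anyNA(idx) || anyNA(us_idx)) {
    bad <- unique(paste(country, year)[is.na(idx) | is.na(us_idx)])
    stop("missing GNI per capita for: ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  spec$base_vsl * (spec$gni$gni_pc[idx] / spec$us_gni$gni_pc[us_idx])^spec$elasticity
}

#' Monetize premature deaths
#'
#' Multiplies each record's deaths by the country-year VSL; losses are in
#' constant 2019 USD.
#'
#' @param draw_tbl A `health_draws` table (or any tibble with `market`,
#'   `year`, `deaths`).
#' @param spec A [vsl_spec()].
#' @return The input with `vsl_usd2019` and `losses_usd2019` columns added.
#' @export
monetize <- function(draw_tbl, spec) {
  if (!all(c("market", "year", "deaths") %in% names(draw_tbl))) {
    stop("monetize needs `market`, `year` and `deaths` columns ",
         "(aggregate no further than country-year before valuation)",
         call. = FALSE)
  }
  draw_tbl$vsl_usd2019 <- country_vsl(spec, draw_tbl$market, draw_tbl$year)
  draw_tbl$losses_usd2019 <- draw_tbl$deaths * draw_tbl$vsl_usd2019
  draw_tbl
}
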