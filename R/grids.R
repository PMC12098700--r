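#' Gridded monthly fields
#'
#' A `field_grid` stores one gridded variable (runoff, PM2.5, fire emissions,
#' a meteorological field, ...) as a dense cell-by-month matrix together with
#' the cell coordinates.  This is the in-memory analogue of a small
#' NetCDF-style array with latitude/longitude/month coordinates.
#'
#' @param cells Data frame with columns `cell_id` (unique), `lon`, `lat`
#'   (decimal degrees, cell centers).
#' @param months Character vector of `"YYYY-MM"` labels (consecutive).
#' @param values Numeric matrix, `nrow(cells)` x `length(months)`.
#' @param unit Unit string, e.g. `"mm/h"` or `"ug/m3"`.
#' @param name Variable name.
#' @return An object of class `field_grid`.
#' @export
field_grid <- function(cells, months, values, unit = "", name = "") {
  cells <- tibble::as_tibble(cells)
  stopifnot(all(c("cell_id", "lon", "lat") %in% names(cells)))
  if (anyDuplicated(cells$cell_id)) stop("duplicate cell_id in grid", call. = FALSE)
  assert_month_run(months)
  values <- as.matrix(values)
  if (nrow(values) != nrow(cells) || ncol(values) != length(months)) {
    stop("`values` must be nrow(cells) x length(months)", call. = FALSE)
  }
  rownames(values) <- cells$cell_id
  colnames(values) <- months
  structure(list(cells = cells, months = months, values = values,
                 unit = unit, name = name),
            class = "field_grid")
}

#' @export
print.field_grid <- function(x, ...) {
  cat(sprintf("<field_grid '%s'> %d cells x %d months (%s .. %s)%s\n",
              x$name, nrow(x$cells), length(x$months),
              x$months[1L], x$months[length(x$months)],
              if (nzchar(x$unit)) paste0(" [", x$unit, "]") else ""))
  invisible(x)
}

#' Great-circle distances from a point to grid cells
#'
#' @param grid A `field_grid` (or anything with a `cells` data frame).
#' @param lon,lat Point coordinates in decimal degrees.
#' @return Numeric vector of haversine distances in kilometres, one per cell.
#' @export
cell_distances_km <- function(grid, lon, lat) {
  cells <- if (is.data.frame(grid)) grid else grid$cells
  geosphere::distHaversine(cbind(cells$lon, cells$lat), c(lon, lat)) / 1000
}

#' Convert a field grid to/from long format
#'
#' Long format (`cell_id`, `month`, `value`) is the package's delimited-text
#' interchange schema for gridded inputs.
#'
#' @param grid A `field_grid`.
#' @return A tibble with one row per cell-month.
#' @export
grid_to_long <- function(grid) {
  tibble::tibble(
    cell_id = rep(grid$cells$cell_id, times = length(grid$months)),
    lon = rep(grid$cells$lon, times = length(grid$months)),
    lat = rep(grid$cells$lat, times = length(grid$months)),
    month = rep(grid$months, each = nrow(grid$cells)),
    value = as.vector(grid$values)
  )
}

#' @rdname grid_to_long
#' @param long Long-format data frame with `cell_id`, `lon`, `lat`, `month`,
#'   `value`.
#' @inheritParams field_grid
#' @export
grid_from_long <- function(long, unit = "", name = "") {
  long <- tibble::as_tibble(long)
  cells <- dplyr::distinct(long, .data$cell_id, .data$lon, .data$lat)
  months <- sort(unique(long$month))
  values <- matrix(NA_real_, nrow(cells), length(months),
                   dimnames = list(cells$cell_id, months))
  values[cbind(match(long$cell_id, cells$cell_id), match(long$month, months))] <- long$value
  if (anyNA(values)) stop("long grid has missing cell-months", call. = FALSE)
  field_grid(cells, months, values, unit = unit, name = name)
}

#' Read/write a field grid as CSV
#'
#' @param path File path.
#' @inheritParams grid_to_long
#' @inheritParams field_grid
#' @export
write_grid_csv <- function(grid, path) {
  utils::write.csv(grid_to_long(grid), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_grid_csv
#' @export
read_grid_csv <- function(path, unit = "", name = "") {
  grid_from_long(utils::read.csv(path, stringsAsFactors = FALSE), unit = unit, name = name)
}
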