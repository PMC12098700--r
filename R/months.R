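#' Month-label utilities
#'
#' Months are represented throughout the package as `"YYYY-MM"` character
#' labels at monthly frequency.
#'
#' @param from,to First and last month, as `"YYYY-MM"`.
#' @return `month_seq()` returns a character vector of consecutive month
#'   labels, inclusive of both endpoints.
#' @examples
#' month_seq("2000-11", "2001-02")
#' @export
month_seq <- function(from, to) {
  d0 <- as.Date(paste0(from, "-01"))
  d1 <- as.Date(paste0(to, "-01"))
  if (is.na(d0) || is.na(d1) || d1 < d0) {
    stop("`from` and `to` must be valid 'YYYY-MM' labels with from <= to", call. = FALSE)
  }
  format(seq(d0, d1, by = "month"), "%Y-%m")
}

#' @rdname month_seq
#' @param month Character vector of `"YYYY-MM"` labels.
#' @return `month_year()` and `month_cal()` return integer years and
#'   calendar months (1-12); `month_days()` the number of calendar days.
#' @export
month_year <- function(month) as.integer(substr(month, 1L, 4L))

#' @rdname month_seq
#' @export
month_cal <- function(month) as.integer(substr(month, 6L, 7L))

#' @rdname month_seq
#' @export
month_days <- function(month) {
  y <- month_year(month)
  m <- month_cal(month)
  base <- c(31L, 28L, 31L, 30L, 31L, 30L, 31L, 31L, 30L, 31L, 30L, 31L)[m]
  leap <- (y %% 4L == 0L & y %% 100L != 0L) | (y %% 400L == 0L)
  base + ifelse(m == 2L & leap, 1L, 0L)
}

# Validate that labels form a gap-free monthly sequence.
assert_month_run <- function(month) {
  if (!identical(month, month_seq(month[1L], month[length(month)]))) {
    stop("month labels must form a consecutive monthly sequence", call. = FALSE)
  }
  invisible(month)
}
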