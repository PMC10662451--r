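#' Annual flux series
#'
#' A contiguous year-indexed series of fluxes (e.g. an in-country annual
#' bookkeeping estimate) used as the reference when rescaling estimates
#' reported over different periods.
#'
#' @param years Integer vector of contiguous calendar years.
#' @param values Numeric fluxes, one per year.
#' @param unit Unit string carried as metadata (default `"MgCO2e/yr"`).
#' @return An `annual_series` tibble with columns `year`, `value`.
#' @export
annual_series <- function(years, values, unit = "MgCO2e/yr") {
  years <- as.integer(years)
  if (!length(years)) stop("data error: series needs at least one year", call. = FALSE)
  if (length(years) != length(values)) {
    stop("data error: years and values differ in length", call. = FALSE)
  }
  o <- order(years)
  years <- years[o]; values <- values[o]
  if (length(years) > 1 && any(diff(years) != 1L)) {
    stop("data error: series years must be contiguous", call. = FALSE)
  }
  x <- tibble::tibble(year = years, value = as.numeric(values))
  attr(x, "unit") <- unit
  class(x) <- c("annual_series", class(x))
  x
}

# arithmetic mean over calendar years, both endpoints inclusive
series_mean <- function(series, period) {
  yrs <- period[1]:period[2]
  if (!all(yrs %in% series$year)) {
    stop(sprintf("data error: series does not cover %d-%d", period[1], period[2]),
         call. = FALSE)
  }
  mean(series$value[match(yrs, series$year)])
}

#' Rescale a period-average flux to a different period
#'
#' Multiplies a flux reported as an average over `short_period` by the
#' fractional difference of a reference annual series between the target and
#' short periods: `x * mean(ref over target) / mean(ref over short)`. Applied
#' independently to gross emissions and gross removals (and per region); the
#' net flux is recomputed afterwards, never rescaled directly.
#'
#' @param x_short Flux (average-annual) over `short_period`; vectorized.
#' @param ref An [annual_series] covering both periods.
#' @param short_period,target_period Integer `c(start, end)` year ranges.
#' @return Rescaled flux over `target_period`.
#' @export
fractional_rescale <- function(x_short, ref, short_period, target_period) {
  m_short <- series_mean(ref, short_period)
  m_target <- series_mean(ref, target_period)
  if (m_short == 0) {
    stop("undefined-scaling error: reference mean over the short period is zero",
         call. = FALSE)
  }
  x_short * m_target / m_short
}

#' Extend an annual series by repeating its last value
#'
#' Years from the series end up to `to_year` carry the last reported value;
#' earlier values are untouched. Used to carry a final inventory year forward
#' so that periods align (idempotent).
#'
#' @param series An [annual_series].
#' @param to_year Final year of the extended series (>= the series start).
#' @return An [annual_series] ending at `to_year`.
#' @export
extend_last_year <- function(series, to_year) {
  last <- max(series$year)
  if (to_year < min(series$year)) {
    stop("argument error: to_year precedes the series start", call. = FALSE)
  }
  if (to_year <= last) return(series)
  extra <- (last + 1L):to_year
  annual_series(c(series$year, extra),
                c(series$value, rep(series$value[series$year == last], length(extra))),
                unit = attr(series, "unit"))
}

#' Read/write an annual series as a two-column CSV (`year`, `value`)
#'
#' @param series An [annual_series].
#' @param path File path.
#' @param unit Unit metadata applied on read.
#' @return The series (read) or `path` invisibly (write).
#' @export
write_series <- function(series, path) {
  utils::write.csv(series[c("year", "value")], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname write_series
#' @export
read_series <- function(path, unit = "MgCO2e/yr") {
  df <- utils::read.csv(path)
  annual_series(df$year, df$value, unit = unit)
}
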