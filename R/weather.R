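#' Column mapping for weather tables
#'
#' Describes how the columns of a daily weather CSV map onto the fields the
#' package needs (date, tmin, tmax, precip, optional snow), what units the
#' temperatures are in, and the date format. The default matches the
#' station-export dialect `date,tmin_c,tmax_c,precip_mm,snow_mm`.
#'
#' @param date,tmin,tmax,precip,snow Column names in the source table. `snow`
#'   may be absent from the file.
#' @param units `"C"` or `"F"`; Fahrenheit temperatures are converted on read.
#' @param date_format A `strptime` format string.
#' @return A list of class `weather_dialect`.
#' @export
weather_dialect <- function(date = "date", tmin = "tmin_c", tmax = "tmax_c",
                            precip = "precip_mm", snow = "snow_mm",
                            units = c("C", "F"), date_format = "%Y-%m-%d") {
  units <- match.arg(units)
  structure(list(date = date, tmin = tmin, tmax = tmax, precip = precip,
                 snow = snow, units = units, date_format = date_format),
            class = "weather_dialect")
}

#' Read a weather dialect from a small YAML config file
#'
#' Keys: `date`, `tmin`, `tmax`, `precip`, `snow`, `units`, `date_format`;
#' missing keys take the [weather_dialect()] defaults.
#'
#' @param path Path to a YAML file.
#' @return A `weather_dialect`.
#' @export
read_weather_dialect <- function(path) {
  cfg <- yaml::read_yaml(path)
  allowed <- c("date", "tmin", "tmax", "precip", "snow", "units", "date_format")
  bad <- setdiff(names(cfg), allowed)
  if (length(bad)) stop("unknown dialect keys: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  do.call(weather_dialect, cfg)
}

#' Construct a weather series from columns
#'
#' @param date Vector of `Date`s.
#' @param tmin,tmax Daily temperatures, degC.
#' @param precip Daily precipitation, mm (rain water).
#' @param snow Optional daily snowfall, mm.
#' @param station_id Station label.
#' @return A `weather_series` data frame sorted by date.
#' @export
weather_series <- function(date, tmin, tmax, precip, snow = NULL,
                           station_id = "station") {
  df <- data.frame(date = as.Date(date), tmin = as.numeric(tmin),
                   tmax = as.numeric(tmax), precip = as.numeric(precip))
  if (!is.null(snow)) df$snow <- as.numeric(snow)
  df <- df[order(df$date), , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "station_id") <- station_id
  class(df) <- c("weather_series", "data.frame")
  df
}

#' Read a daily weather table
#'
#' Parses a CSV with a header row into a [weather_series], applying a column
#' mapping and unit conversion. Rows whose date or numbers cannot be parsed
#' are dropped with a warning naming their row indices; validation of the
#' physical invariants (tmin <= tmax, calendar continuity) is deferred to
#' [validate_and_fill()].
#'
#' @param source File path or connection to CSV text with a header row.
#' @param dialect A [weather_dialect()].
#' @param station_id Station label attached to the result.
#' @return A `weather_series`, sorted ascending by date.
#' @export
read_weather_table <- function(source, dialect = weather_dialect(),
                               station_id = "station") {
  raw <- tryCatch(
    utils::read.csv(source, stringsAsFactors = FALSE, check.names = FALSE),
    error = function(e) stop("cannot read weather table: ", conditionMessage(e),
                             call. = FALSE))
  required <- c("date", "tmin", "tmax", "precip")
  for (f in required) {
    if (!dialect[[f]] %in% names(raw)) {
      stop(sprintf("weather table is missing required column '%s' (field %s)",
                   dialect[[f]], f), call. = FALSE)
    }
  }
  date <- as.Date(raw[[dialect$date]], format = dialect$date_format)
  tmin <- suppressWarnings(as.numeric(raw[[dialect$tmin]]))
  tmax <- suppressWarnings(as.numeric(raw[[dialect$tmax]]))
  precip <- suppressWarnings(as.numeric(raw[[dialect$precip]]))
  has_snow <- dialect$snow %in% names(raw)
  snow <- if (has_snow) suppressWarnings(as.numeric(raw[[dialect$snow]])) else NULL

  bad <- is.na(date) | is.na(tmin) | is.na(tmax) | is.na(precip)
  if (any(bad)) {
    warning("dropped ", sum(bad), " unparseable row(s): index ",
            paste(utils::head(which(bad), 10), collapse = ", "),
            if (sum(bad) > 10) ", ..." else "", call. = FALSE)
  }
  keep <- !bad
  if (dialect$units == "F") {
    tmin <- (tmin - 32) * 5 / 9
    tmax <- (tmax - 32) * 5 / 9
  }
  weather_series(date[keep], tmin[keep], tmax[keep], precip[keep],
                 snow = if (has_snow) snow[keep] else NULL,
                 station_id = station_id)
}

#' Write a weather series to CSV
#'
#' Writes the default-dialect columns `date,tmin_c,tmax_c,precip_mm[,snow_mm]`
#' so that [read_weather_table()] round-trips the series.
#'
#' @param series A `weather_series`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_weather_table <- function(series, path) {
  df <- as.data.frame(series)
  out <- data.frame(date = format(df$date, "%Y-%m-%d"),
                    tmin_c = df$tmin, tmax_c = df$tmax, precip_mm = df$precip)
  if ("snow" %in% names(df)) out$snow_mm <- df$snow
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Validate a weather series and fill short calendar gaps
#'
#' Enforces the physical invariants of a daily weather record: `tmin <= tmax`
#' on every day, non-negative precipitation, and calendar continuity.
#' Records violating `tmin <= tmax` are removed (sensor errors should not
#' silently become data); set `drop_invalid = FALSE` to make them fatal
#' instead. Calendar gaps of at most `max_gap` missing days are filled by
#' linear interpolation of `tmin` and `tmax` between the flanking days, with
#' precipitation (and snowfall) set to 0 on filled days so that invented
#' rainfall cannot bias downstream covariates. Longer gaps are a
#' data-quality failure and raise an error naming the span.
#'
#' @param series A `weather_series`.
#' @param max_gap Longest fillable run of missing calendar days (default 3).
#' @param drop_invalid If `TRUE` (default), drop `tmin > tmax` records with a
#'   warning; if `FALSE`, raise an error.
#' @return A `weather_series` with consecutive dates; idempotent.
#' @export
validate_and_fill <- function(series, max_gap = 3, drop_invalid = TRUE) {
  df <- as.data.frame(series)
  if (nrow(df) == 0) stop("empty weather series", call. = FALSE)
  if (anyDuplicated(df$date)) {
    stop("duplicate dates in weather series: ",
         paste(format(df$date[duplicated(df$date)]), collapse = ", "),
         call. = FALSE)
  }
  bad <- df$tmin > df$tmax
  if (any(bad)) {
    msg <- paste0(sum(bad), " record(s) with tmin > tmax (",
                  paste(format(df$date[bad]), collapse = ", "), ")")
    if (!drop_invalid) stop(msg, call. = FALSE)
    warning("removed ", msg, call. = FALSE)
    df <- df[!bad, , drop = FALSE]
    if (nrow(df) == 0) stop("no valid records remain", call. = FALSE)
  }
  if (any(df$precip < 0, na.rm = TRUE)) {
    stop("negative precipitation values present", call. = FALSE)
  }
  full <- seq(min(df$date), max(df$date), by = "day")
  missing <- setdiff(as.character(full), as.character(df$date))
  if (length(missing)) {
    runs <- split(as.Date(missing),
                  cumsum(c(TRUE, diff(as.Date(missing)) > 1)))
    too_long <- Filter(function(r) length(r) > max_gap, runs)
    if (length(too_long)) {
      spans <- vapply(too_long, function(r) {
        sprintf("%s..%s (%d days)", min(r), max(r), length(r))
      }, character(1))
      stop("calendar gap(s) longer than max_gap = ", max_gap, ": ",
           paste(spans, collapse = "; "), call. = FALSE)
    }
    filled <- data.frame(date = full)
    filled$tmin <- stats::approx(df$date, df$tmin, xout = full)$y
    filled$tmax <- stats::approx(df$date, df$tmax, xout = full)$y
    filled$precip <- 0
    present <- match(df$date, full)
    filled$precip[present] <- df$precip
    if ("snow" %in% names(df)) {
      filled$snow <- 0
      filled$snow[present] <- df$snow
    }
    df <- filled
  }
  weather_series(df$date, df$tmin, df$tmax, df$precip,
                 snow = if ("snow" %in% names(df)) df$snow else NULL,
                 station_id = attr(series, "station_id") %||% "station")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
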