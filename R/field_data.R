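#' Read a sweep-net capture table
#'
#' Expects a CSV with header `site_id,date,count` (count = adult WSS per 100
#' sweeps). A `year` column is derived from the date. Already-annotated
#' tables (with `cum_gdd`, `cum_precip`) are passed through.
#'
#' @param source File path or connection.
#' @return A data frame with columns `site_id`, `date`, `year`, `count`
#'   (plus any annotation columns present in the file).
#' @export
read_sweep_table <- function(source) {
  raw <- utils::read.csv(source, stringsAsFactors = FALSE)
  for (f in c("site_id", "date", "count")) {
    if (!f %in% names(raw)) {
      stop("sweep table is missing required column '", f, "'", call. = FALSE)
    }
  }
  raw$date <- as.Date(raw$date)
  if (any(is.na(raw$date))) stop("unparseable dates in sweep table", call. = FALSE)
  if (any(raw$count < 0)) stop("negative capture counts", call. = FALSE)
  raw$year <- as.integer(format(raw$date, "%Y"))
  cols <- c("site_id", "date", "year", "count",
            intersect(c("cum_gdd", "cum_precip"), names(raw)))
  raw[, cols, drop = FALSE]
}

#' Write sweep samples to CSV
#'
#' @param samples Sweep-sample data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sweep_table <- function(samples, path) {
  out <- samples
  out$date <- format(out$date, "%Y-%m-%d")
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Annotate sweep samples with cumulative degree-days and precipitation
#'
#' Joins each capture record to the degree-day and weather series of its
#' year, attaching `cum_gdd` (cumulative degree-days on the sampling date)
#' and `cum_precip` (total rainfall from the biofix through the sampling
#' date, mm).
#'
#' @param samples Sweep-sample data frame (`site_id`, `date`, `year`, `count`).
#' @param gdd A `gdd_series` from [accumulate_gdd()] covering the sample dates.
#' @param weather The validated `weather_series` the degree-days came from.
#' @return `samples` with `cum_gdd` and `cum_precip` columns added.
#' @export
annotate_samples <- function(samples, gdd, weather) {
  wdf <- as.data.frame(weather)
  idx <- match(samples$date, gdd$date)
  if (any(is.na(idx))) {
    miss <- samples[is.na(idx), , drop = FALSE][1, ]
    stop(sprintf(
      "sample at site %s on %s is outside degree-day coverage (biofix onward)",
      miss$site_id, format(miss$date)), call. = FALSE)
  }
  samples$cum_gdd <- gdd$cumulative_dd[idx]
  # cumulative rainfall from each year's biofix through the sample date
  params <- attr(gdd, "params") %||% degree_day_params()
  cum_p <- vapply(seq_len(nrow(samples)), function(i) {
    y <- samples$year[i]
    biofix <- as.Date(sprintf("%d-%02d-%02d", y, params$biofix_month,
                              params$biofix_day))
    sel <- wdf$date >= biofix & wdf$date <= samples$date[i]
    if (!any(sel) || min(wdf$date) > biofix) {
      stop(sprintf(
        "sample at site %s on %s is outside weather coverage from biofix %s",
        samples$site_id[i], format(samples$date[i]), format(biofix)),
        call. = FALSE)
    }
    sum(wdf$precip[sel])
  }, numeric(1))
  samples$cum_precip <- cum_p
  samples
}

#' Cumulative-proportion emergence curve
#'
#' Pools capture records across sites and years, sorts them by cumulative
#' degree-days, merges ties at identical `cum_gdd` (counts summed, so the
#' curve is a function of GDD), and converts the running capture total into
#' a cumulative proportion of all captures. This is the transform behind the
#' probit characterisation of the flight.
#'
#' @param samples Annotated sweep samples (must carry `cum_gdd`).
#' @return A `cumulative_curve`: data frame with columns `cum_gdd`,
#'   `captures`, `cum_captures`, `cum_proportion`, with attribute
#'   `total_captures`.
#' @export
#' @examples
#' s <- data.frame(cum_gdd = c(100, 150, 200, 250), count = c(0, 5, 5, 10))
#' cumulative_proportion(s)$cum_proportion
cumulative_proportion <- function(samples) {
  if (!"cum_gdd" %in% names(samples)) {
    stop("samples must be annotated with cum_gdd first", call. = FALSE)
  }
  total <- sum(samples$count)
  if (total <= 0) stop("all capture counts are zero; no emergence curve exists",
                       call. = FALSE)
  agg <- stats::aggregate(count ~ cum_gdd, data = samples, FUN = sum)
  agg <- agg[order(agg$cum_gdd), , drop = FALSE]
  out <- data.frame(cum_gdd = agg$cum_gdd, captures = agg$count,
                    cum_captures = cumsum(agg$count))
  out$cum_proportion <- out$cum_captures / total
  rownames(out) <- NULL
  attr(out, "total_captures") <- total
  class(out) <- c("cumulative_curve", "data.frame")
  out
}

#' Captures before degree-day cutpoints
#'
#' For each cutpoint, counts the captures that occurred strictly before that
#' cumulative-GDD value and reports the fraction of all captures. "Before X
#' GDD" is strict (`cum_gdd < X`).
#'
#' @param samples Annotated sweep samples.
#' @param thresholds Numeric vector of cumulative-GDD cutpoints.
#' @return Data frame with columns `cutpoint`, `captures_before`,
#'   `fraction_before`.
#' @export
#' @examples
#' s <- data.frame(cum_gdd = c(100, 200, 300), count = c(10, 20, 70))
#' capture_fractions(s, c(150, 250))
capture_fractions <- function(samples, thresholds) {
  if (nrow(samples) == 0) stop("no samples", call. = FALSE)
  if (!"cum_gdd" %in% names(samples)) {
    stop("samples must be annotated with cum_gdd first", call. = FALSE)
  }
  total <- sum(samples$count)
  res <- vapply(thresholds, function(x) sum(samples$count[samples$cum_gdd < x]),
                numeric(1))
  data.frame(cutpoint = thresholds, captures_before = res,
             fraction_before = if (total > 0) res / total else NA_real_)
}

#' Captures within a degree-day interval
#'
#' Closed-interval query, e.g. peak plus or minus 10 GDD.
#'
#' @param samples Annotated sweep samples.
#' @param center Interval midpoint (cumulative GDD).
#' @param halfwidth Interval half-width (GDD).
#' @return One-row data frame: `lower`, `upper`, `captures`, `fraction`.
#' @export
capture_interval <- function(samples, center, halfwidth) {
  if (nrow(samples) == 0) stop("no samples", call. = FALSE)
  total <- sum(samples$count)
  lo <- center - halfwidth; hi <- center + halfwidth
  n <- sum(samples$count[samples$cum_gdd >= lo & samples$cum_gdd <= hi])
  data.frame(lower = lo, upper = hi, captures = n,
             fraction = if (total > 0) n / total else NA_real_)
}
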