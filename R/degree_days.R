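#' Degree-day accumulation parameters
#'
#' Bundles the thermal thresholds, biofix, and method used to turn daily
#' minimum/maximum temperatures into degree-days. The defaults (base 10 degC,
#' upper threshold 30 degC, biofix January 1, single-sine method) are the
#' standard settings for wheat stem sawfly phenology in winter wheat: the
#' larval diapause is broken by sustained development near 10 degC and larval
#' development is optimal near 30 degC.
#'
#' @param base Lower developmental threshold, degC. Temperature below this
#'   contributes no thermal time.
#' @param upper Upper threshold, degC. Temperature above this contributes as
#'   if it equalled `upper` (horizontal cutoff).
#' @param biofix Month-day string `"MM-DD"` at which accumulation restarts
#'   each calendar year.
#' @param method `"single-sine"` (default) or `"simple-average"`.
#' @return An object of class `degree_day_params`.
#' @export
#' @examples
#' degree_day_params()
#' degree_day_params(base = 50, upper = 86) # Fahrenheit thresholds
degree_day_params <- function(base = 10, upper = 30, biofix = "01-01",
                              method = c("single-sine", "simple-average")) {
  method <- match.arg(method)
  if (!is.numeric(base) || !is.numeric(upper) || base >= upper) {
    stop("`base` must be numeric and strictly below `upper`", call. = FALSE)
  }
  md <- parse_month_day(biofix)
  structure(
    list(base = base, upper = upper, biofix = biofix,
         biofix_month = md[1], biofix_day = md[2], method = method),
    class = "degree_day_params"
  )
}

parse_month_day <- function(x) {
  if (!is.character(x) || length(x) != 1 ||
      !grepl("^[0-9]{2}-[0-9]{2}$", x)) {
    stop("biofix must be a 'MM-DD' string", call. = FALSE)
  }
  md <- as.integer(strsplit(x, "-", fixed = TRUE)[[1]])
  # validate against a non-leap year; Feb 29 is disallowed as a biofix
  probe <- tryCatch(as.Date(sprintf("2001-%02d-%02d", md[1], md[2])),
                    error = function(e) as.Date(NA))
  if (is.na(probe)) stop("biofix '", x, "' is not a valid month-day", call. = FALSE)
  md
}

#' @export
print.degree_day_params <- function(x, ...) {
  cat(sprintf("Degree-day parameters: base %g, upper %g, biofix %s, %s method\n",
              x$base, x$upper, x$biofix, x$method))
  invisible(x)
}

#' Daily degree-days by the single-sine method with horizontal cutoff
#'
#' Models the within-day temperature trajectory as one symmetric sine wave
#' between `tmin` and `tmax` and returns the area (in degC-days) between that
#' curve and the base threshold, truncating the curve at the upper threshold.
#' The value is the closed-form evaluation of
#' \deqn{\frac{1}{2\pi}\int_0^{2\pi} \max\{0, \min(T(t), U) - B\}\,dt,}
#' where \eqn{T(t) = M + A\sin t}, \eqn{M = (t_{max}+t_{min})/2} and
#' \eqn{A = (t_{max}-t_{min})/2}, handled by the six-case analysis on the
#' position of `tmin`/`tmax` relative to the two thresholds (the
#' Baskerville-Emin construction extended with a horizontal upper cutoff).
#'
#' @param tmin,tmax Daily minimum and maximum temperature, degC (vectorised;
#'   `tmin <= tmax` elementwise).
#' @param base,upper Thresholds, degC, with `base < upper`.
#' @return Numeric vector of daily degree-days, each in `[0, upper - base]`.
#' @export
#' @examples
#' daily_single_sine_dd(10, 30)            # curve between thresholds: 10
#' daily_single_sine_dd(0, 20)             # base-intercepted: 10/pi
#' daily_single_sine_dd(32, 40)            # saturated: upper - base
daily_single_sine_dd <- function(tmin, tmax, base = 10, upper = 30) {
  if (!is.numeric(base) || !is.numeric(upper) ||
      length(base) != 1 || length(upper) != 1 || base >= upper) {
    stop("`base` must be strictly below `upper`", call. = FALSE)
  }
  n <- max(length(tmin), length(tmax))
  tmin <- rep_len(tmin, n); tmax <- rep_len(tmax, n)
  if (any(tmin > tmax, na.rm = TRUE)) {
    stop("tmin > tmax for ", sum(tmin > tmax, na.rm = TRUE), " day(s)",
         call. = FALSE)
  }
  m <- (tmax + tmin) / 2
  a <- (tmax - tmin) / 2
  dd <- rep(NA_real_, n)

  below    <- !is.na(tmax) & tmax <= base
  above    <- !is.na(tmin) & tmin >= upper
  interior <- !is.na(tmin) & !below & !above & tmin >= base & tmax <= upper
  base_cut <- !is.na(tmin) & tmin < base & tmax > base & tmax <= upper
  up_cut   <- !is.na(tmin) & tmin >= base & tmin < upper & tmax > upper
  both_cut <- !is.na(tmin) & tmin < base & tmax > upper

  dd[below] <- 0
  dd[above] <- upper - base
  dd[interior] <- m[interior] - base

  if (any(base_cut)) {
    i <- base_cut
    t1 <- asin(clamp1((base - m[i]) / a[i]))
    dd[i] <- ((m[i] - base) * (pi / 2 - t1) + a[i] * cos(t1)) / pi
  }
  if (any(up_cut)) {
    i <- up_cut
    t2 <- asin(clamp1((upper - m[i]) / a[i]))
    dd[i] <- ((m[i] - base) * (t2 + pi / 2) +
                (upper - base) * (pi / 2 - t2) - a[i] * cos(t2)) / pi
  }
  if (any(both_cut)) {
    i <- both_cut
    t1 <- asin(clamp1((base - m[i]) / a[i]))
    t2 <- asin(clamp1((upper - m[i]) / a[i]))
    dd[i] <- ((m[i] - base) * (t2 - t1) + a[i] * (cos(t1) - cos(t2)) +
                (upper - base) * (pi / 2 - t2)) / pi
  }
  # guard against -0 and tiny negative rounding in the near-degenerate cases
  pmin(pmax(dd, 0), upper - base)
}

clamp1 <- function(x) pmin(1, pmax(-1, x))

#' Daily degree-days by the simple-average method
#'
#' The traditional baseline: `max(0, min((tmax + tmin) / 2, upper) - base)`.
#' Included for comparison only; the single-sine method approximates true
#' thermal accumulation more closely when the daily trajectory crosses a
#' threshold.
#'
#' @inheritParams daily_single_sine_dd
#' @return Numeric vector of daily degree-days.
#' @export
daily_simple_average_dd <- function(tmin, tmax, base = 10, upper = 30) {
  if (base >= upper) stop("`base` must be strictly below `upper`", call. = FALSE)
  n <- max(length(tmin), length(tmax))
  tmin <- rep_len(tmin, n); tmax <- rep_len(tmax, n)
  if (any(tmin > tmax, na.rm = TRUE)) stop("tmin > tmax", call. = FALSE)
  pmax(0, pmin((tmax + tmin) / 2, upper) - base)
}

#' Accumulate degree-days from the biofix
#'
#' Computes daily degree-days for every day of a validated weather series and
#' the running (cumulative) total within each calendar year, restarting at
#' the biofix. Days before the biofix in a given year are excluded. Years
#' whose records begin after the biofix carry no valid accumulation and are
#' omitted from the output (they may still serve as context, e.g. prior
#' autumn weather for winter snowfall sums); if no year in the series covers
#' its biofix, a coverage error is raised.
#'
#' @param series A [weather_series] (validated; see [validate_and_fill()]).
#' @param params A [degree_day_params] object.
#' @return A `gdd_series`: a data frame with columns `date`, `year`,
#'   `daily_dd`, `cumulative_dd`, carrying `params` as an attribute.
#' @export
#' @examples
#' ws <- simulate_weather(weather_scenario(seed = 1), 2020)
#' gdd <- accumulate_gdd(ws, degree_day_params())
#' head(gdd)
accumulate_gdd <- function(series, params = degree_day_params()) {
  stopifnot(inherits(params, "degree_day_params"))
  df <- as.data.frame(series)
  if (nrow(df) == 0) stop("empty weather series", call. = FALSE)
  yrs <- as.integer(format(df$date, "%Y"))
  out <- lapply(sort(unique(yrs)), function(y) {
    biofix <- as.Date(sprintf("%d-%02d-%02d", y, params$biofix_month,
                              params$biofix_day))
    if (min(df$date[yrs == y]) > biofix) return(NULL)
    sub <- df[yrs == y & df$date >= biofix, , drop = FALSE]
    daily <- switch(params$method,
      "single-sine" = daily_single_sine_dd(sub$tmin, sub$tmax,
                                           params$base, params$upper),
      "simple-average" = daily_simple_average_dd(sub$tmin, sub$tmax,
                                                 params$base, params$upper))
    data.frame(date = sub$date, year = y, daily_dd = daily,
               cumulative_dd = cumsum(daily))
  })
  out <- Filter(Negate(is.null), out)
  if (length(out) == 0) {
    stop(sprintf(
      "no year in the series covers its biofix (%s); series starts %s, first missing date is %d-%s",
      params$biofix, min(df$date), min(yrs), params$biofix), call. = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "params") <- params
  class(res) <- c("gdd_series", "data.frame")
  res
}

#' First date on which cumulative degree-days reach a target
#'
#' @param gdd A `gdd_series` from [accumulate_gdd()].
#' @param target Cumulative degree-day threshold (degC-days).
#' @return Data frame with one row per year: `year`, `date` (first date with
#'   `cumulative_dd >= target`; `NA` if never reached), `cumulative_dd`.
#' @export
threshold_date <- function(gdd, target) {
  stopifnot(is.numeric(target), length(target) == 1, target >= 0)
  res <- lapply(split(gdd, gdd$year), function(g) {
    hit <- which(g$cumulative_dd >= target)
    if (length(hit) == 0) {
      data.frame(year = g$year[1], date = as.Date(NA), cumulative_dd = NA_real_)
    } else {
      data.frame(year = g$year[1], date = g$date[hit[1]],
                 cumulative_dd = g$cumulative_dd[hit[1]])
    }
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Convert Celsius degree-days to Fahrenheit degree-days
#'
#' Degree-day totals scale by the ratio of the temperature intervals, so the
#' conversion is a pure factor of 9/5 with no offset: a model stated as
#' 148/224/354 GDD (base 10 degC, upper 30 degC) is equivalently 266/403/637
#' FDD (base 50 degF, upper 86 degF) after integer rounding.
#'
#' @param gdd_c Non-negative Celsius degree-day value(s).
#' @return `gdd_c * 9 / 5`, in degF-days.
#' @export
#' @examples
#' round(celsius_to_fahrenheit_dd(c(148, 224, 354)))
celsius_to_fahrenheit_dd <- function(gdd_c) {
  if (any(gdd_c < 0, na.rm = TRUE)) {
    stop("degree-day values must be non-negative", call. = FALSE)
  }
  gdd_c * 9 / 5
}
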