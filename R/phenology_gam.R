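#' Bin cumulative degree-days into factor levels
#'
#' The coefficient-isolation model treats cumulative GDD as a random-effect
#' factor, so the continuous axis is discretised into left-closed bins
#' `[k*w, (k+1)*w)` labelled by their midpoints. The default width of 10 GDD
#' is roughly two days of accumulation near the flight, balancing resolution
#' against the number of observations per level.
#'
#' @param samples Annotated sweep samples (with `cum_gdd`).
#' @param bin_width Bin width in degree-days (> 0; default 10).
#' @return `samples` with a numeric `gdd_bin` column holding bin midpoints.
#' @export
#' @examples
#' bin_gdd(data.frame(cum_gdd = c(223.4, 220, 219.9)), 10)$gdd_bin
bin_gdd <- function(samples, bin_width = 10) {
  if (!is.numeric(bin_width) || length(bin_width) != 1 || bin_width <= 0) {
    stop("bin_width must be a positive number", call. = FALSE)
  }
  if (!"cum_gdd" %in% names(samples)) {
    stop("samples must be annotated with cum_gdd first", call. = FALSE)
  }
  samples$gdd_bin <- floor(samples$cum_gdd / bin_width) * bin_width +
    bin_width / 2
  attr(samples, "gdd_bin_width") <- bin_width
  samples
}

#' Poisson random-effects capture model with an isolated degree-day term
#'
#' Fits captures per 100 sweeps as Poisson counts with a log link and
#' independent random intercepts for the GDD bin, a cumulative-precipitation
#' bin, the site-by-year combination, and the site:
#' `count ~ 1 + (1 | gdd_bin) + (1 | precip_bin) + (1 | site_year) + (1 | site_id)`.
#' The non-GDD terms are present only to absorb variance associated with
#' precipitation, year-to-year magnitude, and site, so that the predicted
#' random-effect coefficients (conditional modes) of the GDD bins isolate
#' the relative over/under-abundance of captures at each degree-day
#' accumulation. Those coefficients, centred to mean zero across bins, are
#' the input to [smooth_and_detect()].
#'
#' @param samples Binned sweep samples (see [bin_gdd()]); must carry
#'   `cum_precip`, `site_id`, `year`, integer-valued `count`.
#' @param precip_bin_width Width of the cumulative-precipitation bins, mm
#'   (default 10).
#' @return A `gdd_coefficients` data frame: `bin_center`, `coefficient`,
#'   `n_obs`, with the fitted `merMod` in attribute `"model"`.
#' @export
fit_capture_model <- function(samples, precip_bin_width = 10) {
  for (f in c("gdd_bin", "cum_precip", "site_id", "year", "count")) {
    if (!f %in% names(samples)) {
      stop("samples are missing column '", f, "'; annotate and bin first",
           call. = FALSE)
    }
  }
  if (length(unique(samples$gdd_bin)) < 2) {
    stop("degenerate design: fewer than 2 distinct GDD bins", call. = FALSE)
  }
  sy <- interaction(samples$site_id, samples$year, drop = TRUE)
  if (nlevels(sy) < 2) {
    stop("degenerate design: fewer than 2 site-years", call. = FALSE)
  }
  if (any(abs(samples$count - round(samples$count)) > 1e-8)) {
    stop("capture counts must be integers for the Poisson model", call. = FALSE)
  }
  d <- data.frame(
    count = as.integer(round(samples$count)),
    gdd_bin = factor(samples$gdd_bin),
    precip_bin = factor(floor(samples$cum_precip / precip_bin_width)),
    site_year = sy,
    site_id = factor(samples$site_id)
  )
  fit <- lme4::glmer(
    count ~ 1 + (1 | gdd_bin) + (1 | precip_bin) + (1 | site_year) + (1 | site_id),
    data = d, family = stats::poisson(link = "log"),
    control = lme4::glmerControl(calc.derivs = FALSE)
  )
  re <- lme4::ranef(fit)$gdd_bin
  centers <- as.numeric(rownames(re))
  coefs <- re[["(Intercept)"]] - mean(re[["(Intercept)"]])
  ord <- order(centers)
  out <- data.frame(bin_center = centers[ord], coefficient = coefs[ord],
                    n_obs = as.integer(table(d$gdd_bin)[ord]))
  rownames(out) <- NULL
  attr(out, "model") <- fit
  class(out) <- c("gdd_coefficients", "data.frame")
  out
}

#' Locate start, peak, and end of emergence from smoothed GDD coefficients
#'
#' Fits a penalised cubic regression spline (smoothness chosen by GCV)
#' through the per-bin GDD coefficients, evaluates it on a dense grid, and
#' reads off the phenology events: the start of emergence is where the
#' smooth crosses from non-positive to positive (linearly interpolated
#' between grid points), the peak is the grid argmax, and the end is the
#' first crossing back to non-positive after the peak. A smooth that touches
#' zero without changing sign is not a crossing.
#'
#' @param coefs A `gdd_coefficients` data frame (or any data frame with
#'   `bin_center` and `coefficient`), at least 5 bins.
#' @param grid_step Evaluation grid step in degree-days (default 1).
#' @param k Spline basis dimension (default 10, reduced if few bins).
#' @return A `phenology_events` list: `start_gdd`, `peak_gdd`, `end_gdd`,
#'   with the smooth curve (`data.frame(gdd, value)`) in attribute
#'   `"smooth"`. Warns if the smooth is still positive at a grid boundary
#'   (flight not fully observed).
#' @export
smooth_and_detect <- function(coefs, grid_step = 1, k = 10) {
  df <- as.data.frame(coefs)
  if (!all(c("bin_center", "coefficient") %in% names(df))) {
    stop("coefs must have bin_center and coefficient columns", call. = FALSE)
  }
  if (nrow(df) < 5) {
    stop("need at least 5 GDD bins to smooth; got ", nrow(df), call. = FALSE)
  }
  k_use <- max(3, min(k, nrow(df) - 1))
  fit <- mgcv::gam(coefficient ~ s(bin_center, k = k_use, bs = "cr"),
                   data = df, method = "GCV.Cp")
  grid <- seq(min(df$bin_center), max(df$bin_center), by = grid_step)
  val <- as.numeric(mgcv::predict.gam(fit, data.frame(bin_center = grid)))

  if (all(val <= 0)) {
    stop("smoothed coefficient curve is never positive: no emergence detected",
         call. = FALSE)
  }
  if (val[1] > 0 || val[length(val)] > 0) {
    warning("smoothed curve is positive at a grid boundary; the flight may ",
            "not be fully observed", call. = FALSE)
  }
  cross_up <- which(val[-length(val)] <= 0 & val[-1] > 0)
  peak_idx <- which.max(val)
  start_gdd <- if (length(cross_up)) {
    interp_zero(grid[cross_up[1]], grid[cross_up[1] + 1],
                val[cross_up[1]], val[cross_up[1] + 1])
  } else {
    grid[1] # positive from the left boundary onward
  }
  after_peak <- seq(peak_idx, length(val) - 1)
  cross_down <- after_peak[val[after_peak] > 0 & val[after_peak + 1] <= 0]
  end_gdd <- if (length(cross_down)) {
    interp_zero(grid[cross_down[1]], grid[cross_down[1] + 1],
                val[cross_down[1]], val[cross_down[1] + 1])
  } else {
    grid[length(grid)]
  }
  events <- structure(
    list(start_gdd = start_gdd, peak_gdd = grid[peak_idx], end_gdd = end_gdd),
    class = "phenology_events")
  if (!(events$start_gdd < events$peak_gdd && events$peak_gdd < events$end_gdd)) {
    stop(sprintf(
      "detected events are not ordered (start %.1f, peak %.1f, end %.1f)",
      events$start_gdd, events$peak_gdd, events$end_gdd), call. = FALSE)
  }
  attr(events, "smooth") <- data.frame(gdd = grid, value = val)
  events
}

# linear interpolation of the zero crossing between (x0, y0) and (x1, y1)
interp_zero <- function(x0, x1, y0, y1) {
  if (y1 == y0) return(x1)
  x0 - y0 * (x1 - x0) / (y1 - y0)
}

#' @export
print.phenology_events <- function(x, ...) {
  cat(sprintf(
    "Emergence phenology (cumulative GDD): start %.0f, peak %.0f, end %.0f\n",
    x$start_gdd, x$peak_gdd, x$end_gdd))
  invisible(x)
}

#' Full coefficient-isolation phenology pipeline
#'
#' Convenience wrapper: [bin_gdd()] then [fit_capture_model()] then
#' [smooth_and_detect()].
#'
#' @param samples Annotated sweep samples.
#' @param bin_width GDD bin width (default 10).
#' @param grid_step Grid step for event detection (default 1).
#' @param ... Passed to [smooth_and_detect()].
#' @return A `phenology_events` object with the coefficient table in
#'   attribute `"coefficients"`.
#' @export
fit_phenology <- function(samples, bin_width = 10, grid_step = 1, ...) {
  binned <- bin_gdd(samples, bin_width)
  coefs <- fit_capture_model(binned)
  events <- smooth_and_detect(coefs, grid_step = grid_step, ...)
  attr(events, "coefficients") <- coefs
  events
}
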