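#' Weather simulation scenario
#'
#' Parameters of a stochastic daily weather generator for a High Plains
#' winter-wheat station: a sinusoidal annual cycle in mean temperature with
#' Gaussian day-to-day noise, a jittered diurnal range split symmetrically
#' about the mean, and Bernoulli-Gamma daily moisture that falls as snow on
#' days with sub-freezing mean temperature and as rain otherwise. The
#' defaults are calibrated so that (i) mean daily single-sine degree-day
#' accumulation (base 10 degC, upper 30 degC) over May 15 to June 15 is
#' about 5.4 GDD per day, matching the accumulation rate observed near the
#' sawfly flight, and (ii) rainfall accumulated from January 1 to mid-May
#' falls in the observed 69-257 mm range.
#'
#' @param annual_mean Annual mean temperature, degC.
#' @param annual_amplitude Amplitude of the annual temperature cycle, degC
#'   (minimum in mid-January, maximum in mid-July).
#' @param diurnal_range_mean,diurnal_range_sd Mean and jitter SD of the
#'   daily tmax - tmin range, degC.
#' @param temp_noise_sd Day-to-day SD of mean temperature around the annual
#'   cycle, degC.
#' @param rain_prob Daily probability of a moisture event.
#' @param rain_shape,rain_scale Gamma parameters of the moisture amount, mm.
#' @param seed Optional integer seed; if supplied, [simulate_weather()] is
#'   reproducible per (seed, year).
#' @return A list of class `weather_scenario`.
#' @export
weather_scenario <- function(annual_mean = 8.3, annual_amplitude = 9.4,
                             diurnal_range_mean = 14, diurnal_range_sd = 3,
                             temp_noise_sd = 3.5,
                             rain_prob = 0.35, rain_shape = 1.2,
                             rain_scale = 3.6, seed = NULL) {
  stopifnot(diurnal_range_mean > 0, diurnal_range_sd >= 0, temp_noise_sd >= 0,
            rain_prob >= 0, rain_prob <= 1, rain_shape > 0, rain_scale > 0)
  structure(list(annual_mean = annual_mean, annual_amplitude = annual_amplitude,
                 diurnal_range_mean = diurnal_range_mean,
                 diurnal_range_sd = diurnal_range_sd,
                 temp_noise_sd = temp_noise_sd, rain_prob = rain_prob,
                 rain_shape = rain_shape, rain_scale = rain_scale, seed = seed),
            class = "weather_scenario")
}

#' Flight simulation scenario
#'
#' Parameters of the synthetic sawfly study. Emergence timing is modelled on
#' the cumulative-GDD axis, not the calendar: the expected capture at a date
#' with cumulative degree-days g is proportional to a Gaussian profile
#' `exp(-(g - mu)^2 / (2 sigma^2))`, peaking at the site-year abundance
#' level. The default centre (223 GDD) and spread (42 GDD) are the values
#' implied by the reference emergence-quantile table
#' ([wss_reference_quantiles()] via [fit_quantile_pairs()]). Site-year
#' abundance follows a log-linear model in the environmental covariates
#' with the reference effect sizes ([wss_reference_env_effects()], applied
#' to mean-centred covariates), plus site and year random effects and
#' residual noise on the log scale. Realised counts are Poisson.
#'
#' @param mu Emergence centre, cumulative degC-days (default 223).
#' @param sigma Emergence spread, degC-days (default 42).
#' @param n_sites Number of sites (default 8).
#' @param years Integer vector of study years (default 12 consecutive years).
#' @param sampling_interval Days between sweep samples (default 7, weekly).
#' @param season_start,season_end Month-day strings bounding the sampling
#'   season (defaults April 15 and June 20).
#' @param log_peak_intercept Log expected peak capture per 100 sweeps for a
#'   site-year with covariates at their reference means and zero random
#'   effects (default `log(25)`).
#' @param env_effects Data frame of covariate effects on log abundance
#'   (columns `term`, `coefficient`); default
#'   [wss_reference_env_effects()]. Terms absent from it have no effect.
#' @param env_centers Named numeric vector of centring points for the
#'   covariate effects: the coefficients multiply deviations of each
#'   site-year's covariate from these values, so `log_peak_intercept`
#'   remains the typical log peak abundance. The defaults are the expected
#'   covariate values under the default [weather_scenario()] climate.
#' @param site_sd,year_sd SDs of the site and year random effects on the log
#'   scale (default 0.5).
#' @param noise_sd Residual log-scale SD per site-year (default 0.2).
#' @param seed Optional integer seed for [simulate_study()].
#' @return A list of class `flight_scenario`.
#' @export
flight_scenario <- function(mu = 223, sigma = 42, n_sites = 8,
                            years = 2012:2023, sampling_interval = 7,
                            season_start = "04-15", season_end = "06-20",
                            log_peak_intercept = log(25),
                            env_effects = wss_reference_env_effects(),
                            env_centers = c(emergence_length = 30,
                                            prior_rainfall = 150,
                                            tmin_during = 0.5,
                                            tmax_before = 26,
                                            tmax_during = 30),
                            site_sd = 0.5, year_sd = 0.5, noise_sd = 0.2,
                            seed = NULL) {
  stopifnot(sigma > 0, n_sites >= 1, sampling_interval >= 1,
            site_sd >= 0, year_sd >= 0, noise_sd >= 0)
  parse_month_day(season_start); parse_month_day(season_end)
  structure(list(mu = mu, sigma = sigma, n_sites = n_sites, years = years,
                 sampling_interval = sampling_interval,
                 season_start = season_start, season_end = season_end,
                 log_peak_intercept = log_peak_intercept,
                 env_effects = env_effects, env_centers = env_centers,
                 site_sd = site_sd,
                 year_sd = year_sd, noise_sd = noise_sd, seed = seed),
            class = "flight_scenario")
}

#' Simulate one year of daily weather
#'
#' Daily mean temperature follows
#' `annual_mean + annual_amplitude * sin(2*pi*(doy - 105)/365)` plus
#' Gaussian noise; `tmin`/`tmax` sit half the (jittered) diurnal range below
#' and above it. Moisture is Bernoulli-Gamma; on days with sub-freezing mean
#' temperature it is recorded as snowfall, otherwise as rainfall. The series
#' covers January 1 to December 31.
#'
#' @param scenario A [weather_scenario()].
#' @param year Calendar year.
#' @return A `weather_series` with columns `date`, `tmin`, `tmax`, `precip`
#'   (rain, mm), `snow` (mm).
#' @export
simulate_weather <- function(scenario, year) {
  stopifnot(inherits(scenario, "weather_scenario"))
  if (!is.null(scenario$seed)) {
    set.seed((as.integer(scenario$seed) * 1009L + as.integer(year)) %% 2147483647L)
  }
  dates <- seq(as.Date(sprintf("%d-01-01", year)),
               as.Date(sprintf("%d-12-31", year)), by = "day")
  doy <- as.integer(format(dates, "%j"))
  n <- length(dates)
  tmean <- scenario$annual_mean +
    scenario$annual_amplitude * sin(2 * pi * (doy - 105) / 365) +
    stats::rnorm(n, 0, scenario$temp_noise_sd)
  rng <- pmax(1, stats::rnorm(n, scenario$diurnal_range_mean,
                              scenario$diurnal_range_sd))
  wet <- stats::rbinom(n, 1, scenario$rain_prob) == 1
  amount <- numeric(n)
  amount[wet] <- stats::rgamma(sum(wet), shape = scenario$rain_shape,
                               scale = scenario$rain_scale)
  freezing <- tmean < 0
  precip <- ifelse(freezing, 0, amount)
  snow <- ifelse(freezing, amount, 0)
  weather_series(dates, tmean - rng / 2, tmean + rng / 2, precip, snow = snow,
                 station_id = sprintf("sim-%d", year))
}

#' Simulate one site-year of sweep-net captures
#'
#' Sampling dates run from `season_start` to `season_end` every
#' `sampling_interval` days. At a date with cumulative degree-days `g` the
#' expected capture is `site_year_mean * exp(-(g - mu)^2 / (2 sigma^2))`
#' (so the expectation equals `site_year_mean` exactly at the emergence
#' centre), and the realised count is Poisson.
#'
#' @param scenario A [flight_scenario()].
#' @param gdd A `gdd_series` covering the sampling window of `year`.
#' @param site_year_mean Expected capture per 100 sweeps at the flight peak.
#' @param site_id,year Labels attached to the samples.
#' @return A sweep-sample data frame (`site_id`, `date`, `year`, `count`).
#' @export
simulate_flight <- function(scenario, gdd, site_year_mean,
                            site_id = "site1", year = NULL) {
  stopifnot(inherits(scenario, "flight_scenario"), site_year_mean >= 0)
  if (is.null(year)) year <- max(gdd$year)
  start <- as.Date(sprintf("%d-%s", year, scenario$season_start))
  end <- as.Date(sprintf("%d-%s", year, scenario$season_end))
  dates <- seq(start, end, by = scenario$sampling_interval)
  g <- gdd$cumulative_dd[match(dates, gdd$date)]
  if (any(is.na(g))) {
    stop("degree-day series does not cover the sampling window ",
         format(start), "..", format(end), call. = FALSE)
  }
  lambda <- site_year_mean * exp(-(g - scenario$mu)^2 / (2 * scenario$sigma^2))
  data.frame(site_id = site_id, date = dates, year = as.integer(year),
             count = stats::rpois(length(dates), lambda))
}

#' Simulate a complete multi-site, multi-year monitoring study
#'
#' For every site-year: two calendar years of weather are simulated (the
#' prior year supplies the winter snowfall window), degree-days are
#' accumulated from the biofix, the environmental covariates are computed
#' over the "true" flight window (the dates over which cumulative GDD passes
#' from `mu - 2 sigma` to `mu + 2 sigma`), the site-year log abundance is
#' assembled from the covariate effects plus site/year random effects and
#' noise, and a Poisson capture series is drawn along the Gaussian emergence
#' profile. Samples are returned already annotated with `cum_gdd` and
#' `cum_precip`.
#'
#' @param flight A [flight_scenario()].
#' @param weather A [weather_scenario()].
#' @param params Degree-day parameters (default [degree_day_params()]).
#' @param seed Integer seed; overrides `flight$seed` if given. All
#'   randomness in the study flows from it.
#' @return A list of class `wss_study`:
#' \describe{
#'   \item{samples}{annotated sweep samples for all site-years}
#'   \item{weather}{named list of `weather_series`, one per site-year
#'     (key `"<site>_<year>"`), each covering the prior and focal year}
#'   \item{gdd}{named list of matching `gdd_series`}
#'   \item{truth}{generating parameters: `mu`, `sigma`, effects table, the
#'     per-site-year covariates and expected peak abundances, random
#'     effects}
#' }
#' @export
simulate_study <- function(flight = flight_scenario(),
                           weather = weather_scenario(),
                           params = degree_day_params(), seed = NULL) {
  stopifnot(inherits(flight, "flight_scenario"),
            inherits(weather, "weather_scenario"))
  seed <- seed %||% flight$seed
  if (!is.null(seed)) set.seed(as.integer(seed))
  weather$seed <- NULL # one RNG stream for the whole study

  sites <- sprintf("site%02d", seq_len(flight$n_sites))
  site_eff <- stats::setNames(stats::rnorm(length(sites), 0, flight$site_sd),
                              sites)
  year_eff <- stats::setNames(stats::rnorm(length(flight$years), 0,
                                           flight$year_sd),
                              as.character(flight$years))
  eff <- flight$env_effects
  samples <- list(); weather_by <- list(); gdd_by <- list(); truth_rows <- list()

  for (y in flight$years) {
    for (s in sites) {
      key <- paste0(s, "_", y)
      ws <- rbind(simulate_weather(weather, y - 1), simulate_weather(weather, y))
      ws <- weather_series(ws$date, ws$tmin, ws$tmax, ws$precip, snow = ws$snow,
                           station_id = key)
      gdd <- accumulate_gdd(ws, params)
      gy <- gdd[gdd$year == y, , drop = FALSE]
      # true flight window on the calendar: GDD passing mu +/- 2 sigma
      lo <- flight$mu - 2 * flight$sigma
      hi <- flight$mu + 2 * flight$sigma
      i0 <- which(gy$cumulative_dd >= lo)[1]
      i1 <- which(gy$cumulative_dd >= hi)[1]
      if (is.na(i0)) i0 <- nrow(gy)
      if (is.na(i1)) i1 <- nrow(gy)
      cov <- window_covariates(ws, gdd, gy$date[i0], gy$date[i1], y, params)
      dev <- 0
      for (j in seq_len(nrow(eff))) {
        x <- cov[[eff$term[j]]]
        ctr <- if (eff$term[j] %in% names(flight$env_centers)) {
          flight$env_centers[[eff$term[j]]]
        } else eff$mean[j]
        if (!is.null(x) && is.finite(x)) {
          dev <- dev + eff$coefficient[j] * (x - ctr)
        }
      }
      log_mean <- flight$log_peak_intercept + dev + site_eff[[s]] +
        year_eff[[as.character(y)]] + stats::rnorm(1, 0, flight$noise_sd)
      sy_mean <- exp(log_mean)
      fl <- simulate_flight(flight, gy, sy_mean, site_id = s, year = y)
      fl <- annotate_samples(fl, gdd, ws)
      samples[[key]] <- fl
      weather_by[[key]] <- ws
      gdd_by[[key]] <- gdd
      truth_rows[[key]] <- data.frame(site_id = s, year = y,
                                      expected_peak = sy_mean,
                                      as.data.frame(cov))
    }
  }
  structure(list(
    samples = do.call(rbind, c(samples, list(make.row.names = FALSE))),
    weather = weather_by,
    gdd = gdd_by,
    truth = list(mu = flight$mu, sigma = flight$sigma,
                 env_effects = eff,
                 log_peak_intercept = flight$log_peak_intercept,
                 site_effects = site_eff, year_effects = year_eff,
                 site_years = do.call(rbind, c(truth_rows,
                                               list(make.row.names = FALSE))))
  ), class = "wss_study")
}

#' @export
print.wss_study <- function(x, ...) {
  cat(sprintf(
    "Synthetic WSS monitoring study: %d samples, %d site-years, mu = %g, sigma = %g\n",
    nrow(x$samples), length(x$weather), x$truth$mu, x$truth$sigma))
  invisible(x)
}

# Environmental covariates over a flight window [start_date, end_date]
# (shared by the simulator and summarize_site_year so both use the same
# definitions). `year` is the focal year; biofix from `params`.
window_covariates <- function(weather, gdd, start_date, end_date, year,
                              params = degree_day_params()) {
  wdf <- as.data.frame(weather)
  biofix <- as.Date(sprintf("%d-%02d-%02d", year, params$biofix_month,
                            params$biofix_day))
  before <- wdf$date >= biofix & wdf$date < start_date
  during <- wdf$date >= start_date & wdf$date <= end_date
  # prior winter snowfall: Oct 1 of the previous year through Mar 31
  winter <- wdf$date >= as.Date(sprintf("%d-10-01", year - 1)) &
    wdf$date <= as.Date(sprintf("%d-03-31", year))
  g0 <- gdd$cumulative_dd[match(start_date, gdd$date)]
  g1 <- gdd$cumulative_dd[match(end_date, gdd$date)]
  len <- as.integer(end_date - start_date) + 1L
  list(
    first_detection_doy = as.integer(format(start_date, "%j")),
    emergence_length = len,
    mean_gdd_per_day = (g1 - g0) / len,
    prior_snow = if ("snow" %in% names(wdf)) sum(wdf$snow[winter]) else 0,
    prior_rainfall = sum(wdf$precip[before]),
    rain_during = sum(wdf$precip[during]),
    tmin_before = if (any(before)) min(wdf$tmin[before]) else NA_real_,
    tmin_during = if (any(during)) min(wdf$tmin[during]) else NA_real_,
    tmax_before = if (any(before)) max(wdf$tmax[before]) else NA_real_,
    tmax_during = if (any(during)) max(wdf$tmax[during]) else NA_real_
  )
}
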