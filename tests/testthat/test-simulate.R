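test_that("weather simulation is reproducible and respects noise-free limits", {
  sc <- weather_scenario(seed = 5)
  expect_equal(as.data.frame(simulate_weather(sc, 2019)),
               as.data.frame(simulate_weather(sc, 2019)))

  quiet <- weather_scenario(temp_noise_sd = 0, diurnal_range_sd = 0,
                            rain_prob = 0, seed = 1)
  ws <- simulate_weather(quiet, 2019)
  expect_true(all(ws$precip == 0) && all(ws$snow == 0))
  doy <- as.integer(format(ws$date, "%j"))
  expect_equal((ws$tmin + ws$tmax) / 2,
               quiet$annual_mean +
                 quiet$annual_amplitude * sin(2 * pi * (doy - 105) / 365),
               tolerance = 1e-12)
  expect_equal(ws$tmax - ws$tmin, rep(quiet$diurnal_range_mean, nrow(ws)))
})

test_that("simulated weather passes the validators unchanged", {
  set.seed(2)
  ws <- simulate_weather(weather_scenario(), 2020)
  v <- validate_and_fill(ws)
  expect_equal(as.data.frame(v), as.data.frame(ws))
})

test_that("spring degree-day accumulation sits near 5.4 GDD per day", {
  sc <- weather_scenario()
  set.seed(77)
  rates <- vapply(1:60, function(i) {
    y <- 2000 + i
    gdd <- accumulate_gdd(simulate_weather(sc, y))
    win <- gdd$date >= as.Date(sprintf("%d-05-15", y)) &
      gdd$date <= as.Date(sprintf("%d-06-15", y))
    mean(gdd$daily_dd[win])
  }, numeric(1))
  expect_lt(abs(mean(rates) - 5.4), 0.5)
})

test_that("flight counts peak at the site-year mean on the GDD axis", {
  sc <- flight_scenario()
  ws <- simulate_weather(weather_scenario(seed = 4), 2020)
  gdd <- accumulate_gdd(ws)
  set.seed(1)
  zero <- simulate_flight(sc, gdd, site_year_mean = 0, year = 2020)
  expect_true(all(zero$count == 0))
  # with a large mean, the realised counts trace the Gaussian profile:
  # the capture-weighted mean GDD approximates the flight centre
  set.seed(2)
  fl <- simulate_flight(sc, gdd, site_year_mean = 5000, year = 2020)
  ann <- annotate_samples(fl, gdd, ws)
  wmean <- sum(ann$cum_gdd * ann$count) / sum(ann$count)
  expect_lt(abs(wmean - sc$mu), 15)

  short <- gdd[gdd$date < as.Date("2020-06-01"), ]
  class(short) <- class(gdd)
  expect_error(simulate_flight(sc, short, 10, year = 2020), "cover")
})

test_that("a full study is seed-deterministic with plausible covariates", {
  fl <- flight_scenario(n_sites = 2, years = 2019:2020)
  a <- simulate_study(fl, seed = 9)
  b <- simulate_study(fl, seed = 9)
  expect_equal(a$samples, b$samples)
  expect_equal(a$truth$site_years, b$truth$site_years)
  c_ <- simulate_study(fl, seed = 10)
  expect_false(identical(a$samples$count, c_$samples$count))

  ty <- a$truth$site_years
  expect_true(all(ty$emergence_length >= 6 & ty$emergence_length <= 43))
  expect_true(all(ty$prior_rainfall >= 0))
  expect_true(all(ty$expected_peak > 0))
  # samples arrive annotated and valid
  expect_true(all(c("cum_gdd", "cum_precip") %in% names(a$samples)))
  expect_true(all(a$samples$count >= 0))
})

test_that("null effects and zero dispersion give identical site-years", {
  eff <- wss_reference_env_effects()
  eff$coefficient <- 0
  fl <- flight_scenario(n_sites = 3, years = 2020, env_effects = eff,
                        site_sd = 0, year_sd = 0, noise_sd = 0)
  study <- simulate_study(fl, seed = 3)
  peaks <- study$truth$site_years$expected_peak
  expect_equal(peaks, rep(exp(fl$log_peak_intercept), 3))
})

test_that("the generator's emergence quantiles match large-sample empirics", {
  # equal-abundance site-years so the pooled curve is not dominated by a
  # few large flights; this isolates the generator's timing distribution
  eff <- wss_reference_env_effects()
  eff$coefficient <- 0
  fl <- flight_scenario(env_effects = eff, site_sd = 0, year_sd = 0,
                        noise_sd = 0, log_peak_intercept = log(80))
  study <- simulate_study(fl, seed = 5)
  curve <- cumulative_proportion(study$samples)
  emp <- function(p) approx(curve$cum_proportion, curve$cum_gdd, p,
                            ties = "ordered")$y
  expect_lt(abs(emp(0.5) - study$truth$mu), 10)
  # spread: central 80% span vs 2 * 1.2816 * sigma
  span <- emp(0.9) - emp(0.1)
  expect_lt(abs(span - 2 * qnorm(0.9) * study$truth$sigma), 20)
})
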