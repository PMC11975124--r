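test_that("single-sine closed form reproduces the analytic threshold cases", {
  # interior: whole curve between thresholds, DD = mean - base
  expect_equal(daily_single_sine_dd(10, 30, 10, 30), 10)
  # entirely below base
  expect_equal(daily_single_sine_dd(5, 8, 10, 30), 0)
  # saturated above the upper threshold
  expect_equal(daily_single_sine_dd(32, 40, 10, 30), 20)
  # base-intercepted, symmetric about the base: (1/pi) * A
  expect_equal(daily_single_sine_dd(0, 20, 10, 30), 10 / pi, tolerance = 1e-12)
  # upper-intercepted (value frozen from the quadrature oracle)
  expect_equal(daily_single_sine_dd(15, 35, 10, 30), 13.910022190,
               tolerance = 1e-8)
})

test_that("closed form agrees with quadrature of the defining integral", {
  set.seed(101)
  tuples <- random_dd_tuples(200)
  for (i in seq_len(nrow(tuples))) { # thresholds vary per row

    got <- daily_single_sine_dd(tuples$tmin[i], tuples$tmax[i],
                                tuples$base[i], tuples$upper[i])
    want <- sine_dd_quadrature(tuples$tmin[i], tuples$tmax[i],
                               tuples$base[i], tuples$upper[i])
    expect_equal(got, want, tolerance = 1e-6,
                 label = sprintf("tuple %d (tmin %.2f tmax %.2f)", i,
                                 tuples$tmin[i], tuples$tmax[i]))
  }
})

test_that("daily degree-days are monotone in tmin/tmax and bounded", {
  set.seed(7)
  for (rep in 1:50) {
    tmin <- runif(1, -10, 25); tmax <- tmin + runif(1, 0, 25)
    base <- runif(1, 0, 15); upper <- base + runif(1, 3, 20)
    d0 <- daily_single_sine_dd(tmin, tmax, base, upper)
    expect_gte(daily_single_sine_dd(tmin, tmax + 1, base, upper), d0)
    expect_gte(daily_single_sine_dd(tmin + 0.5, max(tmax, tmin + 0.5),
                                    base, upper), d0)
    expect_lte(daily_single_sine_dd(tmin, tmax, base + 1, base + 1 + (upper - base)),
               d0 + 1e-12) # non-increasing in base, width held fixed
    expect_gte(d0, 0)
    expect_lte(d0, upper - base + 1e-12)
    expect_lte(d0, max(0, (tmax + tmin) / 2 - base) + (tmax - tmin) / 2 + 1e-12)
  }
})

test_that("a flat day degenerates to the clipped constant", {
  for (c_ in c(-3, 10, 17.2, 30, 42)) {
    expect_equal(daily_single_sine_dd(c_, c_, 10, 30),
                 max(0, min(c_, 30) - 10), tolerance = 1e-12)
  }
})

test_that("Fahrenheit-threshold computation is 1.8x the Celsius one", {
  set.seed(11)
  tmin_c <- runif(40, -10, 30); tmax_c <- tmin_c + runif(40, 0, 20)
  dd_c <- daily_single_sine_dd(tmin_c, tmax_c, 10, 30)
  dd_f <- daily_single_sine_dd(tmin_c * 9 / 5 + 32, tmax_c * 9 / 5 + 32, 50, 86)
  expect_equal(dd_f, 1.8 * dd_c, tolerance = 1e-9)
})

test_that("invalid inputs are rejected", {
  expect_error(daily_single_sine_dd(20, 10), "tmin > tmax")
  expect_error(daily_single_sine_dd(5, 10, base = 30, upper = 10), "base")
  expect_error(celsius_to_fahrenheit_dd(-1), "non-negative")
  expect_error(degree_day_params(base = 30, upper = 10), "below")
  expect_error(degree_day_params(biofix = "13-40"), "valid month-day")
})

test_that("accumulation is a per-year running sum that resets at the biofix", {
  ws <- weather_series(c(as.Date("2020-01-01") + 0:2, as.Date("2021-01-01") + 0:2),
                       tmin = rep(c(12, 2, 15.4), 2),
                       tmax = rep(c(12, 2, 15.4), 2),
                       precip = 0)
  gdd <- accumulate_gdd(ws, degree_day_params())
  expect_equal(gdd$daily_dd, c(2, 0, 5.4, 2, 0, 5.4))
  expect_equal(gdd$cumulative_dd, c(2, 2, 7.4, 2, 2, 7.4))
  expect_equal(gdd$year, c(2020, 2020, 2020, 2021, 2021, 2021))

  # a leading partial year that misses its biofix is context, not output
  lead_ws <- weather_series(c(as.Date("2019-10-01") + 0:2,
                              as.Date("2020-01-01") + 0:2),
                            tmin = 12, tmax = 12, precip = 0)
  gdd2 <- accumulate_gdd(lead_ws)
  expect_equal(unique(gdd2$year), 2020)
  expect_equal(nrow(gdd2), 3)

  cold <- toy_weather(5, "2021-01-01", tmin = -5, tmax = 2)
  expect_true(all(accumulate_gdd(cold)$cumulative_dd == 0))

  late <- toy_weather(5, "2021-03-01", tmin = 5, tmax = 20)
  expect_error(accumulate_gdd(late), "biofix")
})

test_that("threshold_date finds the first date reaching the target per year", {
  ws <- toy_weather(10, "2021-01-01", tmin = 12, tmax = 12) # 2 GDD/day
  gdd <- accumulate_gdd(ws)
  td <- threshold_date(gdd, 7)
  expect_equal(td$date, as.Date("2021-01-04"))
  expect_true(is.na(threshold_date(gdd, 1000)$date))
})

test_that("Celsius degree-day landmarks convert to the Fahrenheit scale", {
  expect_equal(celsius_to_fahrenheit_dd(0), 0)
  expect_equal(celsius_to_fahrenheit_dd(148), 266.4)
  expect_equal(round(celsius_to_fahrenheit_dd(c(148, 224))), c(266, 403))
})
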