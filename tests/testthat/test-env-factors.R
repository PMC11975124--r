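make_toy_site_year <- function() {
  # 2 years of weather: constant 2 GDD/day, rain 1 mm/day up to Apr 30,
  # none afterwards; snow every prior-winter day
  dates <- seq(as.Date("2020-10-01"), as.Date("2021-06-30"), by = "day")
  precip <- ifelse(dates <= as.Date("2021-04-30"), 1, 0)
  snow <- ifelse(dates <= as.Date("2021-03-31"), 2, 0)
  ws <- weather_series(dates, tmin = 12, tmax = 12, precip = precip,
                       snow = snow)
  gdd <- accumulate_gdd(ws)
  s <- data.frame(site_id = "s1",
                  date = as.Date(c("2021-04-20", "2021-05-01", "2021-05-15",
                                   "2021-06-05", "2021-06-12")),
                  year = 2021L, count = c(0, 3, 10, 2, 0))
  list(samples = s, weather = ws, gdd = gdd)
}

test_that("site-year summaries compute windows and sums as defined", {
  toy <- make_toy_site_year()
  sm <- summarize_site_year(toy$samples, toy$weather, toy$gdd)
  expect_equal(sm$mean_capture, mean(c(0, 3, 10, 2, 0)))
  # flight window: first to last positive capture, inclusive day span
  expect_equal(sm$first_detection_doy,
               as.integer(format(as.Date("2021-05-01"), "%j")))
  expect_equal(sm$emergence_length, as.integer(as.Date("2021-06-05") -
                                                 as.Date("2021-05-01")) + 1)
  expect_equal(sm$mean_gdd_per_day, 2 * 35 / 36)
  # rainfall: 1 mm/day Jan 1 .. Apr 30; before-window ends Apr 30
  expect_equal(sm$prior_rainfall, as.numeric(as.Date("2021-04-30") -
                                               as.Date("2021-01-01")) + 1)
  expect_equal(sm$rain_during, 0)
  # prior winter snow: Oct 1 .. Mar 31 at 2 mm/day
  expect_equal(sm$prior_snow, 2 * 182)
  expect_equal(sm$tmin_during, 12)
  expect_equal(sm$tmax_before, 12)
})

test_that("captureless site-years flag their timing covariates as absent", {
  toy <- make_toy_site_year()
  toy$samples$count <- 0
  sm <- summarize_site_year(toy$samples, toy$weather, toy$gdd)
  expect_equal(sm$mean_capture, 0)
  expect_true(is.na(sm$emergence_length))
})

test_that("alpha = 1 disables selection and keeps the full model", {
  s <- simulate_env_summaries(n = 60, seed = 21)
  fit <- fit_env_model(s, alpha = 1)
  expect_length(fit$dropped_terms, 0)
  expect_equal(sort(setdiff(fit$terms$name, "(Intercept)")),
               sort(wssphen:::env_fixed_terms))
  expect_true(fit$r_squared >= 0 && fit$r_squared <= 1)
  expect_true(fit$deviance_explained <= 1)
  expect_named(fit$random_effect_tests)
})

test_that("backward selection is reproducible and drops one term per step", {
  s <- simulate_env_summaries(n = 80, seed = 31)
  a <- fit_env_model(s, alpha = 0.05)
  b <- fit_env_model(s, alpha = 0.05)
  expect_identical(a$dropped_terms, b$dropped_terms)
  expect_identical(a$terms, b$terms)
  # dropped + retained partition the candidate set
  retained <- setdiff(a$terms$name, "(Intercept)")
  expect_setequal(c(retained, a$dropped_terms), wssphen:::env_fixed_terms)
  # every retained term is significant at alpha
  expect_true(all(a$terms$p_value[a$terms$name != "(Intercept)"] <= 0.05))
})

test_that("a single strong true effect survives selection alone", {
  eff <- wss_reference_env_effects()
  eff <- eff[eff$term == "prior_rainfall", ]
  kept <- vapply(1:10, function(i) {
    s <- simulate_env_summaries(n = 100, effects = eff, seed = 300 + i)
    fit <- fit_env_model(s, alpha = 0.05)
    retained <- setdiff(fit$terms$name, "(Intercept)")
    "prior_rainfall" %in% retained
  }, logical(1))
  expect_gte(mean(kept), 0.9)
})

test_that("summaries of a simulated study feed the model end to end", {
  study <- default_study()
  sm <- summarize_study(study$samples, study$weather, study$gdd)
  expect_equal(nrow(sm), length(study$weather))
  expect_true(all(sm$tmin_during <= sm$tmax_during, na.rm = TRUE))
  expect_true(all(sm$prior_rainfall >= 0, na.rm = TRUE))
  fit <- fit_env_model(sm, alpha = 0.05)
  expect_s3_class(fit, "env_model")
  expect_true(all(c("year_f", "site_f") %in% names(fit$random_effect_tests)))
})
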