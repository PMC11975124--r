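test_that("GDD bins are left-closed with midpoint labels", {
  s <- data.frame(cum_gdd = c(223.4, 220, 219.999, 0))
  b <- bin_gdd(s, 10)
  expect_equal(b$gdd_bin, c(225, 225, 215, 5))
  b1 <- bin_gdd(data.frame(cum_gdd = c(3.2, 3.9)), 1)
  expect_equal(b1$gdd_bin, c(3.5, 3.5))
  expect_error(bin_gdd(s, 0), "positive")
  expect_error(bin_gdd(data.frame(x = 1), 10), "cum_gdd")
})

test_that("event detection on an exact parabola finds its roots and vertex", {
  g <- seq(100, 400, by = 10)
  coefs <- data.frame(bin_center = g,
                      coefficient = -(g - 150) * (g - 350) / 1e4)
  ev <- smooth_and_detect(coefs, grid_step = 1)
  expect_lt(abs(ev$start_gdd - 150), 1)
  expect_equal(ev$peak_gdd, 250, tolerance = 1)
  expect_lt(abs(ev$end_gdd - 350), 1)
  expect_true(ev$start_gdd < ev$peak_gdd && ev$peak_gdd < ev$end_gdd)
})

test_that("event detection refuses flightless input and tiny designs", {
  g <- seq(100, 300, by = 20)
  flat <- data.frame(bin_center = g, coefficient = -1 - 0.001 * g)
  expect_error(smooth_and_detect(flat), "never positive")
  expect_error(smooth_and_detect(data.frame(bin_center = 1:4,
                                            coefficient = 1:4)),
               "at least 5")
})

test_that("detected events are equivariant under a GDD translation", {
  g <- seq(100, 400, by = 10)
  set.seed(6)
  coefs <- data.frame(bin_center = g,
                      coefficient = -(g - 150) * (g - 350) / 1e4 +
                        rnorm(length(g), 0, 0.02))
  ev <- smooth_and_detect(coefs)
  shifted <- transform(coefs, bin_center = bin_center + 77)
  ev2 <- smooth_and_detect(shifted)
  expect_equal(ev2$start_gdd, ev$start_gdd + 77, tolerance = 1e-6)
  expect_equal(ev2$peak_gdd, ev$peak_gdd + 77, tolerance = 1e-6)
  expect_equal(ev2$end_gdd, ev$end_gdd + 77, tolerance = 1e-6)
})

test_that("the capture model enforces its design preconditions", {
  s <- data.frame(site_id = "a", year = 2020L, count = 1,
                  cum_gdd = c(100, 150), cum_precip = 10)
  b <- bin_gdd(s, 10)
  expect_error(fit_capture_model(b), "site-years")
  one_bin <- bin_gdd(data.frame(site_id = c("a", "b"), year = 2020L,
                                count = 1, cum_gdd = c(101, 102),
                                cum_precip = 10), 10)
  expect_error(fit_capture_model(one_bin), "2 distinct GDD bins")
  frac <- bin_gdd(data.frame(site_id = c("a", "b"), year = 2020L,
                             count = 1.5, cum_gdd = c(101, 202),
                             cum_precip = 10), 10)
  expect_error(fit_capture_model(frac), "integers")
})

test_that("isolated GDD coefficients peak near the generating flight centre", {
  study <- default_study() # true peak 224 GDD
  binned <- bin_gdd(study$samples, 10)
  coefs <- fit_capture_model(binned)
  expect_s3_class(coefs, "gdd_coefficients")
  expect_true(all(diff(coefs$bin_center) > 0))
  expect_true(all(coefs$n_obs >= 1))
  expect_equal(mean(coefs$coefficient), 0, tolerance = 1e-8)
  peak_bin <- coefs$bin_center[which.max(coefs$coefficient)]
  expect_lt(abs(peak_bin - 224), 15)

  ev <- suppressWarnings(smooth_and_detect(coefs))
  expect_true(ev$start_gdd < ev$peak_gdd && ev$peak_gdd < ev$end_gdd)
  expect_lt(abs(ev$peak_gdd - 224), 10)
})

test_that("flat expected counts give near-zero isolated coefficients", {
  set.seed(12)
  grid <- expand.grid(site_id = c("a", "b", "c"), year = 2019:2021,
                      i = 1:12)
  s <- data.frame(site_id = grid$site_id, year = grid$year,
                  cum_gdd = 10 + grid$i * 25 + runif(nrow(grid), 0, 5),
                  cum_precip = runif(nrow(grid), 0, 60),
                  count = rpois(nrow(grid), 20))
  coefs <- fit_capture_model(bin_gdd(s, 25))
  expect_lt(max(abs(coefs$coefficient)), 0.15)
})
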