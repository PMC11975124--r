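# Independent quadrature oracle for the daily single-sine degree-day value:
# numerically integrates the defining expression rather than using any of
# the closed-form case formulas.
# (midpoint rule with 2^16 panels: the integrand has derivative kinks where
# the sine crosses a threshold, which defeat adaptive quadrature's error
# control; the composite midpoint rule is O(h^2) there, ~1e-8 at this n)
sine_dd_quadrature <- function(tmin, tmax, base, upper, n = 65536L) {
  m <- (tmax + tmin) / 2
  a <- (tmax - tmin) / 2
  t <- (seq_len(n) - 0.5) * 2 * pi / n
  mean(pmax(0, pmin(m + a * sin(t), upper) - base))
}

# Random (tmin, tmax, base, upper) tuples stratified so that all six
# threshold cases (below, saturated, interior, base-cut, upper-cut, both)
# occur with non-trivial frequency.
random_dd_tuples <- function(n) {
  base <- runif(n, -5, 15)
  upper <- base + runif(n, 2, 25)
  span <- upper - base
  center <- base + runif(n, -1.5, 2.5) * span
  halfrange <- runif(n, 0, 2) * span
  data.frame(tmin = center - halfrange, tmax = center + halfrange,
             base = base, upper = upper)
}

# Small fixed weather table used by io / annotation tests.
toy_weather <- function(n = 10, start = "2020-01-01", tmin = 5, tmax = 15,
                        precip = 0) {
  weather_series(seq(as.Date(start), by = "day", length.out = n),
                 rep_len(tmin, n), rep_len(tmax, n), rep_len(precip, n))
}

# One shared default synthetic study per test run (the heavier pipeline
# tests reuse it instead of regenerating).
default_study <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_study(flight_scenario(mu = 224), seed = 42)
    }
    cache
  }
})
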