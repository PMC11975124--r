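# wssphen

Growing degree-day phenology models for the wheat stem sawfly (WSS,
*Cephus cinctus*), the most damaging insect pest of wheat in the North
American Great Plains. Adult WSS emerge from stubble for a few weeks in
late spring; because the calendar timing shifts by weeks between years
while thermal time does not, monitoring and management decisions are best
made on a cumulative growing degree-day (GDD) axis — base 10 °C, upper
threshold 30 °C, biofix January 1. `wssphen` is aimed at entomologists and
agronomists building or validating such models from sweep-net monitoring
data and daily station weather.

The package provides:

* **Single-sine degree-days** with horizontal upper-threshold cutoff — the
  exact closed form of
  (1/2π) ∫ max{0, min(M + A·sin t, U) − B} dt, six-case analysis, plus
  accumulation from the biofix, threshold-date queries, and the exact 9/5
  Celsius↔Fahrenheit degree-day scaling.
* **Coefficient-isolation phenology model**: Poisson random-effects model
  `count ~ 1 + (1|gdd_bin) + (1|precip_bin) + (1|site_year) + (1|site_id)`
  whose GDD-bin conditional modes, smoothed by a penalised spline, locate
  the start (zero up-crossing), peak (maximum), and end (zero
  down-crossing) of the flight.
* **Cumulative-proportion probit model**: pooled captures become a
  cumulative emergence curve; a quasibinomial probit fit
  Φ⁻¹(p) = α + βg is equivalent to Gaussian emergence times with
  μ = −α/β, σ = 1/β and answers any quantile query μ + σΦ⁻¹(p).
* **Environmental-factors model**: site-year mean captures on ten
  weather/timing covariates with year and site random intercepts and
  backward selection.
* A **seeded simulator** of multi-site, multi-year weather and capture
  data with this exact statistical structure, so the whole chain is
  testable without field data, plus a `degday` command-line wrapper
  (`inst/cli/degday.R`) with `compute`, `threshold-date`, `simulate`,
  `fit-gam`, `fit-probit`, `env-model`, and `report` subcommands.

## Worked example

```r
library(wssphen)

# The reference emergence-quantile table for eastern Colorado winter wheat
# implies a Gaussian flight on the GDD axis:
fit <- fit_quantile_pairs(wss_reference_quantiles())
fit
#> Probit emergence model on the cumulative degree-day axis
#>   mu (50% emergence): 222.6 GDD   sigma (spread): 41.8 GDD
#>   intercept -5.3234, slope 0.02392, n = 7, R^2 = 1.000
round(probit_quantile(fit, c(0.05, 0.50, 0.95)))
#> [1] 154 223 291
```

So 5% of the flight has emerged by 154 GDD, half by 223 GDD, and 95% by
291 GDD — the numbers a scout would use to time first visits and to know
when the flight is effectively over.

```r
# A synthetic monitoring study (8 sites x 12 years, weekly sweeps),
# then both timing models run on it:
study <- simulate_study(flight_scenario(), seed = 1)
study
#> Synthetic WSS monitoring study: 960 samples, 96 site-years, mu = 223, sigma = 42

fit_phenology(study$samples)
#> Emergence phenology (cumulative GDD): start 122, peak 221, end 323

fit_probit(cumulative_proportion(study$samples))
#> Probit emergence model on the cumulative degree-day axis
#>   mu (50% emergence): 217.8 GDD   sigma (spread): 42.2 GDD
#>   intercept -5.1569, slope 0.02367, n = 960, R^2 = 1.000
```

Both estimators recover the generator's flight (centre 223 GDD, spread
42): the coefficient-isolation pipeline puts the peak at 221 GDD and the
probit fit puts the median at 217.8 GDD (weekly calendar sampling is
denser per GDD before the peak than after, which pulls the pooled median
down a few GDD — see the methods vignette).

```r
# Which environmental conditions drive flight magnitude?
sm  <- summarize_study(study$samples, study$weather, study$gdd)
fit_env_model(sm, alpha = 0.05)
#> Environmental-factors model (n = 96 site-years, alpha = 0.05)
#>               name coefficient std_error   df t_value  p_value
#> 1      (Intercept)       26.53    21.707 87.5    1.22 2.25e-01
#> 2 emergence_length        1.01     0.134 91.5    7.55 3.22e-11
#> 3      tmax_during       -1.58     0.702 90.0   -2.25 2.71e-02
#> Dropped (in order): rain_during, tmin_during, mean_gdd_per_day, tmin_before,
#>   first_detection_doy, prior_snow, tmax_before, prior_rainfall
#> R^2 = 0.478, variance explained = 47.7%
```

Longer flights mean more captures; hotter maxima during the flight mean
fewer — the qualitative pattern observed in the field.

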