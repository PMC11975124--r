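---
title: "Degree-day phenology models for wheat stem sawfly: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Degree-day phenology models for wheat stem sawfly: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wssphen)
```

# The problem

The wheat stem sawfly (WSS, *Cephus cinctus*) is a univoltine stem-boring
pest of North American wheat. Adults emerge from stubble in late spring,
live about a week, and lay eggs in growing stems; almost the entire life
cycle is spent protected inside the stem, so management actions (scouting,
swathing, insecticide timing) hinge on predicting when adults fly. Calendar
dates predict the flight poorly — emergence can shift by weeks between
years — but thermal time does not: on a cumulative growing degree-day (GDD)
axis with a base of 10 °C, an upper threshold of 30 °C, and accumulation
starting (biofix) January 1, the flight is well aligned across years. The
10 °C base reflects the sawfly's chilling/diapause biology (development
effectively stops below it) and 30 °C is near the larval developmental
optimum.

`wssphen` implements the full modelling chain behind such a phenology
model: degree-day accumulation from daily weather, two complementary
characterisations of flight timing (a coefficient-isolation Poisson
random-effects model and a cumulative-proportion probit model), a model of
what drives flight *magnitude* between site-years, and a seeded simulator
that generates multi-site, multi-year datasets with the statistical
structure these models assume, so every stage is testable end to end
without access to raw monitoring data.

# Single-sine degree-days

The daily temperature trajectory is idealised as one sine wave between the
day's minimum and maximum. Writing $M = (T_{max}+T_{min})/2$ and
$A = (T_{max}-T_{min})/2$, the day's degree-days with base $B$ and a
*horizontal* cutoff at the upper threshold $U$ are

$$\mathrm{DD} \;=\; \frac{1}{2\pi}\int_0^{2\pi}
  \max\{0,\ \min(M + A\sin t,\ U) - B\}\,dt .$$

`daily_single_sine_dd()` evaluates this exactly by the classical six-case
analysis (the Baskerville–Emin construction extended with the upper
cutoff), distinguishing days entirely below $B$, entirely above $U$,
entirely between the thresholds, and the three intercepted geometries. The
horizontal cutoff — temperature above $U$ contributes as if it equalled
$U$ — is the standard convention in the phenology literature and bounds the
daily value by $U - B$. The closed form is tested against blind numerical
quadrature of the defining integral on a thousand random days covering all
six cases, to $10^{-6}$ °C·day; adaptive quadrature is used only as the
test oracle, never in the computation.

Degree-day totals are scale-equivariant: computing with Fahrenheit inputs
and thresholds 50/86 °F gives exactly $9/5$ times the Celsius value, with
no offset, so the Celsius landmarks 148/224/354 GDD are 266/403/637 FDD.

`accumulate_gdd()` restarts the running sum at the biofix of each calendar
year. Years in a series that begin after their biofix carry no valid
accumulation and are omitted (they remain available as context, e.g. the
prior autumn for winter snowfall sums). The simple-average method
$\max(0, \min(M, U) - B)$ is included only as the inferior comparison
baseline.

## Weather input

Daily weather arrives as CSV (`date,tmin_c,tmax_c,precip_mm[,snow_mm]`,
remappable and unit-convertible via a small dialect config).
`validate_and_fill()` enforces $T_{min} \le T_{max}$ (offending records are
removed, not swapped — sensor errors should not silently become data) and
calendar continuity: gaps of at most `max_gap = 3` days are filled by
linear interpolation of the temperatures with precipitation set to zero
(degree-days need a continuous temperature record, whereas invented
rainfall would bias the environmental covariates); longer gaps are treated
as a data-quality failure. No public convention exists for handling missing
station days in this setting; the interpolation rule is this package's own
choice and is idempotent by construction.

# Flight timing I: coefficient isolation

`fit_capture_model()` fits sweep-net captures per 100 sweeps as Poisson
counts with log link and independent random intercepts:

```
count ~ 1 + (1 | gdd_bin) + (1 | precip_bin) + (1 | site_year) + (1 | site_id)
```

The precipitation, site-by-year, and site terms exist only to absorb
variance from those sources; the conditional modes (BLUPs) of the GDD-bin
intercepts then isolate the relative over/under-abundance of captures at
each degree-day accumulation. Continuous GDD must become factor levels for
this; the package bins at 10 GDD by default (about two days of accumulation
near the flight), a balance between resolution and data per level, and
mirrors the treatment for cumulative precipitation (10 mm bins).
Estimation is penalised (Laplace) likelihood via `lme4`; conditional
modes, not marginal means, are extracted, and they are centred to mean
zero across bins so that sign carries meaning: positive means
above-average relative abundance.

`smooth_and_detect()` passes the centred coefficients through a penalised
cubic regression spline (basis dimension 10, smoothness by GCV, via
`mgcv`), evaluates it on a 1-GDD grid, and reads off the phenology events:
emergence **start** where the smooth crosses from non-positive to positive
(position refined by linear interpolation between grid points), **peak**
at the grid argmax, and **end** at the first crossing back after the peak.
A curve that touches zero without changing sign is not a crossing, and a
curve still positive at a grid boundary triggers a warning that the flight
was not fully observed.

# Flight timing II: cumulative-proportion probit

Pooling all captures, sorting by cumulative GDD, merging ties, and dividing
the running total by the grand total yields a cumulative emergence curve
(`cumulative_proportion()`). A probit regression of that proportion on GDD,

$$\Phi^{-1}(p) = \alpha + \beta g,$$

is exactly the statement that emergence times are Gaussian on the GDD axis
with centre $\mu = -\alpha/\beta$ and spread $\sigma = 1/\beta$.
`fit_probit()` estimates it by IRLS under a quasibinomial variance with
probit link; quasibinomial is a variance assumption, not a likelihood, so
the point estimates equal the binomial fit and the free dispersion only
rescales standard errors. Observations are the per-sample pooled
proportions, unweighted; boundary values 0 and 1 are retained and handled
by the link's weighting rather than transformed directly. Any emergence
fraction is then answerable as $\mu + \sigma\,\Phi^{-1}(p)$
(`probit_quantile()`), rounded to integer GDD only when reported.

`fit_quantile_pairs()` solves the inverse problem — given a printed table
of (GDD, fraction) landmarks, recover the implied Gaussian by ordinary
least squares of GDD on $\Phi^{-1}(p)$. Applied to the reference quantile
table for Colorado winter wheat (`wss_reference_quantiles()`), this gives
$\mu \approx 222.6$ and $\sigma \approx 41.8$ GDD, which is where the
simulator's defaults (223 and 42) come from.

# Flight magnitude: environmental factors

`summarize_site_year()` reduces each site-year to a response (mean capture
per 100 sweeps across the season's sampling dates) and ten covariates: day
of year of first detection; emergence length (first to last positive
sampling date, inclusive); mean GDD per day across that window; prior
winter snowfall (October 1 of the previous year through March 31 — the
window is not standardised anywhere, so it is exposed rather than
hard-coded); rainfall from the biofix to the day before first detection;
rainfall during the flight; and the min/max temperature extremes before
and during the flight. `fit_env_model()` fits the Gaussian identity-link
mixed model with random intercepts for year and site (the response is a
seasonal mean, for which the identity scale is the natural choice, and the
reference coefficient scales are consistent with it), then backward
selection removes the single least significant fixed term with $p >
\alpha$ (default 0.05) per step until all survivors are significant; the
random effects are never candidates for removal. Fixed-term tests use
Satterthwaite degrees of freedom (`lmerTest`); the year and site effects
are reported with likelihood-ratio tests.

One statistical caveat documented deliberately: at realistic effect sizes
(coefficients of a few tenths against residual noise of ~2.7 captures),
several true effects have population $t$-values near 2, so backward
selection at $\alpha = 0.05$ retains them with power well below one. Users
should read a dropped term as "not demonstrable at this sample size", not
"absent". The retention behaviour is characterised by simulation in the
package's tests.

# The simulator

`simulate_study()` is first-class, tested code, not a fixture. Its layers:

* **Weather** (`simulate_weather()`): daily mean temperature follows a
  sinusoidal annual cycle (coldest mid-January) plus Gaussian noise;
  tmin/tmax sit half a jittered diurnal range either side; daily moisture
  is Bernoulli–Gamma and falls as snow on sub-freezing days. The default
  climate (annual mean 8.3 °C, amplitude 9.4 °C, diurnal range 14 ± 3 °C,
  day-to-day noise 3.5 °C, moisture Bernoulli(0.35) · Gamma(1.2, 3.6) mm)
  was calibrated once, before the recovery tests were written, to three
  field benchmarks: mean single-sine accumulation of ~5.4 GDD/day over
  May 15–June 15, January-to-flight rainfall inside the observed
  69–257 mm range, and 223 GDD reached near the end of May. Verified over
  120 simulated years: ~5.6 GDD/day, rainfall 89–219 mm, 223 GDD at
  median day-of-year 154.
* **Timing**: emergence lives on the GDD axis, not the calendar — the
  expected capture at cumulative GDD $g$ is proportional to
  $\exp\{-(g-\mu)^2/2\sigma^2\}$ with defaults $\mu = 223$, $\sigma = 42$
  from the quantile-table fit above. Weekly sampling runs April 15 to
  June 20 (weekly is the cadence matching the reference capture figures;
  the interval is a parameter).
* **Magnitude**: per site-year, the log of the expected *peak* capture is
  an intercept (default $\log 25$) plus the reference covariate effects
  (`wss_reference_env_effects()`) applied to that site-year's simulated
  covariates, plus site and year random effects (SD 0.5 each — producing
  between-year totals varying by roughly an order of magnitude, as real
  monitoring series do) and residual noise (SD 0.2). The covariate
  effects are centred on the *generator's own* expected covariate values
  (`flight_scenario(env_centers=)`), not on the reference means: the
  simulated High Plains climate that meets the degree-day calibration has
  slightly cooler covariate means, and centring elsewhere would merely
  shift every site-year's abundance by a constant factor while leaving
  the coefficients — the quantities the recovery tests target — untouched.
* **Counts** are Poisson, consistent with the dispersion of observed
  captures, and every draw flows from one seed, so studies are
  byte-reproducible.

For recovery studies of the environmental model specifically,
`simulate_env_summaries()` bypasses the weather layer and draws covariates
uniformly over their reference ranges with a specified noise SD (default
2.7), which makes the true signal-to-noise of each coefficient exactly
computable.

## What the simulator does and does not emulate

It reproduces the statistical skeleton the models assume: Gaussian flight
profile on thermal time, Poisson counts, log-scale site/year heterogeneity,
covariate-linked magnitude. It does not simulate spatial correlation
between sites, within-season weather autocorrelation, observer effects,
sex-biased emergence, or mechanistic diapause physiology. Passing recovery
tests therefore demonstrate that the estimators recover the parameters of
this data-generating process at realistic sample sizes — not that field
data satisfy those assumptions.

One intentional subtlety: because spring accumulation accelerates, weekly
*calendar* sampling is denser per unit GDD before the peak than after, so
the pooled capture mass is slightly left-weighted on the GDD axis and the
probit fit recovers a centre 4–5 GDD below the generator's $\mu$ at the
default study size. Real weekly monitoring data share this geometry; it is
a property of the design, not an estimator bug, and it sits comfortably
inside the ±5 GDD recovery tolerance used in the tests.

# Numerical choices and degenerate inputs

* Bin boundaries are left-closed, labels are midpoints; `bin_gdd(x, w)`
  puts a value exactly on a boundary into the upper bin.
* "Before $X$ GDD" is strict ($< X$); "peak ± 10" is the closed interval.
* Ties in cumulative GDD are pooled (counts summed) before proportions are
  formed, so the emergence curve is a function of GDD.
* A flat day ($T_{min}=T_{max}=c$) degenerates exactly to
  $\max(0, \min(c,U)-B)$.
* All-zero captures: `cumulative_proportion()` refuses (no curve exists);
  `summarize_site_year()` returns `mean_capture = 0` with timing
  covariates flagged `NA`, and such rows are dropped (with a message)
  before the environmental fit.
* Fewer than 3 interior proportion points, fewer than 2 distinct GDD bins,
  fewer than 2 site-years, or fewer than 5 bins to smooth: each raises an
  informative error rather than a silent degenerate fit.
* Singular random-effect fits (a variance estimated at zero) are allowed —
  expected, for instance, when the generating process has no site/year
  heterogeneity.

# Problem sizes

The bundled studies used throughout the tests and the reproduction script
are 8 sites × 12 years with weekly sampling (≈ 960 samples, ≈ 30 GDD
bins), environmental recovery at n = 100 site-years with 50 replicates for
retention-rate estimates, and 120–200 simulated years for weather
calibration checks. These sizes mirror the scale of the motivating
monitoring programme while keeping a full test run in the low tens of
seconds.

# Known limitations

* The phenology landmarks shipped as reference values derive from eastern
  Colorado winter wheat; applying them elsewhere requires local validation.
* The GDD-bin width (10) and spline basis (10) are sensible defaults, not
  fitted quantities; very sparse data may need coarser bins.
* The environmental model's identity-link Gaussian response can in
  principle predict negative mean captures; at the reference effect sizes
  this is immaterial, but a log-link variant would be the natural next
  step if used for extrapolation.
* Backward selection inherits all the usual caveats of stepwise inference;
  reported p-values of the reduced model are conditional on the selection
  path.
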