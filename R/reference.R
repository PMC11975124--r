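#' Reference emergence quantiles for WSS in eastern Colorado winter wheat
#'
#' The published degree-day accumulations (base 10 degC, upper 30 degC,
#' biofix Jan 1) by which stated fractions of the adult wheat stem sawfly
#' flight have emerged, from thirteen years of sweep-net monitoring. These
#' pairs determine the Gaussian emergence distribution on the GDD axis that
#' the simulator and the probit model use as their reference: fitting a
#' probit line through them (see [fit_quantile_pairs()]) gives a flight
#' centred near 223 GDD with spread near 42 GDD.
#'
#' @return Data frame with columns `proportion` and `gdd`.
#' @export
#' @examples
#' fit_quantile_pairs(wss_reference_quantiles())
wss_reference_quantiles <- function() {
  data.frame(
    proportion = c(0.01, 0.05, 0.10, 0.50, 0.90, 0.95, 0.99),
    gdd = c(125, 154, 169, 223, 276, 291, 320)
  )
}

#' Reference phenology events for WSS in eastern Colorado winter wheat
#'
#' The published start / peak / end of the adult flight on the cumulative
#' degree-day axis (base 10 degC, upper 30 degC, biofix Jan 1), used as
#' simulator defaults and recovery targets.
#'
#' @return Named numeric vector `c(start = 148, peak = 224, end = 354)`
#'   in Celsius degree-days.
#' @export
wss_reference_events <- function() {
  c(start = 148, peak = 224, end = 354)
}

#' Reference environmental effects on WSS population magnitude
#'
#' The covariates retained by the published site-year population-magnitude
#' model, with their observed ranges, means, and fitted coefficients
#' (response: mean adult WSS per 100 sweeps over the season). Used as the
#' simulator's default effect sizes and covariate ranges.
#'
#' @return Data frame with columns `term`, `min`, `max`, `mean`,
#'   `coefficient`, `std_error`.
#' @export
wss_reference_env_effects <- function() {
  data.frame(
    term = c("emergence_length", "prior_rainfall", "tmin_during",
             "tmax_before", "tmax_during"),
    min = c(6, 68.6, -1.7, 27.2, 24.4),
    max = c(43, 256.5, 6.7, 32.8, 37.2),
    mean = c(21, 147.1, 4.5, 30.1, 29.4),
    coefficient = c(0.058, -0.021, 0.348, 0.300, -0.407),
    std_error = c(0.029, 0.006, 0.112, 0.136, 0.071)
  )
}
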