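#' Probit model of cumulative emergence over degree-days
#'
#' Fits `Phi^-1(p) = intercept + slope * gdd` to a cumulative-proportion
#' emergence curve by iteratively reweighted least squares under a
#' quasibinomial variance with a probit link. Because quasibinomial is a
#' variance assumption rather than a likelihood, the point estimates equal
#' the binomial-probit fit; the free dispersion only rescales standard
#' errors. A probit regression of cumulative emergence on GDD is equivalent
#' to assuming Gaussian emergence times on the GDD axis, so the fit is
#' reported both as (intercept, slope) and as the Gaussian location/scale
#' `mu = -intercept/slope`, `sigma = 1/slope`.
#'
#' Boundary proportions (0 and 1) are retained: the IRLS weights, not a
#' direct probit transform of the data, handle them.
#'
#' @param curve A `cumulative_curve` from [cumulative_proportion()] with at
#'   least 3 points whose proportions lie strictly in (0, 1).
#' @return A `probit_fit`: list with `intercept`, `slope`, `mu`, `sigma`,
#'   `n_points`, `r_squared` (squared correlation between fitted and
#'   observed proportions), and `dispersion`.
#' @export
#' @examples
#' g <- seq(100, 350, by = 50)
#' curve <- data.frame(cum_gdd = g, cum_proportion = pnorm((g - 223) / 42))
#' fit_probit(curve)
fit_probit <- function(curve) {
  df <- as.data.frame(curve)
  if (!all(c("cum_gdd", "cum_proportion") %in% names(df))) {
    stop("curve must have cum_gdd and cum_proportion columns", call. = FALSE)
  }
  interior <- df$cum_proportion > 0 & df$cum_proportion < 1
  if (sum(interior) < 3) {
    stop("need at least 3 points with proportions strictly in (0, 1); got ",
         sum(interior), call. = FALSE)
  }
  fit <- stats::glm(cum_proportion ~ cum_gdd, data = df,
                    family = stats::quasibinomial(link = "probit"))
  co <- stats::coef(fit)
  if (!is.finite(co[2]) || co[2] <= 0) {
    stop("fitted probit slope is not positive; emergence proportions must ",
         "increase with GDD", call. = FALSE)
  }
  structure(list(
    intercept = unname(co[1]),
    slope = unname(co[2]),
    mu = unname(-co[1] / co[2]),
    sigma = unname(1 / co[2]),
    n_points = nrow(df),
    r_squared = stats::cor(stats::fitted(fit), df$cum_proportion)^2,
    dispersion = summary(fit)$dispersion
  ), class = "probit_fit")
}

#' @export
print.probit_fit <- function(x, ...) {
  cat("Probit emergence model on the cumulative degree-day axis\n")
  cat(sprintf("  mu (50%% emergence): %.1f GDD   sigma (spread): %.1f GDD\n",
              x$mu, x$sigma))
  cat(sprintf("  intercept %.4f, slope %.5f, n = %d, R^2 = %.3f\n",
              x$intercept, x$slope, x$n_points, x$r_squared))
  invisible(x)
}

#' Degree-day accumulation for a given emergence fraction
#'
#' Inverts a probit emergence fit: the GDD by which a proportion `p` of the
#' flight has emerged is `mu + sigma * Phi^-1(p)`.
#'
#' @param fit A `probit_fit`.
#' @param p Proportion(s) strictly in (0, 1).
#' @return GDD value(s), unrounded (round only for reporting).
#' @export
#' @examples
#' fit <- fit_quantile_pairs(wss_reference_quantiles())
#' round(probit_quantile(fit, c(0.05, 0.5, 0.95)))
probit_quantile <- function(fit, p) {
  stopifnot(inherits(fit, "probit_fit"))
  if (any(p <= 0 | p >= 1)) {
    stop("emergence proportions must lie strictly in (0, 1)", call. = FALSE)
  }
  fit$mu + fit$sigma * stats::qnorm(p)
}

#' Fit a probit line through (GDD, proportion) quantile pairs
#'
#' Recovers the Gaussian emergence distribution implied by a table of
#' emergence quantiles: ordinary least squares of GDD on the standard-normal
#' quantile of the proportion, `gdd = mu + sigma * Phi^-1(p)`. With the
#' reference quantile table ([wss_reference_quantiles()]) this yields the
#' flight centre and spread used throughout the package (mu ~ 223, sigma
#' ~ 42 GDD).
#'
#' @param pairs Data frame with columns `gdd` and `proportion` (at least two
#'   pairs, proportions strictly in (0, 1), no duplicated proportions).
#' @return A `probit_fit` (with `r_squared` from the least-squares line).
#' @export
#' @examples
#' fit_quantile_pairs(data.frame(proportion = c(0.25, 0.75),
#'                               gdd = 200 + 30 * qnorm(c(0.25, 0.75))))
fit_quantile_pairs <- function(pairs) {
  df <- as.data.frame(pairs)
  if (!all(c("gdd", "proportion") %in% names(df))) {
    stop("pairs must have gdd and proportion columns", call. = FALSE)
  }
  if (nrow(df) < 2) stop("need at least 2 quantile pairs", call. = FALSE)
  if (any(df$proportion <= 0 | df$proportion >= 1)) {
    stop("proportions must lie strictly in (0, 1)", call. = FALSE)
  }
  if (anyDuplicated(df$proportion)) {
    stop("duplicated proportions in quantile pairs", call. = FALSE)
  }
  z <- stats::qnorm(df$proportion)
  fit <- stats::lm(gdd ~ z, data = data.frame(gdd = df$gdd, z = z))
  mu <- unname(stats::coef(fit)[1])
  sigma <- unname(stats::coef(fit)[2])
  if (!is.finite(sigma) || sigma <= 0) {
    stop("quantile pairs imply a non-positive spread; gdd must increase ",
         "with proportion", call. = FALSE)
  }
  structure(list(
    intercept = -mu / sigma,
    slope = 1 / sigma,
    mu = mu,
    sigma = sigma,
    n_points = nrow(df),
    r_squared = 1 - sum(stats::resid(fit)^2) / sum((df$gdd - mean(df$gdd))^2),
    dispersion = NA_real_
  ), class = "probit_fit")
}
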