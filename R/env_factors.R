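#' Summarise one site-year for the environmental-factors model
#'
#' Computes the site-year response and covariates: the mean capture per 100
#' sweeps over the season's sampling dates, and summaries of the weather
#' before and during the observed flight. The flight window runs from the
#' first to the last sampling date with a positive count; the "before"
#' window runs from the biofix to the day before first detection; prior
#' winter snowfall is summed from October 1 of the previous year through
#' March 31. Temperature extremes are the min of daily `tmin` / max of daily
#' `tmax` over the relevant window; `mean_gdd_per_day` is the degree-day
#' accumulation across the flight window divided by its length in days.
#'
#' @param samples Sweep samples for a single site-year.
#' @param weather The `weather_series` for that site (ideally covering the
#'   prior October onward; the snowfall sum uses whatever is covered).
#' @param gdd The matching `gdd_series`.
#' @param params Degree-day parameters (for the biofix; default
#'   [degree_day_params()]).
#' @return One-row data frame of class `site_year_summary` row: `site_id`,
#'   `year`, `mean_capture`, `first_detection_doy`, `emergence_length`,
#'   `mean_gdd_per_day`, `prior_snow`, `prior_rainfall`, `rain_during`,
#'   `tmin_before`, `tmin_during`, `tmax_before`, `tmax_during`. If no
#'   captures occurred, `mean_capture` is 0 and the timing covariates are
#'   `NA`.
#' @export
summarize_site_year <- function(samples, weather, gdd,
                                params = degree_day_params()) {
  if (nrow(samples) == 0) stop("no samples for this site-year", call. = FALSE)
  if (length(unique(samples$site_id)) != 1 || length(unique(samples$year)) != 1) {
    stop("samples must come from exactly one site-year", call. = FALSE)
  }
  base <- data.frame(site_id = samples$site_id[1], year = samples$year[1],
                     mean_capture = mean(samples$count))
  pos <- samples$date[samples$count > 0]
  if (length(pos) == 0) {
    cov <- stats::setNames(as.list(rep(NA_real_, 10)),
                           c("first_detection_doy", "emergence_length",
                             "mean_gdd_per_day", "prior_snow", "prior_rainfall",
                             "rain_during", "tmin_before", "tmin_during",
                             "tmax_before", "tmax_during"))
  } else {
    cov <- window_covariates(weather, gdd, min(pos), max(pos),
                             samples$year[1], params)
  }
  cbind(base, as.data.frame(cov))
}

#' Summarise every site-year of a study
#'
#' Applies [summarize_site_year()] across the site-years of a simulated or
#' assembled study.
#'
#' @param samples Sweep samples for all site-years.
#' @param weather_by,gdd_by Named lists keyed `"<site>_<year>"` (as produced
#'   by [simulate_study()]), or single objects shared by all site-years.
#' @param params Degree-day parameters.
#' @return Data frame with one row per site-year.
#' @export
summarize_study <- function(samples, weather_by, gdd_by,
                            params = degree_day_params()) {
  keys <- unique(paste0(samples$site_id, "_", samples$year))
  rows <- lapply(keys, function(k) {
    sub <- samples[paste0(samples$site_id, "_", samples$year) == k, ,
                   drop = FALSE]
    w <- if (inherits(weather_by, "weather_series")) weather_by else weather_by[[k]]
    g <- if (inherits(gdd_by, "gdd_series")) gdd_by else gdd_by[[k]]
    summarize_site_year(sub, w, g, params)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

env_fixed_terms <- c("first_detection_doy", "emergence_length",
                     "mean_gdd_per_day", "prior_snow", "prior_rainfall",
                     "rain_during", "tmin_before", "tmin_during",
                     "tmax_before", "tmax_during")

#' Environmental-factors model of population magnitude
#'
#' Fits mean site-year capture on the ten environmental covariates with
#' random intercepts for year and site (Gaussian response, identity link),
#' then performs backward selection: the fixed term with the largest
#' p-value above `alpha` is dropped and the model refit, one term per step,
#' until every remaining fixed term is significant at `alpha`. The random
#' effects are never dropped. Fixed-effect t-tests use Satterthwaite
#' denominator degrees of freedom; the random effects are tested by
#' likelihood-ratio tests of removing each one from the final model.
#'
#' @param summaries Site-year summaries from [summarize_study()] (rows with
#'   missing timing covariates, i.e. site-years without captures, are
#'   dropped with a message).
#' @param alpha Significance level for retention (default 0.05).
#' @param terms Character vector of candidate fixed terms (default all ten).
#' @return An `env_model` list: `terms` (coefficient table of the reduced
#'   model), `dropped_terms` (in drop order), `random_effect_tests`,
#'   `r_squared`, `deviance_explained`, `alpha`, `n`, and the final
#'   `lmerMod` as `model`.
#' @export
fit_env_model <- function(summaries, alpha = 0.05, terms = env_fixed_terms) {
  df <- as.data.frame(summaries)
  miss <- setdiff(c("mean_capture", "site_id", "year", terms), names(df))
  if (length(miss)) stop("summaries are missing columns: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  ok <- stats::complete.cases(df[, c("mean_capture", terms)])
  if (any(!ok)) {
    message("dropping ", sum(!ok),
            " site-year(s) with missing covariates (no captures)")
    df <- df[ok, , drop = FALSE]
  }
  if (nrow(df) < 20) stop("need at least 20 complete site-years; got ",
                          nrow(df), call. = FALSE)
  if (length(unique(df$year)) < 2 || length(unique(df$site_id)) < 2) {
    stop("need at least 2 years and 2 sites", call. = FALSE)
  }
  df$year_f <- factor(df$year)
  df$site_f <- factor(df$site_id)

  fit_once <- function(fixed) {
    fml <- stats::reformulate(c(fixed, "(1 | year_f)", "(1 | site_f)"),
                              response = "mean_capture")
    suppressMessages(suppressWarnings(
      lmerTest::lmer(fml, data = df, REML = TRUE,
                     control = lme4::lmerControl(check.conv.singular =
                                                   "ignore"))))
  }
  coef_table <- function(fit) {
    ct <- stats::coef(summary(fit))
    data.frame(name = rownames(ct), coefficient = ct[, "Estimate"],
               std_error = ct[, "Std. Error"], df = ct[, "df"],
               t_value = ct[, "t value"], p_value = ct[, "Pr(>|t|)"],
               row.names = NULL)
  }

  retained <- terms
  dropped <- character(0)
  fit <- fit_once(retained)
  repeat {
    ct <- coef_table(fit)
    cand <- ct[ct$name != "(Intercept)", , drop = FALSE]
    worst <- cand[which.max(cand$p_value), , drop = FALSE]
    if (nrow(cand) == 0 || worst$p_value <= alpha) break
    retained <- setdiff(retained, worst$name)
    dropped <- c(dropped, worst$name)
    if (length(retained) == 0) break
    fit <- fit_once(retained)
  }
  if (length(retained) == 0) {
    stop("backward selection dropped every fixed term at alpha = ", alpha,
         call. = FALSE)
  }
  y <- df$mean_capture
  fitted_c <- stats::fitted(fit)
  ran <- as.data.frame(suppressMessages(suppressWarnings(lmerTest::ranova(fit))))
  ran <- ran[-1, , drop = FALSE] # first row is the full model
  re_tests <- lapply(seq_len(nrow(ran)), function(i) {
    list(LRT = ran[i, "LRT"], df = ran[i, "Df"], p = ran[i, "Pr(>Chisq)"])
  })
  names(re_tests) <- sub("^\\(1 \\| (.*)\\)$", "\\1", rownames(ran))

  structure(list(
    terms = coef_table(fit),
    dropped_terms = dropped,
    random_effect_tests = re_tests,
    r_squared = stats::cor(fitted_c, y)^2,
    deviance_explained = 1 - sum((y - fitted_c)^2) / sum((y - mean(y))^2),
    alpha = alpha, n = nrow(df), model = fit
  ), class = "env_model")
}

#' @export
print.env_model <- function(x, ...) {
  cat(sprintf(
    "Environmental-factors model (n = %d site-years, alpha = %g)\n", x$n,
    x$alpha))
  print(x$terms, digits = 3)
  if (length(x$dropped_terms)) {
    cat("Dropped (in order):", paste(x$dropped_terms, collapse = ", "), "\n")
  }
  cat(sprintf("R^2 = %.3f, variance explained = %.1f%%\n", x$r_squared,
              100 * x$deviance_explained))
  invisible(x)
}

#' Simulate site-year summaries with known covariate effects
#'
#' Generates the covariate table directly (bypassing the weather and capture
#' simulators) for calibration and recovery studies of the
#' environmental-factors model: covariates are drawn uniformly over their
#' reference ranges, and the response is the linear model with the supplied
#' coefficients (applied to mean-centred covariates) plus optional site and
#' year random effects and Gaussian noise.
#'
#' @param n Number of site-years.
#' @param effects Data frame with `term`, `coefficient`, `min`, `max`,
#'   `mean`; default [wss_reference_env_effects()]. Covariates not listed
#'   are drawn over plausible default ranges with zero coefficient.
#' @param intercept Response level at reference-mean covariates
#'   (default 7.283, mean captures per 100 sweeps).
#' @param noise_sd Residual SD (default 2.7).
#' @param n_sites,n_years Grid of site and year labels the rows are spread
#'   over (default 10 x 10).
#' @param site_sd,year_sd Random-effect SDs (default 0, pure noise).
#' @param seed Optional integer seed.
#' @return Data frame shaped like [summarize_study()] output, with the
#'   generating coefficient vector in attribute `"truth"`.
#' @export
simulate_env_summaries <- function(n = 100,
                                   effects = wss_reference_env_effects(),
                                   intercept = 7.283, noise_sd = 2.7,
                                   n_sites = 10, n_years = 10,
                                   site_sd = 0, year_sd = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  # fallback ranges for covariates the supplied effects table does not cover
  default_ranges <- rbind(
    wss_reference_env_effects()[, c("term", "min", "max")],
    data.frame(
      term = c("first_detection_doy", "mean_gdd_per_day", "prior_snow",
               "rain_during", "tmin_before"),
      min = c(115, 3, 10, 2, -25),
      max = c(160, 8, 180, 90, -5)))
  ranges <- rbind(effects[, c("term", "min", "max")], default_ranges)
  ranges <- ranges[!duplicated(ranges$term), , drop = FALSE]
  ranges <- ranges[match(env_fixed_terms, ranges$term), , drop = FALSE]

  X <- vapply(seq_len(nrow(ranges)), function(j) {
    stats::runif(n, ranges$min[j], ranges$max[j])
  }, numeric(n))
  colnames(X) <- ranges$term
  beta <- stats::setNames(rep(0, length(env_fixed_terms)), env_fixed_terms)
  beta[effects$term] <- effects$coefficient
  centers <- stats::setNames((ranges$min + ranges$max) / 2, ranges$term)
  centers[effects$term] <- effects$mean

  site <- sprintf("site%02d", 1 + (seq_len(n) - 1) %% n_sites)
  year <- 2000 + 1 + (seq_len(n) - 1) %/% n_sites %% n_years
  site_eff <- stats::setNames(stats::rnorm(n_sites, 0, site_sd),
                              sprintf("site%02d", seq_len(n_sites)))
  year_eff <- stats::setNames(stats::rnorm(n_years, 0, year_sd),
                              as.character(2000 + seq_len(n_years)))
  y <- intercept + as.numeric((X - matrix(centers[colnames(X)], n,
                                          ncol(X), byrow = TRUE)) %*%
                                beta[colnames(X)]) +
    site_eff[site] + year_eff[as.character(year)] +
    stats::rnorm(n, 0, noise_sd)
  out <- data.frame(site_id = site, year = year, mean_capture = y,
                    as.data.frame(X))
  attr(out, "truth") <- list(beta = beta, intercept = intercept,
                             noise_sd = noise_sd)
  out
}
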