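#' Precision drift over the deployment period
#'
#' Ordinary least-squares regression of duplicate-pair precision on time of
#' operation, measured in days since the first observation. Reports the
#' usual simple-regression summary plus the fitted precision at the first
#' and last timestamps and the relative annual change,
#' `100 * slope * 365 / starting_precision` (origin-invariant, so it does
#' not depend on the choice of time origin).
#'
#' @param times Timestamps (POSIXct) or numeric days; span must be > 0.
#' @param precisions Pair precisions (dimensionless), same length, n >= 3;
#'   `NA` pairs dropped.
#' @return A `pa_trend_result` list: `n`, `intercept`, `intercept_se`,
#'   `slope` (per day), `slope_se`, `r2_adj`, `se_estimate`, `f`, `z`
#'   (slope/SE), `p_value`, `starting_precision`, `ending_precision`,
#'   `relative_annual_change_pct`.
#' @export
precision_trend <- function(times, precisions) {
  keep <- !is.na(times) & !is.na(precisions)
  times <- times[keep]; precisions <- precisions[keep]
  pa_assert(length(times) >= 3, "need at least 3 observations")
  if (inherits(times, "POSIXct")) {
    days <- as.numeric(times - min(times), units = "days")
  } else {
    days <- as.numeric(times) - min(as.numeric(times))
  }
  span <- max(days)
  if (span <= 0) pa_stop("degenerate time axis: all timestamps equal",
                         "paqc_domain_error")
  fit <- lm(precisions ~ days)
  sm <- suppressWarnings(summary(fit))
  co <- sm$coefficients
  slope <- co["days", "Estimate"]
  start_fit <- unname(predict(fit, newdata = data.frame(days = 0)))
  end_fit <- unname(predict(fit, newdata = data.frame(days = span)))
  structure(list(
    n = length(days),
    intercept = co["(Intercept)", "Estimate"],
    intercept_se = co["(Intercept)", "Std. Error"],
    slope = slope,
    slope_se = co["days", "Std. Error"],
    r2_adj = sm$adj.r.squared,
    se_estimate = sm$sigma,
    f = unname(sm$fstatistic["value"]),
    z = slope / co["days", "Std. Error"],
    p_value = co["days", "Pr(>|t|)"],
    starting_precision = start_fit,
    ending_precision = end_fit,
    relative_annual_change_pct = 100 * slope * 365 / start_fit,
    span_days = span
  ), class = "pa_trend_result")
}

#' @export
print.pa_trend_result <- function(x, ...) {
  cat(sprintf(
    "Precision drift: n=%d, slope %.3g/day (SE %.2g), z=%.1f, adj-R2=%.2g\n",
    x$n, x$slope, x$slope_se, x$z, x$r2_adj))
  cat(sprintf("  fitted precision %.4g -> %.4g over %.0f days (%+.1f%%/yr)\n",
              x$starting_precision, x$ending_precision, x$span_days,
              x$relative_annual_change_pct))
  invisible(x)
}

#' Relative annual change implied by a drift slope
#'
#' Reconstruction helper for published drift tables: the percentage change
#' in precision per year of operation relative to the starting level.
#'
#' @param slope Drift slope in precision units per day.
#' @param starting_precision Fitted precision at the start (> 0).
#' @return `100 * slope * 365 / starting_precision`.
#' @export
relative_annual_change <- function(slope, starting_precision) {
  pa_assert(all(starting_precision > 0), "starting precision must be > 0")
  100 * slope * 365 / starting_precision
}

#' Log-normal structure of a concentration series
#'
#' Orders the values, assigns each a normal score from a plotting-position
#' rule, and regresses log10(value) on the score -- the analytic form of a
#' log-probability plot. A log-normal sample falls on a straight line whose
#' intercept is log10(GM) and slope log10(GSD); the R-squared of the fit
#' measures how log-normal the series is (heavy upper tails, e.g. wildfire
#' episodes, pull it down).
#'
#' @param values Strictly positive concentrations (ug/m3). Zeros must be
#'   excluded upstream (see [zero_exclusion_report()]) -- they carry real
#'   information about vendor thresholding and are accounted, not plotted.
#' @param positions_rule `"blom"` ((i - 0.375)/(n + 0.25), the default
#'   normal-scores rule) or `"hazen"` ((i - 0.5)/n).
#' @return A `pa_qq_result` list: `n`, `gm`, `gsd`, `r2`, `positions_rule`,
#'   and `points` (tibble of normal score vs log10 value, for plotting).
#' @export
lognormal_probability_stats <- function(values,
                                        positions_rule = c("blom", "hazen")) {
  positions_rule <- match.arg(positions_rule)
  values <- values[!is.na(values)]
  if (any(values <= 0)) {
    pa_stop("values must be > 0: exclude and count zeros upstream (zero_exclusion_report)",
            "paqc_domain_error")
  }
  pa_assert(length(values) >= 3, "need at least 3 positive values")
  n <- length(values)
  v <- sort(values)
  i <- seq_len(n)
  p <- switch(positions_rule,
              blom = (i - 0.375) / (n + 0.25),
              hazen = (i - 0.5) / n)
  score <- qnorm(p)
  logv <- log10(v)
  fit <- lm(logv ~ score)
  sm <- suppressWarnings(summary(fit))
  structure(list(
    n = n,
    gm = 10^unname(coef(fit)[1]),
    gsd = 10^unname(coef(fit)[2]),
    r2 = sm$r.squared,
    positions_rule = positions_rule,
    points = tibble::tibble(score = score, log10_value = logv)
  ), class = "pa_qq_result")
}

#' @export
print.pa_qq_result <- function(x, ...) {
  cat(sprintf(
    "Log-probability fit (%s positions): n=%d, GM=%.3g ug/m3, GSD=%.3g, R2=%.4f\n",
    x$positions_rule, x$n, x$gm, x$gsd, x$r2))
  invisible(x)
}

#' Partition a series into positive values and counted zeros
#'
#' Vendor algorithms assign zero below an internal threshold; those records
#' cannot appear on a logarithmic axis but must be accounted for. Splits a
#' non-negative series into its positive part and an excluded-zero count.
#'
#' @param values Non-negative concentration series.
#' @return List with `positive` (the subset > 0), `n_total`, `n_excluded`,
#'   `fraction_excluded` (full precision; round to 2 d.p. for display).
#' @export
zero_exclusion_report <- function(values) {
  values <- values[!is.na(values)]
  pa_assert(all(values >= 0), "values must be >= 0")
  pos <- values[values > 0]
  n <- length(values)
  list(
    positive = pos,
    n_total = n,
    n_excluded = n - length(pos),
    fraction_excluded = if (n > 0) (n - length(pos)) / n else NA_real_
  )
}
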