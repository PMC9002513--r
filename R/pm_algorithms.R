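#' Size-bin scheme for optical particle counts
#'
#' Defines the particle-diameter intervals used to convert counts to mass and
#' the representative diameter assigned to each interval. The default is the
#' three smallest Plantower size categories, 0.3--0.5, 0.5--1.0 and
#' 1.0--2.5 um, whose sum covers PM2.5 (the two smallest cover PM1).
#'
#' @param bounds Two-column numeric matrix (or coercible) of interval bounds
#'   in um; intervals must be contiguous, strictly increasing and positive.
#' @param diameter_rule How to pick the representative diameter of each
#'   interval: `"geometric"` (sqrt(lo*hi), the default used for PurpleAir
#'   work), `"arithmetic"` ((lo+hi)/2), or `"explicit"` (supply `diameters`).
#' @param diameters Numeric vector of explicit representative diameters (um),
#'   required when `diameter_rule = "explicit"`. Lets users reproduce any
#'   published coefficient set, including rounded diameters.
#' @return An object of class `pa_bin_scheme`: a list with elements `bounds`,
#'   `diameters` and `diameter_rule`.
#' @examples
#' bin_scheme()$diameters  # 0.3873, 0.7071, 1.5811
#' @export
bin_scheme <- function(bounds = cbind(lo = c(0.3, 0.5, 1.0), hi = c(0.5, 1.0, 2.5)),
                       diameter_rule = c("geometric", "arithmetic", "explicit"),
                       diameters = NULL) {
  diameter_rule <- match.arg(diameter_rule)
  bounds <- matrix(as.numeric(as.matrix(bounds)), ncol = 2,
                   dimnames = list(NULL, c("lo", "hi")))
  pa_assert(nrow(bounds) >= 1 && all(is.finite(bounds)) && all(bounds > 0),
            "bin bounds must be finite and positive")
  pa_assert(all(bounds[, "hi"] > bounds[, "lo"]),
            "each bin must have hi > lo")
  if (nrow(bounds) > 1) {
    pa_assert(all(abs(bounds[-nrow(bounds), "hi"] - bounds[-1, "lo"]) < 1e-12),
              "bins must be contiguous (hi of one = lo of the next)")
  }
  scheme <- structure(
    list(bounds = bounds, diameters = NULL, diameter_rule = diameter_rule),
    class = "pa_bin_scheme"
  )
  if (diameter_rule == "explicit") {
    pa_assert(!is.null(diameters) && length(diameters) == nrow(bounds) &&
                all(diameters > 0),
              "explicit rule requires one positive diameter per bin",
              "paqc_config_error")
    scheme$diameters <- as.numeric(diameters)
  } else {
    scheme$diameters <- representative_diameters(scheme)
  }
  scheme
}

#' Representative diameter of each size bin
#'
#' Geometric rule: sqrt(lo*hi); arithmetic rule: (lo+hi)/2. For the 0.3--0.5
#' um bin these are 0.3873 and 0.4 um. Diameters are kept at full precision:
#' rounding sqrt(0.15) to 0.37 before cubing would bias the smallest-bin mass
#' by about 13%.
#'
#' @param scheme A [bin_scheme()].
#' @return Numeric vector of diameters in um, one per bin.
#' @export
representative_diameters <- function(scheme) {
  stopifnot(inherits(scheme, "pa_bin_scheme"))
  lo <- scheme$bounds[, "lo"]
  hi <- scheme$bounds[, "hi"]
  switch(scheme$diameter_rule,
    geometric  = sqrt(lo * hi),
    arithmetic = (lo + hi) / 2,
    explicit   = scheme$diameters
  )
}

#' Configuration of the count-to-mass conversion
#'
#' Parameters of the ALT-CF3 style conversion. The defaults are the values
#' established for PurpleAir PA-II monitors: particle density of water
#' (1 g/cm3), calibration factor 3.0 from gravimetric co-location
#' experiments, geometric-mean bin diameters, and a saturation limit of
#' 1000 ug/m3 (~1 mg/m3) above which the optics under-report.
#'
#' @param density Particle density in g/cm3 (> 0).
#' @param calibration_factor Dimensionless multiplier aligning the optical
#'   estimate with a reference method (> 0).
#' @param scheme A [bin_scheme()].
#' @param saturation_limit Upper credible concentration in ug/m3 (> 0);
#'   values at or above it are flagged, not dropped.
#' @return An object of class `pa_alt_config`. The counts-volume conversion
#'   is fixed at 1e4 dL per m3 (counts are reported per deciliter).
#' @export
alt_config <- function(density = 1.0, calibration_factor = 3.0,
                       scheme = bin_scheme(), saturation_limit = 1000) {
  pa_assert(is.numeric(density) && density > 0, "density must be > 0",
            "paqc_config_error")
  pa_assert(calibration_factor > 0, "calibration_factor must be > 0",
            "paqc_config_error")
  pa_assert(saturation_limit > 0, "saturation_limit must be > 0",
            "paqc_config_error")
  stopifnot(inherits(scheme, "pa_bin_scheme"))
  structure(
    list(density = density, calibration_factor = calibration_factor,
         scheme = scheme, saturation_limit = saturation_limit,
         dl_per_m3 = 1e4),
    class = "pa_alt_config"
  )
}

#' Difference cumulative "greater-than" counts into per-bin counts
#'
#' Plantower-style sensors report cumulative particle counts per deciliter
#' above each diameter threshold; the count in bin i is the difference of the
#' counts above its two bounding thresholds.
#'
#' @param counts_gt Numeric vector of cumulative counts at ascending
#'   thresholds (e.g. >0.3, >0.5, >1.0, >2.5 um), or a matrix with one row
#'   per record. Must be non-increasing across thresholds.
#' @return Per-bin counts: a vector of length `length(counts_gt) - 1`, or a
#'   matrix with one fewer column than the input.
#' @examples
#' cumulative_to_bins(c(1110, 110, 10, 0))  # 1000 100 10
#' @export
cumulative_to_bins <- function(counts_gt) {
  if (is.matrix(counts_gt)) {
    pa_assert(all(is.finite(counts_gt)) && all(counts_gt >= 0),
              "cumulative counts must be finite and >= 0")
    d <- counts_gt[, -ncol(counts_gt), drop = FALSE] -
      counts_gt[, -1, drop = FALSE]
    pa_assert(all(d >= 0),
              "cumulative counts must be non-increasing across ascending thresholds")
    return(d)
  }
  pa_assert(length(counts_gt) >= 2 && all(is.finite(counts_gt)) &&
              all(counts_gt >= 0),
            "cumulative counts must be finite and >= 0")
  d <- -diff(counts_gt)
  pa_assert(all(d >= 0),
            "cumulative counts must be non-increasing across ascending thresholds")
  d
}

# Mass coefficient per unit count (ug/m3 per count/dL) for each bin:
# CF * rho * (pi/6) d^3 * 1e-2, where 1e-2 combines 1e4 dL/m3 with the
# 1e-6 ug per g*um3/cm3 unit change.
alt_bin_coefficients <- function(config) {
  d <- representative_diameters(config$scheme)
  config$calibration_factor * config$density * (pi / 6) * d^3 * 1e-2
}

#' ALT-style mass concentration from size-bin counts
#'
#' Converts per-bin particle counts (per deciliter) to a mass concentration
#' by treating particles as spheres at each bin's representative diameter:
#' mass = CF x rho x 1e-2 x sum_i N_i (pi/6) d_i^3, in ug/m3. Using the two
#' smallest bins gives PM1, all three gives PM2.5.
#'
#' @param bins Numeric vector of per-bin counts (one per bin of the scheme),
#'   or a matrix with one row per record.
#' @param config An [alt_config()].
#' @param n_bins_used Number of leading bins summed: 2 for PM1, 3 for PM2.5.
#' @return Mass concentration(s) in ug/m3; zero iff all used bins are zero.
#' @examples
#' alt_pm(c(1000, 100, 10), alt_config())  # 2.089 ug/m3
#' @export
alt_pm <- function(bins, config = alt_config(), n_bins_used = 3L) {
  n_bins <- nrow(config$scheme$bounds)
  pa_assert(n_bins_used >= 1 && n_bins_used <= n_bins,
            "n_bins_used must be between 1 and the number of bins",
            "paqc_config_error")
  coefs <- alt_bin_coefficients(config)
  if (is.matrix(bins)) {
    pa_assert(ncol(bins) == n_bins,
              "bin count columns must match the bin scheme",
              "paqc_config_error")
    pa_assert(all(bins >= 0), "bin counts must be >= 0")
    return(as.numeric(bins[, seq_len(n_bins_used), drop = FALSE] %*%
                        coefs[seq_len(n_bins_used)]))
  }
  pa_assert(length(bins) == n_bins,
            "bin count length must match the bin scheme",
            "paqc_config_error")
  pa_assert(all(bins >= 0), "bin counts must be >= 0")
  sum(bins[seq_len(n_bins_used)] * coefs[seq_len(n_bins_used)])
}

#' Flag concentrations at or above the sensor saturation limit
#'
#' @param value Concentration(s) in ug/m3, >= 0.
#' @param config An [alt_config()]; the limit defaults to 1000 ug/m3.
#' @return Logical, `TRUE` where `value >= saturation_limit` (inclusive at
#'   the boundary). Saturated records remain in the data, flagged.
#' @export
flag_saturation <- function(value, config = alt_config()) {
  pa_assert(all(value >= 0, na.rm = TRUE), "values must be >= 0")
  value >= config$saturation_limit
}

#' Add ALT PM1/PM2.5 columns to a monitor series
#'
#' Convenience wrapper applying [cumulative_to_bins()] and [alt_pm()] to the
#' canonical count columns of a monitor series, adding `alt_pm1`, `alt_pm25`
#' and a logical `saturated` column.
#'
#' @param series A monitor series tibble (see [read_purpleair_csv()]).
#' @param config An [alt_config()].
#' @return The series with three columns added.
#' @export
compute_alt_pm <- function(series, config = alt_config()) {
  cnt <- as.matrix(series[, c("n_gt_0p3_dl", "n_gt_0p5_dl",
                              "n_gt_1p0_dl", "n_gt_2p5_dl")])
  bins <- cumulative_to_bins(cnt)
  series$alt_pm1 <- alt_pm(bins, config, n_bins_used = 2L)
  series$alt_pm25 <- alt_pm(bins, config, n_bins_used = 3L)
  series$saturated <- flag_saturation(series$alt_pm25, config)
  series
}

#' Count vendor-reported zero concentrations
#'
#' The Plantower CF1/ATM algorithms assign zero to all concentrations below
#' an internal threshold; this tabulates how much of a series is lost that
#' way. Exact zeros are counted; the fraction is carried at full precision
#' (round for display).
#'
#' @param values Vendor-reported PM2.5 series (ug/m3, >= 0; `NA` ignored).
#' @param sensor_id,location Labels carried into the report.
#' @return One-row tibble: `sensor_id`, `location`, `n_obs`, `n_zeros`,
#'   `fraction_zero`.
#' @export
count_reported_zeros <- function(values, sensor_id = NA_character_,
                                 location = NA_character_) {
  values <- values[!is.na(values)]
  pa_assert(all(values >= 0), "vendor PM values must be >= 0")
  n <- length(values)
  nz <- sum(values == 0)
  tibble::tibble(
    sensor_id = sensor_id, location = location,
    n_obs = n, n_zeros = nz,
    fraction_zero = if (n > 0) nz / n else NA_real_
  )
}
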