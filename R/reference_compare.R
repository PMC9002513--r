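#' Ratio of sensor to reference means with propagated standard error
#'
#' For a source experiment in which a sensor and a co-located reference
#' monitor measured the same aerosol, the comparison statistic is the ratio
#' of means, `R = mean(sensor) / mean(reference)`, with first-order
#' error propagation under independence:
#' `SE_R = R * sqrt((SE_s/mean_s)^2 + (SE_r/mean_r)^2)`,
#' each SE being the standard error of the mean (sd/sqrt(n)).
#'
#' @param sensor,reference Equal-length matched concentration series
#'   (ug/m3); reference mean must be > 0.
#' @param source Label of the source experiment.
#' @param saturated Optional logical vector (or scalar) marking sensor
#'   records at the saturation limit; any `TRUE` flags the result, since a
#'   saturated sensor depresses the ratio.
#' @return One-row tibble: `source`, `n`, `sensor_mean`, `sensor_se`,
#'   `reference_mean`, `reference_se`, `ratio`, `ratio_se`, `saturated`.
#' @export
ratio_with_propagated_se <- function(sensor, reference, source = NA_character_,
                                     saturated = FALSE) {
  keep <- !is.na(sensor) & !is.na(reference)
  sensor <- sensor[keep]; reference <- reference[keep]
  n <- length(sensor)
  if (n == 0 || length(reference) != n) {
    pa_stop("need equal-length, non-empty matched series (check upstream precision filtering losses)",
            "paqc_domain_error")
  }
  ms <- mean(sensor); mr <- mean(reference)
  if (mr <= 0) pa_stop("reference mean must be > 0", "paqc_domain_error")
  ses <- if (n > 1) sd(sensor) / sqrt(n) else 0
  ser <- if (n > 1) sd(reference) / sqrt(n) else 0
  ratio <- ms / mr
  tibble::tibble(
    source = source, n = n,
    sensor_mean = ms, sensor_se = ses,
    reference_mean = mr, reference_se = ser,
    ratio = ratio,
    ratio_se = ratio * sqrt((ses / ms)^2 + (ser / mr)^2),
    saturated = any(saturated)
  )
}

#' Expected sensor/reference ratio when density dominates
#'
#' An optical sensor computing mass with an assumed particle density will
#' read low against a reference calibrated on a denser aerosol roughly by
#' the density ratio; e.g. water density (1 g/cm3) against an Arizona Road
#' Dust calibration (2.6 g/cm3) predicts a ratio near 1/2.6 ~ 0.4.
#'
#' @param sensor_density,reference_calibrant_density Densities in g/cm3
#'   (> 0).
#' @return `sensor_density / reference_calibrant_density`.
#' @export
expected_density_ratio <- function(sensor_density, reference_calibrant_density) {
  pa_assert(all(sensor_density > 0) && all(reference_calibrant_density > 0),
            "densities must be > 0")
  sensor_density / reference_calibrant_density
}

#' Tabulate ratio results across source experiments
#'
#' @param results A tibble of rows from [ratio_with_propagated_se()] (or a
#'   list of such rows), typically one per source per algorithm.
#' @param algorithm Optional vector of algorithm labels, recycled to rows.
#' @return Tibble sorted by source label (then algorithm).
#' @export
experiment_table <- function(results, algorithm = NULL) {
  if (is.list(results) && !is.data.frame(results)) {
    results <- dplyr::bind_rows(results)
  }
  pa_assert(nrow(results) >= 1, "need at least one ratio result")
  if (!is.null(algorithm)) results$algorithm <- algorithm
  ord <- if ("algorithm" %in% names(results)) {
    order(results$source, results$algorithm)
  } else {
    order(results$source)
  }
  results[ord, ]
}
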