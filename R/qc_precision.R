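#' Duplicate-pair precision
#'
#' Precision of a duplicate reading is the absolute difference divided by the
#' sum, `|a - b| / (a + b)`: 0 for identical channels, 1 when one channel
#' reads zero, undefined (`NA`) when both do. It is scale-invariant, so ALT
#' values give the same precision under any calibration factor.
#'
#' @param a,b Non-negative PM2.5 readings (ug/m3); vectorised.
#' @return Precision in `[0, 1]`, `NA` where `a + b = 0`.
#' @examples
#' pair_precision(3, 1)  # 0.5
#' @export
pair_precision <- function(a, b) {
  if (any(a < 0, na.rm = TRUE) || any(b < 0, na.rm = TRUE)) {
    pa_stop("pair_precision requires non-negative readings",
            "paqc_domain_error")
  }
  s <- a + b
  ifelse(s > 0, abs(a - b) / s, NA_real_)
}

#' Filter paired observations by precision and account for the loss
#'
#' Retains pairs with precision strictly below the cutoff (the conventional
#' acceptance rule is "better than 20%", i.e. `precision < 0.2`). Pairs
#' whose two values are both zero -- the signature of vendor zero-assignment,
#' which never occurs for ALT values -- have undefined precision and are
#' counted as `lost_to_zero` before the precision filter is applied; a pair
#' with one zero and one positive value has precision 1 and is lost to the
#' cutoff, not to zeros.
#'
#' @param paired Paired-observation tibble from [pair_channels()].
#' @param cutoff Precision cutoff in (0, 1]; default 0.2.
#' @param precision_source `"self"`: filter on each pair's own precision;
#'   `"alt"`: filter on the precision of the companion ALT-CF3 pair at the
#'   same timestamp (pass it as `alt_reference`), used to put vendor values
#'   through the ALT acceptance mask.
#' @param alt_reference Companion ALT-CF3 paired tibble, required when
#'   `precision_source = "alt"`.
#' @return List with `filtered` (the retained tibble) and `loss`, a one-row
#'   tibble (`total_obs`, `lost_to_zero`, `lost_to_precision`, `remaining`,
#'   `fraction_lost`) satisfying
#'   `total_obs = lost_to_zero + lost_to_precision + remaining`.
#' @export
apply_precision_filter <- function(paired, cutoff = 0.2,
                                   precision_source = c("self", "alt"),
                                   alt_reference = NULL) {
  precision_source <- match.arg(precision_source)
  pa_assert(cutoff > 0 && cutoff <= 1, "cutoff must be in (0, 1]",
            "paqc_config_error")
  total <- nrow(paired)
  zero <- (paired$a_value + paired$b_value) == 0
  kept0 <- paired[!zero, , drop = FALSE]
  if (precision_source == "self") {
    accept <- !is.na(kept0$precision) & kept0$precision < cutoff
  } else {
    if (is.null(alt_reference)) {
      pa_stop("precision_source = 'alt' requires a companion alt_reference series",
              "paqc_config_error")
    }
    idx <- match(as.numeric(kept0$timestamp),
                 as.numeric(alt_reference$timestamp))
    ref_prec <- alt_reference$precision[idx]
    accept <- !is.na(ref_prec) & ref_prec < cutoff
  }
  filtered <- kept0[accept, , drop = FALSE]
  loss <- tibble::tibble(
    total_obs = total,
    lost_to_zero = sum(zero),
    lost_to_precision = nrow(kept0) - nrow(filtered),
    remaining = nrow(filtered),
    fraction_lost = if (total > 0) (total - nrow(filtered)) / total else NA_real_
  )
  list(filtered = filtered, loss = loss)
}

#' Summarise a precision distribution
#'
#' Mean, standard error of the mean, quartiles, 90th percentile and maximum
#' of a set of pair precisions -- the columns of the standard precision
#' table. Quantiles use linear interpolation between order statistics
#' (`stats::quantile` type 7).
#'
#' @param x Numeric vector of precisions, or a paired-observation tibble
#'   (its `precision` column is used; `NA` dropped).
#' @param algorithm,filter Labels carried into the summary row.
#' @return One-row tibble: `algorithm`, `filter`, `valid_n`, `mean`, `se`,
#'   `lower_quartile`, `median`, `upper_quartile`, `p90`, `max`.
#' @export
precision_summary <- function(x, algorithm = NA_character_,
                              filter = NA_character_) {
  if (is.data.frame(x)) x <- x$precision
  x <- x[!is.na(x)]
  if (!length(x)) {
    pa_stop("cannot summarise an empty precision collection",
            "paqc_domain_error")
  }
  q <- quantile(x, c(0.25, 0.5, 0.75, 0.9), names = FALSE, type = 7)
  tibble::tibble(
    algorithm = algorithm, filter = filter,
    valid_n = length(x),
    mean = mean(x),
    se = sd(x) / sqrt(length(x)),
    lower_quartile = q[1], median = q[2], upper_quartile = q[3],
    p90 = q[4], max = max(x)
  )
}

#' Per-sensor bias relative to the ensemble mean
#'
#' For sensors measuring a common atmosphere over a common period, each
#' sensor's relative bias is its mean concentration's percentage deviation
#' from the grand mean of all sensors; the overall bias is the mean of the
#' absolute per-sensor biases, with its standard error across sensors.
#'
#' @param sensor_means Named numeric vector of per-sensor mean PM2.5
#'   (ug/m3) over a common period; length >= 2, grand mean > 0.
#' @return List with `per_sensor` (tibble: `sensor`, `mean`, `bias_pct`),
#'   `grand_mean`, `overall_abs_bias_pct`, `overall_se_pct`.
#' @examples
#' relative_bias(c(s1 = 4, s2 = 6))  # biases -20%, +20%; overall 20%
#' @export
relative_bias <- function(sensor_means) {
  pa_assert(length(sensor_means) >= 2, "need at least 2 sensors")
  pa_assert(all(sensor_means >= 0), "sensor means must be >= 0")
  grand <- mean(sensor_means)
  pa_assert(grand > 0, "grand mean must be > 0")
  bias <- 100 * (sensor_means - grand) / grand
  nm <- names(sensor_means) %||% paste0("sensor_", seq_along(sensor_means))
  list(
    per_sensor = tibble::tibble(sensor = nm, mean = unname(sensor_means),
                                bias_pct = unname(bias)),
    grand_mean = grand,
    overall_abs_bias_pct = mean(abs(bias)),
    overall_se_pct = sd(abs(bias)) / sqrt(length(bias))
  )
}

#' Compare data loss between two algorithms on the same observations
#'
#' Places two loss reports from [apply_precision_filter()] side by side,
#' checking that they account for the same underlying observations and that
#' an ALT-labelled report carries no zero losses (the ALT conversion never
#' returns zero, since the smallest size bin is never empty).
#'
#' @param alt_report,cf1_report One-row loss tibbles for the ALT and vendor
#'   streams.
#' @return Two-row tibble (one per algorithm) with counts, remaining
#'   fractions, and the remaining-count difference in an attribute
#'   `alt_advantage`.
#' @export
data_loss_comparison <- function(alt_report, cf1_report) {
  if (alt_report$total_obs != cf1_report$total_obs) {
    pa_stop("loss reports do not cover the same observations",
            "paqc_consistency_error")
  }
  if (alt_report$lost_to_zero > 0) {
    pa_stop("ALT loss report claims zero-valued pairs; the ALT conversion never returns zero",
            "paqc_consistency_error")
  }
  out <- dplyr::bind_rows(
    dplyr::mutate(alt_report, algorithm = "ALT_CF3", .before = 1),
    dplyr::mutate(cf1_report, algorithm = "CF1", .before = 1)
  )
  out$fraction_remaining <- out$remaining / out$total_obs
  attr(out, "alt_advantage") <- alt_report$remaining - cf1_report$remaining
  out
}
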