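#' @section Canonical columns:
#' A monitor series is a tibble with one row per record of one channel:
#' `timestamp` (POSIXct, UTC), `monitor_id`, `channel` ("a"/"b"), `location`
#' ("indoor"/"outdoor"), cumulative particle counts per deciliter
#' `n_gt_0p3_dl`, `n_gt_0p5_dl`, `n_gt_1p0_dl`, `n_gt_2p5_dl`, and optional
#' vendor-reported `pm25_cf1`, `pm25_atm` (ug/m3).
#' @name paqc-data-model
#' @keywords internal
NULL

pa_count_cols <- c("n_gt_0p3_dl", "n_gt_0p5_dl", "n_gt_1p0_dl", "n_gt_2p5_dl")
pa_canonical_cols <- c("timestamp", "monitor_id", "channel", "location",
                       pa_count_cols, "pm25_cf1", "pm25_atm")

# Column vocabularies of the two real-world PurpleAir export formats.
pa_dialect_map <- function(dialect) {
  switch(dialect,
    simple = setNames(pa_canonical_cols, pa_canonical_cols),
    sdcard = c(timestamp = "UTCDateTime", monitor_id = "mac_address",
               channel = "channel", location = "location",
               n_gt_0p3_dl = "p_0_3_um", n_gt_0p5_dl = "p_0_5_um",
               n_gt_1p0_dl = "p_1_0_um", n_gt_2p5_dl = "p_2_5_um",
               pm25_cf1 = "pm2_5_cf_1", pm25_atm = "pm2_5_atm"),
    api = c(timestamp = "time_stamp", monitor_id = "sensor_index",
            channel = "channel", location = "location",
            n_gt_0p3_dl = "0.3_um_count", n_gt_0p5_dl = "0.5_um_count",
            n_gt_1p0_dl = "1.0_um_count", n_gt_2p5_dl = "2.5_um_count",
            pm25_cf1 = "pm2.5_cf_1", pm25_atm = "pm2.5_atm")
  )
}

#' Read a PurpleAir-style delimited file into a monitor series
#'
#' Reads one monitor's records (both channels) from CSV, normalises column
#' names to the canonical vocabulary, parses timestamps to UTC, sorts by
#' time, and drops rows whose cumulative counts are negative, non-finite or
#' increase across ascending size thresholds. Dropped-row counts are
#' attached as the `read_report` attribute.
#'
#' @param path Path to a delimited text file with a header row.
#' @param dialect Column vocabulary: `"simple"` (the canonical header written
#'   by [write_records_csv()]), `"sdcard"` (PurpleAir SD-card style,
#'   `p_0_3_um` etc.), or `"api"` (PurpleAir API style, `0.3_um_count` etc.).
#' @param column_map Optional named character vector overriding the dialect
#'   map, names being canonical column names.
#' @param monitor_id,location,channel Optional values used when the file
#'   lacks the corresponding column.
#' @return A tibble in canonical form, time-sorted, with attribute
#'   `read_report`: a list with `n_read`, `n_dropped_invalid_counts`,
#'   `n_kept`.
#' @seealso [write_records_csv()], [read_report()]
#' @export
read_purpleair_csv <- function(path, dialect = c("simple", "sdcard", "api"),
                               column_map = NULL, monitor_id = NULL,
                               location = NULL, channel = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    pa_stop(sprintf("cannot read '%s': no such file", path), "paqc_io_error")
  }
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  map <- pa_dialect_map(dialect)
  if (!is.null(column_map)) map[names(column_map)] <- column_map

  out <- tibble::tibble(.rows = nrow(raw))
  for (canon in pa_canonical_cols) {
    src <- map[[canon]]
    if (!is.null(src) && src %in% names(raw)) out[[canon]] <- raw[[src]]
  }
  if (!"monitor_id" %in% names(out)) {
    out$monitor_id <- if (is.null(monitor_id)) NA_character_ else monitor_id
  }
  if (!"location" %in% names(out)) {
    out$location <- if (is.null(location)) NA_character_ else location
  }
  if (!"channel" %in% names(out)) {
    out$channel <- if (is.null(channel)) NA_character_ else channel
  }
  missing_cols <- setdiff(c("timestamp", pa_count_cols), names(out))
  if (length(missing_cols)) {
    pa_stop(sprintf("no recognizable columns for: %s (dialect '%s')",
                    paste(missing_cols, collapse = ", "), dialect),
            "paqc_format_error")
  }
  for (pm in c("pm25_cf1", "pm25_atm")) {
    if (!pm %in% names(out)) out[[pm]] <- NA_real_
  }
  out$timestamp <- parse_utc(out$timestamp)
  out$monitor_id <- as.character(out$monitor_id)
  for (cc in pa_count_cols) out[[cc]] <- as.numeric(out[[cc]])

  n_read <- nrow(out)
  cnt <- as.matrix(out[, pa_count_cols])
  ok <- rowSums(!is.finite(cnt) | cnt < 0) == 0 & !is.na(out$timestamp)
  mono <- rowSums(cnt[, -1, drop = FALSE] > cnt[, -4, drop = FALSE]) == 0
  keep <- ok & mono
  keep[is.na(keep)] <- FALSE
  out <- out[keep, , drop = FALSE]
  out <- out[order(out$timestamp), pa_canonical_cols]
  attr(out, "read_report") <- list(
    n_read = n_read,
    n_dropped_invalid_counts = n_read - nrow(out),
    n_kept = nrow(out)
  )
  out
}

parse_utc <- function(x) {
  if (inherits(x, "POSIXct")) return(as.POSIXct(format(x, tz = "UTC"), tz = "UTC"))
  if (is.numeric(x)) return(as.POSIXct(x, origin = "1970-01-01", tz = "UTC"))
  x <- sub("Z$", "", as.character(x))
  x <- sub("T", " ", x, fixed = TRUE)
  as.POSIXct(x, tz = "UTC",
             tryFormats = c("%Y-%m-%d %H:%M:%OS", "%Y-%m-%d %H:%M",
                            "%Y/%m/%d %H:%M:%OS", "%Y-%m-%d"))
}

#' Extract the read/pairing report attached to a result
#'
#' @param x An object returned by [read_purpleair_csv()] or
#'   [pair_channels()].
#' @return The report list (`NULL` when absent).
#' @export
read_report <- function(x) {
  attr(x, "read_report") %||% attr(x, "pairing_report")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a monitor series to the canonical CSV form
#'
#' Writes the documented canonical header (`timestamp, monitor_id, channel,
#' location, n_gt_0p3_dl, n_gt_0p5_dl, n_gt_1p0_dl, n_gt_2p5_dl, pm25_cf1,
#' pm25_atm`) with ISO-8601 UTC timestamps. `read_purpleair_csv(dialect =
#' "simple")` inverts it exactly for finite values.
#'
#' @param series A canonical monitor series tibble.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_records_csv <- function(series, path) {
  out <- series[, pa_canonical_cols]
  out <- out[order(out$timestamp), ]
  out$timestamp <- format(out$timestamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  ok <- tryCatch({
    readr::write_csv(out, path, progress = FALSE)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) pa_stop(sprintf("cannot write '%s'", path), "paqc_io_error")
  invisible(path)
}

# One-to-one nearest-neighbour matching of two sorted numeric time vectors
# within a tolerance. Greedy in time order: each left point takes the nearest
# still-unused right point inside the window; deterministic, O(n) for
# regular cadences.
match_nearest <- function(t1, t2, tolerance) {
  n1 <- length(t1); n2 <- length(t2)
  i_out <- integer(min(n1, n2)); j_out <- integer(min(n1, n2))
  k <- 0L; j <- 1L
  for (i in seq_len(n1)) {
    while (j <= n2 && t2[j] < t1[i] - tolerance) j <- j + 1L
    if (j > n2) break
    best <- NA_integer_; bestd <- Inf; jj <- j
    while (jj <= n2 && t2[jj] <= t1[i] + tolerance) {
      d <- abs(t2[jj] - t1[i])
      if (d < bestd) { bestd <- d; best <- jj }
      jj <- jj + 1L
    }
    if (!is.na(best)) {
      k <- k + 1L
      i_out[k] <- i; j_out[k] <- best
      j <- best + 1L
    }
  }
  list(i = i_out[seq_len(k)], j = j_out[seq_len(k)])
}

#' Pair the two channels of a duplicate-sensor monitor
#'
#' Matches each channel-a record to the nearest channel-b record within a
#' time tolerance (one-to-one), and computes for every pair the mean
#' `mu = (a+b)/2`, the duplicate standard deviation `sigma = |a-b|/sqrt(2)`,
#' and the pair precision `|a-b|/(a+b)`. Precision is undefined (`NA`) when
#' `a + b = 0`. These satisfy the identity `mu/sigma = 1/(sqrt(2) precision)`
#' whenever both are defined.
#'
#' @param series A canonical monitor series containing both channels.
#' @param values Name of the per-record PM2.5 column to pair (e.g.
#'   `"alt_pm25"` after [compute_alt_pm()], or `"pm25_cf1"`).
#' @param tolerance_seconds Maximum |time difference| for a match; defaults
#'   to 60 s, half the nominal 2-min cadence.
#' @param algorithm Label stored in the result (`"ALT_CF3"`, `"CF1"`,
#'   `"ATM"`).
#' @return Tibble of paired observations: `timestamp` (channel a's),
#'   `a_value`, `b_value`, `mu`, `sigma`, `precision`, `algorithm`; with
#'   attribute `pairing_report` counting matched and unmatched records.
#' @export
pair_channels <- function(series, values = "alt_pm25",
                          tolerance_seconds = 60,
                          algorithm = c("ALT_CF3", "CF1", "ATM")) {
  algorithm <- match.arg(algorithm)
  pa_assert(tolerance_seconds >= 0, "tolerance_seconds must be >= 0")
  pa_assert(values %in% names(series),
            sprintf("column '%s' not found in series", values),
            "paqc_config_error")
  a <- series[series$channel == "a", ]
  b <- series[series$channel == "b", ]
  a <- a[order(a$timestamp), ]; b <- b[order(b$timestamp), ]
  m <- match_nearest(as.numeric(a$timestamp), as.numeric(b$timestamp),
                     tolerance_seconds)
  av <- a[[values]][m$i]
  bv <- b[[values]][m$j]
  out <- tibble::tibble(
    timestamp = a$timestamp[m$i],
    a_value = av, b_value = bv,
    mu = (av + bv) / 2,
    sigma = abs(av - bv) / sqrt(2),
    precision = pair_precision(av, bv),
    algorithm = algorithm
  )
  attr(out, "pairing_report") <- list(
    n_a = nrow(a), n_b = nrow(b), n_pairs = nrow(out),
    n_unmatched_a = nrow(a) - nrow(out),
    n_unmatched_b = nrow(b) - nrow(out)
  )
  out
}

#' Match indoor and outdoor paired series on time
#'
#' One-to-one nearest-neighbour match of two monitors' paired observations
#' (their pair means `mu`) within a time tolerance, producing the
#' indoor--outdoor concentration pairs used for infiltration and
#' distributional analysis.
#'
#' @param indoor,outdoor Paired-observation tibbles from [pair_channels()],
#'   time-sorted.
#' @param tolerance_seconds Maximum |time difference| for a match.
#' @return Tibble with `timestamp`, `indoor_value`, `outdoor_value`.
#' @export
match_locations <- function(indoor, outdoor, tolerance_seconds = 60) {
  pa_assert(tolerance_seconds >= 0, "tolerance_seconds must be >= 0")
  indoor <- indoor[order(indoor$timestamp), ]
  outdoor <- outdoor[order(outdoor$timestamp), ]
  m <- match_nearest(as.numeric(indoor$timestamp),
                     as.numeric(outdoor$timestamp), tolerance_seconds)
  tibble::tibble(
    timestamp = indoor$timestamp[m$i],
    indoor_value = indoor$mu[m$i],
    outdoor_value = outdoor$mu[m$j]
  )
}
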