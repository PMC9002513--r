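#' Default pipeline settings
#'
#' Reproduce-by-default settings of the full QA pipeline: calibration
#' factor 3, density 1 g/cm3, geometric bin diameters, precision cutoff 0.2,
#' LOD blocks of 100 with mu/sigma ratio 3, Blom plotting positions,
#' matching tolerance 60 s.
#'
#' @param cutoff Precision acceptance cutoff.
#' @param alt An [alt_config()].
#' @param block_size,ratio_threshold,max_fail_per_block LOD scan settings.
#' @param tolerance_seconds Channel/location matching tolerance.
#' @param positions_rule Plotting-position rule for log-probability fits.
#' @return A `pa_pipeline_config` list.
#' @export
pipeline_config <- function(cutoff = 0.2, alt = alt_config(),
                            block_size = 100L, ratio_threshold = 3,
                            max_fail_per_block = 5L,
                            tolerance_seconds = 60,
                            positions_rule = "blom") {
  structure(list(cutoff = cutoff, alt = alt, block_size = block_size,
                 ratio_threshold = ratio_threshold,
                 max_fail_per_block = max_fail_per_block,
                 tolerance_seconds = tolerance_seconds,
                 positions_rule = positions_rule),
            class = "pa_pipeline_config")
}

#' Run the full sensor-evaluation pipeline
#'
#' End-to-end orchestration over a manifest of monitor files: read each
#' CSV, compute ALT PM1/PM2.5 from the counts, pair the duplicate channels
#' under both the ALT and vendor CF1 values, tabulate vendor zeros per
#' channel, apply the precision cutoff to both streams and compare the data
#' loss, estimate the detection limit (block scan and exact definition) on
#' the accepted ALT pairs, regress precision on time, and fit the
#' log-normal probability structure of the accepted concentrations. If the
#' manifest contains both an indoor and an outdoor monitor their accepted
#' ALT pair means are matched on time. Deterministic given inputs and
#' configuration.
#'
#' @param manifest Data frame with columns `monitor_id`, `location`, `path`
#'   (one row per monitor CSV in canonical form), or a character vector of
#'   paths (ids/locations then read from the files).
#' @param out_dir Output directory; a `run_summary.json` and per-table CSVs
#'   are written there. Partial outputs are removed if a stage fails.
#' @param config A [pipeline_config()].
#' @return Invisibly, the run summary as a nested list (also serialised to
#'   JSON).
#' @export
run_pipeline <- function(manifest, out_dir, config = pipeline_config()) {
  if (is.character(manifest)) {
    manifest <- tibble::tibble(monitor_id = NA_character_,
                               location = NA_character_, path = manifest)
  }
  for (p in manifest$path) {
    if (!file.exists(p)) {
      pa_stop(sprintf("[manifest] input file missing: %s", p),
              "paqc_io_error")
    }
  }
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  written <- character(0)
  emit_csv <- function(df, name) {
    p <- file.path(out_dir, name)
    readr::write_csv(df, p, progress = FALSE)
    written <<- c(written, p)
    p
  }

  stage <- "setup"
  result <- tryCatch({
    monitors <- list()
    for (r in seq_len(nrow(manifest))) {
      stage <- sprintf("read[%s]", manifest$path[r])
      series <- read_purpleair_csv(manifest$path[r], dialect = "simple",
                                   monitor_id = manifest$monitor_id[r],
                                   location = manifest$location[r])
      if (!is.na(manifest$monitor_id[r])) {
        series$monitor_id <- manifest$monitor_id[r]
      }
      if (!is.na(manifest$location[r])) {
        series$location <- manifest$location[r]
      }
      id <- series$monitor_id[1]
      loc <- series$location[1]
      message(sprintf("[read] %s (%s): %d records kept, %d dropped",
                      id, loc, attr(series, "read_report")$n_kept,
                      attr(series, "read_report")$n_dropped_invalid_counts))

      stage <- sprintf("compute[%s]", id)
      series <- compute_alt_pm(series, config$alt)

      stage <- sprintf("qc[%s]", id)
      alt_pairs <- pair_channels(series, "alt_pm25",
                                 config$tolerance_seconds, "ALT_CF3")
      cf1_pairs <- pair_channels(series, "pm25_cf1",
                                 config$tolerance_seconds, "CF1")
      zero_reports <- dplyr::bind_rows(lapply(c("a", "b"), function(ch) {
        count_reported_zeros(series$pm25_cf1[series$channel == ch],
                             sensor_id = paste0(id, ch), location = loc)
      }))
      alt_f <- apply_precision_filter(alt_pairs, config$cutoff)
      cf1_f <- apply_precision_filter(cf1_pairs, config$cutoff)
      loss <- data_loss_comparison(alt_f$loss, cf1_f$loss)
      loss$monitor_id <- id
      prec <- dplyr::bind_rows(
        precision_summary(alt_f$filtered, "ALT_CF3",
                          sprintf("precision < %g", config$cutoff)),
        precision_summary(cf1_f$filtered, "CF1",
                          sprintf("precision < %g", config$cutoff))
      )
      prec$monitor_id <- id
      message(sprintf("[qc] %s: ALT %d/%d kept, CF1 %d/%d kept",
                      id, alt_f$loss$remaining, alt_f$loss$total_obs,
                      cf1_f$loss$remaining, cf1_f$loss$total_obs))

      stage <- sprintf("lod[%s]", id)
      lod_block <- lod_block_search(alt_f$filtered, config$block_size,
                                    config$ratio_threshold,
                                    config$max_fail_per_block)
      lod_oracle <- lod_exact_oracle(alt_f$filtered,
                                     config$ratio_threshold)

      stage <- sprintf("trend[%s]", id)
      trend <- precision_trend(alt_f$filtered$timestamp,
                               alt_f$filtered$precision)

      stage <- sprintf("dist[%s]", id)
      zr <- zero_exclusion_report(alt_f$filtered$mu)
      qq <- lognormal_probability_stats(zr$positive,
                                        config$positions_rule)

      monitors[[id]] <- list(
        monitor_id = id, location = loc,
        read_report = attr(series, "read_report"),
        zero_reports = zero_reports,
        loss = loss, precision = prec,
        alt_pairs = alt_f$filtered,
        lod_block = lod_block, lod_oracle = lod_oracle,
        trend = trend, qq = qq
      )
    }

    stage <- "match_locations"
    matched <- NULL
    locs <- vapply(monitors, function(m) m$location, "")
    if (any(locs == "indoor") && any(locs == "outdoor")) {
      ind <- monitors[[which(locs == "indoor")[1]]]$alt_pairs
      out <- monitors[[which(locs == "outdoor")[1]]]$alt_pairs
      matched <- match_locations(ind, out, config$tolerance_seconds)
      message(sprintf("[match] %d indoor-outdoor pairs", nrow(matched)))
    }

    stage <- "write"
    emit_csv(dplyr::bind_rows(lapply(monitors, `[[`, "precision")),
             "precision_summary.csv")
    emit_csv(dplyr::bind_rows(lapply(monitors, `[[`, "loss")),
             "data_loss.csv")
    emit_csv(dplyr::bind_rows(lapply(monitors, `[[`, "zero_reports")),
             "zero_reports.csv")
    if (!is.null(matched)) emit_csv(matched, "matched_pairs.csv")

    summary <- list(
      software = list(package = "paqc",
                      version = as.character(utils::packageVersion("paqc"))),
      config = list(cutoff = config$cutoff,
                    calibration_factor = config$alt$calibration_factor,
                    density = config$alt$density,
                    block_size = config$block_size,
                    ratio_threshold = config$ratio_threshold,
                    tolerance_seconds = config$tolerance_seconds),
      inputs = lapply(seq_len(nrow(manifest)), function(r) {
        list(path = manifest$path[r],
             md5 = unname(tools::md5sum(manifest$path[r])))
      }),
      monitors = lapply(monitors, function(m) {
        list(
          monitor_id = m$monitor_id, location = m$location,
          read_report = m$read_report,
          zero_reports = m$zero_reports,
          loss = m$loss[, setdiff(names(m$loss), "monitor_id")],
          precision = m$precision[, setdiff(names(m$precision), "monitor_id")],
          lod = list(block = unclass(m$lod_block)[
                       c("lod", "n_total", "n_above", "fraction_above")],
                     oracle = unclass(m$lod_oracle)[
                       c("lod", "n_total", "n_above", "fraction_above")]),
          trend = unclass(m$trend),
          lognormal = unclass(m$qq)[c("n", "gm", "gsd", "r2",
                                      "positions_rule")]
        )
      }),
      n_matched_indoor_outdoor = if (is.null(matched)) 0L else nrow(matched)
    )
    sp <- file.path(out_dir, "run_summary.json")
    jsonlite::write_json(summary, sp, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    written <- c(written, sp)
    summary
  }, error = function(e) {
    unlink(written)
    pa_stop(sprintf("pipeline failed at stage '%s': %s", stage,
                    conditionMessage(e)), "paqc_pipeline_error")
  })
  invisible(result)
}
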