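#' Configuration of the synthetic dual-channel monitor generator
#'
#' Parameters of a generative model for a home with indoor and outdoor
#' duplicate-channel particle monitors. Outdoor PM2.5 follows a stationary
#' log-AR(1) process (log-normal marginal with the configured geometric mean
#' and GSD); indoor PM2.5 is the infiltrated outdoor fraction plus episodic
#' indoor source events (instant rise, exponential decay at the configured
#' air-change rate, emulating cooking and similar activities). Each monitor
#' has two channels with their own small multiplicative gain offsets and
#' per-record multiplicative noise; particle counts are obtained by
#' inverting the count-to-mass formula through fixed mass fractions and
#' (optionally) Poisson sampling. Vendor CF1 behaviour is emulated
#' phenomenologically: values are inflated by a multiplier and assigned zero
#' whenever an internal, jittered value falls below a threshold, so that
#' reported zeros co-occur with low-but-nonzero ALT values.
#'
#' The defaults describe an 18-month deployment at 2-min cadence in a
#' tight single-family home (air-change rate 0.25/h, infiltration 0.5) with
#' moderately clean ambient air; under them the indoor CF1 zero fraction
#' falls in the 12--23% range typical of vendor-reported indoor data.
#'
#' @param duration_hours Length of the simulated record (default 18 months).
#' @param step_seconds Sampling cadence (default 120 s).
#' @param outdoor_gm,outdoor_gsd Geometric mean (ug/m3) and geometric
#'   standard deviation of the stationary outdoor process.
#' @param ar1 Per-step autocorrelation of log outdoor concentration.
#' @param infiltration Equilibrium indoor/outdoor fraction absent indoor
#'   sources, in `[0, 1]`.
#' @param event_rate_per_day Mean number of indoor source events per day.
#' @param event_gm,event_gsd Log-normal parameters of event peak magnitude
#'   (ug/m3).
#' @param decay_ach Indoor event decay rate in air changes per hour.
#' @param gain_sd_log SD of per-channel log gain around 1.
#' @param noise_cv Per-channel, per-record multiplicative noise CV.
#' @param count_sampling `"poisson"` (counts drawn from Poisson at the
#'   expected value) or `"deterministic"` (rounded).
#' @param mass_fractions Fractions of PM2.5 mass in the three size bins;
#'   must sum to 1.
#' @param cf1_multiplier Vendor-value inflation relative to true PM.
#' @param cf1_zero_threshold Internal threshold (ug/m3, true-PM scale) below
#'   which the emulated vendor value is reported as zero.
#' @param cf1_jitter_sd_log SD of the log-normal jitter applied to the
#'   internal pre-threshold value (decouples zeros from the ALT value).
#' @param cf1_extra_noise_cv Additional multiplicative noise CV on vendor
#'   values (the vendor pathway is noisier than the raw counts).
#' @param seed Optional integer seed used by [make_fixture_dataset()].
#' @return A validated `pa_synth_config` list.
#' @export
synth_config <- function(duration_hours = 13140, step_seconds = 120,
                         outdoor_gm = 4.5, outdoor_gsd = 2.8, ar1 = 0.995,
                         infiltration = 0.5, event_rate_per_day = 0.8,
                         event_gm = 10, event_gsd = 2.5, decay_ach = 0.25,
                         gain_sd_log = 0.03, noise_cv = 0.10,
                         count_sampling = c("poisson", "deterministic"),
                         mass_fractions = c(0.6, 0.25, 0.15),
                         cf1_multiplier = 2, cf1_zero_threshold = 0.7,
                         cf1_jitter_sd_log = 1.2, cf1_extra_noise_cv = 0.15,
                         seed = NULL) {
  count_sampling <- match.arg(count_sampling)
  cfg <- list(
    duration_hours = duration_hours, step_seconds = step_seconds,
    outdoor_gm = outdoor_gm, outdoor_gsd = outdoor_gsd, ar1 = ar1,
    infiltration = infiltration, event_rate_per_day = event_rate_per_day,
    event_gm = event_gm, event_gsd = event_gsd, decay_ach = decay_ach,
    gain_sd_log = gain_sd_log, noise_cv = noise_cv,
    count_sampling = count_sampling, mass_fractions = mass_fractions,
    cf1_multiplier = cf1_multiplier,
    cf1_zero_threshold = cf1_zero_threshold,
    cf1_jitter_sd_log = cf1_jitter_sd_log,
    cf1_extra_noise_cv = cf1_extra_noise_cv,
    seed = seed
  )
  validate_synth_config(cfg)
  structure(cfg, class = "pa_synth_config")
}

validate_synth_config <- function(cfg) {
  pos <- c("duration_hours", "step_seconds", "outdoor_gm", "event_gm",
           "decay_ach", "cf1_multiplier", "cf1_zero_threshold")
  for (f in pos) {
    pa_assert(is.numeric(cfg[[f]]) && cfg[[f]] > 0,
              sprintf("%s must be > 0", f), "paqc_config_error")
  }
  pa_assert(cfg$outdoor_gsd >= 1 && cfg$event_gsd >= 1,
            "GSDs must be >= 1", "paqc_config_error")
  pa_assert(cfg$ar1 >= 0 && cfg$ar1 < 1, "ar1 must be in [0, 1)",
            "paqc_config_error")
  pa_assert(cfg$infiltration >= 0 && cfg$infiltration <= 1,
            "infiltration must be in [0, 1]", "paqc_config_error")
  pa_assert(cfg$event_rate_per_day >= 0, "event rate must be >= 0",
            "paqc_config_error")
  pa_assert(cfg$gain_sd_log >= 0 && cfg$noise_cv >= 0 &&
              cfg$cf1_jitter_sd_log >= 0 && cfg$cf1_extra_noise_cv >= 0,
            "noise parameters must be >= 0", "paqc_config_error")
  pa_assert(length(cfg$mass_fractions) == 3 && all(cfg$mass_fractions > 0) &&
              abs(sum(cfg$mass_fractions) - 1) < 1e-9,
            "mass_fractions must be 3 positive values summing to 1",
            "paqc_config_error")
  invisible(TRUE)
}

#' Number of records per channel implied by a generator configuration
#'
#' @param config A [synth_config()].
#' @return `floor(duration_hours * 3600 / step_seconds)`.
#' @export
n_records <- function(config) {
  as.integer(floor(config$duration_hours * 3600 / config$step_seconds))
}

#' Simulate true indoor and outdoor concentration series
#'
#' Generates the ground-truth processes of the generator model: a
#' stationary log-AR(1) outdoor series and an indoor series equal to
#' `infiltration * outdoor` plus superposed source events with exponential
#' decay (half-life `ln(2)/decay_ach` hours).
#'
#' @param config A [synth_config()].
#' @return A `pa_ground_truth` list: `time` (POSIXct UTC), `outdoor`,
#'   `indoor` (ug/m3), `events` (tibble: `time`, `magnitude`), `config`.
#' @export
simulate_concentrations <- function(config) {
  validate_synth_config(config)
  n <- n_records(config)
  pa_assert(n >= 2, "configuration yields fewer than 2 records",
            "paqc_config_error")
  step_h <- config$step_seconds / 3600
  t0 <- as.POSIXct("2021-01-01 00:00:00", tz = "UTC")
  time <- t0 + (seq_len(n) - 1) * config$step_seconds

  m <- log(config$outdoor_gm)
  s <- log(config$outdoor_gsd)
  phi <- config$ar1
  x <- numeric(n)
  innov <- rnorm(n, 0, s * sqrt(1 - phi^2))
  x[1] <- rnorm(1, 0, s)
  for (i in 2:n) x[i] <- phi * x[i - 1] + innov[i]
  outdoor <- exp(m + x)

  n_events <- rpois(1, config$event_rate_per_day * config$duration_hours / 24)
  src <- numeric(n)
  events <- tibble::tibble(time = time[integer(0)], magnitude = numeric(0))
  if (n_events > 0) {
    ev_idx <- sort(sample.int(n, n_events, replace = TRUE))
    ev_mag <- rlnorm(n_events, log(config$event_gm), log(config$event_gsd))
    events <- tibble::tibble(time = time[ev_idx], magnitude = ev_mag)
    inject <- numeric(n)
    for (k in seq_len(n_events)) {
      inject[ev_idx[k]] <- inject[ev_idx[k]] + ev_mag[k]
    }
    decay <- exp(-config$decay_ach * step_h)
    src[1] <- inject[1]
    for (i in 2:n) src[i] <- src[i - 1] * decay + inject[i]
  }
  indoor <- config$infiltration * outdoor + src

  structure(list(time = time, outdoor = outdoor, indoor = indoor,
                 events = events, config = config),
            class = "pa_ground_truth")
}

cv_to_sdlog <- function(cv) sqrt(log(1 + cv^2))

#' Simulate a dual-channel monitor observing a ground truth
#'
#' Applies the sensor model to a true concentration series: per-channel
#' gain and multiplicative noise, inversion of the count-to-mass formula
#' through the configured mass fractions to expected per-bin counts
#' (per dL), count sampling, accumulation into cumulative
#' greater-than counts (the smallest-bin cumulative count is forced >= 1:
#' particles are always present in the smallest size category), and the
#' vendor CF1/ATM emulation with its zero threshold.
#'
#' @param truth A `pa_ground_truth` from [simulate_concentrations()].
#' @param config A [synth_config()] (normally `truth$config`).
#' @param monitor_id,location Identity of the simulated monitor; `location`
#'   selects the indoor or outdoor truth series.
#' @return A canonical monitor series tibble (both channels, time-sorted)
#'   with attribute `gains` (the per-channel gains actually drawn).
#' @export
simulate_monitor <- function(truth, config = truth$config,
                             monitor_id = "M1",
                             location = c("indoor", "outdoor")) {
  location <- match.arg(location)
  validate_synth_config(config)
  true_pm <- if (location == "indoor") truth$indoor else truth$outdoor
  n <- length(true_pm)
  acfg <- alt_config()
  coefs <- alt_bin_coefficients(acfg)
  f <- config$mass_fractions
  gains <- stats::setNames(rlnorm(2, 0, config$gain_sd_log), c("a", "b"))
  noise_sdlog <- cv_to_sdlog(config$noise_cv)
  extra_sdlog <- cv_to_sdlog(config$cf1_extra_noise_cv)

  channel_frame <- function(ch) {
    noisy <- true_pm * gains[[ch]] * rlnorm(n, 0, noise_sdlog)
    expected <- outer(noisy, f) / rep(coefs, each = n)   # n x 3 counts/dL
    counts <- if (config$count_sampling == "poisson") {
      matrix(rpois(3L * n, lambda = as.vector(expected)), ncol = 3)
    } else {
      round(expected)
    }
    counts[, 1] <- pmax(counts[, 1], 1)
    cf1 <- config$cf1_multiplier * noisy *
      rlnorm(n, 0, extra_sdlog)
    internal <- noisy * rlnorm(n, 0, config$cf1_jitter_sd_log)
    cf1[internal < config$cf1_zero_threshold] <- 0
    atm <- ifelse(cf1 <= 28, cf1, 28 + 0.7 * (cf1 - 28))
    tibble::tibble(
      timestamp = truth$time,
      monitor_id = monitor_id,
      channel = ch,
      location = location,
      n_gt_0p3_dl = counts[, 1] + counts[, 2] + counts[, 3],
      n_gt_0p5_dl = counts[, 2] + counts[, 3],
      n_gt_1p0_dl = counts[, 3],
      n_gt_2p5_dl = 0,
      pm25_cf1 = cf1,
      pm25_atm = atm
    )
  }
  out <- dplyr::bind_rows(channel_frame("a"), channel_frame("b"))
  out <- out[order(out$timestamp, out$channel), ]
  attr(out, "gains") <- gains
  out
}

#' Write a complete synthetic fixture dataset to disk
#'
#' Simulates one ground truth and one indoor plus one outdoor monitor,
#' writes each monitor as a canonical CSV, the truth series as a CSV, and a
#' JSON file of generator metadata (config, event times, channel gains).
#' Byte-identical across runs for a fixed `config$seed`.
#'
#' @param config A [synth_config()]; its `seed` (default 1 when unset)
#'   seeds all randomness.
#' @param out_dir Writable output directory (created if absent).
#' @return Invisibly, a named list of the file paths written.
#' @export
make_fixture_dataset <- function(config = synth_config(), out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  pa_assert(dir.exists(out_dir), "cannot create output directory",
            "paqc_io_error")
  set.seed(config$seed %||% 1L)
  truth <- simulate_concentrations(config)
  indoor <- simulate_monitor(truth, config, monitor_id = "M1",
                             location = "indoor")
  outdoor <- simulate_monitor(truth, config, monitor_id = "M2",
                              location = "outdoor")
  paths <- list(
    indoor = file.path(out_dir, "monitor_M1_indoor.csv"),
    outdoor = file.path(out_dir, "monitor_M2_outdoor.csv"),
    truth = file.path(out_dir, "ground_truth.csv"),
    meta = file.path(out_dir, "ground_truth.json")
  )
  write_records_csv(indoor, paths$indoor)
  write_records_csv(outdoor, paths$outdoor)
  readr::write_csv(tibble::tibble(
    timestamp = format(truth$time, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
    outdoor = truth$outdoor, indoor = truth$indoor
  ), paths$truth, progress = FALSE)
  meta <- list(
    config = unclass(config)[!vapply(unclass(config), is.null, TRUE)],
    events = list(
      time = format(truth$events$time, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
      magnitude = truth$events$magnitude
    ),
    gains = list(indoor = as.list(attr(indoor, "gains")),
                 outdoor = as.list(attr(outdoor, "gains")))
  )
  jsonlite::write_json(meta, paths$meta, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(paths)
}
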