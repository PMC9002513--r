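small_cfg <- function(...) {
  synth_config(duration_hours = 48, ...)
}

test_that("configuration validation rejects out-of-range parameters", {
  expect_s3_class(synth_config(), "pa_synth_config")
  expect_error(synth_config(infiltration = 1.2), class = "paqc_config_error")
  expect_error(synth_config(outdoor_gsd = 0.8), class = "paqc_config_error")
  expect_error(synth_config(mass_fractions = c(0.5, 0.5, 0.5)),
               class = "paqc_config_error")
  expect_error(synth_config(ar1 = 1), class = "paqc_config_error")
})

test_that("the default deployment is 18 months of 2-minute records", {
  expect_equal(n_records(synth_config()), 394200)
  expect_equal(n_records(small_cfg()), 48 * 30)
})

test_that("with no indoor sources and full infiltration, indoor equals outdoor", {
  set.seed(101)
  truth <- simulate_concentrations(small_cfg(event_rate_per_day = 0,
                                             infiltration = 1))
  expect_equal(truth$indoor, truth$outdoor)
  expect_equal(nrow(truth$events), 0)
})

test_that("the outdoor process is stationary at the configured GM and GSD", {
  set.seed(202)
  # lower autocorrelation for this check so the effective sample size
  # supports a +/-5% comparison
  cfg <- synth_config(duration_hours = 24 * 140, ar1 = 0.9,
                      outdoor_gm = 4.5, outdoor_gsd = 2.8)
  truth <- simulate_concentrations(cfg)
  expect_gt(length(truth$outdoor), 1e5)
  expect_equal(exp(mean(log(truth$outdoor))), 4.5, tolerance = 0.05)
  expect_equal(exp(sd(log(truth$outdoor))), 2.8, tolerance = 0.05)
})

test_that("indoor source events decay exponentially at the air-change rate", {
  set.seed(303)
  cfg <- small_cfg(event_rate_per_day = 4, infiltration = 0, decay_ach = 0.25)
  truth <- simulate_concentrations(cfg)
  expect_gt(nrow(truth$events), 0)
  last_idx <- max(match(truth$events$time, truth$time))
  tail_idx <- seq(last_idx + 1, length(truth$indoor))
  expect_gt(length(tail_idx), 10)
  ratios <- truth$indoor[tail_idx[-1]] / truth$indoor[tail_idx[-length(tail_idx)]]
  expect_equal(ratios, rep(exp(-0.25 * 120 / 3600), length(ratios)),
               tolerance = 1e-9)
  # excess halves every ln(2)/a hours
  half_steps <- log(2) / 0.25 * 3600 / 120
  i <- tail_idx[1]
  expect_equal(truth$indoor[i + round(half_steps)] / truth$indoor[i], 0.5,
               tolerance = 0.01)
})

test_that("a noiseless deterministic monitor inverts back to the truth", {
  set.seed(404)
  cfg <- small_cfg(noise_cv = 0, gain_sd_log = 0,
                   count_sampling = "deterministic")
  truth <- simulate_concentrations(cfg)
  mon <- compute_alt_pm(simulate_monitor(truth, cfg, "M1", "indoor"))
  a <- mon[mon$channel == "a", ]
  hi <- truth$indoor > 1
  expect_gt(sum(hi), 50)
  expect_equal(a$alt_pm25[hi], truth$indoor[hi], tolerance = 0.02)
  # identical channels when all noise is off: precision exactly 0
  p <- pair_channels(mon, "alt_pm25")
  expect_true(all(p$precision == 0))
})

test_that("generated counts are cumulative-monotone with a never-empty smallest bin", {
  set.seed(505)
  cfg <- small_cfg()
  truth <- simulate_concentrations(cfg)
  mon <- simulate_monitor(truth, cfg, "M1", "indoor")
  expect_true(all(mon$n_gt_0p3_dl >= mon$n_gt_0p5_dl))
  expect_true(all(mon$n_gt_0p5_dl >= mon$n_gt_1p0_dl))
  expect_true(all(mon$n_gt_1p0_dl >= mon$n_gt_2p5_dl))
  expect_true(all(mon$n_gt_0p3_dl >= 1))
  # the ALT values derived from them are therefore never zero
  mon <- compute_alt_pm(mon)
  expect_true(all(mon$alt_pm25 > 0))
})

test_that("vendor emulation reports zeros alongside nonzero ALT values", {
  set.seed(606)
  cfg <- synth_config(duration_hours = 24 * 14)
  truth <- simulate_concentrations(cfg)
  mon <- compute_alt_pm(simulate_monitor(truth, cfg, "M1", "indoor"))
  zr <- count_reported_zeros(mon$pm25_cf1, "M1a", "indoor")
  expect_gt(zr$fraction_zero, 0.05)
  expect_true(all(mon$alt_pm25[mon$pm25_cf1 == 0] > 0))
  # the vendor pathway inflates concentrations roughly twofold
  pos <- mon$pm25_cf1 > 0
  expect_gt(mean(mon$pm25_cf1[pos]) / mean(mon$alt_pm25[pos]), 1.4)
  # CF1 and ATM agree below the regime boundary
  low <- mon$pm25_cf1 <= 28
  expect_equal(mon$pm25_atm[low], mon$pm25_cf1[low])
})

test_that("fixture datasets are deterministic under a seed and re-readable", {
  cfg <- synth_config(duration_hours = 10 / 3, seed = 77)  # 100 records
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  p1 <- make_fixture_dataset(cfg, d1)
  p2 <- make_fixture_dataset(cfg, d2)
  for (f in c("indoor", "outdoor", "truth", "meta")) {
    expect_identical(readLines(p1[[f]]), readLines(p2[[f]]), label = f)
  }
  back <- read_purpleair_csv(p1$indoor, dialect = "simple")
  expect_equal(nrow(back), 200)  # 100 timestamps x 2 channels
  expect_equal(read_report(back)$n_dropped_invalid_counts, 0)
  meta <- jsonlite::read_json(p1$meta)
  expect_equal(meta$config$seed, 77)
  expect_length(meta$gains$indoor, 2)
})
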