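test_that("canonical CSV round-trips exactly through write and read", {
  s <- make_series(n = 3)
  s <- rbind(s, s[1, ])          # duplicate-free sorting check below
  s <- s[-nrow(s), ]
  path <- withr::local_tempfile(fileext = ".csv")
  write_records_csv(s, path)
  back <- read_purpleair_csv(path, dialect = "simple")
  expect_equal(nrow(back), nrow(s))
  s_sorted <- s[order(s$timestamp), ]
  for (col in setdiff(names(s_sorted), "timestamp")) {
    expect_equal(back[[col]], s_sorted[[col]], info = col)
  }
  expect_equal(as.numeric(back$timestamp), as.numeric(s_sorted$timestamp))
  expect_equal(read_report(back)$n_dropped_invalid_counts, 0)
})

test_that("empty series writes a header-only file", {
  s <- make_series(n = 1)[0, ]
  path <- withr::local_tempfile(fileext = ".csv")
  write_records_csv(s, path)
  expect_length(readLines(path), 1L)
})

test_that("reader drops rows violating count monotonicity and reports them", {
  s <- make_series(n = 3, channels = "a")
  s$n_gt_0p5_dl[2] <- s$n_gt_0p3_dl[2] + 50  # more >0.5 um than >0.3 um
  path <- withr::local_tempfile(fileext = ".csv")
  write_records_csv(s, path)
  back <- read_purpleair_csv(path)
  expect_equal(nrow(back), 2)
  expect_equal(read_report(back)$n_dropped_invalid_counts, 1)
  expect_equal(read_report(back)$n_read, 3)
})

test_that("reader understands sdcard and api vocabularies and custom maps", {
  lines_sd <- c(
    "UTCDateTime,mac_address,p_0_3_um,p_0_5_um,p_1_0_um,p_2_5_um,pm2_5_cf_1,pm2_5_atm",
    "2021-03-01T00:02:00Z,aa:bb,500,60,5,0,2.5,2.5",
    "2021-03-01T00:00:00Z,aa:bb,400,50,4,0,2.0,2.0"
  )
  p1 <- withr::local_tempfile(fileext = ".csv")
  writeLines(lines_sd, p1)
  sd <- read_purpleair_csv(p1, dialect = "sdcard", channel = "a",
                           location = "outdoor")
  expect_equal(sd$n_gt_0p3_dl, c(400, 500))   # sorted by time
  expect_equal(sd$monitor_id, rep("aa:bb", 2))
  expect_equal(sd$pm25_cf1, c(2.0, 2.5))

  lines_api <- c(
    "time_stamp,sensor_index,0.3_um_count,0.5_um_count,1.0_um_count,2.5_um_count,pm2.5_cf_1,pm2.5_atm",
    "1614556800,12345,400,50,4,0,2.0,2.0"
  )
  p2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(lines_api, p2)
  api <- read_purpleair_csv(p2, dialect = "api", channel = "a")
  expect_equal(api$n_gt_0p3_dl, 400)
  expect_equal(format(api$timestamp, "%Y-%m-%d", tz = "UTC"), "2021-03-01")

  # custom column name rescued through column_map
  lines_odd <- c("when,c03,c05,c10,c25", "2021-03-01 00:00:00,9,5,1,0")
  p3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(lines_odd, p3)
  odd <- read_purpleair_csv(p3, column_map = c(
    timestamp = "when", n_gt_0p3_dl = "c03", n_gt_0p5_dl = "c05",
    n_gt_1p0_dl = "c10", n_gt_2p5_dl = "c25"))
  expect_equal(odd$n_gt_0p3_dl, 9)

  expect_error(read_purpleair_csv(p3, dialect = "simple"),
               class = "paqc_format_error")
  expect_error(read_purpleair_csv(file.path(tempdir(), "nope.csv")),
               class = "paqc_io_error")
})

test_that("channel pairing evaluates mu, sigma and precision from the definitions", {
  s <- make_series(n = 1)
  s <- compute_alt_pm(s)
  s$alt_pm25 <- c(3, 1)  # channel a = 3, channel b = 1
  p <- pair_channels(s, "alt_pm25")
  expect_equal(nrow(p), 1)
  expect_equal(p$mu, 2)
  expect_equal(p$sigma, sqrt(2))
  expect_equal(p$precision, 0.5)

  s$alt_pm25 <- c(5, 5)
  p2 <- pair_channels(s, "alt_pm25")
  expect_equal(p2$precision, 0)
  expect_equal(p2$sigma, 0)
})

test_that("pairing is one-to-one within tolerance and reports unmatched records", {
  a <- make_series(n = 3, channels = "a")
  b <- make_series(n = 3, channels = "b")
  b$timestamp <- b$timestamp + 3600  # far outside tolerance
  s <- compute_alt_pm(rbind(a, b))
  p <- pair_channels(s, "alt_pm25", tolerance_seconds = 60)
  expect_equal(nrow(p), 0)
  rep <- read_report(p)
  expect_equal(rep$n_unmatched_a, 3)
  expect_equal(rep$n_unmatched_b, 3)

  # offset grids within tolerance pair fully, one-to-one
  b$timestamp <- a$timestamp + 30
  s2 <- compute_alt_pm(rbind(a, b))
  p2 <- pair_channels(s2, "alt_pm25", tolerance_seconds = 60)
  expect_equal(nrow(p2), 3)
  expect_lte(nrow(p2), min(sum(s2$channel == "a"), sum(s2$channel == "b")))
  rep2 <- read_report(p2)
  expect_equal(rep2$n_pairs + rep2$n_unmatched_a, rep2$n_a)
  expect_equal(rep2$n_pairs + rep2$n_unmatched_b, rep2$n_b)
})

test_that("mu, sigma and precision obey the exact 1/sqrt(2) identity", {
  set.seed(7)
  a <- rlnorm(500, 1, 1)
  b <- rlnorm(500, 1, 1)
  p <- make_pairs(a, b)
  defined <- p$sigma > 0
  expect_equal((p$mu[defined] / p$sigma[defined]) * p$precision[defined],
               rep(1 / sqrt(2), sum(defined)))
})

test_that("indoor/outdoor matching is nearest-neighbour one-to-one within tolerance", {
  ind <- make_pairs(1:5, 1:5)
  out <- make_pairs(2 * (1:5), 2 * (1:5))
  m <- match_locations(ind, out, tolerance_seconds = 60)
  expect_equal(nrow(m), 5)
  expect_equal(m$indoor_value, ind$mu)
  expect_equal(m$outdoor_value, out$mu)

  out2 <- out
  out2$timestamp <- out2$timestamp + 86400 * 30
  expect_equal(nrow(match_locations(ind, out2, 60)), 0)

  out3 <- out
  out3$timestamp <- out3$timestamp + 45
  expect_equal(nrow(match_locations(ind, out3, 60)), 5)
})
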