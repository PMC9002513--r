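test_that("pair precision follows |a-b|/(a+b) and is undefined at 0/0", {
  expect_equal(pair_precision(5, 5), 0)
  expect_equal(pair_precision(3, 1), 0.5)
  expect_true(is.na(pair_precision(0, 0)))
  expect_equal(pair_precision(1, 0), 1)
  expect_error(pair_precision(-1, 2), class = "paqc_domain_error")
  # scale invariance: the same precision under any calibration factor
  set.seed(3)
  a <- rlnorm(200); b <- rlnorm(200); k <- runif(200, 0.1, 50)
  expect_equal(pair_precision(k * a, k * b), pair_precision(a, b))
})

test_that("precision filter is strict at the cutoff and conserves counts", {
  mu <- rep(10, 4)
  prec <- c(0.1, 0.19, 0.2, 0.3)
  # a = mu(1+p), b = mu(1-p) gives pair precision exactly p
  p <- make_pairs(mu * (1 + prec), mu * (1 - prec))
  res <- apply_precision_filter(p, cutoff = 0.2)
  expect_equal(res$loss$remaining, 2)
  expect_equal(res$loss$lost_to_precision, 2)
  expect_equal(res$loss$lost_to_zero, 0)
  expect_equal(with(res$loss, lost_to_zero + lost_to_precision + remaining),
               res$loss$total_obs)

  # identical channels: nothing lost
  same <- make_pairs(rep(4, 10), rep(4, 10))
  expect_equal(apply_precision_filter(same)$loss$fraction_lost, 0)

  # filtering is idempotent
  again <- apply_precision_filter(res$filtered, cutoff = 0.2)
  expect_equal(again$filtered, res$filtered)
  expect_equal(again$loss$remaining, nrow(res$filtered))
})

test_that("a stream built with a known 8% out-of-tolerance rate retains ~92%", {
  set.seed(12)
  n <- 2e4
  bad <- runif(n) < 0.08
  prec <- ifelse(bad, runif(n, 0.21, 0.9), runif(n, 0, 0.19))
  mu <- rlnorm(n, 1, 0.5)
  p <- make_pairs(mu * (1 + prec), mu * (1 - prec))
  res <- apply_precision_filter(p, 0.2)
  expect_equal(res$loss$remaining / res$loss$total_obs, 0.92,
               tolerance = 0.011)
})

test_that("vendor zeros are separated from precision losses", {
  a <- c(0, 0, 3, 10, 10)
  b <- c(0, 4, 0, 10, 16)   # both-zero; one-zero (precision 1); clean; noisy
  p <- make_pairs(a, b, algorithm = "CF1")
  res <- apply_precision_filter(p, 0.2)
  expect_equal(res$loss$lost_to_zero, 1)       # only the (0,0) pair
  expect_equal(res$loss$lost_to_precision, 3)  # (0,4), (3,0), (10,16)
  expect_equal(res$loss$remaining, 1)
})

test_that("the companion-ALT precision mask can filter a vendor stream", {
  alt <- make_pairs(c(10, 10, 10), c(10.5, 18, 10.2))  # precisions ~0.024, 0.286, 0.01
  cf1 <- make_pairs(c(25, 25, 25), c(25, 25, 25), algorithm = "CF1")
  res <- apply_precision_filter(cf1, 0.2, precision_source = "alt",
                                alt_reference = alt)
  expect_equal(res$loss$remaining, 2)  # the middle timestamp fails the ALT mask
  expect_error(apply_precision_filter(cf1, 0.2, precision_source = "alt"),
               class = "paqc_config_error")
})

test_that("precision summaries report the documented quantile rule", {
  s <- precision_summary(rep(0.05, 100), "ALT_CF3", "none")
  expect_equal(s$mean, 0.05)
  expect_equal(s$se, 0)
  expect_equal(s$median, 0.05)
  expect_equal(s$max, 0.05)
  expect_equal(s$valid_n, 100)

  s2 <- precision_summary(c(0.1, 0.2, 0.3, 0.4))
  expect_equal(s2$median, 0.25)
  expect_equal(s2$lower_quartile, 0.175)  # linear interpolation rule
  expect_true(s2$lower_quartile <= s2$median &&
                s2$median <= s2$upper_quartile &&
                s2$upper_quartile <= s2$p90 && s2$p90 <= s2$max)

  set.seed(8)
  s3 <- precision_summary(runif(1e5, 0, 0.2))
  expect_equal(s3$mean, 0.1, tolerance = 0.02)

  expect_error(precision_summary(numeric(0)), class = "paqc_domain_error")
})

test_that("relative bias against the ensemble mean matches direct arithmetic", {
  eq <- relative_bias(c(a = 5, b = 5, c = 5))
  expect_equal(eq$per_sensor$bias_pct, c(0, 0, 0))
  expect_equal(eq$overall_abs_bias_pct, 0)

  two <- relative_bias(c(s1 = 4, s2 = 6))
  expect_equal(two$per_sensor$bias_pct, c(-20, 20))
  expect_equal(two$overall_abs_bias_pct, 20)
  expect_equal(two$overall_se_pct, 0)

  expect_error(relative_bias(c(0, 0)), "grand mean")
  expect_error(relative_bias(5), "at least 2")
})

test_that("multiplicative gains at 3% sd produce ~2.4% mean absolute bias (half-normal oracle)", {
  set.seed(11)
  vals <- replicate(60, {
    gains <- exp(rnorm(8, 0, 0.03))
    relative_bias(setNames(5 * gains, paste0("s", 1:8)))$overall_abs_bias_pct
  })
  # E|N(0, 3%)| = 3% * sqrt(2/pi) ~ 2.4%, slightly shrunk by the 8-sensor
  # grand mean
  expect_gt(mean(vals), 1.9)
  expect_lt(mean(vals), 2.9)
})

test_that("data-loss comparison enforces conservation and the no-ALT-zeros invariant", {
  alt <- tibble::tibble(total_obs = 100, lost_to_zero = 0,
                        lost_to_precision = 8, remaining = 92,
                        fraction_lost = 0.08)
  cf1 <- tibble::tibble(total_obs = 100, lost_to_zero = 15,
                        lost_to_precision = 25, remaining = 60,
                        fraction_lost = 0.40)
  cmp <- data_loss_comparison(alt, cf1)
  expect_equal(nrow(cmp), 2)
  expect_equal(attr(cmp, "alt_advantage"), 32)
  expect_true(cmp$fraction_remaining[cmp$algorithm == "CF1"] <
                cmp$fraction_remaining[cmp$algorithm == "ALT_CF3"])

  same <- data_loss_comparison(alt, alt)
  expect_equal(attr(same, "alt_advantage"), 0)

  bad_alt <- alt; bad_alt$lost_to_zero <- 3
  expect_error(data_loss_comparison(bad_alt, cf1),
               class = "paqc_consistency_error")
  bad_tot <- cf1; bad_tot$total_obs <- 99
  expect_error(data_loss_comparison(alt, bad_tot),
               class = "paqc_consistency_error")
})
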