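# Shared builders and independent oracles for the test suite.

t0_utc <- as.POSIXct("2021-01-01 00:00:00", tz = "UTC")

# Paired-observation tibble from raw channel values (the container
# pair_channels() would produce), built directly from the definitions.
make_pairs <- function(a, b, algorithm = "ALT_CF3", step = 120) {
  tibble::tibble(
    timestamp = t0_utc + step * seq_along(a),
    a_value = a, b_value = b,
    mu = (a + b) / 2,
    sigma = abs(a - b) / sqrt(2),
    precision = pair_precision(a, b),
    algorithm = algorithm
  )
}

# Minimal canonical monitor series with valid cumulative counts.
make_series <- function(n = 3, monitor_id = "T1", location = "indoor",
                        channels = c("a", "b"), step = 120,
                        base_counts = c(1110, 110, 10, 0)) {
  rows <- lapply(channels, function(ch) {
    tibble::tibble(
      timestamp = t0_utc + step * seq_len(n),
      monitor_id = monitor_id, channel = ch, location = location,
      n_gt_0p3_dl = base_counts[1] + seq_len(n),
      n_gt_0p5_dl = base_counts[2] + seq_len(n),
      n_gt_1p0_dl = base_counts[3] + seq_len(n),
      n_gt_2p5_dl = base_counts[4],
      pm25_cf1 = 1.5 * seq_len(n), pm25_atm = 1.5 * seq_len(n)
    )
  })
  do.call(rbind, rows)
}

# Quadratic-time transcription of the tail LOD definition, kept independent
# of the package's O(n log n) scan.
brute_force_lod <- function(mu, sigma, ratio = 3, pass_fraction = 0.95,
                            min_tail = 100) {
  pass <- sigma == 0 | mu / sigma > ratio
  worst <- -Inf
  for (s in mu) {
    in_tail <- mu > s
    if (sum(in_tail) >= min_tail) {
      if (mean(pass[in_tail]) <= pass_fraction) worst <- max(worst, s)
    }
  }
  if (!is.finite(worst)) return(min(mu))
  cand <- mu[mu > worst]
  if (!length(cand)) return(Inf)
  min(cand)
}

# Paired stream with a constant additive noise floor on a log-uniform
# signal: the construction used for detection-limit recovery checks.
noise_floor_pairs <- function(n = 1e4, noise_sd = 0.3, lo = 0.01, hi = 10) {
  truth <- 10^runif(n, log10(lo), log10(hi))
  a <- pmax(0, truth + rnorm(n, 0, noise_sd))
  b <- pmax(0, truth + rnorm(n, 0, noise_sd))
  make_pairs(a, b)
}
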