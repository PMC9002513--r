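#' Limit of detection by blockwise mu/sigma scan
#'
#' Operational LOD for continuous duplicate-sensor data: an observation
#' "passes" when its pair mean exceeds its pair standard deviation by more
#' than `ratio_threshold` (mu/sigma > 3 by default; sigma = 0 counts as a
#' pass). Observations are sorted by `mu` ascending and partitioned into
#' consecutive blocks of `block_size`; the scan runs over all blocks and the
#' LOD is the largest failing `mu` within the last block containing at least
#' `max_fail_per_block` failures (5 in 100, i.e. a local 5% failure rate).
#' A final partial block uses the proportional threshold
#' `ceiling(max_fail_per_block/block_size * size)`. If no block ever
#' accumulates that many failures the whole series is detectable and the LOD
#' is the smallest observed `mu`.
#'
#' Note `mu/sigma > 3` is algebraically equivalent to pair precision below
#' `1/(3 sqrt(2)) ~ 0.236`, so this criterion is a precision criterion.
#'
#' @param paired Paired-observation tibble with `mu` and `sigma` (rows with
#'   `NA` in either are dropped).
#' @param block_size Observations per block (>= 10).
#' @param ratio_threshold Required mu/sigma ratio (default 3).
#' @param max_fail_per_block Failures that disqualify a block (default 5).
#' @return A `pa_lod_result` list: `lod`, `method = "block"`, `block_size`,
#'   `ratio_threshold`, `pass_fraction`, `n_total`, `n_above`,
#'   `fraction_above` (percent of observations with `mu > lod`, strict),
#'   `all_below` (TRUE with `lod = Inf` when even the top block fails), and
#'   a per-block diagnostic tibble `blocks`.
#' @export
lod_block_search <- function(paired, block_size = 100L, ratio_threshold = 3,
                             max_fail_per_block = 5L) {
  pa_assert(block_size >= 10, "block_size must be >= 10", "paqc_config_error")
  mu <- paired$mu; sigma <- paired$sigma
  keep <- !is.na(mu) & !is.na(sigma)
  mu <- mu[keep]; sigma <- sigma[keep]
  if (!length(mu)) pa_stop("no observations with defined mu and sigma",
                           "paqc_domain_error")
  o <- order(mu)
  mu <- mu[o]; sigma <- sigma[o]
  fail <- sigma > 0 & mu / sigma < ratio_threshold
  n <- length(mu)
  n_blocks <- ceiling(n / block_size)
  fail_frac <- max_fail_per_block / block_size
  blk <- tibble::tibble(
    block = seq_len(n_blocks),
    from = (seq_len(n_blocks) - 1L) * block_size + 1L,
    to = pmin(seq_len(n_blocks) * block_size, n)
  )
  blk$size <- blk$to - blk$from + 1L
  blk$n_fail <- vapply(seq_len(n_blocks),
                       function(b) sum(fail[blk$from[b]:blk$to[b]]), 0L)
  blk$threshold <- ifelse(blk$size < block_size,
                          ceiling(fail_frac * blk$size),
                          as.integer(max_fail_per_block))
  blk$qualifies <- blk$n_fail >= blk$threshold & blk$threshold > 0
  last <- if (any(blk$qualifies)) max(blk$block[blk$qualifies]) else NA_integer_

  if (is.na(last)) {
    # no block ever disqualifies: everything is detectable
    return(pa_lod_result(mu[1], "block", mu, FALSE, n_above = n,
                         block_size = block_size,
                         ratio_threshold = ratio_threshold,
                         pass_fraction = 1 - fail_frac, blocks = blk))
  }
  idx <- blk$from[last]:blk$to[last]
  lod <- max(mu[idx][fail[idx]])
  all_below <- !any(mu > lod)
  if (all_below) lod <- Inf
  pa_lod_result(lod, "block", mu, all_below,
                block_size = block_size, ratio_threshold = ratio_threshold,
                pass_fraction = 1 - fail_frac, blocks = blk)
}

#' Limit of detection by the exact tail definition
#'
#' Direct transcription of the definitional criterion: the LOD is the lowest
#' mean value above which more than `pass_fraction` (95%) of observations
#' have mu/sigma above `ratio_threshold`. Concretely: the smallest observed
#' `mu` value `t` such that for every observed threshold `s >= t` with at
#' least `min_tail` observations above it, the fraction of `{mu > s}`
#' passing mu/sigma > ratio strictly exceeds `pass_fraction` ("more than
#' 95%"). The scan over sorted thresholds is O(n log n).
#'
#' @inheritParams lod_block_search
#' @param pass_fraction Required passing fraction in the tail (default
#'   0.95).
#' @param min_tail Smallest tail size on which the 95% criterion is
#'   evaluated (default 100; a 5% criterion is meaningless on smaller
#'   tails).
#' @return A `pa_lod_result` list (`method = "oracle"`), as for
#'   [lod_block_search()]; `all_below = TRUE` with `lod = Inf` when no
#'   observed value lies above the last violating threshold.
#' @export
lod_exact_oracle <- function(paired, ratio_threshold = 3,
                             pass_fraction = 0.95, min_tail = 100L) {
  mu <- paired$mu; sigma <- paired$sigma
  keep <- !is.na(mu) & !is.na(sigma)
  mu <- mu[keep]; sigma <- sigma[keep]
  n <- length(mu)
  pa_assert(n >= min_tail, "need at least min_tail observations",
            "paqc_domain_error")
  o <- order(mu)
  mu <- mu[o]; sigma <- sigma[o]
  pass <- sigma == 0 | mu / sigma > ratio_threshold
  # suffix counts of passes; tail above threshold mu[k] starts after the
  # last tied value
  suf <- rev(cumsum(rev(pass)))
  upper <- findInterval(mu, mu)     # index of last element <= mu[k] (ties)
  tail_n <- n - upper
  frac <- ifelse(tail_n > 0, ifelse(upper < n, suf[pmin(upper + 1L, n)], 0) / tail_n, NA_real_)
  evaluable <- tail_n >= min_tail
  # "more than 95%" is strict: a tail passing at exactly pass_fraction
  # still violates
  violates <- evaluable & frac <= pass_fraction
  if (!any(violates)) {
    return(pa_lod_result(mu[1], "oracle", mu, FALSE, n_above = n,
                         ratio_threshold = ratio_threshold,
                         pass_fraction = pass_fraction, min_tail = min_tail))
  }
  worst <- max(mu[violates])
  above <- mu[mu > worst]
  if (!length(above)) {
    return(pa_lod_result(Inf, "oracle", mu, TRUE,
                         ratio_threshold = ratio_threshold,
                         pass_fraction = pass_fraction, min_tail = min_tail))
  }
  pa_lod_result(min(above), "oracle", mu, FALSE,
                ratio_threshold = ratio_threshold,
                pass_fraction = pass_fraction, min_tail = min_tail)
}

pa_lod_result <- function(lod, method, mu, all_below, n_above = NULL, ...) {
  n <- length(mu)
  if (is.null(n_above)) {
    n_above <- if (is.finite(lod)) sum(mu > lod) else 0L
  }
  structure(
    c(list(lod = lod, method = method, n_total = n, n_above = n_above,
           fraction_above = 100 * n_above / n, all_below = all_below),
      list(...)),
    class = "pa_lod_result"
  )
}

#' @export
print.pa_lod_result <- function(x, ...) {
  cat(sprintf("LOD (%s method): %.4g ug/m3; %d of %d obs above (%.1f%%)\n",
              x$method, x$lod, x$n_above, x$n_total, x$fraction_above))
  if (isTRUE(x$all_below)) cat("  [all observations below detection]\n")
  invisible(x)
}

#' Percentage of observations above a detection limit
#'
#' @param values Concentration series (ug/m3).
#' @param lod Detection limit (>= 0).
#' @return Percentage of values strictly greater than `lod`.
#' @export
fraction_above_lod <- function(values, lod) {
  values <- values[!is.na(values)]
  if (!length(values)) pa_stop("empty series", "paqc_domain_error")
  pa_assert(lod >= 0, "lod must be >= 0")
  100 * sum(values > lod) / length(values)
}
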