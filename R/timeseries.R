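#' Autocorrelation time of a scalar series
#'
#' The smallest lag at which the empirical normalized autocorrelation function
#' (biased, 1/n estimator as in [stats::acf()]) drops to `exp(-1)` or below.
#' For an AR(1) process with coefficient `rho` this converges to
#' `-1 / log(rho)` (rounded up), which the test-suite uses as its oracle.
#' Reported in frames of the series as given; apply any stride first.
#'
#' @param series Numeric vector, length >= 10, non-constant.
#' @return Integer lag (>= 1).
#' @export
autocorrelation_time <- function(series) {
  n <- length(series)
  if (n < 10) stop_hd("Series too short (need >= 10 points).", "series_error")
  if (sd(series) == 0) {
    stop_hd("Series is constant; autocorrelation undefined.",
            "zero_variance_error")
  }
  target <- exp(-1)
  lag_max <- min(n - 1L, 1000L)
  repeat {
    rho <- as.numeric(acf(series, lag.max = lag_max, plot = FALSE,
                          demean = TRUE)$acf)[-1]
    hit <- which(rho <= target)
    if (length(hit) > 0) return(as.integer(hit[1]))
    if (lag_max >= n - 1L) return(as.integer(n - 1L))
    lag_max <- min(n - 1L, lag_max * 4L)
  }
}

#' Moving-block-bootstrap standard error of a time-series mean
#'
#' Resamples `ceiling(n / block_length)` overlapping blocks of consecutive
#' observations with replacement, concatenates and trims to length `n`, and
#' reports the standard deviation of the resampled means. The block length
#' defaults to the ceiling of the series' autocorrelation time, so that
#' blocks are approximately independent.
#'
#' @param series Numeric vector.
#' @param block_length Block size in frames (default `ceiling(tau)`).
#' @param n_boot Number of bootstrap resamples.
#' @param seed RNG seed.
#' @return A one-row tibble: `mean`, `sem`, `tau`, `block_length`, `n_boot`,
#'   `seed`, `n`.
#' @export
moving_block_bootstrap_sem <- function(series, block_length = NULL,
                                       n_boot = 1000L, seed = 1L) {
  n <- length(series)
  tau <- NA_real_
  if (is.null(block_length)) {
    tau <- autocorrelation_time(series)
    block_length <- as.integer(ceiling(tau))
  }
  block_length <- as.integer(block_length)
  if (block_length < 1L || block_length > n) {
    stop_hd("Block length must be in 1..length(series).", "block_error")
  }
  if (sd(series) == 0) {
    return(tibble(mean = series[1], sem = 0, tau = tau,
                  block_length = block_length, n_boot = n_boot,
                  seed = seed, n = n))
  }
  m <- ceiling(n / block_length)
  n_starts <- n - block_length + 1L
  offs <- 0:(block_length - 1L)
  boot_means <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      starts <- sample.int(n_starts, m, replace = TRUE)
      idx <- rep(starts, each = block_length) + offs
      mean(series[idx[seq_len(n)]])
    }, numeric(1))
  })
  tibble(mean = mean(series), sem = sd(boot_means), tau = tau,
         block_length = block_length, n_boot = as.integer(n_boot),
         seed = as.integer(seed), n = n)
}

#' Mean and standard error across replica means
#'
#' Combines per-replica averages into a grand mean with the standard error of
#' the mean computed across replicas (`sd / sqrt(R)`). A single replica has
#' no between-replica variance; its SEM is reported as `NA` and flagged.
#'
#' @param per_replica_means Numeric vector of replica averages.
#' @return One-row tibble: `mean`, `sem`, `n_replicas`, `sem_defined`.
#' @export
replica_mean_sem <- function(per_replica_means) {
  r <- length(per_replica_means)
  if (r == 0) stop_hd("No replica means supplied.", "empty_input_error")
  tibble(mean = mean(per_replica_means),
         sem = if (r > 1) sd(per_replica_means) / sqrt(r) else NA_real_,
         n_replicas = r, sem_defined = r > 1)
}

#' Stationary AR(1) series with unit marginal variance
#'
#' `x[t] = rho * x[t-1] + sqrt(1 - rho^2) * eps[t]`, with
#' `x[1] ~ N(0, 1)`, so the marginal variance is 1 for every `t`. The
#' population autocorrelation function is `rho^k`, giving the closed-form
#' autocorrelation time `-1 / log(rho)` used in validation.
#'
#' @param n Length (>= 10).
#' @param rho Lag-1 autocorrelation, `|rho| < 1`.
#' @param seed RNG seed.
#' @return Numeric vector of length `n`.
#' @export
gen_ar1 <- function(n, rho, seed = 1L) {
  if (abs(rho) >= 1) {
    stop_hd("AR(1) requires |rho| < 1 for stationarity.",
            "nonstationary_error")
  }
  if (n < 10) stop_hd("Need n >= 10.", "series_error")
  with_seed(seed, {
    eps <- rnorm(n)
    x <- numeric(n)
    x[1] <- eps[1]
    s <- sqrt(1 - rho^2)
    for (t in 2:n) x[t] <- rho * x[t - 1] + s * eps[t]
    x
  })
}
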