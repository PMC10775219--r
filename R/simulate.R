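#' Discrete-event simulation of an M/M/s queue
#'
#' Event-driven validation oracle for the analytic Erlang-C formulas:
#' Poisson arrivals, exponential service, `s` parallel servers,
#' first-come-first-served. Each arrival's queue wait is
#' `max(0, earliest server free time - arrival time)`. The mean queue wait
#' is estimated after a warm-up period, and its standard error is computed
#' by the method of batch means because successive waits in a queue are
#' strongly autocorrelated (a naive `sd/sqrt(n)` would understate the
#' error).
#'
#' @inheritParams erlang_c
#' @param n_arrivals Number of simulated arrivals (at least 10^4).
#' @param seed Integer seed; the run is reproducible under a fixed seed.
#' @param warmup Number of initial arrivals discarded (default 1000).
#' @param n_batches Number of batches for the batch-means standard error
#'   (default 50).
#' @return A list with `mean_wq` (working-days), `se` (batch-means standard
#'   error), `n_used`, and the analytic settings.
#' @examples
#' sim <- simulate_mms(1, 2, 1, n_arrivals = 2e4, seed = 1)
#' abs(sim$mean_wq - 0.5) < 3 * sim$se
#' @export
simulate_mms <- function(lambda, mu, s, n_arrivals = 1e5, seed,
                         warmup = 1000, n_batches = 50) {
  check_queue_spec(lambda, mu, s)
  if (lambda <= 0) stop("simulation needs a positive arrival rate", call. = FALSE)
  if (lambda / (s * mu) >= 1) {
    stop("refusing to simulate an unstable queue (utilization >= 1)",
         call. = FALSE)
  }
  if (n_arrivals < 1e4) stop("n_arrivals must be at least 10^4", call. = FALSE)
  if (missing(seed)) stop("a seed is required for reproducibility", call. = FALSE)
  set.seed(seed)

  arrivals <- cumsum(stats::rexp(n_arrivals, lambda))
  service <- stats::rexp(n_arrivals, mu)
  free <- numeric(s) # next time each server becomes free
  wq <- numeric(n_arrivals)
  for (i in seq_len(n_arrivals)) {
    k <- which.min(free)
    start <- max(arrivals[i], free[k])
    wq[i] <- start - arrivals[i]
    free[k] <- start + service[i]
  }

  kept <- wq[(warmup + 1):n_arrivals]
  n <- length(kept)
  batch_size <- n %/% n_batches
  batches <- colMeans(matrix(kept[seq_len(batch_size * n_batches)],
                             nrow = batch_size))
  list(
    mean_wq = mean(kept),
    se = stats::sd(batches) / sqrt(n_batches),
    n_used = n,
    lambda = lambda, mu = mu, s = s, seed = seed
  )
}
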