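#' Erlang-C delay probability for an M/M/s queue
#'
#' Probability that an arriving sample finds all `s` servers busy and must
#' wait. Computed through the Erlang-B recurrence
#' `B(k) = a B(k-1) / (k + a B(k-1))` with offered load `a = lambda/mu`,
#' then `C = B / (1 - rho + rho B)`; this is numerically stable for large
#' `s` where the textbook factorial sum overflows.
#'
#' @param lambda Arrival rate (samples per working day).
#' @param mu Service rate per server (samples per working day).
#' @param s Number of parallel servers.
#' @return The delay probability in `[0, 1]`.
#' @examples
#' erlang_c(1, 2, 1)  # 0.5: for s = 1 the delay probability equals rho
#' @export
erlang_c <- function(lambda, mu, s) {
  check_queue_spec(lambda, mu, s)
  if (lambda == 0) return(0)
  rho <- lambda / (s * mu)
  if (rho >= 1) {
    stop(sprintf("unstable queue: utilization %.4f >= 1 (lambda=%g, mu=%g, s=%d)",
                 rho, lambda, mu, s), call. = FALSE)
  }
  a <- lambda / mu
  b <- 1
  for (k in seq_len(s)) b <- a * b / (k + a * b)
  b / (1 - rho + rho * b)
}

#' Steady-state metrics for an M/M/s queue
#'
#' Utilization, Erlang-C delay probability, expected queue wait `Wq` and
#' expected time in system `W = Wq + 1/mu`, all in working-days. An
#' unstable queue (`rho >= 1`) is reported with `stable = FALSE` and
#' infinite waits rather than an error, so that network evaluation can
#' surface which site is overloaded.
#'
#' @inheritParams erlang_c
#' @return A list of class `queue_metrics` with elements `lambda`, `mu`,
#'   `s`, `utilization`, `p_wait`, `Wq`, `W`, `stable`.
#' @examples
#' mms_metrics(1, 2, 1)$Wq  # 0.5 working-days (M/M/1: rho / (mu - lambda))
#' @export
mms_metrics <- function(lambda, mu, s) {
  check_queue_spec(lambda, mu, s)
  rho <- lambda / (s * mu)
  if (rho >= 1) {
    out <- list(lambda = lambda, mu = mu, s = s, utilization = rho,
                p_wait = 1, Wq = Inf, W = Inf, stable = FALSE)
    return(structure(out, class = "queue_metrics"))
  }
  p_wait <- erlang_c(lambda, mu, s)
  Wq <- if (lambda == 0) 0 else p_wait / (s * mu - lambda)
  structure(
    list(lambda = lambda, mu = mu, s = s, utilization = rho,
         p_wait = p_wait, Wq = Wq, W = Wq + 1 / mu, stable = TRUE),
    class = "queue_metrics"
  )
}

#' @export
print.queue_metrics <- function(x, ...) {
  cat(sprintf("M/M/%d queue: lambda=%g, mu=%g | rho=%.3f p_wait=%.3f Wq=%.4g W=%.4g (%s)\n",
              x$s, x$lambda, x$mu, x$utilization, x$p_wait, x$Wq, x$W,
              if (x$stable) "stable" else "UNSTABLE"))
  invisible(x)
}

check_queue_spec <- function(lambda, mu, s) {
  if (length(lambda) != 1 || length(mu) != 1 || length(s) != 1 ||
      lambda < 0 || mu <= 0 || s < 1 || s != floor(s)) {
    stop("invalid queue spec: need lambda >= 0, mu > 0, integer s >= 1",
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Expected time in system at a central laboratory
#'
#' A central lab processes samples in two consecutive stages: (1) data
#' entry by `n_entry_servers` staff, modelled as an M/M/s queue at
#' `entry_service_rate` per server, and (2) machine testing, modelled as a
#' single-stream M/M/1 queue at `machine_service_rate`. Both stages see the
#' same total arrival rate (in-county assigned demand plus out-of-county
#' background), and the expected time in system is the sum of the two
#' stage times.
#'
#' @param site One row of an instance's `sites` table (a central lab).
#' @param lambda_total Total arrival rate, samples per working day.
#' @param entry_rate_is_pooled If `TRUE`, interpret `entry_service_rate` as
#'   the pooled lab-level rate and divide it by `n_entry_servers` to get
#'   the per-server rate. Default `FALSE`: the printed rate is per server.
#' @return Expected time in system, working-days.
#' @export
central_lab_wait <- function(site, lambda_total, entry_rate_is_pooled = FALSE) {
  stopifnot(site$kind == "central_lab")
  mu_entry <- site$entry_service_rate
  if (entry_rate_is_pooled) mu_entry <- mu_entry / site$n_entry_servers
  entry <- mms_metrics(lambda_total, mu_entry, site$n_entry_servers)
  if (!entry$stable) {
    stop(sprintf("unstable entry stage at %s: utilization %.3f >= 1",
                 site$id, entry$utilization), call. = FALSE)
  }
  machine <- mms_metrics(lambda_total, site$machine_service_rate, 1L)
  if (!machine$stable) {
    stop(sprintf("unstable machine stage at %s: utilization %.3f >= 1",
                 site$id, machine$utilization), call. = FALSE)
  }
  entry$W + machine$W
}

#' Expected time in system at a point-of-care hub
#'
#' A hub with `n_machines` point-of-care machines is an M/M/s queue with
#' `s = n_machines`. Because the machines are multi-disease platforms, only
#' a fraction `vl_fraction` of each machine's throughput is dedicated to
#' viral-load samples, which scales the effective per-machine service rate:
#' `mu_eff = machine_service_rate * vl_fraction`.
#'
#' @param site One row of an instance's `sites` table (a hub).
#' @param lambda Assigned arrival rate, samples per working day.
#' @return Expected time in system, working-days.
#' @export
poc_hub_wait <- function(site, lambda) {
  stopifnot(site$kind %in% c("existing_hub", "candidate_hub"))
  mu_eff <- site$machine_service_rate * site$vl_fraction
  m <- mms_metrics(lambda, mu_eff, as.integer(site$n_machines))
  if (!m$stable) {
    stop(sprintf("unstable hub queue at %s: utilization %.3f >= 1",
                 site$id, m$utilization), call. = FALSE)
  }
  m$W
}

#' Out-of-county background arrival rate at a central lab
#'
#' Central labs also accept samples from other counties. If a fraction `f`
#' of a lab's samples come from the modelled county and the lab receives
#' `baseline_assigned` in-county samples per working day under the existing
#' referral network, its background rate is
#' `baseline_assigned * (1 - f) / f`. The background is held constant when
#' the in-county referral network is re-optimized.
#'
#' @param f In-county share of the lab's samples, in `(0, 1]`.
#' @param baseline_assigned In-county samples per working day under the
#'   existing network.
#' @return Background samples per working day.
#' @examples
#' background_rate(0.24, 24) # 76
#' @export
background_rate <- function(f, baseline_assigned) {
  if (length(f) != 1 || is.na(f) || f <= 0 || f > 1) {
    stop("in-county fraction must lie in (0, 1]", call. = FALSE)
  }
  if (baseline_assigned < 0) {
    stop("baseline assigned demand must be non-negative", call. = FALSE)
  }
  baseline_assigned * (1 - f) / f
}
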