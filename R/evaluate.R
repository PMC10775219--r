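#' Turnaround-time decomposition for a referral network
#'
#' Computes, for every facility, the three additive components of expected
#' sample turnaround time under a given referral network: the batching
#' delay at the clinic, the transport time to its assigned site, and the
#' expected time in system (queue wait plus service) at that site. Site
#' waits come from the steady-state queueing model — [central_lab_wait()]
#' for labs (assigned plus background arrivals) and [poc_hub_wait()] for
#' hubs — and are identical for all facilities assigned to the same site.
#' Queue waits in working-days are converted to clock minutes at
#' `workday_hours * 60` minutes per working day.
#'
#' Sites loaded above the utilization cap but below 1 are reported with a
#' warning; a site at or above utilization 1 is an error naming the site.
#'
#' @param instance A [problem_instance()].
#' @param network A `referral_network` from [solve_allocation()],
#'   [existing_network()] or [bruteforce_allocation()].
#' @param scenario Label stored in the report (free text).
#' @return A `system_report`: list with `scenario`, `facility_tat` (one row
#'   per facility: `facility_id`, `site_id`, `batching_min`,
#'   `transport_min`, `waiting_min`, `total_min`), `mean_tat_min` /
#'   `sd_tat_min` (unweighted across facilities), `total_sample_hours`
#'   (demand-weighted total time per working day, hours),
#'   `component_shares` (demand-weighted proportions summing to 1), and
#'   `site_metrics` (per open site: arrival rates, utilization, expected
#'   time in system).
#' @export
evaluate_network <- function(instance, network, scenario = "custom") {
  stopifnot(inherits(instance, "poc_instance"),
            inherits(network, "referral_network"))
  fac <- instance$facilities
  sites <- instance$sites
  assignment <- network$assignment[fac$id]
  if (anyNA(assignment)) {
    stop("network does not assign every facility", call. = FALSE)
  }
  closed <- setdiff(unique(assignment), network$open_sites)
  if (length(closed)) {
    stop("facilities assigned to closed site(s): ",
         paste(closed, collapse = ", "), call. = FALSE)
  }

  tmat <- transport_minutes(instance)
  b <- instance$batching$expected_delay_min
  min_per_day <- instance$workday_hours * 60

  open <- network$open_sites
  assigned_load <- vapply(open, function(j) {
    sum(fac$daily_demand[assignment == j])
  }, numeric(1))

  site_rows <- match(open, sites$id)
  waits_min <- numeric(length(open))
  util <- numeric(length(open))
  for (k in seq_along(open)) {
    site <- sites[site_rows[k], ]
    if (site$kind == "central_lab") {
      lambda <- assigned_load[k] + site$background_demand
      util[k] <- lambda / min(site$n_entry_servers * site$entry_service_rate,
                              site$machine_service_rate)
      w <- central_lab_wait(site, lambda)
    } else {
      lambda <- assigned_load[k]
      util[k] <- lambda /
        (site$n_machines * site$machine_service_rate * site$vl_fraction)
      w <- poc_hub_wait(site, lambda)
    }
    waits_min[k] <- w * min_per_day
  }
  over <- open[util > instance$utilization_cap & util < 1]
  if (length(over)) {
    warning("utilization above the planning cap at: ",
            paste(over, collapse = ", "), call. = FALSE)
  }

  k_of_fac <- match(assignment, open)
  facility_tat <- data.frame(
    facility_id = fac$id,
    site_id = unname(assignment),
    batching_min = rep(b, nrow(fac)),
    transport_min = tmat[cbind(fac$id, assignment)],
    waiting_min = waits_min[k_of_fac],
    stringsAsFactors = FALSE
  )
  facility_tat$total_min <- facility_tat$batching_min +
    facility_tat$transport_min + facility_tat$waiting_min

  d <- fac$daily_demand
  total_d <- sum(d)
  shares <- if (total_d > 0) {
    c(batching = sum(d * facility_tat$batching_min),
      transport = sum(d * facility_tat$transport_min),
      waiting = sum(d * facility_tat$waiting_min)) /
      sum(d * facility_tat$total_min)
  } else {
    c(batching = NA_real_, transport = NA_real_, waiting = NA_real_)
  }

  site_metrics <- data.frame(
    site_id = open,
    kind = sites$kind[site_rows],
    assigned_demand = assigned_load,
    background_demand = ifelse(sites$kind[site_rows] == "central_lab",
                               sites$background_demand[site_rows], 0),
    utilization = util,
    wait_min = waits_min,
    stringsAsFactors = FALSE
  )
  rownames(site_metrics) <- NULL

  structure(
    list(
      scenario = scenario,
      facility_tat = facility_tat,
      mean_tat_min = mean(facility_tat$total_min),
      sd_tat_min = stats::sd(facility_tat$total_min),
      total_sample_hours = sum(d * facility_tat$total_min) / 60,
      component_shares = shares,
      site_metrics = site_metrics,
      network = network,
      batching_mode = instance$batching$mode,
      transport_mode = instance$transport$mode
    ),
    class = "system_report"
  )
}

#' Run one of the three planning scenarios
#'
#' * Scenario 1 evaluates the *existing* referral network: central labs
#'   only, no optimization.
#' * Scenario 2 re-optimizes the referral network over the central labs
#'   and existing hubs (no hubs added).
#' * Scenario 3 additionally opens `p_add` new hubs (1-7) at optimized
#'   locations.
#'
#' @param instance A [problem_instance()].
#' @param scenario 1, 2 or 3.
#' @param p_add Number of added hubs for scenario 3.
#' @param fairness Fairness constraint for scenario 3 (default from the
#'   instance).
#' @param ... Passed on to [solve_allocation()].
#' @return A `system_report`.
#' @export
run_scenario <- function(instance, scenario, p_add = instance$n_added_hubs,
                         fairness = instance$fairness, ...) {
  stopifnot(scenario %in% 1:3)
  network <- switch(as.character(scenario),
    "1" = existing_network(instance),
    "2" = solve_allocation(instance, n_added = 0, fairness = FALSE, ...),
    "3" = {
      if (p_add < 0 || p_add > 7) {
        stop("scenario 3 expects between 0 and 7 added hubs", call. = FALSE)
      }
      solve_allocation(instance, n_added = p_add, fairness = fairness, ...)
    }
  )
  evaluate_network(instance, network,
                   scenario = sprintf("scenario %d", scenario))
}

#' @export
print.system_report <- function(x, ...) {
  cat(sprintf("System report (%s): batching %s, transport %s\n",
              x$scenario, x$batching_mode, x$transport_mode))
  cat(sprintf("  mean TAT %.1f min (%.1f h), SD %.1f min across %d facilities\n",
              x$mean_tat_min, x$mean_tat_min / 60, x$sd_tat_min,
              nrow(x$facility_tat)))
  cat(sprintf("  total sample-time %.1f h/workday\n", x$total_sample_hours))
  cat(sprintf("  demand-weighted shares: batching %.1f%%, waiting %.1f%%, transport %.1f%%\n",
              100 * x$component_shares[["batching"]],
              100 * x$component_shares[["waiting"]],
              100 * x$component_shares[["transport"]]))
  invisible(x)
}

#' @export
summary.system_report <- function(object, ...) {
  cat(sprintf("Scenario: %s\n", object$scenario))
  print(object)
  cat("\nOpen-site loads:\n")
  print(object$site_metrics, digits = 3)
  invisible(object)
}

#' @export
plot.system_report <- function(x, ...) {
  comp <- rbind(
    batching = x$facility_tat$batching_min,
    transport = x$facility_tat$transport_min,
    waiting = x$facility_tat$waiting_min
  )
  graphics::barplot(comp, names.arg = rep("", ncol(comp)),
                    col = c("grey70", "steelblue", "firebrick"),
                    border = NA, space = 0,
                    xlab = "facility", ylab = "minutes",
                    main = sprintf("TAT decomposition (%s)", x$scenario), ...)
  graphics::legend("topright", legend = rownames(comp),
                   fill = c("grey70", "steelblue", "firebrick"), bty = "n")
  invisible(x)
}
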