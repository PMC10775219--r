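#' Assemble and validate a testing-network problem instance
#'
#' Bundles everything one scenario run needs: the clinics with their demand,
#' the testing sites (central labs, existing point-of-care hubs, candidate
#' hubs), the clinic-by-site road-distance matrix, and the run-level
#' conventions (transport mode, batching policy, utilization cap, working
#' time). Facility daily demand is derived from the annual client volumes
#' via [estimate_annual_demand()] and [estimate_daily_demand()] and cached
#' on the facility table. Each central lab's out-of-county background
#' arrival rate is derived from its in-county share via [background_rate()],
#' using the in-county demand it receives under the *existing* referral
#' network; the background rate is held constant across scenarios.
#'
#' @param facilities Data frame with columns `id`, `name`, `level` (1-5),
#'   `sub_county`, `lat`, `lon`, `annual_child_volume`,
#'   `annual_adult_volume`, `current_site_id`.
#' @param sites Data frame with columns `id`, `name`, `kind` (one of
#'   `central_lab`, `existing_hub`, `candidate_hub`), `level` (may be `NA`
#'   for labs), `sub_county`, `lat`, `lon`, `n_entry_servers`,
#'   `entry_service_rate`, `machine_service_rate`, `n_machines`,
#'   `kisumu_fraction`, `vl_fraction`, `fixed_open`.
#' @param distance_km Numeric matrix, facilities in rows and sites in
#'   columns (dimnames must match the id columns), road distance in km.
#' @param transport A [transport_params()] object.
#' @param batching A [batching_policy()] object.
#' @param n_added_hubs Default number of hubs to add in expansion scenarios.
#' @param fairness Default for the sub-county fairness constraint.
#' @param utilization_cap Planned utilization ceiling (default 0.9).
#' @param workday_hours Hours per working day (default 7).
#' @param workdays_per_month Working days per month (default 20).
#' @param time_min Optional facility-by-site travel-time matrix (minutes)
#'   that overrides computed transport times.
#' @return A list of class `poc_instance`.
#' @seealso [generate_instance()] for a seeded synthetic county,
#'   [read_instance()]/[write_instance()] for the CSV schemas.
#' @export
problem_instance <- function(facilities, sites, distance_km,
                             transport = transport_params(),
                             batching = batching_policy(),
                             n_added_hubs = 0, fairness = FALSE,
                             utilization_cap = 0.9, workday_hours = 7,
                             workdays_per_month = 20, time_min = NULL) {
  facilities <- as.data.frame(facilities, stringsAsFactors = FALSE)
  sites <- as.data.frame(sites, stringsAsFactors = FALSE)

  fac_cols <- c("id", "name", "level", "sub_county", "lat", "lon",
                "annual_child_volume", "annual_adult_volume", "current_site_id")
  miss <- setdiff(fac_cols, names(facilities))
  if (length(miss)) {
    stop("facilities table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  site_cols <- c("id", "name", "kind", "sub_county", "lat", "lon",
                 "n_entry_servers", "entry_service_rate",
                 "machine_service_rate", "n_machines", "kisumu_fraction",
                 "vl_fraction", "fixed_open")
  miss <- setdiff(site_cols, names(sites))
  if (length(miss)) {
    stop("sites table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (!"level" %in% names(sites)) sites$level <- NA_integer_

  if (anyDuplicated(facilities$id)) stop("duplicate facility ids", call. = FALSE)
  if (anyDuplicated(sites$id)) stop("duplicate site ids", call. = FALSE)
  if (!all(facilities$level %in% 1:5)) {
    stop("facility levels must be integers in 1..5", call. = FALSE)
  }
  if (any(facilities$annual_child_volume < 0) ||
      any(facilities$annual_adult_volume < 0)) {
    stop("client volumes must be non-negative", call. = FALSE)
  }
  if (!all(sites$kind %in% c("central_lab", "existing_hub", "candidate_hub"))) {
    stop("site kind must be central_lab, existing_hub or candidate_hub",
         call. = FALSE)
  }
  labs <- sites$kind == "central_lab"
  hubs <- !labs
  if (any(sites$machine_service_rate <= 0) || any(sites$n_machines < 1)) {
    stop("machine service rates must be positive and machine counts >= 1",
         call. = FALSE)
  }
  if (any(labs & (is.na(sites$n_entry_servers) | sites$n_entry_servers < 1))) {
    stop("central labs need n_entry_servers >= 1", call. = FALSE)
  }
  if (any(labs & (is.na(sites$entry_service_rate) | sites$entry_service_rate <= 0))) {
    stop("central labs need a positive entry_service_rate", call. = FALSE)
  }
  kf <- sites$kisumu_fraction[labs]
  if (any(is.na(kf) | kf <= 0 | kf > 1)) {
    stop("central-lab kisumu_fraction must lie in (0, 1]", call. = FALSE)
  }
  vf <- sites$vl_fraction[hubs]
  if (any(is.na(vf) | vf <= 0 | vf > 1)) {
    stop("hub vl_fraction must lie in (0, 1]", call. = FALSE)
  }
  if (!all(sites$fixed_open[sites$kind %in% c("central_lab", "existing_hub")])) {
    stop("central labs and existing hubs must be fixed_open", call. = FALSE)
  }
  if (any(sites$fixed_open[sites$kind == "candidate_hub"])) {
    stop("candidate hubs must not be fixed_open", call. = FALSE)
  }

  lab_ids <- sites$id[labs]
  dangling <- setdiff(unique(facilities$current_site_id), lab_ids)
  if (length(dangling)) {
    stop("current_site_id refers to unknown central lab(s): ",
         paste(dangling, collapse = ", "), call. = FALSE)
  }

  distance_km <- as.matrix(distance_km)
  if (is.null(rownames(distance_km)) || is.null(colnames(distance_km)) ||
      !setequal(rownames(distance_km), facilities$id) ||
      !setequal(colnames(distance_km), sites$id)) {
    stop("distance matrix dimnames must match facility and site ids",
         call. = FALSE)
  }
  distance_km <- distance_km[facilities$id, sites$id, drop = FALSE]
  if (anyNA(distance_km) || any(distance_km < 0)) {
    stop("distance matrix must be complete and non-negative", call. = FALSE)
  }
  if (!is.null(time_min)) {
    time_min <- as.matrix(time_min)[facilities$id, sites$id, drop = FALSE]
    if (anyNA(time_min) || any(time_min < 0)) {
      stop("travel-time matrix must be complete and non-negative", call. = FALSE)
    }
  }

  n_candidates <- sum(sites$kind == "candidate_hub")
  if (n_added_hubs < 0 || n_added_hubs > n_candidates) {
    stop("n_added_hubs must lie in 0..", n_candidates, call. = FALSE)
  }
  if (utilization_cap <= 0 || utilization_cap > 1) {
    stop("utilization_cap must lie in (0, 1]", call. = FALSE)
  }
  stopifnot(workday_hours > 0, workdays_per_month > 0)
  stopifnot(inherits(transport, "transport_params"),
            inherits(batching, "batching_policy"))

  facilities$daily_demand <- estimate_daily_demand(
    estimate_annual_demand(facilities$annual_child_volume,
                           facilities$annual_adult_volume),
    workdays_per_month
  )

  # out-of-county background load at each central lab, from its in-county
  # share and the demand it receives under the existing network
  sites$background_demand <- 0
  for (j in which(labs)) {
    assigned <- sum(facilities$daily_demand[
      facilities$current_site_id == sites$id[j]])
    sites$background_demand[j] <- background_rate(sites$kisumu_fraction[j],
                                                  assigned)
  }

  structure(
    list(
      facilities = facilities, sites = sites, distance_km = distance_km,
      time_min = time_min, transport = transport, batching = batching,
      n_added_hubs = n_added_hubs, fairness = fairness,
      utilization_cap = utilization_cap, workday_hours = workday_hours,
      workdays_per_month = workdays_per_month
    ),
    class = "poc_instance"
  )
}

#' @export
print.poc_instance <- function(x, ...) {
  kinds <- table(factor(x$sites$kind,
                        c("central_lab", "existing_hub", "candidate_hub")))
  cat("Testing-network problem instance\n")
  cat(sprintf("  %d facilities in %d sub-counties, total demand %.1f samples/workday\n",
              nrow(x$facilities), length(unique(x$facilities$sub_county)),
              sum(x$facilities$daily_demand)))
  cat(sprintf("  sites: %d central labs, %d existing hubs, %d candidate hubs\n",
              kinds[["central_lab"]], kinds[["existing_hub"]],
              kinds[["candidate_hub"]]))
  cat(sprintf("  batching %s, transport %s, utilization cap %.0f%%\n",
              x$batching$mode, x$transport$mode, 100 * x$utilization_cap))
  invisible(x)
}
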