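#' Configuration for the synthetic county generator
#'
#' Describes a synthetic county testing network in the image of a western
#' Kenyan county: ~146 clinics clustered into sub-counties, three central
#' labs (one in-county, two remote), seven existing point-of-care hubs with
#' machine counts 4/2/1/1/1/1/1 placed one per sub-county at the largest
#' local facility, and twelve candidate hub sites at large level-3+
#' facilities.
#'
#' Facility demand is drawn from a right-skewed distribution and then
#' rescaled so that, under the existing referral network, the in-county
#' central lab operates near-critically (`main_lab_utilization`, default
#' 0.9985): the legacy network runs the standard-of-care lab at the edge of
#' its capacity, which is what makes waiting a substantial share of
#' turnaround time before the network is re-optimized. The two remote labs
#' carry large out-of-county background loads and sit far below saturation.
#' Out-of-county background demand is derived from each lab's in-county
#' share via [background_rate()], never drawn independently. Road
#' distances are great-circle distances times a circuity factor.
#'
#' @param n_facilities Number of clinics (default 146).
#' @param n_subcounties Number of sub-county clusters (default 7).
#' @param n_existing_hubs Existing hubs, one per sub-county (default 7).
#' @param existing_hub_machines Machine counts for the existing hubs.
#' @param n_candidate_hubs Candidate hub sites (default 12).
#' @param added_hub_machines Machines at each added hub (default 2).
#' @param demand_max_daily Ceiling on facility daily demand (default 37).
#' @param level_distribution Proportions of facilities at levels 1-5;
#'   levels are assigned by demand rank (largest facilities get the
#'   highest levels).
#' @param bbox County bounding box, `c(lon_min, lat_min, lon_max, lat_max)`
#'   in decimal degrees.
#' @param circuity_factor Road-distance multiplier on great-circle
#'   distance (default 1.3).
#' @param remote_km Distances of the two remote central labs from the
#'   county centre (default 95 and 140 km).
#' @param kisumu_fractions In-county sample shares of the three labs; the
#'   first entry belongs to the in-county lab.
#' @param main_lab_utilization Calibrated utilization of the in-county lab
#'   under the existing network (default 0.9985).
#' @param misassignment Fraction of clinics whose legacy lab is not their
#'   nearest one (default 0.2).
#' @param seed Integer seed (mandatory; generation is fully reproducible).
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(n_facilities = 146, n_subcounties = 7,
                             n_existing_hubs = 7,
                             existing_hub_machines = c(4, 2, 1, 1, 1, 1, 1),
                             n_candidate_hubs = 12, added_hub_machines = 2,
                             demand_max_daily = 37,
                             level_distribution = c(0.35, 0.30, 0.22, 0.10, 0.03),
                             bbox = c(34.35, -0.45, 34.85, -0.05),
                             circuity_factor = 1.3,
                             remote_km = c(95, 140),
                             kisumu_fractions = c(0.13, 0.24, 0.05),
                             main_lab_utilization = 0.9985,
                             misassignment = 0.2, seed) {
  if (missing(seed)) stop("a seed is mandatory for reproducibility", call. = FALSE)
  stopifnot(
    n_facilities > 0, n_subcounties > 0,
    n_existing_hubs == n_subcounties,
    length(existing_hub_machines) == n_existing_hubs,
    all(existing_hub_machines >= 1),
    n_candidate_hubs >= n_subcounties,
    added_hub_machines >= 1,
    demand_max_daily > 0,
    length(level_distribution) == 5,
    abs(sum(level_distribution) - 1) < 1e-9,
    length(remote_km) == 2, all(remote_km > 0),
    length(kisumu_fractions) == 3,
    all(kisumu_fractions > 0 & kisumu_fractions <= 1),
    main_lab_utilization > 0 && main_lab_utilization < 1,
    misassignment >= 0 && misassignment < 1
  )
  structure(
    list(n_facilities = n_facilities, n_subcounties = n_subcounties,
         n_existing_hubs = n_existing_hubs,
         existing_hub_machines = existing_hub_machines,
         n_candidate_hubs = n_candidate_hubs,
         added_hub_machines = added_hub_machines,
         demand_max_daily = demand_max_daily,
         level_distribution = level_distribution, bbox = bbox,
         circuity_factor = circuity_factor, remote_km = remote_km,
         kisumu_fractions = kisumu_fractions,
         main_lab_utilization = main_lab_utilization,
         misassignment = misassignment, seed = seed),
    class = "generator_config"
  )
}

#' Generate a synthetic county problem instance
#'
#' Draws a complete, validated [problem_instance()] from a
#' [generator_config()]: clustered facility coordinates, demand-ranked
#' facility levels, existing hubs and eligible candidate hubs (each
#' sub-county is guaranteed at least one level-3+ candidate, so the
#' fairness constraint is always satisfiable), legacy lab assignments
#' (nearest lab with a misassigned fraction), circuity-adjusted road
#' distances and the near-critical in-county lab calibration. Identical
#' seeds give identical instances.
#'
#' @param config A [generator_config()].
#' @return A `poc_instance` with default settings: twice-weekly batching,
#'   motorbike transport at average road and weather conditions, 7 added
#'   hubs, fairness on.
#' @export
generate_instance <- function(config = generator_config(seed = 1)) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  nf <- config$n_facilities
  K <- config$n_subcounties
  bbox <- config$bbox
  centre <- c(lon = (bbox[1] + bbox[3]) / 2, lat = (bbox[2] + bbox[4]) / 2)

  # sub-county cluster centres: downtown plus a ring
  sc_names <- paste0("SC", seq_len(K))
  ang <- 2 * pi * (seq_len(K - 1) - 1) / (K - 1)
  sc_lon <- c(centre["lon"], centre["lon"] + 0.18 * cos(ang))
  sc_lat <- c(centre["lat"], centre["lat"] + 0.13 * sin(ang))

  counts <- rep(nf %/% K, K) + (seq_len(K) <= nf %% K)
  sc_of <- rep(seq_len(K), counts)
  lon <- pmin(pmax(sc_lon[sc_of] + stats::rnorm(nf, 0, 0.030), bbox[1]), bbox[3])
  lat <- pmin(pmax(sc_lat[sc_of] + stats::rnorm(nf, 0, 0.025), bbox[2]), bbox[4])
  fac_ids <- sprintf("F%03d", seq_len(nf))

  # skewed raw demand; hub hosts (facility nearest each sub-county centre)
  # receive the largest demand of their sub-county, the downtown host the
  # largest overall -- county hospitals are the biggest facilities
  d_raw <- stats::rgamma(nf, shape = 0.45, rate = 1)
  host <- integer(K)
  for (k in seq_len(K)) {
    members <- which(sc_of == k)
    dist_c <- (lon[members] - sc_lon[k])^2 + (lat[members] - sc_lat[k])^2
    host[k] <- members[which.min(dist_c)]
    i_max <- members[which.max(d_raw[members])]
    d_raw[c(host[k], i_max)] <- d_raw[c(i_max, host[k])]
  }
  i_max <- which.max(d_raw)
  d_raw[c(host[1], i_max)] <- d_raw[c(i_max, host[1])]

  # levels by demand rank
  level <- integer(nf)
  qs <- cumsum(rev(config$level_distribution)) # shares of levels 5,4,3,2,1
  rk <- rank(-d_raw, ties.method = "first") / nf
  level[rk <= qs[1]] <- 5L
  level[rk > qs[1] & rk <= qs[2]] <- 4L
  level[rk > qs[2] & rk <= qs[3]] <- 3L
  level[rk > qs[3] & rk <= qs[4]] <- 2L
  level[rk > qs[4]] <- 1L
  level[host] <- pmax(level[host], 4L) # hub hosts are county hospitals

  # candidate hubs: the largest level-3+ non-host facility per sub-county
  # (bumping a facility to level 3 if a sub-county has none), then the
  # largest remaining level-3+ facilities until n_candidate_hubs
  cand <- integer(0)
  for (k in seq_len(K)) {
    members <- setdiff(which(sc_of == k), host)
    ok <- members[level[members] >= 3]
    if (!length(ok)) {
      bump <- members[which.max(d_raw[members])]
      level[bump] <- 3L
      ok <- bump
    }
    cand <- c(cand, ok[which.max(d_raw[ok])])
  }
  needed <- config$n_candidate_hubs - K
  pool <- setdiff(which(level >= 3), c(host, cand))
  if (length(pool) < needed) {
    # promote the largest remaining facilities so the candidate list fills
    extra <- setdiff(order(-d_raw), c(host, cand, pool))
    promote <- extra[seq_len(needed - length(pool))]
    level[promote] <- 3L
    pool <- c(pool, promote)
  }
  pool <- pool[order(-d_raw[pool])]
  cand <- c(cand, pool[seq_len(needed)])

  # central labs: one in-county (downtown), two remote
  lab_ids <- c("LAB1", "LAB2", "LAB3")
  p2 <- geosphere::destPoint(centre, 45, config$remote_km[1] * 1000)
  p3 <- geosphere::destPoint(centre, 200, config$remote_km[2] * 1000)
  lab_lon <- c(centre[["lon"]] + 0.01, p2[1], p3[1])
  lab_lat <- c(centre[["lat"]] - 0.01, p2[2], p3[2])

  # legacy assignment: nearest lab, with a misassigned fraction sent to a
  # random other lab
  dist_to_labs <- geosphere::distHaversine(
    cbind(rep(lon, 3), rep(lat, 3)),
    cbind(rep(lab_lon, each = nf), rep(lab_lat, each = nf)))
  dist_to_labs <- matrix(dist_to_labs, nf, 3)
  current <- lab_ids[apply(dist_to_labs, 1, which.min)]
  n_mis <- round(config$misassignment * nf)
  if (n_mis > 0) {
    mis <- sample.int(nf, n_mis)
    for (i in mis) {
      current[i] <- sample(setdiff(lab_ids, current[i]), 1)
    }
  }

  # calibration: scale demand so the in-county lab runs at the target
  # utilization under the legacy network
  f_in <- config$kisumu_fractions[1]
  stage_cap <- min(2 * 710, 1500)
  target_assigned <- config$main_lab_utilization * f_in * stage_cap
  assigned_raw <- sum(d_raw[current == "LAB1"])
  if (assigned_raw <= 0) stop("degenerate draw: no demand at the in-county lab")
  d_daily <- pmin(d_raw * target_assigned / assigned_raw,
                  config$demand_max_daily)

  # annual client volumes consistent with the demand formula
  # (child volume ~ 10% of adult volume); kept at 0.01 precision so the
  # calibrated utilization survives the volume representation
  adult <- round(d_daily * 240 / (1.08 + 0.2), 2)
  child <- round(0.1 * adult, 2)

  facilities <- data.frame(
    id = fac_ids,
    name = ifelse(seq_len(nf) %in% host,
                  paste0("County Hospital ", sc_names[sc_of]),
                  paste0("Clinic ", fac_ids)),
    level = level, sub_county = sc_names[sc_of], lat = round(lat, 6),
    lon = round(lon, 6), annual_child_volume = child,
    annual_adult_volume = adult, current_site_id = current,
    stringsAsFactors = FALSE
  )

  labs <- data.frame(
    id = lab_ids,
    name = c("Central Lab A (in-county)", "Central Lab B", "Central Lab C"),
    kind = "central_lab", level = NA_integer_,
    sub_county = c(sc_names[1], "out_of_county", "out_of_county"),
    lat = round(lab_lat, 6), lon = round(lab_lon, 6),
    n_entry_servers = 2L, entry_service_rate = 710,
    machine_service_rate = 1500, n_machines = 1L,
    kisumu_fraction = config$kisumu_fractions,
    vl_fraction = NA_real_, fixed_open = TRUE, stringsAsFactors = FALSE
  )
  hubs <- data.frame(
    id = sprintf("HUB%d", seq_len(K)),
    name = paste0("POC Hub ", sc_names),
    kind = "existing_hub", level = level[host], sub_county = sc_names,
    lat = round(lat[host], 6), lon = round(lon[host], 6),
    n_entry_servers = NA_integer_, entry_service_rate = NA_real_,
    machine_service_rate = 12, n_machines = config$existing_hub_machines,
    kisumu_fraction = NA_real_, vl_fraction = 1, fixed_open = TRUE,
    stringsAsFactors = FALSE
  )
  cands <- data.frame(
    id = sprintf("CAND%02d", seq_along(cand)),
    name = paste0("Candidate Hub ", fac_ids[cand]),
    kind = "candidate_hub", level = level[cand], sub_county = sc_names[sc_of[cand]],
    lat = round(lat[cand], 6), lon = round(lon[cand], 6),
    n_entry_servers = NA_integer_, entry_service_rate = NA_real_,
    machine_service_rate = 12, n_machines = config$added_hub_machines,
    kisumu_fraction = NA_real_, vl_fraction = 1, fixed_open = FALSE,
    stringsAsFactors = FALSE
  )
  sites <- rbind(labs, hubs, cands)

  dist_km <- geosphere::distHaversine(
    cbind(rep(facilities$lon, nrow(sites)), rep(facilities$lat, nrow(sites))),
    cbind(rep(sites$lon, each = nf), rep(sites$lat, each = nf))) / 1000
  dist_km <- round(matrix(dist_km, nf, nrow(sites),
                          dimnames = list(facilities$id, sites$id)) *
                     config$circuity_factor, 4)

  instance <- problem_instance(
    facilities = facilities, sites = sites, distance_km = dist_km,
    transport = transport_params("motorbike"),
    batching = batching_policy("twice_weekly"),
    n_added_hubs = min(7, config$n_candidate_hubs), fairness = TRUE
  )

  # generation-time guarantees: a stable legacy network and enough total
  # capacity for the optimized scenarios
  caps <- site_capacities(instance$sites, instance$utilization_cap)
  if (sum(caps) < sum(instance$facilities$daily_demand)) {
    stop("generated instance is infeasible: total capacity below total demand",
         call. = FALSE)
  }
  lab1 <- instance$sites[instance$sites$id == "LAB1", ]
  assigned1 <- sum(instance$facilities$daily_demand[
    instance$facilities$current_site_id == "LAB1"])
  rho1 <- (assigned1 + lab1$background_demand) / stage_cap
  if (rho1 >= 1) {
    stop("generated instance is infeasible: legacy in-county lab unstable",
         call. = FALSE)
  }
  instance
}

#' Small deterministic fixture instance
#'
#' A seven-facility, two-lab, one-hub, three-candidate instance small
#' enough for [bruteforce_allocation()], with moderately tight capacities
#' so that the capacity constraints actually bind. Deterministic under the
#' seed and feasible for 0-3 added hubs.
#'
#' @param seed Integer seed.
#' @return A `poc_instance`.
#' @export
make_fixture_small <- function(seed = 1) {
  set.seed(seed)
  n <- 7
  fac_ids <- sprintf("F%d", seq_len(n))
  sc <- c("A", "A", "A", "B", "B", "B", "B")
  lon <- 34.5 + stats::runif(n, 0, 0.2) + ifelse(sc == "B", 0.25, 0)
  lat <- -0.2 + stats::runif(n, 0, 0.15)
  d_target <- round(stats::runif(n, 0.5, 6), 2)
  adult <- round(d_target * 240 / 1.28, 1)
  child <- round(0.1 * adult, 1)
  current <- sample(c("LAB1", "LAB2"), n, replace = TRUE, prob = c(0.8, 0.2))

  facilities <- data.frame(
    id = fac_ids, name = paste("Clinic", fac_ids),
    level = c(4L, 3L, 1L, 4L, 3L, 2L, 1L), sub_county = sc,
    lat = round(lat, 6), lon = round(lon, 6),
    annual_child_volume = child, annual_adult_volume = adult,
    current_site_id = current, stringsAsFactors = FALSE
  )
  sites <- data.frame(
    id = c("LAB1", "LAB2", "HUB1", "CAND1", "CAND2", "CAND3"),
    name = c("Lab near", "Lab far", "Hub A", "Cand A", "Cand B1", "Cand B2"),
    kind = c("central_lab", "central_lab", "existing_hub",
             rep("candidate_hub", 3)),
    level = c(NA, NA, 4L, 4L, 3L, 3L),
    sub_county = c("A", "out_of_county", "A", "A", "B", "B"),
    lat = round(c(-0.15, -0.6, lat[1], lat[2], lat[5], lat[6]), 6),
    lon = round(c(34.55, 34.9, lon[1], lon[2], lon[5], lon[6]), 6),
    n_entry_servers = c(1L, 1L, NA, NA, NA, NA),
    entry_service_rate = c(80, 90, NA, NA, NA, NA),
    machine_service_rate = c(100, 110, 12, 12, 12, 12),
    n_machines = c(1L, 1L, 2L, 1L, 1L, 1L),
    kisumu_fraction = c(0.5, 0.25, NA, NA, NA, NA),
    vl_fraction = c(NA, NA, 1, 1, 1, 0.5),
    fixed_open = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE
  )
  dist_km <- geosphere::distHaversine(
    cbind(rep(facilities$lon, nrow(sites)), rep(facilities$lat, nrow(sites))),
    cbind(rep(sites$lon, each = n), rep(sites$lat, each = n))) / 1000
  dist_km <- round(matrix(dist_km, n, nrow(sites),
                          dimnames = list(facilities$id, sites$id)) * 1.3, 4)

  problem_instance(
    facilities = facilities, sites = sites, distance_km = dist_km,
    transport = transport_params("motorbike"),
    batching = batching_policy("twice_weekly"),
    n_added_hubs = 0, fairness = FALSE
  )
}
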