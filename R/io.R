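#' Write a problem instance to a directory of CSV files
#'
#' Writes the three input schemas plus a JSON snapshot of the run-level
#' settings:
#'
#' * `facilities.csv`: `id,name,level,sub_county,lat,lon,
#'   annual_child_volume,annual_adult_volume,current_site_id`
#' * `sites.csv`: `id,name,kind,level,sub_county,lat,lon,n_entry_servers,
#'   entry_service_rate,machine_service_rate,n_machines,kisumu_fraction,
#'   vl_fraction,fixed_open`
#' * `distances.csv`: long format `origin_id,dest_id,km` (complete
#'   facility-by-site), plus a `minutes` column when the instance carries a
#'   travel-time override
#' * `config.json`: transport, batching and planning settings
#'
#' @param instance A [problem_instance()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_instance <- function(instance, dir) {
  stopifnot(inherits(instance, "poc_instance"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fac <- instance$facilities
  fac$daily_demand <- NULL # derived, not part of the schema
  sites <- instance$sites
  sites$background_demand <- NULL # derived from the legacy network
  utils::write.csv(fac, file.path(dir, "facilities.csv"), row.names = FALSE)
  utils::write.csv(sites, file.path(dir, "sites.csv"), row.names = FALSE)

  dm <- instance$distance_km
  long <- data.frame(
    origin_id = rep(rownames(dm), ncol(dm)),
    dest_id = rep(colnames(dm), each = nrow(dm)),
    km = as.vector(dm), stringsAsFactors = FALSE
  )
  if (!is.null(instance$time_min)) {
    long$minutes <- as.vector(instance$time_min)
  }
  utils::write.csv(long, file.path(dir, "distances.csv"), row.names = FALSE)

  cfg <- list(
    transport = unclass(instance$transport),
    batching = list(mode = instance$batching$mode,
                    workday_hours = instance$batching$workday_hours),
    n_added_hubs = instance$n_added_hubs, fairness = instance$fairness,
    utilization_cap = instance$utilization_cap,
    workday_hours = instance$workday_hours,
    workdays_per_month = instance$workdays_per_month
  )
  jsonlite::write_json(cfg, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a problem instance from a directory of CSV files
#'
#' Inverse of [write_instance()]; `read_instance(write_instance(x))`
#' reproduces `x`.
#'
#' @param dir Directory containing `facilities.csv`, `sites.csv`,
#'   `distances.csv` and optionally `config.json`.
#' @return A `poc_instance`.
#' @export
read_instance <- function(dir) {
  paths <- file.path(dir, c("facilities.csv", "sites.csv", "distances.csv"))
  missing_files <- paths[!file.exists(paths)]
  if (length(missing_files)) {
    stop("missing input file(s): ", paste(missing_files, collapse = ", "),
         call. = FALSE)
  }
  fac <- utils::read.csv(paths[1], stringsAsFactors = FALSE,
                         colClasses = c(id = "character",
                                        current_site_id = "character"))
  sites <- utils::read.csv(paths[2], stringsAsFactors = FALSE,
                           colClasses = c(id = "character"))
  long <- utils::read.csv(paths[3], stringsAsFactors = FALSE,
                          colClasses = c(origin_id = "character",
                                         dest_id = "character"))
  for (col in c("origin_id", "dest_id", "km")) {
    if (!col %in% names(long)) {
      stop("distances.csv is missing column: ", col, call. = FALSE)
    }
  }
  fids <- unique(long$origin_id)
  sids <- unique(long$dest_id)
  dm <- matrix(NA_real_, length(fids), length(sids),
               dimnames = list(fids, sids))
  dm[cbind(long$origin_id, long$dest_id)] <- long$km
  tm <- NULL
  if ("minutes" %in% names(long)) {
    tm <- dm
    tm[cbind(long$origin_id, long$dest_id)] <- long$minutes
  }

  cfg_path <- file.path(dir, "config.json")
  if (file.exists(cfg_path)) {
    cfg <- jsonlite::read_json(cfg_path, simplifyVector = TRUE)
    transport <- transport_params(cfg$transport$mode, cfg$transport$speed_kmh,
                                  cfg$transport$road_coeff,
                                  cfg$transport$weather_coeff)
    batching <- batching_policy(cfg$batching$mode, cfg$batching$workday_hours)
    problem_instance(fac, sites, dm, transport = transport,
                     batching = batching, n_added_hubs = cfg$n_added_hubs,
                     fairness = cfg$fairness,
                     utilization_cap = cfg$utilization_cap,
                     workday_hours = cfg$workday_hours,
                     workdays_per_month = cfg$workdays_per_month,
                     time_min = tm)
  } else {
    problem_instance(fac, sites, dm, time_min = tm)
  }
}

#' Write a system report to JSON and CSV
#'
#' `report.json` holds the full report (scenario label, summaries,
#' component shares, per-facility decomposition, per-site metrics);
#' `report.csv` holds the per-facility rows only.
#'
#' @param report A `system_report`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "system_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  payload <- list(
    scenario = report$scenario,
    batching_mode = report$batching_mode,
    transport_mode = report$transport_mode,
    mean_tat_min = report$mean_tat_min,
    sd_tat_min = report$sd_tat_min,
    total_sample_hours = report$total_sample_hours,
    component_shares = as.list(report$component_shares),
    facility_tat = report$facility_tat,
    site_metrics = report$site_metrics,
    network = list(
      open_sites = report$network$open_sites,
      assignment = as.list(report$network$assignment),
      objective_value = report$network$objective_value,
      solver_status = report$network$solver_status,
      n_added = report$network$n_added,
      fairness = report$network$fairness,
      weighted = report$network$weighted
    )
  )
  jsonlite::write_json(payload, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  utils::write.csv(report$facility_tat, file.path(dir, "report.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Read a system report back from `report.json`
#'
#' @param path Path to a `report.json` written by [write_report()].
#' @return A `system_report`.
#' @export
read_report <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  net <- new_referral_network(
    open_sites = p$network$open_sites,
    assignment = unlist(p$network$assignment),
    objective_value = p$network$objective_value,
    solver_status = p$network$solver_status,
    n_added = p$network$n_added, fairness = p$network$fairness,
    weighted = p$network$weighted
  )
  structure(
    list(scenario = p$scenario,
         facility_tat = as.data.frame(p$facility_tat),
         mean_tat_min = p$mean_tat_min, sd_tat_min = p$sd_tat_min,
         total_sample_hours = p$total_sample_hours,
         component_shares = unlist(p$component_shares),
         site_metrics = as.data.frame(p$site_metrics),
         network = net,
         batching_mode = p$batching_mode,
         transport_mode = p$transport_mode),
    class = "system_report"
  )
}

#' Export a referral network as GeoJSON
#'
#' Writes a `FeatureCollection` with one `Point` per site (property `role`:
#' `central_lab`, `existing_hub` or `added_hub`), one `Point` per facility
#' (property `role = "facility"`, `assigned_to` naming its testing site)
#' and one `LineString` per facility-to-site referral link.
#'
#' @param instance A [problem_instance()].
#' @param network A `referral_network`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_network_geojson <- function(instance, network, path) {
  stopifnot(inherits(instance, "poc_instance"),
            inherits(network, "referral_network"))
  sites <- instance$sites
  fac <- instance$facilities
  open <- network$open_sites

  feat <- list()
  for (j in match(open, sites$id)) {
    role <- if (sites$kind[j] == "candidate_hub") "added_hub" else sites$kind[j]
    feat[[length(feat) + 1L]] <- list(
      type = "Feature",
      geometry = list(type = "Point",
                      coordinates = c(sites$lon[j], sites$lat[j])),
      properties = list(id = sites$id[j], name = sites$name[j], role = role)
    )
  }
  for (i in seq_len(nrow(fac))) {
    dest <- network$assignment[[fac$id[i]]]
    feat[[length(feat) + 1L]] <- list(
      type = "Feature",
      geometry = list(type = "Point", coordinates = c(fac$lon[i], fac$lat[i])),
      properties = list(id = fac$id[i], name = fac$name[i],
                        role = "facility", assigned_to = dest)
    )
    jd <- match(dest, sites$id)
    feat[[length(feat) + 1L]] <- list(
      type = "Feature",
      geometry = list(
        type = "LineString",
        coordinates = list(c(fac$lon[i], fac$lat[i]),
                           c(sites$lon[jd], sites$lat[jd]))
      ),
      properties = list(facility_id = fac$id[i], site_id = dest,
                        role = "referral_link")
    )
  }
  jsonlite::write_json(list(type = "FeatureCollection", features = feat),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a sensitivity sweep to CSV
#'
#' Long-format table with one row per (parameter setting, scenario).
#'
#' @param sweep A `sensitivity_result` from [sensitivity_sweep()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sensitivity <- function(sweep, path) {
  stopifnot(inherits(sweep, "sensitivity_result"))
  utils::write.csv(as.data.frame(sweep), path, row.names = FALSE)
  invisible(path)
}
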