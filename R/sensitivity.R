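#' Default one-way sensitivity grid
#'
#' One row per parameter setting to sweep, mirroring the usual planning
#' questions: central-lab operating capacity (x1.25, x1.5), extra machines
#' at existing hubs (+1, +2), extra machines at added hubs (+1, +2),
#' transport mode, road and weather conditions, and batching mode. The
#' baseline (twice-weekly batching, motorbike, average road and weather)
#' is not itself a row; percentage changes are computed against it.
#'
#' @return Data frame with columns `parameter` and `setting`.
#' @export
default_sensitivity_grid <- function() {
  rbind(
    data.frame(parameter = "central_lab_capacity", setting = c("1.25", "1.5")),
    data.frame(parameter = "existing_hub_machines", setting = c("1", "2")),
    data.frame(parameter = "added_hub_machines", setting = c("1", "2")),
    data.frame(parameter = "transport_mode", setting = c("walk", "bike", "car")),
    data.frame(parameter = "road", setting = c("good", "bad")),
    data.frame(parameter = "weather", setting = c("good", "bad")),
    data.frame(parameter = "batching", setting = c("daily", "once_weekly"))
  )
}

condition_coeff <- function(level) {
  switch(level, good = 0.8, average = 1.0, bad = 1.2,
         stop("unknown condition level: ", level, call. = FALSE))
}

# apply one sweep setting to an instance, returning the modified instance
apply_setting <- function(instance, parameter, setting) {
  inst <- instance
  switch(parameter,
    central_lab_capacity = {
      mult <- as.numeric(setting)
      labs <- inst$sites$kind == "central_lab"
      inst$sites$entry_service_rate[labs] <-
        inst$sites$entry_service_rate[labs] * mult
      inst$sites$machine_service_rate[labs] <-
        inst$sites$machine_service_rate[labs] * mult
    },
    existing_hub_machines = {
      k <- as.integer(setting)
      hubs <- inst$sites$kind == "existing_hub"
      inst$sites$n_machines[hubs] <- inst$sites$n_machines[hubs] + k
    },
    added_hub_machines = {
      k <- as.integer(setting)
      cand <- inst$sites$kind == "candidate_hub"
      inst$sites$n_machines[cand] <- inst$sites$n_machines[cand] + k
    },
    transport_mode = {
      inst$transport <- transport_params(
        setting, road_coeff = inst$transport$road_coeff,
        weather_coeff = inst$transport$weather_coeff)
    },
    road = {
      inst$transport$road_coeff <- condition_coeff(setting)
    },
    weather = {
      inst$transport$weather_coeff <- condition_coeff(setting)
    },
    batching = {
      inst$batching <- batching_policy(setting, inst$workday_hours)
    },
    stop("unknown sensitivity parameter: ", parameter, call. = FALSE)
  )
  inst
}

#' One-way sensitivity sweep over scenarios
#'
#' Re-solves and re-evaluates each scenario under each parameter setting of
#' the grid, and reports the mean turnaround time and its percentage change
#' against the stored baseline run of the same scenario (twice-weekly
#' batching, motorbike transport, average road and weather unless the
#' instance says otherwise). Individual run failures are recorded and the
#' sweep continues.
#'
#' @param instance A [problem_instance()].
#' @param grid Data frame with columns `parameter`, `setting`; default
#'   [default_sensitivity_grid()].
#' @param scenarios Integer subset of 1:3 (default all three).
#' @param p_add Added hubs for scenario 3 (default 7).
#' @param fairness Fairness constraint for scenario 3 (default `TRUE`).
#' @return Data frame of class `sensitivity_result` with one row per
#'   (setting, scenario): `parameter`, `setting`, `scenario`,
#'   `mean_tat_min`, `sd_tat_min`, `pct_change` and `error` (NA unless the
#'   run failed).
#' @export
sensitivity_sweep <- function(instance, grid = default_sensitivity_grid(),
                              scenarios = 1:3, p_add = 7, fairness = TRUE) {
  stopifnot(all(c("parameter", "setting") %in% names(grid)))
  baseline <- lapply(scenarios, function(sc) {
    suppressWarnings(run_scenario(instance, sc, p_add = p_add,
                                  fairness = fairness))
  })
  names(baseline) <- as.character(scenarios)

  rows <- list()
  for (r in seq_len(nrow(grid))) {
    parameter <- grid$parameter[r]
    setting <- grid$setting[r]
    inst_r <- apply_setting(instance, parameter, setting)
    for (sc in scenarios) {
      base_mean <- baseline[[as.character(sc)]]$mean_tat_min
      res <- tryCatch(
        suppressWarnings(run_scenario(inst_r, sc, p_add = p_add,
                                      fairness = fairness)),
        error = function(e) e
      )
      rows[[length(rows) + 1L]] <- if (inherits(res, "error")) {
        data.frame(parameter = parameter, setting = setting, scenario = sc,
                   mean_tat_min = NA_real_, sd_tat_min = NA_real_,
                   pct_change = NA_real_, error = conditionMessage(res),
                   stringsAsFactors = FALSE)
      } else {
        data.frame(parameter = parameter, setting = setting, scenario = sc,
                   mean_tat_min = res$mean_tat_min,
                   sd_tat_min = res$sd_tat_min,
                   pct_change = 100 * (res$mean_tat_min - base_mean) / base_mean,
                   error = NA_character_, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "baseline") <- data.frame(
    scenario = scenarios,
    mean_tat_min = vapply(baseline, function(b) b$mean_tat_min, numeric(1)),
    sd_tat_min = vapply(baseline, function(b) b$sd_tat_min, numeric(1))
  )
  class(out) <- c("sensitivity_result", "data.frame")
  out
}
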