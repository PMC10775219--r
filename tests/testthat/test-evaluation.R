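test_that("turnaround decomposition is exactly additive", {
  inst <- make_fixture_small(seed = 2)
  rep1 <- suppressWarnings(run_scenario(inst, 1))
  tat <- rep1$facility_tat
  expect_equal(tat$total_min,
               tat$batching_min + tat$transport_min + tat$waiting_min,
               tolerance = 1e-12)
  expect_true(all(tat[, c("batching_min", "transport_min", "waiting_min")] >= 0))
  expect_equal(sum(rep1$component_shares), 1, tolerance = 1e-9)
  expect_equal(rep1$mean_tat_min, mean(tat$total_min))
  expect_equal(rep1$sd_tat_min, sd(tat$total_min))
  d <- inst$facilities$daily_demand
  expect_equal(rep1$total_sample_hours, sum(d * tat$total_min) / 60)
})

test_that("single-facility composition matches hand arithmetic", {
  # one clinic, one empty lab: total = B + t + service-only wait
  fac <- data.frame(id = "F1", name = "F1", level = 3L, sub_county = "A",
                    lat = 0, lon = 34, annual_child_volume = 0,
                    annual_adult_volume = 240, current_site_id = "LAB",
                    stringsAsFactors = FALSE)
  sites <- data.frame(
    id = "LAB", name = "Lab", kind = "central_lab", level = NA_integer_,
    sub_county = "A", lat = 0, lon = 34.5, n_entry_servers = 2L,
    entry_service_rate = 710, machine_service_rate = 1500, n_machines = 1L,
    kisumu_fraction = 1, vl_fraction = NA_real_, fixed_open = TRUE,
    stringsAsFactors = FALSE)
  dm <- matrix(40, 1, 1, dimnames = list("F1", "LAB"))
  inst <- problem_instance(fac, sites, dm,
                           transport = transport_params("motorbike"),
                           batching = batching_policy("daily"))
  rep <- evaluate_network(inst, existing_network(inst))
  d <- inst$facilities$daily_demand # 1.08 samples/day
  lam <- d + 0 # kisumu_fraction 1: no background
  w_min <- central_lab_wait(sites, lam) * 7 * 60
  expect_equal(rep$facility_tat$total_min, 210 + 60 + w_min)
  expect_equal(rep$total_sample_hours, d * (210 + 60 + w_min) / 60)
})

test_that("zero-demand facilities enter the mean but not the totals", {
  inst <- line_instance(n_fac = 6, seed = 3)
  inst$facilities$annual_child_volume[1] <- 0
  inst$facilities$annual_adult_volume[1] <- 0
  inst <- problem_instance(inst$facilities,
                           subset(inst$sites, select = -background_demand),
                           inst$distance_km, inst$transport, inst$batching)
  rep <- suppressWarnings(evaluate_network(inst, existing_network(inst)))
  expect_equal(nrow(rep$facility_tat), 6)
  d <- inst$facilities$daily_demand
  expect_equal(rep$total_sample_hours,
               sum(d * rep$facility_tat$total_min) / 60)
  expect_equal(rep$mean_tat_min, mean(rep$facility_tat$total_min))
})

test_that("changing one lever moves only its own TAT component", {
  inst <- make_fixture_small(seed = 4)
  net <- solve_allocation(inst, n_added = 1)
  base <- evaluate_network(inst, net)

  inst_b <- inst
  inst_b$batching <- batching_policy("daily")
  rep_b <- evaluate_network(inst_b, net)
  expect_equal(rep_b$facility_tat$transport_min, base$facility_tat$transport_min)
  expect_equal(rep_b$facility_tat$waiting_min, base$facility_tat$waiting_min)
  expect_true(all(rep_b$facility_tat$batching_min <
                    base$facility_tat$batching_min))

  inst_t <- inst
  inst_t$transport <- transport_params("car")
  rep_t <- evaluate_network(inst_t, net)
  expect_equal(rep_t$facility_tat$batching_min, base$facility_tat$batching_min)
  expect_equal(rep_t$facility_tat$waiting_min, base$facility_tat$waiting_min)
  expect_true(all(rep_t$facility_tat$transport_min <=
                    base$facility_tat$transport_min))
})

test_that("faster service weakly reduces waiting for a fixed assignment", {
  inst <- make_fixture_small(seed = 6)
  net <- solve_allocation(inst, n_added = 2)
  base <- evaluate_network(inst, net)
  inst2 <- inst
  inst2$sites$machine_service_rate <- inst2$sites$machine_service_rate * 1.5
  inst2$sites$entry_service_rate <- inst2$sites$entry_service_rate * 1.5
  faster <- evaluate_network(inst2, net)
  expect_true(all(faster$facility_tat$waiting_min <=
                    base$facility_tat$waiting_min + 1e-12))
})

test_that("scenario runner composes solver and evaluation correctly", {
  inst <- make_fixture_small(seed = 1)
  r2 <- run_scenario(inst, 2)
  r3zero <- run_scenario(inst, 3, p_add = 0)
  expect_equal(r2$facility_tat, r3zero$facility_tat) # p_add = 0 is scenario 2
  expect_error(run_scenario(inst, 3, p_add = 11), "between 0 and 7")
  expect_error(run_scenario(inst, 4), "scenario")
  # assignment to a closed site is rejected at evaluation
  net <- existing_network(inst)
  net$assignment[1] <- "CAND1"
  expect_error(evaluate_network(inst, net), "closed site")
})

test_that("sensitivity sweep reports percent changes against the baseline", {
  inst <- make_fixture_small(seed = 1)
  grid <- data.frame(parameter = c("batching", "batching", "road"),
                     setting = c("daily", "once_weekly", "bad"))
  sw <- sensitivity_sweep(inst, grid, scenarios = c(1, 2), p_add = 0,
                          fairness = FALSE)
  expect_s3_class(sw, "sensitivity_result")
  expect_equal(nrow(sw), 6)
  base <- attr(sw, "baseline")
  for (r in seq_len(nrow(sw))) {
    b <- base$mean_tat_min[base$scenario == sw$scenario[r]]
    expect_equal(sw$pct_change[r], 100 * (sw$mean_tat_min[r] - b) / b)
  }
  # directionality: daily shortens, once-weekly lengthens, bad roads lengthen
  expect_true(all(sw$pct_change[sw$setting == "daily"] < 0))
  expect_true(all(sw$pct_change[sw$setting == "once_weekly"] > 0))
  expect_true(all(sw$pct_change[sw$setting == "bad"] > 0))
  # failures are recorded without aborting the sweep
  bad_grid <- data.frame(parameter = "central_lab_capacity", setting = "0.01")
  sw2 <- sensitivity_sweep(inst, bad_grid, scenarios = 1, p_add = 0)
  expect_false(is.na(sw2$error[1]))
  expect_true(is.na(sw2$mean_tat_min[1]))
})
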