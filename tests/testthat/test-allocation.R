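test_that("hub candidacy respects facility-level eligibility", {
  inst <- line_instance()
  sites <- inst$sites
  expect_setequal(eligible_candidates(sites), c("CANDP", "CANDQ", "CANDR"))
  sites$level[sites$id == "CANDP"] <- 2L
  expect_setequal(eligible_candidates(sites), c("CANDQ", "CANDR"))
  expect_setequal(eligible_candidates(sites, eligible_levels = 4:5), c("CANDQ", "CANDR"))
  sites$level[sites$kind == "candidate_hub"] <- NA_integer_
  expect_error(eligible_candidates(sites), "level")
  expect_length(eligible_candidates(sites[sites$kind == "central_lab", ]), 0)
})

test_that("site capacity applies the utilization cap and background load", {
  hub <- data.frame(kind = "existing_hub", machine_service_rate = 12,
                    n_machines = 2, vl_fraction = 1)
  expect_equal(site_capacity(hub, 0.9), 21.6)
  hub$n_machines <- 1
  hub$vl_fraction <- 0.5
  expect_equal(site_capacity(hub, 0.9), 5.4)
  lab <- data.frame(id = "L", kind = "central_lab", n_entry_servers = 2,
                    entry_service_rate = 710, machine_service_rate = 1500,
                    n_machines = 1, background_demand = 1000)
  expect_equal(site_capacity(lab, 0.9), 0.9 * min(1420, 1500) - 1000)
  lab$background_demand <- 1400
  expect_error(site_capacity(lab, 0.9), "no net capacity")
})

test_that("the existing network evaluates the legacy assignment as-is", {
  inst <- make_fixture_small(seed = 5)
  net <- existing_network(inst)
  expect_setequal(net$open_sites,
                  inst$sites$id[inst$sites$kind == "central_lab"])
  expect_identical(unname(net$assignment[inst$facilities$id]),
                   inst$facilities$current_site_id)
  expect_identical(net$solver_status, "existing")
  # objective is the demand-weighted batching + transport total
  tmat <- pocnet:::transport_minutes(inst)
  b <- inst$batching$expected_delay_min
  manual <- sum(inst$facilities$daily_demand *
                  (b + tmat[cbind(inst$facilities$id,
                                  inst$facilities$current_site_id)]))
  expect_equal(net$objective_value, manual)

  # overloading the legacy lab warns but does not error
  inst2 <- make_fixture_small(seed = 5)
  inst2$facilities$annual_adult_volume <- inst2$facilities$annual_adult_volume * 2.4
  inst2 <- problem_instance(inst2$facilities, subset(inst2$sites, select = -background_demand),
                            inst2$distance_km, inst2$transport, inst2$batching)
  expect_warning(existing_network(inst2), "exceeds the capacity cap")
})

test_that("solver matches exhaustive enumeration on seeded small instances", {
  for (seed in 1:8) {
    inst <- line_instance(n_fac = 6, seed = seed)
    for (p in c(0, 1, 2)) {
      a <- solve_allocation(inst, n_added = p)
      b <- bruteforce_allocation(inst, n_added = p)
      expect_equal(a$objective_value, b$objective_value,
                   info = sprintf("seed=%d p=%d", seed, p))
      expect_setequal(a$open_sites, b$open_sites)
    }
  }
})

test_that("solver and oracle agree under fairness and on the bundled fixture", {
  for (seed in c(2, 9)) {
    inst <- make_fixture_small(seed = seed)
    for (p in 0:3) {
      a <- solve_allocation(inst, n_added = p)
      b <- bruteforce_allocation(inst, n_added = p)
      expect_equal(a$objective_value, b$objective_value,
                   info = sprintf("fixture seed=%d p=%d", seed, p))
    }
    af <- solve_allocation(inst, n_added = 2, fairness = TRUE)
    bf <- bruteforce_allocation(inst, n_added = 2, fairness = TRUE)
    expect_equal(af$objective_value, bf$objective_value)
    expect_gte(af$objective_value,
               solve_allocation(inst, n_added = 2)$objective_value - 1e-9)
  }
})

test_that("returned networks satisfy the structural feasibility contract", {
  inst <- line_instance(n_fac = 8, seed = 11)
  net <- solve_allocation(inst, n_added = 2, fairness = TRUE)
  fac <- inst$facilities
  # completeness: every facility exactly once
  expect_setequal(names(net$assignment), fac$id)
  # open-site consistency and exact added-hub count
  expect_true(all(net$assignment %in% net$open_sites))
  expect_true(all(inst$sites$id[inst$sites$fixed_open] %in% net$open_sites))
  cand_open <- intersect(net$open_sites,
                         inst$sites$id[inst$sites$kind == "candidate_hub"])
  expect_length(cand_open, 2)
  # capacity respected under the cap
  caps <- sapply(seq_len(nrow(inst$sites)),
                 function(j) site_capacity(inst$sites[j, ], 0.9))
  names(caps) <- inst$sites$id
  load <- tapply(fac$daily_demand, net$assignment[fac$id], sum)
  expect_true(all(load <= caps[names(load)] + 1e-6))
})

test_that("with slack capacity every facility goes to its nearest open site", {
  inst <- line_instance(n_fac = 6, seed = 4, hub_machines = 50,
                        cand_machines = 50, lab_entry_rate = 5000)
  net <- solve_allocation(inst, n_added = 0)
  tmat <- pocnet:::transport_minutes(inst)[, net$open_sites]
  nearest <- colnames(tmat)[apply(tmat, 1, which.min)]
  expect_identical(unname(net$assignment[rownames(tmat)]), nearest)
})

test_that("infeasibility and fairness relaxation are reported", {
  inst <- line_instance(n_fac = 6, seed = 6)
  expect_error(solve_allocation(inst, n_added = 5), "eligible candidates")
  # no candidate in a sub-county with facilities: fairness is relaxed
  inst2 <- line_instance(n_fac = 6, seed = 6)
  inst2$sites$sub_county[inst2$sites$kind == "candidate_hub"] <- "east"
  inst2$sites$sub_county[inst2$sites$kind == "existing_hub"] <- "east"
  expect_warning(net <- solve_allocation(inst2, n_added = 1, fairness = TRUE),
                 "relaxed")
  expect_identical(net$solver_status, "relaxed_fairness")
  # demand beyond all capped capacity is a structured infeasibility
  inst3 <- line_instance(n_fac = 6, seed = 6)
  inst3$facilities$annual_adult_volume <- inst3$facilities$annual_adult_volume * 2000
  inst3 <- problem_instance(inst3$facilities,
                            subset(inst3$sites, select = -background_demand),
                            inst3$distance_km, inst3$transport, inst3$batching)
  expect_error(suppressWarnings(solve_allocation(inst3, n_added = 0)),
               "capacity")
})

test_that("unweighted mode counts facilities instead of samples", {
  inst <- line_instance(n_fac = 6, seed = 12)
  nw <- solve_allocation(inst, n_added = 1, weighted = FALSE)
  bw <- bruteforce_allocation(inst, n_added = 1, weighted = FALSE)
  expect_equal(nw$objective_value, bw$objective_value)
  # objective now has units of facility-minutes: batching contributes
  # B * n_facilities
  b <- inst$batching$expected_delay_min
  expect_gte(nw$objective_value, b * nrow(inst$facilities))
})
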