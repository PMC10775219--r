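test_that("annual demand follows the weighted client-volume formula", {
  expect_identical(estimate_annual_demand(0, 0), 0)
  expect_equal(estimate_annual_demand(100, 1000), 1280)
  expect_equal(estimate_annual_demand(50, 0), 100)
  # linearity: doubling both volumes doubles demand
  for (case in list(c(3, 17), c(120, 960), c(0, 5))) {
    expect_equal(estimate_annual_demand(2 * case[1], 2 * case[2]),
                 2 * estimate_annual_demand(case[1], case[2]))
  }
  expect_error(estimate_annual_demand(-1, 10), "non-negative")
})

test_that("daily demand divides annual demand over working days", {
  expect_equal(estimate_daily_demand(2400, 20), 10)
  expect_equal(estimate_daily_demand(0, 20), 0)
  expect_equal(estimate_daily_demand(1280, 20), 1280 / 240)
  expect_error(estimate_daily_demand(100, 0), "positive")
  expect_error(estimate_daily_demand(-5), "non-negative")
})

test_that("batching delays reproduce the dispatch-frequency accounting", {
  expect_equal(expected_batching_delay("daily"), 210)
  expect_equal(expected_batching_delay("twice_weekly"), 1860)
  expect_equal(expected_batching_delay("once_weekly"), 3090)
  # strictly increasing as dispatch gets rarer
  delays <- vapply(c("daily", "twice_weekly", "once_weekly"),
                   expected_batching_delay, numeric(1))
  expect_true(all(diff(delays) > 0))
  # the general working-day form recovers other day lengths consistently
  expect_equal(expected_batching_delay("daily", workday_hours = 8), 240)
  expect_equal(expected_batching_delay("twice_weekly", workday_hours = 8),
               (24 + 8) * 60)
  expect_error(expected_batching_delay("hourly"), "unknown batching mode")
})

test_that("transport time is linear in distance and multiplicative in conditions", {
  expect_equal(transport_time(40, transport_params("motorbike")), 60)
  expect_equal(transport_time(0, transport_params("walk")), 0)
  expect_equal(
    transport_time(10, transport_params("walk", road_coeff = 1.2,
                                        weather_coeff = 1.2)),
    172.8)
  base <- transport_params("bike")
  good_road <- transport_params("bike", road_coeff = 0.8)
  for (km in c(1, 7.5, 60)) {
    expect_equal(transport_time(2 * km, base), 2 * transport_time(km, base))
    expect_equal(transport_time(km, good_road), 0.8 * transport_time(km, base))
  }
  expect_error(transport_time(-1, base), "non-negative")
  expect_error(transport_params("rocket"), "unknown transport mode")
})

test_that("problem_instance validates structure and derives demand", {
  inst <- make_fixture_small(seed = 3)
  fac <- inst$facilities
  expect_equal(
    fac$daily_demand,
    estimate_daily_demand(
      estimate_annual_demand(fac$annual_child_volume, fac$annual_adult_volume),
      inst$workdays_per_month))

  # background demand at each lab matches the share-based derivation
  labs <- inst$sites[inst$sites$kind == "central_lab", ]
  for (j in seq_len(nrow(labs))) {
    assigned <- sum(fac$daily_demand[fac$current_site_id == labs$id[j]])
    expect_equal(labs$background_demand[j],
                 background_rate(labs$kisumu_fraction[j], assigned))
  }

  bad <- fac
  bad$level[1] <- 9
  expect_error(problem_instance(bad, inst$sites, inst$distance_km),
               "levels")
  bad <- fac
  bad$current_site_id[2] <- "NOWHERE"
  expect_error(problem_instance(bad, inst$sites, inst$distance_km),
               "unknown central lab")
  expect_error(problem_instance(fac[, -3], inst$sites, inst$distance_km),
               "missing column")
})
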