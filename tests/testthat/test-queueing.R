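test_that("Erlang-C matches the direct-sum formula across a wide grid", {
  grid <- expand.grid(s = c(1, 2, 3, 5, 10, 25, 50),
                      rho = c(0.1, 0.5, 0.8, 0.95, 0.99),
                      mu = c(0.5, 4, 710))
  for (r in seq_len(nrow(grid))) {
    s <- grid$s[r]
    mu <- grid$mu[r]
    lambda <- grid$rho[r] * s * mu
    expect_equal(erlang_c(lambda, mu, s),
                 erlang_c_direct(lambda, mu, s),
                 tolerance = 1e-12,
                 info = sprintf("s=%d rho=%g mu=%g", s, grid$rho[r], mu))
  }
})

test_that("single-server metrics recover the M/M/1 closed forms", {
  m <- mms_metrics(1, 2, 1)
  expect_equal(m$p_wait, 0.5) # for s = 1, p_wait equals rho
  expect_equal(m$Wq, 0.5)     # rho / (mu - lambda)
  expect_equal(m$W, 1)        # 1 / (mu - lambda)
  for (lambda in c(0.3, 2, 7)) {
    mu <- 8
    m <- mms_metrics(lambda, mu, 1)
    expect_equal(m$Wq, lambda / mu / (mu - lambda))
    expect_equal(m$W, 1 / (mu - lambda))
  }
})

test_that("empty and unstable queues are handled as specified", {
  expect_equal(erlang_c(0, 5, 3), 0)
  m0 <- mms_metrics(0, 4, 2)
  expect_equal(m0$Wq, 0)
  expect_equal(m0$W, 1 / 4)
  expect_error(erlang_c(10, 2, 1), "unstable")
  mu <- mms_metrics(10, 2, 1)
  expect_false(mu$stable)
  expect_identical(mu$Wq, Inf)
  expect_error(mms_metrics(-1, 2, 1), "invalid queue spec")
})

test_that("queue waits move monotonically with load, servers and speed", {
  base <- mms_metrics(10, 4, 3)$Wq
  expect_gt(mms_metrics(11, 4, 3)$Wq, base)   # more arrivals wait longer
  expect_lt(mms_metrics(10, 4, 4)$Wq, base)   # more servers wait less
  expect_lt(mms_metrics(10, 5, 3)$Wq, base)   # faster service waits less
  # across a sweep of utilizations Wq increases in lambda
  wqs <- vapply(seq(1, 11, by = 0.5), function(l) mms_metrics(l, 4, 3)$Wq,
                numeric(1))
  expect_true(all(diff(wqs) > 0))
})

test_that("two-stage central-lab wait is the sum of the stage times", {
  site <- data.frame(id = "L", kind = "central_lab", n_entry_servers = 2,
                     entry_service_rate = 710, machine_service_rate = 1500,
                     n_machines = 1, stringsAsFactors = FALSE)
  # empty lab: pure service times
  expect_equal(central_lab_wait(site, 0), 1 / 710 + 1 / 1500)
  # loaded lab: independent two-queue evaluation
  lam <- 600
  expect_equal(central_lab_wait(site, lam),
               (wq_direct(lam, 710, 2) + 1 / 710) +
                 (wq_direct(lam, 1500, 1) + 1 / 1500))
  # pooled-rate reading divides the entry rate across servers
  expect_equal(central_lab_wait(site, 100, entry_rate_is_pooled = TRUE),
               (wq_direct(100, 355, 2) + 1 / 355) +
                 (wq_direct(100, 1500, 1) + 1 / 1500))
  expect_error(central_lab_wait(site, 2 * 710), "entry stage")
  expect_error(central_lab_wait(site, 1499, entry_rate_is_pooled = TRUE),
               "entry stage")
})

test_that("hub wait is M/M/s on the viral-load-dedicated capacity", {
  hub1 <- data.frame(id = "H", kind = "existing_hub", machine_service_rate = 12,
                     n_machines = 1, vl_fraction = 1, stringsAsFactors = FALSE)
  expect_equal(poc_hub_wait(hub1, 6), 1 / (12 - 6)) # M/M/1 closed form
  expect_equal(poc_hub_wait(hub1, 0), 1 / 12)
  hub2 <- hub1
  hub2$n_machines <- 2
  hub2$vl_fraction <- 0.5
  expect_equal(poc_hub_wait(hub2, 10),
               wq_direct(10, 6, 2) + 1 / 6)
  # a fully dedicated hub equals plain M/M/s metrics
  hub3 <- hub1
  hub3$n_machines <- 3
  expect_equal(poc_hub_wait(hub3, 20), mms_metrics(20, 12, 3)$W)
  expect_error(poc_hub_wait(hub1, 12), "unstable hub")
})

test_that("background rate scales in-county demand by the external share", {
  expect_equal(background_rate(1, 40), 0)
  expect_equal(background_rate(0.24, 24), 76)
  expect_equal(background_rate(0.05, 5), 95)
  # consistency: in-county share of the total is f again
  for (f in c(0.24, 0.13, 0.05)) {
    assigned <- 37
    total <- assigned + background_rate(f, assigned)
    expect_equal(assigned / total, f)
  }
  expect_error(background_rate(0, 10), "in-county fraction")
  expect_error(background_rate(1.2, 10), "in-county fraction")
})
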