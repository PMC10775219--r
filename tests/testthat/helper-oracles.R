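# Independent oracles, deliberately coded apart from the package internals.

# Erlang-C by the textbook finite sum (log-scale terms for stability)
erlang_c_direct <- function(lambda, mu, s) {
  a <- lambda / mu
  rho <- lambda / (s * mu)
  stopifnot(rho < 1)
  if (lambda == 0) return(0)
  log_terms <- (0:(s - 1)) * log(a) - lgamma(1:s)
  sum_terms <- sum(exp(log_terms))
  term_s <- exp(s * log(a) - lgamma(s + 1)) / (1 - rho)
  term_s / (sum_terms + term_s)
}

# Expected M/M/s queue wait via the direct formula
wq_direct <- function(lambda, mu, s) {
  if (lambda == 0) return(0)
  erlang_c_direct(lambda, mu, s) / (s * mu - lambda)
}

# a tiny instance built by hand for allocation tests: n facilities on a
# line, sites at fixed points, controllable capacities
line_instance <- function(n_fac = 6, seed = 1, batching = "twice_weekly",
                          hub_machines = 1, cand_machines = 1,
                          lab_entry_rate = 40, misc_vl = 1) {
  set.seed(seed)
  fac_ids <- sprintf("F%d", seq_len(n_fac))
  lon <- sort(round(stats::runif(n_fac, 34.0, 34.6), 6))
  lat <- rep(0, n_fac)
  d <- round(stats::runif(n_fac, 0.5, 5), 2)
  adult <- round(d * 240 / 1.28, 2)
  facilities <- data.frame(
    id = fac_ids, name = fac_ids, level = rep(c(3L, 2L), length.out = n_fac),
    sub_county = rep(c("east", "west"), length.out = n_fac),
    lat = lat, lon = lon,
    annual_child_volume = round(0.2 * adult, 2), annual_adult_volume = adult,
    current_site_id = "LABA", stringsAsFactors = FALSE
  )
  sites <- data.frame(
    id = c("LABA", "LABB", "HUBX", "CANDP", "CANDQ", "CANDR"),
    name = c("Lab A", "Lab B", "Hub X", "Cand P", "Cand Q", "Cand R"),
    kind = c("central_lab", "central_lab", "existing_hub",
             rep("candidate_hub", 3)),
    level = c(NA, NA, 4L, 3L, 4L, 5L),
    sub_county = c("east", "out", "west", "east", "west", "east"),
    lat = rep(0, 6),
    lon = c(34.1, 34.9, 34.3, 34.2, 34.5, 34.55),
    n_entry_servers = c(2L, 2L, NA, NA, NA, NA),
    entry_service_rate = c(lab_entry_rate, lab_entry_rate, NA, NA, NA, NA),
    machine_service_rate = c(60, 60, 12, 12, 12, 12),
    n_machines = c(1L, 1L, hub_machines, cand_machines, cand_machines,
                   cand_machines),
    kisumu_fraction = c(0.5, 0.3, NA, NA, NA, NA),
    vl_fraction = c(NA, NA, misc_vl, 1, 1, 1),
    fixed_open = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE
  )
  dm <- outer(lon, sites$lon, function(a, b) round(abs(a - b) * 111, 4))
  dimnames(dm) <- list(fac_ids, sites$id)
  problem_instance(facilities, sites, dm,
                   transport = transport_params("motorbike"),
                   batching = batching_policy(batching))
}

# the shared full-size synthetic county used by the slower checks
default_synthetic <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_instance(generator_config(seed = 1))
    cache
  }
})

`%||%` <- function(a, b) if (is.null(a)) b else a
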