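#' Candidate hubs eligible to host a point-of-care machine
#'
#' Clinics below level 3 of the national facility classification lack the
#' infrastructure (power, laboratory space, trained staff) to host a
#' point-of-care machine, so only candidate sites at levels 3-5 are
#' eligible. Sites that are already open (`fixed_open`) pass unconditionally.
#'
#' @param sites An instance's `sites` table.
#' @param eligible_levels Integer set of admissible levels (default 3:5).
#' @return Character vector of eligible candidate-hub site ids.
#' @export
eligible_candidates <- function(sites, eligible_levels = 3:5) {
  cand <- sites[sites$kind == "candidate_hub", , drop = FALSE]
  if (nrow(cand) == 0) return(character(0))
  if (anyNA(cand$level)) {
    stop("candidate hubs must carry a facility level", call. = FALSE)
  }
  cand$id[cand$level %in% eligible_levels]
}

#' Planning capacity of a testing site
#'
#' The daily in-county demand a site may be assigned under the utilization
#' cap. For a hub: `n_machines * machine_service_rate * vl_fraction * cap`.
#' For a central lab the binding stage applies and the constant
#' out-of-county background is deducted:
#' `cap * min(n_entry_servers * entry_service_rate, machine_service_rate) -
#' background_demand`. A lab whose background alone exceeds its capped
#' capacity has no room for in-county samples and is rejected.
#'
#' @param site One row of an instance's `sites` table.
#' @param utilization_cap Planned utilization ceiling (default 0.9).
#' @return Assignable samples per working day.
#' @export
site_capacity <- function(site, utilization_cap = 0.9) {
  if (site$kind == "central_lab") {
    stage_cap <- min(site$n_entry_servers * site$entry_service_rate,
                     site$machine_service_rate)
    cap <- utilization_cap * stage_cap - site$background_demand
    if (cap <= 0) {
      stop(sprintf(
        "central lab %s has no net capacity: background %.1f/day exceeds %.1f/day",
        site$id, site$background_demand, utilization_cap * stage_cap),
        call. = FALSE)
    }
    cap
  } else {
    site$n_machines * site$machine_service_rate * site$vl_fraction *
      utilization_cap
  }
}

site_capacities <- function(sites, utilization_cap) {
  vapply(seq_len(nrow(sites)),
         function(j) site_capacity(sites[j, ], utilization_cap), numeric(1))
}

#' The existing (unoptimized) referral network
#'
#' Scenario 1: every clinic keeps sending samples to its current central
#' lab; only the central labs are open and no optimization is performed.
#' Capacity-cap violations by the existing assignment are reported with a
#' warning, not an error, since the legacy network may well exceed the
#' planning cap.
#'
#' @param instance A [problem_instance()].
#' @return A `referral_network` object.
#' @export
existing_network <- function(instance) {
  stopifnot(inherits(instance, "poc_instance"))
  fac <- instance$facilities
  sites <- instance$sites
  labs <- sites$id[sites$kind == "central_lab"]
  assignment <- stats::setNames(fac$current_site_id, fac$id)

  caps <- stats::setNames(site_capacities(sites, instance$utilization_cap),
                          sites$id)
  load <- tapply(fac$daily_demand, factor(fac$current_site_id, labs), sum,
                 default = 0)
  over <- names(load)[load > caps[names(load)] + 1e-9]
  if (length(over)) {
    warning("existing assignment exceeds the capacity cap at: ",
            paste(over, collapse = ", "), call. = FALSE)
  }

  tmat <- transport_minutes(instance)
  b <- instance$batching$expected_delay_min
  obj <- sum(fac$daily_demand *
               (b + tmat[cbind(fac$id, fac$current_site_id)]))
  new_referral_network(
    open_sites = labs, assignment = assignment, objective_value = obj,
    solver_status = "existing", n_added = 0, fairness = FALSE,
    weighted = TRUE
  )
}

#' Optimize hub selection and the referral network
#'
#' Solves the binary program at the heart of the planning tool: choose
#' exactly `n_added` new hubs among the eligible candidates (all central
#' labs and existing hubs stay open) and assign every clinic to exactly one
#' open site, minimizing the demand-weighted batching-plus-transport time
#' \deqn{\sum_i d_i (B + t_{ij}) x_{ij}}
#' subject to assignment completeness, site capacity under the utilization
#' cap, the exact count of added hubs, and (optionally) the fairness
#' requirement that every sub-county retain at least one open hub. Queue
#' waiting time is deliberately excluded from the objective (it would make
#' the program nonlinear); it is added afterwards by [evaluate_network()].
#'
#' The solver enumerates candidate subsets, pruning most of them with a
#' Lagrangian bound priced by transportation-LP duals, and solves each
#' surviving capacitated-assignment subproblem by branch-and-bound (exact
#' min-cost-flow relaxation at the root, subgradient-refined Lagrangian
#' bounds in the tree). Every run returns a certified optimality gap; a
#' run whose node budget stops the proof is labelled `near_optimal` and
#' reports how far from proven-optimal it can possibly be.
#'
#' @param instance A [problem_instance()].
#' @param n_added Number of candidate hubs to open (default from instance).
#' @param fairness Require at least one open hub per sub-county? A
#'   sub-county in which no hub can possibly be opened is relaxed with a
#'   warning and `solver_status = "relaxed_fairness"`.
#' @param utilization_cap Planned utilization ceiling.
#' @param eligible_levels Candidate eligibility levels (default 3:5).
#' @param weighted If `TRUE` (default) each facility's time is weighted by
#'   its daily demand; if `FALSE` all facilities weigh equally.
#' @param labs_only Restrict open sites to the central labs (an optimized
#'   labs-only variant of scenario 1); requires `n_added = 0`.
#' @param node_limit Branch-and-bound node budget per candidate subset
#'   (the winning subset gets ten times this for certification). Negative
#'   means unlimited. When a budget stops a proof, the returned network
#'   carries `solver_status = "near_optimal"` together with the certified
#'   lower bound (`objective_bound`) and relative `gap`.
#' @return A `referral_network` object; `objective_bound` and `gap` report
#'   the optimality certificate.
#' @export
solve_allocation <- function(instance, n_added = instance$n_added_hubs,
                             fairness = instance$fairness,
                             utilization_cap = instance$utilization_cap,
                             eligible_levels = 3:5, weighted = TRUE,
                             labs_only = FALSE, node_limit = 1000) {
  stopifnot(inherits(instance, "poc_instance"))
  fac <- instance$facilities
  sites <- instance$sites
  if (labs_only && n_added > 0) {
    stop("labs_only networks cannot add hubs", call. = FALSE)
  }

  fixed_ids <- sites$id[sites$fixed_open]
  if (labs_only) fixed_ids <- sites$id[sites$kind == "central_lab"]
  cand_ids <- if (labs_only) character(0) else {
    sort(eligible_candidates(sites, eligible_levels))
  }
  if (n_added > length(cand_ids)) {
    stop(sprintf("infeasible: %d hubs requested but only %d eligible candidates",
                 n_added, length(cand_ids)), call. = FALSE)
  }

  # fairness bookkeeping: sub-counties that still need a hub, and whether
  # any candidate could provide one
  status <- "optimal"
  need_cover <- character(0)
  if (fairness) {
    sc_all <- unique(fac$sub_county)
    hub_sc <- sites$sub_county[sites$kind == "existing_hub" & sites$fixed_open]
    if (labs_only) hub_sc <- character(0)
    uncovered <- setdiff(sc_all, hub_sc)
    cand_sc <- stats::setNames(sites$sub_county[match(cand_ids, sites$id)],
                               cand_ids)
    coverable <- intersect(uncovered, unique(cand_sc))
    relaxed <- setdiff(uncovered, coverable)
    if (length(coverable) > n_added) {
      stop(sprintf(
        "infeasible fairness constraint: %d uncovered sub-counties but only %d hubs to add",
        length(coverable), n_added), call. = FALSE)
    }
    if (length(relaxed)) {
      warning("fairness relaxed for sub-counties without an eligible site: ",
              paste(relaxed, collapse = ", "), call. = FALSE)
      status <- "relaxed_fairness"
    }
    need_cover <- coverable
  }

  caps <- stats::setNames(site_capacities(sites, utilization_cap), sites$id)
  tmat <- transport_minutes(instance)
  b <- instance$batching$expected_delay_min
  d <- stats::setNames(fac$daily_demand, fac$id)
  w <- if (weighted) d else rep(1, length(d))
  names(w) <- fac$id

  # subsets of candidates to enumerate
  subsets <- if (n_added == 0) list(character(0)) else {
    cs <- utils::combn(cand_ids, n_added, simplify = FALSE)
    if (length(need_cover)) {
      cand_sc <- sites$sub_county[match(cand_ids, sites$id)]
      names(cand_sc) <- cand_ids
      cs <- Filter(function(s) all(need_cover %in% cand_sc[s]), cs)
      if (!length(cs)) {
        stop("infeasible fairness constraint: no candidate subset covers all sub-counties",
             call. = FALSE)
      }
    }
    cs
  }

  # Lagrangian subset bounds: price every site with the dual values of the
  # all-candidates-open transportation relaxation; for any subset S,
  #   sum_i d_i min_{j in S} (c_ij/d_i + v_j) - sum_{j in S} v_j cap_j
  # is a valid lower bound on its assignment cost, so most subsets are
  # pruned before their branch-and-bound ever runs
  all_open <- c(fixed_ids, if (n_added > 0) cand_ids)
  cost_all <- tmat[, all_open, drop = FALSE] * w
  d_pos <- pmax(d, .Machine$double.eps)
  lp_all <- lp_bound_cpp(cost_all, unname(d), unname(caps[all_open]))
  if (!isTRUE(lp_all$feasible)) {
    stop("infeasible: total site capacity cannot absorb the assigned demand",
         call. = FALSE)
  }
  duals <- stats::setNames(lp_all$duals, all_open)
  priced <- sweep(cost_all / d_pos, 2, duals[all_open], "+")
  capable <- outer(unname(d), unname(caps[all_open]), "<=")
  priced[!capable] <- Inf

  lbs <- vapply(subsets, function(s) {
    open <- c(fixed_ids, s)
    sum(d * apply(priced[, open, drop = FALSE], 1, min)) -
      sum(duals[open] * caps[open])
  }, numeric(1))
  ord <- order(lbs)

  cert_lb <- lbs # per-subset certified lower bound, sharpened when solved
  best <- list(obj = Inf, assignment = NULL, open = NULL, proven = TRUE)
  for (k in ord) {
    if (!is.null(best$assignment) && lbs[k] >= best$obj - 1e-9) break
    open <- c(fixed_ids, subsets[[k]])
    sol <- solve_assignment(tmat[, open, drop = FALSE], d, w, caps[open],
                            upper = best$obj, node_limit = node_limit,
                            v0 = duals[open])
    if (is.finite(sol$lb)) cert_lb[k] <- max(cert_lb[k], sol$lb)
    if (sol$feasible && sol$obj < best$obj - 1e-9) {
      best <- list(obj = sol$obj, assignment = sol$assignment,
                   open = sort(open), proven = sol$proven, k = k)
    }
    if (sol$proven) {
      # exhausted search: the subset holds nothing below the incumbent
      cert_lb[k] <- max(cert_lb[k],
                        if (sol$feasible) sol$obj else best$obj)
    }
  }
  if (is.null(best$assignment)) {
    stop("infeasible: total site capacity cannot absorb the assigned demand",
         call. = FALSE)
  }
  if (!best$proven) {
    # give the winning subset one longer certification run
    sol <- solve_assignment(tmat[, best$open, drop = FALSE], d, w,
                            caps[best$open], upper = Inf,
                            node_limit = 10 * node_limit)
    if (sol$feasible && sol$obj <= best$obj + 1e-9) {
      best$obj <- sol$obj
      best$assignment <- sol$assignment
      best$proven <- sol$proven
      if (sol$proven) cert_lb[best$k] <- max(cert_lb[best$k], sol$obj)
    }
  }

  global_lb <- min(cert_lb) + b * sum(w)
  objective <- best$obj + b * sum(w)
  if (!best$proven && status == "optimal") status <- "near_optimal"
  net <- new_referral_network(
    open_sites = best$open, assignment = best$assignment[fac$id],
    objective_value = objective, solver_status = status,
    n_added = n_added, fairness = fairness, weighted = weighted
  )
  net$objective_bound <- global_lb
  net$gap <- max(0, (objective - global_lb) / max(objective, 1e-12))
  net
}

# exact capacitated assignment: minimize sum_i w_i * t[i, j(i)] subject to
# sum_{i: j(i)=j} d_i <= cap_j.  Branch-and-bound in compiled code
# (src/assignment_bb.cpp); returns NULL if no assignment beats `upper`.
# Columns are sorted by site id so cost ties resolve deterministically.
solve_assignment <- function(tmat, d, w, caps, upper = Inf,
                             node_limit = -1, v0 = NULL) {
  tmat <- tmat[, sort(colnames(tmat)), drop = FALSE]
  caps <- caps[colnames(tmat)]
  if (!is.null(v0)) v0 <- unname(v0[colnames(tmat)])
  fac_ids <- rownames(tmat)
  cost <- tmat * w[fac_ids]

  # zero-demand facilities never bind a capacity and, in weighted mode,
  # never affect the objective: assign to the nearest site directly
  zero <- d[fac_ids] == 0 & w[fac_ids] == 0
  fixed_assign <- character(0)
  if (any(zero)) {
    ids0 <- fac_ids[zero]
    pick <- apply(tmat[ids0, , drop = FALSE], 1, function(r) {
      colnames(tmat)[which.min(r)]
    })
    fixed_assign <- stats::setNames(pick, ids0)
    fac_ids <- fac_ids[!zero]
  }
  if (length(fac_ids) == 0) {
    return(list(feasible = TRUE, obj = 0, assignment = fixed_assign,
                proven = TRUE, lb = 0))
  }

  res <- bb_assign_cpp(cost[fac_ids, , drop = FALSE],
                       unname(d[fac_ids]), unname(caps), upper,
                       max_nodes = node_limit, v_init = v0)
  lb <- if (is.null(res$root_lb)) -Inf else res$root_lb
  if (!isTRUE(res$feasible)) {
    return(list(feasible = FALSE, obj = Inf, assignment = NULL,
                proven = isTRUE(res$proven), lb = lb))
  }
  assignment <- stats::setNames(colnames(tmat)[res$assignment], fac_ids)
  list(feasible = TRUE, obj = res$objective,
       assignment = c(assignment, fixed_assign),
       proven = isTRUE(res$proven), lb = lb)
}

new_referral_network <- function(open_sites, assignment, objective_value,
                                 solver_status, n_added, fairness, weighted) {
  structure(
    list(open_sites = open_sites, assignment = assignment,
         objective_value = objective_value, solver_status = solver_status,
         n_added = n_added, fairness = fairness, weighted = weighted),
    class = "referral_network"
  )
}

#' @export
print.referral_network <- function(x, ...) {
  cat("Referral network (", x$solver_status, ")\n", sep = "")
  cat(sprintf("  %d open sites, %d facilities assigned, %d added hubs%s\n",
              length(x$open_sites), length(x$assignment), x$n_added,
              if (isTRUE(x$fairness)) ", fairness on" else ""))
  cat(sprintf("  objective (batching + transport): %.1f %s\n",
              x$objective_value,
              if (isTRUE(x$weighted)) "sample-minutes/workday"
              else "facility-minutes"))
  invisible(x)
}
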