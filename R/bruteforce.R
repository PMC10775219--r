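#' Exhaustive-enumeration allocation oracle
#'
#' Independent verification oracle for [solve_allocation()] on small
#' instances: enumerates every candidate subset of size `n_added` and,
#' within each subset, every feasible facility-to-site assignment by
#' depth-first enumeration (sites tried in lexicographic id order, so ties
#' resolve deterministically to the lexicographically smallest optimal
#' assignment). Guard-railed to at most 8 facilities and 5 candidate
#' sites.
#'
#' @inheritParams solve_allocation
#' @return A `referral_network` object with the global optimum.
#' @export
bruteforce_allocation <- function(instance, n_added = instance$n_added_hubs,
                                  fairness = instance$fairness,
                                  utilization_cap = instance$utilization_cap,
                                  eligible_levels = 3:5, weighted = TRUE) {
  stopifnot(inherits(instance, "poc_instance"))
  fac <- instance$facilities
  sites <- instance$sites
  if (nrow(fac) > 8 || sum(sites$kind == "candidate_hub") > 5) {
    stop("bruteforce_allocation refuses instances beyond 8 facilities / 5 candidates",
         call. = FALSE)
  }

  fixed_ids <- sites$id[sites$fixed_open]
  cand_ids <- sort(eligible_candidates(sites, eligible_levels))
  if (n_added > length(cand_ids)) {
    stop("infeasible: not enough eligible candidates", call. = FALSE)
  }
  caps <- stats::setNames(site_capacities(sites, utilization_cap), sites$id)
  tmat <- transport_minutes(instance)
  b <- instance$batching$expected_delay_min
  d <- stats::setNames(fac$daily_demand, fac$id)
  w <- if (weighted) d else stats::setNames(rep(1, nrow(fac)), fac$id)

  subsets <- if (n_added == 0) list(character(0)) else {
    utils::combn(cand_ids, n_added, simplify = FALSE)
  }
  if (fairness) {
    sc_all <- unique(fac$sub_county)
    # a subset must cover every sub-county that could possibly host a hub
    hub_pool <- c(sites$id[sites$kind == "existing_hub"], cand_ids)
    coverable <- intersect(sc_all, sites$sub_county[match(hub_pool, sites$id)])
    keep <- vapply(subsets, function(s) {
      open_hubs <- c(sites$id[sites$kind == "existing_hub"], s)
      all(coverable %in% sites$sub_county[match(open_hubs, sites$id)])
    }, logical(1))
    subsets <- subsets[keep]
    if (!length(subsets)) stop("infeasible fairness constraint", call. = FALSE)
  }

  fac_ids <- fac$id
  best <- list(obj = Inf, assignment = NULL, open = NULL)
  for (s in subsets) {
    open <- sort(c(fixed_ids, s))
    res <- enumerate_assignments(tmat[, open, drop = FALSE], d[fac_ids],
                                 w[fac_ids], caps[open])
    if (!is.null(res) && res$obj < best$obj - 1e-9) {
      best <- list(obj = res$obj, assignment = res$assignment, open = open)
    }
  }
  if (is.null(best$assignment)) {
    stop("infeasible: no feasible assignment exists", call. = FALSE)
  }
  new_referral_network(
    open_sites = best$open, assignment = best$assignment[fac_ids],
    objective_value = unname(best$obj) + b * sum(w),
    solver_status = "optimal", n_added = n_added, fairness = fairness,
    weighted = weighted
  )
}

# plain recursive enumeration of all capacity-feasible assignments
enumerate_assignments <- function(tmat, d, w, caps) {
  fac_ids <- rownames(tmat)
  site_ids <- sort(colnames(tmat))
  n <- length(fac_ids)
  best_obj <- Inf
  best <- NULL
  assign <- character(n)

  recurse <- function(i, resid, acc) {
    if (acc >= best_obj - 1e-9) return(invisible(NULL))
    if (i > n) {
      best_obj <<- acc
      best <<- assign
      return(invisible(NULL))
    }
    for (j in site_ids) {
      if (resid[j] >= d[i] - 1e-9) {
        assign[i] <<- j
        resid2 <- resid
        resid2[j] <- resid2[j] - d[i]
        recurse(i + 1, resid2, acc + w[i] * tmat[fac_ids[i], j])
      }
    }
    invisible(NULL)
  }
  recurse(1, caps[site_ids], 0)
  if (is.null(best)) return(NULL)
  list(obj = best_obj, assignment = stats::setNames(best, fac_ids))
}
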