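#' Expected batching delay at the collecting clinic
#'
#' Samples accumulate at a clinic until the next scheduled dispatch, so the
#' expected pre-dispatch delay is set by the dispatch frequency. With an
#' `h`-hour working day (default 7) the three supported modes give:
#'
#' * `daily`: half a working day, `h/2` hours (210 min at the default);
#' * `twice_weekly`: one calendar day plus one working day, `24 + h` hours
#'   (1860 min);
#' * `once_weekly`: half of four calendar days plus one working day,
#'   `(4 * 24 + h) / 2` hours (3090 min).
#'
#' The delay is computed from the mode, not hard-coded, so a different
#' working-day length propagates consistently.
#'
#' @param mode One of `"daily"`, `"twice_weekly"`, `"once_weekly"`.
#' @param workday_hours Length of the working day in hours (default 7).
#' @return Expected delay in minutes.
#' @examples
#' expected_batching_delay("daily")        # 210
#' expected_batching_delay("twice_weekly") # 1860
#' expected_batching_delay("once_weekly")  # 3090
#' @export
expected_batching_delay <- function(mode, workday_hours = 7) {
  mode <- match_batching_mode(mode)
  if (workday_hours <= 0) stop("workday_hours must be positive", call. = FALSE)
  hours <- switch(mode,
    daily        = workday_hours / 2,
    twice_weekly = 24 + workday_hours,
    once_weekly  = (4 * 24 + workday_hours) / 2
  )
  hours * 60
}

#' Batching policy
#'
#' Bundles a dispatch-frequency mode with its derived expected delay.
#'
#' @inheritParams expected_batching_delay
#' @return A list of class `batching_policy` with elements `mode`,
#'   `workday_hours` and `expected_delay_min`.
#' @export
batching_policy <- function(mode = "twice_weekly", workday_hours = 7) {
  mode <- match_batching_mode(mode)
  structure(
    list(
      mode = mode,
      workday_hours = workday_hours,
      expected_delay_min = expected_batching_delay(mode, workday_hours)
    ),
    class = "batching_policy"
  )
}

batching_modes <- c("daily", "twice_weekly", "once_weekly")

match_batching_mode <- function(mode) {
  if (length(mode) != 1 || !mode %in% batching_modes) {
    stop("unknown batching mode: ", paste(mode, collapse = ","),
         " (expected one of ", paste(batching_modes, collapse = ", "), ")",
         call. = FALSE)
  }
  mode
}

#' @export
print.batching_policy <- function(x, ...) {
  cat(sprintf("Batching policy: %s (expected delay %.0f min)\n",
              x$mode, x$expected_delay_min))
  invisible(x)
}
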