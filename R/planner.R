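#' Expand an entry schedule into a portfolio timeline (prospective plan)
#'
#' Prospective ("funding-based") planning: the user specifies how many
#' candidates enter which phase in which year, and the model forecasts
#' costs, occupancies, and expected launches.
#'
#' @param schedule Data frame with columns `archetype`, `entry_phase`
#'   (ordinal, NA for archetype default), `entry_year`, `entrants`
#'   (non-negative, may be fractional).
#' @param ps A `p2i_params` object.
#' @param estimate Cost column, as in [project_timeline()].
#' @return A `p2i_timeline`, as from [aggregate_portfolio()].
#' @export
#' @examples
#' ps <- default_params()
#' sched <- data.frame(archetype = "repurposed_simple", entry_phase = NA,
#'                     entry_year = 2017:2019, entrants = 1)
#' plan_prospective(sched, ps)
plan_prospective <- function(schedule, ps,
                             estimate = c("point", "low", "high")) {
  estimate <- match.arg(estimate)
  portfolio <- schedule_to_portfolio(schedule, ps)
  aggregate_portfolio(portfolio, ps, estimate = estimate)
}

#' Convert an entry schedule to a portfolio data frame
#'
#' @inheritParams plan_prospective
#' @return Portfolio data frame (one [project()] row per schedule row with
#'   `entrants > 0`).
#' @export
schedule_to_portfolio <- function(schedule, ps) {
  rows <- lapply(seq_len(NROW(schedule)), function(i) {
    s <- schedule[i, ]
    if (s$entrants < 0) stop("entrants must be >= 0")
    if (s$entrants == 0) return(NULL)
    ep <- if (is.null(s$entry_phase) || is.na(s$entry_phase)) NULL
          else as.integer(s$entry_phase)
    project(s$archetype, entry_year = s$entry_year, entry_phase = ep,
            multiplicity = s$entrants, ps = ps)
  })
  do.call(rbind, rows)
}

#' Solve for the entrants needed to hit an outcome target (retrospective plan)
#'
#' Retrospective ("outcome-based") planning: given a desired expected
#' number of candidates at a target phase (or expected launches) by a
#' given time, works back through the attrition chain to the number of
#' candidates that must enter, and the calendar year they must enter, at
#' the archetype's entry phase.
#'
#' @param archetype Archetype id.
#' @param target_phase Phase ordinal 0-3, or `"launch"` for expected
#'   launches.
#' @param target_count Desired expected count at the target (> 0).
#' @param by_year Decimal calendar year by which the target must be
#'   reached.
#' @param ps A `p2i_params` object.
#' @param entry_phase Entry phase ordinal; defaults to the archetype's
#'   default entry phase.
#' @param enforce_horizon If `TRUE` (default), error when the required
#'   entry year falls before the parameter set's horizon start
#'   (infeasible target).
#' @return List with `entrants` (expected-value, fractional),
#'   `entrants_ceiling` (integerized variant), `entry_year` (decimal),
#'   `entry_phase`, and `lead_time` (years from entry to target).
#' @export
#' @examples
#' ps <- default_params()
#' solve_entrants("vaccine_simple", "launch", 1, by_year = 2030, ps = ps)
solve_entrants <- function(archetype, target_phase, target_count, by_year,
                           ps,
                           entry_phase = entry_phase_default(ps, archetype),
                           enforce_horizon = TRUE) {
  .check_archetype(ps, archetype)
  if (target_count <= 0) stop("target_count must be > 0")
  is_launch <- identical(target_phase, "launch")
  last_traversed <- if (is_launch) 3L else as.integer(target_phase) - 1L
  if (!is_launch && (target_phase < entry_phase || target_phase > 3)) {
    stop("target phase ", target_phase, " not reachable from entry phase ",
         entry_phase)
  }
  p <- cumulative_pos(ps, archetype, entry_phase, last_traversed)
  lead <- total_cycle_time(ps, archetype, entry_phase, last_traversed)
  entrants <- target_count / p
  entry_year <- by_year - lead
  if (enforce_horizon && entry_year < ps$horizon_start) {
    stop("infeasible target: development must start in ",
         round(entry_year, 2), ", before the horizon start ",
         ps$horizon_start)
  }
  list(entrants = entrants,
       entrants_ceiling = ceiling(entrants),
       entry_year = entry_year,
       entry_phase = entry_phase,
       lead_time = lead)
}

#' Steady-state portfolio size and annual cost under constant entrants
#'
#' Under a constant flow of `entrants_per_year` new candidates, the flow
#' into phase k equilibrates at (entrants) x (cumulative PoS of prior
#' phases), and by flow equilibrium (Little's law) the number of
#' simultaneously active candidates in phase k is that flow times the
#' phase duration. The steady-state annual cost is the sum over phases of
#' flow-in times phase cost.
#'
#' @param entrants_per_year Named numeric vector: archetype id -> entrants
#'   per year (>= 0), entering at each archetype's default entry phase.
#' @param ps A `p2i_params` object.
#' @param estimate Cost column, as in [project_timeline()].
#' @return List with `occupancy` (data frame: archetype, phase ordinal,
#'   flow_in, occupancy, annual_cost), `total_active` (expected projects
#'   active at any instant), and `annual_cost` ($M/year).
#' @export
#' @examples
#' ps <- default_params()
#' steady_state(c(repurposed_simple = 1), ps)$annual_cost  # ~13.84
steady_state <- function(entrants_per_year, ps,
                         estimate = c("point", "low", "high")) {
  estimate <- match.arg(estimate)
  cost_col <- switch(estimate, point = "cost_point",
                     low = "cost_low", high = "cost_high")
  if (any(entrants_per_year < 0)) stop("entrant rates must be >= 0")
  out <- list()
  for (a in names(entrants_per_year)) {
    .check_archetype(ps, a)
    rate <- entrants_per_year[[a]]
    e <- entry_phase_default(ps, a)
    rows <- .phases_of(ps, a)
    for (k in e:3) {
      r <- rows[rows$phase_ordinal == k, ]
      flow <- rate * cumulative_pos(ps, a, e, k - 1L)
      out[[length(out) + 1]] <- data.frame(
        archetype = a, phase = k, flow_in = flow,
        occupancy = flow * r$duration,
        annual_cost = flow * r[[cost_col]],
        stringsAsFactors = FALSE)
    }
  }
  occ <- if (length(out) > 0) do.call(rbind, out) else
    data.frame(archetype = character(0), phase = integer(0),
               flow_in = numeric(0), occupancy = numeric(0),
               annual_cost = numeric(0))
  list(occupancy = occ,
       total_active = sum(occ$occupancy),
       annual_cost = sum(occ$annual_cost))
}

#' Expected budget for one calendar year of a timeline
#'
#' @param timeline A `p2i_timeline` from [aggregate_portfolio()] or
#'   [plan_prospective()].
#' @param year Calendar year inside the timeline's range.
#' @return Expected cost in $M allocated to that year.
#' @export
annual_budget <- function(timeline, year) {
  i <- match(year, timeline$years$year)
  if (is.na(i)) {
    stop("year ", year, " outside the timeline range ",
         min(timeline$years$year), "-", max(timeline$years$year))
  }
  timeline$years$cost[i]
}
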